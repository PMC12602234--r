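test_that("relevance overlap matches its defining ratio", {
  mask <- make_lesion_mask(c(16, 16), semi_axes = c(5, 4))
  expect_equal(relevance_overlap(mask, mask), 1)           # all mass inside G
  expect_equal(relevance_overlap(1 - mask, mask), 0)       # all mass outside G
  uniform <- matrix(1, 16, 16)
  expect_equal(relevance_overlap(uniform, mask), sum(mask) / 256)
  set.seed(41)
  sal <- random_map(16, 16)
  expect_equal(relevance_overlap(sal, mask), oracle_relevance_overlap(sal, mask),
               tolerance = 1e-12)
})

test_that("scoring rejects unscorable inputs with explicit errors", {
  mask <- make_lesion_mask(c(8, 8), semi_axes = c(2, 2))
  expect_error(relevance_overlap(matrix(0, 8, 8), mask), "zero total mass")
  expect_error(relevance_overlap(matrix(1, 4, 4), mask), "identical shapes")
  expect_error(relevance_overlap(matrix(1, 8, 8), matrix(0, 8, 8)), "foreground")
  expect_error(relevance_overlap(matrix(-1, 8, 8), mask), "nonnegative")
})

test_that("dispersion penalty complements WRO at radius 0 and shrinks with dilation", {
  mask <- make_lesion_mask(c(20, 20), semi_axes = c(6, 5))
  expect_equal(dispersion_penalty(mask, mask, 0), 0)
  expect_equal(dispersion_penalty(1 - mask, mask, 0), 1)
  set.seed(42)
  for (i in 1:20) {
    sal <- random_map(20, 20)
    expect_equal(dispersion_penalty(sal, mask, 0),
                 1 - relevance_overlap(sal, mask), tolerance = 1e-12)
    expect_lte(dispersion_penalty(sal, mask, 3), dispersion_penalty(sal, mask, 0))
  }
})

test_that("WRO and DP are invariant under positive rescaling of the map", {
  mask <- make_lesion_mask(c(20, 20), semi_axes = c(6, 5))
  set.seed(43)
  sal <- random_map(20, 20)
  for (a in c(0.01, 3, 1e4)) {
    expect_equal(relevance_overlap(a * sal, mask), relevance_overlap(sal, mask),
                 tolerance = 1e-12)
    expect_equal(dispersion_penalty(a * sal, mask, 2),
                 dispersion_penalty(sal, mask, 2), tolerance = 1e-12)
  }
})

test_that("disc dilation matches the brute-force distance definition", {
  set.seed(44)
  for (r in 0:3) {
    mask <- matrix(as.numeric(runif(15 * 15) < 0.1), 15, 15)
    if (sum(mask) == 0) mask[8, 8] <- 1
    expect_equal(dilate_disc(mask, r), oracle_dilate(mask, r))
  }
})

test_that("boundary extraction returns the 4-connectivity inner boundary", {
  single <- matrix(0, 5, 5); single[3, 4] <- 1
  expect_equal(extract_boundary(single), cbind(3L, 4L))
  square <- matrix(0, 8, 8); square[3:6, 2:5] <- 1
  b <- extract_boundary(square)
  expect_equal(nrow(b), 12L)  # 4x4 block has 12 perimeter pixels
  expect_false(any(b[, 1] %in% 4:5 & b[, 2] %in% 3:4))  # interior excluded
  full <- matrix(1, 6, 7)
  bf <- extract_boundary(full)
  expect_equal(nrow(bf), 2 * 6 + 2 * 7 - 4)  # border ring via off-image neighbours
  expect_equal(nrow(extract_boundary(matrix(0, 4, 4))), 0L)
})

test_that("Hausdorff distance matches direct evaluation and the all-pairs oracle", {
  a <- cbind(1, 1)
  expect_equal(hausdorff_distance(a, a, "max"), 0)
  expect_equal(hausdorff_distance(a, a, "average"), 0)
  expect_equal(hausdorff_distance(cbind(0, 0), cbind(3, 4), "max"), 5)
  set.seed(45)
  for (i in 1:30) {
    p <- random_point_set(sample(1:50, 1))
    q <- random_point_set(sample(1:50, 1))
    expect_equal(hausdorff_distance(p, q, "max"), oracle_hausdorff(p, q, "max"),
                 tolerance = 1e-9)
    expect_equal(hausdorff_distance(p, q, "average"),
                 oracle_hausdorff(p, q, "average"), tolerance = 1e-9)
  }
  expect_error(hausdorff_distance(a, matrix(numeric(0), 0, 2)), "non-empty")
})

test_that("Hausdorff max variant is a metric on sampled point sets", {
  set.seed(46)
  for (i in 1:10) {
    p <- random_point_set(10); q <- random_point_set(10); r <- random_point_set(10)
    dpq <- hausdorff_distance(p, q); dqr <- hausdorff_distance(q, r)
    dpr <- hausdorff_distance(p, r)
    expect_equal(dpq, hausdorff_distance(q, p))   # symmetry
    expect_gte(dpq, 0)
    expect_lte(dpr, dpq + dqr + 1e-9)             # triangle inequality
  }
})

test_that("boundary agreement follows the normalised inverse Hausdorff form", {
  mask <- make_lesion_mask(c(32, 32), semi_axes = c(9, 7))
  expect_equal(boundary_agreement(mask, mask), 1)
  # two single-pixel contours 5 apart in a 224x224 frame
  g <- matrix(0, 224, 224); g[100, 100] <- 1
  e <- matrix(0, 224, 224); e[103, 104] <- 1
  expect_equal(boundary_agreement(g, e), 1 - 5 / 224)
  # tolerance band forgives distances up to its width
  expect_equal(boundary_agreement(g, e, tolerance = 5), 1)
  expect_equal(boundary_agreement(g, e, tolerance = 2), 1 - 3 / 224)
  # empty explanation hits the sentinel, empty mask errors
  expect_equal(boundary_agreement(mask, matrix(0, 32, 32)), 0)
  expect_error(boundary_agreement(matrix(0, 32, 32), mask), "foreground")
})

test_that("perfect alignment scores 0.9 and off-target clamps to 0 under default weights", {
  mask <- make_lesion_mask(c(48, 48), semi_axes = c(12, 9))
  res <- xalign(mask, mask)
  expect_equal(res$wro, 1)
  expect_equal(res$bas, 1)
  expect_equal(res$dp, 0)
  expect_equal(res$score, 0.9)
  expect_equal(res$raw, res$score)
  off <- make_saliency_phantom(mask, "off_target", noise = 0, seed = 7L)
  res2 <- xalign(off, mask)
  expect_equal(res2$wro, 0)
  expect_equal(res2$dp, 1)
  expect_lte(res2$raw, res2$score)
  # fully off-target across a large frame: negative raw, clamped floor
  g <- matrix(0, 224, 224); g[16:40, 16:40] <- 1
  e <- matrix(0, 224, 224); e[190:210, 190:210] <- 1
  far <- xalign(e, g)
  expect_lt(far$raw, 0)
  expect_equal(far$score, 0)
  # component form of the same situation: raw = -gamma exactly
  expect_equal(combine_components(0, 0, 1), 0)
})

test_that("the result invariants hold: raw recombination and clamping", {
  mask <- make_lesion_mask(c(32, 32), semi_axes = c(8, 6))
  set.seed(47)
  for (i in 1:10) {
    sal <- random_map(32, 32)
    r <- xalign(sal, mask)
    expect_equal(r$raw, 0.5 * r$wro + 0.4 * r$bas - 0.1 * r$dp, tolerance = 1e-12)
    expect_equal(r$score, min(1, max(0, r$raw)))
    expect_gte(r$score, 0); expect_lte(r$score, 1)
  }
})

test_that("scores recombine linearly over the weight grid", {
  set.seed(48)
  grid <- list(c(0.6, 0.3, 0.1), c(0.5, 0.4, 0.1), c(0.4, 0.4, 0.2),
               c(0.3, 0.5, 0.2), c(0.2, 0.6, 0.2))
  for (i in 1:10) {
    w <- runif(1); b <- runif(1); d <- runif(1)
    for (g in grid) {
      expect_equal(combine_components(w, b, d, xalign_weights(g[1], g[2], g[3])),
                   min(1, max(0, g[1] * w + g[2] * b - g[3] * d)),
                   tolerance = 1e-12)
    }
  }
})

test_that("the score is monotone in each component at fixed weights", {
  set.seed(49)
  for (i in 1:20) {
    w <- runif(1); b <- runif(1); d <- runif(1); eps <- runif(1, 0, 1 - max(w, b))
    base <- combine_components(w, b, d)
    expect_gte(combine_components(w + eps, b, d), base)
    expect_gte(combine_components(w, b + eps, d), base)
    expect_lte(combine_components(w, b, d + runif(1, 0, 1 - d)), base)
  }
})

test_that("weights validate as nonnegative and warn when they do not sum to 1", {
  expect_warning(xalign_weights(0.5, 0.5, 0.5), "sum")
  expect_silent(xalign_weights(0.5, 0.4, 0.1))
  expect_error(xalign_weights(-0.1, 0.9, 0.2), "nonnegative")
})

test_that("tidy and glance expose the components of a result", {
  mask <- make_lesion_mask(c(24, 24), semi_axes = c(7, 5))
  r <- xalign(mask, mask)
  td <- tidy(r)
  expect_equal(td$component, c("wro", "bas", "dp"))
  expect_equal(td$value, c(1, 1, 0))
  expect_equal(td$weight, c(0.5, 0.4, -0.1))
  gl <- glance(r)
  expect_equal(gl$score, 0.9)
  expect_equal(nrow(gl), 1L)
})
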