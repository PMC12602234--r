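make_tier_scores <- function(n = 6, seed = 5L) {
  ds <- phantom_dataset(n, tiers = c("aligned", "scattered"), seed = seed)
  score_saliency(ds)
}

test_that("aggregation reports mean, sample SD and n per group", {
  scores <- tibble::tibble(method = c("a", "a", "a", "b"),
                           score = c(0.2, 0.4, 0.6, 0.5))
  agg <- aggregate_scores(scores)
  a <- agg[agg$method == "a", ]
  expect_equal(a$mean, 0.4)
  expect_equal(a$sd, 0.2)  # (n-1)-denominator SD of {0.2, 0.4, 0.6}
  expect_equal(a$n, 3L)
  b <- agg[agg$method == "b", ]
  expect_equal(b$sd, 0)    # singleton group reports SD 0
  # permutation invariance of the mean
  perm <- scores[sample(nrow(scores)), ]
  expect_equal(aggregate_scores(perm)$mean, agg$mean)
  expect_error(aggregate_scores(scores, group = "missing"), "No column")
})

test_that("the weight grid reproduces the linear recombination exactly", {
  comps <- tibble::tibble(method = "only", wro = 1, bas = 1, dp = 0)
  g <- weight_sensitivity_grid(comps)
  expect_equal(g$mean_score, g$alpha + g$beta)  # score alpha+beta at every triple
  expect_error(weight_sensitivity_grid(comps, tibble::tibble(alpha = -1, beta = 1, gamma = 0)),
               "nonnegative")
})

test_that("a one-triple grid agrees with direct xalign scoring", {
  sc <- make_tier_scores()
  g <- weight_sensitivity_grid(sc, tibble::tibble(alpha = 0.5, beta = 0.4, gamma = 0.1),
                               group = "tier")
  agg <- aggregate_scores(sc, group = "tier")
  expect_equal(sort(g$mean_score), sort(agg$mean), tolerance = 1e-12)
})

test_that("grid scores equal per-item recombination before averaging", {
  sc <- make_tier_scores()
  g <- weight_sensitivity_grid(sc, group = "tier")
  for (i in seq_len(nrow(g))) {
    w <- suppressWarnings(xalign_weights(g$alpha[i], g$beta[i], g$gamma[i]))
    sub <- sc[sc$tier == g$tier[i], ]
    expect_equal(g$mean_score[i],
                 mean(combine_components(sub$wro, sub$bas, sub$dp, w)),
                 tolerance = 1e-12)
  }
  expect_true(ranking_stable(g))
})

test_that("a single informative channel yields identical scores across k", {
  m <- make_lesion_mask(c(48, 48), semi_axes = c(12, 9))
  st <- make_activation_stack(m, 10, informative_fraction = 0.1, seed = 2L,
                              noise_sd = 0)  # background channels exactly zero
  data <- tibble::tibble(tier = "single", stack = list(st), mask = list(m))
  g <- param_sensitivity_grid(data, k_values = c(10, 20, 40), t_values = 0.5)
  expect_equal(length(unique(round(g$mean_score, 12))), 1L)
})

test_that("an unreachable threshold triggers the empty-map BAS sentinel and the run continues", {
  m <- make_lesion_mask(c(32, 32), semi_axes = c(9, 7))
  sal <- 0.4 * m + 0.01
  r <- xalign(sal, m, policy = threshold_policy("fixed", 1))
  # min-max rescaling tops out just below 1, so T = 1 empties the binary map
  expect_equal(r$bas, 0)
  expect_gt(r$wro, 0)
  st <- make_activation_stack(m, 5, 0.2, seed = 9L)
  data <- tibble::tibble(tier = "x", stack = list(st), mask = list(m))
  g <- param_sensitivity_grid(data, k_values = 20, t_values = c(0.5, 1))
  expect_equal(nrow(g), 2L)  # both cells scored despite the sentinel
})

test_that("majority voting follows the strict-majority and tie-break rules", {
  expect_equal(majority_vote(c(1, 1, 1)), 1)
  expect_equal(majority_vote(c(0, 0)), 0)
  expect_equal(majority_vote(c(1, 1, 0)), 1)
  # tie with scores: the side with higher mean per-slice score wins
  expect_equal(majority_vote(c(1, 0), probs = c(0.4, 0.7)), 0)
  expect_equal(majority_vote(c(1, 0, 1, 0), probs = c(0.9, 0.2, 0.8, 0.3)), 1)
  # tie without scores: positive label wins
  expect_equal(majority_vote(c(1, 0)), 1)
  expect_error(majority_vote(numeric(0)), "non-empty")
})

test_that("score_saliency carries metadata columns and emits all components", {
  sc <- make_tier_scores(n = 3)
  expect_true(all(c("id", "tier", "wro", "bas", "dp", "raw", "score") %in% names(sc)))
  expect_equal(nrow(sc), 6L)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_s3_class(sc, "xalign_scores")
})

test_that("directory scoring matches by basename across PNG and CSV", {
  dir <- withr::local_tempdir()
  sal_dir <- file.path(dir, "sal"); mask_dir <- file.path(dir, "mask")
  dir.create(sal_dir); dir.create(mask_dir)
  ds <- phantom_dataset(3, tiers = "aligned", shape = c(48, 48), seed = 9L)
  for (i in 1:3) {
    write_matrix_csv(ds$sal[[i]], file.path(sal_dir, paste0(ds$id[i], ".csv")))
    write_gray_png(ds$mask[[i]], file.path(mask_dir, paste0(ds$id[i], ".png")))
  }
  sc <- score_dir(sal_dir, mask_dir)
  expect_equal(sc$id, sort(ds$id[1:3]))
  direct <- score_saliency(ds)
  expect_equal(sc$score, direct$score, tolerance = 1e-12)
})

test_that("run manifests record version, options and input digests", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "input.csv")
  write_matrix_csv(matrix(1:4, 2, 2), f)
  mf <- file.path(dir, "run.json")
  write_run_manifest(mf, seed = 123L, options = list(threshold = 0.5),
                     inputs = f, timestamp = FALSE)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  expect_equal(man$package, "xalign")
  expect_equal(man$seed, 123L)
  expect_equal(man$options$threshold, 0.5)
  expect_equal(names(man$input_digests), "input.csv")
  expect_match(man$input_digests[[1]], "^[0-9a-f]{32}$")
})

test_that("autoplot methods return ggplot objects", {
  sc <- make_tier_scores(n = 3)
  expect_s3_class(ggplot2::autoplot(sc, group = "tier"), "ggplot")
  g <- weight_sensitivity_grid(sc, group = "tier")
  expect_s3_class(ggplot2::autoplot(g), "ggplot")
  expect_s3_class(ggplot2::autoplot(simulate_if(c(0.2, 1.5), neuron_params())),
                  "ggplot")
})
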