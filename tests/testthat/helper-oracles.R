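# Independent brute-force oracles used to validate the vectorised
# implementations. These deliberately use naive loops and direct formula
# evaluation, sharing no code with the package internals.

# Bilinear resampling by direct evaluation of the interpolation formula at
# every output pixel centre (half-pixel convention, clamped at the border),
# with isotropic scaling and symmetric zero padding (extra bottom/right).
oracle_resize <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  s <- min(out_h / h, out_w / w)
  sh <- max(1L, round(h * s)); sw <- max(1L, round(w * s))
  scaled <- matrix(0, sh, sw)
  for (r in seq_len(sh)) {
    for (c in seq_len(sw)) {
      y <- min(max((r - 0.5) * h / sh - 0.5, 0), h - 1)
      x <- min(max((c - 0.5) * w / sw - 0.5, 0), w - 1)
      y0 <- floor(y); x0 <- floor(x)
      y1 <- min(y0 + 1, h - 1); x1 <- min(x0 + 1, w - 1)
      fy <- y - y0; fx <- x - x0
      scaled[r, c] <-
        img[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) +
        img[y0 + 1, x1 + 1] * (1 - fy) * fx +
        img[y1 + 1, x0 + 1] * fy * (1 - fx) +
        img[y1 + 1, x1 + 1] * fy * fx
    }
  }
  out <- matrix(0, out_h, out_w)
  top <- (out_h - sh) %/% 2L; left <- (out_w - sw) %/% 2L
  out[top + seq_len(sh), left + seq_len(sw)] <- scaled
  out
}

# All-pairs Hausdorff distances via a double loop.
oracle_hausdorff <- function(a, b, variant = "max") {
  na <- nrow(a); nb <- nrow(b)
  min_ab <- numeric(na); min_ba <- rep(Inf, nb)
  for (i in seq_len(na)) {
    best <- Inf
    for (j in seq_len(nb)) {
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < best) best <- d
      if (d < min_ba[j]) min_ba[j] <- d
    }
    min_ab[i] <- best
  }
  if (variant == "max") max(max(min_ab), max(min_ba))
  else (mean(min_ab) + mean(min_ba)) / 2
}

# Exhaustive scan of all 256 candidate bin edges for the Otsu threshold:
# recompute class weights and means per candidate with explicit sums.
oracle_otsu <- function(map) {
  bins <- pmin(floor(map * 256), 255)
  vals <- (bins + 0.5) / 256
  n <- length(vals)
  best_var <- -Inf; best_k <- NA
  for (k in 1:255) {
    t <- k / 256
    lo <- vals[vals < t]; hi <- vals[vals >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    v <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (v > best_var + 1e-15) { best_var <- v; best_k <- k }
  }
  if (is.na(best_k)) 0 else best_k / 256
}

# Exact two-sided signed-rank p-value by explicit enumeration of all 2^n
# sign assignments over the midranks of the nonzero |differences|.
oracle_wilcoxon_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-12)
  p_ge <- mean(w_all >= w_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# Relevance sums by explicit double loop.
oracle_relevance_overlap <- function(sal, mask) {
  inside <- 0; total <- 0
  for (i in seq_len(nrow(sal))) {
    for (j in seq_len(ncol(sal))) {
      total <- total + sal[i, j]
      if (mask[i, j] == 1) inside <- inside + sal[i, j]
    }
  }
  inside / total
}

# Disc dilation by checking, for every pixel, whether any foreground pixel
# lies within the radius.
oracle_dilate <- function(mask, radius) {
  fg <- which(mask == 1, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      d2 <- (fg[, 1] - i)^2 + (fg[, 2] - j)^2
      if (any(d2 <= radius^2)) out[i, j] <- 1
    }
  }
  out
}

random_map <- function(h, w) matrix(runif(h * w), h, w)

random_point_set <- function(n, extent = 100) {
  cbind(sample.int(extent, n, replace = TRUE), sample.int(extent, n, replace = TRUE))
}
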