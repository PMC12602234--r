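# The native explanation head: turn a C-channel activation stack from a
# network's last convolutional block into a soft and a binary heatmap via
# channel ranking, top-k aggregation, min-max normalisation, thresholding
# and nearest-neighbour upscaling.

#' Construct an activation stack
#'
#' A list of `C >= 1` equally shaped finite numeric matrices, one per channel.
#'
#' @param channels List of numeric matrices with identical dimensions.
#' @return An object of class `activation_stack`.
#' @export
activation_stack <- function(channels) {
  if (!is.list(channels) || length(channels) < 1L) {
    abort("`channels` must be a non-empty list of matrices.")
  }
  for (i in seq_along(channels)) assert_grid(channels[[i]], sprintf("channel %d", i))
  d <- dim(channels[[1L]])
  same <- vapply(channels, function(m) identical(dim(m), d), logical(1))
  if (!all(same)) abort("All channels must share the same shape.")
  structure(channels, class = "activation_stack")
}

as_activation_stack <- function(x) {
  if (inherits(x, "activation_stack")) return(x)
  activation_stack(x)
}

#' @export
print.activation_stack <- function(x, ...) {
  cat(sprintf("<activation_stack> %d channels, %d x %d\n",
              length(x), nrow(x[[1]]), ncol(x[[1]])))
  invisible(x)
}

#' Per-channel mean activation
#'
#' @param stack An [activation_stack()] (or plain list of matrices).
#' @return Numeric vector of length `C`: the arithmetic mean of each channel.
#' @export
channel_means <- function(stack) {
  stack <- as_activation_stack(stack)
  vapply(stack, mean, numeric(1))
}

# round-half-up, used for channel counts (round() in R rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Select the top-k% channels by mean activation
#'
#' Picks the `max(1, round(k_percent * C / 100))` channels with the largest
#' means (half-up rounding). Ties are broken by ascending channel index, and
#' the returned indices are sorted ascending.
#'
#' @param means Numeric vector of channel means.
#' @param k_percent Percentage in `(0, 100]`; the default 20 keeps the top
#'   fifth of channels.
#' @return Integer vector of selected channel indices (1-based).
#' @export
select_top_channels <- function(means, k_percent = 20) {
  if (length(means) < 1L) abort("`means` must be non-empty.")
  if (!all(is.finite(means))) abort("`means` must be finite.")
  if (!is.numeric(k_percent) || length(k_percent) != 1L ||
      k_percent <= 0 || k_percent > 100) {
    abort("`k_percent` must lie in (0, 100].")
  }
  C <- length(means)
  m <- max(1L, as.integer(round_half_up(k_percent * C / 100)))
  ord <- order(-means, seq_len(C))  # ties -> lowest index first
  sort(ord[seq_len(m)])
}

#' Aggregate selected channels into a focused map
#'
#' @param stack An [activation_stack()].
#' @param selected Integer indices of channels to sum (1-based).
#' @return A list of class `focused_map` with elements `values` (the pixelwise
#'   sum) and `selected_channels`.
#' @export
focused_map <- function(stack, selected) {
  stack <- as_activation_stack(stack)
  selected <- as.integer(selected)
  if (length(selected) < 1L) abort("`selected` must be non-empty.")
  if (any(is.na(selected)) || any(selected < 1L) || any(selected > length(stack))) {
    abort(sprintf("`selected` indices must lie in [1, %d].", length(stack)))
  }
  values <- Reduce(`+`, stack[selected])
  structure(list(values = values, selected_channels = sort(unique(selected))),
            class = "focused_map")
}

#' Min-max normalisation to [0, 1]
#'
#' `(x - min) / (max - min + eps)`; the small `eps` keeps constant maps
#' well-defined (they map to all zeros).
#'
#' @param map Numeric matrix (or a `focused_map`).
#' @param eps Positive guard against division by zero.
#' @return Matrix with values in `[0, 1]`.
#' @export
minmax_normalize <- function(map, eps = 1e-8) {
  if (inherits(map, "focused_map")) map <- map$values
  assert_grid(map, "map")
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0) {
    abort("`eps` must be a single positive number.")
  }
  (map - min(map)) / (max(map) - min(map) + eps)
}

#' Thresholding policy for binarisation
#'
#' @param mode `"fixed"` (threshold at `value` in `[0, 1]`, default 0.5),
#'   `"percentile"` (threshold at the `value`-th percentile of the map,
#'   `value` in `(0, 100)`), or `"otsu"` (adaptive threshold maximising
#'   between-class variance on a 256-bin histogram; `value` ignored).
#' @param value Threshold parameter for the chosen mode.
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(mode = c("fixed", "percentile", "otsu"), value = 0.5) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (!is.numeric(value) || value < 0 || value > 1)) {
    abort("Fixed threshold must lie in [0, 1].")
  }
  if (mode == "percentile" && (!is.numeric(value) || value <= 0 || value >= 100)) {
    abort("Percentile must lie in (0, 100).")
  }
  structure(list(mode = mode, value = if (mode == "otsu") NA_real_ else value),
            class = "threshold_policy")
}

#' Otsu's threshold on a 256-bin histogram
#'
#' Scans all 256 candidate bin edges of a histogram over `[0, 1]` and returns
#' the edge maximising between-class variance; ties resolve to the lowest
#' edge. Degenerate maps whose values fall into a single bin return 0.
#'
#' @param map Numeric matrix with values in `[0, 1]`.
#' @return The threshold, a value in `[0, 1)`; binarisation uses `x >= T`.
#' @export
otsu_threshold <- function(map) {
  assert_grid(map, "map")
  if (min(map) < 0 || max(map) > 1) abort("`map` values must lie in [0, 1].")
  bins <- pmin(floor(map * 256), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  n <- sum(counts)
  centers <- (seq_len(256L) - 0.5) / 256
  w0 <- cumsum(counts)[1:255]               # class 0: bins < k, k = 1..255
  s0 <- cumsum(counts * centers)[1:255]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) return(0)
  mu0 <- s0 / w0
  mu1 <- (sum(counts * centers) - s0) / w1
  sigma_b <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  sigma_b[!valid] <- -Inf
  k <- which.max(sigma_b)                   # which.max takes the first maximum
  k / 256
}

#' Binarise a normalised map
#'
#' Applies the threshold from a [threshold_policy()]; a pixel is foreground
#' when its value is greater than or equal to the threshold.
#'
#' @param map Numeric matrix with values in `[0, 1]`.
#' @param policy A [threshold_policy()]; the default is a fixed threshold of 0.5.
#' @return Binary matrix.
#' @export
binarize <- function(map, policy = threshold_policy("fixed", 0.5)) {
  assert_grid(map, "map")
  if (min(map) < 0 || max(map) > 1) abort("`map` values must lie in [0, 1].")
  if (!inherits(policy, "threshold_policy")) abort("`policy` must be a threshold_policy.")
  t <- switch(policy$mode,
    fixed = policy$value,
    percentile = unname(stats::quantile(map, policy$value / 100, type = 7)),
    otsu = otsu_threshold(map)
  )
  (map >= t) * 1
}

#' Nearest-neighbour upscaling of a binary mask
#'
#' Binary heatmaps are resized back to the original image resolution with
#' nearest-neighbour sampling so the output stays strictly binary.
#'
#' @param mask Binary matrix.
#' @param out_h,out_w Target dimensions.
#' @return Binary `out_h x out_w` matrix.
#' @export
upscale_binary <- function(mask, out_h, out_w) {
  assert_binary_grid(mask)
  out_h <- as.integer(out_h); out_w <- as.integer(out_w)
  if (is.na(out_h) || is.na(out_w) || out_h < 1L || out_w < 1L) {
    abort("`out_h` and `out_w` must be positive integers.")
  }
  h <- nrow(mask); w <- ncol(mask)
  ri <- pmin(pmax(floor((seq_len(out_h) - 0.5) * h / out_h) + 1L, 1L), h)
  ci <- pmin(pmax(floor((seq_len(out_w) - 0.5) * w / out_w) + 1L, 1L), w)
  mask[ri, ci, drop = FALSE]
}

#' Run the full explanation-head pipeline on an activation stack
#'
#' Convenience wrapper chaining [channel_means()], [select_top_channels()],
#' [focused_map()], [minmax_normalize()] and [binarize()], optionally
#' upscaling the binary heatmap to a target resolution.
#'
#' @param stack An [activation_stack()].
#' @param k_percent Top-k channel percentage (default 20).
#' @param policy Binarisation [threshold_policy()] (default fixed 0.5).
#' @param eps Guard for min-max normalisation.
#' @param out_shape Optional `c(H, W)` to upscale the binary map to.
#' @return A list with `soft` (normalised map), `binary` (thresholded map,
#'   upscaled if requested) and `selected` (channel indices).
#' @export
explain_stack <- function(stack, k_percent = 20,
                          policy = threshold_policy("fixed", 0.5),
                          eps = 1e-8, out_shape = NULL) {
  stack <- as_activation_stack(stack)
  mu <- channel_means(stack)
  sel <- select_top_channels(mu, k_percent)
  soft <- minmax_normalize(focused_map(stack, sel), eps)
  bin <- binarize(soft, policy)
  if (!is.null(out_shape)) bin <- upscale_binary(bin, out_shape[1], out_shape[2])
  list(soft = soft, binary = bin, selected = sel)
}
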