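#' @keywords internal
#' @importFrom rlang abort warn .data
#' @importFrom stats quantile rnorm runif sd pnorm
#' @importFrom utils write.csv head
"_PACKAGE"

# ---- grid validation helpers -------------------------------------------------

assert_grid <- function(x, arg = "img") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    abort(sprintf("`%s` must have at least one row and one column.", arg))
  }
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  invisible(x)
}

assert_binary_grid <- function(x, arg = "mask") {
  assert_grid(x, arg)
  if (!all(x == 0 | x == 1)) {
    abort(sprintf("`%s` must be binary (values in {0, 1}).", arg))
  }
  invisible(x)
}

#' Test whether a matrix is a strictly binary image grid
#'
#' @param x A numeric matrix.
#' @return `TRUE` if every entry is 0 or 1.
#' @export
is_binary_grid <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x)) && all(x == 0 | x == 1)
}

# ---- spatial standardisation -------------------------------------------------

#' Resize an image with bilinear interpolation and aspect-preserving padding
#'
#' Standardises an image grid to a target resolution. The image is scaled
#' isotropically so it fits inside the target frame, sampled with bilinear
#' interpolation at output pixel centres (half-pixel convention), and
#' zero-padded symmetrically where the aspect ratios differ. Padding is split
#' as evenly as possible, with the extra row/column on the bottom/right.
#'
#' @param img Numeric matrix (H x W), all values finite.
#' @param out_h,out_w Target height and width (positive integers).
#' @return A numeric `out_h x out_w` matrix.
#' @examples
#' resize_bilinear(diag(4), 8, 8)[1:2, 1:2]
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  assert_grid(img)
  out_h <- as.integer(out_h); out_w <- as.integer(out_w)
  if (is.na(out_h) || is.na(out_w) || out_h < 1L || out_w < 1L) {
    abort("`out_h` and `out_w` must be positive integers.")
  }
  h <- nrow(img); w <- ncol(img)
  s <- min(out_h / h, out_w / w)
  sh <- max(1L, as.integer(round(h * s)))
  sw <- max(1L, as.integer(round(w * s)))
  scaled <- bilinear_sample(img, sh, sw)
  if (sh == out_h && sw == out_w) return(scaled)
  out <- matrix(0, out_h, out_w)
  top <- (out_h - sh) %/% 2L
  left <- (out_w - sw) %/% 2L
  out[top + seq_len(sh), left + seq_len(sw)] <- scaled
  out
}

# Plain bilinear sampling to an exact target shape, half-pixel centres,
# coordinates clamped at the image border.
bilinear_sample <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  ry <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  rx <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  ry <- pmin(pmax(ry, 0), h - 1)
  rx <- pmin(pmax(rx, 0), w - 1)
  y0 <- floor(ry); x0 <- floor(rx)
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- ry - y0; fx <- rx - x0
  # 1-based indexing into img for the four neighbours of every output pixel
  Y0 <- matrix(y0 + 1, out_h, out_w); Y1 <- matrix(y1 + 1, out_h, out_w)
  X0 <- matrix(x0 + 1, out_h, out_w, byrow = TRUE)
  X1 <- matrix(x1 + 1, out_h, out_w, byrow = TRUE)
  FY <- matrix(fy, out_h, out_w); FX <- matrix(fx, out_h, out_w, byrow = TRUE)
  v00 <- img[cbind(c(Y0), c(X0))]; v01 <- img[cbind(c(Y0), c(X1))]
  v10 <- img[cbind(c(Y1), c(X0))]; v11 <- img[cbind(c(Y1), c(X1))]
  top <- v00 * (1 - c(FX)) + v01 * c(FX)
  bot <- v10 * (1 - c(FX)) + v11 * c(FX)
  matrix(top * (1 - c(FY)) + bot * c(FY), out_h, out_w)
}

#' Affine intensity normalisation
#'
#' Applies `(x - mean) / sd` elementwise, the standard channel normalisation
#' with mean 0.5 and standard deviation 0.5 used to centre 8-bit medical
#' images on zero.
#'
#' @param img Numeric matrix.
#' @param mean,sd Normalisation constants; `sd` must be positive.
#' @return Normalised matrix of the same shape.
#' @export
normalize_intensity <- function(img, mean = 0.5, sd = 0.5) {
  assert_grid(img)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    abort("`sd` must be a single positive number.")
  }
  (img - mean) / sd
}

#' Replicate a grayscale grid across three channels
#'
#' @param img Numeric matrix.
#' @return A list of class `rgb_stack` with elements `r`, `g`, `b`, each equal
#'   to `img`.
#' @export
gray_to_rgb <- function(img) {
  assert_grid(img)
  structure(list(r = img, g = img, b = img), class = "rgb_stack")
}

#' @export
print.rgb_stack <- function(x, ...) {
  cat(sprintf("<rgb_stack> 3 x %d x %d (replicated grayscale)\n",
              nrow(x$r), ncol(x$r)))
  invisible(x)
}
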