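# File exchange: 8-bit grayscale PNG for masks and quantised saliency,
# headerless CSV matrices for lossless float maps, and a CSV + JSON-sidecar
# container for activation stacks.

#' Read a binary mask from an 8-bit grayscale PNG
#'
#' Any pixel whose 8-bit value exceeds 127 is foreground.
#'
#' @param path Path to a PNG file.
#' @return Binary numeric matrix (0/1).
#' @export
read_mask_png <- function(path) {
  img <- read_gray_png(path)
  (img * 255 > 127) * 1
}

#' Read a saliency map from an 8-bit grayscale PNG
#'
#' Pixel values 0–255 map linearly to `[0, 1]`.
#'
#' @inheritParams read_mask_png
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_saliency_png <- function(path) {
  read_gray_png(path)
}

read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # collapse RGB(A) to first channel
  assert_grid(img, "png image")
  img
}

#' Write a grid to an 8-bit grayscale PNG
#'
#' Values are clamped to `[0, 1]` and quantised to 8 bits; binary masks are
#' written as 0/255.
#'
#' @param img Numeric matrix in `[0, 1]` (or binary).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  assert_grid(img)
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read / write a headerless CSV matrix
#'
#' One CSV row per image row, no header, no row names. This is the lossless
#' exchange format for float-valued saliency maps and activation channels.
#'
#' @param path File path.
#' @return For the reader, a numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  assert_grid(m, basename(path))
  m
}

#' @rdname read_matrix_csv
#' @param m Numeric matrix to write.
#' @export
write_matrix_csv <- function(m, path) {
  assert_grid(m)
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write an activation stack as CSV plus a JSON sidecar
#'
#' The stack's `C` channels are stored row-blocked in a single headerless CSV
#' (`C * H` rows by `W` columns); the sidecar `<path>.json` records
#' `{"channels": C, "height": H, "width": W}`.
#'
#' @param path Path to the CSV file (the sidecar lives at `paste0(path, ".json")`).
#' @return For the reader, an [activation_stack()].
#' @export
read_activation_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- read_matrix_csv(path)
  C <- meta$channels; H <- meta$height; W <- meta$width
  if (nrow(m) != C * H || ncol(m) != W) {
    abort("Activation stack CSV does not match its JSON sidecar dimensions.")
  }
  channels <- lapply(seq_len(C), function(c) m[(c - 1L) * H + seq_len(H), , drop = FALSE])
  activation_stack(channels)
}

#' @rdname read_activation_stack
#' @param stack An [activation_stack()].
#' @export
write_activation_stack <- function(stack, path) {
  stack <- as_activation_stack(stack)
  H <- nrow(stack[[1L]]); W <- ncol(stack[[1L]])
  write_matrix_csv(do.call(rbind, stack), path)
  jsonlite::write_json(
    list(channels = length(stack), height = H, width = W),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Write a debugging overlay of a mask contour on a saliency map
#'
#' Renders the saliency map in gray and paints the mask's boundary pixels
#' white. Intended purely for eyeballing phantoms and scores; makes no
#' fidelity promise about rendering.
#'
#' @param sal Saliency matrix in `[0, 1]`.
#' @param mask Binary mask of the same shape.
#' @param path Output PNG path.
#' @export
write_overlay_png <- function(sal, mask, path) {
  assert_grid(sal); assert_binary_grid(mask)
  img <- pmin(pmax(sal, 0), 1) * 0.8
  b <- extract_boundary(mask)
  if (nrow(b) > 0L) img[b] <- 1
  write_gray_png(img, path)
}
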