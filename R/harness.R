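# Evaluation harness: batch scoring, dataset-level aggregation, sensitivity
# grids, majority voting and run manifests. Everything takes and returns
# tibbles so pipelines compose with the pipe.

#' Score a table of saliency/mask pairs with XAlign
#'
#' @param data A tibble (or data frame) with list-columns `sal` (nonnegative
#'   saliency matrices) and `mask` (binary masks); any other columns (e.g.
#'   `id`, `method`, `tier`) are carried through.
#' @inheritParams xalign
#' @return The input tibble (minus the list-columns) with numeric columns
#'   `wro`, `bas`, `dp`, `raw` and `score` appended; class `xalign_scores`.
#' @export
score_saliency <- function(data, weights = xalign_weights(),
                           policy = threshold_policy("fixed", 0.5),
                           variant = c("max", "average"), tolerance = 0,
                           dilation_radius = 0, eps = 1e-8) {
  variant <- match.arg(variant)
  if (!all(c("sal", "mask") %in% names(data))) {
    abort("`data` must have list-columns `sal` and `mask`.")
  }
  res <- purrr::map2(data$sal, data$mask, function(s, m) {
    r <- xalign(s, m, weights, policy, variant, tolerance, dilation_radius, eps)
    tibble::tibble(wro = r$wro, bas = r$bas, dp = r$dp, raw = r$raw,
                   score = r$score)
  }) |> purrr::list_rbind()
  out <- dplyr::bind_cols(
    dplyr::select(tibble::as_tibble(data), -dplyr::all_of(c("sal", "mask"))),
    res
  )
  class(out) <- c("xalign_scores", class(out))
  out
}

#' Score paired saliency and mask files from two directories
#'
#' Files are matched by basename (extension stripped); saliency maps may be
#' PNG (8-bit, mapped to `[0, 1]`) or headerless CSV, masks are PNG
#' (foreground where the 8-bit value exceeds 127) or CSV.
#'
#' @param saliency_dir,mask_dir Directories of saliency maps and masks.
#' @inheritParams xalign
#' @return An `xalign_scores` tibble with one row per matched pair.
#' @export
score_dir <- function(saliency_dir, mask_dir, weights = xalign_weights(),
                      policy = threshold_policy("fixed", 0.5),
                      variant = c("max", "average"), tolerance = 0,
                      dilation_radius = 0, eps = 1e-8) {
  variant <- match.arg(variant)
  sal_files <- list.files(saliency_dir, pattern = "\\.(png|csv)$", full.names = TRUE)
  mask_files <- list.files(mask_dir, pattern = "\\.(png|csv)$", full.names = TRUE)
  ids <- intersect(strip_ext(sal_files), strip_ext(mask_files))
  if (length(ids) == 0L) abort("No saliency/mask basenames match.")
  ids <- sort(ids)
  data <- tibble::tibble(
    id = ids,
    sal = purrr::map(ids, ~ read_map_file(sal_files[strip_ext(sal_files) == .x][1])),
    mask = purrr::map(ids, ~ read_mask_file(mask_files[strip_ext(mask_files) == .x][1]))
  )
  score_saliency(data, weights, policy, variant, tolerance, dilation_radius, eps)
}

strip_ext <- function(paths) sub("\\.[^.]+$", "", basename(paths))

read_map_file <- function(path) {
  if (grepl("\\.png$", path)) read_saliency_png(path) else read_matrix_csv(path)
}

read_mask_file <- function(path) {
  if (grepl("\\.png$", path)) read_mask_png(path) else {
    m <- read_matrix_csv(path)
    assert_binary_grid(m, basename(path))
    m
  }
}

#' Dataset-level aggregation of scores
#'
#' Mean, sample (n-1) standard deviation and count of a score column per
#' group — the "mean +/- SD" summary used for dataset-level reporting.
#' Groups of size one report SD 0.
#'
#' @param scores A data frame of per-item scores.
#' @param group Name of the grouping column (default `"method"`; use `"tier"`
#'   for phantom datasets).
#' @param value Name of the score column (default `"score"`).
#' @return Tibble with columns `<group>`, `n`, `mean`, `sd`.
#' @export
aggregate_scores <- function(scores, group = "method", value = "score") {
  if (!group %in% names(scores)) abort(sprintf("No column `%s` in `scores`.", group))
  if (!value %in% names(scores)) abort(sprintf("No column `%s` in `scores`.", value))
  out <- tibble::as_tibble(scores) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      sd = if (dplyr::n() > 1L) stats::sd(.data[[value]]) else 0,
      .groups = "drop"
    )
  if (any(out$n == 0L)) abort("Empty group encountered.")
  out
}

#' The default weight-sensitivity grid
#'
#' Five `(alpha, beta, gamma)` triples, each summing to 1, spanning the
#' region explored in the weighting-robustness analysis.
#'
#' @return Tibble with columns `alpha`, `beta`, `gamma`.
#' @export
default_weight_grid <- function() {
  tibble::tribble(
    ~alpha, ~beta, ~gamma,
    0.6, 0.3, 0.1,
    0.5, 0.4, 0.1,
    0.4, 0.4, 0.2,
    0.3, 0.5, 0.2,
    0.2, 0.6, 0.2
  )
}

#' Weight-sensitivity grid over precomputed components
#'
#' XAlign is linear in its weights, so each grid triple is evaluated by
#' recombining stored `(WRO, BAS, DP)` triples (clamping to `[0, 1]` before
#' averaging) — no rescoring of pixels. For each triple the per-group mean
#' score and the induced ranking are reported.
#'
#' @param components A data frame with columns `wro`, `bas`, `dp` and a
#'   grouping column (typically the output of [score_saliency()]).
#' @param grid A data frame of nonnegative `alpha`, `beta`, `gamma` triples
#'   (default [default_weight_grid()]).
#' @param group Grouping column name (default `"method"`).
#' @return A tibble of class `sensitivity_grid` with columns `alpha`, `beta`,
#'   `gamma`, `<group>`, `mean_score`, `rank` (1 = best within the triple),
#'   and attribute `stable_ranking` (`TRUE` when the ranking is identical at
#'   every triple).
#' @export
weight_sensitivity_grid <- function(components, grid = default_weight_grid(),
                                    group = "method") {
  if (!all(c("wro", "bas", "dp") %in% names(components))) {
    abort("`components` must have columns `wro`, `bas`, `dp`.")
  }
  if (!group %in% names(components)) {
    abort(sprintf("No column `%s` in `components`.", group))
  }
  grid <- tibble::as_tibble(grid)
  if (any(grid$alpha < 0 | grid$beta < 0 | grid$gamma < 0)) {
    abort("Grid weights must be nonnegative.")
  }
  out <- purrr::pmap(grid, function(alpha, beta, gamma) {
    w <- suppressWarnings(xalign_weights(alpha, beta, gamma))
    components |>
      tibble::as_tibble() |>
      dplyr::mutate(.score = combine_components(.data$wro, .data$bas, .data$dp, w)) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
      dplyr::summarise(mean_score = mean(.data$.score), .groups = "drop") |>
      dplyr::mutate(alpha = alpha, beta = beta, gamma = gamma,
                    rank = rank(-.data$mean_score, ties.method = "min"))
  }) |> purrr::list_rbind() |>
    dplyr::relocate(dplyr::all_of(c("alpha", "beta", "gamma")))
  rankings <- out |>
    dplyr::arrange(.data$alpha, .data$beta, .data$gamma, .data[[group]]) |>
    dplyr::group_by(.data$alpha, .data$beta, .data$gamma) |>
    dplyr::summarise(key = paste(.data$rank, collapse = ","), .groups = "drop")
  attr(out, "stable_ranking") <- length(unique(rankings$key)) == 1L
  class(out) <- c("sensitivity_grid", class(out))
  out
}

#' Is the group ranking identical across a sensitivity grid?
#'
#' @param grid A `sensitivity_grid` from [weight_sensitivity_grid()] or
#'   [param_sensitivity_grid()].
#' @return Logical.
#' @export
ranking_stable <- function(grid) {
  isTRUE(attr(grid, "stable_ranking"))
}

#' Explanation-parameter sensitivity grid
#'
#' Runs the full explanation-head pipeline for every combination of top-k
#' channel percentage and binarisation threshold, scores the resulting soft
#' map against the paired mask with XAlign (BAS uses the cell's threshold),
#' and reports per-group mean scores and ranking stability across cells.
#'
#' @param data A tibble with list-columns `stack` ([activation_stack()]s) and
#'   `mask` (binary masks at the stack's resolution), plus a grouping column.
#' @param k_values Top-k percentages (default `c(10, 20, 30, 40)`).
#' @param t_values Fixed binarisation thresholds (default `c(0.4, 0.5, 0.6)`).
#' @param weights XAlign weights for scoring.
#' @param group Grouping column name (default `"tier"`).
#' @return A tibble of class `sensitivity_grid` with columns `k`, `t`,
#'   `<group>`, `mean_score`, `rank`, and attribute `stable_ranking`.
#' @export
param_sensitivity_grid <- function(data, k_values = c(10, 20, 30, 40),
                                   t_values = c(0.4, 0.5, 0.6),
                                   weights = xalign_weights(),
                                   group = "tier") {
  if (!all(c("stack", "mask") %in% names(data))) {
    abort("`data` must have list-columns `stack` and `mask`.")
  }
  if (!group %in% names(data)) abort(sprintf("No column `%s` in `data`.", group))
  if (any(k_values <= 0 | k_values > 100)) abort("`k_values` must lie in (0, 100].")
  if (any(t_values < 0 | t_values > 1)) abort("`t_values` must lie in [0, 1].")
  out <- purrr::map(k_values, function(k) {
    soft_maps <- purrr::map(data$stack, function(st) {
      sel <- select_top_channels(channel_means(st), k)
      minmax_normalize(focused_map(st, sel))
    })
    purrr::map(t_values, function(tt) {
      scores <- purrr::map2_dbl(soft_maps, data$mask, function(soft, mask) {
        xalign(soft, mask, weights, threshold_policy("fixed", tt))$score
      })
      tibble::tibble(k = k, t = tt, !!group := data[[group]], score = scores) |>
        dplyr::group_by(.data$k, .data$t, dplyr::across(dplyr::all_of(group))) |>
        dplyr::summarise(mean_score = mean(.data$score), .groups = "drop") |>
        dplyr::mutate(rank = rank(-.data$mean_score, ties.method = "min"))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rankings <- out |>
    dplyr::arrange(.data$k, .data$t, .data[[group]]) |>
    dplyr::group_by(.data$k, .data$t) |>
    dplyr::summarise(key = paste(.data$rank, collapse = ","), .groups = "drop")
  attr(out, "stable_ranking") <- length(unique(rankings$key)) == 1L
  class(out) <- c("sensitivity_grid", class(out))
  out
}

#' Majority vote over per-slice predictions
#'
#' Aggregates slice-level binary predictions into a patient-level label. The
#' label with strictly more votes wins; an exact tie is broken by the higher
#' mean per-slice score when `probs` is supplied, otherwise by the positive
#' label.
#'
#' @param labels Vector of per-slice labels (0/1).
#' @param probs Optional per-slice scores, same length.
#' @return The winning label.
#' @export
majority_vote <- function(labels, probs = NULL) {
  if (length(labels) == 0L) abort("`labels` must be non-empty.")
  if (!is.null(probs) && length(probs) != length(labels)) {
    abort("`probs` must match `labels` in length.")
  }
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(type_match(top, labels))
  if (!is.null(probs)) {
    means <- vapply(top, function(l) mean(probs[labels == l]), numeric(1))
    return(type_match(top[which.max(means)], labels))
  }
  type_match(max(top), labels)  # positive label wins ties without scores
}

type_match <- function(value, template) {
  if (is.numeric(template)) as.numeric(value) else value
}

#' Write a JSON run manifest
#'
#' Records the package version, seed, options and MD5 digests of the input
#' files so a scoring run can be reproduced and audited.
#'
#' @param path Output JSON path.
#' @param seed Integer seed used for the run (or `NA`).
#' @param options Named list of run options.
#' @param inputs Character vector of input file paths to digest.
#' @param timestamp Logical; include a wall-clock timestamp (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed = NA_integer_, options = list(),
                               inputs = character(), timestamp = TRUE) {
  digests <- if (length(inputs) > 0L) {
    d <- tools::md5sum(sort(normalizePath(inputs)))
    stats::setNames(unname(d), basename(names(d)))
  } else NULL
  manifest <- list(
    package = "xalign",
    version = as.character(utils::packageVersion("xalign")),
    seed = seed,
    options = options,
    input_digests = as.list(digests)
  )
  if (timestamp) manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
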