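# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an XAlign result into one row per component
#'
#' @param x An `xalign_result` from [xalign()].
#' @param ... Unused.
#' @return Tibble with columns `component`, `value`, `weight` (the dispersion
#'   penalty's weight is reported with its negative sign, as it enters the
#'   score subtractively).
#' @method tidy xalign_result
#' @export
tidy.xalign_result <- function(x, ...) {
  tibble::tibble(
    component = c("wro", "bas", "dp"),
    value = c(x$wro, x$bas, x$dp),
    weight = c(x$weights$alpha, x$weights$beta, -x$weights$gamma)
  )
}

#' One-row summary of an XAlign result
#'
#' @inheritParams tidy.xalign_result
#' @return Tibble with `wro`, `bas`, `dp`, `raw`, `score` and the weights.
#' @method glance xalign_result
#' @export
glance.xalign_result <- function(x, ...) {
  tibble::tibble(
    wro = x$wro, bas = x$bas, dp = x$dp, raw = x$raw, score = x$score,
    alpha = x$weights$alpha, beta = x$weights$beta, gamma = x$weights$gamma
  )
}

#' Tidy a Wilcoxon signed-rank result
#'
#' @param x A `wilcoxon_test` from [wilcoxon_signed_rank()].
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `n_effective`, `p_value`, `mode`.
#' @method tidy wilcoxon_test
#' @export
tidy.wilcoxon_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, n_effective = x$n_effective,
                 p_value = x$p_value, mode = x$mode)
}

#' @rdname tidy.wilcoxon_test
#' @method glance wilcoxon_test
#' @export
glance.wilcoxon_test <- tidy.wilcoxon_test

#' Tidy a spike record into long format
#'
#' @param x A `spike_record` from [simulate_if()].
#' @param ... Unused.
#' @return Tibble with columns `timestep`, `neuron`, `potential`, `spike`.
#' @method tidy spike_record
#' @export
tidy.spike_record <- function(x, ...) {
  T <- nrow(x$spikes); n <- ncol(x$spikes)
  tibble::tibble(
    timestep = rep(seq_len(T), n),
    neuron = rep(seq_len(n), each = T),
    potential = as.vector(x$potentials),
    spike = as.vector(x$spikes)
  )
}

#' One-row summary of a spike record
#'
#' @inheritParams tidy.spike_record
#' @return Tibble with `timesteps`, `neurons`, `n_spikes`, `sparsity`.
#' @method glance spike_record
#' @export
glance.spike_record <- function(x, ...) {
  tibble::tibble(
    timesteps = nrow(x$spikes), neurons = ncol(x$spikes),
    n_spikes = sum(x$spikes), sparsity = spike_sparsity(x)
  )
}
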