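# Forward simulation of the integrate-and-fire layer that motivates the
# model's sparsity claims: V(t+1) = beta*V(t) + drive, a spike wherever the
# pre-reset potential reaches the threshold, and a hard reset to zero.

#' Integrate-and-fire neuron parameters
#'
#' @param beta_decay Membrane decay factor in `[0, 1]` (default 0.9).
#' @param v_threshold Positive firing threshold (default 1.0).
#' @param timesteps Number of discrete simulation steps (default 10).
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(beta_decay = 0.9, v_threshold = 1.0, timesteps = 10L) {
  if (!is.numeric(beta_decay) || beta_decay < 0 || beta_decay > 1) {
    abort("`beta_decay` must lie in [0, 1].")
  }
  if (!is.numeric(v_threshold) || v_threshold <= 0) {
    abort("`v_threshold` must be positive.")
  }
  timesteps <- as.integer(timesteps)
  if (is.na(timesteps) || timesteps < 1L) abort("`timesteps` must be a positive integer.")
  structure(list(beta_decay = beta_decay, v_threshold = v_threshold,
                 timesteps = timesteps),
            class = "neuron_params")
}

#' One integrate-and-fire step with hard reset
#'
#' The pre-reset potential is `beta * v + drive`; units at or above the
#' threshold emit a spike and reset to zero, others keep the accumulated
#' potential.
#'
#' @param v Membrane potential vector.
#' @param drive Input drive vector (synaptic current `W . f`), same length.
#' @param params A [neuron_params()] object.
#' @return List with `v_next` (post-reset potentials) and `spikes` (0/1).
#' @export
if_step <- function(v, drive, params = neuron_params()) {
  if (length(v) != length(drive)) abort("`v` and `drive` must have equal length.")
  if (!all(is.finite(drive)) || !all(is.finite(v))) {
    abort("`v` and `drive` must be finite.")
  }
  v_pre <- params$beta_decay * v + drive
  spikes <- as.numeric(v_pre >= params$v_threshold)
  list(v_next = v_pre * (1 - spikes), spikes = spikes)
}

#' Simulate an integrate-and-fire layer over T timesteps
#'
#' Starts from `V(0) = 0` and iterates [if_step()], recording the post-reset
#' potential and the spike indicator of every unit at every step. A constant
#' drive vector is re-presented at each step; a `T x N` matrix supplies
#' per-step drive.
#'
#' @param drive Numeric vector of length `N` (constant drive) or a
#'   `timesteps x N` matrix.
#' @param params A [neuron_params()] object.
#' @return An object of class `spike_record`: list with `potentials` and
#'   `spikes` (both `T x N` matrices) and `drive`.
#' @examples
#' rec <- simulate_if(0.2, neuron_params())
#' which(rec$spikes[, 1] == 1)  # first crossing of the threshold
#' @export
simulate_if <- function(drive, params = neuron_params()) {
  T <- params$timesteps
  if (is.matrix(drive)) {
    if (nrow(drive) != T) abort("Per-step drive must have `timesteps` rows.")
    drv <- drive
  } else {
    drv <- matrix(rep(as.numeric(drive), each = T), nrow = T)
  }
  if (!all(is.finite(drv))) abort("`drive` must be finite.")
  n <- ncol(drv)
  potentials <- matrix(0, T, n)
  spikes <- matrix(0, T, n)
  v <- rep(0, n)
  for (t in seq_len(T)) {
    st <- if_step(v, drv[t, ], params)
    v <- st$v_next
    potentials[t, ] <- v
    spikes[t, ] <- st$spikes
  }
  structure(list(potentials = potentials, spikes = spikes, drive = drv,
                 params = params),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %d timesteps x %d neurons, %.1f%% inactive\n",
              nrow(x$spikes), ncol(x$spikes), 100 * spike_sparsity(x)))
  invisible(x)
}

#' Piecewise-linear surrogate gradient
#'
#' The training-time stand-in for the derivative of the spike nonlinearity:
#' `max(0, 1 - |v - v_threshold|)`, a triangular bump peaking at the
#' threshold with support of width 2.
#'
#' @param v Membrane potential (vectorised).
#' @param v_threshold Firing threshold (default 1.0).
#' @return Values in `[0, 1]`.
#' @export
surrogate_gradient <- function(v, v_threshold = 1.0) {
  pmax(0, 1 - abs(v - v_threshold))
}

#' Spike sparsity of a simulation record
#'
#' Fraction of (timestep, neuron) entries with no spike, i.e. the mean
#' per-timestep inactivity rate — the efficiency proxy for event-driven
#' computation.
#'
#' @param record A `spike_record` from [simulate_if()].
#' @return Value in `[0, 1]`.
#' @export
spike_sparsity <- function(record) {
  if (!inherits(record, "spike_record")) abort("`record` must be a spike_record.")
  if (length(record$spikes) == 0L) abort("Empty spike record.")
  mean(record$spikes == 0)
}

#' Closed-form subthreshold potential under constant drive
#'
#' Before the first spike, `V(t) = I * (1 - beta^t) / (1 - beta)` (or `I * t`
#' when `beta = 1`). Useful as an analytic check on the simulator.
#'
#' @param drive Constant drive `I`.
#' @param t Timestep (vectorised, `t >= 1`).
#' @param beta_decay Decay factor.
#' @return Potential values.
#' @export
if_closed_form <- function(drive, t, beta_decay = 0.9) {
  if (beta_decay == 1) drive * t
  else drive * (1 - beta_decay^t) / (1 - beta_decay)
}
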