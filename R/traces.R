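#' Time-trace specification
#'
#' Parameters of a ground-truth fluorescence time trace, either a sparse
#' calcium-transient trace for a target source (soma-like) or a non-sparse
#' rapidly fluctuating trace for a neuropil-like source. The resting
#' fluorescence baseline F0 defaults to 0: only activity-driven transients
#' are modeled, as for low-baseline genetically encoded calcium indicators.
#'
#' @param kind `"target"` or `"neuropil"`.
#' @param n_frames number of frames.
#' @param frame_rate acquisition rate in Hz (default 10).
#' @param spike_times integer frame indices of transient onsets (target
#'   traces only; 1-based, in `[1, n_frames]`).
#' @param decay_tau transient decay time constant in seconds (default 1.0).
#' @param amplitude peak amplitude per transient, arbitrary fluorescence
#'   units; scalar or one value per spike.
#' @param baseline_F0 resting fluorescence (default 0).
#' @param seed integer seed (neuropil traces only).
#' @return an object of class `trace_spec`.
#' @export
trace_spec <- function(kind = c("target", "neuropil"),
                       n_frames, frame_rate = 10,
                       spike_times = integer(),
                       decay_tau = 1.0, amplitude = 1,
                       baseline_F0 = 0, seed = 0) {
  kind <- match.arg(kind)
  stopifnot(n_frames >= 1, frame_rate > 0, baseline_F0 >= 0,
            all(amplitude > 0))
  if (length(spike_times) &&
      (any(spike_times < 1) || any(spike_times > n_frames))) {
    stop("spike_times must lie in [1, n_frames]")
  }
  structure(list(kind = kind, n_frames = as.integer(n_frames),
                 frame_rate = frame_rate,
                 spike_times = as.integer(spike_times),
                 decay_tau = decay_tau, amplitude = amplitude,
                 baseline_F0 = baseline_F0, seed = seed),
            class = "trace_spec")
}

#' Generate a sparse calcium-transient trace
#'
#' Each spike contributes an instantaneous rise to its amplitude followed by
#' a single-exponential decay `a * exp(-(t - t_spike) / tau)`; overlapping
#' transients add linearly. With no spikes and F0 = 0 the trace is
#' identically zero.
#'
#' @param spec a [trace_spec()] with `kind = "target"`.
#' @return numeric vector of length `n_frames`, nonnegative.
#' @examples
#' s <- trace_spec("target", n_frames = 50, frame_rate = 10,
#'                 spike_times = 11, decay_tau = 1)
#' generate_calcium_trace(s)[11]   # 1 at the spike frame
#' @export
generate_calcium_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  if (spec$kind != "target") stop("spec$kind must be 'target'")
  if (spec$decay_tau <= 0) stop("decay_tau must be positive")
  n <- spec$n_frames
  amp <- rep_len(spec$amplitude, length(spec$spike_times))
  impulses <- numeric(n)
  for (i in seq_along(spec$spike_times)) {
    t0 <- spec$spike_times[i]
    impulses[t0] <- impulses[t0] + amp[i]
  }
  decay <- exp(-1 / (spec$decay_tau * spec$frame_rate))
  trace <- numeric(n)
  acc <- 0
  for (t in seq_len(n)) {
    acc <- acc * decay + impulses[t]
    trace[t] <- acc
  }
  spec$baseline_F0 + trace
}

#' Generate a non-sparse neuropil-like trace
#'
#' Seeded rapidly fluctuating nonnegative trace modeling diffuse neuropil
#' background: white Gaussian noise is rectified and smoothed with a 3-frame
#' moving average, then scaled to the requested peak amplitude. The result
#' is non-sparse (most frames carry signal well above zero) and fluctuates
#' faster than the calcium transients of target sources.
#'
#' @param spec a [trace_spec()] with `kind = "neuropil"`; `amplitude` sets
#'   the trace maximum (0 gives an all-zero trace).
#' @return numeric vector of length `n_frames`, nonnegative.
#' @export
generate_neuropil_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  if (spec$kind != "neuropil") stop("spec$kind must be 'neuropil'")
  n <- spec$n_frames
  amp <- spec$amplitude[1]
  if (amp == 0) return(numeric(n))
  z <- with_seed(substream_seed(spec$seed, "neuropil"), stats::rnorm(n + 2))
  z <- pmax(z, 0)
  y <- (z[1:n] + z[2:(n + 1)] + z[3:(n + 2)]) / 3
  spec$baseline_F0 + amp * y / max(y)
}
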