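#' Camera model
#'
#' Digitization model for the proximal-end camera. Two presets mirror the
#' hardware tiers of interest: a 16-bit scientific CMOS (`"sCMOS"`, shot
#' noise on, 2-count read noise) and an 8-bit miniscope CMOS
#' (`"miniscope"`, 10 Hz). Counts are clipped at `2^bit_depth - 1`;
#' saturated pixels are reported because they corrupt the demixed traces of
#' every source whose fingerprint covers them.
#'
#' @param preset `"sCMOS"` or `"miniscope"`, or `NULL` to set fields
#'   directly.
#' @param bit_depth 8 or 16.
#' @param gain counts per fluorescence intensity unit.
#' @param read_noise_sd Gaussian read noise, counts.
#' @param shot_noise logical; Poisson noise on the expected counts.
#' @param frame_rate Hz.
#' @param illumination_power_uW metadata: excitation power through the
#'   fiber.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(preset = c("sCMOS", "miniscope", "custom"),
                         bit_depth = NULL, gain = NULL,
                         read_noise_sd = NULL, shot_noise = NULL,
                         frame_rate = NULL, illumination_power_uW = 9.5) {
  preset <- match.arg(preset)
  def <- switch(preset,
    sCMOS = list(bit_depth = 16L, gain = 3000, read_noise_sd = 2,
                 shot_noise = TRUE, frame_rate = 10),
    miniscope = list(bit_depth = 8L, gain = 40, read_noise_sd = 1,
                     shot_noise = TRUE, frame_rate = 10),
    custom = list(bit_depth = 16L, gain = 1, read_noise_sd = 0,
                  shot_noise = FALSE, frame_rate = 10)
  )
  cam <- list(
    preset = preset,
    bit_depth = as.integer(if (is.null(bit_depth)) def$bit_depth else bit_depth),
    gain = if (is.null(gain)) def$gain else gain,
    read_noise_sd = if (is.null(read_noise_sd)) def$read_noise_sd else read_noise_sd,
    shot_noise = if (is.null(shot_noise)) def$shot_noise else shot_noise,
    frame_rate = if (is.null(frame_rate)) def$frame_rate else frame_rate,
    illumination_power_uW = illumination_power_uW
  )
  if (!cam$bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  cam$saturation <- 2^cam$bit_depth - 1
  structure(cam, class = "camera_model")
}

#' Source set
#'
#' Bundles the ground truth of an experiment: one fingerprint, one time
#' trace, one position, and one role per source.
#'
#' @param fingerprints list of `fingerprint_pattern`s (all the same size).
#' @param traces list of nonnegative per-frame numeric vectors (all the same
#'   length).
#' @param positions list of [source_position()]s.
#' @param roles character vector, `"target"` or `"neuropil"` per source.
#' @return an object of class `source_set`.
#' @export
source_set <- function(fingerprints, traces, positions, roles) {
  n <- length(fingerprints)
  stopifnot(length(traces) == n, length(positions) == n, length(roles) == n,
            all(roles %in% c("target", "neuropil")))
  sizes <- vapply(fingerprints, function(f) nrow(f$image), integer(1))
  lens <- vapply(traces, length, integer(1))
  if (length(unique(sizes)) > 1) stop("all fingerprints must share one image size")
  if (length(unique(lens)) > 1) stop("all traces must share one length")
  if (any(vapply(traces, function(h) any(h < 0), logical(1)))) {
    stop("traces must be nonnegative")
  }
  structure(list(fingerprints = fingerprints, traces = traces,
                 positions = positions, roles = roles),
            class = "source_set")
}

#' @export
print.source_set <- function(x, ...) {
  cat(sprintf("source_set: %d sources (%d target, %d neuropil), %d frames\n",
              length(x$traces), sum(x$roles == "target"),
              sum(x$roles == "neuropil"), length(x$traces[[1]])))
  invisible(x)
}

#' Video stack
#'
#' T camera frames of nonnegative counts plus camera metadata.
#'
#' @param frames numeric array `[rows, cols, T]` of counts.
#' @param bit_depth camera bit depth (8 or 16).
#' @param frame_rate Hz.
#' @param saturation_mask optional logical array marking clipped pixels.
#' @return an object of class `video_stack`.
#' @export
video_stack <- function(frames, bit_depth = 16L, frame_rate = 10,
                        saturation_mask = NULL) {
  stopifnot(length(dim(frames)) == 3, all(frames >= 0))
  structure(list(frames = frames, bit_depth = as.integer(bit_depth),
                 frame_rate = frame_rate,
                 saturation_mask = saturation_mask),
            class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  nsat <- if (is.null(x$saturation_mask)) 0 else sum(x$saturation_mask)
  cat(sprintf("video_stack: %dx%d px, %d frames, %d-bit, %d saturated px\n",
              d[1], d[2], d[3], x$bit_depth, nsat))
  invisible(x)
}

#' Render a camera video from ground-truth sources
#'
#' The noiseless frame at time t is the linear superposition
#' `sum_i w_i * h_i(t)` of the source fingerprints weighted by their traces.
#' The camera then applies gain, optional Poisson shot noise and Gaussian
#' read noise, integer quantization, and clipping at `2^bit_depth - 1`;
#' clipped pixels are recorded in the saturation mask.
#'
#' @param sources a [source_set()].
#' @param camera a [camera_model()].
#' @param noise_seed integer seed for shot and read noise.
#' @param noiseless logical; if `TRUE`, skip noise, quantization and
#'   clipping and return the continuous superposition (useful for linearity
#'   checks).
#' @return a [video_stack()].
#' @export
render_video <- function(sources, camera = camera_model("sCMOS"),
                         noise_seed = 0, noiseless = FALSE) {
  stopifnot(inherits(sources, "source_set"))
  imgs <- lapply(sources$fingerprints, `[[`, "image")
  n_px_side <- nrow(imgs[[1]])
  W <- vapply(imgs, as.vector, numeric(n_px_side^2))   # pixels x sources
  H <- do.call(rbind, sources$traces)                  # sources x T
  M <- W %*% H                                         # pixels x T, intensity
  n_t <- ncol(M)
  if (noiseless) {
    return(video_stack(array(M, c(n_px_side, n_px_side, n_t)),
                       bit_depth = camera$bit_depth,
                       frame_rate = camera$frame_rate))
  }
  expected <- camera$gain * M
  counts <- with_seed(substream_seed(noise_seed, "camera_noise"), {
    x <- if (camera$shot_noise) {
      matrix(stats::rpois(length(expected), lambda = expected),
             nrow(expected), ncol(expected))
    } else expected
    if (camera$read_noise_sd > 0) {
      x <- x + matrix(stats::rnorm(length(x), 0, camera$read_noise_sd),
                      nrow(x), ncol(x))
    }
    x
  })
  counts <- round(counts)
  counts[counts < 0] <- 0
  sat <- counts >= camera$saturation
  counts[sat] <- camera$saturation
  video_stack(array(counts, c(n_px_side, n_px_side, n_t)),
              bit_depth = camera$bit_depth,
              frame_rate = camera$frame_rate,
              saturation_mask = array(sat, c(n_px_side, n_px_side, n_t)))
}
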