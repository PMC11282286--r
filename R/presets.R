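#' Generate a complete synthetic demixing experiment
#'
#' Builds ground-truth fingerprints, time traces, and a rendered camera
#' video for one of the bench-scenario presets, at desk scale:
#'
#' * `six_bead`: 6 target sources, one close to the core edge (its
#'   fingerprint is dim and low-contrast, so it is expected to demix
#'   poorly), 1500 frames.
#' * `dense_26_neuropil`: 25 targets + 1 neuropil source (#20); targets
#'   #23--25 near the core edge and #26 outside the field of view, 2000
#'   frames.
#' * `dense_26_parafilm`: as above, with a scattering layer (strength 1)
#'   between sources and fiber.
#' * `dominant_neuropil_21`: 10 targets + 11 sources sharing one non-sparse
#'   neuropil trace, calibrated so the time-averaged total neuropil signal
#'   is 6x the time-averaged ensemble target signal.
#' * `single_source_scan`: one source stepped radially in 10%-of-core
#'   steps, active in consecutive time blocks (for fingerprint-geometry
#'   studies).
#'
#' Exposure is calibrated per experiment so the expected peak count sits at
#' half the camera saturation level (saturated pixels corrupt demixing and
#' are avoided during recording).
#'
#' @param preset one of the names above.
#' @param seed master integer seed; every stream of randomness (positions,
#'   spikes, textures, layer, camera noise) derives from it.
#' @param n_frames number of frames; `NULL` uses the preset default.
#' @param image_size proximal image side length in pixels (default 48).
#' @param camera camera preset name or a [camera_model()].
#' @param model fingerprint model, `"phenomenological"` (default; fast and
#'   guaranteed-unique textures) or `"physical"` (LP-mode forward model).
#' @param scatter_strength scattering-layer strength; `NULL` uses the
#'   preset default (0 except `dense_26_parafilm`).
#' @param fiber a [fiber_spec()]; default is the scaled fiber.
#' @return a list of class `fiber_experiment` with elements `video`
#'   ([video_stack()]), `sources` ([source_set()]), and `config` (a fully
#'   serializable record of every parameter and calibration used).
#' @export
generate_experiment <- function(preset, seed = 0, n_frames = NULL,
                                image_size = 48, camera = "sCMOS",
                                model = c("phenomenological", "physical"),
                                scatter_strength = NULL,
                                fiber = fiber_spec()) {
  presets <- c("six_bead", "dense_26_neuropil", "dense_26_parafilm",
               "dominant_neuropil_21", "single_source_scan")
  if (!preset %in% presets) {
    stop(sprintf("unknown preset '%s'; available: %s", preset,
                 paste(presets, collapse = ", ")))
  }
  model <- match.arg(model)
  if (is.character(camera)) camera <- camera_model(camera)
  a <- fiber$core_radius

  layout <- switch(preset,
    six_bead = list(
      rel_d = c(0.15, 0.30, 0.45, 0.55, 0.70, 0.97),
      roles = rep("target", 6), n_frames = 1500, scatter = 0,
      shared_neuropil = integer()),
    dense_26_neuropil = ,
    dense_26_parafilm = list(
      rel_d = c(seq(0.15, 0.88, length.out = 19),
                rep(0.30, 1),                    # neuropil, central
                0.60, 0.75, 0.95, 1.00, 1.05, 1.15),
      roles = c(rep("target", 19), "neuropil", rep("target", 6)),
      n_frames = 2000,
      scatter = if (preset == "dense_26_parafilm") 1 else 0,
      shared_neuropil = integer()),
    dominant_neuropil_21 = list(
      # neuropil-like sources at #1 and #11--#20, targets at #2--#10 and #21
      rel_d = c(0.25, seq(0.15, 0.80, length.out = 9),
                seq(0.20, 0.85, length.out = 10), 0.55),
      roles = c("neuropil", rep("target", 9), rep("neuropil", 10), "target"),
      n_frames = 1500, scatter = 0,
      shared_neuropil = TRUE),
    single_source_scan = list(
      rel_d = seq(0, 0.9, by = 0.1),
      roles = rep("target", 10), n_frames = 500, scatter = 0,
      shared_neuropil = integer())
  )
  if (is.null(n_frames)) n_frames <- layout$n_frames
  if (is.null(scatter_strength)) scatter_strength <- layout$scatter
  n_src <- length(layout$rel_d)
  frame_rate <- camera$frame_rate

  azimuths <- with_seed(substream_seed(seed, "azimuth"),
                        stats::runif(n_src, 0, 2 * pi))
  positions <- lapply(seq_len(n_src), function(i) {
    source_position(d = layout$rel_d[i] * a, azimuth = azimuths[i])
  })

  # --- fingerprints -------------------------------------------------------
  modes <- if (model == "physical") solve_lp_modes(fiber) else NULL
  fingerprints <- lapply(seq_len(n_src), function(i) {
    fp <- if (model == "physical") {
      fingerprint_physical(fiber, positions[[i]], image_size = image_size,
                           seed = substream_seed(seed, "fiber_disorder"),
                           modes = modes)
    } else {
      fingerprint_phenomenological(positions[[i]], image_size = image_size,
                                   texture_seed = substream_seed(seed, "texture", i),
                                   core_radius = a)
    }
    if (scatter_strength > 0) {
      fp <- apply_scattering_layer(fp, layer_seed = substream_seed(seed, "layer"),
                                   strength = scatter_strength)
    }
    # unit-peak normalization: brightness differences are carried by traces
    # and the physical roll-off of edge sources (relative peak retained)
    fp
  })
  peaks <- vapply(fingerprints, function(f) max(f$image), numeric(1))
  ref_peak <- max(peaks)
  fingerprints <- lapply(fingerprints, function(f) {
    f$image <- f$image / ref_peak
    f
  })

  # --- traces -------------------------------------------------------------
  spike_rate <- 0.015                    # expected transient onsets per frame
  traces <- vector("list", n_src)
  if (preset == "single_source_scan") {
    block <- floor(n_frames / n_src)
    for (i in seq_len(n_src)) {
      h <- numeric(n_frames)
      h[seq((i - 1) * block + 1, i * block)] <- 1
      traces[[i]] <- h
    }
  } else {
    for (i in seq_len(n_src)) {
      if (layout$roles[i] == "target") {
        sp <- with_seed(substream_seed(seed, "spikes", i), {
          k <- max(3L, stats::rpois(1, spike_rate * n_frames))
          list(t = sort(sample.int(n_frames, k)),
               a = stats::runif(k, 0.6, 1.4))
        })
        traces[[i]] <- generate_calcium_trace(trace_spec(
          "target", n_frames = n_frames, frame_rate = frame_rate,
          spike_times = sp$t, decay_tau = 1.0, amplitude = sp$a))
      } else {
        traces[[i]] <- generate_neuropil_trace(trace_spec(
          "neuropil", n_frames = n_frames, frame_rate = frame_rate,
          amplitude = 1, seed = substream_seed(seed, "neuropil_trace", i)))
      }
    }
  }

  neuropil_scale <- NA_real_
  if (isTRUE(layout$shared_neuropil)) {
    # all neuropil sources share one trace; calibrate its amplitude so the
    # time-averaged total neuropil signal (fingerprint-weighted) is 6x the
    # time-averaged ensemble target signal
    shared <- generate_neuropil_trace(trace_spec(
      "neuropil", n_frames = n_frames, frame_rate = frame_rate,
      amplitude = 1, seed = substream_seed(seed, "neuropil_trace", 0)))
    wsum <- vapply(fingerprints, function(f) sum(f$image), numeric(1))
    idx_np <- which(layout$roles == "neuropil")
    idx_tg <- which(layout$roles == "target")
    target_mean <- sum(vapply(idx_tg, function(i) wsum[i] * mean(traces[[i]]),
                              numeric(1)))
    np_mean_unit <- sum(wsum[idx_np]) * mean(shared)
    neuropil_scale <- 6 * target_mean / np_mean_unit
    for (i in idx_np) traces[[i]] <- neuropil_scale * shared
  }

  sources <- source_set(fingerprints, traces, positions, layout$roles)

  # --- exposure calibration and rendering ---------------------------------
  clean <- render_video(sources, camera, noiseless = TRUE)
  peak_intensity <- max(clean$frames)
  camera$gain <- 0.5 * camera$saturation / peak_intensity
  video <- render_video(sources, camera,
                        noise_seed = substream_seed(seed, "noise"))

  config <- list(
    preset = preset, seed = seed, n_frames = n_frames,
    image_size = image_size, model = model,
    scatter_strength = scatter_strength,
    camera = unclass(camera)[c("preset", "bit_depth", "gain",
                               "read_noise_sd", "shot_noise", "frame_rate")],
    fiber = unclass(fiber),
    rel_d = layout$rel_d, azimuths = azimuths, roles = layout$roles,
    spike_rate = spike_rate, decay_tau = 1.0,
    neuropil_scale = neuropil_scale,
    n_sources = n_src
  )
  structure(list(video = video, sources = sources, config = config),
            class = "fiber_experiment")
}

#' @export
print.fiber_experiment <- function(x, ...) {
  cat(sprintf("fiber_experiment '%s' (seed %d): ", x$config$preset,
              x$config$seed))
  print(x$sources)
  invisible(x)
}

#' Generate an experiment with a dominant global fluorescence background
#'
#' Ten target sources plus one spatially broad, non-sparse dynamic
#' background component whose maximum ensemble signal is `ratio` times the
#' maximum ensemble target-activity signal. Used to probe how demixing
#' degrades as the background overtakes source activity.
#'
#' @param ratio max background over max target-activity ensemble signal
#'   (default 2.0).
#' @param seed master integer seed.
#' @param n_frames number of frames (default 1000).
#' @param image_size image side length (default 48).
#' @param camera camera preset name or [camera_model()].
#' @param fiber a [fiber_spec()].
#' @return a `fiber_experiment`; the background is the last source, with
#'   role `"neuropil"`.
#' @export
generate_background_experiment <- function(ratio = 2.0, seed = 0,
                                           n_frames = 1000, image_size = 48,
                                           camera = "sCMOS",
                                           fiber = fiber_spec()) {
  stopifnot(ratio >= 0)
  if (is.character(camera)) camera <- camera_model(camera)
  a <- fiber$core_radius
  n_tg <- 10L
  rel_d <- seq(0.15, 0.85, length.out = n_tg)
  azimuths <- with_seed(substream_seed(seed, "azimuth"),
                        stats::runif(n_tg, 0, 2 * pi))
  positions <- lapply(seq_len(n_tg), function(i) {
    source_position(rel_d[i] * a, azimuths[i])
  })
  fingerprints <- lapply(seq_len(n_tg), function(i) {
    fingerprint_phenomenological(positions[[i]], image_size = image_size,
                                 texture_seed = substream_seed(seed, "texture", i),
                                 core_radius = a)
  })

  # broad, smooth background footprint covering the whole core
  g <- pixel_grid(image_size, image_size / 2)
  r <- sqrt(g$x^2 + g$y^2)
  r_core_px <- image_size / 2 / 1.3
  z <- with_seed(substream_seed(seed, "bg_texture"),
                 matrix(stats::rnorm(image_size^2), image_size, image_size))
  z <- gaussian_blur(z, 0.1 * image_size)
  bg_img <- (1 + 0.3 * z / stats::sd(z))
  bg_img[bg_img < 0] <- 0
  bg_img <- bg_img * exp(-(r / (1.05 * r_core_px))^6)
  bg_fp <- new_fingerprint(bg_img, measured_ring_radius(bg_img))

  traces <- lapply(seq_len(n_tg), function(i) {
    sp <- with_seed(substream_seed(seed, "spikes", i), {
      k <- max(3L, stats::rpois(1, 0.015 * n_frames))
      list(t = sort(sample.int(n_frames, k)), a = stats::runif(k, 0.6, 1.4))
    })
    generate_calcium_trace(trace_spec(
      "target", n_frames = n_frames, frame_rate = camera$frame_rate,
      spike_times = sp$t, decay_tau = 1.0, amplitude = sp$a))
  })
  bg_trace <- generate_neuropil_trace(trace_spec(
    "neuropil", n_frames = n_frames, frame_rate = camera$frame_rate,
    amplitude = 1, seed = substream_seed(seed, "bg_trace")))

  # calibrate: max ensemble background = ratio * max ensemble target signal
  wsum_tg <- vapply(fingerprints, function(f) sum(f$image), numeric(1))
  tgt_ensemble <- Reduce(`+`, Map(function(w, h) w * h, wsum_tg, traces))
  bg_unit <- sum(bg_img) * bg_trace
  scale <- if (max(bg_unit) > 0) ratio * max(tgt_ensemble) / max(bg_unit) else 0
  bg_trace <- scale * bg_trace

  sources <- source_set(c(fingerprints, list(bg_fp)),
                        c(traces, list(bg_trace)),
                        c(positions, list(source_position(0, 0, diameter = 2 * a))),
                        c(rep("target", n_tg), "neuropil"))
  clean <- render_video(sources, camera, noiseless = TRUE)
  camera$gain <- 0.5 * camera$saturation / max(clean$frames)
  video <- render_video(sources, camera,
                        noise_seed = substream_seed(seed, "noise"))
  config <- list(preset = "background_ratio", ratio = ratio, seed = seed,
                 n_frames = n_frames, image_size = image_size,
                 background_scale = scale,
                 camera = unclass(camera)[c("preset", "bit_depth", "gain",
                                            "read_noise_sd", "shot_noise",
                                            "frame_rate")],
                 n_sources = n_tg + 1L)
  structure(list(video = video, sources = sources, config = config),
            class = "fiber_experiment")
}
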