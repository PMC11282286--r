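#' Read a multi-page TIFF video
#'
#' Loads frames in page order from an unsigned 8- or 16-bit multi-page
#' TIFF. Pixel values are kept as raw integer counts; the bit depth is
#' taken from the file metadata (so an 8-bit stack gets a saturation level
#' of 255). Mixed page shapes or sample depths are rejected with the
#' offending page named.
#'
#' @param path TIFF file path.
#' @param frame_rate frame rate to record on the stack (Hz, default 10;
#'   TIFF carries no rate metadata).
#' @return a [video_stack()].
#' @export
read_video_tiff <- function(path, frame_rate = 10) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  bits <- vapply(pages, function(p) {
    b <- attr(p, "bits.per.sample")
    if (is.null(b)) 16L else as.integer(b)
  }, integer(1))
  for (i in seq_along(pages)) {
    if (!identical(dims[[i]], dims[[1]])) {
      stop(sprintf("page %d has shape %s, expected %s", i,
                   paste(dims[[i]], collapse = "x"),
                   paste(dims[[1]], collapse = "x")))
    }
    if (bits[i] != bits[1]) {
      stop(sprintf("page %d has %d bits per sample, expected %d",
                   i, bits[i], bits[1]))
    }
  }
  arr <- array(0, c(dims[[1]][1], dims[[1]][2], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  video_stack(arr, bit_depth = bits[1], frame_rate = frame_rate)
}

#' Write a video stack as a multi-page TIFF
#'
#' Plain uncompressed multi-page TIFF, one page per frame, unsigned 8- or
#' 16-bit according to the stack's bit depth.
#'
#' @param video a [video_stack()].
#' @param path output file path.
#' @param compression `"none"` (default) or `"deflate"`.
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(video, path, compression = "none") {
  stopifnot(inherits(video, "video_stack"))
  maxc <- 2^video$bit_depth - 1
  frames <- lapply(seq_len(dim(video$frames)[3]), function(t) {
    f <- video$frames[, , t]
    f <- pmin(pmax(round(f), 0), maxc)
    f / maxc   # writeTIFF expects [0, 1]
  })
  tiff::writeTIFF(frames, path, bits.per.sample = video$bit_depth,
                  compression = compression)
  invisible(path)
}

# Scale a list of nonnegative float images jointly to 16-bit and write as a
# multi-page TIFF; the common scale is returned so the images can be
# restored exactly up to quantization.
write_images_tiff <- function(images, path) {
  peak <- max(vapply(images, max, numeric(1)), .Machine$double.eps)
  pages <- lapply(images, function(im) pmin(pmax(im / peak, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  peak
}

#' Write the ground-truth sidecar bundle of an experiment
#'
#' Writes the rendered video (TIFF), ground-truth fingerprints (multi-page
#' TIFF, jointly scaled to 16-bit), traces (CSV: frame, source_1..N),
#' and positions/roles/config (JSON).
#'
#' @param experiment a `fiber_experiment` from [generate_experiment()].
#' @param out_dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_truth_bundle <- function(experiment, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_video_tiff(experiment$video, file.path(out_dir, "video.tif"))
  fp_scale <- write_images_tiff(
    lapply(experiment$sources$fingerprints, `[[`, "image"),
    file.path(out_dir, "fingerprints_gt.tif"))
  traces <- do.call(cbind, experiment$sources$traces)
  colnames(traces) <- paste0("source_", seq_len(ncol(traces)))
  utils::write.csv(data.frame(frame = seq_len(nrow(traces)), traces),
                   file.path(out_dir, "traces_gt.csv"), row.names = FALSE)
  meta <- list(
    config = experiment$config,
    fingerprint_scale = fp_scale,
    positions = lapply(experiment$sources$positions, unclass),
    roles = experiment$sources$roles
  )
  jsonlite::write_json(meta, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a demixing/evaluation results bundle
#'
#' Writes demixed spatial components (multi-page TIFF), temporal components
#' (CSV), loss history, correlation tables and summaries (CSV), the solver
#' configuration, and finally a manifest with MD5 content hashes of every
#' file. The manifest is written last, so a partial write leaves no
#' manifest; re-running with unchanged inputs reproduces identical hashes.
#'
#' @param result a `demix_result` from [demix_video()].
#' @param out_dir output directory (created if needed).
#' @param report optional `evaluation_report` from [evaluate_demix()].
#' @return the manifest as a named list, invisibly.
#' @export
write_results_bundle <- function(result, out_dir, report = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  comp_scale <- write_images_tiff(result$spatial,
                                  file.path(out_dir, "components.tif"))
  files <- c(files, "components.tif")

  temporal <- t(result$temporal)
  colnames(temporal) <- paste0("component_", seq_len(ncol(temporal)))
  utils::write.csv(data.frame(frame = seq_len(nrow(temporal)), temporal),
                   file.path(out_dir, "temporal.csv"), row.names = FALSE)
  files <- c(files, "temporal.csv")

  utils::write.csv(data.frame(iteration = seq_along(result$loss_history),
                              loss = result$loss_history),
                   file.path(out_dir, "loss_history.csv"), row.names = FALSE)
  files <- c(files, "loss_history.csv")

  summary_json <- list(
    rank = result$rank, converged = result$converged,
    iterations = length(result$loss_history),
    final_loss = utils::tail(result$loss_history, 1),
    bin_factor = result$bin_factor,
    component_scale = comp_scale,
    config = unclass(result$config)
  )
  if (!is.null(report)) {
    utils::write.csv(as.data.frame(unclass(report$gt_nmf)),
                     file.path(out_dir, "gt_nmf_correlations.csv"))
    utils::write.csv(as.data.frame(unclass(report$gt_gt)),
                     file.path(out_dir, "gt_gt_correlations.csv"))
    files <- c(files, "gt_nmf_correlations.csv", "gt_gt_correlations.csv")
    if (!is.null(report$crosstalk)) {
      utils::write.csv(as.data.frame(report$crosstalk$ae_matrix),
                       file.path(out_dir, "ae_matrix.csv"))
      files <- c(files, "ae_matrix.csv")
    }
    summary_json$evaluation <- list(
      assignment = report$assignment$pairs,
      delta_avg = report$diagonal$delta_avg,
      sigma_delta = report$diagonal$sigma_delta,
      zeta_avg = if (!is.null(report$crosstalk)) report$crosstalk$zeta_avg,
      sigma_zeta = if (!is.null(report$crosstalk)) report$crosstalk$sigma_zeta,
      fingerprint_correlations = report$fingerprint_correlations,
      subset = report$diagonal$subset
    )
  }
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "summary.json")

  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  manifest <- list(files = hashes, created_by = "fiberdemix")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
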