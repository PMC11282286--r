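#' Pearson correlation table between two sets of traces
#'
#' Entry (i, j) is the Pearson correlation of trace `A[[i]]` with trace
#' `B[[j]]`. Used both for the ground-truth-vs-demixed table (nu) and the
#' ground-truth-vs-ground-truth table (gamma); the latter matters because
#' ground-truth traces are never perfectly orthogonal, and cross-talk must
#' be judged against that intrinsic correlation. Constant traces yield 0
#' with a warning.
#'
#' @param traces_a,traces_b lists of numeric vectors, or matrices with one
#'   trace per row; all traces must share one length >= 3.
#' @param labels_a,labels_b optional row/column labels.
#' @return a `correlation_table`: numeric matrix with dimnames, carrying a
#'   `"scale"` attribute (`"fraction"`).
#' @export
pearson_table <- function(traces_a, traces_b,
                          labels_a = NULL, labels_b = NULL) {
  A <- as_trace_matrix(traces_a)
  B <- as_trace_matrix(traces_b)
  if (ncol(A) != ncol(B)) stop("traces must share one length")
  if (ncol(A) < 3) stop("traces must have length >= 3")
  tab <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    tab[i, j] <- safe_cor(A[i, ], B[j, ])
  }
  rownames(tab) <- labels_a %||% paste0("GT", seq_len(nrow(A)))
  colnames(tab) <- labels_b %||% paste0("C", seq_len(nrow(B)))
  structure(tab, scale = "fraction", class = c("correlation_table", "matrix"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_trace_matrix <- function(x) {
  if (is.list(x)) do.call(rbind, x) else if (is.matrix(x)) x else rbind(x)
}

#' Greedy descending assignment of demixed components to sources
#'
#' Repeatedly takes the globally largest remaining entry of the
#' ground-truth-vs-demixed correlation table, assigns that source to that
#' component, and removes both from contention; ties are broken by lowest
#' (row, column). The output order is descending assigned correlation,
#' mirroring the convention of sorting source indices by recovery quality.
#' Sources left without a component (when there are fewer components than
#' sources) are marked unrecovered.
#'
#' @param gt_nmf a `correlation_table` (sources x components).
#' @return a list of class `assignment` with `pairs` (data frame: `gt`,
#'   `component`, `correlation`, in descending order) and `unassigned`
#'   (source indices without a component).
#' @export
assign_and_sort <- function(gt_nmf) {
  stopifnot(nrow(gt_nmf) >= 1, ncol(gt_nmf) >= 1)
  tab <- unclass(gt_nmf)
  n_g <- nrow(tab); n_c <- ncol(tab)
  pairs <- data.frame(gt = integer(), component = integer(),
                      correlation = numeric())
  used_g <- logical(n_g); used_c <- logical(n_c)
  for (k in seq_len(min(n_g, n_c))) {
    best <- -Inf; bi <- bj <- NA_integer_
    for (i in which(!used_g)) for (j in which(!used_c)) {
      if (tab[i, j] > best) { best <- tab[i, j]; bi <- i; bj <- j }
    }
    used_g[bi] <- TRUE; used_c[bj] <- TRUE
    pairs <- rbind(pairs, data.frame(gt = bi, component = bj,
                                     correlation = best))
  }
  structure(list(pairs = pairs, unassigned = which(!used_g),
                 n_gt = n_g, n_components = n_c),
            class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("assignment: %d of %d sources matched\n",
              nrow(x$pairs), x$n_gt))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

# Square GT-indexed table from the raw sources x components table and an
# assignment: entry (i, j) = correlation of GT trace i with the component
# assigned to GT j. Rows/cols follow the descending assignment order.
assigned_table <- function(gt_nmf, assignment) {
  p <- assignment$pairs
  tab <- unclass(gt_nmf)[p$gt, p$component, drop = FALSE]
  rownames(tab) <- colnames(tab) <- rownames(gt_nmf)[p$gt]
  structure(tab, scale = attr(gt_nmf, "scale"),
            class = c("correlation_table", "matrix"))
}

resolve_subset <- function(subset, n) {
  if (is.null(subset)) seq_len(n)
  else if (length(subset) == 1 && subset <= n && all(subset == floor(subset)) &&
           subset >= 1 && length(subset) == 1) seq_len(subset)
  else as.integer(subset)
}

#' Diagonal (recovery-fidelity) summary
#'
#' The diagonal entries of the assigned correlation table are the per-source
#' recovery fidelities delta; their mean and population standard deviation
#' over a subset of sources summarize the experiment. The subset "first k"
#' means the k best-recovered sources in the descending assignment order.
#'
#' @param assigned a square GT-indexed `correlation_table` in assignment
#'   order (see [evaluate_demix()]), or an `assignment`.
#' @param subset `NULL` for all assigned sources, a single integer k for
#'   the first k, or an explicit index vector into the sorted order.
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return list of class `diagonal_summary` with `per_source_diagonals`,
#'   `delta_avg`, `sigma_delta`, `subset`.
#' @export
diagonal_summary <- function(assigned, subset = NULL,
                             sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  diags <- if (inherits(assigned, "assignment")) {
    assigned$pairs$correlation
  } else diag(unclass(assigned))
  idx <- resolve_subset(subset, length(diags))
  if (length(idx) == 0) stop("subset must be nonempty")
  d <- diags[idx]
  sigma <- if (sd_type == "population") {
    sqrt(mean((d - mean(d))^2))
  } else stats::sd(d)
  structure(list(per_source_diagonals = d, delta_avg = mean(d),
                 sigma_delta = sigma, subset = idx, sd_type = sd_type),
            class = "diagonal_summary")
}

#' @export
print.diagonal_summary <- function(x, ...) {
  cat(sprintf("delta_avg = %.3f, sigma_delta = %.3f over %d sources\n",
              x$delta_avg, x$sigma_delta, length(x$subset)))
  invisible(x)
}

#' Cross-talk summary (absolute error beyond intrinsic correlation)
#'
#' Off-diagonal entries of the assigned table measure apparent cross-talk,
#' but ground-truth traces are themselves correlated; the meaningful error
#' is `AE[i, j] = |nu[i, j] - gamma[i, j]|` for i != j, the absolute
#' difference between the demixed-vs-truth and truth-vs-truth correlation
#' tables. `zeta_avg` is the arithmetic mean of these off-diagonal absolute
#' errors over the chosen subset and `sigma_zeta` their (population)
#' standard deviation. A printed-prefactor variant that divides the sum by
#' `2 (N_s - 1)` instead of the number of off-diagonal elements is
#' available for comparison (`prefactor = "half_ns_minus_1"`).
#'
#' @param gt_nmf square GT-indexed assigned `correlation_table` (nu).
#' @param gt_gt matching GT-vs-GT `correlation_table` (gamma), same labels
#'   and order.
#' @param subset as in [diagonal_summary()]; must select >= 2 sources.
#' @param prefactor `"mean"` (default) or `"half_ns_minus_1"`.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return list of class `crosstalk_summary` with `ae_matrix`, `zeta_avg`,
#'   `sigma_zeta`, `subset`.
#' @export
crosstalk_summary <- function(gt_nmf, gt_gt, subset = NULL,
                              prefactor = c("mean", "half_ns_minus_1"),
                              sd_type = c("population", "sample")) {
  prefactor <- match.arg(prefactor)
  sd_type <- match.arg(sd_type)
  nu <- unclass(gt_nmf); ga <- unclass(gt_gt)
  if (!all(dim(nu) == dim(ga))) stop("tables must have matching shape")
  if (nrow(nu) != ncol(nu)) stop("tables must be square over the subset")
  idx <- resolve_subset(subset, nrow(nu))
  if (length(idx) < 2) stop("subset must contain at least 2 sources")
  nu <- nu[idx, idx, drop = FALSE]
  ga <- ga[idx, idx, drop = FALSE]
  ae <- abs(nu - ga)
  diag(ae) <- NA
  off <- ae[!is.na(ae)]
  zeta_avg <- if (prefactor == "mean") {
    mean(off)
  } else {
    sum(off) / (2 * (length(idx) - 1))
  }
  sigma <- if (sd_type == "population") {
    sqrt(mean((off - mean(off))^2))
  } else stats::sd(off)
  structure(list(ae_matrix = ae, zeta_avg = zeta_avg, sigma_zeta = sigma,
                 subset = idx, prefactor = prefactor, sd_type = sd_type),
            class = "crosstalk_summary")
}

#' @export
print.crosstalk_summary <- function(x, ...) {
  cat(sprintf("zeta_avg = %.4f, sigma_zeta = %.4f over %d sources\n",
              x$zeta_avg, x$sigma_zeta, length(x$subset)))
  invisible(x)
}

#' Spatial correlation of demixed components with ground-truth fingerprints
#'
#' For each assigned (source, component) pair, the Pearson correlation of
#' the flattened images after max-normalization (Pearson is scale
#' invariant, so the normalization is cosmetic only).
#'
#' @param gt_fingerprints list of `fingerprint_pattern`s or matrices.
#' @param components list of component images (matrices).
#' @param assignment an `assignment` from [assign_and_sort()].
#' @return numeric vector of spatial correlations, one per assigned pair,
#'   in assignment order.
#' @export
fingerprint_match <- function(gt_fingerprints, components, assignment) {
  imgs <- lapply(gt_fingerprints, function(f) {
    if (inherits(f, "fingerprint_pattern")) f$image else f
  })
  if (!all(dim(imgs[[1]]) == dim(components[[1]]))) {
    stop("fingerprint and component images must have the same size")
  }
  p <- assignment$pairs
  vapply(seq_len(nrow(p)), function(k) {
    gt <- imgs[[p$gt[k]]]
    cm <- components[[p$component[k]]]
    gt <- gt / max(gt, .Machine$double.eps)
    cm <- cm / max(cm, .Machine$double.eps)
    safe_cor(as.vector(gt), as.vector(cm))
  }, numeric(1))
}

#' Ensemble (photometric) trace of a video
#'
#' The classical fiber-photometry readout: the sum of all pixel counts per
#' frame. Also reports the dynamic range, defined here as the maximum of
#' the ensemble trace divided by its smallest positive value (definition
#' recorded in the result, since conventions vary).
#'
#' @param video a [video_stack()].
#' @return list with `trace` (length T) and `dynamic_range`.
#' @export
ensemble_trace <- function(video) {
  stopifnot(inherits(video, "video_stack"))
  tr <- apply(video$frames, 3, sum)
  pos <- tr[tr > 0]
  dr <- if (length(pos)) max(tr) / min(pos) else NA_real_
  list(trace = tr, dynamic_range = dr,
       dr_definition = "max(ensemble)/min positive(ensemble)")
}

#' Evaluate a demixing result against ground truth
#'
#' Builds the full evaluation report: the source-vs-component correlation
#' table, greedy descending assignment, the square assigned table (nu), the
#' ground-truth-vs-ground-truth table (gamma) in the same order, the
#' diagonal and cross-talk summaries over a subset, and the spatial
#' fingerprint correlations.
#'
#' @param result a `demix_result` from [demix_video()].
#' @param sources the ground-truth [source_set()].
#' @param subset sources to summarize: `NULL` (all assigned), integer k
#'   (first k in descending order), or an index vector into the sorted
#'   order.
#' @param gt_index optional subset of ground-truth source indices to
#'   evaluate against (e.g. only target sources); default all.
#' @param scale `"fraction"` (default) or `"percent"` for reported
#'   summaries.
#' @return a list of class `evaluation_report`.
#' @export
evaluate_demix <- function(result, sources, subset = NULL, gt_index = NULL,
                           scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  stopifnot(inherits(result, "demix_result"), inherits(sources, "source_set"))
  gt_index <- gt_index %||% seq_along(sources$traces)
  gt_traces <- sources$traces[gt_index]
  labels <- paste0("GT", gt_index)
  comp_traces <- lapply(seq_len(result$rank), function(j) result$temporal[j, ])

  gt_nmf_raw <- suppressWarnings(
    pearson_table(gt_traces, comp_traces, labels_a = labels))
  asg <- assign_and_sort(gt_nmf_raw)
  nu <- assigned_table(gt_nmf_raw, asg)

  gt_sorted <- gt_traces[asg$pairs$gt]
  gamma <- suppressWarnings(
    pearson_table(gt_sorted, gt_sorted,
                  labels_a = rownames(nu), labels_b = rownames(nu)))

  dsum <- diagonal_summary(nu, subset = subset)
  csum <- if (nrow(nu) >= 2) {
    crosstalk_summary(nu, gamma, subset = subset)
  } else NULL
  fmatch <- fingerprint_match(sources$fingerprints[gt_index],
                              result$spatial, asg)

  rep <- list(gt_nmf = gt_nmf_raw, nu = nu, gt_gt = gamma,
              assignment = asg, diagonal = dsum, crosstalk = csum,
              fingerprint_correlations = fmatch,
              n_sources = length(gt_index), gt_index = gt_index,
              scale = scale)
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  mult <- if (x$scale == "percent") 100 else 1
  unit <- if (x$scale == "percent") "%" else ""
  cat(sprintf("evaluation over %d sources, %d assigned\n",
              x$n_sources, nrow(x$assignment$pairs)))
  cat(sprintf("  delta_avg = %.1f%s (sigma %.1f%s) over %d sources\n",
              mult * x$diagonal$delta_avg, unit,
              mult * x$diagonal$sigma_delta, unit,
              length(x$diagonal$subset)))
  if (!is.null(x$crosstalk)) {
    cat(sprintf("  zeta_avg  = %.2f%s (sigma %.2f%s)\n",
                mult * x$crosstalk$zeta_avg, unit,
                mult * x$crosstalk$sigma_zeta, unit))
  }
  invisible(x)
}
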