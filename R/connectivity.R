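# ROI time-series connectivity: soft ICA cleanup, discrete-cosine
# high-pass filtering, group overlap masks, first-eigenvariate
# extraction and Fisher-z ROI-pair correlations.

#' Soft ICA cleanup of voxel time series
#'
#' Three steps: (1) residualize voxels and component time courses on the
#' motion regressors (with intercept); (2) regress each voxel's time
#' course on ALL component time courses jointly; (3) subtract only the
#' noise components times their fitted coefficients. Variance shared
#' between signal and noise components is retained (hence "soft").
#' With every component labelled noise this equals the full component
#' regression residual; with none labelled it equals motion-only
#' residualization.
#'
#' @param voxel_ts voxels-by-time matrix.
#' @param component_ts time-by-K component matrix.
#' @param noise_labels indices (or logical) of noise components.
#' @param motion optional time-by-M motion regressor matrix.
#' @return cleaned voxels-by-time matrix.
#' @export
soft_ica_cleanup <- function(voxel_ts, component_ts, noise_labels,
                             motion = NULL) {
  voxel_ts <- as.matrix(voxel_ts)
  C <- as.matrix(component_ts)
  N <- ncol(voxel_ts)
  if (nrow(C) != N)
    stop("components and voxels must share the timepoint count")
  if (is.logical(noise_labels)) noise_labels <- which(noise_labels)
  if (length(noise_labels) && (max(noise_labels) > ncol(C) || min(noise_labels) < 1))
    stop("noise_labels must index the component set")
  X <- if (is.null(motion)) matrix(1, N, 1) else cbind(1, as.matrix(motion))
  Vr <- t(stats::lm.fit(X, t(voxel_ts))$residuals)
  Cr <- stats::lm.fit(X, C)$residuals
  qrC <- qr(Cr)
  if (qrC$rank < ncol(Cr)) {
    dropped <- setdiff(seq_len(ncol(Cr)), qrC$pivot[seq_len(qrC$rank)])
    nm <- if (!is.null(colnames(C))) colnames(C)[dropped] else dropped
    stop("component matrix is rank deficient; collinear component(s): ",
         paste(nm, collapse = ", "))
  }
  if (length(noise_labels) == 0) return(Vr)
  B <- qr.coef(qrC, t(Vr))            # K x voxels, all components jointly
  Vr - t(Cr[, noise_labels, drop = FALSE] %*%
           B[noise_labels, , drop = FALSE])
}

#' High-pass filter by discrete-cosine basis regression
#'
#' Removes fluctuations slower than the cutoff by regressing out a
#' discrete-cosine set spanning periods longer than `1/cutoff_hz`
#' (plus the constant), the approach used in the SPM lineage. Output has
#' mean approximately zero.
#'
#' @param ts numeric vector, or voxels-by-time matrix.
#' @param cutoff_hz cutoff frequency (default 0.01 Hz).
#' @param tr_seconds sampling interval.
#' @export
highpass <- function(ts, cutoff_hz = 0.01, tr_seconds) {
  vec <- is.null(dim(ts))
  M <- if (vec) matrix(ts, nrow = 1) else as.matrix(ts)
  N <- ncol(M)
  if (cutoff_hz >= 1 / (2 * tr_seconds))
    stop("cutoff must be below the Nyquist frequency")
  K <- floor(2 * N * tr_seconds * cutoff_hz)
  tt <- seq_len(N) - 1
  basis <- cbind(1, if (K >= 1)
    sapply(seq_len(K), function(k) cos(pi * (2 * tt + 1) * k / (2 * N))))
  out <- t(stats::lm.fit(basis, t(M))$residuals)
  if (vec) as.numeric(out) else out
}

#' Group overlap mask
#'
#' Keeps a voxel iff it is present in at least `min_frac` of the
#' individual masks (inclusive, so exactly 50% is kept at the default).
#'
#' @param masks list of logical vectors/arrays on a common grid.
#' @param min_frac minimum fraction of masks containing the voxel.
#' @return logical mask of the common shape.
#' @export
group_overlap_mask <- function(masks, min_frac = 0.5) {
  if (length(masks) == 0) stop("empty mask list")
  dims <- lapply(masks, function(m) dim(m) %||% length(m))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("masks must share a common grid")
  acc <- Reduce(`+`, lapply(masks, function(m) m * 1))
  out <- acc / length(masks) >= min_frac
  if (!is.null(dim(masks[[1]]))) dim(out) <- dim(masks[[1]])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' First eigenvariate of a voxel-by-time matrix
#'
#' The leading principal time course: voxels are centered (and by
#' default standardized to unit variance, so high-variance voxels do not
#' dominate), the first right singular vector is scaled by its singular
#' value over the square root of the voxel count, and the sign is
#' aligned so the result correlates non-negatively with the mean voxel
#' time course. Downstream correlations are invariant to the scaling
#' convention.
#'
#' @param mat voxels-by-time matrix, at least 2 voxels.
#' @param standardize scale each voxel to unit variance first.
#' @return numeric time course (length = timepoints).
#' @export
first_eigenvariate <- function(mat, standardize = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 voxels")
  mat <- sweep(mat, 1, rowMeans(mat))
  sds <- sqrt(rowSums(mat^2) / (ncol(mat) - 1))
  if (all(sds == 0)) stop("zero-variance matrix")
  if (standardize) {
    keep <- sds > 0
    mat <- mat[keep, , drop = FALSE] / sds[keep]
  }
  sv <- svd(mat, nu = 0, nv = 1)
  v <- sv$v[, 1] * sv$d[1] / sqrt(nrow(mat))
  if (cor(v, colMeans(mat)) < 0) v <- -v
  v
}

#' ROI-pair connectivity across runs
#'
#' Pearson correlation between two ROI-representative time courses per
#' run, Fisher z per run, and the run-averaged z.
#'
#' @param tsA,tsB lists (one element per run) of numeric time courses.
#' @return object of class `roi_connectivity`: `pearson_r`, `fisher_z`
#'   (per run) and `mean_z`.
#' @export
roi_connectivity <- function(tsA, tsB) {
  if (is.numeric(tsA)) tsA <- list(tsA)
  if (is.numeric(tsB)) tsB <- list(tsB)
  if (length(tsA) != length(tsB)) stop("run counts differ")
  r <- mapply(function(a, b) {
    if (length(a) != length(b)) stop("timepoint counts differ")
    cor(a, b)
  }, tsA, tsB)
  if (any(abs(r) >= 1))
    stop("|r| = 1: degenerate input, Fisher z undefined")
  z <- atanh(r)
  structure(list(pearson_r = r, fisher_z = z, mean_z = mean(z)),
            class = "roi_connectivity")
}

#' @export
print.roi_connectivity <- function(x, ...) {
  cat("ROI connectivity: r =", paste(round(x$pearson_r, 3), collapse = ", "),
      "| mean Fisher z =", round(x$mean_z, 4), "\n")
  invisible(x)
}

#' Run the connectivity chain for one subject
#'
#' Soft ICA cleanup, high-pass filtering and eigenvariate extraction per
#' ROI and run, then the run-averaged Fisher-z connectivity for a pair
#' of ROIs.
#'
#' @param runs list (one element per run) with `ts` (named list of
#'   voxels-by-time matrices), `components`, `noise_labels`, `motion`,
#'   `tr_seconds`, as produced by [gen_roi_timeseries()].
#' @param pair character vector of the two ROI names.
#' @param cutoff_hz high-pass cutoff.
#' @param cleanup apply [soft_ica_cleanup()].
#' @return an [roi_connectivity()] result.
#' @export
subject_connectivity <- function(runs, pair = c("EV", "DLPFC"),
                                 cutoff_hz = 0.01, cleanup = TRUE) {
  eig <- lapply(runs, function(run) {
    lapply(run$ts[pair], function(v) {
      if (cleanup)
        v <- soft_ica_cleanup(v, run$components, run$noise_labels, run$motion)
      v <- highpass(v, cutoff_hz, run$tr_seconds)
      first_eigenvariate(v)
    })
  })
  roi_connectivity(lapply(eig, `[[`, pair[1]), lapply(eig, `[[`, pair[2]))
}
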