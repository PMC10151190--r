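#' Detrend and bandpass-filter ROI time series
#'
#' Removes the linear trend from each ROI's series, then applies an ideal
#' (rectangular) frequency-domain bandpass: Fourier components outside
#' `[low_hz, high_hz]` are zeroed. The ideal filter keeps in-band amplitudes
#' essentially unchanged while removing out-of-band power, matching the
#' conventional resting-state conditioning step (default band 0.01-0.08 Hz).
#'
#' @param series K x T matrix (rows = ROIs).
#' @param tr_seconds Sampling interval.
#' @param low_hz,high_hz Passband edges; `0 < low < high < ` Nyquist.
#' @return Filtered K x T matrix.
#' @export
detrend_bandpass <- function(series, tr_seconds = 2, low_hz = 0.01,
                             high_hz = 0.08) {
  series <- as.matrix(series)
  T_ <- ncol(series)
  if (T_ < 16L) stop("need at least 16 timepoints", call. = FALSE)
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("infeasible band: need 0 < low < high < Nyquist", call. = FALSE)
  }
  tt <- seq_len(T_) - (T_ + 1) / 2
  beta <- as.numeric(series %*% tt) / sum(tt^2)
  x <- series - rowMeans(series) - outer(beta, tt)
  fr <- (seq_len(T_) - 1) / (T_ * tr_seconds)
  fr <- pmin(fr, 1 / tr_seconds - fr)  # fold to physical frequency
  keep <- fr >= low_hz & fr <= high_hz
  sp <- t(stats::mvfft(t(x)))
  sp[, !keep] <- 0
  Re(t(stats::mvfft(t(sp), inverse = TRUE))) / T_
}

#' Mean ROI time courses from a 4D volume
#'
#' @param volume4d A 4D array (x, y, z, t).
#' @param atlas Integer-labelled parcellation ([volume3d()] or array).
#' @return K x T matrix of per-ROI mean series.
#' @export
roi_timeseries <- function(volume4d, atlas) {
  a <- vol_data(atlas)
  d4 <- dim(volume4d)
  if (!identical(d4[1:3], dim(a))) stop("atlas and volumes are not on one grid", call. = FALSE)
  K <- max(a)
  counts <- tabulate(a, K)
  if (any(counts == 0L)) stop("atlas has empty ROI label(s)", call. = FALSE)
  mat <- matrix(volume4d, prod(d4[1:3]), d4[4])
  rowsum(mat, as.vector(a)) / counts
}

#' Functional connectivity matrix (Fisher z)
#'
#' Pairwise Pearson correlations between ROI series, clamped to
#' `+/-(1 - 1e-7)` and Fisher z-transformed (`atanh`); the diagonal is zero.
#' Zero-variance rows are flagged as masked and their pairs set to zero.
#'
#' @param series K x T matrix.
#' @return K x K symmetric z matrix with attribute `masked_rois` (integer ids
#'   of degenerate ROIs) and `modality = "FC"`.
#' @export
fc_matrix <- function(series) {
  series <- as.matrix(series)
  v <- apply(series, 1, stats::var)
  degen <- which(!(v > 0))
  r <- suppressWarnings(stats::cor(t(series)))
  if (length(degen)) {
    r[degen, ] <- 0
    r[, degen] <- 0
  }
  r <- pmax(pmin(r, 1 - 1e-7), -(1 - 1e-7))
  z <- atanh(r)
  diag(z) <- 0
  attr(z, "masked_rois") <- as.integer(degen)
  attr(z, "modality") <- "FC"
  z
}

# ROI ids touched by >= 1 lesioned voxel.
lesion_overlap_rois <- function(lesion_mask, atlas) {
  a <- vol_data(atlas)
  m <- vol_data(lesion_mask) != 0
  sort(unique(a[m & a > 0]))
}

#' Zero functional connections of lesion-overlapping ROIs
#'
#' Any ROI overlapping the subject's lesion by at least one voxel (regardless
#' of amount) has every incident pair set to zero, so no connection emanates
#' from lesioned tissue.
#'
#' @param fc K x K Fisher-z matrix from [fc_matrix()].
#' @param lesion_mask Binary lesion [volume3d()].
#' @param atlas Parcellation on the same grid.
#' @return The masked matrix; `masked_rois` is extended with the overlapping
#'   ROI ids.
#' @export
lesion_mask_fc <- function(fc, lesion_mask, atlas) {
  hit <- lesion_overlap_rois(lesion_mask, atlas)
  prev <- attr(fc, "masked_rois")
  if (length(hit)) {
    fc[hit, ] <- 0
    fc[, hit] <- 0
  }
  attr(fc, "masked_rois") <- sort(unique(c(prev, hit)))
  attr(fc, "modality") <- "FC"
  fc
}

#' Symmetrize and lesion-mask a structural connectome
#'
#' Averages the two reciprocal connections of a (possibly asymmetric) raw
#' streamline-probability matrix, then zeroes every connection incident to an
#' ROI whose damaged fraction exceeds `damage_thr` (strict `>`).
#'
#' @param raw K x K non-negative matrix (seed x target probabilities).
#' @param lesion_mask Optional binary lesion [volume3d()].
#' @param atlas Parcellation (required when masking).
#' @param damage_thr Damaged-fraction threshold (default 0.95).
#' @return Symmetric K x K matrix with attributes `masked_rois`, `modality =
#'   "SC"`.
#' @export
symmetrize_and_mask_sc <- function(raw, lesion_mask = NULL, atlas = NULL,
                                   damage_thr = 0.95) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("structural connection values must be non-negative", call. = FALSE)
  s <- (raw + t(raw)) / 2
  diag(s) <- 0
  masked <- integer(0)
  if (!is.null(lesion_mask)) {
    if (is.null(atlas)) stop("atlas required for lesion masking", call. = FALSE)
    dmg <- roi_damage_fraction(lesion_mask, atlas)
    masked <- which(dmg > damage_thr)
    if (length(masked)) {
      s[masked, ] <- 0
      s[, masked] <- 0
    }
  }
  attr(s, "masked_rois") <- as.integer(masked)
  attr(s, "modality") <- "SC"
  s
}

#' Vectorize the lower triangle of a connectivity matrix
#'
#' Extracts the strictly-lower-triangle entries in column-major order —
#' (2,1), (3,1), ..., (K,1), (3,2), ... — giving `K(K-1)/2` features per
#' subject in an order that is identical across subjects (K = 200 gives
#' 19,900 features).
#'
#' @param conn Symmetric K x K matrix.
#' @param tol Symmetry tolerance.
#' @return Numeric feature vector of length `K(K-1)/2`.
#' @export
vectorize_lower <- function(conn, tol = 1e-8) {
  conn <- unclass(conn)
  if (!isSymmetric(unname(as.matrix(conn)), tol = tol)) {
    stop("connectivity matrix must be symmetric", call. = FALSE)
  }
  conn[lower.tri(conn)]
}

#' @rdname vectorize_lower
#' @param v Feature vector of length `K(K-1)/2`.
#' @param K Number of ROIs.
#' @export
unvectorize_lower <- function(v, K) {
  if (length(v) != K * (K - 1) / 2) stop("length(v) must be K(K-1)/2", call. = FALSE)
  m <- matrix(0, K, K)
  m[lower.tri(m)] <- v
  m + t(m)
}

#' Feature index to ROI-pair mapping
#'
#' The fixed lower-triangle scan order used by [vectorize_lower()], so model
#' weights map back to ROI pairs deterministically.
#'
#' @param K Number of ROIs.
#' @return Data frame with columns `feature`, `i`, `j` (`i > j`).
#' @export
pair_index_map <- function(K) {
  ij <- which(lower.tri(diag(K)), arr.ind = TRUE)
  data.frame(feature = seq_len(nrow(ij)), i = ij[, 1], j = ij[, 2])
}

#' Build connectivity feature matrices for a synthetic cohort
#'
#' Applies the full per-subject pipeline: for FC, optional
#' detrending/bandpass, Fisher-z correlation, lesion-overlap masking; for SC,
#' reciprocal averaging and >95%-damage masking. Each subject's matrix is
#' vectorized over the fixed lower-triangle order.
#'
#' @param cohort A `synthetic_cohort`.
#' @param modality `"FC"`, `"SC"` or `"FCSC"` (column-concatenated).
#' @param bandpass Apply [detrend_bandpass()] to the time series first.
#' @return Subjects x features matrix with attribute `pair_map`.
#' @export
cohort_features <- function(cohort, modality = c("FC", "SC", "FCSC"),
                            bandpass = TRUE) {
  modality <- match.arg(modality)
  K <- cohort$config$n_rois
  pm <- pair_index_map(K)
  fc_rows <- function() {
    t(vapply(seq_along(cohort$lesions), function(s) {
      ts <- cohort$timeseries$patients[[s]]
      if (bandpass) {
        ts <- detrend_bandpass(ts, cohort$config$tr_seconds)
      }
      z <- fc_matrix(ts)
      z <- lesion_mask_fc(z, cohort$lesions[[s]]$mask, cohort$atlas)
      vectorize_lower(z)
    }, numeric(nrow(pm))))
  }
  sc_rows <- function() {
    t(vapply(seq_along(cohort$lesions), function(s) {
      sc <- symmetrize_and_mask_sc(cohort$sc[[s]], cohort$lesions[[s]]$mask,
                                   cohort$atlas)
      vectorize_lower(sc)
    }, numeric(nrow(pm))))
  }
  X <- switch(modality,
              FC = fc_rows(),
              SC = sc_rows(),
              FCSC = cbind(fc_rows(), sc_rows()))
  attr(X, "pair_map") <- pm
  attr(X, "modality") <- modality
  X
}
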