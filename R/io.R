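#' Write / read a behavioural battery as TSV
#'
#' The TSV holds one row per subject plus a final `maximum` row carrying each
#' test's stated maximum (`NA` where none is stated).
#'
#' @param battery A `battery` object.
#' @param path Output TSV path.
#' @return `write_battery_tsv` returns `path` invisibly; `read_battery_tsv`
#'   returns a `battery` object.
#' @export
write_battery_tsv <- function(battery, path) {
  scores <- as.matrix(battery$scores)
  df <- data.frame(subject = c(sprintf("sub-%03d", seq_len(nrow(scores))),
                               "maximum"),
                   rbind(scores, battery$maxima),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_battery_tsv
#' @export
read_battery_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  is_max <- df$subject == "maximum"
  scores <- as.matrix(df[!is_max, -1, drop = FALSE])
  rownames(scores) <- NULL
  maxima <- as.numeric(df[is_max, -1])
  names(maxima) <- colnames(scores)
  structure(list(scores = scores, maxima = maxima), class = "battery")
}

#' Write a synthetic cohort to disk
#'
#' Lesion masks and abnormality images as NIfTI, the battery as TSV, ROI
#' time series and structural connectomes as per-subject TSV, the atlas as
#' NIfTI and the ground truth as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  for (sub in c("", "lesions", "timeseries", "sc")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE, recursive = TRUE)
  }
  write_nifti_volume(cohort$atlas, file.path(dir, "atlas.nii.gz"))
  for (s in seq_along(cohort$lesions)) {
    m <- cohort$lesions[[s]]
    write_nifti_volume(volume3d(m$mask$data * 1L, m$mask$voxel_mm),
                       file.path(dir, "lesions", sprintf("sub-%03d_mask.nii.gz", s)))
    write_nifti_volume(m$abnormality,
                       file.path(dir, "lesions", sprintf("sub-%03d_abnormality.nii.gz", s)))
    utils::write.table(cohort$timeseries$patients[[s]],
                       file.path(dir, "timeseries", sprintf("sub-%03d.tsv", s)),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(cohort$sc[[s]],
                       file.path(dir, "sc", sprintf("sub-%03d.tsv", s)),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_battery_tsv(cohort$battery, file.path(dir, "battery.tsv"))
  truth <- cohort$truth
  jsonlite::write_json(list(critical_roi_ids = truth$critical_roi_ids,
                            factor_effect_weights = truth$factor_effect_weights,
                            test_loading_matrix = truth$test_loading_matrix,
                            fc_community_assignment = truth$fc_community_assignment,
                            sc_signal_pairs = truth$sc_signal_pairs,
                            sc_latent = truth$sc_latent),
                       file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
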