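# End-to-end feature extraction: recording -> preprocessed signal ->
# named feature vector -> cohort feature matrix.

#' Extract the full QEEG feature vector of one recording
#'
#' Runs the requested feature families on a recording and concatenates
#' them into one named vector: relative power ("RP_<band>_<channel>", 76
#' values), pairwise coherence ("COH_<scheme>_<a>-<b>", 64), spectral
#' entropy ("SPECEN_<channel>", 19) and spectral dispersion entropy
#' ("SPECDE_<channel>", 19).
#'
#' @param rec An \code{eeg_recording}; preprocessed with
#'   \code{\link{preprocess_recording}} first unless \code{preprocess}
#'   is TRUE.
#' @param methods Subset of "power", "coherence", "complexity".
#' @param preprocess Band-pass and resample first (default TRUE).
#' @param rp_bands Bands for relative power (default delta-beta).
#' @param cfg Dispersion configuration for SPECDE.
#' @return Named numeric feature vector.
#' @export
extract_features <- function(rec,
                             methods = c("power", "coherence", "complexity"),
                             preprocess = TRUE,
                             rp_bands = c("delta", "theta", "alpha", "beta"),
                             cfg = dispersion_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (preprocess) rec <- preprocess_recording(rec)
  out <- numeric(0)
  if ("power" %in% methods)
    out <- c(out, .rp_feature_vector(relative_power(rec, bands = rp_bands)))
  if ("coherence" %in% methods)
    out <- c(out, coherence_features(rec))
  if ("complexity" %in% methods)
    out <- c(out, complexity_features(rec, cfg = cfg))
  out
}

#' Feature matrix of a cohort
#'
#' Applies \code{\link{extract_features}} to every recording of a cohort
#' and assembles the subjects x features data frame consumed by
#' \code{\link{screen_features}} and \code{\link{crossval_classify}}.
#'
#' @param cohort A \code{synthetic_cohort}, or a plain list of
#'   \code{eeg_recording} objects with group labels attached.
#' @param ... Passed to \code{\link{extract_features}}.
#' @return Data frame: \code{subject_id}, \code{group}, then one numeric
#'   column per feature (names kept verbatim, including "-").
#' @export
cohort_features <- function(cohort, ...) {
  recs <- if (inherits(cohort, "synthetic_cohort")) cohort$recordings else cohort
  rows <- lapply(recs, extract_features, ...)
  feat_names <- names(rows[[1]])
  mat <- do.call(rbind, rows)
  fm <- data.frame(
    subject_id = vapply(recs, function(r) r$subject_id, character(1)),
    group = vapply(recs, function(r)
      if (is.null(r$group)) NA_character_ else r$group, character(1)),
    stringsAsFactors = FALSE)
  fm <- cbind(fm, as.data.frame(mat, check.names = FALSE))
  rownames(fm) <- NULL
  colnames(fm) <- c("subject_id", "group", feat_names)
  fm
}
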