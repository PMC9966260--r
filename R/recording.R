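#' Construct an EEG recording object
#'
#' The universal container for multichannel EEG in this package: a
#' channels-by-time numeric matrix plus channel names, the sampling rate in
#' Hz, and optional subject metadata.
#'
#' @param samples Numeric matrix, channels in rows, samples in columns.
#' @param channel_names Character vector, one unique name per row.
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id Optional subject identifier string.
#' @param group Optional group label: "normal", "stroke_mci" or
#'   "stroke_dementia".
#' @return An object of class \code{eeg_recording}.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(19 * 250), 19), channels_1020(), fs = 250)
#' rec
eeg_recording <- function(samples, channel_names, fs, subject_id = "",
                          group = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (length(channel_names) != nrow(samples))
    stop("channel_names length (", length(channel_names),
         ") does not match number of sample rows (", nrow(samples), ")")
  if (anyDuplicated(channel_names))
    stop("duplicate channel names: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (!is.null(group)) group <- match.arg(group, eeg_groups())
  dimnames(samples) <- list(channel_names, NULL)
  structure(list(samples = samples,
                 channel_names = as.character(channel_names),
                 fs = as.numeric(fs),
                 subject_id = as.character(subject_id),
                 group = group),
            class = "eeg_recording")
}

#' Diagnostic group levels
#'
#' @return Character vector of the three diagnostic group labels, in
#'   severity order.
#' @export
eeg_groups <- function() c("normal", "stroke_mci", "stroke_dementia")

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording>", if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
      if (!is.null(x$group)) paste0("[", x$group, "]") else "", "\n")
  cat("  ", nrow(x$samples), " channels x ", ncol(x$samples), " samples @ ",
      x$fs, " Hz (", round(ncol(x$samples) / x$fs, 2), " s)\n", sep = "")
  cat("  channels:", paste(x$channel_names, collapse = " "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An \code{eeg_recording}.
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$fs

#' Normalize clinical channel labels onto the 10-20 montage
#'
#' Strips whitespace, "EEG" prefixes and reference suffixes such as
#' "-REF" or "-A1A2", then matches case-insensitively against the
#' canonical 19-channel set. Clinical EDF exports label channels
#' inconsistently ("EEG Fp1-Ref", "FP1", ...); this makes them comparable.
#'
#' @param labels Character vector of raw channel labels.
#' @return Character vector of canonical names, with \code{NA} where a
#'   label does not correspond to any montage electrode.
#' @export
#' @examples
#' normalize_channel_labels(c("EEG Fp1-Ref", "FZ", "ECG"))
normalize_channel_labels <- function(labels) {
  x <- trimws(labels)
  x <- sub("^EEG[ _]*", "", x, ignore.case = TRUE)
  x <- sub("-(REF|A1A2|A1|A2|AVG|LE)$", "", x, ignore.case = TRUE)
  x <- trimws(x)
  canon <- channels_1020()
  canon[match(toupper(x), toupper(canon))]
}

# Reorder a name->row mapping onto the canonical montage, erroring with the
# names of any absent electrodes.
.canonical_order <- function(found_names) {
  canon <- channels_1020()
  idx <- match(canon, found_names)
  if (anyNA(idx))
    stop("recording is missing canonical channel(s): ",
         paste(canon[is.na(idx)], collapse = ", "))
  idx
}

#' Read a multichannel EEG recording
#'
#' Reads an EDF file or a delimited text file and returns an
#' \code{eeg_recording} with channels reordered onto the canonical
#' 19-channel 10-20 montage. Channel labels are normalized with
#' \code{\link{normalize_channel_labels}}; a missing montage electrode is
#' an error naming it.
#'
#' Delimited text may hold one channel per column (header row of channel
#' names) or one channel per row (first field the channel name); the
#' orientation is auto-detected by matching the first line against the
#' montage. The sampling rate must be supplied via \code{fs} for text
#' input; for EDF it comes from the file header.
#'
#' @param path Path to the file.
#' @param format "edf" or "csv" (any delimited text).
#' @param fs Sampling rate in Hz, required for \code{format = "csv"}.
#' @param sep Field separator for text input (default ",").
#' @param subject_id,group Optional metadata attached to the recording.
#' @return An \code{eeg_recording} with 19 canonical channels.
#' @export
read_recording <- function(path, format = c("csv", "edf"), fs = NULL,
                           sep = ",", subject_id = "", group = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") {
    edf <- read_edf(path)
    rates <- vapply(edf$signals, function(s) s$fs, numeric(1))
    names0 <- vapply(edf$signals, function(s) s$label, character(1))
    canon_names <- normalize_channel_labels(names0)
    keep <- !is.na(canon_names)
    if (length(unique(rates[keep])) > 1L)
      stop("inconsistent per-channel sampling rates in EDF: ",
           paste(unique(rates[keep]), collapse = ", "))
    mat <- do.call(rbind, lapply(edf$signals[keep], function(s) s$data))
    idx <- .canonical_order(canon_names[keep])
    eeg_recording(mat[idx, , drop = FALSE], channels_1020(),
                  fs = rates[keep][1],
                  subject_id = if (nzchar(subject_id)) subject_id else edf$patient,
                  group = group)
  } else {
    if (is.null(fs)) stop("fs must be supplied for delimited text input")
    first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
    header_match <- normalize_channel_labels(first)
    if (sum(!is.na(header_match)) >= 2L) {
      # channels in columns, header row of names
      tab <- utils::read.table(path, header = TRUE, sep = sep,
                               check.names = FALSE)
      canon_names <- normalize_channel_labels(colnames(tab))
      keep <- which(!is.na(canon_names))
      mat <- t(as.matrix(tab[, keep, drop = FALSE]))
      idx <- .canonical_order(canon_names[keep])
    } else {
      # channels in rows, first field the channel name
      tab <- utils::read.table(path, header = FALSE, sep = sep,
                               stringsAsFactors = FALSE)
      canon_names <- normalize_channel_labels(tab[[1]])
      keep <- which(!is.na(canon_names))
      mat <- as.matrix(tab[keep, -1, drop = FALSE])
      storage.mode(mat) <- "double"
      idx <- .canonical_order(canon_names[keep])
    }
    eeg_recording(mat[idx, , drop = FALSE], channels_1020(), fs = fs,
                  subject_id = subject_id, group = group)
  }
}

#' Write an EEG recording to disk
#'
#' Inverse of \code{\link{read_recording}}: writes either an EDF file or a
#' delimited text file with channels in columns and a header row of
#' channel names.
#'
#' @param rec An \code{eeg_recording}.
#' @param path Output path.
#' @param format "edf" or "csv".
#' @param sep Field separator for text output.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "edf"), sep = ",") {
  format <- match.arg(format)
  if (format == "edf") {
    write_edf(path, rec$samples, rec$channel_names, rec$fs,
              patient = rec$subject_id)
  } else {
    tab <- as.data.frame(t(rec$samples))
    colnames(tab) <- rec$channel_names
    utils::write.table(tab, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  }
  invisible(path)
}
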