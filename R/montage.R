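#' The canonical 19-channel 10-20 montage
#'
#' Returns the ordered electrode names of the standard 19-channel 10-20
#' scalp montage used throughout the package. Odd trailing digits denote
#' left-hemisphere sites, even digits right-hemisphere sites, and a trailing
#' "z" the midline.
#'
#' @return Character vector of 19 electrode names in canonical order.
#' @export
#' @examples
#' channels_1020()
channels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Hemisphere membership of a 10-20 electrode
#'
#' @param channel Character vector of electrode names.
#' @return Character vector with values "left", "right" or "midline".
#' @export
#' @examples
#' channel_hemisphere(c("Fp1", "Cz", "T6"))
channel_hemisphere <- function(channel) {
  last <- substring(channel, nchar(channel))
  out <- rep("midline", length(channel))
  lateral <- tolower(last) != "z"
  out[lateral] <- ifelse(as.integer(last[lateral]) %% 2L == 1L,
                         "left", "right")
  out
}

# Lateral electrodes per hemisphere in the anchor order used by the
# intrahemispheric pair tables (frontal to occipital).
.left_lateral  <- c("Fp1", "F3", "F7", "C3", "T3", "P3", "T5", "O1")
.right_lateral <- c("Fp2", "F4", "F8", "C4", "T4", "P4", "T6", "O2")

.all_unordered_pairs <- function(chs) {
  n <- length(chs)
  a <- character(0); b <- character(0)
  for (i in seq_len(n - 1L)) {
    a <- c(a, rep(chs[i], n - i))
    b <- c(b, chs[(i + 1L):n])
  }
  cbind(a, b, deparse.level = 0)
}

#' Build an electrode-pair scheme for coherence analysis
#'
#' Constructs one of the three canonical pair schemes used for EEG
#' coherence: the 8 homologous interhemispheric pairs, or the 28 pairs
#' forming the complete graph over the 8 lateral electrodes of one
#' hemisphere. Midline electrodes (Fz, Cz, Pz) never appear in any scheme.
#'
#' @param name One of "interhemispheric", "left_intra", "right_intra".
#' @return An object of class \code{pair_scheme}: a list with elements
#'   \code{name} and \code{pairs} (an n x 2 character matrix, each row one
#'   electrode pair in table order).
#' @export
#' @examples
#' build_pair_scheme("interhemispheric")$pairs
build_pair_scheme <- function(name = c("interhemispheric", "left_intra", "right_intra")) {
  name <- match.arg(name)
  # interhemispheric: homologous pairs Fp1-Fp2, F3-F4, F7-F8, C3-C4,
  # T3-T4, P3-P4, T5-T6, O1-O2; intra: complete graph on one hemisphere's
  # lateral electrodes, anchors frontal to occipital.
  pairs <- switch(name,
    interhemispheric = cbind(.left_lateral, .right_lateral, deparse.level = 0),
    left_intra  = .all_unordered_pairs(.left_lateral),
    right_intra = .all_unordered_pairs(.right_lateral)
  )
  dimnames(pairs) <- NULL
  structure(list(name = name, pairs = pairs), class = "pair_scheme")
}

#' @export
print.pair_scheme <- function(x, ...) {
  cat("<pair_scheme> ", x$name, ": ", nrow(x$pairs), " pairs\n", sep = "")
  cat(paste0(x$pairs[, 1], "-", x$pairs[, 2], collapse = ", "), "\n")
  invisible(x)
}

# Short labels used in coherence feature names.
.scheme_label <- function(name) {
  switch(name,
         interhemispheric = "inter",
         left_intra = "left",
         right_intra = "right",
         stop("unknown scheme: ", name))
}
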