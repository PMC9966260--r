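# Band-averaged magnitude-squared coherence per electrode pair. One scalar
# per pair: the unweighted mean of the MSC bins across the analysis band
# (1-30 Hz by default). Segment FFTs are computed once per channel and
# reused across the 64 pairs.

#' Coherence features over electrode-pair schemes
#'
#' Computes Welch magnitude-squared coherence for every pair of each
#' requested scheme and reduces it to one scalar per pair: the mean of the
#' coherence bins with frequency in [\code{f_lo}, \code{f_hi}]. With the
#' three canonical schemes this yields 8 interhemispheric + 28 left + 28
#' right = 64 features named "COH_<scheme>_<a>-<b>".
#'
#' @param rec A preprocessed \code{eeg_recording}.
#' @param schemes List of \code{pair_scheme} objects (default: all three
#'   canonical schemes).
#' @param f_lo,f_hi Analysis band in Hz (defaults 1 and 30).
#' @param window_s,overlap Welch segmentation (defaults 2 s, 0.75).
#' @return Named numeric vector of band-mean coherences in [0, 1].
#' @export
coherence_features <- function(rec,
                               schemes = lapply(c("interhemispheric",
                                                  "left_intra",
                                                  "right_intra"),
                                                build_pair_scheme),
                               f_lo = 1, f_hi = 30,
                               window_s = 2, overlap = 0.75) {
  needed <- unique(unlist(lapply(schemes, function(s) as.vector(s$pairs))))
  missing <- setdiff(needed, rec$channel_names)
  if (length(missing))
    stop("recording lacks channel(s) required by pair schemes: ",
         paste(missing, collapse = ", "))
  # per-channel windowed segment FFTs, shared across pairs
  fs <- rec$fs
  specs <- lapply(needed, function(chn) {
    sg <- .welch_segments(rec$samples[chn, ] - mean(rec$samples[chn, ]),
                          fs, window_s, overlap)
    if (sg$nseg < 2L)
      stop("coherence needs at least 2 Welch segments per channel")
    os <- .one_sided(sg$L, fs)
    sg$fft[seq_len(os$nf), , drop = FALSE]
  })
  names(specs) <- needed
  os <- .one_sided(round(window_s * fs), fs)
  band <- os$freqs >= f_lo & os$freqs <= f_hi
  out <- numeric(0)
  for (s in schemes) {
    lab <- .scheme_label(s$name)
    for (k in seq_len(nrow(s$pairs))) {
      a <- s$pairs[k, 1]; b <- s$pairs[k, 2]
      fa <- specs[[a]]; fb <- specs[[b]]
      pxy <- rowMeans(fa * Conj(fb))
      pxx <- rowMeans(Mod(fa)^2)
      pyy <- rowMeans(Mod(fb)^2)
      coh <- Mod(pxy)^2 / (pxx * pyy)
      coh[!is.finite(coh)] <- 0
      val <- mean(pmin(pmax(coh[band], 0), 1))
      out[paste0("COH_", lab, "_", a, "-", b)] <- val
    }
  }
  out
}
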