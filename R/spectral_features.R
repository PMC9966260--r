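# Relative band power: DB2 wavelet band segmentation composed with Welch
# spectral estimation. Each channel is split into band components, the
# absolute power of each component is integrated from its Welch PSD over
# the band's nominal interval, and powers are normalized across the
# included bands.

# Integrate a Welch PSD over [f_lo, f_hi) (density * df), optionally
# deconvolving a band component's own power response so the result is an
# unbiased estimate of the underlying signal's in-band power.
.band_power <- function(psd, f_lo, f_hi, node = NULL, fs = NULL) {
  sel <- psd$freqs >= f_lo & psd$freqs < f_hi
  df <- psd$freqs[2] - psd$freqs[1]
  p <- psd$power[sel]
  if (!is.null(node))
    p <- p / .band_response2(psd$freqs, fs, node)[sel]
  sum(p) * df
}

#' Relative band power per channel
#'
#' For every channel: split into wavelet band components
#' (\code{\link{wavelet_band_split}}), estimate each component's absolute
#' power by Welch integration over the band's nominal interval,
#' deconvolving the component's own power response bin by bin (DB2
#' responses are not brick-wall; the components are alias-free, so this
#' division makes in-band power unbiased for any spectral shape), and
#' normalize by the summed power of the included bands. Each channel's
#' relative powers therefore sum to 1, making the feature scale-free
#' (amplitude differences across subjects cancel).
#'
#' Gamma is excluded by default: with a 1-30 Hz band-pass upstream the
#' 30-60 Hz band holds only noise, leaving 4 bands x 19 channels = 76
#' features.
#'
#' @param rec A preprocessed \code{eeg_recording} at 240 Hz.
#' @param bands Included bands (default delta, theta, alpha, beta).
#' @param window_s,overlap Welch segmentation (defaults 2 s, 0.75).
#' @return Numeric matrix channels x bands of values in [0, 1], rows
#'   summing to 1; attribute \code{feature_names} gives the flattened
#'   "RP_<band>_<channel>" naming.
#' @export
relative_power <- function(rec, bands = c("delta", "theta", "alpha", "beta"),
                           window_s = 2, overlap = 0.75) {
  bands <- match.arg(bands, c("delta", "theta", "alpha", "beta", "gamma"),
                     several.ok = TRUE)
  defs <- band_definitions(fs = rec$fs)
  defs <- defs[match(bands, defs$band), , drop = FALSE]
  nch <- nrow(rec$samples)
  out <- matrix(NA_real_, nch, length(bands),
                dimnames = list(rec$channel_names, bands))
  for (ch in seq_len(nch)) {
    x <- rec$samples[ch, ]
    if (all(x == 0))
      stop("relative power undefined for all-zero channel ",
           rec$channel_names[ch])
    comp <- wavelet_band_split(x, fs = rec$fs)
    p_abs <- vapply(seq_along(bands), function(b) {
      psd <- welch_psd(comp[[bands[b]]], rec$fs, window_s, overlap)
      .band_power(psd, defs$f_lo[b], defs$f_hi[b], defs$node[b], rec$fs)
    }, numeric(1))
    out[ch, ] <- p_abs / sum(p_abs)
  }
  attr(out, "feature_names") <- as.vector(t(outer(
    rownames(out), colnames(out), function(chn, bn) paste0("RP_", bn, "_", chn))))
  out
}

# Flatten a relative_power matrix into the named feature vector
# RP_<band>_<channel>, channel-major in montage order.
.rp_feature_vector <- function(rp) {
  v <- as.vector(t(rp))   # per channel: its bands in order
  names(v) <- as.vector(vapply(rownames(rp),
    function(chn) paste0("RP_", colnames(rp), "_", chn),
    character(ncol(rp))))
  v
}
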