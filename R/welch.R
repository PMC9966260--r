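# Welch cross-/auto-spectral estimation. Segments are Hamming-windowed with
# 75% overlap by default; one-sided density scaling so that
# sum(power) * df ~ variance (Parseval).

# Segment a series into the windowed segment matrix and FFT it.
# Returns complex matrix [nfft x nseg] and the window used.
.welch_segments <- function(x, fs, window_s, overlap) {
  L <- round(window_s * fs)
  n <- length(x)
  if (n < L)
    stop("series of length ", n, " is shorter than one Welch window (",
         L, " samples)")
  step <- max(1L, round(L * (1 - overlap)))
  nseg <- floor((n - L) / step) + 1L
  w <- signal::hamming(L)
  idx <- outer(seq_len(L), (seq_len(nseg) - 1L) * step, "+")
  seg <- matrix(x[idx], nrow = L) * w
  list(fft = stats::mvfft(seg), window = w, L = L, nseg = nseg)
}

# One-sided frequency grid and bin-doubling weights for an L-point FFT.
.one_sided <- function(L, fs) {
  nf <- floor(L / 2) + 1L
  freqs <- (seq_len(nf) - 1L) * fs / L
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  list(freqs = freqs, dbl = dbl, nf = nf)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the series is split into
#' Hamming-windowed segments of \code{window_s} seconds with fractional
#' \code{overlap}, each segment's periodogram is computed, and the
#' segment average forms the estimate. One-sided density scaling (power
#' per Hz), so \code{sum(power) * df} approximates the series variance.
#'
#' @param x Numeric series (one channel).
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds (default 2).
#' @param overlap Fractional segment overlap in [0, 1) (default 0.75).
#' @param demean Subtract the series mean first (default TRUE).
#' @return An object of class \code{psd_estimate}: list with \code{freqs}
#'   (Hz, 0 to fs/2), \code{power} (density, >= 0), \code{window_s},
#'   \code{overlap}, \code{n_segments}, \code{fs}.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 30, by = 1 / 240))
#' p <- welch_psd(x, fs = 240)
#' p$freqs[which.max(p$power)]  # 10 Hz
welch_psd <- function(x, fs, window_s = 2, overlap = 0.75, demean = TRUE) {
  if (demean) x <- x - mean(x)
  sg <- .welch_segments(x, fs, window_s, overlap)
  os <- .one_sided(sg$L, fs)
  scale <- 1 / (fs * sum(sg$window^2))
  pxx <- rowMeans(Mod(sg$fft[seq_len(os$nf), , drop = FALSE])^2) * scale * os$dbl
  structure(list(freqs = os$freqs, power = pxx, window_s = window_s,
                 overlap = overlap, n_segments = sg$nseg, fs = fs),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat("<psd_estimate> ", length(x$freqs), " bins, 0-", max(x$freqs),
      " Hz (df = ", signif(x$freqs[2], 4), " Hz), ", x$n_segments,
      " segments of ", x$window_s, " s\n", sep = "")
  invisible(x)
}

# Averaged one-sided cross-spectral density of two equal-length series
# (complex), plus the two auto-spectra, sharing one segmentation.
.welch_cross <- function(x, y, fs, window_s, overlap) {
  stopifnot(length(x) == length(y))
  sx <- .welch_segments(x - mean(x), fs, window_s, overlap)
  sy <- .welch_segments(y - mean(y), fs, window_s, overlap)
  os <- .one_sided(sx$L, fs)
  ix <- sx$fft[seq_len(os$nf), , drop = FALSE]
  iy <- sy$fft[seq_len(os$nf), , drop = FALSE]
  list(freqs = os$freqs,
       pxy = rowMeans(ix * Conj(iy)),
       pxx = rowMeans(Mod(ix)^2),
       pyy = rowMeans(Mod(iy)^2),
       n_segments = sx$nseg)
}

#' Magnitude-squared coherence of two series
#'
#' Welch-averaged magnitude-squared coherence
#' \eqn{C_{xy}(f) = |P_{xy}(f)|^2 / (P_{xx}(f) P_{yy}(f))}, the
#' frequency-resolved linear coupling of two signals, in [0, 1] at every
#' bin. At least two segments are required: single-segment coherence is
#' identically 1 regardless of the signals.
#'
#' @param x,y Equal-length numeric series.
#' @param fs Sampling rate in Hz.
#' @param window_s,overlap Welch segmentation (defaults 2 s, 0.75).
#' @return List with \code{freqs} (Hz) and \code{coherence} (values in
#'   [0, 1]), plus \code{n_segments}.
#' @export
msc <- function(x, y, fs, window_s = 2, overlap = 0.75) {
  cs <- .welch_cross(x, y, fs, window_s, overlap)
  if (cs$n_segments < 2L)
    stop("coherence needs at least 2 Welch segments; a single segment is ",
         "degenerate (identically 1). Use a longer series or shorter window.")
  coh <- Mod(cs$pxy)^2 / (cs$pxx * cs$pyy)
  coh[!is.finite(coh)] <- 0      # bins with zero power in either signal
  coh <- pmin(pmax(coh, 0), 1)
  list(freqs = cs$freqs, coherence = coh, n_segments = cs$n_segments)
}
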