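# Daubechies-2 wavelet band segmentation. A 5-level DB2 multiresolution
# analysis (maximal-overlap / undecimated form) splits a 240 Hz series into
# same-length band components whose dyadic frequency supports are the
# classical EEG rhythms (A5 delta, D5 theta, D4 alpha, D3 beta, D2 gamma).
# The MRA is evaluated in the frequency domain: the magnitude responses of
# the analysis/synthesis filter cascades form an exact partition of unity,
# so the components are alias-free, carry zero phase, and sum exactly back
# to the input. Mirror extension handles the boundaries symmetrically.

# Orthonormal DB2 (4-tap) scaling filter; wavelet filter by the quadrature
# mirror relation h[n] = (-1)^n g[L-1-n].
.db2_g <- c(0.4829629131445341, 0.8365163037378079,
            0.2241438680420134, -0.1294095225512604)
.db2_h <- rev(.db2_g) * c(1, -1, 1, -1)

# Frequency response of the MODWT-normalized filter upsampled by 2^l at
# angular frequencies w (radians/sample).
.modwt_response <- function(coefs, l, w) {
  ct <- coefs / sqrt(2)
  as.vector(exp(outer(w * 2^l, 0:3, function(a, b) -1i * a * b)) %*% ct)
}

# Amplitude masks of the level-1..levels details plus final smooth at
# angular frequencies w. Masks are squared cascade magnitudes (analysis
# followed by time-reversed synthesis), and sum to 1 at every frequency.
.mra_masks <- function(w, levels = 5) {
  cascade <- rep(1 + 0i, length(w))
  masks <- vector("list", levels + 1L)
  for (j in seq_len(levels)) {
    masks[[j]] <- Mod(.modwt_response(.db2_h, j - 1, w) * cascade)^2
    cascade <- cascade * .modwt_response(.db2_g, j - 1, w)
  }
  masks[[levels + 1L]] <- Mod(cascade)^2
  names(masks) <- c(paste0("D", seq_len(levels)), paste0("A", levels))
  masks
}

# Cache for masks and response grids (keyed on grid geometry).
.gain_cache <- new.env(parent = emptyenv())

# Power response (mask squared) of a band's component evaluated at the
# given frequency grid; used to deconvolve band-power integration (the
# component PSD is mask^2 times the signal PSD, exactly, because the MRA
# components are alias-free LTI filterings of the input).
.band_response2 <- function(freqs, fs, node, levels = 5) {
  key <- paste("r", fs, levels, node, length(freqs),
               signif(freqs[min(2, length(freqs))], 10))
  if (is.null(.gain_cache[[key]]))
    .gain_cache[[key]] <- .mra_masks(2 * pi * freqs / fs, levels)[[node]]^2
  .gain_cache[[key]]
}

#' Dyadic wavelet band definitions
#'
#' The EEG band edges induced by a \code{levels}-deep dyadic decomposition
#' at sampling rate \code{fs}: the level-k detail spans
#' [fs / 2^(k+1), fs / 2^k] Hz and the final approximation spans
#' [0, fs / 2^(levels+1)]. At fs = 240 Hz and 5 levels this yields
#' delta 0-3.75 (A5), theta 3.75-7.5 (D5), alpha 7.5-15 (D4),
#' beta 15-30 (D3) and gamma 30-60 (D2).
#'
#' @param fs Sampling rate in Hz (default 240).
#' @param levels Decomposition depth (default 5).
#' @return Data frame with columns \code{band}, \code{node}, \code{f_lo},
#'   \code{f_hi}, ordered from delta upward.
#' @export
band_definitions <- function(fs = 240, levels = 5) {
  ks <- levels:2
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma")[seq_len(length(ks) + 1)],
    node = c(paste0("A", levels), paste0("D", ks)),
    f_lo = c(0, fs / 2^(ks + 1)),
    f_hi = c(fs / 2^(levels + 1), fs / 2^ks),
    stringsAsFactors = FALSE
  )
}

#' Split a series into EEG frequency-band components
#'
#' Five-level DB2 wavelet multiresolution analysis of a 240 Hz series:
#' one same-length reconstructed component per EEG band (delta = A5,
#' theta = D5, alpha = D4, beta = D3, gamma = D2). The components are
#' alias-free and zero-phase, and together with the discarded D1 residual
#' (60-120 Hz, returned as an attribute) they sum exactly back to the
#' input; for signals band-limited below 60 Hz the five named bands alone
#' reconstruct it. DB2 filters are short, so each component's response
#' bleeds beyond its nominal band; downstream band power handles this by
#' integrating over the nominal interval only and calibrating by the
#' in-band response (see \code{\link{relative_power}}).
#'
#' @param x Numeric series sampled at 240 Hz.
#' @param fs Sampling rate; must be 240 (resample first otherwise).
#' @return Named list of numeric series (delta, theta, alpha, beta,
#'   gamma), each \code{length(x)} long, with attribute \code{residual}.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 5, by = 1 / 240))
#' b <- wavelet_band_split(x)
#' sapply(b, function(s) sum(s^2)) / sum(x^2)  # energy mostly in alpha
wavelet_band_split <- function(x, fs = 240) {
  if (fs != 240)
    stop("wavelet band segmentation is defined at fs = 240 Hz; ",
         "resample_to(rec, 240) first (got fs = ", fs, ")")
  n <- length(x)
  xe <- c(x, rev(x))                      # mirror extension
  m <- length(xe)
  key <- paste0("m", m)
  if (is.null(.gain_cache[[key]])) {      # masks depend on length only
    w <- 2 * pi * (seq_len(m) - 1) / m
    .gain_cache[[key]] <- .mra_masks(w, levels = 5)
  }
  masks <- .gain_cache[[key]]
  xf <- stats::fft(xe)
  comp <- lapply(masks, function(mask)
    Re(stats::fft(xf * mask, inverse = TRUE))[seq_len(n)] / m)
  out <- list(delta = comp$A5, theta = comp$D5, alpha = comp$D4,
              beta = comp$D3, gamma = comp$D2)
  attr(out, "residual") <- comp$D1
  out
}
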