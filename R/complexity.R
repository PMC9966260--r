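# Signal-complexity features: spectral entropy (Shannon entropy of the
# normalized Welch PSD, in bits), dispersion entropy (Shannon entropy of
# NCDF-quantized embedding patterns, in nats), and spectral dispersion
# entropy (dispersion entropy applied to the ordered spectral bin series).

#' Dispersion-entropy configuration
#'
#' @param m Embedding (template) length, >= 2 (default 2).
#' @param c Number of quantization classes, >= 2 (default 6).
#' @param d Time delay, >= 1 (default 1).
#' @return An object of class \code{dispersion_config}.
#' @export
dispersion_config <- function(m = 2, c = 6, d = 1) {
  stopifnot(m >= 2, c >= 2, d >= 1)
  structure(list(m = as.integer(m), c = as.integer(c), d = as.integer(d)),
            class = "dispersion_config")
}

#' NCDF class mapping
#'
#' Maps a series to integer classes 1..c: values are passed through the
#' normal cumulative distribution function with the series' own mean and
#' standard deviation, giving y in (0, 1), then quantized with half-up
#' rounding of c*y + 0.5 and clipped to [1, c]. A constant series (zero
#' standard deviation) is degenerate: all values map to class 1 and the
#' result carries \code{attr(, "degenerate") = TRUE}, which downstream
#' dispersion entropy treats as a single repeated pattern (entropy 0).
#'
#' @param x Numeric series of length >= 2.
#' @param c Number of classes.
#' @return Integer vector of classes in 1..c, same length as \code{x}.
#' @export
ncdf_map <- function(x, c = 6) {
  stopifnot(length(x) >= 2)
  s <- stats::sd(x)
  if (s == 0 || !is.finite(s)) {
    z <- rep(1L, length(x))
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  y <- stats::pnorm(x, mean = mean(x), sd = s)
  z <- as.integer(pmin(pmax(floor(c * y + 0.5 + 0.5), 1), c))  # half-up round
  attr(z, "degenerate") <- FALSE
  z
}

#' Dispersion entropy
#'
#' Quantizes the series into \code{cfg$c} classes via
#' \code{\link{ncdf_map}} (unless \code{mapped = TRUE}), forms the
#' embedding vectors \eqn{(z_i, z_{i+d}, ..., z_{i+(m-1)d})} for
#' \eqn{i = 1, ..., N-(m-1)d}, counts the resulting dispersion patterns
#' among the \eqn{c^m} possibilities, and returns the Shannon entropy of
#' the pattern distribution in nats. Values lie in [0, m ln c]; 0 is
#' attained iff a single pattern occurs.
#'
#' @param x Numeric series, or an integer class series in 1..c when
#'   \code{mapped = TRUE}.
#' @param cfg A \code{\link{dispersion_config}} (default m=2, c=6, d=1).
#' @param mapped Set TRUE if \code{x} is already a class series.
#' @return Dispersion entropy in nats, with attribute
#'   \code{pattern_probs}: the named non-zero pattern probabilities.
#' @export
#' @examples
#' dispersion_entropy(rep(c(1, 2), 50), mapped = TRUE)  # ln 2
dispersion_entropy <- function(x, cfg = dispersion_config(), mapped = FALSE) {
  m <- cfg$m; cc <- cfg$c; d <- cfg$d
  n <- length(x)
  n_emb <- n - (m - 1L) * d
  if (n_emb < 1L)
    stop("series of length ", n, " too short for m = ", m, ", d = ", d,
         " (need N - (m-1)d >= 1)")
  if (mapped) {
    z <- as.integer(x)
    if (any(z < 1L | z > cc)) stop("mapped classes must lie in 1..c")
    degenerate <- FALSE
  } else {
    z <- ncdf_map(x, cc)
    degenerate <- isTRUE(attr(z, "degenerate"))
  }
  if (degenerate) {
    out <- 0
    attr(out, "pattern_probs") <- stats::setNames(1, paste(rep(1L, m), collapse = ""))
    return(out)
  }
  # integer pattern code: sum (z_{i+l*d} - 1) * c^l
  code <- integer(n_emb)
  idx <- seq_len(n_emb)
  for (l in 0:(m - 1L)) code <- code + (z[idx + l * d] - 1L) * cc^l
  counts <- table(code)
  p <- as.numeric(counts) / n_emb
  out <- -sum(p * log(p))
  # human-readable pattern labels, digits v0 v1 ... v_{m-1}
  codes <- as.integer(names(counts))
  labs <- vapply(codes, function(cd) {
    paste(((cd %/% cc^(0:(m - 1L))) %% cc) + 1L, collapse = "")
  }, character(1))
  attr(out, "pattern_probs") <- stats::setNames(p, labs)
  out
}

# Shannon entropy of a probability vector (normalizes first).
.shannon <- function(p, base = 2) {
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Spectral entropy
#'
#' Shannon entropy (base 2) of the Welch power spectral density restricted
#' to [\code{f_lo}, \code{f_hi}] and normalized to a probability
#' distribution over bins. High values mean power spread over frequencies
#' (complex, noise-like signal); a single-bin spectrum gives 0 and an
#' exactly flat spectrum over B bins gives log2(B).
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param f_lo,f_hi Analysis band in Hz (defaults 1 and 30).
#' @param window_s,overlap Welch segmentation (defaults 2 s, 0.75).
#' @return Spectral entropy in bits.
#' @export
spectral_entropy <- function(x, fs, f_lo = 1, f_hi = 30,
                             window_s = 2, overlap = 0.75) {
  psd <- welch_psd(x, fs, window_s, overlap)
  sel <- psd$freqs >= f_lo & psd$freqs <= f_hi
  p <- psd$power[sel]
  if (sum(p) <= 0) stop("zero power in [", f_lo, ", ", f_hi, "] Hz band")
  .shannon(p, base = 2)
}

#' Spectral dispersion entropy
#'
#' Dispersion entropy of the spectrum: the Welch PSD bins over
#' [\code{f_lo}, \code{f_hi}], ordered by frequency, are treated as a
#' series and passed through the NCDF class mapping and dispersion-entropy
#' pattern count. Where spectral entropy sees only the bin value
#' distribution, the dispersion patterns are sensitive to the *shape* of
#' the spectrum along frequency. A flat spectrum is degenerate under the
#' NCDF mapping and returns 0.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param cfg A \code{\link{dispersion_config}} (default m=2, c=6, d=1).
#' @param f_lo,f_hi Analysis band in Hz (defaults 1 and 30).
#' @param window_s,overlap Welch segmentation (defaults 2 s, 0.75).
#' @return Spectral dispersion entropy in nats.
#' @export
spectral_dispersion_entropy <- function(x, fs, cfg = dispersion_config(),
                                        f_lo = 1, f_hi = 30,
                                        window_s = 2, overlap = 0.75) {
  psd <- welch_psd(x, fs, window_s, overlap)
  sel <- psd$freqs >= f_lo & psd$freqs <= f_hi
  p <- psd$power[sel]
  if (length(p) < (cfg$m - 1L) * cfg$d + 1L)
    stop("only ", length(p), " spectral bins in band; need at least ",
         (cfg$m - 1L) * cfg$d + 1L, " for m = ", cfg$m, ", d = ", cfg$d)
  as.numeric(dispersion_entropy(p, cfg))
}

#' Per-channel complexity features of a recording
#'
#' @param rec A preprocessed \code{eeg_recording}.
#' @param cfg A \code{\link{dispersion_config}}.
#' @param f_lo,f_hi Analysis band in Hz.
#' @return Named numeric vector: "SPECEN_<channel>" (bits) for every
#'   channel, then "SPECDE_<channel>" (nats).
#' @export
complexity_features <- function(rec, cfg = dispersion_config(),
                                f_lo = 1, f_hi = 30) {
  se <- vapply(rec$channel_names, function(chn)
    spectral_entropy(rec$samples[chn, ], rec$fs, f_lo, f_hi), numeric(1))
  sde <- vapply(rec$channel_names, function(chn)
    spectral_dispersion_entropy(rec$samples[chn, ], rec$fs, cfg, f_lo, f_hi),
    numeric(1))
  stats::setNames(c(se, sde),
                  c(paste0("SPECEN_", rec$channel_names),
                    paste0("SPECDE_", rec$channel_names)))
}
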