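#' Band-pass filter specification
#'
#' Describes the Butterworth band-pass applied before feature extraction:
#' a high-pass and a low-pass section, each specified by passband edge,
#' maximum passband droop and minimum stopband attenuation. Filter orders
#' are derived from these specs by standard Butterworth order estimation.
#'
#' @param f_hp High-pass passband edge in Hz (default 1).
#' @param f_lp Low-pass passband edge in Hz (default 30).
#' @param ripple_db Maximum passband droop in dB (default 1).
#' @param atten_db Minimum stopband attenuation in dB (default 80).
#' @param f_stop_hp,f_stop_lp Stopband edges in Hz (defaults 0.5 and 35).
#' @return An object of class \code{filter_spec}.
#' @export
filter_spec <- function(f_hp = 1, f_lp = 30, ripple_db = 1, atten_db = 80,
                        f_stop_hp = 0.5, f_stop_lp = 35) {
  stopifnot(f_hp > 0, f_lp > f_hp, ripple_db > 0, atten_db > 0,
            f_stop_hp < f_hp, f_stop_lp > f_lp)
  structure(list(f_hp = f_hp, f_lp = f_lp, ripple_db = ripple_db,
                 atten_db = atten_db, f_stop_hp = f_stop_hp,
                 f_stop_lp = f_stop_lp, family = "butterworth"),
            class = "filter_spec")
}

# Butterworth order meeting (ripple_db at f_pass, atten_db at f_stop);
# `ratio` is f_stop/f_pass for low-pass, f_pass/f_stop for high-pass (>1).
.butter_order <- function(ripple_db, atten_db, ratio) {
  eps2 <- 10^(ripple_db / 10) - 1
  as2 <- 10^(atten_db / 10) - 1
  ceiling(log10(as2 / eps2) / (2 * log10(ratio)))
}

# Squared-magnitude Butterworth responses with the passband-edge (ripple)
# cutoff convention: droop is exactly ripple_db at f_pass.
.butter_lp_mag2 <- function(f, f_pass, ripple_db, n) {
  eps2 <- 10^(ripple_db / 10) - 1
  1 / (1 + eps2 * (f / f_pass)^(2 * n))
}

.butter_hp_mag2 <- function(f, f_pass, ripple_db, n) {
  eps2 <- 10^(ripple_db / 10) - 1
  out <- numeric(length(f))
  nz <- f > 0
  out[nz] <- 1 / (1 + eps2 * (f_pass / f[nz])^(2 * n))
  out
}

# Band-pass magnitude response of `spec` on frequency grid f (Hz).
.bandpass_response <- function(f, spec) {
  n_hp <- .butter_order(spec$ripple_db, spec$atten_db, spec$f_hp / spec$f_stop_hp)
  n_lp <- .butter_order(spec$ripple_db, spec$atten_db, spec$f_stop_lp / spec$f_lp)
  sqrt(.butter_hp_mag2(f, spec$f_hp, spec$ripple_db, n_hp) *
       .butter_lp_mag2(f, spec$f_lp, spec$ripple_db, n_lp))
}

# Zero-phase filtering of one series by a real magnitude response:
# even (mirror) extension to length 2N, circular frequency-domain
# multiplication, first N samples kept.
.zero_phase_apply <- function(x, response_fun) {
  n <- length(x)
  xe <- c(x, rev(x))
  m <- length(xe)
  f <- (seq_len(m) - 1) / m           # cycles per sample, two-sided
  f <- pmin(f, 1 - f)                 # fold to [0, 1/2]
  h <- response_fun(f)
  Re(stats::fft(stats::fft(xe) * h, inverse = TRUE)) [seq_len(n)] / m
}

#' Band-pass filter a recording
#'
#' Applies the Butterworth band-pass described by \code{spec} identically
#' to every channel. The filter is applied zero-phase in the frequency
#' domain using the exact analytic Butterworth magnitude response (orders
#' from standard order estimation), with mirror extension at the edges, so
#' no filter phase is injected into any channel and the stopband
#' attenuation meets the spec exactly.
#'
#' @param rec An \code{eeg_recording}.
#' @param spec A \code{\link{filter_spec}} (default: 1-30 Hz, 1 dB / 80 dB).
#' @return The filtered \code{eeg_recording}, same length and channels.
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  if (spec$f_lp >= rec$fs / 2)
    stop("low-pass edge (", spec$f_lp, " Hz) must be below Nyquist (",
         rec$fs / 2, " Hz)")
  fs <- rec$fs
  resp <- function(f_norm) .bandpass_response(f_norm * fs, spec)
  out <- rec
  out$samples <- t(apply(rec$samples, 1, .zero_phase_apply, response_fun = resp))
  rownames(out$samples) <- rec$channel_names
  out
}

#' Resample a recording to a new rate
#'
#' Rational polyphase resampling (e.g. 250 to 240 Hz is the exact ratio
#' 24/25) with the anti-alias filtering of \code{signal::resample}.
#' Duration is preserved to within one sample period.
#'
#' @param rec An \code{eeg_recording}.
#' @param fs_new Target sampling rate in Hz.
#' @return The resampled \code{eeg_recording}.
#' @export
resample_to <- function(rec, fs_new) {
  stopifnot(fs_new > 0)
  if (fs_new == rec$fs) return(rec)
  frac <- .as_ratio(fs_new / rec$fs)
  n_new <- round(ncol(rec$samples) * fs_new / rec$fs)
  res <- t(apply(rec$samples, 1, function(x) {
    y <- signal::resample(x, frac[1], frac[2])
    if (length(y) >= n_new) y[seq_len(n_new)]
    else c(y, rep(y[length(y)], n_new - length(y)))
  }))
  out <- rec
  out$samples <- res
  rownames(out$samples) <- rec$channel_names
  out$fs <- fs_new
  out
}

# Small-denominator rational approximation of a positive ratio.
.as_ratio <- function(r, max_den = 1000L) {
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p >= 1 && abs(p / q - r) < 1e-9) return(c(p, q))
  }
  stop("cannot express resampling ratio ", r, " as a small rational")
}

#' Extract a time epoch from a recording
#'
#' Returns the half-open slice [t_start, t_end) of the recording, e.g. the
#' stimulus phase of a task protocol.
#'
#' @param rec An \code{eeg_recording}.
#' @param t_start,t_end Epoch boundaries in seconds from recording start.
#' @param label Optional epoch label (kept in \code{subject_id} suffix-free
#'   form; informational only).
#' @return The sliced \code{eeg_recording}.
#' @export
extract_epoch <- function(rec, t_start, t_end, label = NULL) {
  dur <- duration_s(rec)
  if (t_start < 0 || t_end > dur + 1e-9 || t_start >= t_end)
    stop("epoch [", t_start, ", ", t_end, ") out of range for a ",
         round(dur, 3), " s recording")
  k0 <- round(t_start * rec$fs) + 1L
  k1 <- round(t_end * rec$fs)
  out <- rec
  out$samples <- rec$samples[, k0:k1, drop = FALSE]
  out
}

#' Standard preprocessing: band-pass then resample
#'
#' The canonical preparation for feature extraction: band-pass at the
#' native rate (default 1-30 Hz Butterworth), then resample to the rate
#' used by the wavelet band segmentation (default 240 Hz).
#'
#' @param rec An \code{eeg_recording} (artifact-free input assumed).
#' @param spec A \code{\link{filter_spec}}.
#' @param fs_target Target rate in Hz (default 240).
#' @return The preprocessed \code{eeg_recording}.
#' @export
preprocess_recording <- function(rec, spec = filter_spec(), fs_target = 240) {
  resample_to(bandpass(rec, spec), fs_target)
}
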