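#' Design a zero-phase FIR filter kernel
#'
#' Hamming-windowed sinc kernel (EEGLAB-style) for low- or high-pass
#' filtering; the high-pass is obtained by spectral inversion of the
#' complementary low-pass, so both are exactly linear-phase (symmetric kernel,
#' even order).
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff_hz -6 dB cutoff frequency (Hz).
#' @param order Filter order (tap count - 1); must be even.
#' @param rate_hz Sampling rate (Hz).
#' @return Numeric kernel of length `order + 1`.
#' @export
#' @examples
#' k <- design_fir("lowpass", 10, 330, 250)
#' length(k)
design_fir <- function(kind = c("lowpass", "highpass"), cutoff_hz, order,
                       rate_hz) {
  kind <- match.arg(kind)
  if (order < 2 || order %% 2 != 0) {
    abort("`order` must be an even integer >= 2 (symmetric kernel).")
  }
  if (cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2) {
    abort("`cutoff_hz` must lie strictly between 0 and the Nyquist frequency.")
  }
  # Hamming-windowed ideal sinc centred on the kernel midpoint; the -6 dB
  # point sits at the cutoff by construction
  m <- order / 2
  i <- seq(-m, m)
  h <- 2 * cutoff_hz / rate_hz * sinc(2 * cutoff_hz / rate_hz * i)
  win <- as.numeric(signal::hamming(order + 1))
  k <- h * win
  k <- k / sum(k)                   # unit DC gain
  if (kind == "highpass") {
    # spectral inversion of the complementary lowpass: exact zero at DC
    k <- -k
    k[m + 1] <- k[m + 1] + 1
  }
  k
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Frequency response magnitude of a kernel
#'
#' @param kernel FIR kernel.
#' @param freq_hz Frequencies to evaluate (Hz).
#' @param rate_hz Sampling rate (Hz).
#' @return `|H(f)|` at `freq_hz`.
#' @export
fir_response <- function(kernel, freq_hz, rate_hz) {
  n <- seq_along(kernel) - 1
  vapply(freq_hz, function(f) {
    Mod(sum(kernel * exp(-2i * pi * f / rate_hz * n)))
  }, numeric(1))
}

#' Apply an FIR kernel with zero net phase
#'
#' Single-pass linear-phase filtering with group-delay compensation: the
#' signal is zero-padded, convolved with the symmetric kernel via FFT, and the
#' integer group delay `order/2` removed, so the output is time-aligned with
#' the input.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param kernel Symmetric FIR kernel (odd length).
#' @return Filtered signal, same shape as `x`.
#' @export
apply_zero_phase <- function(x, kernel) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, apply_zero_phase, kernel = kernel))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  nk <- length(kernel)
  if (length(x) <= nk) abort("signal must be longer than the kernel.")
  delay <- (nk - 1) / 2
  nfft <- nextn(length(x) + nk - 1, 2)
  y <- Re(fft(fft(c(x, numeric(nfft - length(x)))) *
              fft(c(kernel, numeric(nfft - nk))), inverse = TRUE)) / nfft
  y[(delay + 1):(delay + length(x))]
}

#' Band-limit a recording with the standard oddball filters
#'
#' Low-pass at 10 Hz (order 330) followed by high-pass at 0.1 Hz (order 8250),
#' both zero-phase Hamming-windowed sinc filters, applied to every EEG
#' channel. Orders scale with the sampling rate if it differs from 250 Hz.
#'
#' @param rec An `eeg_recording`.
#' @param lowpass_hz,lowpass_order,highpass_hz,highpass_order Filter settings.
#' @return The filtered `eeg_recording`.
#' @export
filter_recording <- function(rec, lowpass_hz = 10, lowpass_order = 330,
                             highpass_hz = 0.1, highpass_order = 8250) {
  lp <- design_fir("lowpass", lowpass_hz, lowpass_order, rec$rate)
  rec$eeg <- apply_zero_phase(rec$eeg, lp)
  if (ncol(rec$eeg) > highpass_order + 1) {
    hp <- design_fir("highpass", highpass_hz, highpass_order, rec$rate)
    rec$eeg <- apply_zero_phase(rec$eeg, hp)
  } else {
    # recording shorter than the high-pass kernel: subtract the channel mean,
    # the DC limit of the same filter
    rec$eeg <- rec$eeg - rowMeans(rec$eeg)
    warn("recording shorter than the high-pass kernel; removed channel means instead.")
  }
  rec
}
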