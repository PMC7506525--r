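#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero phase) to every node column.
#'
#' @param tc A [node_timecourses] object.
#' @param band A [band_spec]; `band$f_hi` must be below the Nyquist rate.
#' @param order Butterworth order (default 4).
#' @return A [node_timecourses] with the band annotation set; same length.
#' @export
bandpass_filter <- function(tc, band, order = 4L) {
  stopifnot(inherits(tc, "node_timecourses"), inherits(band, "band_spec"))
  nyq <- tc$fs / 2
  if (band$f_hi >= nyq)
    stop("bandpass_filter: band upper edge ", band$f_hi,
         " Hz reaches Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, c(band$f_lo, band$f_hi) / nyq, type = "pass")
  out <- apply(tc$data, 2L, function(x) signal::filtfilt(bf, x))
  node_timecourses(out, tc$fs, tc$subject_id, band)
}

# Analytic signal per column via FFT: positive frequencies doubled, negative
# zeroed (Marple's convention; Nyquist/DC bins kept once).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert amplitude envelope
#'
#' Magnitude of the analytic signal per node column: the instantaneous
#' amplitude of a band-limited oscillation.
#'
#' @param tc A [node_timecourses] (band-limited input expected).
#' @return Nonnegative time x node envelope matrix at the input rate.
#' @export
hilbert_envelope <- function(tc) {
  stopifnot(inherits(tc, "node_timecourses"))
  apply(tc$data, 2L, function(x) Mod(analytic_signal(x)))
}

#' Despike, downsample to 1 Hz and trim an envelope
#'
#' Runs a per-column running-median filter, averages over non-overlapping
#' 1-second windows (yielding 1 sample/s) and trims samples from each end
#' to discard filter and edge effects.
#'
#' @param env Time x node envelope matrix at rate `fs`.
#' @param fs Sampling rate of `env` in Hz.
#' @param median_window Running-median width in seconds (default 0.25).
#' @param trim Seconds trimmed from each end after downsampling (default 2).
#' @return Envelope matrix at 1 sample/s, `floor(T/fs) - 2*trim` rows.
#' @export
despike_downsample <- function(env, fs, median_window = 0.25, trim = 2) {
  env <- as.matrix(env)
  n_sec <- floor(nrow(env) / fs)
  if (n_sec - 2 * trim < 10)
    stop("despike_downsample: fewer than 10 s of envelope left after trimming")
  k <- max(3L, as.integer(round(median_window * fs)))
  if (k %% 2L == 0L) k <- k + 1L  # runmed needs odd width
  sm <- apply(env, 2L, function(x) stats::runmed(x, k, endrule = "median"))
  n_use <- n_sec * fs
  grp <- rep(seq_len(n_sec), each = fs)
  ds <- apply(sm[seq_len(n_use), , drop = FALSE], 2L,
              function(x) tapply(x, grp, mean))
  ds <- matrix(ds, nrow = n_sec)
  keep <- seq.int(trim + 1L, n_sec - trim)
  ds[keep, , drop = FALSE]
}
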