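# Periodic Hann window
hannWindow <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Welch power spectral density
#'
#' Mean of Hann-tapered periodograms over 50%-overlapping segments.
#' Used for band powers and channel quality screening; the 125 ms power
#' bins of the TC pipeline use single-segment periodograms instead (32
#' samples at 256 Hz admit no sub-segmentation at 8 Hz resolution).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nfft segment length in samples (power of two recommended).
#' @param overlap fractional overlap between segments.
#' @param demean subtract the segment mean before tapering.
#' @return a data.frame with columns `freq` (Hz) and `psd`.
#' @export
welchPsd <- function(x, fs, nfft = 512L, overlap = 0.5, demean = TRUE) {
  n <- length(x)
  if (n < nfft) stop("series shorter than one Welch segment")
  hop <- max(1L, as.integer(round(nfft * (1 - overlap))))
  starts <- seq(1L, n - nfft + 1L, by = hop)
  h <- hannWindow(nfft)
  scale <- fs * sum(h^2)
  segs <- vapply(starts, function(s) x[s:(s + nfft - 1L)],
                 numeric(nfft))
  segs <- matrix(segs, nrow = nfft)
  if (demean) segs <- sweep(segs, 2, colMeans(segs))
  spec <- Mod(mvfft(segs * h))^2 / scale
  nf <- nfft %/% 2 + 1L
  psd <- rowMeans(spec)[seq_len(nf)]
  # one-sided: double everything except DC (and Nyquist for even nfft)
  psd[-c(1L, if (nfft %% 2 == 0) nf)] <- 2 * psd[-c(1L, if (nfft %% 2 == 0) nf)]
  data.frame(freq = (seq_len(nf) - 1L) * fs / nfft, psd = psd)
}

#' Log high-gamma power in 125 ms bins
#'
#' Per channel, the recording is cut into non-overlapping windows of
#' `powerWindow` seconds (32 samples at 256 Hz). Each window is Hann-tapered
#' and its single-segment periodogram evaluated at the native 8 Hz bin
#' spacing; the median power over frequency bins inside the high-gamma band
#' is taken and log10-transformed. Bins overlapping masked time, bins of bad
#' channels and zero-variance (degenerate) windows are marked invalid, not
#' turned into -Inf.
#'
#' @param rec a preprocessed [Recording-class] at 256 Hz.
#' @param params a [TcParams-class].
#' @return a [PowerSeries-class].
#' @export
highGammaPower <- function(rec, params = tcParams()) {
  stopifnot(is(rec, "Recording"), is(params, "TcParams"))
  fs <- rec@rate
  nw <- as.integer(round(params@powerWindow * fs))   # 32 samples
  nBins <- ncol(rec@samples) %/% nw
  if (nBins < 1) stop("recording shorter than one power bin")
  h <- hannWindow(nw)
  freqs <- (0:(nw %/% 2)) * fs / nw
  bandIdx <- which(freqs >= params@hgBand[1] & freqs <= params@hgBand[2])
  if (!length(bandIdx)) stop("high-gamma band contains no frequency bin")
  nCh <- nrow(rec@samples)
  values <- matrix(NA_real_, nCh, nBins)
  valid <- matrix(FALSE, nCh, nBins)
  binStart <- (seq_len(nBins) - 1L) * params@powerWindow
  binEnd <- binStart + params@powerWindow
  maskedBin <- rep(FALSE, nBins)
  if (nrow(rec@maskIntervals))
    for (k in seq_len(nrow(rec@maskIntervals)))
      maskedBin <- maskedBin | (binEnd > rec@maskIntervals[k, 1] &
                                binStart < rec@maskIntervals[k, 2])
  for (ch in seq_len(nCh)) {
    if (rec@bad[ch]) next
    seg <- matrix(rec@samples[ch, seq_len(nBins * nw)], nrow = nw)
    rows <- lapply(seq_len(nw), function(i) seg[i, ])
    constant <- do.call(pmax, rows) == do.call(pmin, rows)
    spec <- Mod(mvfft(seg * h))^2           # nw x nBins
    p <- colMedians(spec[bandIdx, , drop = FALSE])
    ok <- !constant & p > 0 & !maskedBin
    values[ch, ok] <- log10(p[ok])
    valid[ch, ] <- ok
  }
  new("PowerSeries", values = values, binRate = 1 / params@powerWindow,
      valid = valid, labels = rec@labels)
}

#' Band powers per 120-second segment
#'
#' Median Welch power per frequency band, channel and non-overlapping
#' segment. Segments overlapping masked time (seizure padding) and bad
#' channels are omitted.
#'
#' @param rec a preprocessed [Recording-class].
#' @param scheme named list of `c(lo, hi)` band edges in Hz; see
#'   [defaultBandScheme()].
#' @param segmentSeconds segment length in seconds.
#' @param nfft Welch segment length in samples (0.5 Hz resolution at 256 Hz
#'   with the default 512).
#' @return a data.frame with columns `channel`, `segment_start_s`, `band`,
#'   `power`.
#' @export
bandPowers <- function(rec, scheme = defaultBandScheme(),
                       segmentSeconds = 120, nfft = 512L) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@rate
  segLen <- as.integer(segmentSeconds * fs)
  nSeg <- ncol(rec@samples) %/% segLen
  if (nSeg < 1) stop("recording shorter than one segment")
  bands <- names(scheme)
  chs <- character(); t0s <- numeric(); pows <- list()
  for (ch in seq_len(nrow(rec@samples))) {
    if (rec@bad[ch]) next
    for (sgi in seq_len(nSeg)) {
      t0 <- (sgi - 1L) * segmentSeconds
      t1 <- t0 + segmentSeconds
      if (nrow(rec@maskIntervals) &&
          any(t1 > rec@maskIntervals[, 1] & t0 < rec@maskIntervals[, 2]))
        next
      x <- rec@samples[ch, ((sgi - 1L) * segLen + 1L):(sgi * segLen)]
      ps <- welchPsd(x, fs, nfft = nfft)
      chs <- c(chs, rec@labels[ch]); t0s <- c(t0s, t0)
      pows[[length(pows) + 1L]] <- vapply(bands, function(b) {
        idx <- ps$freq >= scheme[[b]][1] & ps$freq <= scheme[[b]][2]
        median(ps$psd[idx])
      }, numeric(1))
    }
  }
  if (!length(pows))
    return(data.frame(channel = character(), segment_start_s = numeric(),
                      band = character(), power = numeric()))
  nb <- length(bands)
  data.frame(channel = rep(chs, each = nb),
             segment_start_s = rep(t0s, each = nb),
             band = rep(bands, times = length(chs)),
             power = as.numeric(do.call(cbind, pows)))
}

#' Standard frequency band scheme
#'
#' The six analysis bands: delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30,
#' gamma 30-45 and high-gamma 55-95 Hz.
#'
#' @return named list of `c(lo, hi)` band edges in Hz.
#' @export
defaultBandScheme <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 45), high_gamma = c(55, 95))
}

#' Band scheme for the vigilance index
#'
#' Adds the two bands the vigilance denominator needs beyond the standard
#' scheme. Their edges are configurable interpretations (spindle 11-16 Hz,
#' high beta 20-30 Hz).
#'
#' @param spindle,betaHigh `c(lo, hi)` band edges in Hz.
#' @return named list of band edges covering delta, theta, alpha, spindle
#'   and high beta.
#' @export
vigilanceBandScheme <- function(spindle = c(11, 16), betaHigh = c(20, 30)) {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       spindle = spindle, beta_high = betaHigh)
}
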