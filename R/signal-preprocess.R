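#' Preprocess a multichannel recording
#'
#' Standard conditioning ahead of all power computations: band-stop (notch)
#' filters remove 50 and 100 Hz line noise; the signal is anti-alias
#' filtered and decimated to the common 256 Hz rate; a 0.1 Hz high-pass
#' removes slow drifts (the nominal 128 Hz upper band edge coincides with
#' the Nyquist frequency at 256 Hz, so the low-pass side is realised by the
#' decimation filter); channels that are constant or show abnormal
#' narrow-band spectral peaks are flagged bad; seizure intervals are
#' expanded by +-600 s and recorded as masked time.
#'
#' @param rec a [Recording-class] with rate >= 256 Hz (an integer multiple
#'   of 256).
#' @param targetRate output rate, 256 Hz.
#' @param seizurePadSeconds padding applied around each seizure interval.
#' @param peakIqrFactor channel rejection threshold: a channel is flagged if
#'   any detrended log-spectral value exceeds Q3 + `peakIqrFactor` * IQR of
#'   that channel's detrended spectrum (narrow-band peak screen).
#' @return a [Recording-class] at `targetRate` with `preprocessed = TRUE`,
#'   bad channels flagged, and mask intervals populated.
#' @export
preprocessRecording <- function(rec, targetRate = 256,
                                seizurePadSeconds = 600,
                                peakIqrFactor = 6) {
  stopifnot(is(rec, "Recording"))
  if (rec@rate < targetRate)
    stop(sprintf("sampling rate %g Hz is below the common rate %g Hz",
                 rec@rate, targetRate))
  q <- rec@rate / targetRate
  if (abs(q - round(q)) > 1e-9)
    stop("sampling rate must be an integer multiple of the target rate")
  q <- as.integer(round(q))
  x <- rec@samples
  nyq <- rec@rate / 2
  # notch out line noise at 50 and 100 Hz (zero-phase band-stop)
  for (f0 in c(50, 100)) {
    if (f0 >= nyq) next
    bs <- signal::butter(2, c(f0 - 2, f0 + 2) / nyq, type = "stop")
    x <- t(apply(x, 1, function(ch) signal::filtfilt(bs, ch)))
  }
  # anti-alias filter + decimate to the common rate
  if (q > 1L)
    x <- t(apply(x, 1, function(ch) signal::decimate(ch, q)))
  # high-pass 0.1 Hz removes slow drifts (upper edge = Nyquist, see above)
  hp <- signal::butter(2, 0.1 / (targetRate / 2), type = "high")
  x <- t(apply(x, 1, function(ch) signal::filtfilt(hp, ch)))
  bad <- rec@bad | apply(x, 1, function(ch) {
    var(ch) == 0 || hasAbnormalPeak(ch, targetRate, peakIqrFactor)
  })
  mask <- rec@maskIntervals
  if (nrow(rec@seizures)) {
    dur <- ncol(x) / targetRate
    mask <- rbind(mask, cbind(pmax(0, rec@seizures$start_s - seizurePadSeconds),
                              pmin(dur, rec@seizures$end_s + seizurePadSeconds)))
  }
  new("Recording", samples = x, rate = targetRate, labels = rec@labels,
      seizures = rec@seizures, bad = bad, maskIntervals = mask,
      preprocessed = TRUE)
}

# Narrow-band peak screen for channel rejection. The log10 Welch spectrum
# is detrended by a running median (so a smooth 1/f background does not
# trigger); a channel is abnormal if any residual exceeds
# Q3 + factor * IQR of the residuals. The steep low-frequency continuum
# below 2 Hz is excluded: the detrend cannot follow it at the spectrum
# edge and it carries no narrow-band artifact information.
hasAbnormalPeak <- function(ch, fs, factor, nfft = 512L) {
  if (length(ch) < nfft) return(FALSE)
  ps <- welchPsd(ch, fs, nfft = nfft)
  keep <- ps$freq >= 2 & ps$psd > 0
  lp <- log10(ps$psd[keep])
  k <- 21L
  bg <- runningMedian(lp, k)
  resid <- lp - bg
  # drop the half-window edges where the background estimate is one-sided
  half <- k %/% 2L
  resid <- resid[(half + 1L):(length(resid) - half)]
  q <- quantile(resid, c(0.25, 0.75), names = FALSE)
  any(resid > q[2] + factor * (q[2] - q[1]))
}

runningMedian <- function(x, k) {
  n <- length(x)
  half <- k %/% 2
  vapply(seq_len(n), function(i)
    median(x[max(1, i - half):min(n, i + half)]), numeric(1))
}
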