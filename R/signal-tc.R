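#' Windowed autocorrelation functions of a power series
#'
#' Per channel, consecutive windows of `acfWindow` seconds are placed every
#' `acfWindow - acfOverlap` seconds (120 s windows every 30 s by default).
#' For each window containing only valid bins, the biased sample
#' autocorrelation of the mean-subtracted bin series is computed at lags
#' from one bin up to `maxLag`. Windows containing any invalid bin, or with
#' zero variance, are skipped. Lag 0 is excluded throughout: it is 1 by
#' definition and independent of noise level.
#'
#' @param ps a [PowerSeries-class].
#' @param params a [TcParams-class].
#' @param channels channel labels to include (default: all).
#' @return an [AcfSet-class] pooling the accepted windows of all requested
#'   channels (possibly empty).
#' @export
windowedAcf <- function(ps, params = tcParams(), channels = ps@labels) {
  stopifnot(is(ps, "PowerSeries"), is(params, "TcParams"))
  br <- ps@binRate
  winBins <- as.integer(round(params@acfWindow * br))
  hopBins <- as.integer(round((params@acfWindow - params@acfOverlap) * br))
  nLags <- as.integer(round(params@maxLag * br))
  nBins <- ncol(ps@values)
  blocks <- list(); chOf <- character(); starts <- numeric()
  for (ch in which(ps@labels %in% channels)) {
    if (nBins < winBins) next
    wins <- list(); ws <- numeric()
    for (s0 in seq(1L, nBins - winBins + 1L, by = hopBins)) {
      idx <- s0:(s0 + winBins - 1L)
      if (!all(ps@valid[ch, idx])) next
      x <- ps@values[ch, idx]
      if (var(x) == 0) next
      wins[[length(wins) + 1L]] <- x
      ws <- c(ws, (s0 - 1L) / br)
    }
    if (!length(wins)) next
    blocks[[length(blocks) + 1L]] <- fftAcf(do.call(cbind, wins), nLags)
    chOf <- c(chOf, rep(ps@labels[ch], length(wins)))
    starts <- c(starts, ws)
  }
  acfs <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(numeric(), nrow = nLags, ncol = 0)
  new("AcfSet", acfs = acfs, lagSeconds = seq_len(nLags) / br,
      channelOf = chOf, startSeconds = starts)
}

#' Temporal-correlation statistic from an ACF set
#'
#' The per-window ACFs are aggregated element-wise by the median; the
#' baseline is the median of the aggregated ACF over the 40-60 s lag band;
#' the threshold sits halfway between the lag-1 (0.125 s) value and the
#' baseline; the statistic is the half-decay width measured from the lag-1
#' peak: `(first lag >= 2 below threshold - 1) * 0.125` seconds. The floor
#' is therefore one bin, 0.125 s. If the ACF never crosses within the
#' maximum lag the value is capped at 60 s and flagged; if the lag-1 value
#' does not exceed the baseline the floor is returned, flagged degenerate.
#'
#' @param acfs an [AcfSet-class] (or a lags-by-windows matrix).
#' @param params a [TcParams-class].
#' @return a [TcValue-class].
#' @export
tcFromAcf <- function(acfs, params = tcParams()) {
  m <- if (is(acfs, "AcfSet")) acfs@acfs else acfs
  if (!ncol(m)) stop("empty ACF set: no complete window available")
  br <- 1 / params@powerWindow
  lagSec <- seq_len(nrow(m)) / br
  agg <- colMedians(t(m))
  baselineIdx <- which(lagSec >= params@baselineBand[1] &
                       lagSec <= params@baselineBand[2])
  tcFromAcfVector(agg, baselineIdx, lagUnit = params@powerWindow,
                  maxValue = nrow(m), nWindows = ncol(m))
}

#' Surrogate temporal correlations from time-shuffled power series
#'
#' Each surrogate permutes the valid power bins of every channel in time
#' (preserving the power distribution, destroying temporal structure) and
#' runs the full windowed-ACF + TC pipeline. Shuffled series are
#' temporally uncorrelated, so surrogate TCs sit at the 0.125 s floor.
#'
#' @param ps a [PowerSeries-class].
#' @param params a [TcParams-class].
#' @param n number of surrogates (>= 1).
#' @param seed integer seed governing all permutations.
#' @return a data.frame with one row per surrogate: `surrogate`, `tc_s`,
#'   `capped`.
#' @export
surrogateTc <- function(ps, params = tcParams(), n = 100, seed) {
  stopifnot(is(ps, "PowerSeries"))
  if (n < 1) stop("n must be >= 1")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  out <- lapply(seq_len(n), function(k) {
    shuf <- ps
    for (ch in seq_len(nrow(ps@values))) {
      v <- which(ps@valid[ch, ])
      shuf@values[ch, v] <- ps@values[ch, v][sample.int(length(v))]
    }
    tcv <- tcFromAcf(windowedAcf(shuf, params), params)
    data.frame(surrogate = k, tc_s = tcv@tc, capped = tcv@capped)
  })
  do.call(rbind, out)
}

#' Subsampled comparison of two ACF sets
#'
#' When two states contribute unequal numbers of windows, the majority set
#' is repeatedly subsampled without replacement to the minority size, the
#' TC computed for both, and results averaged over repetitions, so both
#' states are estimated from equally many windows.
#'
#' @param windowsA,windowsB [AcfSet-class] objects (both non-empty).
#' @param nRep number of subsampling repetitions.
#' @param seed integer seed governing all repetitions.
#' @param params a [TcParams-class].
#' @return named numeric `c(tc_a, tc_b)` in seconds.
#' @export
subsampleCompare <- function(windowsA, windowsB, nRep = 100, seed,
                             params = tcParams()) {
  stopifnot(is(windowsA, "AcfSet"), is(windowsB, "AcfSet"))
  nA <- ncol(windowsA@acfs); nB <- ncol(windowsB@acfs)
  if (!nA || !nB) stop("both ACF sets must be non-empty")
  if (missing(seed)) stop("seed is required")
  m <- min(nA, nB)
  if (nA == nB)
    return(c(tc_a = tcFromAcf(windowsA, params)@tc,
             tc_b = tcFromAcf(windowsB, params)@tc))
  set.seed(seed)
  reps <- vapply(seq_len(nRep), function(r) {
    ia <- if (nA > m) sample.int(nA, m) else seq_len(nA)
    ib <- if (nB > m) sample.int(nB, m) else seq_len(nB)
    c(tcFromAcf(windowsA@acfs[, ia, drop = FALSE], params)@tc,
      tcFromAcf(windowsB@acfs[, ib, drop = FALSE], params)@tc)
  }, numeric(2))
  c(tc_a = mean(reps[1, ]), tc_b = mean(reps[2, ]))
}

#' Hurst exponent by detrended fluctuation analysis
#'
#' First-order DFA: the mean-subtracted series is integrated; for each
#' dyadic scale the profile is cut into non-overlapping windows, linearly
#' detrended, and the root-mean-square fluctuation computed; the exponent
#' is the log-log slope of fluctuation versus scale. Cross-check for the
#' temporal-correlation statistic: both peak at criticality.
#'
#' @param x numeric series (power bins), length >= 256.
#' @param minScale,maxScale smallest/largest window, in samples; dyadic
#'   scales in between are used. `maxScale` defaults to length(x)/4.
#' @return the estimated exponent (0.5 for white noise, 1.5 for its
#'   integral).
#' @export
dfaHurst <- function(x, minScale = 4L, maxScale = floor(length(x) / 4)) {
  n <- length(x)
  if (n < 256) stop("series too short for DFA (need >= 256 points)")
  y <- cumsum(x - mean(x))
  scales <- unique(floor(2^seq(log2(minScale), log2(maxScale), by = 0.5)))
  fluct <- vapply(scales, function(s) {
    nWin <- n %/% s
    t <- seq_len(s)
    res <- vapply(seq_len(nWin), function(w) {
      seg <- y[((w - 1) * s + 1):(w * s)]
      fit <- lm.fit(cbind(1, t), seg)
      mean(fit$residuals^2)
    }, numeric(1))
    sqrt(mean(res))
  }, numeric(1))
  unname(coef(lm(log2(fluct) ~ log2(scales)))[2])
}
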