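#' Specification of one synthetic multichannel recording
#'
#' Describes an iEEG-like signal with known ground truth: a band-limited
#' (55-100 Hz) Gaussian carrier amplitude-modulated by a log-AR(1) envelope
#' whose correlation time at the 8 Hz bin clock is `envelopeTau`; a 1/f
#' background; optional slow-wave epochs (added 0.5-4 Hz power), spike-like
#' transients at given times, and 50/100 Hz line sinusoids.
#'
#' @slot duration seconds.
#' @slot rate sampling rate, 256 Hz.
#' @slot nChannels number of channels.
#' @slot envelopeTau ground-truth high-gamma envelope correlation time in
#'   seconds (defined at the 8 bins/s envelope clock).
#' @slot swsEpochs data.frame `start_s`, `end_s`, `boost_db`.
#' @slot iedTimes data.frame `channel`, `time_s`.
#' @slot lineNoise amplitude of the 50 Hz line component (100 Hz harmonic
#'   at half amplitude); 0 disables.
#' @slot seed integer seed; generation is bit-reproducible given it.
#' @export
setClass("SignalSpec", representation(
  duration = "numeric", rate = "numeric", nChannels = "numeric",
  envelopeTau = "numeric", swsEpochs = "data.frame", iedTimes = "data.frame",
  lineNoise = "numeric", seed = "numeric"
))

setValidity("SignalSpec", function(object) {
  msg <- character()
  if (object@envelopeTau <= 0) msg <- c(msg, "envelopeTau must be positive")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (nrow(object@swsEpochs) &&
      any(object@swsEpochs$start_s < 0 |
          object@swsEpochs$end_s > object@duration))
    msg <- c(msg, "slow-wave epochs must lie within the duration")
  if (length(msg)) msg else TRUE
})

#' @param duration,rate,nChannels,envelopeTau,swsEpochs,iedTimes,lineNoise,seed
#'   see the corresponding slots.
#' @return `signalSpec()` returns a validated [SignalSpec-class].
#' @rdname SignalSpec-class
#' @export
signalSpec <- function(duration, rate = 256, nChannels = 1L,
                       envelopeTau = 0.5,
                       swsEpochs = data.frame(start_s = numeric(),
                                              end_s = numeric(),
                                              boost_db = numeric()),
                       iedTimes = data.frame(channel = character(),
                                             time_s = numeric()),
                       lineNoise = 0, seed = 1L) {
  new("SignalSpec", duration = duration, rate = rate, nChannels = nChannels,
      envelopeTau = envelopeTau, swsEpochs = swsEpochs, iedTimes = iedTimes,
      lineNoise = lineNoise, seed = seed)
}

# Zero-phase band-limiting by FFT mask (exact band edges, no ripple).
fftBandFilter <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)                  # two-sided frequency axis
  X <- fft(x)
  X[f < lo | f > hi] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

# Stereotyped interictal-spike template: 70 ms sharp biphasic transient
# followed by a 300 ms slow half-wave of opposite polarity.
iedTemplate <- function(fs) {
  n1 <- round(0.07 * fs); n2 <- round(0.30 * fs)
  t1 <- seq_len(n1) / n1
  sharp <- sin(2 * pi * t1) * hannWindow(n1)
  t2 <- seq_len(n2) / n2
  slow <- -0.4 * sin(pi * t2)
  c(sharp, slow)
}

#' Generate a synthetic recording with known ground truth
#'
#' See [SignalSpec-class] for the generative model. Per channel the log
#' high-gamma envelope is an AR(1) process at the 8 Hz bin clock with lag-1
#' coefficient `exp(-0.125 / envelopeTau)`, exponentiated, linearly
#' upsampled to 256 Hz and multiplied onto a 55-100 Hz Gaussian carrier;
#' a 1/f background is added, then slow-wave epochs, spike transients and
#' line noise as specified. All draws are seeded.
#'
#' @param spec a [SignalSpec-class].
#' @return a list with `recording` (a [Recording-class]) and `truth`
#'   (data.frame: channel, envelope_tau, n_ied, sws_seconds).
#' @examples
#' out <- genSignal(signalSpec(duration = 150, envelopeTau = 1, seed = 7))
#' out$truth
#' @export
genSignal <- function(spec) {
  stopifnot(is(spec, "SignalSpec"))
  validObject(spec)
  fs <- spec@rate
  nSamp <- as.integer(round(spec@duration * fs))
  binRate <- 8
  nBins <- as.integer(ceiling(spec@duration * binRate)) + 1L
  phi <- exp(-(1 / binRate) / spec@envelopeTau)
  sigmaE <- 0.4
  samples <- matrix(0, spec@nChannels, nSamp)
  labels <- paste0("ch", seq_len(spec@nChannels))
  tSec <- (seq_len(nSamp) - 1) / fs
  truth <- list()
  for (ch in seq_len(spec@nChannels)) {
    set.seed(spec@seed + 1000L * ch)
    # AR(1) log-envelope at the bin clock, stationary start
    z <- numeric(nBins)
    z[1] <- rnorm(1)
    innov <- rnorm(nBins - 1, sd = sqrt(1 - phi^2))
    for (k in 2:nBins) z[k] <- phi * z[k - 1] + innov[k - 1]
    zUp <- approx(x = (seq_len(nBins) - 1) / binRate, y = z, xout = tSec,
                  rule = 2)$y
    envelope <- exp(sigmaE * zUp)
    carrier <- fftBandFilter(rnorm(nSamp), fs, 55, 100)
    carrier <- carrier / sd(carrier)
    # 1/f background
    wn <- fft(rnorm(nSamp))
    f <- (0:(nSamp - 1)) * fs / nSamp
    f <- pmin(f, fs - f)
    shape <- ifelse(f > 0, 1 / sqrt(pmax(f, 0.1)), 0)
    bg <- Re(fft(wn * shape, inverse = TRUE)) / nSamp
    bg <- bg / sd(bg)
    x <- carrier * envelope + bg
    swsSec <- 0
    if (nrow(spec@swsEpochs)) {
      deltaBg <- fftBandFilter(bg, fs, 0.5, 4)
      deltaSd <- sd(deltaBg)
      for (k in seq_len(nrow(spec@swsEpochs))) {
        e <- spec@swsEpochs[k, ]
        idx <- which(tSec >= e$start_s & tSec < e$end_s)
        extra <- fftBandFilter(rnorm(length(idx)), fs, 0.5, 4)
        if (sd(extra) > 0)
          x[idx] <- x[idx] + extra / sd(extra) * deltaSd * 10^(e$boost_db / 20)
        swsSec <- swsSec + (e$end_s - e$start_s)
      }
    }
    ied <- spec@iedTimes[spec@iedTimes$channel == labels[ch], , drop = FALSE]
    if (nrow(ied)) {
      tpl <- iedTemplate(fs) * 6 * sd(x)
      for (t0 in ied$time_s) {
        i0 <- as.integer(round(t0 * fs)) + 1L
        idx <- i0:min(nSamp, i0 + length(tpl) - 1L)
        if (i0 >= 1 && length(idx))
          x[idx] <- x[idx] + tpl[seq_along(idx)]
      }
    }
    if (spec@lineNoise > 0)
      x <- x + spec@lineNoise * sin(2 * pi * 50 * tSec) +
        0.5 * spec@lineNoise * sin(2 * pi * 100 * tSec)
    samples[ch, ] <- x
    truth[[ch]] <- data.frame(channel = labels[ch],
                              envelope_tau = spec@envelopeTau,
                              n_ied = nrow(ied), sws_seconds = swsSec)
  }
  list(recording = recording(samples, rate = fs, labels = labels),
       truth = do.call(rbind, truth))
}

#' Specification of a synthetic cohort
#'
#' Per-subject latent envelope correlation times (lognormal), multiday
#' medication schedules with tapering (high-load days shorten the day's
#' envelope correlation time by `asmFactor`), slow-wave epochs, spike
#' events, and cognitive test scores whose domain-impairment probability
#' decreases with the subject's latent correlation time through a logistic
#' link in `log(tau)`.
#'
#' @slot nSubjects number of subjects (>= 2).
#' @slot nDays recording days per subject.
#' @slot dayDuration seconds of signal per day.
#' @slot nChannels channels per subject.
#' @slot tauLogMean,tauLogSd lognormal parameters of the latent per-subject
#'   envelope correlation time (seconds).
#' @slot asmFactor multiplier (< 1) applied to the envelope correlation
#'   time on the highest-load day (intermediate days interpolate in the
#'   exponent).
#' @slot impairSlope slope of the logistic impairment link on `-log(tau)`;
#'   0 decouples impairment from dynamics.
#' @slot tauRef reference tau (seconds) at which impairment probability is
#'   0.5.
#' @slot iedRatePerMin spike event rate per channel.
#' @slot swsFraction fraction of each day covered by slow-wave epochs.
#' @slot swsBoostDb delta-power boost of slow-wave epochs in dB.
#' @slot seed integer master seed.
#' @export
setClass("CohortSpec", representation(
  nSubjects = "numeric", nDays = "numeric", dayDuration = "numeric",
  nChannels = "numeric", tauLogMean = "numeric", tauLogSd = "numeric",
  asmFactor = "numeric", impairSlope = "numeric", tauRef = "numeric",
  iedRatePerMin = "numeric", swsFraction = "numeric", swsBoostDb = "numeric",
  seed = "numeric"
))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 2) msg <- c(msg, "nSubjects must be >= 2")
  if (object@asmFactor <= 0 || object@asmFactor > 1)
    msg <- c(msg, "asmFactor must lie in (0, 1]")
  if (object@swsFraction < 0 || object@swsFraction > 0.5)
    msg <- c(msg, "swsFraction must lie in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' @param nSubjects,nDays,dayDuration,nChannels,tauLogMean,tauLogSd,asmFactor,impairSlope,tauRef,iedRatePerMin,swsFraction,swsBoostDb,seed
#'   see the corresponding slots.
#' @return `cohortSpec()` returns a validated [CohortSpec-class]. Defaults
#'   emulate the study conditions at desk scale: latent correlation times
#'   with median 0.5 s (the reported group means sit near 0.5-1 s),
#'   slow-wave epochs covering ~18% of each day, in-bin spike rates, and
#'   medication tapering across three days.
#' @rdname CohortSpec-class
#' @export
cohortSpec <- function(nSubjects = 80L, nDays = 3L, dayDuration = 300,
                       nChannels = 1L, tauLogMean = log(0.5),
                       tauLogSd = 0.5, asmFactor = 0.7, impairSlope = 2.5,
                       tauRef = 0.5, iedRatePerMin = 6, swsFraction = 0.18,
                       swsBoostDb = 10, seed = 1L) {
  new("CohortSpec", nSubjects = nSubjects, nDays = nDays,
      dayDuration = dayDuration, nChannels = nChannels,
      tauLogMean = tauLogMean, tauLogSd = tauLogSd, asmFactor = asmFactor,
      impairSlope = impairSlope, tauRef = tauRef,
      iedRatePerMin = iedRatePerMin, swsFraction = swsFraction,
      swsBoostDb = swsBoostDb, seed = seed)
}

#' Generate a synthetic cohort
#'
#' Draws every latent quantity of the cohort (per-subject correlation
#' times, per-day medication loads and the induced day-level correlation
#' times, slow-wave epochs, spike events, cognitive scores) and returns
#' them together with the ground-truth table. Signals themselves are
#' generated lazily per day via [daySignalSpec()] so large cohorts need not
#' hold all samples in memory.
#'
#' Day contexts: day 1 carries the highest medication load (`first`), the
#' last day an intermediate load (`last`), and day 2 the lowest
#' (`low_asm`); with `nDays = 2` the low-load day doubles as the last day.
#'
#' @param spec a [CohortSpec-class].
#' @return a list with `subjects` (subject, tau_s, impair_prob), `days`
#'   (subject, day, context, load_ddd, tau_day_s, seed), `schedules`
#'   (subject, day, drug, dose, defined_daily_dose, rescue), `epochs`
#'   (slow-wave epochs per subject-day), `events` (spike events per
#'   subject-day-channel), `scores` (cognitive tests), `truth` (latent
#'   parameters joined), and `spec`.
#' @export
genCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(spec@seed)
  nS <- spec@nSubjects
  subjects <- data.frame(
    subject = sprintf("S%03d", seq_len(nS)),
    tau_s = rlnorm(nS, meanlog = spec@tauLogMean, sdlog = spec@tauLogSd))
  subjects$impair_prob <- plogis(
    spec@impairSlope * (log(spec@tauRef) - log(subjects$tau_s)))
  # medication: one maintenance drug, tapered; day 1 highest, day 2 lowest
  baseDose <- rlnorm(nS, meanlog = log(2000), sdlog = 0.3)
  relLoad <- c(1, 0.3, seq(0.65, 0.95, length.out = max(0, spec@nDays - 2)))
  relLoad <- relLoad[seq_len(spec@nDays)]
  days <- do.call(rbind, lapply(seq_len(nS), function(i) {
    load <- baseDose[i] * relLoad / 3000          # DDD-normalised
    loadNorm <- (load - min(load)) / (max(load) - min(load))
    ctx <- rep("other", spec@nDays)
    ctx[1] <- "first"
    ctx[which.min(load)] <- "low_asm"
    ctx[spec@nDays] <- if (spec@nDays > 2) "last" else ctx[spec@nDays]
    data.frame(subject = subjects$subject[i], day = seq_len(spec@nDays),
               context = ctx, load_ddd = load,
               tau_day_s = subjects$tau_s[i] * spec@asmFactor^loadNorm,
               seed = spec@seed + 131L * i + 17L * seq_len(spec@nDays))
  }))
  schedules <- data.frame(subject = days$subject, day = days$day,
                          drug = "levetiracetam",
                          dose = days$load_ddd * 3000,
                          defined_daily_dose = 3000, rescue = FALSE)
  # slow-wave epochs: 30-s blocks at random positions covering swsFraction
  nEp <- max(1L, round(spec@swsFraction * spec@dayDuration / 30))
  epochs <- do.call(rbind, lapply(seq_len(nrow(days)), function(k) {
    set.seed(days$seed[k] + 7L)
    nSlots <- floor(spec@dayDuration / 30)
    slots <- sort(sample.int(nSlots, min(nEp, nSlots)))
    data.frame(subject = days$subject[k], day = days$day[k],
               start_s = (slots - 1) * 30, end_s = slots * 30,
               boost_db = spec@swsBoostDb)
  }))
  # spike events: homogeneous Poisson per channel
  events <- do.call(rbind, lapply(seq_len(nrow(days)), function(k) {
    set.seed(days$seed[k] + 13L)
    out <- lapply(seq_len(spec@nChannels), function(ch) {
      nEv <- stats::rpois(1, spec@iedRatePerMin * spec@dayDuration / 60)
      if (!nEv) return(NULL)
      data.frame(subject = days$subject[k], day = days$day[k],
                 channel = paste0("ch", ch),
                 time_s = sort(runif(nEv, 0, spec@dayDuration - 0.5)))
    })
    do.call(rbind, out)
  }))
  # cognitive scores: 3 tests per domain, norm 100 +- 15; impairment drawn
  # from the logistic link, scores redrawn until consistent with the flag
  set.seed(spec@seed + 999983L)
  domains <- c("language", "verbal_memory", "working_memory", "attention")
  scores <- do.call(rbind, lapply(seq_len(nS), function(i) {
    do.call(rbind, lapply(domains, function(dm) {
      impaired <- runif(1) < subjects$impair_prob[i]
      for (try in 1:100) {
        z <- if (impaired) c(rnorm(2, -1.8, 0.4), rnorm(1, -0.5, 0.7))
             else rnorm(3, 0, 0.9)
        if ((sum(z <= -1) >= 2) == impaired) break
      }
      data.frame(subject = subjects$subject[i], domain = dm,
                 test = paste0(dm, "_t", 1:3), score = 100 + 15 * z,
                 norm_mean = 100, norm_sd = 15)
    }))
  }))
  truth <- merge(days, subjects, by = "subject")
  list(subjects = subjects, days = days, schedules = schedules,
       epochs = epochs, events = events, scores = scores, truth = truth,
       spec = spec)
}

#' Signal specification for one subject-day
#'
#' Assembles the [SignalSpec-class] of a given subject and day from a
#' generated cohort, including that day's medication-adjusted envelope
#' correlation time, slow-wave epochs and spike events.
#'
#' @param cohort result of [genCohort()].
#' @param subject subject identifier.
#' @param day day number.
#' @return a [SignalSpec-class].
#' @export
daySignalSpec <- function(cohort, subject, day) {
  d <- cohort$days[cohort$days$subject == subject & cohort$days$day == day, ]
  if (nrow(d) != 1) stop("unknown subject/day")
  ep <- cohort$epochs[cohort$epochs$subject == subject &
                      cohort$epochs$day == day,
                      c("start_s", "end_s", "boost_db")]
  ev <- cohort$events[cohort$events$subject == subject &
                      cohort$events$day == day, c("channel", "time_s")]
  if (is.null(ev)) ev <- data.frame(channel = character(), time_s = numeric())
  signalSpec(duration = cohort$spec@dayDuration,
             nChannels = cohort$spec@nChannels,
             envelopeTau = d$tau_day_s, swsEpochs = ep, iedTimes = ev,
             seed = d$seed)
}
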