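#' Vigilance index of a 30-second window
#'
#' Band-power ratio (theta + delta) / (alpha + high beta + spindle). High
#' values indicate slow-wave dominated, sleep-like activity.
#'
#' @param powers named numeric with elements `delta`, `theta`, `alpha`,
#'   `beta_high`, `spindle` (all >= 0), or a data.frame with columns `band`
#'   and `power` covering those bands.
#' @return the index, or `NA` if the denominator is zero (window dropped).
#' @export
vigilanceIndex <- function(powers) {
  if (is.data.frame(powers))
    powers <- setNames(powers$power, powers$band)
  need <- c("delta", "theta", "alpha", "beta_high", "spindle")
  if (!all(need %in% names(powers)))
    stop("powers must supply bands: ", paste(need, collapse = ", "))
  if (any(powers[need] < 0)) stop("band powers must be non-negative")
  den <- sum(powers[c("alpha", "beta_high", "spindle")])
  if (den == 0) return(NA_real_)
  unname(sum(powers[c("theta", "delta")]) / den)
}

#' Slow-wave labels for one day of vigilance indices
#'
#' A 30-s window is labelled slow-wave sleep iff its vigilance index
#' exceeds that day's mean plus one (population) standard deviation. The
#' threshold is computed per day, so labels are invariant to rescaling all
#' of a day's indices by a positive constant.
#'
#' @param indices numeric vigilance indices of one day's 30-s windows
#'   (length >= 2; NA windows are dropped from the threshold and labelled
#'   NA).
#' @return logical vector of the same length.
#' @export
swsLabels <- function(indices) {
  ok <- !is.na(indices)
  if (sum(ok) < 2)
    stop("need at least two windows per day to define the threshold")
  m <- mean(indices[ok])
  # population SD: divide by n, not n - 1
  s <- sqrt(mean((indices[ok] - m)^2))
  out <- indices > m + s
  out[!ok] <- NA
  out
}

#' Map 30-s slow-wave labels onto 120-s analysis windows
#'
#' A 120-s window is slow-wave iff at least one of its four constituent
#' 30-s windows is. Windows with incomplete coverage are unlabelled (NA).
#'
#' @param labels30 logical vector of 30-s labels (chronological).
#' @return logical vector, one element per complete 120-s window.
#' @export
mapSwsToTcWindows <- function(labels30) {
  n <- length(labels30) %/% 4L
  if (n < 1) return(logical(0))
  vapply(seq_len(n), function(k) {
    g <- labels30[((k - 1L) * 4L + 1L):(k * 4L)]
    if (any(is.na(g))) NA else any(g)
  }, logical(1))
}

#' Bin interictal-spike rates and filter channels
#'
#' Counts spike events per channel and 120-s window, converts to events per
#' minute, and bins: `none` (zero events), `ied` (5-30 events/min, the
#' contrast bin), `other` (rates in (0, 5) or above 30; excluded from the
#' contrast). Channels are retained only if they have at least `minSegments`
#' windows in EACH of the `none` and `ied` categories.
#'
#' @param events data.frame with columns `channel` and `time_s`.
#' @param channels character vector of all channels under consideration.
#' @param nWindows number of 120-s windows in the recording.
#' @param windowSeconds window length (120 s).
#' @param rateRange inclusive events-per-minute range of the contrast bin.
#' @param minSegments retention threshold per category.
#' @return a list with `labels` (data.frame: channel, window_start_s,
#'   n_events, rate_per_min, ied_bin) and `retained` (character vector of
#'   channels passing the filter).
#' @export
iedBinAndFilter <- function(events, channels, nWindows, windowSeconds = 120,
                            rateRange = c(5, 30), minSegments = 50) {
  labels <- do.call(rbind, lapply(channels, function(ch) {
    tms <- events$time_s[events$channel == ch]
    idx <- findInterval(tms, (0:nWindows) * windowSeconds,
                        rightmost.closed = FALSE)
    counts <- tabulate(idx[idx >= 1 & idx <= nWindows], nbins = nWindows)
    rate <- counts / (windowSeconds / 60)
    bin <- ifelse(counts == 0, "none",
                  ifelse(rate >= rateRange[1] & rate <= rateRange[2],
                         "ied", "other"))
    data.frame(channel = ch,
               window_start_s = (seq_len(nWindows) - 1) * windowSeconds,
               n_events = counts, rate_per_min = rate, ied_bin = bin)
  }))
  counts <- table(labels$channel, labels$ied_bin)
  haveNone <- if ("none" %in% colnames(counts)) counts[, "none"] else 0
  haveIed <- if ("ied" %in% colnames(counts)) counts[, "ied"] else 0
  retained <- rownames(counts)[haveNone >= minSegments & haveIed >= minSegments]
  list(labels = labels, retained = retained)
}

#' Classify medication days as high and low load
#'
#' Daily drug doses are normalised by their defined daily dose (DDD) and
#' summed per day. Days with rescue medication (midazolam, diazepam,
#' lorazepam, or an explicit flag) are excluded. The days with the highest
#' and lowest summed load are returned; ties go to the earliest day. If
#' fewer than two eligible days remain, or all eligible daily sums are
#' equal (no tapering), the subject is excluded (returns NULL).
#'
#' @param schedule data.frame with columns `day`, `drug`, `dose`,
#'   `defined_daily_dose`, and optionally `rescue` (logical).
#' @return a list with `high`, `low` (day identifiers) and `loads` (named
#'   per-day summed normalised dose), or NULL if the subject is excluded.
#' @export
asmDayClasses <- function(schedule) {
  stopifnot(all(c("day", "drug", "dose", "defined_daily_dose") %in%
                names(schedule)))
  if (any(schedule$dose < 0)) stop("doses must be non-negative")
  if (any(schedule$defined_daily_dose <= 0))
    stop("defined daily doses must be positive")
  rescueDrugs <- c("midazolam", "diazepam", "lorazepam")
  rescue <- tolower(schedule$drug) %in% rescueDrugs
  if (!is.null(schedule$rescue)) rescue <- rescue | schedule$rescue
  rescueDays <- unique(schedule$day[rescue])
  elig <- schedule[!(schedule$day %in% rescueDays), , drop = FALSE]
  if (!nrow(elig)) return(NULL)
  loads <- c(tapply(elig$dose / elig$defined_daily_dose, elig$day, sum))
  if (length(loads) < 2) return(NULL)
  if (max(loads) == min(loads)) return(NULL)    # no tapering
  days <- names(loads)
  list(high = days[which.max(loads)], low = days[which.min(loads)],
       loads = loads)
}
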