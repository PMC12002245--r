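#' Extract per-subject features from a synthetic cohort
#'
#' Runs the full signal pipeline for every subject and requested day
#' context: generate the day's recording, preprocess, compute the log
#' high-gamma power series, windowed ACFs and the temporal-correlation
#' statistic; shuffled-series surrogate TCs; median band powers; the
#' annotation-based spike rate; the slow-wave fraction from the vigilance
#' index; and the day's medication load. The result is the long-format
#' cohort table consumed by [runComparisonGrid()].
#'
#' @param cohort result of [genCohort()].
#' @param contexts day contexts to extract (subset of the contexts present
#'   in `cohort$days`).
#' @param params a [TcParams-class].
#' @param nSurrogates surrogates per subject-context for the surrogate-TC
#'   feature.
#' @param preprocess run [preprocessRecording()] on each generated signal
#'   (the generator already emits 256 Hz signals, so this exercises the
#'   filtering stages; disable to save time in large simulations).
#' @param verbose print progress.
#' @return a data.frame with columns `subject`, `context`, `feature`,
#'   `value` covering features `tc`, `surrogate_tc`, the six band powers,
#'   `ied_rate`, `sws_frac` and `asm_load`.
#' @export
cohortFeatures <- function(cohort, contexts = c("first", "last", "low_asm"),
                           params = tcParams(), nSurrogates = 3L,
                           preprocess = FALSE, verbose = FALSE) {
  days <- cohort$days[cohort$days$context %in% contexts, ]
  scheme <- defaultBandScheme()
  vigScheme <- vigilanceBandScheme()
  out <- vector("list", nrow(days))
  for (k in seq_len(nrow(days))) {
    d <- days[k, ]
    if (verbose && k %% 20 == 1)
      message("cohort features: ", k, "/", nrow(days))
    sp <- daySignalSpec(cohort, d$subject, d$day)
    rec <- genSignal(sp)$recording
    if (preprocess) rec <- preprocessRecording(rec)
    ps <- highGammaPower(rec, params)
    acfs <- windowedAcf(ps, params)
    tc <- if (ncol(acfs@acfs)) tcFromAcf(acfs, params)@tc else NA_real_
    sur <- if (ncol(acfs@acfs))
      mean(surrogateTc(ps, params, n = nSurrogates,
                       seed = d$seed + 59L)$tc_s) else NA_real_
    bp <- bandPowers(rec, scheme)
    bandMed <- tapply(bp$power, bp$band, median)
    nWin <- floor(sp@duration / 120)
    ev <- cohort$events[cohort$events$subject == d$subject &
                        cohort$events$day == d$day, , drop = FALSE]
    iedRate <- (if (is.null(ev)) 0 else nrow(ev)) /
      (sp@duration / 60) / sp@nChannels
    swsFrac <- tryCatch({
      vp <- bandPowers(rec, vigScheme, segmentSeconds = 30)
      vi <- vapply(split(vp, vp$segment_start_s),
                   vigilanceIndex, numeric(1))
      lab120 <- mapSwsToTcWindows(swsLabels(vi))
      mean(lab120, na.rm = TRUE)
    }, error = function(e) NA_real_)
    feats <- c(tc = tc, surrogate_tc = sur,
               setNames(as.numeric(bandMed[names(scheme)]), names(scheme)),
               ied_rate = iedRate, sws_frac = swsFrac,
               asm_load = d$load_ddd)
    out[[k]] <- data.frame(subject = d$subject, context = d$context,
                           feature = names(feats), value = unname(feats))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Impairment table of a synthetic cohort
#'
#' Applies [impairmentFlags()] to the generated cognitive scores and
#' returns the per-subject-per-domain flags in the long format expected by
#' [runComparisonGrid()].
#'
#' @param cohort result of [genCohort()].
#' @return data.frame with columns `subject`, `domain`, `impaired`.
#' @export
cohortImpairment <- function(cohort) {
  out <- do.call(rbind, lapply(split(cohort$scores, cohort$scores$subject),
                               function(sc) {
    fl <- impairmentFlags(sc)$domains
    data.frame(subject = sc$subject[1], domain = fl$domain,
               impaired = fl$impaired)
  }))
  rownames(out) <- NULL
  out
}
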