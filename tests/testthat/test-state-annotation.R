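test_that("vigilance index is the stated band-power ratio", {
  all1 <- c(delta = 1, theta = 1, alpha = 1, beta_high = 1, spindle = 1)
  expect_equal(vigilanceIndex(all1), 2 / 3)
  deltaDom <- c(delta = 10, theta = 1, alpha = 1, beta_high = 1, spindle = 1)
  expect_equal(vigilanceIndex(deltaDom), 11 / 3)
  zeroDen <- c(delta = 1, theta = 1, alpha = 0, beta_high = 0, spindle = 0)
  expect_true(is.na(vigilanceIndex(zeroDen)))
  expect_error(vigilanceIndex(c(delta = 1)), "must supply")
})

test_that("slow-wave threshold is one population SD over the day mean", {
  idx <- c(1, 1, 1, 1, 5)     # mean 1.8, population SD 1.6, threshold 3.4
  expect_identical(swsLabels(idx), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_true(all(!swsLabels(rep(2, 6))))      # zero SD labels nothing
  # invariance under positive rescaling of a day's indices
  set.seed(1)
  v <- rlnorm(40)
  expect_identical(swsLabels(v), swsLabels(7.3 * v))
  expect_error(swsLabels(c(1)), "at least two windows")
})

test_that("any slow-wave 30-s window marks the enclosing 120-s window", {
  expect_identical(mapSwsToTcWindows(c(FALSE, FALSE, TRUE, FALSE)), TRUE)
  expect_identical(mapSwsToTcWindows(rep(FALSE, 4)), FALSE)
  expect_identical(mapSwsToTcWindows(rep(TRUE, 4)), TRUE)
  expect_identical(mapSwsToTcWindows(c(rep(FALSE, 4), TRUE, TRUE, FALSE,
                                       FALSE)), c(FALSE, TRUE))
  expect_identical(mapSwsToTcWindows(c(NA, rep(FALSE, 3))), NA)
})

test_that("spike-rate bins and the 50-segment channel filter behave as stated", {
  # 12 events in 120 s -> 6/min (contrast bin); 2 events -> 1/min (other)
  ev <- data.frame(channel = "c1",
                   time_s = c(seq(1, 112, by = 10), 125, 180))
  out <- iedBinAndFilter(ev, channels = "c1", nWindows = 3)
  expect_identical(out$labels$ied_bin, c("ied", "other", "none"))
  expect_equal(out$labels$rate_per_min, c(6, 1, 0))
  # channel with 49 event-free + 200 in-bin windows is excluded at 50
  mkEv <- function(ch, nIn, offset = 0)
    data.frame(channel = ch,
               time_s = as.vector(outer(seq(0.5, 110, by = 10),
                                        (offset + seq_len(nIn) - 1) * 120,
                                        "+")))
  evA <- mkEv("chA", 200)             # windows 1..200 in-bin, 201..249 free
  evB <- mkEv("chB", 150)             # windows 1..150 in-bin, 99 free
  out2 <- iedBinAndFilter(rbind(evA, evB), channels = c("chA", "chB"),
                          nWindows = 249)
  expect_identical(out2$retained, "chB")
})

test_that("medication days classify by DDD-normalised load with rescue exclusion", {
  sch <- data.frame(day = 1:3, drug = "lamotrigine", dose = c(400, 200, 600),
                    defined_daily_dose = 300)
  cl <- asmDayClasses(sch)
  expect_equal(cl$high, "3"); expect_equal(cl$low, "2")
  expect_equal(unname(cl$loads), c(400, 200, 600) / 300)
  # ties resolve to the earliest day
  sch2 <- data.frame(day = 1:3, drug = "valproate",
                     dose = c(2000, 500, 2000), defined_daily_dose = 1000)
  cl2 <- asmDayClasses(sch2)
  expect_equal(cl2$high, "1")         # days 1 and 3 tie; earliest wins
  expect_equal(cl2$low, "2")
  # a rescue-flagged day is removed entirely; if the remaining days carry
  # equal loads the subject no longer shows tapering and is excluded
  sch3 <- data.frame(day = c(1, 2, 2, 3),
                     drug = c("valproate", "valproate", "Lorazepam",
                              "valproate"),
                     dose = c(2000, 500, 2, 2000),
                     defined_daily_dose = c(1500, 1500, 2.5, 1500))
  expect_null(asmDayClasses(sch3))
  # constant load -> no tapering -> subject excluded
  expect_null(asmDayClasses(data.frame(day = 1:3, drug = "x",
                                       dose = 100, defined_daily_dose = 50)))
  expect_error(asmDayClasses(data.frame(day = 1, drug = "x", dose = -1,
                                        defined_daily_dose = 1)),
               "non-negative")
})

test_that("injected slow-wave epochs are detected with high sensitivity and specificity", {
  hits <- misses <- falseAlarms <- rejections <- 0
  for (s in 1:20) {
    set.seed(s)
    slots <- sort(sample.int(10, 2))
    ep <- data.frame(start_s = (slots - 1) * 30, end_s = slots * 30,
                     boost_db = 10)
    sig <- genSignal(signalSpec(duration = 300, envelopeTau = 0.5,
                                swsEpochs = ep, seed = 1000 + s))
    vp <- bandPowers(sig$recording, vigilanceBandScheme(),
                     segmentSeconds = 30)
    vi <- vapply(split(vp, vp$segment_start_s), vigilanceIndex, numeric(1))
    lab <- swsLabels(vi)
    truth <- seq_len(10) %in% slots
    hits <- hits + sum(lab & truth); misses <- misses + sum(!lab & truth)
    falseAlarms <- falseAlarms + sum(lab & !truth)
    rejections <- rejections + sum(!lab & !truth)
  }
  expect_gte(hits / (hits + misses), 0.9)              # sensitivity
  expect_gte(rejections / (rejections + falseAlarms), 0.9)  # specificity
})
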