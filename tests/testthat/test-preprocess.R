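test_that("resampling preserves content and yields the expected length", {
  rec400 <- synthesizeRecord(syntheticRecordSpec(fs = 400, seed = 1))$record
  expect_identical(resampleRecord(rec400, 400), rec400)

  rec300 <- ECGRecord(matrix(rnorm(3000 * 12, sd = 0.1), 3000, 12), 300)
  out <- resampleRecord(rec300, 400)
  expect_equal(nrow(ecgSignal(out)), 4000)  # 10 s x 400 Hz
  expect_equal(samplingRate(out), 400)

  t6 <- (0:5999) / 600
  sig <- matrix(sin(2 * pi * 5 * t6), 6000, 12)
  out <- resampleRecord(ECGRecord(sig, 600), 400)
  t4 <- (0:(nrow(ecgSignal(out)) - 1)) / 400
  ideal <- sin(2 * pi * 5 * t4)
  core <- 50:(length(t4) - 50)   # ignore filter edge transients
  expect_gt(stats::cor(ecgSignal(out)[core, 1], ideal[core]), 0.999)

  expect_error(resampleRecord(rec400, -1), "positive")
})

test_that("zero-padding reaches the target length without altering content", {
  rec <- ECGRecord(matrix(rnorm(2800 * 12), 2800, 12), 400)
  out <- zeroPadRecord(rec)
  expect_equal(nrow(ecgSignal(out)), 4096)
  expect_identical(ecgSignal(out)[1:2800, ], ecgSignal(rec))
  expect_true(all(ecgSignal(out)[2801:4096, ] == 0))
  expect_equal(sum(abs(ecgSignal(out))), sum(abs(ecgSignal(rec))))
  expect_equal(colSums(ecgSignal(out)^2), colSums(ecgSignal(rec)^2))

  sym <- zeroPadRecord(rec, placement = "symmetric")
  expect_identical(ecgSignal(sym)[649:3448, ], ecgSignal(rec))

  rec4096 <- ECGRecord(matrix(1, 4096, 12), 400)
  expect_identical(zeroPadRecord(rec4096), rec4096)

  long <- ECGRecord(matrix(0, 5000, 12), 400)
  expect_error(zeroPadRecord(long), "longer")
  expect_equal(nrow(ecgSignal(zeroPadRecord(long, long_policy = "crop"))),
               4096)
})

test_that("preprocessing always yields the fixed 4096 x 12 input", {
  for (seed in 1:3) {
    sp <- syntheticRecordSpec(duration = c(7, 8.5, 10)[seed],
                              fs = c(300, 500, 600)[seed], seed = seed)
    pp <- preprocessRecord(synthesizeRecord(sp)$record)
    expect_equal(dim(ecgSignal(pp)), c(4096L, 12L))
    expect_equal(samplingRate(pp), 400)
    # idempotence
    expect_identical(preprocessRecord(pp), pp)
  }
  z <- preprocessRecord(ECGRecord(matrix(0, 3000, 12), 300))
  expect_true(all(ecgSignal(z) == 0))
})

test_that("R-peak detection finds sinus beats and ignores offsets", {
  rec <- recordFromRTimes(seq(0.5, 9.5, by = 1), fs = 400, duration = 10)
  pk <- detectRPeaks(rec)
  expect_true(length(pk) %in% 9:11)
  expect_true(all(abs(diff(pk) - 400) <= 2))

  expect_identical(detectRPeaks(ECGRecord(matrix(0, 4000, 12), 400)),
                   integer(0))

  shifted <- ECGRecord(ecgSignal(rec) + 0.5, 400)
  expect_identical(detectRPeaks(shifted), pk)

  expect_error(detectRPeaks(ECGRecord(matrix(0, 100, 12), 400)), "2 s")
})

test_that("measurements recover known RR series", {
  rec <- recordFromRTimes(0.5 + cumsum(c(0, rep(1, 8))), fs = 400)
  m <- measureRecord(rec)
  expect_equal(m$heart_rate, 60, tolerance = 0.01)
  expect_equal(m$sdnn, 0, tolerance = 3)      # quantization only
  expect_equal(m$n_beats, 9)

  rec2 <- recordFromRTimes(0.5 + cumsum(c(0, 0.8, 0.85, 0.75)), fs = 400)
  m2 <- measureRecord(rec2)
  expect_equal(m2$heart_rate, 75, tolerance = 0.5)

  flat <- measureRecord(ECGRecord(matrix(0, 4000, 12), 400))
  expect_true(is.na(flat$heart_rate))
  expect_equal(flat$n_beats, 0)
})

test_that("measurement oracle recovers generator ground truth", {
  # noise-free closure across classes, rates and sampling frequencies
  for (cls in list(character(0), "SB", "ST", "1dAVb", "RBBB")) {
    for (seed in 1:3) {
      sp <- syntheticRecordSpec(flags = labelVector(cls),
                                duration = 7 + seed,
                                fs = c(300, 400, 600)[seed], seed = seed,
                                noise = noiseFree())
      r <- synthesizeRecord(sp)
      m <- measureRecord(r$record)
      expect_equal(m$heart_rate, r$measurements$heart_rate, tolerance = 2 /
                     r$measurements$heart_rate)
      expect_equal(m$qrs_duration, r$measurements$qrs_duration,
                   tolerance = 10 / r$measurements$qrs_duration)
      expect_equal(m$pr_interval, r$measurements$pr_interval,
                   tolerance = 10 / r$measurements$pr_interval)
    }
  }
})

test_that("a generated first-degree AV block record measures a long PR", {
  sp <- syntheticRecordSpec("1dAVb", duration = 10, fs = 400, seed = 21,
                            noise = noiseFree())
  r <- synthesizeRecord(sp)
  m <- measureRecord(r$record)
  expect_gte(r$measurements$pr_interval, 215)
  expect_equal(m$pr_interval, r$measurements$pr_interval,
               tolerance = 10 / r$measurements$pr_interval)
})

test_that("dataset splits respect sizes, patients and chronology", {
  meta <- data.frame(exam_id = sprintf("e%03d", 1:100),
                     patient_id = sprintf("p%03d", 1:100),
                     date = as.character(as.Date("2017-01-01") + 0:99))
  sp <- splitDataset(meta, "random", seed = 3)
  expect_equal(lengths(sp), c(train = 90L, validation = 5L, test = 5L))
  expect_setequal(unlist(sp), 1:100)
  expect_identical(splitDataset(meta, "random", seed = 3), sp)

  one <- data.frame(exam_id = sprintf("e%d", 1:10), patient_id = "p1",
                    date = NA)
  bp <- splitDataset(one, "by_patient", seed = 1)
  expect_equal(sum(lengths(bp) > 0), 1L)
  expect_equal(length(bp$train), 10L)

  multi <- data.frame(exam_id = sprintf("e%03d", 1:100),
                      patient_id = rep(sprintf("p%02d", 1:20), each = 5),
                      date = NA)
  bp2 <- splitDataset(multi, "by_patient", seed = 2)
  for (part in bp2) {
    pats <- multi$patient_id[part]
    other <- multi$patient_id[setdiff(1:100, part)]
    expect_length(intersect(pats, other), 0)
  }

  ch <- splitDataset(meta, "chronological")
  expect_true(max(meta$date[ch$train]) <= min(meta$date[ch$validation]))
  expect_true(max(meta$date[ch$validation]) <= min(meta$date[ch$test]))

  noPat <- meta; noPat$patient_id <- NULL
  expect_error(splitDataset(noPat, "by_patient"), "patient_id")
  noDate <- meta; noDate$date <- NA
  expect_error(splitDataset(noDate, "chronological"), "date")
})
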