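test_that("beat synthesis handles the zero and absent-P cases", {
  m0 <- beatMorphology(amplitudes = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  expect_true(all(synthesizeBeat(m0, 400) == 0))

  mNoP <- beatMorphology(p_present = FALSE)
  amps <- c(P = 0, Q = -0.15, R = 1.0, S = -0.25, T = 0.30)
  mZeroP <- beatMorphology(amplitudes = amps)
  a <- synthesizeBeat(mNoP, 400)
  b <- synthesizeBeat(mZeroP, 400)
  # same waveform over the region both cover (the P-less beat starts later)
  off <- nrow(b) - nrow(a)
  expect_equal(unclass(a)[, ], unclass(b)[(off + 1):nrow(b), ],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("QRS support of a synthesized beat matches the parameter", {
  m <- beatMorphology(qrs_duration = 120,
                      amplitudes = c(P = 0, Q = -0.15, R = 1, S = -0.25,
                                     T = 0))
  beat <- synthesizeBeat(m, 400)
  support <- sum(abs(beat[, "II"]) > 0.02)
  expect_equal(support, 48, tolerance = 0.15)  # 0.120 s x 400 Hz
})

test_that("beat synthesis validates its inputs", {
  expect_error(beatMorphology(qrs_duration = -5), "positive")
  expect_error(beatMorphology(p_sigma = 0), "positive")
  expect_error(synthesizeBeat(beatMorphology(), fs = 0), "positive")
})

test_that("P onset precedes QRS onset by exactly the PR interval", {
  fs <- 500
  for (pr in c(140, 190, 240)) {
    qrs <- 100
    m <- beatMorphology(pr_interval = pr, qrs_duration = qrs,
                        amplitudes = c(P = 0.15, Q = 0, R = 0, S = 0, T = 0))
    beat <- synthesizeBeat(m, fs)
    t <- (seq_len(nrow(beat)) - attr(beat, "r_index")) / fs * 1000
    # isolated P bump: the modeled onset is where it crosses its 2-sd level
    lvl <- 0.15 * exp(-2)
    pOn <- min(t[beat[, "II"] >= lvl])
    qrsOn <- -qrs / 2
    expect_equal(qrsOn - pOn, pr, tolerance = 1000 / fs * 1.5)
  }
})

test_that("RR sampling matches its rhythm model", {
  r <- rhythmSpec(mean_hr = 60, rr_jitter_sd = 0)
  set.seed(1)
  rr <- sampleRRSequence(r, 10)
  expect_true(all(rr == 1.0))
  expect_gte(sum(rr), 10)

  r75 <- rhythmSpec(mean_hr = 75, rr_jitter_sd = 0)
  rr75 <- sampleRRSequence(r75, 10)
  expect_true(all(abs(rr75 - 0.8) < 1e-12))
  expect_equal(length(rr75), 13)  # 13 x 0.8 s = 10.4 s first reaches 10 s

  set.seed(2)
  af <- rhythmSpec(mean_hr = 80, rr_model = "irregular_af")
  draws <- sampleRRSequence(af, 0.75 * 10000)
  expect_gt(length(draws), 9000)
  expect_equal(stats::sd(draws), rrAnalyticSd(af), tolerance = 0.1)
  # reproducibility under a fixed seed
  set.seed(9); a <- sampleRRSequence(af, 50)
  set.seed(9); b <- sampleRRSequence(af, 50)
  expect_identical(a, b)
})

test_that("abnormality flags map to their defining parameters", {
  for (seed in 1:4) {
    r <- synthesizeRecord(syntheticRecordSpec("SB", seed = seed))
    expect_lt(r$measurements$heart_rate, 50)
    r <- synthesizeRecord(syntheticRecordSpec("ST", seed = seed))
    expect_gt(r$measurements$heart_rate, 100)
    r <- synthesizeRecord(syntheticRecordSpec("1dAVb", seed = seed))
    expect_gte(r$measurements$pr_interval, 200)
    r <- synthesizeRecord(syntheticRecordSpec("RBBB", seed = seed))
    expect_gte(r$measurements$qrs_duration, 120)
    r <- synthesizeRecord(syntheticRecordSpec(seed = seed))
    expect_true(r$measurements$heart_rate >= 50 &&
                r$measurements$heart_rate <= 100)
    expect_lt(r$measurements$pr_interval, 200)
    expect_lt(r$measurements$qrs_duration, 115)
    expect_identical(r$labels, labelVector())
  }
})

test_that("AF records have no P wave and elevated RR variability", {
  sp <- syntheticRecordSpec("AF", duration = 10, fs = 400, seed = 11,
                            noise = noiseFree())
  r <- synthesizeRecord(sp)
  m <- measureRecord(r$record)
  expect_false(m$p_present)
  expect_true(is.na(m$pr_interval))
  expect_gt(m$sdnn, 60)   # well above the 30 ms sinus-jitter default
})

test_that("bundle-branch-block beats have opposite V1/V6 polarity", {
  qrsPolarity <- function(r) {
    rec <- r$record
    pk <- detectRPeaks(rec)[3]
    w <- (pk - round(0.06 * 400)):(pk + round(0.06 * 400))
    sig <- ecgSignal(rec)
    c(v1 = sig[w, "V1"][which.max(abs(sig[w, "V1"]))],
      v6 = sig[w, "V6"][which.max(abs(sig[w, "V6"]))])
  }
  rb <- qrsPolarity(synthesizeRecord(
    syntheticRecordSpec("RBBB", fs = 400, seed = 2, noise = noiseFree())))
  lb <- qrsPolarity(synthesizeRecord(
    syntheticRecordSpec("LBBB", fs = 400, seed = 2, noise = noiseFree())))
  expect_gt(rb["v1"], 0); expect_lt(rb["v6"], 0)
  expect_lt(lb["v1"], 0); expect_gt(lb["v6"], 0)
})

test_that("record specs reject conflicting or out-of-range settings", {
  expect_error(syntheticRecordSpec("SB", "AF"), "mutually exclusive")
  expect_error(syntheticRecordSpec("AF", "1dAVb"), "cannot be combined")
  expect_error(syntheticRecordSpec(duration = 12), "duration")
  expect_error(syntheticRecordSpec(fs = 200), "fs")
})

test_that("generated datasets honour prevalences and exclusivity", {
  lab <- ecgdx:::.drawLabels(10000, defaultPrevalences())
  n1 <- sum(lab[, "1dAVb"])
  expect_lt(abs(n1 - 150), 3 * sqrt(10000 * 0.015 * 0.985))
  expect_true(all(rowSums(lab[, c("SB", "AF", "ST")]) <= 1))
  expect_true(all(rowSums(lab[, c("RBBB", "LBBB")]) <= 1))
  expect_false(any(lab[, "AF"] & lab[, "1dAVb"]))
  expect_error(
    ecgdx:::.drawLabels(10, c("1dAVb" = 0, RBBB = 0, LBBB = 0,
                              SB = 0.5, AF = 0.4, ST = 0.3)),
    "rhythm")

  lab0 <- ecgdx:::.drawLabels(1000, defaultPrevalences() * 0)
  expect_false(any(lab0))
})

test_that("dataset generation is reproducible and label-consistent", {
  a <- generateDataset(30, prevalences = balancedPrevalences(), seed = 5)
  b <- generateDataset(30, prevalences = balancedPrevalences(), seed = 5)
  expect_identical(labelSidecar(a), labelSidecar(b))
  expect_identical(ecgSignal(records(a)[[7]]), ecgSignal(records(b)[[7]]))

  gt <- groundTruth(a); lab <- labelMatrix(a)
  expect_true(all(gt$heart_rate[lab[, "SB"]] < 50))
  expect_true(all(gt$heart_rate[lab[, "ST"]] > 100))
  expect_true(all(gt$qrs_duration[lab[, "RBBB"] | lab[, "LBBB"]] >= 120))
  expect_true(all(gt$pr_interval[lab[, "1dAVb"]] >= 200))
  expect_true(all(is.na(gt$pr_interval[lab[, "AF"]])))
})
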