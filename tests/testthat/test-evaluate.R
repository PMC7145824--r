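test_that("the precision-recall curve matches hand-enumerated points", {
  pc <- prCurve(c(0.9, 0.8, 0.3), c(1, 0, 1))
  at08 <- pc[pc$threshold == 0.8, ]
  expect_equal(at08$precision, 0.5)
  expect_equal(at08$recall, 0.5)
  expect_equal(pc$recall[1], 1.0)                   # lowest threshold
  expect_true(all(diff(pc$recall) <= 0))            # non-increasing in t

  # perfect separation: precision 1 everywhere
  pc2 <- prCurve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(all(pc2$precision[pc2$threshold >= 0.8] == 1))
  expect_true(all(prCurve(stats::runif(1000), rep(c(TRUE, FALSE),
                                                  500))$recall[1] == 1))

  expect_error(prCurve(c(0.5, 0.2), c(0, 0)), "no positive")
})

test_that("F1-max threshold selection equals exhaustive search", {
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(c(20, 100, 500), 1)
    scores <- round(stats::runif(n), 2)   # ties on purpose
    labels <- stats::runif(n) < 0.3
    if (!any(labels)) labels[1] <- TRUE
    got <- selectThresholdMaxF1(scores, labels)
    want <- bruteForceMaxF1(scores, labels)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
    expect_equal(got$threshold, want$threshold)
  }
  # duplicating a record never changes the optimal F1
  s <- c(0.9, 0.7, 0.6, 0.4, 0.2); y <- c(1, 1, 0, 1, 0)
  a <- selectThresholdMaxF1(s, y)
  b <- selectThresholdMaxF1(c(s, 0.7), c(y, 1))
  expect_equal(b$f1, bruteForceMaxF1(c(s, 0.7), c(y, 1))$f1)
  expect_equal(a$f1, bruteForceMaxF1(s, y)$f1)
})

test_that("per-class metrics follow their defining formulas", {
  scores <- matrix(c(rep(0.9, 9), 0.9, rep(0.1, 1), rep(0.1, 89)), ncol = 1)
  labels <- matrix(c(rep(TRUE, 9), FALSE, TRUE, rep(FALSE, 89)), ncol = 1)
  cs <- classScores(scores, labels, 0.5)
  expect_equal(cs$tp, 9); expect_equal(cs$fp, 1)
  expect_equal(cs$fn, 1); expect_equal(cs$tn, 89)
  expect_equal(cs$precision, 0.9)
  expect_equal(cs$recall, 0.9)
  expect_equal(cs$f1, 0.9)
  expect_equal(cs$specificity, 89 / 90)

  # all-negative predictions: recall 0, precision undefined (missing)
  cs2 <- classScores(matrix(0.1, 4, 1), matrix(c(TRUE, TRUE, FALSE, FALSE)),
                     0.5)
  expect_equal(cs2$recall, 0)
  expect_true(is.na(cs2$precision))
  expect_true(is.na(cs2$f1))

  # perfect predictions
  cs3 <- classScores(matrix(c(0.9, 0.9, 0.1), 3, 1),
                     matrix(c(TRUE, TRUE, FALSE)), 0.5)
  expect_true(all(unlist(cs3[, c("precision", "recall", "specificity",
                                 "f1")]) == 1))
})

test_that("micro average precision equals the rank-by-rank oracle", {
  expect_equal(microAveragePrecision(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1)

  set.seed(5)
  s <- sample(seq(0.01, 0.99, by = 0.01), 30)  # distinct scores
  y <- stats::runif(30) < 0.4
  y[1] <- TRUE
  expect_equal(microAveragePrecision(s, y), rankApOracle(s, y),
               tolerance = 1e-12)

  sm <- matrix(sample(s), 5, 6); ym <- matrix(y[1:30], 5, 6)
  if (!any(ym)) ym[1] <- TRUE
  perm <- sample(6)
  expect_equal(microAveragePrecision(sm, ym),
               microAveragePrecision(sm[, perm], ym[, perm]))

  expect_error(microAveragePrecision(c(.1, .2), c(0, 0)), "no positive")
})

test_that("bootstrap distributions are seeded and contain the estimate", {
  set.seed(77)
  n <- 200
  scores <- matrix(stats::runif(n * 2), n, 2,
                   dimnames = list(NULL, c("A", "B")))
  labels <- cbind(A = scores[, 1] + stats::rnorm(n, 0, 0.3) > 0.5,
                  B = scores[, 2] + stats::rnorm(n, 0, 0.3) > 0.6)
  thr <- c(0.5, 0.6)
  bs1 <- bootstrapScores(scores, labels, thr, n_resamples = 200, seed = 4)
  bs2 <- bootstrapScores(scores, labels, thr, n_resamples = 200, seed = 4)
  expect_identical(bs1, bs2)

  iv <- bs1$intervals
  expect_true(all(iv$lower <= iv$point + 1e-12 &
                  iv$point <= iv$upper + 1e-12))
  # bootstrap mean close to the point estimate
  pt <- classScores(scores, labels, thr)
  for (j in 1:2) {
    mu <- mean(bs1$distributions["f1", j, ], na.rm = TRUE)
    se <- stats::sd(bs1$distributions["f1", j, ], na.rm = TRUE)
    expect_lt(abs(mu - pt$f1[j]), 3 * se)
  }

  # zero-variance data give a degenerate distribution at the estimate
  sc0 <- matrix(c(rep(0.9, 50), rep(0.1, 50)), ncol = 1)
  lb0 <- matrix(c(rep(TRUE, 50), rep(FALSE, 50)), ncol = 1)
  bs0 <- bootstrapScores(sc0, lb0, 0.5, n_resamples = 50, seed = 1)
  expect_true(all(bs0$distributions["f1", 1, ] == 1))
})

test_that("the McNemar test matches closed forms and the stats oracle", {
  # symmetric discordance
  ea <- c(rep(TRUE, 5), rep(FALSE, 5), rep(FALSE, 10))
  eb <- c(rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 10))
  expect_equal(mcnemarTest(ea, eb, method = "chisq")$statistic, 0)

  # b = 10, c = 2
  ea2 <- c(rep(TRUE, 10), rep(FALSE, 2), rep(FALSE, 8))
  eb2 <- c(rep(FALSE, 10), rep(TRUE, 2), rep(FALSE, 8))
  mt <- mcnemarTest(ea2, eb2, method = "chisq")
  expect_equal(mt$statistic, (10 - 2)^2 / 12, tolerance = 1e-12)
  ref <- stats::mcnemar.test(table(factor(ea2, c(FALSE, TRUE)),
                                   factor(eb2, c(FALSE, TRUE))),
                             correct = FALSE)
  expect_equal(mt$statistic, unname(ref$statistic))
  expect_equal(mt$p.value, ref$p.value)

  # continuity-corrected variant vs stats::mcnemar.test(correct = TRUE)
  mtc <- mcnemarTest(ea2, eb2, method = "chisq_corrected")
  refc <- stats::mcnemar.test(table(factor(ea2, c(FALSE, TRUE)),
                                    factor(eb2, c(FALSE, TRUE))),
                              correct = TRUE)
  expect_equal(mtc$statistic, unname(refc$statistic))

  # exact two-sided binomial tail for b = 3, c = 0
  ea3 <- c(TRUE, TRUE, TRUE, FALSE); eb3 <- c(FALSE, FALSE, FALSE, FALSE)
  ex <- mcnemarTest(ea3, eb3, method = "exact")
  expect_equal(ex$p.value, 2 * 0.5^3, tolerance = 1e-12)
  expect_equal(ex$p.value,
               stats::binom.test(0, 3, 0.5)$p.value, tolerance = 1e-12)

  # no discordance
  nd <- mcnemarTest(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(nd$statistic, 0); expect_equal(nd$p.value, 1)
})

test_that("Cohen's kappa matches closed forms and the e1071 oracle", {
  a <- rep(c(TRUE, FALSE), c(10, 10))
  expect_equal(cohenKappa(a, a), 1)

  # 2x2 table (40, 10, 10, 40): po 0.8, pe 0.5, kappa 0.6
  x <- rep(c(TRUE, TRUE, FALSE, FALSE), c(40, 10, 10, 40))
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 10, 40))
  expect_equal(cohenKappa(x, y), 0.6, tolerance = 1e-12)
  skip_if_not_installed("e1071")
  expect_equal(cohenKappa(x, y),
               e1071::classAgreement(table(x, y))$kappa, tolerance = 1e-12)

  # complete disagreement on a balanced table
  b <- rep(c(TRUE, FALSE), c(10, 10))
  expect_equal(cohenKappa(b, !b), -1)

  expect_error(cohenKappa(c(TRUE), c(TRUE, FALSE)), "length")
})

test_that("the evaluation report ties thresholds, metrics and curves", {
  set.seed(9)
  n <- 300
  labels <- matrix(stats::runif(n * 6) < 0.25, n, 6,
                   dimnames = list(NULL, ecgClasses()))
  scores <- 0.65 * labels + matrix(stats::runif(n * 6) * 0.5, n, 6)
  scores <- pmin(scores, 0.999)
  rep <- evalReport(scores, labels, n_resamples = 50, seed = 2)
  # the selected thresholds maximize F1: any other cut-point is no better
  for (j in 1:6) {
    other <- bruteForceMaxF1(scores[, j], labels[, j])
    expect_equal(rep$class_scores$f1[j], other$f1, tolerance = 1e-12)
  }
  # metric closure from the reported confusion counts
  cs <- rep$class_scores
  expect_equal(cs$precision, cs$tp / (cs$tp + cs$fp))
  expect_equal(cs$recall, cs$tp / (cs$tp + cs$fn))
  expect_equal(cs$specificity, cs$tn / (cs$tn + cs$fp))
  expect_true(rep$micro_ap > 0 && rep$micro_ap <= 1)
})

test_that("median-rule model selection picks the mAP just above median", {
  maps <- c(0.946, 0.961, 0.950, 0.952, 0.948, 0.955, 0.947, 0.953,
            0.951, 0.958)
  i <- selectModelByMAP(maps)
  expect_equal(maps[i], min(maps[maps > stats::median(maps)]))
})
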