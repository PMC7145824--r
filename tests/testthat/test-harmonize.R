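mkBundle <- function(expert = labelVector(), unig = labelVector(),
                     minnesota = labelVector(), hr = NA, pr = NA, qrs = NA,
                     sdnn = NA, id = "e1") {
  annotationBundle(id, expert, unig, minnesota,
                   measurementSet(heart_rate = hr, pr_interval = pr,
                                  qrs_duration = qrs, sdnn = sdnn))
}
statusOf <- function(res, cl) res$status[res$class == cl]

test_that("stage-1 agreement logic accepts and rejects as specified", {
  r <- harmonize(mkBundle(expert = labelVector("RBBB"),
                          unig = labelVector("RBBB")))
  expect_equal(statusOf(r, "RBBB"), "accepted")
  expect_equal(r$rule[r$class == "RBBB"], "s1_agreement")

  # single automatic claim against the expert and the other source
  r2 <- harmonize(mkBundle(unig = labelVector("LBBB"), qrs = 150))
  expect_equal(statusOf(r2, "LBBB"), "rejected")
  expect_equal(r2$rule[r2$class == "LBBB"], "s1_lone_automatic")

  # unclaimed classes are simply absent
  expect_true(all(r2$status[r2$class != "LBBB"] == "rejected"))
  expect_true(all(r2$rule[r2$class != "LBBB"] == "s0_no_claim"))
})

test_that("measurement rules reject at the printed boundaries", {
  # expert-only ST claim at a heart rate just below / at the cutoff
  # (stage-2 rules act on claims the agreement stage left undecided)
  st99 <- harmonize(mkBundle(expert = labelVector("ST"), hr = 99))
  expect_equal(statusOf(st99, "ST"), "rejected")
  st100 <- harmonize(mkBundle(expert = labelVector("ST"), hr = 100))
  expect_equal(statusOf(st100, "ST"), "accepted")

  sb45 <- harmonize(mkBundle(expert = labelVector("SB"), hr = 45))
  expect_equal(statusOf(sb45, "SB"), "accepted")  # stage-3 expert accept
  sb51 <- harmonize(mkBundle(expert = labelVector("SB"), hr = 51))
  expect_equal(statusOf(sb51, "SB"), "rejected")

  af600 <- harmonize(mkBundle(expert = labelVector("AF"), sdnn = 600))
  expect_equal(statusOf(af600, "AF"), "needs_review")
  af650 <- harmonize(mkBundle(expert = labelVector("AF"), sdnn = 650))
  expect_equal(statusOf(af650, "AF"), "accepted")

  avb <- harmonize(mkBundle(expert = labelVector("1dAVb"), pr = 185))
  expect_equal(statusOf(avb, "1dAVb"), "rejected")

  # expert-only LBBB is not in the stage-3 accept list
  lb <- harmonize(mkBundle(expert = labelVector("LBBB"), qrs = 150))
  expect_equal(statusOf(lb, "LBBB"), "needs_review")
})

test_that("each measurement rule flips exactly once, at its boundary", {
  survivorGrid <- function(cls, measure, grid) {
    dec <- vapply(grid, function(v) {
      b <- do.call(mkBundle, c(list(expert = labelVector(cls)),
                               stats::setNames(list(v), measure)))
      statusOf(harmonize(b), cls) != "rejected"
    }, logical(1))
    expect_equal(sum(diff(dec) != 0), 1L)   # exactly one flip on the sweep
    grid[dec]
  }
  expect_equal(min(survivorGrid("ST", "hr", 40:160)), 100)
  expect_equal(max(survivorGrid("SB", "hr", 30:120)), 50)
  expect_equal(min(survivorGrid("RBBB", "qrs", 80:160)), 115)
  expect_equal(min(survivorGrid("LBBB", "qrs", 80:160)), 115)
  expect_equal(min(survivorGrid("1dAVb", "pr", 120:260)), 190)

  # AF acceptance boundary: accepted only strictly above the threshold
  acc <- vapply(600:700, function(v)
    statusOf(harmonize(mkBundle(expert = labelVector("AF"), sdnn = v)),
             "AF") == "accepted", logical(1))
  expect_equal(sum(diff(acc) != 0), 1L)
  expect_equal(max((600:700)[!acc]), 646)
})

test_that("missing measurements leave stage-2 rules silent", {
  r <- harmonize(mkBundle(expert = labelVector("ST")))  # no heart rate
  expect_equal(statusOf(r, "ST"), "accepted")           # stage 3
  r2 <- harmonize(mkBundle(expert = labelVector("AF")))
  expect_equal(statusOf(r2, "AF"), "needs_review")
})

test_that("stage-1 rejections are never overturned later", {
  # lone-automatic ST claim with a qualifying heart rate stays rejected
  r <- harmonize(mkBundle(unig = labelVector("ST"), hr = 150))
  expect_equal(statusOf(r, "ST"), "rejected")
  expect_equal(r$rule[r$class == "ST"], "s1_lone_automatic")
})

test_that("harmonization is deterministic and idempotent", {
  b <- mkBundle(expert = labelVector("AF", "RBBB"),
                unig = labelVector("RBBB"), hr = 80, qrs = 130, sdnn = 700)
  expect_identical(harmonize(b), harmonize(b))
  expect_equal(statusOf(harmonize(b), "RBBB"), "accepted")
  expect_equal(statusOf(harmonize(b), "AF"), "accepted")
})

test_that("bundles are validated", {
  expect_error(annotationBundle("e", c(TRUE, FALSE)), "canonical")
  expect_error(annotationBundle("e", labelVector(), measurements = list()),
               "MeasurementSet")
})

test_that("the review queue lists exactly the undecided diagnoses", {
  bundles <- list(
    mkBundle(expert = labelVector("LBBB"), qrs = 150, id = "e1"),
    mkBundle(expert = labelVector("AF"), sdnn = 600, id = "e2"),
    mkBundle(expert = labelVector("SB"), hr = 40, id = "e3"))
  res <- harmonizeAll(bundles)
  q <- reviewQueue(res)
  expect_equal(nrow(q), sum(res$status == "needs_review"))
  expect_setequal(q$exam_id, c("e1", "e2"))

  path <- tempfile(fileext = ".csv")
  reviewQueue(res[res$status != "needs_review", ], path)
  empty <- utils::read.csv(path)
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty), c("exam_id", "class", "rule"))
  unlink(path)
})
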