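# Three-stage harmonization of expert and automatic annotations with
# measurement-based accept/reject rules.
#
# Stage 1 (agreement): accept when the expert and at least one automatic
# source (Uni-G statement or Minnesota code) agree on the abnormality; reject
# when a single automatic source claims it against both the expert and the
# other automatic source.
# Stage 2 (measurement rejections, strict comparisons by literal reading):
# ST rejected when heart rate < 100 bpm; SB rejected when heart rate > 50;
# RBBB/LBBB rejected when QRS duration < 115 ms; 1dAVb rejected when the PR
# interval < 190 ms. Missing measurements leave the rule silent.
# Stage 3 (remaining acceptances): RBBB, 1dAVb, SB and ST accepted on an
# expert-positive claim; AF accepted on expert-positive plus NN-interval
# standard deviation above the threshold (default 646). Anything still
# undecided goes to manual review.

#' Harmonization rule thresholds
#'
#' @param st_hr heart rate (bpm) below which a sinus tachycardia claim is
#'   rejected (default 100, strict `<`).
#' @param sb_hr heart rate above which a sinus bradycardia claim is rejected
#'   (default 50, strict `>`).
#' @param bbb_qrs QRS duration (ms) below which a bundle-branch-block claim
#'   is rejected (default 115, strict `<`).
#' @param avb_pr PR interval (ms) below which a first-degree AV block claim
#'   is rejected (default 190, strict `<`).
#' @param af_sdnn SDNN value above which an expert-positive AF claim is
#'   auto-accepted (default 646, strict `>`). The unit follows whatever unit
#'   the supplied measurements use; no unit is asserted.
#' @return object of class "RuleSet".
#' @export
ruleSet <- function(st_hr = 100, sb_hr = 50, bbb_qrs = 115, avb_pr = 190,
                    af_sdnn = 646) {
  structure(list(st_hr = st_hr, sb_hr = sb_hr, bbb_qrs = bbb_qrs,
                 avb_pr = avb_pr, af_sdnn = af_sdnn), class = "RuleSet")
}

#' Bundle the annotation sources for one exam
#'
#' @param examId exam identifier.
#' @param expert,unig,minnesota named logical label vectors in canonical
#'   class order (see [labelVector()]): the text-derived expert label and the
#'   two automatic-classifier labels.
#' @param measurements a [measurementSet()] (missing values allowed;
#'   measurement rules then cannot fire).
#' @return object of class "AnnotationBundle".
#' @export
annotationBundle <- function(examId, expert, unig = labelVector(),
                             minnesota = labelVector(),
                             measurements = measurementSet()) {
  chk <- function(v, what) {
    if (length(v) != 6L || !identical(names(v), ecgClasses()) ||
        !is.logical(v))
      stop(sprintf("'%s' must be a named logical vector in canonical class order",
                   what))
    v
  }
  if (!inherits(measurements, "MeasurementSet"))
    stop("'measurements' must be a MeasurementSet")
  structure(list(examId = as.character(examId), expert = chk(expert, "expert"),
                 unig = chk(unig, "unig"),
                 minnesota = chk(minnesota, "minnesota"),
                 measurements = measurements),
            class = "AnnotationBundle")
}

#' Harmonize one annotation bundle into per-class decisions
#'
#' Applies the three-stage accept/reject logic described above. Every class
#' receives exactly one status (`accepted`, `rejected` or `needs_review`) and
#' the identifier of the rule that fired.
#'
#' @param bundle an [annotationBundle()].
#' @param rules a [ruleSet()].
#' @return data.frame with columns `exam_id`, `class`, `status`, `rule`.
#' @export
harmonize <- function(bundle, rules = ruleSet()) {
  stopifnot(inherits(bundle, "AnnotationBundle"),
            inherits(rules, "RuleSet"))
  ms <- bundle$measurements
  hr <- ms$heart_rate; qrs <- ms$qrs_duration
  pr <- ms$pr_interval; sdnn <- ms$sdnn
  res <- lapply(ecgClasses(), function(cl) {
    e <- bundle$expert[[cl]]; u <- bundle$unig[[cl]]
    m <- bundle$minnesota[[cl]]
    # no source claims the abnormality: it is simply absent
    if (!e && !u && !m) return(c("rejected", "s0_no_claim"))
    # stage 1: agreement logic
    if (e && (u || m)) return(c("accepted", "s1_agreement"))
    if (!e && xor(u, m)) return(c("rejected", "s1_lone_automatic"))
    # stage 2: measurement-based rejections (strict comparisons)
    if (cl == "ST" && !is.na(hr) && hr < rules$st_hr)
      return(c("rejected", "s2_st_hr"))
    if (cl == "SB" && !is.na(hr) && hr > rules$sb_hr)
      return(c("rejected", "s2_sb_hr"))
    if (cl %in% c("RBBB", "LBBB") && !is.na(qrs) && qrs < rules$bbb_qrs)
      return(c("rejected", "s2_bbb_qrs"))
    if (cl == "1dAVb" && !is.na(pr) && pr < rules$avb_pr)
      return(c("rejected", "s2_avb_pr"))
    # stage 3: remaining acceptances
    if (cl %in% c("RBBB", "1dAVb", "SB", "ST") && e)
      return(c("accepted", "s3_expert"))
    if (cl == "AF" && e && !is.na(sdnn) && sdnn > rules$af_sdnn)
      return(c("accepted", "s3_af_sdnn"))
    c("needs_review", "s4_undecided")
  })
  out <- data.frame(exam_id = bundle$examId, class = ecgClasses(),
                    status = vapply(res, `[`, character(1), 1L),
                    rule = vapply(res, `[`, character(1), 2L))
  class(out) <- c("HarmonizationResult", "data.frame")
  out
}

#' Harmonize a list of bundles
#' @param bundles list of [annotationBundle()] objects.
#' @param rules a [ruleSet()].
#' @return long data.frame, one row per exam x class.
#' @export
harmonizeAll <- function(bundles, rules = ruleSet()) {
  out <- do.call(rbind, lapply(bundles, harmonize, rules = rules))
  rownames(out) <- NULL
  out
}

#' Export the manual-review queue
#'
#' Collects every exam x class decision with status `needs_review`, together
#' with its firing-rule audit trail, and optionally writes it as CSV (an
#' empty queue yields a header-only file).
#'
#' @param results harmonization results (from [harmonize()]/[harmonizeAll()]).
#' @param path optional CSV path.
#' @return data.frame with columns `exam_id`, `class`, `rule` (invisibly when
#'   `path` is given).
#' @export
reviewQueue <- function(results, path = NULL) {
  q <- results[results$status == "needs_review",
               c("exam_id", "class", "rule"), drop = FALSE]
  rownames(q) <- NULL
  q <- as.data.frame(q)
  if (!is.null(path)) {
    utils::write.csv(q, path, row.names = FALSE, quote = FALSE)
    return(invisible(q))
  }
  q
}
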