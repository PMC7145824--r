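# Multi-label evaluation statistics: precision-recall curves, F1-maximizing
# operating points, micro average precision, bootstrap confidence intervals,
# McNemar test and Cohen's kappa.
#
# Conventions (documented, configurable nowhere): a record is predicted
# positive when its score is >= the threshold; the precision-recall curve has
# one point per distinct score value; average precision uses the step-wise
# (rectangle) convention sum((R_i - R_{i-1}) * P_i) without interpolation;
# undefined ratios (zero denominators) are reported as NA, never as zero.

#' Precision-recall curve for one class
#'
#' @param scores numeric vector of predicted probabilities.
#' @param labels logical/0-1 vector of true labels.
#' @return data.frame with columns `threshold`, `recall`, `precision`,
#'   ordered by increasing threshold (recall non-increasing).
#' @export
prCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels)
  if (P == 0) stop("precision-recall curve undefined: no positive labels")
  thr <- sort(unique(scores))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); pp <- seq_along(y)
  # index of the last record with score >= t = position of each threshold
  last <- length(s) + 1L - match(thr, rev(s))
  data.frame(threshold = thr,
             recall = tp[last] / P,
             precision = tp[last] / pp[last])
}

#' Select the F1-maximizing decision threshold for one class
#'
#' Exhaustive search over all distinct score values as cut-points (predicted
#' positive when score >= threshold); returns the highest threshold achieving
#' the global maximum F1.
#'
#' @inheritParams prCurve
#' @return list with `threshold` and the achieved `f1`.
#' @export
selectThresholdMaxF1 <- function(scores, labels) {
  pc <- prCurve(scores, labels)
  f1 <- 2 * pc$precision * pc$recall / (pc$precision + pc$recall)
  f1[is.na(f1)] <- -Inf
  best <- max(f1)
  list(threshold = max(pc$threshold[f1 == best]), f1 = best)
}

.confusion <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  labels <- as.logical(labels)
  c(tp = sum(pred & labels), fp = sum(pred & !labels),
    fn = sum(!pred & labels), tn = sum(!pred & !labels))
}

.metricsFromCounts <- function(cc) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(cc["tp"], cc["tp"] + cc["fp"])
  recall <- ratio(cc["tp"], cc["tp"] + cc["fn"])
  specificity <- ratio(cc["tn"], cc["tn"] + cc["fp"])
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  c(precision = unname(precision), recall = unname(recall),
    specificity = unname(specificity), f1 = unname(f1))
}

#' Per-class operating-point metrics
#'
#' Precision (PPV), recall (sensitivity), specificity, F1 and the confusion
#' counts at fixed per-class thresholds. Ratios with zero denominators are
#' reported missing (NA), not zero.
#'
#' @param scores n x k score matrix.
#' @param labels n x k logical label matrix.
#' @param thresholds length-k vector of decision thresholds.
#' @return data.frame, one row per class, with counts and metrics.
#' @export
classScores <- function(scores, labels, thresholds) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  stopifnot(all(dim(scores) == dim(labels)),
            length(thresholds) == ncol(scores))
  cls <- colnames(scores)
  if (is.null(cls)) cls <- paste0("class", seq_len(ncol(scores)))
  rows <- lapply(seq_len(ncol(scores)), function(j) {
    cc <- .confusion(scores[, j], labels[, j], thresholds[j])
    mm <- .metricsFromCounts(cc)
    data.frame(class = cls[j], threshold = thresholds[j],
               t(as.data.frame(c(cc, mm))), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Micro average precision
#'
#' Average precision computed on the flattened record x class score/label
#' pairs (micro scheme), using the step-wise precision-recall area
#' convention. `scheme = "macro"` instead averages per-class average
#' precisions.
#'
#' @param scores n x k score matrix (or vector).
#' @param labels matching label matrix (or vector).
#' @param scheme "micro" (default) or "macro".
#' @return scalar average precision.
#' @export
microAveragePrecision <- function(scores, labels, scheme = c("micro",
                                                             "macro")) {
  scheme <- match.arg(scheme)
  if (scheme == "macro") {
    sm <- as.matrix(scores); lm <- as.matrix(labels)
    return(mean(vapply(seq_len(ncol(sm)), function(j)
      microAveragePrecision(sm[, j], lm[, j]), numeric(1))))
  }
  s <- as.vector(as.matrix(scores)); y <- as.logical(as.matrix(labels))
  if (!sum(y)) stop("average precision undefined: no positive labels")
  # step-wise area: walk thresholds from high to low; each threshold
  # contributes its recall increment times the precision reached there
  pc <- prCurve(s, y)
  pc <- pc[order(pc$threshold, decreasing = TRUE), , drop = FALSE]
  sum(diff(c(0, pc$recall)) * pc$precision)
}

#' Bootstrap distributions of the per-class metrics
#'
#' Resamples records with replacement (`n_resamples` sets, each of the
#' original size), recomputing the per-class metrics at fixed thresholds for
#' each resample. Resamples in which a metric is undefined (e.g. a class with
#' zero positives) record NA for that metric and are excluded from its
#' percentile interval; the count of valid resamples is reported.
#'
#' @inheritParams classScores
#' @param n_resamples number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param level confidence level of the percentile intervals (default 0.95).
#' @return list with `distributions` (metric x class x resample array),
#'   `intervals` (per class/metric lower/upper/point), and `n_valid`.
#' @export
bootstrapScores <- function(scores, labels, thresholds, n_resamples = 1000,
                            seed = 1, level = 0.95) {
  stopifnot(n_resamples >= 1)
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  n <- nrow(scores)
  metrics <- c("precision", "recall", "specificity", "f1")
  point <- classScores(scores, labels, thresholds)
  cls <- point$class
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  dist <- array(NA_real_, c(length(metrics), length(cls), n_resamples),
                dimnames = list(metrics, cls, NULL))
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(n, n, replace = TRUE)
    cs <- classScores(scores[idx, , drop = FALSE],
                      labels[idx, , drop = FALSE], thresholds)
    dist[, , b] <- t(as.matrix(cs[, metrics]))
  }
  a <- (1 - level) / 2
  intervals <- do.call(rbind, lapply(seq_along(cls), function(j) {
    do.call(rbind, lapply(metrics, function(mname) {
      v <- dist[mname, j, ]
      data.frame(class = cls[j], metric = mname,
                 point = point[[mname]][j],
                 lower = stats::quantile(v, a, na.rm = TRUE, names = FALSE),
                 upper = stats::quantile(v, 1 - a, na.rm = TRUE,
                                         names = FALSE),
                 n_valid = sum(!is.na(v)))
    }))
  }))
  rownames(intervals) <- NULL
  list(distributions = dist, intervals = intervals,
       n_resamples = n_resamples, level = level)
}

#' McNemar test on paired misclassification indicators
#'
#' Compares two classifiers on the same records via the discordant counts
#' b (A wrong, B right) and c (A right, B wrong). The reported statistic is
#' (b - c)^2 / (b + c) (the continuity-corrected variant replaces the
#' numerator with (|b - c| - 1)^2). The p-value uses the chi-squared
#' distribution, or the exact two-sided binomial tail when `method = "exact"`
#' (the default "auto" uses the exact test when b + c < 25).
#'
#' @param errors_a,errors_b logical vectors: TRUE where each classifier is
#'   wrong on the record.
#' @param method "auto", "exact", "chisq" or "chisq_corrected".
#' @return list with `statistic`, `b`, `c`, `p.value`, `method`.
#' @export
mcnemarTest <- function(errors_a, errors_b,
                        method = c("auto", "exact", "chisq",
                                   "chisq_corrected")) {
  method <- match.arg(method)
  stopifnot(length(errors_a) == length(errors_b))
  errors_a <- as.logical(errors_a); errors_b <- as.logical(errors_b)
  b <- sum(errors_a & !errors_b)
  cc <- sum(!errors_a & errors_b)
  nd <- b + cc
  if (nd == 0)
    return(list(statistic = 0, b = b, c = cc, p.value = 1,
                method = "degenerate"))
  if (method == "auto") method <- if (nd < 25) "exact" else "chisq"
  stat <- if (method == "chisq_corrected") (abs(b - cc) - 1)^2 / nd
          else (b - cc)^2 / nd
  p <- switch(method,
    exact = min(1, 2 * stats::pbinom(min(b, cc), nd, 0.5)),
    stats::pchisq(stat, df = 1, lower.tail = FALSE))
  list(statistic = stat, b = b, c = cc, p.value = p, method = method)
}

#' Cohen's kappa for paired binary ratings
#'
#' kappa = (p_o - p_e) / (1 - p_e) from the 2 x 2 agreement table. In the
#' degenerate case p_e = 1 (both raters constant with identical marginals),
#' kappa is 1 by convention.
#'
#' @param labels_a,labels_b paired binary (or categorical) ratings.
#' @return scalar kappa in \[-1, 1\].
#' @export
cohenKappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("rating vectors must have equal length")
  lv <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lv); b <- factor(labels_b, levels = lv)
  tab <- table(a, b) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (1 - pe < .Machine$double.eps) return(1)
  (po - pe) / (1 - pe)
}

#' Full multi-label evaluation report
#'
#' Selects per-class F1-maximizing thresholds, computes operating-point
#' metrics, precision-recall curves, micro average precision and bootstrap
#' percentile intervals.
#'
#' @param scores n x 6 score matrix (canonical class order).
#' @param labels n x 6 logical label matrix.
#' @param thresholds optional fixed thresholds; default: per-class F1 maxima.
#' @param n_resamples bootstrap resamples (0 disables bootstrap).
#' @param seed integer seed for the bootstrap.
#' @return object of class "EvalReport": list with `class_scores`,
#'   `thresholds`, `pr_curves`, `micro_ap`, `bootstrap`.
#' @export
evalReport <- function(scores, labels, thresholds = NULL,
                       n_resamples = 1000, seed = 1) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  if (is.null(colnames(scores))) colnames(scores) <- ecgClasses()
  if (is.null(thresholds))
    thresholds <- vapply(seq_len(ncol(scores)), function(j)
      selectThresholdMaxF1(scores[, j], labels[, j])$threshold, numeric(1))
  cs <- classScores(scores, labels, thresholds)
  curves <- lapply(seq_len(ncol(scores)), function(j)
    prCurve(scores[, j], labels[, j]))
  names(curves) <- colnames(scores)
  bs <- if (n_resamples > 0)
    bootstrapScores(scores, labels, thresholds, n_resamples, seed)
  else NULL
  structure(list(class_scores = cs, thresholds = thresholds,
                 pr_curves = curves,
                 micro_ap = microAveragePrecision(scores, labels),
                 bootstrap = bs),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("Multi-label evaluation report\n")
  cat(sprintf("  micro average precision: %.3f\n", x$micro_ap))
  df <- x$class_scores
  cat("  per-class metrics at F1-max thresholds:\n")
  print(df[, c("class", "threshold", "precision", "recall", "specificity",
               "f1")], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Median-rule model selection by micro average precision
#'
#' Given the micro average precisions of several training runs, returns the
#' index of the run whose mAP is immediately above the median of all runs.
#'
#' @param maps numeric vector of mAP values, one per run.
#' @return integer index into `maps`.
#' @export
selectModelByMAP <- function(maps) {
  med <- stats::median(maps)
  above <- which(maps > med)
  if (!length(above)) return(which.max(maps))
  above[which.min(maps[above])]
}
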