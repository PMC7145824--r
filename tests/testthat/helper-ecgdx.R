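# Shared fixtures and independent oracles used across test files.

# Tiny network configuration for fast structural / gradient tests.
tinyConfig <- function(seed = 7, dropout = 0) {
  modelConfig(input_len = 64, n_leads = 2, n_classes = 3, n_blocks = 2,
              kernel = 5, init_filters = 4, filter_increment = 4,
              subsample = 2, dropout = dropout, seed = seed)
}

# Build an ECGRecord with beats placed at prescribed R times (seconds),
# bypassing the rhythm sampler; used to test measurements on known RR series.
recordFromRTimes <- function(rTimes, fs = 400, duration = NULL,
                             morph = beatMorphology()) {
  if (is.null(duration)) duration <- max(rTimes) + 0.6
  n <- round(duration * fs)
  sig <- matrix(0, n, 12)
  beat <- synthesizeBeat(morph, fs)
  rIdx <- attr(beat, "r_index")
  for (rt in rTimes) {
    at <- round(rt * fs) + 1L
    lo <- at - rIdx + 1L
    hi <- lo + nrow(beat) - 1L
    if (lo > n || hi < 1L) next
    bi <- seq(max(1L, lo), min(n, hi))
    sig[bi, ] <- sig[bi, ] + beat[bi - lo + 1L, ]
  }
  ECGRecord(sig, fs)
}

# Brute-force lazy-associative-classification oracle: enumerate every subset
# of the query features (up to the model's antecedent cap), score rules from
# raw corpus counts, and aggregate mean confidence per class. Independent of
# the package implementation.
bruteForceLac <- function(docs, labels, features, min_support,
                          min_confidence, max_antecedent = 3L) {
  docs <- lapply(docs, unique)
  features <- unique(features)
  nDocs <- length(docs)
  confs <- list()
  for (sz in seq_len(min(max_antecedent, length(features)))) {
    for (s in utils::combn(features, sz, simplify = FALSE)) {
      inDoc <- vapply(docs, function(d) all(s %in% d), logical(1))
      if (sum(inDoc) / nDocs < min_support || !any(inDoc)) next
      tab <- table(labels[inDoc])
      for (cl in names(tab)) {
        cf <- tab[[cl]] / sum(inDoc)
        if (cf >= min_confidence) confs[[cl]] <- c(confs[[cl]], cf)
      }
    }
  }
  if (!length(confs)) return(numeric(0))
  sort(vapply(confs, mean, numeric(1)), decreasing = TRUE)
}

# Exhaustive F1-maximizing threshold search (independent cut-point oracle).
bruteForceMaxF1 <- function(scores, labels) {
  labels <- as.logical(labels)
  best <- -Inf; bestThr <- NA_real_
  for (t in sort(unique(scores))) {
    pred <- scores >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels)
    if (tp + fp == 0 || tp + fn == 0) next
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    if (prec + rec == 0) next
    f1 <- 2 * prec * rec / (prec + rec)
    if (f1 > best || (f1 == best && t > bestThr)) { best <- f1; bestThr <- t }
  }
  list(threshold = bestThr, f1 = best)
}

# Rank-by-rank average precision oracle for distinct scores.
rankApOracle <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  ranks <- which(y)
  mean(vapply(seq_along(ranks), function(i) i / ranks[i], numeric(1)))
}
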