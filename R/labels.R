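# Text-report label extraction: stop-word removal + n-gram features, lazy
# associative classification (LAC), and rule-based class disambiguation.
# Also ships a synthetic report generator (templated Portuguese phrases per
# class) so the pipeline is testable without clinical text.

#' Default Portuguese stop-word list for ECG reports
#' @return character vector.
#' @export
defaultStopwords <- function() {
  c("de", "do", "da", "dos", "das", "e", "o", "a", "os", "as", "em", "no",
    "na", "nos", "nas", "com", "para", "por", "um", "uma", "ao", "à", "que")
}

#' Turn a text report into an n-gram feature set
#'
#' Lower-cases, strips punctuation, tokenises on whitespace, removes
#' stop-words, then forms all contiguous n-grams up to order `n` from the
#' remaining token sequence (stop-words are removed before n-gram formation).
#'
#' @param text report text (single string).
#' @param stopwords stop-word list; see [defaultStopwords()].
#' @param n maximum n-gram order (>= 1).
#' @return character vector of unique n-gram features (possibly empty).
#' @export
preprocessText <- function(text, stopwords = defaultStopwords(), n = 2L) {
  stopifnot(n >= 1L)
  x <- tolower(text)
  x <- gsub("[^[:alnum:]à-ü]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks <- toks[nzchar(toks) & !(toks %in% stopwords)]
  if (!length(toks)) return(character(0))
  grams <- unlist(lapply(seq_len(min(n, length(toks))), function(k) {
    if (k == 1L) return(toks)
    vapply(seq_len(length(toks) - k + 1L), function(i)
      paste(toks[i:(i + k - 1L)], collapse = " "), character(1))
  }))
  unique(grams)
}

#' Train a lazy associative classifier
#'
#' Stores the training corpus (feature-set, class-label pairs) together with
#' the rule-mining parameters; rules are mined lazily at query time,
#' restricted to the query's own features.
#'
#' @param docs list of character vectors (feature sets, e.g. from
#'   [preprocessText()]).
#' @param labels character vector of class labels, one per document
#'   ("normal" is an ordinary label).
#' @param min_support minimum rule support, fraction of corpus documents
#'   containing the antecedent (in (0, 1]).
#' @param min_confidence minimum rule confidence (in (0, 1]).
#' @param max_antecedent maximum antecedent size considered (default 3).
#' @return object of class "LacModel".
#' @export
lacTrain <- function(docs, labels, min_support = 0.01, min_confidence = 0.5,
                     max_antecedent = 3L) {
  stopifnot(length(docs) == length(labels),
            min_support > 0, min_support <= 1,
            min_confidence > 0, min_confidence <= 1)
  structure(list(docs = lapply(docs, unique), labels = as.character(labels),
                 min_support = min_support, min_confidence = min_confidence,
                 max_antecedent = as.integer(max_antecedent)),
            class = "LacModel")
}

#' Classify a feature set with the lazy associative classifier
#'
#' Projects the corpus onto the query's features and lazily enumerates
#' association rules `antecedent -> class` (antecedent a subset of the query
#' features, up to `max_antecedent` items) meeting the support and confidence
#' thresholds. Classes are scored by the mean confidence of their rules and
#' returned ranked (ties broken by rule count, then canonical class order).
#'
#' @param model a [lacTrain()] model.
#' @param features character vector of query features.
#' @return data.frame with columns `class`, `score`, `n_rules`, ordered by
#'   decreasing score; zero rows when no rule fires.
#' @export
lacClassify <- function(model, features) {
  stopifnot(inherits(model, "LacModel"))
  features <- unique(features)
  nDocs <- length(model$docs)
  if (!length(features) || !nDocs)
    return(data.frame(class = character(0), score = numeric(0),
                      n_rules = integer(0)))
  proj <- lapply(model$docs, function(d) sort(intersect(d, features)))
  # candidate antecedents: subsets (<= max size) of projected documents
  cand <- new.env(parent = emptyenv())
  for (d in proj) {
    k <- length(d)
    if (!k) next
    for (sz in seq_len(min(k, model$max_antecedent))) {
      combs <- utils::combn(d, sz, simplify = FALSE)
      for (s in combs) assign(paste(s, collapse = "\r"), s, envir = cand)
    }
  }
  keys <- ls(cand)
  if (!length(keys))
    return(data.frame(class = character(0), score = numeric(0),
                      n_rules = integer(0)))
  scores <- list()
  for (key in keys) {
    ante <- get(key, envir = cand)
    inDoc <- vapply(model$docs, function(d) all(ante %in% d), logical(1))
    supp <- sum(inDoc) / nDocs
    if (supp < model$min_support) next
    tab <- table(model$labels[inDoc])
    conf <- as.numeric(tab) / sum(inDoc)
    for (j in seq_along(tab)) {
      if (conf[j] >= model$min_confidence) {
        cl <- names(tab)[j]
        scores[[cl]] <- c(scores[[cl]], conf[j])
      }
    }
  }
  if (!length(scores))
    return(data.frame(class = character(0), score = numeric(0),
                      n_rules = integer(0)))
  out <- data.frame(class = names(scores),
                    score = vapply(scores, mean, numeric(1)),
                    n_rules = vapply(scores, length, integer(1)),
                    row.names = NULL)
  canon <- c(ecgClasses(), "normal")
  ord <- order(-out$score, -out$n_rules,
               match(out$class, canon, nomatch = length(canon) + 1L))
  out[ord, , drop = FALSE]
}

#' Synonym phrases used for negation scoping
#' @return named list mapping each class to its trigger phrases.
#' @export
classPhrases <- function() {
  list(
    "1dAVb" = c("bloqueio atrioventricular primeiro grau", "bav primeiro grau",
                "intervalo pr prolongado"),
    RBBB = c("bloqueio ramo direito", "brd"),
    LBBB = c("bloqueio ramo esquerdo", "bre"),
    SB = c("bradicardia sinusal"),
    AF = c("fibrilacao atrial", "fibrilação atrial"),
    ST = c("taquicardia sinusal"))
}

#' Disambiguate scored labels into a final label vector
#'
#' Applies the precedence rules: classes are kept when their aggregated
#' confidence reaches `conf_threshold`; the mutually exclusive rhythm classes
#' SB/AF/ST are resolved to the highest-confidence one; when the source text
#' is supplied, class mentions preceded (within `negation_window` tokens) by
#' a negation cue suppress that class.
#'
#' @param scored data.frame from [lacClassify()].
#' @param text optional raw report text for negation scoping.
#' @param negations negation cue tokens.
#' @param conf_threshold minimum confidence to assert a class.
#' @param negation_window how many tokens before a class phrase a cue may sit.
#' @return named logical label vector (see [labelVector()]).
#' @export
disambiguate <- function(scored, text = NULL,
                         negations = c("sem", "ausencia", "ausência",
                                       "nao", "não", "descartada",
                                       "descartado"),
                         conf_threshold = 0.6, negation_window = 3L) {
  v <- labelVector()
  if (!nrow(scored)) return(v)
  keep <- scored[scored$class %in% ecgClasses() &
                 scored$score >= conf_threshold, , drop = FALSE]
  v[keep$class] <- TRUE
  rhythm <- intersect(keep$class, c("SB", "AF", "ST"))
  if (length(rhythm) > 1L) {
    best <- keep$class[keep$class %in% rhythm][1]   # keep is ranked
    v[setdiff(rhythm, best)] <- FALSE
  }
  if (!is.null(text)) {
    toks <- strsplit(trimws(gsub("[^[:alnum:]à-ü]+", " ",
                                 tolower(text))), "\\s+")[[1]]
    # drop stop-words so phrases match regardless of connective words
    toks <- toks[nzchar(toks) & !(toks %in% defaultStopwords())]
    for (cl in names(which(v))) {
      for (ph in classPhrases()[[cl]]) {
        ph_toks <- strsplit(ph, " ")[[1]]
        ph_toks <- ph_toks[!(ph_toks %in% defaultStopwords())]
        hit <- .phrasePos(toks, ph_toks)
        if (length(hit)) {
          negated <- vapply(hit, function(i) {
            pre <- toks[max(1L, i - negation_window):max(1L, i - 1L)]
            i > 1L && any(pre %in% negations)
          }, logical(1))
          if (length(negated) && all(negated)) v[cl] <- FALSE
        }
      }
    }
  }
  v
}

# starting positions where the token sequence `ph` occurs in `toks`
.phrasePos <- function(toks, ph) {
  k <- length(ph)
  if (!k || length(toks) < k) return(integer(0))
  Filter(function(i) all(toks[i:(i + k - 1L)] == ph),
         seq_len(length(toks) - k + 1L))
}

#' Extract label vectors from free-text reports
#'
#' Full text pipeline: [preprocessText()] -> [lacClassify()] ->
#' [disambiguate()], one label vector per report.
#'
#' @param texts character vector of report texts.
#' @param model a [lacTrain()] model.
#' @param stopwords,n see [preprocessText()].
#' @param ... passed to [disambiguate()].
#' @return n x 6 logical label matrix in canonical class order.
#' @export
labelReports <- function(texts, model, stopwords = defaultStopwords(),
                         n = 2L, ...) {
  out <- t(vapply(texts, function(tx) {
    disambiguate(lacClassify(model, preprocessText(tx, stopwords, n)),
                 text = tx, ...)
  }, logical(6)))
  dimnames(out) <- list(NULL, ecgClasses())
  out
}

.reportTemplates <- function() {
  list(
    "1dAVb" = c("bloqueio atrioventricular de primeiro grau",
                "bav de primeiro grau com intervalo pr prolongado"),
    RBBB = c("bloqueio de ramo direito",
             "bloqueio completo de ramo direito"),
    LBBB = c("bloqueio de ramo esquerdo",
             "bloqueio completo de ramo esquerdo"),
    SB = c("bradicardia sinusal",
           "ritmo sinusal com bradicardia sinusal"),
    AF = c("fibrilacao atrial",
           "fibrilacao atrial com resposta ventricular"),
    ST = c("taquicardia sinusal",
           "ritmo sinusal com taquicardia sinusal"),
    normal = c("ecg dentro dos limites da normalidade",
               "tracado normal", "ritmo sinusal normal"))
}

#' Generate synthetic cardiologist reports for a label matrix
#'
#' Templated Portuguese phrases per class; a stand-in for real clinical text
#' used to exercise the extraction pipeline. Each positive class contributes
#' one phrase; all-negative records get a normal-report phrase; with
#' probability `negation_rate` a negated mention of a negative class is
#' appended (e.g. "sem fibrilacao atrial") to exercise negation scoping.
#'
#' @param labels n x 6 logical matrix (canonical class order).
#' @param negation_rate probability of appending a negated mention.
#' @param seed integer seed.
#' @return character vector of report texts.
#' @export
generateReports <- function(labels, negation_rate = 0.2, seed = 1) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tpl <- .reportTemplates()
  apply(labels, 1, function(row) {
    pos <- ecgClasses()[as.logical(row)]
    parts <- if (length(pos))
      vapply(pos, function(cl) sample(tpl[[cl]], 1L), character(1))
    else sample(tpl$normal, 1L)
    if (stats::runif(1) < negation_rate) {
      negcl <- sample(setdiff(ecgClasses(), pos), 1L)
      parts <- c(parts, paste("sem", tpl[[negcl]][1]))
    }
    paste(parts, collapse = ". ")
  })
}

#' Build the training corpus for the report classifier
#'
#' A small dictionary of (feature set, class) pairs derived from the phrase
#' templates, playing the role of the labelled-report dictionary that a real
#' deployment would assemble.
#'
#' @param n_per_class template repetitions per class.
#' @param ... passed to [preprocessText()].
#' @return a [lacTrain()] model.
#' @export
defaultLacModel <- function(n_per_class = 1L, ...) {
  tpl <- .reportTemplates()
  docs <- list(); labs <- character(0)
  for (cl in names(tpl)) {
    for (ph in rep(tpl[[cl]], n_per_class)) {
      docs[[length(docs) + 1L]] <- preprocessText(ph, ...)
      labs <- c(labs, cl)
    }
  }
  lacTrain(docs, labs)
}
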