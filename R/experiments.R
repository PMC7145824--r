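# Desk-scale end-to-end experiment: can a scaled-down residual network
# recover the generator's ground-truth labels from the raw signal?

#' Balanced generator prevalences for training experiments
#'
#' Class rates high enough that a few thousand records contain several
#' hundred positives per class (rhythm classes still mutually exclusive).
#' @return named numeric vector of length 6.
#' @export
balancedPrevalences <- function() {
  stats::setNames(c(0.18, 0.15, 0.15, 0.20, 0.20, 0.20), ecgClasses())
}

#' Label-recovery experiment
#'
#' Trains a scaled-down network (2 residual blocks, 16 initial filters) on
#' synthetic records with balanced prevalences and evaluates macro-F1 against
#' the generator's ground truth on held-out records, using per-class
#' F1-maximizing thresholds on the held-out scores. The desk-scale analogue
#' of the full-scale study evaluation.
#'
#' @param n_train records generated for training (10% held out internally as
#'   the validation split driving checkpoint selection).
#' @param n_test held-out test records (generated with an independent seed).
#' @param epochs training epochs.
#' @param seed integer seed for generation, initialization and training.
#' @param batch_size optimization batch size.
#' @param learning_rate Adam learning rate.
#' @param dropout dropout rate for the scaled network.
#' @param verbose print per-epoch progress.
#' @return list with `macro_f1`, per-class `f1`, the evaluation `report`,
#'   training `history` and the trained `network`.
#' @export
labelRecoveryExperiment <- function(n_train = 4000, n_test = 500,
                                    epochs = 6, seed = 1, batch_size = 64,
                                    learning_rate = 0.001, dropout = 0,
                                    verbose = FALSE) {
  prev <- balancedPrevalences()
  ptr <- generateTensor(n_train, prevalences = prev, seed = seed)
  pte <- generateTensor(n_test, prevalences = prev, seed = seed + 1000L)
  sp <- splitDataset(data.frame(exam_id = seq_len(n_train)), "random",
                     c(0.9, 0.05, 0.05), seed = seed)
  vidx <- c(sp$validation, sp$test)
  mcfg <- modelConfig(n_blocks = 2, init_filters = 16,
                      filter_increment = 16, dropout = dropout, seed = seed)
  tcfg <- trainConfig(learning_rate = learning_rate, max_epochs = epochs,
                      plateau_patience = min(7, max(1, epochs - 1)),
                      batch_size = batch_size, seed = seed)
  net <- buildNetwork(mcfg)
  fit <- trainNetwork(net, ptr$x, ptr$y,
                      ptr$x[vidx, , , drop = FALSE],
                      ptr$y[vidx, , drop = FALSE], tcfg, verbose = verbose,
                      subset = sp$train)
  scores <- predictProba(fit$network, pte$x)
  rep <- evalReport(scores, pte$y, n_resamples = 0)
  f1 <- stats::setNames(rep$class_scores$f1, rep$class_scores$class)
  list(macro_f1 = mean(f1), f1 = f1, report = rep, history = fit$history,
       network = fit$network)
}
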