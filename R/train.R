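# Optimization loop: average binary cross-entropy, Adam, plateau learning-
# rate schedule, best-on-validation checkpointing.

#' Training configuration
#'
#' Defaults follow the published recipe: Adam with default moment parameters
#' and learning rate 0.001, reduced by a factor of 10 after seven consecutive
#' epochs without validation-loss improvement, 50 epochs, keeping the weights
#' of the epoch with the best validation loss.
#'
#' @param learning_rate initial learning rate.
#' @param max_epochs training epochs.
#' @param plateau_patience consecutive non-improving epochs before a
#'   learning-rate reduction.
#' @param lr_reduction_factor division factor at each reduction.
#' @param batch_size records per optimization step.
#' @param beta1,beta2,adam_eps Adam moment/stabilization constants.
#' @param seed integer seed controlling shuffling and dropout.
#' @return object of class "TrainConfig".
#' @export
trainConfig <- function(learning_rate = 0.001, max_epochs = 50,
                        plateau_patience = 7, lr_reduction_factor = 10,
                        batch_size = 32, beta1 = 0.9, beta2 = 0.999,
                        adam_eps = 1e-8, seed = 1) {
  stopifnot(learning_rate > 0, max_epochs > 0, plateau_patience > 0,
            plateau_patience < max_epochs || max_epochs == 1,
            lr_reduction_factor > 1, batch_size > 0)
  structure(list(learning_rate = learning_rate, max_epochs = max_epochs,
                 plateau_patience = plateau_patience,
                 lr_reduction_factor = lr_reduction_factor,
                 batch_size = batch_size, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, seed = seed),
            class = "TrainConfig")
}

#' Average multi-label binary cross-entropy
#'
#' Mean over records and classes of -\[y log p + (1 - y) log(1 - p)\], with
#' predictions clipped to \[eps, 1 - eps\].
#'
#' @param predictions matrix of predicted probabilities.
#' @param labels matching 0/1 (or logical) matrix.
#' @param eps clipping constant (default 1e-7).
#' @return scalar loss.
#' @export
multilabelLoss <- function(predictions, labels, eps = 1e-7) {
  predictions <- as.matrix(predictions); labels <- as.matrix(labels) * 1
  stopifnot(all(dim(predictions) == dim(labels)))
  p <- pmin(pmax(predictions, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Initialize plateau learning-rate schedule state
#' @param learning_rate initial learning rate.
#' @param patience consecutive non-improving epochs before reduction.
#' @param factor division factor.
#' @return schedule state list.
#' @export
lrScheduleInit <- function(learning_rate = 0.001, patience = 7,
                           factor = 10) {
  list(lr = learning_rate, best = Inf, wait = 0L, patience = patience,
       factor = factor)
}

#' Advance the plateau learning-rate schedule by one epoch
#'
#' Improvement means a strictly lower validation loss than the best seen so
#' far; it resets the counter. After exactly `patience` consecutive
#' non-improving epochs the learning rate is divided by `factor` and the
#' counter resets.
#'
#' @param state schedule state from [lrScheduleInit()].
#' @param val_loss this epoch's validation loss.
#' @return updated state (element `lr` holds the current learning rate).
#' @export
lrScheduleStep <- function(state, val_loss) {
  if (val_loss < state$best) {
    state$best <- val_loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- state$lr / state$factor
      state$wait <- 0L
    }
  }
  state
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, opt, lr, cfg) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - cfg$beta1^opt$t
  bc2 <- 1 - cfg$beta2^opt$t
  for (k in names(params)) {
    opt$m[[k]] <- cfg$beta1 * opt$m[[k]] + (1 - cfg$beta1) * grads[[k]]
    opt$v[[k]] <- cfg$beta2 * opt$v[[k]] + (1 - cfg$beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (opt$m[[k]] / bc1) / (sqrt(opt$v[[k]] / bc2) + cfg$adam_eps)
  }
  list(params = params, opt = opt)
}

#' Train a network
#'
#' Minimizes the average binary cross-entropy with Adam, shuffling each
#' epoch, reducing the learning rate on validation plateaus, and keeping a
#' checkpoint of the weights whenever the validation loss improves. The final
#' model is the best-on-validation checkpoint. Fully reproducible under the
#' training seed (single-threaded).
#'
#' @param net an [ECGNetwork-class] (untrained or to fine-tune).
#' @param x,y training tensor (n x input_len x n_leads) and n x n_classes
#'   label matrix.
#' @param xval,yval validation tensor and labels (disjoint from training).
#' @param cfg a [trainConfig()].
#' @param verbose print one line per epoch.
#' @param subset optional integer indices: train only on these rows of
#'   `x`/`y` (avoids copying a large tensor to subset it).
#' @return object of class "TrainResult": list with `network` (best
#'   checkpoint), `history` (data.frame epoch/train_loss/val_loss/lr),
#'   `best_epoch`.
#' @export
trainNetwork <- function(net, x, y, xval, yval, cfg = trainConfig(),
                         verbose = FALSE, subset = NULL) {
  stopifnot(methods::is(net, "ECGNetwork"), inherits(cfg, "TrainConfig"))
  pool <- if (is.null(subset)) seq_len(dim(x)[1]) else as.integer(subset)
  n <- length(pool)
  if (n == 0 || dim(xval)[1] == 0) stop("empty training or validation set")
  y <- as.matrix(y) * 1; yval <- as.matrix(yval) * 1
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  mcfg <- net@config
  params <- net@params; state <- net@state
  opt <- .adamInit(params)
  sched <- lrScheduleInit(cfg$learning_rate, cfg$plateau_patience,
                          cfg$lr_reduction_factor)
  best <- list(loss = Inf, params = params, state = state, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- pool[sample.int(n)]
    tl <- 0; nb <- 0L
    for (lo in seq(1L, n, by = cfg$batch_size)) {
      hi <- min(lo + cfg$batch_size - 1L, n)
      idx <- ord[lo:hi]
      xb <- aperm(x[idx, , , drop = FALSE], c(2, 3, 1))
      yb <- y[idx, , drop = FALSE]
      step <- .fwdbwd(params, state, mcfg, xb, yb)
      if (!is.finite(step$loss))
        stop(sprintf("non-finite training loss at epoch %d (diverged); %s",
                     epoch, "reduce the learning rate"))
      state <- step$state
      upd <- .adamStep(params, step$grads, opt, sched$lr, cfg)
      params <- upd$params; opt <- upd$opt
      tl <- tl + step$loss * length(idx); nb <- nb + length(idx)
    }
    tmpNet <- methods::new("ECGNetwork", config = mcfg, params = params,
                           state = state, nParams = net@nParams)
    pv <- predictProba(tmpNet, xval, batch_size = cfg$batch_size)
    vl <- multilabelLoss(pv, yval)
    if (vl < best$loss)
      best <- list(loss = vl, params = params, state = state, epoch = epoch)
    sched <- lrScheduleStep(sched, vl)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / nb,
                                   val_loss = vl, lr = sched$lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %g",
                      epoch, tl / nb, vl, sched$lr))
  }
  bestNet <- methods::new("ECGNetwork", config = mcfg, params = best$params,
                          state = best$state, nParams = net@nParams)
  structure(list(network = bestNet, history = hist,
                 best_epoch = best$epoch), class = "TrainResult")
}

#' @export
print.TrainResult <- function(x, ...) {
  cat(sprintf("TrainResult: %d epochs, best validation loss %.4f at epoch %d\n",
              nrow(x$history), min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' Save / load network weights
#'
#' Plain-text JSON checkpoint holding the configuration, weights and
#' batch-normalization running statistics.
#'
#' @param net an [ECGNetwork-class].
#' @param path checkpoint file path.
#' @return `saveNetwork` the path (invisibly); `loadNetwork` the network.
#' @export
saveNetwork <- function(net, path) {
  obj <- list(config = net@config,
              params = lapply(net@params, function(p)
                list(dim = dim(p) %||% length(p), data = as.numeric(p))),
              state = net@state)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveNetwork
#' @export
loadNetwork <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$filter_schedule <- as.numeric(cfg$filter_schedule)
  params <- lapply(obj$params, function(p) {
    d <- as.integer(p$dim)
    if (length(d) > 1L) array(as.numeric(p$data), d) else as.numeric(p$data)
  })
  state <- lapply(obj$state, as.numeric)
  class(cfg) <- "ModelConfig"
  methods::new("ECGNetwork", config = unclass(cfg), params = params,
               state = state,
               nParams = sum(vapply(params, length, numeric(1))))
}
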