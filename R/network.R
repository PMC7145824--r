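# The unidimensional residual network: configuration, construction,
# forward pass (training and inference modes) and introspection.
#
# Topology: initial convolution (no activation) -> `n_blocks` pre-activation
# residual blocks, each BN -> ReLU -> Dropout -> Conv (x2, the second conv
# carrying the stride-4 subsampling), with a skip path of max-pooling (by the
# subsampling factor) plus a kernel-length-1 convolution when the channel
# count changes -> final BN -> ReLU -> flatten -> dense -> sigmoid.
# Convolutions are same-length zero-padded so temporal lengths are governed
# only by the subsampling. Weights use He-normal initialization, biases zero.

#' Network configuration
#'
#' Defaults mirror the published architecture: 4096-sample 12-lead input,
#' kernel length 16, 64 initial filters with 64 more every second residual
#' block (schedule 64, 64, 128, 128), subsampling by 4 in each of the 4
#' blocks, sigmoid head with 6 outputs.
#'
#' @param input_len input samples per lead; must be divisible by
#'   `subsample^n_blocks`.
#' @param n_leads input channels (12).
#' @param n_classes sigmoid outputs (6).
#' @param n_blocks number of residual blocks (default 4).
#' @param kernel convolution filter length (default 16).
#' @param init_filters filters of the initial convolution (default 64).
#' @param filter_increment filters added every second residual block
#'   (default 64).
#' @param filter_schedule optional explicit per-block filter counts,
#'   overriding the increment rule (the "every second block" reading is
#'   ambiguous; the literal default gives 64, 64, 128, 128).
#' @param subsample temporal subsampling factor per block (default 4).
#' @param dropout dropout rate applied after each in-block ReLU
#'   (default 0.8).
#' @param seed integer seed for weight initialization.
#' @return object of class "ModelConfig".
#' @export
modelConfig <- function(input_len = 4096, n_leads = 12, n_classes = 6,
                        n_blocks = 4, kernel = 16, init_filters = 64,
                        filter_increment = 64, filter_schedule = NULL,
                        subsample = 4, dropout = 0.8, seed = 1) {
  if (input_len %% subsample^n_blocks != 0)
    stop(sprintf("input_len %d is not divisible by subsample^n_blocks = %d",
                 input_len, subsample^n_blocks))
  stopifnot(n_leads > 0, n_classes > 0, n_blocks > 0, kernel > 0,
            init_filters > 0, subsample >= 1, dropout >= 0, dropout < 1)
  if (is.null(filter_schedule))
    filter_schedule <- init_filters +
      filter_increment * ((seq_len(n_blocks) - 1L) %/% 2L)
  stopifnot(length(filter_schedule) == n_blocks)
  structure(list(input_len = input_len, n_leads = n_leads,
                 n_classes = n_classes, n_blocks = n_blocks, kernel = kernel,
                 init_filters = init_filters,
                 filter_schedule = filter_schedule, subsample = subsample,
                 dropout = dropout, seed = seed),
            class = "ModelConfig")
}

#' ECGNetwork: a built (possibly trained) residual network
#'
#' @slot config the [modelConfig()] list.
#' @slot params flat named list of weight arrays.
#' @slot state flat named list of batch-normalization running statistics.
#' @slot nParams total trainable parameter count.
#' @aliases ECGNetwork-class
#' @export
setClass("ECGNetwork",
  representation(config = "list", params = "list", state = "list",
                 nParams = "numeric"))

.he <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build a residual network
#'
#' Allocates and He-initializes all weights for the topology described by the
#' configuration; biases start at zero, batch-norm scale/shift at 1/0.
#' Deterministic under the configuration seed.
#'
#' @param cfg a [modelConfig()].
#' @return an [ECGNetwork-class].
#' @export
buildNetwork <- function(cfg) {
  stopifnot(inherits(cfg, "ModelConfig"))
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  k <- cfg$kernel
  p <- list(); s <- list()
  p[["conv0.W"]] <- .he(k * cfg$n_leads, cfg$init_filters, k * cfg$n_leads)
  p[["conv0.b"]] <- numeric(cfg$init_filters)
  cin <- cfg$init_filters
  for (i in seq_len(cfg$n_blocks)) {
    co <- cfg$filter_schedule[i]
    pre <- sprintf("blk%d.", i)
    p[[paste0(pre, "bn1.g")]] <- rep(1, cin)
    p[[paste0(pre, "bn1.b")]] <- numeric(cin)
    s[[paste0(pre, "bn1.rm")]] <- numeric(cin)
    s[[paste0(pre, "bn1.rv")]] <- rep(1, cin)
    p[[paste0(pre, "conv1.W")]] <- .he(k * cin, co, k * cin)
    p[[paste0(pre, "conv1.b")]] <- numeric(co)
    p[[paste0(pre, "bn2.g")]] <- rep(1, co)
    p[[paste0(pre, "bn2.b")]] <- numeric(co)
    s[[paste0(pre, "bn2.rm")]] <- numeric(co)
    s[[paste0(pre, "bn2.rv")]] <- rep(1, co)
    p[[paste0(pre, "conv2.W")]] <- .he(k * co, co, k * co)
    p[[paste0(pre, "conv2.b")]] <- numeric(co)
    if (cin != co) {
      p[[paste0(pre, "skip.W")]] <- .he(cin, co, cin)
      p[[paste0(pre, "skip.b")]] <- numeric(co)
    }
    cin <- co
  }
  p[["bnF.g"]] <- rep(1, cin)
  p[["bnF.b"]] <- numeric(cin)
  s[["bnF.rm"]] <- numeric(cin)
  s[["bnF.rv"]] <- rep(1, cin)
  lf <- cfg$input_len / cfg$subsample^cfg$n_blocks
  p[["dense.W"]] <- .he(lf * cin, cfg$n_classes, lf * cin)
  p[["dense.b"]] <- numeric(cfg$n_classes)
  methods::new("ECGNetwork", config = unclass(cfg), params = p, state = s,
               nParams = sum(vapply(p, length, numeric(1))))
}

#' @describeIn buildNetwork total trainable parameter count
#' @param object an ECGNetwork
#' @export
setGeneric("parameterCount", function(object) standardGeneric("parameterCount"))
#' @export
setMethod("parameterCount", "ECGNetwork", function(object) object@nParams)

setMethod("show", "ECGNetwork", function(object) {
  cfg <- object@config
  cat(sprintf(
    "ECGNetwork: %d x %d input, %d residual blocks, filters (%s), %s params\n",
    cfg$input_len, cfg$n_leads, cfg$n_blocks,
    paste(cfg$filter_schedule, collapse = ", "),
    format(object@nParams, big.mark = ",")))
})

.sigmoid <- function(z) 1 / (1 + exp(-z))

.dropoutMask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  array((stats::runif(prod(dims)) >= rate) / (1 - rate), dims)
}

# Forward pass over one batch.
# x: cube (L, n_leads, B). Returns probabilities and, when train = TRUE,
# the caches needed for the backward pass plus updated BN running stats.
.fwd <- function(params, state, cfg, x, train = FALSE, momentum = 0.9,
                 eps = 1e-5) {
  cache <- list()
  bnRelu <- function(name, h) {
    o <- .bn_fwd(h, params[[paste0(name, ".g")]],
                 params[[paste0(name, ".b")]],
                 state[[paste0(name, ".rm")]],
                 state[[paste0(name, ".rv")]], train, momentum, eps, TRUE)
    if (train) {
      state[[paste0(name, ".rm")]] <<- as.numeric(o$rmean)
      state[[paste0(name, ".rv")]] <<- as.numeric(o$rvar)
      cache[[name]] <<- list(mean = as.numeric(o$mean),
                             invstd = as.numeric(o$invstd))
    }
    o$y
  }
  drop <- function(name, h) {
    if (!train || cfg$dropout <= 0) return(h)
    m <- .dropoutMask(dim(h), cfg$dropout)
    cache[[name]] <<- m
    h * m
  }
  h <- .conv1d_fwd(x, params[["conv0.W"]], params[["conv0.b"]], 1L)
  if (train) cache[["conv0.x"]] <- x
  for (i in seq_len(cfg$n_blocks)) {
    pre <- sprintf("blk%d.", i)
    xin <- h
    r1 <- bnRelu(paste0(pre, "bn1"), xin)
    d1 <- drop(paste0(pre, "do1"), r1)
    c1 <- .conv1d_fwd(d1, params[[paste0(pre, "conv1.W")]],
                      params[[paste0(pre, "conv1.b")]], 1L)
    r2 <- bnRelu(paste0(pre, "bn2"), c1)
    d2 <- drop(paste0(pre, "do2"), r2)
    c2 <- .conv1d_fwd(d2, params[[paste0(pre, "conv2.W")]],
                      params[[paste0(pre, "conv2.b")]], cfg$subsample)
    mp <- .maxpool1d_fwd(xin, cfg$subsample, cfg$subsample)
    sk <- mp$y
    hasSkipConv <- !is.null(params[[paste0(pre, "skip.W")]])
    if (hasSkipConv)
      skc <- .conv1d_fwd(sk, params[[paste0(pre, "skip.W")]],
                         params[[paste0(pre, "skip.b")]], 1L)
    else skc <- sk
    if (train)
      cache[[paste0(pre, "io")]] <- list(xin = xin, r1 = r1, d1 = d1,
                                         c1 = c1, r2 = r2, d2 = d2,
                                         mparg = mp$arg, sk = sk)
    h <- c2 + skc
  }
  rF <- bnRelu("bnF", h)
  if (train) cache[["head"]] <- list(hlast = h, rF = rF)
  dmn <- dim(rF)
  flat <- t(matrix(rF, dmn[1] * dmn[2], dmn[3]))       # B x (Lf*Cf)
  logits <- sweep(flat %*% params[["dense.W"]], 2, params[["dense.b"]], "+")
  prob <- .sigmoid(logits)
  list(prob = prob, flat = flat, cache = cache, state = state)
}

# Forward + backward over one batch; returns mean binary cross-entropy,
# gradients (flat list matching params) and the updated BN running stats.
.fwdbwd <- function(params, state, cfg, x, y, eps_clip = 1e-7) {
  fw <- .fwd(params, state, cfg, x, train = TRUE)
  p <- pmin(pmax(fw$prob, eps_clip), 1 - eps_clip)
  n <- length(p)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  g <- list()
  cache <- fw$cache
  dlogits <- (fw$prob - y) / n
  g[["dense.W"]] <- crossprod(fw$flat, dlogits)
  g[["dense.b"]] <- colSums(dlogits)
  dflat <- dlogits %*% t(params[["dense.W"]])
  hd <- cache[["head"]]
  dmn <- dim(hd$rF)
  dh <- array(t(dflat), dmn)
  bb <- .bn_bwd(dh, hd$rF, hd$hlast, cache[["bnF"]]$mean,
                cache[["bnF"]]$invstd, params[["bnF.g"]], TRUE)
  g[["bnF.g"]] <- as.numeric(bb$dgamma)
  g[["bnF.b"]] <- as.numeric(bb$dbeta)
  dh <- bb$dx
  for (i in rev(seq_len(cfg$n_blocks))) {
    pre <- sprintf("blk%d.", i)
    io <- cache[[paste0(pre, "io")]]
    # skip branch
    if (!is.null(params[[paste0(pre, "skip.W")]])) {
      sb <- .conv1d_bwd(io$sk, params[[paste0(pre, "skip.W")]], dh, 1L, TRUE)
      g[[paste0(pre, "skip.W")]] <- sb$dW
      g[[paste0(pre, "skip.b")]] <- as.numeric(sb$db)
      dsk <- sb$dx
    } else dsk <- dh
    dx_skip <- .maxpool1d_bwd(dsk, io$mparg, dim(io$xin)[1])
    # main branch
    cb2 <- .conv1d_bwd(io$d2, params[[paste0(pre, "conv2.W")]], dh,
                       cfg$subsample, TRUE)
    g[[paste0(pre, "conv2.W")]] <- cb2$dW
    g[[paste0(pre, "conv2.b")]] <- as.numeric(cb2$db)
    dd2 <- cb2$dx
    if (!is.null(cache[[paste0(pre, "do2")]]))
      dd2 <- dd2 * cache[[paste0(pre, "do2")]]
    b2 <- .bn_bwd(dd2, io$r2, io$c1, cache[[paste0(pre, "bn2")]]$mean,
                  cache[[paste0(pre, "bn2")]]$invstd,
                  params[[paste0(pre, "bn2.g")]], TRUE)
    g[[paste0(pre, "bn2.g")]] <- as.numeric(b2$dgamma)
    g[[paste0(pre, "bn2.b")]] <- as.numeric(b2$dbeta)
    cb1 <- .conv1d_bwd(io$d1, params[[paste0(pre, "conv1.W")]], b2$dx, 1L,
                       TRUE)
    g[[paste0(pre, "conv1.W")]] <- cb1$dW
    g[[paste0(pre, "conv1.b")]] <- as.numeric(cb1$db)
    dd1 <- cb1$dx
    if (!is.null(cache[[paste0(pre, "do1")]]))
      dd1 <- dd1 * cache[[paste0(pre, "do1")]]
    b1 <- .bn_bwd(dd1, io$r1, io$xin, cache[[paste0(pre, "bn1")]]$mean,
                  cache[[paste0(pre, "bn1")]]$invstd,
                  params[[paste0(pre, "bn1.g")]], TRUE)
    g[[paste0(pre, "bn1.g")]] <- as.numeric(b1$dgamma)
    g[[paste0(pre, "bn1.b")]] <- as.numeric(b1$dbeta)
    dh <- b1$dx + dx_skip
  }
  cb0 <- .conv1d_bwd(cache[["conv0.x"]], params[["conv0.W"]], dh, 1L, FALSE)
  g[["conv0.W"]] <- cb0$dW
  g[["conv0.b"]] <- as.numeric(cb0$db)
  list(loss = loss, grads = g, state = fw$state)
}

#' Forward pass: predicted class probabilities
#'
#' Runs the network in inference mode (batch-normalization running
#' statistics, dropout off); deterministic for identical inputs.
#'
#' @param net an [ECGNetwork-class].
#' @param x input tensor: n x input_len x n_leads array (a single
#'   input_len x n_leads matrix is promoted to a batch of one).
#' @param batch_size records per forward batch.
#' @return n x n_classes matrix of probabilities in (0, 1).
#' @export
predictProba <- function(net, x, batch_size = 64L) {
  cfg <- net@config
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  d <- dim(x)
  if (length(d) != 3L || d[2] != cfg$input_len || d[3] != cfg$n_leads)
    stop(sprintf("input shape mismatch: expected n x %d x %d, got %s",
                 cfg$input_len, cfg$n_leads, paste(d, collapse = " x ")))
  out <- matrix(NA_real_, d[1], cfg$n_classes,
                dimnames = list(NULL, if (cfg$n_classes == 6) ecgClasses()))
  for (lo in seq(1L, d[1], by = batch_size)) {
    hi <- min(lo + batch_size - 1L, d[1])
    xb <- aperm(x[lo:hi, , , drop = FALSE], c(2, 3, 1))
    out[lo:hi, ] <- .fwd(net@params, net@state, cfg, xb, train = FALSE)$prob
  }
  out
}

#' Layer-by-layer shape and parameter report
#'
#' @param net an [ECGNetwork-class].
#' @return data.frame with columns `layer`, `out_len`, `filters`, `params`,
#'   plus a `total_params` attribute.
#' @export
describeNetwork <- function(net) {
  cfg <- net@config
  p <- net@params
  np <- function(keys) sum(vapply(keys, function(k)
    length(p[[k]]), numeric(1)))
  L <- cfg$input_len
  rows <- list(data.frame(layer = "conv0", out_len = L,
                          filters = cfg$init_filters,
                          params = np(c("conv0.W", "conv0.b"))))
  for (i in seq_len(cfg$n_blocks)) {
    L <- L / cfg$subsample
    pre <- sprintf("blk%d.", i)
    keys <- grep(paste0("^", pre), names(p), value = TRUE, fixed = FALSE)
    rows[[i + 1L]] <- data.frame(layer = sprintf("resblock%d", i),
                                 out_len = L,
                                 filters = cfg$filter_schedule[i],
                                 params = np(keys))
  }
  rows[[length(rows) + 1L]] <-
    data.frame(layer = "head", out_len = 1,
               filters = cfg$n_classes,
               params = np(c("bnF.g", "bnF.b", "dense.W", "dense.b")))
  out <- do.call(rbind, rows)
  attr(out, "total_params") <- sum(out$params)
  out
}
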