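# Residual feed-forward classifier for tabular data, implemented directly in
# base R matrix code: an input linear transform to the hidden width, a stack
# of residual blocks (feed-forward -> layer norm -> ReLU -> dropout ->
# feed-forward -> layer norm, plus the skip connection, then ReLU), and a
# sigmoid head so the output is always a probability.

.ln_eps <- 1e-5

#' Network architecture configuration
#'
#' @param input_dim number of design-matrix columns.
#' @param hidden_width width of the hidden representation (default 64).
#' @param n_residual_blocks number of residual blocks (default 2).
#' @param dropout_rate dropout probability in `[0, 1)` applied after the
#'   first activation of each block during training (default 0.25).
#' @return a `net_config` list.
#' @export
net_config <- function(input_dim, hidden_width = 64L, n_residual_blocks = 2L,
                       dropout_rate = 0.25) {
  .assert(input_dim >= 1, "input_dim must be >= 1")
  .assert(hidden_width >= 1, "hidden_width must be >= 1")
  .assert(n_residual_blocks >= 1, "n_residual_blocks must be >= 1")
  .assert(dropout_rate >= 0 && dropout_rate < 1,
          "dropout_rate must lie in [0, 1)")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_width = as.integer(hidden_width),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 dropout_rate = dropout_rate),
            class = "net_config")
}

#' Build an (untrained) residual network classifier
#'
#' Weights use He-style initialization, reproducible from the seed. The
#' returned object predicts probabilities via [predict_proba()]; with
#' dropout disabled (the default outside training) it is a deterministic
#' function of its input.
#'
#' @param config a [net_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `resnet_classifier`.
#' @export
build_network <- function(config, seed = 1L) {
  .assert(inherits(config, "net_config"), "config must be a net_config")
  d <- config$input_dim; h <- config$hidden_width
  params <- withr::with_seed(seed, {
    blocks <- lapply(seq_len(config$n_residual_blocks), function(i) {
      list(W1 = matrix(stats::rnorm(h * h, 0, sqrt(2 / h)), h, h),
           b1 = numeric(h), g1 = rep(1, h), be1 = numeric(h),
           W2 = matrix(stats::rnorm(h * h, 0, sqrt(2 / h)), h, h),
           b2 = numeric(h), g2 = rep(1, h), be2 = numeric(h))
    })
    list(W0 = matrix(stats::rnorm(d * h, 0, sqrt(2 / d)), d, h),
         b0 = numeric(h),
         blocks = blocks,
         w = stats::rnorm(h, 0, sqrt(1 / h)),
         b = 0)
  })
  structure(
    list(config = config, params = params, seed = seed,
         specs = NULL, feature_names = NULL,
         center = NULL, scale = NULL,
         trained = FALSE, history = NULL, best_epoch = NULL),
    class = "resnet_classifier"
  )
}

#' Number of trainable parameters of a network
#' @param net a `resnet_classifier`.
#' @return integer parameter count.
#' @export
n_parameters <- function(net) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, 0)) else length(x)
  cnt(net$params)
}

.layer_norm <- function(a, g, be) {
  m <- rowMeans(a)
  xc <- a - m
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + .ln_eps)
  xh <- xc * inv
  y <- sweep(sweep(xh, 2, g, "*"), 2, be, "+")
  list(y = y, xh = xh, inv = inv)
}

# dy -> gradients wrt the LN input and its affine parameters (population
# normalization over the hidden dimension of each row).
.layer_norm_backward <- function(dy, g, cache) {
  dg <- colSums(dy * cache$xh)
  dbe <- colSums(dy)
  dxh <- sweep(dy, 2, g, "*")
  da <- (dxh - rowMeans(dxh) - cache$xh * rowMeans(dxh * cache$xh)) * cache$inv
  list(da = da, dg = dg, dbe = dbe)
}

# Forward pass. X is the (already standardized) numeric design matrix.
# dropout_rate > 0 consumes the RNG stream (training only).
.net_forward <- function(params, X, dropout_rate = 0, keep_cache = FALSE) {
  z <- sweep(X %*% params$W0, 2, params$b0, "+")
  blocks <- if (keep_cache) vector("list", length(params$blocks))
  for (i in seq_along(params$blocks)) {
    pb <- params$blocks[[i]]
    zin <- z
    a1 <- sweep(zin %*% pb$W1, 2, pb$b1, "+")
    ln1 <- .layer_norm(a1, pb$g1, pb$be1)
    r1 <- pmax(ln1$y, 0)
    if (dropout_rate > 0) {
      mask <- matrix(stats::rbinom(length(r1), 1L, 1 - dropout_rate),
                     nrow(r1)) / (1 - dropout_rate)
      d1 <- r1 * mask
    } else {
      mask <- NULL
      d1 <- r1
    }
    a2 <- sweep(d1 %*% pb$W2, 2, pb$b2, "+")
    ln2 <- .layer_norm(a2, pb$g2, pb$be2)
    zpre <- zin + ln2$y
    z <- pmax(zpre, 0)
    if (keep_cache) {
      blocks[[i]] <- list(zin = zin, ln1 = ln1, d1 = d1, mask = mask,
                          ln2 = ln2, zpre = zpre)
    }
  }
  s <- drop(z %*% params$w) + params$b
  out <- list(p = .sigmoid(s), s = s)
  if (keep_cache) {
    out$z <- z
    out$blocks <- blocks
  }
  out
}

# Backward pass for mean binary cross-entropy: dL/ds = (p - y) / n.
# The returned tree mirrors the field order of `params` exactly, since
# .map_params combines trees positionally.
.net_backward <- function(params, X, fw, dL_ds) {
  grads <- list(W0 = NULL, b0 = NULL,
                blocks = vector("list", length(params$blocks)),
                w = colSums(fw$z * dL_ds), b = sum(dL_ds))
  dz <- tcrossprod(dL_ds, params$w)  # n x h
  for (i in rev(seq_along(params$blocks))) {
    pb <- params$blocks[[i]]
    cb <- fw$blocks[[i]]
    dpre <- dz * (cb$zpre > 0)
    l2 <- .layer_norm_backward(dpre, pb$g2, cb$ln2)
    gW2 <- crossprod(cb$d1, l2$da)
    dd1 <- tcrossprod(l2$da, pb$W2)
    if (!is.null(cb$mask)) dd1 <- dd1 * cb$mask
    dl1 <- dd1 * (cb$ln1$y > 0)
    l1 <- .layer_norm_backward(dl1, pb$g1, cb$ln1)
    gW1 <- crossprod(cb$zin, l1$da)
    grads$blocks[[i]] <- list(W1 = gW1, b1 = colSums(l1$da),
                              g1 = l1$dg, be1 = l1$dbe,
                              W2 = gW2, b2 = colSums(l2$da),
                              g2 = l2$dg, be2 = l2$dbe)
    dz <- dpre + tcrossprod(l1$da, pb$W1)
  }
  grads$W0 <- crossprod(X, dz)
  grads$b0 <- colSums(dz)
  grads
}

# Element-wise combination of two parameter trees with identical shape.
.map_params <- function(f, a, b) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- .map_params(f, a[[i]], b[[i]])
    a
  } else {
    f(a, b)
  }
}

# Encode a raw feature table (or pass through a numeric matrix) and apply the
# standardization learned at training time.
.net_encode <- function(net, features) {
  X <- if (is.matrix(features)) features
       else if (is.null(net$specs)) as.matrix(features)
       else build_design_matrix(net$specs, features)
  if (!is.null(net$feature_names) && !is.null(colnames(X))) {
    X <- X[, net$feature_names, drop = FALSE]
  }
  if (!is.null(net$center)) {
    X <- sweep(sweep(X, 2, net$center, "-"), 2, net$scale, "/")
  }
  X
}

#' Predict outcome probabilities from a fitted model
#'
#' Generic probability interface used by the attribution module: any object
#' with a `predict_proba` method (the residual network, the logistic
#' benchmark fit, or a plain R function mapping a feature table to
#' probabilities) can be scored.
#'
#' @param model a fitted model.
#' @param features data frame of raw features (or, for the network, an
#'   already encoded numeric matrix).
#' @param ... passed to methods.
#' @return numeric vector of probabilities in `(0, 1)`.
#' @export
predict_proba <- function(model, features, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.resnet_classifier <- function(model, features, ...) {
  .net_forward(model$params, .net_encode(model, features))$p
}

#' @rdname predict_proba
#' @export
predict_proba.function <- function(model, features, ...) {
  p <- model(features)
  .assert(is.numeric(p), "model function must return numeric probabilities")
  p
}

#' @export
print.resnet_classifier <- function(x, ...) {
  cat(sprintf(
    "<resnet_classifier> input %d -> hidden %d, %d residual blocks, dropout %.2f; %s (%d parameters)\n",
    x$config$input_dim, x$config$hidden_width, x$config$n_residual_blocks,
    x$config$dropout_rate,
    if (x$trained) sprintf("trained, best epoch %d", x$best_epoch)
    else "untrained",
    n_parameters(x)))
  invisible(x)
}
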