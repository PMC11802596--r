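## Shallow multilayer perceptron for the 269-feature session representation:
## two ReLU hidden layers (20-40 units), softmax output, class-weighted
## cross-entropy, Adam (beta1 = 0.95, beta2 = 0.99) with inverse-scaling
## learning-rate decay (power 0.5), trained full batch (the cohorts are
## tiny). Written in plain matrix algebra so initialization, updates and
## stopping are fully seed-deterministic.

#' Network configuration
#'
#' @param units hidden units per layer, in `[20, 40]`.
#' @param learning_rate initial Adam step size, in `[0.001, 0.01]`; decays
#'   as `lr / t^0.5` over epochs (inverse scaling, power 0.5).
#' @param max_epochs full-batch epoch cap.
#' @param adam_beta1,adam_beta2 Adam moment decays.
#' @param seed initialization seed.
#' @param n_layers hidden layer count (fixed at 2).
#' @return list of class `net_config`.
#' @export
net_config <- function(units = 30, learning_rate = 0.01, max_epochs = 500,
                       adam_beta1 = 0.95, adam_beta2 = 0.99, seed = 1,
                       n_layers = 2) {
  stopifnot(units >= 20, units <= 40,
            learning_rate >= 0.001, learning_rate <= 0.01,
            n_layers == 2, max_epochs >= 1)
  structure(list(units = units, learning_rate = learning_rate,
                 max_epochs = max_epochs, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, seed = as.integer(seed),
                 n_layers = 2L),
            class = "net_config")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fit the session-level neural network
#'
#' The caller is expected to normalize features with train-only parameters
#' (see [normalize_fit()]); non-finite inputs (unimputed missing-value
#' sentinels) are an error, never silently dropped.
#'
#' @param x numeric matrix (sessions x features), already normalized.
#' @param y factor of class labels (one per row).
#' @param config a [net_config()].
#' @param class_weights named per-class weights from
#'   [compute_class_weights()]; `NULL` for unweighted.
#' @return object of class `kinetap_net` with a `predict` method returning
#'   class probabilities.
#' @export
fit_session_net <- function(x, y, config = net_config(),
                            class_weights = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x)))
    stop("non-finite feature values; impute or drop sentinel columns ",
         "before fitting")
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  if (K < 2) stop("need at least 2 classes")
  n <- nrow(x); p <- ncol(x)
  yi <- as.integer(y)
  Yhot <- matrix(0, n, K); Yhot[cbind(seq_len(n), yi)] <- 1
  w <- if (is.null(class_weights)) rep(1, n)
       else unname(class_weights[as.character(y)])
  w <- w / sum(w)

  u <- config$units
  dims <- list(c(p, u), c(u, u), c(u, K))
  params <- with_seed(config$seed, function() {
    lapply(dims, function(d)
      list(W = matrix(stats::rnorm(d[1] * d[2], 0, sqrt(2 / d[1])),
                      d[1], d[2]),
           b = rep(0, d[2])))
  })
  adam_m <- lapply(params, function(l) list(W = l$W * 0, b = l$b * 0))
  adam_v <- adam_m
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  eps <- 1e-8
  loss_hist <- rep(NA_real_, config$max_epochs)
  step <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ## forward
    z1 <- sweep(x %*% params[[1]]$W, 2, params[[1]]$b, `+`)
    a1 <- pmax(z1, 0)
    z2 <- sweep(a1 %*% params[[2]]$W, 2, params[[2]]$b, `+`)
    a2 <- pmax(z2, 0)
    z3 <- sweep(a2 %*% params[[3]]$W, 2, params[[3]]$b, `+`)
    probs <- softmax_rows(z3)
    loss <- -sum(w * log(pmax(probs[cbind(seq_len(n), yi)], 1e-12)))
    loss_hist[epoch] <- loss
    ## plateau stop: no meaningful improvement over the last 25 epochs
    if (epoch > 25 &&
        (loss_hist[epoch - 25] - loss) < 1e-7 * max(1, abs(loss))) break
    ## backward (weighted cross-entropy)
    d3 <- (probs - Yhot) * w
    g3 <- list(W = t(a2) %*% d3, b = colSums(d3))
    d2 <- (d3 %*% t(params[[3]]$W)) * (z2 > 0)
    g2 <- list(W = t(a1) %*% d2, b = colSums(d2))
    d1 <- (d2 %*% t(params[[2]]$W)) * (z1 > 0)
    g1 <- list(W = t(x) %*% d1, b = colSums(d1))
    grads <- list(g1, g2, g3)
    step <- step + 1L
    lr <- config$learning_rate / sqrt(step)
    for (l in 1:3) {
      for (nm in c("W", "b")) {
        adam_m[[l]][[nm]] <- b1 * adam_m[[l]][[nm]] +
          (1 - b1) * grads[[l]][[nm]]
        adam_v[[l]][[nm]] <- b2 * adam_v[[l]][[nm]] +
          (1 - b2) * grads[[l]][[nm]]^2
        mhat <- adam_m[[l]][[nm]] / (1 - b1^step)
        vhat <- adam_v[[l]][[nm]] / (1 - b2^step)
        params[[l]][[nm]] <- params[[l]][[nm]] -
          lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  structure(list(params = params, levels = levels(y), config = config,
                 n_epochs = epoch, loss = loss_hist[seq_len(epoch)]),
            class = "kinetap_net")
}

#' @export
predict.kinetap_net <- function(object, newdata,
                                type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  p <- object$params
  a1 <- pmax(sweep(x %*% p[[1]]$W, 2, p[[1]]$b, `+`), 0)
  a2 <- pmax(sweep(a1 %*% p[[2]]$W, 2, p[[2]]$b, `+`), 0)
  probs <- softmax_rows(sweep(a2 %*% p[[3]]$W, 2, p[[3]]$b, `+`))
  colnames(probs) <- object$levels
  if (type == "class")
    factor(object$levels[max.col(probs, ties.method = "first")],
           levels = object$levels)
  else probs
}

#' @export
print.kinetap_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<kinetap_net> 2x%d ReLU units -> %d classes; Adam lr %.4g, %d epochs\n",
    cfg$units, length(x$levels), cfg$learning_rate, x$n_epochs))
  invisible(x)
}
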