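#' Gradient reversal configuration
#'
#' The gradient reversal layer (GRL) is the identity in the forward pass
#' and multiplies the upstream gradient by `-alpha` in the backward pass,
#' so that minimizing the domain-classification loss drives the feature
#' extractor toward domain-invariant (subject-invariant) representations.
#'
#' @param enabled logical; when `FALSE` the layer is a no-op in both
#'   passes and the domain branch is omitted from training entirely (the
#'   "without GRL" ablation).
#' @param alpha reversal strength, >= 0. The reference setting is 0.1.
#' @param scheme `"binary_source_target"` (source subjects vs the
#'   unlabeled held-out subject) or `"per_subject"` (multiclass over
#'   training subjects).
#' @return object of class `grl_config`.
#' @export
grl_config <- function(enabled = TRUE, alpha = 0.1,
                       scheme = c("binary_source_target", "per_subject")) {
  scheme <- match.arg(scheme)
  stopifnot(is.logical(enabled), alpha >= 0)
  structure(list(enabled = enabled, alpha = alpha, scheme = scheme),
            class = "grl_config")
}

#' @rdname grl_config
#' @param x input array (any shape).
#' @param cfg a [grl_config()].
#' @return `grl_forward`: `x`, unchanged (identity forward pass).
#' @export
grl_forward <- function(x, cfg) {
  x
}

#' @rdname grl_config
#' @param upstream_gradient gradient flowing back from the domain branch.
#' @return `grl_backward`: `-alpha * upstream_gradient` when enabled,
#'   otherwise the gradient unchanged.
#' @export
grl_backward <- function(upstream_gradient, cfg) {
  if (!cfg$enabled) return(upstream_gradient)
  -cfg$alpha * upstream_gradient
}

#' Initialize the domain classifier
#'
#' A fully connected network with one hidden layer of `hidden_width`
#' units, batch normalization, ReLU activation and a LogSoftmax output
#' over domain labels.
#'
#' @param input_dim width of the (flattened) pooled feature vector.
#' @param n_domains number of domain classes (2 for source-vs-target).
#' @param hidden_width hidden layer width; the reference setting is 100.
#' @param seed optional local seed.
#' @return parameter list: `W1`, `b1`, `gamma`, `beta` (batch-norm scale
#'   and shift), `W2`, `b2`, plus running `mu`/`va` statistics used when
#'   `train = FALSE`.
#' @export
init_domain_params <- function(input_dim, n_domains, hidden_width = 100L,
                               seed = NULL) {
  build <- function() {
    list(W1 = glorot(input_dim, hidden_width),
         b1 = numeric(hidden_width),
         gamma = rep(1, hidden_width),
         beta = numeric(hidden_width),
         W2 = glorot(hidden_width, n_domains),
         b2 = numeric(n_domains))
  }
  p <- if (is.null(seed)) build() else with_seed(seed, build())
  attr(p, "running") <- list(mu = numeric(hidden_width),
                             va = rep(1, hidden_width), n = 0)
  p
}

bn_eps <- 1e-5

#' Domain classifier forward pass
#'
#' @param X batch x D matrix of (gradient-reversed) pooled features.
#' @param params from [init_domain_params()].
#' @param train use batch statistics (`TRUE`) or running statistics for
#'   the batch-norm layer.
#' @return list with `logp` (log-probabilities over domains; `exp` of a
#'   row sums to 1) and the intermediates needed for backprop.
#' @export
domain_classify <- function(X, params, train = TRUE) {
  if (ncol(X) != nrow(params$W1)) {
    stop("feature width ", ncol(X), " does not match domain classifier (",
         nrow(params$W1), ")")
  }
  a1 <- sweep(X %*% params$W1, 2L, params$b1, "+")
  if (train || nrow(X) > 1L) {
    mu <- colMeans(a1)
    va <- colMeans(a1^2) - mu^2
  } else {
    run <- attr(params, "running")
    mu <- run$mu
    va <- run$va
  }
  invstd <- 1 / sqrt(va + bn_eps)
  xhat <- sweep(sweep(a1, 2L, mu, "-"), 2L, invstd, "*")
  bn <- sweep(sweep(xhat, 2L, params$gamma, "*"), 2L, params$beta, "+")
  r <- relu(bn)
  logits <- sweep(r %*% params$W2, 2L, params$b2, "+")
  m <- apply(logits, 1L, max)
  logp <- logits - m - log(rowSums(exp(logits - m)))
  list(logp = logp, X = X, a1 = a1, xhat = xhat, invstd = invstd,
       bn = bn, r = r, logits = logits)
}

# negative log-likelihood loss and gradient at the logits
domain_nll <- function(dc, d_labels) {
  n <- nrow(dc$logp)
  loss <- -mean(dc$logp[cbind(seq_len(n), d_labels)])
  dlogits <- (exp(dc$logp) - one_hot(d_labels, ncol(dc$logp))) / n
  list(loss = loss, dlogits = dlogits)
}

# backward through the domain classifier; returns parameter grads and the
# gradient at its input (before the GRL is applied to it)
domain_backward <- function(params, dc, dlogits) {
  n <- nrow(dc$X)
  g <- list(W1 = NULL, b1 = NULL, gamma = NULL, beta = NULL,
            W2 = crossprod(dc$r, dlogits), b2 = colSums(dlogits))
  dr <- dlogits %*% t(params$W2)
  dbn <- dr * (dc$bn > 0)
  g$gamma <- colSums(dbn * dc$xhat)
  g$beta <- colSums(dbn)
  dxhat <- sweep(dbn, 2L, params$gamma, "*")
  # batch-norm backward (batch statistics)
  sum_dxhat <- colSums(dxhat)
  sum_dxhat_xhat <- colSums(dxhat * dc$xhat)
  da1 <- sweep(
    sweep(n * dxhat, 2L, sum_dxhat, "-") -
      sweep(dc$xhat, 2L, sum_dxhat_xhat, "*"),
    2L, dc$invstd / n, "*")
  g$W1 <- crossprod(dc$X, da1)
  g$b1 <- colSums(da1)
  dX <- da1 %*% t(params$W1)
  list(grads = g, dX = dX)
}
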