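# Manual backpropagation through the network.
#
# No autodiff framework is available in the target environment, so the
# gradients of every stage are derived and implemented by hand:
#   layer:   H = X W;  M = H A;  S = M H^T;  P = rowsoftmax(S);
#            G = (P + P^T)/2;  Z = G H;  out = relu(Z) (not after last)
#   pooling: omega_i = Z_i . v + b;  beta = softmax(omega); Z'_i = beta_i Z_i
#   head:    four affine layers with ReLU between, softmax + cross-entropy
# Correctness is established by finite-difference gradient checks in the
# test suite.

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

tree_add <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.list(a)) {
    keys <- names(a) %||% seq_along(a)
    for (i in keys) a[[i]] <- tree_add(a[[i]], b[[i]])
    a
  } else {
    a + b
  }
}

# gradient of the cross-entropy loss w.r.t. logits, averaged over the batch
ce_loss_grad <- function(probs, y) {
  n <- nrow(probs)
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), y)], 1e-12)))
  dlogits <- (probs - one_hot(y, ncol(probs))) / n
  list(loss = loss, dlogits = dlogits)
}

# backward through the classifier head; returns param grads and dX
head_backward <- function(head, hc, dlogits, activation) {
  act <- activation == "relu"
  g <- list()
  da <- dlogits
  for (i in 4:1) {
    hin <- if (i == 1L) hc$X else hc$h[[i - 1L]]
    g[[paste0("W", i)]] <- crossprod(hin, da)
    g[[paste0("b", i)]] <- colSums(da)
    dh <- da %*% t(head[[paste0("W", i)]])
    if (i > 1L) {
      da <- if (act) dh * (hc$a[[i - 1L]] > 0) else dh
    } else {
      dX <- dh
    }
  }
  list(grads = g, dX = dX)
}

# backward through pooling; dflat is B x (E*F'); returns per-item dZ list
# and pool grads
pool_backward <- function(params, config, cache, dflat) {
  Zl <- cache$Zl
  B <- length(Zl)
  E <- nrow(Zl[[1L]])
  Fp <- ncol(Zl[[1L]])
  if (config$pooling == "global_attention") {
    beta <- cache$pool$beta
    v <- params$pool$v
    dZl <- vector("list", B)
    dbeta <- matrix(0, B, E)
    for (b in seq_len(B)) {
      dZp <- matrix(dflat[b, ], E, Fp)
      dbeta[b, ] <- rowSums(dZp * Zl[[b]])  # through Z'_i = beta_i Z_i
      dZl[[b]] <- dZp * beta[b, ]
    }
    domega <- row_softmax_backward(beta, dbeta)
    dv <- numeric(Fp)
    for (b in seq_len(B)) {
      dv <- dv + drop(crossprod(Zl[[b]], domega[b, ]))
      dZl[[b]] <- dZl[[b]] + domega[b, ] %o% v  # omega_i = Z_i . v + b
    }
    list(dZ = dZl, pool = list(v = dv, b = sum(domega)))
  } else {
    # Z' = sum_i Z_i: gradient copies to every node
    dZl <- lapply(seq_len(B), function(b) {
      matrix(dflat[b, ], E, Fp, byrow = TRUE)
    })
    list(dZ = dZl, pool = NULL)
  }
}

# backward through the layer stack; dZout is a per-item gradient list at
# the stack output; returns per-layer W/A grads and the input gradients
stack_backward <- function(params, config, stack_cache, dZout) {
  L <- length(stack_cache)
  grads <- vector("list", L)
  dOut <- dZout
  for (l in L:1) {
    cc <- stack_cache[[l]]
    B <- length(cc$H)
    dZl <- if (cc$applied_act) {
      lapply(seq_len(B), function(b) dOut[[b]] * (cc$Z[[b]] > 0))
    } else {
      dOut
    }
    W <- params$layers[[l]]$W
    dW <- W * 0
    dXl <- vector("list", B)
    if (config$conv == "attention") {
      A <- params$layers[[l]]$A
      dA <- A * 0
      for (b in seq_len(B)) {
        Hb <- cc$H[[b]]
        dZb <- dZl[[b]]
        # Z = G H
        dG <- tcrossprod(dZb, Hb)
        dH <- cc$G[[b]] %*% dZb          # G symmetric
        # G = (P + P^T)/2, P = rowsoftmax(S)
        dP <- (dG + t(dG)) / 2
        dS <- row_softmax_backward(cc$P[[b]], dP)
        # S = M H^T
        dM <- dS %*% Hb
        dH <- dH + crossprod(dS, cc$M[[b]])
        # M = H A
        dH <- dH + tcrossprod(dM, A)
        dA <- dA + crossprod(Hb, dM)
        # H = X W
        dW <- dW + crossprod(cc$X[[b]], dH)
        dXl[[b]] <- tcrossprod(dH, W)
      }
      grads[[l]] <- list(W = dW, A = dA)
    } else {
      Ahat <- config$static_adjacency
      for (b in seq_len(B)) {
        dH <- Ahat %*% dZl[[b]]          # Ahat symmetric
        dW <- dW + crossprod(cc$X[[b]], dH)
        dXl[[b]] <- tcrossprod(dH, W)
      }
      grads[[l]] <- list(W = dW)
    }
    dOut <- dXl
  }
  list(layers = grads, dX = dOut)
}

#' Backward pass of the full model
#'
#' Computes gradients of a scalar loss with respect to all model
#' parameters, given the gradient at the logits and/or an extra gradient
#' injected at the pooled features (the path used by the domain branch
#' after gradient reversal).
#'
#' @param params model parameters.
#' @param config a [model_config()].
#' @param fwd result of [model_forward()] with `keep_cache = TRUE`.
#' @param dlogits gradient at the logits (B x n_classes), or `NULL` when
#'   only the pooled-feature path carries gradient.
#' @param dflat_extra additional gradient at the pooled flattened
#'   features (B x D), or `NULL`.
#' @return list with `grads` (same shape as `params`) and `dX` (gradient
#'   at the input tensor).
#' @export
model_backward <- function(params, config, fwd, dlogits = NULL,
                           dflat_extra = NULL) {
  cache <- fwd$cache
  stopifnot(!is.null(cache))
  dflat <- dflat_extra
  grads <- list(layers = NULL, head = NULL)
  if (!is.null(dlogits)) {
    hb <- head_backward(params$head, cache$head, dlogits, config$activation)
    grads$head <- hb$grads
    dflat <- if (is.null(dflat)) hb$dX else dflat + hb$dX
  } else {
    grads$head <- zeros_like(params$head)
  }
  pb <- pool_backward(params, config, cache, dflat)
  if (!is.null(pb$pool)) grads$pool <- pb$pool
  sb <- stack_backward(params, config, cache$stack, pb$dZ)
  grads$layers <- sb$layers
  # order fields like params for optimizer traversal
  out <- list(layers = grads$layers)
  if (!is.null(params$pool)) out$pool <- grads$pool
  out$head <- grads$head
  list(grads = out, dX = list_to_array(sb$dX))
}
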