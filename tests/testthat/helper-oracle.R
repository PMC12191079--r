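# Independent brute-force oracle for the network forward pass: scalar
# loops and naive softmaxes only, sharing no code with the package's
# vectorized/batched implementation.

naive_softmax <- function(x) exp(x) / sum(exp(x))

oracle_forward <- function(X, params, config) {
  B <- dim(X)[1L]
  E <- dim(X)[2L]
  act <- function(M) if (config$activation == "relu") pmax(M, 0) else M
  L <- length(params$layers)
  stages <- list()
  Zs <- vector("list", B)
  for (b in seq_len(B)) {
    cur <- matrix(X[b, , ], E)
    for (l in seq_len(L)) {
      W <- params$layers[[l]]$W
      A <- params$layers[[l]]$A
      H <- matrix(0, E, ncol(W))
      for (i in seq_len(E)) {
        for (j in seq_len(ncol(W))) {
          H[i, j] <- sum(cur[i, ] * W[, j])
        }
      }
      S <- matrix(0, E, E)
      for (i in seq_len(E)) {
        for (j in seq_len(E)) {
          S[i, j] <- drop(H[i, , drop = FALSE] %*% A %*% H[j, ])
        }
      }
      P <- t(apply(S, 1L, naive_softmax))
      G <- matrix(0, E, E)
      for (i in seq_len(E)) {
        for (j in seq_len(E)) G[i, j] <- (P[i, j] + P[j, i]) / 2
      }
      Z <- matrix(0, E, ncol(W))
      for (i in seq_len(E)) {
        for (f in seq_len(ncol(W))) Z[i, f] <- sum(G[i, ] * H[, f])
      }
      stages[[paste(b, l, sep = "_")]] <-
        list(H = H, S = S, P = P, G = G, Z = Z)
      cur <- if (l < L) act(Z) else Z
    }
    Zs[[b]] <- cur
  }
  # global attention pooling
  probs <- matrix(0, B, config$n_classes)
  flats <- vector("list", B)
  betas <- vector("list", B)
  for (b in seq_len(B)) {
    Z <- Zs[[b]]
    omega <- numeric(E)
    for (i in seq_len(E)) omega[i] <- sum(Z[i, ] * params$pool$v) + params$pool$b
    beta <- naive_softmax(omega)
    Zp <- Z
    for (i in seq_len(E)) Zp[i, ] <- beta[i] * Z[i, ]
    flat <- as.vector(Zp)  # electrode index fastest, matching the package
    h <- flat
    for (k in 1:3) {
      Wk <- params$head[[paste0("W", k)]]
      bk <- params$head[[paste0("b", k)]]
      h <- act(matrix(drop(h %*% Wk) + bk, nrow = 1L))
      h <- drop(h)
    }
    logits <- drop(h %*% params$head$W4) + params$head$b4
    probs[b, ] <- naive_softmax(logits)
    flats[[b]] <- flat
    betas[[b]] <- beta
  }
  list(probs = probs, Z = Zs, stages = stages, flat = flats, beta = betas)
}

tiny_config <- function(E = 3L, F_in = 2L, layer_dims = c(3L, 2L),
                        n_classes = 3L, ...) {
  model_config(E = E, F_in = F_in, layer_dims = layer_dims,
               classifier_dims = c(5L, 4L, 3L), n_classes = n_classes, ...)
}
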