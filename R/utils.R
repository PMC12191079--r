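# small numerical helpers shared across modules

# row-wise softmax with max-subtraction stabilization
row_softmax <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  Z <- exp(S - m)
  Z / rowSums(Z)
}

# backward of row_softmax: given P = row_softmax(S) and dP, return dS
row_softmax_backward <- function(P, dP) {
  P * (dP - rowSums(dP * P))
}

relu <- function(x) pmax(x, 0)

# batched projection: (B x E x F) array times (F x F') matrix
bmm_project <- function(X, W) {
  d <- dim(X)
  out <- matrix(X, nrow = d[1L] * d[2L]) %*% W
  array(out, c(d[1L], d[2L], ncol(W)))
}

# slice batch item b of a (B x E x F) array as an E x F matrix
bslice <- function(X, b) {
  d <- dim(X)
  matrix(X[b, , ], d[2L], d[3L])
}

# batch array (B x E x F) <-> list of per-item E x F matrices; the list
# representation keeps each item contiguous, which is what the training
# loop uses internally (strided first-axis slicing dominates runtime
# otherwise)
array_to_list <- function(X) {
  Xp <- aperm(X, c(2L, 3L, 1L))
  d <- dim(Xp)
  lapply(seq_len(d[3L]), function(b) {
    M <- Xp[, , b, drop = FALSE]
    dim(M) <- d[1:2]
    M
  })
}

list_to_array <- function(Xl) {
  d <- dim(Xl[[1L]])
  aperm(array(unlist(Xl, use.names = FALSE),
              c(d[1L], d[2L], length(Xl))), c(3L, 1L, 2L))
}

one_hot <- function(y, n_classes) {
  M <- matrix(0, length(y), n_classes)
  M[cbind(seq_along(y), y)] <- 1
  M
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
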