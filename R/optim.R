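# Adam optimizer over nested parameter lists (parameter "trees").

#' Initialize Adam optimizer state
#'
#' @param params nested list of numeric arrays.
#' @return optimizer state (first/second moment trees and step counter).
#' @export
adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

#' One Adam update step
#'
#' Standard Adam with bias correction (beta1 = 0.9, beta2 = 0.999,
#' eps = 1e-8).
#'
#' @param params nested list of numeric arrays.
#' @param grads gradient tree of the same shape.
#' @param state from [adam_init()].
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam constants.
#' @return list with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  t <- state$t + 1L
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- names(p) %||% seq_along(p)
      for (i in keys) {
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      list(p = p - lr * (m2 / bc1) / (sqrt(v2 / bc2) + eps),
           m = m2, v = v2)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
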