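# Adam optimiser over a named parameter set.

#' Create Adam state for a parameter set
#'
#' @param ps A parameter-set environment (internal to the models).
#' @param lr Learning rate.
#' @param beta1,beta2 Moment decay rates. `beta1 = 0.5` is the customary
#'   choice for adversarial training; `beta2 = 0.999` is standard.
#' @param eps Numerical floor in the update denominator.
#' @return An environment holding the optimiser state.
#' @keywords internal
adam_new <- function(ps, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(ps$v, function(x) x * 0)
  st$s <- lapply(ps$v, function(x) x * 0)
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

# One Adam update in place; `grads` is a named list aligned with ps$v
# (NULL entries are skipped).
adam_step <- function(st, ps, grads) {
  st$t <- st$t + 1L
  c1 <- 1 - st$beta1^st$t
  c2 <- 1 - st$beta2^st$t
  for (nm in names(ps$v)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- st$beta1 * st$m[[nm]] + (1 - st$beta1) * g
    st$s[[nm]] <- st$beta2 * st$s[[nm]] + (1 - st$beta2) * g * g
    ps$v[[nm]] <- ps$v[[nm]] -
      st$lr * (st$m[[nm]] / c1) / (sqrt(st$s[[nm]] / c2) + st$eps)
  }
  invisible(ps)
}
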