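# Gradient correctness of the autodiff tape: every custom
# vector-Jacobian product is checked against central finite differences,
# and a full generator pass is checked end to end.

ag <- function(name) get(name, envir = asNamespace("boldfill"))

# Check d(fn)/d(inputs) at a handful of coordinates per input.
grad_check <- function(fn, xs, probe = 3L, tol = 1e-5, seed = 99) {
  ag("ag_tape_start")()
  nodes <- lapply(xs, ag("ag_leaf"))
  out <- fn(nodes)
  ag("ag_backward")(out)
  grads <- lapply(nodes, function(n) n$grad)
  ag("ag_tape_stop")()

  set.seed(seed)
  for (nm in names(xs)) {
    ks <- sample(length(xs[[nm]]), min(probe, length(xs[[nm]])))
    for (k in ks) {
      eps <- 1e-6
      up <- xs; up[[nm]][k] <- up[[nm]][k] + eps
      dn <- xs; dn[[nm]][k] <- dn[[nm]][k] - eps
      num <- (fn(up) - fn(dn)) / (2 * eps)
      ana <- if (is.null(grads[[nm]])) 0 else grads[[nm]][k]
      expect_equal(ana, num, tolerance = tol,
                   label = sprintf("grad of %s[%d] (%s)", nm, k,
                                   deparse(substitute(fn))))
    }
  }
}

# Reduce a matrix output to a scalar with fixed weights so any op can be
# gradient-checked through a scalar loss.
to_scalar <- function(x, seed = 7) {
  v <- ag("ag_value")(x)
  set.seed(seed)
  w <- matrix(stats::rnorm(length(v)), nrow(v), ncol(v))
  ag("ag_mean")(ag("ag_mul")(x, w))
}

test_that("layer norm, affine and attention gradients match finite differences", {
  x <- rand_mat(5, 8, 1); g <- runif(8); b <- rnorm(8)
  grad_check(function(p) to_scalar(ag("ag_layernorm")(p$x, p$g, p$b)),
             list(x = x, g = g, b = b))

  W <- rand_mat(8, 6, 2); bb <- rnorm(6)
  grad_check(function(p) to_scalar(ag("ag_affine")(p$x, p$W, p$b)),
             list(x = x, W = W, b = bb))

  qkv <- rand_mat(6, 24, 3)   # N = 6 tokens, d = 8, 2 heads
  grad_check(function(p) to_scalar(ag("ag_mha_qkv")(p$qkv, 2L, 4)),
             list(qkv = qkv))
})

test_that("structural op gradients match finite differences", {
  x1 <- rand_mat(3, 8, 4); x2 <- rand_mat(3, 8, 5)
  grad_check(function(p) to_scalar(ag("ag_interleave2")(p$x1, p$x2, 2L, 4L)),
             list(x1 = x1, x2 = x2))
  x <- rand_mat(3, 12, 6)   # 2 ROIs x 6 samples flattened
  grad_check(function(p) to_scalar(ag("ag_pad_crop")(p$x, 2L, 6L, 7L)),
             list(x = x))
  grad_check(function(p) to_scalar(ag("ag_avgpool2")(p$x)), list(x = x))
  W1 <- rand_mat(4, 3, 7); W2 <- rand_mat(4, 3, 8); b <- rnorm(4)
  xa <- rand_mat(3, 10, 9); xb <- rand_mat(3, 10, 10)
  grad_check(function(p) {
    to_scalar(ag("ag_affine_left2")(p$W1, p$xa, p$W2, p$xb, p$b))
  }, list(W1 = W1, xa = xa, W2 = W2, xb = xb, b = b))
})

test_that("correlation-based op gradients match finite differences", {
  x <- rand_mat(5, 9, 11); y <- rand_mat(5, 9, 12)
  grad_check(function(p) to_scalar(ag("ag_corr_rows")(p$x)), list(x = x))
  grad_check(function(p) ag("ag_mcc_rows")(p$x, p$y), list(x = x, y = y))
  grad_check(function(p) ag("ag_mean_abs_diff")(p$x, p$y),
             list(x = x, y = y))
  grad_check(function(p) {
    to_scalar(ag("ag_ccp_features")(ag("ag_corr_rows")(p$x), c(2L, 4L)))
  }, list(x = x))
})

test_that("fused transformer block gradients match finite differences", {
  N <- 4L; T <- 6L; d <- 4L
  F <- rand_mat(2, N * T, 13)
  lg <- runif(T, 0.5, 1.5); lb <- rnorm(T)
  Wqkv <- rand_mat(T, 3 * d, 14); bqkv <- rnorm(3 * d)
  grad_check(function(p) {
    to_scalar(ag("ag_ltc_in")(p$F, 2L, N, T, p$lg, p$lb, p$Wqkv, p$bqkv))
  }, list(F = F, lg = lg, lb = lb, Wqkv = Wqkv, bqkv = bqkv))

  A <- rand_mat(N, d, 15); Wo <- rand_mat(d, T, 16); bo <- rnorm(T)
  grad_check(function(p) {
    to_scalar(ag("ag_attn_out")(p$F, 1L, N, T, p$A, p$Wo, p$bo, 0, FALSE))
  }, list(F = F, A = A, Wo = Wo, bo = bo))

  x <- rand_mat(N, T, 17)
  W1 <- rand_mat(T, 2 * T, 18); b1 <- rnorm(2 * T)
  W2 <- rand_mat(2 * T, T, 19); b2 <- rnorm(T)
  grad_check(function(p) {
    to_scalar(ag("ag_ffn")(p$x, p$lg, p$lb, p$W1, p$b1, p$W2, p$b2,
                           0, FALSE))
  }, list(x = x, lg = lg, lb = lb, W1 = W1, b1 = b1, W2 = W2, b2 = b2))
})

test_that("a full generator pass backpropagates correctly into every layer type", {
  set.seed(21)
  G <- build_generator(generator_config(L = 2, heads = 2, d_model = 16,
                                        dropout = 0), 8, 32)
  mask <- missing_mask(2, "prior")
  se <- ts_values(small_subject(2))
  sm <- ts_values(apply_mask_and_fill(small_subject(2), mask))

  loss_of <- function() {
    res <- ag("gen_apply")(G$params$v, G, sm, mask)
    ag("ag_value")(l_mrc(res$sg, se))
  }
  ag("ag_tape_start")()
  p <- ag("ps_resolve")(G$params)
  res <- ag("gen_apply")(p, G, sm, mask)
  ag("ag_backward")(l_mrc(res$sg, se))
  grads <- ag("ps_grads")(p)
  ag("ag_tape_stop")()

  # gradient flows to every learned map: no dead branches
  norms <- vapply(grads, function(g) if (is.null(g)) 0 else sum(abs(g)),
                  numeric(1))
  expect_true(all(norms > 0))

  # spot-check one parameter of each layer family numerically
  for (nm in c("enc0.ch1.Wqkv", "enc1.ch2.ln1_g", "cd1.W1", "bot.ch3.Wo",
               "cu2.W2", "skip1.W", "dec0.ch1.W1", "final.W", "final.b")) {
    k <- min(2L, length(G$params$v[[nm]]))
    eps <- 1e-6
    p0 <- G$params$v[[nm]][k]
    G$params$v[[nm]][k] <- p0 + eps; up <- loss_of()
    G$params$v[[nm]][k] <- p0 - eps; dn <- loss_of()
    G$params$v[[nm]][k] <- p0
    expect_equal(grads[[nm]][k], (up - dn) / (2 * eps), tolerance = 1e-4,
                 label = paste("generator grad", nm))
  }
})

test_that("ops fall back to plain numeric evaluation without a tape", {
  x <- rand_mat(4, 6, 22)
  expect_identical(ag("ag_avgpool2")(x),
                   (x[, c(1, 3, 5)] + x[, c(2, 4, 6)]) / 2)
  expect_equal(ag("ag_mean_abs_diff")(x, x * 0), mean(abs(x)))
  expect_false(ag("is_ag_node")(ag("ag_add")(x, x)))
})
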