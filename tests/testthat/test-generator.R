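# Architecture contracts of the U-shaped transformer generator.

test_that("generator config validates depth, heads and embedding width", {
  expect_error(generator_config(heads = 3, d_model = 64), "d_model")
  expect_error(build_generator(generator_config(L = 6), 8, 32), "too short")
  cfg <- generator_config(L = 2, heads = 2, d_model = 16)
  expect_identical(cfg$skip_mode, "concat_project")
  expect_identical(cfg$attn_scale, "paper_2l")
})

test_that("forward pass at AAL scale keeps shape, ladder and layer count", {
  set.seed(1)
  G <- build_generator(generator_config(), 90, 187)
  expect_identical(G$ladder, c(187L, 93L, 46L, 23L, 11L, 5L))
  fx <- make_paper_scale_fixture(1, seed = 3)[[1]]
  mask <- missing_mask(41, "prior")
  sm <- apply_mask_and_fill(fx, mask)
  sg <- generator_forward(G, sm, mask)
  expect_identical(dim(sg$values), c(90L, 187L))
  expect_identical(attr(sg, "mta_count"), 11L)   # 2L + 1 at L = 5
  # composite rule: observed rows bit-identical, synthesised rows in [0,1]
  expect_identical(sg$values[-41, ], sm$values[-41, ])
  expect_true(all(sg$values[41, ] >= 0 & sg$values[41, ] <= 1))
})

test_that("MT-Attention executes 2L+1 times for other depths too", {
  set.seed(2)
  ts <- small_subject(4)
  mask <- missing_mask(3, "prior")
  sm <- apply_mask_and_fill(ts, mask)
  for (L in 1:2) {
    G <- build_generator(generator_config(L = L, heads = 2, d_model = 16),
                         8, 32)
    sg <- generator_forward(G, sm, mask)
    expect_identical(attr(sg, "mta_count"), 2L * L + 1L)
  }
})

test_that("strided sampling halves/doubles lengths with floor semantics", {
  gen <- asNamespace("boldfill")
  set.seed(3)
  ps <- gen$ps_new()
  gen$init_cd(ps, "cd", 1L)
  F <- matrix(runif(8 * 187), 1, 8 * 187)
  out <- gen$cd_forward(ps$v, "cd", F, 1L, 8L, 187L)
  expect_identical(dim(out), c(2L, 8L * 93L))
  F16 <- matrix(runif(8 * 16), 1, 8 * 16)
  expect_identical(dim(gen$cd_forward(ps$v, "cd", F16, 1L, 8L, 16L)),
                   c(2L, 8L * 8L))

  ps2 <- gen$ps_new()
  gen$init_cu(ps2, "cu", 4L)
  F4 <- matrix(runif(4 * 8 * 8), 4, 8 * 8)
  up <- gen$cu_forward(ps2$v, "cu", F4, 4L, 8L, 8L, 16L)
  expect_identical(dim(up), c(2L, 8L * 16L))
  # odd target: 2 x 46 = 92, pad one repeated sample to 93
  F46 <- matrix(runif(4 * 8 * 46), 4, 8 * 46)
  up93 <- gen$cu_forward(ps2$v, "cu", F46, 4L, 8L, 46L, 93L)
  expect_identical(dim(up93), c(2L, 8L * 93L))

  # per-row independence of the strided convolution: zeroing ROI row r
  # zeroes only output row r (kernels have no cross-ROI support)
  ps3 <- gen$ps_new()
  gen$init_cd(ps3, "cd", 1L)
  S <- rand_mat(4, 16, 5)
  S[2, ] <- 0
  o <- gen$cd_forward(ps3$v, "cd", gen$flatten_feature(S), 1L, 4L, 16L)
  chan <- matrix(o[1, ], 4, 8, byrow = TRUE)
  bias <- ps3$v[["cd.b"]][1]
  expect_true(all(abs(chan[2, ] - bias) < 1e-12))
  expect_true(all(abs(chan[-2, ] - bias) > 1e-6))
})

test_that("attention maps are row-stochastic at every level", {
  set.seed(4)
  G <- build_generator(generator_config(L = 2, heads = 2, d_model = 16),
                       8, 32)
  mask <- missing_mask(2, "prior")
  sm <- apply_mask_and_fill(small_subject(5), mask)
  collect <- new.env(); collect$maps <- list()
  generator_forward(G, sm, mask, collect = collect)
  expect_gt(length(collect$maps), 0)
  for (heads in collect$maps) {
    for (A in heads) {
      expect_true(all(A >= 0))
      expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
    }
  }
})

test_that("the LTC block is the identity when its output maps are zero", {
  gen <- asNamespace("boldfill")
  set.seed(5)
  ps <- gen$ps_new()
  gen$init_ltc(ps, "blk", 16L, 8L)
  ps$v[["blk.Wo"]][] <- 0; ps$v[["blk.bo"]][] <- 0
  ps$v[["blk.W2"]][] <- 0; ps$v[["blk.b2"]][] <- 0
  S <- rand_mat(6, 16, 6)
  out <- gen$ltc_forward(ps$v, "blk", gen$flatten_feature(S), 1L, 6L, 16L,
                         heads = 2L, d_model = 8L, dropout = 0,
                         attn_scale = "paper_2l")
  expect_equal(out, S, tolerance = 1e-14)
})

test_that("eval-mode forwards are deterministic; dropout varies them", {
  set.seed(6)
  G <- build_generator(generator_config(L = 2, heads = 2, d_model = 16,
                                        dropout = 0.2), 8, 32)
  mask <- missing_mask(2, "prior")
  sm <- apply_mask_and_fill(small_subject(7), mask)
  a <- generator_forward(G, sm, mask)
  b <- generator_forward(G, sm, mask)
  expect_identical(a$values, b$values)
  set.seed(8); tr1 <- generator_forward(G, sm, mask, training = TRUE)
  set.seed(9); tr2 <- generator_forward(G, sm, mask, training = TRUE)
  expect_false(identical(tr1$values[2, ], tr2$values[2, ]))
  set.seed(8); tr3 <- generator_forward(G, sm, mask, training = TRUE)
  expect_identical(tr1$values, tr3$values)
})

test_that("additive and shared-parameter variants run and keep the contract", {
  set.seed(10)
  mask <- missing_mask(5, "prior")
  sm <- apply_mask_and_fill(small_subject(11), mask)
  for (cfg in list(generator_config(L = 2, heads = 2, d_model = 16,
                                    skip_mode = "add"),
                   generator_config(L = 2, heads = 2, d_model = 16,
                                    share_ltc = TRUE),
                   generator_config(L = 2, heads = 2, d_model = 16,
                                    attn_scale = "sqrt_dhead"))) {
    G <- build_generator(cfg, 8, 32)
    sg <- generator_forward(G, sm, mask)
    expect_identical(dim(sg$values), c(8L, 32L))
    expect_identical(sg$values[-5, ], sm$values[-5, ])
  }
})
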