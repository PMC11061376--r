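# The alternating training loop: smoke behaviour, update routing,
# reproducibility, checkpoint round-trips and the experiment drivers
# (scales kept small for turnaround; the study-scale run lives with the
# acceptance checks).

test_that("training produces finite losses and a complete log", {
  ds <- mini_dataset(1)
  fit <- train(mini_config(epochs = 3), ds)
  expect_identical(nrow(fit$log), 3L)
  expect_true(all(is.finite(as.matrix(fit$log[, -1]))))
  expect_true(all(c("loss_d", "loss_g", "l_mrc", "l_mrc_tmae", "l_mrc_mcc",
                    "l_mrc_topo", "om_real", "om_fake") %in% names(fit$log)))
  # o_m batch means are logged every epoch; epoch-0 evaluation is present
  expect_identical(fit$eval_log$epoch[1L], 0L)
  expect_identical(nrow(fit$eval_log), 4L)
})

test_that("identical seeds reproduce the whole loss trajectory", {
  ds <- mini_dataset(2)
  f1 <- train(mini_config(epochs = 2, seed = 5), ds)
  f2 <- train(mini_config(epochs = 2, seed = 5), ds)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$eval_log, f2$eval_log)
  f3 <- train(mini_config(epochs = 2, seed = 6), ds)
  expect_false(identical(f1$log$loss_g, f3$log$loss_g))
})

test_that("each update touches only its own model's parameters", {
  ns <- asNamespace("boldfill")
  ds <- mini_dataset(3)
  cfg <- mini_config(epochs = 1)
  subjects <- lapply(ds, `[[`, "ts")
  set.seed(cfg$seed)
  G <- build_generator(cfg$generator, 10, 32)
  D <- build_discriminator(cfg$discriminator, 10, 32, 1)
  state <- new.env()
  state$G <- G; state$D <- D; state$config <- cfg
  state$adamG <- ns$adam_new(G$params, 0)      # frozen generator
  state$adamD <- ns$adam_new(D$params, cfg$lr_discriminator)
  sm <- ns$ts_values(apply_mask_and_fill(subjects[[1]], cfg$mask, seed = 1))
  batch <- list(list(se = ns$ts_values(subjects[[1]]), sm = sm))
  g_before <- G$params$v; d_before <- D$params$v
  rec <- train_step(batch, state)
  expect_true(all(vapply(rec[c("loss_d", "loss_g", "l_mrc")],
                         is.finite, logical(1))))
  expect_identical(G$params$v, g_before)            # lr 0: G untouched
  expect_false(identical(D$params$v, d_before))     # D moved

  # and the converse: freeze D, move G
  state$adamG <- ns$adam_new(G$params, cfg$lr_generator)
  state$adamD <- ns$adam_new(D$params, 0)
  d_mid <- D$params$v
  train_step(batch, state)
  expect_identical(D$params$v, d_mid)
  expect_false(identical(G$params$v, g_before))
})

test_that("the best checkpoint reloads and reproduces its evaluation MAE", {
  ns <- asNamespace("boldfill")
  ds <- mini_dataset(4)
  d <- withr::local_tempdir()
  cfg <- mini_config(epochs = 2)
  fit <- train(cfg, ds, out_dir = d)
  expect_true(file.exists(file.path(d, "generator.rds")))
  expect_true(file.exists(file.path(d, "generator.rds.json")))
  expect_true(file.exists(file.path(d, "train_log.jsonl")))

  G2 <- load_checkpoint(file.path(d, "generator.rds"))
  test_ts <- lapply(ds[fit$test_idx], `[[`, "ts")
  mae <- mean(vapply(seq_along(test_ts), function(i) {
    sm <- apply_mask_and_fill(test_ts[[i]], cfg$mask,
                              seed = ns$fill_seed(cfg, fit$test_idx[i]))
    mae_missing(generator_forward(G2, sm, cfg$mask), test_ts[[i]], cfg$mask)
  }, numeric(1)))
  expect_equal(mae, fit$best$mae, tolerance = 1e-6)

  # restore_timeseries keeps observed rows and fills the missing one
  out <- restore_timeseries(fit$generator, test_ts[[1]], cfg$mask)
  expect_identical(out$values[-4, ], test_ts[[1]]$values[-4, ])
})

test_that("training rejects inconsistent inputs with clear messages", {
  expect_error(train(mini_config(), list()), "empty")
  ds <- mini_dataset(5, n_subjects = 2)
  bad <- mini_config()
  bad$generator <- generator_config(L = 5)
  expect_error(train(bad, ds), "too short")
  expect_error(train(mini_config(mask = missing_mask(11, "prior")), ds),
               "exceeds ROI count")
})

test_that("the fill-strategy study tabulates all four strategies reproducibly", {
  ds <- mini_dataset(6)
  cfg <- mini_config(epochs = 1)
  tab <- run_init_study(cfg, ds, seeds = 3)
  expect_identical(nrow(tab), 4L)
  expect_setequal(tab$strategy, c("zero", "random", "gaussian", "prior"))
  expect_true(all(is.finite(tab$mean_mae)))
  tab2 <- run_init_study(cfg, ds, seeds = 3)
  expect_identical(tab, tab2)
})

test_that("cumulative masking tabulates one row per missing count", {
  ds <- mini_dataset(7)
  cfg <- mini_config(epochs = 1)
  tab <- run_cumulative_masking(cfg, ds, max_missing = 2)
  expect_identical(tab$n_missing, 1:2)
  expect_true(all(is.finite(tab$mean_mae)))
  expect_identical(run_cumulative_masking(cfg, ds, max_missing = 2), tab)
  expect_error(run_cumulative_masking(cfg, ds, max_missing = 10), "< N")
})
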