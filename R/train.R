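# Alternating adversarial training (discriminator step, then generator
# step, once each per batch), periodic held-out evaluation, best-by-MAE
# checkpointing, and the fill-strategy / cumulative-masking experiment
# drivers.

#' Training configuration
#'
#' @param generator A [generator_config()].
#' @param discriminator A [discriminator_config()].
#' @param loss A [loss_config()].
#' @param mask A [missing_mask()] defining the restoration scenario (which
#'   ROIs are missing and how they are initialised).
#' @param lr_generator Generator Adam learning rate (default 3e-4).
#' @param lr_discriminator Discriminator Adam learning rate (default 1e-4).
#' @param batch_size Subjects per batch (default 16).
#' @param epochs Training epochs (default 500).
#' @param optimizer Only `"adam"` (moments 0.5/0.999).
#' @param seed Integer seed governing initialisation, fills, dropout and
#'   shuffling; identical seeds reproduce the full loss trajectory.
#' @param eval_every Held-out evaluation period in epochs (default 10).
#' @return An object of class `train_config`.
#' @export
train_config <- function(generator = generator_config(),
                         discriminator = discriminator_config(),
                         loss = loss_config(),
                         mask = missing_mask(1L, "prior"),
                         lr_generator = 3e-4, lr_discriminator = 1e-4,
                         batch_size = 16L, epochs = 500L,
                         optimizer = "adam", seed = 1L, eval_every = 10L) {
  stopifnot(lr_generator > 0, lr_discriminator > 0, batch_size >= 1L,
            epochs >= 1L, identical(optimizer, "adam"), eval_every >= 1L)
  structure(list(generator = generator, discriminator = discriminator,
                 loss = loss, mask = mask,
                 lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 seed = as.integer(seed),
                 eval_every = as.integer(eval_every)),
            class = "train_config")
}

# Normalise dataset input: accept roi_timeseries lists or
# generate_dataset() output (list of $ts/$connectivity pairs).
dataset_series <- function(dataset) {
  if (length(dataset) == 0L) stop("dataset is empty")
  lapply(dataset, function(d) {
    if (inherits(d, "roi_timeseries")) d
    else if (is.list(d) && inherits(d$ts, "roi_timeseries")) d$ts
    else stop("dataset elements must be roi_timeseries (or carry $ts)")
  })
}

fill_seed <- function(config, subject_idx) {
  as.integer((as.numeric(config$seed) * 131L + subject_idx) %% 2147483587)
}

#' One alternating adversarial update
#'
#' First updates the discriminator on the batch (real samples scored
#' against generated samples treated as constants), then updates the
#' generator on its adversarial loss plus `alpha` times the
#' multi-resolution consistency loss. Parameters of the model not being
#' updated are left untouched.
#'
#' @param batch List of elements with `se` (empirical matrix) and `sm`
#'   (masked-and-filled matrix), shapes consistent with the state's models.
#' @param state Training state from [train()] internals: an environment
#'   with generator `G`, discriminator `D`, their Adam states, the
#'   `config` and `mask`.
#' @return A structured loss record: `loss_d`, `loss_g`, `l_mrc` (with its
#'   three term subtotals), and batch-mean scores `om_real`, `om_fake`.
#' @export
train_step <- function(batch, state) {
  G <- state$G; D <- state$D
  cfg <- state$config
  mask <- cfg$mask
  n <- length(batch)

  # generated samples for the discriminator update (constants: no tape)
  fakes <- lapply(batch, function(b) {
    ag_value(gen_apply(G$params$v, G, b$sm, mask, training = TRUE)$sg)
  })

  ag_tape_start()
  pD <- ps_resolve(D$params)
  d_loss <- 0; om_r <- 0; om_f <- 0
  for (i in seq_len(n)) {
    sr <- disc_apply(pD, D, batch[[i]]$se, mask, training = TRUE)$om
    sf <- disc_apply(pD, D, fakes[[i]], mask, training = TRUE)$om
    d_loss <- ag_add(d_loss, loss_D(sr, sf))
    om_r <- om_r + ag_value(sr); om_f <- om_f + ag_value(sf)
  }
  d_loss <- ag_scale(d_loss, 1 / n)
  d_val <- ag_value(d_loss)
  if (!is.finite(d_val)) {
    ag_tape_stop()
    stop("non-finite discriminator loss (loss_D = ", d_val, ")")
  }
  ag_backward(d_loss)
  gD <- ps_grads(pD)
  ag_tape_stop()
  adam_step(state$adamD, D$params, gD)

  # generator update: adversarial + weighted consistency loss
  ag_tape_start()
  pG <- ps_resolve(G$params)
  g_adv <- 0; g_mrc <- 0
  t1 <- 0; t2 <- 0; t3 <- 0
  for (i in seq_len(n)) {
    res <- gen_apply(pG, G, batch[[i]]$sm, mask, training = TRUE)
    sf <- disc_apply(D$params$v, D, res$sg, mask, training = TRUE)$om
    g_adv <- ag_add(g_adv, loss_G(sf))
    lm <- l_mrc(res$sg, batch[[i]]$se, cfg$loss, detail = TRUE)
    g_mrc <- ag_add(g_mrc, lm$total)
    t1 <- t1 + lm$tmae_term; t2 <- t2 + lm$mcc_term; t3 <- t3 + lm$topo_term
  }
  g_total <- ag_scale(ag_add(g_adv, ag_scale(g_mrc, cfg$loss$alpha)), 1 / n)
  g_val <- ag_value(g_total)
  if (!is.finite(g_val)) {
    adv <- ag_value(g_adv); mrc <- ag_value(g_mrc)
    ag_tape_stop()
    stop("non-finite generator loss (loss_G = ", adv, ", l_mrc = ", mrc, ")")
  }
  ag_backward(g_total)
  gG <- ps_grads(pG)
  ag_tape_stop()
  adam_step(state$adamG, G$params, gG)

  list(loss_d = d_val,
       loss_g = ag_value(g_adv) / n,
       l_mrc = ag_value(g_mrc) / n,
       l_mrc_tmae = t1 / n, l_mrc_mcc = t2 / n, l_mrc_topo = t3 / n,
       om_real = om_r / n, om_fake = om_f / n)
}

# Held-out evaluation: restore each test subject (dropout off) and average
# the missing-ROI metrics.
eval_split <- function(G, subjects, sms, mask) {
  per <- lapply(seq_along(subjects), function(i) {
    sg <- generator_forward(G, sms[[i]], mask, training = FALSE)
    rep <- evaluate_restoration(sg, subjects[[i]], mask)
    rep$mcc_val <- mcc(miss_rows(sg, mask), miss_rows(subjects[[i]], mask))
    rep
  })
  list(mae = mean(vapply(per, `[[`, numeric(1), "mae")),
       rmse = mean(vapply(per, `[[`, numeric(1), "rmse")),
       r2 = mean(vapply(per, `[[`, numeric(1), "r2")),
       dtw = mean(vapply(per, `[[`, numeric(1), "dtw")),
       mcc = mean(vapply(per, `[[`, numeric(1), "mcc_val")))
}

#' Train the adversarial restoration model
#'
#' Splits the dataset 80/20 by subject (the trailing fifth is held out),
#' builds generator and discriminator for the dataset geometry, then runs
#' `epochs` of alternating updates. The held-out missing-ROI MAE is
#' evaluated before training (epoch 0) and every `eval_every` epochs; the
#' best-by-MAE parameters are kept as the returned model.
#'
#' @param config A [train_config()].
#' @param dataset List of [roi_timeseries()] subjects (the output of
#'   [generate_dataset()] is accepted directly). At least 2 subjects.
#' @param out_dir Optional directory: saves the best generator checkpoint
#'   (`generator.rds`) and a JSONL training log (`train_log.jsonl`).
#' @param verbose Print a line per evaluation.
#' @return An object of class `boldfill_fit`: the best `generator`, final
#'   `discriminator`, `config`, per-epoch `log` data frame, `eval_log`
#'   data frame (epoch 0 included), `best` (epoch and MAE) and the
#'   held-out subject indices.
#' @export
train <- function(config, dataset, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  subjects <- dataset_series(dataset)
  if (length(subjects) < 2L) stop("need at least 2 subjects (train + test)")
  N <- nrow(subjects[[1L]]$values); T <- ncol(subjects[[1L]]$values)
  for (s in subjects) stopifnot(all(dim(s$values) == c(N, T)))
  check_mask(config$mask, N)
  if (T %/% 2L^config$generator$L < 2L) {
    stop("T = ", T, " too short for generator depth L = ",
         config$generator$L)
  }

  set.seed(config$seed)
  n <- length(subjects)
  n_test <- max(1L, round(0.2 * n))
  test_idx <- seq.int(n - n_test + 1L, n)
  train_idx <- setdiff(seq_len(n), test_idx)

  G <- build_generator(config$generator, N, T)
  D <- build_discriminator(config$discriminator, N, T,
                           length(config$mask$missing_indices))
  state <- new.env(parent = emptyenv())
  state$G <- G; state$D <- D; state$config <- config
  state$adamG <- adam_new(G$params, config$lr_generator)
  state$adamD <- adam_new(D$params, config$lr_discriminator)

  sms <- lapply(seq_len(n), function(i) {
    ts_values(apply_mask_and_fill(subjects[[i]], config$mask,
                                  seed = fill_seed(config, i)))
  })
  ses <- lapply(subjects, ts_values)
  test_se <- subjects[test_idx]
  test_sm <- sms[test_idx]

  ev0 <- eval_split(G, test_se, test_sm, config$mask)
  best <- list(epoch = 0L, mae = ev0$mae, params = G$params$v)
  eval_log <- data.frame(epoch = 0L, mae = ev0$mae, rmse = ev0$rmse,
                         r2 = ev0$r2, dtw = ev0$dtw, mcc = ev0$mcc)
  if (verbose) message(sprintf("epoch %4d  eval MAE %.4f", 0L, ev0$mae))

  log_rows <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- if (length(train_idx) == 1L) train_idx else sample(train_idx)
    recs <- list()
    for (start in seq.int(1L, length(ord), by = config$batch_size)) {
      ids <- ord[seq.int(start, min(start + config$batch_size - 1L,
                                    length(ord)))]
      batch <- lapply(ids, function(i) list(se = ses[[i]], sm = sms[[i]]))
      recs[[length(recs) + 1L]] <- train_step(batch, state)
    }
    agg <- function(f) mean(vapply(recs, `[[`, numeric(1), f))
    log_rows[[ep]] <- data.frame(
      epoch = ep, loss_d = agg("loss_d"), loss_g = agg("loss_g"),
      l_mrc = agg("l_mrc"), l_mrc_tmae = agg("l_mrc_tmae"),
      l_mrc_mcc = agg("l_mrc_mcc"), l_mrc_topo = agg("l_mrc_topo"),
      om_real = agg("om_real"), om_fake = agg("om_fake"))

    if (ep %% config$eval_every == 0L || ep == config$epochs) {
      ev <- eval_split(G, test_se, test_sm, config$mask)
      eval_log <- rbind(eval_log,
                        data.frame(epoch = ep, mae = ev$mae, rmse = ev$rmse,
                                   r2 = ev$r2, dtw = ev$dtw, mcc = ev$mcc))
      if (ev$mae < best$mae) {
        best <- list(epoch = ep, mae = ev$mae, params = G$params$v)
      }
      if (verbose) message(sprintf("epoch %4d  eval MAE %.4f", ep, ev$mae))
    }
  }

  G$params$v <- best$params   # the fit exposes the best-by-MAE generator
  fit <- structure(list(generator = G, discriminator = D, config = config,
                        log = do.call(rbind, log_rows), eval_log = eval_log,
                        best = best[c("epoch", "mae")],
                        test_idx = test_idx),
                   class = "boldfill_fit")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(G, file.path(out_dir, "generator.rds"))
    con <- file(file.path(out_dir, "train_log.jsonl"), "w")
    for (i in seq_len(nrow(fit$log))) {
      writeLines(jsonlite::toJSON(as.list(fit$log[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    }
    close(con)
  }
  fit
}

#' @export
print.boldfill_fit <- function(x, ...) {
  cat(sprintf("<boldfill_fit> %d epochs; best eval MAE %.4f at epoch %d\n",
              max(x$log$epoch), x$best$mae, x$best$epoch))
  invisible(x)
}

#' Restore the missing ROIs of a time-series with a trained generator
#'
#' Applies the configured mask-and-fill initialisation and runs the
#' generator in evaluation mode.
#'
#' @param model A trained [build_generator()] (e.g. `fit$generator`).
#' @param ts A normalised [roi_timeseries()].
#' @param mask A [missing_mask()].
#' @param seed Seed for stochastic fill strategies.
#' @return The restored [roi_timeseries()].
#' @export
restore_timeseries <- function(model, ts, mask, seed = 1L) {
  sm <- apply_mask_and_fill(ts, mask, seed = seed)
  generator_forward(model, sm, mask, training = FALSE)
}

#' Compare missing-ROI fill strategies
#'
#' Trains one model per fill strategy (all other settings and seeds
#' shared) and tabulates the held-out missing-ROI MAE with its standard
#' error across seeds.
#'
#' @param config A [train_config()]; its mask supplies the missing indices.
#' @param dataset As in [train()].
#' @param strategies Fill strategies to compare (default all four).
#' @param seeds Integer seeds (default three consecutive from
#'   `config$seed`).
#' @return Data frame with one row per strategy: `strategy`, `mean_mae`,
#'   `stderr`.
#' @export
run_init_study <- function(config, dataset,
                           strategies = c("zero", "random", "gaussian", "prior"),
                           seeds = config$seed + 0:2) {
  rows <- lapply(strategies, function(st) {
    maes <- vapply(seeds, function(sd) {
      cfg <- config
      cfg$mask <- missing_mask(config$mask$missing_indices, st)
      cfg$seed <- as.integer(sd)
      train(cfg, dataset)$best$mae
    }, numeric(1))
    data.frame(strategy = st, mean_mae = mean(maes),
               stderr = stats::sd(maes) / sqrt(length(maes)))
  })
  do.call(rbind, rows)
}

#' Restoration error as missing ROIs accumulate
#'
#' Cumulatively masks adjacent ROI indices (starting from the first index
#' of the configured mask) and trains/evaluates a model at each
#' `N_m = 1..max_missing`, averaging over seeds.
#'
#' @inheritParams run_init_study
#' @param max_missing Largest number of missing ROIs; `< N`.
#' @return Data frame with `n_missing` and `mean_mae`, one row per `N_m`.
#' @export
run_cumulative_masking <- function(config, dataset, max_missing,
                                   seeds = config$seed) {
  subjects <- dataset_series(dataset)
  N <- nrow(subjects[[1L]]$values)
  if (max_missing >= N) stop("max_missing must be < N")
  start <- min(config$mask$missing_indices)
  if (start + max_missing - 1L > N) stop("adjacent mask would exceed N")
  rows <- lapply(seq_len(max_missing), function(nm) {
    maes <- vapply(seeds, function(sd) {
      cfg <- config
      cfg$mask <- missing_mask(seq.int(start, start + nm - 1L),
                               config$mask$fill_strategy)
      cfg$seed <- as.integer(sd)
      train(cfg, dataset)$best$mae
    }, numeric(1))
    data.frame(n_missing = nm, mean_mae = mean(maes))
  })
  do.call(rbind, rows)
}
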