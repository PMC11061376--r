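# The multi-resolution relational discriminator. Three learned
# dimension-halving (DH) convolutions produce views at T/2, T/4 and T/8;
# each view is scored by (a) a multi-head ROI-attention branch pooled into
# a scalar header and (b) a central-connectivity-perception (CCP) branch
# that reads the missing-ROI rows of the Pearson connectivity matrix.
# The per-resolution scores o1..o3 aggregate as o_m = (o1 + o2 + o3) / 6 —
# the divisor averages the six underlying branch scalars. Scores are
# unbounded reals (least-squares GAN convention with targets 1/0), so the
# equilibrium value o_m -> 0.5 emerges from the loss, not from a sigmoid.

#' Discriminator configuration
#'
#' @param heads Number of attention heads in the MHA branches (default 4).
#' @param d_model Attention embedding width (default 64); divisible by
#'   `heads`.
#' @param header_hidden Hidden width of the two-layer scoring header
#'   (default 32).
#' @param sigmoid If `TRUE`, squash branch scores through a sigmoid
#'   (optional variant; default `FALSE`, unbounded least-squares scores).
#' @return An object of class `discriminator_config`.
#' @export
discriminator_config <- function(heads = 4L, d_model = 64L,
                                 header_hidden = 32L, sigmoid = FALSE) {
  stopifnot(heads >= 1L, d_model >= heads, d_model %% heads == 0L,
            header_hidden >= 1L)
  structure(list(heads = as.integer(heads), d_model = as.integer(d_model),
                 header_hidden = as.integer(header_hidden),
                 sigmoid = isTRUE(sigmoid)),
            class = "discriminator_config")
}

#' Build a discriminator for a fixed geometry and mask size
#'
#' Each of the three resolutions owns independent parameters for its DH
#' convolution, attention branch, header and CCP linear map (3 x 2
#' parameter groups). The CCP feature length is `N_m * (N - 1)`, so the
#' model is tied to the number of missing ROIs it scores.
#'
#' @param cfg A [discriminator_config()].
#' @param N Number of ROIs.
#' @param T Number of timepoints; requires `T >= 24` so that the deepest
#'   view keeps `T/8 >= 3` samples for correlation.
#' @param n_missing Number of missing ROIs `N_m` the CCP branch attends to.
#' @return An object of class `boldfill_discriminator`.
#' @export
build_discriminator <- function(cfg, N, T, n_missing = 1L) {
  stopifnot(inherits(cfg, "discriminator_config"), n_missing >= 1L,
            n_missing < N)
  Ts <- c(T %/% 2L, T %/% 4L, T %/% 8L)
  if (Ts[3L] < 3L) stop("T >= 24 required: the T/8 view needs >= 3 samples")
  ps <- ps_new()
  for (i in 1:3) {
    # learned stride-2 kernel, initialised near plain averaging
    ps_add(ps, paste0("dh", i, ".w1"), 0.5 + stats::rnorm(1L, 0, 0.05))
    ps_add(ps, paste0("dh", i, ".w2"), 0.5 + stats::rnorm(1L, 0, 0.05))
    ps_add(ps, paste0("dh", i, ".b"), 0)
    init_ltc(ps, paste0("mha", i), Ts[i], cfg$d_model)
    ps_add(ps, paste0("head", i, ".W1"),
           glorot(Ts[i], cfg$header_hidden))
    ps_add(ps, paste0("head", i, ".b1"), rep(0, cfg$header_hidden))
    ps_add(ps, paste0("head", i, ".W2"),
           glorot(cfg$header_hidden, 1L) * 0.1)
    ps_add(ps, paste0("head", i, ".b2"), 0)
    ps_add(ps, paste0("ccp", i, ".W"),
           glorot(n_missing * (N - 1L), 1L) * 0.1)
    ps_add(ps, paste0("ccp", i, ".b"), 0)
  }
  structure(list(params = ps, cfg = cfg, N = as.integer(N),
                 T = as.integer(T), n_missing = as.integer(n_missing),
                 T_levels = Ts),
            class = "boldfill_discriminator")
}

#' @export
print.boldfill_discriminator <- function(x, ...) {
  cat(sprintf("<boldfill_discriminator> N = %d, T = %d, views T/2 T/4 T/8 = %s, N_m = %d\n",
              x$N, x$T, paste(x$T_levels, collapse = "/"), x$n_missing))
  invisible(x)
}

# Learned stride-2, kernel-2 convolution per ROI row, channels unchanged.
dh_apply <- function(p, prefix, S, N) {
  T <- ncol(ag_value(S))
  To <- T %/% 2L
  odd <- seq.int(1L, by = 2L, length.out = To)
  ag_add(ag_add(ag_mul(ag_cols(S, odd), p[[paste0(prefix, ".w1")]]),
                ag_mul(ag_cols(S, odd + 1L), p[[paste0(prefix, ".w2")]])),
         p[[paste0(prefix, ".b")]])
}

#' Learned dimension-halving of a multi-ROI view
#'
#' Applies resolution `level`'s learned stride-2 convolution (kernel 2,
#' channel count preserved, per ROI row): `N x T -> N x floor(T/2)`. This
#' is the discriminator's trainable resampler — deliberately a different
#' code path from the deterministic [dh_resample()] used inside the loss.
#'
#' @param model A [build_discriminator()] object.
#' @param S An `N x T_cur` matrix ([roi_timeseries()] accepted), `T >= 2`.
#' @param level Which DH stage's parameters to use (1, 2 or 3).
#' @return An `N x floor(T/2)` matrix.
#' @export
dh_module <- function(model, S, level = 1L) {
  v <- ts_values(S)
  if (ncol(v) < 2L) stop("T >= 2 required for halving")
  p <- ps_resolve(model$params)
  ag_value(dh_apply(p, paste0("dh", level), v, nrow(v)))
}

mha_header_apply <- function(p, model, i, R, training = FALSE) {
  cfg <- model$cfg
  Rf <- flatten_node(R)
  h <- ltc_forward(p, paste0("mha", i), Rf, 1L, model$N, model$T_levels[i],
                   cfg$heads, cfg$d_model, dropout = 0,
                   attn_scale = "sqrt_dhead", training = training)
  pooled <- ag_mean_rows(h)
  z <- ag_relu(ag_affine(pooled, p[[paste0("head", i, ".W1")]],
                         p[[paste0("head", i, ".b1")]]))
  out <- ag_as_scalar(ag_affine(z, p[[paste0("head", i, ".W2")]],
                                p[[paste0("head", i, ".b2")]]))
  if (cfg$sigmoid) out <- ag_sigmoid(out)
  out
}

ccp_apply <- function(p, i, R, missing, sigmoid = FALSE) {
  C <- ag_corr_rows(R)
  feat <- ag_ccp_features(C, missing)
  out <- ag_as_scalar(ag_affine(feat, p[[paste0("ccp", i, ".W")]],
                                p[[paste0("ccp", i, ".b")]]))
  if (sigmoid) out <- ag_sigmoid(out)
  out
}

#' Attention-branch score of one resampled view
#'
#' One transformer attention block over ROI tokens (own parameters per
#' resolution), mean-pooled over tokens and mapped to a single unbounded
#' real by a two-layer header.
#'
#' @inheritParams dh_module
#' @param R An `N x T_cur` matrix view.
#' @return A finite scalar.
#' @export
mha_header <- function(model, R, level = 1L) {
  p <- ps_resolve(model$params)
  ag_value(mha_header_apply(p, model, level, ts_values(R)))
}

#' Connectivity-branch score of one resampled view
#'
#' Transforms the view into a Pearson connectivity matrix, extracts for
#' each missing ROI the `N - 1` off-diagonal entries of its row
#' (`N_m * (N - 1)` features in total) and maps them to one scalar with a
#' single learned linear layer.
#'
#' @inheritParams mha_header
#' @param mask A [missing_mask()] with the model's `N_m` indices.
#' @return A finite scalar.
#' @export
ccp_branch <- function(model, R, mask, level = 1L) {
  v <- ts_values(R)
  if (ncol(v) < 3L) stop("T >= 3 required for the connectivity branch")
  check_mask(mask, model$N)
  stopifnot(length(mask$missing_indices) == model$n_missing)
  p <- ps_resolve(model$params)
  ag_value(ccp_apply(p, level, v, mask$missing_indices, model$cfg$sigmoid))
}

# Core scoring pass on resolved parameters; S plain matrix or tape node.
disc_apply <- function(p, model, S, mask, training = FALSE) {
  N <- model$N
  R1 <- dh_apply(p, "dh1", S, N)
  R2 <- dh_apply(p, "dh2", R1, N)
  R3 <- dh_apply(p, "dh3", R2, N)
  Rs <- list(R1, R2, R3)
  os <- vector("list", 3L)
  for (i in 1:3) {
    os[[i]] <- ag_add(mha_header_apply(p, model, i, Rs[[i]], training),
                      ccp_apply(p, i, Rs[[i]], mask$missing_indices,
                                model$cfg$sigmoid))
  }
  om <- ag_scale(ag_add(ag_add(os[[1L]], os[[2L]]), os[[3L]]), 1 / 6)
  list(o1 = os[[1L]], o2 = os[[2L]], o3 = os[[3L]], om = om)
}

#' Score a multi-ROI time-series at three temporal resolutions
#'
#' Resamples the input through the three learned DH stages, scores each
#' view with its attention branch plus its connectivity branch, and
#' aggregates `o_m = (o1 + o2 + o3) / 6` (exactly — the mean of the six
#' branch scalars).
#'
#' @param model A [build_discriminator()] object.
#' @param S A [roi_timeseries()] or `N x T` matrix with the model's
#'   geometry.
#' @param mask A [missing_mask()] with `N_m` equal to the model's.
#' @param training If `TRUE`, stochastic layers are active.
#' @return List of finite scalars `o1`, `o2`, `o3`, `om`.
#' @export
discriminator_forward <- function(model, S, mask, training = FALSE) {
  v <- ts_values(S)
  stopifnot(nrow(v) == model$N, ncol(v) == model$T)
  check_mask(mask, model$N)
  stopifnot(length(mask$missing_indices) == model$n_missing)
  p <- ps_resolve(model$params)
  out <- disc_apply(p, model, v, mask, training)
  lapply(out, ag_value)
}
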