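# The hierarchical topological transformer generator: a U-shaped
# encoder-decoder over ROI time-series. The encoder alternates L rounds of
# MT-Attention (channel-wise ROI attention) with strided convolutional
# down-sampling; one MT-Attention sits at the bottleneck; the decoder
# mirrors the encoder with transposed-convolution up-sampling and skip
# connections, for 2L+1 MT-Attention layers in total. Only the masked ROI
# rows of the output are synthesised: observed rows pass through verbatim.

#' Generator configuration
#'
#' @param L Depth: number of down-sampling stages (default 5, the depth at
#'   which restoration error bottoms out between under- and over-fitting).
#'   The input length must satisfy `floor(T / 2^L) >= 2`.
#' @param heads Number of attention heads (default 4).
#' @param d_model Attention embedding width (default 64); divisible by
#'   `heads`.
#' @param dropout Dropout probability in `[0, 1)` (default 0.1), active
#'   only during training.
#' @param skip_mode `"concat_project"` (default): concatenate the encoder
#'   MT-Attention output with the up-sampled decoder feature along channels
#'   and project back with a learned 1x1 map; `"add"` uses an additive skip.
#' @param attn_scale `"paper_2l"` (default) divides attention logits by
#'   `2 * heads`; `"sqrt_dhead"` uses the conventional `sqrt(d_model/heads)`.
#' @param share_ltc If `TRUE`, channels within one MT-Attention layer share
#'   LTC parameters (a small-data regime option); default `FALSE`, each
#'   channel slice owns its parameters.
#' @param ffn_mult Feed-forward expansion factor (default 2).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(L = 5L, heads = 4L, d_model = 64L, dropout = 0.1,
                             skip_mode = c("concat_project", "add"),
                             attn_scale = c("paper_2l", "sqrt_dhead"),
                             share_ltc = FALSE, ffn_mult = 2L) {
  stopifnot(L >= 1L, heads >= 1L, d_model >= heads,
            d_model %% heads == 0L, dropout >= 0, dropout < 1)
  structure(list(L = as.integer(L), heads = as.integer(heads),
                 d_model = as.integer(d_model), dropout = dropout,
                 skip_mode = match.arg(skip_mode),
                 attn_scale = match.arg(attn_scale),
                 share_ltc = isTRUE(share_ltc),
                 ffn_mult = as.integer(ffn_mult)),
            class = "generator_config")
}

#' Build a generator for a fixed input geometry
#'
#' Initialises all learned maps (seeded through the caller's RNG state) and
#' records the encoder temporal-length ladder `T, floor(T/2), ...,
#' floor(T/2^L)` that the decoder re-pads to.
#'
#' @param cfg A [generator_config()].
#' @param N Number of ROIs.
#' @param T Number of timepoints; requires `floor(T / 2^L) >= 2`.
#' @return An object of class `boldfill_generator`.
#' @export
build_generator <- function(cfg, N, T) {
  stopifnot(inherits(cfg, "generator_config"))
  ladder <- integer(cfg$L + 1L)
  ladder[1L] <- as.integer(T)
  for (i in seq_len(cfg$L)) ladder[i + 1L] <- ladder[i] %/% 2L
  if (ladder[cfg$L + 1L] < 2L) {
    stop("input too short for depth L = ", cfg$L,
         ": floor(T / 2^L) must be >= 2")
  }
  ps <- ps_new()
  for (i in seq_len(cfg$L)) {
    C <- 2L^(i - 1L)
    init_mta(ps, paste0("enc", i - 1L), C, ladder[i], cfg)
    init_cd(ps, paste0("cd", i), C)
  }
  init_mta(ps, "bot", 2L^cfg$L, ladder[cfg$L + 1L], cfg)
  for (i in rev(seq_len(cfg$L))) {
    C_out <- 2L^(i - 1L)
    init_cu(ps, paste0("cu", i), 2L * C_out)
    if (cfg$skip_mode == "concat_project") {
      # start the merge favouring the encoder skip (0.8) over the decoded
      # branch (0.2): with near-identity blocks the network then begins at
      # (approximately) the identity on its filled input
      eye <- diag(C_out)
      ps_add(ps, paste0("skip", i - 1L, ".W"),
             cbind(0.2 * eye, 0.8 * eye) +
               glorot_shaped(C_out, 2L * C_out, 2L * C_out, C_out) * 0.1)
      ps_add(ps, paste0("skip", i - 1L, ".b"), rep(0, C_out))
    }
    init_mta(ps, paste0("dec", i - 1L), C_out, ladder[i], cfg)
  }
  ps_add(ps, "final.W", matrix(1, 1L, 1L))
  ps_add(ps, "final.b", 0)      # identity collapse at the start
  structure(list(params = ps, cfg = cfg, N = as.integer(N),
                 T = as.integer(T), ladder = ladder),
            class = "boldfill_generator")
}

#' @export
print.boldfill_generator <- function(x, ...) {
  cat(sprintf("<boldfill_generator> N = %d, T = %d, L = %d (%d MT-Attention layers)\n",
              x$N, x$T, x$cfg$L, 2L * x$cfg$L + 1L))
  cat("  encoder length ladder:", paste(x$ladder, collapse = " -> "), "\n")
  invisible(x)
}

# Core U-shaped pass on resolved parameters. `sm` is a plain N x T matrix.
gen_apply <- function(p, model, sm, mask, training = FALSE, collect = NULL) {
  cfg <- model$cfg
  N <- model$N
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  F <- flatten_feature(sm)
  C <- 1L
  enc_out <- vector("list", cfg$L)
  for (i in seq_len(cfg$L)) {
    Tc <- model$ladder[i]
    F <- mta_forward(p, paste0("enc", i - 1L), F, C, N, Tc, cfg,
                     training, counter, collect)
    enc_out[[i]] <- F
    F <- cd_forward(p, paste0("cd", i), F, C, N, Tc)
    C <- 2L * C
  }
  F <- mta_forward(p, "bot", F, C, N, model$ladder[cfg$L + 1L], cfg,
                   training, counter, collect)
  for (i in rev(seq_len(cfg$L))) {
    target_T <- model$ladder[i]
    F <- cu_forward(p, paste0("cu", i), F, C, N, model$ladder[i + 1L], target_T)
    C <- C %/% 2L
    if (cfg$skip_mode == "concat_project") {
      F <- ag_affine_left(p[[paste0("skip", i - 1L, ".W")]],
                          ag_rbind2(F, enc_out[[i]]),
                          p[[paste0("skip", i - 1L, ".b")]])
    } else {
      F <- ag_add(F, enc_out[[i]])
    }
    F <- mta_forward(p, paste0("dec", i - 1L), F, C, N, target_T, cfg,
                     training, counter, collect)
  }
  out <- ag_affine_left(p[["final.W"]], F, p[["final.b"]])
  S_full <- ag_clamp01(ag_row_mat(out, 1L, N, model$T))
  sg <- ag_row_replace(S_full, sm, mask$missing_indices)
  list(sg = sg, mta_count = counter$n)
}

#' Run the generator on a masked-and-filled time-series
#'
#' Executes the full U-shaped pass and applies the composite rule: observed
#' ROI rows of the result are bit-identical to the input, only masked rows
#' are synthesised (clamped to `[0, 1]`).
#'
#' @param model A [build_generator()] object.
#' @param sm The masked-and-filled input ([roi_timeseries()] or matrix) of
#'   the geometry the model was built for.
#' @param mask A [missing_mask()].
#' @param training If `TRUE`, dropout is active (draws from the session
#'   RNG).
#' @param collect Optional environment with a list field `maps`; every
#'   attention call deposits its per-head attention matrices there.
#' @return A [roi_timeseries()] with attribute `mta_count`, the number of
#'   MT-Attention layers executed (always `2L + 1`).
#' @export
generator_forward <- function(model, sm, mask, training = FALSE,
                              collect = NULL) {
  v <- ts_values(sm)
  stopifnot(nrow(v) == model$N, ncol(v) == model$T)
  check_mask(mask, model$N)
  p <- ps_resolve(model$params)
  res <- gen_apply(p, model, v, mask, training, collect)
  out <- roi_timeseries(ag_value(res$sg),
                        if (inherits(sm, "roi_timeseries")) sm$roi_labels else NULL,
                        if (inherits(sm, "roi_timeseries")) sm$tr_seconds else 3.0)
  attr(out, "mta_count") <- res$mta_count
  out
}
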