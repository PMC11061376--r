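# Shared neural building blocks: parameter sets, initialisers, the
# ROI-attention (LTC) transformer block, its channel-wise wrapper
# (MT-Attention), and the strided convolutional down/up-sampling.
#
# Features flow as flattened C x (N*T) matrices: one row per channel,
# columns ordered ROI-major with time fastest. Attention operates on one
# channel at a time as an N x T matrix whose tokens are the N ROIs and
# whose token embedding is derived from the T temporal samples.

ps_new <- function() {
  ps <- new.env(parent = emptyenv())
  ps$v <- list()
  ps
}

ps_add <- function(ps, name, value) {
  ps$v[[name]] <- value
  invisible(ps)
}

# Resolve parameters for a forward pass: tape leaves when recording,
# raw matrices otherwise.
ps_resolve <- function(ps) {
  if (ag_recording()) lapply(ps$v, ag_leaf) else ps$v
}

# Collect accumulated gradients from resolved leaf nodes (NULL when a
# parameter did not participate in the pass).
ps_grads <- function(resolved) {
  lapply(resolved, function(n) if (is_ag_node(n)) n$grad else NULL)
}

glorot <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

## ---- LTC: the per-channel ROI-attention transformer block -------------------

# Parameters of one LTC block operating on N x T slices. The Q/K/V
# projections are stored column-fused (T x 3*d_model) so the block's first
# stage is a single tape node.
init_ltc <- function(ps, prefix, T, d_model, ffn_mult = 2L) {
  ff <- max(2L, ffn_mult * T)
  ps_add(ps, paste0(prefix, ".ln1_g"), rep(1, T))
  ps_add(ps, paste0(prefix, ".ln1_b"), rep(0, T))
  ps_add(ps, paste0(prefix, ".Wqkv"),
         cbind(glorot(T, d_model), glorot(T, d_model), glorot(T, d_model)))
  ps_add(ps, paste0(prefix, ".bqkv"), rep(0, 3L * d_model))
  # near-identity start: tiny output maps leave the residual path dominant
  # while keeping nonzero gradients everywhere
  ps_add(ps, paste0(prefix, ".Wo"), glorot(d_model, T) * 0.02)
  ps_add(ps, paste0(prefix, ".bo"), rep(0, T))
  ps_add(ps, paste0(prefix, ".ln2_g"), rep(1, T))
  ps_add(ps, paste0(prefix, ".ln2_b"), rep(0, T))
  ps_add(ps, paste0(prefix, ".W1"), glorot(T, ff))
  ps_add(ps, paste0(prefix, ".b1"), rep(0, ff))
  ps_add(ps, paste0(prefix, ".W2"), glorot(ff, T) * 0.02)
  ps_add(ps, paste0(prefix, ".b2"), rep(0, T))
  invisible(ps)
}

attn_denom <- function(attn_scale, heads, d_model) {
  switch(attn_scale,
         paper_2l = 2 * heads,
         sqrt_dhead = sqrt(d_model / heads),
         stop("unknown attention scaling: ", attn_scale))
}

# One pre-norm transformer block on channel `c` of a flattened feature:
# residual multi-head ROI attention (Norm -> joint Q/K/V projection ->
# per-head softmax attention -> merge -> dropout -> residual), then a
# residual feed-forward transform (Norm -> expand -> dropout -> contract).
# With the output maps Wo/W2 (and biases) zero it is the identity. Returns
# the updated N x T slice.
ltc_forward <- function(p, prefix, F, c, N, T, heads, d_model, dropout,
                        attn_scale, training = FALSE, collect = NULL) {
  nm <- paste0(prefix, ".",
               c("ln1_g", "ln1_b", "Wqkv", "bqkv", "Wo", "bo",
                 "ln2_g", "ln2_b", "W1", "b1", "W2", "b2"))
  QKV <- ag_ltc_in(F, c, N, T, p[[nm[1L]]], p[[nm[2L]]], p[[nm[3L]]],
                   p[[nm[4L]]])
  A <- ag_mha_qkv(QKV, heads, attn_denom(attn_scale, heads, d_model), collect)
  att <- ag_attn_out(F, c, N, T, A, p[[nm[5L]]], p[[nm[6L]]], dropout,
                     training)
  ag_ffn(att, p[[nm[7L]]], p[[nm[8L]]], p[[nm[9L]]], p[[nm[10L]]],
         p[[nm[11L]]], p[[nm[12L]]], dropout, training)
}

## ---- MT-Attention: channel-wise split / LTC / concatenate -------------------

init_mta <- function(ps, prefix, C, T, cfg) {
  if (isTRUE(cfg$share_ltc)) {
    init_ltc(ps, paste0(prefix, ".shared"), T, cfg$d_model, cfg$ffn_mult)
  } else {
    for (c in seq_len(C)) {
      init_ltc(ps, paste0(prefix, ".ch", c), T, cfg$d_model, cfg$ffn_mult)
    }
  }
  invisible(ps)
}

# Split a C x (N*T) feature along channels, apply LTC per channel and
# re-stack. `counter` (an env with $n) instruments the MT-Attention count.
mta_forward <- function(p, prefix, F, C, N, T, cfg, training = FALSE,
                        counter = NULL, collect = NULL) {
  if (C < 1L) stop("C = 0: nothing to split")
  if (!is.null(counter)) counter$n <- counter$n + 1L
  outs <- vector("list", C)
  for (c in seq_len(C)) {
    blk <- if (isTRUE(cfg$share_ltc)) "shared" else paste0("ch", c)
    outs[[c]] <- ltc_forward(p, paste0(prefix, ".", blk), F, c, N, T,
                             cfg$heads, cfg$d_model, cfg$dropout,
                             cfg$attn_scale, training, collect)
  }
  if (C == 1L) flatten_node(outs[[1L]]) else ag_stack_tmats(outs)
}

## ---- convolutional sampling -------------------------------------------------

# Column indices of odd/even temporal positions for a flattened feature.
stride2_idx <- function(N, T) {
  To <- T %/% 2L
  base <- rep((seq_len(N) - 1L) * T, each = To)
  t1 <- base + rep(seq.int(1L, by = 2L, length.out = To), N)
  list(odd = t1, even = t1 + 1L, T_out = To)
}

glorot_shaped <- function(nrow, ncol, fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -a, a), nrow, ncol)
}

# Down-sampling starts near channel-duplicating average pooling (plus
# symmetry-breaking noise), so the whole U starts close to the identity on
# its input and training refines rather than rebuilds the signal path.
init_cd <- function(ps, prefix, C_in) {
  C_out <- 2L * C_in
  dup <- matrix(0, C_out, C_in)
  dup[cbind(seq_len(C_out), ((seq_len(C_out) - 1L) %% C_in) + 1L)] <- 0.5
  ps_add(ps, paste0(prefix, ".W1"),
         dup + glorot_shaped(C_out, C_in, 2L * C_in, C_out) * 0.1)
  ps_add(ps, paste0(prefix, ".W2"),
         dup + glorot_shaped(C_out, C_in, 2L * C_in, C_out) * 0.1)
  ps_add(ps, paste0(prefix, ".b"), rep(0, C_out))
  invisible(ps)
}

# Strided (stride 2, kernel 2) 1-D convolution along time applied per ROI
# row: halves the temporal length (floor), doubles the channels.
cd_forward <- function(p, prefix, F, C_in, N, T) {
  idx <- stride2_idx(N, T)
  X1 <- ag_cols(F, idx$odd)
  X2 <- ag_cols(F, idx$even)
  ag_affine_left2(p[[paste0(prefix, ".W1")]], X1,
                  p[[paste0(prefix, ".W2")]], X2,
                  p[[paste0(prefix, ".b")]])
}

# Up-sampling starts near nearest-neighbour upsampling that averages the
# two stacked channel copies (the inverse of init_cd's starting point).
init_cu <- function(ps, prefix, C_in) {
  C_out <- C_in %/% 2L
  mix <- matrix(0, C_out, C_in)
  mix[cbind(seq_len(C_out), seq_len(C_out))] <- 0.5
  mix[cbind(seq_len(C_out), seq_len(C_out) + C_out)] <- 0.5
  ps_add(ps, paste0(prefix, ".W1"),
         mix + glorot_shaped(C_out, C_in, C_in, 2L * C_out) * 0.1)
  ps_add(ps, paste0(prefix, ".W2"),
         mix + glorot_shaped(C_out, C_in, C_in, 2L * C_out) * 0.1)
  ps_add(ps, paste0(prefix, ".b"), rep(0, C_out))
  invisible(ps)
}

# Transposed (stride 2) 1-D convolution along time: doubles the temporal
# length, halves the channels, then crops or right-pads (repeating the
# last sample) to the recorded encoder length at the target level.
cu_forward <- function(p, prefix, F, C_in, N, T, target_T) {
  if (C_in %% 2L != 0L) stop("C must be even for up-sampling")
  Z1 <- ag_affine_left(p[[paste0(prefix, ".W1")]], F, p[[paste0(prefix, ".b")]])
  Z2 <- ag_affine_left(p[[paste0(prefix, ".W2")]], F, rep(0, C_in %/% 2L))
  U <- ag_interleave2(Z1, Z2, N, T)
  ag_pad_crop(U, N, 2L * T, target_T)
}

# Flatten an N x T matrix into the 1 x (N*T) single-channel feature layout.
flatten_feature <- function(S) {
  matrix(as.vector(t(S)), 1L)
}

# Node-aware single-matrix flatten (a degenerate ag_stack_tmats).
flatten_node <- function(S) {
  if (is_ag_node(S)) ag_stack_tmats(list(S)) else flatten_feature(S)
}
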