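# Checkpointing: a flat named-parameter container plus a JSON sidecar
# recording the configuration and exact geometry (for the generator, the
# encoder length ladder the decoder re-pads to).

#' Save a generator or discriminator checkpoint
#'
#' Writes the flat named-parameter container to `path` and a human-readable
#' JSON sidecar (`<path>.json`) with the configuration and geometry.
#'
#' @param model A `boldfill_generator` or `boldfill_discriminator`.
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  kind <- if (inherits(model, "boldfill_generator")) "generator"
          else if (inherits(model, "boldfill_discriminator")) "discriminator"
          else stop("not a boldfill model")
  meta <- list(kind = kind, config = unclass(model$cfg),
               N = model$N, T = model$T)
  if (kind == "generator") meta$ladder <- model$ladder
  if (kind == "discriminator") {
    meta$n_missing <- model$n_missing
    meta$T_levels <- model$T_levels
  }
  saveRDS(list(meta = meta, params = model$params$v), path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return The rebuilt model with its saved parameters.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  meta <- obj$meta
  # rebuild inside a scoped RNG so loading never perturbs the session state
  model <- withr_seed(0L, {
    if (meta$kind == "generator") {
      cfg <- do.call(generator_config, meta$config[c("L", "heads", "d_model",
                                                     "dropout", "skip_mode",
                                                     "attn_scale", "share_ltc",
                                                     "ffn_mult")])
      build_generator(cfg, meta$N, meta$T)
    } else {
      cfg <- do.call(discriminator_config,
                     meta$config[c("heads", "d_model", "header_hidden",
                                   "sigmoid")])
      build_discriminator(cfg, meta$N, meta$T, meta$n_missing)
    }
  })
  stopifnot(identical(sort(names(model$params$v)), sort(names(obj$params))))
  model$params$v <- obj$params
  model
}
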