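# YAML-backed configuration mirroring train_config / synthetic_spec, and
# directory-level dataset I/O used by the command-line interface.

#' Build a training configuration from a YAML file
#'
#' The file mirrors [train_config()]: optional blocks `generator`,
#' `discriminator`, `loss`, `mask` (with `missing_indices` and
#' `fill_strategy`) and scalar fields (`lr_generator`, `epochs`, `seed`,
#' ...). Omitted entries keep package defaults. An optional `synthetic`
#' block is returned alongside as a [synthetic_spec()].
#'
#' @param path YAML file path.
#' @return List with `train` (a [train_config()]) and `synthetic` (a
#'   [synthetic_spec()] or `NULL`).
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(block, fn) {
    if (is.null(block)) fn() else do.call(fn, block)
  }
  mask <- if (is.null(y$mask)) missing_mask(1L, "prior") else {
    missing_mask(unlist(y$mask$missing_indices), y$mask$fill_strategy)
  }
  args <- list(generator = take(y$generator, generator_config),
               discriminator = take(y$discriminator, discriminator_config),
               loss = take(y$loss, loss_config),
               mask = mask)
  for (f in c("lr_generator", "lr_discriminator", "batch_size", "epochs",
              "seed", "eval_every")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  list(train = do.call(train_config, args),
       synthetic = if (is.null(y$synthetic)) NULL
                   else do.call(synthetic_spec, y$synthetic))
}

#' Write a synthetic dataset as delimited files
#'
#' One TSV per subject (`subject_01.tsv`, ...) plus the spec as
#' `spec.yaml`.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_dataset(spec)
  for (i in seq_along(ds)) {
    write_timeseries(ds[[i]]$ts,
                     file.path(dir, sprintf("subject_%02d.tsv", i)))
  }
  yaml::write_yaml(unclass(spec), file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' Load a dataset of subject TSV/CSV files from a directory
#'
#' Reads every `subject_*.tsv`/`.csv` in lexical order.
#'
#' @param dir Directory produced by [write_dataset()] (or hand-assembled).
#' @param tr_seconds Repetition time attached to the subjects.
#' @return List of [roi_timeseries()].
#' @export
load_dataset <- function(dir, tr_seconds = 3.0) {
  files <- sort(list.files(dir, pattern = "^subject_.*\\.(tsv|csv)$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no subject_*.tsv files in ", dir)
  lapply(files, read_timeseries, tr_seconds = tr_seconds)
}
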