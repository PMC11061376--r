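# The hybrid objective: least-squares adversarial losses plus the
# multi-resolution consistency loss (temporal MAE, row-wise
# cross-correlation and connectivity agreement across the pooling pyramid).
#
# Every function here accepts either plain matrices/scalars or autodiff
# tape nodes, so the identical code computes reported loss values and
# training gradients.

#' Loss configuration
#'
#' @param alpha Nonnegative weight of the multi-resolution consistency loss
#'   in the generator objective (default 0.9, the value at which the
#'   restoration error bottoms out in the reference experiments).
#' @param mcc_mode `"one_minus_mcc"` (default) turns the cross-correlation
#'   similarity into a proper loss `1 - MCC` per level; `"raw_mcc"` keeps
#'   the literal signed similarity (useful only for fidelity experiments:
#'   minimising it drives correlation to -1).
#' @param topo_mode `"per_level"` (default) evaluates the connectivity term
#'   at every pyramid level; `"level0_only"` uses the full-resolution
#'   connectivity difference summed four times.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.9,
                        mcc_mode = c("one_minus_mcc", "raw_mcc"),
                        topo_mode = c("per_level", "level0_only")) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
  structure(list(alpha = alpha,
                 mcc_mode = match.arg(mcc_mode),
                 topo_mode = match.arg(topo_mode)),
            class = "loss_config")
}

#' Least-squares discriminator loss
#'
#' `(score_real - 1)^2 + score_fake^2`: zero for a perfect discriminator,
#' 0.5 at the adversarial equilibrium where both scores are 0.5.
#'
#' @param score_real Discriminator aggregate score on an empirical sample.
#' @param score_fake Discriminator aggregate score on a generated sample.
#' @return Nonnegative scalar (tape node if the inputs are nodes).
#' @export
loss_D <- function(score_real, score_fake) {
  ag_add(ag_sq(ag_sub(score_real, 1)), ag_sq(score_fake))
}

#' Least-squares generator loss
#'
#' `(score_fake - 1)^2`: zero iff the generator fully fools the
#' discriminator.
#'
#' @inheritParams loss_D
#' @return Nonnegative scalar (tape node if the input is a node).
#' @export
loss_G <- function(score_fake) {
  ag_sq(ag_sub(score_fake, 1))
}

#' Temporal mean absolute error
#'
#' `1/(N T) * sum |Sg - Se|` over all elements.
#'
#' @param sg,se Same-shape matrices, [roi_timeseries()] objects or tape
#'   nodes.
#' @return Nonnegative scalar.
#' @export
tmae <- function(sg, se) {
  g <- if (is_ag_node(sg)) sg else ts_values(sg)
  e <- if (is_ag_node(se)) se else ts_values(se)
  stopifnot(all(dim(ag_value(g)) == dim(ag_value(e))))
  ag_mean_abs_diff(g, e)
}

#' Mean row-wise cross-correlation coefficient
#'
#' The Pearson correlation between matching ROI rows of `sg` and `se`,
#' averaged over ROIs; in `[-1, 1]`. Rows with zero variance on either side
#' contribute 0 by convention.
#'
#' @inheritParams tmae
#' @return Scalar in `[-1, 1]`.
#' @export
mcc <- function(sg, se) {
  g <- if (is_ag_node(sg)) sg else ts_values(sg)
  e <- if (is_ag_node(se)) se else ts_values(se)
  vg <- ag_value(g); ve <- ag_value(e)
  stopifnot(all(dim(vg) == dim(ve)))
  if (ncol(vg) < 3L) stop("T >= 3 required for cross-correlation")
  ag_mcc_rows(g, e)
}

#' Multi-resolution consistency loss
#'
#' Builds the deterministic four-level average-pooling pyramids of the
#' restored and empirical series and sums, over levels `k = 0..3`: the
#' temporal MAE, a cross-correlation term (`1 - MCC` under the default
#' configuration) and the mean absolute difference between the two Pearson
#' connectivity matrices. Zero exactly when `sg == se` under the defaults.
#'
#' @inheritParams tmae
#' @param cfg A [loss_config()].
#' @param detail If `TRUE`, also return the three numeric term subtotals.
#' @return Scalar loss (tape node when `sg` is a node); with
#'   `detail = TRUE`, a list `total`, `tmae_term`, `mcc_term`, `topo_term`
#'   (the subtotals are always plain numbers).
#' @export
l_mrc <- function(sg, se, cfg = loss_config(), detail = FALSE) {
  g <- if (is_ag_node(sg)) sg else ts_values(sg)
  e <- ts_values(se)
  stopifnot(all(dim(ag_value(g)) == dim(e)))
  if (ncol(e) < 24L) stop("T >= 24 required (deepest level needs T/8 >= 3)")

  gs <- vector("list", 4L); es <- vector("list", 4L)
  gs[[1L]] <- g; es[[1L]] <- e
  for (k in 2:4) {
    gs[[k]] <- ag_avgpool2(gs[[k - 1L]])
    es[[k]] <- ag_avgpool2(es[[k - 1L]])
  }

  t1 <- 0; t2 <- 0; t3 <- 0
  for (k in 1:4) {
    t1 <- ag_add(t1, ag_mean_abs_diff(gs[[k]], es[[k]]))
    m <- ag_mcc_rows(gs[[k]], es[[k]])
    t2 <- if (cfg$mcc_mode == "one_minus_mcc") {
      ag_add(t2, ag_sub(1, m))
    } else {
      ag_add(t2, m)
    }
    if (cfg$topo_mode == "per_level") {
      t3 <- ag_add(t3, ag_mean_abs_diff(ag_corr_rows(gs[[k]]),
                                        ag_corr_rows(es[[k]])))
    }
  }
  if (cfg$topo_mode == "level0_only") {
    t3 <- ag_scale(ag_mean_abs_diff(ag_corr_rows(gs[[1L]]),
                                    ag_corr_rows(es[[1L]])), 4)
  }
  total <- ag_add(ag_add(t1, t2), t3)
  if (!detail) return(total)
  list(total = total, tmae_term = ag_value(t1), mcc_term = ag_value(t2),
       topo_term = ag_value(t3))
}

#' Total generator and discriminator objectives
#'
#' Routes the hybrid objective to the two alternating updates: the
#' discriminator minimises the least-squares real/fake loss; the generator
#' minimises its adversarial loss plus `alpha` times the multi-resolution
#' consistency loss.
#'
#' @inheritParams tmae
#' @param score_real,score_fake Aggregate discriminator scores.
#' @param cfg A [loss_config()].
#' @return List with `gen_total` and `disc_total`.
#' @export
total_losses <- function(sg, se, score_real, score_fake, cfg = loss_config()) {
  gen <- loss_G(score_fake)
  if (cfg$alpha > 0) gen <- ag_add(gen, ag_scale(l_mrc(sg, se, cfg), cfg$alpha))
  list(gen_total = gen, disc_total = loss_D(score_real, score_fake))
}
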