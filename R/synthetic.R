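# Synthetic resting-state-like multi-ROI signals. Band-limited latent
# oscillations are mixed into every ROI through a low-rank loading matrix
# (so any masked ROI is predictable from the rest -- the premise of the
# restoration task), then AR(1) noise is added and the matrix is min-max
# normalised. The noise-free mixing also yields an analytic ground-truth
# connectivity for testing the Pearson machinery.

#' Specification of a synthetic multi-ROI dataset
#'
#' @param n_rois Number of ROIs `N` (default 16, the desk-scale size).
#' @param n_timepoints Number of timepoints `T` (default 64).
#' @param latent_rank Number of shared latent oscillations (default 3);
#'   must be `< n_rois`.
#' @param freq_band_hz Frequency band of the latent oscillations in Hz
#'   (default `c(0.01, 0.08)`, the classic slow resting-state band); must
#'   lie inside `(0, 1/(2 tr_seconds))`.
#' @param tr_seconds Sampling interval (default 3.0 s).
#' @param noise_sd Innovation standard deviation of the AR(1) ROI noise
#'   (default 0.1, on the unit scale of the standardised latents).
#' @param ar_coeff AR(1) coefficient in `[0, 1)` (default 0.3), emulating
#'   residual autocorrelation left after band-pass filtering.
#' @param loading_jitter_sd Standard deviation of the per-subject deviation
#'   from the group loading matrix (default 0.1). Functional parcellations
#'   share strong group-level connectivity structure; the jitter supplies
#'   realistic between-subject variation while keeping the restoration
#'   mapping learnable across subjects.
#' @param n_subjects Number of subjects (default 10).
#' @param seed Integer base seed; the group loading matrix derives from it
#'   directly, per-subject randomness from seeds derived per subject.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_rois = 16L, n_timepoints = 64L, latent_rank = 3L,
                           freq_band_hz = c(0.01, 0.08), tr_seconds = 3.0,
                           noise_sd = 0.1, ar_coeff = 0.3,
                           loading_jitter_sd = 0.1,
                           n_subjects = 10L, seed = 1L) {
  stopifnot(n_rois >= 2L, n_timepoints >= 8L,
            latent_rank >= 1L, latent_rank < n_rois,
            length(freq_band_hz) == 2L, freq_band_hz[1L] > 0,
            freq_band_hz[2L] > freq_band_hz[1L],
            freq_band_hz[2L] < 1 / (2 * tr_seconds),
            noise_sd >= 0, ar_coeff >= 0, ar_coeff < 1,
            loading_jitter_sd >= 0, n_subjects >= 1L)
  structure(list(n_rois = as.integer(n_rois),
                 n_timepoints = as.integer(n_timepoints),
                 latent_rank = as.integer(latent_rank),
                 freq_band_hz = freq_band_hz, tr_seconds = tr_seconds,
                 noise_sd = noise_sd, ar_coeff = ar_coeff,
                 loading_jitter_sd = loading_jitter_sd,
                 n_subjects = as.integer(n_subjects), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Group-level loading matrix: every ROI loads on every latent with
# magnitude bounded away from zero (random sign), deterministically from
# the spec seed.
group_loadings <- function(spec) {
  withr_seed(spec$seed, {
    matrix(sample(c(-1, 1), spec$n_rois * spec$latent_rank, replace = TRUE) *
             stats::runif(spec$n_rois * spec$latent_rank, 0.4, 1.2),
           spec$n_rois, spec$latent_rank)
  })
}

subject_seed <- function(spec, subject_index) {
  as.integer((as.numeric(spec$seed) * 10007 + subject_index * 97) %% 2147483587)
}

#' Generate one synthetic subject
#'
#' Draws `latent_rank` standardised oscillations as random mixtures of
#' sinusoids whose frequencies sit on the discrete Fourier grid inside
#' `freq_band_hz` (grid alignment makes the band limitation exact over the
#' acquisition window), mixes them into `n_rois` channels through the
#' subject's loading matrix — the group matrix of the spec plus
#' per-subject jitter, entries bounded away from zero so every ROI shares
#' latent structure — then adds AR(1) noise and min-max normalises.
#'
#' @param spec A [synthetic_spec()].
#' @param subject_index Positive integer; output is a deterministic
#'   function of `(spec, subject_index)`.
#' @return List with `ts` (a [roi_timeseries()] in `[0, 1]`) and
#'   `connectivity` (the `N x N` Pearson matrix of the noise-free mixed
#'   signal — the ground truth the empirical connectivity approaches as
#'   `noise_sd` shrinks).
#' @export
generate_subject <- function(spec, subject_index = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), subject_index >= 1L)
  group <- group_loadings(spec)
  withr_seed(subject_seed(spec, subject_index), {
    N <- spec$n_rois; T <- spec$n_timepoints; K <- spec$latent_rank
    window <- T * spec$tr_seconds
    k_lo <- ceiling(spec$freq_band_hz[1L] * window)
    k_hi <- floor(spec$freq_band_hz[2L] * window)
    if (k_hi < k_lo) stop("frequency band contains no Fourier grid point; ",
                          "increase n_timepoints or widen the band")
    tt <- (seq_len(T) - 1L) * spec$tr_seconds
    n_sin <- 8L
    lat <- matrix(0, K, T)
    for (k in seq_len(K)) {
      ks <- sample(seq.int(k_lo, k_hi), n_sin, replace = TRUE)
      amp <- stats::runif(n_sin, 0.5, 1)
      ph <- stats::runif(n_sin, 0, 2 * pi)
      s <- colSums(amp * sin(outer(ks / window, tt, function(f, t) 2 * pi * f * t) + ph))
      lat[k, ] <- (s - mean(s)) / stats::sd(s)
    }
    load <- group + matrix(stats::rnorm(N * K, 0, spec$loading_jitter_sd),
                           N, K)
    clean <- load %*% lat
    noise <- t(vapply(seq_len(N), function(i) {
      as.numeric(stats::filter(stats::rnorm(T, 0, spec$noise_sd),
                               spec$ar_coeff, method = "recursive"))
    }, numeric(T)))
    ts <- normalize_minmax(roi_timeseries(clean + noise,
                                          roi_labels = sprintf("ROI_%02d", seq_len(N)),
                                          tr_seconds = spec$tr_seconds))
    list(ts = ts, connectivity = pcc_matrix(clean))
  })
}

#' Generate a full synthetic dataset
#'
#' `n_subjects` independent subjects with per-subject derived seeds;
#' deterministic given the spec.
#'
#' @param spec A [synthetic_spec()].
#' @return List of length `n_subjects`, each element as in
#'   [generate_subject()].
#' @export
generate_dataset <- function(spec) {
  lapply(seq_len(spec$n_subjects), function(i) generate_subject(spec, i))
}

#' Synthetic subjects at the dimensions of a standard AAL acquisition
#'
#' A convenience fixture with 90 ROIs and 187 timepoints at TR 3.0 s —
#' the shape of an AAL-parcellated resting-state scan — for integration
#' tests at realistic scale.
#'
#' @param n_subjects Number of subjects (default 1).
#' @param seed Base seed (default 1).
#' @return List of [roi_timeseries()] objects, each `90 x 187` in `[0, 1]`.
#' @export
make_paper_scale_fixture <- function(n_subjects = 1L, seed = 1L) {
  spec <- synthetic_spec(n_rois = 90L, n_timepoints = 187L, latent_rank = 5L,
                         n_subjects = n_subjects, seed = seed)
  lapply(generate_dataset(spec), function(s) s$ts)
}

#' Out-of-sample predictability of one ROI from the others
#'
#' Ridge-regression oracle certifying that the restoration task is
#' well-posed: the ROI row is regressed on all other rows, fit on the first
#' half of the timepoints and scored by out-of-sample R-squared on the
#' second half. Values above 0.5 mean the masked ROI is substantially
#' recoverable from the observed ROIs before any adversarial training.
#'
#' @param ts A [roi_timeseries()] or matrix.
#' @param roi ROI row index to predict.
#' @param lambda Ridge penalty (default 0.1 on standardised predictors).
#' @return Out-of-sample R-squared (can be negative for unpredictable rows).
#' @export
masked_roi_predictability <- function(ts, roi, lambda = 0.1) {
  v <- ts_values(ts)
  stopifnot(roi >= 1L, roi <= nrow(v))
  X <- t(v[-roi, , drop = FALSE])
  y <- v[roi, ]
  half <- floor(length(y) / 2)
  tr <- seq_len(half); te <- (half + 1L):length(y)
  mu <- colMeans(X[tr, , drop = FALSE])
  sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  ym <- mean(y[tr])
  b <- solve(crossprod(Z[tr, , drop = FALSE]) + lambda * diag(ncol(Z)),
             crossprod(Z[tr, , drop = FALSE], y[tr] - ym))
  pred <- Z[te, , drop = FALSE] %*% b + ym
  1 - sum((y[te] - pred)^2) / sum((y[te] - mean(y[te]))^2)
}

#' Fraction of signal power inside a frequency band
#'
#' Mean over ROIs of the periodogram power fraction falling inside `band`
#' (DC excluded). A diagnostic for the band-limited construction of the
#' synthetic signals.
#'
#' @param ts A [roi_timeseries()] or matrix.
#' @param band Length-2 frequency band in Hz.
#' @param tr_seconds Sampling interval; taken from `ts` when available.
#' @return Scalar in `[0, 1]`.
#' @export
band_power_fraction <- function(ts, band = c(0.01, 0.08), tr_seconds = NULL) {
  v <- ts_values(ts)
  if (is.null(tr_seconds)) {
    tr_seconds <- if (inherits(ts, "roi_timeseries")) ts$tr_seconds else 1
  }
  T <- ncol(v)
  freqs <- seq_len(floor(T / 2)) / (T * tr_seconds)
  frac <- vapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ] - mean(v[i, ])
    p <- Mod(stats::fft(x))^2
    p <- p[1L + seq_len(floor(T / 2))]
    sum(p[freqs >= band[1L] & freqs <= band[2L]]) / sum(p)
  }, numeric(1))
  mean(frac)
}
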