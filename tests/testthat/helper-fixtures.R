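# Shared fixtures: all built in code, deterministic under explicit seeds.

# A random matrix with rows guaranteed non-constant.
rand_mat <- function(n, t, seed) {
  set.seed(seed)
  matrix(stats::runif(n * t), n, t)
}

# A small normalised subject for structural tests.
small_subject <- function(seed = 1, n_rois = 8, n_timepoints = 32) {
  generate_subject(synthetic_spec(n_rois = n_rois,
                                  n_timepoints = n_timepoints,
                                  latent_rank = 2, seed = seed), 1)$ts
}

# Mini dataset + config for fast training tests (depth-2 generator, small
# attention width). Scales chosen for test-suite turnaround; the study-scale
# configuration lives in the acceptance tests.
mini_dataset <- function(seed = 11, n_subjects = 5) {
  generate_dataset(synthetic_spec(n_rois = 10, n_timepoints = 32,
                                  latent_rank = 2, noise_sd = 0.1,
                                  n_subjects = n_subjects, seed = seed))
}

mini_config <- function(epochs = 2, seed = 3, alpha = 0.9,
                        mask = missing_mask(4, "prior")) {
  train_config(generator = generator_config(L = 2, heads = 2, d_model = 16),
               discriminator = discriminator_config(heads = 2, d_model = 16,
                                                    header_hidden = 8),
               loss = loss_config(alpha = alpha),
               mask = mask, epochs = epochs, seed = seed, eval_every = 1)
}

# Central-difference numerical gradient of f (scalar-valued) w.r.t. the
# k-th element of the named parameter inside a parameter list.
num_grad <- function(f, params, name, k, eps = 1e-6) {
  p <- params[[name]]
  params[[name]][k] <- p[k] + eps
  up <- f(params)
  params[[name]][k] <- p[k] - eps
  dn <- f(params)
  (up - dn) / (2 * eps)
}
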