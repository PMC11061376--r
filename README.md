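# boldfill

Restores missing ROI-level BOLD time-series in resting-state fMRI with an
adversarially trained U-shaped convolutional transformer.

## The problem

Parcellated resting-state fMRI reduces each scan to an `N x T` matrix:
one time-series per atlas region (e.g. 90 AAL parcels, 187 volumes at
TR = 3 s). Implanted hardware — the motivating case is deep-brain-
stimulation electrodes — corrupts the signal in nearby parcels, leaving
rows of the matrix unusable and biasing every downstream functional-
connectivity analysis. Because parcels are strongly coupled, the missing
rows are recoverable from the observed ones. `boldfill` is for
neuroimaging methodologists who need that restoration step: it learns the
mapping adversarially and evaluates it on the missing rows only.

## The model

The generator `G` maps the masked matrix `S_m` (missing rows replaced by
an initial fill) to a restored matrix `S_g`. It is a U-shaped
encoder-decoder of depth `L` (default 5): each level applies
channel-split multi-head self-attention across ROIs — tokens are the `N`
parcels, embeddings are learned projections of the temporal samples, so
attention maps are `N x N` and route signal from observed into missing
parcels — interleaved with stride-2 1-D convolutions that halve/double
the temporal length (`2L + 1` attention layers in total). Observed rows
pass through verbatim; only masked rows are synthesised.

The discriminator scores a sample at three temporal resolutions
(`T/2, T/4, T/8`, learned stride-2 halvings). Each view is scored by an
attention branch and by a connectivity branch that reads the missing
ROIs' rows of the Pearson correlation matrix; the aggregate is
`o_m = (o1 + o2 + o3) / 6`, with least-squares targets 1 (real) / 0
(fake), so `o_m -> 0.5` at equilibrium.

Training minimises, alternately,

```
L_D = (o_m(S_e) - 1)^2 + o_m(S_g)^2
L_G = (o_m(S_g) - 1)^2 + alpha * L_MRC,     alpha = 0.9
```

where the multi-resolution consistency loss sums, over a four-level
average-pooling pyramid `DH^k`, the temporal MAE, a `1 - MCC`
cross-correlation term, and the absolute difference between Pearson
connectivity matrices:

```
L_MRC = sum_k TMAE(DH^k S_g, DH^k S_e)
      + sum_k [1 - MCC(DH^k S_g, DH^k S_e)]
      + sum_k TMAE(PCC(DH^k S_g), PCC(DH^k S_e))
```

Restoration quality is reported on the missing rows only: MAE, RMSE,
R², dynamic time warping, and the maximum change in missing-ROI-related
connectivity.

There is no torch in this stack: the package implements its own
reverse-mode autodiff tape, attention/convolution layers and Adam
optimiser in R (gradients are verified against finite differences in the
test suite).

## Worked example

No scanner data is required: a latent-factor generator produces
BOLD-like multi-ROI signals (band-limited group-structured oscillations
plus AR(1) noise) with known ground truth.

```r
library(boldfill)

spec <- synthetic_spec(n_rois = 10, n_timepoints = 32, latent_rank = 2,
                       noise_sd = 0.1, n_subjects = 5, seed = 21)
dataset <- generate_dataset(spec)

mask <- missing_mask(4, "prior")        # ROI 4 missing, prior-value fill
cfg <- train_config(generator = generator_config(L = 2, heads = 2, d_model = 16),
                    discriminator = discriminator_config(heads = 2, d_model = 16,
                                                         header_hidden = 8),
                    mask = mask, epochs = 40, batch_size = 1, seed = 31)
fit <- train(cfg, dataset)              # 4 train / 1 held-out subject
fit
#> <boldfill_fit> 40 epochs; best eval MAE 0.0604 at epoch 15

se <- dataset[[5]]$ts                   # the held-out subject
sg <- restore_timeseries(fit$generator, se, mask)
evaluate_restoration(sg, se, mask)
#> <eval_report> 1 missing ROI(s)
#>   MAE 0.0604  RMSE 0.0827  R2 0.8497  DTW 1.8824  max|dFC| 0.0702
```

The report reads: the restored ROI-4 time-series deviates from the true
(never seen) series by 0.060 on the `[0, 1]` amplitude scale, explains
85% of its variance, and no ROI-4 functional connection moved by more
than 0.07 in Pearson correlation. The prior-fill initialisation alone
scores MAE 0.090 on the same subject. Restoration quality at such small
subject counts depends strongly on how well the prior fill aligns with
the missing row (see the vignette's limitations section); with
cohort-sized data, longer training and the default depth-5 generator,
the same code paths apply unchanged.

A thin CLI wraps the same functions
(`inst/cli/boldfill.R`: `simulate`, `train`, `evaluate`, `init-study`,
`mask-study`), configured by a YAML file mirroring `train_config()`.

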