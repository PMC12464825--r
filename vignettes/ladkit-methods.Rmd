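---
title: "Methods: LAD calling and quantitative pA-DamID analysis with ladkit"
author: "ladkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LAD calling and quantitative pA-DamID analysis with ladkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladkit)
```

## The measurement and its normalization

pA-DamID profiles contacts between the genome and a nuclear-envelope
protein as counts of adenine-methylated fragments produced by an
antibody-tethered Dam methyltransferase. Because methylation also tracks
chromatin accessibility and amplification bias, every experiment carries a
Dam-only control, and the signal of interest is the per-bin ratio

$$y_i = \log_2 \frac{\mathrm{ab\_cpm}_i + 1}{\mathrm{dam\_cpm}_i + 1},$$

with counts scaled to reads per million and a pseudocount of 1
(`normalize_log_ratio()`). Bins are 0-based, half-open, 20 kb wide by
default, tiled from position 0; the final partial bin of a chromosome is
kept and treated like any other. Missing bins stay missing throughout —
no imputation is ever applied.

Replicate tracks are z-scored genome-wide (`zscale_track()`) before being
averaged per condition (`average_replicates()`). Z-scoring first and
averaging second is the package default: it equalizes per-replicate
dynamic range before replicates are combined, which is the motivation for
z-scoring in the first place. The reverse order is available by simply
calling the two functions the other way around; for deeply sequenced
replicates of similar quality the two orders differ negligibly.

## Two-state segmentation

`fit_two_state_hmm()` fits a hidden Markov model with two states
("inside", the LAD-like state with the higher emission location, and
"outside") by Baum–Welch. Key numerical choices:

* **Emissions.** Student-t with df fixed at 3 by default. The t's heavy
  tails keep isolated outlier bins from dragging the state means;
  estimating df from data adds little for segmentation and is out of
  scope. A Gaussian alternative is available (`emission = "gaussian"`)
  and is what the parameter-recovery tests use, since their generative
  model is Gaussian. The t M-step uses the standard latent-scale
  weighting $u = (\nu + 1)/(\nu + z^2)$, which preserves EM monotonicity;
  the test suite asserts the log-likelihood never decreases by more than
  1e-8 on any fit.
* **Initialization.** Emission locations start at the 25th/75th
  percentiles of the data, equal scales at half the overall SD, stay
  probabilities at 0.99. With two well-separated states this is
  reproducible without random restarts, so fits are deterministic.
* **Missing bins.** A missing observation contributes likelihood 1 in
  both states, which advances the chain across gaps without breaking it.
* **Identifiability.** After convergence states are ordered by location;
  the higher-location state is reported as LAD.
* **Degenerate input.** Constant (near-zero-variance) tracks and tracks
  with fewer than 50 informative bins are rejected with an error.

`segment_domains()` decodes the Viterbi path per chromosome and merges
runs into alternating LAD/iLAD intervals; `min_bins` absorbs shorter runs
by flipping the shortest run's state until none remain, which keeps the
tiling and alternation invariants. Chromosomes with no usable bins emit
no domains and are logged. LADs are intended to be called once on the
averaged control track; the coordinates are then reused for every sample
so that per-sample LAD scores are comparable.

The Viterbi implementation is verified against exhaustive enumeration of
all $2^{12}$ state paths on 12-bin instances, and segmentation accuracy
is measured on simulated genomes with a 2-unit contrast gap and SD 0.5,
where it exceeds 99% bin-level accuracy. Boundary placement is assessed
as precision: each *reported* boundary must lie within one bin of a true
boundary. The geometric domain-length law occasionally generates 1–2-bin
micro-domains whose boundaries the decoder legitimately smooths over;
counting those as boundary errors would measure the generator's tail, not
localization accuracy.

## Domain scores and the moderated differential test

The LAD score of a domain is the mean z-scored signal over its bins
(`lad_score()`, `lad_score_matrix()`). Differential testing
(`moderated_diff_test()`) follows the voom/limma logic, adapted to
continuous domain scores rather than log-CPM counts — no count offsets or
library-size terms:

1. A lowess curve (span 0.5) of the square root of residual SD against
   the row mean (`fit_mean_variance_trend()`) is evaluated by linear
   interpolation with flat extrapolation; fewer than 20 usable rows fall
   back to the constant pooled SD with a warning. Weights are the
   reciprocal predicted *variances*. Because a two-group design gives
   every observation in a row the same weight, the weights do not change
   the t statistic itself; they place the empirical-Bayes shrinkage on a
   scale where the trend has been divided out, which is their purpose.
2. Residual variances are shrunk toward a scaled-F prior whose
   parameters are estimated by the method of moments on $\log s^2$
   (digamma/trigamma matching, with a Newton inversion of the trigamma
   function). When the moment equation has no positive solution the
   prior df is infinite and all variances shrink fully to the prior.
   The estimator is cross-checked in the test suite against an
   independent implementation (limma's `squeezeVar`).
3. Moderated t statistics use residual-plus-prior degrees of freedom;
   two-sided p-values are Benjamini–Hochberg adjusted (`bh_adjust()`,
   a validated wrapper over the standard step-up procedure), and domains
   with adjusted p below `alpha` (0.05) are called `gain` or `loss` by
   the sign of the score change.

Per-replicate z-scored tracks feed the score matrix by default; whether
averaged or per-replicate tracks are used upstream is configurable by the
caller, since either can be defended.

Error control and power are verified by simulation: under a null with
500 LADs and 4 vs 4 replicates, the mean fraction of BH-significant calls
stays within Monte-Carlo error of zero and raw p-values are uniform
(Kolmogorov–Smirnov at 10 000 LADs). With 10% of LADs shifted by three
per-LAD standard errors, sensitivity at raw p < 0.05 exceeds 0.8. At
that effect size the BH-adjusted sensitivity is intrinsically capped near
0.5 — the adaptive threshold lands near 0.005, where even a z test has
only ~55% power — so raw-p sensitivity is the meaningful power metric,
with false-discovery control checked separately.

## Spike-in calibration

With a constant-fraction spike-in of cells from a second species (20% in
the default generator), `compute_spikein_scaling()` derives per-sample
affine factors — the mean and SD of the sample's spike-genome log-ratio
track — and `apply_scaling()` applies those *same* factors to the target
genome. Both offset and scale are used: converting the spike profile to
a z-score implies a full affine transform, and the spike factors applied
to the spike track itself reproduce `zscale_track()` exactly (tested).
Spike bins are larger (250 kb by default) because spike reads are sparse
and larger bins stabilize the estimates; at least 20 non-missing spike
bins are required.

The point of the method is preserved quantitatively: when the target
contrast of one condition is halved while spike distributions stay
identical, the calibrated LAD–iLAD contrast ratio recovers 0.5 (mean
within ±0.05 over ten simulations), whereas per-sample z-scaling pushes
the ratio strongly toward 1. In the noise-free limit self-z-scaling
returns exactly 1.0; with realistic negative-binomial count noise in the
bin variances it lands near 0.74 in our simulations — still a large
upward bias that would mask the true global change.

## Border profiles

`extract_borders()` takes LAD flanks as borders and applies two exclusion
rules: borders within 50 kb of a chromosome end are not real borders, and
borders adjacent to any domain shorter than 50 kb (two 20-kb bins) would
contribute a noisy single-sided data point and are dropped.
`border_profile()` assigns every bin to its *closest* border only, so each
position contributes exactly once even where borders are dense; exact
ties go to the lower-coordinate border (the tie rule is an implementation
decision — ties are measure-zero in real data). Distances are measured
from bin centres, making inside/outside relative positions symmetric;
profile positions therefore sit at half-bin offsets. The confidence band
is the normal-theory mean ± 1.96 SE, reported where at least two bins
contribute.

## De-partitioning metrics

* `departition_slope()` regresses the differential track on the control
  track; if the perturbed signal is $(1-k)$ times the control plus noise,
  the slope estimates $-k$ exactly (and equals the slope of perturbed on
  control minus one, an identity the tests assert).
* `bimodality_assess()` fits one- and two-component Gaussian mixtures
  (via mclust) and combines the BIC comparison with Ashman's
  $D = \sqrt{2}\,|\mu_1-\mu_2| / \sqrt{\sigma_1^2+\sigma_2^2}$; the
  verdict is bimodal iff BIC favours two components *and* $D > 2$.
  De-partitioning is usually shown as density plots without a named
  statistic, so this is the package's own reproducible
  operationalization: scale-free,
  affine-invariant, and robust to EM degeneracies (a vanishing component
  yields a flagged unimodal verdict).
* `domain_score_compare()` applies Welch's t or the two-sided Wilcoxon
  rank-sum test to LAD vs iLAD per-domain means; percentile trimming
  (0.5% per tail by default) affects only the reported score lists for
  plotting, never the test.
* `domain_overlap()` reports base-pair overlap in Mb plus a two-sided
  Fisher exact test on a 2×2 table of fixed-width genome bins (a bin
  belongs to a set when its centre does); the exact-unit choice of the
  contingency table is the package's, since binned overlap testing can be
  defined per-bin or per-domain.
* `track_correlation()` is Pearson correlation over pairwise non-missing
  bins with an optional concordance mask, p from the exact t transform
  with n − 2 df.

## Nucleosome linkers and pile-ups

`linker_lengths()` assigns dyads to the domains containing them, takes
distances between consecutive dyads *within the same domain* (pairs
spanning a boundary are excluded — the conservative reading of
intersect-then-measure), subtracts the 147-bp nucleosome footprint from
distances above 100 bp, and keeps linkers of 1–100 bp grouped by state.
`scaled_region_pileup()` mirrors deepTools' scale-regions matrices:
flanks at native column resolution (10 kb), the domain body rescaled to a
fixed number of columns by area-weighted averaging (each output column
averages the signal over its fractional span — deterministic and
oracle-checkable), missing data and out-of-genome positions as zero, and
an optional all-zero-row filter. With the defaults the matrix has
50 + 100 + 50 = 200 columns.

## The synthetic-data generator

`simulation_config()` fixes the study conditions the tests run under:

| parameter | default | meaning |
|---|---|---|
| `bin_size` | 20 kb | analysis bin width |
| `lad_mean_len`, `ilad_mean_len` | 1 Mb | geometric mean domain length |
| `mu_lad`, `mu_ilad` | +1 / −1 | latent log2 contrast per state |
| `sigma_bin` | 0.3 | per-bin, per-replicate biological SD |
| `dam_depth`, `ab_depth` | 1e6 | expected reads per sample |
| `dispersion` | 0.05 | negative-binomial overdispersion |
| `n_replicates` | 2 | replicates per condition |
| `spike_fraction` | 0.20 | spike-genome read fraction |

Domain lengths are geometric in bins, matching the sojourn law of the
downstream Markov model. Counts are negative binomial (Poisson in the
zero-dispersion limit) over a log-normal random-walk accessibility
background shared between the antibody and Dam sample of a pair — this
makes Dam normalization genuinely necessary rather than decorative. The
contrast gap of 2 log2 units with per-bin SD 0.3 and ~1 M reads per
sample produces tracks whose bimodality, segmentation difficulty and
replicate scatter resemble a clean pA-DamID experiment. The spike genome
carries a single latent contrast shared by all samples, reflecting a
spike-in taken from one biological sample; per-sample spike differences
are purely technical. Perturbations shrink every bin's contrast toward
the genome mean by a factor $1-k$ and may add constant shifts to sampled
domains, giving known ground truth for both global de-partitioning and
domain-level differential calls.

What the generator does **not** emulate: GATC-fragment sequence structure
and read-level artefacts, copy-number variation, mappability gaps,
chromosome-scale covariates (gene density, replication timing), or
correlated biological noise between neighbouring domains. Passing tests
therefore demonstrate correctness of the algorithms under the stated
statistical assumptions, not robustness to every artefact of real
sequencing data.

Dyads are laid down with state-specific nucleosome repeat lengths
(defaults 197 bp in LADs, 187 bp in iLADs, matching the direction of
reported heterochromatin/euchromatin spacing differences), Gaussian
jitter, and a hard 148-bp minimum spacing so nucleosomes never overlap.

## Problem sizes and runtime

The test suite and acceptance script use one-chromosome genomes of
20–50 Mb (1000–2500 bins), 50 000-bin chains for HMM parameter recovery,
100–200 null runs of 500 domains for error control, and 10–20 seeds for
stochastic recovery checks. These sizes give Monte-Carlo error well below
every asserted tolerance while keeping a full run of suite plus script
around a minute of CPU; all sizes are parameters, so users can scale any
experiment up.

## Known limitations

* Two states only; no semi-Markov duration modelling and no df
  estimation for the t emissions.
* Two-condition designs only in the differential test; no covariates.
* Spike-in species assignment is by label (synthetic data) or by
  reference-name prefix after competitive alignment with MAPQ ≥ 10
  (real data); the package does not perform alignment.
* The bimodality verdict is a package-defined metric, intended for
  comparing conditions within one analysis rather than as an absolute
  claim about multimodality.
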