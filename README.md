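# ladkit

Quantitative analysis of genome–nuclear-lamina (NL) interaction maps from
pA-DamID and related protein-directed DamID protocols.

Large genomic regions contact the filamentous lamina at the nuclear
periphery in megabase-scale lamina-associated domains (LADs). pA-DamID
measures these contacts as adenine-methylated fragment counts from an
antibody-directed Dam methyltransferase, normalized against a freely
diffusing Dam-only control that captures accessibility and amplification
bias. `ladkit` implements the full downstream pipeline for such data —
LAD calling, domain scoring, differential testing between conditions,
spike-in calibration, border profiles, de-partitioning metrics and
nucleosome linker analysis — together with a synthetic-data generator with
known ground truth, so every stage is testable end to end without any
sequencing data.

## The model in brief

**Normalization.** Antibody and Dam-only reads are counted in fixed
genomic bins (20 kb by default). With library-size scaling to reads per
million and a pseudocount of 1, the per-bin signal is

```
y_i = log2( (ab_cpm_i + 1) / (dam_cpm_i + 1) )
```

Replicate tracks are z-scored genome-wide (mean 0, SD 1) to equalize
dynamic range between experiments, then averaged per condition.

**Segmentation.** The averaged control track is segmented by a two-state
hidden Markov model with Student-t emissions (df = 3; Gaussian optional),
fitted by Baum–Welch and decoded by Viterbi. The state with the higher
emission location is the LAD state. LAD coordinates from the control are
reused for all samples.

**Domain scoring and differential testing.** The LAD score is the mean
z-scored signal over a domain's bins. Per-LAD, per-replicate scores enter
a voom/limma-style test: a lowess mean–variance trend supplies per-LAD
precision weights, residual variances are shrunk toward an empirical-Bayes
prior (method of moments on log s²), and moderated t statistics with
residual-plus-prior degrees of freedom give p-values that are
Benjamini–Hochberg adjusted (significance: adjusted p < 0.05).

**Spike-in calibration.** When a fixed fraction of cells from a second
species is spiked in, each sample's spike-genome log-ratio track (250-kb
bins) yields affine factors `(x − mean) / sd`; applying the *same*
factors to the target genome puts samples on a common scale while
preserving genuine global changes in NL interaction strength that ordinary
per-sample z-scaling would erase.

**De-partitioning metrics.** Loss of LAD/iLAD partitioning is quantified
by the slope of the differential track (perturbed − control) regressed on
the control track (a slope of −k means the contrast shrank by factor
1 − k), by collapse of the bimodal signal distribution (Gaussian-mixture
BIC plus Ashman's D), and by domain-score comparisons (Welch / Wilcoxon)
and binned genomic-overlap Fisher tests.

**Nucleosome linkers.** From nucleosome dyad positions, distances between
consecutive dyads within the same domain are converted to linker lengths
(distances > 100 bp have the 147-bp nucleosome footprint subtracted;
lengths in 1–100 bp are kept) and compared between LADs and iLADs.

## Worked example

Simulate a 50-Mb genome with a known LAD structure, generate
negative-binomial pA-DamID counts for two conditions (the perturbed one
with a 30% de-partitioning of the latent contrast), and run the pipeline:

```r
library(ladkit)

cfg <- simulation_config(chrom_sizes = c(chr1 = 5e7), seed = 7,
  perturbation = perturbation_spec(departition_factor = 0.3))
truth  <- simulate_genome(cfg)
sim    <- simulate_counts(truth, cfg)

tracks <- pa_damid_tracks(sim)        # log2(ab:Dam), z-scored, per replicate
cond   <- attr(tracks, "condition")
ctrl   <- average_replicates(tracks[cond == "control"])
pert   <- average_replicates(tracks[cond == "perturbed"])

lads <- call_lads(ctrl)
lads$model
#> <hmm_model> t emissions (df = 3)
#>   outside: location -0.7373 scale 0.2826 | inside (LAD): location 1.0138 scale 0.2784
#>   stay probabilities: 0.9791 / 0.9716; loglik -1334.27 after 14 iterations (converged)
lads$domains
#> <domain_set> 61 domains (30 LAD, 31 iLAD) on 1 chromosome(s)

scores <- lad_score_matrix(lads$domains, tracks)
head(moderated_diff_test(scores, factor(cond, c("control", "perturbed"))), 3)
#>             id      delta      t_mod df_total         p     p_adj call
#> 1 LAD_chr1_002 -0.1955198 -1.9598320 5.096208 0.1062271 0.5153699   ns
#> 2 LAD_chr1_004 -0.1318290 -1.2229695 5.096208 0.2748640 0.5153699   ns
#> 3 LAD_chr1_006 -0.1206046 -0.5254273 5.096208 0.6213382 0.9028533   ns

departition_slope(ctrl, differential_track(pert, ctrl))
#> <slope_result> slope -0.2477, r -0.391 (p 5.83e-92, n 2500)
bimodality_assess(ctrl)
#> <bimodality_result> verdict bimodal (Ashman's D 4.98, delta BIC 1532.2)
```

The fitted emission locations straddle the two configured contrast states;
the 61 called domains track the simulated LAD/iLAD tiling; `delta` is the
perturbed-minus-control change in mean z-score per LAD with its moderated
t statistic and BH-adjusted p; the negative slope on z-scored tracks
reflects the injected de-partitioning (on raw log-ratio tracks it
approaches −0.3); and the control distribution is clearly bimodal, as in
unperturbed cells.

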