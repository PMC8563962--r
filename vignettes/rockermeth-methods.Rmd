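---
title: "Detecting differentially methylated regions by AUC segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differentially methylated regions by AUC segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rockermeth)
```

## The problem

Cancer tissue differs from its normal counterpart not only at single CpG
sites but over contiguous genomic regions: promoter CpG islands of tumor
suppressors gain methylation, while large, mostly intergenic blocks lose it.
A differentially methylated region (DMR) caller must work across platforms
with very different site densities (whole-genome bisulfite sequencing,
reduced-representation protocols, 450k-style arrays) and detect events
ranging from a few hundred base pairs to megabases, without fixing a window
size in advance.

`rockermeth` addresses this with a rank-based per-site statistic and a
segmentation model that is aware of genomic distance.

## The model

**Step 1 — per-site AUC.** For each CpG site the beta values (percent
methylation) of the test group are compared with the control group through
the area under the ROC curve, computed as the normalized Mann–Whitney U
statistic with midranks for ties:

$$\mathrm{AUC} = \frac{\#\{t > n\} + \tfrac12\,\#\{t = n\}}{n_t\,n_n}.$$

AUC near 1 means hypermethylation in the test group, near 0
hypomethylation, 0.5 no difference. Because the AUC depends only on ranks
it is insensitive to the magnitude scale of the assay, which is what makes
the same pipeline applicable to arrays and sequencing alike. The sample
standard deviation of all retained AUC values, pooled across chromosomes,
is the dispersion estimate $\sigma_{Tot}$ used below. (Pooling across
chromosomes is a deliberate choice: the null AUC noise is a property of the
group sizes, not of a chromosome.)

**Step 2 — heterogeneous HMM.** The genome-ordered AUC track is modelled by
a three-state hidden Markov model: state 1 hypomethylated, state 2 neutral,
state 3 hypermethylated. Emissions are Gaussians truncated to $[0,1]$ with
means $0.5-\mu,\; 0.5,\; 0.5+\mu$ and standard deviations
$(1-F)\sigma_{Tot},\; F\sigma_{Tot},\; (1-F)\sigma_{Tot}$. The state means
are fixed, not estimated: 0.5 is forced by the null value of the AUC, and
$\mu$ sets the differential resolution; estimating them by EM would let a
noisy dataset pull the differential states toward the null. Transitions
between adjacent sites $i$ and $i+1$ at distance $d_i$ use

$$\Pr(\text{jump}) = p\,\bigl(1 - e^{-d_i / d_{Norm}}\bigr),$$

split evenly between the two target states, with the diagonal holding the
remainder. Adjacent sites a few base pairs apart therefore almost never
change state, while sites separated by tens of kilobases approach the
homogeneous jump probability $p$. Decoding is by the Viterbi algorithm in
log space, independently per chromosome, with a uniform initial
distribution (its influence is forgotten within a few observations, so any
non-degenerate prior gives the same segments).

Two readings of the model deserve a note. The second component of each
emission parameter pair is treated as a standard deviation, not a variance:
the expressions $(1-F)\sigma_{Tot}$ are linear in $\sigma_{Tot}$ and only
make dimensional sense that way. And $\mu$ is interpreted as the symmetric
offset from 0.5, so the default $\mu = 0.25$ puts the differential means at
0.25 and 0.75.

**Step 3 — segment testing and filtering.** Within each non-neutral
segment, beta values are averaged per CpG site within each group and the
two per-site-mean vectors are compared by a two-sided Wilcoxon–Mann–Whitney
test (exact when the segment has at most 25 sites and no ties; normal
approximation with tie and continuity correction otherwise). The
two-sample rank-sum form follows the test's name; a paired signed-rank
alternative would answer a subtly different question and is not offered.
P-values are Benjamini–Hochberg corrected over all tested segments of the
run; neutral segments are never DMR candidates, so they are excluded from
the family rather than allowed to dilute it. Segments with FDR $\ge$ 0.05
or fewer than 6 sites are discarded — both boundaries taken literally, so
FDR = 0.049 with 6 sites survives. Survivors are classified: any
gain-of-methylation region is `hyper`; loss-of-methylation regions are
`hypo` up to 10 kb and `hypo_block` beyond, the operative proxy for
partially methylated domains.

**Step 4 — sample scores.** Against a DMR catalog, each sample (or cell)
receives a robust Z-score per DMR: the sample's median beta inside the DMR,
centred on the median of the control samples' medians and scaled by their
median absolute deviation (1.4826-scaled), floored at one percentage point
so that near-constant control references cannot inflate scores. The
dispersion estimator defaults to the conventional 1.4826-scaled median
absolute deviation; `mad_type` switches to the unscaled MAD or to the
maximum absolute deviation for sensitivity analyses. The
per-sample fraction of supporting events (PSFSE) counts DMRs whose score
strictly exceeds +3 (hyper) or falls strictly below −3 (hypo and
hypo-block); a score exactly at the threshold does not count, fixing the
Heaviside convention at 0. Missing scores stay in the denominator, making
the fraction conservative under missing data. The single-cell variant
(PCFSE) first drops cells with ≥ 50% scoreless DMRs in any class.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `p` | 0.05 | probability | homogeneous jump probability; resolution of the segmentation (larger = shorter segments) |
| `f` | 0.4 | — | variance split: neutral state gets $F\sigma_{Tot}$, differential states $(1-F)\sigma_{Tot}$ |
| `mu` | 0.25 | AUC | offset of the differential state means from 0.5 |
| `d_norm` | 1e5 | bp | distance normalization of the transition decay |
| `min_sites` | 6 | sites | minimum CpG support for a DMR |
| `fdr_alpha` | 0.05 | — | BH threshold on the segment test |
| `max_distance` | off | bp | optional segment split at larger inter-site gaps (sparse arrays) |
| `hypo_block_len` | 1e4 | bp | hypo vs hypo-block length boundary |
| `score_threshold` | 3 | Z | PSFSE support threshold (strict) |
| `min_normals` | 10 | samples | control-group size below which a warning is issued |

The control-group rule is a warning, not an error: it encodes the
dataset-selection practice of requiring at least 10 normals, but small
control sets are common (e.g. pooled WGBS normals) and the method still
runs, with noisier per-site AUC values.

## The synthetic benchmark generator

`simulate_dataset()` builds fully labelled datasets so that every stage of
the pipeline can be tested without downloads. Its design mirrors the class
1–5 benchmark convention: background methylation is bimodal (CpG-island-like
low mode centred at 0.2, open-sea-like high mode at 0.8); within an
implanted DMR, the test-group signal mean is the baseline reflected toward
the opposite mode; and each test-group observation at an implanted site is
drawn from the signal component with probability $c$ (the mixture factor)
and from the baseline otherwise. Classes 1–5 map to
$c = 1.0, 0.85, 0.7, 0.6, 0.55$: only the class-5 value is a fixed,
published constant; the intermediate values are calibration knobs of the
emulation. On top of the mixture, every value carries a per-sample
logit-scale offset (purity and composition differences, SD 0.4), a
per-observation logit-scale biological noise term (SD 1.0), and
beta-distributed measurement noise (precision 12 for sequencing layouts,
40 for the array layout, where the biological term is also tightened to
0.5).

The free parameters of the emulation — group sizes, noise SDs, precision,
and the implant size distribution (2–14 sites for sequencing layouts,
deliberately including implants below the 6-site filter, since short DMRs
are a realistic part of any benchmark) — were calibrated once, by a small
grid search, so that the generator reproduces the difficulty profile the
class convention describes: class-1 implants are recovered nearly whenever
they meet the site filter, class-5 recall sits near one third, and null
data stay above 0.99 site-wise specificity. The defaults are 6 test and 6
control samples, typical of WGBS benchmark cohorts. They were frozen before
the acceptance checks were written and are not adjusted per run.

The hm450 layout is fixed by design rather than calibrated: one array-like
chromosome with 120 promoter clusters (8–20 probes, 100–500 bp spacing)
interleaved with open-sea probes (5–50 kb spacing), carrying exactly 60
promoter DMRs of 8–20 probes (gain, promoters start unmethylated) and 20
non-promoter DMRs of 5–10 probes (loss).

What the generator does **not** emulate: read-depth-dependent missingness,
copy-number-induced beta shifts, batch effects, spatially correlated noise
beyond the per-sample offset, and real CpG density landscapes. Passing
tests on this generator therefore demonstrate the statistical machinery —
they do not certify performance on any particular real cohort.

```{r example, eval = FALSE}
sim <- simulate_dataset("wgbs", class_label = 2, seed = 4)
fit <- detect_dmrs(sim$tumor, sim$normal)
glance(fit)
evaluate_predictions(tidy(fit), sim)
autoplot(fit)
```

## The evaluation harness

`evaluate_predictions()` reports segment-wise and site-wise precision,
recall and F1, plus site-wise specificity. Segment matching requires an
overlap strictly greater than 30% of the *predicted* DMR's length with a
truth DMR of the same direction — the predicted region is the subject of
the matching sentence — with `denominator = "truth"` or `"either"`
available for sensitivity analyses. Direction must match; a hypo-block and
a hypo prediction both count as loss.

## The multi-dataset catalog

`partition_multi()` cuts the genome at the union of all per-dataset DMR
boundaries (the `bedtools multiinter` idea, implemented on
`GenomicRanges::disjoin`), and `refine_catalog()` keeps an atom for a
dataset only if, in that dataset, it has at least 6 probes, a BH-corrected
two-sided rank-sum test of per-sample median betas below 0.05, a mean beta
difference above 5 percentage points in magnitude, and at least 3 CpG
sites with concordant per-site signal (AUC < 0.25 for loss, > 0.75 for
gain). BH families are per dataset, mirroring the per-dataset testing
language. Atoms supported by several datasets need a dominant direction —
a strict majority among supporting datasets; ties are discarded, since no
consensus label would be defensible. Adjacent atoms with identical support
and labels are merged back to undo fragmentation introduced by boundary
arithmetic, and the 10 kb hypo/hypo-block split is re-applied to the merged
intervals.

## Numerical choices and degenerate inputs

* Internal coordinates are 1-based inclusive; all BED output is 0-based
  half-open. Beta values are stored as percentages because the score floor
  ("1") and the catalog effect-size rule (">5") are stated in percentage
  points.
* Emission log-densities are floored at −745 (the smallest double whose
  exponential is positive) so the Viterbi recursion never propagates
  `-Inf`; a gap of exactly 0 bp yields an identity transition matrix and
  the floor keeps its logarithm usable.
* Sites with fewer than two usable values in either group carry no rank
  information; they are dropped from the AUC track (with a reported count)
  and the inter-site distances are recomputed between retained sites.
* A segment whose test cannot be computed (no usable sites) keeps a
  missing p-value and is discarded by the FDR filter.
* Ties in the rank-sum test switch the p-value to the corrected normal
  approximation; the AUC itself always uses midranks.
* An empty DMR set writes an empty BED file and scores to an empty table —
  never an error — so pipelines can run unattended over many datasets.

## Problem sizes used by the checks

The packaged checks run the full pipeline on 20 replicates of 20,000 sites
with 25 samples per group for the specificity property, five class-5
datasets at generator defaults for the recall target, and exhaustive-
enumeration oracles (all $3^n$ state paths for tracks up to 9 sites, all
$\binom{2m}{m}$ labelings for segments up to 8 sites, all test–control
pairs for groups up to 6) for exact agreement of the core statistics.
These sizes were chosen so the whole suite completes in a few minutes while
keeping every Monte-Carlo margin wide.

## Known limitations

* No covariate adjustment: confounded designs need a different tool.
* Not designed for differentially *variable* regions.
* The per-site AUC saturates at modest group sizes; with very small control
  groups the segmentation still runs but boundary placement degrades
  (hence the `min_normals` warning).
* The segment test treats per-site group means as exchangeable units;
  strong spatial autocorrelation of noise within a segment would make the
  p-values anti-conservative. The FDR filter and the 6-site rule absorb
  most of this in practice, as the null-simulation specificity shows.
* Class labels 2–4 of the generator are interpolations of the published
  class convention, not re-derivations of the original datasets.
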