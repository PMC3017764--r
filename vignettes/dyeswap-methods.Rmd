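---
title: "Methods: mixed-model normalization and mixture-based DE calling for dye-swap arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model normalization and mixture-based DE calling for dye-swap arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyemix)
```

## The problem

Two-colour microarray experiments with a handful of hybridisations — here a
cattle study contrasting three horn phenotypes (Polled, Horned, Scurred)
across two sexes on four 4-array chips, with dye-swapped labelling — cannot
be normalized array-by-array without discarding most of their information.
`dyemix` implements the joint-modelling alternative: all background-corrected
log2 channel intensities enter one linear mixed model, normalization and
per-gene expression estimation happen simultaneously, and differential
expression is called from the model's phenotype-by-gene solutions through a
two-component mixture with a posterior-probability FDR rule.

## Spot quality control

Each spot channel carries a foreground mean and median, a background mean
and the SD of the background pixels. Two filters are applied:

* **Signal-to-noise** `s = (fg_mean - bg_mean) / bg_sd`, kept when `s > 1`
  (strict). A non-positive background SD cannot form the ratio and fails the
  spot with a warning.
* **Mean/median agreement** `r = min(mean, median) / max(mean, median)`,
  kept when `r >= 0.85`. Both strict and at-or-above conventions appear in
  the literature for this filter; the at-or-above rule retains the boundary
  spots, which is the rationale usually cited for the 0.85 threshold, and
  `apply_qc(r_strict = TRUE)` switches to the strict form.

Background correction is plain subtraction, and a spot whose corrected
intensity is non-positive fails regardless of the filters (its log2 value
would be undefined). Passing spots contribute `log2(fg_mean - bg_mean)`;
the foreground *mean* feeds the corrected intensity, the median enters only
through `r`. Failing spots are recorded as a literal zero in written tables
but are treated as *missing* inside the model — a genuine zero would
corrupt every log-scale mean they touch.

## The normalization mixed model

For the background-adjusted log2 intensity of gene $g$ in channel $c$:

$$ y = \mu + C_c + G_g + AG_{ag} + DG_{dg} + HG_{hg} + SG_{sg} + \varepsilon $$

* $C$ — fixed *comparison* effect, one level per (chip, array, dye)
  channel: 32 levels in the default design. This term absorbs all
  channel-level artefacts (scanner gain, dye bias, chip effects) and is the
  normalization.
* $G, AG, DG, HG, SG$ — random gene, array-by-gene, dye-by-gene,
  phenotype-by-gene and sex-by-gene effects, i.i.d. normal with variances
  $\sigma^2_g, \sigma^2_{ag}, \sigma^2_{dg}, \sigma^2_{hg}, \sigma^2_{sg}$,
  mutually independent; $\varepsilon$ i.i.d. $N(0, \sigma^2_e)$.

Observations are channel-wise: one response per probe per dye channel.
The phenotype-by-gene solutions $\widehat{HG}$ are the per-gene normalized
expression profiles everything downstream is built from.

### REML fitting

Variance components are estimated by REML. Every random term is
gene-indexed, so the mixed-model equations decompose into one symmetric
block of `1 + n_arrays + 2 + n_phenotypes + n_sexes` effects per gene,
coupled only through the fixed channel effects; the fitter absorbs the
fixed effects by a Schur complement over these blocks and groups genes
with identical patterns of observed channels so that one factorisation
serves the whole group. On clean (no missing spot) data there is a single
pattern and a fit at 2,000 probes takes a few seconds.

Each iteration computes the EM-REML update and, from the second iteration
on, an average-information (AI) Newton step from the analytical gradient;
the AI candidate is accepted only when its restricted likelihood is at
least the EM candidate's, so the criterion is non-decreasing over accepted
iterations and retains EM's robustness near boundaries. Updates are
truncated below at `1e-10` (components pinned there are reported as
boundary estimates), and convergence requires a relative change below
`1e-6` in every component or a log-likelihood change below `1e-8`.
Prediction-error variances (PEV) of the $HG$ solutions come from the exact
per-gene block inverses corrected by the fixed-effect Schur term.

### Contrast statistics

For each gene the three phenotype differences — Polled−Horned (PvH),
Polled−Scurred (PvS), Horned−Scurred (HvS) — are standardized by the
square root of the PEV of that difference,
$t_g = (\widehat{HG}_{1g} - \widehat{HG}_{2g}) / \sqrt{PEV_d}$. The exact
denominator of the published statistic is not recoverable from its source;
treating it as the prediction-error SE of the BLUP difference is this
package's documented interpretation.

One consequence worth stating: this statistic is *not* unit-variance under
the null. BLUP shrinkage gives
$\mathrm{Var}(\hat d) = 2\sigma^2_{hg} - PEV_d$, so the null spread of $t$
is $\sqrt{(2\sigma^2_{hg} - PEV_d)/PEV_d}$ — the test suite checks this
identity directly. The mixture step below estimates the null scale from
the data, so DE calling is unaffected by the non-unit scale.

## Mixture-based DE calling

Each contrast's statistics are modelled as a two-component normal mixture
fitted by EM (quantile-split initialisation at the 90th percentile of
$|t|$, five random restarts, degenerate components rejected and
restarted). The component whose mean is closest to zero — ties broken by
the smaller variance — is the null; the other component's posterior
probabilities rank the genes. The DE set is the largest top-ranked set
whose estimated FDR, the mean of $1 - \text{posterior}$ over the set,
stays below the 1% target. An empty set is a legitimate outcome. The three
contrasts are fitted separately (`de_analysis(pooled = TRUE)` pools them
into one mixture when a single experiment-wise fit is preferred).

Log2 differences convert to signed fold changes by the negated-reciprocal
convention: $2^d$ for $d \ge 0$ and $-2^{-d}$ otherwise.

## qPCR validation: the ddCt GLM

Relative quantification fits `Ct ~ phenotype * gene` by least squares on
the records of one contrast's two phenotypes and the target plus reference
gene, and estimates $\Delta\Delta C_t$ as the combinational-effect
contrast `CE1 - CE2 - CE3 + CE4` of the fitted cell means (first
phenotype/target − second phenotype/target − first phenotype/reference +
second phenotype/reference). Because the interaction model is saturated,
this equals the raw cell-mean difference-of-differences in any design, and
animal effects — shared between a target and reference measurement of the
same animal — cancel exactly in balanced data. The SE, t and two-sided
p-value come from the linear-model contrast. Technical replicates enter as
observations, matching the minimal stated model (no animal or replicate
term); `average_replicates = TRUE` collapses them to per-animal means
first, which leaves the balanced point estimate unchanged and reduces the
degrees of freedom. Fold change is $2^{-\Delta\Delta C_t}$ with the same
negated-reciprocal convention; a negative $\Delta\Delta C_t$ means higher
expression in the first-named phenotype.

## Probe annotation rules

`annotate_probes()` is a deterministic cascade over precomputed interval
and BLAST tables (all coordinates 0-based half-open; strand is ignored;
interval work is delegated to IRanges):

1. bovine **exon** overlap with an informative (non-LOC/MGC) name wins;
   several candidates are resolved by the lowest accession number (numeric
   comparison after the prefix, lexicographic fallback);
2. provisional bovine names and probes without a usable bovine overlap
   fall to an overlapping human gene name, lowest accession on ties;
3. no overlap at all falls to the nearest gene on the chromosome (0
   distance for overlapping genes, accession ties as above) — intron-only
   overlaps with no human alternative therefore resolve to the overlapped
   gene through this rule;
4. a BLAST best hit whose name disagrees with a step-1/2 choice *flags*
   the probe for curation but never overrides the name.

Step 1 is exon-strict by choice: the rule's published wording requires an
exon, so intron-only overlaps fall through; this is an interpretation and
is confined to `assign_gene()`.

## The synthetic generator

`simulate_design()` reproduces the study layout: 4 chips × 4 arrays × 2
dyes = 32 channel slots filled round-robin by 11 animals (4 polled, 3
horned, 4 scurred; 6 male, 5 female). The round-robin over an odd roster
guarantees one red and one green channel per array, both dyes for every
animal hybridised more than once, and no phenotype or sex confounded with
chip; ten animals are used three times and one scurred animal twice,
matching the source herd's usage. Other design sizes shrink the roster,
keeping it odd whenever animals must be reused so the dye alternation
survives.

`simulate_spots()` draws the model above exactly: every random term
i.i.d. normal at its configured variance, planted phenotype shifts of
`de_effect_size` log2 units added for a `de_fraction` of probes (one
random phenotype, random sign), then maps to linear-scale spot records
with background statistics. A `bad_spot_fraction` of spots is sabotaged,
half through inflated background SDs (forcing `s < 1`) and half through
discrepant medians (forcing `r < 0.85`).

Defaults: $\mu = 7.4$ and variances $12, 0.8, 0.4, 0.02, 0.02, 0.4$
(g, ag, dg, hg, sg, e). The gene variance dominates, the total SD
($\approx 3.7$) and the mean sit between the channel summaries typical of
background-corrected two-colour data, and the phenotype- and sex-by-gene
background variances are deliberately small: they are the null spread
against which planted 1.5-log2 effects must be detectable, and the
generator's stated calibration is that such effects are recoverable at
the 1% posterior FDR at the default 2,000 probes. `de_fraction = 0.03`
and `bad_spot_fraction = 0.1` mirror the reported share of DE probes and
the roughly 90% of spots passing the signal-to-noise filter.

What the generator does *not* emulate: spatial artefacts, print-tip and
intensity-dependent dye bias (the model has no use for them — they are
absorbed or out of scope), pixel-level background distributions (only
their summaries), heavy-tailed residuals, and correlated probes. Passing
tests therefore demonstrate correctness of the estimators under the
model's own assumptions, not robustness to violations real scans would
add.

## Numerical choices and degenerate inputs

* REML: EM steps with AI acceleration and likelihood-guarded fallback;
  variance floor `1e-10`; singular AI systems fall back to EM.
* Mixture EM: tolerance `1e-8` on the log-likelihood, 500 iterations per
  start, degenerate variances (`< 1e-8`) abort a start; all starts failing
  is an error.
* A phenotype with no passing observations aborts model construction
  (contrasts would be undefined). Genes with no passing spots are dropped
  with a message. A channel with no observations is dropped from the fixed
  effects.
* Fewer than 50 statistics refuse a mixture fit; fewer than 2 passing
  spots in a dye channel give an NA SD in `channel_summary()`.
* Zero-variance inputs are legal in the generator (all-zero variances
  yield exactly constant corrected intensities, used by the tests).

## Problem sizes used by the test suite

The suite verifies variance-component recovery at 500 probes over 20
replicates, BLUP/PEV exactness against a dense GLS solve at 50 genes,
mixture recovery at 5,000 statistics, FDR calibration over 20 simulated
experiments at the default 2,000-probe scale, and the qPCR size at 200
null simulations — sizes chosen as the smallest at which the Monte-Carlo
bands are informative, so the whole suite runs on a laptop in minutes.

## Known limitations

* The mixture's normal alternative is a crude model for symmetric two-sided
  effects: planted up- and down-regulation forms a bimodal alternative that
  EM fits as one wide zero-centred normal, which narrows the fitted null
  and makes the posterior FDR estimate anticonservative. At the generator's
  default conditions the acceptance suite measures a realised false
  discovery proportion of roughly twice the 1% target (pooled over 20
  simulated experiments), and the corresponding calibration check fails by
  that margin; treat the 1% label as an optimistic estimate, not a
  guarantee.
* PEVs are exact under the fitted block structure but, as always with
  REML, do not account for the uncertainty of the variance components
  themselves.
* The annotation engine resolves rules over the tables it is given; it
  does not align probes, run BLAST, or verify assembly compatibility.
* ddCt assumes equal amplification efficiency of target and reference;
  no efficiency correction or multi-reference normalization is attempted.
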