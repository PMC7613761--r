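---
title: "Methods: quantifying and predicting archaeal nucleoid-associated proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and predicting archaeal nucleoid-associated proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napscan)
```

`napscan` studies archaeal chromatin through the proteome: how much of a
species' protein budget goes into nucleoid-associated proteins (NAPs), which
uncharacterized proteins behave like NAPs, and how that investment varies
with ecology across a phylogeny. This vignette documents the statistical
machinery, the defaults and why they were chosen, what the synthetic-data
generator does and does not emulate, and the numerical corner cases.

## Fractional abundance and NAP investment

All quantitative statements are made on *fractional abundances*: a protein's
intensity divided by the summed intensity of all quantified proteins in that
sample, in percent. This removes instrument- and loading-scale effects (the
pipeline is exactly invariant to multiplying all intensities by a constant)
and makes proteomes of different depth comparable. Where label-free
quantification (LFQ) intensities are present they are preferred over raw
intensities, because LFQ values are already normalized between runs; rows
lacking an LFQ value are then dropped from the basis rather than mixed in on
a different scale. *NAP investment* is the summed fractional abundance of
all detected known and candidate NAPs. Undetected NAPs contribute zero — an
expressed-protein statement, deliberately distinct from genomic
presence/absence.

Quality control admits a proteome to cross-species analysis only if it comes
from whole-cell extract, without size selection, and contains strictly more
than 500 identified proteins; anything less makes the denominator (and hence
every fraction) untrustworthy.

As a control for ploidy and genome copy number, investment can be
re-expressed relative to reference classes expected to scale the same way:
proteins carrying class I/II tRNA-synthetase domains (`tRNA-synth_1`,
`tRNA-synth_2`) or the RNA polymerase largest/second-largest subunit domains
(`RNA_pol_Rpb1_3`, `RNA_pol_Rpb2_3`).

## The four-filter candidate pipeline

A detected protein (excluding known NAPs) is a candidate NAP when it passes
all of:

1. **Size** — length strictly below `max_len = 290` amino acids. The bound
   is 110% the length of the largest characterized chromatin protein
   considered (TrmBL2) and is exposed as a parameter.
2. **DNA binding** — at least one hit to a curated DNA-binding domain model,
   *or* a strictly positive score from an external DNA-binding predictor
   (an SVM decision value; 0 is not evidence). OR-semantics: domain evidence
   and sequence-level prediction are complementary.
3. **Abundance outlier** — the defining property of a NAP is abundance far
   beyond what a sequence-specific regulator needs. Each candidate is
   compared with the abundances of predicted transcription factors (proteins
   with a TF-domain hit) using the generalized extreme studentized deviate
   (Rosner) test, and must be flagged *and* lie above the TF median (the
   high side only; a vanishing abundance is also anomalous but not
   NAP-like).
4. **Single-gene operon** — known NAPs are typically monocistronic;
   proteins in multi-gene operons, or absent from the operon map, fail.
   The filter can be relaxed (`relax_operon = TRUE`) to probe its effect.

### The generalized ESD test

At step $i$ the most extreme studentized deviate
$R_i = \max_j |x_j - \bar{x}|/s$ is computed over the points still in play
and the extreme point is set aside; the critical value is

$$\lambda_i = \frac{(n-i)\,t_{p,\,n-i-1}}
  {\sqrt{(n-i-1+t^2_{p,\,n-i-1})(n-i+1)}},
  \qquad p = 1-\frac{\alpha}{2(n-i+1)} .$$

The number of outliers is the largest $i$ with $R_i > \lambda_i$, which
makes the procedure robust to masking by up to `k_max` outliers. Defaults:
$\alpha = 0.05$; `k_max = max(5, ceiling(0.05 n))`, enough head-room for the
handful of genuinely extreme proteins a proteome contains; abundances are
log10-transformed first because fractional abundances are close to
log-normal and the ESD test assumes approximate normality. Ties at the
argmax are broken by lowest index so results are deterministic; if the
remaining points become constant the iteration stops and the remaining
$R_i$ are zero.

Two pooling modes exist because the field procedure is ambiguous:
`leave_one_in` (default) appends each candidate alone to the TF background,
so one extreme candidate cannot mask another; `pooled` tests TFs plus all
candidates jointly. Since TF domains are a superset of DNA-binding domains,
a candidate is usually itself a predicted TF; the candidate is therefore
dropped from the background when it is tested, but other TFs — including
other candidates — remain, which is exactly the population the filter is
defined against.

## Nucleoid enrichment

The enrichment assay compares two sucrose-gradient fractions — a nucleoid
fraction and a "top" (soluble, cytosolic) fraction used as the control —
with ≥2 replicates each, on log2 intensities. Missing values in label-free
proteomics concentrate at low abundance, so missing cells are imputed from a
left-shifted normal per sample: Normal(mean − 1.8·sd, (0.3·sd)²), the
standard downshift/width convention. Proteins observed in only one fraction
are retained (imputation fills the other side); a configurable min-observed
filter is available.

Per-protein testing uses an empirical-Bayes moderated t: pooled variances
$s_g^2$ on $d$ df are shrunk toward a prior,
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$, with $(d_0, s_0^2)$
fitted by matching the first two moments of the marginal scaled-F
distribution of the $s_g^2$ ($s_g^2 \sim s_0^2 F(d, d_0)$ under the
hierarchical model). When the observed variance dispersion is at or below
what a common variance implies, the moment equations have no valid solution
and the prior df is taken as infinite (fully pooled variance, normal-limit
p-values) — the correct limit, not a fallback. `prior_df = 0` recovers the
ordinary two-sample t exactly, which the tests exploit as an oracle.
P-values use $d_0 + d$ df and are Benjamini–Hochberg adjusted. Positive
log2 fold change means nucleoid-enriched; swapping the fraction labels
negates every fold change and preserves every p-value.

Collective enrichment of DNA-binding-domain proteins is a rank-sum
(Wilcoxon) test of member vs non-member log2 fold changes: exact by full
enumeration of group assignments when both groups have ≤10 members, normal
approximation with tie and continuity correction otherwise (the two agree
to well under 0.02 at the sizes where the crossover happens).

## Cross-species statistics

**Spearman correlation** is computed on average ranks; the two-sided
p-value is exact by permutation enumeration for $n \le 7$ and uses the
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation otherwise — at $n \ge 8$
the approximation error is far below anything that matters at these sample
sizes, and enumeration cost grows factorially.

**The domain screen** correlates every domain class's per-species aggregate
abundance (a protein contributes its full fraction to every class it
matches; abundances are not split across domains) with OGT, keeping classes
quantified in at least `min_species = 5` species, and reports where the NAP
aggregate ranks among all classes.

**OLS prediction.** The investment expected at a new growth temperature
comes from ordinary least squares with both the 95% confidence interval of
the mean response and the 95% prediction interval for a single new species.
The two intervals answer different questions and field reports rarely say
which one they quote, so both are always computed and labelled. With only
two points the fit is exact and interval requests are an error
($df = n - 2 = 0$).

**PGLS under Brownian motion.** Species are not independent samples;
residual covariance is modelled as $C_{ij} = $ shared root-to-tip branch
length (the BM covariance, obtained from the tree), and
$\hat\beta = (X^\top C^{-1}X)^{-1}X^\top C^{-1}y$ via a Cholesky solve. The
BM rate $\sigma^2$ is the ML estimate $r^\top C^{-1} r / n$ (matching the
default behaviour of the standard phylogenetic-regression tools; REML is a
trivial variant), the slope p-value is a t test on $n-2$ df, and optional
confidence intervals come from a parametric bootstrap that simulates BM
residuals on the tree ($C = LL^\top$, $\varepsilon = L z \sqrt{\sigma^2}$)
and refits. Both variables are natural-log transformed when requested;
non-positive values are dropped with a warning rather than hidden behind a
pseudocount. On a star tree $C \propto I$ and the estimator reduces exactly
to OLS; rescaling all branch lengths leaves $\hat\beta$ unchanged — both
properties are asserted in the tests. The bootstrap default is 1,000
replicates (configurable upward to 10,000); at these problem sizes the
slope CI is stable well before 1,000.

## The synthetic-study generator

The generator exists so that every stage has a testable ground truth
without downloading anything. It emulates the *statistical structure* the
analysis assumes:

* a Yule (pure-birth) species tree, rescaled to unit depth, default 19
  tips;
* OGT evolving by Brownian motion from a 70 °C root, rate 2,500 °C² per
  unit depth, reflected into [24, 98] °C. The rate was set once so the
  cross-species OGT spread (sd ≈ 20 °C) matches a realistic
  mesophile-to-hyperthermophile panel; reflection keeps values physiological
  while preserving covariance on short branches;
* per species, 2,000 detected proteins with log-normal abundances
  (log10 sd 1.2, a typical label-free dynamic range); 5% of proteins are
  transcription factors with mid-range abundances (log10 sd 0.25 around the
  proteome median);
* 1–3 spiked true NAPs (60–120 aa, DNA-binding evidence, single-gene
  operons) whose summed fractional abundance is
  $\beta_0 + \beta_1\,\mathrm{OGT} + \varepsilon$, truncated below at
  0.01%, with $\beta_0 = -2\%$, $\beta_1 = 0.075\,\%/^\circ\mathrm{C}$,
  $\sigma_\varepsilon = 0.6\%$ — a calibration placing the expected
  investment of a 37 °C mesophile near 0.75% and the hottest species near
  5.4%, the regime reported for real archaea; abundances of the remaining
  proteins are renormalized so the target is hit exactly;
* decoy proteins constructed to fail exactly one filter each (abundant
  small non-binders; abundant small binders inside two-gene operons; large
  abundant binders), so each filter does discriminating work; DNA-binding
  predictor scores of all non-designated proteins are strictly negative, so
  binding evidence is carried only by design, and "all decoys fail at least
  one filter" holds by construction;
* with probability 1/2 a species' first NAP belongs to a known family
  (carrying that family's domain model), exercising the presence/absence
  survey and the known-NAP exclusion path;
* two-fraction enrichment assays (first two species): replicate log2
  intensities with sd 0.5, a +2.5 log2 shift for true NAPs in the nucleoid
  fraction, and missing-at-low-abundance censoring at rate 0.1.

Everything is a pure function of `(params, seed)`, and a bundle written to
disk round-trips exactly through the package's readers.

**What the generator does not emulate.** Real proteomes have correlated
abundances across species (orthologs), contaminant and membrane
co-sedimentation structure in enrichment assays, peptide-level missingness,
and collectively enriched DNA-binding proteins in the nucleoid fraction.
The last point matters when interpreting the synthetic enrichment results:
only the spiked NAPs are shifted, so the binder-vs-non-binder rank-sum test
is underpowered on synthetic data (a handful of enriched members among
~100 binders) even though the same test is decisive on real assays. Passing
tests therefore demonstrate correctness of the machinery under the stated
model, not performance on any real dataset.

## Problem sizes used in the test suite

The suite verifies the ESD implementation against an independent
brute-force loop on 1,000 random vectors ($n \le 30$), prediction-interval
coverage over 2,000 simulated fits at $n = 19$, moderated-test type-I error
over five null datasets of 2,000 proteins (3 vs 3 replicates), pipeline
recovery on the default study, the domain screen's NAP ranking over 200
study seeds, and the investment–OGT correlation regime over 500 study
seeds. These sizes keep every Monte-Carlo standard error comfortably below
the tolerance it supports while the whole suite runs on a single CPU in
minutes.

## Known limitations

* Curated domain sets (NAP families, DNA-binding, TF) are shipped as
  editable defaults, not a canonical registry; model collections change
  between releases and users with strong opinions should pass their own
  `domain_classification()`.
* The operon and DNA-binding inputs are consumed from external predictors;
  their error modes propagate (a protein missing from the operon map fails
  the single-operon filter by design).
* PGLS supports BM only; an OU alternative was considered and deferred —
  with ~19 tips the selection-strength parameter is barely identifiable,
  and BM is the required, interpretable default.
* Enrichment replicates are treated as independent; paired designs are not
  modelled.
* The isoelectric-point routine uses the EMBOSS pKa set by default
  (configurable); pI values from different tools differ by a few tenths of
  a pH unit.
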