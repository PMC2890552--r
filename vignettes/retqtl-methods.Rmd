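---
title: "From dye-swap arrays to QTL candidate genes: methods and design notes"
author: "retqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dye-swap arrays to QTL candidate genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retqtl)
```

## The problem

Two albino mouse strains — BALB/cByJ ("C") and B6(Cg)-Tyr(c-2J)/J ("B6a") —
differ markedly in how fast their photoreceptors die with age.  Crosses
between them localize much of that difference to quantitative trait loci
(QTL) on chromosome 6 (77.5–93.0 Mb) and chromosome 10 (15.4–20.8 Mb).
`retqtl` implements the computational path from raw two-colour competitive
microarray hybridizations of the two strains (posterior eyecups at 4 and 8
months) to a ranked list of candidate genes in those intervals, together
with the statistics used to validate candidates: qPCR relative expression
and outer-nuclear-layer (ONL) thickness association with genotype.

The pipeline has five analysis stages, each an exported module:

1. **normalize** — per-chip lowess intensity correction, cross-chip SD
   rescaling, dye-swap dye-effect estimation and removal, missing-value
   filtering;
2. **diffexpr** — four strain/age contrasts with SAM-style permutation FDR;
3. **go_enrich** — MAPPFinder-style Gene Ontology overrepresentation;
4. **candidates** — interval mapping, the strain-haplotype SNP filter, and
   the 0/1/2 evidence score;
5. **qpcr / phenotype** — comparative-Ct fold changes and ONL genotype
   association, both using one-way ANOVA with Holm–Šidák pairwise
   comparisons.

A sixth module, **synthetic_data**, generates seeded inputs for every stage
with ground-truth labels, so each stage has a recovery test that needs no
external downloads.

## Normalization model

A chip hybridizes Cy3- and Cy5-labelled cDNA from the two strains.  Per
spot we form `M = log2(ch2/ch1)` (Cy5/Cy3) and `A = log2(sqrt(ch1*ch2))`.
Spots that are flagged or have a non-positive channel give missing M —
missingness is propagated, never imputed, because the downstream
missing-value filter presumes it exists.

Three nuisance components sit between M and the strain effect of interest:

* **Intensity-dependent dye bias.**  Removed per chip by subtracting a
  lowess fit of M on A with span `f = 0.33` — Cleveland's tricube-weighted
  local linear regression with three robustifying iterations, evaluated at
  the observed A.  `stats::lowess` implements exactly this smoother and is
  used behind `lowess_correct()`.  The correction can be skipped
  (`span = NULL`) for inputs known to carry no intensity trend, such as
  idealized simulations; on real chips it should always run.
* **Per-chip scale.**  Chips differ in overall log-ratio spread; each chip
  is linearly rescaled so its SD (over non-missing values, denominator
  n−1) equals the median per-chip SD before scaling.
* **Gene-specific dye preference.**  Some sequences incorporate Cy5 more
  efficiently regardless of which strain carries the dye.  In a balanced
  dye swap the strain effect flips sign with orientation while this dye
  effect does not, so per gene
  `D = (mean over C-on-Cy5 chips + mean over B6a-on-Cy5 chips) / 2`.
  Orientation-1 chips are corrected as `v − D`, dye-swapped chips as
  `−v + D`, after which every chip estimates `log2(C/B6a)`.

Probe-level values are collapsed to genes by the per-chip median (robust
to one bad cDNA clone); the collapse point — after dye correction, before
the missing filter — is a design choice: the dye effect is a property of
the probe sequence, so it is estimated per probe.  Finally, genes missing
half or more of the chips in either orientation are dropped ("four or more
of eight" in the canonical 16-chip design; `ceiling(n/2)` for other
balanced designs — the generalization reproduces the canonical rule
exactly at n = 8).

## Differential expression and FDR

Four contrasts are computed on the corrected matrix: the C/B6a difference
over all chips, over the 4-month chips, over the 8-month chips (one-group
t against zero, `t = mean/(sd/sqrt(n))`), and the age dependency of the
strain difference (Welch two-sample t of 4 m vs 8 m values; Welch because
equal variances across ages is not something the design guarantees).
The t statistic is the plain one — no variance-shrinkage constant is
added, matching the stated one-group t; `permutation_fdr()` accepts the
statistics as given, so a moderated variant could be substituted upstream.

FDR is estimated SAM-style.  Null statistics come from chip-level
permutations that preserve the gene–gene correlation structure: random
sign flips of whole chips for the one-group contrasts (under the null of
no strain difference, the dye-swap-corrected chip sign is exchangeable) and
age-label shuffles for the age contrast.  For a threshold c,
`q(c) = median over permutations of #null{|t| >= c} / #observed{|t| >= c}`;
each gene receives q at its own |t|, monotonized so q never increases with
|t| (BH-style running minimum from the least significant end), and capped
at 1.  A gene is then called **regulated** when `FC >= 1.2 or FC <= 0.8`
(inclusive, so a printed fold of exactly 0.8 counts) **and** `q < 0.05`.
The conjunction reading — fold filter AND FDR gate — is deliberate: the
alternative parse would let a 1.2-fold change with no statistical support
count as differential expression.

## GO overrepresentation

For a term with `n` measured annotated genes of which `r` changed, against
`N` measured annotated genes with `R` changed overall, the Z score is the
standardized hypergeometric statistic

$$ z = \frac{r - nR/N}{\sqrt{n \frac{R}{N}\left(1 - \frac{R}{N}\right)\left(1 - \frac{n-1}{N-1}\right)}} $$

(the MAPPFinder statistic; the test suite verifies it against exact
hypergeometric moments by enumeration for every N ≤ 30).  The permutation
p shuffles the changed/unchanged labels over measured genes and reports
`(1 + #{null z >= z_obs}) / (1 + n_perm)`, so p is never exactly 0 — a
printed "0" in a ranked table is read as "below resolution".  The ranked
list keeps terms with `p < 0.01`, `z >= 2`, percent changed strictly
above 10, and at least 2 changed genes, sorted by p then z.  Up- and
down-regulated lists per age are scored in separate runs (four blocks).
Annotation rollup to ancestor terms (`rollup_annotations()`) is optional
and off by default, since whether the original analysis rolled up the full
DAG or used a slim is not recoverable; the enrichment machinery is
agnostic to where the gene sets came from, so pathway collections can be
scored identically.

## Candidate scoring

Genes in a QTL interval (closed Mb intervals, any overlap counts — the
boundary gene convention matches "encompassing" counts) are filtered by
the strain haplotype rule: at least one SNP with `B6 != C` **and**
`A != C`.  The logic is that the A-vs-B6 cross showed no QTL here, so an
allele driving the phenotype should separate C from both A and B6.  An
unknown A allele cannot establish a pass.  Surviving genes get

`score = I[in the keyword-evidence (PosMed) list] + I[regulated at either age]`

Either age suffices for the regulation criterion (the published tables
score genes regulated at only one age as 2 when also in the evidence
list).  Genes not present on the array carry false regulation flags; `NP`
is a sentinel distinct from a fold of 1.  The two transcribed candidate
tables shipped in `inst/extdata/` carry a `de_listed` column marking genes
the original differential-expression analysis flagged in a contrast whose
fold is not printed per age; the one gene whose printed per-age folds do
not pass the fold rule but which is nonetheless scored as regulated
(Gkn1, printed folds 1 and 0.9) is covered by that column.

## qPCR and phenotype statistics

Relative expression uses the comparative-Ct equation `y = (1+AE)^ΔΔCt`
with AE = 1 (a perfect doubling per cycle) and β-actin as reference.
Technical triplicate wells are averaged to one Ct per biological
replicate; `ΔCt = Ct_target − Ct_reference`; the fold for a group is
`(1+AE)^(ΔCt_calibrator − ΔCt_group)` with B6a at 4 months as calibrator.
The exponent is oriented so that a more abundant target gives fold > 1;
the equation's prose definition, read literally, would invert this, and
the implementation follows the direction in which the study's fold values
are reported.

Group comparisons use one-way ANOVA followed by Holm–Šidák pairwise
comparisons: order the m raw pairwise p values ascending and adjust
`p_(k) → max_{j≤k} (1 − (1 − p_(j))^(m−j+1))`, clipped at 1.  This
stepdown is not in `stats::p.adjust` (which offers Holm–Bonferroni) and is
implemented directly; raw pairwise p values come from pooled-SD t tests.
ANOVA is run on the ΔCt scale, where normality is more plausible than on
folds; `anova_holm_sidak()` takes plain values, so callers can switch
scales.

ONL thickness follows the published sampling scheme: 9 sets × 3 positions
per hemisphere, 54 slots per section; slots lost to tears are masked.
The per-animal mean is the unit of analysis — the 54 raw points within a
section are spatially correlated, so treating them as independent would
overstate precision.  For three genotype groups the additivity gap
`mean(HET) − (mean(hom1) + mean(hom2))/2` is reported; near zero it
supports an additive allele effect.

## What the generators emulate — and what they do not

`gen_two_color_experiment()` plants, per spot,
`M = scale_j (±s_g + d_g + ε) + 0.4 sin((A−6)/2.5)`, with gene abundances
A uniform on [6, 14] log2 units, per-chip scales in [0.9, 1.1], spot noise
σ = 0.2, gene dye preference SD 0.3, and 5% missingness — magnitudes
typical of spotted cDNA arrays.  The sine curve exercises the nonlinear
lowess; the gene-specific `d_g` exercises the dye-swap correction (the two
are distinct on purpose: lowess can only remove dye bias that is a
function of intensity).  Defaults follow the study design: 4 chips per
orientation × age cell, 16 chips.  Not emulated: spatial print-tip
effects, background structure, saturation, and correlated missingness —
so passing recovery tests demonstrates correctness of the estimators
under the stated model, not robustness to every artifact of real scans.
The qPCR generator plants folds via `ΔCt = ΔCt_cal − log2(fold)/log2(1+AE)`
with biological ΔCt SD 0.2 cycles over 3 replicate pools, mirroring the
triplicate-pool design; the ONL generator draws animal means per genotype
(defaults 44/40/36 µm, between-animal SD 2 µm) with within-section slot
noise.

## Numerical choices and degenerate inputs

* Zero or flagged intensities → missing, never imputed; a chip with zero
  log-ratio SD, a gene with zero spread (t undefined), or all-degenerate
  ANOVA groups raise errors or flagged exclusions rather than silent
  answers.
* `lowess_correct` requires ≥ 10 non-missing pairs and a span window of
  ≥ 2 points; fits are interpolated back to observed A with constant
  extrapolation at the range ends.
* Zero-variance enrichment nulls (R = 0, R = N, n = N) define z = 0 with a
  warning; permutation p is bounded below by `1/(1+n_perm)`.
* FDR q ties share the observed count at the tied |t|; q is capped at 1.
* Rescaling enforces equal chip SDs to within 1e-12; the orientation-flip
  identity is exact in floating point up to 1e-10 under chip reordering.

## Problem sizes in the test suite

The recovery suites run at 500 genes × 16 chips with 1000 permutations
(FDR calibration over 10 seeds; GO filter recovery and qPCR fold recovery
over 100 seeds) — large enough for the stochastic bounds being asserted
to be stable, small enough to iterate on quickly.  The end-to-end
dye-swap criterion (planted-D correlation above 0.9, strain-effect bias
below 0.02 log2 units) runs on one seeded 500-gene experiment at the
canonical design.

## Known limitations

* The exact SAM variant of the original analysis (one-class vs paired,
  fudge-factor rule) is not recoverable from its description; the plain
  one-group t with s0 = 0 is the default and documented as such.
* Whether probe collapse happened before or after the missing-value rule
  in the original pipeline is ambiguous at the probe/gene level; here the
  filter runs at gene level after the median collapse.
* Interval membership and haplotype filtering depend on the SNP and locus
  tables supplied; database-version-dependent counts are out of scope.
* The enrichment rollup implements is_a/part_of only.
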