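---
title: "Methods: from DNA-repair variants to immunophenotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from DNA-repair variants to immunophenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repairimmune)
```

`repairimmune` chains five analysis stages — repair-pathway status, tumor
mutation burden (TMB), neoantigen calling, immune-infiltration calling and
immunophenotype scoring — on top of a shared statistics layer. This
vignette documents the model behind each stage, the parameters that
matter, the numerical conventions, and what the synthetic-data validation
does and does not establish.

## Deleterious-variant classification

A somatic variant counts as deleterious when it is a nonsense mutation, a
frameshift or in-frame indel, a splicing error, or a missense change with
SIFT < 0.05 or CADD (phred-scaled) > 20. Both inequalities are strict:
a SIFT of exactly 0.05 or a CADD of exactly 20 does not qualify. A
splicing error means a variant within 2 bp on the intronic side of an
intron/exon junction; when the MAF carries no intron-offset annotation the
splice classification of the file is trusted. Three conventions were
genuinely open and are resolved as follows:

* A missense variant with neither score available is **not** deleterious.
  Annotation pipelines normally supply at least one score, so a missing
  score signals an annotation gap rather than benignity, but calling such
  variants deleterious would make the carrier flag sensitive to missing
  data; the conservative choice keeps the filter deterministic in what it
  can see.
* "Indels" is read as covering both frameshift and in-frame indels.
* Multiple deleterious variants in one gene increment the affected-gene
  count once: the count is over distinct genes, which is the natural unit
  for a gene-level dose–response display.

The gene panels are fixed: 15 homologous-recombination genes (ATR, ATM,
CHEK1, CHEK2, BRCA1, BRCA2, BAP1, BARD1, FANCD2, FANCE, FANCC, FANCA,
RAD50, RAD51, PALB2), 18 mismatch-repair genes (MLH1, MLH3, MSH2, MSH3,
MSH4, MSH5, MSH6, PMS1, PMS2, PMS2L3, PCNA, EXO1, POLD1, RFC1–RFC5) and
POLE. Gene symbols are uppercased at ingest and no alias remapping is
attempted — inputs are expected to use HGNC names.

## Mutation burden and the median split

`mutation_burden()` exposes two counting modes: `"all"` (every MAF row;
the default, since a display of overall mutation load is the common
convention) and `"nonsynonymous"` (excluding silent and unclassified
rows), which is the subset relevant to neoantigen formation. The cohort
median split labels a sample "high" only when its count is strictly above
the median; ties at the median go to "low". The tie rule is arbitrary but
must be fixed for the group sizes to be reproducible; it is configurable
at the call site by pre-shifting values if the other convention is wanted.

## Neoantigen calling

For each annotated missense variant the package enumerates every 9-mer
window of the protein that covers the mutated residue, clipped at the
protein ends: window starts run from `max(1, pos - 8)` to
`min(pos, L - 8)`, giving `min(pos, L - 8) - max(1, pos - 8) + 1` windows.
Each wild-type/mutant pair differs at exactly one residue. A mutant
peptide is a neoantigen for an allele when three conditions hold
simultaneously:

* mutant IC50 < 500 nM (strong binder),
* wild-type IC50 > 500 nM **on the same allele** (the parental peptide
  binds weakly, so the epitope is tumor-specific),
* the variant's gene has positive expression in that sample.

An IC50 of exactly 500 nM fails both inequalities. The per-allele pairing
of mutant and wild-type affinities is a design choice: comparing a mutant
on its best allele against the wild-type on a different allele would
overstate specificity. The default burden unit counts distinct mutant
peptides passing on at least one allele (`"peptide"`); counting
(peptide, allele) pairs is available as `"peptide_allele"`. Both are
defensible; the peptide unit avoids rewarding promiscuous binders, and
the choice is exposed rather than asserted.

MHC affinity prediction itself is out of scope: affinities arrive as a
(peptide, allele) → IC50 table, or as any function with that signature. A
missing entry is an error, never silently imputed. `toy_predictor()` is a
deterministic position-weight hash provided so that tests and synthetic
cohorts have a reproducible affinity surface spanning both sides of
500 nM; it has no biochemical content. Frameshift-derived neo-open reading
frames are a documented limitation: only single-residue substitutions
generate peptides here.

## Infiltration calling

Each sample is reduced to a ranking of all genes by its cohort z-score
(per gene, across samples, sample SD with n−1; zero-variance genes get
z = 0 and a flag so downstream medians stay defined). For a metagene set
of size k over N ranked genes the enrichment score is the signed maximum
deviation of a running sum that gains `|z|^α / Σ_hits |z|^α` at set genes
and loses `1/(N − k)` elsewhere — the weighted Kolmogorov–Smirnov
convention, with α = 1 by default (α = 0 gives a rank-only statistic).
The implementation is cross-checked in the test suite against an
independent GSEA implementation (`fgsea::calcGseaStat`).

Because the statistic is single-sample, a sample-label permutation null
does not exist; the null is instead random gene sets of the same size
drawn from the same ranking, with `p = (1 + #{ES_null ≥ ES_obs}) / (B + 1)`
(one-sided: only positive enrichment can make an infiltration call).
B defaults to 1000; B = 200–500 is adequate for the q ≤ 0.10 decision at
a compendium of ~24 cell types and is what the heavier simulations use.
Null draws are shared across equal-sized sets within a sample, and the
full call table is bit-reproducible under a fixed seed.

q-values are computed per sample across cell types (the decision
"which cell types infiltrate this tumor" is per-sample); pooling all
sample × cell-type tests globally is available via `q_batch = "global"`.
With two dozen cell types per batch the single-λ π̂₀ estimate is stable;
with very few tests per batch it becomes noisy, which is one reason the
default compendium has 24 cell types.

Co-infiltration is summarised by the Pearson correlation of the binary
infiltration indicators (the phi coefficient) with pairwise p-values;
constant indicators yield missing entries rather than errors.

## Immunophenotype and the combined score

The 2×2 grouping crosses the repair-variant flag with activated T-cell
infiltration: I = neither, II = variant only, III = infiltration only,
IV = both. "Activated T-cell infiltrated" defaults to activated CD4 OR
activated CD8 called (`"either"`); `"both"`, `"cd4"` and `"cd8"` are
available since group definitions in the field sometimes use the joint
rule and displays often separate the subtypes.

The combined score confers one point each for a TGFB1 z-score strictly
above the cohort median of TGFB1 z-scores, a WNT2 z-score strictly above
its cohort median, and the absence of any deleterious repair variant.
Medians are taken over the whole cohort, not within groups, and an
exactly-median z contributes nothing. Scores of 0–1 are "low"; low scores
are the predictor of activated T-cell infiltration. The score is antitone
in carrier status and monotone in each expression indicator by
construction.

## Statistics layer

* **Two-proportion z**: pooled-variance standard error, no continuity
  correction, two-sided normal p. A pooled proportion of 0 or 1 leaves
  the statistic undefined (reported missing). The confidence interval for
  the difference uses the unpooled standard error, as is conventional.
* **t-tests**: Student (pooled) or Welch (Satterthwaite df), two-sided.
* **ANOVA + Tukey**: one-way fixed effects; pairwise p-values from the
  studentized range with k groups and N − k error df. With k = 2 the
  Tukey p equals the ANOVA p, which equals the squared-t identity — both
  are asserted in the tests.
* **Storey q-values**: π̂₀ = min(1, #{p > λ} / ((1 − λ) m)) with λ = 0.5
  (the single-λ estimator rather than the spline smoother; simpler,
  deterministic, and exact enough at the m used here), then the running
  minimum of π̂₀ · m · p₍ᵢ₎ / i from the largest p downward. When π̂₀ = 1
  this is exactly Benjamini–Hochberg, an identity the tests assert. λ is
  configurable.
* **Multinomial logistic regression**: maximum likelihood via `nnet`,
  standard errors from the inverse observed information, two-sided Wald
  p-values (matching the coefficient/SE/p presentation customary for such
  tables). Numeric predictors are standardized by default so
  coefficients are comparable across genes. Perfect collinearity is
  detected before fitting; non-convergence and likely separation
  (|β| > 15 or a singular information matrix) are flagged on the returned
  object, never silently passed through.
* **Survival**: Kaplan–Meier product-limit curves, the standard log-rank
  test, and the hazard ratio from a univariate Cox fit with Breslow tie
  handling, CI = exp(β̂ ± 1.96·SE). When an arm has no events the HR is
  reported missing while the log-rank test is still computed. The Cox
  estimate is checked against a brute-force grid maximization of the
  Breslow partial likelihood on a small fixture.

## The synthetic cohort generator

`simulate_cohort()` emits a MAF, an expression matrix, metagene sets, a
clinical table, protein sequences and an affinity surface with planted,
recoverable structure. Defaults describe the cohort the package is
designed around: 178 samples; a 30% carrier fraction; negative-binomial
mutation counts (mean 200, dispersion 4) with a 2.5-fold carrier
increase, which puts the cohort median near 230 mutations; carriers
receive one planted deleterious variant in a random HR/MMR/POLE gene plus
a Poisson(0.4) number of additional affected genes; background missense
variants carry SIFT/CADD values on both sides of the cutoffs, and any
background variant landing in a repair gene is forced benign so the
planted carrier flag is the exact truth. The expression matrix is
log-normal (within-gene log-SD 0.5); 30% of samples are "infiltrated" and
have a seven-cell-type co-infiltrating block (activated CD4/CD8, effector
memory CD4, Th2, memory B, myeloid DC, MDSC) shifted up 2 within-gene SDs
on the log scale, while non-infiltrated samples have TGFB1 and WNT2
shifted up 1.5 SDs — so a low combined score and infiltration co-occur
with a large planted odds ratio without being hard-wired to each other.
About 4% of each sample's mutations (capped at 25) are emitted as fully
annotated missense variants in a 30-protein pool so neoantigen burden
scales with TMB; a planted fraction (default 20%) of those candidates is
given a strong mutant / weak wild-type binding pair on one allele.
Survival is exponential with per-group hazard ratios (all 1 by default)
and ~30% censoring. Everything is a pure function of the parameter object
including its mandatory seed.

What passing recovery tests shows — and what it does not: the generator
reproduces the *statistical skeleton* of a tumor cohort (overdispersed
burden, block-correlated immune expression, marker shifts, exponential
survival), so recovery demonstrates that the pipeline's inference is
correct when its assumptions hold. Real tumors add mutational signatures,
correlated expression programs beyond the planted blocks, subclonality,
purity variation and annotation noise, none of which are emulated;
performance numbers from synthetic cohorts therefore do not transfer to
real data as accuracies, only as evidence of implementation correctness.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate at these scales, chosen
to give stable Monte-Carlo estimates: brute-force filter re-scans on
1000-variant tables and 1000 peptide pairs × 6 alleles; 200 random
(protein length, position) windowing cases; 200 no-signal cohorts
(4 samples × 200 genes, 24 sets, B = 200) for the null infiltration rate;
100 cohorts of n = 200 each for the TMB fold-change and combined-score
detection rates (B = 250, 600 genes, set size 15 for the infiltration
stage); 1000 null replicates per test for type-I calibration; 100 runs of
n = 500 per arm for hazard-ratio recovery.

## Known limitations

* Binary infiltration calls only; no fractional deconvolution.
* Only missense-derived 9-mers; no frameshift neo-ORFs, no
  proteasomal-processing or TAP-transport modelling.
* HLA typing and MHC affinity prediction are consumed as inputs.
* The metagene compendium is consumed as a GMT input; the package does
  not derive cell-type signatures.
* Univariate survival contrasts only; no multivariable adjustment.
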