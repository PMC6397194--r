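# repairimmune

Tumors that cannot repair their own DNA accumulate somatic mutations, and
some of those mutations yield *neoantigens* — mutant peptides presented on
MHC class I that T cells can recognise. Whether that immunogenic potential
translates into actual T-cell infiltration, however, also depends on
immunosuppressive signals in the microenvironment, notably TGF-β and Wnt
signalling. `repairimmune` implements the full analysis chain that connects
these layers for a bulk tumor cohort (the motivating setting is lung
squamous cell carcinoma):

1. **DNA repair status** — classify somatic variants in 15 homologous
   recombination genes, 18 mismatch repair genes and *POLE* as deleterious
   (nonsense, indel, splice ≤ 2 bp intronic, or missense with SIFT < 0.05
   or CADD > 20) and flag carrier samples.
2. **Mutation burden** — per-sample mutation counts (TMB) and the cohort
   median split.
3. **Neoantigen burden** — 9-mer mutant/wild-type peptide windows around
   missense sites, filtered by the rule
   IC50(mut) < 500 nM ∧ IC50(wt) > 500 nM ∧ expression > 0
   across up to six HLA alleles.
4. **Immune infiltration** — per sample and immune cell type, a
   single-sample gene-set enrichment score (weighted Kolmogorov–Smirnov
   running sum over the cohort z-score ranking, hits weighted |z|^α),
   a permutation p-value against random same-size gene sets, and a Storey
   q-value; a cell type infiltrates a sample when q ≤ 0.10.
5. **Immunophenotype** — the 2×2 classification (repair variant ×
   activated T-cell infiltration → groups I–IV) and the combined 0–3
   score: one point each for TGFB1 z > median, WNT2 z > median, and
   absence of repair variants; score ≤ 1 predicts activated T-cell
   infiltration.
6. **Statistics** — pooled two-proportion z, Student/Welch t, one-way
   ANOVA with Tukey comparisons, Pearson correlation, Storey q-values
   (single-λ estimator, q = cummin of π̂₀·m·p₍ᵢ₎/i), multinomial logistic
   regression with Wald inference, and Kaplan–Meier / log-rank / Cox
   hazard ratios.

Every stage is exercisable without external data through a synthetic-cohort
generator (`simulate_cohort()`) that plants recoverable effects: carrier
fractions, negative-binomial TMB with a carrier fold-change, metagene
shifts in infiltrated samples, TGFB1/WNT2 shifts in non-infiltrated
samples, planted neoantigens and exponential survival.

## Worked example

```r
library(repairimmune)

params <- sim_params(seed = 42)                       # 178-sample cohort
cohort <- simulate_cohort(params,
                          components = c("maf", "expression", "clinical"))

status <- classify_repair(cohort$maf,
                          samples = cohort$truth$samples$sample_id)
two_sample_t(status$tmb[status$any_variant], status$tmb[!status$any_variant])
#> # A tibble: 1 × 6
#>   estimate statistic    df        p conf_low conf_high
#>      <dbl>     <dbl> <dbl>    <dbl>    <dbl>     <dbl>
#> 1     306.      9.84   176 1.71e-18     245.      367.
```

Samples carrying a deleterious HR/MMR/POLE variant average ~306 more
mutations than wild-type samples (the generator plants a 2.5-fold
increase), and the contrast is overwhelming at n = 178. Infiltration
calling, phenotype grouping and the combined score follow:

```r
calls <- call_infiltration(cohort$expression, cohort$sets, B = 500, seed = 42)
act   <- activated_t_flag(calls)             # activated CD4 or CD8 called
score <- combined_score(cohort$expression, status)
phen  <- build_phenotype(status, act, score)
table(phen$group)
#>   I  II III  IV
#>  84  36  47  11

low <- phen$score_class == "low"
cd4 <- with(subset(calls, cell_type == "Act_CD4"),
            setNames(infiltrated, sample_id))[phen$sample_id]
two_proportion_z(sum(cd4[low]), sum(low), sum(cd4[!low]), sum(!low))
#> # A tibble: 1 × 7
#>   estimate statistic        p conf_low conf_high    n1    n2
#>      <dbl>     <dbl>    <dbl>    <dbl>     <dbl> <int> <int>
#> 1    0.466      6.60 4.21e-11    0.339     0.592    77   101
```

Low combined scores (≤ 1) are 47 percentage points more likely to be
infiltrated by activated CD4 T cells — the association the score is built
to capture. Survival contrasts use the same grammar:

```r
km <- km_logrank_hr(cohort$clinical$os_time, cohort$clinical$os_event,
                    phen$any_variant)
km
#> <km_fit> TRUE vs FALSE, n = 178
#>   log-rank chi-sq = 0.022 (df 1), p = 0.8828
#>   HR = 0.971 [0.652-1.444], p = 0.8829
autoplot(km)        # Kaplan-Meier step curves
```

Repair status does not move survival here because the generator's default
hazard ratios are 1. Fitted objects support `tidy()` and `glance()`;
`plot_burden()`, `plot_coinfiltration()` and `plot_volcano()` cover the
standard figures, and `run_pipeline(pipeline_config(...))` executes every
stage in order and writes the per-stage TSV tables plus a seeded manifest.

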