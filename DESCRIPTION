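Package: repairimmune
Title: DNA Repair Variants, Mutation Burden and Tumor Immune Infiltration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An immunogenomic analysis pipeline linking deleterious somatic
    variants in DNA repair pathways (homologous recombination, mismatch
    repair, POLE) to tumor mutation burden, neoantigen burden, immune
    cell infiltration called by single-sample gene-set enrichment, a 2x2
    immunophenotype classification, and a combined DNA-repair/TGFB1/WNT2
    score that predicts activated T cell infiltration. Includes readers for
    MAF, expression-matrix, GMT, clinical and peptide-affinity tables, a
    statistics battery (two-proportion z, t-tests, ANOVA with Tukey
    adjustment, Pearson correlation, Storey q-values, multinomial logistic
    regression, Kaplan-Meier/log-rank/hazard ratios), and a synthetic-cohort
    generator with planted, recoverable effects so every stage can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
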