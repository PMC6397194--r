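#' Default immune cell-type panel of the synthetic compendium
#'
#' The 24 immune cell types the infiltration analysis screens: activated
#' and memory T-cell subsets, helper subsets, B cells, dendritic-cell and
#' myeloid populations, granulocytes and NK subsets.
#'
#' @return Character vector of 24 cell-type names.
#' @export
default_cell_types <- function() {
  c("Act_CD4", "Act_CD8", "Tem_CD4", "Tem_CD8", "Tcm", "Tfh", "Th2",
    "Tregs", "Tgd", "B_Mem", "mDC", "DC", "iDC", "pDC", "Mac", "Neu",
    "Mono", "Eos", "Mast", "NK", "NK_Bright", "NK_Dim", "NKT", "MDSC")
}

default_hla_alleles <- function() {
  c("HLA-A*01:01", "HLA-A*02:01", "HLA-B*07:02", "HLA-B*08:01",
    "HLA-C*04:01", "HLA-C*07:01")
}

#' Simulation parameters for a synthetic cohort
#'
#' Bundles and validates every knob of [simulate_cohort()]. Defaults
#' emulate the statistical structure of a 178-sample lung squamous cell
#' carcinoma cohort: overdispersed mutation counts with a cohort median
#' near 230, a 30% carrier fraction with a 2.5-fold burden increase,
#' co-infiltrating activated T-cell/myeloid metagene signal in 30% of
#' samples, and TGFB1/WNT2 elevated in the non-infiltrated samples.
#'
#' @param n_samples Cohort size.
#' @param p_repair_carrier Probability a sample carries at least one
#'   deleterious HR/MMR/POLE variant.
#' @param tmb_baseline_mean Negative-binomial mean mutation count for
#'   non-carriers.
#' @param tmb_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param tmb_fold_change Multiplicative burden increase in carriers
#'   (1 = no effect).
#' @param extra_genes_lambda Poisson mean of additional affected repair
#'   genes per carrier beyond the first.
#' @param neoantigen_rate Probability an annotated missense candidate is a
#'   planted strong binder.
#' @param neo_candidate_frac Fraction of a sample's mutations emitted as
#'   fully annotated missense variants in the protein pool (the
#'   neoantigen-eligible subset), so neoantigen burden scales with
#'   mutation burden; capped at `neo_candidate_cap` per sample to bound
#'   the affinity table.
#' @param neo_candidate_cap Per-sample cap on annotated candidates.
#' @param n_genes Number of genes in the expression matrix (inclusive of
#'   metagenes and marker panels).
#' @param cell_types Cell-type names of the metagene compendium.
#' @param set_size Genes per metagene set.
#' @param infiltration_prevalence Fraction of samples with planted immune
#'   infiltration.
#' @param infiltrated_block Cell types whose metagenes are shifted in
#'   infiltrated samples (a co-infiltrating block).
#' @param metagene_shift Planted shift of metagene expression in
#'   infiltrated samples, in within-gene SD units on the log scale.
#' @param tgfb1_wnt2_shift Planted shift of TGFB1/WNT2 in non-infiltrated
#'   samples, in SD units.
#' @param alleles HLA alleles typed for every sample.
#' @param os_baseline_hazard,dfs_baseline_hazard Exponential baseline
#'   hazards (per day).
#' @param os_group_hr,dfs_group_hr Named hazard ratios per immunophenotype
#'   group I-IV.
#' @param censoring_rate Expected fraction of censored observations under
#'   a unit hazard ratio.
#' @param seed Mandatory integer seed; the bundle is a pure function of
#'   the parameters.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_samples = 178L,
                       p_repair_carrier = 0.3,
                       tmb_baseline_mean = 200,
                       tmb_dispersion = 4,
                       tmb_fold_change = 2.5,
                       extra_genes_lambda = 0.4,
                       neoantigen_rate = 0.2,
                       neo_candidate_frac = 0.04,
                       neo_candidate_cap = 25L,
                       n_genes = 1000L,
                       cell_types = default_cell_types(),
                       set_size = 30L,
                       infiltration_prevalence = 0.3,
                       infiltrated_block = c("Act_CD4", "Act_CD8", "Tem_CD4",
                                             "Th2", "B_Mem", "mDC", "MDSC"),
                       metagene_shift = 2,
                       tgfb1_wnt2_shift = 1.5,
                       alleles = default_hla_alleles(),
                       os_baseline_hazard = 1 / 1000,
                       dfs_baseline_hazard = 1 / 700,
                       os_group_hr = c(I = 1, II = 1, III = 1, IV = 1),
                       dfs_group_hr = c(I = 1, II = 1, III = 1, IV = 1),
                       censoring_rate = 0.3,
                       seed = NULL) {
  p <- as.list(environment())
  if (is.null(p$seed)) abort("`seed` is mandatory for a synthetic cohort")
  if (p$n_samples < 2L) abort("n_samples must be >= 2")
  for (nm in c("p_repair_carrier", "infiltration_prevalence",
               "neoantigen_rate", "neo_candidate_frac", "censoring_rate")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1]", nm))
    }
  }
  for (nm in c("tmb_baseline_mean", "tmb_dispersion", "tmb_fold_change",
               "os_baseline_hazard", "dfs_baseline_hazard")) {
    if (p[[nm]] <= 0) abort(sprintf("`%s` must be positive", nm))
  }
  if (!all(p$infiltrated_block %in% p$cell_types)) {
    abort("infiltrated_block must be a subset of cell_types")
  }
  min_genes <- length(p$cell_types) * p$set_size +
    length(pathway_gene_lists()$wnt_panel) + 20L
  if (p$n_genes < min_genes) {
    abort(sprintf("n_genes must be at least %d for this panel layout", min_genes))
  }
  structure(p, class = "sim_params")
}

aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

#' Simulate a complete synthetic cohort with planted truth
#'
#' Generates a somatic variant table, expression matrix, metagene sets,
#' clinical table, protein sequences and a peptide-allele affinity surface
#' whose planted effects the pipeline should recover:
#' carriers receive deleterious variants in randomly chosen HR/MMR/POLE
#' genes and negative-binomial mutation counts inflated by
#' `tmb_fold_change`; infiltrated samples have the co-infiltrating
#' metagene block shifted up by `metagene_shift` SD; non-infiltrated
#' samples have TGFB1/WNT2 shifted up; survival is exponential with
#' per-group hazard ratios; planted neoantigens get strong mutant and weak
#' wild-type binding. The bundle is byte-reproducible from the seed.
#'
#' @param params A [sim_params()] object.
#' @param components Which expensive components to generate; `"maf"`,
#'   `"expression"` and `"clinical"` are cheap, `"neoantigen"` adds
#'   proteins plus the full affinity table.
#' @return A list of class `synthetic_cohort`: `maf`, `expression`
#'   (expr_matrix), `clinical`, `sets`, `proteins`, `affinity`, `alleles`
#'   and `truth` (list: `samples` tibble, `neoantigens` tibble, `params`).
#' @export
simulate_cohort <- function(params,
                            components = c("maf", "expression", "clinical",
                                           "neoantigen")) {
  if (!inherits(params, "sim_params")) {
    abort("`params` must come from sim_params()")
  }
  components <- match.arg(components, several.ok = TRUE)
  withr::with_seed(params$seed, simulate_cohort_impl(params, components))
}

simulate_cohort_impl <- function(p, components) {
  ids <- sprintf("S%04d", seq_len(p$n_samples))
  lists <- pathway_gene_lists()
  repair_genes <- c(lists$hr, lists$mmr, lists$pole)

  # gene layout: metagenes, marker panels, neo pool, background
  sets <- lapply(setNames(nm = p$cell_types), function(ct) {
    sprintf("%s_G%02d", toupper(ct), seq_len(p$set_size))
  })
  marker_genes <- toupper(lists$wnt_panel)
  neo_pool <- sprintf("NEO%04d", 1:30)
  n_bg <- p$n_genes - length(unlist(sets)) - length(marker_genes) -
    length(neo_pool)
  bg_genes <- sprintf("BG%04d", seq_len(max(n_bg, 0L)))
  all_genes <- c(unlist(sets, use.names = FALSE), marker_genes, neo_pool,
                 bg_genes)

  # planted per-sample truth
  carrier <- runif(p$n_samples) < p$p_repair_carrier
  infiltrated <- runif(p$n_samples) < p$infiltration_prevalence
  group <- assign_group(carrier, infiltrated)
  truth_samples <- tibble(sample_id = ids, carrier = carrier,
                          infiltrated = infiltrated, group = group)

  bundle <- list(sets = sets, alleles = p$alleles)

  proteins <- setNames(vapply(neo_pool, function(g) random_protein(100L), ""),
                       neo_pool)

  if ("maf" %in% components) {
    maf_parts <- vector("list", p$n_samples)
    planted_genes <- vector("list", p$n_samples)
    neo_candidates <- vector("list", p$n_samples)
    n_bg_rows <- integer(p$n_samples)
    for (i in seq_len(p$n_samples)) {
      mu <- p$tmb_baseline_mean * ifelse(carrier[i], p$tmb_fold_change, 1)
      total <- rnbinom(1, size = p$tmb_dispersion, mu = mu)
      planted <- if (carrier[i]) {
        k <- min(1L + rpois(1, p$extra_genes_lambda), length(repair_genes))
        g <- sample(repair_genes, k)
        planted_genes[[i]] <- g
        planted_variant_rows(ids[i], g)
      } else {
        planted_genes[[i]] <- character()
        empty_variant_table()
      }
      n_cand <- min(p$neo_candidate_cap, round(total * p$neo_candidate_frac),
                    max(total - nrow(planted), 0L))
      cand <- if (n_cand > 0L && "neoantigen" %in% components) {
        candidate_variant_rows(ids[i], sample(neo_pool, n_cand,
                                              replace = TRUE), proteins)
      } else empty_variant_table()
      neo_candidates[[i]] <- cand
      n_bg_rows[i] <- max(total - nrow(planted) - nrow(cand), 0L)
      maf_parts[[i]] <- bind_rows(planted, cand)
    }
    bg <- background_variant_rows(rep(ids, n_bg_rows), all_genes,
                                  repair_genes)
    bundle$maf <- bind_rows(bind_rows(maf_parts), bg) |>
      arrange(.data$sample_id)
    truth_samples$planted_genes <- planted_genes
    candidates <- bind_rows(neo_candidates)
  } else {
    candidates <- empty_variant_table()
  }

  if ("expression" %in% components) {
    sdlog <- 0.5
    meanlog <- rnorm(length(all_genes), mean = 3, sd = 0.7)
    logx <- matrix(rnorm(length(all_genes) * p$n_samples, mean = meanlog,
                         sd = sdlog),
                   nrow = length(all_genes),
                   dimnames = list(all_genes, ids))
    block_genes <- unlist(sets[p$infiltrated_block], use.names = FALSE)
    logx[block_genes, infiltrated] <-
      logx[block_genes, infiltrated] + p$metagene_shift * sdlog
    for (g in c("TGFB1", "WNT2")) {
      logx[g, !infiltrated] <- logx[g, !infiltrated] +
        p$tgfb1_wnt2_shift * sdlog
    }
    bundle$expression <- compute_zscores(expr_matrix(exp(logx)))
  }

  if ("neoantigen" %in% components && nrow(candidates) > 0L) {
    bundle$proteins <- proteins
    pairs <- peptide_pairs(candidates, proteins)
    aff <- tidyr::crossing(
      peptide = unique(c(pairs$wt_peptide, pairs$mut_peptide)),
      allele = p$alleles)
    aff$ic50_nM <- toy_predictor(aff$peptide, aff$allele,
                                 seed_constant = p$seed %% 1000L)
    # plant true neoantigens on a central window and one allele each
    cand_key <- candidates[runif(nrow(candidates)) < p$neoantigen_rate, ]
    planted_neo <- list()
    if (nrow(cand_key) > 0L) {
      for (j in seq_len(nrow(cand_key))) {
        v <- cand_key[j, ]
        pw <- pairs[pairs$sample_id == v$sample_id & pairs$gene == v$gene &
                      pairs$protein_pos == v$protein_pos, ]
        if (nrow(pw) == 0L) next
        w <- pw[which.min(abs((v$protein_pos - pw$window_start) - 4L)), ]
        al <- sample(p$alleles, 1)
        aff$ic50_nM[aff$peptide == w$mut_peptide & aff$allele == al] <-
          runif(1, 50, 400)
        aff$ic50_nM[aff$peptide == w$wt_peptide & aff$allele == al] <-
          runif(1, 600, 5000)
        planted_neo[[length(planted_neo) + 1L]] <-
          tibble(sample_id = v$sample_id, gene = v$gene,
                 protein_pos = v$protein_pos, mut_peptide = w$mut_peptide,
                 allele = al)
      }
    }
    bundle$affinity <- aff
    truth_neo <- bind_rows(planted_neo)
  } else {
    truth_neo <- tibble(sample_id = character(), gene = character(),
                        protein_pos = integer(), mut_peptide = character(),
                        allele = character())
  }

  if ("clinical" %in% components) {
    os_rate <- p$os_baseline_hazard * unname(p$os_group_hr[as.character(group)])
    dfs_rate <- p$dfs_baseline_hazard *
      unname(p$dfs_group_hr[as.character(group)])
    cens_factor <- p$censoring_rate / max(1 - p$censoring_rate, 1e-9)
    os_t <- rexp(p$n_samples, os_rate)
    os_c <- rexp(p$n_samples, p$os_baseline_hazard * cens_factor)
    dfs_t <- rexp(p$n_samples, dfs_rate)
    dfs_c <- rexp(p$n_samples, p$dfs_baseline_hazard * cens_factor)
    bundle$clinical <- tibble(
      sample_id = ids,
      os_time = round(pmin(os_t, os_c), 1),
      os_event = os_t <= os_c,
      dfs_time = round(pmin(dfs_t, dfs_c), 1),
      dfs_event = dfs_t <= dfs_c,
      subtype = sample(c("basal", "classical", "primitive", "secretory"),
                       p$n_samples, replace = TRUE),
      smoking = sample(c("current", "former", "never"), p$n_samples,
                       replace = TRUE, prob = c(0.5, 0.4, 0.1))
    )
  }

  bundle$truth <- list(samples = truth_samples, neoantigens = truth_neo,
                       params = p)
  structure(bundle, class = "synthetic_cohort")
}

# one deleterious variant row in each of the given repair genes
planted_variant_rows <- function(sample_id, genes) {
  rows <- lapply(genes, function(g) {
    type <- sample(c("nonsense", "frameshift_indel", "splice", "missense"),
                   1, prob = c(0.3, 0.25, 0.15, 0.3))
    r <- tibble(sample_id = sample_id, gene = g, classification = type,
                protein_pos = NA_integer_, ref_aa = NA_character_,
                alt_aa = NA_character_, sift = NA_real_, cadd = NA_real_,
                intron_offset = NA_real_)
    if (type == "missense") {
      if (runif(1) < 0.5) r$sift <- runif(1, 0, 0.049) else
        r$cadd <- runif(1, 21, 40)
      aa <- sample(aa_alphabet(), 2)
      r$protein_pos <- sample.int(400L, 1)
      r$ref_aa <- aa[1]; r$alt_aa <- aa[2]
    }
    if (type == "splice") r$intron_offset <- sample(c(-1, -2), 1)
    r
  })
  bind_rows(rows)
}

# fully annotated missense rows in the neo pool (peptide-eligible)
candidate_variant_rows <- function(sample_id, genes, proteins) {
  rows <- lapply(genes, function(g) {
    pos <- sample(5:96, 1)
    ref <- substr(proteins[[g]], pos, pos)
    alt <- sample(setdiff(aa_alphabet(), ref), 1)
    tibble(sample_id = sample_id, gene = g, classification = "missense",
           protein_pos = pos, ref_aa = ref, alt_aa = alt,
           sift = runif(1, 0.05, 1), cadd = runif(1, 0, 20),
           intron_offset = NA_real_)
  })
  bind_rows(rows)
}

# background mutations; never deleterious when they land in a repair gene
background_variant_rows <- function(sample_id, all_genes, repair_genes) {
  n <- length(sample_id)
  if (n == 0L) return(empty_variant_table())
  gene <- sample(all_genes, n, replace = TRUE)
  cls <- sample(c("missense", "silent", "nonsense", "frameshift_indel",
                  "inframe_indel", "splice", "other"),
                n, replace = TRUE,
                prob = c(0.55, 0.2, 0.05, 0.04, 0.02, 0.04, 0.1))
  in_repair <- gene %in% repair_genes
  cls[in_repair] <- sample(c("missense", "silent"), sum(in_repair),
                           replace = TRUE, prob = c(0.5, 0.5))
  sift <- rep(NA_real_, n); cadd <- rep(NA_real_, n)
  off <- rep(NA_real_, n)
  mis <- cls == "missense"
  sift[mis] <- runif(sum(mis))
  cadd[mis] <- runif(sum(mis), 0, 40)
  # benign scores for missense in repair genes
  fix <- mis & in_repair
  sift[fix] <- runif(sum(fix), 0.05, 1)
  cadd[fix] <- runif(sum(fix), 0, 20)
  spl <- cls == "splice"
  off[spl] <- sample(c(-2, -1, 1, 2, NA), sum(spl), replace = TRUE)
  # splice rows with NA offset are trusted as deleterious; keep them out
  # of repair genes (handled above by never assigning splice there)
  tibble(sample_id = sample_id, gene = gene, classification = cls,
         protein_pos = NA_integer_, ref_aa = NA_character_,
         alt_aa = NA_character_, sift = sift, cadd = cadd,
         intron_offset = off)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples, seed %d\n",
              nrow(x$truth$samples), x$truth$params$seed))
  cat(sprintf("  components: %s\n",
              paste(intersect(c("maf", "expression", "clinical", "affinity"),
                              names(x)), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic cohort bundle to disk
#'
#' Emits `cohort.maf`, `expr.tsv`, `clinical.tsv`, `sets.gmt`,
#' `affinity.tsv`, `proteins.fasta`, `alleles.txt` and `truth.json` under
#' `dir`, all in the plain-text formats the readers of this package parse.
#'
#' @param bundle A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  if (!is.null(bundle$maf)) {
    paths["maf"] <- file.path(dir, "cohort.maf")
    write_maf(bundle$maf, paths["maf"])
  }
  if (!is.null(bundle$expression)) {
    paths["expression"] <- file.path(dir, "expr.tsv")
    write_expression(bundle$expression, paths["expression"])
  }
  if (!is.null(bundle$clinical)) {
    paths["clinical"] <- file.path(dir, "clinical.tsv")
    write_clinical(bundle$clinical, paths["clinical"])
  }
  paths["sets"] <- file.path(dir, "sets.gmt")
  write_gmt(bundle$sets, paths["sets"])
  if (!is.null(bundle$affinity)) {
    paths["affinity"] <- file.path(dir, "affinity.tsv")
    write_affinity(bundle$affinity, paths["affinity"])
  }
  if (!is.null(bundle$proteins)) {
    paths["proteins"] <- file.path(dir, "proteins.fasta")
    write_protein_fasta(bundle$proteins, paths["proteins"])
  }
  paths["alleles"] <- file.path(dir, "alleles.txt")
  writeLines(bundle$alleles, paths["alleles"])
  paths["truth"] <- file.path(dir, "truth.json")
  truth <- bundle$truth
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Recovery scorecard against planted truth
#'
#' Compares pipeline outputs with the planted flags of a synthetic cohort:
#' sensitivity/specificity of the recovered carrier status and of the
#' activated T-cell infiltration flag, and the relative bias of the mean
#' mutation burden against its planted expectation.
#'
#' @param results Named list; any of `repair_status` (from
#'   [classify_repair()]), `act_flags` (from [activated_t_flag()]),
#'   `burden` (from [mutation_burden()]).
#' @param truth The `truth` element of a [simulate_cohort()] bundle.
#' @return Tibble with `metric` and `value` rows for each comparable stage.
#' @export
truth_scorecard <- function(results, truth) {
  ts <- truth$samples
  rows <- list()
  sens_spec <- function(pred, actual) {
    c(sensitivity = if (any(actual)) mean(pred[actual]) else NA_real_,
      specificity = if (any(!actual)) mean(!pred[!actual]) else NA_real_)
  }
  check_ids <- function(tbl, what) {
    if (!setequal(tbl$sample_id, ts$sample_id)) {
      abort(sprintf("sample identifiers of `%s` do not match the truth", what))
    }
  }
  if (!is.null(results$repair_status)) {
    check_ids(results$repair_status, "repair_status")
    rs <- results$repair_status[match(ts$sample_id,
                                      results$repair_status$sample_id), ]
    ss <- sens_spec(rs$any_variant, ts$carrier)
    rows$carrier <- tibble(metric = c("carrier_sensitivity",
                                      "carrier_specificity"),
                           value = unname(ss))
  }
  if (!is.null(results$act_flags)) {
    check_ids(results$act_flags, "act_flags")
    af <- results$act_flags[match(ts$sample_id,
                                  results$act_flags$sample_id), ]
    ss <- sens_spec(af$act_t_infiltrated, ts$infiltrated)
    rows$infil <- tibble(metric = c("infiltration_sensitivity",
                                    "infiltration_specificity"),
                         value = unname(ss))
  }
  if (!is.null(results$burden)) {
    check_ids(results$burden, "burden")
    p <- truth$params
    expected <- p$tmb_baseline_mean *
      ifelse(ts$carrier, p$tmb_fold_change, 1)
    b <- results$burden[match(ts$sample_id, results$burden$sample_id), ]
    rows$tmb <- tibble(metric = "tmb_relative_bias",
                       value = mean(b$n_mutations) / mean(expected) - 1)
  }
  if (length(rows) == 0L) {
    abort("no comparable pipeline outputs supplied")
  }
  bind_rows(rows)
}
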