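#' Pipeline run configuration
#'
#' Collects every analysis knob in one object; defaults are the printed
#' thresholds of the underlying analysis (SIFT 0.05, CADD 20, IC50 500 nM,
#' q-cut 10%, combined-score cut 1). Either supply file paths or set
#' `simulate` to generate a synthetic cohort in memory.
#'
#' @param maf,expression,clinical,gmt,affinity,proteins,alleles Input file
#'   paths (any may be NULL when `simulate` is given).
#' @param simulate Optional [sim_params()] object; when present the inputs
#'   above are ignored and a synthetic cohort is generated.
#' @param out_dir Output directory for the stage TSVs and manifest; NULL
#'   keeps everything in memory.
#' @param sift_cut,cadd_cut Deleteriousness thresholds.
#' @param ic50_cut Neoantigen binding threshold in nM.
#' @param q_cut Infiltration FDR threshold.
#' @param score_cut Combined-score threshold for the `"low"` class.
#' @param tmb_mode `"all"` or `"nonsynonymous"` burden counting.
#' @param burden_unit Neoantigen burden unit, `"peptide"` or
#'   `"peptide_allele"`.
#' @param act_t_convention Activated T-cell rule (see [activated_t_flag()]).
#' @param storey_lambda Lambda of the Storey q-value estimator.
#' @param B Permutation null draws for the infiltration stage.
#' @param seed Integer seed for all stochastic stages.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(maf = NULL, expression = NULL, clinical = NULL,
                            gmt = NULL, affinity = NULL, proteins = NULL,
                            alleles = NULL, simulate = NULL, out_dir = NULL,
                            sift_cut = 0.05, cadd_cut = 20, ic50_cut = 500,
                            q_cut = 0.10, score_cut = 1L,
                            tmb_mode = "all", burden_unit = "peptide",
                            act_t_convention = "either",
                            storey_lambda = 0.5, B = 1000L, seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(simulate) && (is.null(maf) || is.null(expression) ||
                            is.null(gmt))) {
    abort("either `simulate` or the maf/expression/gmt inputs must be given")
  }
  structure(cfg, class = "run_config")
}

#' Run the full immunogenomic pipeline
#'
#' Executes every stage in dependency order: input loading (or synthetic
#' generation), cohort z-scoring, repair-pathway status and mutation
#' burden, neoantigen calling (when affinity inputs exist), infiltration
#' calling, immunophenotype grouping and the combined score, and the
#' association/survival summary tables. When `out_dir` is set each stage
#' table is written as TSV together with a JSON manifest stamped with the
#' configuration hash and seed, so a rerun with the same config reproduces
#' the outputs bit-exactly.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a named list of stage tibbles plus the manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    abort("`config` must come from pipeline_config()")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }

  if (!is.null(config$simulate)) {
    bundle <- stage("simulate", simulate_cohort(config$simulate))
  } else {
    bundle <- stage("load", list(
      maf = read_maf(config$maf),
      expression = read_expression(config$expression),
      clinical = if (!is.null(config$clinical)) read_clinical(config$clinical),
      sets = read_gmt(config$gmt),
      affinity = if (!is.null(config$affinity)) read_affinity(config$affinity),
      proteins = if (!is.null(config$proteins))
        read_protein_fasta(config$proteins),
      alleles = if (!is.null(config$alleles))
        readLines(config$alleles, warn = FALSE)
    ))
  }

  em <- stage("zscore", compute_zscores(bundle$expression))
  ids <- colnames(em$values)

  status <- stage("repair_status", classify_repair(
    bundle$maf, sift_cut = config$sift_cut, cadd_cut = config$cadd_cut,
    samples = ids, tmb_mode = config$tmb_mode))

  neo_burden <- NULL
  if (!is.null(bundle$affinity) && !is.null(bundle$proteins)) {
    neo_burden <- stage("neoantigen", {
      pairs <- peptide_pairs(bundle$maf, bundle$proteins)
      calls <- call_neoantigens(pairs, bundle$alleles, bundle$affinity, em,
                                ic50_cut = config$ic50_cut)
      neoantigen_burden(calls, unit = config$burden_unit, samples = ids)
    })
  }

  infiltration <- stage("infiltration", call_infiltration(
    em, bundle$sets, q_cut = config$q_cut, B = config$B,
    seed = config$seed))

  phenotype <- stage("phenotype", {
    act <- activated_t_flag(infiltration,
                            convention = config$act_t_convention)
    sc <- combined_score(em, status, score_cut = config$score_cut)
    build_phenotype(status, act, sc)
  })

  associations <- stage("associations", {
    rows <- list()
    if (any(phenotype$any_variant) && any(!phenotype$any_variant)) {
      tt <- two_sample_t(phenotype$tmb[phenotype$any_variant],
                         phenotype$tmb[!phenotype$any_variant])
      rows$tmb <- mutate(tt, test = "tmb_by_repair_variant", .before = 1)
    }
    for (ct in intersect(c("Act_CD4", "Act_CD8"), infiltration$cell_type)) {
      inf <- infiltration$infiltrated[infiltration$cell_type == ct]
      names(inf) <- infiltration$sample_id[infiltration$cell_type == ct]
      inf <- inf[phenotype$sample_id]
      low <- phenotype$score_class == "low"
      if (any(low) && any(!low)) {
        pz <- two_proportion_z(sum(inf[low]), sum(low),
                               sum(inf[!low]), sum(!low))
        rows[[ct]] <- mutate(pz, test = paste0("infiltration_", ct,
                                               "_by_low_score"),
                             .before = 1)
      }
    }
    bind_rows(rows)
  })

  surv_tab <- NULL
  if (!is.null(bundle$clinical)) {
    surv_tab <- stage("survival", {
      cl <- bundle$clinical[match(phenotype$sample_id,
                                  bundle$clinical$sample_id), ]
      split_tmb <- median_split(phenotype$tmb, phenotype$sample_id)
      fits <- list(
        os_by_tmb = km_logrank_hr(cl$os_time, cl$os_event, split_tmb$group),
        dfs_by_tmb = km_logrank_hr(cl$dfs_time, cl$dfs_event,
                                   split_tmb$group),
        os_by_repair = km_logrank_hr(cl$os_time, cl$os_event,
                                     phenotype$any_variant),
        dfs_by_repair = km_logrank_hr(cl$dfs_time, cl$dfs_event,
                                      phenotype$any_variant)
      )
      imap(fits, function(f, nm) mutate(glance(f), contrast = nm,
                                        .before = 1)) |> list_rbind()
    })
  }

  results <- list(status = status, neoantigen_burden = neo_burden,
                  infiltration = infiltration, phenotype = phenotype,
                  associations = associations, survival = surv_tab)
  results <- results[!vapply(results, is.null, TRUE)]

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    n_samples = length(ids),
    stages = names(results),
    thresholds = config[c("sift_cut", "cadd_cut", "ic50_cut", "q_cut",
                          "score_cut")]
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(results)) {
      readr::write_tsv(results[[nm]],
                       file.path(config$out_dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  results$manifest <- manifest
  invisible(results)
}
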