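#' Activated T-cell infiltration flag per sample
#'
#' Reduces the infiltration calls of the activated CD4 and activated CD8
#' cell types to one per-sample flag. The default convention, `"either"`,
#' counts a sample as infiltrated by activated T cells when either subtype
#' is called.
#'
#' @param calls Infiltration table from [call_infiltration()].
#' @param convention `"either"`, `"both"`, `"cd4"` or `"cd8"`.
#' @param cd4,cd8 Cell-type names of the activated CD4/CD8 sets.
#' @return Tibble with `sample_id` and `act_t_infiltrated`.
#' @export
activated_t_flag <- function(calls, convention = c("either", "both", "cd4", "cd8"),
                             cd4 = "Act_CD4", cd8 = "Act_CD8") {
  convention <- match.arg(convention)
  for (ct in c(cd4, cd8)) {
    if (!ct %in% calls$cell_type) {
      abort(sprintf("cell type '%s' missing from the infiltration calls", ct))
    }
  }
  wide <- calls |>
    filter(.data$cell_type %in% c(cd4, cd8)) |>
    select("sample_id", "cell_type", "infiltrated") |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "infiltrated")
  a <- wide[[cd4]]
  b <- wide[[cd8]]
  flag <- switch(convention,
                 either = a | b, both = a & b, cd4 = a, cd8 = b)
  tibble(sample_id = wide$sample_id, act_t_infiltrated = flag)
}

#' Assign the 2x2 immunophenotype group
#'
#' Group I: repair variant absent, not infiltrated; II: variant present,
#' not infiltrated; III: variant absent, infiltrated; IV: variant present,
#' infiltrated.
#'
#' @param repair_variant Logical vector: any deleterious HR/MMR/POLE variant.
#' @param act_t_infiltrated Logical vector: activated T-cell infiltration.
#' @return Factor with levels `I`, `II`, `III`, `IV`.
#' @export
assign_group <- function(repair_variant, act_t_infiltrated) {
  if (length(repair_variant) != length(act_t_infiltrated)) {
    abort("flag vectors must have equal length")
  }
  if (anyNA(repair_variant) || anyNA(act_t_infiltrated)) {
    abort("group assignment needs both flags defined for every sample")
  }
  idx <- 1L + repair_variant + 2L * act_t_infiltrated
  factor(c("I", "II", "III", "IV")[idx], levels = c("I", "II", "III", "IV"))
}

#' Combined DNA-repair/TGFB1/WNT2 score
#'
#' One point each for a TGFB1 and a WNT2 expression z-score strictly above
#' the cohort median of that gene's z-scores, plus one point for the
#' absence of any deleterious DNA repair gene variant. Scores of 1 or less
#' are classed `"low"`; low scores predict activated T-cell infiltration.
#'
#' @param em Expression matrix (z-scores computed on the fly if absent).
#' @param repair_status Tibble from [classify_repair()] (needs `sample_id`
#'   and `any_variant`).
#' @param tgfb1,wnt2 Gene symbols to use for the two expression points.
#' @param score_cut Upper bound of the `"low"` class, default 1.
#' @return Tibble with `sample_id`, `combined_score` (0-3), `score_class`
#'   (factor low/high).
#' @export
combined_score <- function(em, repair_status, tgfb1 = "TGFB1", wnt2 = "WNT2",
                           score_cut = 1L) {
  z <- zscores_of(em)
  for (g in c(tgfb1, wnt2)) {
    if (!g %in% rownames(z)) {
      abort(sprintf("gene '%s' absent from the expression matrix", g))
    }
  }
  missing <- setdiff(repair_status$sample_id, colnames(z))
  if (length(missing) > 0L) {
    abort(sprintf("sample(s) absent from expression matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  zt <- z[tgfb1, repair_status$sample_id]
  zw <- z[wnt2, repair_status$sample_id]
  med_t <- median(z[tgfb1, ])
  med_w <- median(z[wnt2, ])
  score <- (zt > med_t) + (zw > med_w) + (!repair_status$any_variant)
  tibble(sample_id = repair_status$sample_id,
         combined_score = as.integer(score),
         score_class = factor(ifelse(score <= score_cut, "low", "high"),
                              levels = c("low", "high")))
}

#' Assemble the per-sample phenotype table
#'
#' Joins repair status, the activated T-cell flag and the combined score
#' into the sample-phenotype table used by the group-level analyses.
#'
#' @param repair_status Tibble from [classify_repair()].
#' @param act_flags Tibble from [activated_t_flag()].
#' @param scores Tibble from [combined_score()].
#' @return Tibble with one row per sample: flags, `group`,
#'   `combined_score`, `score_class`, TMB.
#' @export
build_phenotype <- function(repair_status, act_flags, scores) {
  out <- repair_status |>
    inner_join(act_flags, by = "sample_id") |>
    inner_join(scores, by = "sample_id")
  mutate(out, group = assign_group(.data$any_variant,
                                   .data$act_t_infiltrated))
}

#' Per-gene ANOVA with Tukey comparisons across phenotype groups
#'
#' Runs a one-way ANOVA of expression on the group labels for every gene
#' of a panel, with Tukey-adjusted pairwise p-values. Genes that cannot be
#' tested (fewer than 2 usable groups) are reported with a reason instead
#' of a result.
#'
#' @param groups Named vector or tibble (`sample_id`, `group`) of group
#'   labels.
#' @param em Expression matrix.
#' @param panel Character vector of gene symbols to test.
#' @param use `"zscore"` (default) or `"value"`: which view to compare.
#' @return List with `anova` (per-gene F/p) and `pairwise` (long tibble
#'   `gene`, `comparison`, `diff`, `p_adj`, `note`).
#' @export
panel_comparison <- function(groups, em, panel, use = c("zscore", "value")) {
  use <- match.arg(use)
  mat <- if (use == "zscore") zscores_of(em) else
    (if (inherits(em, "expr_matrix")) em$values else em)
  if (is.data.frame(groups)) {
    groups <- setNames(groups$group, groups$sample_id)
  }
  ids <- intersect(colnames(mat), names(groups))
  g <- factor(groups[ids])
  anova_rows <- list()
  pair_rows <- list()
  for (gene in panel) {
    if (!gene %in% rownames(mat)) {
      anova_rows[[gene]] <- tibble(gene = gene, statistic = NA_real_,
                                   p = NA_real_, note = "gene absent")
      next
    }
    vals <- mat[gene, ids]
    tab <- table(g)
    usable <- names(tab)[tab >= 2]
    if (length(usable) < 2L) {
      anova_rows[[gene]] <- tibble(gene = gene, statistic = NA_real_,
                                   p = NA_real_,
                                   note = "fewer than 2 groups with >= 2 samples")
      next
    }
    keep <- g %in% usable
    res <- anova_tukey(vals[keep], droplevels(g[keep]))
    anova_rows[[gene]] <- mutate(res$anova, gene = gene, note = NA_character_,
                                 .before = 1)
    pair_rows[[gene]] <- mutate(res$pairwise, gene = gene, .before = 1)
  }
  list(anova = bind_rows(anova_rows), pairwise = bind_rows(pair_rows))
}

#' Differential expression signature between two sample classes
#'
#' Per-gene two-sample t-test between a binary split (high/low TMB, high/low
#' neoantigen burden, or any two-level label) with Storey q-values across
#' the panel; the volcano-plot table.
#'
#' @param labels Tibble (`sample_id`, `group`) or named vector with exactly
#'   2 levels.
#' @param em Expression matrix.
#' @param panel Genes to test; defaults to every gene in the matrix.
#' @param welch Use Welch's t-test.
#' @param use `"zscore"` or `"value"` view.
#' @return Tibble with `gene`, `estimate` (mean difference, level2 -
#'   level1), `statistic`, `p`, `q`.
#' @export
signature_table <- function(labels, em, panel = NULL, welch = FALSE,
                            use = c("zscore", "value")) {
  use <- match.arg(use)
  mat <- if (use == "zscore") zscores_of(em) else
    (if (inherits(em, "expr_matrix")) em$values else em)
  if (is.data.frame(labels)) labels <- setNames(labels$group, labels$sample_id)
  ids <- intersect(colnames(mat), names(labels))
  g <- factor(labels[ids])
  if (nlevels(g) != 2L) abort("labels must have exactly 2 levels")
  panel <- panel %||% rownames(mat)
  panel <- intersect(panel, rownames(mat))
  res <- map(panel, function(gene) {
    a <- mat[gene, ids][g == levels(g)[1]]
    b <- mat[gene, ids][g == levels(g)[2]]
    out <- tryCatch(two_sample_t(b, a, welch = welch),
                    error = function(e) tibble(estimate = NA_real_,
                                               statistic = NA_real_,
                                               df = NA_real_, p = NA_real_,
                                               conf_low = NA_real_,
                                               conf_high = NA_real_))
    mutate(out, gene = gene, .before = 1)
  }) |> list_rbind()
  ok <- !is.na(res$p)
  res$q <- NA_real_
  res$q[ok] <- storey_q(res$p[ok])
  select(res, "gene", "estimate", "statistic", "p", "q")
}

#' Association between a variant flag and a categorical subtype
#'
#' For each subtype level, compares the proportion of flagged samples
#' inside the level against the proportion outside it with the pooled
#' two-proportion z-test, then Storey-adjusts across levels.
#'
#' @param flags Tibble (`sample_id`, logical flag column) or named logical
#'   vector (e.g. MMR-variant status).
#' @param labels Tibble (`sample_id`, `subtype`) or named vector of
#'   categorical labels with >= 2 levels.
#' @return Tibble with one row per level: counts, `estimate`, `statistic`,
#'   `p`, `q`.
#' @export
subtype_association <- function(flags, labels) {
  if (is.data.frame(flags)) {
    flag_col <- setdiff(names(flags), "sample_id")[1]
    flags <- setNames(flags[[flag_col]], flags$sample_id)
  }
  if (is.data.frame(labels)) {
    lab_col <- setdiff(names(labels), "sample_id")[1]
    labels <- setNames(labels[[lab_col]], labels$sample_id)
  }
  ids <- intersect(names(flags), names(labels))
  f <- as.logical(flags[ids])
  l <- factor(labels[ids])
  l <- droplevels(l)
  if (nlevels(l) < 2L) abort("need at least 2 subtype levels")
  empty <- setdiff(levels(l), unique(as.character(l)))
  if (length(empty) > 0L) {
    warn(sprintf("skipping empty subtype level(s): %s",
                 paste(empty, collapse = ", ")))
  }
  rows <- map(levels(l), function(lv) {
    inside <- l == lv
    res <- two_proportion_z(sum(f[inside]), sum(inside),
                            sum(f[!inside]), sum(!inside))
    mutate(res, level = lv, x_in = sum(f[inside]), n_in = sum(inside),
           x_out = sum(f[!inside]), n_out = sum(!inside), .before = 1)
  }) |> list_rbind()
  ok <- !is.na(rows$p)
  rows$q <- NA_real_
  rows$q[ok] <- storey_q(rows$p[ok])
  select(rows, "level", "x_in", "n_in", "x_out", "n_out", "estimate",
         "statistic", "p", "q")
}
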