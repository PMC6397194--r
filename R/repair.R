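#' DNA-repair pathway and marker gene lists
#'
#' The fixed gene panels used throughout the analysis: 15 homologous
#' recombination (HR) genes, 18 mismatch repair (MMR) genes, POLE, the
#' antigen-presentation machinery, and the TGF-beta/Wnt immunosuppressive
#' panel used for immunophenotype comparisons.
#'
#' @return Named list of character vectors: `hr`, `mmr`, `pole`,
#'   `antigen_presentation`, `wnt_panel`.
#' @export
pathway_gene_lists <- function() {
  list(
    hr = c("ATR", "ATM", "CHEK1", "CHEK2", "BRCA1", "BRCA2", "BAP1",
           "BARD1", "FANCD2", "FANCE", "FANCC", "FANCA", "RAD50", "RAD51",
           "PALB2"),
    mmr = c("MLH1", "MLH3", "MSH2", "MSH3", "MSH4", "MSH5", "MSH6", "PMS1",
            "PMS2", "PMS2L3", "PCNA", "EXO1", "POLD1", "RFC1", "RFC2",
            "RFC3", "RFC4", "RFC5"),
    pole = "POLE",
    antigen_presentation = c("HLA-A", "HLA-B", "HLA-C", "B2M", "TAP2",
                             "PSMB8"),
    wnt_panel = c("APC", "CTNNB1", "WNT1", "WNT2", "WNT3A", "WNT5A",
                  "WNT7A", "TGFB1", "TGFB2", "TGFB3", "VEGFA")
  )
}

#' Flag deleterious somatic variants
#'
#' A variant is deleterious when it is a nonsense mutation, an indel
#' (frameshift or in-frame), a splicing error, or a missense mutation with
#' SIFT < `sift_cut` or CADD > `cadd_cut` (strict inequalities). Splicing
#' errors are variants within 2 bp on the intronic side of an intron/exon
#' junction; when `intron_offset` is absent the MAF splice classification is
#' trusted. A missense variant with neither score available is treated as
#' not deleterious.
#'
#' @param variants Variant tibble (see [read_maf()]).
#' @param sift_cut SIFT threshold, default 0.05 (deleterious below).
#' @param cadd_cut CADD phred threshold, default 20 (deleterious above).
#' @return Logical vector, one element per variant row.
#' @export
is_deleterious <- function(variants, sift_cut = 0.05, cadd_cut = 20) {
  cls <- variants$classification
  sift <- variants$sift %||% rep(NA_real_, nrow(variants))
  cadd <- variants$cadd %||% rep(NA_real_, nrow(variants))
  off <- variants$intron_offset %||% rep(NA_real_, nrow(variants))

  auto <- cls %in% c("nonsense", "frameshift_indel", "inframe_indel")
  splice_ok <- cls == "splice" & (is.na(off) | (off < 0 & off >= -2))
  mis <- cls == "missense" &
    ((!is.na(sift) & sift < sift_cut) | (!is.na(cadd) & cadd > cadd_cut))
  auto | splice_ok | mis
}

#' Per-sample DNA-repair pathway status
#'
#' Flags each sample for carrying at least one deleterious variant in the
#' HR, MMR or POLE gene panels, counts the distinct affected genes across
#' the three panels, and attaches the tumor mutation burden.
#'
#' @param variants Variant tibble grouped implicitly by `sample_id`.
#' @param lists Gene panels, see [pathway_gene_lists()].
#' @param sift_cut,cadd_cut Deleteriousness thresholds, see
#'   [is_deleterious()].
#' @param samples Optional character vector of sample identifiers that must
#'   appear in the output even with no variants (all flags FALSE, TMB 0).
#' @param tmb_mode Counting mode passed to [mutation_burden()].
#' @return Tibble with one row per sample: `sample_id`, `hr_variant`,
#'   `mmr_variant`, `pole_variant`, `any_variant`, `affected_gene_count`,
#'   `tmb`.
#' @export
classify_repair <- function(variants, lists = pathway_gene_lists(),
                            sift_cut = 0.05, cadd_cut = 20,
                            samples = NULL, tmb_mode = "all") {
  ids <- union(samples %||% character(), unique(variants$sample_id))
  del <- variants[is_deleterious(variants, sift_cut, cadd_cut), ]
  flag_for <- function(panel) {
    hit <- del[del$gene %in% panel, ]
    ids %in% hit$sample_id
  }
  hr <- flag_for(lists$hr)
  mmr <- flag_for(lists$mmr)
  pole <- flag_for(lists$pole)
  panel_all <- c(lists$hr, lists$mmr, lists$pole)
  counts <- del[del$gene %in% panel_all, c("sample_id", "gene")] |>
    distinct() |>
    count(.data$sample_id, name = "affected_gene_count")
  burden <- mutation_burden(variants, mode = tmb_mode, samples = ids)
  tibble(sample_id = ids, hr_variant = hr, mmr_variant = mmr,
         pole_variant = pole, any_variant = hr | mmr | pole) |>
    left_join(counts, by = "sample_id") |>
    mutate(affected_gene_count =
             ifelse(is.na(.data$affected_gene_count), 0L,
                    .data$affected_gene_count)) |>
    left_join(burden, by = "sample_id") |>
    rename(tmb = "n_mutations")
}

#' Tumor mutation burden per sample
#'
#' @param variants Variant tibble.
#' @param mode `"all"` counts every variant row; `"nonsynonymous"` excludes
#'   silent and "other" classes.
#' @param samples Optional sample identifiers to force into the output with
#'   a count of 0 (a warning lists them).
#' @return Tibble with `sample_id` and `n_mutations`.
#' @export
mutation_burden <- function(variants, mode = c("all", "nonsynonymous"),
                            samples = NULL) {
  mode <- match.arg(mode)
  keep <- if (mode == "all") rep(TRUE, nrow(variants)) else
    !variants$classification %in% c("silent", "other")
  counts <- variants[keep, ] |> count(.data$sample_id, name = "n_mutations")
  ids <- union(samples %||% character(), unique(variants$sample_id))
  missing <- setdiff(ids, variants$sample_id)
  if (length(missing) > 0L) {
    warn(sprintf("%d sample(s) absent from the variant table get burden 0: %s",
                 length(missing), paste(head(missing, 5), collapse = ", ")))
  }
  tibble(sample_id = ids) |>
    left_join(counts, by = "sample_id") |>
    mutate(n_mutations = ifelse(is.na(.data$n_mutations), 0L,
                                as.integer(.data$n_mutations)))
}

#' Split a cohort at the median
#'
#' Labels each sample `"high"` when its value is strictly greater than the
#' cohort median; ties at the median go to `"low"`.
#'
#' @param values Numeric vector (e.g. per-sample mutation counts).
#' @param ids Sample identifiers; defaults to `names(values)` or an index.
#' @return Tibble with `sample_id`, `value`, `group` (factor low/high);
#'   the median is attached as attribute `"median"`.
#' @export
median_split <- function(values, ids = NULL) {
  if (length(values) < 2L) abort("median_split needs at least 2 values")
  ids <- ids %||% names(values) %||% as.character(seq_along(values))
  med <- median(values)
  lab <- factor(ifelse(unname(values) > med, "high", "low"),
                levels = c("low", "high"))
  if (all(lab == "low")) {
    warn("all values at or below the median; every sample labeled 'low'")
  }
  out <- tibble(sample_id = ids, value = unname(values), group = lab)
  attr(out, "median") <- med
  out
}
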