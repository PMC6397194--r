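#' Enumerate mutant/wild-type peptide windows around a missense site
#'
#' Lists every k-mer of the protein whose span contains the mutated residue,
#' clipped to the protein ends: window starts run from `max(1, pos - k + 1)`
#' to `min(pos, L - k + 1)`. The wild-type peptide is taken from the
#' original sequence and the mutant peptide substitutes `alt_aa` at the
#' mutated position, so each pair differs at exactly one residue.
#'
#' @param protein Amino-acid string (uppercase).
#' @param pos 1-based residue index of the mutation.
#' @param ref_aa,alt_aa Single-letter reference and alternate residues;
#'   `protein[pos]` must equal `ref_aa`.
#' @param k Window length, default 9.
#' @return Tibble with `window_start`, `wt_peptide`, `mut_peptide`.
#' @export
mutant_windows <- function(protein, pos, ref_aa, alt_aa, k = 9L) {
  protein <- toupper(protein)
  L <- nchar(protein)
  if (k > L) abort(sprintf("window size %d exceeds protein length %d", k, L))
  if (pos < 1L || pos > L) {
    abort(sprintf("mutation position %d outside protein of length %d", pos, L))
  }
  if (substr(protein, pos, pos) != ref_aa) {
    abort(sprintf(
      "reference residue mismatch at position %d: protein has '%s', variant says '%s'",
      pos, substr(protein, pos, pos), ref_aa))
  }
  mut_protein <- protein
  substr(mut_protein, pos, pos) <- alt_aa
  starts <- seq.int(max(1L, pos - k + 1L), min(pos, L - k + 1L))
  tibble(
    window_start = starts,
    wt_peptide = substring(protein, starts, starts + k - 1L),
    mut_peptide = substring(mut_protein, starts, starts + k - 1L)
  )
}

#' Peptide pairs for every annotated missense variant in a cohort
#'
#' Applies [mutant_windows()] to each missense variant that carries a
#' protein position and residue annotation and whose gene has a protein
#' sequence. Non-missense variants and unannotated missense rows are
#' skipped: only single-residue substitutions generate peptide pairs here.
#'
#' @param variants Variant tibble (see [read_maf()]).
#' @param proteins Named character vector of protein sequences keyed by gene.
#' @param k Window length, default 9.
#' @return Tibble with `sample_id`, `gene`, `protein_pos`, `window_start`,
#'   `wt_peptide`, `mut_peptide`.
#' @export
peptide_pairs <- function(variants, proteins, k = 9L) {
  cand <- variants |>
    filter(.data$classification == "missense",
           !is.na(.data$protein_pos), !is.na(.data$ref_aa),
           !is.na(.data$alt_aa), .data$gene %in% names(proteins))
  if (nrow(cand) == 0L) {
    return(tibble(sample_id = character(), gene = character(),
                  protein_pos = integer(), window_start = integer(),
                  wt_peptide = character(), mut_peptide = character()))
  }
  pmap(list(cand$sample_id, cand$gene, cand$protein_pos, cand$ref_aa,
            cand$alt_aa),
       function(sid, g, pos, ref, alt) {
         mutant_windows(proteins[[g]], pos, ref, alt, k = k) |>
           mutate(sample_id = sid, gene = g, protein_pos = pos,
                  .before = 1)
       }) |>
    list_rbind()
}

#' Deterministic toy MHC-binding predictor
#'
#' A self-contained stand-in for an MHC class I affinity predictor, used to
#' give synthetic cohorts and tests a reproducible peptide-allele IC50
#' surface. Each residue position contributes a pseudo-random weight keyed
#' by (residue, position, allele); the mean weight is mapped onto
#' `50000^(1 - s)` nM so that scores span both sides of the 500 nM binding
#' threshold. Identical inputs always give identical outputs, and changing
#' any single residue changes the score. It makes no claim to biochemical
#' realism.
#'
#' @param peptide Character vector of 9-mer peptides.
#' @param allele Character vector of HLA allele names (recycled).
#' @param seed_constant Integer mixed into the hash so different synthetic
#'   worlds get different surfaces.
#' @return Numeric vector of IC50 values in nM.
#' @export
toy_predictor <- function(peptide, allele, seed_constant = 0L) {
  peptide <- toupper(peptide)
  if (any(nchar(peptide) != 9L)) {
    abort("toy_predictor scores 9-mer peptides only")
  }
  n <- max(length(peptide), length(allele))
  peptide <- rep_len(peptide, n)
  allele <- rep_len(allele, n)
  akey <- vapply(allele, function(a) sum(utf8ToInt(a) * seq_len(nchar(a))),
                 0, USE.NAMES = FALSE)
  codes <- vapply(peptide, utf8ToInt, integer(9L), USE.NAMES = FALSE)
  h <- codes * 17.23 + seq_len(9L) * 131.71 +
    rep(akey * 0.618 + seed_constant * 7919, each = 9L)
  score <- colMeans(abs(sin(h) * 43758.5453) %% 1)
  50000 ^ (1 - unname(score))
}

resolve_affinity <- function(peptides, alleles, affinity) {
  if (is.function(affinity)) {
    return(affinity(peptides, alleles))
  }
  key <- paste(peptides, alleles, sep = "|")
  tab_key <- paste(affinity$peptide, affinity$allele, sep = "|")
  idx <- match(key, tab_key)
  if (anyNA(idx)) {
    missing <- unique(key[is.na(idx)])
    abort(sprintf(
      "no affinity entry for %d peptide/allele pair(s), e.g. %s",
      length(missing),
      paste(head(sub("\\|", " on ", missing), 3), collapse = "; ")))
  }
  affinity$ic50_nM[idx]
}

#' Apply the neoantigen binding/expression filter
#'
#' A mutant peptide is called a neoantigen for an allele when the mutant
#' IC50 is below 500 nM (strong binder), the wild-type IC50 on the same
#' allele is above 500 nM (the parental peptide binds weakly), and the
#' variant's gene is expressed (> 0) in that sample. IC50 of exactly 500 nM
#' fails both inequalities.
#'
#' @param pairs Peptide-pair tibble from [peptide_pairs()] or
#'   [mutant_windows()] (the latter needs `sample_id`/`gene` columns added).
#' @param alleles Character vector of HLA alleles to test (at most 6 in the
#'   intended use; more are allowed).
#' @param affinity Either an affinity tibble (`peptide`, `allele`,
#'   `ic50_nM`) covering every queried pair, or a predictor
#'   `function(peptide, allele) -> IC50`.
#' @param em Expression matrix used for the expression gate.
#' @param ic50_cut Binding threshold in nM, default 500.
#' @return The pairs tibble expanded to one row per pair x allele with
#'   `mut_ic50`, `wt_ic50`, `expressed`, `is_neoantigen`.
#' @export
call_neoantigens <- function(pairs, alleles, affinity, em, ic50_cut = 500) {
  if (nrow(pairs) == 0L) {
    return(mutate(pairs, allele = character(), mut_ic50 = double(),
                  wt_ic50 = double(), expressed = logical(),
                  is_neoantigen = logical()))
  }
  values <- if (inherits(em, "expr_matrix")) em$values else em
  calls <- tidyr::crossing(pairs, allele = alleles)
  calls$mut_ic50 <- resolve_affinity(calls$mut_peptide, calls$allele, affinity)
  calls$wt_ic50 <- resolve_affinity(calls$wt_peptide, calls$allele, affinity)
  missing_genes <- setdiff(unique(calls$gene), rownames(values))
  if (length(missing_genes) > 0L) {
    abort(sprintf("gene(s) absent from expression matrix: %s",
                  paste(head(missing_genes, 5), collapse = ", ")))
  }
  missing_samples <- setdiff(unique(calls$sample_id), colnames(values))
  if (length(missing_samples) > 0L) {
    abort(sprintf("sample(s) absent from expression matrix: %s",
                  paste(head(missing_samples, 5), collapse = ", ")))
  }
  expr_val <- values[cbind(match(calls$gene, rownames(values)),
                           match(calls$sample_id, colnames(values)))]
  calls$expressed <- expr_val > 0
  calls$is_neoantigen <- calls$mut_ic50 < ic50_cut &
    calls$wt_ic50 > ic50_cut & calls$expressed
  calls
}

#' Per-sample neoantigen burden
#'
#' @param calls Call tibble from [call_neoantigens()].
#' @param unit `"peptide"` counts distinct mutant peptides passing for at
#'   least one allele; `"peptide_allele"` counts passing (peptide, allele)
#'   pairs.
#' @param samples Optional sample identifiers forced into the output with
#'   burden 0.
#' @return Tibble with `sample_id` and `n_neoantigens`.
#' @export
neoantigen_burden <- function(calls, unit = c("peptide", "peptide_allele"),
                              samples = NULL) {
  unit <- match.arg(unit)
  pass <- calls[calls$is_neoantigen, , drop = FALSE]
  keys <- if (unit == "peptide") c("sample_id", "mut_peptide") else
    c("sample_id", "mut_peptide", "allele")
  counts <- pass[keys] |> distinct() |>
    count(.data$sample_id, name = "n_neoantigens")
  ids <- union(samples %||% character(), unique(calls$sample_id))
  tibble(sample_id = ids) |>
    left_join(counts, by = "sample_id") |>
    mutate(n_neoantigens = ifelse(is.na(.data$n_neoantigens), 0L,
                                  as.integer(.data$n_neoantigens)))
}

#' Export mutant peptides as FASTA
#'
#' Writes the mutant 9-mers in the FASTA form used as the intermediate of
#' MHC-binding pipelines, one record per (sample, gene, position, window).
#'
#' @param pairs Peptide-pair tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(pairs, path) {
  ids <- sprintf("%s_%s_p%d_w%d", pairs$sample_id, pairs$gene,
                 pairs$protein_pos, pairs$window_start)
  write_protein_fasta(setNames(pairs$mut_peptide, ids), path)
}
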