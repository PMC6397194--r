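#' Single-sample gene-set enrichment score
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic over one sample's gene
#' ranking. Genes are ordered by decreasing z-score; at each gene in the set
#' (a "hit") the running sum gains `|z|^alpha / sum(|z_hits|^alpha)`, at
#' each miss it loses `1 / (N - N_hits)`; the score is the signed maximum
#' deviation from zero. With `alpha = 0` the score depends only on ranks.
#'
#' @param z Named numeric vector of per-sample z-scores (one sample, all
#'   genes).
#' @param gene_set Character vector of gene symbols.
#' @param alpha Weight exponent, default 1.
#' @return Enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(z, gene_set, alpha = 1) {
  if (is.null(names(z))) abort("`z` must be named by gene")
  ord <- order(z, decreasing = TRUE)
  zs <- z[ord]
  hit <- names(zs) %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) {
    abort("gene set has no overlap with the ranked genes")
  }
  if (nh == length(zs)) {
    abort("gene set covers every ranked gene; enrichment undefined")
  }
  es_from_hits(abs(zs)^alpha, hit)
}

# core running-sum given sorted weights and a hit indicator
es_from_hits <- function(w, hit) {
  N <- length(w)
  nh <- sum(hit)
  step <- rep.int(-1 / (N - nh), N)
  sw <- sum(w[hit])
  step[hit] <- if (sw > 0) w[hit] / sw else 1 / nh
  r <- cumsum(step)
  r[which.max(abs(r))]
}

# B null scores from random same-size gene sets over sorted weights
null_es <- function(w, set_size, B) {
  N <- length(w)
  vapply(seq_len(B), function(b) {
    hit <- logical(N)
    hit[sample.int(N, set_size)] <- TRUE
    es_from_hits(w, hit)
  }, 0)
}

#' Permutation p-value for an enrichment score
#'
#' One-sided p-value against a null of random gene sets of the same size
#' drawn from the same ranking: `p = (1 + #{null ES >= observed}) / (B + 1)`.
#' Sample-label permutation is unavailable for a single-sample statistic, so
#' the gene-set null stands in for it.
#'
#' @param es_observed Observed enrichment score.
#' @param z Named z-score vector of the sample.
#' @param set_size Number of set genes present in the ranking.
#' @param B Number of null draws (>= 100).
#' @param alpha Weight exponent, default 1.
#' @return Permutation p-value in (0, 1].
#' @export
permutation_p <- function(es_observed, z, set_size, B = 1000L, alpha = 1) {
  if (B < 100L) abort("B must be at least 100")
  if (set_size > length(z)) abort("set_size exceeds the number of ranked genes")
  w <- abs(z[order(z, decreasing = TRUE)])^alpha
  nulls <- null_es(w, set_size, B)
  (1 + sum(nulls >= es_observed)) / (B + 1)
}

#' Call immune cell infiltration per sample
#'
#' For each sample and metagene set, computes the enrichment score of the
#' sample's cohort z-score ranking, a permutation p-value against random
#' same-size gene sets, and a Storey q-value; a cell type is called
#' infiltrating when q is at or below `q_cut` (10% by default). Only
#' positive enrichment can be called (the null is one-sided). Null draws
#' are shared across sets of equal size within a sample, and the whole
#' table is reproducible under a fixed seed.
#'
#' @param em Expression matrix (z-scores computed on the fly if absent).
#' @param sets Named list of metagene sets (see [read_gmt()]).
#' @param q_cut FDR threshold for the infiltration call, default 0.10.
#' @param B Null draws per sample/set size, default 1000.
#' @param alpha Weight exponent of the enrichment statistic.
#' @param seed Optional integer seed for the permutation null.
#' @param q_batch `"sample"` computes q across cell types within each sample
#'   (default); `"global"` pools all sample-by-cell-type tests.
#' @param min_overlap Minimum number of set genes that must be present in
#'   the matrix; sets below it raise an error.
#' @return Long tibble: `sample_id`, `cell_type`, `n_genes`, `es`, `p`,
#'   `q`, `infiltrated`.
#' @export
call_infiltration <- function(em, sets, q_cut = 0.10, B = 1000L, alpha = 1,
                              seed = NULL, q_batch = c("sample", "global"),
                              min_overlap = 1L) {
  q_batch <- match.arg(q_batch)
  z <- zscores_of(em)
  if (ncol(z) < 2L) abort("infiltration calling needs at least 2 samples")
  genes <- rownames(z)
  overlaps <- lapply(sets, intersect, x = genes)
  sizes <- vapply(overlaps, length, 0L)
  if (any(sizes < min_overlap)) {
    abort(sprintf("gene set(s) with no usable overlap: %s",
                  paste(names(sets)[sizes < min_overlap], collapse = ", ")))
  }
  run <- function() {
    per_sample <- lapply(colnames(z), function(s) {
      zi <- z[, s]
      ord <- order(zi, decreasing = TRUE)
      nm <- genes[ord]
      w <- abs(zi[ord])^alpha
      es <- vapply(overlaps, function(g) es_from_hits(w, nm %in% g), 0)
      nulls <- lapply(setNames(nm = unique(sizes)), function(k)
        null_es(w, k, B))
      p <- vapply(seq_along(es), function(i) {
        (1 + sum(nulls[[as.character(sizes[i])]] >= es[i])) / (B + 1)
      }, 0)
      tibble(sample_id = s, cell_type = names(sets),
             n_genes = unname(sizes), es = unname(es), p = p)
    })
    bind_rows(per_sample)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- if (q_batch == "sample") {
    out |> group_by(.data$sample_id) |>
      mutate(q = storey_q(.data$p)) |> ungroup()
  } else {
    mutate(out, q = storey_q(.data$p))
  }
  mutate(out, infiltrated = .data$q <= q_cut)
}

#' Co-infiltration correlation between cell types
#'
#' Pearson correlation of the binary infiltration indicators (the phi
#' coefficient) between every pair of cell types, with pairwise p-values.
#' Pairs involving a constant indicator are reported with missing r/p.
#'
#' @param calls Infiltration table from [call_infiltration()].
#' @return Tibble with `cell_type_1`, `cell_type_2`, `r`, `p` for every
#'   unordered pair; the wide indicator matrix is attached as attribute
#'   `"indicators"`.
#' @export
coinfiltration_matrix <- function(calls) {
  wide <- calls |>
    select("sample_id", "cell_type", "infiltrated") |>
    tidyr::pivot_wider(names_from = "cell_type",
                       values_from = "infiltrated")
  mat <- as.matrix(wide[, -1, drop = FALSE]) * 1
  rownames(mat) <- wide$sample_id
  if (ncol(mat) < 2L) abort("need at least 2 cell types")
  if (nrow(mat) < 3L) abort("need at least 3 samples")
  pairs <- utils::combn(colnames(mat), 2)
  res <- apply(pairs, 2, function(pr) {
    a <- mat[, pr[1]]; b <- mat[, pr[2]]
    if (sd(a) == 0 || sd(b) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(cor.test(a, b, method = "pearson"))
    c(unname(ct$estimate), ct$p.value)
  })
  out <- tibble(cell_type_1 = pairs[1, ], cell_type_2 = pairs[2, ],
                r = res[1, ], p = res[2, ])
  attr(out, "indicators") <- mat
  out
}
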