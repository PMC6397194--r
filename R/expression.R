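#' Expression matrix container
#'
#' A light wrapper around a genes-by-samples numeric matrix of normalized
#' expression values, optionally carrying the per-gene cohort z-score view
#' computed by [compute_zscores()].
#'
#' @param values Numeric matrix, rownames = gene symbols (uppercased on
#'   construction), colnames = sample identifiers.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `zscores` (NULL until computed) and `zero_variance` (logical per gene).
#' @export
expr_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrix needs gene rownames and sample colnames")
  }
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values))) {
    format_error("duplicate gene identifiers in expression matrix")
  }
  if (anyDuplicated(colnames(values))) {
    format_error("duplicate sample identifiers in expression matrix")
  }
  structure(list(values = values, zscores = NULL, zero_variance = NULL),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples; z-scores %s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$zscores)) "not computed" else "computed"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Standardize each gene across the cohort
#'
#' Computes the per-gene z-score view: `z[g, s] = (x[g, s] - mean(x[g, ])) /
#' sd(x[g, ])` with the sample (n-1) standard deviation. Genes with zero
#' variance get z = 0 and are flagged in `zero_variance` so that downstream
#' median comparisons stay defined.
#'
#' @param em An [expr_matrix()] object (or plain matrix).
#' @return The `expr_matrix` with `zscores` and `zero_variance` filled in.
#' @export
compute_zscores <- function(em) {
  if (is.matrix(em)) em <- expr_matrix(em)
  x <- em$values
  if (ncol(x) < 2L) {
    abort("z-scores are undefined with fewer than 2 samples")
  }
  mu <- rowMeans(x)
  sdev <- apply(x, 1, sd)
  zero <- sdev == 0 | !is.finite(sdev)
  sdev[zero] <- 1
  z <- (x - mu) / sdev
  z[zero, ] <- 0
  em$zscores <- z
  em$zero_variance <- setNames(zero, rownames(x))
  em
}

# z-scores, computing them on the fly if absent
zscores_of <- function(em) {
  if (is.matrix(em)) em <- expr_matrix(em)
  if (is.null(em$zscores)) em <- compute_zscores(em)
  em$zscores
}

#' Convert an expression matrix to a long tibble
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `sample_id`, `value` and, when
#'   computed, `zscore`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  out <- as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "value")
  if (!is.null(x$zscores)) {
    zl <- as_tibble(x$zscores, rownames = "gene") |>
      tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "zscore")
    out <- left_join(out, zl, by = c("gene", "sample_id"))
  }
  out
}
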