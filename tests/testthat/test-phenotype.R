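mk_infiltration <- function(cd4, cd8, ids = sprintf("S%02d", seq_along(cd4))) {
  dplyr::bind_rows(
    tibble::tibble(sample_id = ids, cell_type = "Act_CD4", infiltrated = cd4),
    tibble::tibble(sample_id = ids, cell_type = "Act_CD8", infiltrated = cd8))
}

test_that("activated T flag follows the chosen convention", {
  calls <- mk_infiltration(cd4 = c(TRUE, FALSE, TRUE, FALSE),
                           cd8 = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(activated_t_flag(calls, "either")$act_t_infiltrated,
               c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(activated_t_flag(calls, "both")$act_t_infiltrated,
               c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(activated_t_flag(calls, "cd4")$act_t_infiltrated,
               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(activated_t_flag(calls, "cd8")$act_t_infiltrated,
               c(FALSE, FALSE, TRUE, TRUE))
  expect_error(activated_t_flag(calls, cd4 = "Missing_Type"), "missing")
})

test_that("group assignment implements the 2x2 scheme and partitions the cohort", {
  expect_equal(as.character(assign_group(c(FALSE, TRUE, FALSE, TRUE),
                                         c(FALSE, FALSE, TRUE, TRUE))),
               c("I", "II", "III", "IV"))
  set.seed(6)
  rv <- runif(100) < 0.4
  inf <- runif(100) < 0.5
  g <- assign_group(rv, inf)
  expect_equal(sum(table(g)), 100)
  expect_error(assign_group(TRUE, c(TRUE, FALSE)), "equal length")
  expect_error(assign_group(c(TRUE, NA), c(TRUE, FALSE)), "defined")
})

test_that("combined score confers points per the scoring rule", {
  # 4 samples; TGFB1 z medians split them cleanly
  em <- toy_expr(c(1, 2, 3, 4,
                   4, 3, 2, 1,
                   5, 5, 6, 6), c("TGFB1", "WNT2", "OTHER"),
                 paste0("S", 1:4))
  status <- tibble::tibble(sample_id = paste0("S", 1:4),
                           any_variant = c(FALSE, TRUE, TRUE, FALSE))
  sc <- combined_score(em, status)
  # S1: TGFB1 below, WNT2 above, no variant -> 2 (high)
  # S2: below/above median? TGFB1 z2 < median? values 1..4 median 2.5 -> S2 low
  expect_equal(sc$combined_score, c(2L, 1L, 1L, 2L))
  expect_equal(as.character(sc$score_class), c("high", "low", "low", "high"))
  # extremes of the rule
  st0 <- tibble::tibble(sample_id = paste0("S", 1:4),
                        any_variant = c(FALSE, FALSE, TRUE, TRUE))
  sc0 <- combined_score(em, st0)
  expect_equal(sc0$combined_score[4], 1L)  # variant, TGFB1 above, WNT2 below
  expect_error(combined_score(em, status, tgfb1 = "NOPE"), "NOPE")
})

test_that("combined score is antitone in variant status and monotone in z", {
  set.seed(33)
  m <- matrix(rexp(80), nrow = 2,
              dimnames = list(c("TGFB1", "WNT2"), sprintf("S%02d", 1:40)))
  em <- compute_zscores(expr_matrix(m))
  base <- tibble::tibble(sample_id = colnames(m), any_variant = FALSE)
  with_var <- dplyr::mutate(base, any_variant = TRUE)
  expect_true(all(combined_score(em, base)$combined_score >=
                    combined_score(em, with_var)$combined_score))
})

test_that("exactly-median z-scores contribute no points", {
  # 3 samples with symmetric values: middle sample sits exactly at the median
  em <- toy_expr(c(1, 2, 3, 1, 2, 3), c("TGFB1", "WNT2"), paste0("S", 1:3))
  status <- tibble::tibble(sample_id = paste0("S", 1:3), any_variant = TRUE)
  sc <- combined_score(em, status)
  expect_equal(sc$combined_score, c(0L, 0L, 2L))
})

test_that("panel comparison finds a planted group shift and reports degeneracy", {
  set.seed(44)
  n_per <- 50
  ids <- sprintf("S%03d", 1:(4 * n_per))
  groups <- tibble::tibble(sample_id = ids,
                           group = rep(c("I", "II", "III", "IV"),
                                       each = n_per))
  vals <- matrix(rnorm(3 * length(ids)), nrow = 3,
                 dimnames = list(c("TGFB1", "WNT2", "NULLG"), ids))
  vals["TGFB1", groups$group == "II"] <-
    vals["TGFB1", groups$group == "II"] + 1.5
  em <- compute_zscores(expr_matrix(exp(vals)))
  res <- panel_comparison(groups, em, c("TGFB1", "NULLG", "ABSENT"))
  ii_iv <- res$pairwise[res$pairwise$gene == "TGFB1" &
                          res$pairwise$comparison %in% c("IV-II", "II-IV"), ]
  expect_lt(ii_iv$p_adj, 0.01)
  expect_gt(res$anova$p[res$anova$gene == "NULLG"], 0.001)
  expect_equal(res$anova$note[res$anova$gene == "ABSENT"], "gene absent")
  # single gene, two groups: ANOVA p equals the t-test p
  g2 <- dplyr::filter(groups, group %in% c("I", "II"))
  res2 <- panel_comparison(g2, em, "TGFB1")
  z <- zscores <- compute_zscores(em)$zscores["TGFB1", g2$sample_id]
  tt <- two_sample_t(z[g2$group == "I"], z[g2$group == "II"])
  expect_equal(res2$anova$p[1], tt$p, tolerance = 1e-9)
})

test_that("signature table recovers planted differential genes and honors permutation", {
  set.seed(45)
  n <- 60
  ids <- sprintf("S%03d", 1:(2 * n))
  labels <- tibble::tibble(sample_id = ids,
                           group = rep(c("low", "high"), each = n))
  genes <- sprintf("G%02d", 1:50)
  vals <- matrix(rnorm(50 * 2 * n), nrow = 50, dimnames = list(genes, ids))
  vals[1:5, labels$group == "high"] <- vals[1:5, labels$group == "high"] + 1
  em <- compute_zscores(expr_matrix(exp(vals)))
  sig <- signature_table(labels, em)
  top5 <- sig$gene[order(sig$q)][1:5]
  expect_setequal(top5, genes[1:5])
  # permuting labels destroys the signal
  set.seed(46)
  perm <- labels
  perm$group <- sample(perm$group)
  sig_perm <- signature_table(perm, em)
  expect_lt(max(-log10(sig_perm$q), na.rm = TRUE),
            max(-log10(sig$q), na.rm = TRUE))
})

test_that("subtype association flags an aligned level and controls the null", {
  set.seed(47)
  n <- 160
  ids <- sprintf("S%03d", 1:n)
  subtype <- rep(c("basal", "classical", "primitive", "secretory"),
                 each = n / 4)
  aligned <- subtype == "secretory"
  flags <- tibble::tibble(sample_id = ids, mmr_variant = aligned)
  labels <- tibble::tibble(sample_id = ids, subtype = subtype)
  res <- subtype_association(flags, labels)
  expect_lt(res$q[res$level == "secretory"], 1e-6)
  # independent flag: small q only rarely
  nulls <- vapply(1:40, function(i) {
    f2 <- dplyr::mutate(flags, mmr_variant = sample(c(TRUE, FALSE), n,
                                                    replace = TRUE))
    min(subtype_association(f2, labels)$q, na.rm = TRUE)
  }, 0)
  expect_gte(mean(nulls >= 0.05), 0.75)
  one_level <- dplyr::mutate(labels, subtype = "basal")
  expect_error(subtype_association(flags, one_level), "2 subtype levels")
})

test_that("build_phenotype joins stages into one row per sample", {
  status <- tibble::tibble(sample_id = c("S1", "S2"),
                           hr_variant = c(TRUE, FALSE),
                           mmr_variant = FALSE, pole_variant = FALSE,
                           any_variant = c(TRUE, FALSE),
                           affected_gene_count = c(1L, 0L), tmb = c(300L, 120L))
  act <- tibble::tibble(sample_id = c("S1", "S2"),
                        act_t_infiltrated = c(FALSE, TRUE))
  sc <- tibble::tibble(sample_id = c("S1", "S2"), combined_score = c(1L, 3L),
                       score_class = factor(c("low", "high"),
                                            levels = c("low", "high")))
  ph <- build_phenotype(status, act, sc)
  expect_equal(nrow(ph), 2)
  expect_equal(as.character(ph$group), c("II", "III"))
})
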