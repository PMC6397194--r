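test_that("mutant_windows enumerates clipped k-mer windows around the site", {
  prot <- paste(rep(LETTERS[1:20], 1), collapse = "")  # ABCDEFGHIJKLMNOPQRST
  w <- mutant_windows(prot, 10, "J", "A")
  expect_equal(nrow(w), 9)
  expect_equal(w$window_start, 2:10)
  # boundary: mutation at position 1 leaves a single window
  w1 <- mutant_windows(prot, 1, "A", "V")
  expect_equal(nrow(w1), 1)
  expect_equal(w1$window_start, 1L)
  # length-9 protein: single window equal to the full sequence
  w9 <- mutant_windows("ACDEFGHIK", 5, "F", "Y")
  expect_equal(nrow(w9), 1)
  expect_equal(w9$wt_peptide, "ACDEFGHIK")
  expect_equal(w9$mut_peptide, "ACDEYGHIK")
})

test_that("window counts match the closed form over random (L, pos) cases", {
  set.seed(23)
  for (i in 1:200) {
    L <- sample(9:60, 1)
    pos <- sample(L, 1)
    prot <- paste(sample(c("A", "C", "D", "E", "G"), L, replace = TRUE),
                  collapse = "")
    ref <- substr(prot, pos, pos)
    alt <- setdiff(c("A", "C", "D", "E", "G", "W"), ref)[1]
    w <- mutant_windows(prot, pos, ref, alt)
    expect_equal(nrow(w), min(pos, L - 8) - max(1, pos - 8) + 1)
    # every pair differs at exactly one residue, and it is the mutated one
    diffs <- mapply(function(a, b) {
      which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }, w$wt_peptide, w$mut_peptide)
    expect_true(all(diffs == pos - w$window_start + 1))
  }
})

test_that("mutant_windows validates its inputs", {
  expect_error(mutant_windows("ACDEFGHIK", 3, "Q", "A"), "mismatch")
  expect_error(mutant_windows("ACDEFGHIK", 20, "A", "V"), "outside")
  expect_error(mutant_windows("ACDEF", 2, "C", "A"), "exceeds")
})

test_that("the neoantigen filter applies the three-way conjunction with strict bounds", {
  pair <- mutant_windows("ACDEFGHIKL", 5, "F", "Y") |>
    dplyr::mutate(sample_id = "S1", gene = "NEO1", protein_pos = 5L,
                  .before = 1)
  em <- toy_expr(c(5.2, 5.2, 0, 0), c("NEO1", "NEO2"), c("S1", "S2"))
  aff_case <- function(mut, wt) {
    function(peptide, allele) {
      ifelse(peptide %in% pair$mut_peptide, mut, wt)
    }
  }
  call1 <- call_neoantigens(pair, "HLA-A*02:01", aff_case(400, 600), em)
  expect_true(all(call1$is_neoantigen))
  # parental peptide also binds -> not a neoantigen
  call2 <- call_neoantigens(pair, "HLA-A*02:01", aff_case(400, 450), em)
  expect_false(any(call2$is_neoantigen))
  # expression gate: same variant in an unexpressed sample fails
  pair0 <- dplyr::mutate(pair, sample_id = "S2", gene = "NEO2")
  em0 <- toy_expr(c(5.2, 5.2, 0, 0), c("NEO1", "NEO2"), c("S1", "S2"))
  call3 <- call_neoantigens(pair0, "HLA-A*02:01", aff_case(400, 600), em0)
  expect_true(all(call3$expressed == FALSE))
  expect_false(any(call3$is_neoantigen))
  # exactly 500 nM fails both strict inequalities
  call4 <- call_neoantigens(pair, "HLA-A*02:01", aff_case(500, 600), em)
  expect_false(any(call4$is_neoantigen))
  call5 <- call_neoantigens(pair, "HLA-A*02:01", aff_case(400, 500), em)
  expect_false(any(call5$is_neoantigen))
})

test_that("missing affinity entries are an error, never a silent default", {
  pair <- mutant_windows("ACDEFGHIK", 5, "F", "Y") |>
    dplyr::mutate(sample_id = "S1", gene = "NEO1", protein_pos = 5L,
                  .before = 1)
  em <- toy_expr(c(1, 1, 1, 1), c("NEO1", "X"), c("S1", "S2"))
  aff <- tibble::tibble(peptide = pair$mut_peptide, allele = "HLA-A*02:01",
                        ic50_nM = 100)  # wild-type entries absent
  expect_error(call_neoantigens(pair, "HLA-A*02:01", aff, em),
               "no affinity entry")
})

test_that("burden counts distinct peptides or peptide-allele pairs", {
  calls <- tibble::tibble(
    sample_id = "S1",
    mut_peptide = c("AAAAAAAAK", "AAAAAAAAK", "CCCCCCCCK"),
    allele = c("A1", "A2", "A1"),
    is_neoantigen = c(TRUE, TRUE, FALSE)
  )
  expect_equal(neoantigen_burden(calls, unit = "peptide")$n_neoantigens, 1L)
  expect_equal(neoantigen_burden(calls, unit = "peptide_allele")$n_neoantigens,
               2L)
  none <- dplyr::mutate(calls, is_neoantigen = FALSE)
  expect_equal(neoantigen_burden(none)$n_neoantigens, 0L)
})

test_that("burden is monotone in the allele list", {
  set.seed(9)
  prot <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K"), 40,
                       replace = TRUE), collapse = "")
  pairs <- dplyr::bind_rows(lapply(c(5, 12, 30), function(pos) {
    ref <- substr(prot, pos, pos)
    alt <- setdiff(c("L", "M", "N"), ref)[1]
    mutant_windows(prot, pos, ref, alt) |>
      dplyr::mutate(sample_id = "S1", gene = "NEO1", protein_pos = pos,
                    .before = 1)
  }))
  em <- toy_expr(c(3, 3), "NEO1", c("S1", "S2"))
  alleles <- paste0("HLA-", 1:4)
  burdens <- vapply(seq_along(alleles), function(k) {
    calls <- call_neoantigens(pairs, alleles[1:k], toy_predictor, em)
    neoantigen_burden(calls)$n_neoantigens
  }, 0L)
  expect_true(all(diff(burdens) >= 0))
  pa <- vapply(seq_along(alleles), function(k) {
    calls <- call_neoantigens(pairs, alleles[1:k], toy_predictor, em)
    neoantigen_burden(calls, unit = "peptide_allele")$n_neoantigens
  }, 0L)
  expect_true(all(diff(pa) >= 0))
})

test_that("toy predictor is deterministic, residue-sensitive and spans 500 nM", {
  p <- c("ACDEFGHIK", "ACDEFGHIL", "WCDEFGHIK")
  a <- "HLA-A*02:01"
  expect_identical(toy_predictor(p, a), toy_predictor(p, a))
  expect_true(toy_predictor(p[1], a) != toy_predictor(p[2], a))
  expect_true(toy_predictor(p[1], a) != toy_predictor(p[1], "HLA-B*07:02"))
  expect_error(toy_predictor("SHORT", a), "9-mer")
  set.seed(2)
  peps <- vapply(1:200, function(i) {
    paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"), 9,
                 replace = TRUE), collapse = "")
  }, "")
  scores <- toy_predictor(peps, a)
  expect_true(all(scores > 0))
  expect_gt(sum(scores < 500), 10)
  expect_gt(sum(scores > 500), 10)
})

test_that("raising the wild-type cut from 500 to 1000 nM only removes calls", {
  set.seed(31)
  prot <- paste(sample(aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                               "L", "M"), 60, replace = TRUE), collapse = "")
  pairs <- dplyr::bind_rows(lapply(seq(5, 55, by = 5), function(pos) {
    ref <- substr(prot, pos, pos)
    mutant_windows(prot, pos, ref, setdiff(aa, ref)[1]) |>
      dplyr::mutate(sample_id = "S1", gene = "NEO1", protein_pos = pos,
                    .before = 1)
  }))
  em <- toy_expr(c(3, 3), "NEO1", c("S1", "S2"))
  alleles <- paste0("HLA-", 1:3)
  calls <- call_neoantigens(pairs, alleles, toy_predictor, em)
  # anti-monotone in the wild-type threshold: stricter wt cut, fewer calls
  relaxed <- calls$mut_ic50 < 500 & calls$wt_ic50 > 500 & calls$expressed
  strict <- calls$mut_ic50 < 500 & calls$wt_ic50 > 1000 & calls$expressed
  expect_true(all(strict <= relaxed))
  expect_equal(relaxed, calls$is_neoantigen)
})
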