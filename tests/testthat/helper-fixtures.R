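# fixture builders shared across test files

# a single variant row with overridable fields
variant_row <- function(sample_id = "S1", gene = "TP53",
                        classification = "missense", protein_pos = NA,
                        ref_aa = NA, alt_aa = NA, sift = NA, cadd = NA,
                        intron_offset = NA) {
  tibble::tibble(sample_id = sample_id, gene = gene,
                 classification = classification,
                 protein_pos = as.integer(protein_pos),
                 ref_aa = as.character(ref_aa),
                 alt_aa = as.character(alt_aa),
                 sift = as.numeric(sift), cadd = as.numeric(cadd),
                 intron_offset = as.numeric(intron_offset))
}

# write a minimal TCGA-style MAF to a temp file
write_tmp_maf <- function(rows) {
  path <- withr::local_tempfile(fileext = ".maf",
                                .local_envir = parent.frame())
  writeLines(c(
    paste("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification",
          "Protein_Change", "SIFT", "CADD", sep = "\t"),
    rows), path)
  path
}

# small expression matrix with named genes/samples
toy_expr <- function(values, genes, samples) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  repairimmune::expr_matrix(m)
}

# independent brute-force re-scan of the deleteriousness rules, written
# directly from the filter definition (no package code)
brute_force_deleterious <- function(v, sift_cut = 0.05, cadd_cut = 20) {
  out <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    cls <- v$classification[i]
    if (cls %in% c("nonsense", "frameshift_indel", "inframe_indel")) {
      out[i] <- TRUE
    } else if (cls == "splice") {
      off <- v$intron_offset[i]
      out[i] <- is.na(off) || (off < 0 && abs(off) <= 2)
    } else if (cls == "missense") {
      s <- v$sift[i]; c <- v$cadd[i]
      out[i] <- (!is.na(s) && s < sift_cut) || (!is.na(c) && c > cadd_cut)
    } else {
      out[i] <- FALSE
    }
  }
  out
}
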