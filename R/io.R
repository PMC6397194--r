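#' Variant classes recognised by the pipeline
#'
#' Internal enumeration used for the `classification` column of a somatic
#' variant table: missense, nonsense, frameshift_indel, inframe_indel,
#' splice, silent, other.
#'
#' @return Character vector of the seven recognised classes.
#' @export
variant_classes <- function() {
  c("missense", "nonsense", "frameshift_indel", "inframe_indel",
    "splice", "silent", "other")
}

# TCGA/cBioPortal Variant_Classification values -> internal classes.
# Anything unmapped becomes "other".
tcga_class_map <- c(
  "Missense_Mutation"   = "missense",
  "Nonsense_Mutation"   = "nonsense",
  "Frame_Shift_Del"     = "frameshift_indel",
  "Frame_Shift_Ins"     = "frameshift_indel",
  "In_Frame_Del"        = "inframe_indel",
  "In_Frame_Ins"        = "inframe_indel",
  "Splice_Site"         = "splice",
  "Splice_Region"       = "splice",
  "Silent"              = "silent",
  "Nonstop_Mutation"    = "other",
  "Translation_Start_Site" = "other",
  "3'UTR" = "other", "5'UTR" = "other",
  "3'Flank" = "other", "5'Flank" = "other",
  "Intron" = "other", "RNA" = "other", "IGR" = "other"
)

# inverse mapping used when writing MAF back out
tcga_class_out <- c(
  missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
  frameshift_indel = "Frame_Shift_Del", inframe_indel = "In_Frame_Del",
  splice = "Splice_Site", silent = "Silent", other = "Other"
)

#' MAF column-name dialect
#'
#' cBioPortal and GDC exports of Mutation Annotation Format files disagree on
#' column names; the dialect maps the columns this package needs onto the
#' names found in a particular export. Defaults follow the TCGA conventions.
#'
#' @param sample,gene,classification Required column names.
#' @param protein_change Candidate column names for the protein change
#'   (HGVSp-short style, e.g. `p.A123T`); the first one present is used.
#' @param sift,cadd,intron_offset Optional score/annotation columns.
#' @return A named list usable as the `dialect` argument of [read_maf()].
#' @export
maf_dialect <- function(sample = "Tumor_Sample_Barcode",
                        gene = "Hugo_Symbol",
                        classification = "Variant_Classification",
                        protein_change = c("Protein_Change", "HGVSp_Short"),
                        sift = "SIFT",
                        cadd = "CADD",
                        intron_offset = "Intron_Offset") {
  list(sample = sample, gene = gene, classification = classification,
       protein_change = protein_change, sift = sift, cadd = cadd,
       intron_offset = intron_offset)
}

parse_protein_change <- function(x) {
  # "p.A123T" -> pos 123, ref A, alt T; anything else -> NA fields
  m <- stringr::str_match(x, "^p\\.([A-Z])([0-9]+)([A-Z])$")
  tibble(
    protein_pos = suppressWarnings(as.integer(m[, 3])),
    ref_aa = m[, 2],
    alt_aa = m[, 4]
  )
}

#' Read a somatic variant table in MAF format
#'
#' Reads a tab-delimited Mutation Annotation Format file and returns one row
#' per somatic variant with the columns the downstream pipeline needs.
#' Unknown variant classifications map to `"other"`; missing SIFT/CADD
#' scores are left absent, never imputed; gene symbols are uppercased.
#'
#' @param path Path to a tab-delimited MAF file.
#' @param dialect Column-name mapping, see [maf_dialect()].
#' @return A tibble with columns `sample_id`, `gene`, `classification`,
#'   `protein_pos`, `ref_aa`, `alt_aa`, `sift`, `cadd`, `intron_offset`.
#' @export
read_maf <- function(path, dialect = maf_dialect()) {
  if (!file.exists(path)) format_error(sprintf("MAF file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  if (nrow(raw) == 0L) {
    warn("MAF file has no variant rows; returning an empty table")
    return(empty_variant_table())
  }
  for (col in c("sample", "gene", "classification")) {
    if (!dialect[[col]] %in% names(raw)) {
      format_error(sprintf("MAF is missing required column '%s' (%s)",
                           dialect[[col]], col))
    }
  }
  gene <- raw[[dialect$gene]]
  bad <- which(is.na(gene) | gene == "")
  if (length(bad) > 0L) {
    format_error(sprintf("MAF row %d has no gene symbol", bad[1]))
  }
  cls_raw <- raw[[dialect$classification]]
  cls <- ifelse(cls_raw %in% variant_classes(), cls_raw,
                unname(tcga_class_map[cls_raw]))
  cls[is.na(cls)] <- "other"

  pc_col <- intersect(dialect$protein_change, names(raw))[1]
  pc <- if (!is.na(pc_col)) parse_protein_change(raw[[pc_col]]) else
    tibble(protein_pos = NA_integer_, ref_aa = NA_character_,
           alt_aa = NA_character_)[rep(1, nrow(raw)), ]

  num_col <- function(nm) {
    if (!is.null(nm) && nm %in% names(raw)) {
      suppressWarnings(as.numeric(raw[[nm]]))
    } else rep(NA_real_, nrow(raw))
  }
  out <- tibble(
    sample_id = raw[[dialect$sample]],
    gene = toupper(gene),
    classification = cls,
    protein_pos = pc$protein_pos,
    ref_aa = pc$ref_aa,
    alt_aa = pc$alt_aa,
    sift = num_col(dialect$sift),
    cadd = num_col(dialect$cadd),
    intron_offset = num_col(dialect$intron_offset)
  )
  validate_variants(out)
  out
}

empty_variant_table <- function() {
  tibble(sample_id = character(), gene = character(),
         classification = character(), protein_pos = integer(),
         ref_aa = character(), alt_aa = character(),
         sift = double(), cadd = double(), intron_offset = double())
}

validate_variants <- function(v) {
  if (any(!is.na(v$protein_pos) & v$protein_pos < 1L)) {
    format_error("protein_pos must be >= 1 where present")
  }
  if (any(!is.na(v$sift) & (v$sift < 0 | v$sift > 1))) {
    format_error("SIFT scores must lie in [0, 1]")
  }
  bad_mis <- v$classification == "missense" &
    !is.na(v$ref_aa) & !is.na(v$alt_aa) & v$ref_aa == v$alt_aa
  if (any(bad_mis)) {
    format_error("missense variant with identical reference and alternate residue")
  }
  invisible(v)
}

#' Write a somatic variant table as a MAF file
#'
#' Inverse of [read_maf()] under the default TCGA dialect; round-trips all
#' fields the reader parses.
#'
#' @param variants Variant tibble as returned by [read_maf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(variants, path) {
  out <- tibble(
    Hugo_Symbol = variants$gene,
    Tumor_Sample_Barcode = variants$sample_id,
    Variant_Classification = unname(tcga_class_out[variants$classification]),
    Protein_Change = ifelse(
      is.na(variants$protein_pos) | is.na(variants$ref_aa) |
        is.na(variants$alt_aa), NA_character_,
      sprintf("p.%s%d%s", variants$ref_aa, variants$protein_pos,
              variants$alt_aa)),
    SIFT = variants$sift,
    CADD = variants$cadd,
    Intron_Offset = variants$intron_offset
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a genes-by-samples expression matrix
#'
#' Tab-delimited, first column gene symbols, header row of sample
#' identifiers. Duplicate gene rows are collapsed by their mean (with a
#' message); gene symbols are uppercased.
#'
#' @param path Path to the TSV file.
#' @return An [expr_matrix()] object (no z-scores yet; see
#'   [compute_zscores()]).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) format_error(sprintf("expression file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2L) format_error("expression file needs a gene column plus >= 1 sample")
  genes <- toupper(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  num <- matrix(num, nrow = nrow(vals), dimnames = dimnames(vals))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    format_error(sprintf(
      "non-numeric expression value '%s' at gene %s, sample %s",
      vals[bad[1, 1], bad[1, 2]], genes[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  rownames(num) <- genes
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    inform(sprintf("collapsing %d duplicated gene row(s) by mean: %s",
                   length(dup), paste(head(dup, 5), collapse = ", ")))
    num <- rowsum(num, group = genes) / as.vector(table(genes)[sort(unique(genes))])
    num <- num[match(unique(genes), rownames(num)), , drop = FALSE]
  }
  expr_matrix(num)
}

#' Write an expression matrix to TSV
#'
#' @param em An [expr_matrix()] object or plain matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  values <- if (inherits(em, "expr_matrix")) em$values else em
  df <- as_tibble(values, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then one gene per field. Gene
#' symbols are uppercased and de-duplicated within a set.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (set name -> genes).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) format_error(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3L)
  if (length(short) > 0L) {
    format_error(sprintf("GMT line %d has no genes", short[1]))
  }
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms)) {
    format_error(sprintf("duplicate gene-set name '%s' in GMT",
                         nms[duplicated(nms)][1]))
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- nms
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a peptide-allele binding affinity table
#'
#' TSV with columns `peptide`, `allele`, `ic50_nM`. Peptides are uppercased;
#' IC50 values must be positive.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `peptide`, `allele`, `ic50_nM`.
#' @export
read_affinity <- function(path) {
  if (!file.exists(path)) format_error(sprintf("affinity file not found: %s", path))
  tab <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  need <- c("peptide", "allele", "ic50_nM")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    format_error(sprintf("affinity table missing column '%s'", miss[1]))
  }
  tab$peptide <- toupper(tab$peptide)
  if (any(!is.na(tab$ic50_nM) & tab$ic50_nM <= 0)) {
    format_error("IC50 values must be > 0 nM")
  }
  tab[need]
}

#' Write a peptide-allele affinity table
#' @param affinity Tibble with `peptide`, `allele`, `ic50_nM`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_affinity <- function(affinity, path) {
  readr::write_tsv(affinity[c("peptide", "allele", "ic50_nM")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with `sample_id`, overall-survival (`os_time` days, `os_event` 0/1),
#' disease-free survival (`dfs_time`, `dfs_event`) and optional `subtype`
#' and `smoking` labels.
#'
#' @param path Path to the TSV file.
#' @return Tibble of clinical records.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) format_error(sprintf("clinical file not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(tab)) {
    format_error("clinical table missing column 'sample_id'")
  }
  for (col in intersect(c("os_time", "dfs_time"), names(tab))) {
    if (any(tab[[col]] < 0, na.rm = TRUE)) {
      format_error(sprintf("negative survival time in column '%s'", col))
    }
  }
  for (col in intersect(c("os_event", "dfs_event"), names(tab))) {
    tab[[col]] <- as.logical(tab[[col]])
  }
  tab
}

#' Write a clinical table
#' @param clinical Clinical tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  out <- clinical
  for (col in intersect(c("os_event", "dfs_event"), names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Records are keyed by the first whitespace-delimited token of the header.
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return Named character vector of uppercase protein sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) format_error(sprintf("FASTA file not found: %s", path))
  ss <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) format_error(
                   sprintf("could not parse FASTA: %s", conditionMessage(e))))
  if (length(ss) == 0L) format_error("no FASTA records found")
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write protein sequences to a FASTA file
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path, width = 60L) {
  ss <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
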