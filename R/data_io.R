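#' Sample design tables
#'
#' The design maps each mass-spectrometry sample to its membrane preparation
#' (`LDM`, low density microsomes, or `pHS`, post-high-speed supernatant),
#' its condition (`IgG` control immunoisolation, `basal` immunoprecipitate,
#' or `insulin`-stimulated immunoprecipitate) and a replicate index.
#'
#' @param design a data.frame with columns `sample_id`, `preparation`,
#'   `condition`, `replicate`.
#' @return the validated design data.frame, with `replicate` coerced to
#'   integer, invisibly classed `gsv_design`.
#' @details `(preparation, condition, replicate)` triples must be unique and
#'   every preparation present must contribute at least one IgG and one basal
#'   sample. Insulin samples are optional; without them the pipeline skips
#'   the responsiveness contrast.
#' @export
gsv_design <- function(design) {
  required <- c("sample_id", "preparation", "condition", "replicate")
  miss <- setdiff(required, names(design))
  if (length(miss)) .stopf("design table lacks column(s): %s", paste(miss, collapse = ", "))
  design <- as.data.frame(design)[required]
  design$sample_id <- as.character(design$sample_id)
  design$preparation <- as.character(design$preparation)
  design$condition <- as.character(design$condition)
  design$replicate <- as.integer(design$replicate)
  bad <- setdiff(design$preparation, .preparations)
  if (length(bad)) .stopf("unknown preparation(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(design$condition, .conditions)
  if (length(bad)) .stopf("unknown condition(s): %s", paste(bad, collapse = ", "))
  if (any(design$replicate < 1L)) .stopf("replicate indices must be positive")
  if (anyDuplicated(design$sample_id)) .stopf("duplicate sample_id in design")
  key <- paste(design$preparation, design$condition, design$replicate)
  if (anyDuplicated(key)) {
    .stopf("duplicate (preparation, condition, replicate) triple: %s",
           key[duplicated(key)][1L])
  }
  for (prep in unique(design$preparation)) {
    for (cond in c("IgG", "basal")) {
      if (!any(design$preparation == prep & design$condition == cond)) {
        .stopf("preparation %s has no %s sample", prep, cond)
      }
    }
  }
  class(design) <- c("gsv_design", "data.frame")
  design
}

#' @rdname gsv_design
#' @param path path to a CSV file with the four design columns.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) .stopf("design file not found: %s", path)
  gsv_design(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Column-naming dialect of a protein-groups table
#'
#' Exporters differ in how they head their columns. The defaults follow the
#' MaxQuant `proteinGroups.txt` convention: intensity columns named
#' `"LFQ intensity <sample_id>"` and flag columns `"Reverse"` and
#' `"Potential contaminant"` holding `"+"` for flagged rows.
#'
#' @param intensity_prefix prefix prepended to each design `sample_id` to form
#'   its intensity column name. Ignored when `column_map` is given.
#' @param column_map optional named character vector mapping `sample_id` to an
#'   explicit intensity column name.
#' @param id_col,gene_col columns holding the protein group identifier and the
#'   gene name(s); `gene_col` may be absent from the file.
#' @param reverse_col,contaminant_col flag columns; a cell equal to `"+"`
#'   marks the row as a decoy (reverse) or known contaminant.
#' @return a list of class `gsv_dialect`.
#' @export
gsv_dialect <- function(intensity_prefix = "LFQ intensity ",
                        column_map = NULL,
                        id_col = "Protein IDs",
                        gene_col = "Gene names",
                        reverse_col = "Reverse",
                        contaminant_col = "Potential contaminant") {
  structure(list(intensity_prefix = intensity_prefix,
                 column_map = column_map,
                 id_col = id_col,
                 gene_col = gene_col,
                 reverse_col = reverse_col,
                 contaminant_col = contaminant_col),
            class = "gsv_dialect")
}

#' Read a protein-groups intensity table
#'
#' Reads a tab-separated protein-groups file (MaxQuant-style dialect by
#' default) and aligns its LFQ intensity columns to a sample design. Linear
#' intensities of 0 and empty cells are recorded as missing — in this format
#' a zero means "not quantified", never a measured abundance.
#'
#' @param path tab-separated file with a header row.
#' @param design a [gsv_design] (or data.frame coercible to one).
#' @param dialect a [gsv_dialect] describing the column naming.
#' @return a `protein_table`: list with `protein_id`, `gene_name`,
#'   `intensities` (linear-scale matrix, `NA` = missing, rows named by
#'   protein, columns by sample in design order), `reverse_flag`,
#'   `contaminant_flag`.
#' @export
read_protein_groups <- function(path, design, dialect = gsv_dialect()) {
  if (!file.exists(path)) .stopf("protein-groups file not found: %s", path)
  design <- gsv_design(design)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (!dialect$id_col %in% names(raw)) {
    .stopf("protein id column '%s' not found in %s", dialect$id_col, path)
  }
  wanted <- if (!is.null(dialect$column_map)) {
    unname(dialect$column_map[design$sample_id])
  } else {
    paste0(dialect$intensity_prefix, design$sample_id)
  }
  absent <- !wanted %in% names(raw) | is.na(wanted)
  if (any(absent)) {
    .stopf("no intensity column for design sample '%s' (expected column '%s')",
           design$sample_id[absent][1L], wanted[absent][1L])
  }
  protein_id <- as.character(raw[[dialect$id_col]])
  if (anyDuplicated(protein_id)) {
    .stopf("duplicate protein_id in %s: %s", path,
           protein_id[duplicated(protein_id)][1L])
  }
  intens <- as.matrix(raw[wanted])
  storage.mode(intens) <- "double"
  if (any(intens < 0, na.rm = TRUE)) .stopf("negative intensity values in %s", path)
  intens[!is.na(intens) & intens == 0] <- NA_real_
  dimnames(intens) <- list(protein_id, design$sample_id)
  flag <- function(col) {
    if (col %in% names(raw)) !is.na(raw[[col]]) & raw[[col]] == "+" else rep(FALSE, nrow(raw))
  }
  gene <- if (!is.null(dialect$gene_col) && dialect$gene_col %in% names(raw)) {
    as.character(raw[[dialect$gene_col]])
  } else {
    rep(NA_character_, nrow(raw))
  }
  structure(list(protein_id = protein_id,
                 gene_name = gene,
                 intensities = intens,
                 reverse_flag = flag(dialect$reverse_col),
                 contaminant_flag = flag(dialect$contaminant_col),
                 design = design),
            class = "protein_table")
}

#' Drop decoy and contaminant rows
#'
#' Removes rows carrying a reverse (decoy) or known-contaminant flag;
#' remaining row order is preserved. Idempotent.
#'
#' @param table a `protein_table`.
#' @return the filtered `protein_table` (possibly with zero rows; downstream
#'   stages raise informative errors on empty input).
#' @export
remove_flagged_rows <- function(table) {
  stopifnot(inherits(table, "protein_table"))
  keep <- !(table$reverse_flag | table$contaminant_flag)
  table$protein_id <- table$protein_id[keep]
  table$gene_name <- table$gene_name[keep]
  table$intensities <- table$intensities[keep, , drop = FALSE]
  table$reverse_flag <- table$reverse_flag[keep]
  table$contaminant_flag <- table$contaminant_flag[keep]
  table
}

.result_columns <- c("protein_id", "gene_name", "mean_basal_log2",
                     "z_LDM_enrich", "z_pHS_enrich", "p_enrich",
                     "z_LDM_resp", "z_pHS_resp", "p_resp",
                     "above_median", "tier")

#' Write and read classification results
#'
#' Results are written tab-separated with the fixed column set
#' `protein_id, gene_name, mean_basal_log2, z_LDM_enrich, z_pHS_enrich,
#' p_enrich, z_LDM_resp, z_pHS_resp, p_resp, above_median, tier` and
#' round-trip losslessly through [read_results()].
#'
#' @param records a `gsv_calls` data.frame as produced by [classify_gsv()];
#'   must be non-empty.
#' @param path output file path.
#' @export
write_results <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) .stopf("no classification records to write")
  miss <- setdiff(.result_columns, names(records))
  if (length(miss)) .stopf("records lack column(s): %s", paste(miss, collapse = ", "))
  out <- records[.result_columns]
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .stopf("cannot write results to %s", path)
  invisible(path)
}

#' @rdname write_results
#' @return `read_results` returns the records with the same columns and types.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) .stopf("results file not found: %s", path)
  rec <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  miss <- setdiff(.result_columns, names(rec))
  if (length(miss)) .stopf("results file lacks column(s): %s", paste(miss, collapse = ", "))
  rec$protein_id <- as.character(rec$protein_id)
  rec$gene_name <- as.character(rec$gene_name)
  rec$above_median <- as.logical(rec$above_median)
  rec$tier <- as.character(rec$tier)
  class(rec) <- c("gsv_calls", "data.frame")
  rec
}
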