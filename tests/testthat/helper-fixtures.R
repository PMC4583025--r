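# Shared fixture builders. Everything is generated in code; no data files.

# minimal design: 2 preparations x 3 conditions x n replicates
make_design <- function(n_rep = 2L, conditions = c("IgG", "basal", "insulin")) {
  des <- do.call(rbind, lapply(c("LDM", "pHS"), function(p) {
    data.frame(sample_id = paste(p, rep(conditions, each = n_rep),
                                 rep(seq_len(n_rep), length(conditions)), sep = "_"),
               preparation = p,
               condition = rep(conditions, each = n_rep),
               replicate = rep(seq_len(n_rep), length(conditions)),
               stringsAsFactors = FALSE)
  }))
  gsv_design(des)
}

# wrap a log2 matrix (NA = missing) as a norm_matrix
make_norm_matrix <- function(values, design) {
  stopifnot(ncol(values) == nrow(design))
  colnames(values) <- design$sample_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%04d", seq_len(nrow(values)))
  }
  structure(list(values = values, design = design,
                 gene_name = rep(NA_character_, nrow(values))),
            class = "norm_matrix")
}

# write a MaxQuant-style proteinGroups.txt; intensities on the linear scale,
# 0/NA cells written as 0
write_pg_fixture <- function(path, intensities, design,
                             reverse = rep(FALSE, nrow(intensities)),
                             contaminant = rep(FALSE, nrow(intensities)),
                             ids = sprintf("P%04d", seq_len(nrow(intensities)))) {
  m <- intensities
  m[is.na(m)] <- 0
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                   "Protein IDs" = ids,
                   "Gene names" = tolower(ids))
  for (j in seq_len(ncol(m))) {
    df[[paste0("LFQ intensity ", design$sample_id[j])]] <- m[, j]
  }
  df[["Reverse"]] <- ifelse(reverse, "+", "")
  df[["Potential contaminant"]] <- ifelse(contaminant, "+", "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# design columns of one (preparation, condition)
cols_of <- function(design, prep, cond) {
  design$sample_id[design$preparation == prep & design$condition == cond]
}
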