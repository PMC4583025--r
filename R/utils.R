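# Internal helpers shared across modules.

# Deterministic per-cell seed for the imputation substream. Keyed on
# (run seed, protein_id, sample_id) so that row or column order of the
# matrix can never change a drawn value. Kept below 2^31 - 1.
.cell_seed <- function(seed, protein_id, sample_id) {
  key <- paste(protein_id, sample_id, sep = "\r")
  h <- seed %% 2147483647
  for (code in utf8ToInt(key)) {
    h <- (h * 69069 + code) %% 2147483647
  }
  as.integer(h)
}

# round-half-away-from-zero (base round() is banker's rounding)
.round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

.conditions <- c("IgG", "basal", "insulin")
.preparations <- c("LDM", "pHS")

.stopf <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# columns of a normalized matrix belonging to one (preparation, condition)
.design_cols <- function(design, preparation = NULL, condition = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(preparation)) keep <- keep & design$preparation %in% preparation
  if (!is.null(condition)) keep <- keep & design$condition %in% condition
  design$sample_id[keep]
}
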