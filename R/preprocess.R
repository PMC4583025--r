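#' Log2 transform and MAD-normalize an intensity matrix
#'
#' Each sample (column) is median-centered and rescaled so that its median
#' absolute deviation equals the across-column median of the pre-scaling
#' MADs; the shared location is then set to the median of the per-column
#' medians, keeping values on an interpretable log2-intensity scale rather
#' than collapsing them to unit MAD. Missing cells are untouched.
#'
#' After normalization every column has the same median and the same MAD
#' (within floating-point error), and applying the function twice is a no-op.
#'
#' @param table a `protein_table` from [read_protein_groups()] (linear-scale
#'   intensities), or a `norm_matrix` already on the log2 scale.
#' @return a `norm_matrix`: list with `values` (log2 matrix, `NA` = missing),
#'   `design`, and for provenance the per-column location/scale applied.
#' @export
log2_mad_normalize <- function(table) {
  if (inherits(table, "protein_table")) {
    values <- log2(table$intensities)
    design <- table$design
    gene <- table$gene_name
  } else if (inherits(table, "norm_matrix")) {
    values <- table$values
    design <- table$design
    gene <- table$gene_name
  } else {
    .stopf("expected a protein_table or norm_matrix")
  }
  if (nrow(values) == 0L) .stopf("normalization received an empty table")
  meds <- apply(values, 2L, stats::median, na.rm = TRUE)
  mads <- apply(values, 2L, stats::mad, na.rm = TRUE)
  n_obs <- colSums(!is.na(values))
  if (any(n_obs < 2L)) {
    .stopf("column '%s' has fewer than 2 observed values",
           colnames(values)[n_obs < 2L][1L])
  }
  if (any(mads == 0)) {
    .stopf("column '%s' has zero MAD; cannot normalize",
           colnames(values)[mads == 0][1L])
  }
  target_mad <- stats::median(mads)
  location <- stats::median(meds)
  out <- sweep(values, 2L, meds, "-")
  out <- sweep(out, 2L, target_mad / mads, "*") + location
  structure(list(values = out, design = design, gene_name = gene,
                 column_median = meds, column_mad = mads,
                 target_mad = target_mad, location = location),
            class = "norm_matrix")
}

#' Keep proteins quantified in every basal replicate of each preparation
#'
#' A protein enters a preparation's identified set when it is observed
#' (non-missing) in all of that preparation's basal immunoprecipitate
#' replicates; with two replicates per preparation this is the
#' "identified in both replicates" rule. The merged matrix retains proteins
#' present in both preparations' sets — the two lists are merged before any
#' statistics are computed — while proteins found in only one preparation
#' are returned separately so they can be reported but never classified.
#'
#' @param matrix a `norm_matrix`.
#' @return list with `sets` (character vectors of protein ids per
#'   preparation), `merged` (the `norm_matrix` restricted to the overlap,
#'   original row order), and `partial` (data.frame of proteins complete in
#'   exactly one preparation).
#' @export
filter_complete_in_replicates <- function(matrix) {
  stopifnot(inherits(matrix, "norm_matrix"))
  design <- matrix$design
  preps <- intersect(.preparations, unique(design$preparation))
  if (length(preps) < 2L) .stopf("design must cover both preparations")
  sets <- lapply(preps, function(p) {
    cols <- .design_cols(design, preparation = p, condition = "basal")
    sub <- matrix$values[, cols, drop = FALSE]
    rownames(matrix$values)[rowSums(is.na(sub)) == 0L]
  })
  names(sets) <- preps
  merged_ids <- Reduce(intersect, sets)
  keep <- rownames(matrix$values) %in% merged_ids
  merged <- matrix
  merged$values <- matrix$values[keep, , drop = FALSE]
  merged$gene_name <- matrix$gene_name[keep]
  only <- setdiff(unique(unlist(sets)), merged_ids)
  partial <- data.frame(
    protein_id = only,
    preparation = vapply(only, function(id) {
      paste(preps[vapply(sets, function(s) id %in% s, logical(1))], collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(sets = sets, merged = merged, partial = partial)
}

# pooled within-(preparation, condition) replicate SD per protein; NA when no
# group contributes at least two observed values
.replicate_sd <- function(values, design) {
  groups <- split(design$sample_id, paste(design$preparation, design$condition))
  ss <- numeric(nrow(values))
  df <- numeric(nrow(values))
  for (cols in groups) {
    sub <- values[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    dev <- rowSums((sub - m)^2, na.rm = TRUE)
    use <- n >= 2L
    ss[use] <- ss[use] + dev[use]
    df[use] <- df[use] + (n[use] - 1L)
  }
  out <- rep(NA_real_, nrow(values))
  out[df > 0] <- sqrt(ss[df > 0] / df[df > 0])
  out
}

#' Remove the most variable proteins
#'
#' Drops the `round(fraction * N)` proteins with the highest measurement
#' variability (rounding half away from zero). Variability is the pooled
#' standard deviation of observed values across replicates within each
#' (preparation, condition) group, so that irreproducible quantifications
#' are trimmed without penalizing genuine between-condition differences
#' such as enrichment or insulin-driven depletion.
#'
#' @param matrix a `norm_matrix`.
#' @param fraction fraction of proteins to remove, in `[0, 1)`; default 0.05.
#' @return the trimmed `norm_matrix` (row order preserved).
#' @export
trim_top_variance <- function(matrix, fraction = 0.05) {
  stopifnot(inherits(matrix, "norm_matrix"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction < 0 || fraction >= 1) {
    .stopf("fraction must be a single value in [0, 1)")
  }
  n <- nrow(matrix$values)
  n_remove <- as.integer(.round_half_up(fraction * n))
  if (n_remove == 0L) return(matrix)
  sds <- .replicate_sd(matrix$values, matrix$design)
  ord <- order(sds, decreasing = TRUE, na.last = TRUE)
  drop_idx <- ord[seq_len(n_remove)]
  drop_idx <- drop_idx[!is.na(sds[drop_idx])]  # never trim on undefined SD
  keep <- setdiff(seq_len(n), drop_idx)
  matrix$values <- matrix$values[keep, , drop = FALSE]
  matrix$gene_name <- matrix$gene_name[keep]
  matrix
}

#' Estimate left-censoring imputation parameters
#'
#' Missing LFQ values arise mostly from intensities falling below the
#' detection limit, so draws for them come from a "minimum value
#' distribution": per (preparation, condition), a Gaussian with mean equal to
#' the minimum observed log2 value of that condition's columns and standard
#' deviation equal to the SD of the observed values lying in the lowest
#' quartile of that condition's observed-value distribution.
#'
#' @param matrix a `norm_matrix`.
#' @param conditions conditions whose missing cells will be imputed;
#'   default `c("IgG", "insulin")` (basal columns are complete by
#'   construction after [filter_complete_in_replicates()]).
#' @param n_imputations number of Gaussian draws averaged per missing cell
#'   (default 20).
#' @param seed integer seed for the imputation stream.
#' @return an `imputation_params` object: data.frame with one row per
#'   (preparation, condition) holding `mu`, `sigma` and the observed count,
#'   with the draw settings as attributes.
#' @export
estimate_imputation_params <- function(matrix, conditions = c("IgG", "insulin"),
                                       n_imputations = 20L, seed = 0L) {
  stopifnot(inherits(matrix, "norm_matrix"))
  if (n_imputations < 1L) .stopf("n_imputations must be positive")
  bad <- setdiff(conditions, .conditions)
  if (length(bad)) .stopf("unknown condition(s): %s", paste(bad, collapse = ", "))
  design <- matrix$design
  rows <- list()
  for (prep in intersect(.preparations, unique(design$preparation))) {
    for (cond in conditions) {
      cols <- .design_cols(design, preparation = prep, condition = cond)
      if (!length(cols)) next
      obs <- matrix$values[, cols, drop = FALSE]
      obs <- obs[!is.na(obs)]
      if (length(obs) < 4L) {
        .stopf("condition %s/%s has %d observed values; need >= 4 for the quartile",
               prep, cond, length(obs))
      }
      q1 <- stats::quantile(obs, 0.25, names = FALSE)
      low <- obs[obs <= q1]
      sigma <- if (length(low) >= 2L) stats::sd(low) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        preparation = prep, condition = cond,
        mu = min(obs), sigma = sigma, n_obs = length(obs),
        stringsAsFactors = FALSE)
    }
  }
  params <- do.call(rbind, rows)
  structure(params,
            n_imputations = as.integer(n_imputations),
            seed = as.integer(seed),
            conditions = conditions,
            class = c("imputation_params", "data.frame"))
}

#' Impute missing values from the minimum-value distribution
#'
#' Each missing cell in a column belonging to an imputed condition is
#' replaced by the mean of `n_imputations` independent draws from
#' `Normal(mu, sigma)` for its (preparation, condition). Observed cells are
#' never altered and missing cells in other conditions stay missing. Each
#' cell uses its own random substream keyed on (seed, protein_id,
#' sample_id), so results are reproducible and independent of row order.
#'
#' @param matrix a `norm_matrix`.
#' @param params an `imputation_params` object estimated from this matrix.
#' @return the `norm_matrix` with imputed values filled in; the pattern of
#'   cells that were imputed is recorded in `imputed_mask`.
#' @export
impute_missing <- function(matrix, params) {
  stopifnot(inherits(matrix, "norm_matrix"), inherits(params, "imputation_params"))
  n_imp <- attr(params, "n_imputations")
  seed <- attr(params, "seed")
  values <- matrix$values
  imputed <- array(FALSE, dim(values), dimnames = dimnames(values))
  design <- matrix$design
  for (k in seq_len(nrow(params))) {
    cols <- .design_cols(design, preparation = params$preparation[k],
                         condition = params$condition[k])
    for (sid in cols) {
      miss <- which(is.na(values[, sid]))
      for (i in miss) {
        pid <- rownames(values)[i]
        set.seed(.cell_seed(seed, pid, sid))
        values[i, sid] <- mean(stats::rnorm(n_imp, params$mu[k], params$sigma[k]))
        imputed[i, sid] <- TRUE
      }
    }
  }
  matrix$values <- values
  matrix$imputed_mask <- imputed
  matrix
}
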