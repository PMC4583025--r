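#' Population-median abundance cutoff
#'
#' The second classification gate requires a candidate's basal abundance to
#' exceed the population median. The population is the merged, trimmed,
#' imputed protein set; each protein's abundance is its mean log2 LFQ
#' intensity over the basal immunoprecipitate columns of both preparations.
#'
#' @param matrix a `norm_matrix` restricted to that population.
#' @return the median of `mean_basal_log2` over proteins (single numeric).
#' @export
compute_median_cutoff <- function(matrix) {
  stats::median(mean_basal_log2(matrix))
}

#' @rdname compute_median_cutoff
#' @return `mean_basal_log2` returns the named per-protein vector of mean
#'   basal log2 intensities the cutoff is the median of.
#' @export
mean_basal_log2 <- function(matrix) {
  stopifnot(inherits(matrix, "norm_matrix"))
  if (nrow(matrix$values) == 0L) .stopf("no proteins left to compute the median cutoff")
  cols <- .design_cols(matrix$design, condition = "basal")
  rowMeans(matrix$values[, cols, drop = FALSE], na.rm = TRUE)
}

.tiers <- c("not_enriched", "enriched_low_intensity", "enriched",
            "high_confidence_gsv")

#' Three-criteria GSV classification
#'
#' Applies the classification cascade calibrated on established GSV cargo
#' (GLUT4, IRAP, VAMP2, sortilin): a high-confidence GSV protein must be
#' (1) significantly enriched in basal immunoprecipitates over the IgG
#' control in both preparations (integrated p below `alpha`), (2) more
#' abundant than the population median (strictly greater), and (3)
#' significantly depleted after insulin stimulation in both preparations.
#' Tiers are nested: `high_confidence_gsv` implies `enriched` implies
#' passing the enrichment gate.
#'
#' @param enrich an `integration_result` for the enrichment contrast
#'   (positive quadrant), one row per protein.
#' @param resp optional `integration_result` for the responsiveness contrast
#'   (negative quadrant); when absent tiers cap at `"enriched"` and `p_resp`
#'   is reported as `NA`.
#' @param mean_basal named vector of mean basal log2 intensities
#'   (see [mean_basal_log2()]).
#' @param cutoff the population-median cutoff (finite numeric).
#' @param alpha significance level for both integrated p-values
#'   (default 0.05).
#' @param gene_name optional named character vector of gene names.
#' @return a `gsv_calls` data.frame with the standard result columns
#'   (see [write_results()]); `alpha` and `median_cutoff` are attributes.
#' @export
classify_gsv <- function(enrich, resp = NULL, mean_basal, cutoff, alpha = 0.05,
                         gene_name = NULL) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff)) {
    .stopf("median cutoff must be a single finite number")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    .stopf("alpha must be in (0, 1]")
  }
  ids <- enrich$protein_id
  absent <- ids[!ids %in% names(mean_basal)]
  if (length(absent)) .stopf("no mean basal intensity for protein '%s'", absent[1L])
  mb <- unname(mean_basal[ids])
  if (!is.null(resp)) {
    ridx <- match(ids, resp$protein_id)
    if (anyNA(ridx)) {
      .stopf("responsiveness results missing for protein '%s'", ids[is.na(ridx)][1L])
    }
  }
  p_enrich <- enrich$p_int
  p_resp <- if (is.null(resp)) rep(NA_real_, length(ids)) else resp$p_int[ridx]
  above <- mb > cutoff
  tier <- rep("not_enriched", length(ids))
  sig_e <- p_enrich < alpha
  tier[sig_e & !above] <- "enriched_low_intensity"
  tier[sig_e & above] <- "enriched"
  tier[sig_e & above & !is.na(p_resp) & p_resp < alpha] <- "high_confidence_gsv"
  gn <- if (is.null(gene_name)) rep(NA_character_, length(ids)) else unname(gene_name[ids])
  out <- data.frame(
    protein_id = ids,
    gene_name = gn,
    mean_basal_log2 = mb,
    z_LDM_enrich = enrich$z_ldm,
    z_pHS_enrich = enrich$z_phs,
    p_enrich = p_enrich,
    z_LDM_resp = if (is.null(resp)) NA_real_ else resp$z_ldm[ridx],
    z_pHS_resp = if (is.null(resp)) NA_real_ else resp$z_phs[ridx],
    p_resp = p_resp,
    above_median = above,
    tier = tier,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, alpha = alpha, median_cutoff = cutoff,
            class = c("gsv_calls", "data.frame"))
}
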