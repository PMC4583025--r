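#' Pipeline configuration
#'
#' Defaults are the study's analysis constants: significance level 0.05 for
#' both integrated p-values, 5% variance trim, 20 imputation draws averaged
#' per missing cell, and imputation restricted to the IgG control and
#' insulin-stimulated columns.
#'
#' @param protein_groups,design input file paths (may be `NULL` when the
#'   tables are passed to [run_pipeline()] directly).
#' @param alpha significance level for the integrated p-values.
#' @param variance_trim_fraction fraction of most-variable proteins removed.
#' @param n_imputations Gaussian draws averaged per imputed cell.
#' @param imputed_conditions conditions whose missing values are imputed.
#' @param seed integer seed for the imputation stream.
#' @param apply_bh apply Benjamini-Hochberg adjustment to the integrated
#'   p-values before thresholding (off by default; the classification uses
#'   unadjusted integrated p-values).
#' @param output_dir optional directory where results and the run report are
#'   written.
#' @return a list of class `gsv_config`.
#' @export
gsv_config <- function(protein_groups = NULL, design = NULL, alpha = 0.05,
                       variance_trim_fraction = 0.05, n_imputations = 20L,
                       imputed_conditions = c("IgG", "insulin"), seed = 0L,
                       apply_bh = FALSE, output_dir = NULL) {
  cfg <- list(protein_groups = protein_groups, design = design,
              alpha = alpha, variance_trim_fraction = variance_trim_fraction,
              n_imputations = as.integer(n_imputations),
              imputed_conditions = imputed_conditions,
              seed = as.integer(seed), apply_bh = isTRUE(apply_bh),
              output_dir = output_dir)
  if (cfg$alpha <= 0 || cfg$alpha > 1) .stopf("alpha must be in (0, 1]")
  if (cfg$variance_trim_fraction < 0 || cfg$variance_trim_fraction >= 1) {
    .stopf("variance_trim_fraction must be in [0, 1)")
  }
  if (cfg$n_imputations < 1L) .stopf("n_imputations must be positive")
  bad <- setdiff(cfg$imputed_conditions, .conditions)
  if (length(bad)) .stopf("unknown imputed condition(s): %s", paste(bad, collapse = ", "))
  class(cfg) <- "gsv_config"
  cfg
}

#' Read a pipeline configuration file
#'
#' Flat YAML with exactly the [gsv_config()] fields; unknown keys are hard
#' errors so a typo in a threshold can never pass silently.
#'
#' @param path path to the YAML config file.
#' @return a `gsv_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) .stopf("config must be a mapping of keys to values")
  known <- names(formals(gsv_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(gsv_config, raw)
}

#' Run the full GSV identification pipeline
#'
#' Executes read -> contaminant/decoy removal -> log2 + MAD normalization ->
#' replicate-completeness filter -> variance trim -> left-censored
#' imputation -> moderated t-tests (enrichment and, when insulin samples
#' exist, responsiveness; per preparation) -> t-to-Z conversion ->
#' directional quadrant integration -> population-median cutoff ->
#' three-criteria classification. The run report records the count
#' surviving each stage (All, LDM, pHS, Overlap, Enriched, GSV) and every
#' realized parameter: imputation mu/sigma per (preparation, condition),
#' the variance prior (d0, s0_sq) of each test, the median cutoff, and the
#' seed.
#'
#' @param config a [gsv_config()].
#' @param table optional `protein_table`; read from
#'   `config$protein_groups` when `NULL`.
#' @param design optional design; read from `config$design` when `NULL`.
#' @return an object of class `gsv_result`: list with `calls` (a
#'   `gsv_calls` data.frame), `report`, `partial` (proteins complete in only
#'   one preparation, reported but never classified), and the intermediate
#'   `tests` and `integration` results.
#' @export
run_pipeline <- function(config = gsv_config(), table = NULL, design = NULL) {
  stopifnot(inherits(config, "gsv_config"))
  if (is.null(design)) {
    if (is.null(config$design)) .stopf("no design table given")
    design <- read_design(config$design)
  } else {
    design <- gsv_design(design)
  }
  if (is.null(table)) {
    if (is.null(config$protein_groups)) .stopf("no protein-groups table given")
    table <- read_protein_groups(config$protein_groups, design)
  }
  n_raw <- length(table$protein_id)
  table <- remove_flagged_rows(table)
  n_all <- length(table$protein_id)
  if (n_all == 0L) .stopf("pipeline stage 'flag removal' left no proteins")

  nm <- log2_mad_normalize(table)
  filt <- filter_complete_in_replicates(nm)
  n_sets <- lengths(filt$sets)
  n_overlap <- nrow(filt$merged$values)
  if (n_overlap == 0L) .stopf("pipeline stage 'completeness filter' left no proteins")

  trimmed <- trim_top_variance(filt$merged, config$variance_trim_fraction)
  n_trimmed <- nrow(trimmed$values)
  if (n_trimmed == 0L) .stopf("pipeline stage 'variance trim' left no proteins")

  params <- estimate_imputation_params(trimmed,
                                       conditions = config$imputed_conditions,
                                       n_imputations = config$n_imputations,
                                       seed = config$seed)
  imp <- impute_missing(trimmed, params)

  has_insulin <- all(vapply(.preparations, function(p) {
    length(.design_cols(design, p, "insulin")) >= 2L
  }, logical(1)))

  run_contrast <- function(contrast) {
    spec <- .contrast_spec(contrast)
    tests <- lapply(.preparations, function(p) {
      moderated_t_test(imp,
                       group_a = .design_cols(design, p, spec$a),
                       group_b = .design_cols(design, p, spec$b),
                       contrast = contrast, preparation = p)
    })
    names(tests) <- .preparations
    integ <- integrate_tests(tests$LDM, tests$pHS, quadrant = spec$quadrant)
    if (config$apply_bh) integ$p_int <- stats::p.adjust(integ$p_int, "BH")
    list(tests = tests, integration = integ)
  }

  enr <- run_contrast("enrichment")
  rsp <- if (has_insulin) run_contrast("responsiveness") else NULL

  mb <- mean_basal_log2(imp)
  cutoff <- stats::median(mb)
  gene <- stats::setNames(imp$gene_name, rownames(imp$values))
  calls <- classify_gsv(enr$integration,
                        resp = if (is.null(rsp)) NULL else rsp$integration,
                        mean_basal = mb, cutoff = cutoff,
                        alpha = config$alpha, gene_name = gene)

  n_enriched_any <- sum(calls$p_enrich < config$alpha)
  n_enriched <- sum(calls$tier %in% c("enriched", "high_confidence_gsv"))
  n_gsv <- sum(calls$tier == "high_confidence_gsv")

  priors <- lapply(c(enr = list(enr), resp = if (is.null(rsp)) NULL else list(rsp)),
                   function(ct) lapply(ct$tests, function(t) {
                     list(d0 = attr(t, "d0"), s0_sq = attr(t, "s0_sq"))
                   }))
  names(priors) <- c("enrichment", if (!is.null(rsp)) "responsiveness")

  report <- list(
    counts = c(Raw = n_raw, All = n_all,
               LDM = unname(n_sets["LDM"]), pHS = unname(n_sets["pHS"]),
               Overlap = n_overlap, Trimmed = n_trimmed,
               EnrichedAny = n_enriched_any, Enriched = n_enriched,
               GSV = n_gsv),
    imputation_params = as.data.frame(params),
    variance_priors = priors,
    median_cutoff = cutoff,
    alpha = config$alpha,
    variance_trim_fraction = config$variance_trim_fraction,
    n_imputations = config$n_imputations,
    apply_bh = config$apply_bh,
    seed = config$seed,
    has_insulin = has_insulin)

  structure(list(calls = calls, report = report, partial = filt$partial,
                 tests = list(enrichment = enr$tests,
                              responsiveness = if (is.null(rsp)) NULL else rsp$tests),
                 integration = list(enrichment = enr$integration,
                                    responsiveness = if (is.null(rsp)) NULL else rsp$integration),
                 matrix = imp, config = config),
            class = "gsv_result")
}

#' @export
print.gsv_result <- function(x, ...) {
  cat("GSV immunoisolation analysis\n")
  cat("Filter cascade (proteins surviving each stage):\n")
  cts <- x$report$counts
  for (nm in names(cts)) cat(sprintf("  %-12s %d\n", nm, cts[[nm]]))
  cat(sprintf("Median abundance cutoff: %.4f (log2 LFQ)\n", x$report$median_cutoff))
  cat(sprintf("alpha = %g; %d high-confidence GSV protein(s)\n",
              x$report$alpha, cts[["GSV"]]))
  invisible(x)
}

#' @export
summary.gsv_result <- function(object, ...) {
  print(object)
  cat("\nTier counts:\n")
  print(table(factor(object$calls$tier, levels = .tiers)))
  cat("\nImputation parameters (log2):\n")
  print(object$report$imputation_params, row.names = FALSE)
  cat("\nVariance priors:\n")
  for (ct in names(object$report$variance_priors)) {
    for (p in names(object$report$variance_priors[[ct]])) {
      pr <- object$report$variance_priors[[ct]][[p]]
      cat(sprintf("  %s/%s: d0 = %.4g, s0_sq = %.4g\n", ct, p, pr$d0, pr$s0_sq))
    }
  }
  if (nrow(object$partial)) {
    cat(sprintf("\n%d protein(s) complete in only one preparation (not classified)\n",
                nrow(object$partial)))
  }
  invisible(object)
}

#' Volcano-style plot of the enrichment evidence
#'
#' Integrated enrichment Z against mean basal abundance, colored by tier.
#'
#' @param x a `gsv_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gsv_result <- function(x, ...) {
  calls <- x$calls
  col <- c(not_enriched = "grey60", enriched_low_intensity = "grey30",
           enriched = "orange2", high_confidence_gsv = "red3")[calls$tier]
  z_int <- (calls$z_LDM_enrich + calls$z_pHS_enrich) / sqrt(2)
  graphics::plot(calls$mean_basal_log2, z_int, col = col, pch = 16,
                 xlab = "mean basal log2 LFQ intensity",
                 ylab = "integrated enrichment Z", ...)
  graphics::abline(v = x$report$median_cutoff, lty = 2)
  invisible(x)
}
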