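# Synthetic immunoisolation datasets with known ground truth.
#
# The generator emulates the statistical structure the pipeline assumes:
# log-normal protein abundance, true GSV cargo enriched in basal
# immunoprecipitates over the IgG control and depleted after insulin,
# background binders flat across conditions, and intensity-dependent
# (left-censored) missingness that therefore concentrates in the IgG and
# insulin samples of true cargo.

#' Simulation parameters
#'
#' @param n_proteins number of protein groups.
#' @param frac_true_gsv fraction of proteins that are true GSV residents.
#' @param n_replicates replicates per (preparation, condition); the study
#'   design uses 2.
#' @param baseline_mean,baseline_sd log2 mean and SD of protein base
#'   abundance across the proteome.
#' @param enrich_effect mean log2 enrichment of true GSV proteins in
#'   immunoprecipitates over the IgG control.
#' @param insulin_effect mean log2 depletion of true GSV proteins after
#'   insulin stimulation (nonnegative).
#' @param effect_sd protein-to-protein SD of the realized effect sizes
#'   (log2); realized insulin effects are truncated at 0.
#' @param noise_sd replicate-level log2 measurement noise.
#' @param censor_limit,censor_slope logistic left-censoring: a value `x` is
#'   missing with probability `1 / (1 + exp(censor_slope * (x -
#'   censor_limit)))`, decreasing in `x`.
#' @param mcar_rate additional missing-completely-at-random rate, for null
#'   testing (default 0).
#' @param contaminant_frac fraction of rows flagged as known contaminants.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_proteins = 1000L, frac_true_gsv = 0.05,
                       n_replicates = 2L, baseline_mean = 22,
                       baseline_sd = 2, enrich_effect = 3,
                       insulin_effect = 1.5, effect_sd = 0.3,
                       noise_sd = 0.5, censor_limit = 18,
                       censor_slope = 1, mcar_rate = 0,
                       contaminant_frac = 0.02, seed = 0L) {
  p <- list(n_proteins = as.integer(n_proteins), frac_true_gsv = frac_true_gsv,
            n_replicates = as.integer(n_replicates),
            baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            enrich_effect = enrich_effect, insulin_effect = insulin_effect,
            effect_sd = effect_sd, noise_sd = noise_sd,
            censor_limit = censor_limit, censor_slope = censor_slope,
            mcar_rate = mcar_rate, contaminant_frac = contaminant_frac,
            seed = as.integer(seed))
  if (p$n_proteins < 1L) .stopf("n_proteins must be positive")
  if (p$n_replicates < 1L) .stopf("n_replicates must be positive")
  for (f in c("frac_true_gsv", "mcar_rate", "contaminant_frac")) {
    if (p[[f]] < 0 || p[[f]] > 1) .stopf("%s must lie in [0, 1]", f)
  }
  if (p$insulin_effect < 0) .stopf("insulin_effect must be nonnegative")
  if (p$noise_sd < 0 || p$effect_sd < 0) .stopf("SD parameters must be nonnegative")
  if (p$censor_slope <= 0) .stopf("censor_slope must be positive")
  class(p) <- "sim_params"
  p
}

#' Named simulation presets
#'
#' `"default"` is the standard benchmarking scenario (1000 proteins, 5%
#' true GSV, enrichment 3 log2, insulin depletion 1.5 log2, replicate noise
#' 0.5, mild left-censoring). `"null"` zeroes both effect sizes and
#' disables censoring so that false-positive calibration of the testing and
#' integration chain can be read off directly — minimum-anchored imputation
#' is deliberately anti-conservative, so a calibration check must run on
#' complete data. `"strong"` has larger effects and less noise.
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @param ... overrides passed to [sim_params()].
#' @export
sim_preset <- function(preset = c("default", "null", "strong"), seed = 0L, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    default = list(),
    null = list(enrich_effect = 0, insulin_effect = 0, effect_sd = 0,
                censor_limit = -Inf),
    strong = list(enrich_effect = 4, insulin_effect = 2.5, noise_sd = 0.3))
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(sim_params, args)
}

#' Generate a synthetic immunoisolation dataset
#'
#' Lays out samples as 2 preparations x (IgG, basal, insulin) x
#' `n_replicates`. Per protein, log2 abundance is base + effect terms +
#' Gaussian replicate noise; true GSV proteins gain their realized
#' enrichment effect in basal and insulin immunoprecipitates relative to
#' IgG and lose their realized insulin effect under insulin; background
#' binders (and contaminants, which are additionally flagged) have equal
#' means everywhere. Values are censored to missing by the logistic rule
#' and exported on the linear intensity scale with 0 encoding missing.
#'
#' @param params a [sim_params()] object (or arguments for one via `...`).
#' @param ... overrides when `params` is missing.
#' @return a list of class `gsv_simulation` with `table` (a
#'   `protein_table`), `design` (a `gsv_design`), `truth` (data.frame:
#'   `protein_id, klass, realized_enrich_effect, realized_insulin_effect`)
#'   and `params`.
#' @export
simulate_gsv_dataset <- function(params = sim_params(...), ...) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  design <- expand.grid(replicate = seq_len(params$n_replicates),
                        condition = .conditions,
                        preparation = .preparations,
                        stringsAsFactors = FALSE)
  design <- design[c("sample_id", "preparation", "condition", "replicate")[-1]]
  design$sample_id <- paste(design$preparation, design$condition,
                            design$replicate, sep = "_")
  design <- gsv_design(design[c("sample_id", "preparation", "condition", "replicate")])

  n <- params$n_proteins
  n_gsv <- .round_half_up(params$frac_true_gsv * n)
  n_cont <- min(.round_half_up(params$contaminant_frac * n), n - n_gsv)
  klass <- rep("background_binder", n)
  if (n_gsv > 0) klass[seq_len(n_gsv)] <- "true_gsv"
  if (n_cont > 0) klass[n_gsv + seq_len(n_cont)] <- "contaminant"
  protein_id <- sprintf("P%05d", seq_len(n))

  base <- stats::rnorm(n, params$baseline_mean, params$baseline_sd)
  is_gsv <- klass == "true_gsv"
  enr <- ifelse(is_gsv, stats::rnorm(n, params$enrich_effect, params$effect_sd), 0)
  ins <- ifelse(is_gsv,
                pmax(0, stats::rnorm(n, params$insulin_effect, params$effect_sd)), 0)

  mu <- matrix(base, n, nrow(design))
  ip_cols <- design$condition %in% c("basal", "insulin")
  mu[, ip_cols] <- mu[, ip_cols] + enr
  mu[, design$condition == "insulin"] <- mu[, design$condition == "insulin"] - ins
  x <- mu + matrix(stats::rnorm(n * nrow(design), 0, params$noise_sd), n)

  p_miss <- 1 / (1 + exp(params$censor_slope * (x - params$censor_limit)))
  miss <- matrix(stats::runif(length(x)) < p_miss, n)
  if (params$mcar_rate > 0) {
    miss <- miss | matrix(stats::runif(length(x)) < params$mcar_rate, n)
  }
  x[miss] <- NA_real_
  intens <- 2^x
  dimnames(intens) <- list(protein_id, design$sample_id)

  table <- structure(list(protein_id = protein_id,
                          gene_name = toupper(protein_id),
                          intensities = intens,
                          reverse_flag = rep(FALSE, n),
                          contaminant_flag = klass == "contaminant",
                          design = design),
                     class = "protein_table")
  truth <- data.frame(protein_id = protein_id, klass = klass,
                      realized_enrich_effect = enr,
                      realized_insulin_effect = ins,
                      stringsAsFactors = FALSE)
  structure(list(table = table, design = design, truth = truth,
                 params = params),
            class = "gsv_simulation")
}

#' Write a simulated dataset in the pipeline's input dialect
#'
#' Produces `proteinGroups.txt` (tab-separated, `"LFQ intensity <sample>"`
#' columns, 0 for missing, `"+"` contaminant flags), `design.csv` and
#' `truth.tsv` under `dir`.
#'
#' @param sim a `gsv_simulation`.
#' @param dir output directory (created if needed).
#' @return the three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "gsv_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  intens <- sim$table$intensities
  intens[is.na(intens)] <- 0
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                   "Protein IDs" = sim$table$protein_id,
                   "Gene names" = sim$table$gene_name)
  for (j in seq_len(ncol(intens))) {
    df[[paste0("LFQ intensity ", colnames(intens)[j])]] <- intens[, j]
  }
  df[["Reverse"]] <- ifelse(sim$table$reverse_flag, "+", "")
  df[["Potential contaminant"]] <- ifelse(sim$table$contaminant_flag, "+", "")
  paths <- file.path(dir, c("proteinGroups.txt", "design.csv", "truth.tsv"))
  utils::write.table(df, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(as.data.frame(sim$design), paths[2L], row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth, paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Precision and recall of high-confidence calls against simulation truth
#'
#' A positive call is `tier == "high_confidence_gsv"`; a positive truth is
#' `klass == "true_gsv"`. Recall counts true GSV proteins that never reached
#' classification (filtered out upstream) as misses. Precision is `NA` with
#' `precision_defined = FALSE` when there are no positive calls.
#'
#' @param calls a `gsv_calls` data.frame.
#' @param truth the `truth` data.frame of a `gsv_simulation`; every
#'   classified protein must appear in it.
#' @return list with `precision`, `recall`, `precision_defined` and a
#'   `counts` vector (`tp, fp, tn, fn` over classified proteins, plus
#'   `filtered_true_gsv` lost before classification).
#' @export
evaluate_recovery <- function(calls, truth) {
  extra <- setdiff(calls$protein_id, truth$protein_id)
  if (length(extra)) {
    .stopf("classified protein '%s' absent from truth", extra[1L])
  }
  pos_call <- calls$tier == "high_confidence_gsv"
  truth_class <- truth$klass[match(calls$protein_id, truth$protein_id)]
  pos_truth <- truth_class == "true_gsv"
  tp <- sum(pos_call & pos_truth)
  fp <- sum(pos_call & !pos_truth)
  fn <- sum(!pos_call & pos_truth)
  tn <- sum(!pos_call & !pos_truth)
  filtered <- sum(truth$klass == "true_gsv" &
                    !truth$protein_id %in% calls$protein_id)
  n_true <- sum(truth$klass == "true_gsv")
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       precision_defined = (tp + fp) > 0,
       recall = if (n_true > 0) tp / n_true else NA_real_,
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn,
                  filtered_true_gsv = filtered))
}
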