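# Empirical-Bayes moderated two-sample testing.
#
# With n = 2 replicates per group an ordinary t-test is hopelessly unstable;
# the moderated test shrinks each protein's pooled variance toward a prior
# estimated from the whole variance ensemble, adding d0 prior degrees of
# freedom to the residual df.

# Newton inversion of the trigamma function (solve trigamma(y) = x, x > 0)
.trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) .stopf("trigamma inverse needs a positive finite argument")
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-12) break
  }
  y
}

#' Fit the variance prior of the moderated t-test
#'
#' Method-of-moments fit on the log sample variances under the scaled-F
#' marginal `s^2 ~ s0^2 * F(df_res, d0)`: the empirical mean and variance of
#' `log s^2` are matched to their digamma/trigamma expressions. When the
#' empirical variance of `log s^2` does not exceed `trigamma(df_res/2)` —
#' i.e. sampling variation alone explains all the spread — the prior degrees
#' of freedom are infinite and every posterior variance collapses to
#' `s0_sq`.
#'
#' @param s2_values per-protein pooled sample variances; at least 10 finite
#'   positive values are required.
#' @param df_res residual degrees of freedom of each variance
#'   (`n_a + n_b - 2` for a two-group design).
#' @return list with `d0` (prior df, possibly `Inf`) and `s0_sq`
#'   (prior variance).
#' @export
fit_variance_prior <- function(s2_values, df_res) {
  if (length(df_res) != 1L || !is.finite(df_res) || df_res <= 0) {
    .stopf("df_res must be a single positive value")
  }
  s2 <- s2_values[is.finite(s2_values) & s2_values > 0]
  if (all(s2_values == 0, na.rm = TRUE)) .stopf("all sample variances are zero")
  if (length(s2) < 10L) {
    .stopf("need >= 10 finite positive variances to fit the prior (got %d)", length(s2))
  }
  z <- log(s2)
  e <- z - digamma(df_res / 2) + log(df_res / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - trigamma(df_res / 2)
  if (excess > 0) {
    d0 <- 2 * .trigamma_inverse(excess)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-sample t-test for one contrast in one preparation
#'
#' For each protein computes the log2 fold change `mean(a) - mean(b)`, the
#' pooled two-sample variance, the posterior (shrunk) variance
#' `(d0*s0_sq + df_res*s2) / (d0 + df_res)`, the moderated t-statistic on
#' `df_res + d0` degrees of freedom, a two-sided p-value, and the
#' standard-normal Z-score equivalent of the t-statistic (see [t_to_z()]).
#'
#' @param matrix a `norm_matrix` with no missing values in the tested
#'   columns (run imputation first).
#' @param group_a,group_b disjoint character vectors of sample ids; the fold
#'   change is `a` minus `b`, so for the enrichment contrast `a` is the
#'   basal immunoprecipitate and `b` the IgG control, and for the
#'   responsiveness contrast `a` is insulin and `b` basal.
#' @param prior optional list `(d0, s0_sq)`; fitted from the data with
#'   [fit_variance_prior()] when `NULL`. `d0 = 0` gives the ordinary pooled
#'   t-test; `d0 = Inf` uses the common prior variance for every protein.
#' @param contrast,preparation labels carried into the result.
#' @return a `moderated_test` data.frame with one row per protein
#'   (`protein_id, contrast, preparation, log_fc, s2, s2_post, t_mod,
#'   df_total, p_two, z`) and the prior as attributes.
#' @export
moderated_t_test <- function(matrix, group_a, group_b, prior = NULL,
                             contrast = "enrichment", preparation = NA_character_) {
  stopifnot(inherits(matrix, "norm_matrix"))
  if (length(intersect(group_a, group_b))) .stopf("groups must be disjoint")
  missing_cols <- setdiff(c(group_a, group_b), colnames(matrix$values))
  if (length(missing_cols)) {
    .stopf("sample(s) not in matrix: %s", paste(missing_cols, collapse = ", "))
  }
  a <- matrix$values[, group_a, drop = FALSE]
  b <- matrix$values[, group_b, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) .stopf("each group needs >= 2 samples")
  if (anyNA(a) || anyNA(b)) {
    .stopf("tested columns contain missing values; impute before testing")
  }
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  log_fc <- ma - mb
  df_res <- na + nb - 2L
  s2 <- (rowSums((a - ma)^2) + rowSums((b - mb)^2)) / df_res
  if (is.null(prior)) prior <- fit_variance_prior(s2, df_res)
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    (d0 * s0_sq + df_res * s2) / (d0 + df_res)
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, log_fc / se, ifelse(log_fc == 0, 0, sign(log_fc) * Inf))
  df_total <- df_res + d0
  p_two <- if (is.infinite(df_total)) {
    2 * stats::pnorm(-abs(t_mod))
  } else {
    2 * stats::pt(-abs(t_mod), df_total)
  }
  p_two <- pmax(p_two, .Machine$double.xmin)
  out <- data.frame(protein_id = rownames(matrix$values),
                    contrast = contrast, preparation = preparation,
                    log_fc = log_fc, s2 = s2, s2_post = s2_post,
                    t_mod = t_mod, df_total = df_total, p_two = p_two,
                    z = t_to_z(t_mod, df_total),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, d0 = d0, s0_sq = s0_sq, df_res = df_res,
            n_a = na, n_b = nb,
            class = c("moderated_test", "data.frame"))
}

#' Convert t-statistics to standard-normal Z-scores
#'
#' Maps each t-statistic to the standard-normal quantile with the same
#' lower-tail probability under the t distribution with `df_total` degrees
#' of freedom. Computed tail-wise on the log scale so the conversion stays
#' accurate far into the tails; `|z|` is capped at 8.2, the practical limit
#' of double-precision normal tail probabilities. Non-finite t-statistics
#' propagate as the capped value of matching sign, with a warning.
#'
#' @param t numeric vector of t-statistics.
#' @param df_total degrees of freedom (positive; `Inf` allowed, giving
#'   `z = t` up to the cap). Recycled against `t`.
#' @return numeric vector of Z-scores.
#' @export
t_to_z <- function(t, df_total) {
  if (any(!is.finite(df_total) & !is.infinite(df_total)) || any(df_total <= 0)) {
    .stopf("df_total must be positive")
  }
  n <- max(length(t), length(df_total))
  t <- rep_len(t, n); df_total <- rep_len(df_total, n)
  z <- numeric(n)
  fin <- is.finite(t)
  if (any(!fin)) {
    warning(sprintf("%d non-finite t-statistic(s) capped", sum(!fin)))
    z[!fin] <- ifelse(is.na(t[!fin]), 0, sign(t[!fin]) * 8.2)
  }
  if (any(fin)) {
    tf <- t[fin]; dff <- df_total[fin]
    lp <- ifelse(is.infinite(dff),
                 stats::pnorm(-abs(tf), log.p = TRUE),
                 stats::pt(-abs(tf), dff, log.p = TRUE))
    z[fin] <- sign(tf) * (-stats::qnorm(lp, log.p = TRUE))
  }
  pmin(pmax(z, -8.2), 8.2)
}
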