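# Directional (quadrant) integration of per-preparation Z-scores.
#
# A protein counts as enriched only if it moves up in BOTH the LDM and pHS
# immunoisolations, and as insulin-responsive only if it moves down in both.
# The quadrant test projects the Z-vector (z_LDM, z_pHS) onto the quadrant's
# diagonal unit direction and takes the one-sided upper normal tail of the
# projection — a Stouffer combination along a direction. Discordant proteins
# (one strongly up, one strongly down) project near zero and can never reach
# significance in either quadrant.

#' Integrate two preparation Z-scores along a quadrant direction
#'
#' @param z_ldm,z_phs numeric vectors of Z-scores (recycled to a common
#'   length).
#' @param direction unit 2-vector; `c(1, 1)/sqrt(2)` tests the positive
#'   quadrant (concordant increase), `c(-1, -1)/sqrt(2)` the negative
#'   quadrant (concordant decrease).
#' @param protein_id optional protein identifiers.
#' @param contrast label carried into the result.
#' @return an `integration_result` data.frame: `protein_id, contrast,
#'   z_ldm, z_phs, z_int, p_int` where `z_int = direction . (z_ldm, z_phs)`
#'   and `p_int` is its upper-tail standard-normal probability.
#' @export
integrate_direction <- function(z_ldm, z_phs, direction = c(1, 1) / sqrt(2),
                                protein_id = NULL, contrast = "enrichment") {
  if (length(direction) != 2L || abs(sqrt(sum(direction^2)) - 1) > 1e-8) {
    .stopf("direction must be a unit 2-vector")
  }
  n <- max(length(z_ldm), length(z_phs))
  z_ldm <- rep_len(z_ldm, n); z_phs <- rep_len(z_phs, n)
  if (is.null(protein_id)) protein_id <- rep(NA_character_, n)
  z_int <- direction[1L] * z_ldm + direction[2L] * z_phs
  p_int <- stats::pnorm(z_int, lower.tail = FALSE)
  structure(data.frame(protein_id = protein_id, contrast = contrast,
                       z_ldm = z_ldm, z_phs = z_phs,
                       z_int = z_int, p_int = p_int,
                       stringsAsFactors = FALSE, row.names = NULL),
            direction = direction,
            class = c("integration_result", "data.frame"))
}

#' @rdname integrate_direction
#' @param test_ldm,test_phs `moderated_test` results for the same contrast in
#'   the two preparations; proteins are matched by id.
#' @param quadrant `"positive"` (enrichment) or `"negative"`
#'   (insulin responsiveness).
#' @export
integrate_tests <- function(test_ldm, test_phs,
                            quadrant = c("positive", "negative")) {
  quadrant <- match.arg(quadrant)
  ids <- intersect(test_ldm$protein_id, test_phs$protein_id)
  if (!length(ids)) .stopf("no shared proteins between the two preparations")
  zl <- test_ldm$z[match(ids, test_ldm$protein_id)]
  zp <- test_phs$z[match(ids, test_phs$protein_id)]
  dir <- if (quadrant == "positive") c(1, 1) / sqrt(2) else c(-1, -1) / sqrt(2)
  integrate_direction(zl, zp, dir, protein_id = ids,
                      contrast = test_ldm$contrast[1L])
}

# condition pair (a, b) and quadrant for each named contrast
.contrast_spec <- function(contrast) {
  switch(contrast,
         enrichment = list(a = "basal", b = "IgG", quadrant = "positive"),
         responsiveness = list(a = "insulin", b = "basal", quadrant = "negative"),
         .stopf("unknown contrast '%s'", contrast))
}

#' Permutation oracle for the integrated p-value
#'
#' Validation-only companion to [integrate_direction()]: recomputes the
#' integrated statistic under random relabeling of the two condition labels
#' within each preparation and returns the empirical upper-tail p-value of
#' the observed statistic (with add-one continuity correction). The
#' moderated-variance prior is fitted once on the observed labels and held
#' fixed across permutations.
#'
#' @param matrix a complete (imputed) `norm_matrix`.
#' @param protein_id the protein to test.
#' @param contrast `"enrichment"` or `"responsiveness"`.
#' @param n_perm number of random relabelings, at least 1000.
#' @param seed integer seed.
#' @param prior optional `(d0, s0_sq)` list used for both the observed and
#'   the permuted statistics instead of the fitted prior. `list(d0 = 0)`
#'   makes the statistic the ordinary pooled t, which is exactly
#'   studentized: its conditional permutation distribution matches the t
#'   reference closely, so this setting gives the sharpest validation of
#'   the integration itself. With moderation (`d0 > 0`) the shrunk
#'   denominator is only partially studentized and per-protein agreement is
#'   correspondingly looser.
#' @return the empirical p-value (single numeric).
#' @export
permutation_oracle_p <- function(matrix, protein_id, contrast = "enrichment",
                                 n_perm = 10000L, seed = 0L, prior = NULL) {
  stopifnot(inherits(matrix, "norm_matrix"))
  if (n_perm < 1000L) {
    .stopf("n_perm = %d gives p-value resolution %.3g; need n_perm >= 1000",
           n_perm, 1 / (n_perm + 1))
  }
  if (!protein_id %in% rownames(matrix$values)) {
    .stopf("protein '%s' not in matrix", protein_id)
  }
  spec <- .contrast_spec(contrast)
  design <- matrix$design
  preps <- intersect(.preparations, unique(design$preparation))
  cols_a <- lapply(preps, function(p) .design_cols(design, p, spec$a))
  cols_b <- lapply(preps, function(p) .design_cols(design, p, spec$b))
  n_a <- lengths(cols_a); n_b <- lengths(cols_b)
  n_distinct <- prod(choose(n_a + n_b, n_a))
  if (n_distinct < 1000) {
    .stopf(paste0("only %d distinct relabelings for these group sizes ",
                  "(attainable p-value resolution %.3g); oracle not usable"),
           n_distinct, 1 / n_distinct)
  }
  dir <- if (spec$quadrant == "positive") c(1, 1) / sqrt(2) else c(-1, -1) / sqrt(2)

  # fixed priors from the observed labels, one per preparation
  priors <- lapply(seq_along(preps), function(i) {
    if (!is.null(prior)) {
      return(list(d0 = prior$d0, s0_sq = if (is.null(prior$s0_sq)) 0 else prior$s0_sq))
    }
    tst <- moderated_t_test(matrix, cols_a[[i]], cols_b[[i]],
                            contrast = contrast, preparation = preps[i])
    list(d0 = attr(tst, "d0"), s0_sq = attr(tst, "s0_sq"))
  })

  z_one <- function(x, na, nb, prior) {
    a <- x[seq_len(na)]; b <- x[na + seq_len(nb)]
    df_res <- na + nb - 2
    s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df_res
    s2_post <- if (is.infinite(prior$d0)) prior$s0_sq else {
      (prior$d0 * prior$s0_sq + df_res * s2) / (prior$d0 + df_res)
    }
    tt <- (mean(a) - mean(b)) / sqrt(s2_post * (1 / na + 1 / nb))
    t_to_z(tt, df_res + prior$d0)
  }

  vals <- lapply(seq_along(preps), function(i) {
    unname(matrix$values[protein_id, c(cols_a[[i]], cols_b[[i]])])
  })
  z_obs <- vapply(seq_along(preps), function(i) {
    z_one(vals[[i]], n_a[i], n_b[i], priors[[i]])
  }, numeric(1))
  stat_obs <- sum(dir * z_obs)

  set.seed(seed)
  stat_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    zp <- vapply(seq_along(preps), function(i) {
      z_one(sample(vals[[i]]), n_a[i], n_b[i], priors[[i]])
    }, numeric(1))
    stat_perm[b] <- sum(dir * zp)
  }
  (1 + sum(stat_perm >= stat_obs)) / (n_perm + 1)
}
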