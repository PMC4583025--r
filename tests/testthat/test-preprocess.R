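test_that("MAD normalization removes column shifts and scale differences", {
  des <- make_design(n_rep = 2L)
  set.seed(42)
  base <- matrix(rnorm(50 * 12, 22, 1.5), 50)

  # column 2 = column 1 + 3: identical after normalization
  shifted <- base
  shifted[, 2] <- shifted[, 1] + 3
  nm <- log2_mad_normalize(make_norm_matrix(shifted, des))
  expect_equal(nm$values[, 1], nm$values[, 2], tolerance = 1e-12)

  # distinct scales per column: medians and MADs all equal afterwards,
  # verified by direct recomputation
  scaled <- sweep(sweep(base, 2, seq(0.5, 2, length.out = 12), "*"),
                  2, seq(-3, 3, length.out = 12), "+")
  nm2 <- log2_mad_normalize(make_norm_matrix(scaled, des))
  meds <- apply(nm2$values, 2, median)
  mads <- apply(nm2$values, 2, mad)
  expect_equal(diff(range(meds)), 0, tolerance = 1e-9)
  expect_equal(diff(range(mads)), 0, tolerance = 1e-9)

  # missing mask untouched
  holes <- base
  holes[cbind(1:10, rep(1:4, length.out = 10))] <- NA
  nm3 <- log2_mad_normalize(make_norm_matrix(holes, des))
  expect_identical(unname(is.na(nm3$values)), is.na(holes))
})

test_that("normalization is idempotent and errors on degenerate columns", {
  des <- make_design()
  set.seed(7)
  m <- matrix(rnorm(40 * 12, 22, 2), 40)
  once <- log2_mad_normalize(make_norm_matrix(m, des))
  twice <- log2_mad_normalize(once)
  expect_equal(once$values, twice$values, tolerance = 1e-9)

  allmiss <- m
  allmiss[, 5] <- NA
  expect_error(log2_mad_normalize(make_norm_matrix(allmiss, des)),
               des$sample_id[5])
  constant <- m
  constant[, 3] <- 22
  expect_error(log2_mad_normalize(make_norm_matrix(constant, des)),
               "zero MAD")
})

test_that("completeness filter requires every basal replicate of each preparation", {
  des <- make_design()
  m <- matrix(22, 4, 12)
  # protein 2 misses one LDM basal replicate; protein 3 misses a pHS basal;
  # protein 4 misses only an IgG value (basal rule must ignore it)
  ldm_basal <- which(des$preparation == "LDM" & des$condition == "basal")
  phs_basal <- which(des$preparation == "pHS" & des$condition == "basal")
  igg <- which(des$condition == "IgG")
  m[2, ldm_basal[1]] <- NA
  m[3, phs_basal[2]] <- NA
  m[4, igg[1]] <- NA
  nm <- make_norm_matrix(m, des)
  ids <- rownames(nm$values)

  filt <- filter_complete_in_replicates(nm)
  expect_setequal(filt$sets$LDM, ids[c(1, 3, 4)])
  expect_setequal(filt$sets$pHS, ids[c(1, 2, 4)])
  expect_setequal(rownames(filt$merged$values), ids[c(1, 4)])
  # proteins complete in exactly one preparation are reported on the side
  expect_setequal(filt$partial$protein_id, ids[c(2, 3)])
})

test_that("completeness filter matches brute-force enumeration of presence patterns", {
  des <- make_design()
  ldm_basal <- cols_of(des, "LDM", "basal")
  phs_basal <- cols_of(des, "pHS", "basal")
  # all 2^4 presence patterns over the four basal columns
  pat <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), 4)))
  m <- matrix(22, nrow(pat), 12)
  colnames(m) <- des$sample_id
  for (i in seq_len(nrow(pat))) {
    m[i, c(ldm_basal, phs_basal)][!pat[i, ]] <- NA
  }
  nm <- make_norm_matrix(m, des)
  filt <- filter_complete_in_replicates(nm)
  expect_ldm <- rowSums(pat[, 1:2]) == 2L
  expect_phs <- rowSums(pat[, 3:4]) == 2L
  expect_setequal(filt$sets$LDM, rownames(nm$values)[expect_ldm])
  expect_setequal(filt$sets$pHS, rownames(nm$values)[expect_phs])
  expect_setequal(rownames(filt$merged$values),
                  rownames(nm$values)[expect_ldm & expect_phs])
})

test_that("variance trim removes round(fraction * N) highest-variability proteins", {
  des <- make_design()
  set.seed(3)
  m <- matrix(rnorm(20 * 12, 22, 0.3), 20)
  m[7, ] <- 22 + rnorm(12, 0, 5)  # the one irreproducible protein
  nm <- make_norm_matrix(m, des)

  trimmed <- trim_top_variance(nm, 0.05)  # N = 20 -> exactly 1 removed
  expect_equal(nrow(trimmed$values), 19L)
  expect_false(rownames(nm$values)[7] %in% rownames(trimmed$values))

  expect_identical(trim_top_variance(nm, 0)$values, nm$values)
  expect_error(trim_top_variance(nm, 1), "fraction")
  expect_error(trim_top_variance(nm, -0.1), "fraction")

  # N = 304, fraction 0.05 -> round(15.2) = 15 removed; and the output size
  # is always N - round(fraction * N) (rounding half away from zero)
  set.seed(4)
  big <- make_norm_matrix(matrix(rnorm(304 * 12, 22, 1), 304), des)
  expect_equal(nrow(trim_top_variance(big, 0.05)$values), 304L - 15L)
  for (n in c(10L, 30L, 99L)) {
    sub <- make_norm_matrix(matrix(rnorm(n * 12, 22, 1), n), des)
    for (f in c(0.05, 0.1, 0.5)) {
      expect_equal(nrow(trim_top_variance(sub, f)$values),
                   n - sign(f * n) * floor(abs(f * n) + 0.5))
    }
  }
})

test_that("trim variability is replicate-level, not between-condition signal", {
  # a strongly insulin-responsive protein with tight replicates must rank
  # below a noisy flat protein
  des <- make_design()
  set.seed(9)
  m <- matrix(rnorm(20 * 12, 22, 0.2), 20)
  resp <- which(des$condition == "insulin")
  m[1, resp] <- m[1, resp] - 3           # big biological effect, tiny noise
  m[2, ] <- 22 + rnorm(12, 0, 2)         # pure irreproducibility
  nm <- make_norm_matrix(m, des)
  trimmed <- trim_top_variance(nm, 0.05)
  expect_true(rownames(nm$values)[1] %in% rownames(trimmed$values))
  expect_false(rownames(nm$values)[2] %in% rownames(trimmed$values))
})

test_that("imputation parameters are the condition minimum and lowest-quartile SD", {
  des <- make_design(n_rep = 4L)
  m <- matrix(NA_real_, 2, nrow(des))
  # LDM IgG columns hold the worked distribution {20..27}
  igg_ldm <- which(des$preparation == "LDM" & des$condition == "IgG")
  m[, igg_ldm] <- matrix(c(20, 21, 22, 23, 24, 25, 26, 27), 2, byrow = TRUE)
  other <- setdiff(seq_len(nrow(des)), igg_ldm)
  m[, other] <- 24
  nm <- make_norm_matrix(m, des)

  par <- estimate_imputation_params(nm, conditions = "IgG", seed = 0)
  row <- par[par$preparation == "LDM", ]
  expect_equal(row$mu, 20)
  expect_equal(row$sigma, sd(c(20, 21)))  # values in the lowest quartile

  # degenerate distribution: mu = the value, sigma = 0
  m2 <- m
  m2[, igg_ldm] <- 23
  par2 <- estimate_imputation_params(make_norm_matrix(m2, des), conditions = "IgG")
  expect_equal(par2[par2$preparation == "LDM", c("mu", "sigma")],
               data.frame(mu = 23, sigma = 0), ignore_attr = TRUE)

  # too few observed values in a condition is an estimation error
  m3 <- m
  m3[, igg_ldm] <- NA
  m3[1, igg_ldm[1:3]] <- 21
  expect_error(estimate_imputation_params(make_norm_matrix(m3, des),
                                          conditions = "IgG"), "IgG")
})

test_that("imputation draws from the minimum-value distribution and never touches data", {
  des <- make_design()
  set.seed(5)
  m <- matrix(rnorm(30 * 12, 22, 1), 30)
  miss_cells <- cbind(sample(30, 12), sample(which(des$condition != "basal"), 12, replace = TRUE))
  m[miss_cells] <- NA
  nm <- make_norm_matrix(m, des)
  par <- estimate_imputation_params(nm, seed = 11)
  imp <- impute_missing(nm, par)

  obs <- !is.na(m)
  expect_identical(imp$values[obs], m[obs])      # observed cells bit-identical
  expect_false(anyNA(imp$values[, des$condition != "basal"]))
  expect_identical(which(imp$imputed_mask), which(is.na(m)))

  # no missing cells: identity
  full <- make_norm_matrix(matrix(rnorm(10 * 12, 22, 1), 10), des)
  pfull <- estimate_imputation_params(full)
  expect_identical(impute_missing(full, pfull)$values, full$values)

  # sigma = 0 gives exactly mu
  par0 <- par
  par0$sigma[] <- 0
  imp0 <- impute_missing(nm, par0)
  for (k in seq_len(nrow(par0))) {
    cols <- cols_of(des, par0$preparation[k], par0$condition[k])
    vals <- imp0$values[, cols][is.na(m[, match(cols, des$sample_id)])]
    if (length(vals)) expect_true(all(vals == par0$mu[k]))
  }

  # missing basal cells stay missing (basal not in the imputed set)
  m4 <- m
  m4[1, which(des$condition == "basal")[1]] <- NA
  imp4 <- impute_missing(make_norm_matrix(m4, des), par)
  expect_true(is.na(imp4$values[1, which(des$condition == "basal")[1]]))
})

test_that("imputed values are seed-reproducible and independent of row order", {
  des <- make_design()
  set.seed(6)
  m <- matrix(rnorm(25 * 12, 22, 1), 25)
  m[cbind(1:10, rep(which(des$condition == "IgG"), length.out = 10))] <- NA
  nm <- make_norm_matrix(m, des)
  par <- estimate_imputation_params(nm, seed = 3)
  a <- impute_missing(nm, par)
  b <- impute_missing(nm, par)
  expect_identical(a$values, b$values)

  # permuting input rows permutes output rows identically
  perm <- sample(25)
  nm_p <- nm
  nm_p$values <- nm$values[perm, ]
  par_p <- estimate_imputation_params(nm_p, seed = 3)
  c_ <- impute_missing(nm_p, par_p)
  expect_identical(c_$values, a$values[perm, ])
})

test_that("averaged imputation has the stated mean and variance", {
  # single-draw mean over 10,000 cells lies within 4*sigma/sqrt(10000) of mu
  des <- make_design()
  mu <- 17.3; sigma <- 0.8
  m <- matrix(rnorm(10000 * 12, 22, 0.5), 10000)
  igg <- which(des$condition == "IgG")
  m[, igg[1]] <- NA
  nm <- make_norm_matrix(m, des)
  par <- estimate_imputation_params(nm, conditions = "IgG",
                                    n_imputations = 1L, seed = 2)
  par$mu[] <- mu
  par$sigma[] <- sigma
  imp <- impute_missing(nm, par)
  draws <- imp$values[, igg[1]]
  expect_lt(abs(mean(draws) - mu), 4 * sigma / sqrt(10000))

  # with n_imputations draws averaged, the per-cell SD shrinks by sqrt(n)
  par20 <- par
  attr(par20, "n_imputations") <- 20L
  imp20 <- impute_missing(nm, par20)
  sd20 <- sd(imp20$values[, igg[1]])
  expect_lt(abs(sd20 - sigma / sqrt(20)), 0.1 * sigma / sqrt(20) * 3)
})
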