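toy_matrix <- function(x, conditions = c("cellulose", "glucose"),
                       reps = ncol(x) / 2, logged = FALSE) {
  colnames(x) <- paste(rep(conditions, each = reps), 1:reps, sep = "_")
  rownames(x) <- sprintf("P%02d", seq_len(nrow(x)))
  abundance_matrix(x, data.frame(sample = colnames(x),
                                 condition = rep(conditions, each = reps),
                                 replicate = rep(1:reps, 2)),
                   logged = logged)
}

test_that("valid-value filtering matches a row-scan oracle and is idempotent", {
  # observed once per condition in a 2x3 design -> removed
  x <- matrix(NA_real_, 2, 6)
  x[1, c(1, 4)] <- 10          # one observation per condition
  x[2, ] <- 10                 # fully observed
  m <- toy_matrix(x)
  f <- filter_valid(m)
  expect_identical(rownames(f$intensities), "P02")
  # oracle on a simulated 1000-protein matrix
  sim <- simulate_abundance_matrix(1000, censor_quantile = 0.3, seed = 8)
  kept <- rownames(filter_valid(sim)$intensities)
  cellu <- sim$design$sample[sim$design$condition == "cellulose"]
  gluc <- sim$design$sample[sim$design$condition == "glucose"]
  oracle_keep <- apply(sim$intensities, 1, function(r) {
    sum(!is.na(r[cellu])) >= 2 || sum(!is.na(r[gluc])) >= 2
  })
  expect_identical(kept, rownames(sim$intensities)[oracle_keep])
  expect_identical(rownames(filter_valid(filter_valid(sim))$intensities),
                   kept)
})

test_that("log2 transform maps values and preserves missingness", {
  x <- matrix(c(8, 1, NA, 2, 4, 16, 32, 64), 2, 4)
  m <- toy_matrix(x)
  lt <- log2_transform(m)
  expect_equal(lt$intensities[1, 1], 3)
  expect_equal(lt$intensities[2, 1], 0)
  expect_true(is.na(lt$intensities[1, 2]))
  bad <- toy_matrix(x)
  bad$intensities[2, 2] <- -1  # corrupt after construction
  expect_error(log2_transform(bad), "non-positive intensity")
})

test_that("downshift imputation has the prescribed moments and determinism", {
  set.seed(1)
  n <- 2e5
  x <- matrix(rnorm(n * 4, 25, 2), ncol = 4)
  x[sample(n, 1e5), 1] <- NA
  m <- toy_matrix(x, logged = TRUE)
  mu <- mean(x[, 1], na.rm = TRUE); s <- sd(x[, 1], na.rm = TRUE)
  imp <- impute_downshift(m, seed = 77)
  vals <- imp$intensities[is.na(x[, 1]), 1]
  expect_lt(abs(mean(vals) - (mu - 1.8 * s)) / abs(mu - 1.8 * s), 0.01)
  expect_lt(abs(sd(vals) - 0.3 * s) / (0.3 * s), 0.01)
  # observed cells never altered; same seed -> identical output
  expect_identical(imp$intensities[!is.na(x)], x[!is.na(x)])
  imp2 <- impute_downshift(m, seed = 77)
  expect_identical(imp$intensities, imp2$intensities)
  # no missing values -> identity
  full <- toy_matrix(matrix(rnorm(20, 25, 1), 5, 4), logged = TRUE)
  expect_identical(impute_downshift(full, seed = 1)$intensities,
                   full$intensities)
})

test_that("quantile normalization equalizes column distributions", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  q <- quantile_normalize(x)
  expect_equal(unname(q[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q[, 2]), c(2.5, 3.5, 4.5))
  # identical columns unchanged
  xx <- matrix(rep(c(5, 1, 9), 2), 3, 2)
  expect_equal(unname(quantile_normalize(xx)), unname(xx))
  # defining property on a random matrix: sorted columns all equal
  set.seed(3)
  r <- toy_matrix(matrix(rlnorm(200 * 6, 10, 1), 200, 6))
  qn <- quantile_normalize(r)$intensities
  sorted <- apply(qn, 2, sort)
  expect_equal(max(apply(sorted, 1, function(v) diff(range(v)))), 0,
               tolerance = 1e-12)
  # within-column ranks preserved
  expect_identical(apply(qn, 2, rank), apply(r$intensities, 2, rank))
})

test_that("t statistic with s0 = 0 matches the hand-computed Student t", {
  set.seed(9)
  x <- matrix(rnorm(30, 20, 1), 5, 6)
  m <- toy_matrix(x, logged = TRUE)
  res <- permutation_fdr_ttest(m, s0 = 0, n_perm = 20, seed = 1)
  for (i in 1:5) {
    expect_equal(res$table$t[i], oracle_student_t(x[i, 1:3], x[i, 4:6]),
                 tolerance = 1e-10)
  }
  # identical groups: t = 0 and nothing significant
  xx <- matrix(rep(c(20, 21, 22, 23, 24), 6), 5, 6)
  rr <- permutation_fdr_ttest(toy_matrix(xx, logged = TRUE), s0 = 0.1,
                              n_perm = 20, seed = 1)
  expect_true(all(rr$table$t == 0))
  expect_false(any(rr$table$significant))
})

test_that("global-null simulation stays below the FDR cut-off", {
  sim <- simulate_abundance_matrix(1000, n_upregulated = 0,
                                   censor_quantile = 0.05, seed = 12)
  m <- impute_downshift(log2_transform(filter_valid(sim)), seed = 12)
  res <- permutation_fdr_ttest(m, n_perm = 250, seed = 12)
  expect_lte(mean(res$table$significant), 0.01)
})

test_that("planted effects are recovered with controlled FDR", {
  sim <- simulate_abundance_matrix(1000, n_upregulated = 50, effect_size = 2,
                                   censor_quantile = 0.05, seed = 31)
  truth <- attr(sim, "truth")$upregulated_set
  m <- impute_downshift(log2_transform(filter_valid(sim)), seed = 31)
  res <- permutation_fdr_ttest(m, n_perm = 250, seed = 31)
  called <- res$table$protein[res$table$significant]
  recall <- mean(truth %in% called)
  fdr <- if (length(called)) mean(!called %in% truth) else 0
  expect_gte(recall, 0.8)
  expect_lte(fdr, 0.1)
})

test_that("degenerate permutation spaces fall back to exhaustive enumeration", {
  x <- matrix(rnorm(20, 20, 1), 5, 4)
  m <- toy_matrix(x, logged = TRUE)
  expect_warning(permutation_fdr_ttest(m, n_perm = 100, seed = 1),
                 "degenerate permutation space")
})

test_that("volcano table is sorted by p with consistent transforms", {
  set.seed(2)
  sim <- simulate_abundance_matrix(200, n_upregulated = 10,
                                   censor_quantile = 0, seed = 5)
  res <- permutation_fdr_ttest(log2_transform(sim), n_perm = 50, seed = 5)
  v <- volcano_table(res)
  expect_false(is.unsorted(-v$neg_log10_p))
  expect_true(all(v$protein[v$significant] %in% res$table$protein))
  i <- match(v$protein, res$table$protein)
  expect_equal(v$neg_log10_p, -log10(res$table$p[i]))
  ann <- data.frame(protein = v$protein[1], label = "x")
  va <- volcano_table(res, ann)
  expect_identical(va$label[va$protein == v$protein[1]], "x")
})
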