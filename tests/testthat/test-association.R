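make_expo <- function(H, sigs = NULL) {
  if (is.null(sigs)) sigs <- paste0("sig", seq_len(nrow(H)))
  dimnames(H) <- list(sigs, sprintf("S%03d", seq_len(ncol(H))))
  cohortsig:::new_exposure_matrix(H)
}

# plant a vector of relative sig1 loads (values in [0, 1]) by pairing it
# with a complementary second signature
make_expo1 <- function(loads) make_expo(rbind(loads, 1 - loads))

test_that("group comparison: degenerate equality, symmetry, exclusions", {
  H <- matrix(c(rep(0.3, 10), rep(0.7, 10)), 2, 10, byrow = TRUE)
  expo <- make_expo(H)
  cov <- data.frame(sample_id = expo$sample_ids,
                    smoking_category = rep(c("heavy", "never"), each = 5))
  res <- compare_loads_by_group(expo, "sig1", cov)
  expect_equal(res$effect, 0)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)

  set.seed(3)
  H2 <- rbind(runif(20), runif(20))
  expo2 <- make_expo(H2)
  cov2 <- data.frame(sample_id = expo2$sample_ids,
                     smoking_category = c(rep(c("heavy", "never"), 9),
                                          "unknown", NA))
  r1 <- compare_loads_by_group(expo2, "sig1", cov2,
                               groups = c("heavy", "never"))
  r2 <- compare_loads_by_group(expo2, "sig1", cov2,
                               groups = c("never", "heavy"))
  expect_equal(r1$effect, -r2$effect)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$excluded, 2)
  expect_equal(sum(r1$group_sizes), 18)

  cov3 <- data.frame(sample_id = expo2$sample_ids,
                     smoking_category = c("heavy", rep("never", 19)))
  expect_cohortsig_error(compare_loads_by_group(expo2, "sig1", cov3),
                         "insufficient_data_error")
})

test_that("group comparison detects a planted smoking effect", {
  tr <- simulate_exposures(120, c("S", "K", "flat"), seed = 61)
  sc <- simulate_covariates(
    tr, list(list(covariate = "smoking", signature = "S", effect = 2)),
    seed = 62,
    smoking_categories = rep(c("heavy", "never"), each = 60))
  rel <- sweep(sc$truth$H_true, 2, colSums(sc$truth$H_true), "/")
  expo <- make_expo(rel, rownames(rel))
  res <- compare_loads_by_group(expo, "S", sc$covariates)
  expect_gt(res$effect, 0)
  expect_lt(res$p_value, 0.01)
})

test_that("median-split halves test: split rule and planted link", {
  # n = 4 distinct loads -> 2/2 halves
  expo <- make_expo1(c(0.1, 0.2, 0.3, 0.4))
  cov <- data.frame(sample_id = expo$sample_ids,
                    packs_per_year = c(1, 2, 30, 40))
  res <- load_rank_halves_test(expo, "sig1", cov)
  expect_equal(unname(res$group_sizes), c(2, 2))
  expect_gt(res$effect, 0)

  # monotone load-covariate link: heavy half mean exceeds light half mean
  set.seed(9)
  loads <- runif(40)
  packs <- 10 + 50 * loads + rnorm(40, 0, 2)
  expo2 <- make_expo1(loads)
  cov2 <- data.frame(sample_id = expo2$sample_ids, packs_per_year = packs)
  res2 <- load_rank_halves_test(expo2, "sig1", cov2)
  expect_gt(res2$effect, 0)
  expect_lt(res2$p_value, 0.01)

  cov3 <- data.frame(sample_id = expo2$sample_ids,
                     packs_per_year = NA_real_)
  expect_cohortsig_error(load_rank_halves_test(expo2, "sig1", cov3),
                         "insufficient_data_error")
})

test_that("median-split test holds its type-I error under the null", {
  reject <- 0
  for (s in 1:1000) {
    set.seed(s)
    expo <- make_expo1(runif(60))
    cov <- data.frame(sample_id = expo$sample_ids,
                      packs_per_year = rnorm(60, 20, 5))
    p <- load_rank_halves_test(expo, "sig1", cov)$p_value
    if (p < 0.05) reject <- reject + 1
  }
  expect_gte(reject / 1000, 0.03)
  expect_lte(reject / 1000, 0.07)
})

test_that("load-expression correlation: identity, invariance, errors", {
  set.seed(12)
  loads <- runif(30)
  expo <- make_expo1(loads)
  cov <- data.frame(sample_id = expo$sample_ids, expression.G1 = loads)
  for (m in c("spearman", "pearson")) {
    res <- correlate_load_expression(expo, "sig1", cov, "G1", method = m)
    expect_equal(res$effect, 1)
  }
  # jointly permuting the pairing leaves the coefficient unchanged
  cov2 <- data.frame(sample_id = expo$sample_ids,
                     expression.G1 = loads + rnorm(30, 0, 0.1))
  r0 <- correlate_load_expression(expo, "sig1", cov2, "G1")
  perm <- sample(30)
  r1 <- correlate_load_expression(expo, "sig1", cov2[perm, ], "G1")
  expect_equal(r1$effect, r0$effect)

  cov3 <- data.frame(sample_id = expo$sample_ids, expression.G1 = 2)
  expect_cohortsig_error(correlate_load_expression(expo, "sig1", cov3, "G1"),
                         "validation_error")
  expect_cohortsig_error(
    correlate_load_expression(expo, "sig1", cov2[1:2, ], "G1"),
    "insufficient_data_error")
})

test_that("planted MLH1-like anti-correlation is detected", {
  tr <- simulate_exposures(80, c("H", "flat"), seed = 63)
  sc <- simulate_covariates(
    tr, list(list(covariate = "expression", signature = "H", effect = 3,
                  gene = "MLH1")), seed = 64)
  rel <- sweep(sc$truth$H_true, 2, colSums(sc$truth$H_true), "/")
  expo <- make_expo(rel, rownames(rel))
  res <- correlate_load_expression(expo, "H", sc$covariates, "MLH1")
  expect_lt(res$effect, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("expression-ordered summary sorts by ratio with flags last", {
  expo <- make_expo(matrix(runif(8), 2, 4), c("H", "L"))
  cov <- data.frame(sample_id = expo$sample_ids,
                    expression.MLH1 = c(0.1, 0.5, 0.2, 0.9),
                    expression.TBP = c(1, 1, 1, 0),
                    msi_status = c("MSS", "MSI-H", "MSS", "MSS"))
  out <- expression_ordered_summary(expo, c("H", "L"), cov, "MLH1")
  expect_equal(nrow(out), 4)
  expect_equal(out$sample[1:3], c("S001", "S003", "S002"))
  expect_true(out$flagged[4])
  expect_true(is.na(out$ratio[4]))
  expect_true(all(c("load.H", "load.L", "msi_status") %in% names(out)))
})

test_that("high-load samples concentrate at low expression ratios", {
  tr <- simulate_exposures(120, c("H", "L"), seed = 65)
  sc <- simulate_covariates(
    tr, list(list(covariate = "expression", signature = "H", effect = 4,
                  gene = "MLH1")), seed = 66)
  rel <- sweep(sc$truth$H_true, 2, colSums(sc$truth$H_true), "/")
  expo <- make_expo(rel, rownames(rel))
  out <- expression_ordered_summary(expo, c("H", "L"), sc$covariates,
                                    "MLH1")
  top_load <- out$`load.H` >= quantile(out$`load.H`, 0.75)
  low_half <- seq_len(nrow(out)) <= nrow(out) / 2
  # enrichment of top-quartile loads in the low-ratio half
  expect_gt(sum(top_load & low_half), 0.7 * sum(top_load))
})

test_that("associations are invariant to sample ordering", {
  set.seed(21)
  H <- rbind(runif(30), runif(30))
  expo <- make_expo(H)
  cov <- data.frame(sample_id = expo$sample_ids,
                    smoking_category = sample(c("heavy", "never"), 30, TRUE),
                    packs_per_year = rnorm(30, 20, 5))
  perm <- sample(30)
  r0 <- compare_loads_by_group(expo, "sig1", cov)
  r1 <- compare_loads_by_group(expo, "sig1", cov[perm, ])
  expect_equal(r1$p_value, r0$p_value)
  expect_equal(r1$effect, r0$effect)
  h0 <- load_rank_halves_test(expo, "sig1", cov)
  h1 <- load_rank_halves_test(expo, "sig1", cov[perm, ])
  expect_equal(h1$p_value, h0$p_value)
})
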