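quick_sim_config <- function(out_dir = NULL, seed = 11, ...) {
  run_config(
    simulation = list(n_samples = 16, signature_names = c("S", "K"),
                      burden_lognormal_params = c(log(150), 0.4),
                      effects = list(list(covariate = "smoking",
                                          signature = "S", effect = 2))),
    rank_range = 2:3, n_bootstrap = 3L, n_restarts = 3L,
    seed = seed, out_dir = out_dir, ...)
}

test_that("run_config validates its invariants", {
  expect_cohortsig_error(run_config(), "validation_error")
  expect_cohortsig_error(
    run_config(simulation = list(), inputs = list(mutations = "x")),
    "validation_error")
  expect_cohortsig_error(
    run_config(inputs = list(mutations = "/nonexistent/path.tsv",
                             genome = "/nonexistent/genome.fa")),
    "validation_error")
})

test_that("run_extraction produces a complete, re-parseable run directory", {
  out <- withr::local_tempdir()
  res <- run_extraction(quick_sim_config(out_dir = out))
  expect_true(all(file.exists(file.path(out, c(
    "catalog.tsv", "mutations.tsv", "genome.fa", "cgi.bed",
    "covariates.tsv", "ground_truth.json", "signatures.tsv",
    "exposures_raw.tsv", "exposures_relative.tsv", "consensus.tsv",
    "rank_report.tsv", "rank_report.json", "annotation.tsv",
    "profile.json", "manifest.json")))))
  # outputs round trip through the package's own readers
  cat2 <- read_catalog_tsv(file.path(out, "catalog.tsv"))
  expect_equal(cat2$counts, res$cohort$catalog$counts)
  W2 <- cohortsig:::read_matrix_tsv(file.path(out, "signatures.tsv"))
  expect_equal(W2, res$extraction$signatures$W, tolerance = 1e-5)
  rel <- cohortsig:::read_matrix_tsv(file.path(out,
                                               "exposures_relative.tsv"))
  expect_equal(unname(colSums(rel)), rep(1, ncol(rel)), tolerance = 1e-4)
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$seed, 11)
  expect_equal(manifest$chosen_rank,
               res$extraction$rank_report$chosen_rank)
})

test_that("reruns with the same seed are identical; different seeds differ", {
  r1 <- run_extraction(quick_sim_config(seed = 13))
  r2 <- run_extraction(quick_sim_config(seed = 13))
  expect_identical(r1$cohort$catalog$counts, r2$cohort$catalog$counts)
  expect_identical(r1$extraction$signatures$W, r2$extraction$signatures$W)
  expect_identical(r1$extraction$exposures$H, r2$extraction$exposures$H)
  r3 <- run_extraction(quick_sim_config(seed = 14))
  expect_false(identical(r1$cohort$catalog$counts,
                         r3$cohort$catalog$counts))
})

test_that("non-CGI ablation conserves counts and reports cosines", {
  cfg <- run_config(
    simulation = list(n_samples = 14,
                      signature_names = c("nonCGI", "flat"),
                      burden_lognormal_params = c(log(120), 0.4),
                      cgi_fraction = 0.2),
    rank_range = 2, n_bootstrap = 3L, n_restarts = 3L, seed = 17)
  res <- run_noncgi_ablation(cfg)
  expect_equal(nrow(res$report), 8)
  full_n <- sum(res$full$cohort$catalog$counts)
  abl_n <- sum(res$ablated$catalog$counts)
  expect_equal(full_n - abl_n, res$n_removed)
  expect_true(all(colSums(res$ablated$catalog$counts) <=
                    colSums(res$full$cohort$catalog$counts)))
  expect_s3_class(res$ablated$extraction$rank_report,
                  "RankSelectionReport")
})

test_that("outlier ablation is a no-op without dominant samples", {
  res <- run_outlier_ablation(quick_sim_config(seed = 19))
  expect_match(res$note, "no dominant sample")
  expect_equal(nrow(res$outliers), 0)
})

test_that("outlier ablation removes the dominant sample and re-runs", {
  # plant a sample holding the overwhelming share of the K signature
  cfg <- quick_sim_config(seed = 23)
  full <- run_extraction(cfg)
  expo <- full$extraction$exposures
  H <- expo$H
  k <- expo$signature_ids[1]
  H[k, ] <- 0.01
  H[k, 5] <- 100
  full$extraction$exposures <-
    cohortsig:::new_exposure_matrix(H, expo$sample_ids,
                                    expo$signature_ids)
  res <- run_outlier_ablation(cfg, signature_id = k, full = full)
  expect_equal(unique(res$outliers$sample), expo$sample_ids[5])
  expect_false(expo$sample_ids[5] %in%
                 res$ablated$extraction$exposures$sample_ids)
})

test_that("a sample carrying a signature single-handedly drops the rank when ablated", {
  # one tumor with a huge burden of an otherwise-absent process creates a
  # cohort-level signature; removing it loses that signature
  tr <- simulate_exposures(40, c("S", "K", "nonCGI", "UVB"), seed = 3131)
  tr$H_true["UVB", ] <- 0.5
  tr$H_true["UVB", 7] <- 4000
  M <- simulate_catalog(tr, seed = 3132)
  rs1 <- select_rank(M, 2:6, n_bootstrap = 8, n_restarts = 10, seed = 777)
  expect_equal(rs1$chosen_rank, 4)
  be <- rs1$fits[[as.character(rs1$chosen_rank)]]
  ann <- match_signatures(be$signatures, make_archetypes(), 0.8)
  uvb_sig <- ann$signature_id[ann$archetype == "UVB"][1]
  out <- detect_outlier_samples(be$exposures, uvb_sig, 0.5)
  expect_equal(out$sample, "S007")
  expect_gt(out$share, 0.9)
  M2 <- M$counts[, setdiff(colnames(M$counts), out$sample)]
  rs2 <- select_rank(M2, 2:6, n_bootstrap = 8, n_restarts = 10,
                     seed = 778)
  expect_equal(rs2$chosen_rank, rs1$chosen_rank - 1)
})

test_that("CLI: simulate -> catalog -> extract chain and exit codes", {
  out <- withr::local_tempdir()
  st <- cohortsig_main(c("simulate", paste0("--out_dir=", out),
                         "--n_samples=8", "--signatures=S,K",
                         "--seed=29", "--cgi_fraction=0.3"))
  expect_equal(st, 0L)
  expect_true(file.exists(file.path(out, "mutations.tsv")))

  out2 <- withr::local_tempdir()
  st2 <- cohortsig_main(c("catalog",
                          paste0("--mutations=", file.path(out, "mutations.tsv")),
                          paste0("--genome=", file.path(out, "genome.fa")),
                          paste0("--out_dir=", out2)))
  expect_equal(st2, 0L)
  cat_cli <- read_catalog_tsv(file.path(out2, "catalog.tsv"))
  cat_sim <- read_catalog_tsv(file.path(out, "catalog.tsv"))
  expect_equal(cat_cli$counts, cat_sim$counts)

  # config file + flag override
  cfg_file <- file.path(out, "run.cfg")
  writeLines(c("n_samples=8", "signatures=S,K", "rank_min=2",
               "rank_max=2", "n_bootstrap=2", "n_restarts=2"), cfg_file)
  out3 <- withr::local_tempdir()
  st3 <- cohortsig_main(c("extract", paste0("--config=", cfg_file),
                          paste0("--out_dir=", out3), "--seed=31"))
  expect_equal(st3, 0L)
  expect_true(file.exists(file.path(out3, "manifest.json")))

  # exit codes: unknown command and missing inputs are validation errors
  expect_equal(suppressMessages(cohortsig_main("frobnicate")), 2L)
  expect_equal(suppressMessages(
    cohortsig_main(c("catalog", "--mutations=/does/not/exist.tsv",
                     "--genome=/does/not/exist.fa"))), 2L)
  expect_equal(cohortsig_main(character(0)), 0L)  # usage
})
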