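# Ground-truth simulation: planted signatures, exposures and catalogs.
#
# The generative model is deliberately simple and fully parameterized:
# per-sample mutation burdens are log-normal (heavy-tailed, as observed in
# sequenced cohorts), per-sample signature mixture weights are Dirichlet,
# and observed catalogs are multinomial (or Poisson) draws around the
# expected counts W_true %*% H_true.

new_ground_truth <- function(W_true, H_true, sample_ids, signature_names,
                             covariates = NULL, seed = NA_integer_,
                             params = list()) {
  structure(list(W_true = W_true, H_true = H_true,
                 sample_ids = sample_ids,
                 signature_names = signature_names,
                 covariates = covariates, seed = seed, params = params),
            class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth:", length(x$signature_names), "signatures x",
      length(x$sample_ids), "samples\n")
  cat("  signatures:", paste(x$signature_names, collapse = ", "), "\n")
  cat("  median burden:", stats::median(colSums(x$H_true)), "\n")
  invisible(x)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = k)
  sweep(g, 2, colSums(g), "/")
}

#' Simulate ground-truth signature exposures
#'
#' Draws per-sample total mutation burdens from a log-normal distribution
#' (rounded to integers), per-sample signature mixture weights from a
#' Dirichlet, and forms the expected exposure matrix
#' `H_true[i, j] = burden_j * mixweight[i, j]`.
#'
#' @param n_samples number of samples.
#' @param signature_names archetype names to plant (1 to 7 of them).
#' @param burden_lognormal_params `c(meanlog, sdlog)` of the burden
#'   distribution. Default `c(log(300), 0.7)`: a median burden of 300
#'   SNVs/sample with a heavy right tail, typical of exome cohorts.
#' @param mix_dirichlet_alpha Dirichlet concentration vector (recycled to
#'   the number of signatures). Default 3: moderately concentrated
#'   mixtures (per-signature weight CV around 0.4), so cohorts carry
#'   every planted process in most samples rather than one process per
#'   sample.
#' @param archetypes an [make_archetypes()] library supplying W_true.
#' @param seed integer seed.
#' @return a `GroundTruth` object.
#' @export
simulate_exposures <- function(n_samples,
                               signature_names,
                               burden_lognormal_params = c(log(300), 0.7),
                               mix_dirichlet_alpha = 3,
                               archetypes = make_archetypes(),
                               seed = 1L) {
  assert_that(length(signature_names) >= 1, "signature list must be non-empty")
  assert_that(length(signature_names) <= 7,
              "at most 7 signatures supported, got %d",
              length(signature_names))
  assert_that(n_samples >= 1, "n_samples must be >= 1")
  missing_sigs <- setdiff(signature_names, colnames(archetypes))
  assert_that(length(missing_sigs) == 0, "unknown archetype(s): %s",
              paste(missing_sigs, collapse = ", "))

  r <- length(signature_names)
  alpha <- rep_len(mix_dirichlet_alpha, r)
  with_seed(seed, {
    burdens <- round(stats::rlnorm(n_samples,
                                   meanlog = burden_lognormal_params[1],
                                   sdlog = burden_lognormal_params[2]))
    mix <- rdirichlet(n_samples, alpha)
    H_true <- sweep(mix, 2, burdens, "*")
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    dimnames(H_true) <- list(signature_names, sample_ids)
    W_true <- unclass(archetypes)[, signature_names, drop = FALSE]
    new_ground_truth(W_true, H_true, sample_ids, signature_names,
                     seed = seed,
                     params = list(
                       burden_lognormal_params = burden_lognormal_params,
                       mix_dirichlet_alpha = alpha))
  })
}

new_catalog <- function(counts, sample_ids, scheme = category_scheme(),
                        provenance = list()) {
  storage.mode(counts) <- "double"
  assert_that(nrow(counts) == length(scheme),
              "catalog must have %d rows", length(scheme))
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "catalog counts must be non-negative integers")
  dimnames(counts) <- list(as.vector(unclass(scheme)), sample_ids)
  structure(list(counts = counts, sample_ids = sample_ids, scheme = scheme,
                 provenance = provenance),
            class = "MutationCatalog")
}

#' @export
print.MutationCatalog <- function(x, ...) {
  cat("MutationCatalog:", nrow(x$counts), "categories x",
      ncol(x$counts), "samples;", sum(x$counts), "mutations\n")
  if (length(x$provenance))
    cat("  provenance:", jsonlite::toJSON(x$provenance, auto_unbox = TRUE),
        "\n")
  invisible(x)
}

#' Simulate an observed mutation catalog around a ground truth
#'
#' Each sample's 96-category count vector is drawn with expectation
#' `W_true %*% H_true[, j]`: multinomially (the sample's total count is
#' fixed at its planted burden) or as independent Poisson cells.
#'
#' @param truth a `GroundTruth`.
#' @param noise `"multinomial"` (default) or `"poisson"`.
#' @param seed integer seed.
#' @return a `MutationCatalog`.
#' @export
simulate_catalog <- function(truth, noise = c("multinomial", "poisson"),
                             seed = 1L) {
  assert_that(inherits(truth, "GroundTruth"), "truth must be a GroundTruth")
  if (!is.character(noise) || !all(noise %in% c("multinomial", "poisson")))
    stop_validation("unknown noise model: %s", paste(noise, collapse = ","))
  noise <- match.arg(noise)
  lambda <- truth$W_true %*% truth$H_true
  with_seed(seed, {
    counts <- matrix(0, nrow = nrow(lambda), ncol = ncol(lambda))
    for (j in seq_len(ncol(lambda))) {
      tot <- sum(truth$H_true[, j])
      if (noise == "multinomial") {
        if (tot > 0)
          counts[, j] <- stats::rmultinom(1, size = round(tot),
                                          prob = lambda[, j])
      } else {
        counts[, j] <- stats::rpois(nrow(lambda), lambda[, j])
      }
    }
    new_catalog(counts, truth$sample_ids,
                provenance = list(source = "simulate_catalog", noise = noise,
                                  seed = seed))
  })
}

#' Simulate clinical covariates linked to planted exposures
#'
#' Assigns covariate values and, where an effect is planted, rescales the
#' corresponding ground-truth exposures so that covariate groups differ in
#' signature load. Supported effects:
#'
#' * `covariate = "smoking"`: samples are labeled heavy/light/never
#'   smokers; the named signature's exposure is multiplied by `effect` in
#'   heavy smokers, `sqrt(effect)` in light smokers, 1 in never smokers
#'   (a steadily decreasing scale). Packs/year are drawn per group.
#' * `covariate = "msi"`: samples are labeled MSS/MSI-L/MSI-H; MSI-H
#'   samples get the named signature's exposure multiplied by `effect`,
#'   and carry POLE mutations at higher frequency.
#' * `covariate = "expression"`: a gene-expression column (`gene` field,
#'   e.g. "MLH1") monotonically anti-correlated with the named
#'   signature's relative exposure via
#'   `expr = exp(-effect * relative_load) * noise`; a constant-scale
#'   housekeeping column `TBP` is added alongside.
#'
#' `effect = 1` plants no effect (group distributions identical in law).
#'
#' @param truth a `GroundTruth`.
#' @param effect_spec list of effects; each a list with fields
#'   `covariate`, `signature`, `effect`, and `gene` for expression.
#' @param seed integer seed.
#' @param smoking_categories,msi_statuses optional fixed per-sample label
#'   vectors overriding the random group assignment (for balanced
#'   designs).
#' @return list with the rescaled `truth` and a `covariates` data frame
#'   (one row per sample).
#' @export
simulate_covariates <- function(truth, effect_spec = list(), seed = 1L,
                                smoking_categories = NULL,
                                msi_statuses = NULL) {
  assert_that(inherits(truth, "GroundTruth"), "truth must be a GroundTruth")
  for (eff in effect_spec) {
    assert_that(!is.null(eff$covariate) && !is.null(eff$signature),
                "each effect needs 'covariate' and 'signature' fields")
    assert_that(eff$signature %in% truth$signature_names,
                "effect on unknown signature '%s'", eff$signature)
    assert_that(eff$covariate %in% c("smoking", "msi", "expression"),
                "unknown covariate type '%s'", eff$covariate)
  }
  n <- length(truth$sample_ids)
  with_seed(seed, {
    if (is.null(smoking_categories))
      smoking_categories <- sample(c("heavy", "light", "never", "unknown"),
                                   n, replace = TRUE,
                                   prob = c(0.3, 0.25, 0.4, 0.05))
    if (is.null(msi_statuses))
      msi_statuses <- sample(c("MSS", "MSI-L", "MSI-H"), n, replace = TRUE,
                             prob = c(0.6, 0.2, 0.2))
    assert_that(length(smoking_categories) == n && length(msi_statuses) == n,
                "covariate label vectors must have one entry per sample")
    cov <- data.frame(
      sample_id = truth$sample_ids,
      smoking_category = smoking_categories,
      packs_per_year = NA_real_,
      msi_status = msi_statuses,
      pole_mutant = FALSE,
      site = sample(c("primary", "metastasis"), n, replace = TRUE,
                    prob = c(0.8, 0.2)),
      stringsAsFactors = FALSE
    )
    cov$packs_per_year <- ifelse(
      cov$smoking_category == "never", 0,
      ifelse(cov$smoking_category == "unknown", NA_real_,
             ifelse(cov$smoking_category == "heavy",
                    stats::rlnorm(n, log(50), 0.3),
                    stats::rlnorm(n, log(15), 0.3))))
    cov$pole_mutant <- ifelse(cov$msi_status == "MSI-H",
                              stats::runif(n) < 0.4,
                              stats::runif(n) < 0.02)

    H <- truth$H_true
    for (eff in effect_spec) {
      i <- match(eff$signature, truth$signature_names)
      k <- eff$effect
      if (eff$covariate == "smoking") {
        mult <- c(heavy = k, light = sqrt(k), never = 1, unknown = 1)
        H[i, ] <- H[i, ] * mult[cov$smoking_category]
      } else if (eff$covariate == "msi") {
        H[i, cov$msi_status == "MSI-H"] <-
          H[i, cov$msi_status == "MSI-H"] * k
      }
    }
    # expression effects act on the *final* relative loads
    rel <- sweep(H, 2, pmax(colSums(H), .Machine$double.eps), "/")
    has_expression <- FALSE
    for (eff in effect_spec) {
      if (eff$covariate != "expression") next
      gene <- if (is.null(eff$gene)) "MLH1" else eff$gene
      i <- match(eff$signature, truth$signature_names)
      cov[[paste0("expression.", gene)]] <-
        exp(-eff$effect * rel[i, ]) * stats::rlnorm(n, 0, 0.2)
      has_expression <- TRUE
    }
    if (has_expression)
      cov[["expression.TBP"]] <- stats::rlnorm(n, 0, 0.1)

    truth$H_true <- H
    truth$covariates <- cov
    list(truth = truth, covariates = cov)
  })
}
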