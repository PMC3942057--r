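# NMF under the generalized Kullback-Leibler divergence. Counts are
# Poisson-like, so the KL objective with Lee-Seung/Brunet multiplicative
# updates is the natural fit; the update loop itself lives in src/.

as_catalog_matrix <- function(M) {
  if (inherits(M, "MutationCatalog")) M <- M$counts
  assert_that(is.matrix(M) && is.numeric(M), "M must be a numeric matrix")
  assert_that(all(M >= 0), "M must be non-negative")
  if (all(M == 0)) stop_validation("M is all zero; nothing to factorize")
  M
}

#' Factorize a catalog by multiplicative-update KL-NMF
#'
#' Minimizes the generalized Kullback-Leibler divergence
#' `D(M || WH) = sum(M log(M/WH) - M + WH)` by alternating multiplicative
#' updates. The objective is non-increasing at every iteration; the run
#' stops when its relative change between checkpoints falls below `tol`,
#' or at `max_iter`. Initial `W` and `H` entries are i.i.d. uniform(0, 1]
#' scaled to the data mean, drawn from `seed`, so runs are fully
#' reproducible.
#'
#' @param M non-negative matrix (or `MutationCatalog`), categories x
#'   samples.
#' @param r factorization rank, `1 <= r <= min(dim(M))`.
#' @param seed integer seed for the initialization.
#' @param max_iter iteration cap (default 10000).
#' @param tol relative objective-change threshold (default 1e-6).
#' @param check_every check convergence every this many iterations.
#' @return list with `W_raw`, `H_raw`, `divergence`, `iterations`, and the
#'   objective `trace` at checkpoints.
#' @export
nmf_factorize <- function(M, r, seed = 1L, max_iter = 10000L, tol = 1e-6,
                          check_every = 10L) {
  M <- as_catalog_matrix(M)
  assert_that(r >= 1 && r <= min(dim(M)),
              "rank r=%s out of range [1, %d]", format(r), min(dim(M)))
  scale <- sqrt(mean(M) / (0.25 * r))
  init <- with_seed(seed, {
    list(W = matrix(stats::runif(nrow(M) * r), nrow(M), r) * scale,
         H = matrix(stats::runif(r * ncol(M)), r, ncol(M)) * scale)
  })
  fit <- .kl_nmf_run(M, init$W, init$H, as.integer(max_iter), tol,
                     as.integer(check_every), TRUE)
  list(W_raw = fit$W, H_raw = fit$H, divergence = fit$divergence,
       iterations = fit$iterations, trace = fit$trace)
}

best_of_restarts <- function(M, r, n_restarts, seed, max_iter, tol,
                             refine_max_iter = 2000L, refine_tol = 1e-7) {
  best <- NULL
  for (t in seq_len(n_restarts)) {
    fit <- nmf_factorize(M, r, seed = derive_seed(seed, t),
                         max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$divergence < best$divergence) best <- fit
  }
  # short restarts locate the basin; polish only the winner to tight
  # tolerance
  if (refine_max_iter > 0) {
    f <- .kl_nmf_run(M, best$W_raw, best$H_raw,
                     as.integer(refine_max_iter), refine_tol, 10L, TRUE)
    best <- list(W_raw = f$W, H_raw = f$H, divergence = f$divergence,
                 iterations = best$iterations + f$iterations,
                 trace = c(best$trace, f$trace))
  }
  best
}

#' Generalized KL divergence between a matrix and its reconstruction
#' @param M non-negative matrix.
#' @param W,H factor matrices.
#' @export
kl_divergence <- function(M, W, H) .gkl_divergence(M, W, H)

new_signature_set <- function(W, signature_ids = NULL,
                              scheme = category_scheme(),
                              stability = NULL) {
  assert_that(is.matrix(W) && all(W >= 0), "W must be non-negative")
  cs <- colSums(W)
  assert_that(all(cs > 0), "signature columns must not be all-zero")
  W <- sweep(W, 2, cs, "/")
  if (is.null(signature_ids)) signature_ids <- sprintf("sig%d", seq_len(ncol(W)))
  dimnames(W) <- list(as.vector(unclass(scheme)), signature_ids)
  structure(list(W = W, signature_ids = signature_ids, scheme = scheme,
                 stability = stability),
            class = "SignatureSet")
}

#' @export
print.SignatureSet <- function(x, ...) {
  cat("SignatureSet:", ncol(x$W), "signatures x", nrow(x$W), "categories\n")
  if (!is.null(x$stability))
    cat("  stability (silhouette):",
        paste(sprintf("%s=%.3f", x$signature_ids, x$stability),
              collapse = ", "), "\n")
  invisible(x)
}

new_exposure_matrix <- function(H, sample_ids = NULL,
                                signature_ids = NULL) {
  assert_that(is.matrix(H) && all(H >= 0), "H must be non-negative")
  if (is.null(sample_ids)) sample_ids <- colnames(H)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(ncol(H)))
  if (is.null(signature_ids)) signature_ids <- rownames(H)
  if (is.null(signature_ids)) signature_ids <- sprintf("sig%d", seq_len(nrow(H)))
  dimnames(H) <- list(signature_ids, sample_ids)
  rel <- relative_exposures(H)
  structure(list(H = H, relative = rel$relative,
                 degenerate = rel$degenerate, sample_ids = sample_ids,
                 signature_ids = signature_ids),
            class = "ExposureMatrix")
}

#' @export
print.ExposureMatrix <- function(x, ...) {
  cat("ExposureMatrix:", nrow(x$H), "signatures x", ncol(x$H), "samples\n")
  if (any(x$degenerate))
    cat("  ", sum(x$degenerate), "degenerate (zero-load) samples\n")
  invisible(x)
}

#' Per-sample relative signature loads
#'
#' Divides each sample's exposure vector by its total, so relative loads
#' sum to 1 per sample. All-zero columns are assigned the uniform vector
#' `1/r` and flagged as degenerate.
#'
#' @param H non-negative exposure matrix (signatures x samples) or an
#'   `ExposureMatrix`.
#' @return list with `relative` (columns summing to 1) and `degenerate`
#'   (logical per sample).
#' @export
relative_exposures <- function(H) {
  if (inherits(H, "ExposureMatrix")) H <- H$H
  assert_that(is.matrix(H) && all(H >= 0), "H must be non-negative")
  tot <- colSums(H)
  degenerate <- tot == 0
  rel <- H
  rel[, !degenerate] <- sweep(H[, !degenerate, drop = FALSE], 2,
                              tot[!degenerate], "/")
  if (any(degenerate)) rel[, degenerate] <- 1 / nrow(H)
  list(relative = rel, degenerate = stats::setNames(degenerate, colnames(H)))
}

# Refit exposures against a fixed signature matrix on the original counts,
# by H-only multiplicative updates (deterministic: uniform initialization).
refit_exposures <- function(M, W, max_iter = 5000L, tol = 1e-8) {
  r <- ncol(W)
  H0 <- matrix(rep(pmax(colSums(M), 1e-6) / r, each = r), nrow = r)
  fit <- .kl_nmf_run(M, W, H0, as.integer(max_iter), tol, 10L, FALSE)
  list(H = fit$H, divergence = fit$divergence)
}
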