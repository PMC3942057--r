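# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures.

# a small planted cohort: exposures + catalog (+ optionally genome)
small_cohort <- function(n_samples = 20, sigs = c("S", "K", "nonCGI", "flat"),
                         seed = 7, with_genome = FALSE, cgi_fraction = 0.2) {
  truth <- simulate_exposures(n_samples, sigs, seed = seed)
  catalog <- simulate_catalog(truth, seed = seed + 1)
  out <- list(truth = truth, catalog = catalog)
  if (with_genome) {
    gen <- simulate_genome_and_mutations(catalog, seed = seed + 2,
                                         cgi_fraction = cgi_fraction)
    out <- c(out, gen)
  }
  out
}

# exactly low-rank noiseless matrix w h^T (+ more ranks if needed)
exact_rank_matrix <- function(r = 1, n = 96, m = 8, seed = 3) {
  set.seed(seed)
  W <- matrix(rexp(n * r), n, r)
  H <- matrix(rexp(r * m) * 50, r, m)
  list(M = W %*% H, W = W, H = H)
}

# independent KL-NMF oracle: box-constrained quasi-Newton (L-BFGS-B) on
# the same objective, multi-start; independent of the multiplicative
# update path under test.
oracle_kl_nmf <- function(V, r, n_starts = 8, seed = 1) {
  n <- nrow(V); m <- ncol(V)
  obj <- function(par) {
    W <- matrix(par[1:(n * r)], n, r)
    H <- matrix(par[-(1:(n * r))], r, m)
    WH <- pmax(W %*% H, 1e-12)
    sum(ifelse(V > 0, V * log(V / WH) - V + WH, WH))
  }
  grad <- function(par) {
    W <- matrix(par[1:(n * r)], n, r)
    H <- matrix(par[-(1:(n * r))], r, m)
    WH <- pmax(W %*% H, 1e-12)
    R <- 1 - V / WH
    c(R %*% t(H), t(W) %*% R)
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    set.seed(seed * 1000 + s)
    par0 <- runif((n + m) * r, 0.1, 2) * sqrt(mean(V) / r)
    o <- stats::optim(par0, obj, grad, method = "L-BFGS-B", lower = 1e-9,
                      control = list(maxit = 5000, factr = 10))
    best <- min(best, o$value)
  }
  best
}

# exhaustive assignment oracle: enumerate permutations
oracle_best_assignment <- function(S) {
  r <- nrow(S); k <- ncol(S)
  stopifnot(r <= k)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- -Inf
  for (cols in utils::combn(k, r, simplify = FALSE))
    for (p in perms(cols))
      best <- max(best, sum(S[cbind(seq_len(r), p)]))
  best
}

# brute-force stranded-context enumerator used as the oracle for the
# pyrimidine collapse: builds the expected label from first principles.
oracle_category <- function(five, ref, three, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (ref %in% c("C", "T"))
    sprintf("%s(%s>%s)%s", five, ref, alt, three)
  else
    sprintf("%s(%s>%s)%s", comp[three], comp[ref], comp[alt], comp[five])
}

expect_cohortsig_error <- function(expr, class) {
  expect_error(expr, class = class)
}
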