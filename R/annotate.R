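# Annotation of extracted signatures against the named archetypes, cohort
# profiles, and dominant-sample (outlier) detection.

#' Cosine similarity between two non-negative vectors
#' @param a,b non-negative vectors of equal length, not all-zero.
#' @return `dot(a, b) / (||a|| ||b||)`, in `[0, 1]` for non-negative
#'   inputs.
#' @export
cosine_similarity <- function(a, b) {
  assert_that(length(a) == length(b), "vectors must have equal length")
  assert_that(all(a >= 0) && all(b >= 0), "vectors must be non-negative")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  assert_that(na > 0 && nb > 0, "zero vector has no cosine similarity")
  sum(a * b) / (na * nb)
}

# Exact maximum-weight injective assignment of rows to columns of a
# similarity matrix, by dynamic programming over column bitmasks.
# Deterministic tie-break: earlier rows/columns win on equal totals.
assign_optimal <- function(S) {
  r <- nrow(S); k <- ncol(S)
  nmask <- bitwShiftL(1L, k)
  neg <- -Inf
  f <- matrix(neg, r + 1L, nmask)
  choice <- matrix(NA_integer_, r + 1L, nmask)  # column chosen for row i
  f[1L, 1L] <- 0
  for (i in seq_len(r)) {
    for (mask in 0:(nmask - 1L)) {
      base <- f[i, mask + 1L]
      if (!is.finite(base)) next
      # leave row i unassigned
      if (base > f[i + 1L, mask + 1L]) {
        f[i + 1L, mask + 1L] <- base
        choice[i + 1L, mask + 1L] <- 0L
      }
      for (j in seq_len(k)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) != 0L) next
        v <- base + S[i, j]
        if (v > f[i + 1L, mask + bit + 1L]) {
          f[i + 1L, mask + bit + 1L] <- v
          choice[i + 1L, mask + bit + 1L] <- j
        }
      }
    }
  }
  want <- min(r, k)
  masks <- 0:(nmask - 1L)
  popcnt <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1L))) != 0L), numeric(1))
  cand <- masks[popcnt == want]
  best_mask <- cand[which.max(f[r + 1L, cand + 1L])]
  # backtrack
  assign <- integer(r)
  mask <- best_mask
  for (i in rev(seq_len(r))) {
    j <- choice[i + 1L, mask + 1L]
    assign[i] <- j
    if (j > 0L) mask <- mask - bitwShiftL(1L, j - 1L)
  }
  list(assign = assign, total = f[r + 1L, best_mask + 1L])
}

#' Match extracted signatures to named archetypes
#'
#' Computes all pairwise cosine similarities and finds the one-to-one
#' assignment of signatures to archetypes maximizing total similarity
#' (exact, via bitmask dynamic programming). Signatures left without an
#' exclusive archetype (only possible when there are more signatures than
#' archetypes) are matched greedily to their best archetype and flagged
#' non-exclusive. A signature is `matched` when its similarity reaches
#' `threshold`.
#'
#' @param signatures a `SignatureSet` (or bare 96 x r column-stochastic
#'   matrix).
#' @param archetypes an `ArchetypeLibrary`.
#' @param threshold similarity needed to call a match (default 0.8).
#' @return a `SignatureAnnotation`: data frame with columns
#'   `signature_id, archetype, similarity, matched, exclusive`, plus the
#'   full similarity matrix in `attr(, "similarity")`.
#' @export
match_signatures <- function(signatures, archetypes, threshold = 0.8) {
  W <- if (inherits(signatures, "SignatureSet")) signatures$W else signatures
  A <- unclass(archetypes)
  assert_that(nrow(W) == nrow(A),
              "signature and archetype category schemes differ in length")
  if (inherits(signatures, "SignatureSet") &&
      !identical(as.vector(unclass(signatures$scheme)), rownames(A)))
    stop_validation("signature and archetype category orderings differ")

  S <- matrix(0, ncol(W), ncol(A),
              dimnames = list(colnames(W), colnames(A)))
  for (i in seq_len(ncol(W)))
    for (j in seq_len(ncol(A)))
      S[i, j] <- cosine_similarity(W[, i], A[, j])

  opt <- assign_optimal(S)
  assign <- opt$assign
  exclusive <- assign > 0L
  # greedy fallback for unassigned signatures (non-exclusive)
  for (i in which(!exclusive)) assign[i] <- which.max(S[i, ])

  ann <- data.frame(
    signature_id = colnames(W),
    archetype = colnames(A)[assign],
    similarity = S[cbind(seq_len(ncol(W)), assign)],
    matched = S[cbind(seq_len(ncol(W)), assign)] >= threshold,
    exclusive = exclusive,
    stringsAsFactors = FALSE
  )
  structure(ann, similarity = S, threshold = threshold,
            class = c("SignatureAnnotation", "data.frame"))
}

#' Summarize matched archetypes into a cohort signature profile
#'
#' The profile of a cohort is the *set* of archetype names its matched
#' signatures map to (deduplicated), plus the count of unmatched
#' ("private") signatures. Profiles compare as sets, supporting the
#' observation that cohorts are distinguished by their combination of
#' signatures rather than by private ones.
#'
#' @param annotations a `SignatureAnnotation`.
#' @param cohort cohort label.
#' @return a `SignatureProfile`: list with `cohort`, `archetypes` (sorted
#'   character set) and `n_unmatched`.
#' @export
build_profile <- function(annotations, cohort = "cohort") {
  assert_that(inherits(annotations, "SignatureAnnotation"),
              "annotations must come from match_signatures()")
  structure(list(cohort = cohort,
                 archetypes = sort(unique(annotations$archetype[annotations$matched])),
                 n_unmatched = sum(!annotations$matched)),
            class = "SignatureProfile")
}

#' @export
print.SignatureProfile <- function(x, ...) {
  cat("SignatureProfile [", x$cohort, "]: {",
      paste(x$archetypes, collapse = ", "), "} +", x$n_unmatched,
      "private\n")
  invisible(x)
}

#' Detect samples dominating a signature's cohort-wide exposure
#'
#' Flags samples whose share of the cohort's total raw exposure to one
#' signature exceeds `dominance_threshold`. Such dominant samples can
#' create cohort-level signatures single-handedly; the ablation workflow
#' re-runs extraction without them and compares ranks and profiles.
#'
#' @param exposures an `ExposureMatrix`.
#' @param signature_id the signature to examine.
#' @param dominance_threshold share of total exposure above which a sample
#'   is an outlier (default 0.5).
#' @return data frame `sample, share`, ordered by decreasing share (zero
#'   rows when no sample dominates).
#' @export
detect_outlier_samples <- function(exposures, signature_id,
                                   dominance_threshold = 0.5) {
  assert_that(inherits(exposures, "ExposureMatrix"),
              "exposures must be an ExposureMatrix")
  assert_that(signature_id %in% exposures$signature_ids,
              "unknown signature '%s'", signature_id)
  v <- exposures$H[signature_id, ]
  tot <- sum(v)
  share <- if (tot > 0) v / tot else rep(0, length(v))
  hit <- share > dominance_threshold
  out <- data.frame(sample = exposures$sample_ids[hit],
                    share = unname(share[hit]),
                    stringsAsFactors = FALSE)
  out[order(-out$share), , drop = FALSE]
}
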