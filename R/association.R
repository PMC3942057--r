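# Load-vs-covariate association analyses: group comparisons of relative
# signature loads, median-split load tests against numeric covariates,
# and load-expression correlations.

new_association_result <- function(test, groups, group_sizes, effect,
                                   statistic, p_value, excluded = 0L,
                                   degenerate = FALSE) {
  structure(list(test = test, groups = groups, group_sizes = group_sizes,
                 effect = effect, statistic = statistic,
                 p_value = p_value, tail = "two-sided",
                 excluded = excluded, degenerate = degenerate),
            class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf("%s: %s (n = %s)\n", x$test,
              paste(x$groups, collapse = " vs "),
              paste(x$group_sizes, collapse = "/")))
  cat(sprintf("  effect = %.4g, statistic = %.4g, p = %.3g (%s)\n",
              x$effect, x$statistic, x$p_value, x$tail))
  if (x$excluded > 0) cat("  excluded (missing):", x$excluded, "\n")
  if (x$degenerate) cat("  degenerate: zero variance in both groups\n")
  invisible(x)
}

get_loads <- function(exposures, signature_id, use_relative = TRUE) {
  assert_that(inherits(exposures, "ExposureMatrix"),
              "exposures must be an ExposureMatrix")
  assert_that(signature_id %in% exposures$signature_ids,
              "unknown signature '%s'", signature_id)
  if (use_relative) exposures$relative[signature_id, ]
  else exposures$H[signature_id, ]
}

welch_or_degenerate <- function(x, y, var_equal = FALSE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(list(statistic = 0, p_value = if (mean(x) == mean(y)) 1 else 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       degenerate = FALSE)
}

#' Compare relative signature loads between two covariate groups
#'
#' Two-sided Welch t-test (pooled-variance by flag) on per-sample loads of
#' one signature between two groups of a categorical covariate (e.g.
#' smokers vs never smokers). Samples with a missing or other covariate
#' value are excluded and tallied.
#'
#' @param exposures an `ExposureMatrix`.
#' @param signature_id signature to test.
#' @param covariates data frame with a `sample_id` column and the grouping
#'   column.
#' @param grouping name of the covariate column (default
#'   `"smoking_category"`).
#' @param groups length-2 character: the two levels to compare (effect =
#'   mean of first minus mean of second).
#' @param use_relative test relative loads (default) or raw exposures.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return an `AssociationResult`.
#' @export
compare_loads_by_group <- function(exposures, signature_id, covariates,
                                   grouping = "smoking_category",
                                   groups = c("heavy", "never"),
                                   use_relative = TRUE,
                                   var_equal = FALSE) {
  assert_that(length(groups) == 2, "exactly two groups must be named")
  assert_that(grouping %in% names(covariates),
              "covariate column '%s' not found", grouping)
  loads <- get_loads(exposures, signature_id, use_relative)
  idx <- match(covariates$sample_id, names(loads))
  keep <- !is.na(idx)
  g <- covariates[[grouping]][keep]
  x <- loads[idx[keep]]
  in1 <- !is.na(g) & g == groups[1]
  in2 <- !is.na(g) & g == groups[2]
  excluded <- sum(!(in1 | in2)) + sum(!keep)
  if (sum(in1) < 2 || sum(in2) < 2)
    stop_insufficient_data("need >= 2 samples per group, got %d/%d",
                           sum(in1), sum(in2))
  tt <- welch_or_degenerate(x[in1], x[in2], var_equal)
  new_association_result(
    test = sprintf("%s t-test of %s load by %s",
                   if (var_equal) "pooled" else "Welch",
                   signature_id, grouping),
    groups = groups, group_sizes = c(sum(in1), sum(in2)),
    effect = mean(x[in1]) - mean(x[in2]),
    statistic = tt$statistic, p_value = tt$p_value,
    excluded = excluded, degenerate = tt$degenerate)
}

#' Compare a numeric covariate between heavy- and light-load halves
#'
#' Splits samples at the median load of a signature — samples at or above
#' the median form the heavy half (ties go heavy) — and Welch-tests the
#' numeric covariate (e.g. packs/year) between halves.
#'
#' @param exposures an `ExposureMatrix`.
#' @param signature_id signature whose load defines the split.
#' @param covariates data frame with `sample_id` and the covariate column.
#' @param covariate name of the numeric covariate column (default
#'   `"packs_per_year"`).
#' @param use_relative split on relative loads (default) or raw.
#' @return an `AssociationResult` (effect = heavy-half mean minus
#'   light-half mean of the covariate).
#' @export
load_rank_halves_test <- function(exposures, signature_id, covariates,
                                  covariate = "packs_per_year",
                                  use_relative = TRUE) {
  assert_that(covariate %in% names(covariates),
              "covariate column '%s' not found", covariate)
  loads <- get_loads(exposures, signature_id, use_relative)
  idx <- match(covariates$sample_id, names(loads))
  v <- suppressWarnings(as.numeric(covariates[[covariate]]))
  keep <- !is.na(idx) & !is.na(v)
  excluded <- sum(!keep)
  if (sum(keep) < 4)
    stop_insufficient_data("need >= 4 samples with a numeric covariate, got %d",
                           sum(keep))
  x <- loads[idx[keep]]; v <- v[keep]
  heavy <- x >= stats::median(x)
  if (sum(heavy) < 2 || sum(!heavy) < 2)
    stop_insufficient_data("median split produced halves of size %d/%d",
                           sum(heavy), sum(!heavy))
  tt <- welch_or_degenerate(v[heavy], v[!heavy])
  new_association_result(
    test = sprintf("Welch t-test of %s by %s-load half", covariate,
                   signature_id),
    groups = c("heavy-load", "light-load"),
    group_sizes = c(sum(heavy), sum(!heavy)),
    effect = mean(v[heavy]) - mean(v[!heavy]),
    statistic = tt$statistic, p_value = tt$p_value,
    excluded = excluded, degenerate = tt$degenerate)
}

#' Correlate signature loads with gene expression
#'
#' Spearman (default; robust to expression scale) or Pearson correlation
#' between a signature's per-sample loads and an expression column, with
#' a two-sided p-value.
#'
#' @param exposures an `ExposureMatrix`.
#' @param signature_id signature to test.
#' @param covariates data frame with `sample_id` and `expression.<gene>`
#'   columns.
#' @param gene gene name (matched as column `expression.<gene>`, or used
#'   verbatim if that column is absent).
#' @param method `"spearman"` or `"pearson"`.
#' @param use_relative use relative loads (default).
#' @return an `AssociationResult` (effect = correlation coefficient).
#' @export
correlate_load_expression <- function(exposures, signature_id, covariates,
                                      gene,
                                      method = c("spearman", "pearson"),
                                      use_relative = TRUE) {
  method <- match.arg(method)
  col <- if (paste0("expression.", gene) %in% names(covariates))
    paste0("expression.", gene) else gene
  assert_that(col %in% names(covariates),
              "expression column for gene '%s' not found", gene)
  loads <- get_loads(exposures, signature_id, use_relative)
  idx <- match(covariates$sample_id, names(loads))
  v <- covariates[[col]]
  keep <- !is.na(idx) & !is.na(v)
  if (sum(keep) < 3)
    stop_insufficient_data("need >= 3 paired observations, got %d", sum(keep))
  x <- loads[idx[keep]]; v <- v[keep]
  if (stats::sd(x) == 0 || stats::sd(v) == 0)
    stop_validation("correlation undefined: constant vector")
  ct <- stats::cor.test(x, v, method = method, exact = FALSE)
  new_association_result(
    test = sprintf("%s correlation of %s load with %s", method,
                   signature_id, gene),
    groups = c(signature_id, gene),
    group_sizes = c(sum(keep), sum(keep)),
    effect = unname(ct$estimate),
    statistic = unname(ct$statistic), p_value = ct$p.value,
    excluded = sum(!keep))
}

#' Samples ordered by expression ratio with signature loads attached
#'
#' Orders samples by the expression of a gene relative to a housekeeping
#' gene (un-logged ratio; `log2 = TRUE` for log-ratio) and attaches the
#' per-sample loads of two signatures plus MSI status where available.
#' Samples with a zero housekeeping value have an undefined ratio: they
#' are flagged and placed last.
#'
#' @param exposures an `ExposureMatrix`.
#' @param signature_ids character of length 2.
#' @param covariates data frame with `sample_id` and expression columns.
#' @param gene numerator gene.
#' @param housekeeping denominator gene (default `"TBP"`).
#' @param log2 report log2 ratios instead.
#' @param use_relative use relative loads (default).
#' @return data frame `sample, ratio, load.<sig1>, load.<sig2>,
#'   msi_status, flagged`, one row per input sample, ordered by ratio.
#' @export
expression_ordered_summary <- function(exposures, signature_ids, covariates,
                                       gene, housekeeping = "TBP",
                                       log2 = FALSE, use_relative = TRUE) {
  assert_that(length(signature_ids) == 2,
              "exactly two signature ids expected")
  gcol <- if (paste0("expression.", gene) %in% names(covariates))
    paste0("expression.", gene) else gene
  hcol <- if (paste0("expression.", housekeeping) %in% names(covariates))
    paste0("expression.", housekeeping) else housekeeping
  assert_that(gcol %in% names(covariates), "gene column '%s' not found", gene)
  assert_that(hcol %in% names(covariates),
              "housekeeping column '%s' not found", housekeeping)
  l1 <- get_loads(exposures, signature_ids[1], use_relative)
  l2 <- get_loads(exposures, signature_ids[2], use_relative)
  idx <- match(covariates$sample_id, names(l1))
  keep <- !is.na(idx)
  hk <- covariates[[hcol]][keep]
  flagged <- hk == 0
  ratio <- ifelse(flagged, NA_real_, covariates[[gcol]][keep] / hk)
  if (log2) ratio <- log2(ratio)
  out <- data.frame(
    sample = covariates$sample_id[keep],
    ratio = ratio,
    l1 = l1[idx[keep]],
    l2 = l2[idx[keep]],
    msi_status = if ("msi_status" %in% names(covariates))
      covariates$msi_status[keep] else NA_character_,
    flagged = flagged,
    stringsAsFactors = FALSE
  )
  names(out)[3:4] <- paste0("load.", signature_ids)
  out <- out[order(out$flagged, out$ratio), , drop = FALSE]
  rownames(out) <- NULL
  out
}
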