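#' Named signature archetypes
#'
#' Idealized 96-category probability vectors for the signature families the
#' package annotates against:
#'
#' * `S` — smoking: uniform mass over all 16 C>A trinucleotide categories
#'   (no favored flanking context).
#' * `UVA` — sun exposure (UVA): C>A with a pyrimidine favored at the 5'
#'   side, i.e. mass on `C(C>A)X` and `T(C>A)X`.
#' * `UVB` — sun exposure (UVB): C>T with a 5' pyrimidine, mass on
#'   `C(C>T)X` and `T(C>T)X`.
#' * `K` — kataegis/APOBEC: C>T and C>G in the TpCpX context, mass on
#'   `T(C>T)X` and `T(C>G)X`.
#' * `L` — microsatellite-stable / MSI-low: mass on `T(C>A)T` and
#'   `T(C>T)G`.
#' * `H` — MSI-high / POLE: mass on `C(C>A)X` and `G(C>T)X`.
#' * `nonCGI` — age-related C>T at CpG dinucleotides: mass on `X(C>T)G`.
#' * `flat` — uniform background over all 96 categories.
#'
#' Each archetype places `1 - leak_fraction` of its mass uniformly on its
#' defining support and spreads the remaining `leak_fraction` over the
#' other categories with mild seeded Dirichlet jitter, emulating the
#' imperfect zeros of empirically extracted signatures.
#'
#' @param leak_fraction proportion of mass outside the defining support,
#'   in `[0, 0.5)`. Default 0.05.
#' @param seed integer seed controlling the jitter of the leaked mass.
#' @return an `ArchetypeLibrary`: a 96 x 8 column-stochastic matrix with
#'   category labels as rownames and archetype names as colnames; the
#'   support of each archetype is kept in `attr(, "support")`.
#' @export
make_archetypes <- function(leak_fraction = 0.05, seed = 1L) {
  assert_that(is.numeric(leak_fraction) && length(leak_fraction) == 1 &&
                leak_fraction >= 0 && leak_fraction < 0.5,
              "leak_fraction must lie in [0, 0.5), got %s",
              format(leak_fraction))
  scheme <- category_scheme()
  labels <- as.vector(unclass(scheme))
  sub <- attr(scheme, "substitution")
  five <- attr(scheme, "five_prime")
  three <- attr(scheme, "three_prime")

  supports <- list(
    S      = sub == "C>A",
    UVA    = sub == "C>A" & five %in% c("C", "T"),
    UVB    = sub == "C>T" & five %in% c("C", "T"),
    K      = sub %in% c("C>T", "C>G") & five == "T",
    L      = (sub == "C>A" & five == "T" & three == "T") |
             (sub == "C>T" & five == "T" & three == "G"),
    H      = (sub == "C>A" & five == "C") | (sub == "C>T" & five == "G"),
    nonCGI = sub == "C>T" & three == "G",
    flat   = rep(TRUE, 96L)
  )

  W <- with_seed(derive_seed(seed, 0L), {
    vapply(supports, function(supp) {
      v <- numeric(96L)
      v[supp] <- (1 - leak_fraction) / sum(supp)
      out <- !supp
      if (any(out) && leak_fraction > 0) {
        jitter <- stats::rgamma(sum(out), shape = 5, rate = 1)
        v[out] <- leak_fraction * jitter / sum(jitter)
      } else if (!any(out)) {
        v[supp] <- v[supp] / sum(v[supp])  # flat: no outside mass to leak
      }
      v
    }, numeric(96L))
  })
  rownames(W) <- labels
  structure(W, scheme = scheme, support = supports,
            leak_fraction = leak_fraction, class = "ArchetypeLibrary")
}

#' @export
print.ArchetypeLibrary <- function(x, ...) {
  cat("ArchetypeLibrary:", ncol(x), "archetypes over", nrow(x),
      "categories\n")
  supp <- attr(x, "support")
  for (nm in colnames(x))
    cat(sprintf("  %-7s support size %d\n", nm, sum(supp[[nm]])))
  invisible(x)
}
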