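BASES <- c("A", "C", "G", "T")
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96-category trinucleotide substitution scheme
#'
#' Every somatic SNV is collapsed onto the pyrimidine strand and classified
#' by its substitution (one of `C>A, C>G, C>T, T>A, T>C, T>G`) and its 5'
#' and 3' flanking bases, giving 6 x 4 x 4 = 96 categories. The ordering is
#' fixed: substitutions in the order above; within a substitution, the 5'
#' base varies first (A, C, G, T), then the 3' base. Labels read
#' `"A(C>T)G"` for an A-C-G reference trinucleotide mutating C to T.
#'
#' @return an object of class `CategoryScheme`: a character vector of the
#'   96 labels with attributes `substitution`, `five_prime`, `three_prime`.
#' @export
category_scheme <- function() {
  grid <- expand.grid(three = BASES, five = BASES, sub = SUBSTITUTIONS,
                      stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reorder so that within a
  # substitution the 5' base is the outer loop and the 3' base the inner.
  grid <- grid[order(match(grid$sub, SUBSTITUTIONS),
                     match(grid$five, BASES),
                     match(grid$three, BASES)), ]
  labels <- sprintf("%s(%s)%s", grid$five, grid$sub, grid$three)
  structure(labels,
            substitution = grid$sub,
            five_prime = grid$five,
            three_prime = grid$three,
            class = "CategoryScheme")
}

#' @export
print.CategoryScheme <- function(x, ...) {
  cat("CategoryScheme:", length(x), "pyrimidine-collapsed trinucleotide",
      "categories\n")
  cat("  ", paste(utils::head(unclass(x), 4), collapse = " "), "...",
      paste(utils::tail(unclass(x), 2), collapse = " "), "\n")
  invisible(x)
}

category_label <- function(substitution, five, three) {
  sprintf("%s(%s)%s", five, substitution, three)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

complement_base <- function(b) unname(COMPLEMENT[b])

revcomp_str <- function(x) {
  # reverse-complement of fixed-width strings, vectorized
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Predicate matching X(C>T)G categories
#'
#' The category family of C>T substitutions with a 3' guanine and any 5'
#' base, i.e. C>T mutations at CpG dinucleotides. This is the definition
#' used when stratifying catalogs by CpG-island membership.
#'
#' @param labels character vector of category labels.
#' @return logical vector.
#' @export
is_xcg_category <- function(labels) {
  grepl("^[ACGT]\\(C>T\\)G$", labels)
}
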