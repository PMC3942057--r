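# Plain-text readers/writers for every artifact the pipeline produces.
# All floating point is written at 6 significant digits.

fmt_num <- function(x) signif(x, 6)

#' Write a catalog as TSV (96 labeled rows, one column per sample)
#' @param catalog a `MutationCatalog`.
#' @param path output file; a JSON provenance sidecar is written next to
#'   it as `<path>.provenance.json`.
#' @export
write_catalog_tsv <- function(catalog, path) {
  df <- data.frame(category = rownames(catalog$counts),
                   catalog$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(catalog$provenance,
                       paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a catalog TSV written by [write_catalog_tsv()]
#' @param path input file.
#' @return a `MutationCatalog`.
#' @export
read_catalog_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  scheme <- category_scheme()
  assert_that(identical(df$category, as.vector(unclass(scheme))),
              "catalog file %s does not use the canonical category order",
              path)
  m <- as.matrix(df[, -1, drop = FALSE])
  prov_path <- paste0(path, ".provenance.json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path) else list()
  new_catalog(m, colnames(m), scheme, provenance = prov)
}

write_matrix_tsv <- function(m, path, row_label) {
  df <- data.frame(rownames(m), fmt_num(m), check.names = FALSE)
  names(df)[1] <- row_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a FASTA file wrapped at 60 columns
#' @param genome named character vector of contig sequences.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  genome <- as_genome_strings(genome)
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path input file.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  # keep only the first word of each header, as aligners do
  stats::setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
}

#' Write intervals as BED (0-based half-open)
#' @param gr a `GRanges`.
#' @param path output file.
#' @export
write_bed <- function(gr, path) {
  if (length(gr) == 0) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a normalized `GRanges`
#' @param path input file.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  normalize_intervals(rtracklayer::import(path, format = "BED"))
}

#' Write mutation records as MAF-lite TSV
#' @param records data frame with columns `sample, chrom, pos, ref, alt`.
#' @param path output file.
#' @export
write_maf_lite <- function(records, path) {
  utils::write.table(records[, c("sample", "chrom", "pos", "ref", "alt")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a covariate table as TSV
#' @param covariates data frame with a `sample_id` column.
#' @param path output file.
#' @export
write_covariates_tsv <- function(covariates, path) {
  utils::write.table(covariates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a covariate table written by [write_covariates_tsv()]
#' @param path input file.
#' @export
read_covariates_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(W_true = truth$W_true, H_true = truth$H_true,
         sample_ids = truth$sample_ids,
         signature_names = truth$signature_names,
         seed = truth$seed, params = truth$params),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
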