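# Catalog construction: SNV parsing, pyrimidine-strand collapse, 96 x N
# count matrices, and interval-based stratification.

#' Parse somatic SNVs from MAF-lite TSV or VCF
#'
#' MAF-lite is a tab-separated file whose first five columns are
#' `sample, chrom, pos, ref, alt` (1-based position; extra columns are
#' ignored; a header row is detected by the literal column name `sample`).
#' VCF input is read with `VariantAnnotation`; multi-sample VCFs emit one
#' record per sample carrying a non-reference genotype, and VCFs without
#' genotypes are assigned the sample id `"SAMPLE"`.
#'
#' Only biallelic SNVs are returned; rows with multi-base or non-ACGT
#' alleles are skipped and tallied in `attr(, "skipped")`. Structurally
#' malformed rows (wrong column count, non-numeric position) are an error
#' reporting the offending line number.
#'
#' @param path input file.
#' @param format `"maf-lite"` or `"vcf"`.
#' @return data frame with columns `sample, chrom, pos, ref, alt` and a
#'   `skipped` attribute (named counts of skipped rows by reason).
#' @export
parse_mutations <- function(path, format = c("maf-lite", "vcf")) {
  if (!is.character(format) || !all(format %in% c("maf-lite", "vcf")))
    stop_validation("unknown format: %s", paste(format, collapse = ","))
  format <- match.arg(format)
  assert_that(file.exists(path), "file not found: %s", path)
  if (format == "maf-lite") parse_maf_lite(path) else parse_vcf(path)
}

parse_maf_lite <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(sample = character(), chrom = character(),
                      pos = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE)
  if (length(lines) == 0)
    return(structure(empty, skipped = c(non_snv = 0L)))
  first_line_no <- 1L
  if (grepl("(^|\t)sample($|\t)", tolower(lines[1]))) {
    lines <- lines[-1]
    first_line_no <- 2L
  }
  if (length(lines) == 0)
    return(structure(empty, skipped = c(non_snv = 0L)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5))
    stop_data_integrity("malformed MAF-lite row at line %d: expected >= 5 columns, got %d",
                        which(nf < 5)[1] + first_line_no - 1L,
                        nf[which(nf < 5)[1]])
  m <- t(vapply(fields, function(f) f[1:5], character(5)))
  pos <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(pos))
    stop_data_integrity("malformed MAF-lite row at line %d: non-numeric position '%s'",
                        which(is.na(pos))[1] + first_line_no - 1L,
                        m[which(is.na(pos))[1], 3])
  ref <- toupper(m[, 4]); alt <- toupper(m[, 5])
  is_snv <- ref %in% BASES & alt %in% BASES & ref != alt
  rec <- data.frame(sample = m[is_snv, 1], chrom = m[is_snv, 2],
                    pos = as.integer(pos[is_snv]), ref = ref[is_snv],
                    alt = alt[is_snv], stringsAsFactors = FALSE)
  structure(rec, skipped = c(non_snv = sum(!is_snv)))
}

parse_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  # biallelic SNVs only
  alt1 <- vapply(seq_along(altl), function(i) {
    a <- altl[[i]]
    if (length(a) == 1) as.character(a) else NA_character_
  }, character(1))
  is_snv <- !is.na(alt1) & nchar(ref) == 1 & nchar(alt1) == 1 &
    ref %in% BASES & alt1 %in% BASES & ref != alt1
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)

  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
  if (!is.null(gt) && ncol(gt) > 0) {
    recs <- list()
    for (s in colnames(gt)) {
      carrier <- is_snv & !gt[, s] %in% c("0/0", "0|0", "./.", ".", "0")
      if (any(carrier))
        recs[[s]] <- data.frame(sample = s, chrom = chrom[carrier],
                                pos = pos[carrier], ref = ref[carrier],
                                alt = alt1[carrier],
                                stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
    if (is.null(rec))
      rec <- data.frame(sample = character(), chrom = character(),
                        pos = integer(), ref = character(),
                        alt = character(), stringsAsFactors = FALSE)
  } else {
    rec <- data.frame(sample = "SAMPLE", chrom = chrom[is_snv],
                      pos = pos[is_snv], ref = ref[is_snv],
                      alt = alt1[is_snv], stringsAsFactors = FALSE)
  }
  structure(rec, skipped = c(non_snv = sum(!is_snv)))
}

as_genome_strings <- function(genome) {
  if (inherits(genome, "DNAStringSet"))
    return(stats::setNames(as.character(genome), names(genome)))
  if (is.character(genome)) {
    assert_that(!is.null(names(genome)), "genome must have contig names")
    return(genome)
  }
  stop_validation("genome must be a named character vector or DNAStringSet")
}

# Vectorized pyrimidine-strand classification. Returns the category label
# per record (NA where excluded) plus an exclusion reason vector.
classify_contexts <- function(genome, chrom, pos, ref, alt) {
  genome <- as_genome_strings(genome)
  n <- length(pos)
  category <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  known <- chrom %in% names(genome)
  reason[!known] <- "unknown_contig"
  clen <- rep(NA_integer_, n)
  clen[known] <- nchar(genome[chrom[known]])
  edge <- known & (pos < 2 | pos > clen - 1)
  reason[edge] <- "contig_edge"
  ok <- known & !edge

  ctx <- rep(NA_character_, n)
  ctx[ok] <- substring(genome[chrom[ok]], pos[ok] - 1, pos[ok] + 1)
  hasN <- ok & grepl("[^ACGT]", ctx)
  reason[hasN] <- "ambiguous_context"
  ok <- ok & !hasN

  center <- substr(ctx, 2, 2)
  # plus-strand alleles: a record may be written on either strand
  on_plus <- ok & center == ref
  on_minus <- ok & !on_plus & center == complement_base(ref)
  mism <- ok & !on_plus & !on_minus
  reason[mism] <- "ref_mismatch"

  p_ref <- ifelse(on_plus, ref, complement_base(ref))
  p_alt <- ifelse(on_plus, alt, complement_base(alt))
  use <- on_plus | on_minus

  pyr <- use & p_ref %in% c("C", "T")
  # pyrimidine reference: read the context as-is
  i <- which(pyr)
  category[i] <- category_label(paste0(p_ref[i], ">", p_alt[i]),
                                substr(ctx[i], 1, 1), substr(ctx[i], 3, 3))
  # purine reference: reverse-complement substitution and context
  j <- which(use & !pyr)
  if (length(j)) {
    rc <- revcomp_str(ctx[j])
    category[j] <- category_label(
      paste0(complement_base(p_ref[j]), ">", complement_base(p_alt[j])),
      substr(rc, 1, 1), substr(rc, 3, 3))
  }
  list(category = category, reason = reason)
}

#' Pyrimidine-collapsed trinucleotide category of one mutation
#'
#' Classifies a single SNV into the 96-category scheme. Mutations whose
#' reference base is a purine are reverse-complemented (substitution and
#' flanks) so every mutation is reported on the pyrimidine strand; records
#' written on the minus strand (allele equal to the complement of the
#' genome base) are handled transparently.
#'
#' @param genome named character vector (or `DNAStringSet`) of contigs.
#' @param record one-row data frame (or list) with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @return a category label, e.g. `"A(C>T)G"`.
#' @export
pyrimidine_context <- function(genome, record) {
  res <- classify_contexts(genome, record$chrom, record$pos,
                           toupper(record$ref), toupper(record$alt))
  if (is.na(res$category)) {
    if (identical(res$reason, "ref_mismatch"))
      stop_data_integrity("ref allele does not match genome at %s:%d",
                          record$chrom, record$pos)
    stop_validation("cannot classify record at %s:%s (%s)",
                    record$chrom, record$pos, res$reason)
  }
  res$category
}

#' Build a 96 x N mutation catalog
#'
#' Tabulates classified records into a count matrix with one column per
#' sample in first-appearance order. Duplicated records (identical
#' sample/chrom/pos/ref/alt) are counted once; unclassifiable records
#' (ambiguous context, contig edge, ref mismatch, unknown contig) are
#' excluded and tallied in the catalog provenance.
#'
#' @param records data frame from [parse_mutations()] (columns
#'   `sample, chrom, pos, ref, alt`).
#' @param genome named character vector or `DNAStringSet`.
#' @param dedup drop duplicated records (default TRUE).
#' @param region_filter optional `GRanges`; when supplied, records outside
#'   it are excluded (and tallied). Off by default.
#' @return a `MutationCatalog`.
#' @export
build_catalog <- function(records, genome, dedup = TRUE,
                          region_filter = NULL) {
  assert_that(is.data.frame(records) &&
                all(c("sample", "chrom", "pos", "ref", "alt") %in%
                      names(records)),
              "records must have columns sample, chrom, pos, ref, alt")
  n_input <- nrow(records)
  n_dup <- 0L
  if (dedup && n_input > 0) {
    key <- paste(records$sample, records$chrom, records$pos,
                 records$ref, records$alt, sep = "\r")
    dup <- duplicated(key)
    n_dup <- sum(dup)
    records <- records[!dup, , drop = FALSE]
  }
  n_region <- 0L
  if (!is.null(region_filter) && nrow(records) > 0) {
    gr <- GenomicRanges::GRanges(records$chrom,
                                 IRanges::IRanges(records$pos, records$pos))
    keep <- IRanges::overlapsAny(gr, region_filter)
    n_region <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  res <- classify_contexts(genome, records$chrom, records$pos,
                           toupper(records$ref), toupper(records$alt))
  excl <- table(res$reason[is.na(res$category)])
  keep <- !is.na(res$category)
  if (!any(keep))
    stop_validation("no valid records: catalog would be empty")

  scheme <- category_scheme()
  samples <- unique(records$sample[keep])
  counts <- table(factor(res$category[keep], levels = unclass(scheme)),
                  factor(records$sample[keep], levels = samples))
  counts <- matrix(as.numeric(counts), nrow = length(scheme),
                   dimnames = list(as.vector(unclass(scheme)), samples))
  new_catalog(counts, samples, scheme,
              provenance = list(
                n_input = n_input,
                n_duplicates = n_dup,
                n_outside_region = n_region,
                n_excluded = as.list(excl),
                dedup = dedup))
}

#' Normalize a set of genomic intervals
#'
#' Sorts and merges overlapping intervals per contig.
#'
#' @param intervals a `GRanges`, or a data frame with `chrom, start, end`
#'   (0-based half-open, BED convention).
#' @return a reduced (sorted, non-overlapping) `GRanges`.
#' @export
normalize_intervals <- function(intervals) {
  if (is.data.frame(intervals)) {
    assert_that(all(intervals$start < intervals$end),
                "interval start must be < end")
    intervals <- GenomicRanges::GRanges(
      intervals$chrom,
      IRanges::IRanges(start = intervals$start + 1, end = intervals$end))
  }
  assert_that(inherits(intervals, "GRanges"),
              "intervals must be a GRanges or BED-like data frame")
  GenomicRanges::reduce(sort(intervals))
}

#' Stratify records by category predicate and interval membership
#'
#' Splits the records whose category satisfies `predicate` (default: the
#' `X(C>T)G` family, i.e. C>T at CpG dinucleotides) by whether the mutated
#' base lies inside `intervals`; all other records (including
#' unclassifiable ones) pass through in the `other` bucket. The three
#' buckets are disjoint and their union is the input.
#'
#' @param records data frame of mutation records.
#' @param genome named character vector or `DNAStringSet`.
#' @param intervals a `GRanges` (e.g. CpG islands), normalized internally.
#' @param predicate function mapping category labels to logical; default
#'   [is_xcg_category()].
#' @return list of data frames `inside`, `outside`, `other`.
#' @export
stratify_by_intervals <- function(records, genome, intervals,
                                  predicate = is_xcg_category) {
  intervals <- normalize_intervals(intervals)
  if (nrow(records) == 0)
    return(list(inside = records, outside = records, other = records))
  res <- classify_contexts(genome, records$chrom, records$pos,
                           toupper(records$ref), toupper(records$alt))
  matches <- !is.na(res$category) & predicate(res$category)
  gr <- GenomicRanges::GRanges(records$chrom,
                               IRanges::IRanges(records$pos, records$pos))
  inside <- matches & IRanges::overlapsAny(gr, intervals)
  list(inside = records[inside, , drop = FALSE],
       outside = records[matches & !inside, , drop = FALSE],
       other = records[!matches, , drop = FALSE])
}
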