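make_maf <- function(lines, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  hdr <- if (header) "sample\tchrom\tpos\tref\talt" else NULL
  writeLines(c(hdr, lines), path)
  path
}

test_that("MAF-lite parsing: records, skips and malformed rows", {
  p <- make_maf(c("S1\tchr1\t1000\tC\tT",
                  "S1\tchr1\t1005\tCA\tC",     # indel: skipped
                  "S2\tchr1\t1010\tG\tG",      # ref == alt: skipped
                  "S2\tchr2\t50\tA\tG\textra\tcols"))
  rec <- parse_mutations(p, "maf-lite")
  expect_equal(nrow(rec), 2)
  expect_equal(attr(rec, "skipped")[["non_snv"]], 2)
  expect_equal(rec$sample, c("S1", "S2"))
  expect_equal(rec$pos, c(1000L, 50L))

  empty <- make_maf(character(0))
  rec0 <- parse_mutations(empty, "maf-lite")
  expect_equal(nrow(rec0), 0)

  bad <- make_maf(c("S1\tchr1\t1000\tC\tT", "S1\tchr1\tnotanumber\tC\tT"))
  expect_error(parse_mutations(bad, "maf-lite"), "line 3",
               class = "data_integrity_error")
  short <- make_maf("S1\tchr1\t5")
  expect_error(parse_mutations(short, "maf-lite"), "line 2",
               class = "data_integrity_error")
  expect_cohortsig_error(parse_mutations(p, "xlsx"), "validation_error")
})

test_that("VCF parsing keeps SNVs and expands carrier samples", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=2000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tT1\tT2",
    "chr1\t100\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t200\t.\tCA\tC\t.\tPASS\t.\tGT\t0/1\t0/1",  # indel: skipped
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t1/1\t0/1"
  ), path)
  rec <- parse_mutations(path, "vcf")
  expect_equal(attr(rec, "skipped")[["non_snv"]], 1)
  expect_equal(nrow(rec), 3)  # T1 carries both SNVs, T2 carries one
  expect_equal(sort(unique(rec$sample)), c("T1", "T2"))
  expect_equal(rec$pos[rec$sample == "T2"], 300L)
})

test_that("pyrimidine collapse matches the brute-force oracle on all 192 stranded cases", {
  # one synthetic contig containing every possible stranded trinucleotide
  # with every alt: enumerate (5', ref, 3', alt) and check both the
  # plus-strand record and its strand-flipped representation.
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cases <- expand.grid(five = c("A", "C", "G", "T"),
                       ref = c("A", "C", "G", "T"),
                       three = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  n_checked <- 0
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    genome <- c(ctg = paste0("T", cs$five, cs$ref, cs$three, "A"))
    for (alt in setdiff(c("A", "C", "G", "T"), cs$ref)) {
      expected <- oracle_category(cs$five, cs$ref, cs$three, alt)
      rec <- list(chrom = "ctg", pos = 3, ref = cs$ref, alt = alt)
      expect_equal(pyrimidine_context(genome, rec), expected)
      # the same physical mutation written on the minus strand
      flip <- list(chrom = "ctg", pos = 3, ref = unname(comp[cs$ref]),
                   alt = unname(comp[alt]))
      expect_equal(pyrimidine_context(genome, flip), expected)
      n_checked <- n_checked + 2
    }
  }
  expect_equal(n_checked, 384)  # 192 stranded cases x 2 representations
})

test_that("pyrimidine_context error paths", {
  genome <- c(ctg = "TTACGTT")
  expect_equal(pyrimidine_context(genome, list(chrom = "ctg", pos = 4,
                                               ref = "C", alt = "T")),
               "A(C>T)G")
  expect_cohortsig_error(
    pyrimidine_context(genome, list(chrom = "ctg", pos = 4, ref = "T",
                                    alt = "A")),
    "data_integrity_error")
  expect_cohortsig_error(
    pyrimidine_context(genome, list(chrom = "ctg", pos = 1, ref = "T",
                                    alt = "A")),
    "validation_error")
  genomeN <- c(ctg = "TTNCGTT")
  expect_cohortsig_error(
    pyrimidine_context(genomeN, list(chrom = "ctg", pos = 4, ref = "C",
                                     alt = "T")),
    "validation_error")
})

test_that("build_catalog: column sums, order, dedup, exclusions", {
  genome <- c(ctg = "TTACGTTACGTTACGTT")
  rec <- data.frame(
    sample = c("B", "B", "A", "B"),
    chrom = "ctg",
    pos = c(4, 9, 14, 4),      # last row duplicates the first
    ref = "C", alt = "T",
    stringsAsFactors = FALSE)
  cat1 <- build_catalog(rec, genome)
  # first-appearance order, not alphabetical
  expect_equal(cat1$sample_ids, c("B", "A"))
  expect_equal(unname(colSums(cat1$counts)), c(2, 1))
  expect_equal(cat1$provenance$n_duplicates, 1)
  expect_equal(sum(cat1$counts), 3)
  expect_equal(unname(cat1$counts["A(C>T)G", ]), c(2, 1))

  # duplicates kept when dedup = FALSE
  cat2 <- build_catalog(rec, genome, dedup = FALSE)
  expect_equal(sum(cat2$counts), 4)

  # exclusions tallied, not fatal
  rec_bad <- rbind(rec,
                   data.frame(sample = "A", chrom = "ctg", pos = 1,
                              ref = "T", alt = "A"),
                   data.frame(sample = "A", chrom = "nope", pos = 4,
                              ref = "C", alt = "T"))
  cat3 <- build_catalog(rec_bad, genome)
  expect_equal(sum(cat3$counts), 3)
  expect_equal(cat3$provenance$n_excluded$contig_edge, 1)
  expect_equal(cat3$provenance$n_excluded$unknown_contig, 1)

  # all records invalid -> empty-catalog error
  only_bad <- data.frame(sample = "A", chrom = "nope", pos = 4,
                         ref = "C", alt = "T")
  expect_cohortsig_error(build_catalog(only_bad, genome),
                         "validation_error")

  # optional region restriction excludes and tallies
  region <- GenomicRanges::GRanges("ctg", IRanges::IRanges(1, 10))
  cat4 <- build_catalog(rec, genome, region_filter = region)
  expect_equal(sum(cat4$counts), 2)
  expect_equal(cat4$provenance$n_outside_region, 1)
})

test_that("catalog strand invariance on simulated cohorts", {
  co <- small_cohort(n_samples = 8, seed = 31, with_genome = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flipped <- co$records
  flipped$ref <- unname(comp[flipped$ref])
  flipped$alt <- unname(comp[flipped$alt])
  expect_identical(build_catalog(flipped, co$genome)$counts,
                   build_catalog(co$records, co$genome)$counts)
})

test_that("stratification partitions the input records", {
  co <- small_cohort(n_samples = 10, sigs = c("nonCGI", "S", "flat"),
                     seed = 32, with_genome = TRUE, cgi_fraction = 0.4)
  st <- stratify_by_intervals(co$records, co$genome, co$cgi)
  expect_equal(nrow(st$inside) + nrow(st$outside) + nrow(st$other),
               nrow(co$records))
  # matching records are X(C>T)G by construction
  for (b in c("inside", "outside")) {
    if (nrow(st[[b]]) == 0) next
    cats <- vapply(seq_len(nrow(st[[b]])), function(i)
      pyrimidine_context(co$genome, st[[b]][i, ]), character(1))
    expect_true(all(is_xcg_category(cats)))
  }
  # a predicate matching nothing puts everything in 'other'
  st0 <- stratify_by_intervals(co$records, co$genome, co$cgi,
                               predicate = function(x) rep(FALSE, length(x)))
  expect_equal(nrow(st0$inside), 0)
  expect_equal(nrow(st0$outside), 0)
  expect_equal(nrow(st0$other), nrow(co$records))
})

test_that("interval normalization merges overlaps and validates", {
  df <- data.frame(chrom = c("c1", "c1", "c2"),
                   start = c(10, 15, 0), end = c(20, 30, 5))
  gr <- normalize_intervals(df)
  expect_length(gr, 2)
  expect_equal(GenomicRanges::start(gr), c(11, 1))
  expect_equal(GenomicRanges::end(gr), c(30, 5))
  bad <- data.frame(chrom = "c1", start = 10, end = 10)
  expect_cohortsig_error(normalize_intervals(bad), "validation_error")
})

test_that("catalog TSV round trips through its reader", {
  co <- small_cohort(n_samples = 5, seed = 33)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog_tsv(co$catalog, path)
  back <- read_catalog_tsv(path)
  expect_equal(back$counts, co$catalog$counts)
  expect_equal(back$sample_ids, co$catalog$sample_ids)
})
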