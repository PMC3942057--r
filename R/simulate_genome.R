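# Realizes an integer catalog as concrete mutation records on a synthetic
# contig, so that trinucleotide contexts and CpG-island membership are
# exactly recoverable. Each mutation gets its own 3-base slot (slots are
# separated by one spacer base, so contexts never overlap); a prefix block
# of the contig is declared the CpG island.

#' Simulate a reference genome and mutation list realizing a catalog
#'
#' Every count in the catalog becomes one mutation record placed at a
#' genomic position whose reference trinucleotide matches the category.
#' Records are emitted on the plus or minus strand at random (a
#' minus-strand record carries the complemented ref/alt alleles), so the
#' pyrimidine collapse is exercised on both representations. A
#' configurable fraction of the `X(C>T)G` mutations is placed inside a
#' CpG-island interval at the start of the contig; everything else is
#' placed outside it. Rebuilding a catalog from the returned genome and
#' records reproduces the input exactly.
#'
#' @param catalog a `MutationCatalog` to realize.
#' @param contig_length length of the synthetic contig in bases; `NULL`
#'   (default) sizes it automatically (4 bases per mutation plus padding).
#' @param cgi_fraction fraction of `X(C>T)G` mutations placed inside the
#'   CpG island. Default 0.2, mirroring the minority of genomic CpGs that
#'   sit in islands.
#' @param seed integer seed (strand choices, record shuffling, filler).
#' @param n_contigs split the genome over this many contigs (default 1;
#'   mutations are chunked across contigs, islands stay on the leading
#'   contigs).
#' @param contig_name base name of the contig(s); with `n_contigs > 1`
#'   contigs are named `<contig_name>1`, `<contig_name>2`, ...
#' @param out_dir if non-NULL, write `genome.fa` (60-column FASTA),
#'   `cgi.bed` (0-based half-open) and `mutations.tsv` (MAF-lite) there.
#' @return list with `genome` (named character vector, also convertible to
#'   `Biostrings::DNAStringSet`), `cgi` (a `GRanges` of island intervals),
#'   `records` (MAF-lite data frame: sample, chrom, pos, ref, alt) and
#'   `paths` (written files, if any).
#' @export
simulate_genome_and_mutations <- function(catalog, contig_length = NULL,
                                          cgi_fraction = 0.2, seed = 1L,
                                          n_contigs = 1L,
                                          contig_name = "chrSim",
                                          out_dir = NULL) {
  assert_that(inherits(catalog, "MutationCatalog"),
              "catalog must be a MutationCatalog")
  assert_that(cgi_fraction >= 0 && cgi_fraction <= 1,
              "cgi_fraction must lie in [0, 1]")
  assert_that(n_contigs >= 1, "n_contigs must be >= 1")
  scheme <- catalog$scheme
  counts <- catalog$counts
  n_mut <- sum(counts)
  assert_that(n_mut > 0, "catalog holds no mutations")
  needed <- 4 * n_mut + 4 * n_contigs
  if (is.null(contig_length)) contig_length <- needed
  if (contig_length < needed)
    stop_sizing("contigs too short: need %d bases for %d mutations, got %d",
                needed, n_mut, contig_length)

  # one row per mutation
  idx <- which(counts > 0, arr.ind = TRUE)
  reps <- counts[counts > 0]
  cat_i <- rep(idx[, 1], reps)
  samp_i <- rep(idx[, 2], reps)

  sub <- attr(scheme, "substitution")[cat_i]
  five <- attr(scheme, "five_prime")[cat_i]
  three <- attr(scheme, "three_prime")[cat_i]
  ref_pyr <- substr(sub, 1, 1)
  alt_pyr <- substr(sub, 3, 3)
  is_xcg <- is_xcg_category(unclass(scheme)[cat_i])

  with_seed(seed, {
    n_xcg <- sum(is_xcg)
    n_cgi <- round(cgi_fraction * n_xcg)
    in_cgi <- rep(FALSE, n_mut)
    if (n_cgi > 0)
      in_cgi[sample(which(is_xcg), n_cgi)] <- TRUE

    # slot order: CGI mutations first, the rest shuffled behind them
    ord <- c(sample(which(in_cgi)), sample(which(!in_cgi)))
    slot <- integer(n_mut)
    slot[ord] <- seq_len(n_mut) - 1L          # 0-based global slot index

    # chunk slots over contigs; islands occupy the leading slots
    slots_per <- ceiling(n_mut / n_contigs)
    contig_of <- slot %/% slots_per           # 0-based contig index
    local_slot <- slot %% slots_per
    pos <- 3L + 4L * local_slot               # 1-based center position
    contig_names <- if (n_contigs == 1L) contig_name
                    else paste0(contig_name, seq_len(n_contigs))
    chrom <- contig_names[contig_of + 1L]

    minus <- stats::runif(n_mut) < 0.5
    trinuc <- paste0(five, ref_pyr, three)
    trinuc[minus] <- revcomp_str(trinuc[minus])
    ref_out <- ifelse(minus, complement_base(ref_pyr), ref_pyr)
    alt_out <- ifelse(minus, complement_base(alt_pyr), alt_pyr)

    per_contig_slots <- tabulate(contig_of + 1L, n_contigs)
    spare <- contig_length - 4L * n_mut - 4L * (n_contigs - 1L)
    contig_lengths <- 4L * per_contig_slots + 4L
    contig_lengths[1] <- contig_lengths[1] + (spare - 4L)
    genome <- vapply(seq_len(n_contigs), function(cix) {
      bases <- sample(BASES, contig_lengths[cix], replace = TRUE)
      here <- which(contig_of == cix - 1L)
      for (k in here)
        bases[(pos[k] - 1L):(pos[k] + 1L)] <- strsplit(trinuc[k], "")[[1]]
      paste(bases, collapse = "")
    }, character(1))
    names(genome) <- contig_names

    # CGI intervals: the first n_cgi global slots, mapped per contig
    cgi <- if (n_cgi > 0) {
      full <- pmin(pmax(n_cgi - slots_per * (seq_len(n_contigs) - 1L), 0L),
                   slots_per)
      keep <- full > 0L
      GenomicRanges::GRanges(contig_names[keep],
                             IRanges::IRanges(start = 1,
                                              end = 4L * full[keep]))
    } else {
      GenomicRanges::GRanges()
    }

    records <- data.frame(
      sample = catalog$sample_ids[samp_i],
      chrom = chrom,
      pos = pos,
      ref = ref_out,
      alt = alt_out,
      stringsAsFactors = FALSE
    )
    # keep sample-major order so a rebuilt catalog sees samples in the
    # same first-appearance order as the input catalog
    rownames(records) <- NULL

    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        genome = file.path(out_dir, "genome.fa"),
        cgi = file.path(out_dir, "cgi.bed"),
        mutations = file.path(out_dir, "mutations.tsv")
      )
      write_fasta(genome, paths$genome)
      write_bed(cgi, paths$cgi)
      write_maf_lite(records, paths$mutations)
    }
    list(genome = genome, cgi = cgi, records = records, paths = paths)
  })
}
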