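# End-to-end orchestration: simulate -> catalog -> extract -> annotate ->
# associate, plus the non-CGI and outlier ablation experiments. One master
# seed fans out to per-stage seeds via derive_seed(); every derived seed
# is recorded in the run manifest.

STAGE_COUNTERS <- c(archetypes = 1L, exposures = 2L, covariates = 3L,
                    catalog = 4L, genome = 5L, nmf = 6L)

#' Build and validate a pipeline run configuration
#'
#' Exactly one of `simulation` (a list of synthetic-cohort parameters) or
#' `inputs` (paths to real data) must be supplied.
#'
#' @param simulation list with any of: `n_samples`, `signature_names`,
#'   `burden_lognormal_params`, `mix_dirichlet_alpha`, `leak_fraction`,
#'   `cgi_fraction`, `noise`, `effects` (see [simulate_covariates()]).
#' @param inputs list with `mutations` (path), `format` ("maf-lite" or
#'   "vcf"), `genome` (FASTA path), and optionally `cgi_bed`,
#'   `covariates` (paths).
#' @param rank_range candidate NMF ranks (default 3:7).
#' @param n_bootstrap,n_restarts,max_iter,tol extraction controls.
#' @param match_threshold cosine needed to annotate a signature.
#' @param coph_threshold,stability_threshold rank-selection thresholds.
#' @param dominance_threshold outlier-sample threshold.
#' @param seed master seed.
#' @param out_dir output directory (`NULL`: nothing written).
#' @param cohort cohort label.
#' @return a validated `RunConfig` list.
#' @export
run_config <- function(simulation = NULL, inputs = NULL,
                       rank_range = 3:7, n_bootstrap = 20L,
                       n_restarts = 10L, max_iter = 500L, tol = 1e-4,
                       match_threshold = 0.8, coph_threshold = 0.95,
                       stability_threshold = 0.8,
                       dominance_threshold = 0.5, seed = 1L,
                       out_dir = NULL, cohort = "cohort") {
  assert_that(xor(is.null(simulation), is.null(inputs)),
              "exactly one of 'simulation' or 'inputs' must be given")
  if (!is.null(inputs)) {
    assert_that(!is.null(inputs$mutations), "inputs$mutations is required")
    assert_that(!is.null(inputs$genome), "inputs$genome is required")
    for (f in c("mutations", "genome", "cgi_bed", "covariates"))
      if (!is.null(inputs[[f]]))
        assert_that(file.exists(inputs[[f]]), "%s path not found: %s",
                    f, inputs[[f]])
  } else {
    defaults <- list(n_samples = 120L,
                     signature_names = c("S", "K", "nonCGI", "flat"),
                     burden_lognormal_params = c(log(300), 0.7),
                     mix_dirichlet_alpha = 3,
                     leak_fraction = 0.05, cgi_fraction = 0.2,
                     noise = "multinomial", effects = list())
    # flat merge (modifyList would recurse into and drop the unnamed
    # per-effect lists under 'effects')
    for (k in names(simulation)) defaults[[k]] <- simulation[[k]]
    simulation <- defaults
  }
  structure(list(simulation = simulation, inputs = inputs,
                 rank_range = rank_range, n_bootstrap = n_bootstrap,
                 n_restarts = n_restarts, max_iter = max_iter, tol = tol,
                 match_threshold = match_threshold,
                 coph_threshold = coph_threshold,
                 stability_threshold = stability_threshold,
                 dominance_threshold = dominance_threshold,
                 seed = seed, out_dir = out_dir, cohort = cohort),
            class = "RunConfig")
}

stage_seed <- function(config, stage) {
  derive_seed(config$seed, STAGE_COUNTERS[[stage]])
}

# re-raise any pipeline error with the failing stage's name prefixed,
# preserving its condition class
with_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    if (!grepl("^stage ", conditionMessage(e))) {
      e$message <- sprintf("stage %s: %s", stage, conditionMessage(e))
      stop(e)
    }
  })
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- config[setdiff(names(config), "out_dir")]
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

# Simulation front half: returns truth, covariates, genome, cgi, records,
# catalog (rebuilt from the genome, so context recovery is exercised).
simulate_cohort <- function(config) {
  sim <- config$simulation
  archetypes <- make_archetypes(leak_fraction = sim$leak_fraction,
                                seed = stage_seed(config, "archetypes"))
  truth <- simulate_exposures(sim$n_samples, sim$signature_names,
                              sim$burden_lognormal_params,
                              sim$mix_dirichlet_alpha,
                              archetypes = archetypes,
                              seed = stage_seed(config, "exposures"))
  covariates <- NULL
  if (length(sim$effects)) {
    sc <- simulate_covariates(truth, sim$effects,
                              seed = stage_seed(config, "covariates"))
    truth <- sc$truth
    covariates <- sc$covariates
  }
  catalog0 <- simulate_catalog(truth, sim$noise,
                               seed = stage_seed(config, "catalog"))
  gen <- simulate_genome_and_mutations(catalog0,
                                       cgi_fraction = sim$cgi_fraction,
                                       seed = stage_seed(config, "genome"))
  catalog <- build_catalog(gen$records, gen$genome)
  list(archetypes = archetypes, truth = truth, covariates = covariates,
       catalog = catalog, genome = gen$genome, cgi = gen$cgi,
       records = gen$records)
}

load_cohort <- function(config) {
  inp <- config$inputs
  records <- parse_mutations(inp$mutations,
                             format = if (is.null(inp$format)) "maf-lite"
                                      else inp$format)
  genome <- read_fasta(inp$genome)
  cgi <- if (!is.null(inp$cgi_bed)) read_bed(inp$cgi_bed) else NULL
  covariates <- if (!is.null(inp$covariates))
    read_covariates_tsv(inp$covariates) else NULL
  catalog <- build_catalog(records, genome)
  list(archetypes = make_archetypes(), truth = NULL,
       covariates = covariates, catalog = catalog, genome = genome,
       cgi = cgi, records = records)
}

extract_and_annotate <- function(config, catalog, archetypes) {
  report <- select_rank(catalog, rank_range = config$rank_range,
                        n_bootstrap = config$n_bootstrap,
                        n_restarts = config$n_restarts,
                        seed = stage_seed(config, "nmf"),
                        max_iter = config$max_iter, tol = config$tol,
                        coph_threshold = config$coph_threshold,
                        stability_threshold = config$stability_threshold)
  fit <- report$fits[[as.character(report$chosen_rank)]]
  annotation <- match_signatures(fit$signatures, archetypes,
                                 threshold = config$match_threshold)
  profile <- build_profile(annotation, config$cohort)
  list(rank_report = report, signatures = fit$signatures,
       exposures = fit$exposures, consensus = fit$consensus,
       annotation = annotation, profile = profile)
}

write_run_outputs <- function(res, config, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_catalog_tsv(res$cohort$catalog, file.path(out_dir, "catalog.tsv"))
  if (!is.null(res$cohort$records))
    write_maf_lite(res$cohort$records, file.path(out_dir, "mutations.tsv"))
  if (!is.null(res$cohort$genome) && is.character(res$cohort$genome))
    write_fasta(res$cohort$genome, file.path(out_dir, "genome.fa"))
  if (!is.null(res$cohort$cgi))
    write_bed(res$cohort$cgi, file.path(out_dir, "cgi.bed"))
  if (!is.null(res$cohort$covariates))
    write_covariates_tsv(res$cohort$covariates,
                         file.path(out_dir, "covariates.tsv"))
  if (!is.null(res$cohort$truth))
    write_ground_truth_json(res$cohort$truth,
                            file.path(out_dir, "ground_truth.json"))
  write_matrix_tsv(res$extraction$signatures$W,
                   file.path(out_dir, "signatures.tsv"), "category")
  write_matrix_tsv(res$extraction$exposures$H,
                   file.path(out_dir, "exposures_raw.tsv"), "signature")
  write_matrix_tsv(res$extraction$exposures$relative,
                   file.path(out_dir, "exposures_relative.tsv"), "signature")
  write_matrix_tsv(res$extraction$consensus,
                   file.path(out_dir, "consensus.tsv"), "sample")
  tab <- res$extraction$rank_report$table
  utils::write.table(cbind(tab[1], lapply(tab[-c(1, ncol(tab))], fmt_num),
                           tab[ncol(tab)]),
                     file.path(out_dir, "rank_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(chosen_rank = res$extraction$rank_report$chosen_rank,
         rationale = res$extraction$rank_report$rationale,
         thresholds = as.list(res$extraction$rank_report$thresholds)),
    file.path(out_dir, "rank_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(as.data.frame(res$extraction$annotation),
                     file.path(out_dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(cohort = res$extraction$profile$cohort,
         archetypes = res$extraction$profile$archetypes,
         n_unmatched = res$extraction$profile$n_unmatched),
    file.path(out_dir, "profile.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the full extraction pipeline
#'
#' Simulates or loads a cohort, builds the catalog, scans ranks, extracts
#' and annotates signatures, and (when covariates are available) leaves
#' the pieces in place for association analyses. Deterministic for a
#' fixed master seed. When `config$out_dir` is set, all module outputs
#' plus a JSON manifest (config, derived stage seeds, record counts) are
#' written there.
#'
#' @param config a [run_config()].
#' @return list with `cohort` (catalog, genome, cgi, records, truth,
#'   covariates), `extraction` (rank report, signatures, exposures,
#'   annotation, profile) and `manifest`.
#' @export
run_extraction <- function(config) {
  assert_that(inherits(config, "RunConfig"), "config must be a RunConfig")
  cohort <- with_stage(if (!is.null(config$simulation)) "simulate"
                       else "load-inputs", {
    if (!is.null(config$simulation)) simulate_cohort(config)
    else load_cohort(config)
  })
  extraction <- with_stage("extract-annotate",
    extract_and_annotate(config, cohort$catalog, cohort$archetypes))
  manifest <- list(
    package_version = as.character(utils::packageVersion("cohortsig")),
    config_hash = config_hash(config),
    seed = config$seed,
    stage_seeds = lapply(stats::setNames(names(STAGE_COUNTERS),
                                         names(STAGE_COUNTERS)),
                         function(s) stage_seed(config, s)),
    cohort = config$cohort,
    n_samples = ncol(cohort$catalog$counts),
    n_mutations = sum(cohort$catalog$counts),
    chosen_rank = extraction$rank_report$chosen_rank,
    catalog_provenance = cohort$catalog$provenance
  )
  res <- list(cohort = cohort, extraction = extraction,
              manifest = manifest)
  write_run_outputs(res, config, config$out_dir)
  res
}

#' Non-CGI ablation experiment
#'
#' Runs the full analysis twice — once on all mutations, once after
#' removing the `X(C>T)G` mutations that lie outside CpG islands — and
#' reports each archetype's best-match cosine similarity in both runs.
#' The ablated run re-selects its own rank over the same candidate range
#' (removing a process's mutations legitimately changes how many
#' processes are detectable). A signature carried by non-island CpG C>T
#' mutations collapses in the ablated run.
#'
#' @param config a [run_config()]; CpG-island intervals must be available
#'   (simulated or via `inputs$cgi_bed`).
#' @return list with `full` (the [run_extraction()] result), `ablated`
#'   (catalog + rank report/signatures/exposures/annotation on the
#'   reduced records), `report` (per archetype: best cosine in both
#'   runs, each at its run's chosen rank) and `n_removed`.
#' @export
run_noncgi_ablation <- function(config) {
  full <- run_extraction(config)
  cgi <- full$cohort$cgi
  assert_that(!is.null(cgi), "CpG-island intervals are required")
  strat <- stratify_by_intervals(full$cohort$records, full$cohort$genome,
                                 cgi)
  kept <- rbind(strat$inside, strat$other)
  ablated_catalog <- build_catalog(kept, full$cohort$genome)
  config_abl <- config
  config_abl$out_dir <- NULL
  config_abl$seed <- derive_seed(config$seed, 77L)
  ablated <- extract_and_annotate(config_abl, ablated_catalog,
                                  full$cohort$archetypes)
  A <- full$cohort$archetypes
  best_cos <- function(W) vapply(colnames(A), function(a) {
    max(apply(W, 2, cosine_similarity, unclass(A)[, a]))
  }, numeric(1))
  report <- data.frame(
    archetype = colnames(A),
    cosine_full = unname(best_cos(full$extraction$signatures$W)),
    cosine_ablated = unname(best_cos(ablated$signatures$W)),
    stringsAsFactors = FALSE
  )
  res <- list(full = full,
              ablated = list(catalog = ablated_catalog,
                             extraction = ablated),
              report = report, n_removed = nrow(strat$outside))
  if (!is.null(config$out_dir)) {
    utils::write.table(cbind(report[1], lapply(report[-1], fmt_num)),
                       file.path(config$out_dir, "noncgi_ablation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Outlier-sample ablation experiment
#'
#' Detects samples dominating one signature's cohort-wide exposure,
#' removes them, re-runs rank selection and extraction, and reports the
#' rank and profile changes. When no sample dominates, the experiment is
#' a no-op with a note.
#'
#' @param config a [run_config()].
#' @param signature_id signature to screen for dominant samples; `NULL`
#'   (default) screens all extracted signatures.
#' @param full optionally, an existing [run_extraction()] result to reuse.
#' @return list with `full`, `outliers` (data frame), and — when outliers
#'   were found — `ablated` (extraction without them) plus `rank_change`
#'   and `profile_change`; otherwise `note`.
#' @export
run_outlier_ablation <- function(config, signature_id = NULL, full = NULL) {
  if (is.null(full)) full <- run_extraction(config)
  expo <- full$extraction$exposures
  sigs <- if (is.null(signature_id)) expo$signature_ids else signature_id
  outliers <- do.call(rbind, lapply(sigs, function(s) {
    o <- detect_outlier_samples(expo, s, config$dominance_threshold)
    if (nrow(o)) cbind(signature = s, o) else NULL
  }))
  if (is.null(outliers) || nrow(outliers) == 0)
    return(list(full = full, outliers = data.frame(),
                note = "no dominant sample found; ablation skipped"))
  drop_ids <- unique(outliers$sample)
  records <- full$cohort$records
  kept <- records[!records$sample %in% drop_ids, , drop = FALSE]
  ablated_catalog <- build_catalog(kept, full$cohort$genome)
  config2 <- config
  config2$out_dir <- NULL
  extraction <- extract_and_annotate(config2, ablated_catalog,
                                     full$cohort$archetypes)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- cbind(outliers["signature"], outliers["sample"],
                 share = fmt_num(outliers$share))
    utils::write.table(out, file.path(config$out_dir, "outliers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(full = full, outliers = outliers,
       ablated = list(catalog = ablated_catalog, extraction = extraction),
       rank_change = c(full = full$extraction$rank_report$chosen_rank,
                       ablated = extraction$rank_report$chosen_rank),
       profile_change = list(full = full$extraction$profile$archetypes,
                             ablated = extraction$profile$archetypes))
}
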