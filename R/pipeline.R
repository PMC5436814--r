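#' Configure an end-to-end pipeline run
#'
#' Two modes mirror the two assignment paths: `mock_validation` simulates
#' (or loads) mock-community reads, merges, trims and exact-matches them
#' against the collapsed reference amplicons, then compares observed with
#' expected fractions; `edna_survey` runs the de-novo path — merge, trim,
#' retention filters, greedy OTU clustering and local-alignment
#' identification.
#'
#' @param mode `"mock_validation"` or `"edna_survey"`.
#' @param assay an [assay_definition()].
#' @param refdb a `reference_db`.
#' @param community a [mock_community()] (required for simulation and for
#'   expected fractions in `mock_validation` mode).
#' @param reads optional pre-existing read pairs (data frame as produced by
#'   [simulate_reads()]`$reads`); when `NULL`, reads are simulated.
#' @param n_read_pairs pairs to simulate when `reads` is `NULL`.
#' @param sim_args list of overrides passed to [simulation_config()].
#' @param min_overlap,max_mismatch_rate merge parameters.
#' @param max_primer_mismatch trim parameter.
#' @param min_length,drop_singletons retention-filter parameters
#'   (`edna_survey` mode; the exact-match path needs no retention filters).
#' @param cluster_threshold,min_coverage,min_reads,species_identity
#'   clustering/identification parameters (`edna_survey` mode).
#' @param output_dir optional directory for stage TSV reports; `NULL`
#'   writes nothing.
#' @param seed integer seed governing all randomness of the run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("mock_validation", "edna_survey"),
                            assay, refdb, community = NULL, reads = NULL,
                            n_read_pairs = 10000, sim_args = list(),
                            min_overlap = 16, max_mismatch_rate = 0.1,
                            max_primer_mismatch = 1,
                            min_length = 100, drop_singletons = TRUE,
                            cluster_threshold = 0.97, min_coverage = 80,
                            min_reads = 2, species_identity = 97,
                            output_dir = NULL, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(assay, "assay_definition"), inherits(refdb, "reference_db"))
  if (is.null(reads) && is.null(community)) {
    stop("either reads or a community to simulate from is required",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the pipeline end to end
#'
#' Executes the stages of a [pipeline_config()] in order, carrying a
#' per-stage read ledger; identical config and seed give identical results.
#' When `output_dir` is set, each stage writes its TSV report there.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `pipeline_result` with (mode-dependent):
#'   `assignment`, `abundance`, `regressions` or `otus`, `composition`;
#'   always `accounting` (stage ledger data frame), `truth` (when
#'   simulated) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  acc <- list()
  truth <- NULL
  reads <- config$reads
  if (is.null(reads)) {
    sim_args <- utils::modifyList(
      list(assay = config$assay, community = config$community,
           refdb = config$refdb, n_read_pairs = config$n_read_pairs,
           seed = config$seed),
      config$sim_args)
    sim <- simulate_reads(do.call(simulation_config, sim_args))
    reads <- sim$reads
    truth <- sim$truth
    acc$simulate <- stage_accounting("simulate", nrow(reads), nrow(reads))
  }
  m <- merge_pairs(reads, min_overlap = config$min_overlap,
                   max_mismatch_rate = config$max_mismatch_rate)
  acc$merge <- m$accounting
  tr <- trim_construct(m$reads, config$assay,
                       max_primer_mismatch = config$max_primer_mismatch)
  acc$trim <- tr$accounting

  out <- list(config = config, truth = truth)
  if (config$mode == "mock_validation") {
    collapsed <- collapse_amplicon_otus(config$refdb, config$assay)
    asg <- assign_exact(tr$reads, collapsed$otus)
    acc$assign <- stage_accounting(
      "assign", asg$n_reads,
      as.integer(sum(asg$species_counts)),
      c(ambiguous = as.integer(sum(asg$ambiguous)),
        unassigned = asg$n_unassigned))
    amp_sp <- amplifiable_species(config$assay, config$refdb)
    tab <- abundance_table(asg$species_counts, config$community,
                           amplifiable = amp_sp)
    tab$community_id <- config$community$community_id
    out$assignment <- asg
    out$abundance <- tab
    out$regression <- tryCatch(
      loglog_regression(tab$pct_expected, tab$pct_observed),
      error = function(e) NULL)
  } else {
    fl <- retention_filters(tr$reads, min_length = config$min_length,
                            drop_singletons = config$drop_singletons)
    acc$filter <- fl$accounting
    otus <- cluster_otus(fl$reads, threshold = config$cluster_threshold)
    recs <- identify_otus(otus, config$refdb,
                          min_coverage = config$min_coverage,
                          min_reads = config$min_reads,
                          species_identity = config$species_identity)
    out$otus <- otus
    out$composition <- report_composition(recs, total_reads = nrow(reads))
  }
  out$accounting <- accounting_df(acc)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_report(out$accounting,
                     file.path(config$output_dir, "stage_accounting.tsv"))
    if (!is.null(out$abundance)) {
      write_tsv_report(out$abundance,
                       file.path(config$output_dir, "abundance.tsv"))
    }
    if (!is.null(out$composition)) {
      write_tsv_report(out$composition,
                       file.path(config$output_dir, "otu_composition.tsv"))
    }
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> mode=%s\n", x$config$mode))
  print(x$accounting)
  invisible(x)
}
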