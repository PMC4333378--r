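#' Pipeline configuration
#'
#' @param reference Path to the reference FASTA.
#' @param mutants Path to the sequenced-mutant FASTA.
#' @param regions Optional BED path (STR / coding / hairpin annotations).
#' @param counts Optional colony-count TSV path.
#' @param D,P,NiN Gap-assay parameters (see [gap_assay_params()]).
#' @param grouping_distance Complex-event grouping distance (default 10).
#' @param outdir Output directory.
#' @param seed Seed applied before any stochastic stage.
#' @param verbose Emit progress messages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(reference, mutants, regions = NULL,
                            counts = NULL, D = 147, P = 0.3, NiN = 1,
                            grouping_distance = 10L, outdir = "polfid_out",
                            seed = 1L, verbose = FALSE) {
  if (grouping_distance < 0)
    stop("grouping_distance must be >= 0", call. = FALSE)
  structure(list(reference = reference, mutants = mutants,
                 regions = regions, counts = counts,
                 params = gap_assay_params(D, P, NiN),
                 grouping_distance = as.integer(grouping_distance),
                 outdir = outdir, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: read inputs, call/normalize/group mutations, tabulate the error
#' spectrum (event and group conventions), partition by region (when
#' regions are given), scan for hotspots, and compute the fidelity table
#' (when colony counts are given). All tables are written as TSV under
#' `outdir`, plus a `run_report.json`. Inputs are validated up front so an
#' input error leaves no partial outputs behind.
#'
#' @param config A [pipeline_config()].
#' @return The run report (invisibly a list; also written as JSON):
#'   versions, config echo, per-stage record counts, warnings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(...)
  warnings <- character(0)

  # ---- read and validate everything before writing anything
  reference <- read_reference_fasta(config$reference)
  reads <- read_mutants_fasta(config$mutants)
  if (!is.null(config$regions)) {
    reference$regions <- read_bed_regions(config$regions, reference)
  }
  counts_table <- if (!is.null(config$counts)) read_counts_tsv(config$counts)
  say("inputs: ", nchar(reference$sequence), " nt reference, ",
      nrow(reads), " mutant reads")

  set.seed(config$seed)
  stages <- list()

  events <- call_mutations(reference, reads,
                           grouping_distance = config$grouping_distance)
  stages$call <- nrow(events)
  say("called ", nrow(events), " events")

  spec <- tabulate_spectrum(events)
  spectrum_tbl <- as.data.frame(spec)
  stages$spectrum <- spec$total_events

  group_tbl <- group_convention_table(events)
  results <- list(events = events, spectrum = spectrum_tbl,
                  spectrum_groups = group_tbl)

  if (!is.null(reference$regions)) {
    results$regions <- partition_by_region(events, reference)
    stages$regions <- sum(results$regions$n_groups)
  }

  hs <- hotspot_scan(events, reference, all_positions = TRUE)
  results$hotspots <- hs
  stages$hotspots <- sum(hs$q_value <= 0.05 & hs$event_count > 0)

  if (!is.null(counts_table)) {
    results$fidelity <- lacz_fidelity_table(counts_table,
                                            params = config$params)
    stages$fidelity <- nrow(results$fidelity)
  }

  files <- write_tables(results, config$outdir)
  report <- list(
    package = "polfid",
    version = as.character(utils::packageVersion("polfid")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config[c("reference", "mutants", "regions", "counts",
                      "grouping_distance", "outdir", "seed")],
    params = unclass(config$params),
    n_mutants = attr(events, "n_mutants"),
    stages = stages,
    warnings = warnings,
    files = unname(files))
  jsonlite::write_json(report, file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  say("wrote ", length(files) + 1L, " files to ", config$outdir)
  invisible(report)
}

# Group-convention spectrum: each multi-event group tallied once as
# "complex" (the HSV-tk-style summary), singleton groups by their event
# kind/class.
group_convention_table <- function(events) {
  if (nrow(events) == 0L)
    return(data.frame(category = c("Complex", "Insertions", "Deletions",
                                   "Base Substitutions", "Frameshifts",
                                   "Large Deletions", "Total Groups"),
                      number = 0L, stringsAsFactors = FALSE))
  key <- paste(events$mutant_id, events$group_id)
  per_group <- lapply(split(seq_len(nrow(events)), key), function(idx)
    events[idx, , drop = FALSE])
  cls <- vapply(per_group, classify_group, "")
  tab <- table(factor(cls, levels = c("Complex", "Insertions", "Deletions",
                                      "Base Substitutions")))
  fs <- sum(vapply(per_group, is_frameshift_group, NA))
  ld <- sum(vapply(per_group, is_large_deletion_group, NA))
  data.frame(category = c(names(tab), "Frameshifts", "Large Deletions",
                          "Total Groups"),
             number = c(as.integer(tab), fs, ld, length(per_group)),
             stringsAsFactors = FALSE)
}

classify_group <- function(g) {
  if (nrow(g) > 1L) return("Complex")
  switch(g$kind, insertion = "Insertions", deletion = "Deletions",
         substitution = "Base Substitutions")
}

# Net length change of a group's events
group_net_length <- function(g) {
  sum(ifelse(g$kind == "insertion", g$length,
             ifelse(g$kind == "deletion", -g$length, 0L)))
}

#' Frameshift / large-deletion group classification
#'
#' An indel-containing group is a frameshift when its net length change is
#' not a multiple of 3 and it is not a large deletion; a large deletion is
#' a net deletion of at least `threshold` nt (default 5; a calibration
#' choice, configurable).
#'
#' @param g One group's event data.frame.
#' @param threshold Large-deletion threshold in nt.
#' @name frameshift_classes
#' @keywords internal
is_frameshift_group <- function(g, threshold = 5L) {
  net <- group_net_length(g)
  net %% 3L != 0L && !is_large_deletion_group(g, threshold)
}

#' @rdname frameshift_classes
#' @keywords internal
is_large_deletion_group <- function(g, threshold = 5L) {
  group_net_length(g) <= -threshold
}
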