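#' Error-prone polymerase model
#'
#' Parameters of the simulated polymerase used to exercise the calling,
#' spectrum and fidelity stages end to end:
#'
#' * `substitution_rates`: 4x4 matrix (rows = templating base, columns =
#'   synthesized base) of per-site miscoding probabilities; diagonal 0.
#' * `indel_rate`: per-site probability of a single-base indel outside
#'   homopolymer runs.
#' * `slippage_base`, `slippage_growth`: per-site slippage-indel
#'   probability inside a homopolymer run of length `L >= 2` is
#'   `slippage_base * slippage_growth^(L - 2)` — a geometric stand-in for
#'   the classic primer/template misalignment mechanism that makes long
#'   runs ([T]8, [A]8) indel hotspots.
#' * `insertion_fraction`: fraction of indels that are insertions
#'   (one-unit duplications; the rest are single-base deletions).
#' * `scrunch_rate`, `hairpin_regions`: per-molecule probability that each
#'   annotated hairpin-forming region triggers a template-scrunching
#'   complex event — a loop-base duplication plus a nearby substitution,
#'   within 10 nt, so downstream grouping labels it complex (the
#'   mechanism that expands a [T]2 template to [T]3/[T]4).
#'
#' @param substitution_rates 4x4 numeric matrix, dimnames ACGT.
#' @param indel_rate,slippage_base,scrunch_rate Probabilities in \[0, 1\].
#' @param slippage_growth Multiplicative factor per extra repeat unit
#'   (>= 1).
#' @param insertion_fraction In \[0, 1\].
#' @param hairpin_regions `NULL` or data.frame with columns `start`, `end`
#'   (1-based inclusive).
#' @return List of class `polymerase_error_model`.
#' @export
polymerase_error_model <- function(substitution_rates,
                                   indel_rate = 0,
                                   slippage_base = indel_rate,
                                   slippage_growth = 1,
                                   insertion_fraction = 0.5,
                                   scrunch_rate = 0,
                                   hairpin_regions = NULL) {
  bases <- c("A", "C", "G", "T")
  m <- as.matrix(substitution_rates)
  if (!all(dim(m) == c(4, 4)))
    stop("substitution_rates must be 4x4 (ACGT x ACGT)", call. = FALSE)
  dimnames(m) <- list(bases, bases)
  diag(m) <- 0
  probs <- c(m, indel_rate, slippage_base, scrunch_rate, insertion_fraction)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (slippage_growth < 1)
    stop("slippage_growth must be >= 1", call. = FALSE)
  if (!is.null(hairpin_regions)) {
    hairpin_regions <- as.data.frame(hairpin_regions)
    stopifnot(all(c("start", "end") %in% names(hairpin_regions)))
  }
  structure(list(substitution_rates = m, indel_rate = indel_rate,
                 slippage_base = slippage_base,
                 slippage_growth = slippage_growth,
                 insertion_fraction = insertion_fraction,
                 scrunch_rate = scrunch_rate,
                 hairpin_regions = hairpin_regions),
            class = "polymerase_error_model")
}

#' Calibration preset emulating the published lacZ-alpha spectrum
#'
#' Class proportions follow the observed 95-event spectrum (substitutions
#' 33/95 split across the six strand-collapsed classes as printed,
#' insertions 20/95, deletions 42/95) at an overall average per-site event
#' rate of `total_rate` (default 1e-4, the order of the measured error
#' rate). A calibration preset, not a mechanistic claim: each
#' strand-collapsed class is split equally between its two ordered changes,
#' and the average is taken over a balanced base composition.
#'
#' @param total_rate Average per-site event probability.
#' @param slippage_growth,scrunch_rate,hairpin_regions Optional mechanism
#'   knobs, off/neutral by default.
#' @return A [polymerase_error_model()].
#' @export
primpol_lacz_model <- function(total_rate = 1e-4, slippage_growth = 1,
                               scrunch_rate = 0, hairpin_regions = NULL) {
  class_counts <- c("A>T/T>A" = 1, "A>C/T>G" = 2, "A>G/T>C" = 0,
                    "G>A/C>T" = 24, "G>C/C>G" = 4, "G>T/C>A" = 2)
  n_ins <- 20; n_del <- 42; n_tot <- 95
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (cl in names(class_counts)) {
    r <- substr(cl, 1, 1); a <- substr(cl, 3, 3)
    # 2 * R * n_c / n_tot per ordered pair makes the balanced-composition
    # average substitution rate equal R * n_sub / n_tot
    rate <- 2 * total_rate * class_counts[[cl]] / n_tot
    m[r, a] <- rate
    m[comp[r], comp[a]] <- rate
  }
  polymerase_error_model(
    substitution_rates = m,
    indel_rate = total_rate * (n_ins + n_del) / n_tot,
    slippage_base = total_rate * (n_ins + n_del) / n_tot,
    slippage_growth = slippage_growth,
    insertion_fraction = n_ins / (n_ins + n_del),
    scrunch_rate = scrunch_rate, hairpin_regions = hairpin_regions)
}

# Per-site rates for a model on a concrete reference:
# data.frame(site, base, sub_rate, indel_rate)
site_rates <- function(model, reference) {
  seqb <- strsplit(reference$sequence, "")[[1]]
  len <- length(seqb)
  sub_rate <- rowSums(model$substitution_rates)[seqb]
  runs <- homopolymer_runs(reference$sequence)
  indel <- rep(model$indel_rate, len)
  for (k in which(runs$length >= 2L)) {
    r <- pmin(1, model$slippage_base *
                model$slippage_growth^(runs$length[k] - 2L))
    indel[runs$start[k]:runs$end[k]] <- r
  }
  if (any(sub_rate + indel >= 1))
    stop("per-site total event probability must be < 1", call. = FALSE)
  data.frame(site = seq_len(len), base = seqb,
             sub_rate = unname(sub_rate), indel_rate = indel,
             stringsAsFactors = FALSE)
}

#' Simulate gap-filling synthesis by an error-prone polymerase
#'
#' Draws, molecule by molecule and site by site, substitution and indel
#' events (at most one event per site per molecule; substitutions win the
#' rare collision), then per-hairpin scrunching complex events. Draw order
#' is fixed — substitutions site 1..L, indels site 1..L, then hairpin
#' regions in order — so a seed pins the entire output.
#'
#' Products are returned as a `mutant_pool`: the per-molecule event table
#' plus the reference; sequences are materialized on demand by
#' [pool_reads()] (materializing millions of identical error-free strings
#' up front would be waste).
#'
#' @param model A [polymerase_error_model()].
#' @param reference A [reference_target()].
#' @param n Number of product molecules.
#' @param seed Integer seed (`NULL` = leave RNG state alone).
#' @return Object of class `mutant_pool`: `reference`, `n`, `events`
#'   (columns `molecule`, `kind`, `position`, `ref_allele`, `alt_allele`,
#'   `length`, `scrunch`).
#' @export
simulate_synthesis <- function(model, reference, n, seed = NULL) {
  stopifnot(inherits(model, "polymerase_error_model"),
            inherits(reference, "reference_target"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sr <- site_rates(model, reference)
  bases <- c("A", "C", "G", "T")
  mol <- integer(0); pos <- integer(0); kind <- character(0)
  refa <- character(0); alta <- character(0); scrunch <- logical(0)
  # substitutions
  for (i in sr$site[sr$sub_rate > 0]) {
    k <- stats::rbinom(1L, n, sr$sub_rate[i])
    if (k == 0L) next
    ids <- sample.int(n, k)
    p <- model$substitution_rates[sr$base[i], ]
    alt <- sample(bases, k, replace = TRUE, prob = p / sum(p))
    mol <- c(mol, ids); pos <- c(pos, rep.int(i, k))
    kind <- c(kind, rep.int("substitution", k))
    refa <- c(refa, rep.int(sr$base[i], k)); alta <- c(alta, alt)
    scrunch <- c(scrunch, rep.int(FALSE, k))
  }
  sub_key <- paste(mol, pos)
  # indels (single-base; slippage inside runs)
  for (i in sr$site[sr$indel_rate > 0]) {
    k <- stats::rbinom(1L, n, sr$indel_rate[i])
    if (k == 0L) next
    ids <- sample.int(n, k)
    is_ins <- stats::runif(k) < model$insertion_fraction
    keep <- !(paste(ids, i) %in% sub_key)  # substitution wins collisions
    if (!any(keep)) next
    ids <- ids[keep]; is_ins <- is_ins[keep]; k <- length(ids)
    mol <- c(mol, ids); pos <- c(pos, rep.int(i, k))
    kind <- c(kind, ifelse(is_ins, "insertion", "deletion"))
    refa <- c(refa, ifelse(is_ins, "", sr$base[i]))
    alta <- c(alta, ifelse(is_ins, sr$base[i], ""))
    scrunch <- c(scrunch, rep.int(FALSE, k))
  }
  # hairpin scrunching: loop-base duplication + nearby substitution
  hp <- model$hairpin_regions
  len <- nchar(reference$sequence)
  if (!is.null(hp) && model$scrunch_rate > 0) {
    for (h in seq_len(nrow(hp))) {
      st <- hp$start[h]; en <- min(hp$end[h], len)
      k <- stats::rbinom(1L, n, model$scrunch_rate)
      if (k == 0L) next
      ids <- sample.int(n, k)
      b1 <- sr$base[st]
      sub_pos <- min(st + 3L, en)
      b2 <- sr$base[sub_pos]
      alt2 <- bases[bases != b2][1L]  # deterministic companion change
      mol <- c(mol, ids, ids)
      pos <- c(pos, rep.int(st, k), rep.int(sub_pos, k))
      kind <- c(kind, rep.int("insertion", k), rep.int("substitution", k))
      refa <- c(refa, rep.int("", k), rep.int(b2, k))
      alta <- c(alta, rep.int(b1, k), rep.int(alt2, k))
      scrunch <- c(scrunch, rep.int(TRUE, 2L * k))
    }
  }
  events <- data.frame(molecule = mol, kind = kind, position = pos,
                       ref_allele = refa, alt_allele = alta,
                       length = rep(1L, length(mol)), scrunch = scrunch,
                       stringsAsFactors = FALSE)
  # one event per (molecule, site): scrunch events override site events
  key <- paste(events$molecule, events$position)
  o <- order(!events$scrunch)
  events <- events[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
  events <- events[order(events$molecule, events$position), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(reference = reference, n = n, events = events,
                 model = model),
            class = "mutant_pool")
}

#' @export
print.mutant_pool <- function(x, ...) {
  cat("<mutant_pool> ", x$n, " molecules, ", nrow(x$events), " events in ",
      length(unique(x$events$molecule)), " molecules\n", sep = "")
  invisible(x)
}

#' Materialize product sequences from a simulated pool
#'
#' @param pool A `mutant_pool` from [simulate_synthesis()].
#' @param molecules Molecule indices to materialize (default all `1..n`).
#' @return A [mutant_reads()] data.frame (ids `sim_<index>`).
#' @export
pool_reads <- function(pool, molecules = seq_len(pool$n)) {
  stopifnot(inherits(pool, "mutant_pool"))
  ref_seq <- pool$reference$sequence
  ev_by_mol <- split(pool$events, pool$events$molecule)
  seqs <- vapply(molecules, function(m) {
    ev <- ev_by_mol[[as.character(m)]]
    if (is.null(ev)) ref_seq else apply_events(ref_seq, ev)
  }, "")
  mutant_reads(seqs, ids = paste0("sim_", molecules))
}

#' Assay-screening simulation settings
#'
#' @param expression_p Probability that the error-carrying strand is the
#'   phenotypically expressed one (the assay's `P`).
#' @param background_mf Assay background mutant frequency.
#' @param n_sequenced Mutant products to sample for sequencing.
#' @param detectable Optional 1-based detectable positions overriding the
#'   reference's own detectable-site model.
#' @param seed Integer seed for the screening draws.
#' @return List of class `assay_sim_config`.
#' @export
assay_sim_config <- function(expression_p = 0.3, background_mf = 0,
                             n_sequenced = 0, detectable = NULL,
                             seed = NULL) {
  if (!(expression_p > 0 && expression_p <= 1))
    stop("expression_p must be in (0, 1]", call. = FALSE)
  if (background_mf < 0 || background_mf >= 1)
    stop("background_mf must be in [0, 1)", call. = FALSE)
  structure(list(expression_p = expression_p, background_mf = background_mf,
                 n_sequenced = n_sequenced, detectable = detectable,
                 seed = seed), class = "assay_sim_config")
}

# Does each event overlap a detectable position? Insertions count via
# their left flank (position 1 when anchored before the sequence).
event_detectable <- function(events, detectable) {
  if (is.null(detectable)) return(rep(TRUE, nrow(events)))
  start <- pmax(events$position, 1L)
  end <- ifelse(events$kind == "insertion", start,
                events$position + events$length - 1L)
  vapply(seq_len(nrow(events)), function(i)
    any(detectable >= start[i] & detectable <= end[i]), NA)
}

#' Simulate the colony-screening readout
#'
#' A product scores as a phenotypic mutant iff it carries at least one
#' event overlapping a detectable site and an independent expression draw
#' (probability `expression_p`) succeeds. Background mutants are a
#' binomial draw at `background_mf` over the remaining products. Returns
#' colony counts plus a uniform without-replacement sample of sequenced
#' phenotypic mutants.
#'
#' @param pool A `mutant_pool`.
#' @param config An [assay_sim_config()].
#' @return List of class `assay_sim_result`: `counts` ([colony_counts()]),
#'   `reads` (sequenced sample, [mutant_reads()]), `sequenced_molecules`,
#'   `n_phenotypic`.
#' @export
simulate_colony_assay <- function(pool, config = assay_sim_config()) {
  stopifnot(inherits(pool, "mutant_pool"),
            inherits(config, "assay_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  detectable <- if (!is.null(config$detectable)) config$detectable
                else detectable_positions(pool$reference)
  det <- event_detectable(pool$events, detectable)
  carriers <- sort(unique(pool$events$molecule[det]))
  expressed <- carriers[stats::runif(length(carriers)) < config$expression_p]
  n_background <- stats::rbinom(1L, pool$n - length(expressed),
                                config$background_mf)
  counts <- colony_counts(pool$n, length(expressed) + n_background,
                          config$background_mf)
  n_seq <- min(config$n_sequenced, length(expressed))
  if (config$n_sequenced > length(expressed) && config$n_sequenced > 0)
    warning("only ", length(expressed), " phenotypic mutants available; ",
            "returning all", call. = FALSE)
  sampled <- if (n_seq > 0) sort(sample(expressed, n_seq)) else integer(0)
  reads <- if (n_seq > 0) pool_reads(pool, sampled) else NULL
  structure(list(counts = counts, reads = reads,
                 sequenced_molecules = sampled,
                 n_phenotypic = length(expressed)),
            class = "assay_sim_result")
}

#' Recover the per-site error rate from a simulated assay
#'
#' Pipes the simulated colony counts through
#' [corrected_mutation_frequency()] and [error_rate_gap_assay()]; with a
#' substitution-only uniform model this closes the loop against the true
#' configured rate.
#'
#' @param result An `assay_sim_result`.
#' @param params A [gap_assay_params()] (use `D` = number of detectable
#'   sites and `P` = the simulation's expression probability).
#' @return Estimated errors per base.
#' @export
recover_error_rate <- function(result, params) {
  stopifnot(inherits(result, "assay_sim_result"))
  error_rate_gap_assay(corrected_mutation_frequency(result$counts), params)
}

#' Expected event-category proportions for a model on a reference
#'
#' Marginal per-molecule expected event counts per spectrum category
#' (six substitution classes, insertions, deletions), normalized to
#' proportions — the oracle that simulated spectra are tested against.
#'
#' @param model A [polymerase_error_model()].
#' @param reference A [reference_target()].
#' @return Named numeric vector of proportions (sums to 1).
#' @export
expected_spectrum <- function(model, reference) {
  sr <- site_rates(model, reference)
  cats <- c(substitution_classes(), "Insertions", "Deletions")
  out <- stats::setNames(numeric(length(cats)), cats)
  bases <- c("A", "C", "G", "T")
  for (b in bases) {
    n_b <- sum(sr$base == b)
    for (a in setdiff(bases, b)) {
      cl <- collapse_substitution(b, a)
      out[cl] <- out[cl] + n_b * model$substitution_rates[b, a]
    }
  }
  out["Insertions"] <- sum(sr$indel_rate) * model$insertion_fraction
  out["Deletions"] <- sum(sr$indel_rate) * (1 - model$insertion_fraction)
  hp <- model$hairpin_regions
  if (!is.null(hp) && model$scrunch_rate > 0) {
    for (h in seq_len(nrow(hp))) {
      st <- hp$start[h]
      b2 <- sr$base[min(st + 3L, hp$end[h], nchar(reference$sequence))]
      alt2 <- bases[bases != b2][1L]
      out["Insertions"] <- out["Insertions"] + model$scrunch_rate
      cl <- collapse_substitution(b2, alt2)
      out[cl] <- out[cl] + model$scrunch_rate
    }
  }
  out / sum(out)
}
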