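#' Strand-collapsed substitution classes
#'
#' Forward-assay spectra report base substitutions collapsed over the two
#' strands: a change and its complement (e.g. G>A and C>T) are the same
#' class because the assay cannot tell which strand templated the error.
#' The six classes are `A>T/T>A`, `A>C/T>G`, `A>G/T>C`, `G>A/C>T`,
#' `G>C/C>G`, `G>T/C>A`.
#'
#' @param ref_base,alt_base Single bases in `A`, `C`, `G`, `T`,
#'   `ref_base != alt_base`. Vectorized.
#' @return Class label(s).
#' @examples
#' collapse_substitution("G", "A")  # "G>A/C>T"
#' collapse_substitution("C", "T")  # same class, complement symmetry
#' @export
collapse_substitution <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base)
  alt_base <- toupper(alt_base)
  if (any(!ref_base %in% c("A", "C", "G", "T")) ||
      any(!alt_base %in% c("A", "C", "G", "T")))
    stop("bases must be one of A, C, G, T", call. = FALSE)
  if (any(ref_base == alt_base))
    stop("ref and alt base must differ", call. = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # canonical representative: the purine-templated member (A or G first)
  flip <- ref_base %in% c("C", "T")
  r <- ifelse(flip, comp[ref_base], ref_base)
  a <- ifelse(flip, comp[alt_base], alt_base)
  paste0(r, ">", a, "/", comp[r], ">", comp[a])
}

#' All six substitution-class labels, in spectrum-table order
#' @export
substitution_classes <- function() {
  c("A>T/T>A", "A>C/T>G", "A>G/T>C", "G>A/C>T", "G>C/C>G", "G>T/C>A")
}

#' Tabulate an error spectrum
#'
#' Collapses a called-event table into the spectrum shape of a
#' forward-assay mutation table: counts and percentages per
#' strand-collapsed substitution class, insertions, deletions, plus derived
#' rows (transitions, transversions, G/C-templated vs A/T-templated
#' substitutions). Two complex-event conventions are reported: `by_event`
#' (every event counts in its own category; the lacZ-alpha-style table) and
#' `by_group` (each multi-event group counts once as complex; the
#' HSV-tk-style summary). Both event and group totals are included.
#'
#' @param events Event table from [call_mutations()], or any data.frame
#'   with columns `kind`, `ref_allele`, `alt_allele` (optionally
#'   `mutant_id`, `group_id`, `is_complex`).
#' @param digits Decimals for percentages (default 1, table rendering).
#' @return An object of class `error_spectrum`.
#' @export
tabulate_spectrum <- function(events, digits = 1L) {
  classes <- substitution_classes()
  sub <- events[events$kind == "substitution", , drop = FALSE]
  sub_counts <- stats::setNames(integer(6), classes)
  if (nrow(sub)) {
    tab <- table(collapse_substitution(sub$ref_allele, sub$alt_allele))
    sub_counts[names(tab)] <- as.integer(tab)
  }
  ins <- sum(events$kind == "insertion")
  del <- sum(events$kind == "deletion")
  total <- sum(sub_counts) + ins + del
  pct <- function(k) if (total > 0) round(100 * k / total, digits) else NA_real_
  counts <- c(sub_counts, Insertions = ins, Deletions = del)
  transitions <- sum(sub_counts[c("A>G/T>C", "G>A/C>T")])
  transversions <- sum(sub_counts) - transitions
  gc_templated <- sum(sub_counts[c("G>A/C>T", "G>C/C>G", "G>T/C>A")])
  at_templated <- sum(sub_counts[c("A>T/T>A", "A>C/T>G", "A>G/T>C")])
  n_complex_groups <- 0L
  n_groups <- NA_integer_
  if (all(c("mutant_id", "group_id", "is_complex") %in% names(events)) &&
      nrow(events)) {
    key <- paste(events$mutant_id, events$group_id)
    first <- !duplicated(key)
    n_groups <- sum(first)
    n_complex_groups <- sum(events$is_complex[first])
  } else if (nrow(events) == 0L) n_groups <- 0L
  structure(list(
    counts = counts,
    percentages = vapply(counts, pct, 0),
    total_events = total,
    derived = c(transitions = transitions, transversions = transversions,
                GC_templated = gc_templated, AT_templated = at_templated),
    derived_pct = vapply(c(transitions, transversions, gc_templated,
                           at_templated), pct, 0),
    n_groups = n_groups, n_complex_groups = n_complex_groups,
    digits = digits), class = "error_spectrum")
}

#' @export
print.error_spectrum <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
#' @describeIn tabulate_spectrum Spectrum as a three-column table
#'   (`mutation_type`, `number`, `frequency_pct`).
as.data.frame.error_spectrum <- function(x, ...) {
  d <- data.frame(
    mutation_type = c(names(x$counts), "Total", "A>N/T>N", "G>N/C>N",
                      "Transitions", "Transversions"),
    number = c(unname(x$counts), x$total_events,
               unname(x$derived[c("AT_templated", "GC_templated",
                                  "transitions", "transversions")])),
    frequency_pct = c(unname(x$percentages),
                      if (x$total_events > 0) 100 else NA_real_,
                      unname(x$derived_pct[c(4L, 3L, 1L, 2L)])),
    stringsAsFactors = FALSE)
  d
}

#' Partition event groups by annotated region
#'
#' Assigns each event group to the region containing its span midpoint
#' (deterministic for groups straddling a boundary); groups falling in no
#' region are counted as unassigned. Region totals conserve counts.
#'
#' @param events Event table from [call_mutations()] (needs `mutant_id`,
#'   `group_id`, `position`, `length`, `kind`).
#' @param reference A [reference_target()] with regions annotated.
#' @return data.frame with one row per region plus `unassigned`: columns
#'   `region`, `n_groups`, `n_events`.
#' @export
partition_by_region <- function(events, reference) {
  stopifnot(inherits(reference, "reference_target"))
  regions <- reference$regions
  len <- nchar(reference$sequence)
  labels <- if (is.null(regions)) character(0) else regions$label
  zero <- data.frame(region = c(labels, "unassigned"),
                     n_groups = 0L, n_events = 0L, stringsAsFactors = FALSE)
  if (nrow(events) == 0L) return(zero)
  ev_end <- ifelse(events$kind == "insertion", events$position,
                   events$position + events$length - 1L)
  if (any(events$position < 0L) || any(ev_end > len))
    stop("event span outside reference", call. = FALSE)
  key <- paste(events$mutant_id, events$group_id)
  spans <- do.call(rbind, lapply(split(seq_len(nrow(events)), key),
                                 function(idx)
    c(min(events$position[idx]), max(ev_end[idx]), length(idx))))
  mid <- floor((spans[, 1] + spans[, 2]) / 2)
  assign <- rep("unassigned", nrow(spans))
  for (i in seq_along(labels))
    assign[mid >= regions$start[i] & mid <= regions$end[i] &
             assign == "unassigned"] <- labels[i]
  agg_g <- tapply(rep(1L, nrow(spans)), assign, sum)
  agg_e <- tapply(spans[, 3], assign, sum)
  zero$n_groups <- as.integer(ifelse(is.na(agg_g[zero$region]), 0L,
                                     agg_g[zero$region]))
  zero$n_events <- as.integer(ifelse(is.na(agg_e[zero$region]), 0L,
                                     agg_e[zero$region]))
  zero
}

#' Scan for positional mutation hotspots
#'
#' Tests each reference position's event count against a uniform
#' across-positions binomial null (an exploratory statistic: published
#' hotspots in these assays are typically identified by inspection).
#' Events are assigned to their normalized (left-aligned) position; the
#' p-value is the exact upper binomial tail, BH-adjusted across positions.
#'
#' @param events Event table (column `position`).
#' @param reference A [reference_target()].
#' @param alpha FDR threshold in (0, 1]; positions with `q <= alpha` are
#'   returned, sorted by event count.
#' @param all_positions Return the full per-position table instead of only
#'   the significant ones.
#' @return data.frame: `position`, `event_count`, `expected_count`,
#'   `p_value`, `q_value`.
#' @export
hotspot_scan <- function(events, reference, alpha = 0.05,
                         all_positions = FALSE) {
  if (!(alpha > 0 && alpha <= 1))
    stop("alpha must be in (0, 1]", call. = FALSE)
  len <- nchar(reference$sequence)
  n <- nrow(events)
  if (n == 0L)
    return(data.frame(position = integer(), event_count = integer(),
                      expected_count = numeric(), p_value = numeric(),
                      q_value = numeric()))
  pos <- pmax(events$position, 1L)
  counts <- tabulate(pos, nbins = len)
  p0 <- 1 / len
  # exact upper tail P(X >= k), X ~ Binomial(n, 1/len)
  p <- stats::pbinom(counts - 1L, size = n, prob = p0, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(position = seq_len(len), event_count = counts,
                    expected_count = n * p0, p_value = p, q_value = q)
  if (!all_positions) {
    out <- out[out$q_value <= alpha & out$event_count > 0, , drop = FALSE]
    out <- out[order(-out$event_count, out$position), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
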