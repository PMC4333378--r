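#' Mutation events
#'
#' Events are rows of a data.frame with columns `kind` (`substitution`,
#' `insertion`, `deletion`), `position` (1-based reference coordinate; for
#' insertions the base immediately left of the inserted run, 0 before
#' position 1), `ref_allele`, `alt_allele`, `length`. Substitutions are
#' always length 1: adjacent mismatch columns are reported as separate
#' single-base events so spectrum classes stay single-base.
#'
#' @name mutation_events
NULL

empty_events <- function() {
  data.frame(kind = character(), position = integer(),
             ref_allele = character(), alt_allele = character(),
             length = integer(), stringsAsFactors = FALSE)
}

# Parse a pairwise alignment into raw (not yet normalized) events.
# With mask_n = TRUE, columns where the read carries N are masked: they
# yield no event; the number of masked columns is attached as attribute
# "masked". mask_n = FALSE keeps N columns as events so that the alignment
# can be rebuilt losslessly (used internally by normalize_indels).
parse_alignment_events <- function(alignment, mask_n = TRUE) {
  cols <- alignment_columns(alignment)
  n <- length(cols$ref)
  state <- ifelse(cols$ref == "-", "ins",
           ifelse(cols$read == "-", "del",
           ifelse(cols$ref == cols$read, "match", "mismatch")))
  masked <- mask_n & cols$read == "N" & state %in% c("mismatch", "ins")
  state[masked & state == "mismatch"] <- "match"
  ev <- list()
  i <- 1L
  while (i <= n) {
    s <- state[i]
    if (s == "match" || s == "mismatch") {
      if (s == "mismatch")
        ev[[length(ev) + 1L]] <- data.frame(
          kind = "substitution", position = cols$pos[i],
          ref_allele = cols$ref[i], alt_allele = cols$read[i], length = 1L,
          stringsAsFactors = FALSE)
      i <- i + 1L
    } else {
      j <- i
      while (j < n && state[j + 1L] == s) j <- j + 1L
      if (s == "del") {
        ev[[length(ev) + 1L]] <- data.frame(
          kind = "deletion", position = cols$pos[i],
          ref_allele = paste(cols$ref[i:j], collapse = ""),
          alt_allele = "", length = j - i + 1L, stringsAsFactors = FALSE)
      } else {
        alt <- paste(cols$read[i:j], collapse = "")
        if (!mask_n || !grepl("N", alt, fixed = TRUE))
          ev[[length(ev) + 1L]] <- data.frame(
            kind = "insertion", position = cols$pos[i],
            ref_allele = "", alt_allele = alt,
            length = j - i + 1L, stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else empty_events()
  out <- out[order(out$position, match(out$kind, c("deletion", "insertion",
                                                   "substitution"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "masked") <- sum(masked)
  out
}

# Left-shift indel events against the reference; shifting never crosses a
# previously placed event. Deletion of ref[p..p+L-1] may move to p-1 iff
# ref[p-1] == ref[p+L-1]; an insertion S anchored after position p may move
# left iff its last base equals ref[p] (the allele is rotated).
left_shift_events <- function(events, ref_seq) {
  if (nrow(events) == 0L) return(events)
  events <- events[order(events$position), , drop = FALSE]
  refb <- strsplit(ref_seq, "")[[1]]
  prev_end <- 0L
  for (k in seq_len(nrow(events))) {
    e <- events[k, ]
    if (e$kind == "deletion") {
      p <- e$position
      while (p - 1L > prev_end && refb[p - 1L] == refb[p + e$length - 1L])
        p <- p - 1L
      events$position[k] <- p
      events$ref_allele[k] <- substr(ref_seq, p, p + e$length - 1L)
      prev_end <- p + e$length - 1L
    } else if (e$kind == "insertion") {
      p <- e$position
      s <- e$alt_allele
      while (p > prev_end && p >= 1L &&
             refb[p] == substr(s, e$length, e$length)) {
        s <- paste0(refb[p], substr(s, 1L, e$length - 1L))
        p <- p - 1L
      }
      events$position[k] <- p
      events$alt_allele[k] <- s
      prev_end <- max(prev_end, p)
    } else {
      prev_end <- e$position
    }
  }
  events[order(events$position, match(events$kind,
                                      c("deletion", "insertion",
                                        "substitution"))), , drop = FALSE]
}

# Rebuild gapped alignment rows from the reference and an event list.
events_to_alignment <- function(ref_seq, events, score = NA_real_) {
  ref_out <- character(0)
  read_out <- character(0)
  refb <- strsplit(ref_seq, "")[[1]]
  cursor <- 1L
  # at equal positions, insertions (anchored after that base) come last
  if (nrow(events)) events <- events[order(events$position,
                                           events$kind == "insertion"), ,
                                     drop = FALSE]
  for (k in seq_len(nrow(events))) {
    e <- events[k, ]
    if (e$kind == "insertion") {
      take <- if (e$position >= cursor) refb[seq_len(e$position - cursor + 1L) +
                                             cursor - 1L] else character(0)
      ref_out <- c(ref_out, take, rep("-", e$length))
      read_out <- c(read_out, take, strsplit(e$alt_allele, "")[[1]])
      cursor <- e$position + 1L
    } else {
      if (e$position > cursor) {
        take <- refb[cursor:(e$position - 1L)]
        ref_out <- c(ref_out, take)
        read_out <- c(read_out, take)
      }
      span <- refb[e$position:(e$position + e$length - 1L)]
      if (e$kind == "deletion") {
        ref_out <- c(ref_out, span)
        read_out <- c(read_out, rep("-", e$length))
      } else {
        ref_out <- c(ref_out, span)
        read_out <- c(read_out, strsplit(e$alt_allele, "")[[1]])
      }
      cursor <- e$position + e$length
    }
  }
  if (cursor <= length(refb)) {
    take <- refb[cursor:length(refb)]
    ref_out <- c(ref_out, take)
    read_out <- c(read_out, take)
  }
  new_pairwise_alignment(paste(ref_out, collapse = ""),
                         paste(read_out, collapse = ""), score)
}

#' Canonicalize indel placement in an alignment
#'
#' Shifts every gap run as far left as possible on the reference without
#' changing the implied read, yielding the unique left-aligned canonical
#' form (the standard variant-normalization convention). Without this step,
#' slippage events inside homopolymer runs would be reported at whichever
#' of the score-equivalent placements the aligner happened to emit.
#' Idempotent.
#'
#' @param alignment A `pairwise_alignment`.
#' @return The canonical `pairwise_alignment` (same score).
#' @export
normalize_indels <- function(alignment) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  ref_seq <- degap(alignment$ref_row)
  ev <- parse_alignment_events(alignment, mask_n = FALSE)
  if (!any(ev$kind %in% c("insertion", "deletion"))) return(alignment)
  out <- events_to_alignment(ref_seq, left_shift_events(ev, ref_seq),
                             alignment$score)
  if (degap(out$read_row) != degap(alignment$read_row))
    stop("internal error: normalization changed the implied read")
  out
}

#' Call mutation events from a (normalized) alignment
#'
#' Maximal gap runs become one insertion/deletion event each; each mismatch
#' column becomes a length-1 substitution. Read columns carrying `N` are
#' masked and never yield events (count attached as attribute `masked`).
#' Applying the returned events to the reference reconstructs the read.
#'
#' @param alignment A `pairwise_alignment`, ideally from
#'   [normalize_indels()].
#' @return Event data.frame (see [mutation_events]).
#' @export
call_events <- function(alignment) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  parse_alignment_events(alignment)
}

#' Apply events to a reference sequence
#'
#' Reconstructs the read implied by an event list; the round-trip contract
#' of the calling pipeline.
#'
#' @param ref_seq Reference sequence string.
#' @param events Event data.frame.
#' @return The mutated sequence.
#' @export
apply_events <- function(ref_seq, events) {
  degap(events_to_alignment(ref_seq, events)$read_row)
}

#' Group nearby events into complex-event groups
#'
#' Single-linkage grouping: two events share a group iff their nearest
#' reference coordinates are `<= grouping_distance` apart. The number of
#' groups per mutant is the multiplicity `n` used by the multiple-error
#' correction of the polymerase error frequency (capped at 3 downstream,
#' matching the summation limits of that formula).
#'
#' @param events Event data.frame for one mutant, sorted by position.
#' @param grouping_distance Maximum nearest-coordinate separation within a
#'   group (default 10; errors further apart count as independent).
#' @return List of `event_group` objects: `events`, `span`, `is_complex`.
#' @export
group_events <- function(events, grouping_distance = 10L) {
  if (grouping_distance < 0) stop("grouping_distance must be >= 0",
                                  call. = FALSE)
  if (is.null(events) || nrow(events) == 0L) return(list())
  events <- events[order(events$position), , drop = FALSE]
  start <- events$position
  end <- ifelse(events$kind == "insertion", events$position,
                events$position + events$length - 1L)
  gid <- integer(nrow(events))
  gid[1L] <- 1L
  run_end <- end[1L]
  for (i in seq_len(nrow(events))[-1L]) {
    gid[i] <- if (start[i] - run_end <= grouping_distance)
      gid[i - 1L] else gid[i - 1L] + 1L
    run_end <- max(run_end, end[i])
  }
  lapply(split(seq_len(nrow(events)), gid), function(idx) {
    e <- events[idx, , drop = FALSE]
    rownames(e) <- NULL
    structure(list(events = e,
                   span = c(min(start[idx]), max(end[idx])),
                   is_complex = length(idx) > 1L),
              class = "event_group")
  })
}

#' @export
print.event_group <- function(x, ...) {
  cat("<event_group> ", nrow(x$events), " event(s), span ", x$span[1], "-",
      x$span[2], if (x$is_complex) " (complex)", "\n", sep = "")
  invisible(x)
}

#' Call, normalize and group mutations for a set of sequenced mutants
#'
#' The full calling stage: global alignment, canonical left-aligned indel
#' placement, event calling and `<=` 10-nt grouping for every read.
#'
#' @param reference A [reference_target()].
#' @param reads A [mutant_reads()] data.frame (or character vector).
#' @param scoring An [alignment_scoring()].
#' @param grouping_distance See [group_events()].
#' @param deduplicate Drop identical sequences from the same source
#'   reaction (default `FALSE`; duplicates are flagged either way in the
#'   `duplicate_of` column).
#' @return Event table with columns `mutant_id`, `kind`, `position`,
#'   `ref_allele`, `alt_allele`, `length`, `group_id`, `is_complex`;
#'   attribute `n_mutants` carries the number of reads analysed, attribute
#'   `multiplicity` the per-mutant group counts (names = mutant ids).
#' @export
call_mutations <- function(reference, reads, scoring = alignment_scoring(),
                           grouping_distance = 10L, deduplicate = FALSE) {
  if (is.character(reads)) reads <- mutant_reads(reads)
  dupkey <- paste(reads$source_reaction, reads$sequence, sep = "\r")
  dup_of <- reads$id[match(dupkey, dupkey)]
  dup_of[dup_of == reads$id] <- NA_character_
  if (deduplicate) {
    reads <- reads[is.na(dup_of), , drop = FALSE]
    dup_of <- dup_of[is.na(dup_of)]
  }
  alns <- align_many(reference, reads$sequence, scoring)
  per <- lapply(seq_along(alns), function(i) {
    ev <- call_events(normalize_indels(alns[[i]]))
    grp <- group_events(ev, grouping_distance)
    if (length(grp) == 0L) return(NULL)
    do.call(rbind, lapply(seq_along(grp), function(g) {
      e <- grp[[g]]$events
      cbind(data.frame(mutant_id = reads$id[i], stringsAsFactors = FALSE),
            e, group_id = g, is_complex = grp[[g]]$is_complex)
    }))
  })
  out <- do.call(rbind, per)
  if (is.null(out))
    out <- cbind(data.frame(mutant_id = character(), stringsAsFactors = FALSE),
                 empty_events(), group_id = integer(), is_complex = logical())
  rownames(out) <- NULL
  mult <- vapply(split(out$group_id, out$mutant_id), max, 0L)
  attr(out, "n_mutants") <- nrow(reads)
  attr(out, "multiplicity") <- mult
  attr(out, "duplicate_of") <- stats::setNames(dup_of, reads$id)
  out
}
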