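#' Reference reporter target
#'
#' Container for a reporter target sequence (e.g. a lacZ-alpha gap or an
#' HSV-tk fragment), its annotated regions (STR tract, coding region,
#' hairpin-forming window, ...) and its detectable-site model.
#'
#' Detectable sites are the reference positions at which a polymerase error
#' produces the mutant phenotype. They may be given as explicit 1-based
#' positions, or -- when only the aggregate count `D` is known, as in
#' published gap-assay parameter sets -- as a scalar count with unknown
#' positions.
#'
#' @param sequence DNA string over `A`, `C`, `G`, `T` (lower case accepted).
#' @param id Target identifier.
#' @param regions `NULL`, or a data.frame with columns `label`, `start`,
#'   `end` (1-based inclusive coordinates). Labels must be unique.
#' @param detectable_sites Either `NULL` (all positions detectable), an
#'   integer vector of 1-based positions, or a single scalar count `D`
#'   supplied via `detectable_count`.
#' @param detectable_count Scalar detectable-site count `D`, used when the
#'   positions themselves are unknown. Mutually exclusive with explicit
#'   `detectable_sites` positions.
#' @return An object of class `reference_target`.
#' @examples
#' ref <- reference_target("ACGTACGTTTTTACGT", id = "demo",
#'                         regions = data.frame(label = "run",
#'                                              start = 9, end = 13))
#' @export
reference_target <- function(sequence, id = "target", regions = NULL,
                             detectable_sites = NULL, detectable_count = NULL) {
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("reference sequence must be a single non-empty string", call. = FALSE)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("reference sequence may only contain A, C, G, T", call. = FALSE)
  len <- nchar(sequence)
  if (!is.null(regions)) {
    regions <- as.data.frame(regions)
    need <- c("label", "start", "end")
    if (!all(need %in% names(regions)))
      stop("regions need columns label, start, end", call. = FALSE)
    regions$start <- as.integer(regions$start)
    regions$end <- as.integer(regions$end)
    if (anyDuplicated(regions$label))
      stop("region labels must be unique", call. = FALSE)
    bad <- regions$start < 1L | regions$end > len | regions$start > regions$end
    if (any(bad))
      stop("region(s) outside [1, ", len, "]: ",
           paste(regions$label[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.null(detectable_sites) && !is.null(detectable_count))
    stop("give detectable_sites positions or detectable_count, not both",
         call. = FALSE)
  if (!is.null(detectable_sites)) {
    detectable_sites <- sort(unique(as.integer(detectable_sites)))
    if (any(detectable_sites < 1L | detectable_sites > len))
      stop("detectable sites must lie in [1, ", len, "]", call. = FALSE)
  }
  if (!is.null(detectable_count)) {
    detectable_count <- as.numeric(detectable_count)
    if (length(detectable_count) != 1L || detectable_count < 1)
      stop("detectable_count must be a single count >= 1", call. = FALSE)
  }
  structure(list(id = as.character(id), sequence = sequence,
                 regions = regions, detectable_sites = detectable_sites,
                 detectable_count = detectable_count),
            class = "reference_target")
}

#' @export
print.reference_target <- function(x, ...) {
  cat("<reference_target> ", x$id, ": ", nchar(x$sequence), " nt",
      if (!is.null(x$regions)) paste0(", ", nrow(x$regions), " region(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Number of detectable sites D for a reference target
#'
#' Explicit positions win; otherwise the scalar count; otherwise every
#' position is considered detectable.
#' @param reference A [reference_target()].
#' @return Scalar `D`.
#' @export
detectable_count <- function(reference) {
  stopifnot(inherits(reference, "reference_target"))
  if (!is.null(reference$detectable_sites))
    return(length(reference$detectable_sites))
  if (!is.null(reference$detectable_count))
    return(reference$detectable_count)
  nchar(reference$sequence)
}

#' Detectable-site positions (1-based), or NULL when only a count is known
#' @param reference A [reference_target()].
#' @keywords internal
detectable_positions <- function(reference) {
  if (!is.null(reference$detectable_sites)) return(reference$detectable_sites)
  if (!is.null(reference$detectable_count)) return(NULL)
  seq_len(nchar(reference$sequence))
}

#' Sequenced mutant reads
#'
#' @param sequences Character vector of DNA sequences (alphabet `ACGTN`).
#' @param ids Read identifiers (default `mut_1`, `mut_2`, ...).
#' @param source_reaction Independent-reaction label per read, used for
#'   deduplication bookkeeping.
#' @return A data.frame of class `mutant_reads` with columns `id`,
#'   `sequence`, `source_reaction`.
#' @export
mutant_reads <- function(sequences, ids = NULL, source_reaction = "r1") {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L)
    stop("no read sequences supplied", call. = FALSE)
  if (any(!nzchar(sequences)))
    stop("empty read sequence", call. = FALSE)
  if (any(grepl("[^ACGTN]", sequences)))
    stop("read sequences may only contain A, C, G, T, N", call. = FALSE)
  if (is.null(ids)) ids <- paste0("mut_", seq_along(sequences))
  if (anyDuplicated(ids))
    stop("duplicate read ids", call. = FALSE)
  out <- data.frame(id = as.character(ids), sequence = sequences,
                    source_reaction = rep_len(as.character(source_reaction),
                                              length(sequences)),
                    stringsAsFactors = FALSE)
  class(out) <- c("mutant_reads", "data.frame")
  out
}

# Maximal homopolymer runs of a sequence: data.frame(start, end, base, length)
homopolymer_runs <- function(sequence) {
  b <- strsplit(sequence, "")[[1]]
  r <- rle(b)
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1L, end = end,
             base = r$values, length = r$lengths,
             stringsAsFactors = FALSE)
}
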