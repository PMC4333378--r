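#' Alignment scoring parameters
#'
#' Affine-gap scoring for global alignment of a mutant insert against its
#' reference target. A gap run of length `L` scores
#' `gap_open + L * gap_extend`. The defaults favour calling one substitution
#' over an insertion+deletion pair, so single-base miscoding and slippage
#' events fall into the classes a forward-assay spectrum table distinguishes.
#'
#' @param match Match score (> `mismatch`).
#' @param mismatch Mismatch score.
#' @param gap_open Gap-opening penalty (negative).
#' @param gap_extend Per-base gap-extension penalty (negative).
#' @return A list of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 1, mismatch = -2,
                              gap_open = -4, gap_extend = -1) {
  if (!(match > mismatch))
    stop("match score must exceed mismatch score", call. = FALSE)
  if (gap_open >= 0 || gap_extend >= 0)
    stop("gap penalties must be negative", call. = FALSE)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_scoring")
}

new_pairwise_alignment <- function(ref_row, read_row, score) {
  structure(list(ref_row = ref_row, read_row = read_row, score = score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score ", x$score, "\n  ref:  ", x$ref_row,
      "\n  read: ", x$read_row, "\n", sep = "")
  invisible(x)
}

#' Globally align a mutant read to the reference target
#'
#' End-to-end (Needleman-Wunsch) alignment under affine-gap scoring. The
#' backend is deterministic; among score-equivalent alignments the emitted
#' one is made canonical downstream by [normalize_indels()], which
#' left-aligns every gap run.
#'
#' @param reference A [reference_target()].
#' @param read A single read: one row of [mutant_reads()] or a character
#'   sequence.
#' @param scoring An [alignment_scoring()].
#' @return A `pairwise_alignment`: gapped `ref_row` and `read_row` plus the
#'   alignment `score`.
#' @export
align_to_reference <- function(reference, read, scoring = alignment_scoring()) {
  stopifnot(inherits(reference, "reference_target"))
  seqs <- if (is.character(read)) read else read$sequence
  if (length(seqs) != 1L)
    stop("align_to_reference aligns one read; use call_mutations for sets",
         call. = FALSE)
  align_many(reference, seqs, scoring)[[1L]]
}

# Vectorized core: one C++ call for all reads.
align_many <- function(reference, sequences, scoring = alignment_scoring()) {
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences)) || !nzchar(reference$sequence))
    stop("empty sequence", call. = FALSE)
  if (any(grepl("[^ACGTN]", sequences)))
    stop("read alphabet must be A, C, G, T, N", call. = FALSE)
  raw <- .affine_align(reference$sequence, sequences,
                       scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  lapply(raw, function(x)
    new_pairwise_alignment(x$ref_row, x$read_row, x$score))
}

# Split alignment rows into per-column character vectors, with the 1-based
# reference coordinate of each column (insertions carry the coordinate of
# the reference base to their left; 0 before position 1).
alignment_columns <- function(alignment) {
  rr <- strsplit(alignment$ref_row, "")[[1]]
  dr <- strsplit(alignment$read_row, "")[[1]]
  if (length(rr) != length(dr))
    stop("alignment rows differ in length", call. = FALSE)
  if (any(rr == "-" & dr == "-"))
    stop("column gapped in both rows", call. = FALSE)
  pos <- cumsum(rr != "-")
  list(ref = rr, read = dr, pos = pos)
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)
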