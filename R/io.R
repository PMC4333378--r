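# classed input errors so the CLI can distinguish bad inputs (exit 2)
# from runtime failures (exit 3)
input_stop <- function(...) {
  stop(structure(class = c("polfid_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Read a reference target from FASTA
#'
#' The first record becomes the reference; its FASTA name (up to the first
#' whitespace) is the target id.
#'
#' @param path FASTA file.
#' @param regions Optional region data.frame (see [reference_target()]).
#' @param detectable_count Optional scalar detectable-site count `D`.
#' @return A [reference_target()].
#' @export
read_reference_fasta <- function(path, regions = NULL,
                                 detectable_count = NULL) {
  if (!file.exists(path)) input_stop("file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  if (length(ss) > 1L)
    message("using first of ", length(ss), " records as the reference")
  id <- sub("\\s.*$", "", names(ss)[1L])
  reference_target(as.character(ss[[1L]]), id = id, regions = regions,
                   detectable_count = detectable_count)
}

#' Read sequenced mutant inserts from FASTA
#'
#' One record per independent mutant. A ` reaction=<label>` token in the
#' description, if present, becomes the `source_reaction`.
#'
#' @param path FASTA file (multi-record).
#' @return A [mutant_reads()] data.frame.
#' @export
read_mutants_fasta <- function(path) {
  if (!file.exists(path)) input_stop("file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate mutant ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  rx <- regmatches(names(ss), regexpr("reaction=\\S+", names(ss)))
  reaction <- rep("r1", length(ss))
  has <- grepl("reaction=", names(ss))
  reaction[has] <- sub("^reaction=", "", rx)
  mutant_reads(as.character(ss), ids = ids, source_reaction = reaction)
}

#' Write reads to FASTA
#' @param reads A [mutant_reads()] data.frame.
#' @param path Output file.
#' @export
write_mutants_fasta <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- ifelse(reads$source_reaction == "r1", reads$id,
                      paste0(reads$id, " reaction=", reads$source_reaction))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read region annotations from a BED-like file
#'
#' Four whitespace-delimited columns: chrom, start, end, name. BED
#' coordinates are 0-based half-open; they are converted to the package's
#' 1-based inclusive convention (the conversion is reported). `chrom` must
#' equal the reference id.
#'
#' @param path BED file.
#' @param reference A [reference_target()] (id and length checks).
#' @return Region data.frame (`label`, `start`, `end`).
#' @export
read_bed_regions <- function(path, reference) {
  if (!file.exists(path)) input_stop("file not found: ", path)
  bed <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name"))
  bad <- bed$chrom != reference$id
  if (any(bad))
    stop("BED line(s) ", paste(which(bad), collapse = ", "),
         ": chrom does not match reference id '", reference$id, "'",
         call. = FALSE)
  if (any(bed$start < 0 | bed$end <= bed$start))
    stop("malformed BED interval(s): need 0 <= start < end", call. = FALSE)
  message("converted ", nrow(bed),
          " BED interval(s) from 0-based half-open to 1-based inclusive")
  data.frame(label = bed$name, start = bed$start + 1L, end = bed$end,
             stringsAsFactors = FALSE)
}

#' Read a colony-count table (TSV)
#'
#' Tab-delimited with header `sample  total  mutants  background`.
#'
#' @param path TSV file.
#' @return data.frame with those columns, validated.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) input_stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample", "total", "mutants", "background")
  if (!all(need %in% names(d)))
    stop("counts table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(d$mutants > d$total | d$total < 1 | d$background < 0 |
                 d$background >= 1)
  if (length(bad))
    stop("invalid counts at data line(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  d[need]
}

#' Write a table as TSV (header row, "." for missing)
#' @param x data.frame.
#' @param path Output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Write all pipeline result tables into a directory
#'
#' @param results Named list of data.frames (names become file stems).
#' @param outdir Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
write_tables <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(results), function(nm)
    write_tsv(results[[nm]], file.path(outdir, paste0(nm, ".tsv"))), "")
  invisible(paths)
}
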