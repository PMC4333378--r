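#' Colony counts from a forward-assay screen
#'
#' @param total_colonies Total colonies scored.
#' @param mutant_colonies Mutant (e.g. white, or FUdR-resistant) colonies.
#' @param background_mf Background mutant frequency of the assay
#'   (dimensionless; e.g. 1.7e-5 for the gapped lacZ-alpha plasmid).
#' @return A list of class `colony_counts`.
#' @export
colony_counts <- function(total_colonies, mutant_colonies,
                          background_mf = 0) {
  if (total_colonies < 0 || mutant_colonies < 0 ||
      mutant_colonies > total_colonies)
    stop("need 0 <= mutant_colonies <= total_colonies", call. = FALSE)
  if (background_mf < 0 || background_mf >= 1)
    stop("background_mf must be in [0, 1)", call. = FALSE)
  structure(list(total_colonies = total_colonies,
                 mutant_colonies = mutant_colonies,
                 background_mf = background_mf), class = "colony_counts")
}

#' Gap-assay conversion parameters
#'
#' `D` is the number of detectable sites (reference positions where an
#' error yields the mutant phenotype; for the 64-nt lacZ-alpha gap the
#' published value is 147, the sum of determined detectable base
#' substitutions plus insertions/deletions). `P` is the expression
#' frequency: the probability that the error-carrying strand is the one
#' phenotypically expressed (0.3 for this assay). `NiN` is the Ni/N
#' correction ratio (1 when no correction is applied).
#'
#' @param D Detectable-site count, >= 1.
#' @param P Expression frequency in (0, 1].
#' @param NiN Ni/N ratio, > 0.
#' @return A list of class `gap_assay_params`.
#' @export
gap_assay_params <- function(D = 147, P = 0.3, NiN = 1) {
  if (D < 1) stop("D must be >= 1", call. = FALSE)
  if (!(P > 0 && P <= 1)) stop("P must be in (0, 1]", call. = FALSE)
  if (!(NiN > 0)) stop("NiN must be > 0", call. = FALSE)
  structure(list(D = D, P = P, NiN = NiN), class = "gap_assay_params")
}

#' Background-corrected mutant frequency
#'
#' `max(0, mutant/total - background)`. Negative corrected frequencies are
#' clamped to zero and flagged via the `clamped` attribute.
#'
#' @param counts A [colony_counts()] (or total, mutant, background given
#'   separately).
#' @return Corrected mutant frequency (dimensionless).
#' @examples
#' corrected_mutation_frequency(colony_counts(58555, 96, 1.7e-5))
#' @export
corrected_mutation_frequency <- function(counts) {
  stopifnot(inherits(counts, "colony_counts"))
  if (counts$total_colonies == 0)
    stop("total_colonies must be >= 1", call. = FALSE)
  raw <- counts$mutant_colonies / counts$total_colonies -
    counts$background_mf
  out <- max(0, raw)
  attr(out, "clamped") <- raw < 0
  out
}

#' Convert a corrected mutant frequency to an error rate
#'
#' Errors per base incorporated: `corrected_mf / (D * P * NiN)`.
#' Strictly increasing in the frequency, decreasing in each parameter.
#'
#' @param corrected_mf Corrected mutant frequency.
#' @param params A [gap_assay_params()].
#' @return Error rate (errors per base incorporated).
#' @export
error_rate_gap_assay <- function(corrected_mf, params = gap_assay_params()) {
  stopifnot(inherits(params, "gap_assay_params"))
  div <- params$D * params$P * params$NiN
  if (!(div > 0)) stop("non-positive divisor", call. = FALSE)
  if (corrected_mf < 0) stop("corrected_mf must be >= 0", call. = FALSE)
  corrected_mf / div
}

#' Polymerase error frequency (background-subtracted)
#'
#' Subtracts the single-stranded-DNA background mutant frequency from the
#' observed reporter mutant frequency; clamped at zero.
#'
#' @param observed_mf Observed mutant frequency.
#' @param ssdna_background Background frequency of the unreplicated ssDNA
#'   substrate.
#' @return Pol EF.
#' @export
pol_error_frequency <- function(observed_mf, ssdna_background) {
  if (observed_mf < 0 || ssdna_background < 0)
    stop("frequencies must be >= 0", call. = FALSE)
  max(0, observed_mf - ssdna_background)
}

#' Per-mutant error-group multiplicity
#'
#' Distribution of the number `n` of independent detectable error groups
#' (groups of events > 10 nt apart) per sequenced mutant. Because the
#' multiple-error correction sums `n = 1..3`, mutants with more than three
#' groups are folded into `n = 3` (a message notes the fold).
#'
#' @param counts Named or positional vector: `counts[n]` = number of
#'   mutants with `n` error groups, `n = 1, 2, 3` (longer vectors are
#'   folded).
#' @param total_mutants Total mutants analysed; defaults to `sum(counts)`.
#' @return List of class `error_multiplicity` with `counts` (length 3) and
#'   `total_mutants`.
#' @export
error_multiplicity <- function(counts, total_mutants = sum(counts)) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (length(counts) > 3L) {
    message("folding ", sum(counts[-(1:3)]), " mutant(s) with >3 error ",
            "groups into n = 3")
    counts <- c(counts[1:2], sum(counts[-(1:2)]))
  }
  counts <- c(counts, numeric(3L - length(counts)))
  if (total_mutants < sum(counts) || total_mutants < 1)
    stop("total_mutants must be >= sum(counts) and >= 1", call. = FALSE)
  structure(list(counts = stats::setNames(counts, 1:3),
                 total_mutants = total_mutants),
            class = "error_multiplicity")
}

#' Multiple-error-corrected polymerase error frequency
#'
#' Corrects Pol EF for mutants carrying several independent errors:
#' `Pol_EF_est = Pol_EF / sum_{n=1}^{3} (1/n) (mutants_with_n / total)`.
#' The denominator lies in (0, 1], so the estimate is always >= Pol EF,
#' and at most 3x (since n <= 3).
#'
#' @param pol_ef Pol EF from [pol_error_frequency()].
#' @param multiplicity An [error_multiplicity()].
#' @return Pol EF_est.
#' @export
pol_ef_est <- function(pol_ef, multiplicity) {
  stopifnot(inherits(multiplicity, "error_multiplicity"))
  if (sum(multiplicity$counts) == 0)
    stop("at least one multiplicity count must be > 0", call. = FALSE)
  denom <- sum((1 / (1:3)) * multiplicity$counts / multiplicity$total_mutants)
  pol_ef / denom
}

#' Class-partitioned error frequency, with zero-count upper bound
#'
#' Splits a parent error frequency across mutation classes proportionally
#' to observed counts. A class observed zero times gets the bound implied
#' by assuming a single event (`parent_ef / total_count`), flagged as an
#' upper bound — the convention behind printed "<x" table cells.
#' Optionally an exact binomial 95% upper bound can be used instead
#' (non-default).
#'
#' @param parent_ef Parent error frequency (e.g. region Pol EF_est).
#' @param class_count Events observed in the class.
#' @param total_count Total events in the parent (>= 1).
#' @param zero_rule `"one_event"` (default) or `"binomial95"`.
#' @return List: `frequency`, `is_upper_bound`.
#' @export
class_error_frequency <- function(parent_ef, class_count, total_count,
                                  zero_rule = c("one_event", "binomial95")) {
  zero_rule <- match.arg(zero_rule)
  if (total_count < 1) stop("total_count must be >= 1", call. = FALSE)
  if (class_count < 0 || class_count > total_count)
    stop("need 0 <= class_count <= total_count", call. = FALSE)
  if (class_count > 0)
    return(list(frequency = parent_ef * class_count / total_count,
                is_upper_bound = FALSE))
  frac <- switch(zero_rule,
                 one_event = 1 / total_count,
                 binomial95 = 1 - 0.05^(1 / total_count))
  list(frequency = parent_ef * frac, is_upper_bound = TRUE)
}

#' Fold change between two frequencies
#'
#' @param a,b Frequencies; `b = 0` yields `Inf` with attribute
#'   `undefined = TRUE` rather than an error.
#' @return `a / b`.
#' @export
fold_change <- function(a, b) {
  if (a < 0 || b < 0) stop("frequencies must be >= 0", call. = FALSE)
  if (b == 0) return(structure(Inf, undefined = TRUE))
  a / b
}

#' Render a value at a fixed power-of-ten exponent with one decimal
#'
#' The rendering used by fidelity tables ("1.6 x 10^-3" style): the
#' mantissa at the table's common exponent, rounded to `digits` decimals.
#'
#' @param x Value.
#' @param exponent Power of ten of the table column.
#' @param digits Decimals for the mantissa (default 1).
#' @return The rounded value (numeric, `mantissa * 10^exponent`).
#' @export
round_at_exponent <- function(x, exponent, digits = 1L) {
  round(x / 10^exponent, digits) * 10^exponent
}

#' Fidelity table for a gap-filling assay
#'
#' Computes, per sample, the background-corrected mutant frequency and the
#' error rate. Error rates are derived from the table-rendered corrected
#' frequency (mantissa rounded to one decimal at `1e-3`), mirroring how
#' published tables chain the rounded intermediates; full-precision values
#' are reported alongside.
#'
#' @param counts_table data.frame with columns `sample`, `total`,
#'   `mutants`, `background`.
#' @param params A [gap_assay_params()].
#' @param mf_exponent Exponent at which corrected frequencies are rendered
#'   (default -3).
#' @return data.frame: `sample`, `total`, `mutants`, `corrected_mf`
#'   (full precision), `corrected_mf_2sf` (table-rendered), `error_rate`
#'   (full precision), `error_rate_2sf` (from the rendered frequency,
#'   2 significant figures).
#' @export
lacz_fidelity_table <- function(counts_table, params = gap_assay_params(),
                                mf_exponent = -3L) {
  need <- c("sample", "total", "mutants", "background")
  if (!all(need %in% names(counts_table)))
    stop("counts table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  mf <- vapply(seq_len(nrow(counts_table)), function(i)
    corrected_mutation_frequency(colony_counts(
      counts_table$total[i], counts_table$mutants[i],
      counts_table$background[i])), 0)
  mf_r <- round_at_exponent(mf, mf_exponent)
  data.frame(sample = counts_table$sample,
             total = counts_table$total, mutants = counts_table$mutants,
             corrected_mf = mf, corrected_mf_2sf = mf_r,
             error_rate = vapply(mf, error_rate_gap_assay, 0,
                                 params = params),
             error_rate_2sf = signif(vapply(mf_r, error_rate_gap_assay, 0,
                                            params = params), 2),
             stringsAsFactors = FALSE)
}
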