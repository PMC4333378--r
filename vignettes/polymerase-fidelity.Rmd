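---
title: "Measuring polymerase fidelity from forward mutation assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring polymerase fidelity from forward mutation assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polfid)
```

## The assay and the model

A forward-mutation reporter assay measures a DNA polymerase's intrinsic
error rate without selection for any particular mutation. The polymerase
fills a single-stranded gap in a reporter gene in vitro — typically a short
lacZα fragment (here the canonical configuration is a 64-nt gap) or an
81-nt HSV-tk fragment carrying engineered [T]8/[A]8 short tandem repeats —
and the products are transformed into *E. coli*. Any polymerase error that
inactivates the reporter at a *detectable site* produces a scorable colony
phenotype (a white colony, or FUdR resistance). Sequencing independent
mutant isolates then reveals the spectrum of errors.

`polfid` implements the complete analysis chain, plus a simulator that lets
every stage be tested against a known ground truth.

### From colonies to an error rate

With `total` colonies, `mutants` scored mutant, and an assay `background`
frequency, the corrected mutant frequency is

$$\mathrm{MF} = \max\!\left(0,\ \frac{\text{mutants}}{\text{total}} - \text{background}\right),$$

and the error rate per base incorporated is

$$\mathrm{ER} = \frac{\mathrm{MF}}{D \cdot P \cdot (N_i/N)},$$

where

* **D** — detectable sites: the number of reference positions at which an
  error yields the mutant phenotype (the calibrated value for the 64-nt
  lacZα gap is 147: the sum of known detectable substitutions plus
  indels — note it may exceed the gap length because several changes at
  one position can each be detectable);
* **P** — expression frequency: the probability that the synthesized
  (error-carrying) strand is the one expressed after transformation
  (0.3 for this assay configuration);
* **Ni/N** — an optional correction ratio, 1 when unused.

A reproduction subtlety: published fidelity tables chain *rounded*
intermediates — the error-rate column is computed from the corrected
frequency as rendered in the table (one decimal at the table's common
power of ten), not from full precision. With the canonical colony rows,
full precision gives 3.7 × 10⁻⁵ where the table prints 3.6 × 10⁻⁵.
`lacz_fidelity_table()` therefore reports both: `error_rate` from the
unrounded frequency and `error_rate_2sf` from the table-rendered one. Use
the former for downstream arithmetic, the latter to compare with printed
tables.

### Error frequency with multiple errors per mutant

For HSV-tk-style assays the observed mutant frequency is corrected by
subtracting the unreplicated ssDNA background
(`pol_error_frequency()`), then adjusted for mutants that carry several
independent errors:

$$\mathrm{Pol\,EF_{est}} = \frac{\mathrm{Pol\,EF}}
 {\sum_{n=1}^{3} \frac{1}{n}\,\frac{\text{mutants with } n \text{ errors}}
 {\text{total mutants analyzed}}},$$

where $n$ counts a mutant's groups of detectable errors that lie more than
10 nt apart; errors within 10 nt of one another form a single *complex*
event group. Because the summation runs to 3, mutants with more than three
groups are folded into $n = 3$ (reported when it happens). The denominator
lies in $(0, 1]$, so $\mathrm{EF_{est}} \ge \mathrm{EF}$ always, and at
most $3\,\mathrm{EF}$.

Class rows (frameshifts, large deletions, complex, substitutions) split a
parent EF proportionally to observed counts. A class observed **zero**
times is reported as the upper bound obtained by assuming one event,
$\mathrm{EF} / \text{total}$, flagged `is_upper_bound` — this reproduces
the printed `<x` convention exactly. An exact binomial 95% bound is
available as a non-default alternative (`zero_rule = "binomial95"`); it is
systematically larger (the one-event rule is the field's convention, not a
confidence statement).

## Mutation calling conventions

* **Alignment.** Global (end-to-end) affine-gap alignment, authored in C++
  (Gotoh three-state DP). Defaults: match +1, mismatch −2, gap open −4,
  gap extend −1 (a gap of length $L$ scores $-4 - L$). These favour one
  substitution over an insertion+deletion pair, so single-base miscoding
  lands in the substitution classes a spectrum table distinguishes. The
  publications this pipeline serves never state their alignment procedure,
  so the scoring is user-overridable.
* **Tie-breaking.** At equal score the traceback prefers the aligned
  (diagonal) state, minimizing the number of gap runs; any remaining
  placement freedom is removed by left-normalization. The result: byte-
  identical event tables for identical inputs.
* **Indel normalization.** Every gap run is shifted as far left as
  possible without changing the implied read (`normalize_indels()`, the
  standard variant-normalization convention, idempotent). This is what
  makes slippage events in a homopolymer run report at the run's first
  base regardless of where the aligner placed the gap.
* **Event vocabulary.** Maximal gap runs become one insertion or deletion
  event; each mismatch column is a separate length-1 substitution
  (multi-base substitution blocks are never emitted, matching single-base
  class tables). A deletion of ≥ 2 nt is a single event of that length
  (the reading adopted for tandem deletions). Read columns carrying `N`
  are masked and never yield events.
* **Grouping.** Single-linkage with nearest-coordinate distance ≤ 10 nt;
  a group with more than one event is *complex*. Grouping is a partition:
  merging any two groups, or splitting any one, would violate the rule.
* **Coordinates.** 1-based inclusive internally; insertions anchor on the
  reference base to their left (0 = before position 1). BED input
  (0-based half-open) is converted on read and the conversion reported.
* **Duplicates.** Identical sequences from the same reaction are flagged
  (`duplicate_of`) but kept; `deduplicate = TRUE` drops them. Default off
  because submitted mutant sets are normally already curated to
  independent isolates.

Two complex-event accounting conventions exist in published tables, and
`polfid` emits both: lacZα-style spectra (`tabulate_spectrum()`) tally
every event in its own category; HSV-tk-style summaries
(`spectrum_groups` output) tally each multi-event group once as "complex".
Both event and group totals are reported since published figures are
ambiguous about which unit a "total mutational events" count uses.

## Region partition and hotspot scan

Groups are assigned to annotated regions (STR tract, coding region) by the
region containing their **span midpoint** — deterministic for groups
straddling a boundary — and counts are conserved (regions + unassigned =
total). "Frameshift" means an indel group whose net length change is not a
multiple of 3 and that is not a "large deletion" (net deletion ≥ 5 nt; the
threshold has no published definition, so it is a configurable default).

The hotspot scan is **exploratory**: published hotspots in these assays
are identified by inspection, so no statistic exists to reproduce. Each
position's event count is tested against a uniform-across-positions
binomial null with the exact upper tail $P(X \ge k)$, BH-corrected across
positions, α = 0.05. Exact binomial p-values on small counts are strongly
discrete and therefore conservative; the property suite checks validity
(super-uniformity, $P(p \le t) \le t$) rather than strict uniformity,
which discrete p-values cannot satisfy.

## The simulator: a stated world

`polymerase_error_model()` parameterizes an error-prone polymerase:

| parameter | meaning | preset default |
|---|---|---|
| `substitution_rates` | 4×4 per-site miscoding probabilities (template → synthesized) | Table-calibrated, see below |
| `indel_rate` | per-site single-base indel probability outside runs | 0.65 × total rate |
| `slippage_base`, `slippage_growth` | per-site indel probability in a run of length $L$ is $\text{base} \times \text{growth}^{L-2}$ | base = `indel_rate`, growth 1 (off) |
| `insertion_fraction` | insertions among indels | 20/62 |
| `scrunch_rate`, `hairpin_regions` | per-molecule probability of a hairpin complex event (loop-base duplication + nearby substitution, within 10 nt) | 0 (off) |

The calibration preset `primpol_lacz_model()` encodes the published 95-event
lacZα spectrum of the error-prone primase–polymerase this pipeline was
built around: substitutions 33/95 split across the six strand-collapsed
classes as printed (each class divided equally between its two ordered
changes), insertions 20/95, deletions 42/95, at an overall average
per-site event rate of 10⁻⁴ — the order of the enzyme's measured error
rate. It is a calibration, not a mechanistic claim. Geometric slippage
growth and duplication-style scrunching are likewise invented
parameterizations of mechanisms the literature describes qualitatively
(repeat-tract slippage; [T]2 → [T]3/[T]4 expansion at hairpins); no
quantitative rates are published for either.

Sampling contract: a single seeded generator drives all draws in a
documented order (substitutions site 1..L, indels site 1..L, hairpins in
order; screening draws separately seeded), so a seed pins the entire
output byte-for-byte. At most one event per site per molecule is kept
(substitutions win the rare collision, making the effective indel
probability $d(1-s)$ — negligible at simulated rates and keeping the
substitution-only analytic expectations exact). Products are returned as a
`mutant_pool` (event table + reference); sequences materialize on demand
via `pool_reads()` because building 10⁶ identical 64-nt strings up front
is pure waste.

The screening model: a product scores mutant iff it has ≥ 1 event
overlapping a detectable site **and** an independent expression draw with
probability $P$ succeeds; background mutants are a binomial draw over the
remaining products. Hence the analytic mutant frequency
$qP + (1-qP)\,b$ with $q = 1-(1-r)^D$ for a uniform substitution-only
model — the identity the recovery tests verify, and the reason
`recover_error_rate()` returns $\approx r$ (the $q/D$ concavity bias is
−0.7% at $r = 10^{-4}, D = 147$, well inside sampling noise).

**What a green test establishes — and what it does not.** The simulator
emulates per-site event sampling with the biases above; it does not model
polymerase kinetics, dNTP pools, SSB occupancy, hairpin thermodynamics
(hairpins are user-annotated regions, not computed folds), sequencing
error, or chromatogram artefacts. Parameter recovery being green means the
analysis chain is self-consistent under the stated world; it cannot
validate the assay's biochemical assumptions (the values of D and P
themselves).

## Numerical and design choices

* Negative corrected frequencies clamp to 0 and are flagged; zero-event
  spectra report percentages as `NA`, never 0/0.
* Percentages are rounded to one decimal (published tables mix one- and
  two-decimal renderings; one decimal is used consistently).
* Full precision is kept internally everywhere; table-rendered values are
  additional columns, never replacements.
* The spectrum-recovery test runs the preset at an elevated overall rate:
  class proportions are invariant to the rate scale, and 10⁴ sequenced
  mutants must be reachable from 10⁵ molecules within a test-time budget.
* Exhaustive canonical-placement checks run on all A/T sequences of
  length ≤ 9 with every single-base deletion (the gap-richest alphabet),
  plus random ACGT cases to length 12 — the full 4-letter enumeration to
  length 12 is combinatorially out of reach and adds nothing over the
  placement oracle.

## Known limitations

* Published per-mutant sequences for the source assays are not deposited,
  so the observed HSV-tk frequencies and the class rows derived from them
  are not recomputable; only their ratio structure and the zero-count
  bounds are verified.
* A published EF_est value that is *smaller* than its parent EF cannot be
  produced by the printed formula (denominator ≤ 1); `polfid` follows the
  formula and preserves the invariant EF_est ≥ EF.
* The aligner is global end-to-end: reads must be complete insert
  sequences (no trimming, no quality handling, no multiple alignment).
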