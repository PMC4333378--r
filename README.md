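# polfid

Analysis of **forward-mutation reporter assays** for measuring DNA
polymerase fidelity — the class of experiment in which a polymerase of
interest fills a single-stranded reporter gap (a lacZα fragment, an HSV-tk
fragment) in vitro, the products are screened in *E. coli* for loss of
reporter function, and mutant isolates are sequenced to reveal the enzyme's
error rate and error spectrum.

`polfid` is written for the bench scientist running such an assay: it takes
a reference target (FASTA), the sequenced mutant inserts (FASTA), optional
region annotations (BED) and colony-count tables (TSV), and produces the
standard outputs of the field — a called and grouped mutation-event table,
a strand-collapsed error-spectrum table, region-partitioned error tallies,
a positional hotspot scan, and the fidelity statistics.

## The statistics at its core

* **Corrected mutant frequency**: `MF = max(0, mutants/total − background)`.
* **Gap-assay error rate** (errors per base incorporated):
  `ER = MF / (D · P · Ni/N)`, with `D` the number of detectable sites, `P`
  the expression frequency of the error-carrying strand, and `Ni/N` an
  optional correction ratio.
* **Polymerase error frequency**: `Pol EF = observed MF − ssDNA background`,
  and its multiple-error correction

  `Pol EF_est = Pol EF / Σ_{n=1..3} (1/n)·(mutants with n errors / total mutants)`,

  where `n` counts a mutant's groups of errors more than 10 nt apart
  (errors ≤ 10 nt apart form one *complex* event).
* **Class-partitioned error frequencies** with the one-event upper bound
  `parent EF / total` for classes observed zero times (the printed `<x`
  convention).

Mutation calling uses global affine-gap alignment (Gotoh DP, implemented in
C++) followed by left-normalization of every indel — the standard variant
normalization convention — so slippage events inside homopolymer runs are
always reported at one canonical position.

A seeded simulator of an error-prone polymerase (templating-base-biased
substitutions, homopolymer slippage with geometric run-length growth,
hairpin-associated scrunching complex events) plus the colony-screening
readout closes the loop: simulate → analyse → recover the configured rate.

## Worked example

Simulate a gap-filling assay with the lacZα-calibrated preset and analyse
it end to end:

```r
library(polfid)

ref <- reference_target(
  paste0("ATGACCATGATTACGCCAAGCTTGCATGCCTG", "TTTTTTTT",
         "GAGTCGACCTGCAGGCATGCAAGC"),
  id = "gap64",
  regions = data.frame(label = c("STR", "coding"),
                       start = c(33, 41), end = c(40, 64)))

model  <- primpol_lacz_model(total_rate = 1e-3, slippage_growth = 1.3)
pool   <- simulate_synthesis(model, ref, 50000, seed = 20)
screen <- simulate_colony_assay(pool, assay_sim_config(
  expression_p = 0.3, background_mf = 1.7e-5, n_sequenced = 95, seed = 21))

events <- call_mutations(ref, screen$reads)
tabulate_spectrum(events)
#>  mutation_type number frequency_pct
#>        A>T/T>A      0           0.0
#>        A>C/T>G      1           1.0
#>        A>G/T>C      0           0.0
#>        G>A/C>T     21          21.2
#>        G>C/C>G      3           3.0
#>        G>T/C>A      1           1.0
#>     Insertions     26          26.3
#>      Deletions     47          47.5
#>          Total     99         100.0
#>        A>N/T>N      1           1.0
#>        G>N/C>N     25          25.3
#>    Transitions     21          21.2
#>  Transversions      5           5.1
```

The 95 sequenced simulated mutants carry 99 events; the spectrum shows the
configured indel dominance (insertions + deletions ≈ 74%) and the G/C- over
A/T-templated substitution bias (25.3% vs 1.0%) the preset encodes.

```r
counts <- data.frame(sample = "simulated", total = 50000,
                     mutants = screen$counts$mutant_colonies,
                     background = 1.7e-5)
lacz_fidelity_table(counts, gap_assay_params(D = 64, P = 0.3))
#>      sample total mutants corrected_mf corrected_mf_2sf  error_rate error_rate_2sf
#> 1 simulated 50000    1117     0.022323           0.0223 0.001162656         0.0012
```

1117 of 50,000 colonies scored mutant; after background subtraction and the
`D·P` conversion the recovered error rate (1.2 × 10⁻³ per base) matches the
configured average per-site event rate of 10⁻³ up to the expected upward
drift from slippage-elevated homopolymer sites.

The same stages are available from the command line via the bundled script
(`inst/cli/polfid` after install, or `system.file("cli", "polfid",
package = "polfid")`): subcommands `call`, `spectrum`, `fidelity`,
`simulate`, `pipeline`.

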