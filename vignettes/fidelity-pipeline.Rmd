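---
title: "Measuring XNA polymerase fidelity from watermarked clone sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring XNA polymerase fidelity from watermarked clone sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xnafidelity)
```

## The assay and its computational problem

Engineered polymerases that synthesize xeno nucleic acids (XNAs — TNA, FANA,
HNA, 2'-modified RNA analogs and the like) are characterized by the fidelity
of a full replication cycle: a DNA template is transcribed into XNA, the XNA
strand is reverse transcribed back into cDNA, and the cDNA is amplified,
cloned, and Sanger sequenced. Every sequenced clone is then a noisy copy of
the known template, and the polymerase's fidelity is read off the mutations
the clones accumulated.

Two things make this more than "count the mismatches":

1. **Contamination.** Carried-over template DNA can survive into the PCR and
   masquerade as a replication product. The assay defends against this with
   engineered *watermarks*: the primer-binding sites (PBS) of the starting
   template carry dinucleotide mismatches — an AA in the 5' PBS and a TT in
   the 3' PBS — that a genuine pass through the XNA intermediate converts to
   TT and AA respectively. Only clones reading *both* converted watermarks
   are used; a no-RT control (reverse transcription omitted) should yield no
   passing clones at all, and any that do pass flag PCR-borne DNA
   contamination.
2. **Attribution.** The observed errors are the uncorrected composite of the
   XNA transcription step, the reverse transcription step, and PCR. The
   assay reports this aggregate without attempting to phase errors to a
   step; the package mirrors that, and provides `compose_models()` to reason
   about how sequential error processes compound.

`xnafidelity` implements the computational half of this assay: assay-design
handling, clone orientation and alignment, watermark filtering, mutation
calling, and the fidelity statistics — plus a synthetic clone generator so
that the full pipeline can be verified end to end against planted ground
truth, since real clone datasets for these assays are rarely deposited.

## The fidelity statistics

For each of the 12 substitution types $X \to Y$ the error rate is

$$\mu_{X \to Y} = \frac{\#\text{observed}(X \to Y)}{\#\text{expected}(X)} \times 1000,$$

where $\#\text{expected}(X)$ counts analyzed template positions carrying
source base $X$, summed over watermark-validated clones. "Analyzed" excludes
positions aligned to an N base call and deleted positions: neither offers an
observable substitution opportunity. The total error rate is the sum of the
12 substitution rates.

The aggregate fidelity score counts substitutions *and* indel bases:

$$\text{fidelity} = \left(1 - \frac{\#\text{substitutions} + \#\text{inserted bases} + \#\text{deleted bases}}{\#\text{analyzed positions}}\right) \times 100\%$$

reported to one decimal (round-half-even; full precision is kept in the JSON
report). A multi-base indel run is one *event* but each base counts toward
the error tally, because the natural unit is nucleotide incorporation
events. Note two deliberate, documented readings where the assay's verbal
definitions underdetermine the arithmetic:

* `mu_total` sums only the 12 substitution rates; indels are reported
  separately as `indel_rate`. The aggregate fidelity score, by contrast,
  counts both. Reporting both quantities reconciles the two conventions
  without guessing.
* Because $\#\text{expected}$ is per source base, on a template with uniform
  base composition `mu_total` equals **4×** the overall per-site
  substitution rate (each substitution is divided by roughly a quarter of
  the positions). The estimator that recovers a per-site error probability
  is therefore `sum(observed) / total_positions`, and that identity —
  `mu_total == 4 * error_rate(sum(observed), total_positions)` on
  equal-composition denominators — is asserted in the test suite.
* The aggregate score divides by analyzed template positions (not positions
  plus insertions); a deleted position is excluded from
  $\#\text{expected}$, since it offers no substitution opportunity.

Per-type uncertainty is reported as an exact Poisson (Garwood) interval on
the event count, scaled to the per-1000 rate. Reports resting on fewer than
1000 analyzed positions carry a `low_coverage` flag, reflecting the assay's
own practice of sequencing at least 1000 nucleotide incorporation events.

## Alignment

Published assays of this kind align clones with desktop software under
unstated parameters. For reproducibility the package instead specifies its
aligner completely:

* Global (end-to-end) Needleman–Wunsch/Gotoh with affine gaps — clones are
  full amplicons of a known template, so local alignment would hide
  terminal errors. A gap of length $L$ costs `gap_open + L * gap_extend`.
* Default scoring: match +1, mismatch −2, gap open −4, gap extend −1. At
  the per-site error rates these polymerases operate at (≲2%), this scheme
  prefers calling an isolated substitution over a spurious
  insertion/deletion pair; it is configurable via `scoring_scheme()`.
* N (an uninformative base call) scores 0 against everything and is never
  counted as a match, a mismatch, or an error; N positions are excluded
  from both numerator and denominator of every rate.
* Traceback ties break deterministically: diagonal over gap-in-clone over
  gap-in-template.
* `left_normalize_indels()` shifts every gap run to its leftmost
  score-equivalent position, so an indel inside a homopolymer always gets
  the same coordinates. The operation provably preserves the score and the
  degapped sequences, and is idempotent.

The aligner is verified two independent ways: exhaustively against a pure
path-enumeration oracle (every sequence pair up to 6 nt over a two-letter
alphabet — complete, not sampled), and against `Biostrings::pairwiseAlignment`
on random longer pairs under the same scheme.

Clones whose best-orientation alignment identity falls below 0.7 are
excluded as failed sequencing reads. The assay literature states no such
rule, so the package makes the exclusion explicit, configurable, and logged:
every excluded clone appears in the watermark table with reason
`low_identity`.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` produces clone sets with the statistical structure the
assay assumes:

* **Genuine clones** are the template with both watermarks set to their
  converted state. Watermark positions are dictated by primer synthesis,
  not polymerization, so they are exempt from the error model — which is
  also why the watermark filter's contaminant rejection is exact in
  simulation. Per-site errors in the analysis region are drawn
  independently: deletion with probability `del_rate`, otherwise a base
  from the substitution-matrix row of the template base, plus a single
  uniform-random inserted base after the position with probability
  `ins_rate`. At most one of substitution/deletion occurs per position, and
  insertions are single-base, keeping the planted-truth coordinates exact.
* **Contaminant clones** (`contaminant_fraction`, default 0 — the assay
  papers do not quantify real carryover frequency) are byte-exact template
  copies retaining the unconverted watermarks.
* **Orientation**: each clone is reverse-complemented with probability
  `flip_fraction`, emulating random TOPO-TA insert orientation.
* **Determinism**: every clone draws from a sub-stream keyed by
  `(seed, clone index)`, so identical seeds give byte-identical FASTA
  output and a dataset's first $k$ clones are reproduced by any larger run
  with the same seed.

Deliberately *not* emulated: base-quality scores, sequence-context-dependent
error rates, multi-base indel events, chimeric reads, and separately
simulated PCR errors (these fold into the composite model, matching the
uncorrected values the assay reports). Passing tests therefore demonstrate
correctness of the pipeline's bookkeeping and statistics under the assay's
idealized error structure — not robustness to context-dependent Sanger
artifacts, which real chromatogram data would add.

## Mutation calling conventions

Errors are counted only inside the analysis span between the PBS regions:
primer-dictated bases cannot report on polymerase fidelity, and whether
assay papers count PBS errors outside the watermarks is unstated, so the
conservative choice is made explicit here. Within the span, after left
normalization: mismatched base/base columns are substitutions; a maximal
run of clone gaps is one deletion event (clipped to the span when it
straddles a boundary); a maximal run of template gaps is one insertion
event, anchored after the last preceding template position and counted when
that anchor lies in the span. A gap touching a watermark fails the clone
(`gap_in_watermark`): the conversion is unverifiable, and pass/fail must
err toward fail.

## The bundled design

The real assay's primer sequences live in supplementary material, so the
package ships a structurally equivalent stand-in (`default_design()`, also
as `inst/extdata/default_design.yaml`): a 96-nt template = 20-nt 5' PBS
(AA→TT watermark at PBS positions 2–3) + 56-nt analysis region + 20-nt 3'
PBS (TT→AA watermark). The analysis region is a fixed sequence with exactly
14 of each base — uniform composition makes the per-source-base `expected`
counts equal, which the additivity test exploits — and a maximum
homopolymer length of 3, enough to exercise indel normalization. All
coordinates are 0-based half-open, which keeps span arithmetic free of ±1
ambiguity; real designs are supplied as YAML via `load_design()`.

## Problem sizes and numerical choices

The end-to-end verification simulations use 10,000 clones × the 56-nt
analysis region (560,000 scored positions) per condition — enough that the
one-decimal aggregate fidelity is stable across seeds at every error rate
tested (binomial SE ≈ 0.02% at $p = 0.021$). Unit tests use hundreds of
clones; the truth-table comparison uses 1000 clones at substitution rate
0.01 and indel rates 0.002. Error-model validation tolerates 1e-12 row-sum
drift. Tie-breaks, rounding (one decimal, round-half-even), and the
identity threshold (0.7) are all stated above; degenerate inputs
(`expected = 0`) raise a not-estimable error rather than reporting a 0
rate.

## Worked example

```{r example}
design <- default_design()
model <- uniform_model(p_sub = 0.014)          # FANA-polymerase-like
ds <- simulate_dataset(design, model, n = 500, flip_fraction = 0.5,
                       contaminant_fraction = 0.04, seed = 42)
run <- run_pipeline(design, ds$records)
run
head(run$report$rates)
```

The contaminant clones are rejected by the watermark filter
(`both_unconverted` in `run$watermarks`), and the aggregate fidelity tracks
$1 - p_{\text{sub}}$.

```{r no-rt}
contaminant_only <- simulate_dataset(design, model, n = 50,
                                     contaminant_fraction = 1,
                                     seed = 43)$records
detect_no_rt_contamination(contaminant_only, design)$pass_fraction
```

## Known limitations

* Sanger chromatograms are not parsed; input is base-called FASTA, and all
  N handling assumes the base caller marked uncertain positions.
* Errors are not attributed to transcription vs reverse transcription; the
  package reports the composite, as the assay does.
* The aligner is exact but quadratic; it is sized for amplicon-scale
  templates (hundreds of nt), not genomes.
* Aggregate fidelity compares conditions fairly only under similar
  coverage; the `low_coverage` flag is a guard, not a correction.
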