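---
title: "Probing chloroplast mRNA structure with DMS-MaPseq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing chloroplast mRNA structure with DMS-MaPseq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chloroprobe)
```

## The measurement and its model

Dimethyl sulfate (DMS) methylates nucleotides that are single-stranded and
solvent-exposed. In mutational profiling (MaPseq), the reverse transcriptase
reads through methylated positions and records them as substitutions or
deletions, so the per-position **mutation rate**

$$r_i = \frac{\mathrm{sub}_i + \mathrm{del}_i}{\mathrm{coverage}_i}$$

is the raw reactivity: high at accessible, unpaired positions; low at
base-paired or protein/ribosome-protected positions. DMS reports strongly on
adenosines and cytidines and only weakly on guanosines and uridines, which is
why every analysis step here treats A/C and G/U as separate channels.

chloroprobe implements the analysis from counts onward. Read trimming,
alignment, and pileup are upstream concerns: the package consumes a
documented per-position counts TSV (`transcript_id`, `pos`, `ref_base`,
`coverage`, `sub_count`, `del_count`), transcript FASTA, a gene annotation
table, mask lists, and optionally a reference structure (CT or dot-bracket)
with a solvent-accessibility mask. The accessibility mask is a precomputed
input (one boolean per position, derived externally from a ribosome crystal
structure); the package does not recompute surface areas.

## Filtering and masking

Positions are excluded, with the reason recorded, when they

* lie inside a PCR primer range (no structural information),
* are RNA editing sites (apparent mutations unrelated to DMS),
* are modified rRNA nucleotides (reverse-transcription signatures
  independent of structure), or
* have coverage below `min_coverage` (default **2500** mapped reads).

When several categories apply, precedence is primer > editing > modified >
low coverage, so the per-category exclusion counts in the run log partition
the total. Masked positions never receive reactivities and are never imputed
as zero downstream.

## Two-channel normalization

Within each transcript and channel, raw rates are divided by the average
rate of the 90th–99th percentile window of that transcript–channel, putting
the most reactive (but not outlier) nucleotides at ~1:

```{r, eval = FALSE}
prof <- reactivity_pipeline(counts, masks,
                            min_coverage = 2500,
                            window = c(0.90, 0.99),
                            winsor_level = 0.99)
```

Window semantics had to be pinned down: the divisor is the mean of rates
**strictly above** the 90th percentile and **at or below** the 99th, with
percentiles computed by linear interpolation (R quantile type 7). With heavy
ties the strict window can be empty (e.g. a channel whose rates are all
equal); the window then falls back to inclusive bounds, so a constant
channel normalizes to exactly 1 rather than failing. After normalization the
mean of the window is 1 by construction, which the test suite asserts to
1e-9.

A transcript–channel with fewer than `min_positions = 20` unmasked positions
or with an all-zero window is *flagged unnormalizable* (the flag is in the
profile's `"normalization"` attribute) instead of being silently scaled by a
degenerate divisor. The guard value 20 is a pragmatic minimum for a
percentile window to be meaningful.

Normalization is per sample: replicates are normalized and reported
separately, then summarized at the region level, because per-replicate
tracks are the natural unit of quality control and no pooling rule is
obviously superior.

## Winsorization

Extremely high normalized values are capped by transcript-wise 99%
winsorization, channels pooled, one-sided (upper only): the stated purpose
is removing extreme values, and the low end carries the structural signal.
The cap uses the type-1 (inverse-ECDF) order statistic rather than an
interpolated percentile; with an interpolated cap, winsorizing twice would
move the cap again, whereas with an order-statistic cap the operation is
exactly idempotent.

## Region conventions

All regions are anchored at the first nucleotide of the start codon (+1),
with no position 0 (−1 abuts +1):

| region | relative | length |
|---|---|---|
| start codon | +1..+3 | 3 |
| SD scan window | −22..−2 | 21 |
| translation initiation region (TIR) | −25..+5 | 30 |
| coding region | +1..stop codon end | 3k |

The 30-nt TIR is the only reading under which −25..+5 spans a round 30 nt,
which is what fixes the no-position-zero convention. Regions that would
extend past a transcript end are truncated and flagged. Start-codon mean
reactivity uses adenosines only (the AUG adenosine is the cleanest DMS
reporter there); SD, TIR, and CDS means use A/C. The coding-region metrics
run from the start codon through the stop codon inclusive — whether the TIR
overlap should be excluded is ambiguous, and we chose the inclusive reading
(the overlap is at most 5 nt of a CDS).

## Structure statistics

**Gini index.** Used as a structure score: structured RNAs concentrate
reactivity in few positions (Gini → 1). The default estimator is the
population mean-absolute-difference form

$$G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n^2 \bar x},$$

computed via the sorted-vector identity; the bias-corrected sample form
(divisor $2n(n-1)\bar x$) is available as a switch. Both are tested against
brute-force pairwise summation. Gini uses A/C reactivities by default, with
an ACGU option.

**ROC validation.** Against a reference structure with an accessibility
mask, the positive class is *unpaired AND solvent-accessible*; everything
else (paired, or unpaired but buried) is negative. The curve is a threshold
sweep over normalized reactivity with tie groups collapsed into single
steps, so the trapezoidal AUC equals the Mann–Whitney statistic
$P(s_+ > s_-) + \tfrac12 P(s_+ = s_-)$. The implementation is checked
against brute-force concordant-pair counting and against pROC.

## Shine–Dalgarno strength

SD strength is the minimum hybridization free energy of the anti-SD
(`CCUCCU`, the 3′ tail of the 16S rRNA) scanned along the −22..−2 window at
20 °C. The duplex model is deliberately simple: at each ungapped offset
(including ≥2-nt partial overlaps at the window edges), the best single
contiguous run of Watson–Crick or G·U pairs of length ≥ 2 is scored as one
helix,

$$\Delta G(T) = \Delta G_\mathrm{init}
  + \sum_\mathrm{stacks} \left(\Delta H - T\,\Delta S/1000\right)
  + \text{terminal A·U/G·U penalties},$$

with nearest-neighbor parameters shipped as a human-readable, cited data
file (`inst/extdata/nn_stack_params.tsv`; Watson–Crick stacks from Xia et
al. 1998, G·U wobble stacks from the Turner 2004 set). Temperature enters
only through the $\Delta H - T\Delta S$ reconstruction, and a test asserts
that the reconstructed 37 °C energies reproduce the published table within
0.1 kcal/mol.

Classification: min ΔG < −6 kcal/mol → **strong**, −6..0 → **weak**,
≥ 0 or no duplex → **none**. The published thresholds leave the boundary
values ambiguous; we assign boundaries to the weaker class (−6 → weak,
0 → none), and both thresholds are configurable. Because the model scores
contiguous helices only (no bulges, no co-fold of the full rRNA tail), ΔG
on imperfect SDs may differ from richer co-folding models by ~1–2 kcal/mol;
strong SDs (long GGAGG matches) are robust to this, weak/none boundaries
less so.

## Reactivity-guided folding stand-in

Production structure prediction should use a thermodynamic engine with the
exported SHAPE-style constraint file (`write_constraints()`: one line per
position, A/C reactivities, −999 for masked/G/U/absent positions). The
built-in folder exists so the constraint logic is testable end-to-end and to
produce arc tables: it is a Nussinov-style nested-structure DP maximizing

$$\#\mathrm{pairs} - \lambda \cdot \#\{\text{paired A/C with reactivity} > \theta\},$$

with `min_loop = 3`, optional maximum pairing span, G·U pairs allowed, and a
deterministic tie-break (leftmost position pairs with its smallest
admissible partner). Defaults θ = 0.4, λ = 1: θ sits in the sparse region
between the paired (~0–0.3) and reactive (~1) modes of normalized
reactivity scales, and λ = 1 makes one high-reactivity endpoint exactly
cancel one pair's gain, so reactivity evidence and pairing gain trade off
one-to-one. λ → ∞ recovers a hard constraint. The DP is validated against
exhaustive enumeration of all nested structures on short sequences. It is
*not* a free-energy model: no stacking thermodynamics, no loop penalties,
no pseudoknots.

## The synthetic data generator

Every stage is testable without sequencing data through a
structure-conditioned simulator:

* **Truth:** a position is modified at its channel's "unpaired" rate iff it
  is unpaired *and* solvent-accessible, else at the "paired" rate — the
  same rule that defines the ROC positive class. Editing sites get a fixed
  high apparent rate regardless of structure.
* **Rates (defaults):** unpaired A/C 0.02, paired A/C 0.002, unpaired G/U
  0.006, paired G/U 0.002, error floor 0.001. These are not estimates of
  any real experiment's rates; they are chosen so the A/C channel separates
  strongly and the G/U channel weakly, reproducing the qualitative channel
  ordering that motivates two-channel normalization.
* **Coverage:** negative binomial (default mean 5000, size 10), primer
  ranges at coverage 0; mutation counts binomial at rate + error; the
  mutation count is split 80/20 into substitutions and deletions (the
  analysis sums them, so the split only exercises the file format).
* **Scenarios:** `synth_structured_transcript()` builds a hairpin-rich
  rRNA-like control for ROC validation; `synth_footprint_fixture()` builds
  a transcript whose start codon sits inside a stem whose other arm is
  covered by a protein footprint, so the "in vivo" condition (footprint
  applied, stem released) shows a more accessible start codon and a less
  structured TIR than the "in vitro" (protein-free) condition.

What the simulator does **not** emulate: read-level effects (PCR bias,
RT drop-off, local sequence context of mutations), correlated modification
within reads, partially melted structure ensembles, and real coverage
profiles. Passing tests therefore demonstrate that the analysis recovers
the signal its own model class generates — they do not validate the
upstream experiment.

## Problem sizes in the test and acceptance runs

The packaged checks use a 1500-nt structured transcript at coverage 5000
over 3 simulation seeds for ROC recovery, 20 replicates of the footprint
scenario (~340-nt transcript), 1000 random vectors (n ≤ 200) for the Gini
oracle, 200 instances (n ≤ 50) for the ROC oracle, and 200 random sequences
of length ≤ 12 for the exhaustive folding oracle — sizes at which the
independent oracles (enumeration, pairwise counting) are exact and fast
while the statistics are stable.

## Known limitations

* The SD duplex model is contiguous-helix-only (see above).
* The internal folder is a combinatorial stand-in, not a thermodynamic
  predictor; arc plots from it are illustrative.
* Normalization assumes each transcript–channel contains enough genuinely
  reactive positions for a meaningful 90–99th percentile window; very short
  amplicons are flagged rather than normalized.
* Plastome-scale SD classification depends on the annotation's start-codon
  choices (several plastid genes have alternative starts), which can move
  the class fractions by a few percent.
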