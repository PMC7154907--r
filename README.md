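# chloroprobe

Analysis of **DMS-MaPseq** chemical probing data for chloroplast
transcripts: from per-position mutation counts to normalized reactivities,
structure metrics, and Shine–Dalgarno strength.

Dimethyl sulfate (DMS) methylates nucleotides that are unpaired and
solvent-accessible; mutational profiling (MaPseq) reads those methylations
out as substitutions and deletions during reverse transcription. The
mutation rate of position *i*,

> r_i = (sub_i + del_i) / coverage_i,

is the raw reactivity. chloroprobe turns count tables into interpretable
structure read-outs for questions like: *is this start codon accessible in
vivo but sequestered in refolded RNA? Is this translation initiation region
less structured in vivo? Does this gene even have a Shine–Dalgarno
sequence?* It is aimed at researchers probing organellar (or bacterial-like)
transcripts where translation initiation is governed by mRNA structure and
SD–anti-SD pairing.

## What it computes

* **Reactivity pipeline** — coverage/primer/editing/modified-site
  filtering (default ≥ 2500 reads), separate normalization of the A/C and
  G/U channels by the mean of each transcript–channel's 90–99th percentile
  window, and transcript-wise 99% winsorization.
* **Structure metrics** — regional mean reactivity (start codon: A only;
  SD window, TIR −25..+5, CDS: A/C), Gini index of reactivities
  (G = Σᵢⱼ|xᵢ−xⱼ| / 2n²x̄), and ROC/AUC validation against a reference
  structure whose positive class is *unpaired AND solvent-accessible*.
* **Shine–Dalgarno strength** — minimum nearest-neighbor hybridization
  ΔG of the anti-SD `CCUCCU` scanned over nucleotides −22..−2 at 20 °C
  (Turner parameters shipped as a cited data file); classes strong
  (< −6 kcal/mol), weak (−6..0), none (≥ 0).
* **Folding support** — SHAPE-style constraint-file export for external
  thermodynamic folders, plus a reactivity-guided Nussinov stand-in for
  testable constraint logic and arc-diagram tables.
* **Synthetic data** — a structure-conditioned simulator (channel-specific
  modification rates, negative-binomial coverage, editing confounders,
  primer masks, protein-footprint scenarios) so the whole pipeline is
  testable without sequencing data.

## Worked example

```r
library(chloroprobe)

# 1. simulate a structured control transcript and probe it
fx <- synth_structured_transcript(1500, seed = 42)
track <- assign_true_rates(fx$transcript, fx$structure)
counts <- simulate_counts(track, sim_config(), seed = 43,
                          transcript_id = fx$transcript$id)
prof <- reactivity_pipeline(counts)

# 2. validate reactivity against the known structure
labels <- accessibility_labels(fx$structure)
cat(sprintf("AUC A/C: %.3f   AUC G/U: %.3f\n",
            roc_auc(prof, labels, "AC")$auc,
            roc_auc(prof, labels, "GU")$auc))
#> AUC A/C: 1.000   AUC G/U: 0.997

# 3. structure score
g <- region_gini(prof, list(start = 1, end = fx$transcript$length))
cat(sprintf("Gini (A/C, whole transcript): %.3f on %d positions\n",
            g$value, g$n_used))
#> Gini (A/C, whole transcript): 0.443 on 728 positions

# 4. Shine-Dalgarno strength of a GGAGG-containing window at 20 C
sc <- scan_sd("ACAUAGGAGGUAUAACAUAAC")
cat(sprintf("SD scan: min dG = %.2f kcal/mol -> %s\n", sc$min_dG, sc$sd_class))
#> SD scan: min dG = -10.90 kcal/mol -> strong
```

The AUC values show the simulated A/C channel separating accessible from
protected positions essentially perfectly at coverage 5000, with the weaker
G/U channel close behind; the Gini reflects a transcript where reactivity
concentrates in loops and spacers; the SD scan finds the canonical GGAGG
core pairing the anti-SD well past the −6 kcal/mol "strong" threshold.

For end-to-end runs there are `run_simulate()` / `run_analyze()` (YAML
config, TSV outputs, run log) and a thin CLI at
`inst/cli/chloroprobe.R` with subcommands `simulate`, `analyze`, `sd-scan`,
`fold`, and `roc`.

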