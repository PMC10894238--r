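---
title: "Profiling base-editor outcomes on context substrate libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling base-editor outcomes on context substrate libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beprofiler)
```

## The assay and the model

A base editor deaminates target bases within an editing window of the 20-nt
protospacer (positions 1–20, PAM at 21–23). To measure position and
sequence-context dependence systematically, a substrate library places a
target C or A at chosen protospacer positions and varies the bases
immediately 5' and 3' of it over all four nucleotides, one plasmid member
per combination. Each member carries a unique molecular identifier (UMI)
barcode in the constant region of its amplicon; after editing in cells, the
amplicons are deep-sequenced and each read is attributed to its member by
the UMI. The canonical designs are the 32-member single-position library
({A,C} at position 6 × 16 flank contexts) and the 448-member
window-profiling library (positions 1–14; 224 contexts per target base).

The editing model underlying both the simulator and the statistics is
per-read Bernoulli: a read drawn from member *m* carries the target
conversion (C→T or A→G on the protospacer-containing strand) with
probability *p~m~*, independently of other reads. Efficiency estimates are
therefore binomial proportions, reported as percentages of reads; replicate
efficiencies are averaged first, then member-level values are averaged into
positional or contextual summaries (the dot-then-bar order used in the
figures this style of assay produces).

## Stage by stage

### Library design

`enumerate_context_library()` materialises one member per (target base,
position, 5' flank, 3' flank) combination in deterministic order, assigns
UMIs, and builds amplicons. Choices the assay itself does not fix:

- **Backbone filler.** The protospacer backbone is the alternating G/T
  20-mer `GTGTGTGTGTGTGTGTGTGT`, and all constants plus the PAM (`TGG`) are
  A/C-free. Consequently the only A or C bases in a protospacer are the
  member's target base and its variable flanks, so any observed C→T or A→G
  substitution is unambiguous about which designed base it hits. The filler,
  constants and PAM are configurable via `amplicon_layout()`.
- **Flanks outside the protospacer.** A target at position 1 has its 5'
  flank at "position 0"; it is written into the constant base immediately 5'
  of the protospacer (symmetrically, a position-20 target's 3' flank
  replaces the PAM's N). The window-profiling design includes position 1, so
  flanks must extend beyond the spacer.
- **UMIs.** Length 10 nt with minimum pairwise Hamming distance 3, assigned
  by seeded greedy rejection sampling. Distance 3 guarantees that with at
  most one UMI sequencing error the nearest member UMI is unique
  (`2 × max_mismatch < min_distance`). Neither value is dictated by the
  assay; both are package defaults and arguments of `assign_umis()`.

### Read simulation

`simulate_reads()` emits full-amplicon, single-end, fixed-length reads:
target conversion Bernoulli(*p_target*) at the target position;
cross-conversion Bernoulli(*p_cross*) at every protospacer position carrying
the opposite target base (with the default backbone these are exactly the
member's A or C flanks — the only positions where the opposite conversion is
chemically possible); sequencing substitutions Bernoulli(*e*) per base with
a uniformly chosen alternative base; optional per-read 1-base deletions
(`indel_rate`) to exercise the caller's exclusion path. Base qualities are a
constant Q30 so that quality filtering is tested by explicit low-quality
fixtures rather than by noise. `expand_ground_truth()` returns the exact
rate table the simulator uses, which the round-trip tests treat as the
oracle.

What the generator deliberately does **not** emulate: PCR amplification
bias, per-member depth variation, UMI family structure or consensus
collapsing, paired-end chemistry, adapter read-through, and
context-dependent error profiles. A green round-trip test therefore
establishes that the caller and statistics recover the rates of this stated
world — not that they are robust to every artefact of a real sequencing run.

### Edit calling

`demultiplex()` extracts the read's UMI field at the layout offset and
assigns the read to the unique member within `max_umi_mismatch` (default 1)
Hamming distance; exact matches short-circuit through a hash lookup, and
ties are left unassigned as ambiguous. `classify_read()` compares a read
gaplessly to its member's amplicon: since reads are full-amplicon and fixed
length, any indel changes the read length, so the length comparison is the
indel test — flagged reads are excluded from substitution counting and
reported as an indel fraction, mirroring the substitution/indel separation
of standard amplicon quantifiers. Reads with more than half their bases
below Qmin are discarded as low-quality; in retained reads, sub-Qmin
positions are masked from both numerator and denominator. Defaults:
Qmin = 20, `min_reads` = 100 (members below it are flagged low-coverage and
skipped by downstream averages), LOD = 0.1% (values below it are reported
numerically but flagged `below_lod`). None of these thresholds is dictated
by the assay; all are declared package defaults.

### Profile statistics

- **Position profile**: unweighted mean, per position, of the
  target-position efficiency over all members whose target base sits there.
- **Editing window**: positions whose average is at least a threshold
  fraction (default 0.20) of the peak average. The peak ties break to the
  smallest position. When the above-threshold set is non-contiguous, the
  reported window is the maximal contiguous run containing the peak, and the
  full above-threshold set is also returned — this preserves "positions
  4–8"-style reporting without hiding outliers.
- **Selectivity**: per position in a range (default 4–8), the ratio of
  average C→T to average A→G editing; the summary is the geometric mean,
  `exp(mean(log r))`. A-averages below the LOD are floored at the LOD
  (0.1%) and the result is flagged a lower bound; this turns an undetectable
  denominator into `>= C/0.1` rather than infinity. A zero C-average yields
  ratio 0 and a warned zero mean. Whether published "990-fold" style figures
  arise from exactly this flooring is not stated anywhere we can check; the
  package documents its censoring rule rather than claiming to replicate
  that derivation.
- **Context matrix**: the 16 (5', 3') contexts at one position, optionally
  normalised to the maximum entry (maximum exactly 1 whenever any entry is
  positive).

### Context logos

`context_frequencies()` sums member efficiencies over the window positions
by flank base and divides by the total, yielding frequencies *f~b~* per side.
`information_content()` sets letter heights to
*f~b~* · log₂(*f~b~* / 0.25). Numerical conventions: the logarithm base is a
parameter and defaults to 2 (bits), the sequence-logo convention — the
base is not dictated by the method definition; *f~b~* = 0 contributes height
0 (the x·log x → 0 limit), so single-context logos are well defined; and
negative heights (*f~b~* < 0.25) are retained, consistent with
Kullback–Leibler logo practice. The height sum equals the KL divergence from
the uniform background and is non-negative; the property tests verify this
on random frequency vectors. Logos can be computed over each editor's own
window or any fixed range via the `window` argument, since either convention
appears in practice.

### Selection metrics

Titer is `plaques × dilution factor × 100` PFU/ml; fold enrichment is
output titer over input titer. Cumulative fold-dilution across campaign
segments multiplies per-passage factors for serial (discrete) passaging and
`exp(rate × duration)` for continuous lagoon dilution — the ideal well-mixed
washout contract, used because campaigns report cumulative fold-dilutions
rather than full rate schedules; time-varying rates are supplied as
piecewise-constant segments. Totals accumulate in log10 space because
campaign totals reach ~10^61, far beyond double-precision products of
per-passage factors done naively.

### Pipeline

`run_pipeline()` chains design → simulate → call → stats → logo under one
seed and one config, writes every artifact with an MD5 checksum into the
report, and `validate_config()` reports violations by field path. Identical
config + seed gives byte-identical tables and checksums; the suite asserts
this and also that the report's headline statistics equal module-level
recomputation from the on-disk intermediates.

## Worked check

```{r example}
lib <- enumerate_context_library(context_library_spec(positions = 1:14),
                                 seed = 42)
rates <- position_tapered_rates(lib, peak = 0.9, center = 6, sd = 1.5)
rates[lib$target_base == "A"] <- 0
sim <- simulate_reads(lib, read_sim_config(p_target = rates,
                                           error_rate = 0.001,
                                           depth = 300, seed = 42))
edits <- call_edits(sim$reads[[1]], lib, min_reads = 100)
profC <- position_profile(edits, lib, "C>T")
editing_window(profC)
selectivity_ratio(profC, position_profile(edits, lib, "A>G"), positions = 4:8)
```

## Limitations

- The caller is gapless by design: reads with indels are excluded, not
  realigned, so complex alleles are reported only through the indel
  fraction.
- Substitutions are only scored at protospacer positions 1–20; edits to a
  position-1 target's 5' flank (which lies in the constant region) are not
  tabulated.
- Replicate aggregation is the unweighted mean of efficiencies, not a
  depth-weighted pooled estimate, matching how replicate dots are averaged
  in this assay's figures.
- No between-editor hypothesis testing is provided; the package computes the
  descriptive statistics only.
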