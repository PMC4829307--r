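---
title: "Inferring intron removal order and multi-step splicing from capture pre-mRNA sequencing"
author: "spliceorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring intron removal order and multi-step splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceorder)
```

## The model

A long pre-mRNA is transcribed at a roughly constant elongation rate
(default 2.4 kb/min) and spliced co-transcriptionally: an intron can only
be removed once its 3' splice site exists, and the waiting time to removal
varies widely between introns. Nuclear capture sequencing samples this
steady-state population, so three signals carry information about removal
order:

* **Phase composition.** A read pair is *pre-splicing* when its ends sit in
  intronic or boundary sequence with no exon–exon junction, *intermediate*
  when one end documents a completed junction while the mate shows a
  neighboring intron still present (or when two intronic ends are farther
  apart than the sequenced insert can be — spliced material must lie
  between them), *post-splicing* when both ends are purely exonic/junction,
  and *exon-only* when both ends sit inside one exon and are uninformative.
* **Intron coverage.** The longer an intron lingers in the pool, the deeper
  its coverage: median per-position depth (zeros included), normalized into
  common units by each sample's mean exonic coverage, ranks introns by
  relative removal speed.
* **Split reads.** A skip gap strictly inside one intron is direct evidence
  that the intron is removed in more than one step.

### Splice-ratio

For intron $n$, with $S$ the pairs (junction $n/n{+}1$ ~ intron $n{+}1$)
and $NS$ the pairs (intron $n$ ~ junction $n{+}1/n{+}2$):

$$\text{splice-ratio}(n) = \frac{S}{S + NS}$$

Under the kinetic model this estimates the probability that intron $n$ is
removed before intron $n+1$; for two single-step introns with rates $k_1,
k_2$ and an eligibility lag $\delta$ (the time to transcribe from one 3'
splice site to the next), the analytic value is the exponential-race
probability $(1 - e^{-k_1\delta}) + e^{-k_1\delta}\,k_1/(k_1+k_2)$,
implemented in `race_probability()` and verified against the simulator.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `expected_insert`, `insert_sd` | 400, 100 | nt | insert model; a span above `expected + 3*sd` (700 nt) is "large", which no 250–650-nt fragment can reach without spliced-out sequence between the ends |
| speed `cutoffs` | 90, 130 | normalized depth | fast/slow thresholds; normalization keeps values in read-depth units so the cutoffs stay interpretable |
| `window`, `step` | 5, 3 | introns | sliding relative-ranking windows (26 windows for 78 introns) |
| `epsilon` | 0.05 | ratio | half-width of the "intermediate" band around 0.5 |
| `min_support` | 5 | pairs | S+NS floor below which an order call is "insufficient" |
| `min_gap` | 50 | nt | smallest skip treated as a candidate splicing step (separates indels and NAGNAG-scale variation from events) |
| `boundary_margin` | 50 | nt | non-annotated sites this close to either exon–intron boundary are discarded as junction-wobble artifacts |
| `min_mapped_reads` | 500,000 | pairs | sample yield floor; at 2×100 nt over a ~2.09-Mb span this is about 50-fold coverage |

All thresholds are configuration, not constants.

## Design choices

* **Coordinates** are 1-based fully closed genomic throughout (the SAM/GFF
  convention); BED input is converted on read. Exon/intron indices follow
  transcript order, so "intron *n* sits between exons *n* and *n*+1" holds
  on both strands.
* **The phase table is applied in a fixed precedence** (unassignable >
  exon-only > post > intermediate-by-junction > intermediate-by-span >
  pre), which makes it total and symmetric in end order. One geometric
  corner — an exonic end paired with an intronic end at a large span
  without any junction — is deliberately routed to *pre*: nothing in the
  pair documents a completed splicing step.
* **Speed classes use the global cutoffs**; the sliding windows report only
  the relative ranking of their members. Applying the cutoffs per window
  would make a class depend on which window one looks through, which is
  untestable; the global reading is the reproducible one.
* **Gap refinement** slides an ambiguous junction within the range where
  the flanking sequence permits it and keeps the placement maximizing
  matches to GT (first two skipped bases) plus AG (last two), ties going to
  the genomically leftmost placement. The score never decreases and the
  placement never leaves the ambiguity range.
* **The boundary margin is applied at both intron ends** for non-annotated
  sites: near-3'-boundary artifacts are as suspect as near-5' ones.
  Annotated sites match exactly (0-nt tolerance) after refinement.
* **Intermezzo pairing** re-labels a 5'RS and a 3'RS event in the same
  intron whose internal sites bracket a positive-length cassette; multiple
  pairs per intron are reported and never merged, and unpaired recursive
  events keep their 5'RS/3'RS labels.
* **The last intron** has no downstream junction, so its NS count is
  structurally undefined; its call rests on S-only evidence or is
  "insufficient".
* **Intron lengths are compared between single- and multi-step modes with
  a Wilcoxon rank-sum test** (the groups are unpaired).
* **Degenerate regressions** (constant predictor, or only two points)
  return the exact slope where defined and are flagged rather than given a
  p-value. Outlier introns — a local spike above 5× the intron median in
  the 95th percentile even after masking — are excluded from regressions.

## What the generator emulates — and what it does not

`simulation_config()` / `simulate_gene()` / `simulate_transcripts()` /
`emit_read_pairs()` model: constant-rate initiation (a steady-state
snapshot, matching nuclear RNA harvests, not a pulse-chase), deterministic
elongation, per-intron exponential removal once eligible, planted
multi-step paths (5'RS, 3'RS, nested, intermezzo traverse their steps in
order), uniform fragmentation of 250–650 nt with 2×100-nt ends, canonical
GT/AG at all annotated and planted sites, and byte-deterministic output
given a seed. Planted internal sites must sit at least 50 nt inside the
intron, so the generator's geometry always survives the pipeline's
boundary filter; the event-study configurations draw intron lengths of at
least 1.5 kb so every planted offset fits for any seed.

Not modeled: capture-probe affinity and GC bias (fragment starts are
uniform; masks can emulate probe footprints), PCR duplication, sequencing
error (alignment is bypassed; an error knob would only matter for testing
an aligner), and lariat intermediates. Passing tests therefore demonstrate
the correctness of the inference given ideal alignments — they do not
certify robustness to capture bias or misalignment in real libraries, which
is why replicate-correlation and bias diagnostics are part of the pipeline
itself.

## Problem sizes

The shipped tests and the acceptance script run, per invocation: a
20-intron / ~55-kb gene at 40,000 pairs (about 280-fold coverage) for
order-recovery and coverage-coupling checks; a 6-intron 3-cell-line study
at 3 × 8,000 pairs for event recovery; 10,000 molecules for the kinetic
race; and small hand-built fixtures everywhere else. These sizes give
every supported intron S+NS well above the call floor and every planted
event ≥ 10 supporting reads per line, while a full run of the suite plus
the acceptance script completes in a few minutes on one CPU.

## Limitations

* One isoform per gene model: alternative transcripts are rejected, not
  merged; genes whose splicing intermediates mix isoforms need upstream
  disambiguation.
* Event discovery requires the event to be present in *every* cell line;
  rare, line-specific events are traded away against PCR-duplicate
  artifacts, exactly as in the analysis the package implements.
* Coverage-based speed ranking can be inflated by excised lariats and
  pseudo-exons (the splice-ratio route is immune, which is why the two are
  cross-checked via their correlation rather than either being trusted
  alone).
* The published supplementary event table and the reference genome are
  external inputs: reanalyses of the original study's tables require the
  user to supply them (`read_event_table()` + `classify_event()` +
  `classify_intron_steps()` then reproduce the printed classifications).
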