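# spliceorder

Order of intron removal and multi-step splicing from capture pre-mRNA
sequencing.

## The problem

Long human pre-mRNAs — the 2.2-Mb dystrophin (*DMD*) transcript being the
extreme case, with 79 exons and introns from 107 bp to 360 kb — are spliced
co-transcriptionally, and their introns are not necessarily removed in 5'→3'
order. Deep targeted paired-end sequencing of nuclear (capture) pre-mRNA
makes the intermediates visible: unspliced fragments, fragments caught
mid-splicing, and split reads whose skip gaps land inside a single intron,
betraying removal of that intron in several steps (recursive, intermezzo, or
nested splicing).

`spliceorder` turns those reads into inference, for anyone analyzing
targeted pre-mRNA-seq of a single long transcript:

1. **Phase classification.** Every read pair is assigned one phase from the
   features its ends touch (exon, intron, exon–intron boundary, exon–exon
   junction): *post* (both ends post-splicing: ex~ex, ex~(ex-ex),
   (ex-ex)~(ex-ex)), *intermediate* (a junction end paired with an
   intronic/boundary mate, or two intronic ends whose genomic span exceeds
   the insert model), *pre* (intronic/boundary ends, no junction), or
   *exon-only*.
2. **Coverage-based removal speed.** Per-intron median depth (zeros
   included, masked positions excluded) is normalized across samples by the
   mean exonic coverage; introns with normalized coverage < 90 are *fast*,
   > 130 *slow*, else *intermediate*, with a sliding-window report
   (5 introns, step 3 — 26 windows for 78 introns).
3. **Splice-ratio ordering.** For intron *n*,

   `splice-ratio(n) = S / (S + NS)`

   where S counts pairs with one end on the exon(n)–exon(n+1) junction and
   the mate inside intron n+1 (intron n left first), and NS counts pairs
   with one end inside intron n and the mate on the exon(n+1)–exon(n+2)
   junction (the downstream intron left first). Ratios in (0.5, 1] are
   *sequential*, < 0.5 *non-sequential*, within ε of 0.5 *intermediate*.
   Runs of early-removed introns flanked by late ones define **exon
   blocks** (≥ 3 exons already joined between unspliced introns).
4. **Multi-step events.** Skip gaps ≥ 50 nt inside one intron are refined
   against the genome (sliding toward the best GT…AG placement), filtered
   (no fully annotated gaps, no sites within 50 nt of the exon–intron
   boundary), summed per cell line, intersected across cell lines, and
   classified: **5'RS** (annotated donor, internal acceptor), **3'RS**
   (internal donor, annotated acceptor), **nested** (both internal), and
   **intermezzo** (a 5'RS/3'RS pair bracketing a retained internal
   cassette). Introns carrying events are *multi-step*, the rest
   *single-step*.
5. **Motifs.** 4-nt donor/acceptor contexts per event, position-frequency
   matrices, canonical GT/AG fractions and a Burset-style dinucleotide
   pair table.

A first-class **synthetic data generator** emulates the study design —
transcription at 2.4 kb/min, exponential per-intron removal once an
intron's 3' end is transcribed, planted multi-step paths, fragments of
250–650 nt with 2×100-nt reads — and emits valid SAM plus a complete truth
table, so the whole pipeline is testable offline.

## Worked example

Simulate a 6-intron gene across three "cell lines" with one planted event
of each class, then analyze it:

```r
library(spliceorder)
cfg <- simulation_config(
  n_introns = 6, seed = 42, n_molecules = 800, n_pairs = 8000,
  intron_length_range = c(1500, 5000),
  planted_events = data.frame(
    intron = c(2, 3, 4, 5),
    class  = c("5RS", "3RS", "nested", "intermezzo"),
    off1   = c(400, 600, 300, 200),
    off2   = c(NA, NA, 800, 900)))
st  <- simulate_study(cfg)
res <- analyze_study(st$gene$model, st$aln, genome = st$gene$genome,
                     cell_line_of = setNames(st$samples$cell_line,
                                             st$samples$sample_id))
```

Phase fractions show the pre-mRNA-dominated pool (`frac_pre` 0.949,
`frac_intermediate` 0.047, `frac_post` 0.004 for library 1). The order
calls recover the planted kinetics — intron 5, slowed by its three-step
intermezzo path, is the one non-sequential intron:

```
  intron  S NS splice_ratio    order_class
1      1 48  9         0.84     sequential
2      2 52 19         0.73     sequential
3      3 26 13         0.67     sequential
4      4 36  8         0.82     sequential
5      5  2 20         0.09 non-sequential
6      6  0 NA           NA   insufficient
```

All five planted event steps are found in all three lines and classified
correctly, and the intermezzo pair reports its retained cassette
(`off2 - off1 - 1` = 699 nt):

```
  donor_pos acceptor_pos total_support intron event_class
5      3105         3504           123      2         5RS
1      7108        10014           119      3         3RS
2     10498        10998           124      4      nested
3     12907        13106           148      5  intermezzo
4     13806        16471            47      5  intermezzo

  intron rs5_acceptor rs3_donor retained_length
1      5        13106     13806             699
```

With canonical sites planted, the motif summary reports 100% GT donors and
100% AG acceptors (`res$motifs$recursive$canonical`).

For file-based runs there is a thin CLI over the same functions
(`inst/cli/spliceorder.R`, subcommands `simulate`, `run-all`, and per-stage
aliases) and `run_pipeline()`, which reads SAM/BAM + annotation + FASTA,
enforces the 500,000 gene-mapped-read yield floor, and writes per-stage
TSVs plus a JSON summary.

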