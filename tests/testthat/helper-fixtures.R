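# toy 3-exon model from hand-checkable coordinates
toy_model <- function(strand = "+") {
  gene_model(data.frame(start = c(1, 201, 1001), end = c(100, 300, 1100)),
             gene_id = "toy", chrom = "chrT", strand = strand)
}

# model with wide introns so span-based rules can trigger
wide_model <- function(n_exons = 6L, exon_len = 200L, intron_len = 20000L) {
  starts <- 1L + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
  gene_model(data.frame(start = starts, end = starts + exon_len - 1L),
             gene_id = "wide", chrom = "chrW", strand = "+")
}

# build an alignment table for one pair from block/gap coordinate matrices
pair_aln <- function(b1, b2, g1 = NULL, g2 = NULL, qname = "p1",
                     sample = "s1", chrom = "chrW") {
  as_df <- function(id, m) if (is.null(m)) NULL else
    data.frame(id = id, start = m[, 1L], end = m[, 2L])
  ends <- data.frame(id = 1:2, qname = qname, sample_id = sample,
                     end = 1:2, mapq = 60L, nm = 0L)
  blocks <- rbind(as_df(1L, rbind(b1)), as_df(2L, rbind(b2)))
  gaps <- rbind(as_df(1L, if (is.null(g1)) NULL else rbind(g1)),
                as_df(2L, if (is.null(g2)) NULL else rbind(g2)))
  if (is.null(gaps)) gaps <- data.frame(id = integer(), start = integer(),
                                        end = integer())
  alignment_table(ends, blocks, gaps, chrom = chrom)
}

# lazily computed shared simulations (expensive; reused across test files)
.fixture_env <- new.env(parent = emptyenv())

# 20-intron gene, odd introns removed 10x slower than their downstream
# neighbor (planted non-sequential), deep enough for order calls
sim_order_study <- function() {
  if (is.null(.fixture_env$order)) {
    rates <- rep(c(0.05, 0.5), 10L)
    cfg <- simulation_config(n_introns = 20L, removal_rate = rates, seed = 7L,
                             n_molecules = 3000L, n_pairs = 40000L)
    g <- simulate_gene(cfg)
    sim <- simulate_transcripts(g, cfg)
    er <- emit_read_pairs(g, sim, cfg)
    .fixture_env$order <- list(cfg = cfg, gene = g, sim = sim, aln = er$aln,
                               truth = er$truth,
                               planted = c(rep(c("non-sequential",
                                                 "sequential"), 10L)))
  }
  .fixture_env$order
}

# 6-intron, 3-cell-line study with one planted event of each class
sim_event_study <- function() {
  if (is.null(.fixture_env$events)) {
    cfg <- simulation_config(
      n_introns = 6L, seed = 42L, n_molecules = 800L, n_pairs = 8000L,
      intron_length_range = c(1500L, 5000L),
      planted_events = data.frame(
        intron = c(2L, 3L, 4L, 5L),
        class = c("5RS", "3RS", "nested", "intermezzo"),
        off1 = c(400L, 600L, 300L, 200L),
        off2 = c(NA, NA, 800L, 900L)))
    st <- simulate_study(cfg)
    .fixture_env$events <- c(st, list(cfg = cfg))
  }
  .fixture_env$events
}
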