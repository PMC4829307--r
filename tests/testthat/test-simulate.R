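test_that("identical seeds give byte-identical output", {
  cfg <- simulation_config(n_introns = 4L, seed = 99L, n_molecules = 200L,
                           n_pairs = 1500L)
  run <- function() {
    g <- simulate_gene(cfg)
    sim <- simulate_transcripts(g, cfg)
    er <- emit_read_pairs(g, sim, cfg)
    f <- tempfile(fileext = ".sam")
    write_sam(er$aln, f, chrom_len = sum(Biostrings::width(g$genome)),
              genome = g$genome)
    list(sam = readLines(f), truth = er$truth, genome = as.character(g$genome))
  }
  a <- run(); b <- run()
  expect_identical(a$sam, b$sam)
  expect_identical(a$truth, b$truth)
  expect_identical(a$genome, b$genome)
  # a different seed changes the reads
  cfg2 <- cfg; cfg2$seed <- 100L
  g2 <- simulate_gene(cfg2)
  expect_false(identical(as.character(g2$genome), a$genome))
})

test_that("annotated splice sites are canonical by construction", {
  for (strand in c("+", "-")) {
    cfg <- simulation_config(n_introns = 5L, seed = 3L, strand = strand)
    g <- simulate_gene(cfg)
    chromseq <- as.character(g$genome[[1]])
    it <- introns(g$model)
    for (i in seq_len(nrow(it))) {
      if (strand == "+") {
        expect_equal(substr(chromseq, it$donor_site[i], it$donor_site[i] + 1L), "GT")
        expect_equal(substr(chromseq, it$acceptor_site[i] - 1L, it$acceptor_site[i]), "AG")
      } else {
        # reverse complement reads GT..AG on the transcript sense
        expect_equal(substr(chromseq, it$donor_site[i] - 1L, it$donor_site[i]), "AC")
        expect_equal(substr(chromseq, it$acceptor_site[i], it$acceptor_site[i] + 1L), "CT")
      }
    }
  }
})

test_that("planted sites too close to a boundary are rejected", {
  cfg <- simulation_config(
    n_introns = 3L, seed = 5L,
    planted_events = data.frame(intron = 1L, class = "5RS", off1 = 20L))
  expect_error(simulate_gene(cfg), "too close")
})

test_that("kinetic limits behave as expected", {
  # very fast removal + full transcription: everything spliced
  cfg <- simulation_config(n_introns = 4L, removal_rate = 1e3, seed = 6L,
                           mature = TRUE, n_molecules = 100L)
  g <- simulate_gene(cfg)
  sim <- simulate_transcripts(g, cfg)
  full <- sim$removed[sim$removed$full, ]
  expect_equal(nrow(full), 100L * 4L)
  # effectively zero rates: nothing removed, no junction gaps emitted
  cfg0 <- simulation_config(n_introns = 4L, removal_rate = 1e-9, seed = 6L,
                            n_molecules = 100L, n_pairs = 800L)
  g0 <- simulate_gene(cfg0)
  sim0 <- simulate_transcripts(g0, cfg0)
  expect_equal(nrow(sim0$removed), 0L)
  er0 <- emit_read_pairs(g0, sim0, cfg0)
  expect_equal(nrow(er0$aln$gaps), 0L)
})

test_that("emitted gaps correspond exactly to removed segments", {
  st <- sim_event_study()
  g <- st$gene
  tg <- st$truth$lib1$gaps
  # every gap is either a full intron or a planted event segment
  ev_key <- paste(g$truth_events$t_donor, g$truth_events$t_acceptor)
  in_key <- paste(g$t_intron_start, g$t_intron_end)
  expect_true(all(paste(tg$start, tg$end) %in% c(ev_key, in_key)))
  # full-intron gaps have the annotated intron widths
  iw <- introns(g$model)$length
  full <- tg[tg$full_intron, ]
  expect_true(all((full$end - full$start + 1L) %in% iw))
  # read geometry: blocks disjoint, ascending, total width <= read length
  a <- st$aln$lib1
  spl <- split(a$blocks, a$blocks$id)
  wsum <- vapply(spl, function(b) sum(b$end - b$start + 1L), numeric(1))
  expect_true(all(wsum <= st$cfg$read_length))
  ok <- vapply(spl, function(b) {
    b <- b[order(b$start), ]; all(diff(b$start) > 0) &&
      all(b$start[-1] > b$end[-nrow(b)])
  }, logical(1))
  expect_true(all(ok))
})

test_that("two-intron race matches the analytic exponential-race probability", {
  k1 <- 0.15; k2 <- 0.45
  cfg <- simulation_config(n_introns = 2L, removal_rate = c(k1, k2),
                           seed = 17L, n_molecules = 10000L)
  g <- simulate_gene(cfg)
  sim <- simulate_transcripts(g, cfg)
  delta <- (g$t_intron_end[2] - g$t_intron_end[1]) /
    (cfg$elongation_rate * 1000)
  p_an <- race_probability(k1, k2, delta)
  emp <- mean(sim$removal_time[, 1] < sim$removal_time[, 2])
  se <- sqrt(p_an * (1 - p_an) / nrow(sim$removal_time))
  expect_lt(abs(emp - p_an), 3 * se)
})

test_that("the dystrophin-like preset has 79 exons and 78 long introns", {
  cfg <- dmd_like_config(seed = 2L)
  g <- simulate_gene(cfg)
  expect_equal(nrow(exons(g$model)), 79L)
  expect_equal(nrow(introns(g$model)), 78L)
  expect_true(all(introns(g$model)$length >= 107L))
  expect_true(all(introns(g$model)$length <= 360000L))
})

test_that("SAM round-trip preserves the alignment structure", {
  st <- sim_event_study()
  g <- st$gene
  a <- st$aln$lib1
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(a, f, chrom_len = sum(Biostrings::width(g$genome)),
            genome = g$genome)
  a2 <- read_alignments(f, sample_id = "lib1")
  expect_equal(nrow(a2$ends), nrow(a$ends))
  key <- function(x) {
    m <- match(x$blocks$id, x$ends$id)
    sort(paste(x$ends$qname[m], x$ends$end[m], x$blocks$start, x$blocks$end))
  }
  expect_equal(key(a2), key(a))
  gkey <- function(x) {
    m <- match(x$gaps$id, x$ends$id)
    sort(paste(x$ends$qname[m], x$ends$end[m], x$gaps$start, x$gaps$end))
  }
  expect_equal(gkey(a2), gkey(a))
  # classification is identical on the round-tripped alignments
  p1 <- classify_pairs(a, g$model)
  p2 <- classify_pairs(a2, g$model)
  p2 <- p2[match(p1$pair_id, p2$pair_id), ]
  expect_equal(p2$phase, p1$phase)
})
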