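test_that("split extraction emits one record per qualifying gap", {
  m <- toy_model()
  i2 <- introns(m)$start[2]  # intron 2: 301..1000
  # 40M 3095N-style gapped end inside an intron (here 300N)
  a <- pair_aln(rbind(c(i2 + 10L, i2 + 49L), c(i2 + 350L, i2 + 409L)),
                c(i2 + 420L, i2 + 519L),
                g1 = c(i2 + 50L, i2 + 349L), chrom = "chrT")
  sp <- extract_split_reads(a, m)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$gap_len, 300L)
  # ungapped ends contribute nothing
  a2 <- pair_aln(c(10L, 109L), c(210L, 299L), chrom = "chrT")
  expect_equal(nrow(extract_split_reads(a2, m)), 0L)
  # an end with two gaps yields two records; sub-threshold gaps are dropped
  a3 <- pair_aln(rbind(c(i2, i2 + 9L), c(i2 + 110L, i2 + 119L),
                       c(i2 + 180L, i2 + 289L)),
                 c(i2 + 300L, i2 + 399L),
                 g1 = rbind(c(i2 + 10L, i2 + 109L), c(i2 + 120L, i2 + 179L)),
                 chrom = "chrT")
  sp3 <- extract_split_reads(a3, m, min_gap = 50L)
  expect_equal(nrow(sp3), 2L)
  expect_equal(nrow(extract_split_reads(a3, m, min_gap = 70L)), 1L)
})

test_that("gap boundaries slide to the best splice-site placement", {
  m <- toy_model()
  set.seed(9)
  s <- sample(c("A", "C"), 1100, replace = TRUE)  # no G/T: baseline score 0
  # intended junction: gap 401..600 with GT at 401-402 and AG at 599-600
  s[401:402] <- c("G", "T"); s[599:600] <- c("A", "G")
  s[400] <- "G"   # allows the mis-placed gap 400..599 to slide right
  s[399] <- "A"; s[601] <- "G"; s[602] <- "C"
  genome <- Biostrings::DNAStringSet(paste(s, collapse = ""))
  names(genome) <- "chrT"
  splits <- data.frame(id = 1L, qname = "r1", sample_id = "s1",
                       gap_start = 400L, gap_end = 599L, gap_len = 200L)
  ref <- refine_gap_boundaries(splits, genome, m)
  expect_equal(ref$gap_start, 401L)
  expect_equal(ref$gap_end, 600L)
  expect_equal(ref$motif_score, 4)

  # unambiguous gap: returned unchanged
  s2 <- s
  s2[419] <- "C"; s2[560] <- "A"  # blocks sliding left
  s2[420] <- "A"; s2[561] <- "C"  # blocks sliding right
  genome2 <- Biostrings::DNAStringSet(paste(s2, collapse = ""))
  names(genome2) <- "chrT"
  splits2 <- data.frame(id = 1L, qname = "r1", sample_id = "s1",
                        gap_start = 420L, gap_end = 560L, gap_len = 141L)
  ref2 <- refine_gap_boundaries(splits2, genome2, m)
  expect_equal(ref2$shift, 0L)
  expect_equal(ref2$gap_start, 420L)

  # all placements tie: leftmost chosen, score never decreased
  s3 <- rep("A", 1100)
  genome3 <- Biostrings::DNAStringSet(paste(s3, collapse = ""))
  names(genome3) <- "chrT"
  splits3 <- data.frame(id = 1L, qname = "r1", sample_id = "s1",
                        gap_start = 700L, gap_end = 800L, gap_len = 101L)
  ref3 <- refine_gap_boundaries(splits3, genome3, m, max_shift = 10L)
  expect_equal(ref3$shift, -10L)
  expect_equal(ref3$gap_start, 690L)
})

test_that("refinement stays inside the ambiguity range, score monotone", {
  m <- toy_model()
  set.seed(10)
  for (rep in 1:25) {
    s <- sample(c("A", "C", "G", "T"), 1100, replace = TRUE)
    genome <- Biostrings::DNAStringSet(paste(s, collapse = ""))
    names(genome) <- "chrT"
    gs <- sample(350:500, 1); ge <- gs + sample(60:200, 1)
    splits <- data.frame(id = 1L, qname = "r", sample_id = "s",
                         gap_start = gs, gap_end = ge, gap_len = ge - gs + 1L)
    before <- refine_gap_boundaries(splits, genome, m, max_shift = 0L)
    after <- refine_gap_boundaries(splits, genome, m, max_shift = 8L)
    expect_true(after$shift >= -after$shift_left &
                  after$shift <= after$shift_right)
    expect_gte(after$motif_score, before$motif_score)
    expect_equal(after$gap_end - after$gap_start, ge - gs)  # length preserved
  }
})

test_that("filters keep only mid-intron events with a novel site", {
  m <- toy_model()
  sp <- data.frame(
    id = 1:4, qname = paste0("r", 1:4), sample_id = "s1",
    gap_start = c(101L, 301L, 301L, 401L),
    gap_end = c(200L, 970L, 700L, 980L))
  sp$gap_len <- sp$gap_end - sp$gap_start + 1L
  out <- filter_split_events(sp, m, boundary_margin = 50L)
  # r1: both sites annotated (whole intron 1) -> discarded
  # r2: acceptor 30 nt from the 3' boundary -> discarded
  # r4: donor 100 nt in but acceptor 20 nt from boundary -> discarded
  # r3: annotated donor + mid-intron acceptor -> retained
  expect_equal(out$qname, "r3")
  expect_equal(out$intron, 2L)
  expect_true(out$donor_annotated)
  expect_false(out$acceptor_annotated)
  # a gap spanning an exon (more than one intron) never passes
  sp2 <- data.frame(id = 1L, qname = "x", sample_id = "s1",
                    gap_start = 150L, gap_end = 400L, gap_len = 251L)
  expect_equal(nrow(filter_split_events(sp2, m)), 0L)
})

test_that("event matrices sum libraries within a cell line", {
  sp <- data.frame(id = 1:5, qname = paste0("r", 1:5),
                   sample_id = c("a1", "a1", "a2", "a2", "a2"),
                   gap_start = 400L, gap_end = 900L, gap_len = 501L,
                   donor_pos = 400L, acceptor_pos = 900L, intron = 2L)
  mats <- build_event_matrix(sp, c(a1 = "lineA", a2 = "lineA"))
  expect_equal(unname(mats$lineA["400", "900"]), 5L)
  # empty input -> empty matrix
  mats0 <- build_event_matrix(sp[0, ], c(a1 = "lineA"))
  expect_equal(dim(mats0$lineA), c(0L, 0L))
})

test_that("only events present in every cell line survive intersection", {
  mk <- function(v) matrix(v, 1, 2, dimnames = list("400", c("800", "900")))
  mats <- list(l1 = mk(c(3L, 2L)), l2 = mk(c(1L, 0L)), l3 = mk(c(4L, 9L)))
  ev <- intersect_samples(mats)
  expect_equal(nrow(ev), 1L)  # (400,900) present in only 2 of 3 lines
  expect_equal(ev$acceptor_pos, 800L)
  expect_equal(ev$total_support, 8L)
  expect_error(intersect_samples(list()), "no samples")
})

test_that("event classes and intermezzo pairing follow site annotation", {
  m <- toy_model()  # intron 2: 301..1000, donor 301, acceptor 1000
  ev <- data.frame(donor_pos = c(301L, 600L, 450L, 301L, 659L),
                   acceptor_pos = c(500L, 1000L, 550L, 500L, 1000L))
  cl <- classify_event(ev[1:3, ], m)
  expect_equal(cl$event_class, c("5RS", "3RS", "nested"))
  expect_equal(cl$intron, c(2L, 2L, 2L))
  # 5RS acceptor 500 + 3RS donor 659 -> intermezzo of 158 nt
  imz <- detect_intermezzo(classify_event(ev[4:5, ], m), m)
  expect_equal(imz$pairs$retained_length, 158L)
  expect_equal(imz$events$event_class, c("intermezzo", "intermezzo"))
  # lone 5RS: no intermezzo
  lone <- detect_intermezzo(classify_event(ev[1, , drop = FALSE], m), m)
  expect_equal(nrow(lone$pairs), 0L)
  # overlapping combination (3RS donor upstream of the 5RS acceptor)
  ov <- data.frame(donor_pos = c(301L, 420L), acceptor_pos = c(500L, 1000L))
  expect_equal(nrow(detect_intermezzo(classify_event(ov, m), m)$pairs), 0L)
})

test_that("planted events are fully recovered with correct classes", {
  st <- sim_event_study()
  m <- st$gene$model
  truth <- st$gene$truth_events
  cl_of <- setNames(st$samples$cell_line, st$samples$sample_id)
  splits <- do.call(rbind, lapply(names(st$aln), function(s) {
    sp <- extract_split_reads(st$aln[[s]], m)
    sp <- refine_gap_boundaries(sp, st$gene$genome, m)
    filter_split_events(sp, m)
  }))
  mats <- build_event_matrix(splits, cl_of)
  # truth gaps appear as exactly the planted nonzero cells in each line
  expect_equal(sum(mats[[1]] > 0), nrow(truth))
  ev <- intersect_samples(mats)
  ev <- classify_event(ev, m)
  imz <- detect_intermezzo(ev, m)
  ev <- imz$events
  # recall 1.0 at >= 10 supporting reads per line, classes match truth
  key <- function(d) paste(d$donor_pos, d$acceptor_pos)
  expect_setequal(key(ev), key(truth))
  ev <- ev[match(key(truth), key(ev)), ]
  expect_true(all(as.matrix(ev[grep("^support_", names(ev))]) >= 10))
  expect_equal(ev$event_class, truth$class)
  expect_equal(ev$intron, truth$intron)
  # an event absent from one line never leaks through intersection
  mats2 <- mats
  k <- which(mats2[[1]] > 0)[1]
  mats2[[1]][k] <- 0L
  ev2 <- intersect_samples(mats2)
  expect_equal(nrow(ev2), nrow(truth) - 1L)
  # intron step modes: exactly the planted introns are multi-step
  steps <- classify_intron_steps(ev, m)
  expect_equal(steps$per_intron$mode,
               ifelse(1:6 %in% truth$intron, "multi-step", "single-step"))
  expect_equal(steps$summary$n_multi, 4L)
  # event table round-trips through TSV
  f <- withr::local_tempfile(fileext = ".tsv")
  write_event_table(ev, f)
  expect_equal(read_event_table(f)$donor_pos, ev$donor_pos)
})

test_that("event coordinates ignore which mate carried the gap", {
  st <- sim_event_study()
  m <- st$gene$model
  a <- st$aln$lib1
  sp1 <- extract_split_reads(a, m)
  a2 <- a
  a2$ends$end <- 3L - a2$ends$end  # swap read-1/read-2 labels
  sp2 <- extract_split_reads(a2, m)
  expect_equal(sp1[c("gap_start", "gap_end")], sp2[c("gap_start", "gap_end")])
})
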