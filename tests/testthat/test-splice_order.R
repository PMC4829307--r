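# junction/intron pair geometry on the wide model: S(n) needs one end over
# the exon(n)-exon(n+1) junction with the mate inside intron n+1, NS(n) one
# end inside intron n with the mate over the exon(n+1)-exon(n+2) junction.

jn_blocks <- function(m, i) {
  e <- exons(m)
  rbind(c(e$end[i] - 49L, e$end[i]), c(e$start[i + 1L], e$start[i + 1L] + 49L))
}
in_block <- function(m, i, off = 500L) {
  s <- introns(m)$start[i] + off
  c(s, s + 99L)
}

test_that("order-informative pairs tally S and NS to the right introns", {
  m <- wide_model()
  gap <- function(i) c(introns(m)$start[i], introns(m)$end[i])
  # junction ex2-ex3 + mate in intron 3 -> S(2)
  a <- pair_aln(jn_blocks(m, 2), in_block(m, 3), g1 = gap(2))
  cnt <- count_order_pairs(a, m)
  expect_equal(cnt$S, c(0L, 1L, 0L, 0L, 0L))
  expect_equal(cnt$NS[1:4], rep(0L, 4L))
  # mate in intron 2 + junction ex3-ex4 -> NS(2)
  a <- pair_aln(in_block(m, 2), jn_blocks(m, 3), g2 = gap(3))
  cnt <- count_order_pairs(a, m)
  expect_equal(cnt$NS[2], 1L)
  expect_equal(cnt$S, rep(0L, 5L))
  # both ends exonic -> no tally
  e <- exons(m)
  a <- pair_aln(c(e$start[1], e$start[1] + 99L), c(e$start[2], e$start[2] + 99L))
  cnt <- count_order_pairs(a, m)
  expect_equal(sum(cnt$S, cnt$NS, na.rm = TRUE), 0L)
  # junction whose gap does not match the annotation is ignored here
  a <- pair_aln(rbind(c(e$end[1] - 49L, e$end[1]),
                      c(e$start[2] + 10L, e$start[2] + 59L)),
                in_block(m, 2),
                g1 = c(introns(m)$start[1], introns(m)$end[1] + 10L))
  cnt <- count_order_pairs(a, m)
  expect_equal(sum(cnt$S, cnt$NS, na.rm = TRUE), 0L)
})

test_that("splice-ratio classes follow the 0.5 threshold and support floor", {
  base <- data.frame(intron = 1:4, S = c(8L, 2L, 0L, 1L),
                     NS = c(2L, 8L, 0L, 1L))
  out <- splice_ratio(base)
  expect_equal(out$splice_ratio, c(0.8, 0.2, NA, 0.5))
  expect_equal(out$order_class,
               c("sequential", "non-sequential", "insufficient",
                 "insufficient"))
  # near-0.5 ratios are intermediate within epsilon
  out2 <- splice_ratio(data.frame(intron = 1, S = 51L, NS = 49L))
  expect_equal(out2$order_class, "intermediate")
  # last intron: S-only evidence
  last <- splice_ratio(data.frame(intron = 1:2, S = c(3L, 9L),
                                  NS = c(4L, NA)))
  expect_equal(last$splice_ratio[2], 1)
  expect_equal(last$order_class[2], "sequential")
})

test_that("splice-ratio is invariant under library pooling", {
  set.seed(4)
  for (rep in 1:20) {
    S <- rpois(5, 20); NS <- rpois(5, 10)  # 5 libraries, one intron
    pooled <- sum(S) / (sum(S) + sum(NS))
    w <- (S + NS) / sum(S + NS)
    weighted <- sum(w * S / (S + NS))
    expect_equal(pooled, weighted, tolerance = 1e-12)
    one <- splice_ratio(data.frame(intron = 1, S = sum(S), NS = sum(NS)))
    expect_equal(one$splice_ratio, pooled)
  }
})

test_that("exon blocks are flanked runs of early-removed introns", {
  # introns 13 NS-slow, 14-15 fast, 16 NS-slow -> block exons 14-16
  N <- 20
  oc <- rep("sequential", N); sc <- rep("fast", N)
  oc[c(13, 16)] <- "non-sequential"; sc[c(13, 16)] <- "slow"
  sc[setdiff(1:N, 13:16)] <- "slow"  # isolate the run
  b <- derive_exon_blocks(oc, sc)
  expect_equal(b$first_exon, 14L)
  expect_equal(b$last_exon, 16L)
  expect_equal(b$left_flank, 13L)
  expect_equal(b$right_flank, 16L)

  # introns 44 NS-slow, 45-48 fast, 49 NS-slow -> block exons 45-49
  N <- 60
  oc <- rep("non-sequential", N); sc <- rep("slow", N)
  oc[45:48] <- "sequential"; sc[45:48] <- "fast"
  b <- derive_exon_blocks(oc, sc)
  expect_equal(unlist(b[c("first_exon", "last_exon")], use.names = FALSE),
               c(45L, 49L))

  # all introns fast -> one block spanning the whole transcript
  b <- derive_exon_blocks(rep("sequential", 10), rep("fast", 10))
  expect_equal(nrow(b), 1L)
  expect_equal(unlist(b[c("first_exon", "last_exon")], use.names = FALSE),
               c(1L, 11L))
})

test_that("planted non-sequential introns are recovered from read pairs", {
  fx <- sim_order_study()
  m <- fx$gene$model
  pr <- classify_pairs(fx$aln, m)
  oc <- splice_ratio(count_order_pairs(fx$aln, m, pairs = pr))
  planted <- fx$planted
  support <- oc$S + ifelse(is.na(oc$NS), 0L, oc$NS)
  eval <- support >= 20 & seq_along(planted) < length(planted)
  expect_gt(sum(eval), 10)  # enough supported introns to be meaningful
  expect_gte(mean(oc$order_class[eval] == planted[eval]), 0.9)
})

test_that("coverage correlates negatively with splice-ratio when coupled", {
  fx <- sim_order_study()
  m <- fx$gene$model
  cov <- gene_coverage(fx$aln, m)
  med <- feature_medians(cov, m)
  ri <- med$raw_median[med$feature == "intron"]
  nm <- normalize_coverage(cbind(ri), exon_mean_coverage(cov, m))
  oc <- splice_ratio(count_order_pairs(fx$aln, m))
  res <- order_vs_coverage_correlation(oc$splice_ratio, nm$cross_sample_mean)
  expect_lt(res$r, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("correlation handles exact and null cases", {
  # perfectly anti-monotone vectors
  res <- order_vs_coverage_correlation(1:10 / 10, 10:1)
  expect_equal(res$r, -1)
  # independent vectors: small |r|, p > 0.05, agreeing with a permutation
  # oracle
  set.seed(5)
  x <- runif(78); y <- runif(78)
  res <- order_vs_coverage_correlation(x, y)
  perm <- replicate(500, cor(x, sample(y)))
  p_perm <- mean(abs(perm) >= abs(res$r))
  expect_gt(res$p_value, 0.05)
  expect_gt(p_perm, 0.05)
  # constant vector flagged degenerate
  expect_true(order_vs_coverage_correlation(rep(0.5, 5), 1:5)$degenerate)
})
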