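#' Count order-informative read pairs per intron
#'
#' For intron n, a pair supports sequential removal (S) when one end spans
#' the annotated exon(n)-exon(n+1) junction (the junction created by
#' splicing intron n) and the mate maps fully inside intron n+1, which is
#' therefore still present. A pair supports non-sequential removal (NS of
#' intron n) when one end maps fully inside intron n while the mate spans
#' the exon(n+1)-exon(n+2) junction. A junction end counts only if its skip
#' joins the exact annotated exon ends; the mate must lie entirely inside
#' the named intron. Each pair increments at most one S and one NS tally
#' (necessarily of different introns).
#'
#' @param aln an [alignment_table()].
#' @param model a [gene_model()].
#' @param pairs optional precomputed [classify_pairs()] output; only
#'   intermediate-phase pairs are used.
#' @return data.frame with one row per intron: `intron`, `S`, `NS` (`NS` is
#'   `NA` for the last intron, where no downstream junction exists).
#' @export
count_order_pairs <- function(aln, model, pairs = NULL) {
  if (is.null(pairs)) pairs <- classify_pairs(aln, model)
  pairs <- pairs[pairs$phase == "intermediate", , drop = FALSE]
  ann <- annotate_ends(aln, model)
  N <- nrow(model$introns)
  S <- integer(N); NS <- integer(N)
  jn_by_id <- split(ann$junctions$intron, ann$junctions$id)
  within_intron <- setNames(ann$ends$within_intron, ann$ends$id)
  for (k in seq_len(nrow(pairs))) {
    for (ord in list(c(pairs$id1[k], pairs$id2[k]),
                     c(pairs$id2[k], pairs$id1[k]))) {
      jns <- jn_by_id[[as.character(ord[1L])]]
      w <- within_intron[[as.character(ord[2L])]]
      if (is.null(jns) || is.na(w)) next
      s_hit <- jns[jns == w - 1L]   # junction of intron n, mate in intron n+1
      if (length(s_hit)) S[s_hit[1L]] <- S[s_hit[1L]] + 1L
      ns_hit <- jns[jns == w + 1L]  # mate in intron n, junction of intron n+1
      if (length(ns_hit)) NS[w] <- NS[w] + 1L
    }
  }
  out <- data.frame(intron = seq_len(N), S = S, NS = NS)
  out$NS[N] <- NA_integer_  # exon N+2 does not exist
  out
}

#' Splice-ratio and order class per intron
#'
#' `splice_ratio = S / (S + NS)`. Introns with ratio in (0.5, 1\] are
#' sequentially spliced, ratio < 0.5 non-sequentially; ratios within
#' `epsilon` of 0.5 are intermediate; introns with fewer than `min_support`
#' informative pairs are "insufficient" (ratio undefined when S + NS = 0).
#' For the last intron NS is structurally undefined and the call rests on
#' S-only evidence.
#'
#' @param counts output of [count_order_pairs()].
#' @param epsilon half-width of the intermediate band around 0.5.
#' @param min_support minimum S + NS for a defined call.
#' @return the counts data.frame with `splice_ratio` and `order_class`
#'   columns added.
#' @export
splice_ratio <- function(counts, epsilon = 0.05, min_support = 5L) {
  S <- counts$S
  NS <- ifelse(is.na(counts$NS), 0L, counts$NS)
  tot <- S + NS
  ratio <- ifelse(tot > 0L, S / tot, NA_real_)
  cls <- rep("insufficient", nrow(counts))
  ok <- tot >= min_support
  cls[ok & abs(ratio - 0.5) <= epsilon] <- "intermediate"
  cls[ok & ratio > 0.5 + epsilon] <- "sequential"
  cls[ok & ratio < 0.5 - epsilon] <- "non-sequential"
  counts$splice_ratio <- ratio
  counts$order_class <- cls
  counts
}

#' Derive exon blocks from order and speed calls
#'
#' An exon block is a maximal run of 3 or more exons already joined while
#' both flanking introns are still present: a run of >= 2 consecutive
#' early-removed introns (fast by coverage or sequential by splice-ratio)
#' whose flanking introns on both sides are late-removed (slow or
#' non-sequential); gene ends count as flanks.
#'
#' @param order_class per-intron order class (transcript order).
#' @param speed_class per-intron speed class (same length).
#' @return data.frame: `block`, `first_exon`, `last_exon`, `first_intron`,
#'   `last_intron`, `left_flank`, `right_flank` (intron index or `NA` at a
#'   gene end).
#' @export
derive_exon_blocks <- function(order_class, speed_class) {
  stopifnot(length(order_class) == length(speed_class))
  N <- length(order_class)
  flank <- speed_class == "slow" | order_class == "non-sequential"
  internal <- !flank & (speed_class == "fast" | order_class == "sequential")
  r <- rle(internal)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (j in which(r$values & r$lengths >= 2L)) {
    a <- starts[j]; b <- ends[j]
    left_ok <- a == 1L || flank[a - 1L]
    right_ok <- b == N || flank[b + 1L]
    if (left_ok && right_ok) {
      rows[[length(rows) + 1L]] <- data.frame(
        first_exon = a, last_exon = b + 1L,
        first_intron = a, last_intron = b,
        left_flank = if (a == 1L) NA_integer_ else a - 1L,
        right_flank = if (b == N) NA_integer_ else b + 1L)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(block = integer(), first_exon = integer(),
                      last_exon = integer(), first_intron = integer(),
                      last_intron = integer(), left_flank = integer(),
                      right_flank = integer()))
  out <- do.call(rbind, rows)
  cbind(block = seq_len(nrow(out)), out)
}

#' Pearson correlation of splice-ratio with normalized coverage
#'
#' Slowly removed introns sit longer in the pre-mRNA pool, so higher
#' coverage should accompany lower splice-ratio; a negative `r` is the
#' expected signature.
#'
#' @param splice_ratios per-intron splice-ratios (NAs dropped).
#' @param normalized_coverage per-intron normalized median coverage.
#' @return list(r, p_value, n); `degenerate = TRUE` when either vector is
#'   constant.
#' @export
order_vs_coverage_correlation <- function(splice_ratios, normalized_coverage) {
  keep <- is.finite(splice_ratios) & is.finite(normalized_coverage)
  x <- splice_ratios[keep]; y <- normalized_coverage[keep]
  if (sum(keep) < 3L) .stopf("need >= 3 introns with defined ratios")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(r = NA_real_, p_value = NA_real_, n = sum(keep),
                degenerate = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(keep),
       degenerate = FALSE)
}
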