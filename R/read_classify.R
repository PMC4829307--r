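#' Classify read pairs by splicing phase
#'
#' Every pair overlapping the gene receives exactly one phase:
#' \describe{
#'   \item{post}{both ends are "post-like": fully exonic, with any skip gap
#'     joining two annotated exon ends (ex~ex, ex~(ex-ex), (ex-ex)~(ex-ex)),
#'     spanning more than one exon. Completed splicing.}
#'   \item{exon-only}{both ends inside one and the same exon (uninformative
#'     about splicing).}
#'   \item{intermediate}{one end covers an annotated exon-exon junction while
#'     the mate is intronic or boundary-spanning; or both ends are intronic
#'     with an inferred span exceeding the insert model ("large"), i.e.
#'     spliced material lies between them. Ongoing splicing.}
#'   \item{pre}{one or both ends intronic or boundary-spanning, no junction
#'     end. Unspliced fragments.}
#' }
#' The rules are applied in the precedence order exon-only > post >
#' intermediate(junction) > intermediate(large) > pre, which makes the table
#' total and symmetric in end order. "Large" means inferred span >
#' `expected_insert + 3 * insert_sd`. Masks play no role here.
#'
#' @param aln an [alignment_table()].
#' @param model a [gene_model()].
#' @param expected_insert expected library insert size in nt (default 400).
#' @param insert_sd insert-size standard deviation used for the "large"
#'   threshold (default 100, giving 400 + 300 = 700 nt).
#' @return data.frame with one row per assignable pair: `pair_id`,
#'   `sample_id`, `phase`, `size_label`, `span`, plus end ids `id1`, `id2`.
#'   The number of unassignable pairs (an end outside the gene, or a
#'   singleton end) is in `attr(, "unassignable")`.
#' @export
classify_pairs <- function(aln, model, expected_insert = 400, insert_sd = 100) {
  ann <- annotate_ends(aln, model)
  e <- ann$ends
  e$key <- paste(e$sample_id, e$qname, sep = "\r")
  sp <- split(seq_len(nrow(e)), e$key)
  pairs <- Filter(function(ix) length(ix) == 2L, sp)
  n_un <- length(sp) - length(pairs)
  if (length(pairs) == 0L) {
    out <- data.frame(pair_id = character(), sample_id = character(),
                      phase = character(), size_label = character(),
                      span = integer(), id1 = integer(), id2 = integer())
    attr(out, "unassignable") <- n_un
    return(out)
  }
  i1 <- vapply(pairs, `[`, integer(1), 1L)
  i2 <- vapply(pairs, `[`, integer(1), 2L)
  e1 <- e[i1, ]; e2 <- e[i2, ]

  assignable <- e1$overlaps_gene & e2$overlaps_gene
  n_un <- n_un + sum(!assignable)
  e1 <- e1[assignable, ]; e2 <- e2[assignable, ]

  span <- pmax(e1$last_end, e2$last_end) - pmin(e1$first_start, e2$first_start) + 1L
  large <- span > expected_insert + 3 * insert_sd

  post_like <- function(x) x$all_exonic & !x$has_unannot_gap
  is_jn <- function(x) x$n_junction > 0L
  intronicish <- function(x) x$touches_intron | x$crosses_boundary

  exon_only <- !is.na(e1$single_exon) & !is.na(e2$single_exon) &
    e1$single_exon == e2$single_exon & e1$n_junction == 0L & e2$n_junction == 0L
  post <- post_like(e1) & post_like(e2) & !exon_only
  inter_jn <- (is_jn(e1) | is_jn(e2)) & !post & !exon_only
  inter_large <- e1$touches_intron & e2$touches_intron & large &
    !post & !exon_only & !inter_jn

  phase <- rep("pre", nrow(e1))
  phase[exon_only] <- "exon-only"
  phase[post] <- "post"
  phase[inter_jn | inter_large] <- "intermediate"

  out <- data.frame(
    pair_id = e1$qname, sample_id = e1$sample_id, phase = phase,
    size_label = ifelse(large, "large", "normal"), span = span,
    id1 = e1$id, id2 = e2$id, stringsAsFactors = FALSE)
  attr(out, "unassignable") <- n_un
  out
}

#' Tally splicing-phase categories per sample
#'
#' @param pairs output of [classify_pairs()].
#' @param aln the [alignment_table()] the pairs came from (for base-level
#'   exon/intron fractions); optional.
#' @param model a [gene_model()]; required when `aln` is given.
#' @return data.frame with one row per sample: counts and fractions per
#'   phase (fractions sum to 1 over pre/intermediate/post/exon-only) and,
#'   when `aln` is supplied, the fraction of mapped bases falling in exons
#'   and in introns.
#' @export
tally_categories <- function(pairs, aln = NULL, model = NULL) {
  phases <- c("pre", "intermediate", "post", "exon-only")
  if (nrow(pairs) == 0L) {
    .warnf("no assignable pairs; returning all-zero tallies")
    return(data.frame(sample_id = character(),
                      setNames(as.data.frame(matrix(0, 0, 8)),
                               c(paste0("n_", phases), paste0("frac_", phases)))))
  }
  samples <- sort(unique(pairs$sample_id))
  rows <- lapply(samples, function(s) {
    p <- pairs[pairs$sample_id == s, ]
    n <- vapply(phases, function(ph) sum(p$phase == ph), numeric(1))
    fr <- if (sum(n) > 0) n / sum(n) else n
    row <- data.frame(sample_id = s)
    for (i in seq_along(phases)) {
      row[[paste0("n_", phases[i])]] <- n[i]
      row[[paste0("frac_", phases[i])]] <- fr[i]
    }
    if (!is.null(aln)) {
      stopifnot(!is.null(model))
      ids <- aln$ends$id[aln$ends$sample_id == s]
      bl <- aln$blocks[aln$blocks$id %in% ids, ]
      bir <- IRanges::IRanges(bl$start, bl$end)
      base_overlap <- function(feat) {
        fir <- IRanges::IRanges(feat$start, feat$end)
        ov <- IRanges::findOverlaps(bir, fir)
        sum(IRanges::width(IRanges::pintersect(
          bir[S4Vectors::queryHits(ov)], fir[S4Vectors::subjectHits(ov)])))
      }
      exn <- base_overlap(model$exons)
      inn <- base_overlap(model$introns)
      tot <- sum(IRanges::width(bir))
      row$frac_bases_exonic <- if (tot) exn / tot else NA_real_
      row$frac_bases_intronic <- if (tot) inn / tot else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}
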