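#' Alignment table
#'
#' Lightweight long-format container for paired-end gapped alignments: one
#' row per aligned end in `$ends`, one row per aligned block (CIGAR M run,
#' deletions merged) in `$blocks`, and one row per skip gap (CIGAR N) in
#' `$gaps`, keyed by the integer end `id`. This is the common currency
#' between the SAM/BAM reader, the synthetic read generator and every
#' classification stage.
#'
#' @param ends data.frame(id, qname, sample_id, end, mapq, nm)
#' @param blocks data.frame(id, start, end)
#' @param gaps data.frame(id, start, end)
#' @param chrom contig name the coordinates live on.
#' @return object of class `aln_tbl`.
#' @export
alignment_table <- function(ends, blocks, gaps, chrom = NA_character_) {
  stopifnot(all(c("id", "qname", "sample_id", "end") %in% names(ends)),
            all(c("id", "start", "end") %in% names(blocks)))
  if (is.null(gaps)) gaps <- data.frame(id = integer(), start = integer(),
                                        end = integer())
  structure(list(ends = ends, blocks = blocks, gaps = gaps, chrom = chrom),
            class = "aln_tbl")
}

#' @export
print.aln_tbl <- function(x, ...) {
  cat(sprintf("aln_tbl: %d ends (%d pairs), %d blocks, %d gaps on %s\n",
              nrow(x$ends), length(unique(x$ends$qname)), nrow(x$blocks),
              nrow(x$gaps), x$chrom))
  invisible(x)
}

#' Read paired-end alignments from SAM/BAM
#'
#' Applies the post-alignment quality filters: primary, mapped, uniquely
#' placed records only, with at most `max_mismatches` mismatches per end
#' (NM tag, when present). SAM input is converted with
#' [Rsamtools::asBam()] on the fly.
#'
#' @param file SAM or BAM path.
#' @param sample_id sample label attached to every read.
#' @param max_mismatches per-end mismatch ceiling (default 5).
#' @param min_mapq minimum mapping quality kept (default 1, i.e. uniquely
#'   mapped under most aligners' conventions).
#' @return an [alignment_table()].
#' @export
read_alignments <- function(file, sample_id = "sample1", max_mismatches = 5L,
                            min_mapq = 1L) {
  if (tolower(tools::file_ext(file)) == "sam") {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"), tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  gal <- GenomicAlignments::readGAlignments(file, param = param)
  mq <- S4Vectors::mcols(gal)$mapq
  nm <- S4Vectors::mcols(gal)$NM
  keep <- (is.na(mq) | mq >= min_mapq)
  if (!is.null(nm)) keep <- keep & (is.na(nm) | nm <= max_mismatches)
  gal <- gal[keep]
  n <- length(gal)
  flag <- S4Vectors::mcols(gal)$flag
  ends <- data.frame(
    id = seq_len(n),
    qname = S4Vectors::mcols(gal)$qname,
    sample_id = sample_id,
    end = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    mapq = S4Vectors::mcols(gal)$mapq,
    nm = if (is.null(nm)) NA_integer_ else S4Vectors::mcols(gal)$NM[keep],
    stringsAsFactors = FALSE)
  blk <- GenomicAlignments::grglist(gal)
  nb <- S4Vectors::elementNROWS(blk)
  ublk <- unlist(blk, use.names = FALSE)
  blocks <- data.frame(id = rep(seq_len(n), nb),
                       start = GenomicRanges::start(ublk),
                       end = GenomicRanges::end(ublk))
  jn <- GenomicAlignments::junctions(gal)
  nj <- S4Vectors::elementNROWS(jn)
  ujn <- unlist(jn, use.names = FALSE)
  gaps <- data.frame(id = rep(seq_len(n), nj),
                     start = GenomicRanges::start(ujn),
                     end = GenomicRanges::end(ujn))
  chrom <- if (n > 0L)
    as.character(GenomicRanges::seqnames(gal))[1L] else NA_character_
  alignment_table(ends, blocks, gaps, chrom = chrom)
}

#' Annotate aligned ends against the gene model
#'
#' Derives, per end, the feature set it touches: exon bodies, intron bodies,
#' exon-intron boundaries, and annotated exon-exon junctions (a skip gap
#' that joins two annotated exon ends exactly). Features are derived solely
#' from gene-model overlap.
#'
#' @param aln an [alignment_table()].
#' @param model a [gene_model()].
#' @return list with `ends` (per-end feature summary) and `junctions`
#'   (data.frame id / intron for each annotated-junction gap).
#' @export
annotate_ends <- function(aln, model) {
  ids <- aln$ends$id
  n <- length(ids)
  bl <- aln$blocks
  bir <- IRanges::IRanges(bl$start, bl$end)
  exir <- IRanges::IRanges(model$exons$start, model$exons$end)
  inir <- IRanges::IRanges(model$introns$start, model$introns$end)

  ov_ex <- IRanges::overlapsAny(bir, exir)
  ov_in <- IRanges::overlapsAny(bir, inir)
  win_ex <- IRanges::findOverlaps(bir, exir, type = "within")
  win_in <- IRanges::findOverlaps(bir, inir, type = "within")
  blk_within_exon <- rep(NA_integer_, nrow(bl))
  blk_within_exon[S4Vectors::queryHits(win_ex)] <-
    model$exons$index[S4Vectors::subjectHits(win_ex)]
  blk_within_intron <- rep(NA_integer_, nrow(bl))
  blk_within_intron[S4Vectors::queryHits(win_in)] <-
    model$introns$index[S4Vectors::subjectHits(win_in)]

  f <- factor(bl$id, levels = ids)
  agg_any <- function(x) as.logical(tapply(x, f, any, default = FALSE))
  touches_exon <- agg_any(ov_ex)
  touches_intron <- agg_any(ov_in)
  crosses_boundary <- agg_any(ov_ex & ov_in)
  all_exonic <- as.logical(tapply(!is.na(blk_within_exon), f, all, default = TRUE))
  all_exonic[is.na(all_exonic)] <- FALSE
  one_exon <- tapply(blk_within_exon, f, function(z)
    if (all(!is.na(z)) && length(unique(z)) == 1L) z[1L] else NA_integer_)
  single_exon <- as.integer(one_exon)
  one_intron <- tapply(blk_within_intron, f, function(z)
    if (all(!is.na(z)) && length(unique(z)) == 1L) z[1L] else NA_integer_)
  within_intron <- as.integer(one_intron)
  first_start <- as.integer(tapply(bl$start, f, min))
  last_end <- as.integer(tapply(bl$end, f, max))
  overlaps_gene <- !is.na(first_start) & last_end >= model$span[[1L]] &
    first_start <= model$span[[2L]]

  # annotated junction: gap identical to an intron interval
  ikey <- paste(model$introns$start, model$introns$end)
  gkey <- paste(aln$gaps$start, aln$gaps$end)
  gmatch <- match(gkey, ikey)
  junctions <- data.frame(id = aln$gaps$id[!is.na(gmatch)],
                          intron = model$introns$index[gmatch[!is.na(gmatch)]])
  n_jn <- integer(n)
  if (nrow(junctions)) {
    t1 <- table(factor(junctions$id, levels = ids))
    n_jn <- as.integer(t1)
  }
  n_gap <- integer(n)
  if (nrow(aln$gaps)) n_gap <- as.integer(table(factor(aln$gaps$id, levels = ids)))
  has_unannot_gap <- n_gap > n_jn

  list(
    ends = data.frame(
      id = ids, qname = aln$ends$qname, sample_id = aln$ends$sample_id,
      end = aln$ends$end,
      first_start = first_start, last_end = last_end,
      overlaps_gene = overlaps_gene,
      touches_exon = touches_exon, touches_intron = touches_intron,
      crosses_boundary = crosses_boundary,
      all_exonic = all_exonic, single_exon = single_exon,
      within_intron = within_intron,
      n_junction = n_jn, has_unannot_gap = has_unannot_gap,
      stringsAsFactors = FALSE),
    junctions = junctions)
}
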