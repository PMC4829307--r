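#' Extract 4-nt splice-site contexts for events
#'
#' For every event two contexts are extracted on the transcribed strand:
#' the donor context (2 exon-side bases immediately upstream of the donor,
#' then the first 2 skipped bases -- GT for a canonical donor) and the
#' acceptor context (the last 2 skipped bases -- AG for a canonical
#' acceptor -- then 2 downstream bases). Minus-strand genes are
#' reverse-complemented so a canonical donor always reads "..GT" and a
#' canonical acceptor "AG..".
#'
#' @param events data.frame with `donor_pos`, `acceptor_pos`
#'   (transcript-sense genomic coordinates) and optionally `event_class`.
#' @param genome [Biostrings::DNAStringSet] containing `model$chrom`.
#' @param model a [gene_model()].
#' @return data.frame: one donor and one acceptor row per event, with
#'   `side`, `sequence` (4 uppercase bases), `event_class`. Sites within 2
#'   nt of a contig edge are skipped with a warning.
#' @export
extract_contexts <- function(events, genome, model) {
  chromseq <- toupper(as.character(genome[[model$chrom]]))
  n <- nchar(chromseq)
  grab <- function(a, b) substr(rep(chromseq, length(a)), a, b)
  plus <- model$strand == "+"
  d <- events$donor_pos; a <- events$acceptor_pos
  if (plus) {
    dseq <- grab(d - 2L, d + 1L)   # exon..GT
    aseq <- grab(a - 1L, a + 2L)   # AG..exon
    ok_d <- d - 2L >= 1L & d + 1L <= n
    ok_a <- a - 1L >= 1L & a + 2L <= n
  } else {
    dseq <- .revcomp_chr(grab(d - 1L, d + 2L))
    aseq <- .revcomp_chr(grab(a - 2L, a + 1L))
    ok_d <- d - 1L >= 1L & d + 2L <= n
    ok_a <- a - 2L >= 1L & a + 1L <= n
  }
  if (any(!ok_d | !ok_a))
    .warnf("%d site(s) within 2 nt of a contig edge skipped",
           sum(!ok_d) + sum(!ok_a))
  cls <- if ("event_class" %in% names(events)) events$event_class
  else rep(NA_character_, nrow(events))
  rbind(
    data.frame(event = which(ok_d), side = "donor", sequence = dseq[ok_d],
               event_class = cls[ok_d], stringsAsFactors = FALSE),
    data.frame(event = which(ok_a), side = "acceptor", sequence = aseq[ok_a],
               event_class = cls[ok_a], stringsAsFactors = FALSE))
}

#' Summarize splice-site motifs
#'
#' Builds, per side, a position-frequency matrix (4 positions x A/C/G/T,
#' columns summing to 1, no pseudocounts; ambiguity bases are tallied in a
#' separate `N` bucket and excluded from the canonical fractions), the
#' canonical fractions (donor GT, acceptor AG), and the donor-acceptor
#' dinucleotide pair table over the named canonical and common
#' non-canonical pairs.
#'
#' @param contexts output of [extract_contexts()].
#' @param classes optional event-class filter (e.g. `"nested"` or
#'   `c("5RS", "3RS")`).
#' @return list with `pfm` (list donor/acceptor of 5 x 4 matrices, rows
#'   A,C,G,T,N), `canonical` (named fractions `donor_GT`, `acceptor_AG`),
#'   `pair_table` (named fractions over pairs, summing to 1), `n_events`.
#'   Empty selections return `n_events = 0` with a warning.
#' @export
summarize_motifs <- function(contexts,
                             classes = NULL,
                             pairs = c("GT-AG", "GC-AG", "GT-TG", "GA-AG",
                                       "GT-AC", "AT-AG", "CT-AC")) {
  if (!is.null(classes))
    contexts <- contexts[contexts$event_class %in% classes, , drop = FALSE]
  don <- contexts[contexts$side == "donor", ]
  acc <- contexts[contexts$side == "acceptor", ]
  if (nrow(don) == 0L && nrow(acc) == 0L) {
    .warnf("no contexts in the selected class(es)")
    return(list(pfm = NULL, canonical = c(donor_GT = NA_real_,
                                          acceptor_AG = NA_real_),
                pair_table = NULL, n_events = 0L))
  }
  pfm_of <- function(seqs) {
    m <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
    full <- matrix(0, 5L, 4L, dimnames = list(c("A", "C", "G", "T", "N"),
                                              paste0("pos", 1:4)))
    for (b in rownames(m)) {
      row <- if (b %in% c("A", "C", "G", "T")) b else "N"
      full[row, ] <- full[row, ] + m[b, ]
    }
    sweep(full, 2L, colSums(full), `/`)
  }
  dinuc <- function(x, first) {
    y <- if (first) substr(x, 3L, 4L) else substr(x, 1L, 2L)
    y
  }
  d_dn <- dinuc(don$sequence, TRUE)     # skipped donor dinucleotide
  a_dn <- dinuc(acc$sequence, FALSE)    # skipped acceptor dinucleotide
  unambig_d <- !grepl("[^ACGT]", d_dn)
  unambig_a <- !grepl("[^ACGT]", a_dn)
  canonical <- c(
    donor_GT = if (any(unambig_d)) mean(d_dn[unambig_d] == "GT") else NA_real_,
    acceptor_AG = if (any(unambig_a)) mean(a_dn[unambig_a] == "AG") else NA_real_)

  pair_table <- NULL
  m <- match(acc$event, don$event)
  paired <- !is.na(m)
  if (any(paired)) {
    pr <- paste(d_dn[m[paired]], a_dn[paired], sep = "-")
    lab <- ifelse(pr %in% pairs, pr, "other")
    counts <- table(factor(lab, levels = c(pairs, "other")))
    pair_table <- counts / sum(counts)
  }
  list(pfm = list(donor = if (nrow(don)) pfm_of(don$sequence) else NULL,
                  acceptor = if (nrow(acc)) pfm_of(acc$sequence) else NULL),
       canonical = canonical,
       pair_table = pair_table,
       n_events = length(unique(contexts$event)))
}

#' Write a position-frequency matrix as TSV
#'
#' @param pfm matrix from [summarize_motifs()].
#' @param path output path.
#' @export
write_pfm <- function(pfm, path) {
  utils::write.table(data.frame(base = rownames(pfm), pfm),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
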