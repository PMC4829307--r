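# transcript-sense position of a genomic coordinate (1 = gene 5' end)
.tpos <- function(model, p) {
  if (model$strand == "+") p - model$span[[1L]] + 1L
  else model$span[[2L]] - p + 1L
}

.revcomp_chr <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# transcript-sense donor/acceptor dinucleotides of a skipped gap
# donor = first 2 skipped bases, acceptor = last 2 skipped bases (5'->3')
.gap_dinucs <- function(chromseq, strand, gs, ge) {
  if (strand == "+") {
    list(donor = substr(rep(chromseq, length(gs)), gs, gs + 1L),
         acceptor = substr(rep(chromseq, length(gs)), ge - 1L, ge))
  } else {
    list(donor = .revcomp_chr(substr(rep(chromseq, length(gs)), ge - 1L, ge)),
         acceptor = .revcomp_chr(substr(rep(chromseq, length(gs)), gs, gs + 1L)))
  }
}

#' Extract candidate split alignments (skip gaps) from aligned ends
#'
#' Each end of a pair is treated as a single-end read; every skip gap of at
#' least `min_gap` nt lying inside the gene span yields one candidate
#' record. Ends without gaps contribute nothing; multi-gap ends contribute
#' one record per gap. The gap floor separates short indel/NAGNAG artifacts
#' from splicing-sized gaps.
#'
#' @param aln an [alignment_table()].
#' @param model a [gene_model()].
#' @param min_gap minimum skipped length in nt (default 50).
#' @return data.frame: `id`, `qname`, `sample_id`, `gap_start`, `gap_end`
#'   (genomic first/last skipped base), `gap_len`.
#' @export
extract_split_reads <- function(aln, model, min_gap = 50L) {
  g <- aln$gaps
  if (nrow(g) == 0L)
    return(data.frame(id = integer(), qname = character(),
                      sample_id = character(), gap_start = integer(),
                      gap_end = integer(), gap_len = integer()))
  w <- g$end - g$start + 1L
  keep <- w >= min_gap & g$start >= model$span[[1L]] & g$end <= model$span[[2L]]
  g <- g[keep, , drop = FALSE]
  m <- match(g$id, aln$ends$id)
  data.frame(id = g$id, qname = aln$ends$qname[m],
             sample_id = aln$ends$sample_id[m],
             gap_start = g$start, gap_end = g$end,
             gap_len = g$end - g$start + 1L, row.names = NULL)
}

#' Refine ambiguous gap boundaries against the genome
#'
#' A junction flanked by identical sequence can slide without changing the
#' alignment. Among all placements within the ambiguity range the one whose
#' skipped ends look most like a canonical splice site is chosen: motif
#' score = matches of the first two skipped bases to GT plus matches of the
#' last two skipped bases to AG (transcript sense). Ties take the leftmost
#' (genomically smallest) placement; unambiguous gaps are returned
#' unchanged, and the score never decreases.
#'
#' @param splits output of [extract_split_reads()].
#' @param genome [Biostrings::DNAStringSet] covering the gene span.
#' @param model a [gene_model()].
#' @param max_shift cap on the explored shift range per side (default 10).
#' @return `splits` with refined `gap_start`/`gap_end`, the explored
#'   `shift_left`/`shift_right`, chosen `shift`, and `motif_score`.
#' @export
refine_gap_boundaries <- function(splits, genome, model, max_shift = 10L) {
  if (nrow(splits) == 0L) {
    splits$shift_left <- splits$shift_right <- splits$shift <- integer()
    splits$motif_score <- integer()
    return(splits)
  }
  chromseq <- as.character(genome[[model$chrom]])
  base_at <- function(p) substr(chromseq, p, p)
  res <- lapply(seq_len(nrow(splits)), function(k) {
    gs <- splits$gap_start[k]; ge <- splits$gap_end[k]
    L <- 0L
    while (L < max_shift && gs - L - 1L >= 1L &&
           base_at(gs - L - 1L) == base_at(ge - L)) L <- L + 1L
    R <- 0L
    while (R < max_shift && ge + R + 1L <= nchar(chromseq) &&
           base_at(gs + R) == base_at(ge + R + 1L)) R <- R + 1L
    shifts <- seq.int(-L, R)
    dn <- .gap_dinucs(chromseq, model$strand, gs + shifts, ge + shifts)
    score <- (substr(dn$donor, 1L, 1L) == "G") + (substr(dn$donor, 2L, 2L) == "T") +
      (substr(dn$acceptor, 1L, 1L) == "A") + (substr(dn$acceptor, 2L, 2L) == "G")
    best <- shifts[which.max(score)]  # ties: leftmost (smallest shift)
    c(L, R, best, max(score))
  })
  res <- do.call(rbind, res)
  splits$gap_start <- splits$gap_start + res[, 3L]
  splits$gap_end <- splits$gap_end + res[, 3L]
  splits$shift_left <- res[, 1L]
  splits$shift_right <- res[, 2L]
  splits$shift <- res[, 3L]
  splits$motif_score <- res[, 4L]
  splits
}

#' Filter candidate splits down to within-intron event candidates
#'
#' Retains only gaps lying entirely within one intron; discards gaps whose
#' donor and acceptor are both annotated splice sites (ordinary exon-exon
#' splicing), and gaps whose non-annotated site falls within
#' `boundary_margin` nt of either exon-intron boundary of that intron
#' (near-boundary artifacts such as NAGNAG variation).
#'
#' @param splits refined splits ([refine_gap_boundaries()]).
#' @param model a [gene_model()].
#' @param boundary_margin exclusion margin in nt (default 50).
#' @return the retained splits with `intron`, `donor_pos`, `acceptor_pos`
#'   (transcript-sense genomic coordinates), `donor_annotated`,
#'   `acceptor_annotated`.
#' @export
filter_split_events <- function(splits, model, boundary_margin = 50L) {
  if (model$strand == "+") {
    splits$donor_pos <- splits$gap_start
    splits$acceptor_pos <- splits$gap_end
  } else {
    splits$donor_pos <- splits$gap_end
    splits$acceptor_pos <- splits$gap_start
  }
  intron <- .intron_containing(model, splits$gap_start, splits$gap_end)
  splits$intron <- intron
  keep <- !is.na(intron)
  it <- model$introns[match(intron, model$introns$index), ]
  donor_annot <- splits$donor_pos == it$donor_site
  acceptor_annot <- splits$acceptor_pos == it$acceptor_site
  keep <- keep & !(donor_annot & acceptor_annot)
  near_edge <- function(p) {
    !is.na(p) & (pmin(p - it$start, it$end - p) < boundary_margin)
  }
  keep <- keep & !(!donor_annot & near_edge(splits$donor_pos))
  keep <- keep & !(!acceptor_annot & near_edge(splits$acceptor_pos))
  keep[is.na(keep)] <- FALSE
  splits$donor_annotated <- donor_annot
  splits$acceptor_annotated <- acceptor_annot
  splits[keep, , drop = FALSE]
}

#' Build per-cell-line donor x acceptor event matrices
#'
#' Read counts of libraries from the same cell line are summed before the
#' cross-line intersection.
#'
#' @param splits filtered splits ([filter_split_events()]).
#' @param cell_line_of named character vector mapping `sample_id` to cell
#'   line; by default every sample is its own line.
#' @return named list (one per cell line) of integer matrices with donor
#'   positions as rows and acceptor positions as columns.
#' @export
build_event_matrix <- function(splits, cell_line_of = NULL) {
  if (is.null(cell_line_of)) {
    s <- unique(splits$sample_id)
    cell_line_of <- setNames(s, s)
  }
  line <- unname(cell_line_of[splits$sample_id])
  donors <- sort(unique(splits$donor_pos))
  acceptors <- sort(unique(splits$acceptor_pos))
  lines <- sort(unique(unname(cell_line_of)))
  out <- lapply(lines, function(ln) {
    m <- matrix(0L, length(donors), length(acceptors),
                dimnames = list(donors, acceptors))
    sub <- splits[!is.na(line) & line == ln, , drop = FALSE]
    if (nrow(sub)) {
      tab <- table(factor(sub$donor_pos, levels = donors),
                   factor(sub$acceptor_pos, levels = acceptors))
      m[] <- as.integer(tab)
    }
    m
  })
  names(out) <- lines
  out
}

#' Intersect event matrices across cell lines
#'
#' An event is retained only when its (donor, acceptor) cell has at least
#' one supporting read in every cell line -- observations present in a
#' subset of lines are treated as putative PCR-duplicate artifacts.
#'
#' @param matrices list of matrices from [build_event_matrix()].
#' @return data.frame: `donor_pos`, `acceptor_pos`, one support column per
#'   cell line (`support_<line>`), `total_support`.
#' @export
intersect_samples <- function(matrices) {
  if (length(matrices) == 0L) .stopf("no samples")
  donors <- sort(unique(unlist(lapply(matrices, rownames))))
  acceptors <- sort(unique(unlist(lapply(matrices, colnames))))
  full <- lapply(matrices, function(m) {
    f <- matrix(0L, length(donors), length(acceptors),
                dimnames = list(donors, acceptors))
    if (nrow(m) && ncol(m)) f[rownames(m), colnames(m)] <- m
    f
  })
  present <- Reduce(`&`, lapply(full, function(m) m > 0L))
  idx <- which(present, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(donor_pos = integer(), acceptor_pos = integer(),
                      total_support = integer()))
  out <- data.frame(donor_pos = as.integer(donors[idx[, 1L]]),
                    acceptor_pos = as.integer(acceptors[idx[, 2L]]))
  for (ln in names(full))
    out[[paste0("support_", ln)]] <- full[[ln]][idx]
  out$total_support <- rowSums(as.matrix(out[grep("^support_", names(out))]))
  out[order(out$donor_pos, out$acceptor_pos), , drop = FALSE]
}

#' Classify splicing events as recursive or nested
#'
#' Within one intron: donor at the annotated 5' splice site with an
#' internal acceptor is a 5' recursive step (5RS); an internal donor with
#' the annotated 3' splice site is a 3' recursive step (3RS); two internal
#' sites make a nested event.
#'
#' @param events data.frame with `donor_pos`, `acceptor_pos`
#'   (transcript-sense genomic coordinates, e.g. from
#'   [intersect_samples()]).
#' @param model a [gene_model()].
#' @return `events` with `intron` and `event_class` columns added; events
#'   not contained in a single intron get `NA`.
#' @export
classify_event <- function(events, model) {
  gs <- pmin(events$donor_pos, events$acceptor_pos)
  ge <- pmax(events$donor_pos, events$acceptor_pos)
  intron <- .intron_containing(model, gs, ge)
  it <- model$introns[match(intron, model$introns$index), ]
  d_ann <- events$donor_pos == it$donor_site
  a_ann <- events$acceptor_pos == it$acceptor_site
  cls <- ifelse(d_ann & !a_ann, "5RS",
                ifelse(a_ann & !d_ann, "3RS",
                       ifelse(!d_ann & !a_ann, "nested", "annotated")))
  events$intron <- intron
  events$event_class <- ifelse(is.na(intron), NA_character_, cls)
  events
}

#' Detect intermezzo pairs among recursive events
#'
#' A 5RS step (acceptor `a1`) and a 3RS step (donor `d2`) in the same
#' intron with `d2` downstream of `a1` (transcript sense) bracket an
#' internal cassette of `d2 - a1 - 1` nt that is transiently joined to the
#' flanking exons; both member events are re-labeled "intermezzo". Multiple
#' pairs per intron are reported; co-occurring pairs are never merged.
#' Overlapping combinations (`d2 <= a1`) are not paired.
#'
#' @param events classified events ([classify_event()]).
#' @param model a [gene_model()].
#' @return list with `pairs` (intron, acceptor of the 5RS, donor of the
#'   3RS, retained_length) and `events` (input with members re-labeled).
#' @export
detect_intermezzo <- function(events, model) {
  pairs <- list()
  member <- logical(nrow(events))
  for (i in unique(events$intron[!is.na(events$intron)])) {
    e5 <- which(events$intron == i & events$event_class == "5RS")
    e3 <- which(events$intron == i & events$event_class == "3RS")
    for (k5 in e5) for (k3 in e3) {
      a1 <- events$acceptor_pos[k5]
      d2 <- events$donor_pos[k3]
      if (.tpos(model, d2) > .tpos(model, a1)) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          intron = i, rs5_acceptor = a1, rs3_donor = d2,
          retained_length = abs(d2 - a1) - 1L)
        member[c(k5, k3)] <- TRUE
      }
    }
  }
  events$event_class[member] <- "intermezzo"
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
    data.frame(intron = integer(), rs5_acceptor = integer(),
               rs3_donor = integer(), retained_length = integer()),
    events = events)
}

#' Per-intron splicing mode and gene-level summary
#'
#' An intron is called multi-step when at least one intersected event lies
#' within it, single-step otherwise. The summary compares intron lengths
#' between the two modes with a Wilcoxon rank-sum test.
#'
#' @param events classified (and intermezzo-resolved) events.
#' @param model a [gene_model()].
#' @return list with `per_intron` (intron, n_events, mode) and `summary`
#'   (counts, mean length per mode, rank-sum p-value).
#' @export
classify_intron_steps <- function(events, model) {
  N <- nrow(model$introns)
  n_events <- integer(N)
  tt <- table(events$intron[!is.na(events$intron)])
  n_events[as.integer(names(tt))] <- as.integer(tt)
  mode <- ifelse(n_events > 0L, "multi-step", "single-step")
  per_intron <- data.frame(intron = seq_len(N), n_events = n_events,
                           mode = mode)
  len <- model$introns$length
  multi <- mode == "multi-step"
  p <- if (any(multi) && any(!multi))
    suppressWarnings(stats::wilcox.test(len[multi], len[!multi])$p.value)
  else NA_real_
  list(per_intron = per_intron,
       summary = list(n_single = sum(!multi), n_multi = sum(multi),
                      mean_length_single = mean(len[!multi]),
                      mean_length_multi = mean(len[multi]),
                      wilcoxon_p = p))
}

#' Write / read the event table (TSV)
#'
#' @param events classified events data.frame.
#' @param path TSV path.
#' @return `path` (write) or the events data.frame (read).
#' @export
write_event_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
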