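#' Construct a single-transcript gene model
#'
#' The gene model is the coordinate authority for the whole pipeline: an
#' ordered set of exons for one transcript, with introns derived as the gaps
#' between consecutive exons. All coordinates are 1-based, fully closed,
#' genomic. Exon and intron indices follow transcript (5'->3') order, so
#' "intron n lies between exons n and n+1" holds on both strands.
#'
#' @param exons data.frame with columns `start` and `end` (genomic, 1-based
#'   closed), one row per exon, in any order.
#' @param gene_id character scalar identifier.
#' @param chrom chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param masks optional data.frame with `start`/`end` (1-based closed)
#'   giving regions excluded from coverage statistics; see [apply_masks()].
#' @return object of class `gene_model` with components `gene_id`, `chrom`,
#'   `strand`, `exons`, `introns`, `masks`, `span`. `exons` carries
#'   transcript-order `index`, `start`, `end`, `length`; `introns`
#'   additionally carries `donor_site` (first intronic base at the 5' splice
#'   site) and `acceptor_site` (last intronic base at the 3' splice site),
#'   both strand-aware.
#' @export
gene_model <- function(exons, gene_id = "gene", chrom = "chr1", strand = "+",
                       masks = NULL) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (!strand %in% c("+", "-")) .stopf("strand must be '+' or '-'")
  if (nrow(exons) < 2L) .stopf("gene model needs >= 2 exons")
  ex <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  ex$start <- as.integer(ex$start); ex$end <- as.integer(ex$end)
  if (any(ex$end < ex$start)) .stopf("malformed annotation: exon end < start")
  if (any(ex$start[-1L] <= ex$end[-nrow(ex)]))
    .stopf("malformed annotation: overlapping exons")
  # transcript order: genomic for '+', reversed for '-'
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex$index <- seq_len(nrow(ex))
  ex$length <- ex$end - ex$start + 1L
  rownames(ex) <- NULL

  E <- nrow(ex)
  if (strand == "+") {
    istart <- ex$end[-E] + 1L
    iend <- ex$start[-1L] - 1L
  } else {
    istart <- ex$end[-1L] + 1L
    iend <- ex$start[-E] - 1L
  }
  if (any(iend < istart)) .stopf("malformed annotation: zero-length intron")
  introns <- data.frame(
    index = seq_len(E - 1L),
    start = istart, end = iend,
    length = iend - istart + 1L
  )
  if (strand == "+") {
    introns$donor_site <- introns$start
    introns$acceptor_site <- introns$end
  } else {
    introns$donor_site <- introns$end
    introns$acceptor_site <- introns$start
  }
  model <- structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    exons = ex[, c("index", "start", "end", "length")],
    introns = introns,
    masks = data.frame(start = integer(), end = integer()),
    span = c(start = min(ex$start, introns$start),
             end = max(ex$end, introns$end))
  ), class = "gene_model")
  if (!is.null(masks)) model <- apply_masks(model, masks, zero_based = FALSE)
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s' (%s%s): %d exons, %d introns, span %d-%d (%d nt)\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), nrow(x$introns),
              x$span[1L], x$span[2L], x$span[2L] - x$span[1L] + 1L))
  if (nrow(x$masks)) cat(sprintf("  %d mask interval(s), %d nt masked\n",
                                 nrow(x$masks), sum(x$masks$end - x$masks$start + 1L)))
  invisible(x)
}

#' Accessors for gene model components
#' @param model a [gene_model()]
#' @return data.frame of exon or intron intervals in transcript order.
#' @export
exons <- function(model) model$exons

#' @rdname exons
#' @export
introns <- function(model) model$introns

#' Load a gene model from GFF3/GTF or BED12 annotation
#'
#' Reads an annotation file with `rtracklayer` and extracts the exon chain of
#' exactly one transcript for `gene_id`. Alternative isoforms are rejected:
#' the annotation must resolve to a single exon chain.
#'
#' @param path annotation file (`.gff3`, `.gff`, `.gtf`, or `.bed`).
#' @param gene_id gene or transcript identifier to extract.
#' @param format `"auto"` (by extension) or one of `"gff3"`, `"gtf"`, `"bed"`.
#' @return a [gene_model()].
#' @export
load_gene_model <- function(path, gene_id, format = "auto") {
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gff = "gff3", gff3 = "gff3", gtf = "gtf",
                     bed = "bed", .stopf("cannot guess format of '%s'", path))
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "bed") {
    gr <- gr[!is.na(gr$name) & gr$name == gene_id]
    if (length(gr) == 0L) .stopf("gene not found: '%s'", gene_id)
    if (length(gr) > 1L) .stopf("multiple records for '%s'; one isoform required", gene_id)
    blocks <- gr$blocks[[1L]]  # exon blocks relative to record start
    ex <- data.frame(
      start = GenomicRanges::start(gr) + IRanges::start(blocks) - 1L,
      end = GenomicRanges::start(gr) + IRanges::end(blocks) - 1L
    )
    return(gene_model(ex, gene_id = gene_id,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      strand = as.character(GenomicRanges::strand(gr))))
  }
  meta <- S4Vectors::mcols(gr)
  keep <- rep(FALSE, length(gr))
  for (fld in intersect(c("gene_id", "transcript_id", "Parent", "ID", "Name"),
                        names(meta))) {
    v <- meta[[fld]]
    if (methods::is(v, "List") || is.list(v)) {
      keep <- keep | vapply(v, function(z) any(as.character(z) == gene_id), logical(1))
    } else {
      keep <- keep | (!is.na(v) & as.character(v) == gene_id)
    }
  }
  gr <- gr[keep]
  gr <- gr[as.character(gr$type) == "exon"]
  if (length(gr) == 0L) .stopf("gene not found: '%s'", gene_id)
  tx <- NULL
  if ("transcript_id" %in% names(S4Vectors::mcols(gr))) tx <- gr$transcript_id
  if (is.null(tx) && "Parent" %in% names(S4Vectors::mcols(gr)))
    tx <- vapply(gr$Parent, function(z) as.character(z)[1L], character(1))
  if (!is.null(tx) && length(unique(tx)) > 1L)
    .stopf("gene '%s' has %d isoforms; one isoform required", gene_id,
           length(unique(tx)))
  str <- unique(as.character(GenomicRanges::strand(gr)))
  if (length(str) != 1L || !str %in% c("+", "-"))
    .stopf("malformed annotation: inconsistent or missing strand")
  gene_model(data.frame(start = GenomicRanges::start(gr),
                        end = GenomicRanges::end(gr)),
             gene_id = gene_id,
             chrom = as.character(GenomicRanges::seqnames(gr))[1L],
             strand = str)
}

#' Apply coverage masks to a gene model
#'
#' Masked positions (annotated promoters, UTRs, embedded RNAs, un-probed
#' regions) are excluded from all downstream coverage statistics. Masks do
#' not affect read-pair phase classification.
#'
#' @param model a [gene_model()].
#' @param masks data.frame with `start`/`end` columns, or a BED file path.
#' @param zero_based if `TRUE` (the BED convention, default for file input)
#'   intervals are 0-based half-open and converted internally.
#' @return the model with merged masks attached; intron `effective_length`
#'   (unmasked nt) is available via [effective_lengths()].
#' @export
apply_masks <- function(model, masks, zero_based = NULL) {
  stopifnot(inherits(model, "gene_model"))
  if (is.character(masks)) {
    if (is.null(zero_based)) zero_based <- TRUE
    bed <- utils::read.table(masks, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (nrow(bed) > 0L && ncol(bed) >= 3L) {
      bed <- bed[bed[[1L]] == model$chrom, , drop = FALSE]
    }
    masks <- data.frame(start = as.integer(bed[[2L]]),
                        end = as.integer(bed[[3L]]))
  }
  if (is.null(zero_based)) zero_based <- FALSE
  if (nrow(masks) > 0L && zero_based) {
    masks$start <- masks$start + 1L  # half-open end is already the closed end
  }
  if (nrow(masks) > 0L) {
    outside <- masks$end < model$span[1L] | masks$start > model$span[2L]
    if (any(outside)) {
      .warnf("%d mask interval(s) outside the gene span ignored", sum(outside))
      masks <- masks[!outside, , drop = FALSE]
    }
    masks$start <- pmax(masks$start, model$span[[1L]])
    masks$end <- pmin(masks$end, model$span[[2L]])
  }
  model$masks <- .merge_intervals(rbind(model$masks, masks))
  model
}

#' Unmasked (effective) lengths of gene features
#'
#' @param model a [gene_model()].
#' @param what `"introns"` or `"exons"`.
#' @return data.frame with `index`, `length`, `effective_length`, and
#'   `fully_masked` flag.
#' @export
effective_lengths <- function(model, what = c("introns", "exons")) {
  what <- match.arg(what)
  feat <- model[[what]]
  eff <- feat$length
  if (nrow(model$masks) > 0L) {
    for (i in seq_len(nrow(feat))) {
      eff[i] <- feat$length[i] -
        sum(.overlap_len(feat$start[i], feat$end[i],
                         model$masks$start, model$masks$end))
    }
  }
  data.frame(index = feat$index, length = feat$length,
             effective_length = eff, fully_masked = eff == 0L)
}

# logical vector over the gene span: TRUE where masked
.mask_vector <- function(model) {
  n <- model$span[[2L]] - model$span[[1L]] + 1L
  m <- logical(n)
  if (nrow(model$masks) > 0L) {
    for (i in seq_len(nrow(model$masks))) {
      a <- model$masks$start[i] - model$span[[1L]] + 1L
      b <- model$masks$end[i] - model$span[[1L]] + 1L
      m[a:b] <- TRUE
    }
  }
  m
}

#' Locate genomic positions within the gene model
#'
#' @param model a [gene_model()].
#' @param pos integer vector of genomic positions.
#' @return data.frame with `pos`, `feature` (`"exon"`, `"intron"`, or
#'   `"outside"`) and transcript-order `index` (NA outside the gene).
#' @export
locate_positions <- function(model, pos) {
  feature <- rep("outside", length(pos))
  index <- rep(NA_integer_, length(pos))
  for (nm in c("exons", "introns")) {
    f <- model[[nm]]
    hit <- outer(pos, f$start, ">=") & outer(pos, f$end, "<=")
    w <- which(hit, arr.ind = TRUE)
    if (nrow(w)) {
      feature[w[, 1L]] <- sub("s$", "", nm)
      index[w[, 1L]] <- f$index[w[, 2L]]
    }
  }
  data.frame(pos = pos, feature = feature, index = index)
}

# intron index containing BOTH positions (same intron), else NA; vectorized
.intron_containing <- function(model, p1, p2) {
  it <- model$introns
  out <- rep(NA_integer_, length(p1))
  for (i in seq_len(nrow(it))) {
    inside <- p1 >= it$start[i] & p1 <= it$end[i] &
      p2 >= it$start[i] & p2 <= it$end[i]
    out[inside] <- it$index[i]
  }
  out
}

#' Write / read a gene model as BED12
#'
#' Round-trips exactly: `load_gene_model(write_bed12(m, f), m$gene_id)`
#' reproduces the coordinates of `m`.
#'
#' @param model a [gene_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(model, path) {
  ex <- model$exons[order(model$exons$start), ]
  chrom_start <- min(ex$start) - 1L  # BED is 0-based half-open
  line <- paste(
    model$chrom, chrom_start, max(ex$end), model$gene_id, 0L, model$strand,
    chrom_start, max(ex$end), "0", nrow(ex),
    paste0(paste(ex$length, collapse = ","), ","),
    paste0(paste(ex$start - 1L - chrom_start, collapse = ","), ","),
    sep = "\t")
  writeLines(line, path)
  invisible(path)
}

#' Dump the gene model feature table
#'
#' One row per exon and intron with raw and effective (unmasked) lengths.
#'
#' @param model a [gene_model()].
#' @param path optional TSV output path.
#' @return the table, invisibly if written to file.
#' @export
model_table <- function(model, path = NULL) {
  exl <- effective_lengths(model, "exons")
  inl <- effective_lengths(model, "introns")
  tab <- rbind(
    data.frame(feature = "exon", index = model$exons$index,
               start = model$exons$start, end = model$exons$end,
               length = model$exons$length,
               effective_length = exl$effective_length),
    data.frame(feature = "intron", index = model$introns$index,
               start = model$introns$start, end = model$introns$end,
               length = model$introns$length,
               effective_length = inl$effective_length))
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
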