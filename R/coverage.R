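#' Per-base coverage over the gene span
#'
#' Depth is computed from aligned blocks only (skip gaps contribute
#' nothing), as an integer vector over the gene span. Positions with zero
#' depth are retained.
#'
#' @param aln an [alignment_table()].
#' @param model a [gene_model()].
#' @param sample_id restrict to one sample (default: all ends in `aln`).
#' @return integer vector of length `span`, named attribute `offset` giving
#'   the genomic coordinate of element 1.
#' @export
gene_coverage <- function(aln, model, sample_id = NULL) {
  bl <- aln$blocks
  if (!is.null(sample_id)) {
    ids <- aln$ends$id[aln$ends$sample_id %in% sample_id]
    bl <- bl[bl$id %in% ids, ]
  }
  off <- model$span[[1L]]
  n <- model$span[[2L]] - off + 1L
  s <- pmax(bl$start, off) - off + 1L
  e <- pmin(bl$end, model$span[[2L]]) - off + 1L
  keep <- e >= s & s <= n & e >= 1L
  cov <- as.integer(IRanges::coverage(IRanges::IRanges(s[keep], e[keep]),
                                      width = n))
  attr(cov, "offset") <- off
  cov
}

#' Median coverage of a feature profile
#'
#' Median depth over the unmasked positions of a feature, zero-depth
#' positions included. Even-length profiles take the mean of the central
#' pair (the usual [stats::median()] convention).
#'
#' @param depths non-negative integer vector of per-position depths
#'   (already restricted to unmasked positions).
#' @return the median depth.
#' @export
median_feature_coverage <- function(depths) {
  if (length(depths) == 0L) .stopf("no coverage basis: feature fully masked")
  stats::median(depths)
}

#' Raw median coverage per exon and intron
#'
#' @param cov per-base coverage from [gene_coverage()].
#' @param model a [gene_model()]; masked positions are skipped.
#' @return data.frame: `feature`, `index`, `raw_median` (NA with
#'   `fully_masked = TRUE` when no unmasked position remains).
#' @export
feature_medians <- function(cov, model) {
  off <- attr(cov, "offset") %||% model$span[[1L]]
  maskv <- .mask_vector(model)
  one <- function(feature, f) {
    a <- f$start - off + 1L; b <- f$end - off + 1L
    med <- rep(NA_real_, nrow(f)); fm <- logical(nrow(f))
    for (i in seq_len(nrow(f))) {
      idx <- a[i]:b[i]
      idx <- idx[!maskv[idx]]
      if (length(idx) == 0L) fm[i] <- TRUE else med[i] <- stats::median(cov[idx])
    }
    data.frame(feature = feature, index = f$index, raw_median = med,
               fully_masked = fm)
  }
  rbind(one("exon", model$exons), one("intron", model$introns))
}

#' Mean exon coverage of a sample
#'
#' Mean depth over all unmasked exonic positions; the per-sample
#' normalization basis.
#'
#' @inheritParams feature_medians
#' @return a single number.
#' @export
exon_mean_coverage <- function(cov, model) {
  off <- attr(cov, "offset") %||% model$span[[1L]]
  maskv <- .mask_vector(model)
  idx <- unlist(lapply(seq_len(nrow(model$exons)), function(i) {
    v <- (model$exons$start[i]:model$exons$end[i]) - off + 1L
    v[!maskv[v]]
  }))
  if (length(idx) == 0L) .stopf("no unmasked exonic positions")
  mean(cov[idx])
}

#' Cross-sample coverage normalization
#'
#' Each sample's medians are rescaled into common read-depth units:
#' `normalized(s, f) = raw_median(s, f) * grand_mean / exon_mean(s)`, where
#' `grand_mean` is the average of the per-sample mean exon coverages. A
#' sample whose depths are all multiplied by a constant therefore keeps
#' identical normalized values, and a single sample is returned unchanged.
#'
#' @param raw_medians numeric matrix, features x samples.
#' @param exon_means numeric vector of per-sample mean exon coverage.
#' @return list with `normalized` (matrix, features x samples) and
#'   `cross_sample_mean` (per-feature average over samples).
#' @export
normalize_coverage <- function(raw_medians, exon_means) {
  raw_medians <- as.matrix(raw_medians)
  if (ncol(raw_medians) != length(exon_means))
    .stopf("one exon mean per sample required")
  if (any(exon_means <= 0))
    .stopf("sample rejected: zero exon coverage")
  grand <- mean(exon_means)
  normalized <- sweep(raw_medians, 2L, grand / exon_means, `*`)
  list(normalized = normalized,
       cross_sample_mean = rowMeans(normalized))
}

# shared OLS helper: y on x, two-sided slope p-value
.ols_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2L)
    return(list(slope = NA_real_, p_value = NA_real_, degenerate = TRUE,
                n = length(x)))
  if (length(x) < 3L)  # exact line through two points; p undefined
    return(list(slope = diff(y) / diff(x), p_value = NA_real_,
                degenerate = TRUE, n = length(x)))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  slope <- unname(sm["x", "Estimate"])
  p <- if (nrow(sm) >= 2L && !is.nan(sm["x", "Pr(>|t|)"]))
    unname(sm["x", "Pr(>|t|)"]) else NA_real_
  list(slope = slope, p_value = p, degenerate = !is.finite(p), n = length(x))
}

#' GC-content bias diagnostic
#'
#' Ordinary least squares of median feature coverage on GC fraction. The
#' pipeline proceeds without GC correction when `p >= 0.05` and logs a
#' warning otherwise.
#'
#' @param gc_fraction per-feature GC fraction in \[0, 1\].
#' @param medians per-feature median coverage.
#' @return list(slope, p_value, degenerate, n).
#' @export
gc_bias_regression <- function(gc_fraction, medians) {
  res <- .ols_regression(gc_fraction, medians)
  if (!res$degenerate && res$p_value < 0.05)
    .warnf("significant GC-coverage association (p = %.3g); proceeding uncorrected",
           res$p_value)
  res
}

#' 5'-3' positional bias diagnostic
#'
#' OLS of normalized intron medians on intron index (1..N). A significantly
#' negative slope is the signature of post-transcriptional splicing under
#' continuous initiation (nascent transcripts over-represent the 5' end);
#' its absence supports co-transcriptional splicing.
#'
#' @param normalized_medians per-intron normalized median coverage, in
#'   transcript order.
#' @return list(slope, p_value, degenerate, n).
#' @export
positional_bias_regression <- function(normalized_medians) {
  .ols_regression(seq_along(normalized_medians), normalized_medians)
}

#' GC fraction of gene features
#'
#' @param model a [gene_model()].
#' @param genome a [Biostrings::DNAStringSet] containing `model$chrom`.
#' @return data.frame feature/index/gc_fraction.
#' @export
feature_gc <- function(model, genome) {
  chrom <- genome[[model$chrom]]
  one <- function(feature, f) {
    gc <- vapply(seq_len(nrow(f)), function(i) {
      fr <- Biostrings::letterFrequency(
        Biostrings::subseq(chrom, f$start[i], f$end[i]), c("G", "C"))
      sum(fr) / f$length[i]
    }, numeric(1))
    data.frame(feature = feature, index = f$index, gc_fraction = gc)
  }
  rbind(one("exon", model$exons), one("intron", model$introns))
}

#' Classify intron splicing speed from normalized coverage
#'
#' Global cutoffs assign the class: fast (`< cutoffs[1]`), slow
#' (`> cutoffs[2]`), intermediate otherwise. Sliding windows (size 5, step
#' 3 by default, final partial window allowed) report the relative ranking
#' of their members; with 78 introns this yields 26 windows.
#'
#' @param values cross-sample mean normalized median per intron, transcript
#'   order.
#' @param cutoffs fast/slow depth cutoffs, default `c(90, 130)`.
#' @param window,step sliding-window geometry.
#' @return data.frame intron/value/speed_class with a `windows` attribute
#'   (window id, first/last intron, within-window rank string).
#' @export
classify_intron_speed <- function(values, cutoffs = c(90, 130),
                                  window = 5L, step = 3L) {
  n <- length(values)
  if (n < window) .stopf("need at least %d introns", window)
  speed <- ifelse(values < cutoffs[1L], "fast",
                  ifelse(values > cutoffs[2L], "slow", "intermediate"))
  starts <- seq(1L, n, by = step)
  starts <- starts[starts <= n - 1L]  # a window needs >= 2 members
  windows <- do.call(rbind, lapply(seq_along(starts), function(w) {
    ix <- starts[w]:min(starts[w] + window - 1L, n)
    data.frame(window = w, first = ix[1L], last = ix[length(ix)],
               ranking = paste(ix[order(values[ix])], collapse = ","))
  }))
  out <- data.frame(intron = seq_len(n), value = values, speed_class = speed)
  attr(out, "windows") <- windows
  out
}

#' Flag coverage-spike outlier introns
#'
#' An intron whose unmasked profile still carries a local spike (95th
#' percentile over median) above `spike_ratio` is flagged and excluded from
#' regressions.
#'
#' @param cov per-base coverage ([gene_coverage()]).
#' @param model a [gene_model()].
#' @param spike_ratio flag threshold (default 5).
#' @return logical vector, one element per intron.
#' @export
flag_outlier_introns <- function(cov, model, spike_ratio = 5) {
  off <- attr(cov, "offset") %||% model$span[[1L]]
  maskv <- .mask_vector(model)
  vapply(seq_len(nrow(model$introns)), function(i) {
    idx <- (model$introns$start[i]:model$introns$end[i]) - off + 1L
    idx <- idx[!maskv[idx]]
    if (length(idx) == 0L) return(FALSE)
    v <- cov[idx]
    med <- stats::median(v)
    if (med <= 0) return(FALSE)
    unname(stats::quantile(v, 0.95) / med) > spike_ratio
  }, logical(1))
}

#' Analytic fold coverage of the gene
#'
#' Expected average per-position depth given a read yield:
#' `n_reads * n_ends * read_length / span`.
#'
#' @param n_reads number of read pairs mapped to the gene.
#' @param read_length nt per end (default 100).
#' @param n_ends ends per pair (default 2).
#' @param span gene length in nt.
#' @return fold coverage (a single number).
#' @export
fold_coverage <- function(n_reads, read_length = 100, n_ends = 2, span) {
  n_reads * n_ends * read_length / span
}

#' Replicate coverage correlation on log scale
#'
#' Pearson correlation of two samples' per-intron medians after `log10(x +
#' 1)` transform (the +1 keeps zero-coverage introns defined).
#'
#' @param m1,m2 per-intron medians of the two replicates.
#' @return list(r, p_value, n).
#' @export
replicate_correlation <- function(m1, m2) {
  keep <- is.finite(m1) & is.finite(m2)
  ct <- stats::cor.test(log10(m1[keep] + 1), log10(m2[keep] + 1),
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(keep))
}

#' Reject samples below the mapped-read yield floor
#'
#' @param n_mapped named vector: reads mapped to the gene per sample.
#' @param min_reads floor (default 500000).
#' @return character vector of retained sample names; rejected ones warned.
#' @export
filter_samples <- function(n_mapped, min_reads = 5e5) {
  bad <- n_mapped <= min_reads
  if (any(bad))
    .warnf("sample(s) below %d gene-mapped reads excluded: %s", min_reads,
           paste(names(n_mapped)[bad], collapse = ", "))
  names(n_mapped)[!bad]
}
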