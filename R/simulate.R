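#' Simulation configuration
#'
#' Defaults mirror the capture pre-mRNA sequencing study design: 2 x 100 nt
#' paired reads from fragments uniform in 250-650 nt (expected insert about
#' 400 nt), transcription at 2.4 kb/min, internal exon sizes 32-275 nt, and
#' canonical GT/AG at every annotated and planted splice site. Intron
#' removal follows a kinetic model: an intron (or multi-step segment)
#' becomes eligible once its 3' end is transcribed and completes after an
#' exponential waiting time with the intron's removal rate. The snapshot is
#' a steady-state population under constant initiation.
#'
#' @param n_introns number of introns (exons = n_introns + 1).
#' @param exon_length_range internal exon size range, nt.
#' @param intron_length_range intron size range, nt (log-uniform draw).
#' @param elongation_rate transcription speed, kb/min.
#' @param removal_rate per-intron removal rate (1/min once eligible);
#'   scalar or length-`n_introns` vector. Slower rate = higher coverage.
#' @param planted_events data.frame(intron, class, off1, off2): class one
#'   of "5RS" (off1 = internal acceptor offset within the intron), "3RS"
#'   (off1 = internal donor offset), "nested" (off1 donor, off2 acceptor),
#'   "intermezzo" (off1 = first-part acceptor, off2 = last-part donor).
#'   Offsets are 1-based within the intron, transcript sense, and must stay
#'   >= 50 nt from the intron boundaries.
#' @param canonical_event_sites plant GT/AG at event sites (default TRUE;
#'   FALSE plants CC/TT for motif-negative tests).
#' @param fragment_range,read_length,expected_insert library geometry, nt.
#' @param n_molecules molecules in the snapshot population.
#' @param n_pairs read pairs emitted per sample.
#' @param residence_factor snapshot window as a multiple of total
#'   transcription time (>1 admits fully transcribed, still-maturing
#'   molecules).
#' @param mature emit from fully transcribed, fully spliced molecules only.
#' @param post_transcriptional introns become eligible only after the whole
#'   gene is transcribed (post-transcriptional splicing null model).
#' @param flank flanking sequence either side of the gene, nt.
#' @param chrom,gene_id,strand gene placement.
#' @param seed RNG seed; fully determines all outputs.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(n_introns = 20L,
                              exon_length_range = c(32L, 275L),
                              intron_length_range = c(500L, 5000L),
                              elongation_rate = 2.4,
                              removal_rate = 0.2,
                              planted_events = NULL,
                              canonical_event_sites = TRUE,
                              fragment_range = c(250L, 650L),
                              read_length = 100L,
                              expected_insert = 400L,
                              insert_sd = 100L,
                              n_molecules = 2000L,
                              n_pairs = 20000L,
                              residence_factor = 1.5,
                              mature = FALSE,
                              post_transcriptional = FALSE,
                              flank = 1000L,
                              chrom = "chrSim", gene_id = "simgene",
                              strand = "+", seed = 1L) {
  stopifnot(n_introns >= 1L, all(exon_length_range > 0L),
            all(intron_length_range > 0L), elongation_rate > 0)
  removal_rate <- rep_len(removal_rate, n_introns)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a gene model and genome sequence
#'
#' Draws exon and intron lengths, lays the gene on a synthetic contig, and
#' plants canonical GT/AG dinucleotides at every annotated splice site and
#' (by default) at every planted event site. Identical seeds give
#' byte-identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `model` (a [gene_model()]), `genome`
#'   ([Biostrings::DNAStringSet]), and `truth_events` (planted observable
#'   gaps: intron, class, donor_pos, acceptor_pos, genomic transcript-sense
#'   coordinates; intermezzo plants contribute their two member steps).
#' @export
simulate_gene <- function(config) {
  set.seed(config$seed)
  nI <- config$n_introns
  exl <- sample(config$exon_length_range[1L]:config$exon_length_range[2L],
                nI + 1L, replace = TRUE)
  lr <- log(as.numeric(config$intron_length_range))
  inl <- pmax(150L, as.integer(round(exp(runif(nI, lr[1L], lr[2L])))))

  # transcript-space layout (1 = gene 5' end)
  starts_ex <- integer(nI + 1L); starts_in <- integer(nI)
  pos <- 1L
  for (i in seq_len(nI + 1L)) {
    starts_ex[i] <- pos; pos <- pos + exl[i]
    if (i <= nI) { starts_in[i] <- pos; pos <- pos + inl[i] }
  }
  G <- pos - 1L
  glen <- G + 2L * config$flank
  seqv <- sample(c("A", "C", "G", "T"), glen, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3))
  off <- config$flank  # transcript pos t -> contig index off + t
  tin_start <- starts_in; tin_end <- starts_in + inl - 1L
  for (i in seq_len(nI)) {
    seqv[off + tin_start[i] + 0:1] <- c("G", "T")
    seqv[off + tin_end[i] - 1:0] <- c("A", "G")
  }

  ev <- config$planted_events
  truth <- list()
  site_don <- if (config$canonical_event_sites) c("G", "T") else c("C", "C")
  site_acc <- if (config$canonical_event_sites) c("A", "G") else c("T", "T")
  if (!is.null(ev) && nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      i <- ev$intron[k]; cls <- ev$class[k]
      o1 <- ev$off1[k]; o2 <- if ("off2" %in% names(ev)) ev$off2[k] else NA
      lims <- c(50L, inl[i] - 50L + 1L)
      offs <- c(o1, if (!is.na(o2)) o2)
      if (any(offs <= lims[1L] | offs >= lims[2L]))
        .stopf("planted event site too close to intron %d boundary", i)
      p <- function(o) tin_start[i] + o - 1L  # transcript pos of offset o
      if (cls == "5RS") {
        seqv[off + p(o1) - 1:0] <- site_acc
        truth[[length(truth) + 1L]] <- data.frame(
          intron = i, class = "5RS", t_donor = tin_start[i], t_acceptor = p(o1))
      } else if (cls == "3RS") {
        seqv[off + p(o1) + 0:1] <- site_don
        truth[[length(truth) + 1L]] <- data.frame(
          intron = i, class = "3RS", t_donor = p(o1), t_acceptor = tin_end[i])
      } else if (cls == "nested") {
        seqv[off + p(o1) + 0:1] <- site_don
        seqv[off + p(o2) - 1:0] <- site_acc
        truth[[length(truth) + 1L]] <- data.frame(
          intron = i, class = "nested", t_donor = p(o1), t_acceptor = p(o2))
      } else if (cls == "intermezzo") {
        if (is.na(o2) || o2 <= o1 + 1L)
          .stopf("intermezzo needs off2 > off1 + 1 in intron %d", i)
        seqv[off + p(o1) - 1:0] <- site_acc
        seqv[off + p(o2) + 0:1] <- site_don
        truth[[length(truth) + 1L]] <- data.frame(
          intron = i, class = c("intermezzo", "intermezzo"),
          t_donor = c(tin_start[i], p(o2)), t_acceptor = c(p(o1), tin_end[i]))
      } else .stopf("unknown event class '%s'", cls)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(intron = integer(), class = character(),
               t_donor = integer(), t_acceptor = integer())

  # place on the contig; '-' strand mirrors the contig
  if (config$strand == "+") {
    g_of_t <- function(t) off + t
    genome_seq <- paste(seqv, collapse = "")
  } else {
    g_of_t <- function(t) glen - (off + t) + 1L
    genome_seq <- paste(chartr("ACGT", "TGCA", rev(seqv)), collapse = "")
  }
  ex <- data.frame(start = pmin(g_of_t(starts_ex), g_of_t(starts_ex + exl - 1L)),
                   end = pmax(g_of_t(starts_ex), g_of_t(starts_ex + exl - 1L)))
  model <- gene_model(ex, gene_id = config$gene_id, chrom = config$chrom,
                      strand = config$strand)
  genome <- Biostrings::DNAStringSet(genome_seq)
  names(genome) <- config$chrom
  truth$donor_pos <- g_of_t(truth$t_donor)
  truth$acceptor_pos <- g_of_t(truth$t_acceptor)
  list(model = model, genome = genome, truth_events = truth,
       t_intron_start = tin_start, t_intron_end = tin_end, t_len = G)
}

# per-intron multi-step path in transcript coordinates: list of steps, each
# a matrix of cumulative removed regions (cols start, end)
.intron_paths <- function(gene, config) {
  nI <- config$n_introns
  ts <- gene$t_intron_start; te <- gene$t_intron_end
  paths <- lapply(seq_len(nI), function(i)
    list(cbind(start = ts[i], end = te[i])))
  ev <- gene$truth_events
  if (nrow(ev)) {
    for (i in unique(ev$intron)) {
      steps <- ev[ev$intron == i, , drop = FALSE]
      steps <- steps[order(steps$t_donor), , drop = FALSE]
      cum <- NULL; out <- list()
      for (k in seq_len(nrow(steps))) {
        cum <- rbind(cum, cbind(start = steps$t_donor[k],
                                end = steps$t_acceptor[k]))
        out[[k]] <- cum
      }
      out[[length(out) + 1L]] <- cbind(start = ts[i], end = te[i])
      paths[[i]] <- out
    }
  }
  paths
}

#' Simulate a nascent-transcript population
#'
#' Constant-rate initiation puts molecule ages uniform over a window of
#' `residence_factor` times the total transcription time; the transcribed
#' length is age times the elongation rate, capped at the gene length. Each
#' intron step becomes eligible when the 3' end of its removed segment is
#' transcribed and the previous step is complete, then finishes after an
#' exponential wait at the intron's removal rate.
#'
#' @param gene output of [simulate_gene()].
#' @param config the same [simulation_config()].
#' @param n_molecules override `config$n_molecules`.
#' @param seed override RNG seed (defaults to `config$seed + 1`).
#' @return list: `molecules` (mol, age, tlen), `removed` (mol, start, end
#'   in transcript coords, intron, full-intron flag) at the snapshot, and
#'   `removal_time` (molecules x introns matrix of absolute final-removal
#'   times; snapshot is time 0, future removals are positive).
#' @export
simulate_transcripts <- function(gene, config, n_molecules = NULL,
                                 seed = NULL) {
  set.seed(seed %||% (config$seed + 1L))
  n <- n_molecules %||% config$n_molecules
  G <- gene$t_len
  rate_nt <- config$elongation_rate * 1000
  T_total <- G / rate_nt
  if (config$mature) {
    age <- rep(config$residence_factor * T_total, n)
    tlen <- rep(G, n)
  } else {
    age <- runif(n, 0, config$residence_factor * T_total)
    tlen <- pmin(G, pmax(1L, as.integer(floor(age * rate_nt))))
  }
  paths <- .intron_paths(gene, config)
  nI <- config$n_introns
  removal_time <- matrix(NA_real_, n, nI)
  removed <- vector("list", nI)
  for (i in seq_len(nI)) {
    steps <- paths[[i]]
    K <- length(steps)
    cc <- matrix(NA_real_, n, K)
    prev <- rep(-Inf, n)
    for (k in seq_len(K)) {
      e_k <- max(steps[[k]][, "end"])
      elig_pos <- if (config$post_transcriptional) G else e_k
      elig <- elig_pos / rate_nt - age
      if (config$mature) {
        cc[, k] <- -1  # already complete at snapshot
      } else {
        cc[, k] <- pmax(elig, prev) + rexp(n, config$removal_rate[i])
      }
      prev <- cc[, k]
    }
    removal_time[, i] <- cc[, K]
    k_star <- rowSums(cc <= 0)
    reg <- lapply(which(k_star > 0L), function(m) {
      r <- steps[[k_star[m]]]
      data.frame(mol = m, start = r[, "start"], end = r[, "end"],
                 intron = i,
                 full = r[, "start"] == gene$t_intron_start[i] &
                   r[, "end"] == gene$t_intron_end[i])
    })
    removed[[i]] <- if (length(reg)) do.call(rbind, reg) else NULL
  }
  removed <- do.call(rbind, removed[!vapply(removed, is.null, logical(1))])
  if (is.null(removed))
    removed <- data.frame(mol = integer(), start = integer(),
                          end = integer(), intron = integer(),
                          full = logical())
  list(molecules = data.frame(mol = seq_len(n), age = age, tlen = tlen),
       removed = removed[order(removed$mol, removed$start), , drop = FALSE],
       removal_time = removal_time)
}

#' Analytic two-intron exponential race probability
#'
#' Probability that intron 1 (eligible at time 0, rate `k1`) is removed
#' before intron 2 (eligible `delta` minutes later, rate `k2`):
#' `(1 - exp(-k1 delta)) + exp(-k1 delta) * k1 / (k1 + k2)`.
#'
#' @param k1,k2 removal rates, 1/min.
#' @param delta eligibility lag of intron 2, min (>= 0).
#' @return probability in \[0, 1\].
#' @export
race_probability <- function(k1, k2, delta) {
  (1 - exp(-k1 * delta)) + exp(-k1 * delta) * k1 / (k1 + k2)
}

#' Emit paired-end reads from the simulated population
#'
#' Fragments are drawn uniformly along each molecule's spliced structure
#' (molecules sampled proportional to their current length), with fragment
#' lengths uniform over `fragment_range`; 100-nt ends are taken from both
#' fragment extremities and mapped back to genomic blocks, skip gaps
#' appearing at every removed segment. Molecules shorter than the read
#' length are skipped.
#'
#' @param gene [simulate_gene()] output.
#' @param sim [simulate_transcripts()] output.
#' @param config the [simulation_config()].
#' @param sample_id sample label.
#' @param n_pairs override `config$n_pairs`.
#' @param seed override RNG seed (defaults to `config$seed + 2`).
#' @return list: `aln` (an [alignment_table()]) and `truth` (per-pair
#'   `pairs` with generator-side phase labels, and `gaps`: every emitted
#'   skip gap with its source segment and full-intron flag).
#' @export
emit_read_pairs <- function(gene, sim, config, sample_id = "sample1",
                            n_pairs = NULL, seed = NULL) {
  set.seed(seed %||% (config$seed + 2L))
  n_pairs <- n_pairs %||% config$n_pairs
  rl <- config$read_length
  mols <- sim$molecules
  n <- nrow(mols)

  # kept blocks per molecule, transcript coords: vectorized complement of
  # the (disjoint, sorted) removed regions within [1, tlen]
  r <- sim$removed
  mols_s <- c(seq_len(n), r$mol)
  starts_all <- c(rep(1L, n), r$end + 1L)
  ord_s <- order(mols_s, starts_all)
  mols_e <- c(r$mol, seq_len(n))
  ends_all <- c(r$start - 1L, mols$tlen)
  ord_e <- order(mols_e, ends_all)
  bdf <- data.frame(mol = mols_s[ord_s], start = starts_all[ord_s],
                    end = ends_all[ord_e])
  bdf <- bdf[bdf$end >= bdf$start, , drop = FALSE]
  w <- bdf$end - bdf$start + 1L
  mlen <- as.numeric(tapply(w, factor(bdf$mol, levels = seq_len(n)), sum))
  mlen[is.na(mlen)] <- 0
  # molecule-coordinate layout of each block
  ord <- order(bdf$mol, bdf$start)
  bdf <- bdf[ord, ]; w <- w[ord]
  mstart <- unlist(lapply(split(w, bdf$mol), function(z) cumsum(z) - z + 1L),
                   use.names = FALSE)
  bdf$mstart <- mstart
  bdf$mend <- mstart + w - 1L

  eligible <- which(mlen >= rl)
  if (length(eligible) == 0L) .stopf("no molecule long enough for reads")
  pick <- sample(eligible, n_pairs, replace = TRUE,
                 prob = mlen[eligible] / sum(mlen[eligible]))
  flen <- sample(config$fragment_range[1L]:config$fragment_range[2L],
                 n_pairs, replace = TRUE)
  flen <- pmin(flen, as.integer(mlen[pick]))
  fstart <- as.integer(floor(runif(n_pairs) * (mlen[pick] - flen + 1))) + 1L
  relen <- pmin(rl, flen)
  r1a <- fstart; r1b <- fstart + relen - 1L
  r2b <- fstart + flen - 1L; r2a <- r2b - relen + 1L

  # disjoint global molecule-coordinate space for vectorized mapping
  moff <- cumsum(c(0, mlen))[seq_len(n)]
  reads <- data.frame(
    rid = seq_len(2L * n_pairs),
    pair = rep(seq_len(n_pairs), 2L),
    end = rep(c(1L, 2L), each = n_pairs),
    mol = rep(pick, 2L),
    a = c(r1a, r2a), b = c(r1b, r2b))
  rir <- IRanges::IRanges(moff[reads$mol] + reads$a, moff[reads$mol] + reads$b)
  bir <- IRanges::IRanges(moff[bdf$mol] + bdf$mstart, moff[bdf$mol] + bdf$mend)
  hits <- IRanges::findOverlaps(rir, bir)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  seg_m1 <- pmax(IRanges::start(rir)[qh], IRanges::start(bir)[sh])
  seg_m2 <- pmin(IRanges::end(rir)[qh], IRanges::end(bir)[sh])
  # transcript coords of each read sub-block
  t1 <- bdf$start[sh] + (seg_m1 - (moff[bdf$mol[sh]] + bdf$mstart[sh]))
  t2 <- t1 + (seg_m2 - seg_m1)
  rb <- data.frame(rid = reads$rid[qh], tstart = t1, tend = t2)
  rb <- rb[order(rb$rid, rb$tstart), ]

  # genomic conversion
  span <- gene$model$span
  if (config$strand == "+") {
    gstart <- span[[1L]] + rb$tstart - 1L
    gend <- span[[1L]] + rb$tend - 1L
  } else {
    gstart <- span[[2L]] - rb$tend + 1L
    gend <- span[[2L]] - rb$tstart + 1L
  }
  blocks <- data.frame(id = rb$rid, start = gstart, end = gend)
  blocks <- blocks[order(blocks$id, blocks$start), ]
  # gaps between consecutive blocks of the same read
  gsame <- which(diff(blocks$id) == 0L)
  gaps <- data.frame(id = blocks$id[gsame],
                     start = blocks$end[gsame] + 1L,
                     end = blocks$start[gsame + 1L] - 1L)
  gaps <- gaps[gaps$end >= gaps$start, , drop = FALSE]

  qname <- sprintf("%s_p%06d", sample_id, reads$pair)
  ends <- data.frame(id = reads$rid, qname = qname, sample_id = sample_id,
                     end = reads$end, mapq = 60L, nm = 0L,
                     stringsAsFactors = FALSE)
  aln <- alignment_table(ends, blocks, gaps, chrom = config$chrom)

  truth <- .truth_annotate(gene, sim, config, reads, rb, sample_id)
  list(aln = aln, truth = truth)
}

# generator-side truth: per-read features from the known molecule structure
# (transcript-space), then the phase decision table; plus every emitted gap
# with its source segment.
.truth_annotate <- function(gene, sim, config, reads, rb, sample_id) {
  n_pairs <- nrow(reads) / 2L
  ts <- gene$t_intron_start; te <- gene$t_intron_end
  inir <- IRanges::IRanges(ts, te)
  # exon intervals in transcript space = gaps between intron intervals
  exir <- IRanges::setdiff(IRanges::IRanges(1L, gene$t_len), inir)

  bir <- IRanges::IRanges(rb$tstart, rb$tend)
  ov_in <- IRanges::overlapsAny(bir, inir)
  win_ex <- IRanges::overlapsAny(bir, exir, type = "within")
  f <- factor(rb$rid, levels = reads$rid)
  touches_intron <- as.logical(tapply(ov_in, f, any, default = FALSE))
  all_exonic <- as.logical(tapply(win_ex, f, all, default = FALSE))
  all_exonic[is.na(all_exonic)] <- FALSE
  tmin <- as.integer(tapply(rb$tstart, f, min))
  tmax <- as.integer(tapply(rb$tend, f, max))

  # per-read gaps in transcript space
  gsame <- which(diff(rb$rid) == 0L)
  tg <- data.frame(rid = rb$rid[gsame], start = rb$tend[gsame] + 1L,
                   end = rb$tstart[gsame + 1L] - 1L)
  tg <- tg[tg$end >= tg$start, , drop = FALSE]
  ikey <- paste(ts, te)
  tg$full_intron <- paste(tg$start, tg$end) %in% ikey
  ev <- gene$truth_events
  tg$event <- match(paste(tg$start, tg$end), paste(ev$t_donor, ev$t_acceptor))
  unannot <- annot <- logical(length(reads$rid))
  if (nrow(tg)) {
    fg <- factor(tg$rid, levels = reads$rid)
    unannot <- as.logical(tapply(!tg$full_intron, fg, any, default = FALSE))
    annot <- as.logical(tapply(tg$full_intron, fg, any, default = FALSE))
    unannot[is.na(unannot)] <- FALSE; annot[is.na(annot)] <- FALSE
  }
  se <- .single_exon_of(rb, exir, reads$rid)
  post_like <- all_exonic & !unannot

  i1 <- seq_len(n_pairs); i2 <- i1 + n_pairs
  pspan <- pmax(tmax[i1], tmax[i2]) - pmin(tmin[i1], tmin[i2]) + 1L
  large <- pspan > config$expected_insert + 3 * config$insert_sd
  exonly <- !is.na(se[i1]) & !is.na(se[i2]) & se[i1] == se[i2] &
    !annot[i1] & !annot[i2]
  post <- post_like[i1] & post_like[i2] & !exonly
  inter <- (!post & !exonly) &
    ((annot[i1] | annot[i2]) |
       (touches_intron[i1] & touches_intron[i2] & large))
  phase <- rep("pre", n_pairs)
  phase[exonly] <- "exon-only"
  phase[post] <- "post"
  phase[inter] <- "intermediate"

  pairs <- data.frame(pair_id = sprintf("%s_p%06d", sample_id, i1),
                      sample_id = sample_id, phase = phase,
                      span = as.integer(pspan))
  list(pairs = pairs, gaps = tg)
}

.single_exon_of <- function(rb, exir, rids) {
  bir <- IRanges::IRanges(rb$tstart, rb$tend)
  win <- IRanges::findOverlaps(bir, exir, type = "within")
  exof <- rep(NA_integer_, nrow(rb))
  exof[S4Vectors::queryHits(win)] <- S4Vectors::subjectHits(win)
  f <- factor(rb$rid, levels = rids)
  as.integer(tapply(exof, f, function(z)
    if (all(!is.na(z)) && length(unique(z)) == 1L) z[1L] else NA_integer_))
}

#' Dystrophin-like simulation preset
#'
#' 79 exons and 78 introns with log-uniform lengths spanning 107 nt to 360
#' kb, the full heterogeneity of the longest human gene's introns.
#'
#' @param ... overrides passed to [simulation_config()].
#' @return a `sim_config`.
#' @export
dmd_like_config <- function(...) {
  args <- list(...)
  defaults <- list(n_introns = 78L, intron_length_range = c(107L, 360000L))
  do.call(simulation_config, utils::modifyList(defaults, args))
}

#' Write an alignment table as coordinate-sorted SAM
#'
#' Emits a valid minimal SAM: proper-pair flags (99/147), mapping quality
#' 60, CIGAR from the block/gap structure, `*` sequence and quality by
#' default (bases are filled in from `genome` when supplied).
#'
#' @param aln an [alignment_table()].
#' @param path output `.sam` path.
#' @param chrom_len contig length for the header.
#' @param genome optional [Biostrings::DNAStringSet] to fill in read bases.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, chrom_len, genome = NULL) {
  e <- aln$ends
  bl <- split(aln$blocks, aln$blocks$id)
  n <- nrow(e)
  cig <- character(n)
  posn <- endpos <- integer(n)
  seqs <- rep("*", n)
  chromseq <- if (!is.null(genome)) as.character(genome[[aln$chrom]]) else NULL
  for (k in seq_len(n)) {
    b <- bl[[as.character(e$id[k])]]
    b <- b[order(b$start), , drop = FALSE]
    posn[k] <- b$start[1L]
    endpos[k] <- b$end[nrow(b)]
    widths <- b$end - b$start + 1L
    parts <- character(0)
    for (j in seq_len(nrow(b))) {
      parts <- c(parts, paste0(widths[j], "M"))
      if (j < nrow(b))
        parts <- c(parts, paste0(b$start[j + 1L] - b$end[j] - 1L, "N"))
    }
    cig[k] <- paste(parts, collapse = "")
    if (!is.null(chromseq))
      seqs[k] <- paste(substring(chromseq, b$start, b$end), collapse = "")
  }
  key <- paste(e$sample_id, e$qname)
  mate <- match(paste(key, 3L - e$end), paste(key, e$end))
  matepos <- posn[mate]
  mate_end <- endpos[mate]
  flag <- ifelse(e$end == 1L, 99L, 147L)
  tlen <- ifelse(posn <= matepos, pmax(mate_end, endpos) - posn + 1L,
                 -(pmax(endpos, mate_end) - matepos + 1L))
  tlen[is.na(tlen)] <- 0L
  matepos[is.na(matepos)] <- 0L
  mapq <- if (is.null(e$mapq)) rep(60L, n) else e$mapq
  nmv <- if (is.null(e$nm)) rep(0L, n) else e$nm
  lines <- paste(e$qname, flag, aln$chrom, posn, mapq, cig,
                 "=", matepos, tlen, seqs, "*", paste0("NM:i:", nmv),
                 sep = "\t")
  lines <- lines[order(posn)]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", aln$chrom, chrom_len))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Simulate a multi-sample study
#'
#' One gene and genome shared by all samples; independent molecule
#' populations and read pools per library. The manifest groups libraries
#' into cell lines for within-line summation and cross-line intersection.
#'
#' @param config a [simulation_config()].
#' @param samples data.frame(sample_id, cell_line); default 3 libraries in
#'   3 distinct cell lines.
#' @return list: `gene` ([simulate_gene()] output), `aln` (named list of
#'   [alignment_table()]s), `truth` (named list of per-sample truth),
#'   `samples`.
#' @export
simulate_study <- function(config, samples = NULL) {
  if (is.null(samples))
    samples <- data.frame(sample_id = paste0("lib", 1:3),
                          cell_line = paste0("line", 1:3))
  gene <- simulate_gene(config)
  aln <- list(); truth <- list()
  for (j in seq_len(nrow(samples))) {
    sid <- samples$sample_id[j]
    sim <- simulate_transcripts(gene, config,
                                seed = config$seed + 10L * j + 1L)
    er <- emit_read_pairs(gene, sim, config, sample_id = sid,
                          seed = config$seed + 10L * j + 2L)
    er$truth$sim <- sim
    aln[[sid]] <- er$aln
    truth[[sid]] <- er$truth
  }
  list(gene = gene, aln = aln, truth = truth, samples = samples)
}

#' Merge alignment tables from several samples
#'
#' @param alns named list of [alignment_table()]s on the same contig.
#' @return one [alignment_table()] with globally unique end ids.
#' @export
merge_alignments <- function(alns) {
  off <- 0L
  ends <- list(); blocks <- list(); gaps <- list()
  for (nm in names(alns)) {
    a <- alns[[nm]]
    e <- a$ends; b <- a$blocks; g <- a$gaps
    e$id <- e$id + off; b$id <- b$id + off; g$id <- g$id + off
    ends[[nm]] <- e; blocks[[nm]] <- b; gaps[[nm]] <- g
    if (nrow(e)) off <- max(e$id)
  }
  alignment_table(do.call(rbind, ends), do.call(rbind, blocks),
                  do.call(rbind, gaps), chrom = alns[[1L]]$chrom)
}
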