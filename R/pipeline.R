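#' Analyze a study held in memory
#'
#' Runs every stage of the pipeline on pre-loaded alignment tables: phase
#' classification and tallies, coverage normalization and speed classes,
#' bias regressions, splice-ratio ordering and exon blocks, multi-step
#' event discovery with cross-line intersection and classification, and
#' motif summaries. This is the engine behind [run_pipeline()], exposed so
#' simulated studies can be analyzed without touching disk.
#'
#' @param model a [gene_model()].
#' @param alns named list of [alignment_table()]s, one per library.
#' @param genome optional [Biostrings::DNAStringSet] (needed for boundary
#'   refinement, GC diagnostics and motifs).
#' @param cell_line_of named vector mapping sample_id to cell line
#'   (defaults: each sample its own line).
#' @param params list of stage parameters; recognized entries (with
#'   defaults): `expected_insert` (400), `insert_sd` (100), `cutoffs`
#'   (c(90, 130)), `window` (5), `step` (3), `epsilon` (0.05),
#'   `min_support` (5), `min_gap` (50), `boundary_margin` (50).
#' @return a nested results list (`categories`, `coverage`, `order`,
#'   `events`, `motifs`).
#' @export
analyze_study <- function(model, alns, genome = NULL, cell_line_of = NULL,
                          params = list()) {
  p <- utils::modifyList(list(expected_insert = 400, insert_sd = 100,
                              cutoffs = c(90, 130), window = 5L, step = 3L,
                              epsilon = 0.05, min_support = 5L,
                              min_gap = 50L, boundary_margin = 50L), params)
  samples <- names(alns)
  if (is.null(cell_line_of)) cell_line_of <- setNames(samples, samples)

  ## phase classification
  pairs <- lapply(alns, classify_pairs, model = model,
                  expected_insert = p$expected_insert,
                  insert_sd = p$insert_sd)
  all_pairs <- do.call(rbind, pairs)
  merged <- merge_alignments(alns)
  categories <- tally_categories(all_pairs, merged, model)

  ## coverage
  covs <- lapply(samples, function(s) gene_coverage(merged, model, s))
  names(covs) <- samples
  med <- lapply(covs, feature_medians, model = model)
  intron_raw <- sapply(med, function(m) m$raw_median[m$feature == "intron"])
  exon_means <- vapply(covs, exon_mean_coverage, numeric(1), model = model)
  norm <- normalize_coverage(intron_raw, exon_means)
  outlier <- Reduce(`|`, lapply(covs, flag_outlier_introns, model = model))
  speed <- classify_intron_speed(norm$cross_sample_mean, cutoffs = p$cutoffs,
                                 window = p$window, step = p$step)
  use <- !outlier
  pos_reg <- positional_bias_regression(
    ifelse(use, norm$cross_sample_mean, NA_real_))
  gc_reg <- NULL
  if (!is.null(genome)) {
    gc <- feature_gc(model, genome)
    gci <- gc$gc_fraction[gc$feature == "intron"]
    gc_reg <- suppressWarnings(
      gc_bias_regression(gci[use], norm$cross_sample_mean[use]))
  }

  ## splice order (counts pooled over all libraries)
  counts <- lapply(samples, function(s)
    count_order_pairs(alns[[s]], model, pairs = pairs[[s]]))
  pooled <- counts[[1L]]
  if (length(counts) > 1L) for (k in 2L:length(counts)) {
    pooled$S <- pooled$S + counts[[k]]$S
    pooled$NS <- pooled$NS + counts[[k]]$NS
  }
  order_calls <- splice_ratio(pooled, epsilon = p$epsilon,
                              min_support = p$min_support)
  blocks <- derive_exon_blocks(order_calls$order_class, speed$speed_class)
  corr <- tryCatch(order_vs_coverage_correlation(order_calls$splice_ratio,
                                                 norm$cross_sample_mean),
                   error = function(e) NULL)

  ## multi-step events
  splits <- do.call(rbind, lapply(samples, function(s) {
    sp <- extract_split_reads(alns[[s]], model, min_gap = p$min_gap)
    if (!is.null(genome)) sp <- refine_gap_boundaries(sp, genome, model)
    filter_split_events(sp, model, boundary_margin = p$boundary_margin)
  }))
  matrices <- build_event_matrix(splits, cell_line_of)
  events <- intersect_samples(matrices)
  events <- classify_event(events, model)
  imz <- detect_intermezzo(events, model)
  events <- imz$events
  steps <- classify_intron_steps(events, model)

  ## motifs
  motifs <- NULL
  if (!is.null(genome) && nrow(events)) {
    ctx <- extract_contexts(events, genome, model)
    motifs <- list(
      recursive = summarize_motifs(ctx, classes = c("5RS", "3RS", "intermezzo")),
      nested = summarize_motifs(ctx, classes = "nested"))
  }

  list(
    categories = categories,
    pairs = all_pairs,
    coverage = list(intron_raw = intron_raw, exon_means = exon_means,
                    normalized = norm$normalized,
                    cross_sample_mean = norm$cross_sample_mean,
                    outlier = outlier, speed = speed,
                    positional_regression = pos_reg, gc_regression = gc_reg),
    order = list(calls = order_calls, blocks = blocks,
                 coverage_correlation = corr),
    events = list(table = events, intermezzo = imz$pairs,
                  per_intron = steps$per_intron, summary = steps$summary),
    motifs = motifs)
}

#' Validate pipeline inputs
#'
#' Checks that referenced files exist, BAM headers declare coordinate
#' sorting, and contig names agree between BAM, genome and annotation.
#'
#' @param config pipeline configuration list (see [run_pipeline()]).
#' @return character vector of diagnostics (empty when everything is
#'   consistent); fatal problems stop with an explanatory message.
#' @export
validate_inputs <- function(config) {
  notes <- character(0)
  if (is.null(config$samples) || nrow(config$samples) == 0L)
    .stopf("empty sample manifest")
  for (f in c(config$annotation, config$genome, config$masks,
              config$samples$bam)) {
    if (!is.null(f) && !file.exists(f)) .stopf("input not found: %s", f)
  }
  chrom <- config$chrom
  for (bam in config$samples$bam) {
    if (tolower(tools::file_ext(bam)) == "sam") {
      hd <- grep("^@", readLines(bam, n = 200L), value = TRUE)
      so <- grep("^@HD", hd, value = TRUE)
      sq <- sub(".*SN:([^\t]+).*", "\\1", grep("^@SQ", hd, value = TRUE))
    } else {
      h <- Rsamtools::scanBamHeader(bam)[[1L]]
      so <- paste(h$text[["@HD"]], collapse = "\t")
      sq <- names(h$targets)
    }
    if (length(so) && !any(grepl("SO:coordinate", so)))
      .stopf("coordinate-sorted input required: %s", bam)
    if (!is.null(chrom) && !chrom %in% sq)
      .stopf("contig mismatch: '%s' absent from %s (has: %s); rename contigs to match",
             chrom, bam, paste(utils::head(sq, 3L), collapse = ","))
  }
  notes
}

#' Run the pipeline end-to-end from files
#'
#' @param config list with components: `samples` (data.frame sample_id,
#'   cell_line, bam), `annotation` + `gene_id` (or a ready `model`),
#'   `genome` (FASTA path, optional), `masks` (BED path, optional),
#'   `outdir`, `min_mapped_reads` (default 500000; set 0 for small
#'   simulated studies), `params` (see [analyze_study()]), `seed`.
#' @return the [analyze_study()] results list, invisibly; per-stage TSVs
#'   and a JSON summary are written under `outdir`.
#' @export
run_pipeline <- function(config) {
  model <- config$model
  if (is.null(model))
    model <- load_gene_model(config$annotation, config$gene_id)
  if (!is.null(config$masks)) model <- apply_masks(model, config$masks)
  config$chrom <- model$chrom
  if (!is.null(config$samples$bam)) validate_inputs(config)
  genome <- NULL
  if (!is.null(config$genome)) {
    genome <- if (is.character(config$genome))
      Biostrings::readDNAStringSet(config$genome) else config$genome
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  alns <- config$alns
  if (is.null(alns)) {
    alns <- lapply(seq_len(nrow(config$samples)), function(j)
      read_alignments(config$samples$bam[j],
                      sample_id = config$samples$sample_id[j]))
    names(alns) <- config$samples$sample_id
  }
  min_reads <- config$min_mapped_reads %||% 5e5
  n_mapped <- vapply(alns, function(a)
    length(unique(a$ends$qname)), numeric(1))
  names(n_mapped) <- names(alns)
  keep <- filter_samples(n_mapped, min_reads)
  if (length(keep) == 0L) .stopf("no sample passes the read-yield floor")
  alns <- alns[keep]
  cl <- setNames(config$samples$cell_line, config$samples$sample_id)[keep]

  res <- analyze_study(model, alns, genome = genome, cell_line_of = cl,
                       params = config$params %||% list())

  outdir <- config$outdir
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) utils::write.table(
      x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    w(res$categories, "categories.tsv")
    intron_tab <- data.frame(
      intron = res$order$calls$intron,
      normalized_coverage = res$coverage$cross_sample_mean,
      speed_class = res$coverage$speed$speed_class,
      outlier = res$coverage$outlier,
      S = res$order$calls$S, NS = res$order$calls$NS,
      splice_ratio = res$order$calls$splice_ratio,
      order_class = res$order$calls$order_class)
    w(intron_tab, "introns.tsv")
    w(res$order$blocks, "exon_blocks.tsv")
    w(res$events$table, "events.tsv")
    w(res$events$per_intron, "intron_steps.tsv")
    summary <- list(
      seed = config$seed, samples = keep,
      n_pairs_per_phase = as.list(colSums(
        res$categories[grep("^n_", names(res$categories))])),
      speed_classes = as.list(table(res$coverage$speed$speed_class)),
      order_classes = as.list(table(res$order$calls$order_class)),
      n_exon_blocks = nrow(res$order$blocks),
      event_classes = as.list(table(res$events$table$event_class)),
      n_single_step = res$events$summary$n_single,
      n_multi_step = res$events$summary$n_multi,
      positional_bias = res$coverage$positional_regression[c("slope", "p_value")],
      coverage_vs_ratio = if (!is.null(res$order$coverage_correlation))
        res$order$coverage_correlation[c("r", "p_value")] else NULL)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(res)
}
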