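# Pipeline orchestration: declarative JSON config, staged execution
# (simulate -> map -> call tails -> annotate -> chimeras -> profiles),
# structured per-stage logs, and a machine-readable manifest + summary.

.default_config <- function() {
  list(
    seed = 1L,
    simulate = list(enabled = TRUE, n_reads = 2000L, chimera_fraction = 0.05,
                    cut_probability = 0.5, read_len_min = 20L,
                    read_len_max = 110L, three_prime_extension = 0L,
                    n_genes = NULL),
    inputs = list(reads = NULL, reference = NULL, annotation = NULL,
                  alignments = NULL, tss = NULL, track = NULL),
    tailcall = list(trim_min_run = 4L, min_u = 4L, min_span = 18L,
                    max_mismatch_per_25 = 1L, tail_guard = 12L,
                    unique_margin = 2L, max_remainder_frac = 0.4,
                    pass1_mode = "soft"),
    annotate = list(trna_extension = 60L, downstream_window = 200L),
    chimera = list(enabled = TRUE, min_arm = 12L, min_gap = 4L,
                   max_gap = 10000L),
    profiles = list(bins = 100L, tss_window = 500L, smooth = 5L))
}

.check_range <- function(problems, section, key, value, lo, hi = Inf) {
  if (!is.null(value) && (!is.numeric(value) || value < lo || value > hi))
    c(problems, sprintf("%s.%s must be in [%s, %s] (got %s)", section, key,
                        lo, hi, value))
  else problems
}

#' Validate and normalize a pipeline configuration
#'
#' Fills documented defaults, rejects unknown keys and out-of-range values
#' with one aggregated report, and returns the normalized configuration.
#' Idempotent: normalizing a normalized config is a no-op.
#'
#' @param config A named list, or a path to a JSON config file. An empty
#'   config yields all defaults.
#' @return The normalized config (class `uridylome_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (inherits(config, "uridylome_config")) config <- unclass(config)
  defaults <- .default_config()
  problems <- character(0)
  unknown_top <- setdiff(names(config), names(defaults))
  if (length(unknown_top))
    problems <- c(problems, paste("unknown config section(s):",
                                  paste(unknown_top, collapse = ", ")))
  for (sec in intersect(names(config), names(defaults))) {
    if (sec == "seed") next
    unknown <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(unknown))
      problems <- c(problems, sprintf("unknown key(s) in %s: %s", sec,
                                      paste(unknown, collapse = ", ")))
  }
  cfg <- defaults
  for (sec in intersect(names(config), names(defaults))) {
    if (sec == "seed") { cfg$seed <- config$seed; next }
    known <- intersect(names(config[[sec]]), names(defaults[[sec]]))
    cfg[[sec]][known] <- config[[sec]][known]
  }
  tc <- cfg$tailcall
  problems <- .check_range(problems, "tailcall", "trim_min_run",
                           tc$trim_min_run, 1)
  problems <- .check_range(problems, "tailcall", "min_u", tc$min_u, 1)
  problems <- .check_range(problems, "tailcall", "min_span", tc$min_span, 1)
  problems <- .check_range(problems, "tailcall", "max_remainder_frac",
                           tc$max_remainder_frac, 0, 1)
  if (!tc$pass1_mode %in% c("soft", "strict"))
    problems <- c(problems, "tailcall.pass1_mode must be soft or strict")
  problems <- .check_range(problems, "simulate", "chimera_fraction",
                           cfg$simulate$chimera_fraction, 0, 1)
  problems <- .check_range(problems, "simulate", "n_reads",
                           cfg$simulate$n_reads, 1)
  problems <- .check_range(problems, "profiles", "bins",
                           cfg$profiles$bins, 1)
  problems <- .check_range(problems, "annotate", "trna_extension",
                           cfg$annotate$trna_extension, 0)
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  structure(cfg, class = "uridylome_config")
}

.as_pipeline_config <- function(cfg) {
  tc <- cfg$tailcall
  pipeline_config(trim_min_run = tc$trim_min_run, min_u = tc$min_u,
                  min_span = tc$min_span,
                  max_mismatch_per_25 = tc$max_mismatch_per_25,
                  tail_guard = tc$tail_guard,
                  unique_margin = tc$unique_margin,
                  max_remainder_frac = tc$max_remainder_frac,
                  pass1_mode = tc$pass1_mode,
                  downstream_window = cfg$annotate$downstream_window,
                  trna_extension = cfg$annotate$trna_extension,
                  seed = cfg$seed)
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full uridylome pipeline
#'
#' Orchestrates simulate (or load) -> two-pass map (or import alignments)
#' -> tail calling -> annotation -> chimera detection -> profiles, writes
#' every stage output as TSV under `out_dir`, and finishes with a summary
#' JSON of headline fractions (% U+ reads, % unmapped in pass 1, category
#' shares among U+ reads) plus a manifest (config snapshot, input
#' checksums, per-stage counts, seed, version) that fully determines a
#' rerun. Deterministic for a fixed config + seed.
#'
#' @param config Anything accepted by [validate_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest`, `summary` and the main
#'   in-memory results (`calls`, `chimeras`, `profiles`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pc <- .as_pipeline_config(cfg)
  checksums <- list()

  # --- inputs: simulate or load ------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    ngenes <- cfg$simulate$n_genes
    spec <- if (is.null(ngenes)) reference_spec() else
      reference_spec(n_genes = unlist(ngenes))
    ref <- generate_reference(spec, seed = cfg$seed)
    write_reference(ref, file.path(out_dir, "reference.fa"),
                    file.path(out_dir, "annotation.gff3"))
    sim <- simulate_clip_run(
      ref, model = tail_model(), n_reads = cfg$simulate$n_reads,
      chimera_fraction = cfg$simulate$chimera_fraction,
      read_len = c(cfg$simulate$read_len_min, cfg$simulate$read_len_max),
      cut_probability = cfg$simulate$cut_probability,
      three_prime_extension = cfg$simulate$three_prime_extension,
      seed = cfg$seed, out_dir = out_dir)
    reads <- sim$reads
    index <- annotation_index(ref$genes, features = ref$features,
                              trna_extension = cfg$annotate$trna_extension)
    refidx <- index_reference(ref$seqs)
    .stage_log("simulate", "n_reads=%d chimeric=%d", length(reads),
               sum(sim$truth$is_chimera))
  } else {
    missing <- character(0)
    for (k in c("reads", "reference", "annotation"))
      if (is.null(cfg$inputs[[k]])) missing <- c(missing, k)
    else if (!file.exists(cfg$inputs[[k]]))
      missing <- c(missing, paste0(k, " (", cfg$inputs[[k]], " not found)"))
    if (length(missing))
      stop("pre-flight check failed; missing inputs: ",
           paste(missing, collapse = ", "))
    reads <- read_reads(cfg$inputs$reads)
    refidx <- index_reference(cfg$inputs$reference)
    index <- load_annotation(cfg$inputs$annotation,
                             trna_extension = cfg$annotate$trna_extension)
    for (k in c("reads", "reference", "annotation"))
      checksums[[k]] <- unname(tools::md5sum(cfg$inputs[[k]]))
    .stage_log("load", "n_reads=%d contigs=%d genes=%d", length(reads),
               length(refidx$contigs), length(index$genes))
  }

  # --- mapping + tail calling --------------------------------------------
  if (!is.null(cfg$inputs$alignments)) {
    aln <- import_alignments(cfg$inputs$alignments, refidx)
    checksums$alignments <- unname(tools::md5sum(cfg$inputs$alignments))
    classes <- setNames(rep("unmapped", length(reads)), names(reads))
    classes[aln$read_id] <- "pass1"
    counts <- c(pass1 = sum(classes == "pass1"), pass2 = 0L,
                unmapped = sum(classes == "unmapped"), all_tail = 0L)
    uni <- aln[aln$unique, , drop = FALSE]
    calls <- if (nrow(uni)) do.call(rbind, lapply(seq_len(nrow(uni)),
      function(i) call_untemplated_tail(uni[i, ], refidx, pc)))
      else .empty_calls()
    tl <- list(calls = calls, alignments = aln, classes = classes,
               counts = counts)
  } else {
    tl <- call_tails(reads, refidx, pc)
  }
  .stage_log("map", "pass1=%d pass2=%d unmapped=%d all_tail=%d",
             tl$counts["pass1"], tl$counts["pass2"],
             tl$counts["unmapped"], tl$counts["all_tail"])
  stopifnot(sum(tl$counts) == length(reads))
  write_tsv(tl$alignments, file.path(out_dir, "alignments.tsv"),
            header_lines = config_header(pc))

  # --- annotation --------------------------------------------------------
  calls <- annotate_calls(tl$calls, index,
                          downstream_window = cfg$annotate$downstream_window)
  write_tail_calls(calls, file.path(out_dir, "tail_calls.tsv"), pc)
  tail_calls_bed(calls, file.path(out_dir, "tail_anchors.bed"))
  ends <- classify_end_state(calls)
  write_tsv(ends, file.path(out_dir, "end_states.tsv"))
  .stage_log("annotate", "annotated=%d unannotated=%d uplus=%d",
             sum(!is.na(calls$gene_id)), sum(is.na(calls$gene_id)),
             sum(calls$class == "U+"))

  # --- chimeras ----------------------------------------------------------
  chim <- if (isTRUE(cfg$chimera$enabled)) {
    unmapped <- names(reads)[tl$classes[names(reads)] == "unmapped"]
    find_chimeras(reads[unmapped], refidx, index, pc,
                  min_arm = cfg$chimera$min_arm,
                  min_gap = cfg$chimera$min_gap,
                  max_gap = cfg$chimera$max_gap, prescreen = FALSE)
  } else find_chimeras(character(0), refidx)
  write_tsv(chim, file.path(out_dir, "chimeras.tsv"))
  chimeras_bed12(chim, file.path(out_dir, "chimeras.bed12"))
  .stage_log("chimeras", "called=%d g_consistent=%d", nrow(chim),
             sum(chim$rnase_t1_consistent))

  # --- profiles ----------------------------------------------------------
  hist <- tail_length_histogram(calls, by = "class")
  if (nrow(hist$counts))
    write_tsv(hist$counts, file.path(out_dir, "tail_histogram.tsv"))
  if (nrow(hist$stats))
    write_tsv(hist$stats, file.path(out_dir, "tail_histogram_stats.tsv"))
  upf <- uplus_fraction_by_category(calls)
  write_tsv(upf, file.path(out_dir, "uplus_by_category.tsv"))
  cov <- scaled_coverage(calls, index, bins = cfg$profiles$bins)
  cov_df <- data.frame(gene_id = rownames(cov),
                       category = attr(cov, "category"),
                       stringsAsFactors = FALSE)
  cov_df[paste0("bin", seq_len(ncol(cov)))] <-
    as.data.frame(unname(cov), stringsAsFactors = FALSE)
  write_tsv(cov_df, file.path(out_dir, "scaled_coverage.tsv"))

  tssdf <- NULL
  if (!is.null(cfg$inputs$tss)) {
    tssgr <- rtracklayer::import(cfg$inputs$tss, format = "bed")
    tssdf <- data.frame(contig = as.character(
      GenomicRanges::seqnames(tssgr)),
      pos = GenomicRanges::start(tssgr) - 1L,
      strand = as.character(GenomicRanges::strand(tssgr)),
      stringsAsFactors = FALSE)
  } else if (!is.null(index$features) && length(index$features)) {
    tssf <- index$features[index$features$type == "TSS"]
    if (length(tssf))
      tssdf <- data.frame(
        contig = as.character(GenomicRanges::seqnames(tssf)),
        pos = GenomicRanges::start(tssf) - 1L,
        strand = as.character(GenomicRanges::strand(tssf)),
        stringsAsFactors = FALSE)
  }
  mg <- NULL
  if (!is.null(tssdf) && nrow(tssdf)) {
    mg <- tss_metagene(calls, tssdf, window = cfg$profiles$tss_window,
                       smooth = cfg$profiles$smooth)
    if (!is.null(cfg$inputs$track))
      mg <- overlay_signal_track(mg, cfg$inputs$track)
    write_metagene(mg, file.path(out_dir, "tss_metagene.tsv"))
  }
  .stage_log("profiles", "histogram_groups=%d heatmap_rows=%d",
             nrow(hist$stats), nrow(cov))

  # --- summary + manifest ------------------------------------------------
  n <- length(reads)
  uplus_calls <- calls[calls$class == "U+", , drop = FALSE]
  shares <- if (nrow(uplus_calls)) {
    tab <- table(uplus_calls$category, useNA = "no")
    as.list(round(100 * as.numeric(tab) / sum(tab), 3)) |>
      setNames(names(tab))
  } else list()
  summary <- list(
    n_reads = n,
    pct_uplus = round(100 * sum(calls$class == "U+") / max(n, 1L), 3),
    pct_unmapped_pass1 = round(
      100 * (n - unname(tl$counts["pass1"])) / max(n, 1L), 3),
    uplus_category_shares_pct = shares,
    n_chimeras = nrow(chim),
    median_uplus_len = if (any(calls$class == "U+"))
      stats::median(calls$untemplated_len[calls$class == "U+"]) else NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% c("manifest.json")]
  manifest <- list(
    tool = "uridylome",
    version = as.character(packageVersion("uridylome")),
    seed = cfg$seed,
    config = unclass(cfg),
    input_checksums = checksums,
    counts = c(as.list(tl$counts),
               list(uplus = sum(calls$class == "U+"),
                    chimeric = nrow(chim))),
    output_checksums = as.list(tools::md5sum(sort(outputs))) |>
      setNames(basename(sort(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(list(manifest = manifest, summary = summary, calls = calls,
                 chimeras = chim, coverage = cov, metagene = mg,
                 counts = tl$counts))
}
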