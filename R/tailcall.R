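# Two-pass mapping with 3' oligo(T) trimming and identification of
# non-templated 3' tails. The built-in aligner is a 5'-anchored
# seed-and-extend search suited to desk-scale references; external SAM/BAM
# alignments can be imported instead (see import_alignments()).

#' Pipeline configuration
#'
#' Collects all tunable thresholds of the tail-calling pipeline. Defaults
#' follow the published procedure where stated: reads failing the first
#' mapping pass are trimmed of 3'-terminal T stretches of more than three Ts
#' (`trim_min_run = 4`) and remapped; a read is uridylated (U+) when its
#' untemplated 3' U run is at least `min_u = 4` nt.
#'
#' @param trim_min_run Minimal 3' T-run length that is trimmed before the
#'   second mapping pass (default 4, i.e. runs of more than three Ts).
#' @param min_u Minimal untemplated terminal U run for the U+ class
#'   (default 4).
#' @param min_span Minimal aligned span in nt (default 18); also the exact
#'   seed length of the built-in aligner.
#' @param max_mismatch_per_25 Mismatches allowed per 25 aligned nt
#'   (default 1). The mismatch budget of a span of `k` nt is
#'   `floor(k / 25) * max_mismatch_per_25`.
#' @param tail_guard Width of the mismatch-free window required at the 3'
#'   end of every aligned span (default 12 nt). This keeps the aligner from
#'   absorbing tail bases as mismatches, so 3' tails must match the genome
#'   exactly to count as templated.
#' @param unique_margin Minimal best-minus-second-best score margin for a
#'   placement to be called unique (default 2).
#' @param max_remainder_frac In soft mode, the maximal fraction of the read
#'   that may remain unaligned at the 3' end (default 0.4).
#' @param pass1_mode `"soft"` (3' remainder permitted, default) or
#'   `"strict"` (end-to-end; tailed reads then fail pass 1 and are
#'   recovered after trimming in pass 2).
#' @param downstream_window Window (nt) past a gene's annotated 3' end
#'   within which unassigned anchors are still attributed to the gene
#'   (default 200).
#' @param trna_extension Upstream/downstream extension of tRNA genes for
#'   pre-tRNA annotation (default 60 nt).
#' @param seed Optional integer seed recorded in outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(trim_min_run = 4L, min_u = 4L, min_span = 18L,
                            max_mismatch_per_25 = 1L, tail_guard = 12L,
                            unique_margin = 2L, max_remainder_frac = 0.4,
                            pass1_mode = c("soft", "strict"),
                            downstream_window = 200L, trna_extension = 60L,
                            seed = NULL) {
  pass1_mode <- match.arg(pass1_mode)
  vals <- list(trim_min_run = as.integer(trim_min_run),
               min_u = as.integer(min_u), min_span = as.integer(min_span),
               max_mismatch_per_25 = as.integer(max_mismatch_per_25),
               tail_guard = as.integer(tail_guard),
               unique_margin = as.integer(unique_margin),
               max_remainder_frac = max_remainder_frac,
               pass1_mode = pass1_mode,
               downstream_window = as.integer(downstream_window),
               trna_extension = as.integer(trna_extension), seed = seed)
  pos <- c("trim_min_run", "min_u", "min_span", "unique_margin")
  for (p in pos) if (vals[[p]] < 1L) stop(p, " must be >= 1")
  if (vals$max_mismatch_per_25 < 0L) stop("max_mismatch_per_25 must be >= 0")
  if (vals$tail_guard < 0L) stop("tail_guard must be >= 0")
  if (max_remainder_frac < 0 || max_remainder_frac > 1)
    stop("max_remainder_frac must be in [0,1]")
  structure(vals, class = "pipeline_config")
}

config_header <- function(config) {
  sprintf(paste0("uridylome %s | trim_min_run=%d min_u=%d min_span=%d ",
                 "mismatch=%d/25nt tail_guard=%d unique_margin=%d ",
                 "max_remainder_frac=%g pass1_mode=%s | untemplated tails ",
                 "called under the maximal-templated convention"),
          as.character(packageVersion("uridylome")),
          config$trim_min_run, config$min_u, config$min_span,
          config$max_mismatch_per_25, config$tail_guard,
          config$unique_margin, config$max_remainder_frac,
          config$pass1_mode)
}

#' Index a reference for the built-in aligner
#'
#' @param seqs A [Biostrings::DNAStringSet], a named character vector, or a
#'   path to a FASTA file.
#' @return An object of class `ref_index` (per-contig forward and
#'   reverse-complement character arrays plus the `DNAStringSet`).
#' @export
index_reference <- function(seqs) {
  if (inherits(seqs, "ref_index")) return(seqs)
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- Biostrings::readDNAStringSet(seqs)
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (inherits(seqs, "clip_reference")) seqs <- seqs$seqs
  stopifnot(methods::is(seqs, "DNAStringSet"))
  if (is.null(names(seqs))) names(seqs) <- paste0("contig", seq_along(seqs))
  contigs <- lapply(seq_along(seqs), function(i) {
    xs_fwd <- seqs[[i]]
    xs_rc <- Biostrings::reverseComplement(xs_fwd)
    fwd <- strsplit(as.character(xs_fwd), "", fixed = TRUE)[[1]]
    rc <- strsplit(as.character(xs_rc), "", fixed = TRUE)[[1]]
    list(fwd = fwd, rc = rc, xs_fwd = xs_fwd, xs_rc = xs_rc,
         len = length(fwd))
  })
  names(contigs) <- names(seqs)
  structure(list(seqs = seqs, contigs = contigs), class = "ref_index")
}

# Extend a 5'-anchored placement of read chars `r` on strand-space chars `W`
# starting at 1-based position p. Returns c(span, mismatches) or NULL.
# Span maximizes score = span - 2*mm subject to: running mismatches within
# budget, span ends on a match, and the last `guard` bases are mismatch-free.
.extend_placement <- function(r, W, p, config) {
  n <- length(r)
  kmax <- min(n, length(W) - p + 1L)
  if (kmax < 1L) return(NULL)
  mism <- W[p:(p + kmax - 1L)] != r[seq_len(kmax)]
  cm <- cumsum(mism)
  k <- seq_len(kmax)
  budget <- (k %/% 25L) * config$max_mismatch_per_25
  g <- config$tail_guard
  cm_lag <- c(rep(0L, min(g, kmax)), cm[seq_len(max(kmax - g, 0L))])
  ok <- !mism & cm <= budget & (cm - cm_lag) == 0L
  if (!any(ok)) return(NULL)
  score <- ifelse(ok, k - 2L * cm, -Inf)
  S <- which.max(score)  # ties resolve to the shorter span
  c(span = S, mm = cm[S])
}

# contig-space 0-based half-open coords for a strand-space placement
.placement_coords <- function(p, span, strand, L) {
  if (strand == "+") c(p - 1L, p - 1L + span)
  else c(L - p - span + 1L, L - p + 1L)
}

# Batch seed search: returns per-read list of candidate placements
# (contig, strand, p = 1-based strand-space start).
.seed_hits <- function(reads, refidx, seed_len) {
  n <- length(reads)
  hits <- vector("list", n)
  long <- which(nchar(reads) >= seed_len)
  if (length(long) == 0L) return(hits)
  seeds <- substr(reads[long], 1L, seed_len)
  use_pdict <- length(seeds) > 256L
  pd <- if (use_pdict) Biostrings::PDict(Biostrings::DNAStringSet(seeds))
        else lapply(seeds, Biostrings::DNAString)
  for (cname in names(refidx$contigs)) {
    ctg <- refidx$contigs[[cname]]
    for (strand in c("+", "-")) {
      s <- if (strand == "+") ctg$xs_fwd else ctg$xs_rc
      starts <- if (use_pdict)
        Biostrings::startIndex(Biostrings::matchPDict(pd, s))
      else lapply(pd, function(pat)
        Biostrings::start(Biostrings::matchPattern(pat, s)))
      for (j in seq_along(starts)) {
        st <- starts[[j]]
        if (is.null(st) || length(st) == 0L) next
        ri <- long[j]
        hits[[ri]] <- c(hits[[ri]], list(list(contig = cname,
                                              strand = strand, p = st)))
      }
    }
  }
  hits
}

# Align a batch of reads. Returns a data.frame (possibly 0-row) of best
# placements; reads without a valid placement are absent.
.align_batch <- function(reads, refidx, config, mode = c("soft", "strict"),
                         min_span = NULL) {
  mode <- match.arg(mode)
  min_span <- min_span %||% config$min_span
  if (length(reads) == 0L) return(.empty_alignments())
  stopifnot(!is.null(names(reads)))
  hits <- .seed_hits(reads, refidx, seed_len = min_span)
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    h <- hits[[i]]
    if (is.null(h)) next
    r <- strsplit(reads[[i]], "", fixed = TRUE)[[1]]
    n <- length(r)
    cand <- list()
    for (blk in h) {
      ctg <- refidx$contigs[[blk$contig]]
      W <- if (blk$strand == "+") ctg$fwd else ctg$rc
      for (p in blk$p) {
        e <- .extend_placement(r, W, p, config)
        if (is.null(e)) next
        span <- e[["span"]]; mm <- e[["mm"]]
        if (span < min_span) next
        if (mode == "strict" && span < n) next
        if (mode == "soft" && (n - span) > config$max_remainder_frac * n)
          next
        cand[[length(cand) + 1L]] <-
          list(contig = blk$contig, strand = blk$strand, p = p,
               span = span, mm = mm, score = span - 2L * mm, L = ctg$len)
      }
    }
    if (length(cand) == 0L) next
    scores <- vapply(cand, `[[`, numeric(1), "score")
    ord <- order(-scores)
    best <- cand[[ord[1L]]]
    second <- if (length(ord) > 1L) scores[ord[2L]] else -Inf
    uniq <- (best$score - second) >= config$unique_margin
    cc <- .placement_coords(best$p, best$span, best$strand, best$L)
    out[[i]] <- data.frame(
      read_id = names(reads)[i], contig = best$contig,
      start = cc[1], end = cc[2], strand = best$strand,
      aligned_span = best$span, mismatches = best$mm,
      remainder = substr(reads[[i]], best$span + 1L, n),
      pass = NA_integer_, trimmed_t_count = 0L, unique = uniq,
      score = best$score, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(.empty_alignments())
  do.call(rbind, out)
}

.empty_alignments <- function() {
  data.frame(read_id = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             aligned_span = integer(0), mismatches = integer(0),
             remainder = character(0), pass = integer(0),
             trimmed_t_count = integer(0), unique = logical(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

#' Align a single read with the built-in aligner
#'
#' 5'-anchored seed-and-extend alignment against both strands of all
#' contigs. The aligned span is a prefix of the read; the unaligned suffix
#' is returned as the 3' remainder. A placement is unique when its score
#' beats the second-best placement by at least the configured margin;
#' non-unique placements are reported with `unique = FALSE` and excluded
#' from tail calling downstream.
#'
#' @param read Read sequence (character) or a named length-1 vector.
#' @param ref Reference: anything accepted by [index_reference()].
#' @param config A [pipeline_config()].
#' @param mode `"soft"` (3' remainder allowed) or `"strict"` (end-to-end).
#' @return One-row data.frame (an alignment record) or `NULL` if unmapped.
#' @export
align_read <- function(read, ref, config = pipeline_config(),
                       mode = c("soft", "strict")) {
  mode <- match.arg(mode)
  refidx <- index_reference(ref)
  if (is.null(names(read))) read <- setNames(read, "read1")
  res <- .align_batch(read, refidx, config, mode)
  if (nrow(res) == 0L) NULL else res
}

#' Trim a 3'-terminal oligo(T) stretch from a read
#'
#' Removes the maximal 3'-terminal T run if and only if it is at least
#' `trim_min_run` nt long (default 4, i.e. stretches of more than three Ts);
#' shorter runs are left untouched. Idempotent. A read consisting entirely
#' of Ts is trimmed to the empty string and flagged `all_tail`.
#'
#' @param sequence Non-empty read sequence (DNA alphabet).
#' @param trim_min_run Minimal run length that triggers trimming.
#' @return List with `trimmed`, `removed` (count) and `all_tail` (flag).
#' @examples
#' trim_t_tail("ACGTTTTT")  # trimmed "ACG", removed 5
#' trim_t_tail("ACGTTT")    # unchanged, run of 3 is kept
#' @export
trim_t_tail <- function(sequence, trim_min_run = 4L) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  run <- terminal_run(sequence, "T")
  if (run < trim_min_run)
    return(list(trimmed = sequence, removed = 0L, all_tail = FALSE))
  n <- nchar(sequence)
  list(trimmed = substr(sequence, 1L, n - run), removed = run,
       all_tail = run == n)
}

#' Two-pass mapping with oligo(T) trimming
#'
#' Pass 1 aligns the raw reads (in the configured pass-1 mode). Reads that
#' fail pass 1 are trimmed of 3'-terminal T stretches of at least
#' `trim_min_run` nt and realigned (pass 2, soft mode). Every read is
#' classified exactly once as `pass1`, `pass2`, `unmapped` or `all_tail`;
#' the four categories partition the input.
#'
#' @param reads Named character vector (or `DNAStringSet`) of reads.
#' @param ref Reference accepted by [index_reference()].
#' @param config A [pipeline_config()].
#' @return List with `alignments` (data.frame, one row per mapped read,
#'   unique and non-unique), `classes` (named character vector over all
#'   reads) and `counts` (named integer table of the four categories).
#' @export
two_pass_map <- function(reads, ref, config = pipeline_config()) {
  if (methods::is(reads, "DNAStringSet"))
    reads <- setNames(as.character(reads), names(reads))
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  refidx <- index_reference(ref)
  classes <- setNames(rep("unmapped", length(reads)), names(reads))

  aln1 <- .align_batch(reads, refidx, config, mode = config$pass1_mode)
  if (nrow(aln1)) {
    aln1$pass <- 1L
    classes[aln1$read_id] <- "pass1"
  }
  fail1 <- setdiff(names(reads), aln1$read_id)

  aln2 <- .empty_alignments()
  if (length(fail1)) {
    tr <- lapply(reads[fail1], trim_t_tail, trim_min_run = config$trim_min_run)
    removed <- vapply(tr, `[[`, integer(1), "removed")
    all_tail <- vapply(tr, `[[`, logical(1), "all_tail")
    classes[fail1[all_tail]] <- "all_tail"
    redo <- fail1[!all_tail & removed > 0L]
    if (length(redo)) {
      trimmed <- vapply(tr[redo], `[[`, character(1), "trimmed")
      aln2 <- .align_batch(setNames(trimmed, redo), refidx, config,
                           mode = "soft")
      if (nrow(aln2)) {
        aln2$pass <- 2L
        aln2$trimmed_t_count <- removed[aln2$read_id]
        classes[aln2$read_id] <- "pass2"
      }
    }
  }
  alignments <- rbind(aln1, aln2)
  counts <- c(pass1 = sum(classes == "pass1"),
              pass2 = sum(classes == "pass2"),
              unmapped = sum(classes == "unmapped"),
              all_tail = sum(classes == "all_tail"))
  list(alignments = alignments, classes = classes, counts = counts)
}

#' Classify an untemplated tail sequence
#'
#' A tail is `U+` when its 3'-terminal T run is at least `min_u` nt
#' (at least 4 Us by default), regardless of upstream tail bases.
#' Homopolymer tails below that threshold are labelled by their base
#' (T reported as `U`); heterogeneous tails are `mixed`; empty is `none`.
#'
#' @param tail Untemplated tail sequence over A/C/G/T (may be empty).
#' @param min_u U+ threshold (default 4).
#' @return One of `"U+"`, `"U"`, `"A"`, `"C"`, `"G"`, `"mixed"`, `"none"`.
#' @examples
#' classify_tail("TTTT")   # "U+"
#' classify_tail("ATTTT")  # "U+": terminal run of 4
#' classify_tail("TTTTA")  # "mixed"
#' @export
classify_tail <- function(tail, min_u = 4L) {
  if (!nzchar(tail)) return("none")
  if (grepl("[^ACGT]", tail)) stop("tail must contain only A, C, G, T")
  if (terminal_run(tail, "T") >= min_u) return("U+")
  b <- unique(strsplit(tail, "", fixed = TRUE)[[1]])
  if (length(b) == 1L) return(chartr("T", "U", b))
  "mixed"
}

#' Call the non-templated 3' tail of an aligned read
#'
#' Reconstructs the raw 3' remainder (the unaligned suffix plus any Ts
#' trimmed before pass 2) and extends it base-by-base along the genome past
#' the alignment end, strand-aware. The maximal genome-matching prefix is
#' the templated overlap; the residual is the untemplated tail. This is the
#' maximal-templated convention: tails abutting genomically encoded Ts are
#' conservatively undercounted, since encoded and added Us cannot be told
#' apart at such junctions.
#'
#' @param alignment One-row alignment record (as from [align_read()] or
#'   [two_pass_map()]). Must be a unique alignment.
#' @param ref Reference accepted by [index_reference()].
#' @param config A [pipeline_config()].
#' @return One-row data.frame: the tail call (anchor coordinate of the last
#'   templated base, tail sequence in RNA sense, templated overlap,
#'   per-base untemplated counts, composition class, tail source).
#' @export
call_untemplated_tail <- function(alignment, ref,
                                  config = pipeline_config()) {
  refidx <- index_reference(ref)
  a <- as.list(alignment[1, ])
  ctg <- refidx$contigs[[a$contig]]
  if (is.null(ctg)) stop("reference-mismatch: contig ", a$contig,
                         " absent from the reference")
  L <- ctg$len
  raw_rem <- paste0(a$remainder, strrep("T", a$trimmed_t_count))
  nrem <- nchar(raw_rem)

  # strand-space start of the first base past the alignment
  p_end <- if (a$strand == "+") a$end + 1L else L - a$start + 1L
  W <- if (a$strand == "+") ctg$fwd else ctg$rc
  avail <- max(0L, min(nrem, L - p_end + 1L))
  downstream <- if (avail > 0L)
    paste(W[p_end:(p_end + avail - 1L)], collapse = "") else ""
  tov <- common_prefix_len(raw_rem, downstream)
  untail <- substr(raw_rem, tov + 1L, nrem)

  anchor <- if (a$strand == "+") a$end - 1L + tov else a$start - tov
  cls <- classify_tail(untail, config$min_u)
  chs <- if (nzchar(untail)) strsplit(untail, "", fixed = TRUE)[[1]]
         else character(0)
  src <- if (nrem == 0L) "none"
         else if (a$trimmed_t_count > 0L && nzchar(a$remainder)) "both"
         else if (a$trimmed_t_count > 0L) "trimmed-Ts"
         else "remainder"
  data.frame(
    read_id = a$read_id, contig = a$contig, start = a$start, end = a$end,
    strand = a$strand, pass = a$pass, anchor = anchor,
    tail_seq = to_rna(raw_rem), templated_overlap = tov,
    untemplated_len = nchar(untail),
    n_U = sum(chs == "T"), n_A = sum(chs == "A"),
    n_C = sum(chs == "C"), n_G = sum(chs == "G"),
    class = cls, tail_source = src, stringsAsFactors = FALSE)
}

#' Map reads and call non-templated 3' tails
#'
#' Convenience wrapper: [two_pass_map()] followed by
#' [call_untemplated_tail()] on every uniquely mapped read.
#'
#' @param reads Named character vector or `DNAStringSet`.
#' @param ref Reference accepted by [index_reference()].
#' @param config A [pipeline_config()].
#' @return List with `calls` (data.frame of tail calls, unique reads only),
#'   `alignments`, `classes` and `counts` as in [two_pass_map()].
#' @export
call_tails <- function(reads, ref, config = pipeline_config()) {
  refidx <- index_reference(ref)
  mp <- two_pass_map(reads, refidx, config)
  aln <- mp$alignments
  uni <- aln[aln$unique, , drop = FALSE]
  calls <- if (nrow(uni) == 0L) .empty_calls() else
    do.call(rbind, lapply(seq_len(nrow(uni)), function(i)
      call_untemplated_tail(uni[i, ], refidx, config)))
  list(calls = calls, alignments = aln, classes = mp$classes,
       counts = mp$counts)
}

.empty_calls <- function() {
  data.frame(read_id = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             pass = integer(0), anchor = integer(0), tail_seq = character(0),
             templated_overlap = integer(0), untemplated_len = integer(0),
             n_U = integer(0), n_A = integer(0), n_C = integer(0),
             n_G = integer(0), class = character(0),
             tail_source = character(0), stringsAsFactors = FALSE)
}

#' Write tail calls as TSV (with the configuration in the header)
#'
#' @param calls Tail-call data.frame.
#' @param path Output path.
#' @param config A [pipeline_config()], echoed into the header.
#' @return The path, invisibly.
#' @export
write_tail_calls <- function(calls, path, config = pipeline_config()) {
  write_tsv(calls, path, header_lines = config_header(config))
}

#' BED6 records of tail-call anchor positions
#'
#' One BED6 line per call: the anchor (last templated base) as a 1-nt
#' interval, name = composition class, score = untemplated tail length.
#'
#' @param calls Tail-call data.frame.
#' @param path Optional output path; when given the BED text is written.
#' @return Character vector of BED lines, invisibly if written.
#' @export
tail_calls_bed <- function(calls, path = NULL) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   calls$contig, calls$anchor, calls$anchor + 1L,
                   calls$class, calls$untemplated_len, calls$strand)
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
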