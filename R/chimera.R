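# Detection of hybrid reads produced by intramolecular ligation of two
# RNase T1 fragments of one molecule during the CLIP protocol. The search
# is an exhaustive split: every split point of the read is tried, both
# halves aligned independently, and candidates kept when both halves map
# uniquely. The 5' arm of a genuine RNase T1 ligation ends in G; this is
# recorded as a flag, not used as a filter.

#' Enumerate candidate split alignments of a read
#'
#' For every split point `s` (with both halves at least `min_arm` nt), the
#' 5' half is aligned end-to-end and the 3' half 5'-anchored with a free 3'
#' remainder (the tail). Candidates are retained when both halves map
#' uniquely. This exhaustive search doubles as the test oracle for chimera
#' detection.
#'
#' @param read Read sequence (character) with a name, or unnamed.
#' @param ref Reference accepted by [index_reference()].
#' @param config A [pipeline_config()].
#' @param min_arm Minimal arm length (default 12 nt; also the aligned-span
#'   floor and seed length for the split alignments).
#' @return Data.frame of candidates: split point, per-arm coordinates
#'   (0-based half-open), strand, total aligned length, total mismatches,
#'   and the 3' arm remainder.
#' @export
enumerate_split_candidates <- function(read, ref,
                                       config = pipeline_config(),
                                       min_arm = 12L) {
  refidx <- index_reference(ref)
  id <- names(read) %||% "read1"
  read <- unname(read)
  n <- nchar(read)
  out <- list()
  if (n >= 2L * min_arm) {
    splits <- seq(min_arm, n - min_arm)
    arm1s <- setNames(substr(rep(read, length(splits)), 1L, splits),
                      paste0("s", splits))
    arm2s <- setNames(substr(rep(read, length(splits)), splits + 1L, n),
                      paste0("s", splits))
    cfg2 <- config
    cfg2$max_remainder_frac <- 1  # the 3' arm's remainder is the tail
    a1 <- .align_batch(arm1s, refidx, config, mode = "strict",
                       min_span = min_arm)
    a2 <- .align_batch(arm2s, refidx, cfg2, mode = "soft",
                       min_span = min_arm)
    a1 <- a1[a1$unique, , drop = FALSE]
    a2 <- a2[a2$unique, , drop = FALSE]
    both <- intersect(a1$read_id, a2$read_id)
    for (key in both) {
      r1 <- a1[a1$read_id == key, ]; r2 <- a2[a2$read_id == key, ]
      out[[length(out) + 1L]] <- data.frame(
        read_id = id, split = as.integer(sub("^s", "", key)),
        contig1 = r1$contig, strand1 = r1$strand,
        arm1_start = r1$start, arm1_end = r1$end,
        contig2 = r2$contig, strand2 = r2$strand,
        arm2_start = r2$start, arm2_end = r2$end,
        arm2_remainder = r2$remainder,
        total_aligned = r1$aligned_span + r2$aligned_span,
        total_mm = r1$mismatches + r2$mismatches,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(0), split = integer(0),
                      contig1 = character(0), strand1 = character(0),
                      arm1_start = integer(0), arm1_end = integer(0),
                      contig2 = character(0), strand2 = character(0),
                      arm2_start = integer(0), arm2_end = integer(0),
                      arm2_remainder = character(0),
                      total_aligned = integer(0), total_mm = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# transcript-orientation gap between the arms (nt skipped on the molecule)
.arm_gap <- function(cand) {
  ifelse(cand$strand1 == "+", cand$arm2_start - cand$arm1_end,
         cand$arm1_start - cand$arm2_end)
}

#' Detect an intramolecular-ligation hybrid read
#'
#' Selects, among the enumerated split candidates, the one maximizing the
#' total aligned length with both arms on one strand of one annotated
#' locus, the 5' arm preceding the 3' arm in transcript orientation, and a
#' gap within `[min_gap, max_gap]`. Ties are broken by fewest mismatches,
#' then smallest gap, then leftmost 5' arm. Whether the 5' arm ends in G
#' (RNase T1 consistency) is recorded as a flag. Candidates whose best
#' split places the arms in different loci are reported with
#' `inter_locus = TRUE` and are excluded from hybrid tables by default.
#'
#' @param read Named (or unnamed) read sequence.
#' @param ref Reference accepted by [index_reference()].
#' @param index Optional [annotation_index()]; when supplied, arms must
#'   share a locus (tRNAs match within their extended span).
#' @param config A [pipeline_config()].
#' @param min_arm,min_gap,max_gap Arm-length floor (12 nt) and gap bounds
#'   (4 nt to 10 kb) for an intra-locus ligation.
#' @return One-row data.frame (the chimera call: arm coordinates, 1-based
#'   junction positions in transcript coordinates of the locus, gap,
#'   terminal base of arm 1 and the G flag) or `NULL`.
#' @export
detect_chimera <- function(read, ref, index = NULL,
                           config = pipeline_config(), min_arm = 12L,
                           min_gap = 4L, max_gap = 10000L) {
  refidx <- index_reference(ref)
  id <- names(read) %||% "read1"
  cand <- enumerate_split_candidates(read, refidx, config, min_arm)
  if (nrow(cand) == 0L) return(NULL)
  same <- cand$contig1 == cand$contig2 & cand$strand1 == cand$strand2
  gap <- .arm_gap(cand)
  ok <- same & gap >= min_gap & gap <= max_gap
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  gap <- gap[ok]

  gene1 <- rep(NA_character_, nrow(cand))
  gene2 <- gene1
  if (!is.null(index)) {
    gene1 <- assign_category(index, data.frame(
      contig = cand$contig1, start = cand$arm1_start,
      end = cand$arm1_end, strand = cand$strand1))$gene_id
    gene2 <- assign_category(index, data.frame(
      contig = cand$contig2, start = cand$arm2_start,
      end = cand$arm2_end, strand = cand$strand2))$gene_id
    same_locus <- !is.na(gene1) & !is.na(gene2) & gene1 == gene2
  } else same_locus <- rep(TRUE, nrow(cand))

  # Ties between neighbouring splits are genuine reconstruction
  # ambiguities (the junction base fits either arm); prefer the split
  # whose 5' arm ends in G, consistent with RNase T1 cleavage, then the
  # longer 5' arm.
  raw0 <- unname(read)
  ends_g <- substring(raw0, cand$split, cand$split) == "G"
  ord <- order(-cand$total_aligned, cand$total_mm, gap, !ends_g,
               cand$arm1_start, -cand$split)
  best_all <- ord[1L]
  pick <- ord[same_locus[ord]][1L]
  inter <- FALSE
  if (is.na(pick)) { pick <- best_all; inter <- TRUE }
  b <- cand[pick, ]
  g <- gap[pick]

  # junction identifiability: neighbouring splits can reconstruct the very
  # same read when junction-adjacent bases coincide; if several equally
  # scoring same-locus candidates are RNase-T1-consistent (or none are),
  # the junction cannot be pinned down and the call is flagged ambiguous
  fam <- which(same_locus & cand$total_aligned == b$total_aligned &
               cand$total_mm == b$total_mm & gap == g)
  junc_key <- paste(cand$arm1_end[fam], cand$arm2_start[fam])
  fam_g <- fam[ends_g[fam]]
  ambiguous <- if (length(fam_g) > 0L)
    length(unique(junc_key[match(fam_g, fam)])) > 1L
  else length(unique(junc_key)) > 1L

  last1 <- substr(raw0, b$split, b$split)
  # junction in 1-based transcript coordinates of the locus (if annotated)
  j1 <- NA_integer_; j2 <- NA_integer_
  if (!inter && !is.null(index) && !is.na(gene1[pick])) {
    gr <- index$genes[match(gene1[pick], index$genes$gene_id)]
    gs0 <- GenomicRanges::start(gr) - 1L; ge0 <- GenomicRanges::end(gr)
    if (b$strand1 == "+") {
      j1 <- b$arm1_end - gs0
      j2 <- b$arm2_start - gs0 + 1L
    } else {
      j1 <- ge0 - b$arm1_start
      j2 <- ge0 - b$arm2_end + 1L
    }
  }
  data.frame(
    read_id = id, gene_id = if (inter) NA_character_ else gene1[pick],
    contig = b$contig1, strand = b$strand1,
    arm1_start = b$arm1_start, arm1_end = b$arm1_end,
    arm2_start = b$arm2_start, arm2_end = b$arm2_end,
    junction1 = j1, junction2 = j2, gap = g, split = b$split,
    arm1_terminal_base = last1, rnase_t1_consistent = (last1 == "G"),
    arm2_remainder = b$arm2_remainder, inter_locus = inter,
    ambiguous_junction = ambiguous, stringsAsFactors = FALSE)
}

#' Call the 3' tail of a chimeric read
#'
#' Tail calling is identical to [call_untemplated_tail()], anchored at the
#' end of the 3' arm: the remainder past arm 2 is extended along the genome
#' and the residual is the untemplated tail.
#'
#' @param chimera One-row chimera call from [detect_chimera()].
#' @param ref Reference accepted by [index_reference()].
#' @param config A [pipeline_config()].
#' @return One-row tail-call data.frame.
#' @export
chimera_tail <- function(chimera, ref, config = pipeline_config()) {
  aln <- data.frame(
    read_id = chimera$read_id, contig = chimera$contig,
    start = chimera$arm2_start, end = chimera$arm2_end,
    strand = chimera$strand,
    aligned_span = chimera$arm2_end - chimera$arm2_start,
    mismatches = 0L, remainder = chimera$arm2_remainder,
    pass = 1L, trimmed_t_count = 0L, unique = TRUE, score = 0,
    stringsAsFactors = FALSE)
  call_untemplated_tail(aln, ref, config)
}

#' Screen reads for intramolecular-ligation hybrids
#'
#' Runs [detect_chimera()] on every read that cannot be mapped as a
#' contiguous sequence (reads that map contiguously are skipped, so no
#' false chimeras arise from them). Intended for the `unmapped` set of
#' [two_pass_map()], but will pre-screen any read set it is given.
#'
#' @param reads Named character vector.
#' @param ref Reference accepted by [index_reference()].
#' @param index Optional [annotation_index()].
#' @param config A [pipeline_config()].
#' @param min_arm,min_gap,max_gap Passed to [detect_chimera()].
#' @param prescreen Skip reads that map contiguously (default TRUE).
#' @param keep_ambiguous Keep calls whose junction is not identifiable
#'   (several sequence-identical reconstructions; default FALSE, they are
#'   dropped like inter-locus calls).
#' @return Data.frame of chimera calls with tail-call columns
#'   (`tail_class`, `tail_len`) appended; zero rows when none found.
#' @export
find_chimeras <- function(reads, ref, index = NULL,
                          config = pipeline_config(), min_arm = 12L,
                          min_gap = 4L, max_gap = 10000L,
                          prescreen = TRUE, keep_ambiguous = FALSE) {
  refidx <- index_reference(ref)
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  if (prescreen && length(reads)) {
    mp <- two_pass_map(reads, refidx, config)
    reads <- reads[mp$classes[names(reads)] == "unmapped"]
  }
  out <- list()
  for (id in names(reads)) {
    cc <- detect_chimera(setNames(reads[[id]], id), refidx, index, config,
                         min_arm, min_gap, max_gap)
    if (is.null(cc) || cc$inter_locus) next
    if (cc$ambiguous_junction && !keep_ambiguous) next
    tc <- chimera_tail(cc, refidx, config)
    cc$tail_class <- tc$class
    cc$tail_len <- tc$untemplated_len
    cc$anchor <- tc$anchor
    out[[length(out) + 1L]] <- cc
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(0), gene_id = character(0),
                      contig = character(0), strand = character(0),
                      arm1_start = integer(0), arm1_end = integer(0),
                      arm2_start = integer(0), arm2_end = integer(0),
                      junction1 = integer(0), junction2 = integer(0),
                      gap = integer(0), split = integer(0),
                      arm1_terminal_base = character(0),
                      rnase_t1_consistent = logical(0),
                      arm2_remainder = character(0),
                      inter_locus = logical(0),
                      ambiguous_junction = logical(0),
                      tail_class = character(0),
                      tail_len = integer(0), anchor = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' BED12-style two-block records for chimera calls
#'
#' One line per chimera with two blocks (the arms) for genome-browser
#' viewing; the name carries the junction and the G flag.
#'
#' @param chimeras Data.frame from [find_chimeras()].
#' @param path Optional output path.
#' @return Character vector of BED12 lines.
#' @export
chimeras_bed12 <- function(chimeras, path = NULL) {
  if (nrow(chimeras) == 0L) lines <- character(0)
  else {
    s <- pmin(chimeras$arm1_start, chimeras$arm2_start)
    e <- pmax(chimeras$arm1_end, chimeras$arm2_end)
    b1 <- pmin(chimeras$arm1_start, chimeras$arm2_start)
    w1 <- ifelse(chimeras$arm1_start <= chimeras$arm2_start,
                 chimeras$arm1_end - chimeras$arm1_start,
                 chimeras$arm2_end - chimeras$arm2_start)
    b2 <- pmax(chimeras$arm1_start, chimeras$arm2_start)
    w2 <- ifelse(chimeras$arm1_start <= chimeras$arm2_start,
                 chimeras$arm2_end - chimeras$arm2_start,
                 chimeras$arm1_end - chimeras$arm1_start)
    lines <- sprintf(
      "%s\t%d\t%d\t%s|j%s-%s|G:%s\t0\t%s\t%d\t%d\t0\t2\t%d,%d\t%d,%d",
      chimeras$contig, s, e, chimeras$read_id,
      ifelse(is.na(chimeras$junction1), ".",
             as.character(chimeras$junction1)),
      ifelse(is.na(chimeras$junction2), ".",
             as.character(chimeras$junction2)),
      ifelse(chimeras$rnase_t1_consistent, "yes", "no"),
      chimeras$strand, s, e, w1, w2, 0L, b2 - s)
  }
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
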