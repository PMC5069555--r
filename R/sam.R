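# Import of externally produced alignments (SAM/BAM) into the pipeline's
# alignment records, and a minimal SAM writer for round-trip testing.
# 3' soft-clipped segments become unaligned remainders; secondary and
# supplementary records are dropped; uniqueness is taken from MAPQ.

.parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^\\d+", "", ops)
  list(n = n, op = op)
}

#' Import alignments from SAM/BAM
#'
#' Converts external alignments (e.g. from a genome-scale aligner) into the
#' package's alignment records so that tail calling can proceed identically
#' to the native path. The 3'-most soft-clipped segment (in the read's
#' original orientation) becomes the unaligned remainder; secondary and
#' supplementary alignments are dropped; an alignment is unique when its
#' mapping quality is at least `mapq_floor`.
#'
#' @param path Path to a `.sam` or `.bam` file (SAM is converted via
#'   [Rsamtools::asBam()]).
#' @param ref Reference accepted by [index_reference()]; header contigs
#'   must exist in the reference.
#' @param mapq_floor Minimal MAPQ for uniqueness (default 20).
#' @return Alignment-record data.frame as produced by [two_pass_map()]
#'   (pass is reported as 1, trimmed_t_count 0: external aligners do their
#'   own trimming).
#' @export
import_alignments <- function(path, ref, mapq_floor = 20L) {
  refidx <- index_reference(ref)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos) &
    bitwAnd(b$flag, 0x100L) == 0L & bitwAnd(b$flag, 0x800L) == 0L
  if (!any(keep)) return(.empty_alignments())
  rname <- as.character(b$rname)[keep]
  bad <- setdiff(unique(rname), names(refidx$contigs))
  if (length(bad))
    stop("header/reference contig mismatch: ", paste(bad, collapse = ", "))
  out <- vector("list", sum(keep))
  idx <- which(keep)
  for (k in seq_along(idx)) {
    i <- idx[k]
    cg <- .parse_cigar(b$cigar[i])
    rev <- bitwAnd(b$flag[i], 0x10L) != 0L
    ref_span <- sum(cg$n[cg$op %in% c("M", "D", "N", "=", "X")])
    read_span <- sum(cg$n[cg$op %in% c("M", "I", "=", "X")])
    nops <- length(cg$op)
    clip_left <- if (cg$op[1] == "S") cg$n[1] else 0L
    clip_right <- if (cg$op[nops] == "S") cg$n[nops] else 0L
    seq <- as.character(b$seq[i])  # as stored: reverse-complemented if rev
    # the read's original-orientation 3' clip
    if (!rev) {
      remainder <- if (clip_right > 0L)
        substr(seq, nchar(seq) - clip_right + 1L, nchar(seq)) else ""
    } else {
      remainder <- if (clip_left > 0L)
        revcomp_str(substr(seq, 1L, clip_left)) else ""
    }
    start0 <- b$pos[i] - 1L
    out[[k]] <- data.frame(
      read_id = b$qname[i], contig = as.character(b$rname[i]),
      start = start0, end = start0 + ref_span,
      strand = if (rev) "-" else "+",
      aligned_span = read_span, mismatches = 0L,
      remainder = remainder, pass = 1L, trimmed_t_count = 0L,
      unique = b$mapq[i] >= mapq_floor, score = as.numeric(b$mapq[i]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write alignment records as a minimal SAM file
#'
#' Emits the records the way an external aligner would: aligned span as a
#' match block, the 3' remainder as a soft clip, minus-strand reads
#' reverse-complemented with the clip on the left. Used for round-trip
#' validation of [import_alignments()].
#'
#' @param alignments Alignment-record data.frame.
#' @param reads Named character vector of the full read sequences.
#' @param ref Reference accepted by [index_reference()].
#' @param path Output `.sam` path.
#' @param mapq MAPQ written for unique (default 60) records; non-unique
#'   records get MAPQ 0.
#' @return The path, invisibly.
#' @export
export_sam <- function(alignments, reads, ref, path, mapq = 60L) {
  refidx <- index_reference(ref)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refidx$contigs),
                   vapply(refidx$contigs, `[[`, integer(1), "len")))
  recs <- character(nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    full <- paste0(reads[[a$read_id]])
    # reconstruct the raw read as the aligner saw it (pass-2 trims shown
    # as part of the soft clip)
    rem <- paste0(a$remainder, strrep("T", a$trimmed_t_count))
    aligned_len <- a$aligned_span
    clip <- nchar(rem)
    if (a$strand == "+") {
      cigar <- paste0(aligned_len, "M", if (clip) paste0(clip, "S") else "")
      seq <- paste0(substr(full, 1L, aligned_len), rem)
      flag <- 0L
    } else {
      cigar <- paste0(if (clip) paste0(clip, "S") else "", aligned_len, "M")
      seq <- revcomp_str(paste0(substr(full, 1L, aligned_len), rem))
      flag <- 16L
    }
    recs[i] <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                       a$read_id, flag, a$contig, a$start + 1L,
                       if (a$unique) mapq else 0L, cigar, seq,
                       strrep("I", nchar(seq)))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
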