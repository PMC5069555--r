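# Independent brute-force oracles.
#
# brute_align() scores EVERY placement of a read on every position of both
# strands of every contig (no seeding), under the package's documented
# alignment model: 5'-anchored span, mismatch budget floor(k/25)*m per span
# k, span must end on a match, mismatch-free 3'-terminal guard window,
# score = span - 2*mismatches (ties -> shorter span), uniqueness by
# best-minus-second-best margin. Implemented as vectorized full-matrix
# scans, independent of the package's seed-and-extend path.

brute_align <- function(read, seqs, config = pipeline_config(),
                        mode = c("soft", "strict")) {
  mode <- match.arg(mode)
  if (methods::is(seqs, "DNAStringSet")) {
    seq_list <- lapply(seq_along(seqs), function(i) as.character(seqs[[i]]))
    names(seq_list) <- names(seqs)
  } else seq_list <- as.list(seqs)
  r <- strsplit(unname(read), "", fixed = TRUE)[[1]]
  n <- length(r)
  budget <- (seq_len(n) %/% 25L) * config$max_mismatch_per_25
  g <- config$tail_guard
  placements <- list()
  for (cname in names(seq_list)) {
    fwd <- seq_list[[cname]]
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      W <- if (strand == "+") strsplit(fwd, "", fixed = TRUE)[[1]] else
        strsplit(as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(fwd))), "", fixed = TRUE)[[1]]
      # mismatch matrix over all start positions, padded past contig end
      Wpad <- c(W, rep("!", n))
      M <- matrix(FALSE, nrow = n, ncol = L)
      for (k in seq_len(n))
        M[k, ] <- Wpad[seq_len(L) + k - 1L] != r[k]
      CM <- M * 1L
      for (k in seq_len(n)[-1]) CM[k, ] <- CM[k - 1L, ] + M[k, ]
      ok <- !M & (CM <= budget)
      # guard: no mismatch in the last min(k, g) bases
      for (k in seq_len(n)) {
        lag <- if (k > g) CM[k - g, ] else 0L
        ok[k, ] <- ok[k, ] & (CM[k, ] - lag) == 0L
      }
      score <- matrix(-Inf, nrow = n, ncol = L)
      score[ok] <- (row(CM) - 2L * CM)[ok]
      for (p in seq_len(L)) {
        col <- score[, p]
        if (all(!is.finite(col))) next
        S <- which.max(col)  # first max = shortest span on ties
        mm <- CM[S, p]
        if (S < config$min_span) next
        if (mode == "strict" && S < n) next
        if (mode == "soft" && (n - S) > config$max_remainder_frac * n) next
        placements[[length(placements) + 1L]] <-
          list(contig = cname, strand = strand, p = p, span = S, mm = mm,
               score = S - 2 * mm, L = L)
      }
    }
  }
  if (length(placements) == 0L) return(NULL)
  scores <- vapply(placements, `[[`, numeric(1), "score")
  ord <- order(-scores)
  best <- placements[[ord[1L]]]
  second <- if (length(ord) > 1L) scores[ord[2L]] else -Inf
  s0 <- if (best$strand == "+") best$p - 1L else best$L - best$p - best$span + 1L
  e0 <- if (best$strand == "+") best$p - 1L + best$span else best$L - best$p + 1L
  list(contig = best$contig, strand = best$strand, start = s0, end = e0,
       span = best$span, mm = best$mm, score = best$score,
       remainder = substr(unname(read), best$span + 1L, n),
       unique = (best$score - second) >= config$unique_margin)
}

# independent tail oracle: walk the genome base-by-base past the alignment
brute_tail <- function(raw_remainder, contig_seq, start0, end0, strand,
                       min_u = 4L) {
  down <- if (strand == "+") {
    substr(contig_seq, end0 + 1L, end0 + nchar(raw_remainder))
  } else {
    s <- max(start0 - nchar(raw_remainder) + 1L, 1L)
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(contig_seq, s, start0))))
  }
  tov <- 0L
  while (tov < nchar(raw_remainder) && tov < nchar(down) &&
         substr(raw_remainder, tov + 1L, tov + 1L) ==
         substr(down, tov + 1L, tov + 1L)) tov <- tov + 1L
  untail <- substr(raw_remainder, tov + 1L, nchar(raw_remainder))
  run <- 0L
  while (run < nchar(untail) &&
         substr(untail, nchar(untail) - run, nchar(untail) - run) == "T")
    run <- run + 1L
  cls <- if (!nzchar(untail)) "none"
  else if (run >= min_u) "U+"
  else if (length(unique(strsplit(untail, "")[[1]])) == 1L)
    chartr("T", "U", substr(untail, 1L, 1L))
  else "mixed"
  list(templated_overlap = tov, untemplated = untail, class = cls)
}

# truth-side junction overlap: leading bases of the true tail explainable
# by the genome immediately downstream of the true fragment end
truth_junction_overlap <- function(tail_seq, contig_seq, frag_start,
                                   frag_end, strand) {
  if (!nzchar(tail_seq)) return(0L)
  n <- nchar(tail_seq)
  down <- if (strand == "+") substr(contig_seq, frag_end + 1L, frag_end + n)
  else as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    substr(contig_seq, max(frag_start - n + 1L, 1L), frag_start))))
  j <- 0L
  while (j < n && j < nchar(down) &&
         substr(tail_seq, j + 1L, j + 1L) == substr(down, j + 1L, j + 1L))
    j <- j + 1L
  j
}
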