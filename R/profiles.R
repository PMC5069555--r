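# Positional summaries: tail-length histograms, per-category U+ fractions,
# scaled gene-body coverage matrices, and TSS-anchored metagene profiles.

#' Histograms of untemplated tail lengths
#'
#' One histogram per group (composition class, optionally also category),
#' computed on untemplated tail lengths only, with median and quartiles.
#' Empty groups report an NA median.
#'
#' @param calls Tail-call data.frame (annotated or not).
#' @param by Grouping columns (default `"class"`; use
#'   `c("class", "category")` for per-category panels).
#' @return List of class `tail_histograms`: `counts` (group columns,
#'   `length`, `count`) and `stats` (group columns, `n`, `median`, `q25`,
#'   `q75`).
#' @export
tail_length_histogram <- function(calls, by = "class") {
  stopifnot(all(by %in% names(calls)))
  calls <- calls[calls$untemplated_len > 0L, , drop = FALSE]
  if (nrow(calls) == 0L) {
    counts <- stats_df <- data.frame()
  } else {
    key <- interaction(calls[by], drop = TRUE, sep = "\r")
    counts <- do.call(rbind, lapply(levels(key), function(k) {
      sel <- key == k
      lens <- calls$untemplated_len[sel]
      tab <- table(lens)
      grp <- strsplit(k, "\r", fixed = TRUE)[[1]]
      cbind(as.data.frame(setNames(as.list(grp), by),
                          stringsAsFactors = FALSE)[
              rep(1L, length(tab)), , drop = FALSE],
            data.frame(length = as.integer(names(tab)),
                       count = as.integer(tab)))
    }))
    rownames(counts) <- NULL
    stats_df <- do.call(rbind, lapply(levels(key), function(k) {
      sel <- key == k
      lens <- calls$untemplated_len[sel]
      grp <- strsplit(k, "\r", fixed = TRUE)[[1]]
      cbind(as.data.frame(setNames(as.list(grp), by),
                          stringsAsFactors = FALSE),
            data.frame(n = length(lens), median = stats::median(lens),
                       q25 = unname(stats::quantile(lens, 0.25)),
                       q75 = unname(stats::quantile(lens, 0.75))))
    }))
    rownames(stats_df) <- NULL
  }
  structure(list(counts = counts, stats = stats_df, by = by),
            class = "tail_histograms")
}

#' Percentage of U+ reads per functional category
#'
#' @param calls Annotated tail calls (must carry `category` and `class`).
#' @param categories Optional category universe; members without any read
#'   are excluded from the table with a message.
#' @return Data.frame with `category`, `n_reads` (denominator), `n_uplus`
#'   and `pct_uplus`.
#' @export
uplus_fraction_by_category <- function(calls, categories = NULL) {
  stopifnot(all(c("category", "class") %in% names(calls)))
  calls <- calls[!is.na(calls$category), , drop = FALSE]
  cats <- intersect(clip_priority(), unique(calls$category))
  empty <- setdiff(categories %||% character(0), cats)
  out <- do.call(rbind, lapply(cats, function(cat) {
    sel <- calls$category == cat
    data.frame(category = cat, n_reads = sum(sel),
               n_uplus = sum(sel & calls$class == "U+"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(category = character(0), n_reads = integer(0),
                      n_uplus = integer(0))
  out$pct_uplus <- ifelse(out$n_reads > 0,
                          100 * out$n_uplus / out$n_reads, NA_real_)
  if (length(empty))
    message("categories with 0 reads excluded: ",
            paste(empty, collapse = ", "))
  out
}

# strand-aware bin of a 0-based position within a mature span:
# bin `bins` is the mature 3' end on either strand
.pos_to_bin <- function(pos, gs0, ge0, strand, bins) {
  len <- ge0 - gs0
  rel <- if (strand == "+") pos - gs0 else (ge0 - 1L) - pos
  pmin(pmax(floor(bins * rel / len) + 1L, 1L), bins)
}

#' Scaled gene-body coverage of uridylated reads
#'
#' Each gene's mature length is scaled to 100% and split into `bins` bins
#' (bin `bins` = mature 3' end on both strands). Read coverage (or anchor
#' density) of U+ calls is accumulated per bin and each row normalized to
#' max 1, reproducing the scaled heat-map representation of uridylated
#' read coverage over RNAs.
#'
#' @param calls Annotated tail calls (needs `gene_id`, `start`, `end`,
#'   `anchor`, `strand`, `class`).
#' @param index An [annotation_index()].
#' @param bins Number of body bins (default 100).
#' @param value `"coverage"` (aligned-interval coverage, default) or
#'   `"anchor"` (3'-anchor density).
#' @param classes Which composition classes to include (default `"U+"`).
#' @return Numeric matrix (genes x bins), rows normalized to `[0, 1]`,
#'   with gene ids as rownames and a `category` attribute.
#' @export
scaled_coverage <- function(calls, index, bins = 100L,
                            value = c("coverage", "anchor"),
                            classes = "U+") {
  value <- match.arg(value)
  stopifnot(inherits(index, "annotation_index"))
  calls <- calls[!is.na(calls$gene_id) & calls$class %in% classes, ,
                 drop = FALSE]
  g <- index$genes
  glen <- GenomicRanges::width(g)
  if (any(glen == 0L)) stop("gene model error: zero-length gene")
  ids <- unique(calls$gene_id)
  ids <- ids[order(match(g$category[match(ids, g$gene_id)],
                         index$priority), ids)]
  mat <- matrix(0, nrow = length(ids), ncol = bins,
                dimnames = list(ids, NULL))
  gi <- match(ids, g$gene_id)
  gs0 <- GenomicRanges::start(g)[gi] - 1L
  ge0 <- GenomicRanges::end(g)[gi]
  gstr <- as.character(GenomicRanges::strand(g))[gi]
  for (k in seq_along(ids)) {
    sel <- which(calls$gene_id == ids[k])
    for (i in sel) {
      if (value == "anchor") {
        pos <- calls$anchor[i]
        if (pos < gs0[k] || pos >= ge0[k]) next
        b <- .pos_to_bin(pos, gs0[k], ge0[k], gstr[k], bins)
        mat[k, b] <- mat[k, b] + 1
      } else {
        s <- max(calls$start[i], gs0[k]); e <- min(calls$end[i], ge0[k])
        if (e <= s) next
        bs <- .pos_to_bin(seq(s, e - 1L), gs0[k], ge0[k], gstr[k], bins)
        tb <- tabulate(bs, nbins = bins)
        mat[k, ] <- mat[k, ] + (tb > 0)  # per-read bin coverage
      }
    }
    m <- max(mat[k, ])
    if (m > 0) mat[k, ] <- mat[k, ] / m
  }
  attr(mat, "category") <- g$category[gi]
  mat
}

moving_average <- function(x, width = 5L) {
  if (width <= 1L) return(x)
  k <- rep(1 / width, width)
  as.numeric(stats::filter(x, k, sides = 2, circular = FALSE))
}

#' TSS-anchored metagene profile of U+ reads
#'
#' Each U+ call contributes one count at the offset of its 3' anchor from
#' the nearest TSS, signed in the TSS strand's orientation (negative =
#' upstream of the TSS). Calls on the TSS strand feed the sense profile,
#' opposite-strand calls the antisense profile. Peaks are the offsets of
#' the maxima after moving-average smoothing; in published data the sense
#' peak sits near +50 nt and the antisense peak near -200 nt from mRNA
#' TSSs.
#'
#' @param calls Tail calls (needs `contig`, `anchor`, `strand`, `class`).
#' @param tss Data.frame with `contig`, `pos` (0-based TSS position),
#'   `strand` (and optionally `gene_id`), or a `GRanges` of width-1 TSS
#'   positions.
#' @param window Half-window in nt (default 500).
#' @param smooth Moving-average width in nt for peak finding (default 5).
#' @param classes Composition classes counted (default `"U+"`).
#' @return List of class `metagene_profile`: `profile` (data.frame with
#'   `offset`, `sense`, `antisense`), `peaks` (named vector, NA when a
#'   profile is empty), plus the parameters and the TSS table.
#' @export
tss_metagene <- function(calls, tss, window = 500L, smooth = 5L,
                         classes = "U+") {
  if (methods::is(tss, "GRanges")) {
    tss <- data.frame(
      contig = as.character(GenomicRanges::seqnames(tss)),
      pos = GenomicRanges::start(tss) - 1L,
      strand = as.character(GenomicRanges::strand(tss)),
      stringsAsFactors = FALSE)
  }
  if (nrow(tss) == 0L) stop("empty TSS list")
  calls <- calls[calls$class %in% classes, , drop = FALSE]
  offsets <- seq(-window, window)
  no <- length(offsets)
  sense <- antisense <- numeric(no)
  if (nrow(calls)) {
    # signed offset of every call to every TSS; nearest TSS wins
    off <- matrix(Inf, nrow = nrow(calls), ncol = nrow(tss))
    for (j in seq_len(nrow(tss))) {
      same <- calls$contig == tss$contig[j]
      d <- calls$anchor - tss$pos[j]
      if (tss$strand[j] == "-") d <- -d
      off[same, j] <- d[same]
    }
    jbest <- max.col(-abs(off), ties.method = "first")
    obest <- off[cbind(seq_len(nrow(calls)), jbest)]
    keep <- is.finite(obest) & abs(obest) <= window
    is_sense <- calls$strand == tss$strand[jbest]
    idx <- obest + window + 1L
    sense <- tabulate(idx[keep & is_sense], nbins = no)
    antisense <- tabulate(idx[keep & !is_sense], nbins = no)
  }
  peak_of <- function(v) {
    if (all(v == 0)) return(NA_integer_)
    sm <- moving_average(v, smooth)
    sm[is.na(sm)] <- 0
    offsets[which.max(sm)]
  }
  structure(list(
    profile = data.frame(offset = offsets, sense = as.numeric(sense),
                         antisense = as.numeric(antisense)),
    peaks = c(sense = peak_of(sense), antisense = peak_of(antisense)),
    window = window, smooth = smooth, tss = tss),
    class = "metagene_profile")
}

#' Overlay an external signal track on a metagene profile
#'
#' Averages a user-supplied bedGraph signal (e.g. RNAP II ChIP-seq
#' coverage) over the same TSS-relative offsets as the metagene, producing
#' a side-by-side two-track profile. No statistics are computed across
#' tracks; the external signal is consumed as-is.
#'
#' @param metagene A `metagene_profile` from [tss_metagene()].
#' @param track Path to a bedGraph file, or a `GRanges` with a `score`
#'   column.
#' @return The profile with an `overlay` column added; TSS on contigs
#'   missing from the track are skipped with a message.
#' @export
overlay_signal_track <- function(metagene, track) {
  stopifnot(inherits(metagene, "metagene_profile"))
  if (is.character(track))
    track <- rtracklayer::import(track, format = "bedGraph")
  tss <- metagene$tss
  tcontigs <- unique(as.character(GenomicRanges::seqnames(track)))
  if (!any(tss$contig %in% tcontigs))
    stop("assembly mismatch: no TSS contig found in the signal track")
  skip <- !(tss$contig %in% tcontigs)
  if (any(skip))
    message(sum(skip), " TSS on contigs missing from the track skipped")
  tss <- tss[!skip, , drop = FALSE]
  offsets <- metagene$profile$offset
  acc <- numeric(length(offsets)); nacc <- 0L
  # per-base signal vector per contig
  for (ctg in unique(tss$contig)) {
    tr <- track[as.character(GenomicRanges::seqnames(track)) == ctg]
    L <- max(GenomicRanges::end(tr))
    sig <- numeric(L)
    for (k in seq_along(tr))
      sig[GenomicRanges::start(tr)[k]:GenomicRanges::end(tr)[k]] <-
        S4Vectors::mcols(tr)$score[k]
    for (i in which(tss$contig == ctg)) {
      pos0 <- tss$pos[i]
      idx <- if (tss$strand[i] == "+") pos0 + offsets + 1L
             else pos0 - offsets + 1L
      v <- ifelse(idx >= 1L & idx <= L, sig[pmax(pmin(idx, L), 1L)], 0)
      acc <- acc + v
      nacc <- nacc + 1L
    }
  }
  metagene$profile$overlay <- if (nacc > 0L) acc / nacc else acc
  metagene
}

#' Write a metagene profile as TSV
#'
#' @param metagene A `metagene_profile`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_metagene <- function(metagene, path) {
  hdr <- sprintf(paste0("tss metagene: window=%d smooth=%d ",
                        "peak_sense=%s peak_antisense=%s ",
                        "(offsets signed in TSS orientation, ",
                        "negative = upstream)"),
                 metagene$window, metagene$smooth,
                 metagene$peaks["sense"], metagene$peaks["antisense"])
  write_tsv(metagene$profile, path, header_lines = hdr)
}
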