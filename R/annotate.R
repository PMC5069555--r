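# Priority-ordered functional annotation: assign reads/tail calls to gene
# categories (tRNA > miRNA > snRNA > 5S rRNA > miscRNA > snoRNA > mRNA >
# lincRNA), position anchors relative to mature 3' ends, tRNA subregions,
# and snRNA-style 3'-end states (Mat / Trim / ext).

#' Build an annotation index
#'
#' Wraps a gene set into a strand-aware interval index. tRNA genes are
#' queried with a +/-60 nt extension (so pre-tRNA leaders and trailers
#' annotate to the tRNA) while their mature bounds are retained.
#'
#' @param genes A [GenomicRanges::GRanges] with metadata columns `gene_id`
#'   and `category`, or a data.frame with `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `gene_id`, `category`.
#' @param features Optional `GRanges` of substructure (type `exon`,
#'   `intron`, `five_prime_UTR`, `CDS`, `three_prime_UTR`, `TSS`; metadata
#'   `gene_id`), as produced by [generate_reference()].
#' @param trna_extension Extension of tRNA query intervals (default 60 nt).
#' @param priority Category priority order (default [clip_priority()]).
#' @return An object of class `annotation_index`.
#' @export
annotation_index <- function(genes, features = NULL, trna_extension = 60L,
                             priority = clip_priority()) {
  if (is.data.frame(genes)) {
    genes <- GenomicRanges::GRanges(
      seqnames = genes$contig,
      ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
      strand = genes$strand, gene_id = genes$gene_id,
      category = genes$category)
  }
  stopifnot(methods::is(genes, "GRanges"))
  need <- c("gene_id", "category")
  if (!all(need %in% names(S4Vectors::mcols(genes))))
    stop("genes must carry gene_id and category metadata columns")
  bad <- setdiff(unique(genes$category), .CATEGORIES)
  if (length(bad))
    stop("unknown category label(s): ", paste(bad, collapse = ", "),
         "; accepted labels: ", paste(.CATEGORIES, collapse = ", "))
  query <- genes
  is_trna <- genes$category == "tRNA"
  if (any(is_trna)) {
    ext <- GenomicRanges::resize(
      query[is_trna],
      width = GenomicRanges::width(query[is_trna]) + 2L * trna_extension,
      fix = "center")
    GenomicRanges::start(ext) <- pmax(GenomicRanges::start(ext), 1L)
    query[is_trna] <- ext
  }
  structure(list(genes = genes, query = query, features = features,
                 priority = priority,
                 trna_extension = as.integer(trna_extension)),
            class = "annotation_index")
}

#' Load an annotation from GFF3 or BED
#'
#' GFF3 records must carry the functional category in a `category` (or
#' `gene_biotype`/`biotype`) attribute; for BED the category is taken from
#' the name field, with an optional `"<gene_id>|<category>"` convention.
#' Unknown categories are rejected with a listing of accepted labels.
#' Coordinates follow the file conventions (GFF3 1-based inclusive, BED
#' 0-based half-open) and are held 0-based half-open internally.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param category_map Optional named character vector mapping file labels
#'   to accepted category labels (e.g. `c("5S rRNA" = "5S_rRNA")`).
#' @param trna_extension,priority Passed to [annotation_index()].
#' @return An `annotation_index`.
#' @export
load_annotation <- function(path, category_map = NULL,
                            trna_extension = 60L,
                            priority = clip_priority()) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff3", "gff")) {
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    cat_col <- intersect(c("category", "gene_biotype", "biotype"),
                         names(mc))
    is_gene <- if ("type" %in% names(mc))
      as.character(mc$type) %in% c("gene", .CATEGORIES) else
      rep(TRUE, length(gr))
    genes <- gr[is_gene]
    cats <- if (length(cat_col))
      as.character(S4Vectors::mcols(genes)[[cat_col[1]]]) else
      as.character(S4Vectors::mcols(genes)$type)
    ids <- S4Vectors::mcols(genes)$ID
    if (is.null(ids)) ids <- S4Vectors::mcols(genes)$Name
    if (is.null(ids)) ids <- sprintf("gene_%05d", seq_along(genes))
    feats <- gr[!is_gene]
    features <- NULL
    if (length(feats)) {
      type <- as.character(S4Vectors::mcols(feats)$type)
      parent <- S4Vectors::mcols(feats)$Parent
      parent <- if (is.null(parent)) rep(NA_character_, length(feats)) else
        vapply(as.list(parent), function(x)
          if (length(x)) as.character(x[[1]]) else NA_character_,
          character(1))
      features <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(feats),
        ranges = IRanges::ranges(feats),
        strand = GenomicRanges::strand(feats),
        type = type, gene_id = parent)
    }
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm)) stop("BED annotation needs a name field with the ",
                          "category (or 'gene_id|category')")
    parts <- strsplit(nm, "|", fixed = TRUE)
    ids <- vapply(parts, `[`, character(1), 1L)
    cats <- vapply(parts, function(x) x[length(x)], character(1))
    genes <- gr
    features <- NULL
  } else stop("unsupported annotation format: ", ext)

  if (!is.null(category_map)) {
    hit <- cats %in% names(category_map)
    cats[hit] <- category_map[cats[hit]]
  }
  bad <- setdiff(unique(cats), .CATEGORIES)
  if (length(bad))
    stop("unknown category label(s): ", paste(bad, collapse = ", "),
         "; accepted labels: ", paste(.CATEGORIES, collapse = ", "))
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::ranges(genes),
    strand = GenomicRanges::strand(genes),
    gene_id = ids, category = cats)
  annotation_index(out, features = features,
                   trna_extension = trna_extension, priority = priority)
}

# intervals: data.frame with contig, start, end (0-based h.o.), strand
.intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$contig,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = pmax(intervals$end,
                                         intervals$start + 1L)),
    strand = intervals$strand)
}

#' Assign intervals to gene categories by priority
#'
#' Among all same-strand overlapping genes, the category earliest in the
#' priority order wins; ties within a category are broken by largest
#' overlap, then lexicographic gene id. tRNA genes match within their
#' +/-60 nt extended span.
#'
#' @param index An [annotation_index()].
#' @param intervals Data.frame with `contig`, `start`, `end` (0-based
#'   half-open) and `strand`, one row per read/call.
#' @return Data.frame with `gene_id` and `category` (NA when unannotated),
#'   row-parallel to `intervals`.
#' @export
assign_category <- function(index, intervals) {
  stopifnot(inherits(index, "annotation_index"))
  n <- nrow(intervals)
  res <- data.frame(gene_id = rep(NA_character_, n),
                    category = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L || length(index$query) == 0L) return(res)
  q <- .intervals_to_granges(intervals)
  ov <- GenomicRanges::findOverlaps(q, index$query, ignore.strand = FALSE)
  if (length(ov) == 0L) return(res)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  olap <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(q)[qh], GenomicRanges::ranges(index$query)[sh]))
  rank <- match(index$genes$category[sh], index$priority)
  rank[is.na(rank)] <- length(index$priority) + 1L
  ord <- order(qh, rank, -olap, index$genes$gene_id[sh])
  keep <- ord[!duplicated(qh[ord])]
  res$gene_id[qh[keep]] <- index$genes$gene_id[sh[keep]]
  res$category[qh[keep]] <- index$genes$category[sh[keep]]
  res
}

# strand-aware signed offset of an anchor from the mature 3' end
# (0 = anchor at the last mature base)
.anchor_offset <- function(anchor, gstart0, gend0, strand) {
  ifelse(strand == "+", anchor - (gend0 - 1L), gstart0 - anchor)
}

#' Position a tail-call anchor within a gene model
#'
#' Computes the strand-aware signed offset of the anchor (last templated
#' base) from the gene's mature 3' end, and the region: `5' leader`
#' (upstream of the mature span), `mature`, or `3' extension` (downstream
#' of the mature 3' end, where uridylated precursors and trimming
#' intermediates accumulate). For mRNA genes with substructure the anchor
#' is additionally classified into 5'UTR/CDS/3'UTR/intron; for tRNAs into
#' cloverleaf subregions via [trna_subregion()].
#'
#' @param index An [annotation_index()].
#' @param anchors Data.frame with `contig`, `anchor` (0-based), `strand`
#'   and `gene_id`.
#' @return Data.frame with `offset`, `region` and `subfeature`,
#'   row-parallel to `anchors`.
#' @export
assign_region <- function(index, anchors) {
  stopifnot(inherits(index, "annotation_index"))
  g <- index$genes
  gi <- match(anchors$gene_id, g$gene_id)
  if (anyNA(gi[!is.na(anchors$gene_id)]))
    stop("gene model error: gene id(s) absent from the index")
  gs0 <- GenomicRanges::start(g)[gi] - 1L
  ge0 <- GenomicRanges::end(g)[gi]
  gstr <- as.character(GenomicRanges::strand(g))[gi]
  cat <- g$category[gi]
  off <- .anchor_offset(anchors$anchor, gs0, ge0, anchors$strand)
  mlen <- ge0 - gs0
  region <- ifelse(off > 0L, "3' extension",
                   ifelse(off <= -mlen, "5' leader", "mature"))
  sub <- rep(NA_character_, nrow(anchors))

  # mRNA: classify by substructure overlap of the anchor base
  is_m <- which(!is.na(cat) & cat == "mRNA")
  if (length(is_m) && !is.null(index$features) &&
      length(index$features)) {
    f <- index$features
    keep <- f$type %in% c("five_prime_UTR", "CDS", "three_prime_UTR",
                          "intron")
    f <- f[keep]
    if (length(f)) {
      pts <- GenomicRanges::GRanges(
        seqnames = anchors$contig[is_m],
        ranges = IRanges::IRanges(start = anchors$anchor[is_m] + 1L,
                                  width = 1L),
        strand = anchors$strand[is_m])
      ov <- GenomicRanges::findOverlaps(pts, f, ignore.strand = FALSE)
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      same <- f$gene_id[sh] == anchors$gene_id[is_m][qh]
      # prefer UTR labels over CDS where they overlap
      pref <- match(f$type[sh],
                    c("five_prime_UTR", "three_prime_UTR", "intron", "CDS"))
      ord <- order(qh, !same, pref)
      keep1 <- ord[!duplicated(qh[ord])]
      lab <- c(five_prime_UTR = "5'UTR", CDS = "CDS",
               three_prime_UTR = "3'UTR", intron = "intron")
      sub[is_m[qh[keep1]]] <- lab[f$type[sh[keep1]]]
    }
  }

  # tRNA: cloverleaf subregion from the position within the mature span
  is_t <- which(!is.na(cat) & cat == "tRNA")
  for (i in is_t) {
    pos <- if (anchors$strand[i] == "+") anchors$anchor[i] - gs0[i]
           else (ge0[i] - 1L) - anchors$anchor[i]
    sub[i] <- if (pos < 0L) "5' trailer"
              else if (pos >= mlen[i]) "3' trailer"
              else trna_subregion(pos, mlen[i],
                                  extension = index$trna_extension)
  }
  data.frame(offset = off, region = region, subfeature = sub,
             stringsAsFactors = FALSE)
}

#' Canonical tRNA arm partition (fractions of the mature length)
#'
#' A documented stand-in for structure-derived arm boundaries: the mature
#' tRNA is partitioned linearly into acceptor stem (0--18%), D-arm
#' (18--44%), anticodon arm (44--66%) and T-loop (66--100%); positions
#' outside the mature span are 5'/3' trailers.
#'
#' @return Named numeric vector of right boundaries (fractions).
#' @export
trna_arm_fractions <- function() {
  c(`acceptor stem` = 0.18, `D-arm` = 0.44, `anticodon arm` = 0.66,
    `T-loop` = 1.0)
}

#' tRNA cloverleaf subregion of a position
#'
#' @param pos Position relative to the mature tRNA start, 0-based
#'   (negative = upstream).
#' @param mature_length Mature tRNA length (nt).
#' @param boundaries Arm partition as in [trna_arm_fractions()].
#' @param extension Extended span half-width; positions outside
#'   `[-extension, mature_length + extension)` raise a range error.
#' @return One of `"5' trailer"`, `"acceptor stem"`, `"D-arm"`,
#'   `"anticodon arm"`, `"T-loop"`, `"3' trailer"`.
#' @export
trna_subregion <- function(pos, mature_length,
                           boundaries = trna_arm_fractions(),
                           extension = 60L) {
  if (pos < -extension || pos >= mature_length + extension)
    stop("position outside the extended tRNA span")
  if (pos < 0L) return("5' trailer")
  if (pos >= mature_length) return("3' trailer")
  frac <- (pos + 0.5) / mature_length
  names(boundaries)[which(frac <= boundaries)[1]]
}

#' Per-read 3'-end state relative to the mature 3' end
#'
#' @param offset Signed offset of the 3' anchor from the mature 3' end.
#' @return `"Mat"` (offset 0), `"Trim"` (negative) or `"ext"` (positive).
#' @export
end_state <- function(offset) {
  ifelse(offset == 0L, "Mat", ifelse(offset < 0L, "Trim", "ext"))
}

#' Tally snRNA-style 3'-end states per gene
#'
#' Counts reads with mature (Mat), trimmed (Trim) or extended (ext) 3' ends
#' per gene, plus the number of U+ reads (untemplated 3' oligo(U)).
#'
#' @param calls Annotated tail calls with `gene_id`, `offset` and `class`.
#' @param gene_ids Optional gene ids to include even with zero reads.
#' @return Data.frame with columns `gene_id`, `Mat`, `Trim`, `ext`, `uplus`.
#' @export
classify_end_state <- function(calls, gene_ids = NULL) {
  calls <- calls[!is.na(calls$gene_id) & !is.na(calls$offset), ,
                 drop = FALSE]
  ids <- gene_ids %||% sort(unique(calls$gene_id))
  out <- data.frame(gene_id = ids, Mat = 0L, Trim = 0L, ext = 0L,
                    uplus = 0L, stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(out)
  st <- end_state(calls$offset)
  for (i in seq_along(ids)) {
    sel <- calls$gene_id == ids[i]
    out$Mat[i] <- sum(sel & st == "Mat")
    out$Trim[i] <- sum(sel & st == "Trim")
    out$ext[i] <- sum(sel & st == "ext")
    out$uplus[i] <- sum(sel & calls$class == "U+")
  }
  out
}

#' Annotate tail calls with gene, category, region and offset
#'
#' Categories are assigned from the aligned read interval by priority
#' ([assign_category()]). Calls whose interval overlaps no gene are given a
#' second chance through a downstream window: anchors within
#' `downstream_window` nt past a gene's 3' end (same strand) are attributed
#' to that gene as 3' extensions.
#'
#' @param calls Tail-call data.frame from [call_tails()].
#' @param index An [annotation_index()].
#' @param downstream_window Window past annotated 3' ends (default 200 nt).
#' @return The calls with added `gene_id`, `category`, `offset`, `region`
#'   and `subfeature` columns.
#' @export
annotate_calls <- function(calls, index, downstream_window = 200L) {
  if (nrow(calls) == 0L) {
    calls$gene_id <- character(0); calls$category <- character(0)
    calls$offset <- integer(0); calls$region <- character(0)
    calls$subfeature <- character(0)
    return(calls)
  }
  asg <- assign_category(index, calls)
  miss <- which(is.na(asg$gene_id))
  if (length(miss) && downstream_window > 0L && length(index$genes)) {
    g <- index$genes
    gstr <- as.character(GenomicRanges::strand(g))
    dw <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(g),
      ranges = IRanges::IRanges(
        start = ifelse(gstr == "-",
                       pmax(GenomicRanges::start(g) - downstream_window, 1L),
                       GenomicRanges::start(g)),
        end = ifelse(gstr == "-", GenomicRanges::end(g),
                     GenomicRanges::end(g) + downstream_window)),
      strand = gstr, gene_id = g$gene_id, category = g$category)
    idx2 <- structure(list(genes = g, query = dw, features = index$features,
                           priority = index$priority,
                           trna_extension = index$trna_extension),
                      class = "annotation_index")
    pts <- data.frame(contig = calls$contig[miss],
                      start = calls$anchor[miss],
                      end = calls$anchor[miss] + 1L,
                      strand = calls$strand[miss])
    asg2 <- assign_category(idx2, pts)
    asg$gene_id[miss] <- asg2$gene_id
    asg$category[miss] <- asg2$category
  }
  calls$gene_id <- asg$gene_id
  calls$category <- asg$category
  has <- !is.na(calls$gene_id)
  calls$offset <- NA_integer_
  calls$region <- NA_character_
  calls$subfeature <- NA_character_
  if (any(has)) {
    reg <- assign_region(index, calls[has, c("contig", "anchor", "strand",
                                             "gene_id")])
    calls$offset[has] <- reg$offset
    calls$region[has] <- reg$region
    calls$subfeature[has] <- reg$subfeature
  }
  calls
}
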