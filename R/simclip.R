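# Synthetic CLIP-read simulator: reference + annotation generator, RNase T1
# fragmentation, non-templated 3' tailing, intramolecular-ligation chimeras,
# and a seeded end-to-end run that writes FASTQ + a ground-truth TSV.

#' Specification of a synthetic reference and annotation
#'
#' Describes the annotation universe the simulator emits: how many genes of
#' each functional category, their length ranges, and the layout of the
#' single synthetic contig. Categories mirror the annotation priority scheme
#' (tRNA, miRNA hairpin, snRNA, 5S rRNA, miscRNA, snoRNA, mRNA, lincRNA,
#' pseudogene).
#'
#' @param n_genes Named integer vector of gene counts per category. Names
#'   must come from `clip_priority()`. Missing categories default to 0.
#' @param gene_length Named list of `c(min, max)` length ranges (nt) per
#'   category; sensible defaults are supplied (e.g. tRNA 70--90 nt,
#'   mRNA 500--800 nt). All lengths must be >= 20.
#' @param spacer Intergenic spacer length in nt (default 300).
#' @param gc GC content of the random sequence (default 0.5).
#' @param minus_strand_fraction Fraction of genes placed on the minus strand
#'   (default 0; all genes forward).
#' @param n_duplicate_loci Number of genes whose sequence is inserted a
#'   second time elsewhere on the contig, creating multi-mapping source loci
#'   (default 0).
#' @param n_snoRNA_hosted Number of additional snoRNA annotations nested
#'   inside mRNA introns, producing deliberately overlapping intervals for
#'   priority testing (default 0; requires at least one mRNA).
#' @return An object of class `reference_spec`.
#' @seealso [generate_reference()]
#' @export
reference_spec <- function(n_genes = c(tRNA = 2, miRNA = 2, snRNA = 2,
                                       `5S_rRNA` = 1, miscRNA = 1,
                                       snoRNA = 1, mRNA = 2, lincRNA = 1),
                           gene_length = NULL,
                           spacer = 300L, gc = 0.5,
                           minus_strand_fraction = 0,
                           n_duplicate_loci = 0L,
                           n_snoRNA_hosted = 0L) {
  defaults_len <- list(
    tRNA = c(70, 90), miRNA = c(70, 90), snRNA = c(100, 190),
    `5S_rRNA` = c(115, 125), miscRNA = c(250, 330), snoRNA = c(90, 150),
    mRNA = c(500, 800), lincRNA = c(300, 500), pseudogene = c(200, 400))
  counts <- setNames(integer(length(.CATEGORIES)), .CATEGORIES)
  if (length(n_genes)) {
    bad <- setdiff(names(n_genes), .CATEGORIES)
    if (length(bad))
      stop("unknown categories in n_genes: ", paste(bad, collapse = ", "),
           "; accepted: ", paste(.CATEGORIES, collapse = ", "))
    counts[names(n_genes)] <- as.integer(n_genes)
  }
  if (any(counts < 0L)) stop("gene counts must be >= 0")
  if (!is.null(gene_length)) {
    bad <- setdiff(names(gene_length), .CATEGORIES)
    if (length(bad)) stop("unknown categories in gene_length: ",
                          paste(bad, collapse = ", "))
    defaults_len[names(gene_length)] <- gene_length
  }
  if (any(vapply(defaults_len, min, numeric(1)) < 20))
    stop("gene lengths must be >= 20 nt")
  if (spacer < 0) stop("spacer must be >= 0")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (n_snoRNA_hosted > 0L && counts["mRNA"] == 0L)
    stop("n_snoRNA_hosted requires at least one mRNA gene")
  structure(list(n_genes = counts, gene_length = defaults_len,
                 spacer = as.integer(spacer), gc = gc,
                 minus_strand_fraction = minus_strand_fraction,
                 n_duplicate_loci = as.integer(n_duplicate_loci),
                 n_snoRNA_hosted = as.integer(n_snoRNA_hosted)),
            class = "reference_spec")
}

#' Model of non-templated 3' tailing
#'
#' Describes the tail-composition mixture and tail-length distributions the
#' simulator appends to RNase T1 fragments. Defaults match the observed
#' uridylome structure: oligo(U) tails of 4--20 nt with median 7, while A, C
#' and G additions are short runs of 1--3 nt.
#'
#' @param p_comp Named probabilities for tail composition
#'   (`U`, `A`, `C`, `G`, `none`); must sum to 1.
#' @param u_median Target median oligo(U) tail length (default 7 nt).
#' @param u_support Integer range `c(min, max)` of U tail lengths
#'   (default `c(4, 20)`); minimum must be >= 1.
#' @param acg_support Integer range of A/C/G run lengths (default `c(1, 3)`).
#' @param junction_bias Probability that a tailed fragment is chosen such
#'   that the genomic base immediately downstream equals the first tail base
#'   (templated-junction ambiguity; default 0).
#' @return An object of class `tail_model`. U tail lengths follow a
#'   truncated shifted Poisson: `len = u_min + Pois(u_median - u_min)`
#'   truncated to the support, which has median `u_median`.
#' @export
tail_model <- function(p_comp = c(U = 0.45, A = 0.06, C = 0.06, G = 0.06,
                                  none = 0.37),
                       u_median = 7L, u_support = c(4L, 20L),
                       acg_support = c(1L, 3L), junction_bias = 0) {
  need <- c("U", "A", "C", "G", "none")
  if (!setequal(names(p_comp), need))
    stop("p_comp must have names U, A, C, G, none")
  p_comp <- p_comp[need]
  if (any(p_comp < 0) || any(p_comp > 1) ||
      abs(sum(p_comp) - 1) > 1e-8)
    stop("p_comp entries must lie in [0,1] and sum to 1")
  if (u_support[1] < 1L) stop("u_support minimum must be >= 1")
  if (u_median < u_support[1] || u_median > u_support[2])
    stop("u_median must lie within u_support")
  if (junction_bias < 0 || junction_bias > 1)
    stop("junction_bias must be in [0,1]")
  lens <- u_support[1]:u_support[2]
  pmf <- dpois(lens - u_support[1], lambda = u_median - u_support[1])
  structure(list(p_comp = p_comp, u_median = as.integer(u_median),
                 u_support = as.integer(u_support),
                 acg_support = as.integer(acg_support),
                 junction_bias = junction_bias,
                 u_lens = lens, u_pmf = pmf / sum(pmf)),
            class = "tail_model")
}

# draw one tail (DNA alphabet); returns list(seq, class)
sample_tail <- function(model) {
  cls <- sample(names(model$p_comp), 1L, prob = model$p_comp)
  if (cls == "none") return(list(seq = "", class = "none"))
  if (cls == "U") {
    len <- sample(model$u_lens, 1L, prob = model$u_pmf)
    return(list(seq = strrep("T", len), class = "U"))
  }
  len <- sample_int_range(model$acg_support[1], model$acg_support[2])
  list(seq = strrep(cls, len), class = cls)
}

#' Generate a synthetic reference genome and annotation
#'
#' Lays out the requested genes on a single contig (`chrS`) separated by
#' random spacers, and returns the sequence together with a gene-level
#' annotation. mRNA genes carry a marked TSS and an exon1--intron--exon2
#' structure with UTRs, so that 5'-proximal fragments spanning exon 1 into
#' intron 1 can be simulated. Deterministic for a fixed seed.
#'
#' @param spec A [reference_spec()].
#' @param seed Integer seed.
#' @return A list of class `clip_reference` with elements `seqs`
#'   (a [Biostrings::DNAStringSet]), `genes` (a [GenomicRanges::GRanges]
#'   with `gene_id`, `category` metadata), and `features` (a `GRanges` of
#'   mRNA substructure: exon, intron, five_prime_UTR, CDS, three_prime_UTR,
#'   TSS).
#' @export
generate_reference <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "reference_spec"))
  set.seed(seed)
  counts <- spec$n_genes
  cats <- rep(names(counts), counts)
  if (length(cats)) cats <- sample(cats)  # shuffle gene order on the contig

  pieces <- character(0)
  offset <- 0L  # 0-based position where the next piece starts
  g_start <- integer(0); g_end <- integer(0); g_strand <- character(0)
  g_cat <- character(0); g_id <- character(0)
  f_start <- integer(0); f_end <- integer(0); f_strand <- character(0)
  f_type <- character(0); f_gene <- character(0)
  idx_by_cat <- setNames(integer(length(.CATEGORIES)), .CATEGORIES)
  tx_seqs <- character(0)  # transcript sequence per gene, for duplication

  push <- function(s) { pieces[[length(pieces) + 1L]] <<- s
                        offset <<- offset + nchar(s) }

  add_feature <- function(type, s0, e0, strand, gene) {
    f_start <<- c(f_start, s0); f_end <<- c(f_end, e0)
    f_strand <<- c(f_strand, strand); f_type <<- c(f_type, type)
    f_gene <<- c(f_gene, gene)
  }

  push(random_dna(spec$spacer, spec$gc))
  for (cat in cats) {
    idx_by_cat[cat] <- idx_by_cat[cat] + 1L
    gid <- sprintf("%s_%02d", cat, idx_by_cat[cat])
    rng <- spec$gene_length[[cat]]
    len <- sample_int_range(rng[1], rng[2])
    strand <- if (runif(1) < spec$minus_strand_fraction) "-" else "+"
    tx <- random_dna(len, spec$gc)
    gs0 <- offset; ge0 <- offset + len
    push(if (strand == "+") tx else revcomp_str(tx))
    g_start <- c(g_start, gs0); g_end <- c(g_end, ge0)
    g_strand <- c(g_strand, strand); g_cat <- c(g_cat, cat)
    g_id <- c(g_id, gid); tx_seqs <- c(tx_seqs, tx)

    if (cat == "mRNA") {
      # exon1 (40%) - intron (20%) - exon2 (40%), UTRs at the ends
      e1 <- max(40L, as.integer(0.4 * len))
      ivl <- max(20L, as.integer(0.2 * len))
      e2 <- len - e1 - ivl
      utr5 <- min(30L, e1 %/% 2L); utr3 <- min(30L, e2 %/% 2L)
      # transcript-space intervals, 0-based half-open
      tx_feats <- list(
        c("exon", 0L, e1), c("intron", e1, e1 + ivl),
        c("exon", e1 + ivl, len),
        c("five_prime_UTR", 0L, utr5), c("CDS", utr5, e1),
        c("CDS", e1 + ivl, len - utr3),
        c("three_prime_UTR", len - utr3, len), c("TSS", 0L, 1L))
      for (tf in tx_feats) {
        a <- as.integer(tf[2]); b <- as.integer(tf[3])
        if (strand == "+") add_feature(tf[1], gs0 + a, gs0 + b, strand, gid)
        else add_feature(tf[1], ge0 - b, ge0 - a, strand, gid)
      }
    }
    push(random_dna(spec$spacer, spec$gc))
  }

  # duplicate loci: reinsert identical transcript sequence -> multi-mappers
  n_dup <- min(spec$n_duplicate_loci, length(g_id))
  if (n_dup > 0L) {
    for (i in seq_len(n_dup)) {
      gs0 <- offset; ge0 <- offset + nchar(tx_seqs[i])
      push(if (g_strand[i] == "+") tx_seqs[i] else revcomp_str(tx_seqs[i]))
      g_start <- c(g_start, gs0); g_end <- c(g_end, ge0)
      g_strand <- c(g_strand, g_strand[i]); g_cat <- c(g_cat, g_cat[i])
      g_id <- c(g_id, paste0(g_id[i], "_copy"))
      push(random_dna(spec$spacer, spec$gc))
    }
  }

  # hosted snoRNAs: extra intervals nested inside mRNA introns
  if (spec$n_snoRNA_hosted > 0L) {
    introns <- which(f_type == "intron")
    if (length(introns) == 0L) stop("no mRNA introns available for hosting")
    picks <- rep(introns, length.out = spec$n_snoRNA_hosted)
    for (k in seq_along(picks)) {
      i <- picks[k]
      iw <- f_end[i] - f_start[i]
      w <- min(max(30L, iw - 10L), iw)
      s0 <- f_start[i] + (iw - w) %/% 2L
      g_start <- c(g_start, s0); g_end <- c(g_end, s0 + w)
      g_strand <- c(g_strand, f_strand[i]); g_cat <- c(g_cat, "snoRNA")
      g_id <- c(g_id, sprintf("snoRNA_hosted_%02d", k))
    }
  }

  contig <- paste(pieces, collapse = "")
  seqs <- Biostrings::DNAStringSet(setNames(contig, "chrS"))
  genes <- GenomicRanges::GRanges(
    seqnames = rep("chrS", length(g_start)),
    ranges = IRanges::IRanges(start = g_start + 1L, end = g_end),
    strand = g_strand)
  S4Vectors::mcols(genes)$gene_id <- g_id
  S4Vectors::mcols(genes)$category <- g_cat
  features <- GenomicRanges::GRanges(
    seqnames = rep("chrS", length(f_start)),
    ranges = IRanges::IRanges(start = f_start + 1L, end = f_end),
    strand = f_strand)
  if (length(f_start)) {
    S4Vectors::mcols(features)$type <- f_type
    S4Vectors::mcols(features)$gene_id <- f_gene
  }
  structure(list(seqs = seqs, genes = genes, features = features),
            class = "clip_reference")
}

#' Write a synthetic reference to FASTA + GFF3
#'
#' @param ref A `clip_reference` from [generate_reference()].
#' @param fasta,gff3 Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(ref, fasta, gff3) {
  write_fasta(ref$seqs, fasta)
  g <- ref$genes
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(ref$seqs)[1],
                     Biostrings::width(ref$seqs)[1]))
  fmt <- function(gr, type, attr) {
    sprintf("%s\turidylome_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
            as.character(GenomicRanges::seqnames(gr)), type,
            GenomicRanges::start(gr), GenomicRanges::end(gr),
            as.character(GenomicRanges::strand(gr)), attr)
  }
  for (i in seq_along(g)) {
    lines <- c(lines, fmt(g[i], "gene",
      sprintf("ID=%s;category=%s", g$gene_id[i], g$category[i])))
  }
  f <- ref$features
  for (i in seq_along(f)) {
    lines <- c(lines, fmt(f[i], f$type[i],
      sprintf("Parent=%s", f$gene_id[i])))
  }
  writeLines(lines, gff3)
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Fragment a sequence as RNase T1 does
#'
#' RNase T1 cleaves single-stranded RNA 3' of guanosines, leaving fragments
#' that end in G. Each G is cut independently with probability
#' `cut_probability`; with probability 1 every G is a cut site, with 0 the
#' input is returned whole. Fragments concatenate exactly to the input.
#'
#' @param sequence Non-empty nucleotide string (RNA or DNA alphabet; the
#'   input alphabet is preserved in the output).
#' @param cut_probability Per-G cut probability in \[0,1\].
#' @return A data.frame with columns `start`, `end` (0-based half-open
#'   offsets into the input) and `seq`.
#' @examples
#' fragment_rnase_t1("AUGGAUC", 1)$seq  # "AUG" "G" "AUC"
#' @export
fragment_rnase_t1 <- function(sequence, cut_probability = 0.5) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  if (cut_probability < 0 || cut_probability > 1)
    stop("cut_probability must be in [0,1]")
  n <- nchar(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  gpos <- which(ch %in% c("G", "g"))
  gpos <- gpos[gpos < n]  # a terminal G needs no cut
  cut_after <- if (length(gpos) && cut_probability > 0) {
    gpos[runif(length(gpos)) < cut_probability]
  } else integer(0)
  bounds <- c(0L, cut_after, n)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  data.frame(start = starts, end = ends,
             seq = substring(sequence, starts + 1L, ends),
             stringsAsFactors = FALSE)
}

#' Append a non-templated 3' tail to a fragment
#'
#' Draws a tail from the [tail_model()] (or uses `tail` if supplied) and
#' appends it to the fragment in DNA space (U is written as T, as in
#' sequenced cDNA). The returned truth records the exact appended sequence
#' regardless of whether it coincides with downstream genomic bases.
#'
#' @param fragment Fragment sequence (length >= 1).
#' @param model A [tail_model()]. Ignored when `tail` is given.
#' @param tail Optional forced tail sequence (RNA or DNA alphabet).
#' @return List with `read` (fragment + tail, DNA), `tail` (DNA) and
#'   `class` (`U`, `A`, `C`, `G` or `none`).
#' @export
add_tail <- function(fragment, model = tail_model(), tail = NULL) {
  if (!nzchar(fragment)) stop("fragment must have length >= 1")
  if (is.null(tail)) {
    tl <- sample_tail(model)
  } else {
    tl <- list(seq = to_dna(tail),
               class = if (!nzchar(tail)) "none" else {
                 b <- unique(strsplit(to_dna(tail), "", fixed = TRUE)[[1]])
                 if (length(b) == 1L) chartr("T", "U", b) else "mixed"
               })
  }
  list(read = paste0(to_dna(fragment), tl$seq), tail = tl$seq,
       class = tl$class)
}

#' Join two fragments of one molecule into a chimeric read
#'
#' Emulates the intramolecular ligation of two RNase T1 fragments during the
#' CLIP protocol: the 5' arm must precede the 3' arm on the molecule and,
#' reflecting RNase T1 specificity, must end in G.
#'
#' @param arm5,arm3 Lists with `seq` and `start`/`end` (0-based half-open
#'   coordinates on the source molecule or contig).
#' @return List with `seq` (arm5 + arm3), `arm1`, `arm2` (integer
#'   `c(start, end)`), and `junction` (1-based positions: arm1 3' end,
#'   arm2 5' start).
#' @export
make_chimera <- function(arm5, arm3) {
  if (arm5$end > arm3$start)
    stop("arms must be non-overlapping and in order (arm5 before arm3)")
  last <- to_dna(substr(arm5$seq, nchar(arm5$seq), nchar(arm5$seq)))
  if (last != "G")
    stop("arm5 must end in G (RNase T1 leaves 3'-terminal guanosines)")
  list(seq = paste0(to_dna(arm5$seq), to_dna(arm3$seq)),
       arm1 = c(arm5$start, arm5$end), arm2 = c(arm3$start, arm3$end),
       junction = c(arm5$end, arm3$start + 1L))
}

# transcript-space [s,e) (0-based, 1..len) -> contig-space 0-based half-open
tx_to_contig <- function(s, e, gs0, ge0, strand) {
  if (strand == "+") c(gs0 + s, gs0 + e) else c(ge0 - e, ge0 - s)
}

#' Simulate a CLIP sequencing run with ground truth
#'
#' Draws reads from the genes of a synthetic reference: each read is an
#' RNase T1 fragment of a transcript, optionally 3'-tailed according to the
#' tail model, or (for a fixed fraction) a chimeric read formed by
#' intramolecular ligation of two fragments of one molecule. Ground truth
#' (source locus, fragment coordinates, true tail, chimera arms) is recorded
#' per read. Deterministic for a fixed seed.
#'
#' @param ref A `clip_reference` from [generate_reference()].
#' @param model A [tail_model()], or a named list of models keyed by
#'   category (with an optional `default` entry) for category-specific
#'   tailing.
#' @param n_reads Number of reads (>= 1).
#' @param chimera_fraction Fraction of reads that are chimeric; the chimeric
#'   read count is exactly `round(n_reads * chimera_fraction)`.
#' @param read_len `c(min, max)` read length bounds (default 20--110 nt,
#'   the gel-excised CLIP fragment range).
#' @param cut_probability Per-G RNase T1 cut probability (default 0.5,
#'   partial digestion).
#' @param three_prime_extension Number of downstream genomic nucleotides
#'   appended to each transcript before digestion (default 0); positive
#'   values create 3'-extended precursor reads.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, `reads.fastq` and
#'   `truth.tsv` are written there.
#' @return Invisibly, a list with `reads` (named character vector) and
#'   `truth` (data.frame, one row per read) plus output `files` if written.
#' @export
simulate_clip_run <- function(ref, model = tail_model(), n_reads = 1000L,
                              chimera_fraction = 0, read_len = c(20L, 110L),
                              cut_probability = 0.5,
                              three_prime_extension = 0L,
                              seed = 1L, out_dir = NULL) {
  stopifnot(inherits(ref, "clip_reference"))
  if (n_reads < 1L) stop("n_reads must be >= 1")
  if (chimera_fraction < 0 || chimera_fraction > 1)
    stop("chimera_fraction must be in [0,1]")
  if (length(ref$genes) == 0L) stop("reference has no genes to sample from")
  set.seed(seed)

  models <- if (inherits(model, "tail_model")) list(default = model)
            else model
  get_model <- function(cat) models[[cat]] %||% models$default %||%
    stop("no tail model for category ", cat)

  g <- ref$genes
  contig <- as.character(ref$seqs[[1]])
  clen <- nchar(contig)
  gs0 <- GenomicRanges::start(g) - 1L
  ge0 <- GenomicRanges::end(g)
  gstr <- as.character(GenomicRanges::strand(g))
  gstr[gstr == "*"] <- "+"

  # transcript sequences (5'->3'), optionally with downstream extension
  ext <- as.integer(three_prime_extension)
  tx_of <- function(i) {
    if (gstr[i] == "+") {
      e <- min(ge0[i] + ext, clen)
      substr(contig, gs0[i] + 1L, e)
    } else {
      s <- max(gs0[i] - ext, 0L)
      revcomp_str(substr(contig, s + 1L, ge0[i]))
    }
  }
  txs <- vapply(seq_along(g), tx_of, character(1))

  n_chim <- round(n_reads * chimera_fraction)
  is_chim <- sample(rep(c(TRUE, FALSE), c(n_chim, n_reads - n_chim)))
  lmin <- read_len[1]; lmax <- read_len[2]

  rows <- vector("list", n_reads)
  reads <- character(n_reads)
  ids <- sprintf("read%06d", seq_len(n_reads))

  for (r in seq_len(n_reads)) {
    placed <- FALSE
    for (try in 1:50) {
      i <- sample.int(length(g), 1L)
      tx <- txs[i]
      tlen <- nchar(tx)
      tl <- sample_tail(get_model(g$category[i]))
      ntail <- nchar(tl$seq)
      if (!is_chim[r]) {
        fmin <- max(1L, lmin - ntail); fmax <- lmax - ntail
        if (fmax < 1L) next
        fr <- fragment_rnase_t1(tx, cut_probability)
        ok <- which(fr$end - fr$start >= min(fmin, tlen) &
                    fr$end - fr$start <= fmax)
        if (length(ok) == 0L) {
          # fallback: random window of admissible length
          w <- min(sample_int_range(fmin, fmax), tlen)
          s <- sample.int(tlen - w + 1L, 1L) - 1L
          frag <- list(start = s, end = s + w,
                       seq = substr(tx, s + 1L, s + w))
        } else {
          # templated-junction bias: prefer fragments whose downstream
          # transcript base equals the first tail base
          mdl <- get_model(g$category[i])
          pick <- ok
          if (ntail > 0L && mdl$junction_bias > 0 &&
              runif(1) < mdl$junction_bias) {
            b1 <- substr(tl$seq, 1L, 1L)
            nextb <- substr(tx, fr$end[ok] + 1L, fr$end[ok] + 1L)
            hit <- ok[nextb == b1]
            if (length(hit)) pick <- hit
          }
          j <- pick[sample.int(length(pick), 1L)]
          frag <- list(start = fr$start[j], end = fr$end[j],
                       seq = fr$seq[j])
          w <- frag$end - frag$start
          if (w > fmax) {  # trim from the 5' end, keep 3' end honest
            frag$start <- frag$start + (w - fmax)
            frag$seq <- substr(tx, frag$start + 1L, frag$end)
          }
        }
        # with extension, transcript runs past gene end; map via tx coords
        if (gstr[i] == "+") {
          cc <- c(gs0[i] + frag$start, gs0[i] + frag$end)
        } else {
          top <- ge0[i]
          cc <- c(top - frag$end, top - frag$start)
        }
        reads[r] <- paste0(to_dna(frag$seq), tl$seq)
        if (nchar(reads[r]) < lmin || nchar(reads[r]) > lmax) next
        rows[[r]] <- data.frame(
          read_id = ids[r], locus_id = g$gene_id[i],
          category = g$category[i], contig = "chrS",
          frag_start = cc[1], frag_end = cc[2], strand = gstr[i],
          tail_seq = tl$seq, tail_len = ntail, tail_class = tl$class,
          is_chimera = FALSE, arm1_start = NA_integer_,
          arm1_end = NA_integer_, arm2_start = NA_integer_,
          arm2_end = NA_integer_, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      } else {
        # chimera: arm1 ends at a G, arm2 downstream with a gap
        ch <- strsplit(tx, "", fixed = TRUE)[[1]]
        a1len <- sample_int_range(12L, 30L); a2len <- sample_int_range(12L, 30L)
        gap <- sample_int_range(4L, 30L)
        if (a1len + a2len + ntail > lmax) next
        gp <- which(ch == "G")
        gp <- gp[gp >= a1len & gp + gap + a2len <= tlen]
        if (length(gp) == 0L) next
        cut1 <- gp[sample.int(length(gp), 1L)]
        a1 <- list(start = cut1 - a1len, end = cut1,
                   seq = substr(tx, cut1 - a1len + 1L, cut1))
        a2s <- cut1 + gap
        a2 <- list(start = a2s, end = a2s + a2len,
                   seq = substr(tx, a2s + 1L, a2s + a2len))
        chim <- make_chimera(a1, a2)
        reads[r] <- paste0(chim$seq, tl$seq)
        if (nchar(reads[r]) < lmin || nchar(reads[r]) > lmax) next
        c1 <- if (gstr[i] == "+") c(gs0[i] + a1$start, gs0[i] + a1$end)
              else c(ge0[i] - a1$end, ge0[i] - a1$start)
        c2 <- if (gstr[i] == "+") c(gs0[i] + a2$start, gs0[i] + a2$end)
              else c(ge0[i] - a2$end, ge0[i] - a2$start)
        rows[[r]] <- data.frame(
          read_id = ids[r], locus_id = g$gene_id[i],
          category = g$category[i], contig = "chrS",
          frag_start = min(c1[1], c2[1]), frag_end = max(c1[2], c2[2]),
          strand = gstr[i], tail_seq = tl$seq, tail_len = ntail,
          tail_class = tl$class, is_chimera = TRUE,
          arm1_start = c1[1], arm1_end = c1[2],
          arm2_start = c2[1], arm2_end = c2[2], stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place read ", r,
                      " within the configured length bounds")
  }

  truth <- do.call(rbind, rows)
  reads <- setNames(reads, ids)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fq <- file.path(out_dir, "reads.fastq")
    tt <- file.path(out_dir, "truth.tsv")
    write_fastq(reads, fq)
    write_tsv(truth, tt,
              header_lines = sprintf(
                "uridylome simulate: n_reads=%d chimera_fraction=%g seed=%d",
                n_reads, chimera_fraction, seed))
    files <- c(fastq = fq, truth = tt)
  }
  invisible(list(reads = reads, truth = truth, files = files))
}
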