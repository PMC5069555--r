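# Small shared helpers. Coordinates are 0-based half-open everywhere inside
# the package; 1-based only at GFF3 / report boundaries.

.CATEGORIES <- c("tRNA", "miRNA", "snRNA", "5S_rRNA", "miscRNA", "snoRNA",
                 "mRNA", "lincRNA", "pseudogene")

#' Annotation priority order
#'
#' The fixed category priority used when a read overlaps several genes:
#' tRNA > miRNA > snRNA > 5S rRNA > miscRNA > snoRNA > mRNA > lincRNA.
#' Pseudogenes, when present in an annotation, rank after lincRNA.
#'
#' @return Character vector of category labels, highest priority first.
#' @export
clip_priority <- function() {
  c("tRNA", "miRNA", "snRNA", "5S_rRNA", "miscRNA", "snoRNA",
    "mRNA", "lincRNA", "pseudogene")
}

to_dna <- function(x) chartr("Uu", "Tt", x)
to_rna <- function(x) chartr("Tt", "Uu", x)

revcomp_str <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE, prob = p),
        collapse = "")
}

# length of the 3'-terminal run of `base` in `x`
terminal_run <- function(x, base = "T") {
  n <- nchar(x)
  if (n == 0L) return(0L)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  k <- 0L
  while (k < n && ch[n - k] == base) k <- k + 1L
  k
}

# longest common prefix length of two strings
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- strsplit(substr(a, 1L, n), "", fixed = TRUE)[[1]]
  cb <- strsplit(substr(b, 1L, n), "", fixed = TRUE)[[1]]
  d <- which(ca != cb)
  if (length(d) == 0L) n else d[1L] - 1L
}

write_tsv <- function(df, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

# FASTQ/FASTA reading via Biostrings; returns named character vector (DNA)
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  xs <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(as.character(xs), sub("\\s.*$", "", names(xs)))
}

write_fastq <- function(reads, path) {
  stopifnot(!is.null(names(reads)))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

write_fasta <- function(seqs, path, width = 70L) {
  xs <- if (methods::is(seqs, "DNAStringSet")) seqs else
    Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(xs, path, width = width)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniform integer draw from [lo, hi], safe for lo == hi
sample_int_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}
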