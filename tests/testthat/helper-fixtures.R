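# Shared in-code fixtures for the test suite.

# small seeded reference used across tests
test_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_reference(reference_spec(), seed = 101)
    cache
  }
})

# one contig as plain character
contig_seq <- function(ref) as.character(ref$seqs[[1]])

# a minimal single-gene annotation index
single_gene_index <- function(contig = "chr1", start = 300L, end = 384L,
                              strand = "+", gene_id = "g1",
                              category = "miRNA", ...) {
  annotation_index(data.frame(contig = contig, start = start, end = end,
                              strand = strand, gene_id = gene_id,
                              category = category,
                              stringsAsFactors = FALSE), ...)
}

# an 84-nt hairpin locus embedded in random flanks, with a G at position 28
# (the worked pre-let-7-style chimera case: arms 1-28 + 61-84)
hairpin_fixture <- function(seed = 99) {
  set.seed(seed)
  hp <- uridylome:::random_dna(84)
  substr(hp, 28, 28) <- "G"
  contig <- paste0(uridylome:::random_dna(300), hp,
                   uridylome:::random_dna(300))
  list(hairpin = hp,
       seqs = Biostrings::DNAStringSet(c(chr1 = contig)),
       index = single_gene_index(gene_id = "pre-let-7",
                                 category = "miRNA"),
       read = paste0(substr(hp, 1, 28), substr(hp, 61, 84)))
}

# synthetic U+ calls with anchors at given positions
calls_at <- function(anchors, strand = "+", contig = "chrT",
                     class = "U+") {
  data.frame(read_id = sprintf("r%04d", seq_along(anchors)),
             contig = contig, start = anchors - 10L, end = anchors + 1L,
             strand = strand, pass = 1L, anchor = anchors,
             tail_seq = "UUUU", templated_overlap = 0L,
             untemplated_len = 4L, n_U = 4L, n_A = 0L, n_C = 0L,
             n_G = 0L, class = class, tail_source = "remainder",
             stringsAsFactors = FALSE)
}
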