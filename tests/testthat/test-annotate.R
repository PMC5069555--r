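# Priority annotation, region assignment, tRNA subregions, end states.

test_that("tRNA genes are queried with +/-60 nt extensions", {
  idx <- single_gene_index(contig = "chr1", start = 1000L, end = 1072L,
                           gene_id = "tRNA-Gly", category = "tRNA")
  q <- idx$query
  expect_equal(GenomicRanges::start(q) - 1L, 940)
  expect_equal(GenomicRanges::end(q), 1132)
  # mature bounds retained
  expect_equal(GenomicRanges::start(idx$genes) - 1L, 1000)

  # a read 40 nt downstream of the mature end is assigned to the tRNA
  asg <- assign_category(idx, data.frame(contig = "chr1", start = 1110L,
                                         end = 1130L, strand = "+"))
  expect_equal(asg$category, "tRNA")
})

test_that("GFF3 round trip preserves coordinates and categories", {
  ref <- test_reference()
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_reference(ref, fa, gff)
  idx <- load_annotation(gff)
  expect_equal(length(idx$genes), length(ref$genes))
  m <- match(ref$genes$gene_id, idx$genes$gene_id)
  expect_false(anyNA(m))
  expect_equal(GenomicRanges::start(idx$genes)[m],
               GenomicRanges::start(ref$genes))
  expect_equal(idx$genes$category[m], ref$genes$category)
  # features (TSS, introns) survive the round trip
  expect_true("TSS" %in% idx$features$type)
})

test_that("unknown categories and malformed annotations are rejected", {
  expect_error(annotation_index(data.frame(
    contig = "c", start = 0L, end = 10L, strand = "+", gene_id = "x",
    category = "rRNA_unknown")), "accepted labels")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c\tsrc\tgene\t1\t50\t.\t+\t.\tID=x;category=banana"), gff)
  expect_error(load_annotation(gff), "accepted labels")
  # category_map rescues alias labels
  writeLines(c("##gff-version 3",
               "c\tsrc\tgene\t100\t199\t.\t+\t.\tID=x;category=5S rRNA"),
             gff)
  idx <- load_annotation(gff, category_map = c("5S rRNA" = "5S_rRNA"))
  expect_equal(idx$genes$category, "5S_rRNA")
  # GFF3 1-based 100..199 -> internal 0-based half-open [99, 199)
  expect_equal(GenomicRanges::start(idx$genes) - 1L, 99)
  expect_equal(GenomicRanges::end(idx$genes), 199)
})

test_that("empty annotation leaves every read unannotated", {
  idx <- annotation_index(GenomicRanges::GRanges(
    gene_id = character(0), category = character(0)))
  asg <- assign_category(idx, data.frame(contig = "c", start = 1L,
                                         end = 10L, strand = "+"))
  expect_true(is.na(asg$gene_id))
})

test_that("priority order wins for every ordered category pair", {
  prio <- clip_priority()[1:8]
  for (i in seq_along(prio)) {
    for (j in seq_along(prio)) {
      if (i == j) next
      idx <- annotation_index(data.frame(
        contig = "c", start = c(100L, 120L), end = c(300L, 320L),
        strand = "+", gene_id = c("A", "B"),
        category = c(prio[i], prio[j]), stringsAsFactors = FALSE))
      asg <- assign_category(idx, data.frame(contig = "c", start = 150L,
                                             end = 170L, strand = "+"))
      expect_equal(asg$category, prio[min(i, j)],
                   label = paste(prio[i], "vs", prio[j]))
    }
  }
})

test_that("intronic snoRNA outranks its host mRNA; ties break by overlap", {
  idx <- annotation_index(data.frame(
    contig = "c", start = c(0L, 200L), end = c(1000L, 300L), strand = "+",
    gene_id = c("host", "sno"), category = c("mRNA", "snoRNA"),
    stringsAsFactors = FALSE))
  asg <- assign_category(idx, data.frame(contig = "c", start = 210L,
                                         end = 240L, strand = "+"))
  expect_equal(asg$gene_id, "sno")

  # same category: larger overlap, then lexicographic id
  idx2 <- annotation_index(data.frame(
    contig = "c", start = c(0L, 90L), end = c(100L, 400L), strand = "+",
    gene_id = c("m1", "m2"), category = "mRNA", stringsAsFactors = FALSE))
  asg2 <- assign_category(idx2, data.frame(contig = "c", start = 80L,
                                           end = 200L, strand = "+"))
  expect_equal(asg2$gene_id, "m2")
  idx3 <- annotation_index(data.frame(
    contig = "c", start = c(0L, 0L), end = c(100L, 100L), strand = "+",
    gene_id = c("b", "a"), category = "mRNA", stringsAsFactors = FALSE))
  asg3 <- assign_category(idx3, data.frame(contig = "c", start = 10L,
                                           end = 20L, strand = "+"))
  expect_equal(asg3$gene_id, "a")
})

test_that("category assignment is same-strand only", {
  idx <- single_gene_index(contig = "c", start = 100L, end = 200L,
                           strand = "+", category = "mRNA")
  asg <- assign_category(idx, data.frame(contig = "c", start = 120L,
                                         end = 140L, strand = "-"))
  expect_true(is.na(asg$category))
})

test_that("region assignment computes signed offsets strand-aware", {
  idx <- single_gene_index(contig = "c", start = 100L, end = 200L,
                           strand = "+", gene_id = "g", category = "snRNA")
  reg <- assign_region(idx, data.frame(
    contig = "c", anchor = c(214L, 199L, 150L, 90L), strand = "+",
    gene_id = "g"))
  expect_equal(reg$offset, c(15L, 0L, -49L, -109L))
  expect_equal(reg$region, c("3' extension", "mature", "mature",
                             "5' leader"))

  # minus strand: the mature 3' end is the interval start
  idxm <- single_gene_index(contig = "c", start = 100L, end = 200L,
                            strand = "-", gene_id = "g",
                            category = "snRNA")
  regm <- assign_region(idxm, data.frame(
    contig = "c", anchor = c(85L, 100L, 150L), strand = "-",
    gene_id = "g"))
  expect_equal(regm$offset, c(15L, 0L, -50L))
  expect_equal(regm$region, c("3' extension", "mature", "mature"))
})

test_that("regions partition the extended span with no gaps or overlaps", {
  idx <- single_gene_index(contig = "c", start = 500L, end = 600L,
                           strand = "+", gene_id = "g", category = "snRNA")
  anchors <- 400:699
  reg <- assign_region(idx, data.frame(contig = "c", anchor = anchors,
                                       strand = "+", gene_id = "g"))
  expect_true(all(table(reg$region) ==
                    c(`3' extension` = 100, `5' leader` = 100,
                      mature = 100)))
  # boundaries: one region per anchor, consistent with offset signs
  expect_true(all((reg$offset > 0) == (reg$region == "3' extension")))
  expect_true(all((reg$offset <= -100) == (reg$region == "5' leader")))
})

test_that("mRNA anchors classify into UTRs, CDS and intron", {
  ref <- test_reference()
  idx <- annotation_index(ref$genes, features = ref$features)
  g <- ref$genes[ref$genes$category == "mRNA"][1]
  gid <- g$gene_id
  f <- ref$features[ref$features$gene_id == gid]
  pick <- function(type) {
    iv <- f[f$type == type][1]
    as.integer(GenomicRanges::start(iv)) + 2L  # inside, 0-based-ish
  }
  anchors <- data.frame(
    contig = "chrS",
    anchor = c(pick("five_prime_UTR"), pick("intron"),
               pick("three_prime_UTR")),
    strand = as.character(GenomicRanges::strand(g)), gene_id = gid)
  reg <- assign_region(idx, anchors)
  expect_equal(reg$subfeature, c("5'UTR", "intron", "3'UTR"))
})

test_that("tRNA subregions follow the documented cloverleaf partition", {
  expect_equal(trna_subregion(5L + 72L, 72L), "3' trailer")
  expect_equal(trna_subregion(-10L, 72L), "5' trailer")
  expect_equal(trna_subregion(as.integer(0.8 * 72), 72L), "T-loop")
  expect_equal(trna_subregion(0L, 72L), "acceptor stem")
  expect_equal(trna_subregion(as.integer(0.3 * 72), 72L), "D-arm")
  expect_equal(trna_subregion(as.integer(0.5 * 72), 72L), "anticodon arm")
  expect_error(trna_subregion(-100L, 72L), "outside")
})

test_that("end states tally Mat/Trim/ext and count U+ reads", {
  expect_equal(end_state(c(0L, -3L, 12L)), c("Mat", "Trim", "ext"))
  calls <- data.frame(gene_id = "U12", offset = c(0L, -3L, 12L),
                      class = c("none", "none", "U+"),
                      stringsAsFactors = FALSE)
  tally <- classify_end_state(calls)
  expect_equal(tally$Mat, 1L)
  expect_equal(tally$Trim, 1L)
  expect_equal(tally$ext, 1L)
  expect_equal(tally$uplus, 1L)
  # exactly one state per read
  expect_equal(tally$Mat + tally$Trim + tally$ext, nrow(calls))
  # empty tally
  empty <- classify_end_state(calls[0, ], gene_ids = "U12")
  expect_equal(empty$Mat + empty$Trim + empty$ext + empty$uplus, 0L)
})

test_that("simulated 3'-extended snRNA reads recover the extension rate", {
  spec <- reference_spec(n_genes = c(snRNA = 3))
  ref <- generate_reference(spec, seed = 51)
  idx <- annotation_index(ref$genes)
  # digest precursors extending 25 nt past the mature 3' end
  sim <- simulate_clip_run(ref, n_reads = 600, chimera_fraction = 0,
                           seed = 52, three_prime_extension = 25L)
  res <- call_tails(sim$reads, ref$seqs, pipeline_config())
  ann <- annotate_calls(res$calls, idx)
  ann <- ann[!is.na(ann$offset), ]
  st <- table(end_state(ann$offset))
  # extended fragments exist and are a minority bounded by binomial noise
  expect_gt(st[["ext"]], 0)
  expect_gt(st[["Trim"]], st[["ext"]])
})
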