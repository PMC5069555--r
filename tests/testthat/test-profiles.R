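# Histograms, U+ fractions, scaled coverage, TSS metagene, overlays.

test_that("tail histograms report medians on untemplated lengths", {
  calls <- calls_at(1:4)
  calls$untemplated_len <- c(4L, 6L, 6L, 8L)
  h <- tail_length_histogram(calls)
  expect_equal(h$stats$median, 6)
  expect_equal(sum(h$counts$count), 4L)

  empty <- tail_length_histogram(calls[0, ])
  expect_equal(nrow(empty$counts), 0L)

  # conservation: counts per group equal the number of calls in the group
  set.seed(9)
  calls2 <- calls_at(1:200)
  calls2$untemplated_len <- sample(1:10, 200, TRUE)
  calls2$class <- sample(c("U+", "A", "mixed"), 200, TRUE)
  h2 <- tail_length_histogram(calls2)
  agg <- tapply(h2$counts$count, h2$counts$class, sum)
  expect_equal(as.integer(agg[names(table(calls2$class))]),
               as.integer(table(calls2$class)))
})

test_that("per-category U+ percentages use reported denominators", {
  calls <- calls_at(1:10)
  calls$category <- "tRNA"
  calls$class <- c(rep("U+", 3), rep("none", 7))
  tab <- uplus_fraction_by_category(calls)
  expect_equal(tab$pct_uplus, 30)
  expect_equal(tab$n_reads, 10L)
  expect_message(
    uplus_fraction_by_category(calls, categories = c("tRNA", "miRNA")),
    "miRNA")
})

test_that("scaled coverage maps reads into 100 bins, 3' end = bin 100", {
  idx <- single_gene_index(contig = "chrT", start = 1000L, end = 1200L,
                           gene_id = "g", category = "miscRNA")
  full <- calls_at(1100L)
  full$gene_id <- "g"; full$category <- "miscRNA"
  full$start <- 1000L; full$end <- 1200L
  m <- scaled_coverage(full, idx)
  expect_equal(ncol(m), 100L)
  expect_true(all(m[1, ] == 1))

  half <- full; half$end <- 1100L
  m2 <- scaled_coverage(half, idx)
  expect_true(all(m2[1, 1:50] == 1))
  expect_true(all(m2[1, 51:100] == 0))

  # anchors at the mature 3' end peak in bin 100 (both strands)
  for (strand in c("+", "-")) {
    idxs <- single_gene_index(contig = "chrT", start = 1000L, end = 1200L,
                              strand = strand, gene_id = "g",
                              category = "miscRNA")
    anch <- calls_at(rep(if (strand == "+") 1199L else 1000L, 5),
                     strand = strand)
    anch$gene_id <- "g"
    m3 <- scaled_coverage(anch, idxs, value = "anchor")
    expect_equal(unname(which.max(m3[1, ])), 100L)
  }
})

test_that("scaled coverage is invariant under strand reversal", {
  set.seed(12)
  starts <- sample(1000:1150, 20, TRUE)
  plus <- calls_at(starts + 30L)
  plus$gene_id <- "g"
  plus$start <- starts; plus$end <- starts + 31L
  idxp <- single_gene_index(contig = "chrT", start = 1000L, end = 1200L,
                            strand = "+", gene_id = "g",
                            category = "miscRNA")
  mp <- scaled_coverage(plus, idxp)

  # mirror the gene and its reads onto the minus strand
  minus <- plus
  minus$strand <- "-"
  minus$start <- 1000L + (1200L - plus$end)
  minus$end <- 1000L + (1200L - plus$start)
  minus$anchor <- minus$start
  idxm <- single_gene_index(contig = "chrT", start = 1000L, end = 1200L,
                            strand = "-", gene_id = "g",
                            category = "miscRNA")
  mm <- scaled_coverage(minus, idxm)
  expect_equal(mp[1, ], mm[1, ])
})

test_that("rows with reads are normalized to maximum 1", {
  idx <- single_gene_index(contig = "chrT", start = 0L, end = 500L,
                           gene_id = "g", category = "snRNA")
  set.seed(13)
  anch <- calls_at(sample(0:499, 30, TRUE))
  anch$gene_id <- "g"
  anch$start <- pmax(anch$anchor - 20L, 0L); anch$end <- anch$anchor + 1L
  m <- scaled_coverage(anch, idx)
  expect_equal(max(m[1, ]), 1)
})

test_that("metagene recovers sense and antisense peak offsets", {
  set.seed(14)
  tss <- data.frame(contig = "chrT", pos = c(5000L, 20000L),
                    strand = c("+", "-"))
  mk <- function(n, mean) as.integer(round(rnorm(n, mean, 5)))
  sense_off <- mk(300, 50); anti_off <- mk(300, -200)
  calls <- rbind(
    within(calls_at(5000L + sense_off, strand = "+"), read_id <-
             paste0("s", seq_along(sense_off))),
    within(calls_at(5000L + anti_off, strand = "-"), read_id <-
             paste0("a", seq_along(anti_off))))
  mg <- tss_metagene(calls, tss, window = 500, smooth = 5)
  expect_lte(abs(mg$peaks[["sense"]] - 50), 2)
  expect_lte(abs(mg$peaks[["antisense"]] - (-200)), 2)
  # counts conserved within the window
  expect_equal(sum(mg$profile$sense) + sum(mg$profile$antisense),
               nrow(calls))

  # minus-strand TSS flips the offset sign convention
  calls_m <- calls_at(20000L - 50L, strand = "-")
  mg2 <- tss_metagene(calls_m, tss, window = 500, smooth = 1)
  expect_equal(mg2$profile$sense[mg2$profile$offset == 50], 1)

  expect_error(tss_metagene(calls, tss[0, ]), "empty TSS")
})

test_that("no reads in the window gives a flat profile and NA peaks", {
  tss <- data.frame(contig = "chrT", pos = 5000L, strand = "+")
  mg <- tss_metagene(calls_at(9000L), tss, window = 500)
  expect_true(all(mg$profile$sense == 0))
  expect_true(is.na(mg$peaks[["sense"]]))
})

test_that("signal-track overlay aligns to the same offsets", {
  tss <- data.frame(contig = "chrT", pos = 5000L, strand = "+")
  calls <- calls_at(5000L + 50L)
  mg <- tss_metagene(calls, tss, window = 300)

  flat <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 10000),
                                 score = 2.5)
  ov <- overlay_signal_track(mg, flat)
  expect_true(all(abs(ov$profile$overlay - 2.5) < 1e-9))

  bump <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(1, 5051, 5052), c(5050, 5051, 10000)),
    score = c(0, 9, 0))
  ov2 <- overlay_signal_track(mg, bump)
  expect_equal(ov2$profile$offset[which.max(ov2$profile$overlay)], 50)

  # TSS on contigs missing from the track are skipped with a note
  tss2 <- rbind(tss, data.frame(contig = "chrZ", pos = 100L,
                                strand = "+"))
  mg2 <- tss_metagene(calls, tss2, window = 300)
  expect_message(overlay_signal_track(mg2, flat), "skipped")
  expect_error(
    overlay_signal_track(mg, GenomicRanges::GRanges(
      "chrQ", IRanges::IRanges(1, 10), score = 1)), "assembly mismatch")
})

test_that("plot helpers run headless on the data they are given", {
  pdf(NULL)
  on.exit(dev.off())
  calls <- calls_at(1:20)
  calls$untemplated_len <- sample(4:9, 20, TRUE)
  h <- tail_length_histogram(calls)
  expect_silent(plot_tail_histogram(h))
  tss <- data.frame(contig = "chrT", pos = 100L, strand = "+")
  mg <- tss_metagene(calls_at(150L), tss, window = 200)
  expect_silent(plot_metagene(mg))
})
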