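# Two-pass mapping, trimming, tail calling and classification.

test_that("trim_t_tail trims runs of more than three Ts and is idempotent", {
  expect_equal(trim_t_tail("ACGTTTTT")[c("trimmed", "removed")],
               list(trimmed = "ACG", removed = 5L))
  expect_equal(trim_t_tail("ACGTTT")$removed, 0L)
  expect_equal(trim_t_tail("ACGTTT")$trimmed, "ACGTTT")
  all_t <- trim_t_tail("TTTTTT")
  expect_equal(all_t$trimmed, "")
  expect_equal(all_t$removed, 6L)
  expect_true(all_t$all_tail)
  # idempotence over random tailed sequences
  set.seed(2)
  for (i in 1:20) {
    s <- paste0(uridylome:::random_dna(sample(10:40, 1)),
                strrep("T", sample(0:9, 1)))
    once <- trim_t_tail(s)
    if (once$all_tail) next
    if (nzchar(once$trimmed))
      expect_identical(trim_t_tail(once$trimmed)$trimmed, once$trimmed)
  }
})

test_that("classify_tail follows the U+ / homopolymer / mixed rules", {
  expect_equal(classify_tail("TTTT"), "U+")
  expect_equal(classify_tail("ATTTT"), "U+")   # terminal run of 4
  expect_equal(classify_tail("TTTTA"), "mixed")
  expect_equal(classify_tail("AAA"), "A")
  expect_equal(classify_tail("TTT"), "U")
  expect_equal(classify_tail("G"), "G")
  expect_equal(classify_tail(""), "none")
  expect_equal(classify_tail("TTTT", min_u = 5), "U")
  expect_error(classify_tail("TTNX"), "A, C, G, T")
})

test_that("align_read finds unique exact placements with remainders", {
  set.seed(31)
  contig <- uridylome:::random_dna(10000)
  seqs <- Biostrings::DNAStringSet(c(chr1 = contig))
  cfg <- pipeline_config()

  read <- substr(contig, 5001, 5030)
  a <- align_read(c(r1 = read), seqs, cfg)
  expect_equal(a$start, 5000)
  expect_equal(a$end, 5030)
  expect_equal(a$strand, "+")
  expect_equal(a$remainder, "")
  expect_true(a$unique)

  # identical second occurrence -> non-unique
  contig2 <- paste0(contig, substr(contig, 5001, 5030),
                    uridylome:::random_dna(50))
  a2 <- align_read(c(r1 = read),
                   Biostrings::DNAStringSet(c(chr1 = contig2)), cfg)
  expect_false(a2$unique)

  # 26-nt substring + TTTTT remainder, checked against the brute oracle
  read3 <- paste0(substr(contig, 7001, 7026), "TTTTT")
  a3 <- align_read(c(r3 = read3), seqs, cfg)
  bf <- brute_align(read3, seqs, cfg)
  expect_equal(a3$start, bf$start)
  expect_equal(a3$end, bf$end)
  expect_equal(a3$remainder, bf$remainder)
  expect_equal(a3$unique, bf$unique)

  # minus-strand placement
  read4 <- uridylome:::revcomp_str(substr(contig, 3001, 3040))
  a4 <- align_read(c(r4 = read4), seqs, cfg)
  expect_equal(a4$strand, "-")
  expect_equal(a4$start, 3000)
  expect_equal(a4$end, 3040)
})

test_that("two-pass mapping partitions reads and recovers tailed reads", {
  ref <- test_reference()
  cfg_strict <- pipeline_config(pass1_mode = "strict")

  # a read with 6 untemplated Us: unmapped in strict pass 1, rescued in
  # pass 2 with trimmed_t_count 6
  contig <- contig_seq(ref)
  g <- ref$genes[ref$genes$category == "mRNA"][1]
  s <- GenomicRanges::start(g)
  frag <- substr(contig, s, s + 29)
  frag <- sub("T+$", "", frag)  # avoid merging genomic Ts into the tail
  read <- paste0(frag, "TTTTTT")
  mp <- two_pass_map(c(u1 = read), ref$seqs, cfg_strict)
  expect_equal(unname(mp$classes["u1"]), "pass2")
  expect_equal(mp$alignments$trimmed_t_count[1],
               6L + uridylome:::terminal_run(frag, "T"))

  # tail-free read maps in pass 1
  clean <- substr(contig, s, s + 29)
  mp2 <- two_pass_map(c(c1 = clean), ref$seqs, cfg_strict)
  expect_equal(unname(mp2$classes["c1"]), "pass1")

  # conservation over a full simulated run
  sim <- simulate_clip_run(ref, n_reads = 1000, chimera_fraction = 0,
                           seed = 17)
  mp3 <- two_pass_map(sim$reads, ref$seqs, pipeline_config())
  expect_equal(sum(mp3$counts), 1000L)
  expect_setequal(names(mp3$counts),
                  c("pass1", "pass2", "unmapped", "all_tail"))
})

test_that("call_untemplated_tail applies the maximal-templated convention", {
  cfg <- pipeline_config()
  set.seed(41)
  base <- uridylome:::random_dna(200)

  make_case <- function(downstream, remainder) {
    prefix <- substr(base, 1, 100)
    contig <- paste0(prefix, downstream, substr(base, 101, 160))
    aln <- data.frame(read_id = "x", contig = "c", start = 70L,
                      end = 100L, strand = "+", aligned_span = 30L,
                      mismatches = 0L, remainder = remainder, pass = 1L,
                      trimmed_t_count = 0L, unique = TRUE, score = 30,
                      stringsAsFactors = FALSE)
    call_untemplated_tail(aln, Biostrings::DNAStringSet(c(c = contig)),
                          cfg)
  }

  tc1 <- make_case("GCAA", "TTTT")
  expect_equal(tc1$templated_overlap, 0L)
  expect_equal(tc1$n_U, 4L)
  expect_equal(tc1$class, "U+")
  expect_equal(tc1$anchor, 99L)  # last aligned base

  tc2 <- make_case("TTCA", "TT")
  expect_equal(tc2$templated_overlap, 2L)
  expect_equal(tc2$untemplated_len, 0L)
  expect_equal(tc2$class, "none")
  expect_equal(tc2$anchor, 101L)

  tc3 <- make_case("TGCA", "TTTTT")
  expect_equal(tc3$templated_overlap, 1L)
  expect_equal(tc3$n_U, 4L)
  expect_equal(tc3$class, "U+")

  expect_error(call_untemplated_tail(
    data.frame(read_id = "x", contig = "nope", start = 0L, end = 10L,
               strand = "+", aligned_span = 10L, mismatches = 0L,
               remainder = "", pass = 1L, trimmed_t_count = 0L,
               unique = TRUE, score = 10, stringsAsFactors = FALSE),
    Biostrings::DNAStringSet(c(c = "ACGT")), cfg), "reference-mismatch")
})

test_that("called tails are maximal: no further templated extension", {
  ref <- test_reference()
  contig <- contig_seq(ref)
  sim <- simulate_clip_run(ref, n_reads = 500, chimera_fraction = 0,
                           seed = 23)
  res <- call_tails(sim$reads, ref$seqs, pipeline_config())
  calls <- res$calls[res$calls$untemplated_len > 0, ]
  expect_gt(nrow(calls), 50)
  for (i in seq_len(nrow(calls))) {
    a <- calls[i, ]
    first <- substr(uridylome:::to_dna(a$tail_seq),
                    a$templated_overlap + 1L, a$templated_overlap + 1L)
    nextb <- if (a$strand == "+") substr(contig, a$anchor + 2, a$anchor + 2)
             else uridylome:::revcomp_str(substr(contig, a$anchor, a$anchor))
    expect_false(identical(first, nextb))
  }
})

test_that("tail-call and BED writers record configuration and anchors", {
  ref <- test_reference()
  sim <- simulate_clip_run(ref, n_reads = 50, seed = 4)
  res <- call_tails(sim$reads, ref$seqs, pipeline_config())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tail_calls(res$calls, tsv, pipeline_config())
  expect_match(readLines(tsv, n = 1), "trim_min_run=4 min_u=4")
  back <- uridylome:::read_tsv(tsv)
  expect_equal(nrow(back), nrow(res$calls))
  bed <- tail_calls_bed(res$calls)
  expect_equal(length(bed), nrow(res$calls))
  f <- strsplit(bed[1], "\t")[[1]]
  expect_equal(as.integer(f[3]) - as.integer(f[2]), 1L)
})
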