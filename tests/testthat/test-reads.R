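test_that("UMI extraction splits reads and skips too-short ones", {
  out <- extract_umi(c("ACGTACGTTTTTGG", "ACGTACGT", "AAAACCCCG"))
  expect_equal(out$umi, c("ACGTACGT", "AAAACCCC"))
  expect_equal(out$seq, c("TTTTGG", "G"))
  expect_equal(attr(out, "n_skipped"), 1L)  # exactly 8 bases: no sequence left

  zero <- extract_umi("ACGT", umi_len = 0)
  expect_equal(zero$umi, "")
  expect_equal(zero$seq, "ACGT")
})

test_that("FASTQ round-trip preserves UMIs", {
  skip_if_not_installed("Biostrings")
  cfg <- small_cfg(n_genes = 5L, n_reads = 200L, seed = 2L)
  sim <- simulate_degradome(cfg)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_degradome_fastq(sim$reads, path, read_len = 40L)
  got <- read_fastq_umis(path, umi_len = 8L)
  expect_equal(got$umi, sim$reads$umi)
  expect_true(all(nchar(got$seq) == 32L))
})

test_that("dedup collapses (gene, pos, umi) and is idempotent", {
  r <- reads_at(rep("G1", 5), c(10, 10, 10, 10, 20),
                umi = c("AA", "AA", "AA", "CC", "AA"))
  d1 <- dedup_reads(r)
  expect_equal(nrow(d1), 3L)             # 3 copies of (10, AA) collapsed
  expect_identical(as.data.frame(dedup_reads(d1)), as.data.frame(d1))

  distinct <- reads_at(rep("G1", 4), c(1, 2, 3, 4))
  expect_equal(nrow(dedup_reads(distinct)), 4L)

  # same (pos, umi) on different genes stays distinct
  two <- reads_at(c("G1", "G2"), c(10, 10), umi = c("AA", "AA"))
  expect_equal(nrow(dedup_reads(two)), 2L)
})

test_that("fivep_counts maps reads to anchored positions and conserves reads", {
  tx <- tiny_tx()
  cov <- fivep_counts(reads_at("G1", 86), tx)
  expect_equal(cov$count, 1L)
  expect_equal(start_offset(tx, cov$pos, gene_id = "G1"), -14L)
  expect_equal(cov_library_size(cov), 1L)

  # unknown genes and out-of-range positions are dropped and counted
  r <- reads_at(c("G1", "G1", "GX", "G1"), c(5, 5, 10, 10000))
  cov <- fivep_counts(r, tx)
  expect_equal(sum(cov$count), 2L)
  expect_equal(cov_library_size(cov), 2L)
  expect_equal(cov_dropped(cov), 2L)

  empty <- fivep_counts(reads_at(character(), integer()), tx)
  expect_equal(nrow(empty), 0L)
  expect_equal(cov_library_size(empty), 0L)

  expect_warning(fivep_counts(tibble::tibble(gene_id = "G1", pos = 1L,
                                             umi = "A"), tx),
                 "deduplicated")
})

test_that("fivep_counts is invariant to input record order", {
  tx <- tiny_tx()
  set.seed(4)
  r <- reads_at(sample(tx$gene_id, 300, replace = TRUE),
                sample.int(400, 300, replace = TRUE))
  shuffled <- r[sample.int(nrow(r)), ]
  attr(shuffled, "deduplicated") <- TRUE
  expect_equal(as.data.frame(fivep_counts(r, tx)),
               as.data.frame(fivep_counts(shuffled, tx)))
})

test_that("rpm scaling multiplies by 1e6/library_size and is guarded", {
  tx <- tiny_tx()
  cov <- random_coverage(tx, n_reads = 1000L, seed = 8L)
  rpm <- rpm_normalize(cov)
  expect_equal(cov_scale(rpm), "rpm")
  expect_equal(rpm$count, cov$count * 1e6 / 1000)
  expect_equal(sum(rpm$count), 1e6)     # all reads retained here
  expect_error(rpm_normalize(rpm), "already scaled")

  empty <- fivep_counts(reads_at(character(), integer()), tx)
  expect_error(rpm_normalize(empty), "zero")
})

test_that("BED round-trip preserves reads", {
  skip_if_not_installed("rtracklayer")
  cfg <- small_cfg(n_genes = 5L, n_reads = 200L, seed = 13L)
  sim <- simulate_degradome(cfg)
  path <- withr::local_tempfile(fileext = ".bed")
  write_degradome_bed(sim$reads, path)
  back <- read_fivep_bed(path)
  expect_equal(back$gene_id, sim$reads$gene_id)
  expect_equal(back$pos, sim$reads$pos)
  expect_equal(back$umi, sim$reads$umi)
})

test_that("BAM ingestion takes the biological 5' end, strand-aware", {
  skip_if_not_installed("Rsamtools")
  # two 10-nt alignments on a 480-nt reference: one +, one - strand
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:G1\tLN:480",
    "r1_ACGTACGT\t0\tG1\t87\t60\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "r2_TTTTCCCC\t16\tG1\t87\t60\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "r3_AAAACCCC\t0\tG1\t50\t0\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII"
  )
  samfile <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, samfile)
  bam <- Rsamtools::asBam(samfile, withr::local_tempfile(),
                          overwrite = TRUE, indexDestination = TRUE)
  got <- read_fivep_bam(bam)
  got <- got[order(got$umi), ]
  # + strand: 5' end = leftmost base (1-based 87 -> 0-based 86);
  # - strand: 5' end = rightmost base (1-based 96 -> 0-based 95);
  # MAPQ 0 read excluded
  expect_equal(got$pos, c(86L, 95L))
  expect_equal(got$umi, c("ACGTACGT", "TTTTCCCC"))
})
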