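test_that("reverse_complement matches its definition and is an involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("ACGTA"), "TACGT")
  expect_identical(reverse_complement("NNAC"), "GTNN")
  expect_error(reverse_complement("ACGU"), "non-IUPAC")

  set.seed(11)
  for (i in 1:50) {
    s <- random_dna(sample(1:200, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(reverse_complement(s), naive_rc(s))
  }
})

test_that("read_set enforces its invariants", {
  rs <- read_set(c("a", "b"), c("ACGT", "GGTT"), c("IIII", "JJJJ"),
                 paired = TRUE)
  expect_equal(n_reads(rs), 2)
  expect_error(read_set("a", "ACGT", "III"), "mismatch at read 1")
  expect_error(read_set("a", "", "'"), "empty")
  expect_error(read_set(c("a", "b", "c"), rep("ACGT", 3), rep("IIII", 3),
                        paired = TRUE), "even")
})

test_that("FASTQ round-trips byte-exactly, plain and gzipped", {
  set.seed(7)
  n <- 25
  seqs <- vapply(1:n, function(i) random_dna(sample(50:80, 1)), "")
  quals <- vapply(seqs, function(s)
    rawToChar(as.raw(sample(33:126, nchar(s), replace = TRUE))), "",
    USE.NAMES = FALSE)
  rs <- read_set(paste0("read", 1:n), seqs, quals)

  plain <- withr::local_tempfile(fileext = ".fq")
  gz <- withr::local_tempfile(fileext = ".fq.gz")
  write_fastq(rs, plain)
  write_fastq(rs, gz)
  back <- read_fastq(plain)
  back_gz <- read_fastq(gz)
  for (f in c("id", "seq", "qual")) {
    expect_identical(back[[f]], rs[[f]])
    expect_identical(back_gz[[f]], rs[[f]])
  }
})

test_that("malformed FASTQ is rejected with the record index", {
  f <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), f)
  expect_error(read_fastq(f), "record 2")
  writeLines(c("@r1", "ACGT", "+", "III"), f)
  expect_error(read_fastq(f), "record 1")
})

test_that("two-file pairing interleaves mates in order", {
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@a/1", "AAAA", "+", "IIII", "@b/1", "CCCC", "+", "IIII"), f1)
  writeLines(c("@a/2", "GGGG", "+", "IIII", "@b/2", "TTTT", "+", "IIII"), f2)
  rs <- read_fastq(f1, f2)
  expect_true(rs$paired)
  expect_identical(rs$seq, c("AAAA", "GGGG", "CCCC", "TTTT"))
})

test_that("simulated diploid genomes honor het_rate and determinism", {
  g0 <- simulate_diploid_genome(5000, het_rate = 0, seed = 3)
  expect_identical(g0$hap_a, g0$hap_b)
  expect_equal(nrow(g0$truth), 0)

  g1 <- simulate_diploid_genome(1e5, het_rate = 1e-3, seed = 5)
  g2 <- simulate_diploid_genome(1e5, het_rate = 1e-3, seed = 5)
  expect_identical(g1$hap_a, g2$hap_a)
  expect_identical(g1$truth, g2$truth)
  # Binomial(1e5, 1e-3): mean 100, sd ~10; 4 sigma band
  expect_gt(nrow(g1$truth), 100 - 40)
  expect_lt(nrow(g1$truth), 100 + 40)
  # hap_b is hap_a with exactly the truth substitutions applied
  a <- strsplit(g1$hap_a, "")[[1]]
  b <- strsplit(g1$hap_b, "")[[1]]
  expect_identical(which(a != b), g1$truth$pos)
  expect_identical(b[g1$truth$pos], g1$truth$alt)
})

test_that("repeat planting rejects overfull genomes and places all copies", {
  expect_error(simulate_diploid_genome(1000, 0,
    repeat_spec = data.frame(unit_length = 600, copy_count = 2,
                             family_count = 1), seed = 1),
    "exceeds")
  g <- simulate_diploid_genome(20000, 0,
    repeat_spec = data.frame(unit_length = 100, copy_count = 5,
                             family_count = 2), seed = 1)
  expect_equal(nrow(g$repeat_annotation), 10)
  # planted copies are identical within a family
  ann <- g$repeat_annotation
  for (fam in unique(ann$family)) {
    rows <- ann[ann$family == fam, ]
    copies <- substring(g$hap_a, rows$start, rows$start + rows$length - 1)
    expect_length(unique(copies), 1)
  }
})

test_that("simulated reads reproduce the genome, errors and fragments", {
  # error-free reads from a uniform genome are all A
  g <- list(hap_a = strrep("A", 1000), hap_b = strrep("A", 1000))
  class(g) <- "diploid_genome"
  rs <- simulate_reads(g, coverage = 1, read_len = 50, seed = 2)
  # error-free: every read is the source homopolymer on one or other strand
  expect_true(all(grepl("^(A+|T+)$", rs$seq)))

  # flat 1% error over >= 1e6 bases lands within 4 sigma of 1%
  g2 <- simulate_diploid_genome(50000, het_rate = 0, seed = 9)
  rs2 <- simulate_reads(g2, coverage = 25, read_len = 100,
                        error_rate_by_pos = 0.01, seed = 4)
  truth <- attr(rs2, "truth")
  src <- substring(g2$hap_a, truth$start, truth$start + 99)
  src[truth$strand == "-"] <- naive_rc(src[truth$strand == "-"])
  mism <- sum(vapply(seq_along(src), function(i) {
    sum(charToRaw(rs2$seq[i]) != charToRaw(src[i]))
  }, 0))
  n_bases <- 100 * length(src)
  expect_gt(n_bases, 1e6)
  p_hat <- mism / n_bases
  se <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(p_hat - 0.01), 4 * se)

  # paired reads with fragment_sd = 0: outer distance equals fragment_mean
  rs3 <- simulate_reads(g2, coverage = 2, read_len = 50,
                        fragment_mean = 200, fragment_sd = 0,
                        paired = TRUE, seed = 6)
  truth3 <- attr(rs3, "truth")
  expect_true(all(truth3$fragment_length == 200))
  hap <- g2$hap_a
  for (i in seq_len(10)) {
    fwd <- rs3$seq[2 * i - 1]
    rev <- rs3$seq[2 * i]
    s <- truth3$start[i]
    expect_identical(fwd, substring(hap, s, s + 49))
    expect_identical(rev,
                     reverse_complement(substring(hap, s + 150, s + 199)))
  }
  expect_error(simulate_reads(g2, coverage = 0), "positive")
})
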