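test_that("overlap candidates come from shared seeds on either strand", {
  set.seed(90)
  genome <- random_dna(400)
  # 5 reads overlapping the query's window, 3 far away, 1 reverse strand
  q <- substr(genome, 100, 199)
  near <- substring(genome, c(80, 90, 110, 120), c(179, 189, 209, 219))
  far <- substring(genome, c(250, 280, 300), c(349, 379, 399))
  rcnear <- naive_rc(substr(genome, 130, 229))
  rs <- read_set(paste0("r", 1:9), c(q, near, far, rcnear),
                 strrep("I", nchar(c(q, near, far, rcnear))))
  idx <- build_kmer_index(rs, 31, with_k_plus_1 = FALSE, seed_len = 31)
  cand <- overlap_candidates(idx, 1)
  expect_setequal(cand$read, c(2:5, 9))
  expect_true(cand$rc[cand$read == 9])
  expect_false(any(cand$rc[cand$read != 9]))
  # diagonals recover the planted offsets (candidate start in query frame)
  expect_equal(cand$offset[match(2:5, cand$read)], c(-20, -10, 10, 20))
  expect_equal(cand$offset[cand$read == 9], 30)
})

test_that("repetitive seeds are capped at exactly max_seed_count", {
  set.seed(91)
  seed_kmer <- random_dna(31)
  # the query is exactly the seed, so it has one seed k-mer; the others
  # embed the seed between unique random flanks
  make_set <- function(n_extra) {
    others <- vapply(seq_len(n_extra), function(i)
      paste0(random_dna(10), seed_kmer, random_dna(10)), "")
    seqs <- c(seed_kmer, others)
    read_set(paste0("r", seq_along(seqs)), seqs, strrep("I", nchar(seqs)))
  }
  rs_ok <- make_set(199)   # 200 occurrences in total
  idx_ok <- build_kmer_index(rs_ok, 31, with_k_plus_1 = FALSE,
                             seed_len = 31)
  expect_equal(nrow(overlap_candidates(idx_ok, 1)), 199)

  rs_over <- make_set(200)  # 201 occurrences: skipped
  idx_over <- build_kmer_index(rs_over, 31, with_k_plus_1 = FALSE,
                               seed_len = 31)
  expect_equal(nrow(overlap_candidates(idx_over, 1)), 0)
})

test_that("ungapped overlaps apply the length and identity thresholds", {
  set.seed(92)
  r <- random_dna(100)
  ov <- compute_overlap(r, r, 0)
  expect_equal(ov$start, 1)
  expect_equal(ov$end, 100)
  expect_equal(ov$identity, 1)

  # 60 bp overlap with 2 mismatches: identity ~0.967, accepted
  s <- substr(r, 41, 100)
  substr(s, 10, 10) <- if (substr(s, 10, 10) == "A") "C" else "A"
  substr(s, 20, 20) <- if (substr(s, 20, 20) == "G") "T" else "G"
  s <- paste0(s, random_dna(40))
  ov2 <- compute_overlap(r, s, 40)
  expect_equal(ov2$identity, 58 / 60, tolerance = 1e-12)
  expect_equal(length(ov2$mismatch_pos), 2)

  # 40 bp overlap: below the length threshold
  expect_null(compute_overlap(r, paste0(substr(r, 61, 100),
                                        random_dna(60)), 60))
  # 4 mismatches in 60 bp: identity ~0.933, below the identity threshold
  s3 <- substr(r, 41, 100)
  for (p in c(5, 15, 25, 35))
    substr(s3, p, p) <- if (substr(s3, p, p) == "A") "C" else "A"
  expect_null(compute_overlap(r, paste0(s3, random_dna(40)), 40))
})

test_that("a single planted error among 11 stacked reads gives rate 1/11", {
  set.seed(93)
  base <- random_dna(60)
  seqs <- rep(base, 11)
  substr(seqs[1], 3, 3) <- if (substr(base, 3, 3) == "A") "C" else "A"
  rs <- read_set(paste0("r", 1:11), seqs, rep(strrep("I", 60), 11))
  idx <- build_kmer_index(rs, 31, with_k_plus_1 = FALSE, seed_len = 31)
  ep <- per_base_error_rate(idx, n_sample_reads = 11)
  expect_equal(ep$rate[3], 1 / 11)
  expect_true(all(ep$rate[-3] == 0))
  expect_true(all(ep$assessed == 11))
})

test_that("consensus-support thresholds are exact on both sides", {
  set.seed(94)
  base <- random_dna(100)   # long enough that seeds avoid the mismatches
  sub_at <- function(s, p, b) { substr(s, p, p) <- b; s }
  other <- function(s, p, n = 1) {
    setdiff(c("A", "C", "G", "T"), substr(s, p, p))[n]
  }
  flip <- function(s, p) sub_at(s, p, other(s, p))

  # consensus support 3 at depth 4: the dissenting base is an error
  seqs <- c(flip(base, 5), base, base, base)
  rs <- read_set(paste0("r", 1:4), seqs, rep(strrep("I", 100), 4))
  idx <- build_kmer_index(rs, 31, with_k_plus_1 = FALSE, seed_len = 31)
  ep <- per_base_error_rate(idx, n_sample_reads = 4)
  expect_equal(ep$errors[5], 1)
  expect_true(all(ep$errors[-5] == 0))
  expect_true(all(ep$assessed == 4))

  # consensus support 2 at depth 4 (2/1/1 split): never an error
  seqs2 <- c(sub_at(base, 5, other(base, 5, 1)), base, base,
             sub_at(base, 5, other(base, 5, 2)))
  seqs2[3] <- flip(base, 96)  # keep read 3 distinct elsewhere
  rs2 <- read_set(paste0("r", 1:4), seqs2, rep(strrep("I", 100), 4))
  idx2 <- build_kmer_index(rs2, 31, with_k_plus_1 = FALSE, seed_len = 31)
  ep2 <- per_base_error_rate(idx2, n_sample_reads = 4)
  expect_equal(ep2$errors[5], 0)
  expect_true(all(ep2$assessed >= 4 - 1e-9))

  # a base supported by 4 reads is never called an error ...
  seqs3 <- c(rep(flip(base, 5), 4), rep(base, 6))
  rs3 <- read_set(paste0("r", 1:10), seqs3, rep(strrep("I", 100), 10))
  idx3 <- build_kmer_index(rs3, 31, with_k_plus_1 = FALSE, seed_len = 31)
  ep3 <- per_base_error_rate(idx3, n_sample_reads = 10)
  expect_equal(ep3$errors[5], 0)
  # ... while 3 carriers of the same base are each flagged
  seqs4 <- c(rep(flip(base, 5), 3), rep(base, 7))
  rs4 <- read_set(paste0("r", 1:10), seqs4, rep(strrep("I", 100), 10))
  idx4 <- build_kmer_index(rs4, 31, with_k_plus_1 = FALSE, seed_len = 31)
  ep4 <- per_base_error_rate(idx4, n_sample_reads = 10)
  expect_equal(ep4$errors[5], 3)
})

test_that("error-free coverage yields a zero error profile", {
  set.seed(95)
  g <- simulate_diploid_genome(20000, het_rate = 0, seed = 96)
  rs <- simulate_reads(g, coverage = 15, read_len = 100, seed = 97)
  idx <- build_kmer_index(rs, 31, with_k_plus_1 = FALSE, seed_len = 31)
  ep <- per_base_error_rate(idx, n_sample_reads = 500)
  expect_true(all(ep$errors == 0))
  expect_true(all(ep$rate[ep$assessed > 0] == 0))
})

test_that("quality summaries follow the stored Phred strings", {
  rs <- read_set(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"),
                 c(strrep("5", 10), strrep("I", 10)))  # Q20 and Q40
  qp <- quality_by_position(rs)
  expect_equal(qp$mean, rep(30, 10))
  expect_equal(qp$q10, rep(22, 10))  # deciles span 20..40
  expect_equal(qp$q90, rep(38, 10))

  rs30 <- read_set("a", "ACGT", strrep("?", 4))  # Q30
  qp30 <- quality_by_position(rs30)
  expect_equal(qp30$mean, rep(30, 4))
  expect_equal(qp30$q50, rep(30, 4))
})

test_that("GC-coverage histograms conserve mass and respect GC binning", {
  at_read <- strrep("AT", 30)
  gc_read <- strrep("GC", 30)
  rs <- read_set(c("a", "b"), c(at_read, gc_read),
                 c(strrep("I", 60), strrep("I", 60)))
  idx <- build_kmer_index(rs, 20, with_k_plus_1 = FALSE)
  set.seed(98)
  gch <- gc_coverage_histogram(idx, k = 20, n_samples = 500, gc_bins = 10)
  expect_equal(sum(gch$counts), gch$n_sampled)
  # all mass in the extreme GC columns
  expect_equal(sum(gch$counts[c(1, 10), ]), gch$n_sampled)

  # unbiased simulated coverage: per-GC-column mean counts agree
  set.seed(99)
  g <- simulate_diploid_genome(30000, het_rate = 0, seed = 99)
  rs2 <- simulate_reads(g, coverage = 25, read_len = 100, seed = 100)
  idx2 <- build_kmer_index(rs2, 21, with_k_plus_1 = FALSE)
  gch2 <- gc_coverage_histogram(idx2, k = 21, n_samples = 20000,
                                gc_bins = 10)
  m <- gch2$counts
  col_n <- rowSums(m)
  keep <- which(col_n >= 500)
  mean_count <- sapply(keep, function(i)
    sum(m[i, ] * gch2$count_bins) / col_n[i])
  sd_count <- sapply(keep, function(i) {
    mu <- sum(m[i, ] * gch2$count_bins) / col_n[i]
    sqrt(sum(m[i, ] * (gch2$count_bins - mu)^2) / col_n[i])
  })
  overall <- sum(m * rep(gch2$count_bins, each = nrow(m))) / sum(m)
  z <- abs(mean_count - overall) / (sd_count / sqrt(col_n[keep]))
  expect_true(all(z < 6))
})
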