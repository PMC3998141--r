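params30 <- classifier_params(NULL, read_len = 100, k = 21, lambda = 30)

test_that("branch observations compute the excess-read statistic d", {
  expect_equal(branch_observation(20, 18, 12, 10)$d, 16)
  expect_equal(branch_observation(10, 10, 12, 11)$d, 0)  # floored at 0
  expect_error(branch_observation(5, 9, 1, 1), "higher-coverage")
})

test_that("d likelihoods are normalized and separate variants from repeats", {
  for (cl in c("error", "variant", "repeat")) {
    expect_equal(sum(likelihood_d(0:5000, cl, params30)), 1,
                 tolerance = 1e-8)
  }
  # d = 0: variant model dominates the repeat model when lambda >> rho
  expect_gt(likelihood_d(0, "variant", params30),
            likelihood_d(0, "repeat", params30))
  # d = 2 lambda: repeat model dominates by a wide margin
  expect_gt(likelihood_d(60, "repeat", params30),
            10 * likelihood_d(60, "variant", params30))
})

test_that("balance likelihoods match their closed forms", {
  # uniform Beta-Binomial special case: alpha = beta = 1, n = 2
  p_unif <- classifier_params(NULL, read_len = 100, k = 21, lambda = 30,
                              alpha = 1, beta = 1)
  expect_equal(likelihood_balance(c(2, 1, 0), c(0, 1, 2), "repeat", p_unif),
               rep(1 / 3, 3), tolerance = 1e-12)
  # balanced variant: C(10, 5) / 2^10
  expect_equal(likelihood_balance(5, 5, "variant", params30),
               choose(10, 5) / 2^10, tolerance = 1e-12)
  expect_equal(likelihood_balance(5, 5, "variant", params30), 0.24609,
               tolerance = 1e-4)
  # heavily skewed branch: error model beats variant model
  expect_gt(likelihood_balance(30, 0, "error", params30),
            likelihood_balance(30, 0, "variant", params30))
})

test_that("posterior classification picks the expected class", {
  argmax <- function(p) c("error", "variant", "repeat")[which.max(
    unlist(p[1, c("p_error", "p_variant", "p_repeat")]))]
  # balanced deep branch with no excess reads: variant
  expect_identical(
    argmax(classify_branch(list(c_a = 15, c_b = 15, d = 0), params30)),
    "variant")
  # skewed branch: error
  expect_identical(
    argmax(classify_branch(list(c_a = 28, c_b = 2, d = 0), params30)),
    "error")
  # deep balanced branch with many excess reads: repeat
  expect_identical(
    argmax(classify_branch(list(c_a = 30, c_b = 30, d = 60), params30)),
    "repeat")
})

test_that("posteriors normalize and soft counts conserve the branch total", {
  set.seed(66)
  n <- 200
  obs <- list(c_a = sample(5:60, n, TRUE), c_b = sample(1:30, n, TRUE),
              d = sample(0:80, n, TRUE))
  obs$c_b <- pmin(obs$c_b, obs$c_a)
  post <- classify_branch(obs, params30)
  expect_equal(rowSums(post), rep(1, n), tolerance = 1e-12)
  expect_equal(sum(colSums(post)), n, tolerance = 1e-9)
})

test_that("the R classifier and the C++ classifier used in walks agree", {
  set.seed(67)
  n <- 100
  ca <- sample(5:60, n, TRUE)
  cb <- pmin(sample(1:30, n, TRUE), ca)
  d <- sample(0:80, n, TRUE)
  r_post <- classify_branch(list(c_a = ca, c_b = cb, d = d), params30)
  c_post <- preqcr:::.classify_branches_cpp(
    as.integer(ca), as.integer(cb), as.integer(d),
    preqcr:::.cls_par_list(params30))
  expect_equal(unname(as.matrix(r_post)), unname(c_post), tolerance = 1e-12)
})

test_that("observe_branch reports SNP bubbles and ignores linear sequence", {
  set.seed(70)
  core <- random_dna(61)
  alt <- core
  substr(alt, 31, 31) <- if (substr(core, 31, 31) == "A") "C" else "A"
  rs <- deep_read_set(c(core, alt), depth = 6)
  idx <- build_kmer_index(rs, 21, with_k_plus_1 = TRUE)
  obs <- observe_branch(idx, substr(core, 10, 30))
  expect_false(is.null(obs))
  expect_equal(obs$c_a, obs$c_b)       # both alleles equally covered
  expect_equal(obs$c_a, 12)            # 6 copies on each strand
  expect_lte(obs$d, 1)

  expect_null(observe_branch(idx, substr(core, 1, 21)))
})

test_that("strand validation suppresses branches from one-strand errors", {
  set.seed(71)
  core <- random_dna(61)
  alt <- core
  substr(alt, 31, 31) <- if (substr(core, 31, 31) == "A") "C" else "A"
  # core covered on both strands; the alternative allele only ever on one
  # strand, emulating a strand-specific systematic error
  rs <- read_set(paste0("r", 1:18),
                 c(rep(core, 6), naive_rc(rep(core, 6)), rep(alt, 6)),
                 rep(strrep("I", 61), 18))
  idx <- build_kmer_index(rs, 21, with_k_plus_1 = TRUE)
  x <- substr(core, 10, 30)
  nb <- kmer_neighbors(idx, x, "suffix")
  expect_equal(sum(nb$strand_validated), 1)
  expect_null(observe_branch(idx, x))
  expect_false(is_suffix_branch(idx, x))
})

test_that("reference branch rates match exhaustive enumeration", {
  # no heterozygosity, no repeats: nothing branches
  g0 <- simulate_diploid_genome(4000, het_rate = 0, seed = 80)
  r0 <- reference_branch_rates(g0, 21)
  expect_equal(r0$n_variant, 0)
  expect_equal(r0$n_repeat, 0)

  # one planted SNP in unique sequence: exactly one variant branch per
  # orientation, rate 1/N_h
  g1 <- simulate_diploid_genome(10000, het_rate = 0, seed = 81)
  a <- strsplit(g1$hap_a, "")[[1]]
  b <- a
  b[5000] <- setdiff(c("A", "C", "G", "T"), a[5000])[1]
  g1$hap_b <- paste(b, collapse = "")
  r1 <- reference_branch_rates(g1, 21)
  expect_equal(r1$n_variant, 2)  # the bubble opens once per orientation
  expect_equal(r1$n_repeat, 0)
  expect_equal(r1$variant_rate, 2 / r1$N_h)

  # agreement with the naive R enumeration on genomes with variation and
  # diverged repeats
  g2 <- simulate_diploid_genome(6000, het_rate = 2e-3,
    repeat_spec = data.frame(unit_length = 120, copy_count = 4,
                             family_count = 1, divergence = 0.03),
    seed = 82)
  for (k in c(15, 21)) {
    fast <- reference_branch_rates(g2, k)
    slow <- naive_ref_branch_rates(g2$hap_a, g2$hap_b, k)
    expect_equal(fast$N_h, slow$N_h)
    expect_equal(fast$variant_rate, slow$variant_rate)
    expect_equal(fast$repeat_rate, slow$repeat_rate)
  }
  expect_error(reference_branch_rates(g0, 5000), "exceeds")
})

test_that("identical repeat copies create no branches at unique k-mers", {
  # every junction induced by identical copies lies inside the repeat,
  # where multiplicity excludes the vertex from the homozygous set; the
  # enumeration therefore reports no repeat branches (diverged copies do
  # produce them, as tested above)
  g <- simulate_diploid_genome(12000, het_rate = 0,
    repeat_spec = data.frame(unit_length = 500, copy_count = 2,
                             family_count = 1), seed = 83)
  r <- reference_branch_rates(g, 21)
  expect_equal(r$n_repeat, 0)
  expect_equal(r$n_variant, 0)
  slow <- naive_ref_branch_rates(g$hap_a, g$hap_b, 21)
  expect_equal(slow$repeat_rate, 0)
})

test_that("branch rates on clean haploid data are near zero", {
  set.seed(84)
  g <- simulate_diploid_genome(60000, het_rate = 0, seed = 85)
  rs <- simulate_reads(g, coverage = 40, read_len = 100, seed = 86)
  br <- branch_rates(rs, k_values = c(21, 31), n_sample_reads = 5000,
                     n_hist_reads = 5000)
  vr <- ifelse(is.na(br$variant_rate), 0, br$variant_rate)
  rr <- ifelse(is.na(br$repeat_rate), 0, br$repeat_rate)
  expect_true(all(vr < 1e-4))
  expect_true(all(rr < 1e-4))
  expect_true(all(br$N_h > 0))
})

test_that("rates from soft counts below 2 are suppressed", {
  set.seed(87)
  g <- simulate_diploid_genome(60000, het_rate = 0, seed = 88)
  rs <- simulate_reads(g, coverage = 40, read_len = 100, seed = 89)
  br <- branch_rates(rs, k_values = 31, n_sample_reads = 3000,
                     n_hist_reads = 5000)
  # clean haploid data: every soft count is tiny, so every rate is NA
  expect_true(all(is.na(c(br$variant_rate, br$repeat_rate))))
})
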