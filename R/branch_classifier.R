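#' Parameters of the branch classification model
#'
#' Bundles everything the error/variant/repeat classifier needs. The
#' read-start density per genomic copy is `rho = lambda / (l - k + 1)`:
#' under the error and variant models a read can contain a branch neighbor
#' but not the branching k-mer only when the neighbor is the first k-mer
#' of the read (or the first base of the branching k-mer carries an
#' error), so the excess-read statistic `d` has Poisson mean
#' `mu_ev = rho + mu_epsilon`. Under the repeat model the neighbors have
#' `m` extra genomic copies and `d` has mean `m * lambda + rho`, mixed
#' over repeat states `m = 1..7` with weights taken from the fitted
#' repeat components.
#'
#' @param model A fitted `count_mixture` ([fit_mixture_em()]) supplying `lambda` and the
#'   repeat-state weights, or `NULL` if `lambda` and `repeat_weights` are
#'   given directly.
#' @param read_len Read length `l`.
#' @param k k-mer size being classified.
#' @param lambda Homozygous mean count; defaults to `model$lambda`.
#' @param repeat_weights Weights over extra-copy multipliers 1..7;
#'   defaults to the fitted repeat-component weights, renormalized
#'   (uniform when all are zero).
#' @param p_error_balance Binomial success probability for the minor
#'   neighbor count under the error model (default 0.05).
#' @param alpha,beta Beta-Binomial parameters of the repeat balance model
#'   (default 2, 2: mild overdispersion around 1/2, reflecting uncertainty
#'   in the copy-number configuration of the two neighbors).
#' @param mu_epsilon Small additive allowance in `mu_ev` for first-base
#'   sequencing errors (default 0.05).
#' @param hom_threshold Minimum posterior probability of being homozygous
#'   for a k-mer to be checked for branches (default 0.90).
#' @param min_lambda Minimum coverage `lambda` below which branch
#'   classification is not reported (default 15).
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(model = NULL, read_len, k,
                              lambda = model$lambda,
                              repeat_weights = NULL,
                              p_error_balance = 0.05, alpha = 2, beta = 2,
                              mu_epsilon = 0.05, hom_threshold = 0.90,
                              min_lambda = 15) {
  if (is.null(lambda)) stop("lambda is required (directly or via model)")
  if (is.null(repeat_weights)) {
    repeat_weights <- if (!is.null(model)) model$weights[-(1:3)] else rep(1, 7)
  }
  if (sum(repeat_weights) <= 0) repeat_weights <- rep(1, length(repeat_weights))
  repeat_weights <- repeat_weights / sum(repeat_weights)
  if (k >= read_len) stop("k must be smaller than the read length")
  rho <- lambda / (read_len - k + 1)
  structure(list(lambda = lambda, read_len = read_len, k = k, rho = rho,
                 mu_ev = rho + mu_epsilon, repeat_weights = repeat_weights,
                 p_error_balance = p_error_balance, alpha = alpha,
                 beta = beta, hom_threshold = hom_threshold,
                 min_lambda = min_lambda),
            class = "classifier_params")
}

#' Assemble a branch observation from neighbor counts
#'
#' `c_a >= c_b` are the combined-strand counts of the two highest-coverage
#' strand-validated suffix neighbors of a branching k-mer; `c_ia` and
#' `c_ib` are the counts of the joining (k+1)-mers, i.e. reads containing
#' both the branching k-mer and the respective neighbor. The excess-read
#' statistic is `d = max(0, (c_a - c_ia) + (c_b - c_ib))`: the number of
#' reads containing a neighbor but not the branching k-mer.
#'
#' @param c_a,c_b Neighbor counts with `c_a >= c_b`.
#' @param c_ia,c_ib Joining (k+1)-mer counts.
#' @param k k-mer size (optional bookkeeping).
#' @return An object of class `branch_observation`.
#' @examples
#' branch_observation(20, 18, 12, 10)$d  # 16
#' @export
branch_observation <- function(c_a, c_b, c_ia, c_ib, k = NA_integer_) {
  if (c_b > c_a) stop("c_a must be the higher-coverage neighbor")
  d <- max(0L, (c_a - c_ia) + (c_b - c_ib))
  structure(list(c_a = as.integer(c_a), c_b = as.integer(c_b),
                 c_ia = as.integer(c_ia), c_ib = as.integer(c_ib),
                 d = as.integer(d), k = as.integer(k)),
            class = "branch_observation")
}

#' Observe a suffix branch at a k-mer
#'
#' Checks `x` for at least two strand-validated suffix neighbors; when
#' present, returns the [branch_observation] built from the two
#' highest-coverage neighbors (ties broken in base order A < C < G < T),
#' otherwise `NULL`. Requires k and k+1 to be indexed.
#'
#' @param index A `kmer_index` (see [build_kmer_index()]) with k and k+1 indexed.
#' @param x A single k-mer.
#' @return A [branch_observation] or `NULL`.
#' @export
observe_branch <- function(index, x) {
  x <- .check_kmers(index, x)
  if (!(nchar(x) + 1L) %in% index$k_values)
    stop("k + 1 = ", nchar(x) + 1L, " is not indexed")
  o <- .idx_branch_obs(index$ptr, x)
  if (!length(o)) return(NULL)
  branch_observation(o[1], o[2], o[3], o[4], k = nchar(x))
}

.cls_par_list <- function(params) {
  list(lambda = params$lambda, rho = params$rho, mu_ev = params$mu_ev,
       p_error_balance = params$p_error_balance, alpha = params$alpha,
       beta = params$beta, repeat_weights = params$repeat_weights)
}

#' Likelihood of the excess-read statistic d under each branch class
#'
#' Error and variant branches: `Poisson(d; mu_ev)`. Repeat branches:
#' a mixture over extra-copy states `m`, `sum_m q_m Poisson(d; m * lambda
#' + rho)`.
#'
#' @param d Non-negative integer statistic (vectorized).
#' @param class One of `"error"`, `"variant"`, `"repeat"`.
#' @param params A [classifier_params].
#' @return Numeric vector of probabilities.
#' @export
likelihood_d <- function(d, class = c("error", "variant", "repeat"),
                         params) {
  class <- match.arg(class)
  if (class %in% c("error", "variant"))
    return(stats::dpois(d, params$mu_ev))
  q <- params$repeat_weights
  out <- numeric(length(d))
  for (m in seq_along(q))
    out <- out + q[m] * stats::dpois(d, m * params$lambda + params$rho)
  out
}

# Beta-Binomial pmf
.dbetabinom <- function(x, size, alpha, beta) {
  exp(lchoose(size, x) + lbeta(x + alpha, size - x + beta) -
        lbeta(alpha, beta))
}

#' Likelihood of the neighbor coverage balance under each branch class
#'
#' The minor neighbor count `c_b` out of `c_a + c_b` follows
#' `Binomial(n, 1/2)` for a variant (both alleles equally represented),
#' `Binomial(n, p_error_balance)` for an error (most reads support the
#' true neighbor), and `BetaBinomial(n, alpha, beta)` for a repeat
#' (uncertain copy-number configuration).
#'
#' @param c_a,c_b Neighbor counts, `c_a >= c_b` (vectorized).
#' @inheritParams likelihood_d
#' @return Numeric vector of probabilities.
#' @export
likelihood_balance <- function(c_a, c_b,
                               class = c("error", "variant", "repeat"),
                               params) {
  class <- match.arg(class)
  n <- c_a + c_b
  switch(class,
         error = stats::dbinom(c_b, n, params$p_error_balance),
         variant = stats::dbinom(c_b, n, 0.5),
         `repeat` = .dbetabinom(c_b, n, params$alpha, params$beta))
}

#' Posterior classification of branches
#'
#' Combines the excess-read and coverage-balance likelihoods under a
#' uniform prior (assuming their independence) into posterior
#' probabilities for the error, variant and repeat classes. Accepts a
#' single [branch_observation] or parallel vectors of counts.
#'
#' @param obs A [branch_observation], or a list/data frame with elements
#'   `c_a`, `c_b`, `d` (vectorized).
#' @param params A [classifier_params].
#' @return A data frame with columns `p_error`, `p_variant`, `p_repeat`;
#'   rows sum to one.
#' @export
classify_branch <- function(obs, params) {
  ca <- obs$c_a; cb <- obs$c_b; d <- obs$d
  le <- likelihood_d(d, "error", params) *
    likelihood_balance(ca, cb, "error", params)
  lv <- likelihood_d(d, "variant", params) *
    likelihood_balance(ca, cb, "variant", params)
  lr <- likelihood_d(d, "repeat", params) *
    likelihood_balance(ca, cb, "repeat", params)
  s <- le + lv + lr
  deg <- s <= 0
  if (any(deg)) { le[deg] <- lv[deg] <- lr[deg] <- 1; s[deg] <- 3 }
  data.frame(p_error = le / s, p_variant = lv / s, p_repeat = lr / s)
}

#' Branch rates of the de Bruijn graph across k
#'
#' For each k: builds a transient k/(k+1) index over the reads, samples a
#' count histogram, refits the count mixture (the homozygous mean depends
#' on k), then scans the k-mers of randomly sampled reads. Each k-mer
#' instance whose posterior probability of being homozygous passes the
#' threshold is checked for a suffix branch; branches are soft-classified
#' and the per-class posteriors accumulated into fractional branch counts
#' `F_error`, `F_variant`, `F_repeat`. Rates are `F_x / N_h`, where `N_h`
#' is the number of homozygous k-mer instances checked; a rate whose soft
#' count is below 2 is reported as `NA`, and a k whose fitted coverage
#' `lambda` falls below `min_lambda` is skipped with a notice.
#'
#' @param reads A [read_set].
#' @param k_values k grid (default 21 to 71 in steps of 5).
#' @param n_sample_reads Reads sampled per k for the branch scan
#'   (default 1e6; capped at the available reads).
#' @param n_hist_reads Reads sampled per k for the count histogram.
#' @param ... Overrides passed to [classifier_params()] (e.g.
#'   `hom_threshold`, `alpha`).
#' @return A data frame with one row per k: `k`, `lambda`, `N_h`,
#'   `F_error`, `F_variant`, `F_repeat`, `error_rate`, `variant_rate`,
#'   `repeat_rate`.
#' @export
branch_rates <- function(reads, k_values = seq(21, 71, by = 5),
                         n_sample_reads = 1e6, n_hist_reads = 50000, ...) {
  stopifnot(inherits(reads, "read_set"))
  out <- lapply(k_values, function(k) {
    idx <- build_kmer_index(reads, k, with_k_plus_1 = TRUE)
    res <- .branch_rates_one_k(idx, k, n_sample_reads, n_hist_reads, ...)
    rm(idx); gc(FALSE)
    res
  })
  do.call(rbind, out)
}

.branch_rates_one_k <- function(index, k, n_sample_reads, n_hist_reads,
                                ...) {
  hist <- sample_count_histogram(index, k, n_hist_reads)
  model <- fit_mixture_em(hist)
  params <- classifier_params(model, read_len = index$modal_read_length,
                              k = k, ...)
  empty <- data.frame(k = k, lambda = model$lambda, N_h = NA_real_,
                      F_error = NA_real_, F_variant = NA_real_,
                      F_repeat = NA_real_, error_rate = NA_real_,
                      variant_rate = NA_real_, repeat_rate = NA_real_)
  if (model$lambda < params$min_lambda) {
    message("k = ", k, ": lambda = ", signif(model$lambda, 3),
            " below min_lambda = ", params$min_lambda,
            "; no classification reported")
    return(empty)
  }
  cap <- attr(hist, "cap")
  post_hom <- posterior_homozygous(seq_len(cap), model)
  n_scan <- min(n_sample_reads, index$n_reads)
  ids <- if (n_scan == index$n_reads) seq_len(index$n_reads)
         else sample.int(index$n_reads, n_scan)
  scan <- .idx_scan_branches(index$ptr, ids - 1L, k, post_hom,
                             params$hom_threshold)
  n_h <- scan$n_h
  if (length(scan$ca)) {
    post <- classify_branch(list(c_a = scan$ca, c_b = scan$cb, d = scan$d),
                            params)
    f <- unname(colSums(post))
  } else {
    f <- c(0, 0, 0)
  }
  rate <- ifelse(f >= 2 & n_h > 0, f / n_h, NA_real_)
  data.frame(k = k, lambda = model$lambda, N_h = n_h,
             F_error = f[1], F_variant = f[2], F_repeat = f[3],
             error_rate = rate[1], variant_rate = rate[2],
             repeat_rate = rate[3])
}

#' Exact branch rates from a diploid reference genome
#'
#' Enumerates the canonical k-mer multiset of both haplotypes and counts,
#' over homozygous vertices (multiplicity exactly one on each haplotype),
#' suffix branches in both orientations of each vertex. A branch is a
#' variant when it has exactly two neighbors that are genome-unique and
#' haplotype-specific (one on each haplotype) and a repeat otherwise.
#' `N_h` counts (vertex, orientation) pairs, matching the read-based scan
#' that checks every k-mer instance in its observed orientation, so the
#' rates are directly comparable with [branch_rates()].
#'
#' @param genome A [simulate_diploid_genome()] result (or list with
#'   `hap_a`, `hap_b` strings).
#' @param k k-mer size.
#' @return A list with `variant_rate`, `repeat_rate`, `N_h`,
#'   `n_variant`, `n_repeat`.
#' @export
reference_branch_rates <- function(genome, k) {
  res <- .ref_branch_rates_cpp(genome$hap_a, genome$hap_b, as.integer(k))
  list(variant_rate = res$n_variant / res$n_h,
       repeat_rate = res$n_repeat / res$n_h,
       N_h = res$n_h, n_variant = res$n_variant, n_repeat = res$n_repeat)
}
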