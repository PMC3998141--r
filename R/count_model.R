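#' Sample a k-mer count histogram from the index
#'
#' Samples reads uniformly at random and tallies the combined-strand count
#' of every A/C/G/T k-mer instance they contain. Counts above `cap` are
#' binned at `cap` to bound the cost of model fitting (the far tail is
#' repeat mass). If fewer reads are available than requested, all reads
#' are used once with a notice.
#'
#' @param index A `kmer_index` (see [build_kmer_index()]).
#' @param k Indexed k value.
#' @param n_sample_reads Number of reads to sample (default 50000).
#' @param cap Upper count bin.
#' @return An object of class `count_histogram`: a data frame of `count`
#'   and `freq` with attributes `k` and `n_sampled_reads`.
#' @export
sample_count_histogram <- function(index, k, n_sample_reads = 50000,
                                   cap = 1000) {
  k <- as.integer(k)
  if (!k %in% index$k_values)
    stop("k = ", k, " is not indexed")
  if (n_sample_reads >= index$n_reads) {
    if (n_sample_reads > index$n_reads)
      message("requested ", n_sample_reads, " reads but only ",
              index$n_reads, " available; using all reads once")
    ids <- seq_len(index$n_reads)
  } else {
    ids <- sample.int(index$n_reads, n_sample_reads)
  }
  counts <- .idx_read_kmer_counts(index$ptr, ids - 1L, k)
  counts <- pmin(counts, cap)
  tab <- tabulate(counts, nbins = cap)
  keep <- which(tab > 0L)
  structure(data.frame(count = keep, freq = tab[keep]),
            k = k, n_sampled_reads = length(ids), cap = cap,
            class = c("count_histogram", "data.frame"))
}

#' Zero-truncated Poisson probability mass function
#'
#' The Poisson distribution conditioned on a strictly positive count,
#' `dpois(c, rate) / (1 - exp(-rate))`, evaluated in log space for
#' numerical stability at large rates. Unobserved k-mers have count zero
#' by construction, so sampled k-mer counts follow this truncated form.
#'
#' @param c Positive integer counts (vectorized).
#' @param rate Poisson rate, `rate > 0`.
#' @param log Return log probabilities.
#' @return Probability (or log probability) of each count.
#' @examples
#' ztp_pmf(2, 1.0)  # ~0.29100
#' @export
ztp_pmf <- function(c, rate, log = FALSE) {
  if (any(c < 1)) stop("zero-truncated support starts at c = 1")
  if (any(rate <= 0)) stop("rate must be positive")
  lp <- stats::dpois(c, rate, log = TRUE) - log(-expm1(-rate))
  if (log) lp else exp(lp)
}

#' Initialize the homozygous mean count from a histogram
#'
#' Heuristic initializer for the homozygous-component rate: find the first
#' local minimum of the count spectrum (the trough between the error peak
#' at low counts and the genomic peak) and return the modal count above
#' it. When the histogram is monotone decreasing (error-dominated data)
#' there is no interior trough and the frequency-weighted mean count is
#' returned with a warning.
#'
#' @param hist A [sample_count_histogram()] result (or any data frame of
#'   `count` and `freq`).
#' @return Positive scalar, the initial homozygous mean count.
#' @export
initialize_lambda <- function(hist) {
  if (!nrow(hist) || sum(hist$freq) == 0) stop("empty histogram")
  cmax <- max(hist$count)
  dens <- numeric(cmax)
  dens[hist$count] <- hist$freq
  trough <- NA_integer_
  for (i in seq_len(cmax - 1L)) {
    if (dens[i + 1L] > dens[i]) { trough <- i; break }
  }
  if (is.na(trough)) {
    warning("count histogram is monotone decreasing; ",
            "falling back to the weighted mean count")
    return(sum(hist$count * hist$freq) / sum(hist$freq))
  }
  above <- (trough + 1L):cmax
  as.numeric(above[which.max(dens[above])])
}

# ZTP maximum-likelihood rate for an observed mean count: solves
# lambda / (1 - exp(-lambda)) = mbar
.ztp_rate_from_mean <- function(mbar) {
  if (!is.finite(mbar) || mbar <= 1 + 1e-9) return(1e-6)
  f <- function(l) l / (-expm1(-l)) - mbar
  stats::uniroot(f, c(1e-9, mbar), tol = 1e-10)$root
}

#' Fit the zero-truncated Poisson mixture to a count histogram
#'
#' Models sampled k-mer counts as a mixture of zero-truncated Poisson
#' components: an error component with free rate `lambda_e`, a
#' heterozygous component at rate `lambda / 2`, a homozygous component at
#' rate `lambda`, and repeat components at fixed integer multiples
#' `2 * lambda, ..., (n_components - 2) * lambda` representing extra
#' genomic copies. The mixture weights `w` and `lambda_e` are updated by
#' expectation-maximization; all other rates stay pinned to `lambda`,
#' which is taken from [initialize_lambda()] unless supplied.
#'
#' @param hist A [sample_count_histogram()] result.
#' @param n_components Number of mixture components (default 10: error,
#'   heterozygous, homozygous and seven repeat states).
#' @param max_iter Maximum EM iterations (default 30).
#' @param tol Relative log-likelihood improvement below which iteration
#'   stops.
#' @param lambda Optional homozygous mean count; estimated from the
#'   histogram when `NULL`.
#' @param lambda_e_init Initial error-component rate.
#' @param w_init Initial mixture weights (length `n_components`).
#' @return An object of class `count_mixture` with fields `lambda`,
#'   `lambda_e`, `weights`, `rates`, `loglik_trace`, `k`, `n_obs`.
#' @export
fit_mixture_em <- function(hist, n_components = 10, max_iter = 30,
                           tol = 1e-6, lambda = NULL, lambda_e_init = 1.0,
                           w_init = NULL) {
  if (!nrow(hist)) stop("empty histogram")
  if (n_components < 4) stop("need at least 4 components")
  if (nrow(hist) == 1L)
    warning("degenerate histogram with a single count value")
  if (is.null(lambda)) lambda <- initialize_lambda(hist)
  if (lambda <= 0) stop("lambda must be positive")
  n_rep <- n_components - 3L
  if (is.null(w_init))
    w_init <- c(0.3, 0.1, 0.5, rep(0.1 / n_rep, n_rep))
  stopifnot(length(w_init) == n_components, all(w_init >= 0))
  w <- w_init / sum(w_init)

  cc <- hist$count
  nn <- hist$freq
  ntot <- sum(nn)
  lambda_e <- lambda_e_init
  fixed_rates <- lambda * c(0.5, 1, 1 + seq_len(n_rep))
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    rates <- c(lambda_e, fixed_rates)
    lp <- vapply(rates, function(r) ztp_pmf(cc, r, log = TRUE),
                 numeric(length(cc)))
    lp <- sweep(matrix(lp, nrow = length(cc)), 2L, log(w), "+")
    m <- apply(lp, 1L, max)
    ll_row <- m + log(rowSums(exp(lp - m)))
    trace <- c(trace, sum(nn * ll_row))
    resp <- exp(lp - ll_row)                      # responsibilities
    w_new <- colSums(nn * resp) / ntot
    m0 <- sum(nn * resp[, 1L] * cc) / max(sum(nn * resp[, 1L]), 1e-300)
    lambda_e <- .ztp_rate_from_mean(m0)
    w <- w_new
    if (iter > 1L) {
      prev <- trace[iter - 1L]
      if (abs(trace[iter] - prev) <= tol * abs(prev)) break
    }
  }
  structure(list(lambda = lambda, lambda_e = lambda_e, weights = w,
                 rates = c(lambda_e, fixed_rates),
                 n_components = n_components, loglik_trace = trace,
                 k = attr(hist, "k"), n_obs = ntot),
            class = "count_mixture")
}

#' @export
print.count_mixture <- function(x, ...) {
  cat("count_mixture (k =", x$k, "): lambda =", signif(x$lambda, 4),
      "lambda_e =", signif(x$lambda_e, 4), "\n")
  cat("  weights:", paste(signif(x$weights, 3), collapse = " "), "\n")
  invisible(x)
}

#' Per-count posterior over mixture components
#'
#' @param c Vector of positive counts.
#' @param model A [fit_mixture_em()] result.
#' @return Matrix of responsibilities, one row per count, columns in
#'   component order (error, heterozygous, homozygous, repeats); rows sum
#'   to one.
#' @export
component_posteriors <- function(c, model) {
  lp <- vapply(model$rates, function(r) ztp_pmf(c, r, log = TRUE),
               numeric(length(c)))
  lp <- sweep(matrix(lp, nrow = length(c)), 2L, log(model$weights), "+")
  m <- apply(lp, 1L, max)
  p <- exp(lp - m)
  p / rowSums(p)
}

#' Posterior probability that a k-mer of a given count is homozygous
#'
#' The responsibility of the homozygous component (rate `lambda`) at each
#' count under the fitted mixture.
#'
#' @inheritParams component_posteriors
#' @return Numeric vector of posterior probabilities.
#' @export
posterior_homozygous <- function(c, model) {
  component_posteriors(c, model)[, 3L]
}

#' Estimate genome size from the fitted count model
#'
#' With reads of length `l`, `n` reads contain `n (l - k + 1)` k-mers and
#' a haploid genome of size `G` contains about `G` k-mers, so the mean
#' count of a homozygous k-mer is `lambda = n (l - k + 1) / G`. Error
#' k-mers inflate the k-mer total, so the error-component weight `w0`
#' scales the estimate down:
#' `G = (1 - w0) * n * (l - k + 1) / lambda`.
#'
#' @param model A [fit_mixture_em()] result fitted at the same `k`.
#' @param n_reads Number of reads in the dataset.
#' @param read_len Read length `l` (modal length for mixed-length sets).
#' @param k k value used (default 31).
#' @return An object of class `genome_size_estimate` with field `G`
#'   (bases) and the inputs used.
#' @export
estimate_genome_size <- function(model, n_reads, read_len, k = 31) {
  if (model$lambda <= 0) stop("lambda must be positive")
  w0 <- model$weights[1L]
  G <- (1 - w0) * n_reads * (read_len - k + 1) / model$lambda
  structure(list(G = G, lambda_used = model$lambda, w0_used = w0,
                 k_used = k, n_reads = n_reads, read_len = read_len),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("genome size estimate: %.0f bp (lambda = %.2f, w0 = %.3f, k = %d)\n",
              x$G, x$lambda_used, x$w0_used, x$k_used))
  invisible(x)
}
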