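#' Contig N50
#'
#' The largest length `L` such that pieces of length at least `L` together
#' contain at least half the total length. Returns 0 for empty input.
#'
#' @param lengths Vector of positive lengths.
#' @return Scalar N50.
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4
#' @export
n50 <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  if (!length(lengths)) return(0)
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Estimate the fragment-size distribution by de Bruijn graph walks
#'
#' Samples read pairs and, for each pair (X, Y), walks the k-mer de Bruijn
#' graph greedily from the first k-mer of X, always taking the
#' highest-coverage strand-validated suffix neighbor, until the first
#' k-mer of the reverse complement of Y is reached (forward/reverse mate
#' orientation; set `orientation = "ff"` for forward/forward libraries),
#' a dead end occurs, or `max_steps` extensions have been made. A
#' complete walk yields the fragment length in nucleotides: the distance
#' from X's start to Y's anchor plus the length of Y. At low coverage the
#' estimate is biased toward shorter fragments, since long walks are more
#' likely to be broken by coverage gaps.
#'
#' @param index A `kmer_index` (see [build_kmer_index()]) over a paired [read_set] with `k` indexed.
#' @param n_pairs Number of read pairs to sample (default 100000; capped
#'   at the available pairs).
#' @param k Walk k-mer size (default 51).
#' @param max_steps Maximum walk extensions per pair (default 1500).
#' @param orientation Mate orientation: `"fr"` (forward/reverse, default)
#'   or `"ff"` (forward/forward).
#' @return An object of class `fragment_sizes`: a list with `sizes`
#'   (inferred fragment lengths, bp), `n_attempted`, `n_resolved`.
#' @export
estimate_fragment_sizes <- function(index, n_pairs = 100000, k = 51,
                                    max_steps = 1500,
                                    orientation = c("fr", "ff")) {
  orientation <- match.arg(orientation)
  if (!index$reads$paired) stop("fragment-size estimation needs paired reads")
  if (!k %in% index$k_values) stop("k = ", k, " is not indexed")
  total_pairs <- index$n_reads %/% 2L
  n <- min(n_pairs, total_pairs)
  pair <- if (n == total_pairs) seq_len(total_pairs)
          else sample.int(total_pairs, n)
  x <- index$reads$seq[2L * pair - 1L]
  y <- index$reads$seq[2L * pair]
  ok <- nchar(x) >= k & nchar(y) >= k
  x <- x[ok]; y <- y[ok]
  starts <- substr(x, 1L, k)
  y_orient <- if (orientation == "fr") .rc_cpp(y) else y
  targets <- substr(y_orient, 1L, k)
  valid <- !grepl("[^ACGT]", starts) & !grepl("[^ACGT]", targets)
  steps <- rep(-1L, length(starts))
  if (any(valid))
    steps[valid] <- .idx_walk_fragments(index$ptr, starts[valid],
                                        targets[valid],
                                        as.integer(max_steps))
  resolved <- steps >= 0L
  sizes <- steps[resolved] + nchar(y)[resolved]
  structure(list(sizes = sizes, n_attempted = n,
                 n_resolved = sum(resolved), k = k),
            class = "fragment_sizes")
}

#' @export
print.fragment_sizes <- function(x, ...) {
  cat(sprintf("fragment_sizes: %d/%d pairs resolved; mean %.1f bp, sd %.1f bp\n",
              x$n_resolved, x$n_attempted, mean(x$sizes), stats::sd(x$sizes)))
  invisible(x)
}

#' Simulate de Bruijn assembly and the N50 versus k relationship
#'
#' Mimics an assembler able to resolve error and variant branches but not
#' repeats. For each k: a transient index and count mixture are built,
#' then up to `n_walks` walks are started from the first k-mers of
#' randomly sampled reads whose posterior probability of being homozygous
#' is at least 0.5. Each walk extends in both directions along the
#' highest-coverage strand-validated neighbor, continuing through
#' branches soft-classified as errors or variants and stopping at dead
#' ends, repeat branches, k-mers already visited within the walk, or
#' `max_len` visited k-mers. Visited k-mers are recorded in a Bloom
#' filter and starting k-mers already present are skipped, so walks do
#' not re-trace each other. Contig lengths are the number of k-mers
#' visited.
#'
#' @param reads A [read_set].
#' @param k_values k grid (default 21 to 91 in steps of 5).
#' @param n_walks Walks per k (default 20000).
#' @param max_len Maximum k-mers per walk (default 50000).
#' @param n_hist_reads Reads sampled per k for the count histogram.
#' @param start_threshold Minimum homozygous posterior for a starting
#'   k-mer (default 0.5).
#' @param ... Overrides passed to [classifier_params()].
#' @return A list with `summary` (data frame of `k`, `lambda`, `n_walks`,
#'   `n50`, `total_kmers`) and `lengths` (list of per-k walk lengths).
#' @export
simulate_assembly <- function(reads, k_values = seq(21, 91, by = 5),
                              n_walks = 20000, max_len = 50000,
                              n_hist_reads = 50000, start_threshold = 0.5,
                              ...) {
  stopifnot(inherits(reads, "read_set"))
  lengths <- list()
  rows <- list()
  for (k in k_values) {
    idx <- build_kmer_index(reads, k, with_k_plus_1 = TRUE)
    hist <- sample_count_histogram(idx, k, n_hist_reads)
    model <- fit_mixture_em(hist)
    params <- classifier_params(model, read_len = idx$modal_read_length,
                                k = k, ...)
    cap <- attr(hist, "cap")
    post_hom <- posterior_homozygous(seq_len(cap), model)
    n_starts <- min(idx$n_reads, n_walks * 5L)
    ids <- if (n_starts == idx$n_reads) sample(seq_len(idx$n_reads))
           else sample.int(idx$n_reads, n_starts)
    starts <- substr(idx$reads$seq[ids], 1L, k)
    # Bloom filter sized for the expected genomic k-mer load at ~16
    # bits per element (false-positive rate well under 1%)
    bloom_bits <- max(2^20, 16 * min(n_walks * max_len,
                                     sum(nchar(reads$seq))))
    wl <- .idx_walk_assembly(idx$ptr, as.integer(k), starts, post_hom,
                             start_threshold, .cls_par_list(params),
                             as.integer(n_walks), as.integer(max_len),
                             bloom_bits)
    lengths[[as.character(k)]] <- wl
    rows[[as.character(k)]] <- data.frame(
      k = k, lambda = model$lambda, n_walks = length(wl),
      n50 = n50(wl), total_kmers = sum(wl))
    rm(idx); gc(FALSE)
  }
  list(summary = do.call(rbind, rows), lengths = lengths)
}
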