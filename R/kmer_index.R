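#' Build a k-mer counting index over a read set
#'
#' Constructs exact strand-aware occurrence tables for each requested k,
#' together with an in-memory read store. The index answers the query
#' contract used throughout the package: substring counts on the observed
#' strand, combined forward + reverse-complement counts, random read
#' extraction, and implicit de Bruijn graph neighbor queries. K-mers
#' containing `N` are skipped during counting.
#'
#' Branch observations need (k+1)-mer counts alongside each k; pass
#' `with_k_plus_1 = TRUE` (the default) to index them automatically.
#'
#' @param reads A [read_set].
#' @param k_values Integer vector of k values to index.
#' @param with_k_plus_1 Also index k+1 for every requested k.
#' @param seed_len If positive, additionally record per-read positions of
#'   all `seed_len`-mers to support overlap candidate lookup
#'   ([overlap_candidates()]).
#' @return An object of class `kmer_index`.
#' @examples
#' rs <- read_set("r1", "ACGTA", "IIIII")
#' idx <- build_kmer_index(rs, k_values = 5, with_k_plus_1 = FALSE)
#' kmer_count(idx, "ACGTA")
#' @export
build_kmer_index <- function(reads, k_values, with_k_plus_1 = TRUE,
                             seed_len = 0) {
  stopifnot(inherits(reads, "read_set"))
  k_values <- sort(unique(as.integer(k_values)))
  if (!length(k_values)) stop("k_values must be non-empty")
  if (any(k_values < 1)) stop("k values must be positive")
  ml <- modal_read_length(reads)
  if (min(k_values) > max(nchar(reads$seq)))
    stop("k = ", min(k_values), " is larger than every read")
  all_k <- k_values
  if (with_k_plus_1) all_k <- sort(unique(c(k_values, k_values + 1L)))
  ptr <- .idx_build(reads$seq, all_k, as.integer(seed_len))
  structure(list(ptr = ptr, reads = reads, k_values = all_k,
                 base_k = k_values, seed_len = as.integer(seed_len),
                 n_reads = n_reads(reads), modal_read_length = ml),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index:", x$n_reads, "reads | k =",
      paste(x$k_values, collapse = ", "),
      if (x$seed_len > 0) paste0("| seed postings (", x$seed_len, "-mers)"),
      "\n")
  invisible(x)
}

.check_kmers <- function(index, p) {
  p <- as.character(p)
  if (any(!nzchar(p))) stop("empty pattern")
  len <- nchar(p)
  if (any(!len %in% index$k_values))
    stop("pattern length ", len[which(!len %in% index$k_values)[1]],
         " is not indexed; available k: ",
         paste(index$k_values, collapse = ", "))
  p
}

#' Count k-mer occurrences on the observed strand
#'
#' Exact number of times each pattern occurs in the reads as written
#' (no reverse-complement folding). Pattern lengths must match an indexed
#' k. Vectorized over `p`.
#'
#' @param index A [build_kmer_index()] result.
#' @param p Character vector of k-mers.
#' @return Integer vector of counts.
#' @export
kmer_count <- function(index, p) {
  .idx_count(index$ptr, .check_kmers(index, p))
}

#' Count k-mer occurrences on both strands
#'
#' Returns `kmer_count(P) + kmer_count(reverse_complement(P))` for each
#' pattern; for reverse-complement palindromes both terms refer to the same
#' string and the count is doubled accordingly.
#'
#' @inheritParams kmer_count
#' @return Integer vector of combined counts.
#' @export
kmer_count_rc <- function(index, p) {
  .idx_count_rc(index$ptr, .check_kmers(index, p))
}

#' Extract a read from the index by position
#'
#' @param index A `kmer_index` (see [build_kmer_index()]).
#' @param i 1-based read index.
#' @return A list with `id`, `seq` and `qual` of the i-th input read.
#' @export
extract_read <- function(index, i) {
  if (i < 1 || i > index$n_reads)
    stop("read index out of range [1, ", index$n_reads, "]")
  list(id = index$reads$id[i], seq = index$reads$seq[i],
       qual = index$reads$qual[i])
}

#' Sample read indices uniformly at random
#'
#' Uniform sampling with replacement over the stored reads, driven by R's
#' global random number generator (use `set.seed()` for determinism).
#'
#' @param index A `kmer_index` (see [build_kmer_index()]).
#' @param n Number of reads to sample.
#' @return Integer vector of 1-based read indices.
#' @export
sample_read_ids <- function(index, n) {
  sample.int(index$n_reads, n, replace = TRUE)
}

#' Enumerate de Bruijn neighbors of a k-mer
#'
#' Suffix neighbors of `X = aZ` are the k-mers `Zb` for `b` in A, C, G, T
#' with nonzero combined count; prefix neighbors are defined symmetrically.
#' A neighbor is strand-validated when it was seen at least once on each
#' sequencing strand separately, the condition required for a valid graph
#' edge. Neighbors are reported in fixed base order A < C < G < T.
#'
#' @param index A `kmer_index` (see [build_kmer_index()]).
#' @param x A single k-mer at an indexed length.
#' @param side `"suffix"` or `"prefix"`.
#' @return A data frame with columns `kmer`, `count_rc`,
#'   `strand_validated`.
#' @export
kmer_neighbors <- function(index, x, side = c("suffix", "prefix")) {
  side <- match.arg(side)
  x <- .check_kmers(index, x)
  stopifnot(length(x) == 1L)
  res <- .idx_neighbors(index$ptr, x, side == "suffix")
  data.frame(kmer = as.character(res$kmer),
             count_rc = as.integer(res$count_rc),
             strand_validated = as.logical(res$strand_validated),
             stringsAsFactors = FALSE)
}

#' Test whether a k-mer is a suffix branch
#'
#' A vertex is a suffix branch when it has at least two strand-validated
#' suffix neighbors.
#'
#' @inheritParams kmer_neighbors
#' @return Logical scalar.
#' @export
is_suffix_branch <- function(index, x) {
  nb <- kmer_neighbors(index, x, "suffix")
  sum(nb$strand_validated) >= 2L
}
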