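#' Candidate overlapping reads for a read
#'
#' The union, over the read's seed-length k-mers on both strands, of reads
#' containing them, excluding the read itself and skipping seeds whose
#' combined occurrence count exceeds `max_seed_count` (repetitive seeds).
#' For each candidate the diagonal implied by the first shared seed is
#' reported: `offset` is the start position of the (oriented) candidate in
#' the query read's frame, and `rc` whether the candidate aligns as its
#' reverse complement.
#'
#' @param index A `kmer_index` (see [build_kmer_index()]) built with `seed_len > 0`.
#' @param i 1-based index of the query read.
#' @param max_seed_count Seeds seen more than this many times contribute
#'   no candidates (default 200).
#' @return A data frame with columns `read`, `offset`, `rc`.
#' @export
overlap_candidates <- function(index, i, max_seed_count = 200) {
  if (index$seed_len <= 0)
    stop("index was built without seed postings; set seed_len when building")
  res <- .idx_seed_candidates(index$ptr, as.integer(i) - 1L,
                              as.integer(max_seed_count))
  data.frame(read = as.integer(res$read), offset = as.integer(res$offset),
             rc = as.logical(res$rc))
}

#' Ungapped overlap between two reads at a fixed diagonal
#'
#' Aligns `s` (already oriented) against `r` with `s` starting at `offset`
#' in `r`'s frame and compares the overlapping interval base by base.
#' Returns `NULL` unless the overlap is at least `min_len` bases with
#' identity at least `min_identity`.
#'
#' @param r Query read sequence.
#' @param s Candidate read sequence, oriented to `r`'s strand.
#' @param offset Start of `s` in `r`'s coordinate frame (may be negative).
#' @param min_len Minimum overlap length (default 50).
#' @param min_identity Minimum fraction of matching bases (default 0.95).
#' @return `NULL`, or a list with `start`, `end` (1-based interval on
#'   `r`), `identity` and `mismatch_pos` (positions on `r`).
#' @export
compute_overlap <- function(r, s, offset, min_len = 50,
                            min_identity = 0.95) {
  lr <- nchar(r); ls <- nchar(s)
  start <- max(1L, offset + 1L)
  end <- min(lr, offset + ls)
  len <- end - start + 1L
  if (len < min_len) return(NULL)
  a <- charToRaw(substr(r, start, end))
  b <- charToRaw(substr(s, start - offset, end - offset))
  mism <- which(a != b)
  identity <- 1 - length(mism) / len
  if (identity < min_identity) return(NULL)
  list(start = start, end = end, identity = identity,
       mismatch_pos = start + mism - 1L)
}

#' Per-position sequencing error rate from overlap consensus
#'
#' For each of `n_sample_reads` sampled reads, gathers overlapping reads
#' (seeded by exact seed-length matches, aligned ungapped at the seed
#' diagonal, kept when at least `min_len` bases overlap at
#' `min_identity`), stacks them in the query read's coordinate frame and
#' takes a per-column majority consensus (ties resolved toward the query
#' read's own base). A query base is counted as an error when it differs
#' from the consensus, the consensus is supported by at least 3 reads and
#' the query's base by fewer than 4. Columns covered by fewer than 4
#' reads are not assessed and do not enter the denominator.
#'
#' @param index A `kmer_index` (see [build_kmer_index()]) built with `seed_len > 0`.
#' @param n_sample_reads Number of reads to sample (default 100000;
#'   capped at the available reads).
#' @param max_seed_count,min_len,min_identity Overlap thresholds, see
#'   [overlap_candidates()] and [compute_overlap()].
#' @return An object of class `error_profile`: a data frame with one row
#'   per read position (`pos`, 1-based), `errors`, `assessed`, `rate`.
#' @export
per_base_error_rate <- function(index, n_sample_reads = 100000,
                                max_seed_count = 200, min_len = 50,
                                min_identity = 0.95) {
  if (index$seed_len <= 0)
    stop("index was built without seed postings; set seed_len when building")
  L <- index$modal_read_length
  n_scan <- min(n_sample_reads, index$n_reads)
  ids <- if (n_scan == index$n_reads) seq_len(index$n_reads)
         else sample.int(index$n_reads, n_scan)
  err <- numeric(L); tot <- numeric(L)
  base_codes <- charToRaw("ACGT")
  seqs <- index$reads$seq
  for (i in ids) {
    r <- seqs[i]
    lr <- nchar(r)
    if (lr > L) next
    cand <- overlap_candidates(index, i, max_seed_count)
    if (!nrow(cand)) next
    counts <- matrix(0L, nrow = 4L, ncol = lr)
    r_raw <- charToRaw(r)
    r_code <- match(as.integer(r_raw), as.integer(base_codes))
    okpos <- !is.na(r_code)
    counts[cbind(r_code[okpos], which(okpos))] <- 1L
    n_over <- 0L
    for (j in seq_len(nrow(cand))) {
      s <- seqs[cand$read[j]]
      if (cand$rc[j]) s <- .rc_cpp(s)
      ov <- compute_overlap(r, s, cand$offset[j], min_len, min_identity)
      if (is.null(ov)) next
      n_over <- n_over + 1L
      ss <- charToRaw(substr(s, ov$start - cand$offset[j],
                             ov$end - cand$offset[j]))
      s_code <- match(as.integer(ss), as.integer(base_codes))
      pos <- ov$start:ov$end
      keep <- !is.na(s_code)
      if (any(keep)) {
        ii <- (pos[keep] - 1L) * 4L + s_code[keep]
        counts <- counts + matrix(tabulate(ii, nbins = 4L * lr),
                                  nrow = 4L)
      }
    }
    if (n_over == 0L) next
    depth <- colSums(counts)
    assessed <- depth >= 4L & okpos
    if (!any(assessed)) next
    cmax <- apply(counts, 2L, max)
    own <- counts[cbind(r_code[okpos], which(okpos))]
    # consensus support; tie resolved toward the read's own base
    own_full <- integer(lr); own_full[okpos] <- own
    is_cons <- own_full == cmax
    cons_support <- cmax
    is_err <- assessed & !is_cons & cons_support >= 3L & own_full < 4L
    tot[which(assessed)] <- tot[which(assessed)] + 1
    err[which(is_err)] <- err[which(is_err)] + 1
  }
  rate <- ifelse(tot > 0, err / tot, NA_real_)
  structure(data.frame(pos = seq_len(L), errors = err, assessed = tot,
                       rate = rate),
            n_sampled_reads = n_scan,
            class = c("error_profile", "data.frame"))
}

#' Quality score distribution by read position
#'
#' Decodes Phred+33 qualities of sampled reads and summarizes each read
#' position by its mean and deciles.
#'
#' @param reads A [read_set].
#' @param n_sample_reads Number of reads to sample (capped at the
#'   available reads).
#' @return A data frame with `pos`, `mean` and decile columns `q10` ...
#'   `q90`.
#' @export
quality_by_position <- function(reads, n_sample_reads = 50000) {
  n <- min(n_sample_reads, n_reads(reads))
  ids <- if (n == n_reads(reads)) seq_len(n)
         else sample.int(n_reads(reads), n)
  L <- modal_read_length(reads)
  qm <- matrix(NA_real_, nrow = length(ids), ncol = L)
  for (r in seq_along(ids)) {
    q <- utf8ToInt(reads$qual[ids[r]]) - 33L
    qm[r, seq_len(min(length(q), L))] <- q[seq_len(min(length(q), L))]
  }
  dec <- t(apply(qm, 2L, stats::quantile, probs = seq(0.1, 0.9, by = 0.1),
                 na.rm = TRUE, names = FALSE))
  out <- data.frame(pos = seq_len(L), mean = colMeans(qm, na.rm = TRUE))
  colnames(dec) <- paste0("q", seq(10, 90, by = 10))
  cbind(out, as.data.frame(dec))
}

#' Fixed-k k-mer count histogram for coverage assessment
#'
#' The sampled count spectrum at a fixed k (by default 51), reported
#' separately from the modelling histogram for plotting.
#'
#' @param index A `kmer_index` (see [build_kmer_index()]) with `k` indexed.
#' @param k Fixed k (default 51).
#' @param n_sample_reads Reads to sample.
#' @return A `count_histogram`, see [sample_count_histogram()].
#' @export
kmer_count_histogram <- function(index, k = 51, n_sample_reads = 50000) {
  sample_count_histogram(index, k, n_sample_reads)
}

#' Two-dimensional GC-content by k-mer count histogram
#'
#' Samples k-mer instances from random reads and bins the pairs
#' (GC fraction of the k-mer, combined-strand count) into a 2-D
#' histogram. Under GC-unbiased coverage the count distribution within
#' each GC column is the same.
#'
#' @param index A `kmer_index` (see [build_kmer_index()]).
#' @param k Indexed k (default 51).
#' @param n_samples Number of k-mer instances to sample.
#' @param gc_bins Number of left-closed GC bins over \[0, 1\].
#' @param count_cap Counts above this value are binned at the cap.
#' @return An object of class `gc_coverage_histogram`: a list with the
#'   count matrix `counts` (rows = GC bins, columns = count bins) and the
#'   bin edge vectors `gc_breaks`, `count_bins`.
#' @export
gc_coverage_histogram <- function(index, k = 51, n_samples = 100000,
                                  gc_bins = 20, count_cap = 200) {
  k <- as.integer(k)
  if (!k %in% index$k_values) stop("k = ", k, " is not indexed")
  lens <- nchar(index$reads$seq)
  elig <- which(lens >= k)
  if (!length(elig)) stop("no reads of length >= k")
  ids <- elig[sample.int(length(elig), n_samples, replace = TRUE)]
  pos <- floor(stats::runif(n_samples) * (lens[ids] - k + 1)) + 1L
  kmers <- substr(index$reads$seq[ids], pos, pos + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  kmers <- kmers[ok]
  gc <- (nchar(kmers) - nchar(gsub("[GC]", "", kmers))) / k
  counts <- pmin(kmer_count_rc(index, kmers), count_cap)
  gc_bin <- pmin(floor(gc * gc_bins) + 1L, gc_bins)
  m <- matrix(0, nrow = gc_bins, ncol = count_cap)
  tab <- table(factor(gc_bin, levels = seq_len(gc_bins)),
               factor(counts, levels = seq_len(count_cap)))
  m[] <- as.numeric(tab)
  structure(list(counts = m,
                 gc_breaks = seq(0, 1, length.out = gc_bins + 1L),
                 count_bins = seq_len(count_cap), k = k,
                 n_sampled = length(kmers)),
            class = "gc_coverage_histogram")
}
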