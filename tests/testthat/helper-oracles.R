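# Independent brute-force oracles used to validate the index, the walks and
# the reference-graph enumeration. Everything here is deliberately naive
# (dictionary scans, cumulative sums) and shares no code with the package
# internals it checks.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

naive_rc <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

# all k-length substrings of a set of sequences (with duplicates),
# k-mers containing non-ACGT dropped
naive_kmers <- function(seqs, k) {
  out <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    substring(s, 1:(L - k + 1), k:L)
  }))
  out[!grepl("[^ACGT]", out)]
}

naive_count <- function(seqs, p) {
  sum(naive_kmers(seqs, nchar(p)) == p)
}

naive_count_rc <- function(seqs, p) {
  naive_count(seqs, p) + naive_count(seqs, naive_rc(p))
}

naive_n50 <- function(lengths) {
  if (!length(lengths)) return(0)
  total <- sum(lengths)
  # enumerate candidate lengths from largest down; the largest L for which
  # pieces >= L still cover half the total is the N50
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  0
}

# exhaustive reference-graph branch enumeration mirroring the documented
# definition: homozygous vertices (multiplicity one per haplotype), suffix
# branches in both orientations, variant iff exactly two haplotype-specific
# genome-unique neighbors
naive_ref_branch_rates <- function(hap_a, hap_b, k) {
  canon <- function(x) pmin(x, naive_rc(x))
  ka <- naive_kmers(hap_a, k)
  kb <- naive_kmers(hap_b, k)
  ta <- table(canon(ka))
  tb <- table(canon(kb))
  all_k <- union(names(ta), names(tb))
  ma <- ifelse(all_k %in% names(ta), as.integer(ta[all_k]), 0L)
  mb <- ifelse(all_k %in% names(tb), as.integer(tb[all_k]), 0L)
  names(ma) <- names(mb) <- all_k
  hom <- all_k[ma == 1L & mb == 1L]
  n_var <- 0L; n_rep <- 0L
  lookup <- function(x) {
    cx <- canon(x)
    cbind(ifelse(cx %in% names(ma), ma[cx], 0L),
          ifelse(cx %in% names(mb), mb[cx], 0L))
  }
  for (v in hom) {
    for (x in c(v, naive_rc(v))) {
      nbs <- paste0(substr(x, 2, k), c("A", "C", "G", "T"))
      m <- lookup(nbs)
      present <- rowSums(m) > 0
      if (sum(present) < 2) next
      mm <- m[present, , drop = FALSE]
      variant <- nrow(mm) == 2 &&
        ((mm[1, 1] == 1 && mm[1, 2] == 0 && mm[2, 1] == 0 && mm[2, 2] == 1) ||
         (mm[1, 1] == 0 && mm[1, 2] == 1 && mm[2, 1] == 1 && mm[2, 2] == 0))
      if (variant) n_var <- n_var + 1L else n_rep <- n_rep + 1L
    }
  }
  list(variant_rate = n_var / (2 * length(hom)),
       repeat_rate = n_rep / (2 * length(hom)),
       N_h = 2 * length(hom))
}

# read set providing deep both-strand coverage of the given sequences:
# each sequence and its reverse complement, `depth` times each
deep_read_set <- function(seqs, depth = 5) {
  all <- rep(c(seqs, naive_rc(seqs)), each = depth)
  read_set(paste0("r", seq_along(all)), all, strrep("I", nchar(all)))
}

# draw n counts from a zero-truncated Poisson by rejection
rztp <- function(n, rate) {
  rate <- rep_len(rate, n)
  out <- stats::rpois(n, rate)
  while (any(out == 0)) {
    zero <- out == 0
    out[zero] <- stats::rpois(sum(zero), rate[zero])
  }
  out
}

hist_from_counts <- function(counts, k = 31) {
  tab <- table(counts)
  structure(data.frame(count = as.integer(names(tab)),
                       freq = as.integer(tab)),
            k = k, cap = max(counts), n_sampled_reads = NA_integer_,
            class = c("count_histogram", "data.frame"))
}
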