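#' Simulate a diploid genome with heterozygous sites and repeat families
#'
#' Generates a random haplotype A, optionally plants identical repeat
#' copies, then derives haplotype B by applying heterozygous substitutions
#' drawn independently per base with probability `het_rate`. The true site
#' list and repeat placements are returned so downstream estimates can be
#' validated against a known genome.
#'
#' @param length_bp Genome (haploid) length in bases.
#' @param het_rate Per-base probability of a heterozygous substitution;
#'   must be below 0.1.
#' @param repeat_spec Optional data frame (or list of vectors) with
#'   columns `unit_length`, `copy_count`, `family_count` and optionally
#'   `divergence`: for each row, `family_count` distinct random units of
#'   `unit_length` bases are each planted `copy_count` times at random
#'   non-overlapping positions. With `divergence > 0` each planted copy
#'   is independently mutated at that per-base substitution rate before
#'   planting, emulating diverged repeat families; identical copies
#'   (`divergence = 0`, the default) produce no repeat branches at
#'   genome-unique k-mers because every multi-way junction then lies
#'   inside the repeat itself.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An object of class `diploid_genome` with fields `hap_a`,
#'   `hap_b` (strings), `truth` (data frame of `pos`, `ref`, `alt`) and
#'   `repeat_annotation` (data frame of `start`, `length`, `family`).
#' @examples
#' g <- simulate_diploid_genome(1000, het_rate = 0.001, seed = 1)
#' nrow(g$truth)
#' @export
simulate_diploid_genome <- function(length_bp, het_rate = 0,
                                    repeat_spec = NULL, seed = 1) {
  if (length_bp <= 0) stop("length_bp must be positive")
  if (het_rate < 0 || het_rate >= 0.1)
    stop("het_rate must be in [0, 0.1)")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  hap <- sample(bases, length_bp, replace = TRUE)

  rep_ann <- data.frame(start = integer(), length = integer(),
                        family = integer())
  if (!is.null(repeat_spec)) {
    if (!is.data.frame(repeat_spec))
      repeat_spec <- as.data.frame(do.call(rbind, repeat_spec))
    names(repeat_spec) <- c("unit_length", "copy_count", "family_count",
                            "divergence")[seq_len(ncol(repeat_spec))]
    if (is.null(repeat_spec$divergence)) repeat_spec$divergence <- 0
    total <- sum(repeat_spec$unit_length * repeat_spec$copy_count *
                   repeat_spec$family_count)
    if (total > length_bp)
      stop("repeat content (", total, " bp) exceeds the genome length")
    occupied <- logical(length_bp)
    fam <- 0L
    for (r in seq_len(nrow(repeat_spec))) {
      ul <- repeat_spec$unit_length[r]
      for (f in seq_len(repeat_spec$family_count[r])) {
        fam <- fam + 1L
        unit <- sample(bases, ul, replace = TRUE)
        div <- repeat_spec$divergence[r]
        for (cp in seq_len(repeat_spec$copy_count[r])) {
          copy <- unit
          if (div > 0) {
            mut <- which(stats::runif(ul) < div)
            if (length(mut))
              copy[mut] <- vapply(copy[mut],
                                  function(b) sample(setdiff(bases, b), 1L),
                                  "")
          }
          placed <- FALSE
          for (try in 1:1000) {
            s <- sample.int(length_bp - ul + 1L, 1L)
            if (!any(occupied[s:(s + ul - 1L)])) {
              hap[s:(s + ul - 1L)] <- copy
              occupied[s:(s + ul - 1L)] <- TRUE
              rep_ann <- rbind(rep_ann, data.frame(start = s, length = ul,
                                                   family = fam))
              placed <- TRUE
              break
            }
          }
          if (!placed)
            stop("could not place repeat copies without overlap; ",
                 "reduce repeat content")
        }
      }
    }
  }

  pos <- which(stats::runif(length_bp) < het_rate)
  ref <- hap[pos]
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  hap_b <- hap
  if (length(pos)) hap_b[pos] <- alt
  structure(list(
    hap_a = paste(hap, collapse = ""),
    hap_b = paste(hap_b, collapse = ""),
    truth = data.frame(pos = pos, ref = ref, alt = unname(alt),
                       stringsAsFactors = FALSE),
    repeat_annotation = rep_ann
  ), class = "diploid_genome")
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat("diploid_genome:", nchar(x$hap_a), "bp,", nrow(x$truth),
      "heterozygous sites,", nrow(x$repeat_annotation), "repeat copies\n")
  invisible(x)
}

#' Simulate sequencing reads from a diploid genome
#'
#' Draws fragments uniformly from a randomly chosen haplotype and emits
#' single-end reads or forward/reverse-complement mate pairs. Substitution
#' errors are applied independently per position with the supplied
#' position-specific probabilities. Qualities are constant Q30. Total
#' sequenced bases approximate `coverage` times the haploid length.
#'
#' @param genome A [simulate_diploid_genome()] result, or a single DNA
#'   string for a haploid genome.
#' @param coverage Fold sequence coverage (haploid).
#' @param read_len Read length in bases.
#' @param error_rate_by_pos Per-position substitution error probability;
#'   a single value is recycled across the read.
#' @param fragment_mean,fragment_sd Fragment (insert) size distribution in
#'   bp; used when `paired = TRUE`.
#' @param paired Logical; emit interleaved mate pairs.
#' @param seed Integer seed.
#' @return A [read_set]. The true fragment start, haplotype and length of
#'   each fragment are attached as the `"truth"` attribute.
#' @export
simulate_reads <- function(genome, coverage, read_len = 100,
                           error_rate_by_pos = 0, fragment_mean = 300,
                           fragment_sd = 30, paired = FALSE, seed = 1) {
  if (coverage <= 0) stop("coverage must be positive")
  haps <- if (inherits(genome, "diploid_genome"))
    c(genome$hap_a, genome$hap_b) else c(genome, genome)
  G <- nchar(haps[1])
  if (read_len > G) stop("read_len exceeds the genome length")
  if (paired && fragment_mean < read_len)
    stop("fragment_mean must be at least read_len for paired reads")
  err <- rep_len(error_rate_by_pos, read_len)
  set.seed(seed)

  if (paired) {
    n_frag <- max(1L, round(coverage * G / (2 * read_len)))
    flen <- round(stats::rnorm(n_frag, fragment_mean, fragment_sd))
    flen <- pmin(pmax(flen, read_len), G)
    hap_of <- sample.int(2L, n_frag, replace = TRUE)
    start <- floor(stats::runif(n_frag) * (G - flen + 1)) + 1L
    fwd <- substring(haps[hap_of], start, start + read_len - 1L)
    rev <- .rc_cpp(substring(haps[hap_of], start + flen - read_len,
                             start + flen - 1L))
    seqs <- as.vector(rbind(fwd, rev))
    ids <- as.vector(rbind(paste0("sim_", seq_len(n_frag), "/1"),
                           paste0("sim_", seq_len(n_frag), "/2")))
  } else {
    n_frag <- max(1L, round(coverage * G / read_len))
    flen <- rep(read_len, n_frag)
    hap_of <- sample.int(2L, n_frag, replace = TRUE)
    start <- floor(stats::runif(n_frag) * (G - read_len + 1)) + 1L
    seqs <- substring(haps[hap_of], start, start + read_len - 1L)
    # fragments are sequenced from a random strand
    flip <- stats::runif(n_frag) < 0.5
    seqs[flip] <- .rc_cpp(seqs[flip])
    ids <- paste0("sim_", seq_len(n_frag))
  }

  # apply position-specific substitution errors, one position at a time
  bases <- c("A", "C", "G", "T")
  n_seq <- length(seqs)
  for (j in seq_len(read_len)) {
    if (err[j] <= 0) next
    hit <- which(stats::runif(n_seq) < err[j])
    if (!length(hit)) next
    orig <- substr(seqs[hit], j, j)
    # substitute with one of the three other bases, uniformly
    shift <- sample.int(3L, length(hit), replace = TRUE)
    new <- bases[(match(orig, bases) - 1L + shift) %% 4L + 1L]
    substr(seqs[hit], j, j) <- new
  }

  qual <- strrep(rawToChar(as.raw(30L + 33L)), nchar(seqs))
  rs <- read_set(ids, seqs, qual, paired = paired)
  truth <- data.frame(start = start, hap = hap_of, fragment_length = flen)
  if (!paired) truth$strand <- ifelse(flip, "-", "+")
  attr(rs, "truth") <- truth
  rs
}
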