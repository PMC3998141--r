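#' Construct a read set
#'
#' A `read_set` is the package's container for a collection of sequencing
#' reads: parallel character vectors of identifiers, DNA sequences (over
#' `A`, `C`, `G`, `T`, `N`) and Phred+33 quality strings. When `paired` is
#' `TRUE`, reads `2i - 1` and `2i` (1-based) are mates.
#'
#' @param id Character vector of read identifiers.
#' @param seq Character vector of DNA sequences.
#' @param qual Character vector of quality strings, same lengths as `seq`.
#' @param paired Logical; whether reads are interleaved mate pairs.
#' @return An object of class `read_set`.
#' @examples
#' rs <- read_set("r1", "ACGT", "IIII")
#' n_reads(rs)
#' @export
read_set <- function(id, seq, qual, paired = FALSE) {
  id <- as.character(id); seq <- as.character(seq); qual <- as.character(qual)
  if (length(seq) != length(id) || length(qual) != length(id))
    stop("id, seq and qual must have the same length")
  if (any(!nzchar(seq))) stop("empty read sequence")
  bad <- which(nchar(qual) != nchar(seq))
  if (length(bad))
    stop("sequence/quality length mismatch at read ", bad[1])
  if (any(grepl("[^ACGTN]", seq)))
    stop("read sequences may only contain A, C, G, T, N")
  if (paired && length(seq) %% 2L != 0L)
    stop("a paired read set must contain an even number of reads")
  structure(list(id = id, seq = seq, qual = qual, paired = paired),
            class = "read_set")
}

#' Number of reads in a read set
#' @param reads A [read_set].
#' @return Integer count of reads.
#' @export
n_reads <- function(reads) length(reads$seq)

#' Modal read length of a read set
#'
#' Several metrics assume a common read length `l`; read sets with
#' heterogeneous lengths use the most frequent length.
#' @param reads A [read_set].
#' @return Integer modal length.
#' @export
modal_read_length <- function(reads) {
  tab <- table(nchar(reads$seq))
  as.integer(names(tab)[which.max(tab)])
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", n_reads(x), "reads,",
      if (x$paired) "paired" else "unpaired",
      "| modal length", modal_read_length(x), "\n")
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' Vectorized over the input; `N` maps to `N`. Characters outside
#' `A`, `C`, `G`, `T`, `N` are rejected.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGTA")  # "TACGT"
#' @export
reverse_complement <- function(x) {
  if (any(grepl("[^ACGTN]", x)))
    stop("non-IUPAC character in sequence; only A, C, G, T, N are accepted")
  .rc_cpp(as.character(x))
}

#' Read a FASTQ file into a read set
#'
#' Reads 4-line FASTQ records (Phred+33), transparently decompressing
#' gzipped files. Two files may be given for paired-end data stored as
#' separate mate files; records are interleaved in mate order. A single
#' file with `paired = TRUE` is treated as interleaved.
#'
#' Malformed input (record count not a multiple of four, missing `@`/`+`
#' markers, sequence/quality length disagreement) raises an error naming
#' the offending record.
#'
#' @param path Path to a FASTQ file, optionally gzipped.
#' @param path2 Optional second FASTQ file with mate-2 reads.
#' @param paired Logical; mark the result as paired. Implied by `path2`.
#' @return A [read_set].
#' @export
read_fastq <- function(path, path2 = NULL, paired = !is.null(path2)) {
  parse_one <- function(p) {
    con <- gzfile(p, "r")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    n <- length(lines)
    if (n %% 4L != 0L)
      stop("truncated FASTQ record ", n %/% 4L + 1L, " in ", p)
    if (n == 0L) return(list(id = character(), seq = character(),
                             qual = character()))
    hd <- lines[seq(1L, n, by = 4L)]
    sq <- lines[seq(2L, n, by = 4L)]
    pl <- lines[seq(3L, n, by = 4L)]
    ql <- lines[seq(4L, n, by = 4L)]
    bad <- which(substr(hd, 1L, 1L) != "@" | substr(pl, 1L, 1L) != "+")
    if (length(bad))
      stop("malformed FASTQ record ", bad[1], " in ", p)
    bad <- which(nchar(sq) != nchar(ql))
    if (length(bad))
      stop("sequence/quality length mismatch in FASTQ record ", bad[1],
           " in ", p)
    list(id = sub("^@", "", sub("\\s.*$", "", hd)), seq = toupper(sq),
         qual = ql)
  }
  r1 <- parse_one(path)
  if (is.null(path2))
    return(read_set(r1$id, r1$seq, r1$qual, paired = paired))
  r2 <- parse_one(path2)
  if (length(r1$id) != length(r2$id))
    stop("mate files contain different numbers of records")
  ix <- rep(seq_along(r1$id), each = 2L)
  sel <- rep(c(TRUE, FALSE), length(r1$id))
  id <- ifelse(sel, r1$id[ix], r2$id[ix])
  seq <- ifelse(sel, r1$seq[ix], r2$seq[ix])
  qual <- ifelse(sel, r1$qual[ix], r2$qual[ix])
  read_set(id, seq, qual, paired = TRUE)
}

#' Write a read set to a FASTQ file
#'
#' Uses Biostrings for serialization; a `.gz` suffix on `path` triggers
#' gzip compression.
#'
#' @param reads A [read_set].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  qual <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(dna, filepath = path, format = "fastq",
                              qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
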