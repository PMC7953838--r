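## k-mer spectrum construction. The spectrum is the histogram of distinct
## canonical k-mers (lexicographic minimum of a k-mer and its reverse
## complement, A<C<G<T) by their integer coverage in the read set.

#' Count canonical k-mers in sequencing reads
#'
#' Decomposes reads into all k-length subsequences, canonicalizes them, and
#' builds the coverage histogram (k-mer spectrum). k-mers containing N are
#' skipped. The full k-mer count table can be retained for per-locus
#' heterozygosity-structure analysis.
#'
#' @param reads a character vector of read sequences, a `read_set`, or
#'   path(s) to FASTQ files (optionally gzipped).
#' @param k odd k-mer size, 11..31 (default 21).
#' @param keep_table retain the full `kmer -> count` table (required by
#'   [extract_het_families()]).
#' @return an object of class `kmer_spectrum`: `k`, `bins` (data.frame with
#'   `coverage` and `count` of distinct k-mers), `total_kmers` (number of
#'   k-mers streamed; equals `sum(bins$coverage * bins$count)`), and
#'   optionally `table` (data.frame `kmer`, `count`).
#' @export
count_kmers <- function(reads, k = 21, keep_table = FALSE) {
  if (k %% 2 != 1 || k < 11 || k > 31) stop("k must be odd and in 11..31")
  if (is.data.frame(reads)) reads <- reads$seq
  if (is.character(reads) && length(reads) > 0 && all(file.exists(reads))) {
    reads <- unlist(lapply(reads, read_fastq), use.names = FALSE)
  }
  if (length(reads) == 0) stop("no reads provided")
  if (max(nchar(reads)) < k) stop("k is longer than every read")
  res <- cpp_count_kmers(reads, as.integer(k), isTRUE(keep_table))
  if (res$total_kmers == 0) stop("no valid k-mers in input")
  out <- list(k = as.integer(k),
              bins = data.frame(coverage = res$coverage, count = res$count),
              total_kmers = res$total_kmers)
  if (isTRUE(keep_table)) {
    out$table <- data.frame(kmer = res$kmer, count = res$kmer_count,
                            stringsAsFactors = FALSE)
  }
  structure(out, class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("kmer_spectrum: k =", x$k, "|", sum(x$bins$count), "distinct k-mers |",
      format(x$total_kmers, big.mark = ","), "k-mers streamed\n")
  invisible(x)
}

## dense coverage -> count vector (index c holds the count at coverage c)
dense_bins <- function(spectrum, max_cov = NULL) {
  b <- spectrum$bins
  M <- if (is.null(max_cov)) max(b$coverage) else max_cov
  y <- numeric(M)
  keep <- b$coverage <= M
  y[b$coverage[keep]] <- b$count[keep]
  y
}

#' Error cutoff of a k-mer spectrum
#'
#' Coverage bin below which k-mers are treated as sequencing errors: the
#' first local minimum of the histogram between coverage 1 and the first
#' mode. When the histogram rises immediately (no error peak), the cutoff
#' is 1.
#'
#' @param spectrum a `kmer_spectrum`.
#' @return integer coverage cutoff (k-mers with coverage >= cutoff are kept).
#' @export
error_cutoff <- function(spectrum) {
  y <- dense_bins(spectrum)
  if (length(y) < 3) return(1L)
  for (c in seq_len(length(y) - 1L)) {
    if (y[c + 1L] >= y[c]) return(as.integer(c))
  }
  1L
}

#' Write a k-mer spectrum as two-column text
#'
#' Format: `coverage<TAB>count`, compatible with common spectrum-tool
#' histogram output.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  write.table(spectrum$bins, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a k-mer spectrum from two-column text
#'
#' @param path histogram path (`coverage<TAB>count`).
#' @param k the k the histogram was computed with.
#' @return a `kmer_spectrum` (without a count table).
#' @export
read_spectrum <- function(path, k = 21) {
  b <- read.table(path, header = FALSE, col.names = c("coverage", "count"))
  structure(list(k = as.integer(k), bins = b,
                 total_kmers = sum(b$coverage * b$count)),
            class = "kmer_spectrum")
}

#' Write a k-mer count table as two-column text (`kmer<TAB>count`)
#' @param spectrum a `kmer_spectrum` built with `keep_table = TRUE`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(spectrum, path) {
  if (is.null(spectrum$table)) {
    stop("spectrum has no count table; rerun count_kmers() with keep_table = TRUE")
  }
  write.table(spectrum$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
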