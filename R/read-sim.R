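## Shotgun read simulation: uniform single-end reads with an i.i.d.
## substitution error model and constant Phred+33 qualities.

#' Simulate shotgun reads from a set of sequences
#'
#' Draws single-end reads uniformly from each input sequence at the requested
#' per-copy coverage. Substitution errors are i.i.d. per base; no indels and
#' no quality-score profile are modelled (qualities are constant). The output
#' is deterministic for a fixed seed, and the total number of sequenced bases
#' is within one read of `coverage_per_haplotype * sum(nchar(haplotypes))`.
#'
#' @param haplotypes named character vector of source sequences (e.g.
#'   `simulate_haplotypes(...)$haplotypes`), or a `haplotype_set`.
#' @param coverage_per_haplotype fold coverage per input sequence.
#' @param read_length read length in bp; must not exceed the shortest source
#'   sequence.
#' @param error_rate per-base substitution probability in \[0, 0.05\].
#' @param seed integer seed.
#' @return data.frame of class `read_set`: `id`, `seq`, `source`, `start`
#'   (1-based on the source), `strand`. The `seq` column is the sequenced
#'   (possibly erroneous, possibly reverse-complemented) read.
#' @export
simulate_reads <- function(haplotypes, coverage_per_haplotype, read_length,
                           error_rate = 0, seed = 1L) {
  if (inherits(haplotypes, "haplotype_set")) haplotypes <- haplotypes$haplotypes
  stopifnot(is.character(haplotypes), length(haplotypes) > 0)
  if (is.null(names(haplotypes))) names(haplotypes) <- paste0("seq", seq_along(haplotypes))
  if (coverage_per_haplotype <= 0) stop("coverage_per_haplotype must be > 0")
  if (error_rate < 0 || error_rate > 0.05) stop("error_rate must be in [0, 0.05]")
  lens <- nchar(haplotypes)
  if (read_length > min(lens)) {
    stop("read_length (", read_length, ") exceeds the shortest scaffold (",
         min(lens), ")")
  }
  set.seed(seed)
  out <- vector("list", length(haplotypes))
  for (i in seq_along(haplotypes)) {
    L <- lens[i]
    n <- max(1L, as.integer(round(coverage_per_haplotype * L / read_length)))
    starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    reads <- substring(haplotypes[i], starts, starts + read_length - 1L)
    rev <- strand == "-"
    if (any(rev)) reads[rev] <- revcomp(reads[rev])
    out[[i]] <- data.frame(source = names(haplotypes)[i], start = starts,
                           strand = strand, seq = reads,
                           stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out)
  if (error_rate > 0) {
    nerr <- rbinom(nrow(reads), read_length, error_rate)
    for (j in which(nerr > 0)) {
      pos <- sample.int(read_length, nerr[j])
      chars <- str_chars(reads$seq[j])
      chars[pos] <- vapply(chars[pos],
                           function(b) sample(setdiff(DNA_BASES, b), 1), "")
      reads$seq[j] <- paste(chars, collapse = "")
    }
  }
  reads <- data.frame(id = sprintf("read_%07d", seq_len(nrow(reads))), reads,
                      stringsAsFactors = FALSE)
  class(reads) <- c("read_set", "data.frame")
  reads
}

#' Write reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads a `read_set` data.frame or a character vector of sequences.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (is.data.frame(reads)) {
    ids <- reads$id
    seqs <- reads$seq
  } else {
    seqs <- as.character(reads)
    ids <- if (is.null(names(seqs))) sprintf("read_%07d", seq_along(seqs)) else names(seqs)
  }
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

#' Read sequences from FASTQ
#'
#' @param path FASTQ path (optionally gzipped).
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param type `"DNA"` or `"AA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
       else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA path.
#' @param type `"DNA"` or `"AA"`.
#' @return named character vector.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
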