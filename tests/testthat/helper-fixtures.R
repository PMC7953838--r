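## Shared fixture builders and small independent oracles. Everything is
## generated in code at test time; no stored data files.

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein_chr <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

random_dna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## Independent R oracle for canonical k-mer counting (substring-based),
## used to cross-check the C++ streaming counter on small inputs.
oracle_kmer_counts <- function(reads, k) {
  km <- unlist(lapply(reads, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  km <- km[!grepl("[^ACGT]", km)]
  canon <- pmin(km, rc_chr(km))
  table(canon)
}

oracle_spectrum <- function(reads, k) {
  cts <- oracle_kmer_counts(reads, k)
  tab <- table(as.integer(cts))
  data.frame(coverage = as.integer(names(tab)), count = as.numeric(tab))
}

## number of k-windows of a haplotype pair containing exactly one truth site
windows_with_one_site <- function(sites, L, k) {
  ind <- numeric(L)
  ind[sites] <- 1
  cs <- c(0, cumsum(ind))
  w <- seq_len(L - k + 1)
  sum((cs[w + k] - cs[w]) == 1)
}

## small RepeatMasker-style TE library
make_te_library <- function(seed = 99, lens = c(3000, 2500, 2000, 1500, 2200)) {
  set.seed(seed)
  setNames(vapply(lens, function(l) random_dna(l), ""),
           c("teA#LTR/Gypsy", "teB#LINE/L1", "teC#DNA/hAT",
             "teD#SINE/tRNA", "teE#RC/Helitron"))
}

## assemble a kmer_spectrum object directly from a hand-made count table
spectrum_from_table <- function(kmers, counts, k = 21) {
  tab <- table(counts)
  structure(list(k = as.integer(k),
                 bins = data.frame(coverage = as.integer(names(tab)),
                                   count = as.numeric(tab)),
                 total_kmers = sum(counts),
                 table = data.frame(kmer = kmers, count = counts,
                                    stringsAsFactors = FALSE)),
            class = "kmer_spectrum")
}

## model-generated spectrum: exact expected counts from the NB mixture
model_spectrum <- function(topology, lambda, rho, r, G, k = 21, max_cov = NULL) {
  pl <- nchar(topology)
  w <- topology_weights(topology, r, k)
  M <- if (is.null(max_cov)) ceiling(pl * lambda * 2.5) else max_cov
  cs <- 1:M
  f <- numeric(length(cs))
  for (j in seq_len(nrow(w))) {
    if (w$weight[j] <= 0) next
    mu <- w$copies[j] * lambda
    f <- f + w$weight[j] * dnbinom(cs, mu = mu, size = mu / rho)
  }
  structure(list(k = as.integer(k),
                 bins = data.frame(coverage = cs, count = G * f),
                 total_kmers = sum(cs * G * f)),
            class = "kmer_spectrum")
}

## exhaustive best-chain oracle: enumerate every gap-valid monotone anchor
## subsequence and return the maximum chain score
oracle_best_chain <- function(ra, rb, orientation, max_gap, gap_penalty = 0.1) {
  n <- length(ra)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]
  best <- -Inf
  recurse <- function(last, score) {
    best <<- max(best, score)
    nxt <- if (is.null(last)) seq_len(n) else which(seq_len(n) > last)
    for (i in nxt) {
      if (!is.null(last)) {
        da <- ra[i] - ra[last]
        db <- if (orientation == "same") rb[i] - rb[last] else rb[last] - rb[i]
        if (da < 1 || da > max_gap || db < 1 || db > max_gap) next
        recurse(i, score + 1 - gap_penalty * ((da - 1) + (db - 1)))
      } else {
        recurse(i, 1)
      }
    }
  }
  recurse(NULL, 0)
  best
}

## quick full synthetic species on disk (files for the pipeline tests)
build_species_dir <- function(dir, seed = 1, r = 0.01, n_genes = 40,
                              te_fraction = 0.08, coverage = 15,
                              error_rate = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- make_te_library(seed + 1)
  hs <- simulate_haplotypes(genome_spec(1e5, 2, "AB", c(allelic = r),
                                        seed = seed))
  plan <- feature_plan(te_library = lib, te_target_fraction = te_fraction,
                       n_genes = n_genes,
                       palindrome_implants = list(list(n_genes = 3)),
                       hgt_implants = 3)
  ig <- implant_features(hs, plan, seed = seed + 2)
  rd <- simulate_reads(ig$read_templates, coverage, 100,
                       error_rate = error_rate, seed = seed + 3)
  write_fastq(rd, file.path(dir, "reads.fq.gz"))
  write_genome_package(ig, dir)
  write_fasta(lib, file.path(dir, "te_library.fa"))
  list(dir = dir, genome = ig, lib = lib, haplotypes = hs, reads = rd)
}
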