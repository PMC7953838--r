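## Read-based transposable-element quantification: subsample reads to low
## coverage, assemble the subsample with a greedy exact-overlap assembler
## (repetitive sequence assembles, single-copy sequence mostly does not),
## annotate contigs and leftover reads against a TE library by homology, and
## report per-class nucleotide fractions of the sampled nucleotides.
## "Unknown" repeats (assembled but without library homology) are reported
## but never included in the TE load.

TE_CLASSES <- c("DNA", "LINE", "SINE", "LTR", "Helitron")

#' Subsample reads to a target coverage
#'
#' Uniform random sample without replacement until the summed read length
#' reaches `target_cov * haploid_genome_size`; deterministic per seed.
#'
#' @param reads character vector of read sequences, a `read_set`, or FASTQ
#'   path(s).
#' @param haploid_genome_size haploid genome size in bp (typically
#'   `genome_size_G` from [fit_spectrum()], or a user override).
#' @param target_cov target coverage (default 0.5).
#' @param seed integer seed.
#' @return character vector of sampled read sequences.
#' @export
subsample_reads <- function(reads, haploid_genome_size, target_cov = 0.5,
                            seed = 1L) {
  if (is.data.frame(reads)) reads <- reads$seq
  if (is.character(reads) && length(reads) > 0 && all(file.exists(reads))) {
    reads <- unlist(lapply(reads, read_fastq), use.names = FALSE)
  }
  stopifnot(haploid_genome_size > 0, target_cov > 0)
  need <- target_cov * haploid_genome_size
  total <- sum(nchar(reads))
  if (total < need) {
    stop(sprintf("insufficient reads: %.0f nt available, %.0f nt needed (achievable coverage %.3gx)",
                 total, need, total / haploid_genome_size))
  }
  set.seed(seed)
  ord <- sample.int(length(reads))
  cum <- cumsum(nchar(reads)[ord])
  n <- which(cum >= need)[1]
  reads[ord[seq_len(n)]]
}

#' Greedy overlap assembly of a read subsample
#'
#' Strand-aware greedy assembly by exact suffix-prefix overlaps: overlaps are
#' merged longest-first, reverse complements are handled by assembling over
#' both orientations of every read and deduplicating reverse-complementary
#' contigs, and each read is attributed to at most one contig. Contigs
#' supported by at least `min_reads` reads are repeat candidates; reads in no
#' kept contig are returned as unassembled.
#'
#' @param subsample character vector of read sequences.
#' @param min_overlap minimum exact overlap length (default 31).
#' @param min_reads minimum read support for a repeat contig (default 2).
#' @return an object of class `repeat_assembly`: `contigs` (data.frame
#'   `contig_id`, `seq`, `support`, `read_nt`), `unassembled` (character),
#'   `sampled_nt`, `n_reads`.
#' @export
assemble_repeats <- function(subsample, min_overlap = 31, min_reads = 2) {
  stopifnot(length(subsample) > 0)
  n <- length(subsample)
  nodes <- c(subsample, revcomp(subsample))
  N <- 2L * n
  lens <- nchar(nodes)
  mate <- c(seq_len(n) + n, seq_len(n))

  parent <- seq_len(N)
  find <- function(x) {
    while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
    x
  }
  out_edge <- rep(NA_integer_, N)
  in_edge <- rep(NA_integer_, N)
  out_olap <- rep(NA_integer_, N)

  olaps <- if (max(lens) >= min_overlap) seq(max(lens), min_overlap) else integer(0)
  for (o in olaps) {
    suf_ok <- which(is.na(out_edge) & lens >= o)
    pre_ok <- which(is.na(in_edge) & lens >= o)
    if (length(suf_ok) == 0 || length(pre_ok) == 0) next
    sufs <- substr(nodes[suf_ok], lens[suf_ok] - o + 1L, lens[suf_ok])
    pres <- substr(nodes[pre_ok], 1L, o)
    pre_map <- split(pre_ok, pres)
    hit <- which(sufs %in% names(pre_map))
    for (ii in hit) {
      i <- suf_ok[ii]
      if (!is.na(out_edge[i])) next
      for (j in pre_map[[sufs[ii]]]) {
        if (!is.na(in_edge[j]) || i == j || j == mate[i]) next
        ri <- find(i); rj <- find(j)
        if (ri == rj) next                       # would close a cycle
        if (find(mate[i]) == rj || find(mate[j]) == ri) next
        out_edge[i] <- j; in_edge[j] <- i; out_olap[i] <- o
        parent[ri] <- rj
        break
      }
    }
  }

  ## walk chains from their head nodes
  heads <- which(is.na(in_edge) & !is.na(out_edge))
  chains <- lapply(heads, function(h) {
    path <- h
    while (!is.na(out_edge[path[length(path)]])) {
      path <- c(path, out_edge[path[length(path)]])
    }
    path
  })
  chains <- chains[order(-lengths(chains))]

  claimed <- rep(FALSE, n)
  contigs <- list()
  seen <- character(0)
  rl <- mean(nchar(subsample))
  for (path in chains) {
    seq_out <- nodes[path[1]]
    if (length(path) > 1) {
      for (t in 2:length(path)) {
        o <- out_olap[path[t - 1L]]
        add <- substr(nodes[path[t]], o + 1L, lens[path[t]])
        seq_out <- paste0(seq_out, add)
      }
    }
    key <- min(seq_out, revcomp(seq_out))
    rid <- unique((path - 1L) %% n + 1L)
    rid <- rid[!claimed[rid]]
    if (key %in% seen || length(rid) < min_reads) next
    seen <- c(seen, key)
    claimed[rid] <- TRUE
    contigs[[length(contigs) + 1L]] <-
      data.frame(seq = seq_out, support = length(rid),
                 read_nt = round(length(rid) * rl))
  }
  contigs <- if (length(contigs) > 0) do.call(rbind, contigs) else
    data.frame(seq = character(0), support = integer(0), read_nt = numeric(0))
  if (nrow(contigs) > 0) {
    contigs <- data.frame(contig_id = sprintf("contig_%05d", seq_len(nrow(contigs))),
                          contigs, stringsAsFactors = FALSE)
  } else {
    contigs$contig_id <- character(0)
    contigs <- contigs[, c("contig_id", "seq", "support", "read_nt")]
  }
  structure(list(contigs = contigs, unassembled = subsample[!claimed],
                 sampled_nt = sum(nchar(subsample)), n_reads = n,
                 read_length = rl),
            class = "repeat_assembly")
}

#' @export
print.repeat_assembly <- function(x, ...) {
  cat("repeat_assembly:", x$n_reads, "reads |", nrow(x$contigs), "contigs |",
      length(x$unassembled), "unassembled\n")
  invisible(x)
}

#' Annotate assembled repeats against a TE library
#'
#' Contigs and unassembled reads are aligned to the library by seeded local
#' alignment (exact shared word, then Smith-Waterman); hits require at least
#' `min_identity` identity over `min_aln_len` aligned bases. Annotated
#' nucleotides are the aligned query length of the best hit, attributed to
#' the hit's class and multiplied by the read support the query represents
#' (for contigs: sampled read nucleotides per contig base). Repeat contigs
#' without a TE hit, or hit only by non-TE library entries, contribute to
#' `unknown_repeat_nt`, which is never included in the TE load.
#'
#' @param asm a `repeat_assembly`.
#' @param te_library named character vector; names follow the RepeatMasker
#'   `name#Class/Family` convention and map to classes DNA, LINE, SINE, LTR,
#'   Helitron (others are treated as unknown-class repeats).
#' @param min_identity minimum percent identity / 100 (default 0.70).
#' @param min_aln_len minimum aligned length in bp (default 80).
#' @param seed_word exact-word seed length (default 15).
#' @return an object of class `te_annotation`: `sampled_nt`, `per_class_nt`,
#'   `unknown_repeat_nt`, `te_load` (percent), `per_class_pct`, and `table`
#'   (long format, one row per class).
#' @export
annotate_repeats <- function(asm, te_library, min_identity = 0.70,
                             min_aln_len = 80, seed_word = 15) {
  stopifnot(inherits(asm, "repeat_assembly"))
  if (is.null(te_library) || length(te_library) == 0) {
    stop("empty TE library")
  }
  lib_class <- te_class_of(names(te_library))
  if (any(is.na(lib_class))) {
    warning("library entries without a 'name#Class/Family' label are treated",
            " as unknown-class repeats: ",
            paste(head(names(te_library)[is.na(lib_class)], 3), collapse = ", "))
    lib_class[is.na(lib_class)] <- "other"
  }
  queries <- c(asm$contigs$seq, asm$unassembled)
  is_contig <- c(rep(TRUE, nrow(asm$contigs)), rep(FALSE, length(asm$unassembled)))
  weight <- c(if (nrow(asm$contigs) > 0)
                asm$contigs$read_nt / nchar(asm$contigs$seq) else numeric(0),
              rep(1, length(asm$unassembled)))

  per_class <- setNames(numeric(length(TE_CLASSES)), TE_CLASSES)
  unknown_nt <- 0
  if (length(queries) > 0) {
    idx <- word_index(te_library, seed_word, canonical = TRUE)
    cand <- seed_candidates(queries, idx, seed_word, canonical = TRUE)
    best_class <- rep(NA_character_, length(queries))
    best_score <- rep(-Inf, length(queries))
    best_nt <- numeric(length(queries))
    for (li in seq_along(te_library)) {
      qs <- which(vapply(cand, function(x) li %in% x, TRUE))
      if (length(qs) == 0) next
      for (orient in 1:2) {
        pats <- if (orient == 1) queries[qs] else revcomp(queries[qs])
        hits <- local_align(pats, te_library[[li]], type = "DNA")
        ok <- hits$pid >= 100 * min_identity & hits$aln_len >= min_aln_len
        upd <- ok & hits$score > best_score[qs]
        if (any(upd)) {
          qi <- qs[upd]
          best_score[qi] <- hits$score[upd]
          best_class[qi] <- lib_class[li]
          best_nt[qi] <- hits$aln_len[upd]
        }
      }
    }
    for (q in seq_along(queries)) {
      cls <- best_class[q]
      if (!is.na(cls) && cls %in% TE_CLASSES) {
        per_class[cls] <- per_class[cls] + best_nt[q] * weight[q]
      } else if (is_contig[q]) {
        ## assembled repeat without (TE) annotation
        unknown_nt <- unknown_nt + asm$contigs$read_nt[q]
      }
    }
  }
  sampled_nt <- asm$sampled_nt
  per_class_pct <- 100 * per_class / sampled_nt
  te_load <- sum(per_class_pct)
  structure(list(sampled_nt = sampled_nt, per_class_nt = per_class,
                 unknown_repeat_nt = unknown_nt, te_load = te_load,
                 per_class_pct = per_class_pct,
                 table = data.frame(class = TE_CLASSES,
                                    nt = unname(per_class),
                                    pct = unname(per_class_pct))),
            class = "te_annotation")
}

#' @export
print.te_annotation <- function(x, ...) {
  cat(sprintf("te_annotation: TE load %.2f%% of %s sampled nt (unknown repeats %.2f%%, excluded)\n",
              x$te_load, format(x$sampled_nt, big.mark = ","),
              100 * x$unknown_repeat_nt / x$sampled_nt))
  for (cl in TE_CLASSES) {
    cat(sprintf("  %-9s %6.2f%%\n", cl, x$per_class_pct[[cl]]))
  }
  invisible(x)
}

#' TE load from reads: subsample, assemble, annotate
#'
#' @param reads reads (character vector, `read_set`, or FASTQ path(s)).
#' @param haploid_genome_size haploid genome size in bp.
#' @param te_library named character TE library (`name#Class/Family`).
#' @param target_cov subsampling coverage (default 0.5).
#' @param seed integer seed for the subsample.
#' @param ... passed to [annotate_repeats()].
#' @return a `te_annotation` (see [annotate_repeats()]).
#' @export
te_profile <- function(reads, haploid_genome_size, te_library,
                       target_cov = 0.5, seed = 1L, ...) {
  sub <- subsample_reads(reads, haploid_genome_size, target_cov, seed)
  asm <- assemble_repeats(sub)
  annotate_repeats(asm, te_library, ...)
}
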