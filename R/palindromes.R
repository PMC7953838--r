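## Palindrome detection from gene collinearity: all-vs-all protein homology
## gives anchor pairs, dynamic-programming chaining gives collinear blocks,
## and palindromes are the reverse-orientation blocks whose two sides lie on
## the same scaffold on opposite strands without overlapping -- the only
## arrangement able to fold back and form a hairpin.

#' All-vs-all protein homology search
#'
#' Seeded Smith-Waterman between all protein pairs (exact shared word, then
#' local alignment with BLOSUM62). Hits are kept once per unordered pair,
#' must reach `min_identity` percent identity over at least `min_len`
#' aligned residues, and must have a Karlin-Altschul e-value at most
#' `max_evalue`. Self-hits are excluded.
#'
#' @param proteins named character vector of protein sequences (or an AA
#'   FASTA path).
#' @param max_evalue significance threshold (default 1e-5).
#' @param min_identity minimum percent identity (default 50).
#' @param min_len minimum aligned length in residues (default 100).
#' @param seed_word exact-word seed length (default 5).
#' @return data.frame: `query`, `subject`, `score`, `bitscore`, `evalue`,
#'   `pid`, `aln_len`.
#' @export
all_vs_all_homology <- function(proteins, max_evalue = 1e-5,
                                min_identity = 50, min_len = 100,
                                seed_word = 5) {
  if (is.character(proteins) && length(proteins) == 1 && file.exists(proteins)) {
    proteins <- read_fasta(proteins, type = "AA")
  }
  if (length(proteins) < 2) stop("need at least 2 proteins")
  idx <- word_index(proteins, seed_word)
  cand <- seed_candidates(proteins, idx, seed_word)
  ## unordered candidate pairs (i < j), grouped by subject j
  pairs <- do.call(rbind, lapply(seq_along(proteins), function(i) {
    js <- cand[[i]]
    js <- js[js > i]
    if (length(js) == 0) NULL else data.frame(i = i, j = js)
  }))
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(data.frame(query = character(0), subject = character(0),
                      score = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0), pid = numeric(0),
                      aln_len = integer(0)))
  }
  rows <- list()
  for (j in unique(pairs$j)) {
    is_ <- pairs$i[pairs$j == j]
    hits <- local_align(proteins[is_], proteins[[j]], type = "AA")
    ev <- evalue(hits$score, nchar(proteins[is_]), nchar(proteins[[j]]))
    ok <- ev <= max_evalue & hits$pid >= min_identity & hits$aln_len >= min_len
    if (any(ok)) {
      rows[[length(rows) + 1L]] <- data.frame(
        query = names(proteins)[is_[ok]], subject = names(proteins)[j],
        score = hits$score[ok], bitscore = bitscore(hits$score[ok]),
        evalue = ev[ok], pid = hits$pid[ok], aln_len = hits$aln_len[ok],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(query = character(0), subject = character(0),
                      score = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0), pid = numeric(0),
                      aln_len = integer(0)))
  }
  do.call(rbind, rows)
}

## build anchor table from hits + gene records; same-scaffold anchors closer
## than tandem_min_rank_dist ranks are excluded (tail-to-tail tandem copies
## are indistinguishable from assembly artifacts)
build_anchors <- function(hits, genes, tandem_min_rank_dist = 2) {
  if (nrow(hits) == 0) {
    return(list(anchors = NULL, discarded_tandem = 0L))
  }
  gi <- match(hits$query, genes$gene_id)
  gj <- match(hits$subject, genes$gene_id)
  keep <- !is.na(gi) & !is.na(gj)
  gi <- gi[keep]; gj <- gj[keep]
  a <- data.frame(
    gene_a = genes$gene_id[gi], gene_b = genes$gene_id[gj],
    scaffold_a = genes$scaffold[gi], scaffold_b = genes$scaffold[gj],
    ra = genes$rank[gi], rb = genes$rank[gj],
    strand_a = genes$strand[gi], strand_b = genes$strand[gj],
    stringsAsFactors = FALSE)
  ## orient each anchor: scaffold_a <= scaffold_b, and ra < rb within one
  flip <- a$scaffold_a > a$scaffold_b |
    (a$scaffold_a == a$scaffold_b & a$ra > a$rb)
  if (any(flip)) {
    a[flip, c("gene_a", "gene_b", "scaffold_a", "scaffold_b", "ra", "rb",
              "strand_a", "strand_b")] <-
      a[flip, c("gene_b", "gene_a", "scaffold_b", "scaffold_a", "rb", "ra",
                "strand_b", "strand_a")]
  }
  same <- a$scaffold_a == a$scaffold_b
  tandem <- same & abs(a$ra - a$rb) < tandem_min_rank_dist
  list(anchors = a[!tandem, , drop = FALSE], discarded_tandem = sum(tandem))
}

## best chain among anchors of one (scaffold pair, orientation) group;
## returns indices into the group's rows, or NULL
chain_dp <- function(ra, rb, orientation, max_gap, gap_penalty = 0.1) {
  n <- length(ra)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]
  score <- rep(1, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- if (orientation == "same") rb[i] - rb[j] else rb[j] - rb[i]
      if (da < 1 || da > max_gap || db < 1 || db > max_gap) next
      s <- score[j] + 1 - gap_penalty * ((da - 1) + (db - 1))
      if (s > score[i]) { score[i] <- s; prev[i] <- j }
    }
  }
  end <- which.max(score)
  path <- end
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  list(idx = ord[path], score = score[end])
}

#' Detect collinear blocks by dynamic-programming anchor chaining
#'
#' Homologous gene pairs (anchors) are chained per scaffold pair and
#' orientation: a chain extends when both rank gaps are at most `max_gap`
#' and the subject-side direction matches the chain orientation (increasing
#' for `same`, decreasing for `reverse`). The chain score is the anchor
#' count minus 0.1 per skipped rank unit. Best-scoring non-overlapping
#' chains (no shared genes) are extracted greedily; blocks with fewer than
#' `min_pairs` anchors are dropped. Same-scaffold anchors within
#' `tandem_min_rank_dist` ranks are excluded up front.
#'
#' @param hits data.frame from [all_vs_all_homology()].
#' @param genes gene records (data.frame with `gene_id`, `scaffold`,
#'   `start`, `end`, `strand`, `rank`).
#' @param max_gap maximum rank gap (default 25).
#' @param min_pairs minimum anchors per block (default 1; the strict
#'   MCScanX-like convention uses 5).
#' @param tandem_min_rank_dist same-scaffold anchors closer than this many
#'   ranks are excluded (default 2).
#' @return list of class `collinear_blocks`; each block has `scaffold_a`,
#'   `scaffold_b`, `orientation` (`same`/`reverse`), `score`, `n_pairs` and
#'   `anchors`. The number of tandem-excluded anchors is in
#'   `attr(, "discarded_tandem")`.
#' @export
detect_collinear_blocks <- function(hits, genes, max_gap = 25, min_pairs = 1,
                                    tandem_min_rank_dist = 2) {
  ba <- build_anchors(hits, genes, tandem_min_rank_dist)
  anchors <- ba$anchors
  blocks <- list()
  add_block <- function(sel, orient, score) {
    if (nrow(sel) < min_pairs) return(invisible(NULL))
    blocks[[length(blocks) + 1L]] <<- list(
      scaffold_a = sel$scaffold_a[1], scaffold_b = sel$scaffold_b[1],
      orientation = orient, score = score, n_pairs = nrow(sel),
      anchors = sel[, c("gene_a", "gene_b", "ra", "rb",
                        "strand_a", "strand_b")])
    invisible(NULL)
  }
  if (!is.null(anchors) && nrow(anchors) > 0) {
    anchors$pairkey <- paste(anchors$scaffold_a, anchors$scaffold_b)
    for (pk in unique(anchors$pairkey)) {
      grp <- anchors[anchors$pairkey == pk, , drop = FALSE]
      ## phase 1: multi-anchor chains, best score first, both orientations
      repeat {
        if (nrow(grp) == 0) break
        best <- NULL
        for (orient in c("same", "reverse")) {
          ch <- chain_dp(grp$ra, grp$rb, orient, max_gap)
          if (length(ch$idx) >= 2 &&
              (is.null(best) || ch$score > best$score)) {
            best <- c(ch, list(orient = orient))
          }
        }
        if (is.null(best)) break
        sel <- grp[best$idx, , drop = FALSE]
        add_block(sel, best$orient, best$score)
        used <- unique(c(sel$gene_a, sel$gene_b))
        grp <- grp[!(grp$gene_a %in% used | grp$gene_b %in% used), ,
                   drop = FALSE]
      }
      ## phase 2: leftover anchors as singleton blocks, oriented by strand
      if (nrow(grp) > 0) {
        used <- character(0)
        for (t in seq_len(nrow(grp))) {
          sel <- grp[t, , drop = FALSE]
          if (sel$gene_a %in% used || sel$gene_b %in% used) next
          orient <- if (sel$strand_a != sel$strand_b) "reverse" else "same"
          add_block(sel, orient, 1)
          used <- c(used, sel$gene_a, sel$gene_b)
        }
      }
    }
  }
  structure(blocks, class = "collinear_blocks",
            discarded_tandem = ba$discarded_tandem)
}

#' Filter collinear blocks down to palindromes
#'
#' Keeps blocks that satisfy every palindrome requirement: both sides on the
#' same scaffold, reverse orientation, every anchor pair on opposite
#' strands, and non-overlapping side coordinates. Discarded blocks are
#' logged with their reason in `attr(, "discarded")`.
#'
#' @param blocks a `collinear_blocks` list.
#' @param genes gene records (for side coordinates).
#' @return list of class `palindrome_set`; each palindrome has the block
#'   fields plus `n_genes` (distinct genes across both sides).
#' @export
filter_palindromes <- function(blocks, genes) {
  pals <- list()
  discarded <- list()
  for (b in blocks) {
    reason <- NULL
    if (b$scaffold_a != b$scaffold_b) {
      reason <- "different_scaffold"
    } else if (b$orientation != "reverse") {
      reason <- "same_orientation"
    } else if (any(b$anchors$strand_a == b$anchors$strand_b)) {
      reason <- "strand_inconsistent"
    } else {
      ga <- match(b$anchors$gene_a, genes$gene_id)
      gb <- match(b$anchors$gene_b, genes$gene_id)
      if (max(genes$end[ga]) > min(genes$start[gb]) &&
          max(genes$end[gb]) > min(genes$start[ga])) {
        reason <- "overlapping_sides"
      }
    }
    if (is.null(reason)) {
      b$n_genes <- length(unique(c(b$anchors$gene_a, b$anchors$gene_b)))
      pals[[length(pals) + 1L]] <- b
    } else {
      discarded[[length(discarded) + 1L]] <-
        data.frame(scaffold_a = b$scaffold_a, scaffold_b = b$scaffold_b,
                   orientation = b$orientation, n_pairs = b$n_pairs,
                   reason = reason)
    }
  }
  structure(pals, class = "palindrome_set",
            discarded = if (length(discarded) > 0) do.call(rbind, discarded)
                        else NULL)
}

#' Summarize palindromes
#'
#' Genes are counted once even when they occur in several palindromes.
#'
#' @param palindromes a `palindrome_set`.
#' @param total_gene_count total number of annotated genes.
#' @return list: `n_palindromes`, `n_genes_affected`, `percent_genes`.
#' @export
summarize_palindromes <- function(palindromes, total_gene_count) {
  stopifnot(total_gene_count > 0)
  genes <- unique(unlist(lapply(palindromes, function(p)
    c(p$anchors$gene_a, p$anchors$gene_b))))
  list(n_palindromes = length(palindromes),
       n_genes_affected = length(genes),
       percent_genes = 100 * length(genes) / total_gene_count)
}

#' Shuffle gene order (permutation null)
#'
#' Randomly permutes which gene occupies which annotated slot
#' (scaffold/coordinates/strand are kept, gene identities are reassigned),
#' destroying any true collinearity while preserving the homology network
#' and the gene density per scaffold.
#'
#' @param genes gene records.
#' @param seed integer seed.
#' @return gene records with permuted identities.
#' @export
shuffle_gene_order <- function(genes, seed = 1L) {
  set.seed(seed)
  perm <- sample.int(nrow(genes))
  out <- genes
  out$gene_id <- genes$gene_id[perm]
  out
}

#' Full palindrome scan of an annotated assembly
#'
#' Runs [all_vs_all_homology()], [detect_collinear_blocks()],
#' [filter_palindromes()] and [summarize_palindromes()], optionally with a
#' gene-order permutation null whose mean palindrome count guards against
#' assembly-artifact positives.
#'
#' @param genes gene records (data.frame or a GFF3 path).
#' @param proteins named character protein sequences (or an AA FASTA path).
#' @param mcscanx_strict if `TRUE`, require blocks of at least 5 anchor
#'   pairs (the strict synteny-block convention); default counts individual
#'   genes in palindromic arrangement (`min_pairs = 1`).
#' @param null_shuffles number of gene-order shuffles for the permutation
#'   null (0 to skip).
#' @param seed seed for the permutation null.
#' @param ... passed to [detect_collinear_blocks()].
#' @return list of class `palindrome_report`: `palindromes`, `summary`,
#'   `blocks`, `hits`, `null_counts` (palindrome count per shuffle, or
#'   NULL), `null_mean`.
#' @export
palindrome_scan <- function(genes, proteins, mcscanx_strict = FALSE,
                            null_shuffles = 0, seed = 1L, ...) {
  if (is.character(genes) && length(genes) == 1) genes <- read_gene_records(genes)
  min_pairs <- if (mcscanx_strict) 5 else 1
  hits <- all_vs_all_homology(proteins)
  blocks <- detect_collinear_blocks(hits, genes, min_pairs = min_pairs, ...)
  pals <- filter_palindromes(blocks, genes)
  null_counts <- NULL
  if (null_shuffles > 0) {
    null_counts <- vapply(seq_len(null_shuffles), function(s) {
      g2 <- shuffle_gene_order(genes, seed = seed + s)
      b2 <- detect_collinear_blocks(hits, g2, min_pairs = min_pairs, ...)
      length(filter_palindromes(b2, g2))
    }, 0)
  }
  structure(list(palindromes = pals,
                 summary = summarize_palindromes(pals, nrow(genes)),
                 blocks = blocks, hits = hits,
                 null_counts = null_counts,
                 null_mean = if (is.null(null_counts)) NULL else mean(null_counts)),
            class = "palindrome_report")
}

#' @export
print.palindrome_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("palindrome_report: %d palindromes | %d genes affected (%.2f%%)\n",
              s$n_palindromes, s$n_genes_affected, s$percent_genes))
  if (!is.null(x$null_mean)) {
    cat(sprintf("  permutation null: %.2f palindromes/shuffle over %d shuffles\n",
                x$null_mean, length(x$null_counts)))
  }
  invisible(x)
}
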