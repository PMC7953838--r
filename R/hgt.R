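## Horizontal-gene-transfer candidate calling: each annotated protein is
## compared to a taxon-labelled reference set split into a metazoan and a
## non-metazoan partition. The hU index (best non-metazoan score minus best
## metazoan score) calls candidates; a scaffold-linkage rule controls for
## assembly contamination -- a candidate counts only when its scaffold also
## carries at least one gene of unambiguous metazoan origin.

#' Score gene origin against a labelled protein reference set
#'
#' For each query protein, the best local-alignment score against the
#' metazoan partition (`b_in`) and against the non-metazoan partition
#' (`b_out`) are computed by seeded Smith-Waterman; a missing side
#' contributes score 0. `hU = b_out - b_in`. Calls: `hgt_candidate` when
#' `hU >= threshold`, `metazoan` (unambiguous) when `hU <= -threshold`,
#' `ambiguous` otherwise, `no_hit` when neither partition hits.
#'
#' @param proteins named character vector of query proteins (or AA FASTA
#'   path).
#' @param db_seqs named character vector of reference proteins (or AA FASTA
#'   path).
#' @param db_labels data.frame with `record_id` and `label`
#'   (`metazoan` / `non-metazoan`), or a path to such a TSV.
#' @param threshold hU call threshold H in score units (default 30).
#' @param seed_word exact-word seed length (default 5).
#' @return data.frame of class `origin_scores`: `gene_id`, `b_in`, `b_out`,
#'   `hU`, `call`.
#' @export
score_gene_origin <- function(proteins, db_seqs, db_labels, threshold = 30,
                              seed_word = 5) {
  if (is.character(proteins) && length(proteins) == 1 && file.exists(proteins)) {
    proteins <- read_fasta(proteins, type = "AA")
  }
  if (is.character(db_seqs) && length(db_seqs) == 1 && file.exists(db_seqs)) {
    db_seqs <- read_fasta(db_seqs, type = "AA")
  }
  if (is.character(db_labels) && length(db_labels) == 1 && file.exists(db_labels)) {
    db_labels <- read.table(db_labels, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  }
  lab <- setNames(db_labels$label, db_labels$record_id)[names(db_seqs)]
  if (any(is.na(lab))) stop("reference records without a taxon label")
  if (!any(lab == "metazoan") || !any(lab == "non-metazoan")) {
    stop("both a metazoan and a non-metazoan reference partition are required")
  }
  idx <- word_index(db_seqs, seed_word)
  cand <- seed_candidates(proteins, idx, seed_word)
  b_in <- b_out <- rep(0, length(proteins))
  hit_any <- rep(FALSE, length(proteins))
  ## group alignments by subject for vectorized calls
  pairs <- do.call(rbind, lapply(seq_along(proteins), function(i) {
    if (length(cand[[i]]) == 0) NULL else data.frame(i = i, j = cand[[i]])
  }))
  if (!is.null(pairs) && nrow(pairs) > 0) {
    for (j in unique(pairs$j)) {
      is_ <- pairs$i[pairs$j == j]
      hits <- local_align(proteins[is_], db_seqs[[j]], type = "AA")
      ev <- evalue(hits$score, nchar(proteins[is_]), nchar(db_seqs[[j]]))
      ok <- ev <= 1e-3
      if (!any(ok)) next
      hit_any[is_[ok]] <- TRUE
      if (lab[[j]] == "metazoan") {
        b_in[is_[ok]] <- pmax(b_in[is_[ok]], hits$score[ok])
      } else {
        b_out[is_[ok]] <- pmax(b_out[is_[ok]], hits$score[ok])
      }
    }
  }
  hU <- ifelse(hit_any, b_out - b_in, NA_real_)
  call <- ifelse(!hit_any, "no_hit",
          ifelse(hU >= threshold, "hgt_candidate",
          ifelse(hU <= -threshold, "metazoan", "ambiguous")))
  structure(data.frame(gene_id = names(proteins), b_in = b_in, b_out = b_out,
                       hU = hU, call = call, stringsAsFactors = FALSE),
            class = c("origin_scores", "data.frame"))
}

#' Scaffold-linkage contamination filter and HGT report
#'
#' A prefilter candidate (`call == "hgt_candidate"`) is retained only when
#' its scaffold also encodes at least one gene of unambiguous metazoan
#' origin (`call == "metazoan"`); scaffolds made up entirely of foreign
#' genes therefore contribute zero linked candidates.
#'
#' @param origin_scores an `origin_scores` data.frame.
#' @param genes gene records mapping every gene to a scaffold.
#' @return an object of class `hgt_report`: `n_genes_total`,
#'   `n_candidates_prefilter`, `n_candidates_linked`, `hgt_c_percent`,
#'   `per_scaffold` (tallies), `linked_candidates` (gene ids).
#' @export
linkage_filter <- function(origin_scores, genes) {
  scf <- setNames(genes$scaffold, genes$gene_id)[origin_scores$gene_id]
  if (any(is.na(scf))) {
    stop("gene(s) without a scaffold mapping: ",
         paste(head(origin_scores$gene_id[is.na(scf)], 3), collapse = ", "))
  }
  meta_scf <- unique(scf[origin_scores$call == "metazoan"])
  is_cand <- origin_scores$call == "hgt_candidate"
  linked <- is_cand & scf %in% meta_scf
  per_scaffold <- do.call(rbind, lapply(split(seq_along(scf), scf), function(ii) {
    data.frame(n_genes = length(ii),
               n_metazoan = sum(origin_scores$call[ii] == "metazoan"),
               n_candidates = sum(is_cand[ii]),
               n_linked = sum(linked[ii]))
  }))
  per_scaffold <- data.frame(scaffold = rownames(per_scaffold), per_scaffold,
                             row.names = NULL, stringsAsFactors = FALSE)
  n_total <- nrow(origin_scores)
  structure(list(n_genes_total = n_total,
                 n_candidates_prefilter = sum(is_cand),
                 n_candidates_linked = sum(linked),
                 hgt_c_percent = 100 * sum(linked) / n_total,
                 per_scaffold = per_scaffold,
                 linked_candidates = origin_scores$gene_id[linked]),
            class = "hgt_report")
}

#' @export
print.hgt_report <- function(x, ...) {
  cat(sprintf("hgt_report: %d/%d genes are linked HGT candidates (HGT_C = %.2f%%; %d before linkage filter)\n",
              x$n_candidates_linked, x$n_genes_total, x$hgt_c_percent,
              x$n_candidates_prefilter))
  invisible(x)
}

#' Full HGT-candidate scan
#'
#' Runs [score_gene_origin()] and [linkage_filter()].
#'
#' @param proteins query proteins (named character or AA FASTA path).
#' @param genes gene records (data.frame or GFF3 path).
#' @param db_seqs labelled reference proteins (named character or FASTA path).
#' @param db_labels label table (data.frame or TSV path).
#' @param threshold hU threshold H (default 30).
#' @return an `hgt_report` with the `origin_scores` attached as
#'   `$origin_scores`.
#' @export
hgt_scan <- function(proteins, genes, db_seqs, db_labels, threshold = 30) {
  if (is.character(genes) && length(genes) == 1) genes <- read_gene_records(genes)
  scores <- score_gene_origin(proteins, db_seqs, db_labels, threshold)
  rep <- linkage_filter(scores, genes)
  rep$origin_scores <- scores
  rep
}
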