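## Per-locus heterozygosity structure: families of canonical k-mers that
## differ at exactly one aligned position reveal how many genome copies carry
## each allele of a locus. In a triploid, a biallelic locus where the
## alternative allele sits on a single haplotype produces coverages
## (lambda, 2*lambda) (AAB); a triallelic locus produces three k-mers at
## lambda each.

#' Extract heterozygous k-mer families from a count table
#'
#' Groups canonical k-mers that differ at exactly one aligned position (same
#' flanks, either relative orientation). Only k-mers with coverage between
#' the error cutoff and `ploidy*lambda + 4*sqrt(ploidy*lambda*(1+rho))` (4
#' negative-binomial standard deviations above the highest peak) take part;
#' families with more than `max_members` members are discarded as
#' repeat-induced.
#'
#' @param spectrum a `kmer_spectrum` built with `keep_table = TRUE`.
#' @param lambda_cov haploid per-copy k-mer coverage (from [fit_spectrum()]).
#' @param error_cutoff coverage cutoff (default [error_cutoff()]).
#' @param ploidy genome ploidy.
#' @param rho overdispersion used for the upper coverage bound.
#' @param max_members families exceeding this size are discarded (default 6).
#' @return data.frame of class `het_families`: `family`, `kmer`, `coverage`.
#' @export
extract_het_families <- function(spectrum, lambda_cov, error_cutoff = NULL,
                                 ploidy = 2, rho = 1, max_members = 6) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (is.null(spectrum$table)) {
    stop("spectrum has no k-mer count table; rerun count_kmers() with ",
         "keep_table = TRUE")
  }
  stopifnot(lambda_cov > 0)
  cutoff <- if (is.null(error_cutoff)) error_cutoff(spectrum) else error_cutoff
  upper <- ploidy * lambda_cov + 4 * sqrt(ploidy * lambda_cov * (1 + rho))
  tab <- spectrum$table
  keep <- tab$count >= cutoff & tab$count <= upper
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0) {
    return(structure(data.frame(family = integer(0), kmer = character(0),
                                coverage = numeric(0)),
                     class = c("het_families", "data.frame")))
  }
  fam <- cpp_het_families(tab$kmer, spectrum$k)
  out <- data.frame(family = fam, kmer = tab$kmer, coverage = tab$count,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$family), , drop = FALSE]
  if (nrow(out) > 0) {
    sizes <- table(out$family)
    small <- as.integer(names(sizes)[sizes <= max_members])
    out <- out[out$family %in% small, , drop = FALSE]
    out$family <- match(out$family, sort(unique(out$family)))
    out <- out[order(out$family, -out$coverage), ]
    rownames(out) <- NULL
  }
  structure(out, class = c("het_families", "data.frame"))
}

HET_TEMPLATES <- list(AB = c(1, 1), AAB = c(1, 2), AABB = c(2, 2), AAAB = c(1, 3))

## classify one 2-member family by nearest expected coverage configuration
classify_pair <- function(c_low, c_high, lambda_cov, max_dev = 0.35) {
  devs <- vapply(HET_TEMPLATES, function(tpl) {
    e <- tpl * lambda_cov
    abs(c_low - e[1]) / e[1] + abs(c_high - e[2]) / e[2]
  }, 0)
  bestn <- names(which.min(devs))
  e <- HET_TEMPLATES[[bestn]] * lambda_cov
  member_dev <- c(abs(c_low - e[1]) / e[1], abs(c_high - e[2]) / e[2])
  if (any(member_dev > max_dev)) "AMBIGUOUS" else bestn
}

#' Classify heterozygous k-mer families into allele structures
#'
#' Two-member families are assigned the nearest expected coverage
#' configuration among AB = (lambda, lambda), AAB = (lambda, 2 lambda),
#' AABB = (2 lambda, 2 lambda) and AAAB = (lambda, 3 lambda) by minimum
#' summed relative deviation; a relative deviation above `max_dev` on any
#' member makes the family AMBIGUOUS. Families with three or more members
#' are multiallelic (MULTI). The summary reports fractions relative to
#' classified (non-AMBIGUOUS) families: `biallelic_single_copy` (AAB/AAAB,
#' the alternative allele on a single haplotype), `biallelic_balanced`
#' (AABB), `multiallelic`, and `diploid_AB`.
#'
#' @param families a `het_families` data.frame.
#' @param lambda_cov haploid per-copy k-mer coverage.
#' @param max_dev per-member relative-deviation bound (default 0.35).
#' @return an object of class `structure_summary`: `fractions`,
#'   `n_families`, `n_classified`, `counts` (per raw label), and
#'   `classification` (per-family label vector).
#' @export
classify_structures <- function(families, lambda_cov, max_dev = 0.35) {
  stopifnot(lambda_cov > 0)
  groups <- if (nrow(families) > 0) split(families$coverage, families$family)
            else list()
  labels <- vapply(groups, function(cv) {
    if (length(cv) >= 3) return("MULTI")
    cv <- sort(cv)
    classify_pair(cv[1], cv[2], lambda_cov, max_dev)
  }, "")
  counts <- table(factor(labels, levels = c("AB", "AAB", "AABB", "AAAB",
                                            "MULTI", "AMBIGUOUS")))
  classified <- labels[labels != "AMBIGUOUS"]
  n_cl <- length(classified)
  fractions <- if (n_cl > 0) {
    c(biallelic_single_copy = sum(classified %in% c("AAB", "AAAB")) / n_cl,
      biallelic_balanced = sum(classified == "AABB") / n_cl,
      multiallelic = sum(classified == "MULTI") / n_cl,
      diploid_AB = sum(classified == "AB") / n_cl)
  } else {
    c(biallelic_single_copy = NA_real_, biallelic_balanced = NA_real_,
      multiallelic = NA_real_, diploid_AB = NA_real_)
  }
  structure(list(fractions = fractions, n_families = length(labels),
                 n_classified = n_cl, counts = counts,
                 classification = labels),
            class = "structure_summary")
}

#' @export
print.structure_summary <- function(x, ...) {
  cat("structure_summary:", x$n_families, "families,", x$n_classified,
      "classified\n")
  if (x$n_classified > 0) {
    for (nm in names(x$fractions)) {
      cat(sprintf("  %-22s %.1f%%\n", nm, 100 * x$fractions[[nm]]))
    }
  } else {
    cat("  no classified families (fractions undefined)\n")
  }
  invisible(x)
}
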