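## Multi-haplotype genome simulation with prescribed divergence topologies.
##
## A topology is a string of haplotype letters (e.g. "AAB"): identical letters
## denote byte-identical genome copies, distinct letters are separated by
## substitutions drawn at the per-site rates of the topology's divergence
## layers. Variant sites are substitutions only; indels are out of scope.

TOPOLOGIES <- list(
  AB   = list(ploidy = 2, layers = "allelic"),
  AAB  = list(ploidy = 3, layers = c("homoeolog", "allelic")),
  AAAB = list(ploidy = 4, layers = "homoeolog"),
  AABB = list(ploidy = 4, layers = "homoeolog"),
  ABC  = list(ploidy = 3, layers = c("one_hap", "triallelic")),
  ABCD = list(ploidy = 4, layers = c("one_hap", "all_distinct"))
)

#' Specification of a synthetic multi-haplotype genome
#'
#' Defines the ancestral sequence and the divergence structure between the
#' genome copies of a (possibly polyploid) individual.
#'
#' Divergence layers per topology (all rates are per-site substitution
#' probabilities, at most one layer hits a given site):
#' * `AB`: `allelic` -- the two alleles differ.
#' * `AAB`: `homoeolog` -- the single B copy carries a derived allele
#'   (the two A copies stay identical); optional `allelic` -- one of the two
#'   A copies carries a derived allele.
#' * `AAAB`: `homoeolog` -- the B copy carries a derived allele.
#' * `AABB`: `homoeolog` -- the B pair differs from the A pair.
#' * `ABC`: `one_hap` -- exactly one of the three copies (chosen uniformly)
#'   carries a derived allele; `triallelic` -- all three copies carry
#'   mutually distinct alleles.
#' * `ABCD`: `one_hap` -- one of the four copies carries a derived allele;
#'   `all_distinct` -- all four copies differ.
#'
#' @param ancestral_length length of the ancestral sequence in bp.
#' @param ploidy integer in 2..4; must equal the number of letters in
#'   `topology`.
#' @param topology one of `"AB"`, `"AAB"`, `"AAAB"`, `"AABB"`, `"ABC"`,
#'   `"ABCD"`.
#' @param het_rates named numeric vector of per-site rates, names drawn from
#'   the topology's layers (missing layers default to 0). All rates must lie
#'   in \[0, 0.35\].
#' @param gc_content GC fraction of the ancestral sequence.
#' @param seed integer seed; the simulation is a pure function of the spec.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(ancestral_length, ploidy, topology, het_rates,
                        gc_content = 0.5, seed = 1L) {
  topology <- match.arg(topology, names(TOPOLOGIES))
  info <- TOPOLOGIES[[topology]]
  if (ploidy != nchar(topology)) {
    stop("ploidy (", ploidy, ") must equal the number of haplotype letters in '",
         topology, "'")
  }
  if (ploidy != info$ploidy) stop("unsupported ploidy for topology ", topology)
  het_rates <- unlist(het_rates)
  if (length(het_rates) > 0) {
    bad <- setdiff(names(het_rates), info$layers)
    if (length(bad) > 0) {
      stop("unknown divergence layer(s) for ", topology, ": ",
           paste(bad, collapse = ", "), " (expected: ",
           paste(info$layers, collapse = ", "), ")")
    }
  }
  rates <- setNames(rep(0, length(info$layers)), info$layers)
  rates[names(het_rates)] <- het_rates
  if (any(rates < 0 | rates > 0.35)) stop("all het_rates must be in [0, 0.35]")
  if (sum(rates) > 0.35) stop("summed het_rates exceed 0.35")
  if (ancestral_length < 10 * 31) stop("ancestral_length too short")
  structure(list(ancestral_length = as.integer(ancestral_length),
                 ploidy = as.integer(ploidy), topology = topology,
                 het_rates = rates, gc_content = gc_content,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

## draw derived alleles distinct from the ancestral base at the given sites
derived_alleles <- function(anc_bases) {
  alt <- matrix(DNA_BASES[t(vapply(anc_bases, function(b) which(DNA_BASES != b),
                                   integer(3)))], ncol = 3)
  alt[cbind(seq_along(anc_bases), sample.int(3, length(anc_bases), replace = TRUE))]
}

#' Simulate the haplotypes of a synthetic genome
#'
#' Generates one sequence per haplotype letter of the topology; identical
#' letters (e.g. the two A copies of AAB) are byte-identical, distinct letters
#' differ by independent per-site substitutions at the layer rates of the
#' spec. Every variant site is recorded in a truth table.
#'
#' @param spec a [genome_spec()].
#' @return a list of class `haplotype_set` with elements `haplotypes` (named
#'   character vector, one sequence per genome copy, names like `"A1"`,
#'   `"A2"`, `"B1"`), `letters` (the distinct letters with their copy
#'   numbers), `truth` (data.frame: `pos` 1-based, `layer`, and the allele of
#'   each distinct letter), and `spec`.
#' @export
simulate_haplotypes <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  L <- spec$ancestral_length
  gc <- spec$gc_content
  anc <- sample(DNA_BASES, L, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  letters_uniq <- unique(str_chars(spec$topology))
  copy_number <- table(factor(str_chars(spec$topology), levels = letters_uniq))
  seqs <- setNames(rep(list(anc), length(letters_uniq)), letters_uniq)

  rates <- spec$het_rates
  ## partition sites into layers (at most one layer per site)
  u <- runif(L)
  cuts <- cumsum(rates)
  layer_of <- rep(NA_character_, L)
  lo <- 0
  for (ly in names(rates)) {
    layer_of[u > lo & u <= cuts[[ly]]] <- ly
    lo <- cuts[[ly]]
  }
  sites <- which(!is.na(layer_of))
  truth <- NULL
  if (length(sites) > 0) {
    allele_mat <- matrix(rep(anc[sites], length(letters_uniq)),
                         ncol = length(letters_uniq),
                         dimnames = list(NULL, letters_uniq))
    for (ly in names(rates)) {
      idx <- which(layer_of[sites] == ly)
      if (length(idx) == 0) next
      anc_b <- anc[sites[idx]]
      der <- derived_alleles(anc_b)
      topo <- spec$topology
      if (ly == "allelic" && topo == "AB") {
        allele_mat[idx, "B"] <- der
      } else if (ly == "homoeolog") {
        allele_mat[idx, "B"] <- der
      } else if (ly == "allelic" && topo == "AAB") {
        ## one of the two A copies diverges; realized below by splitting A
        allele_mat[idx, "A"] <- paste0(anc_b, ">", der) # marker, resolved later
      } else if (ly == "one_hap") {
        hap <- sample(letters_uniq, length(idx), replace = TRUE)
        for (h in letters_uniq) {
          sel <- hap == h
          if (any(sel)) allele_mat[idx[sel], h] <- der[sel]
        }
      } else if (ly == "triallelic" || ly == "all_distinct") {
        nl <- length(letters_uniq)
        picks <- t(vapply(seq_along(idx), function(i) sample(DNA_BASES, nl),
                          character(nl)))
        allele_mat[idx, ] <- picks
      } else {
        stop("unhandled layer ", ly, " for topology ", topo)
      }
    }
    truth <- data.frame(pos = sites, layer = layer_of[sites],
                        allele_mat, stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(pos = integer(0), layer = character(0))
  }

  ## materialize per-copy sequences
  haps <- list()
  aab_allelic <- spec$topology == "AAB" && rates[["allelic"]] > 0
  for (h in letters_uniq) {
    x <- seqs[[h]]
    if (nrow(truth) > 0) {
      al <- truth[[h]]
      plain <- !grepl(">", al, fixed = TRUE)
      x[truth$pos[plain]] <- al[plain]
    }
    for (ci in seq_len(copy_number[[h]])) {
      xc <- x
      if (aab_allelic && h == "A" && nrow(truth) > 0) {
        marked <- grepl(">", truth$A, fixed = TRUE)
        if (any(marked)) {
          der <- sub("^.>", "", truth$A[marked])
          anc_b <- sub(">.$", "", truth$A[marked])
          xc[truth$pos[marked]] <- if (ci == 1) der else anc_b
        }
      }
      haps[[paste0(h, ci)]] <- paste(xc, collapse = "")
    }
  }
  structure(list(haplotypes = unlist(haps),
                 letters = as.integer(copy_number),
                 letter_names = letters_uniq,
                 truth = truth, spec = spec),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", x$spec$topology, "genome,",
      x$spec$ancestral_length, "bp ancestor,",
      nrow(x$truth), "variant sites\n")
  invisible(x)
}
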