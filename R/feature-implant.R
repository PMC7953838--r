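## Implantation of genome features with exact truth tables: TE copies up to a
## target genomic fraction, palindromic gene cassettes (a cassette and its
## reverse-complement copy on one scaffold), foreign (non-metazoan) genes on
## host scaffolds, and contaminant-only scaffolds. All features are modelled
## as insertions into the collapsed haploid assembly, so implants can never
## overlap and every coordinate is known exactly.

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

GENETIC_CODE_MAP <- local({
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(SENSE_CODONS)))
  setNames(aa, SENSE_CODONS)
})
## one representative codon per amino acid, for back-translation
BACK_CODON <- local({
  m <- GENETIC_CODE_MAP
  setNames(names(m)[!duplicated(m)], m[!duplicated(m)])
})

random_orf <- function(len) {
  stopifnot(len %% 3 == 0)
  paste(sample(SENSE_CODONS, len / 3, replace = TRUE), collapse = "")
}

translate_orf <- function(dna) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(dna)))
}

back_translate <- function(aa) {
  vapply(aa, function(p) paste(BACK_CODON[str_chars(p)], collapse = ""), "",
         USE.NAMES = FALSE)
}

random_protein <- function(len) {
  paste(sample(names(BACK_CODON), len, replace = TRUE), collapse = "")
}

## substitute bases i.i.d. at the given per-site rate
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- str_chars(seq)
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0) {
    chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(DNA_BASES, b), 1), "")
  }
  paste(chars, collapse = "")
}

#' Plan of features to implant into a synthetic assembly
#'
#' @param te_library named character vector of repeat consensus sequences;
#'   names must follow the RepeatMasker convention `name#Class/Family`.
#' @param te_target_fraction target fraction of the final assembly occupied
#'   by implanted TE copies, in \[0, 0.6\].
#' @param n_genes number of host genes (uniformly random ORFs).
#' @param palindrome_implants list of palindrome specs, each a list with
#'   `n_genes` (cassette gene count) and optionally `scaffold`; a bare integer
#'   vector of cassette sizes is also accepted.
#' @param hgt_implants number of foreign genes placed on host scaffolds
#'   (requires `n_genes >= 1`).
#' @param contaminant_scaffolds number of extra scaffolds carrying only
#'   foreign genes.
#' @param gene_length host gene length in bp (multiple of 3).
#' @param intergenic spacer length between cassette genes.
#' @param te_max_divergence maximum per-copy divergence from the library
#'   consensus (per copy drawn uniformly in \[0, max\]).
#' @param te_max_truncation maximum truncated fraction per TE copy.
#' @param n_foreign_pool size of the non-metazoan reference protein pool
#'   (default: enough for all foreign implants plus 10 decoys).
#' @return an object of class `feature_plan`.
#' @export
feature_plan <- function(te_library = NULL, te_target_fraction = 0,
                         n_genes = 0, palindrome_implants = list(),
                         hgt_implants = 0, contaminant_scaffolds = 0,
                         gene_length = 900, intergenic = 50,
                         te_max_divergence = 0.1, te_max_truncation = 0.5,
                         n_foreign_pool = NULL) {
  if (te_target_fraction < 0 || te_target_fraction > 0.6) {
    stop("te_target_fraction must be in [0, 0.6]")
  }
  if (gene_length %% 3 != 0) stop("gene_length must be a multiple of 3")
  if (is.numeric(palindrome_implants)) {
    palindrome_implants <- lapply(palindrome_implants,
                                  function(m) list(n_genes = as.integer(m)))
  }
  if (hgt_implants > 0 && n_genes < 1) {
    stop("hgt_implants requires at least one host gene (n_genes >= 1)")
  }
  if (is.null(n_foreign_pool)) {
    n_foreign_pool <- hgt_implants + 3 * contaminant_scaffolds + 10
  }
  structure(list(te_library = te_library,
                 te_target_fraction = te_target_fraction,
                 n_genes = as.integer(n_genes),
                 palindrome_implants = palindrome_implants,
                 hgt_implants = as.integer(hgt_implants),
                 contaminant_scaffolds = as.integer(contaminant_scaffolds),
                 gene_length = as.integer(gene_length),
                 intergenic = as.integer(intergenic),
                 te_max_divergence = te_max_divergence,
                 te_max_truncation = te_max_truncation,
                 n_foreign_pool = as.integer(n_foreign_pool)),
            class = "feature_plan")
}

## collapse a haplotype_set to the haploid assembly representation:
## one scaffold per homoeolog group (diploid AB collapses to A alone)
collapse_assembly <- function(haps) {
  if (is.character(haps)) {
    if (is.null(names(haps))) names(haps) <- paste0("scf_", seq_along(haps))
    return(haps)
  }
  stopifnot(inherits(haps, "haplotype_set"))
  letters_uniq <- haps$letter_names
  if (haps$spec$topology == "AB") letters_uniq <- "A"
  setNames(haps$haplotypes[paste0(letters_uniq, "1")],
           paste0("scf_", letters_uniq))
}

#' Implant TEs, palindromes and foreign genes into a synthetic assembly
#'
#' Collapses a haplotype set to a haploid assembly (or takes scaffolds
#' directly), then inserts the features described by the plan. Every implant
#' is recorded in a truth table whose coordinates refer to the final emitted
#' assembly (0-based half-open; GFF3 output is 1-based inclusive).
#'
#' A labelled protein reference set is generated alongside: host-gene
#' proteins form the metazoan partition and the foreign pool (a superset of
#' all implanted foreign proteins) forms the non-metazoan partition, so that
#' HGT calling can be validated with exact truth.
#'
#' @param haplotypes a `haplotype_set` or a named character vector of
#'   scaffolds.
#' @param plan a [feature_plan()].
#' @param seed integer seed.
#' @return an object of class `implanted_genome`: `assembly` (named character
#'   scaffolds), `genes` (gene records with 0-based half-open `start`/`end`,
#'   `strand`, `rank`, `type`), `proteins` (named character),
#'   `read_templates` (per-genome-copy sequences carrying every implant,
#'   the right substrate for [simulate_reads()]; `NULL` when raw scaffolds
#'   were supplied), truth tables `te_truth`, `palindrome_truth`,
#'   `hgt_truth`, and `ref_db` (list with `seqs` and `labels`).
#' @export
implant_features <- function(haplotypes, plan = feature_plan(), seed = 1L) {
  stopifnot(inherits(plan, "feature_plan"))
  set.seed(seed)
  scaffolds <- collapse_assembly(haplotypes)
  base_len <- nchar(scaffolds)

  ## ---- foreign protein pool (non-metazoan reference partition) ----
  aa_len <- plan$gene_length / 3
  n_pool <- max(plan$n_foreign_pool,
                plan$hgt_implants + 3 * plan$contaminant_scaffolds)
  foreign_pool <- if (n_pool > 0) {
    setNames(vapply(seq_len(n_pool), function(i) random_protein(aa_len), ""),
             sprintf("foreign_%04d", seq_len(n_pool)))
  } else character(0)
  pool_cursor <- 0L
  next_pool <- function(n) {
    idx <- pool_cursor + seq_len(n)
    pool_cursor <<- pool_cursor + n
    idx
  }

  ## ---- contaminant scaffolds (built before insertion planning) ----
  contam_events <- list()
  if (plan$contaminant_scaffolds > 0) {
    for (ci in seq_len(plan$contaminant_scaffolds)) {
      nm <- sprintf("contam_%02d", ci)
      backbone <- paste(sample(DNA_BASES, 4000, replace = TRUE), collapse = "")
      scaffolds[nm] <- backbone
      base_len[nm] <- nchar(backbone)
    }
  }

  ## insertion events per scaffold: base_pos (0-based, insert after this many
  ## bases of the base scaffold), seq, type, payload
  events <- setNames(vector("list", length(scaffolds)), names(scaffolds))
  add_event <- function(scf, base_pos, seq, type, payload = NULL) {
    events[[scf]][[length(events[[scf]]) + 1L]] <<-
      list(base_pos = base_pos, seq = seq, type = type, payload = payload)
  }
  host_scfs <- setdiff(names(scaffolds), grep("^contam_", names(scaffolds), value = TRUE))
  rand_pos <- function(scf) sample.int(base_len[[scf]] + 1L, 1L) - 1L

  proteins <- character(0)
  gene_meta <- list() # filled per gene when events are linearized

  ## ---- host genes ----
  if (plan$n_genes > 0) {
    gene_scf <- sample(host_scfs, plan$n_genes, replace = TRUE,
                       prob = base_len[host_scfs])
    for (gi in seq_len(plan$n_genes)) {
      gid <- sprintf("gene_%04d", gi)
      dna <- random_orf(plan$gene_length)
      proteins[gid] <- translate_orf(dna)
      add_event(gene_scf[gi], rand_pos(gene_scf[gi]), dna, "gene",
                list(genes = data.frame(gene_id = gid, offset = 0L,
                                        len = plan$gene_length, strand = "+",
                                        type = "host")))
    }
  }

  ## ---- palindrome implants: cassette + reverse-complement copy ----
  pal_truth <- list()
  if (length(plan$palindrome_implants) > 0) {
    n_pal <- length(plan$palindrome_implants)
    ## spread implants over scaffolds: nested palindromes on one scaffold
    ## would otherwise chain into a single (legitimate) merged block
    auto_scf <- sample(host_scfs, n_pal, replace = n_pal > length(host_scfs))
    for (pi in seq_along(plan$palindrome_implants)) {
      p <- plan$palindrome_implants[[pi]]
      m <- p$n_genes
      scf <- if (!is.null(p$scaffold)) p$scaffold else auto_scf[pi]
      if (!scf %in% names(scaffolds)) stop("unknown scaffold in palindrome implant: ", scf)
      glen <- plan$gene_length
      gdna <- vapply(seq_len(m), function(i) random_orf(glen), "")
      spacer <- if (m > 1) {
        vapply(seq_len(m - 1), function(i)
          paste(sample(DNA_BASES, plan$intergenic, replace = TRUE), collapse = ""), "")
      } else character(0)
      block <- paste(c(rbind(gdna, c(spacer, ""))), collapse = "")
      offs <- (seq_len(m) - 1L) * (glen + plan$intergenic)
      B <- nchar(block)
      left_ids <- sprintf("pal%d_g%d_a", pi, seq_len(m))
      right_ids <- sprintf("pal%d_g%d_b", pi, seq_len(m))
      for (i in seq_len(m)) {
        proteins[left_ids[i]] <- translate_orf(gdna[i])
        proteins[right_ids[i]] <- proteins[left_ids[i]]
      }
      ## the two arms flank a spacer that carries one (host-type) gene, as in
      ## real palindromes; this also keeps the innermost anchor pair clear of
      ## the tandem-proximity exclusion of the palindrome scan
      pos <- sort(sample.int(base_len[[scf]] - 1L, 3L) - 1L)
      add_event(scf, pos[1], block, "pal_left",
                list(pal = pi, genes = data.frame(
                  gene_id = left_ids, offset = offs, len = glen,
                  strand = "+", type = "palindrome")))
      sp_id <- sprintf("pal%d_spacer", pi)
      sp_dna <- random_orf(plan$gene_length)
      proteins[sp_id] <- translate_orf(sp_dna)
      add_event(scf, pos[2], sp_dna, "gene",
                list(genes = data.frame(gene_id = sp_id, offset = 0L,
                                        len = plan$gene_length, strand = "+",
                                        type = "host")))
      add_event(scf, pos[3], revcomp(block), "pal_right",
                list(pal = pi, genes = data.frame(
                  gene_id = right_ids, offset = B - (offs + glen), len = glen,
                  strand = "-", type = "palindrome")))
      pal_truth[[pi]] <- data.frame(pal_id = pi, scaffold = scf, n_genes = 2L * m)
    }
  }

  ## ---- HGT implants: foreign genes on host scaffolds ----
  hgt_truth <- NULL
  if (plan$hgt_implants > 0) {
    idx <- next_pool(plan$hgt_implants)
    src <- names(foreign_pool)[idx]
    ## place only on scaffolds that actually carry a host gene
    host_with_genes <- host_scfs[vapply(events[host_scfs], function(ev)
      any(vapply(ev, function(e) e$type == "gene", TRUE)), TRUE)]
    if (length(host_with_genes) == 0) stop("no host scaffold carries a host gene")
    hg_scf <- sample(host_with_genes, plan$hgt_implants, replace = TRUE)
    rows <- list()
    for (i in seq_len(plan$hgt_implants)) {
      gid <- sprintf("hgt_%04d", i)
      proteins[gid] <- foreign_pool[[idx[i]]]
      add_event(hg_scf[i], rand_pos(hg_scf[i]), back_translate(proteins[gid]),
                "gene", list(genes = data.frame(gene_id = gid, offset = 0L,
                                                len = plan$gene_length,
                                                strand = "+", type = "hgt")))
      rows[[i]] <- data.frame(gene_id = gid, scaffold = hg_scf[i],
                              source_record = src[i])
    }
    hgt_truth <- do.call(rbind, rows)
  }

  ## ---- contaminant genes ----
  if (plan$contaminant_scaffolds > 0) {
    for (ci in seq_len(plan$contaminant_scaffolds)) {
      nm <- sprintf("contam_%02d", ci)
      idx <- next_pool(3L)
      for (j in seq_along(idx)) {
        gid <- sprintf("contam%d_g%d", ci, j)
        proteins[gid] <- foreign_pool[[idx[j]]]
        add_event(nm, rand_pos(nm), back_translate(proteins[gid]), "gene",
                  list(genes = data.frame(gene_id = gid, offset = 0L,
                                          len = plan$gene_length,
                                          strand = "+", type = "contaminant")))
      }
    }
  }

  ## ---- TE copies up to the target fraction ----
  te_rows <- list()
  if (plan$te_target_fraction > 0) {
    lib <- plan$te_library
    if (is.null(lib) || length(lib) == 0 || all(nchar(lib) == 0)) {
      stop("te_target_fraction > 0 requires a non-empty te_library")
    }
    gene_nt <- sum(vapply(unlist(events, recursive = FALSE),
                          function(e) nchar(e$seq), 0))
    non_te <- sum(base_len) + gene_nt
    te_needed <- plan$te_target_fraction / (1 - plan$te_target_fraction) * non_te
    te_nt <- 0
    it <- 0L
    while (te_nt < te_needed) {
      it <- it + 1L
      if (it > 100000L) stop("target TE fraction unreachable with given library")
      li <- sample.int(length(lib), 1L)
      src <- lib[[li]]
      keep <- runif(1, 1 - plan$te_max_truncation, 1)
      tlen <- max(50L, as.integer(round(nchar(src) * keep)))
      tstart <- sample.int(nchar(src) - tlen + 1L, 1L)
      copy <- substr(src, tstart, tstart + tlen - 1L)
      div <- runif(1, 0, plan$te_max_divergence)
      copy <- mutate_seq(copy, div)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") copy <- revcomp(copy)
      scf <- sample(host_scfs, 1L, prob = base_len[host_scfs])
      hdr <- names(lib)[li]
      add_event(scf, rand_pos(scf), copy, "te",
                list(te = data.frame(src = hdr, len = nchar(copy),
                                     divergence = div, truncation = 1 - keep,
                                     strand = strand)))
      te_nt <- te_nt + nchar(copy)
    }
  }

  ## ---- linearize: build final scaffolds and final coordinates ----
  splice_events <- function(base, ev) {
    pieces <- character(2L * length(ev) + 1L)
    prev <- 0L
    for (i in seq_along(ev)) {
      pieces[2L * i - 1L] <- substr(base, prev + 1L, ev[[i]]$base_pos)
      pieces[2L * i] <- ev[[i]]$seq
      prev <- ev[[i]]$base_pos
    }
    pieces[2L * length(ev) + 1L] <- substr(base, prev + 1L, nchar(base))
    paste(pieces, collapse = "")
  }
  events_sorted <- lapply(events, function(ev) {
    if (length(ev) == 0) return(ev)
    ev[order(vapply(ev, function(e) e$base_pos, 0))]
  })
  genes_out <- list()
  te_out <- list()
  pal_blocks <- list() # pal id -> left/right block final coords
  for (scf in names(scaffolds)) {
    ev <- events_sorted[[scf]]
    if (length(ev) == 0) next
    shift <- 0L
    for (i in seq_along(ev)) {
      e <- ev[[i]]
      fstart <- e$base_pos + shift # 0-based final start of the inserted block
      if (e$type %in% c("gene", "pal_left", "pal_right")) {
        g <- e$payload$genes
        g$scaffold <- scf
        g$start <- fstart + g$offset
        g$end <- g$start + g$len
        genes_out[[length(genes_out) + 1L]] <- g
        if (e$type != "gene") {
          key <- paste0(e$payload$pal, "_", sub("pal_", "", e$type))
          pal_blocks[[key]] <- c(fstart, fstart + nchar(e$seq))
        }
      } else if (e$type == "te") {
        t <- e$payload$te
        t$scaffold <- scf
        t$start <- fstart
        t$end <- fstart + t$len
        te_out[[length(te_out) + 1L]] <- t
      }
      shift <- shift + nchar(e$seq)
    }
    scaffolds[[scf]] <- splice_events(scaffolds[[scf]], ev)
  }

  ## ---- per-copy read templates ----
  ## each genome copy of the source individual carries every implant
  ## (homozygous insertions), so simulated reads expose both the divergence
  ## layers and the implanted repeats
  read_templates <- NULL
  if (inherits(haplotypes, "haplotype_set")) {
    read_templates <- character(0)
    for (copy in names(haplotypes$haplotypes)) {
      letter <- substr(copy, 1, 1)
      scf <- if (haplotypes$spec$topology == "AB") "scf_A"
             else paste0("scf_", letter)
      read_templates[[copy]] <-
        splice_events(haplotypes$haplotypes[[copy]], events_sorted[[scf]])
    }
    contam <- grep("^contam_", names(scaffolds), value = TRUE)
    for (nm in contam) read_templates[[nm]] <- scaffolds[[nm]]
  }

  genes <- if (length(genes_out) > 0) do.call(rbind, genes_out) else
    data.frame(gene_id = character(0), offset = integer(0), len = integer(0),
               strand = character(0), type = character(0),
               scaffold = character(0), start = integer(0), end = integer(0))
  if (nrow(genes) > 0) {
    genes <- genes[order(genes$scaffold, genes$start), ]
    genes$rank <- stats::ave(genes$start, genes$scaffold,
                             FUN = function(x) seq_along(x))
    genes <- genes[, c("gene_id", "scaffold", "start", "end", "strand",
                       "rank", "type")]
    rownames(genes) <- NULL
  }
  te_truth <- if (length(te_out) > 0) {
    x <- do.call(rbind, te_out)
    x$te_id <- sprintf("te_%05d", seq_len(nrow(x)))
    x$class <- te_class_of(x$src)
    x[, c("te_id", "scaffold", "start", "end", "strand", "src", "class",
          "divergence", "truncation")]
  } else {
    data.frame(te_id = character(0), scaffold = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               src = character(0), class = character(0),
               divergence = numeric(0), truncation = numeric(0))
  }
  palindrome_truth <- if (length(pal_truth) > 0) {
    pt <- do.call(rbind, pal_truth)
    pt$left_start <- vapply(pt$pal_id, function(i) pal_blocks[[paste0(i, "_left")]][1], 0)
    pt$left_end <- vapply(pt$pal_id, function(i) pal_blocks[[paste0(i, "_left")]][2], 0)
    pt$right_start <- vapply(pt$pal_id, function(i) pal_blocks[[paste0(i, "_right")]][1], 0)
    pt$right_end <- vapply(pt$pal_id, function(i) pal_blocks[[paste0(i, "_right")]][2], 0)
    pt
  } else NULL

  ## ---- labelled reference proteins ----
  host_prot <- proteins[genes$gene_id[genes$type %in% c("host", "palindrome")]]
  host_prot <- host_prot[!duplicated(host_prot)] # palindrome copies share one record
  host_nm <- if (length(host_prot) > 0) paste0("ref_", names(host_prot)) else character(0)
  db_seqs <- c(setNames(host_prot, host_nm), foreign_pool)
  db_labels <- data.frame(
    record_id = names(db_seqs),
    label = c(rep("metazoan", length(host_prot)),
              rep("non-metazoan", length(foreign_pool))),
    stringsAsFactors = FALSE)

  structure(list(assembly = scaffolds, genes = genes, proteins = proteins,
                 read_templates = read_templates,
                 te_truth = te_truth, palindrome_truth = palindrome_truth,
                 hgt_truth = hgt_truth,
                 ref_db = list(seqs = db_seqs, labels = db_labels),
                 plan = plan, seed = seed),
            class = "implanted_genome")
}

## RepeatMasker-style class parsing: "name#Class/Family" -> one of the five
## TE classes; RC/Helitron maps to Helitron; anything else is "other".
te_class_of <- function(headers) {
  cls <- ifelse(grepl("#", headers, fixed = TRUE),
                sub("^[^#]*#", "", headers), NA_character_)
  main <- sub("/.*$", "", cls)
  fam <- ifelse(grepl("/", cls, fixed = TRUE), sub("^[^/]*/", "", cls), "")
  out <- ifelse(main %in% c("DNA", "LINE", "SINE", "LTR", "Helitron"), main,
                ifelse(main == "RC" & fam == "Helitron", "Helitron", "other"))
  out[is.na(cls)] <- NA_character_
  out
}

#' @export
print.implanted_genome <- function(x, ...) {
  cat("implanted_genome:", length(x$assembly), "scaffolds,",
      sum(nchar(x$assembly)), "bp,", nrow(x$genes), "genes,",
      nrow(x$te_truth), "TE copies\n")
  invisible(x)
}

#' Export gene records as GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 output is 1-based
#' inclusive, with `ID=` attributes.
#'
#' @param genes gene-record data.frame (see [implant_features()]).
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$source <- "parthenoscan"
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read gene records from GFF3
#'
#' @param path GFF3 path.
#' @return gene-record data.frame with 0-based half-open `start`/`end` and
#'   per-scaffold `rank` (genes ordered by start).
#' @export
read_gene_records <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  genes <- data.frame(
    gene_id = as.character(S4Vectors::mcols(gr)$ID),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$scaffold, genes$start), ]
  genes$rank <- stats::ave(genes$start, genes$scaffold,
                           FUN = function(x) seq_along(x))
  rownames(genes) <- NULL
  genes
}

#' Write all files of an implanted genome to a directory
#'
#' Emits `assembly.fa`, `proteins.fa`, `genes.gff3`, the labelled reference
#' proteins (`ref_db.fa` + `ref_labels.tsv`) and TSV truth tables.
#'
#' @param x an `implanted_genome`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_genome_package <- function(x, dir) {
  stopifnot(inherits(x, "implanted_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(x$assembly, file.path(dir, "assembly.fa"))
  if (length(x$proteins) > 0) {
    write_fasta(x$proteins, file.path(dir, "proteins.fa"), type = "AA")
  }
  if (nrow(x$genes) > 0) write_gff3(x$genes, file.path(dir, "genes.gff3"))
  write_fasta(x$ref_db$seqs, file.path(dir, "ref_db.fa"), type = "AA")
  tsv <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(x$ref_db$labels, "ref_labels.tsv")
  tsv(x$genes, "truth_genes.tsv")
  tsv(x$te_truth, "truth_te.tsv")
  if (!is.null(x$palindrome_truth)) tsv(x$palindrome_truth, "truth_palindromes.tsv")
  if (!is.null(x$hgt_truth)) tsv(x$hgt_truth, "truth_hgt.tsv")
  invisible(dir)
}
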