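## Per-species orchestration: run the k-mer, TE, palindrome and HGT stages in
## dependency order from a config, write machine-readable intermediates, and
## aggregate per-species reports into a cross-species feature table.

#' Per-species pipeline configuration
#'
#' @param species species name.
#' @param reads FASTQ path(s) (or an in-memory read vector).
#' @param assembly assembly FASTA path (optional; coordinate validation only).
#' @param gff gene annotation GFF3 path (or gene-record data.frame).
#' @param proteins protein FASTA path (or named character vector).
#' @param ploidy,topology k-mer model assignment (user-supplied, from prior
#'   knowledge).
#' @param hybrid_origin `"hybrid"`, `"intraspecific"` or `"unknown"`.
#' @param mechanism cellular mechanism label (free text, e.g.
#'   `"functionally_mitotic"`, `"automixis"`).
#' @param te_library TE library FASTA path or named character vector.
#' @param hgt_db,hgt_labels labelled reference proteins for the HGT stage.
#' @param genome_size optional haploid genome-size override for TE
#'   subsampling (default: fitted G).
#' @param k k-mer size (default 21).
#' @param seeds named list/vector of integer seeds (`kmer`, `te`).
#' @return an object of class `species_config`.
#' @export
species_config <- function(species, reads = NULL, assembly = NULL, gff = NULL,
                           proteins = NULL, ploidy = 2, topology = "AB",
                           hybrid_origin = c("unknown", "hybrid", "intraspecific"),
                           mechanism = "unknown", te_library = NULL,
                           hgt_db = NULL, hgt_labels = NULL,
                           genome_size = NULL, k = 21,
                           seeds = list(kmer = 1L, te = 1L)) {
  hybrid_origin <- match.arg(hybrid_origin)
  if (!topology %in% names(TOPOLOGIES)) stop("unknown topology: ", topology)
  if (ploidy != TOPOLOGIES[[topology]]$ploidy) {
    stop("ploidy/topology inconsistent for species ", species)
  }
  structure(list(species = species, reads = reads, assembly = assembly,
                 gff = gff, proteins = proteins, ploidy = as.integer(ploidy),
                 topology = topology, hybrid_origin = hybrid_origin,
                 mechanism = mechanism, te_library = te_library,
                 hgt_db = hgt_db, hgt_labels = hgt_labels,
                 genome_size = genome_size, k = as.integer(k),
                 seeds = lapply(seeds, as.integer)),
            class = "species_config")
}

#' Read a species config (or a manifest of configs) from YAML
#'
#' @param path YAML path. A file with a top-level `species:` list is a
#'   manifest and returns a list of configs; otherwise a single config is
#'   returned. Relative paths are resolved against the YAML's directory.
#' @return a `species_config` or a list of them.
#' @export
read_species_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix_path <- function(p) {
    if (is.null(p) || !is.character(p)) return(p)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  build <- function(cfg) {
    for (f in c("reads", "assembly", "gff", "proteins", "te_library",
                "hgt_db", "hgt_labels")) {
      cfg[[f]] <- fix_path(cfg[[f]])
    }
    do.call(species_config, cfg)
  }
  if (!is.null(y$species) && is.list(y$species) && is.null(y$species[[1]]$species) == FALSE) {
    lapply(y$species, build)
  } else {
    build(y)
  }
}

stage_result <- function(status, values = NULL, error = NULL, source = NULL) {
  list(status = status, values = values, error = error, source = source)
}

run_stage <- function(enabled, absent_msg, out_file, fun) {
  if (!enabled) return(stage_result("absent", error = absent_msg))
  tryCatch(fun(), error = function(e) {
    stage_result("failed", error = conditionMessage(e), source = out_file)
  })
}

#' Run all pipeline stages for one species
#'
#' Stages run in dependency order: k-mer spectrum fit first (the TE stage
#' subsamples reads using the fitted haploid genome size), then the TE,
#' palindrome and HGT stages. Stages whose inputs are missing are recorded
#' as `absent` (never as zero); a failing stage records its diagnostics and
#' the remaining stages still run. With fixed seeds the report is
#' reproducible bit for bit.
#'
#' @param config a [species_config()].
#' @param out_dir output directory for intermediates and the report
#'   (created; default: a tempdir subdirectory).
#' @return an object of class `feature_report` (also written to
#'   `out_dir/report.json`).
#' @export
run_species <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "species_config"))
  if (is.null(out_dir)) out_dir <- file.path(tempdir(), paste0("parthenoscan_", config$species))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()

  ## stage 1: k-mer spectrum fit (+ structure decomposition for polyploids)
  keep_table <- config$ploidy > 2
  spectrum <- NULL
  fit <- NULL
  stages$kmer <- run_stage(!is.null(config$reads), "no reads provided",
                           file.path(out_dir, "spectrum_fit.json"), function() {
    spectrum <<- count_kmers(config$reads, k = config$k, keep_table = keep_table)
    write_spectrum(spectrum, file.path(out_dir, "kmer_spectrum.hist"))
    fit <<- fit_spectrum(spectrum, config$ploidy, config$topology)
    if (!isTRUE(fit$converged)) stop("spectrum fit did not converge")
    vals <- list(lambda_cov = fit$lambda_cov, rho = fit$rho,
                 het_rates_pct = as.list(fit$het_rates),
                 composite_het_pct = fit$composite_het,
                 composite = fit$composite,
                 genome_size_G = fit$genome_size_G,
                 residual = fit$residual,
                 repeat_fraction = fit$repeat_fraction,
                 error_cutoff = fit$error_cutoff)
    jsonlite::write_json(vals, file.path(out_dir, "spectrum_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    stage_result("ok", vals, source = file.path(out_dir, "spectrum_fit.json"))
  })

  stages$structure <- run_stage(
    keep_table && identical(stages$kmer$status, "ok"),
    "requires reads and ploidy > 2",
    file.path(out_dir, "structure.json"), function() {
    fams <- extract_het_families(spectrum, fit$lambda_cov,
                                 ploidy = config$ploidy, rho = fit$rho)
    summ <- classify_structures(fams, fit$lambda_cov)
    vals <- list(fractions = as.list(summ$fractions),
                 n_families = summ$n_families,
                 n_classified = summ$n_classified)
    jsonlite::write_json(vals, file.path(out_dir, "structure.json"),
                         auto_unbox = TRUE, digits = NA)
    stage_result("ok", vals, source = file.path(out_dir, "structure.json"))
  })

  ## stage 2: TE load (uses fitted G unless overridden)
  G <- config$genome_size
  if (is.null(G) && identical(stages$kmer$status, "ok")) {
    G <- stages$kmer$values$genome_size_G
  }
  stages$te <- run_stage(
    !is.null(config$reads) && !is.null(config$te_library) && !is.null(G),
    "requires reads, a TE library and a genome size",
    file.path(out_dir, "te_load.tsv"), function() {
    lib <- config$te_library
    if (is.character(lib) && length(lib) == 1 && file.exists(lib)) {
      lib <- read_fasta(lib)
    }
    te <- te_profile(config$reads, G, lib, seed = config$seeds$te)
    write.table(te$table, file.path(out_dir, "te_load.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    vals <- list(te_load_pct = te$te_load,
                 per_class_pct = as.list(te$per_class_pct),
                 unknown_repeat_pct = 100 * te$unknown_repeat_nt / te$sampled_nt,
                 sampled_nt = te$sampled_nt)
    stage_result("ok", vals, source = file.path(out_dir, "te_load.tsv"))
  })

  ## stages 3+4 share the annotation inputs
  genes <- NULL
  proteins <- NULL
  have_ann <- !is.null(config$gff) && !is.null(config$proteins)
  if (have_ann) {
    genes <- if (is.data.frame(config$gff)) config$gff else read_gene_records(config$gff)
    proteins <- config$proteins
    if (is.character(proteins) && length(proteins) == 1 && file.exists(proteins)) {
      proteins <- read_fasta(proteins, type = "AA")
    }
  }

  stages$palindromes <- run_stage(have_ann, "no annotation available",
                                  file.path(out_dir, "palindromes.tsv"), function() {
    rep <- palindrome_scan(genes, proteins)
    s <- rep$summary
    write.table(data.frame(species = config$species,
                           palindromes = s$n_palindromes,
                           affected_genes = s$n_genes_affected,
                           percent_genes = s$percent_genes),
                file.path(out_dir, "palindromes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    stage_result("ok", s, source = file.path(out_dir, "palindromes.tsv"))
  })

  stages$hgt <- run_stage(
    have_ann && !is.null(config$hgt_db) && !is.null(config$hgt_labels),
    "no annotation or reference database available",
    file.path(out_dir, "hgt_report.json"), function() {
    rep <- hgt_scan(proteins, genes, config$hgt_db, config$hgt_labels)
    vals <- list(n_genes_total = rep$n_genes_total,
                 n_candidates_prefilter = rep$n_candidates_prefilter,
                 n_candidates_linked = rep$n_candidates_linked,
                 hgt_c_percent = rep$hgt_c_percent)
    jsonlite::write_json(vals, file.path(out_dir, "hgt_report.json"),
                         auto_unbox = TRUE, digits = NA)
    write.table(rep$origin_scores, file.path(out_dir, "origin_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stage_result("ok", vals, source = file.path(out_dir, "hgt_report.json"))
  })

  report <- structure(list(species = config$species,
                           hybrid_origin = config$hybrid_origin,
                           mechanism = config$mechanism,
                           ploidy = config$ploidy, topology = config$topology,
                           stages = stages, out_dir = out_dir),
                      class = "feature_report")
  jsonlite::write_json(
    report[setdiff(names(report), "out_dir")],
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)
  report
}

#' @export
print.feature_report <- function(x, ...) {
  cat("feature_report:", x$species, "(", x$topology, ")\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-12s %s%s\n", nm, st$status,
                if (!is.null(st$error)) paste0(" (", st$error, ")") else ""))
  }
  invisible(x)
}

stage_value <- function(report, stage, field) {
  st <- report$stages[[stage]]
  if (is.null(st) || !identical(st$status, "ok")) return(NA_real_)
  v <- st$values[[field]]
  if (is.null(v)) NA_real_ else v
}

#' Aggregate per-species reports into a cross-species feature table
#'
#' @param reports list of `feature_report`s.
#' @param out_tsv optional path for the feature table.
#' @return list of class `feature_table`: `table` (one row per species),
#'   `te_long` (stacked-bar-ready per-class TE fractions),
#'   `by_origin` and `by_mechanism` (group medians and ranges of composite
#'   heterozygosity and TE load).
#' @export
aggregate_reports <- function(reports, out_tsv = NULL) {
  stopifnot(length(reports) >= 1)
  rows <- lapply(reports, function(r) {
    data.frame(
      species = r$species, hybrid_origin = r$hybrid_origin,
      mechanism = r$mechanism, ploidy = r$ploidy, topology = r$topology,
      composite_het_pct = stage_value(r, "kmer", "composite_het_pct"),
      genome_size_G = stage_value(r, "kmer", "genome_size_G"),
      te_load_pct = stage_value(r, "te", "te_load_pct"),
      palindromes = stage_value(r, "palindromes", "n_palindromes"),
      palindrome_genes_pct = stage_value(r, "palindromes", "percent_genes"),
      hgt_c_pct = stage_value(r, "hgt", "hgt_c_percent"),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  te_long <- do.call(rbind, lapply(reports, function(r) {
    st <- r$stages$te
    if (is.null(st) || !identical(st$status, "ok")) return(NULL)
    data.frame(species = r$species, class = names(st$values$per_class_pct),
               pct = unlist(st$values$per_class_pct), row.names = NULL)
  }))
  summarize_group <- function(by) {
    parts <- split(tab, tab[[by]])
    do.call(rbind, lapply(names(parts), function(g) {
      p <- parts[[g]]
      data.frame(group = g, n = nrow(p),
                 het_median = median(p$composite_het_pct, na.rm = TRUE),
                 het_min = suppressWarnings(min(p$composite_het_pct, na.rm = TRUE)),
                 het_max = suppressWarnings(max(p$composite_het_pct, na.rm = TRUE)),
                 te_median = median(p$te_load_pct, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(out_tsv)) {
    write.table(tab, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(table = tab, te_long = te_long,
                 by_origin = summarize_group("hybrid_origin"),
                 by_mechanism = summarize_group("mechanism")),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  print(x$table)
  invisible(x)
}
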