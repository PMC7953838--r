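test_that("subsampling hits the target nucleotide count deterministically", {
  set.seed(71)
  reads <- vapply(seq_len(4000), function(i) random_dna(100), "")
  sub <- subsample_reads(reads, 2e5, target_cov = 0.5, seed = 5)
  expect_equal(length(sub), 1000) # 0.5 * 2e5 / 100
  expect_identical(subsample_reads(reads, 2e5, 0.5, seed = 5), sub)
  expect_false(identical(subsample_reads(reads, 2e5, 0.5, seed = 6), sub))
  expect_error(subsample_reads(reads[1:10], 2e5, 0.5, seed = 1),
               "achievable coverage")
})

test_that("two identical reads assemble into one contig of multiplicity two", {
  r <- random_dna(100, seed = 72)
  asm <- assemble_repeats(c(r, r))
  expect_equal(nrow(asm$contigs), 1)
  expect_equal(asm$contigs$support, 2)
  expect_true(asm$contigs$seq %in% c(r, rc_chr(r)))
  expect_equal(length(asm$unassembled), 0)
})

test_that("overlapping reads merge across strands into the spanned sequence", {
  g <- random_dna(220, seed = 73)
  r1 <- substr(g, 1, 100)
  r2 <- rc_chr(substr(g, 51, 150)) # reverse-strand read overlapping r1 by 50
  asm <- assemble_repeats(c(r1, r2))
  expect_equal(nrow(asm$contigs), 1)
  merged <- substr(g, 1, 150)
  expect_true(asm$contigs$seq %in% c(merged, rc_chr(merged)))
})

test_that("a repeat-free genome produces a near-zero TE load", {
  g <- random_dna(4e5, seed = 74)
  rd <- simulate_reads(c(chr = g), 0.5, 100, seed = 75)
  asm <- assemble_repeats(rd$seq)
  ## chance genomic overlaps do assemble at 0.5x, but carry no TE homology
  expect_gt(length(asm$unassembled) / length(rd$seq), 0.3)
  ann <- annotate_repeats(asm, make_te_library())
  expect_lt(ann$te_load, 0.5)
})

test_that("an implanted multi-copy TE is reassembled near full length", {
  set.seed(76)
  te <- random_dna(5000)
  backbone <- random_dna(3e5)
  ## 50 interspersed copies
  pieces <- character(0)
  step <- floor(3e5 / 50)
  for (i in 1:50) {
    pieces <- c(pieces, substr(backbone, (i - 1) * step + 1, i * step), te)
  }
  genome <- paste(pieces, collapse = "")
  rd <- simulate_reads(c(chr = genome), 0.5, 100, seed = 77)
  asm <- assemble_repeats(rd$seq)
  ## coverage of the TE consensus by contig 31-mers
  te_words <- unique(substring(te, 1:(5000 - 31 + 1), 31:5000))
  ctg_words <- unlist(lapply(asm$contigs$seq[asm$contigs$support >= 3],
                             function(s) {
    n <- nchar(s)
    w <- substring(s, 1:(n - 31 + 1), 31:n)
    c(w, rc_chr(w))
  }))
  expect_gt(mean(te_words %in% ctg_words), 0.80)
})

test_that("annotation attributes nucleotides to the right classes and excludes unknowns", {
  lib <- make_te_library()
  g <- random_dna(2e5, seed = 78)
  te <- lib[["teA#LTR/Gypsy"]]
  genome <- paste0(g, paste(rep(te, 10), collapse = random_dna(100)))
  rd <- simulate_reads(c(chr = genome), 0.5, 100, seed = 79)
  asm <- assemble_repeats(rd$seq)
  ann <- annotate_repeats(asm, lib)
  expect_equal(ann$te_load, sum(ann$per_class_pct)) # class additivity
  expect_gt(ann$per_class_pct[["LTR"]], 0)
  expect_equal(sum(ann$per_class_pct[setdiff(names(ann$per_class_pct), "LTR")]), 0)
  expect_lte(sum(ann$per_class_nt) + ann$unknown_repeat_nt, ann$sampled_nt * 1.0001)
  expect_error(annotate_repeats(asm, character(0)), "empty")
  ## a library with no homology to the genome annotates nothing
  ann0 <- annotate_repeats(asm, make_te_library(seed = 123))
  expect_equal(ann0$te_load, 0)
  expect_gt(ann0$unknown_repeat_nt, 0)
})

test_that("malformed library class labels fall back to unknown with a warning", {
  lib <- setNames(make_te_library(), c("teA", "teB#LINE/L1", "teC#DNA/hAT",
                                       "teD#SINE/tRNA", "teE#RC/Helitron"))
  asm <- assemble_repeats(c(random_dna(100, seed = 80), random_dna(100)))
  expect_warning(annotate_repeats(asm, lib), "label")
})

test_that("an implanted 10% TE load is recovered within 2 percentage points", {
  lib <- make_te_library()
  hs <- simulate_haplotypes(genome_spec(3e5, 2, "AB", c(allelic = 0.005),
                                        seed = 81))
  ig <- implant_features(hs, feature_plan(te_library = lib,
                                          te_target_fraction = 0.10), seed = 82)
  truth <- 100 * sum(ig$te_truth$end - ig$te_truth$start) / sum(nchar(ig$assembly))
  rd <- simulate_reads(ig$assembly, 2, 100, seed = 83)
  te <- te_profile(rd$seq, sum(nchar(ig$assembly)), lib, seed = 84)
  expect_lt(abs(te$te_load - truth), 2)
})
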