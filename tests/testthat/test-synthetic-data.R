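test_that("zero divergence yields byte-identical haplotypes and an empty truth table", {
  hs <- simulate_haplotypes(genome_spec(1e4, 2, "AB", c(allelic = 0), seed = 3))
  expect_identical(hs$haplotypes[["A1"]], hs$haplotypes[["B1"]])
  expect_equal(nrow(hs$truth), 0)
})

test_that("identical topology letters are byte-identical copies", {
  hs <- simulate_haplotypes(genome_spec(2e4, 3, "AAB",
                                        c(homoeolog = 0.03), seed = 5))
  expect_identical(hs$haplotypes[["A1"]], hs$haplotypes[["A2"]])
  expect_false(identical(hs$haplotypes[["A1"]], hs$haplotypes[["B1"]]))
})

test_that("realized divergence matches the requested rate within 3 binomial SD", {
  L <- 2e5
  r <- 0.02
  hs <- simulate_haplotypes(genome_spec(L, 3, "AAB", c(homoeolog = r), seed = 11))
  d <- pairwise_divergence(hs$haplotypes[["A1"]], hs$haplotypes[["B1"]])
  tol <- 3 * sqrt(r * (1 - r) / L)
  expect_lt(abs(d - r), tol)
})

test_that("ABCD one-haplotype variants give equal pairwise divergences (3 SD)", {
  L <- 2e5
  hs <- simulate_haplotypes(genome_spec(L, 4, "ABCD", c(one_hap = 0.02), seed = 13))
  copies <- c("A1", "B1", "C1", "D1")
  target <- 0.02 * 2 / 4 # a one-hap site separates 3 of the 6 pairs
  tol <- 3 * sqrt(target * (1 - target) / L)
  for (i in 1:3) for (j in (i + 1):4) {
    d <- pairwise_divergence(hs$haplotypes[[copies[i]]], hs$haplotypes[[copies[j]]])
    expect_lt(abs(d - target), tol)
  }
})

test_that("simulation is a pure function of the spec", {
  s <- genome_spec(2e4, 2, "AB", c(allelic = 0.01), seed = 21)
  expect_identical(simulate_haplotypes(s), simulate_haplotypes(s))
})

test_that("invalid genome specs are rejected", {
  expect_error(genome_spec(1e4, 3, "AB", c(allelic = 0.01)), "ploidy")
  expect_error(genome_spec(1e4, 2, "AB", c(allelic = 0.5)), "0.35")
  expect_error(genome_spec(1e4, 2, "AB", c(homoeolog = 0.01)), "layer")
})

test_that("an empty implant plan reproduces the collapsed haplotypes", {
  hs <- simulate_haplotypes(genome_spec(2e4, 3, "ABC",
                                        c(one_hap = 0.01), seed = 2))
  ig <- implant_features(hs, feature_plan(), seed = 1)
  expect_identical(unname(ig$assembly),
                   unname(hs$haplotypes[c("A1", "B1", "C1")]))
  expect_equal(nrow(ig$te_truth), 0)
})

test_that("a palindrome implant emits two strand-flipped, order-reversed gene blocks", {
  hs <- simulate_haplotypes(genome_spec(3e4, 2, "AB", c(allelic = 0), seed = 4))
  ig <- implant_features(hs, feature_plan(
    palindrome_implants = list(list(n_genes = 3))), seed = 8)
  pal <- ig$genes[ig$genes$type == "palindrome", ]
  expect_equal(nrow(pal), 6)
  left <- pal[grepl("_a$", pal$gene_id), ]
  right <- pal[grepl("_b$", pal$gene_id), ]
  expect_true(all(left$strand == "+"))
  expect_true(all(right$strand == "-"))
  ## right block carries the genes in reversed order
  expect_equal(sub("_b$", "", right$gene_id[order(right$start)]),
               rev(sub("_a$", "", left$gene_id[order(left$start)])))
  ## both arms encode identical proteins
  expect_identical(unname(ig$proteins[left$gene_id]),
                   unname(ig$proteins[sub("_a$", "_b", left$gene_id)]))
})

test_that("truth tables exactly describe the emitted assembly", {
  hs <- simulate_haplotypes(genome_spec(4e4, 2, "AB", c(allelic = 0), seed = 6))
  lib <- make_te_library()
  ig <- implant_features(hs, feature_plan(
    te_library = lib, te_target_fraction = 0.10, n_genes = 10,
    te_max_divergence = 0, te_max_truncation = 0), seed = 12)
  ## every gene translates to its recorded protein, strand-aware
  for (i in seq_len(nrow(ig$genes))) {
    g <- ig$genes[i, ]
    dna <- substr(ig$assembly[[g$scaffold]], g$start + 1, g$end)
    if (g$strand == "-") dna <- rc_chr(dna)
    expect_identical(
      as.character(Biostrings::translate(Biostrings::DNAString(dna))),
      unname(ig$proteins[[g$gene_id]]))
  }
  ## undiverged, untruncated TE copies match their library source exactly
  for (i in seq_len(nrow(ig$te_truth))) {
    t <- ig$te_truth[i, ]
    seq <- substr(ig$assembly[[t$scaffold]], t$start + 1, t$end)
    if (t$strand == "-") seq <- rc_chr(seq)
    expect_identical(seq, unname(lib[[t$src]]))
  }
  ## re-parse round trip through GFF3
  gff <- file.path(tempdir(), "truth_roundtrip.gff3")
  write_gff3(ig$genes, gff)
  back <- read_gene_records(gff)
  expect_equal(back$start, ig$genes$start)
  expect_equal(back$end, ig$genes$end)
  expect_equal(back$gene_id, ig$genes$gene_id)
})

test_that("implanted HGT fraction follows from the truth table", {
  hs <- simulate_haplotypes(genome_spec(3e4, 2, "AB", c(allelic = 0), seed = 7))
  ig <- implant_features(hs, feature_plan(n_genes = 100, hgt_implants = 5),
                         seed = 14)
  expect_equal(nrow(ig$hgt_truth), 5)
  expect_equal(nrow(ig$hgt_truth) / nrow(ig$genes), 5 / 105)
})

test_that("TE implantation reaches the target fraction and is truth-consistent", {
  hs <- simulate_haplotypes(genome_spec(5e4, 2, "AB", c(allelic = 0), seed = 9))
  ig <- implant_features(hs, feature_plan(te_library = make_te_library(),
                                          te_target_fraction = 0.15), seed = 3)
  te_nt <- sum(ig$te_truth$end - ig$te_truth$start)
  frac <- te_nt / sum(nchar(ig$assembly))
  expect_gt(frac, 0.14)
  expect_lt(frac, 0.22)
  expect_error(
    implant_features(hs, feature_plan(te_library = NULL,
                                      te_target_fraction = 0.1), seed = 1),
    "library")
})

test_that("read simulation respects coverage arithmetic and determinism", {
  hs <- simulate_haplotypes(genome_spec(5e4, 2, "AB", c(allelic = 0.01), seed = 1))
  rd <- simulate_reads(hs, 10, 100, seed = 2)
  expect_lt(abs(sum(nchar(rd$seq)) - 10 * 2 * 5e4), 100)
  expect_identical(simulate_reads(hs, 10, 100, seed = 2), rd)
  f1 <- file.path(tempdir(), "det1.fq"); f2 <- file.path(tempdir(), "det2.fq")
  write_fastq(rd, f1)
  write_fastq(simulate_reads(hs, 10, 100, seed = 2), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_reads(hs, 10, 1e6, seed = 1), "shortest scaffold")
  expect_error(simulate_reads(hs, 10, 100, error_rate = 0.5), "error_rate")
})

test_that("read errors realign to the source at the requested rate (3 SD)", {
  hs <- simulate_haplotypes(genome_spec(5e4, 2, "AB", c(allelic = 0), seed = 15))
  e <- 0.01
  rd <- simulate_reads(hs, 8, 100, error_rate = e, seed = 16)
  src <- substring(hs$haplotypes[rd$source], rd$start, rd$start + 99)
  obs <- rd$seq
  rev <- rd$strand == "-"
  obs[rev] <- rc_chr(obs[rev])
  mm <- sum(parthenoscan:::cpp_mismatch_count(obs, src))
  tot <- sum(nchar(obs))
  expect_lt(abs(mm / tot - e), 3 * sqrt(e * (1 - e) / tot))
})
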