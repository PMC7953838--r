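## small helper: gene records laid out on one or more scaffolds
make_genes <- function(n, scaffold = "s1", strand = NULL, gap = 1000,
                       len = 900) {
  if (is.null(strand)) strand <- rep("+", n)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)), scaffold = scaffold,
             start = (seq_len(n) - 1L) * (len + gap),
             end = (seq_len(n) - 1L) * (len + gap) + len,
             strand = strand, rank = seq_len(n), stringsAsFactors = FALSE)
}

make_hits <- function(pairs) {
  n <- nrow(pairs)
  data.frame(query = pairs[, 1], subject = pairs[, 2], score = rep(500, n),
             bitscore = rep(100, n), evalue = rep(0, n), pid = rep(100, n),
             aln_len = rep(300L, n), stringsAsFactors = FALSE)
}

test_that("identical proteins give one significant hit; random pairs give none", {
  set.seed(91)
  p <- random_protein_chr(300)
  hits <- all_vs_all_homology(setNames(c(p, p), c("a", "b")))
  expect_equal(nrow(hits), 1)
  expect_lt(hits$evalue, 1e-50)
  ## empirical null: 300 random unrelated pairs, no hit at default threshold
  rnd <- setNames(vapply(seq_len(25), function(i) random_protein_chr(300), ""),
    sprintf("r%02d", 1:25))
  expect_equal(nrow(all_vs_all_homology(rnd)), 0)
  expect_error(all_vs_all_homology(rnd[1]), "at least 2")
})

test_that("an implanted duplicated cassette yields exactly the cross-copy hits", {
  hs <- simulate_haplotypes(genome_spec(4e4, 2, "AB", c(allelic = 0), seed = 92))
  ig <- implant_features(hs, feature_plan(
    palindrome_implants = list(list(n_genes = 3))), seed = 93)
  hits <- all_vs_all_homology(ig$proteins[grep("^pal1_g", names(ig$proteins))])
  expect_equal(nrow(hits), 3)
  expect_true(all(sub("_[ab]$", "", hits$query) == sub("_[ab]$", "", hits$subject)))
})

test_that("monotone decreasing subject ranks chain into one reverse block", {
  genes <- make_genes(10, strand = c(rep("+", 5), rep("-", 5)))
  hits <- make_hits(cbind(c("g01", "g02", "g03"), c("g10", "g09", "g08")))
  blocks <- detect_collinear_blocks(hits, genes)
  expect_equal(length(blocks), 1)
  expect_equal(blocks[[1]]$orientation, "reverse")
  expect_equal(blocks[[1]]$n_pairs, 3)
  expect_equal(blocks[[1]]$score, 3)
})

test_that("anchors separated by more than max_gap split into singleton blocks", {
  genes <- make_genes(45)
  hits <- make_hits(cbind(c("g01", "g02"), c("g05", "g40")))
  blocks <- detect_collinear_blocks(hits, genes, max_gap = 25)
  expect_equal(length(blocks), 2)
  expect_true(all(vapply(blocks, function(b) b$n_pairs, 0) == 1))
})

test_that("genes without homology produce zero blocks", {
  genes <- make_genes(200)
  empty <- make_hits(matrix(character(0), ncol = 2))
  expect_equal(length(detect_collinear_blocks(empty, genes)), 0)
})

test_that("DP chaining equals the exhaustive-enumeration oracle", {
  set.seed(94)
  for (case in 1:25) {
    n <- sample(4:10, 1)
    ra <- sort(sample(30, n))
    rb <- sample(30, n)
    orient <- sample(c("same", "reverse"), 1)
    got <- parthenoscan:::chain_dp(ra, rb, orient, max_gap = 25)
    want <- oracle_best_chain(ra, rb, orient, max_gap = 25)
    expect_equal(got$score, want)
  }
})

test_that("palindrome filtering enforces every hairpin requirement", {
  ## same-orientation duplication: rejected
  genes <- make_genes(10)
  hits <- make_hits(cbind(c("g01", "g02"), c("g06", "g07")))
  blocks <- detect_collinear_blocks(hits, genes)
  pals <- filter_palindromes(blocks, genes)
  expect_equal(length(pals), 0)
  expect_true("same_orientation" %in% attr(pals, "discarded")$reason)
  ## copies on different scaffolds: rejected
  genes2 <- make_genes(10, scaffold = rep(c("s1", "s2"), each = 5),
                       strand = c(rep("+", 5), rep("-", 5)))
  genes2$rank <- c(1:5, 1:5)
  hits2 <- make_hits(cbind(c("g01", "g02"), c("g10", "g09")))
  pals2 <- filter_palindromes(detect_collinear_blocks(hits2, genes2), genes2)
  expect_equal(length(pals2), 0)
  expect_true("different_scaffold" %in% attr(pals2, "discarded")$reason)
  ## reverse order but equal strands: rejected
  genes3 <- make_genes(10)
  hits3 <- make_hits(cbind(c("g01", "g02", "g03"), c("g10", "g09", "g08")))
  pals3 <- filter_palindromes(detect_collinear_blocks(hits3, genes3), genes3)
  expect_true("strand_inconsistent" %in% attr(pals3, "discarded")$reason)
})

test_that("an implanted palindrome is recovered with all its genes", {
  hs <- simulate_haplotypes(genome_spec(5e4, 2, "AB", c(allelic = 0), seed = 95))
  ig <- implant_features(hs, feature_plan(
    n_genes = 20, palindrome_implants = list(list(n_genes = 3))), seed = 96)
  rep <- palindrome_scan(ig$genes, ig$proteins)
  expect_equal(rep$summary$n_palindromes, 1)
  expect_equal(rep$summary$n_genes_affected, 6)
})

test_that("palindrome summaries use set semantics for affected genes", {
  expect_equal(
    summarize_palindromes(structure(list(), class = "palindrome_set"), 100),
    list(n_palindromes = 0, n_genes_affected = 0, percent_genes = 0))
  p1 <- list(anchors = data.frame(gene_a = c("g1", "g2"), gene_b = c("g9", "g8")))
  p2 <- list(anchors = data.frame(gene_a = "g2", gene_b = "g5"))
  s <- summarize_palindromes(list(p1, p2), 100)
  expect_equal(s$n_genes_affected, 5) # g2 shared, counted once
  expect_equal(s$percent_genes, 5)
})
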