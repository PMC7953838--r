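test_that("k-mers differing at one position form a family; two positions do not", {
  set.seed(61)
  base <- random_dna(21)
  one_off <- base
  substr(one_off, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                     substr(base, 11, 11))[1]
  two_off <- one_off
  substr(two_off, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                   substr(base, 3, 3))[1]
  canon <- function(x) pmin(x, rc_chr(x))
  sp1 <- spectrum_from_table(canon(c(base, one_off)), c(20, 40))
  fam1 <- extract_het_families(sp1, lambda_cov = 20, ploidy = 3)
  expect_equal(nrow(fam1), 2)
  expect_equal(unique(fam1$family), 1L)
  sp2 <- spectrum_from_table(canon(c(base, two_off)), c(20, 40))
  fam2 <- extract_het_families(sp2, lambda_cov = 20, ploidy = 3)
  expect_equal(nrow(fam2), 0)
})

test_that("one-substitution pairs are found across strand canonicalization", {
  set.seed(62)
  for (case in 1:20) {
    x <- random_dna(21)
    p <- sample(21, 1)
    y <- x
    substr(y, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(x, p, p)), 1)
    canon <- pmin(c(x, y), rc_chr(c(x, y)))
    if (canon[1] == canon[2]) next # palindromic edge case, no distinct pair
    sp <- spectrum_from_table(canon, c(18, 22))
    fam <- extract_het_families(sp, lambda_cov = 20, ploidy = 2)
    expect_equal(nrow(fam), 2)
  }
})

test_that("coverage bounds and family-size limits are enforced", {
  set.seed(63)
  base <- random_dna(21)
  variants <- vapply(c("A", "C", "G", "T"), function(b) {
    v <- base; substr(v, 5, 5) <- b; v
  }, "")
  variants <- unique(pmin(variants, rc_chr(variants)))
  ## families above max_members are discarded as repeat-induced
  sp <- spectrum_from_table(variants, rep(20, length(variants)))
  fam_all <- extract_het_families(sp, lambda_cov = 20, ploidy = 3)
  expect_equal(nrow(fam_all), length(variants))
  fam <- extract_het_families(sp, lambda_cov = 20, ploidy = 3,
                              max_members = length(variants) - 1)
  expect_equal(nrow(fam), 0)
  ## k-mers below the error cutoff cannot seed families
  spe <- spectrum_from_table(variants[1:2], c(1, 20))
  fame <- extract_het_families(spe, lambda_cov = 20, error_cutoff = 3, ploidy = 3)
  expect_equal(nrow(fame), 0)
  sp_no_table <- structure(list(k = 21L,
                                bins = data.frame(coverage = 1L, count = 1)),
                           class = "kmer_spectrum")
  expect_error(extract_het_families(sp_no_table, 20), "keep_table")
})

test_that("a homozygous genome yields no heterozygous families", {
  hs <- simulate_haplotypes(genome_spec(3e4, 2, "AB", c(allelic = 0), seed = 64))
  rd <- simulate_reads(hs, 20, 100, seed = 65)
  sp <- count_kmers(rd$seq, 21, keep_table = TRUE)
  fam <- extract_het_families(sp, lambda_cov = 16, ploidy = 2)
  expect_lt(nrow(fam) / nrow(sp$table), 0.002)
})

test_that("family count matches the truth-table heterozygous-window count", {
  L <- 1e5; k <- 21
  hs <- simulate_haplotypes(genome_spec(L, 2, "AB", c(allelic = 0.01), seed = 66))
  rd <- simulate_reads(hs, 20, 100, seed = 67)
  sp <- count_kmers(rd$seq, k, keep_table = TRUE)
  fit <- fit_spectrum(sp, 2, "AB")
  fam <- extract_het_families(sp, fit$lambda_cov, ploidy = 2, rho = fit$rho)
  n_fam <- length(unique(fam$family))
  truth <- windows_with_one_site(hs$truth$pos, L, k)
  expect_lt(abs(n_fam - truth) / truth, 0.15)
})

test_that("coverage templates classify biallelic configurations", {
  fams <- data.frame(family = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 5, 6, 6),
                     kmer = "N",
                     coverage = c(20, 40,   # AAB
                                  21, 19,   # AB
                                  41, 39,   # AABB
                                  20, 61,   # AAAB
                                  20, 20, 20, # MULTI
                                  20, 90))  # off every template -> AMBIGUOUS
  s <- classify_structures(fams, lambda_cov = 20)
  expect_equal(unname(s$classification[as.character(1:6)]),
               c("AAB", "AB", "AABB", "AAAB", "MULTI", "AMBIGUOUS"))
  expect_equal(s$n_families, 6)
  expect_equal(s$n_classified, 5)
  expect_equal(sum(s$fractions), 1)
  expect_equal(unname(s$fractions["biallelic_single_copy"]), 2 / 5)
})

test_that("an empty family list yields an undefined-fraction summary", {
  s <- classify_structures(data.frame(family = integer(0), kmer = character(0),
                                      coverage = numeric(0)), 20)
  expect_equal(s$n_families, 0)
  expect_true(all(is.na(s$fractions)))
})
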