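test_that("with zero heterozygosity all weight sits on the ploidy peak", {
  for (tp in c("AB", "AAB", "AAAB", "AABB", "ABC", "ABCD")) {
    w <- topology_weights(tp, setNames(0, NULL), 21)
    expect_equal(w$weight[w$copies == nchar(tp)], 1)
    expect_equal(sum(w$weight), 1)
  }
})

test_that("AB weights follow the closed form a = 1-(1-r)^k", {
  r <- 0.01; k <- 21
  a <- 1 - (1 - r)^k
  w <- topology_weights("AB", c(allelic = r), k)
  expect_equal(w$weight, c(2 * a, 1 - a))
  wn <- topology_weights("AB", c(allelic = r), k, normalize = TRUE)
  expect_equal(wn$weight[1], 2 * a / (1 + a))
})

test_that("AAB has haploid-peak and 2x-peak mass that a pure ABC with a2=0 lacks", {
  w_aab <- topology_weights("AAB", c(homoeolog = 0.02), 21)
  w_abc <- topology_weights("ABC", c(one_hap = 0, triallelic = 0.02), 21)
  expect_gt(w_aab$weight[w_aab$copies == 2], 0)
  expect_equal(w_abc$weight[w_abc$copies == 2], 0)
})

test_that("unknown topology labels and layers are rejected", {
  expect_error(topology_weights("AABBC", c(x = 0.1)), "arg")
  expect_error(topology_weights("AB", c(nope = 0.1)), "layer")
})

test_that("weights match exhaustive window enumeration on simulated haplotypes", {
  ## counting k-mers of the haplotype copies themselves enumerates every
  ## window: bin i of that spectrum holds the distinct k-mers carried by i
  ## copies, the quantity the weights predict as G * w_i
  L <- 1e5; k <- 21
  cases <- list(list(tp = "AB", r = c(allelic = 0.01)),
                list(tp = "AAB", r = c(homoeolog = 0.02)),
                list(tp = "AABB", r = c(homoeolog = 0.02)),
                list(tp = "ABC", r = c(one_hap = 0.02, triallelic = 0.01)))
  for (cs in cases) {
    pl <- nchar(cs$tp)
    hs <- simulate_haplotypes(genome_spec(L, pl, cs$tp, cs$r, seed = 31))
    sp <- count_kmers(hs$haplotypes, k)
    ## condition on the realized per-layer site counts of this simulation
    r_real <- vapply(names(cs$r), function(ly)
      sum(hs$truth$layer == ly) / L, 0)
    w <- topology_weights(cs$tp, r_real, k)
    G <- L - k + 1
    for (i in seq_len(pl)) {
      obs <- sum(sp$bins$count[sp$bins$coverage == i])
      exp_ct <- G * w$weight[w$copies == i]
      ## 3 SD binomial tolerance plus slack for chance k-mer collisions
      tol <- 3 * sqrt(max(exp_ct, 25)) + 0.005 * G
      expect_lt(abs(obs - exp_ct), tol)
    }
  }
})

test_that("parameters are recovered exactly on a model-generated spectrum", {
  sp <- model_spectrum("AB", lambda = 20, rho = 2, r = c(allelic = 0.01),
                       G = 1e6)
  fit <- fit_spectrum(sp, 2, "AB")
  expect_true(fit$converged)
  expect_lt(abs(fit$lambda_cov / 20 - 1), 0.01)
  expect_lt(abs(fit$rho / 2 - 1), 0.05)
  expect_lt(abs(fit$het_rates[["allelic"]] / 1 - 1), 0.01)
  expect_lt(abs(fit$genome_size_G / 1e6 - 1), 0.01)
})

test_that("estimated heterozygosity increases strictly with the true rate", {
  rhat <- vapply(c(0.005, 0.01, 0.02, 0.04), function(r) {
    sp <- model_spectrum("AB", 20, 1.5, c(allelic = r), 5e5)
    fit_spectrum(sp, 2, "AB")$composite_het
  }, 0)
  expect_true(all(diff(rhat) > 0))
})

test_that("as r -> 0 the fit collapses to a single NB at ploidy * lambda", {
  sp <- model_spectrum("AAB", 15, 1.2, c(homoeolog = 0), 4e5)
  fit <- fit_spectrum(sp, 3, "AAB")
  expect_lt(fit$composite_het, 0.02)
  expect_lt(abs(fit$lambda_cov / 15 - 1), 0.02)
  expect_lt(abs(fit$genome_size_G / 4e5 - 1), 0.02)
  expect_true(fit$composite) # AAB layers are reported as composite
})

test_that("degenerate spectra and inconsistent ploidy are rejected", {
  sp <- structure(list(k = 21L, bins = data.frame(coverage = 1L, count = 10),
                       total_kmers = 10), class = "kmer_spectrum")
  expect_error(fit_spectrum(sp, 2, "AB"), "degenerate")
  sp2 <- model_spectrum("AB", 20, 1.5, c(allelic = 0.01), 1e5)
  expect_error(fit_spectrum(sp2, 3, "AB"), "inconsistent")
})

test_that("candidate-topology ranking prefers the generating model's ploidy", {
  hs <- simulate_haplotypes(genome_spec(1e5, 3, "AAB", c(homoeolog = 0.02),
                                        seed = 51))
  rd <- simulate_reads(hs, 12, 100, seed = 52)
  sp <- count_kmers(rd$seq, 21)
  rank <- suppressWarnings(compare_topologies(sp, c("AB", "AAB", "AABB")))
  expect_equal(rank$topology[1], "AAB")
})
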