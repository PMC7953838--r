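## Negative-binomial mixture fit to the k-mer spectrum.
##
## Model: the haploid genome is a sequence of G k-length windows. A window is
## heterozygous in a divergence layer with probability a = 1 - (1-r)^k (r the
## per-site rate), in which case its k-mers split between coverage peaks as
## prescribed by the topology. Peak i (copy number i) is a negative binomial
## with mean i*lambda and size i*lambda/rho, so variance mu*(1+rho); peaks are
## evenly spaced exactly. Expected distinct-k-mer counts are G * w_i per peak.

window_rate <- function(r, k) 1 - (1 - r)^k
rate_from_a <- function(a, k) 1 - (1 - a)^(1 / k)

#' Expected mixture weights over coverage peaks for a divergence topology
#'
#' Returns the expected number of distinct k-mers per ancestral k-length
#' window at each coverage peak `i*lambda` (i = copy number), given per-layer
#' per-site rates. With `a = 1-(1-r)^k` per layer:
#' * `AB`: `{1: 2a, 2: 1-a}`
#' * `AAB`: `{1: a, 2: a, 3: 1-a}` (single-copy divergent B)
#' * `AAAB`: `{1: a, 3: a, 4: 1-a}`
#' * `AABB`: `{2: 2a, 4: 1-a}`
#' * `ABC`: exact window-occupancy algebra over the two site classes. With
#'   `s = r2 + r3`, the probability that a window leaves all three copies
#'   identical is `q0 = (1-s)^k`; the probability that exactly one copy is
#'   distinct is `b = 3*((1-s+r2/3)^k - (1-s)^k)` (all one-haplotype variants
#'   in the window hit the same copy); the remainder `t = 1 - q0 - b` makes
#'   all three copies distinct. Weights: `{1: b+3t, 2: b, 3: q0}`. This
#'   reduces to the linear form `{1: a2+3*a3, 2: a2, 3: 1-a2-a3}` at small
#'   rates but stays exact when windows carry variants of several copies.
#' * `ABCD`: `{1: a1+4*a4, 3: a1, 4: 1-a1-a4}` (small-rate linearization).
#'
#' @param topology topology label.
#' @param r_by_layer named per-site rates (see [genome_spec()] for layer
#'   names; unnamed scalars are accepted for single-layer topologies).
#' @param k k-mer size.
#' @param normalize if `TRUE`, weights are divided by the expected number of
#'   distinct k-mers per window so they sum to 1.
#' @return data.frame with `copies` and `weight` (rows with zero weight are
#'   kept for peaks up to the ploidy).
#' @export
topology_weights <- function(topology, r_by_layer, k = 21, normalize = FALSE) {
  topology <- match.arg(topology, names(TOPOLOGIES))
  layers <- TOPOLOGIES[[topology]]$layers
  r <- setNames(rep(0, length(layers)), layers)
  if (is.null(names(r_by_layer)) && length(r_by_layer) == 1) {
    r[1] <- r_by_layer
  } else {
    bad <- setdiff(names(r_by_layer), layers)
    if (length(bad) > 0) stop("unknown layer(s): ", paste(bad, collapse = ", "))
    r[names(r_by_layer)] <- unlist(r_by_layer)
  }
  a <- window_rate(r, k)
  w <- switch(topology,
    AB   = c(2 * a[["allelic"]], 1 - a[["allelic"]]),
    AAB  = { ah <- a[["homoeolog"]]; al <- a[["allelic"]]
             ## homoeolog window: B kmer (1x) + AA kmer (2x);
             ## allelic window: derived A kmer (1x) + ancestral A+B kmer (2x)
             c(ah + al, ah + al, 1 - ah - al) },
    AAAB = { ah <- a[["homoeolog"]]; c(ah, 0, ah, 1 - ah) },
    AABB = { ah <- a[["homoeolog"]]; c(0, 2 * ah, 0, 1 - ah) },
    ABC  = { r2 <- r[["one_hap"]]; r3 <- r[["triallelic"]]; s <- r2 + r3
             q0 <- (1 - s)^k
             b <- 3 * ((1 - s + r2 / 3)^k - q0)
             c(b + 3 * (1 - q0 - b), b, q0) },
    ABCD = { a1 <- a[["one_hap"]]; a4 <- a[["all_distinct"]]
             c(a1 + 4 * a4, 0, a1, 1 - a1 - a4) })
  out <- data.frame(copies = seq_along(w), weight = unname(w))
  if (normalize) out$weight <- out$weight / sum(out$weight)
  out
}

## model of expected distinct-k-mer counts at integer coverages cs, per window
mixture_shape <- function(cs, lambda, rho, weights) {
  f <- numeric(length(cs))
  for (j in seq_len(nrow(weights))) {
    wi <- weights$weight[j]
    if (wi <= 0) next
    mu <- weights$copies[j] * lambda
    size <- mu / max(rho, 1e-3)
    f <- f + wi * dnbinom(cs, mu = mu, size = size)
  }
  f
}

#' Fit the negative-binomial mixture model to a k-mer spectrum
#'
#' Weighted nonlinear least squares of `G * sum_i w_i NB(c; i*lambda,
#' i*lambda/rho)` against the spectrum counts above the error cutoff, on the
#' square-root scale (variance stabilization). Fitting is multi-started over
#' `lambda` candidates derived from the histogram mode; ties are broken by
#' lowest residual, then lowest heterozygosity. `G` has a closed-form optimum
#' for fixed shape parameters and is profiled out.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param ploidy genome ploidy (2..4); user-supplied, not inferred.
#' @param topology divergence topology label (see [topology_weights()]).
#' @param error_cutoff coverage cutoff below which bins are ignored
#'   (default: [error_cutoff()] of the spectrum).
#' @param max_cov highest coverage bin used for fitting (default: 3x the
#'   histogram argmax above the cutoff).
#' @return an object of class `spectrum_fit`: `lambda_cov` (haploid per-copy
#'   k-mer coverage), `rho` (overdispersion; variance is `mu*(1+rho)`),
#'   `het_rates` (named per-layer rates, percent per site),
#'   `composite_het` (their sum, percent), `genome_size_G` (haploid genome
#'   size in distinct k-mer units), `ploidy`, `topology`, `error_cutoff`,
#'   `residual` (relative sum of squared residuals), `repeat_fraction`
#'   (spectrum mass above the modelled peaks), `range_exceeded`,
#'   `composite` (TRUE when layers cannot be separated), `converged`.
#' @export
fit_spectrum <- function(spectrum, ploidy, topology,
                         error_cutoff = NULL, max_cov = NULL) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  topology <- match.arg(topology, names(TOPOLOGIES))
  if (ploidy != TOPOLOGIES[[topology]]$ploidy) {
    stop("ploidy ", ploidy, " inconsistent with topology ", topology)
  }
  k <- spectrum$k
  cutoff <- if (is.null(error_cutoff)) error_cutoff(spectrum) else as.integer(error_cutoff)
  y_all <- dense_bins(spectrum)
  if (sum(y_all[-seq_len(min(cutoff, length(y_all)))] > 0) < 2) {
    stop("degenerate spectrum: fewer than 2 occupied bins above the error cutoff")
  }
  amax <- which.max(replace(y_all, seq_len(cutoff - 1L), 0))
  ## initial fit range: wide enough to cover the ploidy peak even when the
  ## haploid peak is the histogram mode (high-heterozygosity genomes)
  M <- if (is.null(max_cov)) {
    min(length(y_all), ceiling(1.4 * ploidy * amax))
  } else as.integer(max_cov)
  cs <- seq.int(cutoff, M)
  y <- y_all[cs]
  sy <- sqrt(y)

  layers <- TOPOLOGIES[[topology]]$layers
  ## AAB allelic and homoeolog layers produce identical peak signatures and
  ## cannot be separated from the spectrum: fit one composite rate.
  fit_layers <- if (topology == "AAB") "homoeolog" else layers
  composite <- topology == "AAB"
  n_a <- length(fit_layers)

  R_MAX <- 0.35 # upper bound of the per-site rate parameterization
  objective <- function(par) {
    lambda <- exp(par[1]); rho <- exp(par[2])
    r <- setNames(R_MAX * plogis(par[2 + seq_len(n_a)]), fit_layers)
    w <- topology_weights(topology, r, k)
    f <- mixture_shape(cs, lambda, rho, w)
    if (!all(is.finite(f)) || sum(f) <= 0) return(1e18)
    sf <- sqrt(f)
    g <- sum(sy * sf) / sum(f) # closed-form sqrt(G)
    sum((sy - g * sf)^2)
  }

  starts <- unique(pmax(2, amax / seq_len(ploidy)))
  best <- NULL
  for (l0 in starts) {
    for (r0 in c(0.004, 0.03)) {
      par0 <- c(log(l0), log(0.5), rep(qlogis(r0 / R_MAX), n_a))
      opt <- tryCatch({
        o <- optim(par0, objective, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10))
        optim(o$par, objective, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12))
      }, error = function(e) NULL)
      if (is.null(opt) || !is.finite(opt$value)) next
      cand_r <- sum(R_MAX * plogis(opt$par[2 + seq_len(n_a)]))
      if (is.null(best) || opt$value < best$value - 1e-9 ||
          (abs(opt$value - best$value) <= 1e-9 && cand_r < best$r_sum)) {
        best <- list(value = opt$value, par = opt$par, r_sum = cand_r)
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, topology = topology,
                          ploidy = ploidy, error_cutoff = cutoff,
                          diagnostics = "no optimizer start converged"),
                     class = "spectrum_fit"))
  }
  ## second pass: refit on a range ending 5 NB standard deviations above the
  ## ploidy peak, so the range neither truncates the highest peak nor drags
  ## in unmodelled repeat bins
  if (is.null(max_cov)) {
    l1 <- exp(best$par[1]); rh1 <- exp(best$par[2])
    M2 <- min(length(y_all),
              ceiling(ploidy * l1 + 5 * sqrt(ploidy * l1 * (1 + rh1))))
    if (M2 > cutoff + 2 && M2 != M) {
      cs <- seq.int(cutoff, M2)
      y <- y_all[cs]
      sy <- sqrt(y)
      opt <- tryCatch(optim(best$par, objective, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-12)),
                      error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value)) {
        best <- list(value = opt$value, par = opt$par, r_sum = best$r_sum)
      }
    }
  }
  lambda <- exp(best$par[1]); rho <- exp(best$par[2])
  r <- setNames(R_MAX * plogis(best$par[2 + seq_len(n_a)]), fit_layers)
  w <- topology_weights(topology, r, k)
  f <- mixture_shape(cs, lambda, rho, w)
  g <- sum(sy * sqrt(f)) / sum(f)
  G <- g^2
  fit_counts <- G * f
  residual <- sum((y - fit_counts)^2) / sum(y^2)
  ## mass above the modelled peaks (repeat-like k-mers), relative to all
  ## distinct k-mers above the cutoff
  upper <- ploidy * lambda + 4 * sqrt(ploidy * lambda * (1 + rho))
  above <- sum(y_all[seq_along(y_all) > upper])
  total_kept <- sum(y_all[seq_along(y_all) >= cutoff])
  repeat_fraction <- if (total_kept > 0) above / total_kept else 0
  range_exceeded <- repeat_fraction > 0.30
  if (range_exceeded) {
    warning("spectrum mass above the modelled peaks exceeds 30%; ",
            "divergence may exceed the range quantifiable from the k-mer spectrum")
  }
  converged <- is.finite(residual) && residual < 0.9
  if (!converged) {
    warning("fit did not converge to an acceptable residual (",
            signif(residual, 3), "); inspect diagnostics")
  }
  structure(list(lambda_cov = lambda, rho = rho,
                 het_rates = 100 * r, composite_het = 100 * sum(r),
                 genome_size_G = G, ploidy = as.integer(ploidy),
                 topology = topology, error_cutoff = cutoff,
                 residual = residual, repeat_fraction = repeat_fraction,
                 range_exceeded = range_exceeded, composite = composite,
                 converged = converged, k = k,
                 fit_range = range(cs)),
            class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("spectrum_fit: NOT CONVERGED (", x$topology, ")\n", sep = "")
    return(invisible(x))
  }
  cat("spectrum_fit: ", x$topology, " (ploidy ", x$ploidy, ")\n", sep = "")
  cat(sprintf("  lambda (per-copy coverage): %.2f | rho: %.3f\n",
              x$lambda_cov, x$rho))
  for (ly in names(x$het_rates)) {
    cat(sprintf("  heterozygosity [%s]: %.3f%%\n", ly, x$het_rates[[ly]]))
  }
  cat(sprintf("  composite heterozygosity: %.3f%%%s\n", x$composite_het,
              if (isTRUE(x$composite)) " (layers not separable)" else ""))
  cat(sprintf("  genome size G: %s distinct k-mer units\n",
              format(round(x$genome_size_G), big.mark = ",")))
  cat(sprintf("  residual: %.4g | repeat fraction: %.3f\n",
              x$residual, x$repeat_fraction))
  invisible(x)
}

#' Rank candidate topologies by fit residual
#'
#' Auto mode for polyploid model exploration: fits each candidate topology
#' and reports the ranking by residual without committing to any of them
#' (ploidy/topology assignment remains a user decision).
#'
#' @param spectrum a `kmer_spectrum`.
#' @param candidates topology labels to try.
#' @return data.frame with `topology`, `ploidy`, `residual`,
#'   `composite_het`, ordered by residual.
#' @export
compare_topologies <- function(spectrum,
                               candidates = c("AB", "AAB", "ABC", "AAAB", "AABB")) {
  rows <- lapply(candidates, function(tp) {
    fit <- tryCatch(fit_spectrum(spectrum, TOPOLOGIES[[tp]]$ploidy, tp),
                    warning = function(w) suppressWarnings(
                      fit_spectrum(spectrum, TOPOLOGIES[[tp]]$ploidy, tp)),
                    error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) {
      data.frame(topology = tp, ploidy = TOPOLOGIES[[tp]]$ploidy,
                 residual = NA_real_, composite_het = NA_real_)
    } else {
      data.frame(topology = tp, ploidy = fit$ploidy, residual = fit$residual,
                 composite_het = fit$composite_het)
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$residual), ]
}
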