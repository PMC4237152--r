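# Diversity statistics: unbiased expected heterozygosity, hypergeometric
# rarefaction of allelic richness, and the MHC summary (alleles per
# individual, nucleotide diversity, Ewens theta-K).

# per-locus complete-call gene-copy counts as named integer vectors
locus_spectra <- function(x) allele_counts(x)

#' Unbiased expected heterozygosity
#'
#' Per locus, `H_E = N_g/(N_g - 1) * (1 - sum(p_i^2))` with allele
#' frequencies `p_i = N_i / N_g` computed over complete calls only
#' (`N_g` gene copies). Loci with no complete call are excluded with a
#' warning. The mean across loci is reported with its standard error
#' across loci.
#'
#' @param x A `geno_table`.
#' @return List with `per_locus` (named vector), `mean`, `se`, `n_loci`.
#' @export
#' @examples
#' a <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("i1","i2"), "L1"))
#' b <- matrix(c(2L, 2L), 2, 1, dimnames = list(c("i1","i2"), "L1"))
#' expected_heterozygosity(genotype_table(a, b))$mean
expected_heterozygosity <- function(x) {
  spectra <- locus_spectra(x)
  he <- vapply(spectra, function(cnt) {
    ng <- sum(cnt)
    if (ng < 2) return(NA_real_)
    p <- cnt / ng
    ng / (ng - 1) * (1 - sum(p^2))
  }, numeric(1))
  drop <- is.na(he)
  if (any(drop)) {
    warning("locus with fewer than two gene copies excluded: ",
            paste(names(he)[drop], collapse = ", "))
    he <- he[!drop]
  }
  list(per_locus = he,
       mean = mean(he),
       se = stats::sd(he) / sqrt(length(he)),
       n_loci = length(he))
}

#' Expected number of distinct alleles in a rarefied sample (closed form)
#'
#' Hypergeometric expectation of the number of distinct alleles among `g`
#' gene copies drawn without replacement from a spectrum of counts:
#' `A_g = sum_i [1 - choose(N_g - N_i, g) / choose(N_g, g)]`.
#'
#' @param counts Integer vector of allele counts (gene copies).
#' @param g Rarefaction depth in gene copies, `1 <= g <= sum(counts)`.
#' @return Expected distinct alleles (numeric scalar).
#' @export
#' @examples
#' rarefaction_expected_alleles(c(6, 3, 1), 2)  # 1.6
rarefaction_expected_alleles <- function(counts, g) {
  counts <- counts[counts > 0]
  ng <- sum(counts)
  if (g < 1 || g > ng) abort_ctx("depth g must be in [1, ", ng, "]")
  # log-scale binomial coefficients; choose(ng - Ni, g) = 0 when ng - Ni < g
  miss <- ifelse(ng - counts < g, 0,
                 exp(lchoose(ng - counts, g) - lchoose(ng, g)))
  sum(1 - miss)
}

#' Rarefied allelic richness
#'
#' Per-locus expected number of distinct alleles in a standardized
#' subsample of `g` gene copies (closed-form hypergeometric rarefaction),
#' and the mean across loci. A single global depth is used for all loci;
#' it defaults to the smallest complete-call gene-copy count across loci,
#' and must not exceed any locus's count.
#'
#' @param x A `geno_table`.
#' @param g Depth in gene copies; default `min` over loci of `N_g`.
#' @return List with `per_locus`, `mean`, `se`, `g`.
#' @export
rarefied_allelic_richness <- function(x, g = NULL) {
  spectra <- locus_spectra(x)
  ngs <- vapply(spectra, sum, numeric(1))
  keep <- ngs > 0
  if (!all(keep)) {
    warning("locus with zero complete calls excluded: ",
            paste(names(spectra)[!keep], collapse = ", "))
    spectra <- spectra[keep]; ngs <- ngs[keep]
  }
  if (is.null(g)) g <- min(ngs)
  g <- as.integer(g)
  if (g < 1) abort_ctx("depth g must be >= 1")
  too_small <- ngs < g
  if (any(too_small))
    abort_ctx("depth g = ", g, " exceeds gene copies at locus ",
              names(spectra)[which(too_small)[1]], " (", ngs[which(too_small)[1]], ")")
  ar <- vapply(spectra, rarefaction_expected_alleles, numeric(1), g = g)
  list(per_locus = ar, mean = mean(ar),
       se = stats::sd(ar) / sqrt(length(ar)), g = g)
}

#' Ewens sampling-formula estimate of theta from the number of alleles
#'
#' Solves the Ewens expectation
#' `sum_{m=0}^{n-1} theta / (theta + m) = k` for `theta`, the classic
#' allelic-richness index for haplotype-style data with `k` distinct
#' alleles among `n` observations. The left side is strictly increasing
#' in `theta`, so the root is unique; it is found by bracketed
#' root-finding. `k = 1` gives 0; `k = n` (all singletons) diverges and
#' is reported as `Inf` with a warning.
#'
#' @param k Observed number of distinct alleles.
#' @param n Number of observations (for MHC data: total carrier count).
#' @param tol Convergence tolerance on theta.
#' @return Numeric theta estimate.
#' @export
#' @examples
#' ewens_theta(10, 429)  # about 1.71
ewens_theta <- function(k, n, tol = 1e-10) {
  stopifnot(k >= 1, n >= 1, k <= n)
  if (k == 1) return(0)
  if (k == n) {
    warning("k equals n (all singletons): theta diverges, returning Inf")
    return(Inf)
  }
  f <- function(theta) sum(theta / (theta + 0:(n - 1))) - k
  upper <- 1
  while (f(upper) < 0) upper <- upper * 10
  stats::uniroot(f, c(1e-12, upper), tol = tol)$root
}

# pairwise nucleotide difference matrix between equal-length sequences
pairwise_diff_matrix <- function(seqs) {
  chars <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ])
  }
  d
}

#' Summary diversity statistics for an MHC profile set
#'
#' Treats the number of individuals carrying each allele as haplotype-style
#' observations: with carrier counts `c_i`, `n = sum(c_i)` and
#' `q_i = c_i / n`. Reports the number of distinct alleles observed (`k`),
#' the mean number of alleles per individual (`mhc_ind`), nucleotide
#' diversity `Pi = n/(n-1) * sum_{i != j} q_i q_j d_ij` expressed per
#' amplicon (pairwise differences `d_ij` between allele sequences, not
#' divided by sequence length), and the Ewens theta-K solving the
#' expectation of `k` given `n`.
#'
#' @param x An `mhc_profile_set` (sequences required for `pi`).
#' @return List with `k`, `n_individuals`, `n_carriers`, `mhc_ind`, `pi`
#'   (NA without sequences), `theta_k`.
#' @export
mhc_summary <- function(x) {
  stopifnot(inherits(x, "mhc_profile_set"))
  if (length(x$profiles) < 2) abort_ctx("need at least two individuals")
  cc <- carrier_counts(x)
  cc <- cc[cc > 0]
  k <- length(cc)
  n <- sum(cc)
  q <- cc / n
  pi <- NA_real_
  if (!is.null(x$sequences)) {
    d <- pairwise_diff_matrix(x$sequences[names(cc)])
    pi <- n / (n - 1) * as.numeric(t(q) %*% d %*% q)
  }
  list(k = k,
       n_individuals = length(x$profiles),
       n_carriers = n,
       mhc_ind = mean(lengths(x$profiles)),
       pi = pi,
       theta_k = ewens_theta(k, n))
}

#' Per-stratum diversity report
#'
#' One row per stratum, mirroring the standard catch-year summary table:
#' microsatellite sample size, mean expected heterozygosity with SE,
#' rarefied allelic richness at a shared depth, and (when MHC data are
#' supplied) MHC sample size, number of alleles, mean alleles per
#' individual, nucleotide diversity and theta-K.
#'
#' @param geno A `geno_table` (or NULL).
#' @param frame A `sample_frame`.
#' @param mhc Optional `mhc_profile_set`.
#' @param strata Stratum labels (default all in `frame`).
#' @param depth Rarefaction depth in gene copies; default the smallest
#'   complete-call count over loci and strata, so all strata share one
#'   standardized depth.
#' @return A `data.frame`, one row per stratum.
#' @export
diversity_report <- function(geno, frame, mhc = NULL, strata = NULL,
                             depth = NULL) {
  strata <- strata %||% strata_of(frame)
  subs <- if (!is.null(geno))
    lapply(strata, function(s) subset_stratum(geno, frame, s))
  if (!is.null(geno) && is.null(depth)) {
    depth <- min(vapply(subs, function(tb)
      min(vapply(locus_spectra(tb), sum, numeric(1))), numeric(1)))
    message("rarefaction depth defaulting to g = ", depth, " gene copies")
  }
  rows <- lapply(seq_along(strata), function(i) {
    s <- strata[[i]]
    out <- data.frame(stratum = s, stringsAsFactors = FALSE)
    if (!is.null(geno)) {
      tb <- subs[[i]]
      he <- expected_heterozygosity(tb)
      ar <- rarefied_allelic_richness(tb, g = depth)
      out$n_msat <- n_individuals(tb)
      out$he <- he$mean; out$he_se <- he$se
      out$richness <- ar$mean; out$richness_se <- ar$se
      out$depth <- depth
    }
    if (!is.null(mhc)) {
      ids <- intersect(individuals_in(frame, s), names(mhc$profiles))
      if (length(ids) >= 2) {
        ms <- mhc_summary(subset_individuals(mhc, ids))
        out$n_mhc <- ms$n_individuals; out$mhc_alleles <- ms$k
        out$mhc_ind <- ms$mhc_ind; out$pi <- ms$pi; out$theta_k <- ms$theta_k
      } else {
        out$n_mhc <- length(ids); out$mhc_alleles <- NA_integer_
        out$mhc_ind <- NA_real_; out$pi <- NA_real_; out$theta_k <- NA_real_
      }
    }
    out
  })
  do.call(rbind, rows)
}
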