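# Effective population size from linkage disequilibrium between unlinked
# loci: Burrows composite disequilibrium, sampling-bias correction and
# inversion under the random-mating model.

# copies (0/1/2) of each allele per individual, one matrix per locus
allele_dosage <- function(x) {
  lapply(seq_along(x$loci), function(l) {
    lev <- sort(unique(c(x$a1[, l], x$a2[, l])))
    lev <- lev[!is.na(lev)]
    m <- vapply(lev, function(al)
      (x$a1[, l] == al) + (x$a2[, l] == al), numeric(nrow(x$a1)))
    m <- matrix(m, nrow = nrow(x$a1),
                dimnames = list(x$individuals, as.character(lev)))
    m
  })
}

# Waples (2006) / Waples & Do (2008) random-mating bias correction and
# inversion. S is the (harmonic mean) sample size per comparison.
ldne_invert <- function(r2, S) {
  if (S >= 30) {
    r2p <- r2 - 1 / S - 3.19 / S^2
    if (r2p <= 0) return(Inf)
    disc <- max(0, 1 / 9 - 2.76 * r2p)
    (1 / 3 + sqrt(disc)) / (2 * r2p)
  } else {
    r2p <- r2 - 0.0018 - 0.907 / S - 4.44 / S^2
    if (r2p <= 0) return(Inf)
    disc <- max(0, 0.308^2 - 2.08 * r2p)
    (0.308 + sqrt(disc)) / (2 * r2p)
  }
}

#' LD-based effective population size (random-mating model)
#'
#' For every pair of loci and every retained allele pair, the Burrows
#' composite disequilibrium is estimated over complete-case individuals,
#' `Delta = S/(S-1) * (mean(x*y)/2 - 2*p*q)` with `x`, `y` the per-
#' individual allele dosages, and squared correlation
#' `r^2 = Delta^2 / (p(1-p) q(1-q))`. Alleles with frequency below the
#' floor (or whose complement is, at effectively biallelic loci) are
#' excluded before pairing; when every allele of a locus passes the floor
#' the most common one is dropped as linearly redundant. The unweighted
#' mean `r^2` over comparisons is bias-corrected for sample size and
#' inverted to `N_e` with the random-mating formulas of the LDNE lineage
#' (separate branches for harmonic-mean `S` above/below 30); a corrected
#' mean at or below zero is reported as `Inf`. The confidence interval is
#' parametric (chi-square on the pooled `r^2` with one degree of freedom
#' per comparison).
#'
#' @param x A `geno_table`.
#' @param frame Optional `sample_frame` (with `stratum`) restricting the
#'   estimate to one stratum.
#' @param stratum Stratum label (required with `frame`).
#' @param maf Minor-allele-frequency floor in `[0, 0.5)` (default 0.02).
#' @param ci Confidence level (default 0.95).
#' @return Object of class `ne_estimate`: list with `ne`, `ci` (lower,
#'   upper), `r2_mean`, `r2_expected_null`, `S` (harmonic mean),
#'   `n_comparisons`, `n_locus_pairs`, `maf`.
#' @export
ld_ne <- function(x, frame = NULL, stratum = NULL, maf = 0.02, ci = 0.95) {
  stopifnot(inherits(x, "geno_table"), maf >= 0, maf < 0.5)
  if (!is.null(frame)) {
    if (is.null(stratum)) abort_ctx("stratum must be given with frame")
    x <- subset_stratum(x, frame, stratum)
  }
  L <- length(x$loci)
  if (L < 2) abort_ctx("need at least 2 loci")
  dos <- allele_dosage(x)
  missing_mask <- is.na(x$a1)

  r2_all <- numeric(0); S_all <- numeric(0); pairs_used <- 0L
  for (l1 in seq_len(L - 1)) for (l2 in (l1 + 1):L) {
    ok <- !missing_mask[, l1] & !missing_mask[, l2]
    S <- sum(ok)
    if (S < 10) next
    M1 <- dos[[l1]][ok, , drop = FALSE]
    M2 <- dos[[l2]][ok, , drop = FALSE]
    sel1 <- select_alleles(colMeans(M1) / 2, maf)
    sel2 <- select_alleles(colMeans(M2) / 2, maf)
    if (!length(sel1) || !length(sel2)) next
    M1 <- M1[, sel1, drop = FALSE]; M2 <- M2[, sel2, drop = FALSE]
    p <- colMeans(M1) / 2; q <- colMeans(M2) / 2
    # Burrows composite Delta for all allele pairs at once
    cross <- crossprod(M1, M2) / S / 2          # mean(x*y)/2
    delta <- (S / (S - 1)) * (cross - 2 * outer(p, q))
    denom <- outer(p * (1 - p), q * (1 - q))
    r2 <- delta^2 / denom
    r2_all <- c(r2_all, as.numeric(r2))
    S_all <- c(S_all, rep(S, length(r2)))
    pairs_used <- pairs_used + 1L
  }
  if (!length(r2_all))
    abort_ctx("no usable locus-pair comparison after applying the frequency floor")
  S_harm <- 1 / mean(1 / S_all)
  r2_mean <- mean(r2_all)
  ne <- ldne_invert(r2_mean, S_harm)
  df <- length(r2_all)
  alpha <- 1 - ci
  r2_bounds <- df * r2_mean / stats::qchisq(c(1 - alpha / 2, alpha / 2), df)
  ci_ne <- sort(vapply(r2_bounds, ldne_invert, numeric(1), S = S_harm))
  exp_null <- if (S_harm >= 30) 1 / S_harm + 3.19 / S_harm^2 else
    0.0018 + 0.907 / S_harm + 4.44 / S_harm^2
  structure(list(ne = ne, ci = ci_ne, r2_mean = r2_mean,
                 r2_expected_null = exp_null, S = S_harm,
                 n_comparisons = df, n_locus_pairs = pairs_used, maf = maf),
            class = "ne_estimate")
}

# alleles retained for LD comparisons at one locus: frequency floor on
# both the allele and its complement; if all alleles pass, drop the most
# common (linearly redundant given the others)
select_alleles <- function(freqs, maf) {
  keep <- which(freqs >= maf & freqs <= 1 - maf)
  if (length(keep) == length(freqs) && length(keep) > 1) {
    keep <- keep[-which.max(freqs[keep])]
  }
  keep
}

#' @export
print.ne_estimate <- function(x, ...) {
  ne_txt <- if (is.infinite(x$ne)) "Inf" else sprintf("%.1f", x$ne)
  cat(sprintf(
    "LD Ne estimate: %s (CI %.1f-%s), mean r2 = %.5f over %d comparisons (%d locus pairs), harmonic S = %.1f, MAF floor %.2f\n",
    ne_txt, x$ci[1], if (is.infinite(x$ci[2])) "Inf" else sprintf("%.1f", x$ci[2]),
    x$r2_mean, x$n_comparisons, x$n_locus_pairs, x$S, x$maf))
  invisible(x)
}
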