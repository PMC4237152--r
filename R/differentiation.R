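# Differentiation among strata: Weir-Cockerham F_ST (diploid genotypes and
# a haploid analogue for MHC carrier counts), Jost's D with Nei-Chesser
# corrections, a permutation G-test of global differentiation, and the
# Mantel comparison of distance matrices.

# Weir & Cockerham (1984) variance components a, b, c summed over loci and
# alleles for a list of geno_table samples (one per population).
wc_components <- function(tables) {
  r <- length(tables)
  loci <- tables[[1]]$loci
  A <- B <- C <- 0
  for (l in loci) {
    counts <- lapply(tables, allele_counts, locus = l)
    ni <- vapply(counts, sum, numeric(1)) / 2          # individuals scored
    if (any(ni < 2)) next                              # WC needs nbar > 1
    alleles <- sort(unique(unlist(lapply(counts, names))))
    if (length(alleles) < 2) next                      # monomorphic: skip
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p_i <- vapply(counts, function(ct) {
        v <- ct[al]; if (is.na(v)) 0 else as.numeric(v)
      }, numeric(1)) / (2 * ni)
      # observed heterozygote proportion for this allele in each pop
      h_i <- vapply(seq_len(r), function(i) {
        tb <- tables[[i]]
        g1 <- tb$a1[, l]; g2 <- tb$a2[, l]
        ok <- !is.na(g1)
        ali <- as.integer(al)
        mean(xor(g1[ok] == ali, g2[ok] == ali))
      }, numeric(1))
      pbar <- sum(ni * p_i) / (r * nbar)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A <- A + a; B <- B + b; C <- C + cc
    }
  }
  list(a = A, b = B, c = C)
}

wc_theta_tables <- function(tables) {
  comp <- wc_components(tables)
  den <- comp$a + comp$b + comp$c
  if (den == 0) return(NA_real_)
  comp$a / den
}

# haploid-analogue theta on MHC carrier counts: for each allele,
# MSP/MSG mean squares over populations of haplotype-style observations
haploid_theta <- function(count_list) {
  r <- length(count_list)
  alleles <- sort(unique(unlist(lapply(count_list, names))))
  ni <- vapply(count_list, sum, numeric(1))
  if (any(ni < 2) || length(alleles) < 2) return(NA_real_)
  ntot <- sum(ni)
  nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
  num <- den <- 0
  for (al in alleles) {
    ci <- vapply(count_list, function(ct) {
      v <- ct[al]; if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1))
    p_i <- ci / ni
    pbar <- sum(ci) / ntot
    msp <- sum(ni * (p_i - pbar)^2) / (r - 1)
    msg <- sum(ni * p_i * (1 - p_i)) / sum(ni - 1)
    num <- num + (msp - msg)
    den <- den + (msp + (nc - 1) * msg)
  }
  if (den == 0) return(NA_real_)
  num / den
}

mhc_stratum_counts <- function(x, ids) {
  cc <- carrier_counts(subset_individuals(x, ids))
  cc[cc >= 0]
}

#' Pairwise F_ST between two strata
#'
#' For microsatellite genotypes the Weir-Cockerham (1984) theta estimator
#' is used: variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) are
#' computed per locus and allele, and theta is the ratio of sums. For MHC
#' profile data a haploid analogue on carrier counts is used. Monomorphic
#' loci are skipped; negative estimates are reported as computed. The P
#' value permutes individuals between the two strata and recomputes theta:
#' `P = (1 + #\{theta* >= theta_obs\}) / (permutations + 1)`.
#'
#' @param x A `geno_table` or `mhc_profile_set`.
#' @param frame A `sample_frame`.
#' @param strata_pair Character vector of two stratum labels.
#' @param permutations Number of permutations (default 9999; 0 skips the
#'   test and returns `p = NA`).
#' @param seed Optional integer seed.
#' @return List with `theta`, `p`, `permutations`, `strata`.
#' @export
pairwise_fst <- function(x, frame, strata_pair, permutations = 9999L,
                         seed = NULL) {
  stopifnot(length(strata_pair) == 2)
  ids1 <- intersect(individuals_in(frame, strata_pair[1]), .pool_ids(x))
  ids2 <- intersect(individuals_in(frame, strata_pair[2]), .pool_ids(x))
  if (length(ids1) < 2 || length(ids2) < 2)
    abort_ctx("each stratum needs at least 2 individuals with data")
  theta_fun <- if (inherits(x, "geno_table")) {
    function(i1, i2) wc_theta_tables(list(subset_individuals(x, i1),
                                          subset_individuals(x, i2)))
  } else {
    function(i1, i2) haploid_theta(list(mhc_stratum_counts(x, i1),
                                        mhc_stratum_counts(x, i2)))
  }
  obs <- theta_fun(ids1, ids2)
  p <- NA_real_
  if (permutations > 0) {
    all_ids <- c(ids1, ids2); n1 <- length(ids1)
    with_seed(seed, {
      hits <- 0L
      for (i in seq_len(permutations)) {
        perm <- sample(all_ids)
        th <- theta_fun(perm[seq_len(n1)], perm[-seq_len(n1)])
        if (!is.na(th) && th >= obs) hits <- hits + 1L
      }
      p <- (1 + hits) / (permutations + 1)
    })
  }
  list(theta = obs, p = p, permutations = as.integer(permutations),
       strata = strata_pair)
}

# Nei-Chesser-corrected Hs/Ht and Jost's D per locus for two or more
# frequency spectra; nt = individuals scored per population
jost_d_from_counts <- function(count_list, n_ind) {
  s <- length(count_list)
  alleles <- sort(unique(unlist(lapply(count_list, names))))
  freqs <- vapply(count_list, function(ct) {
    v <- stats::setNames(numeric(length(alleles)), alleles)
    v[names(ct)] <- ct / sum(ct)
    v
  }, numeric(length(alleles)))
  freqs <- matrix(freqs, nrow = length(alleles))
  hs <- mean(1 - colSums(freqs^2))
  pbar <- rowMeans(freqs)
  ht <- 1 - sum(pbar^2)
  nh <- 1 / mean(1 / n_ind)                 # harmonic mean sample size
  hs_est <- (2 * nh / (2 * nh - 1)) * hs
  ht_est <- ht + hs_est / (2 * nh * s)
  if (hs_est >= 1) return(0)
  ((ht_est - hs_est) / (1 - hs_est)) * (s / (s - 1))
}

#' Pairwise Jost's D between two strata
#'
#' Per locus, `D = [(H_T - H_S) / (1 - H_S)] * s/(s-1)` with
#' Nei-Chesser sample-size-corrected `H_S` and `H_T` (harmonic-mean
#' sample size). The multi-locus summary is the harmonic mean of
#' per-locus values when all are positive, otherwise the arithmetic mean
#' (the harmonic mean is undefined at zero); per-locus values are
#' returned so users can recombine.
#'
#' @inheritParams pairwise_fst
#' @return List with `d` (multi-locus), `per_locus`, `strata`.
#' @export
pairwise_dest <- function(x, frame, strata_pair) {
  stopifnot(length(strata_pair) == 2)
  if (inherits(x, "geno_table")) {
    t1 <- subset_stratum(x, frame, strata_pair[1])
    t2 <- subset_stratum(x, frame, strata_pair[2])
    if (n_individuals(t1) < 2 || n_individuals(t2) < 2)
      abort_ctx("each stratum needs at least 2 individuals with data")
    per_locus <- vapply(x$loci, function(l) {
      c1 <- allele_counts(t1, l); c2 <- allele_counts(t2, l)
      if (!sum(c1) || !sum(c2)) return(NA_real_)
      jost_d_from_counts(list(c1, c2), c(sum(c1) / 2, sum(c2) / 2))
    }, numeric(1))
  } else {
    ids1 <- intersect(individuals_in(frame, strata_pair[1]), names(x$profiles))
    ids2 <- intersect(individuals_in(frame, strata_pair[2]), names(x$profiles))
    c1 <- mhc_stratum_counts(x, ids1); c1 <- c1[c1 > 0]
    c2 <- mhc_stratum_counts(x, ids2); c2 <- c2[c2 > 0]
    per_locus <- c(MHC = jost_d_from_counts(list(c1, c2),
                                            c(sum(c1), sum(c2)) / 2))
  }
  pl <- per_locus[!is.na(per_locus)]
  d <- if (all(pl > 0)) 1 / mean(1 / pl) else mean(pl)
  list(d = d, per_locus = per_locus, strata = strata_pair)
}

#' Global permutation test of differentiation across strata
#'
#' Tests the null of identical allele distributions across strata with a
#' permutation G-test: the statistic is the sum over loci of the G
#' statistic of the allele-count x stratum contingency table, and the
#' null distribution is generated by permuting individuals among strata
#' (a permutation scheme standing in for the exact-test Markov chain of
#' the classic implementations, with the same null).
#'
#' @param x A `geno_table`.
#' @param frame A `sample_frame`.
#' @param strata Stratum labels (default all; at least 2).
#' @param steps Number of permutations (default 30000).
#' @param seed Optional integer seed.
#' @return List with `g` (observed statistic), `p`, `steps`.
#' @export
global_exact_test <- function(x, frame, strata = NULL, steps = 30000L,
                              seed = NULL) {
  stopifnot(inherits(x, "geno_table"))
  strata <- strata %||% strata_of(frame)
  if (length(strata) < 2) abort_ctx("need at least 2 strata")
  ids <- unlist(lapply(strata, function(s)
    intersect(individuals_in(frame, s), x$individuals)))
  grp <- rep(seq_along(strata), vapply(strata, function(s)
    length(intersect(individuals_in(frame, s), x$individuals)), integer(1)))
  tab <- subset_individuals(x, ids)
  n <- length(ids); G <- length(strata); L <- length(tab$loci)
  # per-locus integer allele codes per gene copy, individual-indexed
  codes <- lapply(seq_len(L), function(l) {
    lev <- sort(unique(c(tab$a1[, l], tab$a2[, l])))
    lev <- lev[!is.na(lev)]
    list(K = length(lev),
         c1 = match(tab$a1[, l], lev), c2 = match(tab$a2[, l], lev))
  })
  g_stat <- function(grp_vec) {
    tot <- 0
    for (l in seq_len(L)) {
      K <- codes[[l]]$K
      if (K < 2) next
      v <- c(codes[[l]]$c1, codes[[l]]$c2)
      g2 <- c(grp_vec, grp_vec)
      ok <- !is.na(v)
      cnt <- tabulate(v[ok] + K * (g2[ok] - 1L), K * G)
      m <- matrix(cnt, K, G)
      rs <- rowSums(m); cs <- colSums(m); tt <- sum(m)
      if (tt == 0) next
      e <- outer(rs, cs) / tt
      nz <- m > 0
      tot <- tot + 2 * sum(m[nz] * log(m[nz] / e[nz]))
    }
    tot
  }
  obs <- g_stat(grp)
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(steps)) {
      if (g_stat(sample(grp)) >= obs) hits <- hits + 1L
    }
  })
  list(g = obs, p = (1 + hits) / (steps + 1), steps = as.integer(steps))
}

#' Pairwise differentiation matrix over a set of strata
#'
#' @param x A `geno_table` or `mhc_profile_set`.
#' @param frame A `sample_frame`.
#' @param strata Stratum labels (default all).
#' @param method `"fst"` or `"dest"`.
#' @param permutations Permutations for the per-pair F_ST test (D has no
#'   permutation test here).
#' @param seed Optional integer seed.
#' @return Object of class `dist_matrix`: list with `labels`, `stat`
#'   (symmetric matrix, zero diagonal), `p` (matrix or NULL), `method`,
#'   `permutations`, `seed`.
#' @export
differentiation_matrix <- function(x, frame, strata = NULL,
                                   method = c("fst", "dest"),
                                   permutations = 9999L, seed = NULL) {
  method <- match.arg(method)
  strata <- strata %||% strata_of(frame)
  k <- length(strata)
  stat <- matrix(0, k, k, dimnames = list(strata, strata))
  pmat <- if (method == "fst") stat + NA else NULL
  if (method == "fst") diag(pmat) <- NA
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (method == "fst") {
      res <- pairwise_fst(x, frame, c(strata[i], strata[j]),
                          permutations = permutations,
                          seed = if (is.null(seed)) NULL else
                            derive_seed(seed, paste0("fst:", strata[i], ":", strata[j])))
      stat[i, j] <- stat[j, i] <- res$theta
      pmat[i, j] <- pmat[j, i] <- res$p
    } else {
      res <- pairwise_dest(x, frame, c(strata[i], strata[j]))
      stat[i, j] <- stat[j, i] <- res$d
    }
  }
  structure(list(labels = strata, stat = stat, p = pmat, method = method,
                 permutations = as.integer(permutations), seed = seed),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<dist_matrix> %s over %d strata\n", x$method, length(x$labels)))
  print(round(x$stat, digits))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' `r_M` is the Pearson correlation of the lower-triangle entries; the
#' upper-tail P value is obtained by jointly permuting the row/column
#' labels of the second matrix.
#'
#' @param a,b `dist_matrix` objects or plain symmetric matrices with
#'   identical dimnames (at least 4 labels).
#' @param permutations Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @return List with `r`, `p`, `permutations`.
#' @export
mantel_test <- function(a, b, permutations = 9999L, seed = NULL) {
  ma <- if (inherits(a, "dist_matrix")) a$stat else as.matrix(a)
  mb <- if (inherits(b, "dist_matrix")) b$stat else as.matrix(b)
  if (!identical(dimnames(ma)[[1]], dimnames(mb)[[1]]))
    abort_ctx("matrix labels differ or are ordered differently")
  k <- nrow(ma)
  if (k < 4) abort_ctx("need at least 4 strata for a Mantel test")
  lower <- lower.tri(ma)
  r_obs <- stats::cor(ma[lower], mb[lower])
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(permutations)) {
      perm <- sample.int(k)
      r_star <- stats::cor(ma[lower], mb[perm, perm][lower])
      if (r_star >= r_obs) hits <- hits + 1L
    }
  })
  list(r = r_obs, p = (1 + hits) / (permutations + 1),
       permutations = as.integer(permutations))
}
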