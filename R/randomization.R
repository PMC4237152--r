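# Pooled randomization test of change in a diversity statistic between two
# samples (typically the earliest and latest catch years of one population).

# fast per-subset statistic closures over a pooled object; idx indexes
# pooled individuals
rand_stat_closure <- function(pool, statistic, g = NULL) {
  if (is.function(statistic)) {
    # bootstrap draws repeat individuals; rebuild with fresh unique IDs
    if (inherits(pool, "geno_table")) {
      return(function(idx) statistic(genotype_table(
        pool$a1[idx, , drop = FALSE], pool$a2[idx, , drop = FALSE],
        individuals = paste0("r", seq_along(idx)), loci = pool$loci)))
    }
    return(function(idx) statistic(mhc_profile_set(
      stats::setNames(pool$profiles[idx], paste0("r", seq_along(idx))),
      sequences = pool$sequences, universe = pool$universe)))
  }
  if (inherits(pool, "geno_table")) {
    # recode alleles to 1..K per locus once, then tabulate per draw
    L <- length(pool$loci)
    codes1 <- pool$a1; codes2 <- pool$a2; K <- integer(L)
    for (l in seq_len(L)) {
      lev <- sort(unique(c(pool$a1[, l], pool$a2[, l])))
      lev <- lev[!is.na(lev)]
      K[l] <- length(lev)
      codes1[, l] <- match(pool$a1[, l], lev)
      codes2[, l] <- match(pool$a2[, l], lev)
    }
    switch(statistic,
      he = function(idx) {
        tot <- 0; m <- 0L
        for (l in seq_len(L)) {
          v <- c(codes1[idx, l], codes2[idx, l])
          cnt <- tabulate(v[!is.na(v)], K[l])
          ng <- sum(cnt)
          if (ng < 2) next
          p <- cnt / ng
          tot <- tot + ng / (ng - 1) * (1 - sum(p^2)); m <- m + 1L
        }
        if (m == 0L) NA_real_ else tot / m
      },
      richness = {
        if (is.null(g)) abort_ctx("statistic 'richness' needs a depth g")
        function(idx) {
          tot <- 0; m <- 0L
          for (l in seq_len(L)) {
            v <- c(codes1[idx, l], codes2[idx, l])
            cnt <- tabulate(v[!is.na(v)], K[l])
            if (sum(cnt) < g) return(NA_real_)
            tot <- tot + rarefaction_expected_alleles(cnt, g); m <- m + 1L
          }
          if (m == 0L) NA_real_ else tot / m
        }
      },
      abort_ctx("unknown genotype statistic: ", statistic)
    )
  } else if (inherits(pool, "mhc_profile_set")) {
    sizes <- lengths(pool$profiles)
    plist <- pool$profiles
    seqs <- pool$sequences
    switch(statistic,
      mhc_ind = function(idx) mean(sizes[idx]),
      pi = {
        if (is.null(seqs)) abort_ctx("statistic 'pi' needs allele sequences")
        d <- pairwise_diff_matrix(seqs)
        universe <- names(seqs)
        function(idx) {
          cc <- table(factor(unlist(plist[idx], use.names = FALSE),
                             levels = universe))
          n <- sum(cc)
          if (n < 2) return(NA_real_)
          q <- as.numeric(cc) / n
          n / (n - 1) * as.numeric(t(q) %*% d %*% q)
        }
      },
      thetak = function(idx) {
        cc <- table(unlist(plist[idx], use.names = FALSE))
        n <- sum(cc); k <- length(cc)
        if (n < 2 || k == n) return(NA_real_)
        ewens_theta(k, n)
      },
      abort_ctx("unknown MHC statistic: ", statistic)
    )
  } else abort_ctx("unsupported data type for randomization test")
}

.pool_ids <- function(pool)
  if (inherits(pool, "geno_table")) pool$individuals else names(pool$profiles)

# concatenate two same-type objects, renaming to avoid ID clashes
pool_individuals <- function(a, b) {
  if (inherits(a, "geno_table")) {
    ids <- c(paste0("A.", a$individuals), paste0("B.", b$individuals))
    if (!identical(a$loci, b$loci)) abort_ctx("samples have different loci")
    genotype_table(rbind(a$a1, b$a1), rbind(a$a2, b$a2),
                   individuals = ids, loci = a$loci)
  } else {
    profiles <- c(a$profiles, b$profiles)
    names(profiles) <- c(paste0("A.", names(a$profiles)),
                         paste0("B.", names(b$profiles)))
    mhc_profile_set(profiles, sequences = a$sequences %||% b$sequences,
                    universe = union(a$universe, b$universe))
  }
}

#' Pooled randomization test for a difference in a diversity statistic
#'
#' The two samples are pooled; `B` times, two pseudo-samples of the
#' original sizes are drawn from the pool *with replacement* and the
#' statistic difference is recomputed. The two-sided P value is
#' `(1 + #\{|d*| >= |d_obs|\}) / (B + 1)`; the `+1` correction keeps
#' P strictly positive. With `tail = "one"`, only resampled differences
#' at least as extreme *in the observed direction* are counted.
#'
#' Pseudo-samples on which the statistic is undefined (e.g. a locus with
#' no complete call) are redrawn; the number of redraws is recorded.
#'
#' @param a,b Two disjoint samples of the same type (`geno_table` or
#'   `mhc_profile_set`).
#' @param statistic `"he"` or `"richness"` for genotype data; `"mhc_ind"`,
#'   `"pi"` or `"thetak"` for MHC data; or a function mapping a sample to
#'   a scalar.
#' @param B Number of resampling iterations (default 100000; minimum 100).
#' @param seed Optional integer seed.
#' @param tail `"two"` (default) or `"one"`.
#' @param g Rarefaction depth for `statistic = "richness"`; defaults to
#'   the smallest complete-call gene-copy count over loci in `a` and `b`.
#' @return An object of class `randomization_result`: list with
#'   `statistic`, `observed` (a minus b), `B`, `p`, `seed`, `tail`,
#'   `redraws`.
#' @export
randomization_test <- function(a, b, statistic, B = 100000L, seed = NULL,
                               tail = c("two", "one"), g = NULL) {
  tail <- match.arg(tail)
  B <- as.integer(B)
  if (B < 100L) abort_ctx("B < 100 gives an unstable P estimate")
  if (identical(statistic, "richness") && is.null(g)) {
    g <- min(vapply(c(locus_spectra(a), locus_spectra(b)), sum, numeric(1)))
  }
  pool <- pool_individuals(a, b)
  na <- n_individuals(a); nb <- n_individuals(b); np <- na + nb
  fun <- rand_stat_closure(pool, statistic, g = g)
  obs <- fun(seq_len(na)) - fun(na + seq_len(nb))
  if (is.na(obs)) abort_ctx("statistic undefined on an observed sample")
  with_seed(seed, {
    d <- numeric(B); redraws <- 0L
    for (i in seq_len(B)) {
      repeat {
        di <- fun(sample.int(np, na, replace = TRUE)) -
              fun(sample.int(np, nb, replace = TRUE))
        if (!is.na(di)) break
        redraws <- redraws + 1L
        if (redraws > 100L * B) abort_ctx("statistic undefined on too many pseudo-samples")
      }
      d[i] <- di
    }
  })
  if (redraws > 0)
    message(redraws, " pseudo-sample(s) redrawn (statistic undefined)")
  p <- if (tail == "two") {
    (1 + sum(abs(d) >= abs(obs))) / (B + 1)
  } else {
    s <- if (obs >= 0) 1 else -1
    (1 + sum(s * d >= s * obs)) / (B + 1)
  }
  structure(list(statistic = if (is.function(statistic)) "custom" else statistic,
                 observed = obs, B = B, p = p, seed = seed, tail = tail,
                 redraws = redraws),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("Randomization test (%s, %s-tailed): observed difference %.4g, B = %d, P = %.4g\n",
              x$statistic, x$tail, x$observed, x$B, x$p))
  invisible(x)
}
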