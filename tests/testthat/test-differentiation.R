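test_that("Weir-Cockerham theta matches the hand-worked one-locus example", {
  # pop1: AA, AA, AB; pop2: BB, AB, BB. Components worked by hand:
  # per allele a = 7/36, b = 0, c = 1/6 -> theta = 7/13
  toy <- wc_toy()
  r <- pairwise_fst(toy$tb, toy$fr, c("p1_2000", "p2_2000"), permutations = 0)
  expect_equal(r$theta, 7 / 13, tolerance = 1e-12)
})

test_that("F_ST null and fixed-difference extremes", {
  ds <- simulate_source(sim_config(n_source = 40, loci = rep(3L, 8),
                                   missing_rate = 0), seed = 71)
  tb <- ds$geno
  # a stratum against an exact copy of itself
  dup <- genotype_table(rbind(tb$a1, tb$a1), rbind(tb$a2, tb$a2),
                        individuals = c(paste0("a", 1:40), paste0("b", 1:40)),
                        loci = tb$loci)
  fr <- sample_frame(dup$individuals, rep(c("x", "y"), each = 40), 2000)
  r <- pairwise_fst(dup, fr, c("x_2000", "y_2000"), permutations = 199,
                    seed = 72)
  expect_lte(r$theta, 0.01)
  expect_gt(r$p, 0.05)
  # strata fixed for alternate alleles at every locus
  fixed <- genotype_table(matrix(rep(c(1L, 2L), each = 4), 8, 2),
                          matrix(rep(c(1L, 2L), each = 4), 8, 2),
                          individuals = paste0("i", 1:8),
                          loci = c("L1", "L2"))
  fr2 <- sample_frame(fixed$individuals, rep(c("x", "y"), each = 4), 2000)
  r2 <- pairwise_fst(fixed, fr2, c("x_2000", "y_2000"), permutations = 99,
                     seed = 73)
  expect_equal(r2$theta, 1)
  expect_lt(r2$p, 0.05)
  expect_error(pairwise_fst(fixed, fr2, c("x_2000", "nope_1"), permutations = 0),
               "empty or unknown")
})

test_that("MHC haploid-analogue F_ST behaves at the extremes", {
  same <- mhc_profile_set(c(
    stats::setNames(rep(list(c("A01", "A02")), 6), paste0("i", 1:6)),
    stats::setNames(rep(list(c("A01", "A03")), 6), paste0("j", 1:6))))
  fr <- sample_frame(names(same$profiles), rep(c("x", "y"), each = 6), 2000)
  # identical carrier distributions (both strata get a mix)
  mix <- mhc_profile_set(stats::setNames(
    rep(list(c("A01", "A02"), c("A01", "A03")), 6), paste0("k", 1:12)))
  # profiles alternate, so contiguous halves hold identical carrier mixes
  fr_mix <- sample_frame(names(mix$profiles), rep(c("x", "y"), each = 6), 2000)
  r_null <- pairwise_fst(mix, fr_mix, c("x_2000", "y_2000"),
                         permutations = 99, seed = 74)
  # identical carrier mixes: theta is reported as computed, at its exact
  # small-sample null value -1/(n_c - 1), never positive
  expect_lte(r_null$theta, 0.01)
  expect_equal(r_null$theta, -1 / 11, tolerance = 1e-12)
  expect_gt(r_null$p, 0.05)
  # disjoint-ish carrier sets differentiate strongly
  r_diff <- pairwise_fst(same, fr, c("x_2000", "y_2000"), permutations = 99,
                         seed = 75)
  expect_gt(r_diff$theta, r_null$theta)
})

test_that("Jost's D matches its hand-worked and forced cases", {
  # identical allele frequencies -> D estimates 0; the Nei-Chesser
  # finite-sample correction leaves it slightly negative, never positive
  d0 <- translocgen:::jost_d_from_counts(list(c(a = 10, b = 10),
                                              c(a = 10, b = 10)), c(10, 10))
  expect_lte(d0, 0)
  expect_gt(d0, -0.1)
  # fully fixed differences -> D = 1
  tb <- genotype_table(matrix(rep(c(1L, 2L), each = 5), 10, 1),
                       matrix(rep(c(1L, 2L), each = 5), 10, 1),
                       individuals = paste0("i", 1:10), loci = "L1")
  fr <- sample_frame(tb$individuals, rep(c("x", "y"), each = 5), 2000)
  expect_equal(pairwise_dest(tb, fr, c("x_2000", "y_2000"))$d, 1,
               tolerance = 1e-12)
  # two-stratum spectra p = (0.7, 0.3) vs (0.3, 0.7), 20 gene copies each:
  # hs = 0.42, Hs_est = 0.42 * 20/19, Ht_est = 0.5 + Hs_est/40, s = 2
  hs_est <- 0.42 * 20 / 19
  ht_est <- 0.5 + hs_est / 40
  expected_d <- (ht_est - hs_est) / (1 - hs_est) * 2
  d <- translocgen:::jost_d_from_counts(list(c(a = 14, b = 6),
                                             c(a = 6, b = 14)), c(10, 10))
  expect_equal(d, expected_d, tolerance = 1e-12)
  expect_equal(d, 0.2471698113, tolerance = 1e-9)
})

test_that("global exact test: forced extremes", {
  # strata fixed for different alleles: maximal statistic, P = 1/(steps+1)
  tb <- genotype_table(matrix(rep(c(1L, 2L), each = 6), 12, 2),
                       matrix(rep(c(1L, 2L), each = 6), 12, 2),
                       individuals = paste0("i", 1:12),
                       loci = c("L1", "L2"))
  fr <- sample_frame(tb$individuals, rep(c("x", "y"), each = 6), 2000)
  r <- global_exact_test(tb, fr, steps = 499, seed = 81)
  # the observed G is maximal; only a permutation reproducing the exact
  # split (prob 1/choose(12,6) per step) can tie it, so P sits at the floor
  expect_lt(r$p, 0.02)
  expect_gte(r$p, 1 / 500)
  # identical copies of one stratum: null holds, P is not small
  ds <- simulate_source(sim_config(n_source = 15, loci = rep(3L, 4),
                                   missing_rate = 0), seed = 82)
  dup <- genotype_table(rbind(ds$geno$a1, ds$geno$a1),
                        rbind(ds$geno$a2, ds$geno$a2),
                        individuals = c(paste0("a", 1:15), paste0("b", 1:15)),
                        loci = ds$geno$loci)
  fr2 <- sample_frame(dup$individuals, rep(c("x", "y"), each = 15), 2000)
  r2 <- global_exact_test(dup, fr2, steps = 499, seed = 83)
  expect_gt(r2$p, 0.05)
  expect_error(global_exact_test(tb, fr, strata = "x_2000"), "at least 2")
})

test_that("Mantel statistic, affine invariance, oracle agreement and errors", {
  set.seed(91)
  lab <- letters[1:5]
  mk <- function() {
    m <- matrix(0, 5, 5, dimnames = list(lab, lab))
    m[lower.tri(m)] <- runif(10)
    m + t(m)
  }
  a <- mk(); b <- mk()
  expect_equal(mantel_test(a, a, permutations = 99, seed = 1)$r, 1)
  expect_equal(mantel_test(a, 2 * a + 3, permutations = 99, seed = 1)$r, 1)
  # r agrees with vegan's implementation
  skip_if_not_installed("vegan")
  r_ours <- mantel_test(a, b, permutations = 199, seed = 2)
  r_vegan <- suppressMessages(
    vegan::mantel(stats::as.dist(a), stats::as.dist(b), permutations = 99))
  expect_equal(r_ours$r, unname(r_vegan$statistic), tolerance = 1e-12)
  # exhaustive enumeration over all 5! label permutations is the exact P;
  # the permutation estimate must approach it
  perms <- do.call(rbind, combinat_perms(5))  # all 120, identity included
  r_of <- function(p) stats::cor(a[lower.tri(a)], b[p, p][lower.tri(b)])
  rstar <- apply(perms, 1, r_of)
  exact_p <- mean(rstar >= r_ours$r - 1e-12)
  est <- mantel_test(a, b, permutations = 4999, seed = 3)
  expect_lt(abs(est$p - exact_p), 0.03)
  # label mismatch errors
  c_bad <- a; dimnames(c_bad) <- list(LETTERS[1:5], LETTERS[1:5])
  expect_error(mantel_test(a, c_bad), "labels")
  expect_error(mantel_test(a[1:3, 1:3], b[1:3, 1:3]), "at least 4")
})

test_that("theta on drift-diverged populations tracks 1-(1-1/(2Ne))^t (reduced reps)", {
  th <- vapply(1:40, function(i)
    with(wf_diverged_pair(7100 + i, n_e = 50, t = 5),
         pairwise_fst(tb, fr, strata, permutations = 0)$theta),
    numeric(1))
  expected <- 1 - (1 - 1 / 100)^5
  se <- stats::sd(th) / sqrt(length(th))
  expect_lt(abs(mean(th) - expected), 3 * se)
})

test_that("F_ST and D matrices are rank-concordant on drifted strata", {
  # four small isolated populations drifting hard from one source give a
  # clear differentiation ranking for both statistics
  ds <- simulate_source(sim_config(n_source = 60, loci = rep(4L, 25),
                                   missing_rate = 0), seed = 965)
  for (i in 1:4)
    ds <- simulate_translocation(ds, 6, generations = 8, lambda = 1,
                                 K = 6, pop = paste0("isle", i),
                                 seed = 1020 + i)
  fst <- differentiation_matrix(ds$geno, ds$frame, method = "fst",
                                permutations = 0)
  dst <- differentiation_matrix(ds$geno, ds$frame, method = "dest")
  lt <- lower.tri(fst$stat)
  rho <- stats::cor(fst$stat[lt], dst$stat[lt], method = "spearman")
  expect_gt(rho, 0.8)  # soft concordance check
  # permutation P invariant to stratum label order (same derived seeds)
  r_ab <- pairwise_fst(ds$geno, ds$frame,
                       c("isle1_2019", "isle2_2019"), permutations = 99,
                       seed = 99)
  r_ba <- pairwise_fst(ds$geno, ds$frame,
                       c("isle2_2019", "isle1_2019"), permutations = 99,
                       seed = 99)
  expect_equal(r_ab$theta, r_ba$theta, tolerance = 1e-12)
})
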