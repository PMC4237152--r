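test_that("same seed reproduces the dataset exactly", {
  d1 <- simulate_mhc(simulate_source(sim_config(n_source = 30), seed = 5),
                     seed = 6)
  d2 <- simulate_mhc(simulate_source(sim_config(n_source = 30), seed = 5),
                     seed = 6)
  expect_identical(d1$geno$a1, d2$geno$a1)
  expect_identical(d1$mhc$profiles, d2$mhc$profiles)
  expect_identical(d1$truth$msat$freqs, d2$truth$msat$freqs)
  t1 <- simulate_translocation(d1, 10, generations = 2, pop = "isle", seed = 7)
  t2 <- simulate_translocation(d2, 10, generations = 2, pop = "isle", seed = 7)
  expect_identical(t1$geno$a1, t2$geno$a1)
})

test_that("allele-count ceiling binds: two-allele loci never exceed richness 2", {
  ds <- simulate_source(sim_config(n_source = 50, loci = rep(2L, 10)),
                        seed = 15)
  k <- vapply(allele_counts(ds$geno), length, numeric(1))
  expect_true(all(k <= 2))
})

test_that("no mutation: alleles absent among founders never reappear", {
  ds <- simulate_mhc(simulate_source(sim_config(n_source = 40), seed = 25),
                     seed = 26)
  tr <- simulate_translocation(ds, 8, generations = 4, lambda = 2, K = 60,
                               pop = "isle", snapshots = c(0L, 4L), seed = 27)
  founders <- tr$truth$populations$isle$founder_ids
  f_geno <- subset_individuals(ds$geno, founders)
  final <- subset_stratum(tr$geno, tr$frame, "isle_2015")
  for (l in ds$geno$loci) {
    f_alleles <- names(table(c(ds$truth$msat$a1[founders, l],
                               ds$truth$msat$a2[founders, l])))
    expect_true(all(names(allele_counts(final, l)) %in% f_alleles))
  }
  # MHC closure through the same machinery
  f_mhc <- unique(unlist(subset_individuals(tr$mhc, individuals_in(
    tr$frame, "isle_2011"))$profiles))
  final_mhc <- unique(unlist(subset_individuals(tr$mhc, individuals_in(
    tr$frame, "isle_2015"))$profiles))
  expect_true(all(final_mhc %in% f_mhc))
})

test_that("growth-cap demography: lambda 1 with N = K = founders is a copy at gen 0", {
  ds <- simulate_source(sim_config(n_source = 12, loci = rep(3L, 4),
                                   missing_rate = 0), seed = 35)
  tr <- simulate_translocation(ds, 12, generations = 0, lambda = 1, K = 12,
                               pop = "copy", snapshots = 0L, seed = 36)
  snap <- subset_stratum(tr$geno, tr$frame, "copy_2011")
  # same multiset of genotypes as the source (order may differ)
  src_calls <- sort(paste(ds$truth$msat$a1, ds$truth$msat$a2))
  snap_calls <- sort(paste(snap$a1, snap$a2))
  expect_equal(snap_calls, src_calls)
  expect_equal(tr$truth$populations$copy$n_trajectory, 12L)
})

test_that("MHC pool structure: forced profiles for degenerate pools", {
  cfg <- sim_config(n_source = 30)
  cfg$mhc$pools <- list(1L, 2L, 3L, 4L)      # disjoint singletons
  d <- simulate_mhc(simulate_source(cfg, seed = 45), seed = 46)
  expect_true(all(lengths(d$mhc$profiles) == 4L))
  cfg$mhc$pools <- list(1L, 1L, 1L, 1L)      # identical singletons
  d2 <- simulate_mhc(simulate_source(cfg, seed = 45), seed = 46)
  ms <- mhc_summary(d2$mhc)
  expect_equal(ms$k, 1L)
  expect_equal(ms$pi, 0)
})

test_that("heterozygosity decays as (1 - 1/(2N))^t under constant size", {
  # martingale check: population gene diversity after t generations vs
  # the founder generation's, paired per replicate
  n_e <- 30L; t_gen <- 5L; reps <- 150
  gd <- function(tab) {
    mean(vapply(allele_counts(tab), function(ct) {
      p <- ct / sum(ct); 1 - sum(p^2)
    }, numeric(1)))
  }
  diffs <- vapply(seq_len(reps), function(i) {
    cfg <- sim_config(n_source = n_e, loci = rep(4L, 10), missing_rate = 0)
    d <- simulate_source(cfg, seed = 5000 + i)
    d <- simulate_translocation(d, n_e, generations = t_gen, lambda = 1,
                                K = n_e, pop = "wf",
                                snapshots = c(0L, t_gen), seed = 6000 + i)
    h0 <- gd(subset_stratum(d$geno, d$frame, "wf_2011"))
    ht <- gd(subset_stratum(d$geno, d$frame, paste0("wf_", 2011 + t_gen)))
    ht - h0 * (1 - 1 / (2 * n_e))^t_gen
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(reps)
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("larger founder cohorts capture more richness (29 vs 59, paired)", {
  ds <- simulate_source(sim_config(), seed = 55)
  rich <- function(tr, pop) {
    snap <- subset_stratum(tr$geno, tr$frame, paste0(pop, "_2011"))
    mean(vapply(allele_counts(snap), length, numeric(1)))
  }
  reps <- 60
  r29 <- r59 <- numeric(reps)
  for (i in seq_len(reps)) {
    r29[i] <- rich(simulate_translocation(ds, 29, snapshots = 0L,
                                          pop = "a", seed = 7000 + i), "a")
    r59[i] <- rich(simulate_translocation(ds, 59, snapshots = 0L,
                                          pop = "b", seed = 8000 + i), "b")
  }
  expect_gt(mean(r59), mean(r29))
})

test_that("founder draws reproduce the capture model's sampling distribution", {
  ds <- simulate_source(sim_config(n_source = 40, loci = rep(3L, 8),
                                   missing_rate = 0), seed = 65)
  cv <- build_capture_curve(ds$geno, "all", R = 1500, seed = 66)
  n <- 12L
  reps <- 150
  vals <- vapply(seq_len(reps), function(i) {
    tr <- simulate_translocation(ds, n, snapshots = 0L, pop = "f",
                                 seed = 9000 + i)
    snap <- subset_stratum(tr$geno, tr$frame, "f_2011")
    mean(vapply(allele_counts(snap), length, numeric(1)))
  }, numeric(1))
  se <- sqrt(stats::sd(vals)^2 / reps + cv$summary$se[n]^2)
  expect_lt(abs(mean(vals) - cv$summary$mean[n]), 3 * se)
})

test_that("write_dataset emits readable files plus a truth record", {
  d <- simulate_mhc(simulate_source(sim_config(n_source = 15), seed = 75),
                    seed = 76)
  prefix <- file.path(withr::local_tempdir(), "sim")
  files <- write_dataset(d, prefix)
  gp <- read_genepop(paste0(prefix, ".gen"))
  expect_equal(n_individuals(gp$genotypes), 15)
  ps <- read_mhc_profiles(paste0(prefix, "_mhc.csv"),
                          fasta = paste0(prefix, "_mhc.fasta"))
  expect_setequal(unlist(ps$profiles[1]), d$mhc$profiles[[1]])
  truth <- jsonlite::read_json(paste0(prefix, "_truth.json"))
  expect_true(!is.null(truth$msat$freqs))
})
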