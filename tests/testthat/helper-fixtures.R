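# Fixtures built in code; no data files.

# one-locus table realizing a given gene-copy spectrum (total must be even)
geno_from_counts <- function(counts, locus = "L1") {
  copies <- rep(as.integer(names(counts)) %||% seq_along(counts), counts)
  if (length(copies) %% 2L) stop("spectrum must have an even total")
  n <- length(copies) / 2L
  genotype_table(matrix(copies[seq_len(n) * 2L - 1L], n, 1),
                 matrix(copies[seq_len(n) * 2L], n, 1),
                 individuals = paste0("i", seq_len(n)), loci = locus)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# named, allele-sorted gene-copy counts from a raw vector of allele labels
table_as_counts <- function(raw) {
  tab <- table(raw)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(as.integer(names(out)))]
}

# the hand-worked Weir-Cockerham example: pop1 = AA, AA, AB; pop2 = BB, AB, BB
wc_toy <- function() {
  tb <- genotype_table(
    matrix(c(1L, 1L, 1L, 2L, 1L, 2L), 6, 1),
    matrix(c(1L, 1L, 2L, 2L, 2L, 2L), 6, 1),
    individuals = paste0("i", 1:6), loci = "L1")
  fr <- sample_frame(paste0("i", 1:6), rep(c("p1", "p2"), each = 3), 2000)
  list(tb = tb, fr = fr)
}

# a small GenePop file as text
tiny_genepop <- function() {
  c("toy data",
    "LocA", "LocB",
    "POP",
    "north_1993, 0101 0203",
    "north_1993, 0102 0000",
    "POP",
    "south_2005, 0202 0303")
}

# all permutations of seq_len(n), as a list of integer vectors
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

# split one simulated panmictic sample into two null groups
null_split <- function(seed, n = 30L, loci = rep(3L, 3), missing_rate = 0.02) {
  ds <- simulate_source(sim_config(n_source = n, loci = loci,
                                   missing_rate = missing_rate), seed = seed)
  ids <- ds$geno$individuals
  half <- n %/% 2L
  list(a = subset_individuals(ds$geno, ids[seq_len(half)]),
       b = subset_individuals(ds$geno, ids[(half + 1L):n]),
       geno = ds$geno, frame = ds$frame)
}

# two-population Wright-Fisher divergence: t total drift rounds from common
# ancestral frequencies, then each sample drawn as one further gamete-pool
# draw (which the F_ST estimator's sampling correction removes)
wf_diverged_pair <- function(seed, n_e = 50L, t = 5L, n_loci = 30L,
                             k_alleles = 3L) {
  set.seed(seed)
  f0 <- lapply(seq_len(n_loci), function(l) {
    v <- rgamma(k_alleles, 1)
    stats::setNames(v / sum(v), 100L + 2L * seq_len(k_alleles))
  })
  names(f0) <- sprintf("L%02d", seq_len(n_loci))
  cfg <- sim_config(n_source = n_e, loci = rep(k_alleles, n_loci),
                    missing_rate = 0)
  mk <- function(sd2, pop) {
    d <- simulate_source(cfg, seed = sd2, freqs = f0)        # round 1
    d <- simulate_translocation(d, n_e, generations = t - 1L, lambda = 1,
                                K = n_e, pop = pop, seed = sd2 + 1L)
    snap <- subset_stratum(d$geno, d$frame,
                           paste0(pop, "_", 2011 + t - 1L))
    p_t <- lapply(allele_counts(snap), function(ct) ct / sum(ct))
    simulate_source(cfg, seed = sd2 + 7L, freqs = p_t)$geno  # the sample
  }
  p1 <- mk(seed * 13L + 1L, "x"); p2 <- mk(seed * 13L + 7L, "y")
  tb <- genotype_table(rbind(p1$a1, p2$a1), rbind(p1$a2, p2$a2),
                       c(paste0("x", seq_len(n_e)), paste0("y", seq_len(n_e))),
                       p1$loci)
  fr <- sample_frame(tb$individuals, rep(c("x", "y"), each = n_e), 2000)
  list(tb = tb, fr = fr, strata = c("x_2000", "y_2000"))
}

# an isolated Wright-Fisher population at constant size n_e for `gens`
# generations, sampled as the final generation (n_e offspring of the
# parental pool, the sampling scheme the LD-Ne model assumes)
wf_constant_sample <- function(seed, n_e = 50L, gens = 15L, n_loci = 30L,
                               k_alleles = 4L, sample_size = n_e) {
  cfg <- sim_config(n_source = n_e, loci = rep(k_alleles, n_loci),
                    missing_rate = 0)
  d <- simulate_source(cfg, seed = seed)
  d <- simulate_translocation(d, n_e, generations = gens, lambda = 1,
                              K = n_e, pop = "wf", seed = seed + 1L)
  samp <- subset_stratum(d$geno, d$frame, paste0("wf_", 2011 + gens))
  if (sample_size < n_e)
    samp <- subset_individuals(samp, samp$individuals[seq_len(sample_size)])
  samp
}
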