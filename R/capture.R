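# Genetic-capture rarefaction planner: how much of the source population's
# allelic diversity a founder cohort of a given size is expected to carry.

# per-replicate capture trajectories via coupled (growing-subset) sampling:
# one permutation of individuals per replicate, statistic evaluated on each
# prefix. Prefixes of a uniform permutation are uniform draws without
# replacement, so marginals at each n are exact, and the coupling makes
# every replicate trajectory monotone in n.
capture_replicates <- function(source, loci_idx = NULL, R = 1000L,
                               seed = NULL) {
  if (inherits(source, "geno_table")) {
    N <- n_individuals(source)
    a1 <- source$a1[, loci_idx, drop = FALSE]
    a2 <- source$a2[, loci_idx, drop = FALSE]
    L <- ncol(a1)
    with_seed(seed, {
      reps <- matrix(0, R, N)
      for (r in seq_len(R)) {
        perm <- sample.int(N)
        acc <- numeric(N)
        for (l in seq_len(L)) {
          x <- rbind(a1[perm, l], a2[perm, l])  # 2 x N, interleaved copies
          v <- as.vector(x)
          newf <- !duplicated(v) & !is.na(v)
          acc <- acc + cumsum(newf)[c(FALSE, TRUE)]
        }
        reps[r, ] <- acc / L
      }
      reps
    })
  } else {
    N <- n_individuals(source)
    plist <- source$profiles
    with_seed(seed, {
      reps <- matrix(0, R, N)
      for (r in seq_len(R)) {
        perm <- sample.int(N)
        v <- unlist(plist[perm], use.names = FALSE)
        bounds <- cumsum(lengths(plist)[perm])
        reps[r, ] <- cumsum(!duplicated(v))[bounds]
      }
      reps
    })
  }
}

# the capture statistic evaluated exactly on a full sample
capture_statistic <- function(source, loci_idx = NULL) {
  if (inherits(source, "geno_table")) {
    mean(vapply(locus_spectra(source)[loci_idx], length, numeric(1)))
  } else {
    length(unique(unlist(source$profiles, use.names = FALSE)))
  }
}

diverse_loci <- function(source, min_alleles = 4L) {
  k <- vapply(locus_spectra(source), length, numeric(1))
  which(k >= min_alleles)
}

#' Build a genetic-capture rarefaction curve
#'
#' For every founder number `n` from 1 to the source sample size, draws
#' `R` replicate cohorts of `n` individuals without replacement and
#' records the captured diversity: for microsatellites, the mean over
#' included loci of the number of distinct alleles present in the cohort;
#' for MHC, the total number of distinct alleles. The marker set is all
#' loci, the "diverse" loci (those with at least `min_alleles` alleles,
#' default 4, the high-information panel), or the MHC profile set.
#'
#' @param source A `geno_table` or `mhc_profile_set` for the source
#'   population sample.
#' @param filter `"all"`, `"diverse"`, or `"mhc"` (implied for profile
#'   sets).
#' @param R Replicates per founder number (default 1000).
#' @param seed Optional integer seed.
#' @param min_alleles Allele-count threshold defining "diverse" loci.
#' @return An object of class `capture_curve`: list with `summary`
#'   (data.frame `n`, `mean`, `sd`, `se`, `p5`, `p95`), `replicates`
#'   (R x N matrix), `full_value`, `filter`, `loci`, `R`, `seed`.
#' @export
build_capture_curve <- function(source, filter = c("all", "diverse", "mhc"),
                                R = 1000L, seed = NULL, min_alleles = 4L) {
  filter <- match.arg(filter)
  if (inherits(source, "mhc_profile_set")) filter <- "mhc"
  if (n_individuals(source) < 2) abort_ctx("source needs at least 2 individuals")
  loci_idx <- NULL
  if (inherits(source, "geno_table")) {
    loci_idx <- switch(filter,
      all = seq_along(source$loci),
      diverse = diverse_loci(source, min_alleles),
      mhc = abort_ctx("filter 'mhc' needs an mhc_profile_set"))
    if (!length(loci_idx))
      abort_ctx("no locus passes the 'diverse' filter (>= ", min_alleles, " alleles)")
  }
  reps <- capture_replicates(source, loci_idx, R = as.integer(R), seed = seed)
  N <- ncol(reps)
  summary <- data.frame(
    n = seq_len(N),
    mean = colMeans(reps),
    sd = apply(reps, 2, stats::sd),
    p5 = apply(reps, 2, stats::quantile, probs = 0.05),
    p95 = apply(reps, 2, stats::quantile, probs = 0.95))
  summary$se <- summary$sd / sqrt(nrow(reps))
  structure(list(summary = summary[, c("n", "mean", "sd", "se", "p5", "p95")],
                 replicates = reps,
                 full_value = capture_statistic(source, loci_idx),
                 filter = filter,
                 loci = if (is.null(loci_idx)) NULL else
                   (if (inherits(source, "geno_table")) source$loci[loci_idx]),
                 R = as.integer(R), seed = seed),
            class = "capture_curve")
}

#' @export
print.capture_curve <- function(x, ...) {
  cat(sprintf("<capture_curve> marker set '%s', N_source = %d, R = %d, full-sample value %.3f\n",
              x$filter, ncol(x$replicates), x$R, x$full_value))
  invisible(x)
}

#' Smallest founder number reaching a target capture fraction
#'
#' @param curve A `capture_curve`.
#' @param target_fraction Target fraction of the full-sample diversity,
#'   in (0, 1].
#' @return Integer `n*`; if even the full source sample does not reach
#'   the target in expectation the source size is returned with attribute
#'   `attainable = FALSE`.
#' @export
min_founders <- function(curve, target_fraction) {
  stopifnot(inherits(curve, "capture_curve"),
            target_fraction > 0, target_fraction <= 1)
  frac <- curve$summary$mean / curve$full_value
  hit <- which(frac >= target_fraction)
  if (length(hit)) {
    structure(curve$summary$n[hit[1]], attainable = TRUE)
  } else {
    structure(max(curve$summary$n), attainable = FALSE)
  }
}

#' Assess an observed founder cohort against the capture model
#'
#' Compares the diversity actually carried by a founder cohort with the
#' rarefaction distribution at the same cohort size. The one-tailed
#' (lower-tail, capture-shortfall) P value is
#' `(1 + #\{replicates <= observed\}) / (R + 1)`. Alleles of the source
#' absent from the cohort are enumerated with their source frequencies;
#' those below frequency 0.01 are flagged as rare.
#'
#' @param curve A `capture_curve` built from `source`.
#' @param source The source-sample object the curve was built from.
#' @param founder_ids Individual IDs of the founder cohort (subset of the
#'   source individuals).
#' @return List of class `capture_assessment` with `n_founders`,
#'   `observed`, `expected`, `expected_se`, `captured_fraction`, `p`,
#'   and `alleles_lost` (data.frame `locus`, `allele`, `source_freq`,
#'   `rare`).
#' @export
assess_founders <- function(curve, source, founder_ids) {
  stopifnot(inherits(curve, "capture_curve"))
  founder_ids <- as.character(founder_ids)
  cohort <- subset_individuals(source, founder_ids)  # errors on unknown IDs
  n <- length(founder_ids)
  if (n < 1 || n > ncol(curve$replicates))
    abort_ctx("founder number outside curve range")
  loci_idx <- if (is.null(curve$loci)) NULL else match(curve$loci, source$loci)
  obs <- capture_statistic(cohort, loci_idx)
  repvals <- curve$replicates[, n]
  p <- (1 + sum(repvals <= obs)) / (curve$R + 1)
  lost <- if (inherits(source, "geno_table")) {
    rows <- lapply(curve$loci %||% source$loci, function(l) {
      src <- allele_counts(source, l)
      coh <- allele_counts(cohort, l)
      gone <- setdiff(names(src), names(coh))
      if (!length(gone)) return(NULL)
      data.frame(locus = l, allele = gone,
                 source_freq = as.numeric(src[gone]) / sum(src),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    src <- carrier_counts(source); src <- src[src > 0]
    coh <- carrier_counts(cohort)
    gone <- names(src)[coh[names(src)] == 0]
    if (length(gone))
      data.frame(locus = "MHC", allele = gone,
                 source_freq = as.numeric(src[gone]) / sum(src),
                 stringsAsFactors = FALSE)
    else NULL
  }
  if (is.null(lost))
    lost <- data.frame(locus = character(0), allele = character(0),
                       source_freq = numeric(0), stringsAsFactors = FALSE)
  lost$rare <- lost$source_freq < 0.01
  structure(list(n_founders = n, observed = obs,
                 expected = curve$summary$mean[n],
                 expected_se = curve$summary$se[n],
                 captured_fraction = obs / curve$full_value,
                 p = p, alleles_lost = lost),
            class = "capture_assessment")
}

#' @export
print.capture_assessment <- function(x, ...) {
  cat(sprintf(
    "Founder cohort of %d: observed %.3f vs expected %.3f +/- %.3f (captured %.1f%%), lower-tail P = %.4g; %d allele(s) lost (%d rare)\n",
    x$n_founders, x$observed, x$expected, x$expected_se,
    100 * x$captured_fraction, x$p, nrow(x$alleles_lost),
    sum(x$alleles_lost$rare)))
  invisible(x)
}
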