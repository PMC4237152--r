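test_that("GenePop parsing handles codes, missing data and strata", {
  f <- withr::local_tempfile(lines = tiny_genepop(), fileext = ".gen")
  res <- read_genepop(f)
  tb <- res$genotypes
  expect_equal(tb$loci, c("LocA", "LocB"))
  expect_equal(n_individuals(tb), 3L)
  # "0000" is a wholly missing call
  expect_true(is.na(tb$a1[2, "LocB"]) && is.na(tb$a2[2, "LocB"]))
  expect_equal(unname(sort(c(tb$a1[1, ], tb$a2[1, ]))), c(1L, 1L, 2L, 3L))
  # pop_year naming convention parsed into strata
  expect_equal(strata_of(res$frame), c("north_1993", "south_2005"))
  expect_equal(res$frame$year, c(1993L, 1993L, 2005L))
  expect_equal(res$frame$pop[3], "south")
})

test_that("GenePop parse errors name the offending line", {
  bad_width <- c("t", "L1", "POP", "a, 010")
  f <- withr::local_tempfile(lines = bad_width)
  expect_error(read_genepop(f), "line 4")
  bad_count <- c("t", "L1", "L2", "POP", "a, 0101")
  f2 <- withr::local_tempfile(lines = bad_count)
  expect_error(read_genepop(f2), "expected 2 genotypes")
  half <- c("t", "L1", "POP", "a, 0100")
  f3 <- withr::local_tempfile(lines = half)
  expect_error(read_genepop(f3), "half-missing")
  dup <- c("t", "L1", "POP", "a, 0101", "b, 0101", "POP", "a, 0202", "c, 0101")
  f4 <- withr::local_tempfile(lines = dup)
  expect_error(read_genepop(f4), "duplicate individual")
})

test_that("GenePop round-trip preserves genotypes, loci and strata", {
  ds <- simulate_source(sim_config(n_source = 25, loci = rep(3L, 5)), seed = 11)
  ds <- simulate_translocation(ds, 10, generations = 1, pop = "isle", seed = 12)
  f <- withr::local_tempfile(fileext = ".gen")
  write_genepop(ds$geno, ds$frame, f)
  back <- read_genepop(f)
  expect_identical(unname(back$genotypes$a1), unname(ds$geno$a1))
  expect_identical(unname(back$genotypes$a2), unname(ds$geno$a2))
  expect_equal(back$genotypes$loci, ds$geno$loci)
  expect_equal(back$frame$stratum, ds$frame$stratum)
  expect_equal(back$frame$year, ds$frame$year)
  # a second write of the re-read data is byte-identical
  f2 <- withr::local_tempfile(fileext = ".gen")
  write_genepop(back$genotypes, back$frame, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("allele tallies from the parsed table match an independent count of the file text", {
  ds <- simulate_source(sim_config(n_source = 30, loci = rep(4L, 6)), seed = 21)
  f <- withr::local_tempfile(fileext = ".gen")
  write_genepop(ds$geno, ds$frame, f)
  res <- read_genepop(f)
  # independent tally straight from the raw text
  lines <- readLines(f)
  body <- lines[grepl(",", lines, fixed = TRUE)]
  codes <- do.call(rbind, lapply(body, function(ln)
    strsplit(trimws(sub("^[^,]*,", "", ln)), "\\s+")[[1]]))
  for (l in seq_len(ncol(codes))) {
    raw <- c(as.integer(substr(codes[, l], 1, 3)),
             as.integer(substr(codes[, l], 4, 6)))
    raw <- raw[raw != 0L]
    expect_equal(allele_counts(res$genotypes, res$genotypes$loci[l]),
                 table_as_counts(raw), ignore_attr = TRUE)
    expect_equal(sum(allele_counts(res$genotypes, res$genotypes$loci[l])),
                 length(raw))
  }
})

test_that("CSV genotype dialect agrees with the GenePop reader", {
  ds <- simulate_source(sim_config(n_source = 10, loci = rep(3L, 3)), seed = 31)
  rows <- do.call(rbind, lapply(seq_along(ds$geno$individuals), function(i)
    data.frame(ind = ds$geno$individuals[i], pop = ds$frame$pop[i],
               year = ds$frame$year[i], locus = ds$geno$loci,
               a1 = ifelse(is.na(ds$geno$a1[i, ]), 0L, ds$geno$a1[i, ]),
               a2 = ifelse(is.na(ds$geno$a2[i, ]), 0L, ds$geno$a2[i, ]))))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE)
  res <- read_genotype_csv(f)
  expect_identical(unname(res$genotypes$a1), unname(ds$geno$a1))
  expect_identical(unname(res$genotypes$a2), unname(ds$geno$a2))
  expect_equal(res$frame$stratum, ds$frame$stratum)
})

test_that("strata partition individuals and subsetting is idempotent", {
  ds <- simulate_source(sim_config(n_source = 20, loci = rep(2L, 3)), seed = 41)
  ds <- simulate_translocation(ds, 8, generations = 2, pop = "isle",
                               snapshots = c(0L, 2L), seed = 42)
  frame <- ds$frame
  parts <- lapply(strata_of(frame), individuals_in, frame = frame)
  expect_equal(sort(unlist(parts)), sort(frame$id))
  expect_equal(sum(lengths(parts)), nrow(frame))        # disjoint cover
  s1 <- subset_stratum(ds$geno, frame, "isle_2013")
  s2 <- subset_stratum(s1, frame, "isle_2013")
  expect_identical(s1$a1, s2$a1)
  expect_error(individuals_in(frame, "nowhere_1900"), "empty or unknown")
})

test_that("MHC CSV formats, FASTA attachment and error cases", {
  m <- c("ind,A01,A02,A03", "i1,1,1,0", "i2,0,1,1")
  f <- withr::local_tempfile(lines = m, fileext = ".csv")
  ps <- read_mhc_profiles(f)
  expect_equal(ps$profiles$i1, c("A01", "A02"))
  expect_equal(ps$profiles$i2, c("A02", "A03"))
  # long format gives the same profiles
  lg <- c("ind,allele", "i1,A01", "i1,A02", "i2,A02", "i2,A03")
  f2 <- withr::local_tempfile(lines = lg, fileext = ".csv")
  expect_equal(read_mhc_profiles(f2)$profiles, ps$profiles)
  # FASTA: matching sequences attach; universe extends to FASTA-only alleles
  fa <- withr::local_tempfile(
    lines = c(">A01", "ACGT", ">A02", "AGGT", ">A03", "ACGA", ">A04", "TCGA"),
    fileext = ".fasta")
  ps2 <- read_mhc_profiles(f, fasta = fa)
  expect_equal(length(ps2$universe), 4L)
  expect_equal(unname(ps2$sequences["A02"]), "AGGT")
  # allele referenced by the CSV but absent from the FASTA is an error
  fa_bad <- withr::local_tempfile(lines = c(">A01", "ACGT", ">A02", "AGGT"),
                                  fileext = ".fasta")
  expect_error(read_mhc_profiles(f, fasta = fa_bad), "A03")
  # empty allele set is an error
  m0 <- c("ind,A01,A02", "i1,1,0", "i2,0,0")
  f3 <- withr::local_tempfile(lines = m0, fileext = ".csv")
  expect_error(read_mhc_profiles(f3), "empty allele set.*i2")
})

test_that("constructors enforce the documented invariants", {
  expect_error(genotype_table(matrix(1L, 2, 1), matrix(c(1L, NA), 2, 1)),
               "half-missing")
  expect_error(genotype_table(matrix(c(0L, 1L), 2, 1), matrix(c(2L, 1L), 2, 1)),
               "positive")
  expect_error(genotype_table(matrix(1L, 2, 1), matrix(1L, 2, 1),
                              individuals = c("a", "a")), "duplicate")
  expect_error(mhc_profile_set(list(i1 = paste0("A", 1:11))),
               "plausibility")
  expect_error(mhc_profile_set(list(i1 = "A01"),
                               sequences = c(A01 = "ACGX")), "alphabet")
  expect_error(sample_frame(c("a", "a"), "p", 2000), "duplicate")
})
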