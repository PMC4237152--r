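# MHC presence profiles: per-individual sets of named alleles across
# duplicated class I loci where locus zygosity is unobservable.

#' Construct an MHC profile set
#'
#' Because alleles are shared across duplicated MHC loci, locus zygosity
#' cannot be resolved; an individual's MHC genotype is therefore recorded
#' as the *set* of distinct alleles it carries. Optional aligned
#' nucleotide sequences (one per allele, equal length, ACGT) support
#' nucleotide-diversity calculations.
#'
#' @param profiles Named list: individual ID -> character vector of allele
#'   IDs (non-empty; duplicates are collapsed).
#' @param sequences Optional named character vector: allele ID -> sequence.
#' @param universe Optional ordered character vector of all allele IDs;
#'   defaults to the union of profile alleles and sequence names.
#' @param size_range Plausibility range for per-individual set sizes
#'   (default `c(1, 10)`).
#' @return An object of class `mhc_profile_set`.
#' @export
mhc_profile_set <- function(profiles, sequences = NULL, universe = NULL,
                            size_range = c(1L, 10L)) {
  if (is.null(names(profiles)) || anyDuplicated(names(profiles)))
    abort_ctx("profiles must be a list uniquely named by individual ID")
  profiles <- lapply(profiles, function(p) unique(as.character(p)))
  sizes <- lengths(profiles)
  if (any(sizes == 0))
    abort_ctx("empty allele set for individual(s): ",
              paste(names(profiles)[sizes == 0], collapse = ", "))
  if (any(sizes < size_range[1] | sizes > size_range[2]))
    abort_ctx("per-individual allele-set size outside plausibility range [",
              size_range[1], ", ", size_range[2], "] for: ",
              paste(names(profiles)[sizes < size_range[1] | sizes > size_range[2]],
                    collapse = ", "))
  observed <- sort(unique(unlist(profiles, use.names = FALSE)))
  if (is.null(universe)) universe <- union(observed, names(sequences))
  if (!all(observed %in% universe))
    abort_ctx("profile allele(s) missing from universe: ",
              paste(setdiff(observed, universe), collapse = ", "))
  if (!is.null(sequences)) {
    sequences <- toupper(unlist(sequences))
    missing_seq <- setdiff(universe, names(sequences))
    if (length(missing_seq))
      abort_ctx("no sequence for allele(s): ", paste(missing_seq, collapse = ", "))
    sequences <- sequences[universe]
    if (length(unique(nchar(sequences))) != 1L)
      abort_ctx("allele sequences must all have equal length")
    if (any(grepl("[^ACGT]", sequences)))
      abort_ctx("allele sequences must use alphabet {A,C,G,T}")
  }
  structure(list(profiles = profiles, sequences = sequences,
                 universe = as.character(universe)),
            class = "mhc_profile_set")
}

#' @export
print.mhc_profile_set <- function(x, ...) {
  cat(sprintf("<mhc_profile_set> %d individuals, %d alleles in universe%s\n",
              length(x$profiles), length(x$universe),
              if (is.null(x$sequences)) "" else
                sprintf(", %d bp sequences", nchar(x$sequences[1]))))
  invisible(x)
}

#' @export
n_individuals.mhc_profile_set <- function(x) length(x$profiles)

#' @export
subset_individuals.mhc_profile_set <- function(x, ids) {
  ids <- as.character(ids)
  missing_ids <- setdiff(ids, names(x$profiles))
  if (length(missing_ids))
    abort_ctx("unknown individuals: ", paste(missing_ids, collapse = ", "))
  mhc_profile_set(x$profiles[ids], sequences = x$sequences,
                  universe = x$universe)
}

#' Carrier counts of each allele
#'
#' Number of individuals carrying each allele of the universe. These counts,
#' treated as haplotype-style observations, are the frequency basis for
#' nucleotide diversity and theta-K on MHC data.
#'
#' @param x An `mhc_profile_set`.
#' @return Named integer vector over the universe.
#' @export
carrier_counts <- function(x) {
  stopifnot(inherits(x, "mhc_profile_set"))
  v <- unlist(x$profiles, use.names = FALSE)
  cnt <- stats::setNames(integer(length(x$universe)), x$universe)
  tab <- table(v)
  cnt[names(tab)] <- as.integer(tab)
  cnt
}

# read a FASTA into a named character vector of uppercase sequences
read_fasta_seqs <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""), "")
  names(seqs) <- sub("\\s.*$", "", names(dna))
  seqs
}

#' Read MHC presence profiles from CSV (plus optional allele FASTA)
#'
#' Accepts either a 0/1 presence matrix (first column = individual ID,
#' remaining columns named by allele) or a long two-column table
#' (`ind,allele`, one row per carried allele). When a FASTA of allele
#' sequences is given, every allele referenced by the CSV must have a
#' sequence; FASTA-only alleles extend the universe.
#'
#' @param path Path to the CSV.
#' @param fasta Optional path to a FASTA of allele sequences.
#' @return An [mhc_profile_set()].
#' @export
read_mhc_profiles <- function(path, fasta = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) abort_ctx("MHC CSV needs at least two columns")
  vals <- unlist(df[-1], use.names = FALSE)
  if (ncol(df) > 2 && all(vals %in% c(0, 1))) {
    ids <- as.character(df[[1]])
    alleles <- colnames(df)[-1]
    profiles <- lapply(seq_along(ids), function(i)
      alleles[df[i, -1] == 1])
    names(profiles) <- ids
  } else {
    names(df)[1:2] <- c("ind", "allele")
    profiles <- split(as.character(df$allele), as.character(df$ind))
    profiles <- profiles[unique(as.character(df$ind))]
  }
  empty <- names(profiles)[lengths(lapply(profiles, unique)) == 0]
  if (length(empty))
    abort_ctx("empty allele set for individual(s): ", paste(empty, collapse = ", "))
  sequences <- NULL
  if (!is.null(fasta)) {
    sequences <- read_fasta_seqs(fasta)
    used <- unique(unlist(profiles, use.names = FALSE))
    orphan <- setdiff(used, names(sequences))
    if (length(orphan))
      abort_ctx("allele(s) in CSV absent from FASTA: ",
                paste(orphan, collapse = ", "))
  }
  mhc_profile_set(profiles, sequences = sequences)
}

#' Write MHC profiles as a 0/1 presence matrix CSV
#' @param x An `mhc_profile_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mhc_profiles <- function(x, path) {
  stopifnot(inherits(x, "mhc_profile_set"))
  m <- t(vapply(x$profiles, function(p) as.integer(x$universe %in% p),
                integer(length(x$universe))))
  colnames(m) <- x$universe
  df <- data.frame(ind = names(x$profiles), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write allele sequences as FASTA
#' @param x An `mhc_profile_set` with sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mhc_fasta <- function(x, path) {
  if (is.null(x$sequences)) abort_ctx("profile set has no sequences")
  con <- file(path, "w"); on.exit(close(con))
  for (a in names(x$sequences))
    writeLines(c(paste0(">", a), x$sequences[[a]]), con)
  invisible(path)
}
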