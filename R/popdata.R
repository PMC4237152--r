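# Domain data model: diploid genotype tables, sampling strata, and the
# GenePop / CSV interchange formats.

#' Construct a diploid genotype table
#'
#' The central container for codominant multi-locus genotypes. Alleles are
#' opaque positive integer labels (e.g. fragment sizes); no size arithmetic
#' is ever performed on them. A call at one locus is either wholly present
#' (two labels, unordered) or wholly missing (`NA` in both slots);
#' half-calls are rejected so that allele-frequency denominators are
#' unambiguous.
#'
#' @param a1,a2 Integer matrices (individuals x loci) holding the two
#'   allele labels of each call. `NA` marks missing; `a1` and `a2` must be
#'   `NA` at exactly the same cells.
#' @param individuals Character vector of unique individual IDs
#'   (defaults to `rownames(a1)`).
#' @param loci Character vector of unique locus IDs
#'   (defaults to `colnames(a1)`).
#' @return An object of class `geno_table`.
#' @export
#' @examples
#' a1 <- matrix(c(1L, 1L, 2L, NA), 2, 2,
#'              dimnames = list(c("i1", "i2"), c("L1", "L2")))
#' a2 <- matrix(c(1L, 2L, 2L, NA), 2, 2,
#'              dimnames = list(c("i1", "i2"), c("L1", "L2")))
#' genotype_table(a1, a2)
genotype_table <- function(a1, a2,
                           individuals = rownames(a1),
                           loci = colnames(a1)) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    abort_ctx("a1 and a2 must have identical dimensions")
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(a1)))
  individuals <- as.character(individuals); loci <- as.character(loci)
  if (anyDuplicated(individuals))
    abort_ctx("duplicate individual IDs: ",
              paste(unique(individuals[duplicated(individuals)]), collapse = ", "))
  if (anyDuplicated(loci))
    abort_ctx("duplicate locus IDs: ",
              paste(unique(loci[duplicated(loci)]), collapse = ", "))
  if (length(individuals) != nrow(a1) || length(loci) != ncol(a1))
    abort_ctx("dimension mismatch between matrices and ID vectors")
  if (any(xor(is.na(a1), is.na(a2))))
    abort_ctx("half-missing calls are not allowed: a1/a2 NA patterns differ")
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    abort_ctx("allele labels must be positive integers")
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  structure(list(a1 = a1, a2 = a2, individuals = individuals, loci = loci),
            class = "geno_table")
}

#' @export
print.geno_table <- function(x, ...) {
  miss <- mean(is.na(x$a1))
  cat(sprintf("<geno_table> %d individuals x %d loci (%.1f%% missing calls)\n",
              length(x$individuals), length(x$loci), 100 * miss))
  invisible(x)
}

#' Number of individuals in a data object
#' @param x A `geno_table` or `mhc_profile_set`.
#' @return Integer count.
#' @export
n_individuals <- function(x) UseMethod("n_individuals")
#' @export
n_individuals.geno_table <- function(x) length(x$individuals)

#' Per-locus allele counts (gene copies)
#'
#' Tallies gene copies of each allele over individuals with complete calls
#' at the locus. The counts of a locus always sum to twice the number of
#' individuals scored there.
#'
#' @param x A `geno_table`.
#' @param locus Optional locus ID; if omitted, a named list over all loci.
#' @return A named integer vector (allele label -> gene copies), or a list
#'   of such vectors.
#' @export
allele_counts <- function(x, locus = NULL) {
  stopifnot(inherits(x, "geno_table"))
  one <- function(l) {
    v <- c(x$a1[, l], x$a2[, l])
    v <- v[!is.na(v)]
    if (!length(v)) return(integer(0))
    tab <- table(v)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out[order(as.integer(names(out)))]
  }
  if (!is.null(locus)) {
    if (!locus %in% x$loci) abort_ctx("unknown locus: ", locus)
    return(one(locus))
  }
  stats::setNames(lapply(x$loci, one), x$loci)
}

#' Construct a sample frame (population x catch-year strata)
#'
#' Maps each individual to exactly one (population, catch-year) stratum,
#' the unit of analysis throughout the pipeline. The stratum label is
#' `"<pop>_<year>"`, or just the population label when the year is unknown.
#'
#' @param id Character vector of individual IDs (unique).
#' @param pop Character vector of population labels.
#' @param year Integer vector of catch years (`NA` allowed).
#' @return A `data.frame` of class `sample_frame` with columns
#'   `id`, `pop`, `year`, `stratum`.
#' @export
sample_frame <- function(id, pop, year = NA_integer_) {
  id <- as.character(id); pop <- as.character(pop)
  year <- suppressWarnings(as.integer(year))
  n <- length(id)
  pop <- rep_len(pop, n); year <- rep_len(year, n)
  if (anyDuplicated(id))
    abort_ctx("duplicate individual IDs in sample frame: ",
              paste(unique(id[duplicated(id)]), collapse = ", "))
  stratum <- ifelse(is.na(year), pop, paste0(pop, "_", year))
  out <- data.frame(id = id, pop = pop, year = year, stratum = stratum,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_frame", "data.frame")
  out
}

#' Stratum labels present in a sample frame
#' @param frame A `sample_frame`.
#' @return Character vector of stratum labels in order of first appearance.
#' @export
strata_of <- function(frame) unique(frame$stratum)

#' Individuals assigned to a stratum
#' @param frame A `sample_frame`.
#' @param stratum Stratum label.
#' @return Character vector of individual IDs.
#' @export
individuals_in <- function(frame, stratum) {
  ids <- frame$id[frame$stratum == stratum]
  if (!length(ids)) abort_ctx("empty or unknown stratum: ", stratum)
  ids
}

#' Restrict a data object to a set of individuals
#' @param x A `geno_table` or `mhc_profile_set`.
#' @param ids Character vector of individual IDs (all must be present).
#' @return Object of the same class restricted to `ids`, in the given order.
#' @export
subset_individuals <- function(x, ids) UseMethod("subset_individuals")

#' @export
subset_individuals.geno_table <- function(x, ids) {
  ids <- as.character(ids)
  missing_ids <- setdiff(ids, x$individuals)
  if (length(missing_ids))
    abort_ctx("unknown individuals: ", paste(missing_ids, collapse = ", "))
  genotype_table(x$a1[ids, , drop = FALSE], x$a2[ids, , drop = FALSE],
                 individuals = ids, loci = x$loci)
}

#' Restrict a data object to one stratum of a sample frame
#'
#' Individuals present in the data but absent from the frame are simply
#' not selected; individuals in the frame but absent from the data raise
#' an error.
#'
#' @param x A `geno_table` or `mhc_profile_set`.
#' @param frame A `sample_frame`.
#' @param stratum Stratum label.
#' @return Object of the same class.
#' @export
subset_stratum <- function(x, frame, stratum) {
  ids <- individuals_in(frame, stratum)
  present <- if (inherits(x, "geno_table")) x$individuals else names(x$profiles)
  subset_individuals(x, intersect(ids, present))
}

# ---- GenePop interchange -------------------------------------------------

# split "name , codes" at the first comma
.split_ind_line <- function(line, lineno) {
  pos <- regexpr(",", line, fixed = TRUE)
  if (pos < 0)
    abort_ctx(sprintf("line %d: expected '<name>, <genotypes>'", lineno))
  list(name = trimws(substr(line, 1, pos - 1)),
       codes = strsplit(trimws(substr(line, pos + 1, nchar(line))), "\\s+")[[1]])
}

#' Read a GenePop genotype file
#'
#' Parses the GenePop 4 layout: a title line, locus names (one per line or
#' comma-separated on one line), then `POP` blocks of individual lines
#' `"<name>, 0101 0203 ..."`. Both 2- and 3-digit diploid allele codes are
#' accepted; code `0` is missing. A call with one allele coded `0` and the
#' other not (half-call) is rejected.
#'
#' Population labels follow the common GenePop convention that all
#' individuals of a block share one name: when that holds, the shared name
#' is the block label and individual IDs become `"<label>_<i>"`; otherwise
#' individual names are kept as IDs and the block is labelled `"pop<k>"`.
#' A label matching `"<pop>_<year>"` (4-digit year suffix) is split into
#' population and catch year. A `strata` side table (columns `id`, `pop`,
#' `year`) overrides all of this.
#'
#' @param path Path to a GenePop file.
#' @param strata Optional data.frame with columns `id`, `pop`, `year`.
#' @return A list with elements `genotypes` (a [genotype_table()]) and
#'   `frame` (a [sample_frame()]).
#' @export
read_genepop <- function(path, strata = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3) abort_ctx("not a GenePop file: too few lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort_ctx("not a GenePop file: no POP line found")
  locus_lines <- trimws(lines[2:(first_pop - 1)])
  loci <- unlist(strsplit(locus_lines[nzchar(locus_lines)], "\\s*,\\s*"))
  loci <- trimws(loci[nzchar(loci)])
  if (anyDuplicated(loci))
    abort_ctx("duplicate locus names: ",
              paste(unique(loci[duplicated(loci)]), collapse = ", "))
  L <- length(loci)

  blocks <- list(); cur <- NULL; cur_lines <- NULL; k <- 0L
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (toupper(trimws(ln)) == "POP") {
      if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
      cur <- list(rows = list(), linenos = integer(0))
      next
    }
    if (!nzchar(trimws(ln))) next
    parts <- .split_ind_line(ln, i)
    cur$rows[[length(cur$rows) + 1L]] <- parts
    cur$linenos <- c(cur$linenos, i)
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
  if (!length(blocks)) abort_ctx("no individuals found")

  # determine code width from the first genotype code seen
  first_code <- blocks[[1]]$rows[[1]]$codes[1]
  w <- nchar(first_code)
  if (!w %in% c(4L, 6L))
    abort_ctx(sprintf("line %d: genotype code '%s' is neither 4 (2-digit) nor 6 (3-digit) characters",
                      blocks[[1]]$linenos[1], first_code))
  half <- w %/% 2L

  names_all <- character(0); pops <- character(0)
  a1 <- list(); a2 <- list()
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    bn <- vapply(b$rows, `[[`, "", "name")
    for (j in seq_along(b$rows)) {
      codes <- b$rows[[j]]$codes
      lineno <- b$linenos[j]
      if (length(codes) != L)
        abort_ctx(sprintf("line %d: expected %d genotypes, found %d",
                          lineno, L, length(codes)))
      if (any(nchar(codes) != w))
        abort_ctx(sprintf("line %d: genotype code of unexpected width (expected %d characters)",
                          lineno, w))
      if (any(grepl("[^0-9]", codes)))
        abort_ctx(sprintf("line %d: non-numeric genotype code", lineno))
      x1 <- as.integer(substr(codes, 1, half))
      x2 <- as.integer(substr(codes, half + 1, w))
      bad <- xor(x1 == 0L, x2 == 0L)
      if (any(bad))
        abort_ctx(sprintf("line %d: half-missing call at locus %s",
                          lineno, loci[which(bad)[1]]))
      x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
      a1[[length(a1) + 1L]] <- x1; a2[[length(a2) + 1L]] <- x2
    }
    label <- if (length(unique(bn)) == 1L) bn[1] else paste0("pop", k)
    if (length(unique(bn)) == 1L) {
      names_all <- c(names_all, paste0(label, "_", seq_along(bn)))
    } else {
      names_all <- c(names_all, bn)
    }
    pops <- c(pops, rep(label, length(bn)))
  }
  if (anyDuplicated(names_all))
    abort_ctx("duplicate individual IDs: ",
              paste(unique(names_all[duplicated(names_all)]), collapse = ", "))

  A1 <- do.call(rbind, a1); A2 <- do.call(rbind, a2)
  tab <- genotype_table(A1, A2, individuals = names_all, loci = loci)

  if (!is.null(strata)) {
    strata <- as.data.frame(strata)
    keep <- names_all %in% strata$id
    if (!all(keep)) {
      warning(sum(!keep), " individual(s) absent from the supplied strata table were dropped")
      tab <- subset_individuals(tab, names_all[keep])
      names_all <- names_all[keep]
    }
    m <- match(names_all, strata$id)
    frame <- sample_frame(names_all, strata$pop[m], strata$year[m])
  } else {
    yr <- suppressWarnings(as.integer(sub("^.*_(\\d{4})$", "\\1", pops)))
    yr[!grepl("_\\d{4}$", pops)] <- NA_integer_
    pp <- ifelse(is.na(yr), pops, sub("_\\d{4}$", "", pops))
    frame <- sample_frame(names_all, pp, yr)
  }
  list(genotypes = tab, frame = frame)
}

#' Write a GenePop genotype file
#'
#' Emits one `POP` block per stratum of the frame, in stratum order of
#' first appearance. Every individual line carries the stratum label as
#' its name (the conventional GenePop way of recording population
#' membership), so `read_genepop()` recovers strata exactly; individual
#' IDs are regenerated on read.
#'
#' @param x A `geno_table`.
#' @param frame A `sample_frame` covering the individuals of `x`.
#' @param path Output path.
#' @param title Title line.
#' @param digits Allele code width, 2 or 3 (default 3).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, frame, path, title = "translocgen export",
                          digits = 3L) {
  stopifnot(inherits(x, "geno_table"), digits %in% c(2L, 3L))
  if (max(c(x$a1, x$a2), na.rm = TRUE) >= 10^digits)
    abort_ctx("allele label too large for ", digits, "-digit codes")
  fmt <- paste0("%0", digits, "d%0", digits, "d")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(x$loci, con)
  frame <- frame[frame$id %in% x$individuals, , drop = FALSE]
  for (s in unique(frame$stratum)) {
    writeLines("POP", con)
    for (id in frame$id[frame$stratum == s]) {
      g1 <- x$a1[id, ]; g2 <- x$a2[id, ]
      codes <- sprintf(fmt, ifelse(is.na(g1), 0L, g1), ifelse(is.na(g2), 0L, g2))
      writeLines(paste0(s, ", ", paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read the long CSV genotype dialect
#'
#' Columns `ind,pop,year,locus,a1,a2`; allele 0 or empty marks missing.
#'
#' @param path Path to CSV.
#' @return As [read_genepop()]: list of `genotypes` and `frame`.
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ind", "pop", "year", "locus", "a1", "a2")
  if (!all(need %in% names(df)))
    abort_ctx("genotype CSV must have columns: ", paste(need, collapse = ","))
  inds <- unique(df$ind); loci <- unique(df$locus)
  A1 <- matrix(NA_integer_, length(inds), length(loci),
               dimnames = list(inds, loci))
  A2 <- A1
  z1 <- suppressWarnings(as.integer(df$a1)); z2 <- suppressWarnings(as.integer(df$a2))
  z1[is.na(z1) | z1 == 0L] <- NA_integer_; z2[is.na(z2) | z2 == 0L] <- NA_integer_
  bad <- xor(is.na(z1), is.na(z2))
  if (any(bad))
    abort_ctx("half-missing call for individual ", df$ind[which(bad)[1]],
              " at locus ", df$locus[which(bad)[1]])
  idx <- cbind(match(df$ind, inds), match(df$locus, loci))
  A1[idx] <- z1; A2[idx] <- z2
  meta <- df[!duplicated(df$ind), c("ind", "pop", "year")]
  list(genotypes = genotype_table(A1, A2, individuals = inds, loci = loci),
       frame = sample_frame(meta$ind, meta$pop, meta$year))
}
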