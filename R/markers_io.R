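# Data model and file I/O: genetic maps, STR genotypes, cohort tables.
#
# File dialects (all plain text, whitespace/tab delimited, "#" comments):
#  * MAP:    chromosome  name  pos_cM  [pos_bp]  [het]; the focal-variant row
#            is flagged by a "*" suffix on its chromosome label.
#  * PED:    family  individual  carrier(0/1)  then two allele columns per
#            map marker (fragment sizes in bp); missing allele coded 0.
#  * Cohort: tab-delimited with a header row naming the phenotype fields.

MISSING_ALLELE <- 0L

parse_num <- function(x, what, allow_na = FALSE) {
  miss <- x %in% c("NA", "na", ".")
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !miss
  if (any(bad))
    fh_stop("fh_parse_numeric", "malformed numeric %s: '%s'", what,
            x[bad][1L])
  if (!allow_na && any(miss))
    fh_stop("fh_parse_numeric", "%s may not be missing", what)
  v
}

#' Construct a genetic map of STR markers around a focal variant
#'
#' A genetic map is an ordered panel of polymorphic markers (typically
#' dinucleotide STRs) with genetic positions in centimorgan, optional
#' physical positions in bp (1-based) and optional expected heterozygosity,
#' plus the position of the focal variant the panel brackets.
#'
#' @param markers data.frame with columns `name`, `chromosome`, `pos_cM` and
#'   optionally `pos_bp`, `het`. Rows are sorted by `pos_cM`; ties are
#'   rejected.
#' @param focal list with `name`, `pos_cM` and optionally `pos_bp` for the
#'   focal variant.
#' @return An object of class `genetic_map` with elements `markers` (sorted
#'   data.frame), `focal`, and `variant_terminal` (TRUE when the variant
#'   falls outside the marker span).
#' @examples
#' m <- data.frame(name = c("M1", "M2"), chromosome = "14",
#'                 pos_cM = c(1, 3))
#' genetic_map(m, focal = list(name = "V", pos_cM = 2))
#' @export
genetic_map <- function(markers, focal) {
  fh_assert(is.data.frame(markers) && nrow(markers) >= 1L,
            "fh_parse_shape", "markers must be a nonempty data.frame")
  fh_assert(all(c("name", "chromosome", "pos_cM") %in% names(markers)),
            "fh_parse_shape", "markers need name, chromosome, pos_cM")
  if (is.null(markers$pos_bp)) markers$pos_bp <- NA_real_
  if (is.null(markers$het)) markers$het <- NA_real_
  markers$name <- as.character(markers$name)
  fh_assert(all(nzchar(markers$name)), "fh_parse_name",
            "marker names must be nonempty")
  if (anyDuplicated(markers$name))
    fh_stop("fh_parse_duplicate_name", "duplicate marker name: %s",
            markers$name[duplicated(markers$name)][1L])
  fh_assert(all(markers$pos_cM >= 0), "fh_parse_position",
            "pos_cM must be >= 0")
  if (anyDuplicated(markers$pos_cM))
    fh_stop("fh_parse_position_tie", "tied marker positions at %s cM",
            format(markers$pos_cM[duplicated(markers$pos_cM)][1L]))
  het <- markers$het[!is.na(markers$het)]
  fh_assert(all(het > 0 & het < 1), "fh_parse_het",
            "heterozygosity must lie in (0, 1)")
  markers <- markers[order(markers$pos_cM),
                     c("name", "chromosome", "pos_cM", "pos_bp", "het")]
  rownames(markers) <- NULL
  fh_assert(is.list(focal) && !is.null(focal$name) && !is.null(focal$pos_cM),
            "fh_parse_no_focal", "focal variant needs name and pos_cM")
  if (is.null(focal$pos_bp)) focal$pos_bp <- NA_real_
  if (any(markers$pos_cM == focal$pos_cM))
    fh_stop("fh_parse_position_tie",
            "focal variant position ties a marker position")
  terminal <- focal$pos_cM < min(markers$pos_cM) ||
    focal$pos_cM > max(markers$pos_cM)
  structure(list(markers = markers,
                 focal = focal[c("name", "pos_cM", "pos_bp")],
                 variant_terminal = terminal),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map: %d STR markers on chromosome %s\n",
              nrow(x$markers), x$markers$chromosome[1L]))
  cat(sprintf("  focal variant %s at %.4g cM%s%s\n", x$focal$name,
              x$focal$pos_cM,
              if (is.na(x$focal$pos_bp)) "" else
                sprintf(" (bp %.0f)", x$focal$pos_bp),
              if (x$variant_terminal) " [variant-terminal]" else ""))
  print(x$markers, ...)
  invisible(x)
}

read_clean_lines <- function(path) {
  if (!file.exists(path))
    fh_stop("fh_io_error", "file not found: %s", path)
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines[nzchar(lines)]
}

#' Read a genetic map file
#'
#' Parses the MAP dialect: whitespace-delimited columns `chromosome`,
#' `name`, `pos_cM`, optional `pos_bp`, optional `het`; `#` starts a
#' comment. Exactly one row must carry a `*` suffix on its chromosome label,
#' flagging the focal-variant pseudo-locus. Rows are returned sorted by
#' `pos_cM`; duplicate names and tied positions are rejected with named
#' parse errors.
#'
#' @param path path to a MAP-dialect text file.
#' @return A [genetic_map] object.
#' @seealso [write_map()], [read_genotypes()]
#' @export
read_map <- function(path) {
  lines <- read_clean_lines(path)
  fh_assert(length(lines) >= 2L, "fh_parse_shape",
            "map file needs at least one marker and the focal variant")
  toks <- strsplit(lines, "[ \t]+")
  nc <- lengths(toks)
  fh_assert(all(nc >= 3L & nc <= 5L), "fh_parse_shape",
            "map rows must have 3 to 5 columns")
  col <- function(i) vapply(toks, function(t)
    if (length(t) >= i) t[[i]] else "NA", "")
  chrom <- col(1L); name <- col(2L)
  pos_cM <- parse_num(col(3L), "pos_cM")
  pos_bp <- parse_num(col(4L), "pos_bp", allow_na = TRUE)
  het <- parse_num(col(5L), "het", allow_na = TRUE)
  is_focal <- grepl("\\*$", chrom)
  if (sum(is_focal) == 0L)
    fh_stop("fh_parse_no_focal", "no focal-variant row ('*' chromosome flag)")
  if (sum(is_focal) > 1L)
    fh_stop("fh_parse_multiple_focal", "more than one focal-variant row")
  chrom <- sub("\\*$", "", chrom)
  i <- which(is_focal)
  genetic_map(
    markers = data.frame(name = name[-i], chromosome = chrom[-i],
                         pos_cM = pos_cM[-i], pos_bp = pos_bp[-i],
                         het = het[-i], stringsAsFactors = FALSE),
    focal = list(name = name[i], pos_cM = pos_cM[i], pos_bp = pos_bp[i]))
}

#' Write a genetic map file
#'
#' Inverse of [read_map()]: emits the MAP dialect, flagging the focal
#' variant with a `*` chromosome suffix. Numeric columns are written at full
#' precision so that write-then-read round-trips exactly.
#'
#' @param map a [genetic_map].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  m <- map$markers
  fmt <- function(x) ifelse(is.na(x), "NA", format(x, digits = 15,
                                                   scientific = FALSE,
                                                   trim = TRUE))
  rows <- sprintf("%s\t%s\t%s\t%s\t%s", m$chromosome, m$name,
                  fmt(m$pos_cM), fmt(m$pos_bp), fmt(m$het))
  f <- map$focal
  focal_row <- sprintf("%s*\t%s\t%s\t%s\tNA", m$chromosome[1L], f$name,
                       fmt(f$pos_cM), fmt(f$pos_bp))
  pos <- c(m$pos_cM, f$pos_cM)
  writeLines(c(rows, focal_row)[order(pos)], path)
  invisible(path)
}

new_str_genotypes <- function(family_id, individual_id, carrier, a1, a2,
                              markers) {
  colnames(a1) <- colnames(a2) <- markers
  structure(list(family_id = family_id, individual_id = individual_id,
                 carrier = carrier, a1 = a1, a2 = a2, markers = markers),
            class = "str_genotypes")
}

#' @export
print.str_genotypes <- function(x, ...) {
  cat(sprintf("STR genotypes: %d individuals (%d carriers) x %d markers\n",
              length(x$individual_id), sum(x$carrier), length(x$markers)))
  invisible(x)
}

#' Number of genotyped individuals
#' @param x an `str_genotypes` object.
#' @return integer count of rows (individuals).
#' @export
n_individuals <- function(x) length(x$individual_id)

#' Read unphased STR genotypes of carriers
#'
#' Parses the PED dialect: whitespace-delimited rows `family`, `individual`,
#' `carrier` (0/1), then two allele columns per map marker, in map order.
#' Alleles are integer fragment sizes in bp; missing is coded 0 and both
#' slots of a genotype must be missing together (half-missing genotypes are
#' rejected). Reading is order-preserving and total: every row yields
#' exactly one record or one named parse error.
#'
#' @param path path to a PED-dialect text file.
#' @param map the [genetic_map] the genotypes were typed on (fixes the
#'   number and order of allele columns).
#' @return An object of class `str_genotypes`: parallel vectors
#'   `family_id`, `individual_id`, `carrier` and integer allele matrices
#'   `a1`, `a2` (individuals x markers, unordered pairs).
#' @export
read_genotypes <- function(path, map) {
  lines <- read_clean_lines(path)
  m <- nrow(map$markers)
  want <- 3L + 2L * m
  toks <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(toks) != want)
  if (length(bad))
    fh_stop("fh_parse_allele_count",
            "row %d has %d columns, expected %d (2 alleles x %d markers)",
            bad[1L], lengths(toks)[bad[1L]], want, m)
  n <- length(toks)
  fam <- vapply(toks, `[[`, "", 1L)
  ind <- vapply(toks, `[[`, "", 2L)
  carr_raw <- vapply(toks, `[[`, "", 3L)
  fh_assert(all(carr_raw %in% c("0", "1")), "fh_parse_carrier",
            "carrier flag must be 0 or 1")
  carrier <- carr_raw == "1"
  al <- matrix(NA_real_, n, 2L * m)
  for (i in seq_len(n)) {
    v <- suppressWarnings(as.numeric(toks[[i]][-(1:3)]))
    if (anyNA(v))
      fh_stop("fh_parse_numeric", "non-numeric allele in row %d", i)
    al[i, ] <- v
  }
  if (any(al %% 1 != 0) || any(al < 0))
    fh_stop("fh_parse_numeric",
            "alleles must be nonnegative integer fragment sizes")
  a1 <- matrix(as.integer(al[, seq(1L, 2L * m, by = 2L)]), n, m)
  a2 <- matrix(as.integer(al[, seq(2L, 2L * m, by = 2L)]), n, m)
  half <- (a1 == MISSING_ALLELE) != (a2 == MISSING_ALLELE)
  if (any(half))
    fh_stop("fh_parse_half_missing",
            "half-missing genotype (one allele 0) at row %d marker %s",
            which(rowSums(half) > 0)[1L],
            map$markers$name[which(colSums(half) > 0)[1L]])
  new_str_genotypes(fam, ind, carrier, a1, a2, map$markers$name)
}

#' Write STR genotypes in the PED dialect
#'
#' @param geno an `str_genotypes` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  n <- length(geno$individual_id)
  m <- length(geno$markers)
  rows <- vapply(seq_len(n), function(i) {
    pairs <- as.vector(rbind(geno$a1[i, ], geno$a2[i, ]))
    paste(c(geno$family_id[i], geno$individual_id[i],
            as.integer(geno$carrier[i]), pairs), collapse = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

COHORT_FLAGS <- c("taad", "arterial_other", "cardio_other", "connective")
COHORT_COLUMNS <- c("family_id", "individual_id", "sex", "age",
                    COHORT_FLAGS, "reported_z")

parse_flag <- function(x, what) {
  v <- rep(NA, length(x))
  v[x %in% c("1", "TRUE", "true", "T")] <- TRUE
  v[x %in% c("0", "FALSE", "false", "F")] <- FALSE
  if (anyNA(v))
    fh_stop("fh_parse_flag", "flag %s must be 0/1 or TRUE/FALSE, got '%s'",
            what, x[is.na(v)][1L])
  v
}

#' Read a cohort phenotype table
#'
#' Tab-delimited with a header row naming the fields: `family_id`,
#' `individual_id`, `sex` (male/female, M/F accepted), `age` (years,
#' optional), the four phenotype flags `taad` (thoracic aortic
#' aneurysm/dissection), `arterial_other` (non-aortic arterial
#' involvement), `cardio_other` (non-aneurysmal cardiovascular finding),
#' `connective` (connective-tissue finding), and an optional free-text
#' `reported_z` annotation carrying published aortic Z-scores (never
#' computed here). Unknown columns, unknown sex codes and duplicate
#' individuals within a family raise named errors.
#'
#' @param path path to the table.
#' @return A data.frame of class `phenotype_cohort`, one validated record
#'   per row (possibly zero rows).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    fh_stop("fh_io_error", "file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = "character", check.names = FALSE)
  unknown <- setdiff(names(df), COHORT_COLUMNS)
  if (length(unknown))
    fh_stop("fh_parse_unknown_column", "unknown cohort column: %s",
            unknown[1L])
  need <- setdiff(COHORT_COLUMNS, c("reported_z", "age"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    fh_stop("fh_parse_shape", "cohort table lacks column: %s",
            missing_cols[1L])
  if (nrow(df) == 0L) {
    out <- data.frame(family_id = character(), individual_id = character(),
                      sex = character(), age = numeric(),
                      taad = logical(), arterial_other = logical(),
                      cardio_other = logical(), connective = logical(),
                      reported_z = character(), stringsAsFactors = FALSE)
    class(out) <- c("phenotype_cohort", "data.frame")
    return(out)
  }
  sex <- c(male = "male", female = "female", M = "male", F = "female",
           m = "male", f = "female")[df$sex]
  if (anyNA(sex))
    fh_stop("fh_parse_sex", "unknown sex code: '%s'",
            df$sex[is.na(sex)][1L])
  key <- paste(df$family_id, df$individual_id)
  if (anyDuplicated(key))
    fh_stop("fh_parse_duplicate_individual",
            "duplicate individual within family: %s",
            key[duplicated(key)][1L])
  age <- if (is.null(df$age)) rep(NA_real_, nrow(df)) else
    parse_num(df$age, "age", allow_na = TRUE)
  fh_assert(all(is.na(age) | age >= 0), "fh_parse_age", "age must be >= 0")
  out <- data.frame(family_id = df$family_id,
                    individual_id = df$individual_id,
                    sex = unname(sex), age = age,
                    stringsAsFactors = FALSE)
  for (fl in COHORT_FLAGS) out[[fl]] <- parse_flag(df[[fl]], fl)
  out$reported_z <- if (is.null(df$reported_z)) NA_character_ else
    ifelse(df$reported_z %in% c("", "NA"), NA_character_, df$reported_z)
  class(out) <- c("phenotype_cohort", "data.frame")
  out
}

#' Write a cohort phenotype table
#'
#' @param cohort a `phenotype_cohort` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (fl in COHORT_FLAGS) df[[fl]] <- as.integer(df[[fl]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
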