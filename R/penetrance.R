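# Penetrance tabulation and Yates-corrected 2x2 proportion testing.

PENETRANCE_CATEGORIES <- c(COHORT_FLAGS, "arterial_any", "unaffected")

flag_matrix <- function(records) {
  m <- sapply(COHORT_FLAGS, function(f) as.logical(records[[f]]))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(records))
  colnames(m) <- COHORT_FLAGS
  m
}

category_vector <- function(records, category) {
  switch(category,
         arterial_any = records$taad | records$arterial_other,
         unaffected = rowSums(flag_matrix(records)) == 0,
         records[[category]])
}

#' Summarize phenotype categories over a carrier cohort
#'
#' Categories are not mutually exclusive except `unaffected` (all four
#' phenotype flags false); `arterial_any` is `taad | arterial_other`. Age
#' statistics cover the records with a known age.
#'
#' @param records a `phenotype_cohort` data.frame (see [read_cohort()]).
#' @return An object of class `cohort_summary` with counts `n_total`,
#'   `n_male`, `n_female`, `n_taad`, `n_arterial_any`, `n_cardio_other`,
#'   `n_connective`, `n_unaffected` and `age_mean`, `age_min`, `age_max`,
#'   `n_age`.
#' @export
summarize_cohort <- function(records) {
  fh_assert(nrow(records) >= 1L, "fh_domain_error",
            "cohort must be nonempty")
  age <- records$age[!is.na(records$age)]
  structure(list(
    n_total = nrow(records),
    n_male = sum(records$sex == "male"),
    n_female = sum(records$sex == "female"),
    n_taad = sum(records$taad),
    n_arterial_any = sum(category_vector(records, "arterial_any")),
    n_cardio_other = sum(records$cardio_other),
    n_connective = sum(records$connective),
    n_unaffected = sum(category_vector(records, "unaffected")),
    age_mean = if (length(age)) mean(age) else NA_real_,
    age_min = if (length(age)) min(age) else NA_real_,
    age_max = if (length(age)) max(age) else NA_real_,
    n_age = length(age)), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d carriers (%d male / %d female)\n", x$n_total,
              x$n_male, x$n_female))
  cat(sprintf("  TAAD %d, any arterial %d, other cardiovascular %d, connective %d, unaffected %d\n",
              x$n_taad, x$n_arterial_any, x$n_cardio_other, x$n_connective,
              x$n_unaffected))
  if (x$n_age)
    cat(sprintf("  age: mean %.1f, range %g-%g (n=%d with known age)\n",
                x$age_mean, x$age_min, x$age_max, x$n_age))
  invisible(x)
}

#' Counts-only description of a published comparison cohort
#'
#' Holds per-category affected counts for a cohort available only as
#' printed totals (no per-individual records), so it can stand on either
#' side of [compare_cohorts()].
#'
#' @param n_total cohort size.
#' @param counts named numeric vector of affected counts; names from
#'   `taad`, `arterial_other`, `cardio_other`, `connective`,
#'   `arterial_any`, `unaffected`.
#' @param n_male,n_female optional sex counts.
#' @return An object of class `cohort_counts`.
#' @examples
#' cohort_counts(82, c(taad = 33, arterial_any = 38, connective = 76))
#' @export
cohort_counts <- function(n_total, counts, n_male = NA_integer_,
                          n_female = NA_integer_) {
  fh_assert(n_total > 0, "fh_domain_error", "n_total must be > 0")
  bad <- setdiff(names(counts), PENETRANCE_CATEGORIES)
  if (length(bad))
    fh_stop("fh_unknown_category", "unknown category: %s", bad[1L])
  fh_assert(all(counts >= 0 & counts <= n_total), "fh_domain_error",
            "counts must lie in [0, n_total]")
  structure(list(n_total = as.integer(n_total), counts = counts,
                 n_male = n_male, n_female = n_female),
            class = "cohort_counts")
}

#' Penetrance of a phenotype category
#'
#' The fraction of variant carriers expressing a category:
#' `k` affected out of `n` carriers.
#'
#' @param x a `phenotype_cohort` data.frame or a [cohort_counts] object.
#' @param category one of `taad`, `arterial_other`, `cardio_other`,
#'   `connective`, `arterial_any`, `unaffected`.
#' @return A list of class `penetrance` with `k`, `n`, `fraction`
#'   and `category`.
#' @export
penetrance <- function(x, category) UseMethod("penetrance")

#' @export
penetrance.phenotype_cohort <- function(x, category) {
  fh_assert(category %in% PENETRANCE_CATEGORIES, "fh_unknown_category",
            "unknown category: %s", category)
  k <- sum(category_vector(x, category))
  new_penetrance(k, nrow(x), category)
}

#' @export
penetrance.cohort_counts <- function(x, category) {
  fh_assert(category %in% PENETRANCE_CATEGORIES, "fh_unknown_category",
            "unknown category: %s", category)
  k <- x$counts[category]
  if (is.na(k))
    fh_stop("fh_unknown_category",
            "category %s not recorded for this counts-only cohort",
            category)
  new_penetrance(as.integer(k), x$n_total, category)
}

new_penetrance <- function(k, n, category) {
  structure(list(k = k, n = n, fraction = k / n, category = category),
            class = "penetrance")
}

#' @export
print.penetrance <- function(x, ...) {
  cat(sprintf("%s penetrance: %d/%d = %.1f%%\n", x$category, x$k, x$n,
              100 * x$fraction))
  invisible(x)
}

#' Construct a 2x2 contingency table
#'
#' Rows are cohorts, columns affected/unaffected.
#'
#' @param a,b first cohort affected / unaffected counts.
#' @param c,d second cohort affected / unaffected counts.
#' @return A 2x2 integer matrix of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  fh_assert(all(cells >= 0) && all(cells %% 1 == 0), "fh_domain_error",
            "cells must be nonnegative integers")
  fh_assert(sum(cells) > 0, "fh_domain_error", "table must be nonempty")
  structure(matrix(as.integer(cells), 2L, 2L, byrow = TRUE,
                   dimnames = list(cohort = c("A", "B"),
                                   status = c("affected", "unaffected"))),
            class = c("two_by_two", "matrix", "array"))
}

# chi-square(1) upper tail, closed form: erfc(sqrt(q/2)) = 2*Phi(-sqrt(q))
chisq1_tail <- function(q) 2 * pnorm(sqrt(q), lower.tail = FALSE)

#' Chi-square proportion test with Yates continuity correction
#'
#' For cells `a, b, c, d` (n = a+b+c+d) computes
#' \deqn{\chi^2 = n \, (\max(|ad - bc| - n/2,\, 0))^2 /
#'   ((a+b)(c+d)(a+c)(b+d))}
#' with the correction clamped at zero, and the two-sided p-value from the
#' closed-form chi-square(1) upper tail \eqn{p = \mathrm{erfc}(\sqrt{\chi^2/2})}.
#' A zero row or column margin makes the comparison degenerate: the result
#' is `chi2 = 0`, `p = 1`, flagged, never an error.
#'
#' @param table a [two_by_two], a 2x2 matrix, or a length-4 vector
#'   `(a, b, c, d)`.
#' @param correct apply the Yates continuity correction (default TRUE).
#' @return An object of classes `fh_prop_test` and `htest` with
#'   `statistic`, `parameter` (df = 1), `p.value`, and logical fields
#'   `corrected` and `degenerate`.
#' @examples
#' yates_proportion_test(two_by_two(4, 23, 33, 49))
#' @export
yates_proportion_test <- function(table, correct = TRUE) {
  if (is.numeric(table) && length(table) == 4L && is.null(dim(table)))
    table <- two_by_two(table[1L], table[2L], table[3L], table[4L])
  fh_assert(is.matrix(table) && all(dim(table) == 2L), "fh_domain_error",
            "table must be 2x2")
  x <- as.numeric(table)        # column-major: a, c, b, d
  a <- x[1L]; c_ <- x[2L]; b <- x[3L]; d <- x[4L]
  n <- a + b + c_ + d
  fh_assert(n > 0, "fh_domain_error", "table must be nonempty")
  margins <- c(a + b, c_ + d, a + c_, b + d)
  degenerate <- any(margins == 0)
  if (degenerate) {
    chi2 <- 0; p <- 1
  } else {
    dev <- abs(a * d - b * c_) - if (correct) n / 2 else 0
    dev <- max(dev, 0)
    chi2 <- n * dev^2 / prod(margins)
    p <- chisq1_tail(chi2)
  }
  structure(list(statistic = c("X-squared" = chi2),
                 parameter = c(df = 1),
                 p.value = p,
                 method = paste0("2-sample proportion test",
                                 if (correct)
                                   " with Yates continuity correction"),
                 data.name = paste(x[c(1, 3, 2, 4)], collapse = ", "),
                 table = table, corrected = correct,
                 degenerate = degenerate),
            class = c("fh_prop_test", "htest"))
}

#' Compare category penetrance between two cohorts
#'
#' Builds the 2x2 table from the two cohorts' penetrance counts for a
#' category and applies [yates_proportion_test()]. Either cohort may be a
#' record-level `phenotype_cohort` or a counts-only [cohort_counts]
#' object.
#'
#' @param cohort_a,cohort_b the two cohorts.
#' @param category phenotype category name (see [penetrance()]).
#' @return A list of class `cohort_comparison` with `category`,
#'   `penetrance_a`, `penetrance_b`, `table` and `test`.
#' @export
compare_cohorts <- function(cohort_a, cohort_b, category) {
  pa <- penetrance(cohort_a, category)
  pb <- penetrance(cohort_b, category)
  tab <- two_by_two(pa$k, pa$n - pa$k, pb$k, pb$n - pb$k)
  structure(list(category = category, penetrance_a = pa,
                 penetrance_b = pb, table = tab,
                 test = yates_proportion_test(tab)),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Penetrance comparison, category '%s'\n", x$category))
  cat(sprintf("  cohort A: %d/%d (%.0f%%)   cohort B: %d/%d (%.0f%%)\n",
              x$penetrance_a$k, x$penetrance_a$n,
              100 * x$penetrance_a$fraction,
              x$penetrance_b$k, x$penetrance_b$n,
              100 * x$penetrance_b$fraction))
  cat(sprintf("  chi2 = %.3f, df = 1, p = %.4g%s\n",
              x$test$statistic, x$test$p.value,
              if (x$test$corrected) " (Yates-corrected)" else ""))
  invisible(x)
}
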