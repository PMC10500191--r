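# Dating the most recent common ancestor from haplotype decay.
#
# Closed form: if a founder-marker association survives one meiosis with
# probability 1 - theta, the generation count g solving (1 - theta)^g = p
# is g = log(p) / log(1 - theta). The Monte-Carlo estimator inverts the
# forward simulator instead: it scores candidate generation counts by how
# often simulated cohorts reproduce the observed minimal shared span.

#' Convert a genetic distance to a recombination fraction
#'
#' `haldane` applies the Haldane map function
#' \eqn{\theta = (1 - e^{-2d})/2} with `d` in Morgans (no crossover
#' interference); `direct` reads centimorgan as percent recombination,
#' \eqn{\theta = \min(d_{cM}/100, 0.5)}. Both are monotone nondecreasing in
#' distance and bounded by 0.5.
#'
#' @param distance_cM genetic distance in centimorgan, `>= 0` (vectorized).
#' @param map_function `"haldane"` (default) or `"direct"`.
#' @return Recombination fraction(s) in `[0, 0.5)` (haldane) or
#'   `[0, 0.5]` (direct).
#' @examples
#' cM_to_theta(50, "haldane")  # (1 - exp(-1))/2 = 0.3160603
#' cM_to_theta(4, "direct")    # 0.04
#' @export
cM_to_theta <- function(distance_cM, map_function = c("haldane", "direct")) {
  map_function <- match.arg(map_function)
  fh_assert(all(distance_cM >= 0), "fh_domain_error",
            "distance_cM must be >= 0")
  d <- distance_cM / 100   # Morgans
  switch(map_function,
         haldane = (1 - exp(-2 * d)) / 2,
         direct = pmin(d, 0.5))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

new_founder_age <- function(generations_exact, generation_time, method,
                            ci = NULL, ...) {
  structure(list(generations_exact = generations_exact,
                 generations = as.integer(round_half_away(generations_exact)),
                 years = generations_exact * generation_time,
                 generation_time = generation_time,
                 method = method, ci = ci, ...),
            class = "founder_age_estimate")
}

#' @export
print.founder_age_estimate <- function(x, ...) {
  cat(sprintf(
    "Founder age (%s): %.2f generations (rounded %d) ~ %.0f years (%g y/gen)\n",
    x$method, x$generations_exact, x$generations, x$years,
    x$generation_time))
  if (!is.null(x$ci))
    cat(sprintf("  interval: [%g, %g] generations\n", x$ci[1L], x$ci[2L]))
  if (isTRUE(x$lower_bound))
    cat("  note: estimate is a lower bound (no shared flank observed)\n")
  invisible(x)
}

#' Closed-form generation estimate from recombination decay
#'
#' Solves \eqn{(1-\theta)^g = p} for the number of generations `g` to the
#' most recent common ancestor: `g = log(p_term) / log(1 - theta)`. With
#' the cohort values `p_term = 2/5` and `theta = 0.04` this gives 22.45,
#' i.e. 22 generations after rounding (half away from zero). The exact
#' value is always reported alongside the rounded one.
#'
#' @param p_term probability term in `(0, 1]`, e.g. the fraction of
#'   non-recombinant haplotypes.
#' @param theta per-generation recombination probability in `(0, 0.5]`.
#' @param generation_time years per generation (default 20).
#' @return An object of class `founder_age_estimate` with
#'   `generations_exact`, `generations` (rounded), `years`, `method =
#'   "formula"`.
#' @examples
#' estimate_generations_formula(p_term = 2/5, theta = 0.04)
#' @export
estimate_generations_formula <- function(p_term, theta,
                                         generation_time = 20) {
  fh_assert(is.numeric(p_term) && length(p_term) == 1L && p_term > 0 &&
              p_term <= 1, "fh_domain_error", "p_term must be in (0, 1]")
  fh_assert(is.numeric(theta) && length(theta) == 1L && theta > 0 &&
              theta <= 0.5, "fh_domain_error", "theta must be in (0, 0.5]")
  fh_assert(generation_time > 0, "fh_domain_error",
            "generation_time must be > 0")
  g <- log(p_term) / log(1 - theta)
  new_founder_age(g, generation_time, method = "formula",
                  p_term = p_term, theta = theta)
}

#' Convert a generation estimate to calendar years
#'
#' @param estimate a `founder_age_estimate`.
#' @param generation_time years per generation.
#' @return `generations_exact * generation_time` (real years).
#' @export
generations_to_years <- function(estimate, generation_time) {
  fh_assert(generation_time > 0, "fh_domain_error",
            "generation_time must be > 0")
  estimate$generations_exact * generation_time
}

#' Monte-Carlo generation estimate by simulation inversion
#'
#' For each candidate generation count `g` in `grid`, simulates `reps`
#' cohorts of `lineages` independent founder descendants on `map` (Haldane
#' crossovers, population alleles from the map's heterozygosities), runs the
#' same delineation as the analysis, and scores the fraction of simulations
#' whose minimal shared cM span falls within a relative `tolerance` band of
#' the observed span. The estimate is the grid argmax; the reported interval
#' covers every `g` whose score is within a factor `exp(2)` of the maximum
#' (a likelihood-ratio-style cut). Fixed `seed` gives bit-identical results.
#'
#' An observed span of zero (no shared flank) cannot be inverted — the
#' estimate is then the grid maximum, flagged as a lower bound.
#'
#' @param map a [genetic_map] with the marker panel used for delineation.
#' @param observed a `shared_region` from [delineate_shared_region()] (or
#'   any object whose `sizes$cM_min` holds the minimal shared span).
#' @param lineages number of independent carrier chromosomes descending
#'   from the founder.
#' @param grid integer vector of candidate generation counts.
#' @param reps simulations per grid point (>= 100 recommended).
#' @param seed integer seed; all randomness derives from it.
#' @param tolerance relative half-width of the acceptance band on the
#'   minimal span (default 0.25).
#' @param generation_time years per generation (default 20).
#' @return A `founder_age_estimate` with `method = "monte_carlo"`, a `ci`
#'   interval, and the per-grid-point scores in `$scores`.
#' @export
estimate_generations_mc <- function(map, observed, lineages, grid = 2:60,
                                    reps = 200, seed = 1,
                                    tolerance = 0.25,
                                    generation_time = 20) {
  fh_assert(length(grid) >= 1L && all(grid >= 0), "fh_domain_error",
            "grid must be a nonempty vector of generation counts")
  fh_assert(reps >= 1L, "fh_domain_error", "reps must be >= 1")
  grid <- sort(unique(as.integer(grid)))
  obs <- observed$sizes$cM_min
  if (is.na(obs)) obs <- 0
  if (obs <= 0 || length(grid) == 1L) {
    g_hat <- max(grid)
    est <- new_founder_age(g_hat, generation_time, method = "monte_carlo",
                           ci = range(grid),
                           lower_bound = obs <= 0, seed = seed,
                           reps = reps, tolerance = tolerance)
    return(est)
  }
  tmpl <- simulation_config(map, generations = grid[1L],
                            lineages = lineages, seed = seed)
  lo <- obs * (1 - tolerance); hi <- obs * (1 + tolerance)
  scores <- vapply(seq_along(grid), function(gi) {
    spans <- mc_minimal_spans(map, tmpl, grid[gi], lineages, reps,
                              derive_seed(seed, gi))
    mean(spans >= lo & spans <= hi)
  }, 0)
  best <- max(scores)
  g_hat <- grid[which.max(scores)]
  keep <- if (best > 0) scores >= best / exp(2) else rep(TRUE, length(grid))
  ci <- range(grid[keep])
  new_founder_age(as.numeric(g_hat), generation_time,
                  method = "monte_carlo", ci = ci,
                  lower_bound = best == 0, seed = seed, reps = reps,
                  tolerance = tolerance,
                  scores = data.frame(g = grid, score = scores))
}
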