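# Forward simulator of founder-haplotype decay.
#
# Generative model: each carrier chromosome descends from one founder
# through g meioses (star genealogy, lineages independent). Per meiosis,
# crossovers form a Poisson process with rate 1 per Morgan (Haldane, no
# interference) over the map span around the focal variant. A marker keeps
# founder descent iff every meiosis placed an even number of crossovers
# between variant and marker, so the per-marker retention probability is
# (1 - theta_Haldane)^g; the contiguous retained segment is bounded by the
# nearest crossover over all meioses pooled (one-sided length ~ Exp(g)
# Morgans, censored at the map ends). Non-founder material and the whole
# second (non-transmitted) chromosome draw alleles i.i.d. from population
# frequencies: no background LD.

derive_seed <- function(seed, k) {
  ((as.numeric(seed) %% 65011) * 33013 + as.numeric(k) * 7919 + 17) %%
    2147483629
}

# Run fun(i) for i = 1..n, each on its own L'Ecuyer-CMRG substream of
# `seed` (proper independent lineage streams: stream i never depends on how
# much randomness stream j consumed, so n can grow without perturbing
# earlier streams). The caller's RNG state is restored afterwards.
with_rng_streams <- function(seed, n, fun) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = .GlobalEnv))
  suppressWarnings(set.seed(seed %% 2147483629, kind = "L'Ecuyer-CMRG"))
  s <- get(".Random.seed", envir = .GlobalEnv)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    assign(".Random.seed", s, envir = .GlobalEnv)
    out[[i]] <- fun(i)
    s <- parallel::nextRNGStream(s)
  }
  out
}

#' Allele frequencies with a prescribed expected heterozygosity
#'
#' Builds a frequency vector with one major allele and `k_alleles - 1`
#' equifrequent minor alleles whose expected heterozygosity
#' \eqn{H = 1 - \sum p_i^2} equals `H` exactly (closed-form quadratic
#' solve for the major frequency). Feasible only for
#' `H <= 1 - 1/k_alleles` (the equifrequent bound).
#'
#' @param H target expected heterozygosity in `(0, 1)`.
#' @param k_alleles number of alleles (>= 2).
#' @return Numeric frequency vector of length `k_alleles`, major allele
#'   first, summing to 1.
#' @examples
#' allele_freqs_for_heterozygosity(0.75, 4)  # equifrequent quartet
#' @export
allele_freqs_for_heterozygosity <- function(H, k_alleles) {
  fh_assert(H > 0 && H < 1, "fh_domain_error", "H must be in (0, 1)")
  fh_assert(k_alleles >= 2 && k_alleles %% 1 == 0, "fh_domain_error",
            "k_alleles must be an integer >= 2")
  bound <- 1 - 1 / k_alleles
  if (H > bound + 1e-12)
    fh_stop("fh_infeasible_heterozygosity",
            "H = %g exceeds the maximum 1 - 1/k = %g for k = %d alleles",
            H, bound, k_alleles)
  # solve p^2 + (1-p)^2/(k-1) = 1 - H for the major frequency p >= 1/k
  km1 <- k_alleles - 1
  A <- 1 + 1 / km1
  B <- -2 / km1
  C <- 1 / km1 - (1 - H)
  disc <- max(B^2 - 4 * A * C, 0)
  p <- (-B + sqrt(disc)) / (2 * A)
  c(p, rep((1 - p) / km1, km1))
}

#' Configure a founder-decay simulation
#'
#' Defaults emulate a dinucleotide STR panel: each marker gets
#' `k_alleles = 8` alleles spaced 2 bp apart, with frequencies solving the
#' marker's mapped heterozygosity (0.75 where the map has none), and a
#' founder haplotype drawn from those frequencies under the seed.
#'
#' @param map a [genetic_map].
#' @param generations number of meioses `g >= 0` separating each carrier
#'   from the founder.
#' @param lineages number of carrier chromosomes `k >= 1` descending
#'   independently from the founder.
#' @param n_families number of family labels the lineages are spread over
#'   (default one per lineage).
#' @param allele_freqs optional list (one element per marker) of named
#'   numeric vectors: names are allele sizes in bp, values frequencies
#'   summing to 1.
#' @param founder_haplotype optional integer vector of founder alleles,
#'   one per marker, each within the marker's allele set.
#' @param mutation_rate per-meiosis probability of a stepwise STR mutation
#'   on a transmitted founder allele (default 0).
#' @param mutation_step size of one mutation step in bp (default 2,
#'   dinucleotide).
#' @param k_alleles alleles per marker for the default frequency model.
#' @param seed integer seed; each lineage draws from its own
#'   L'Ecuyer-CMRG substream of `seed`, so changing `lineages` never
#'   perturbs other lineages' draws.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(map, generations, lineages,
                              n_families = lineages, allele_freqs = NULL,
                              founder_haplotype = NULL, mutation_rate = 0,
                              mutation_step = 2L, k_alleles = 8L,
                              seed = 1L) {
  fh_assert(inherits(map, "genetic_map"), "fh_domain_error",
            "map must be a genetic_map")
  fh_assert(generations >= 0 && generations %% 1 == 0, "fh_domain_error",
            "generations must be an integer >= 0")
  fh_assert(lineages >= 1 && lineages %% 1 == 0, "fh_domain_error",
            "lineages must be an integer >= 1")
  fh_assert(n_families >= 1 && n_families <= lineages, "fh_domain_error",
            "n_families must be in [1, lineages]")
  fh_assert(mutation_rate >= 0 && mutation_rate <= 1, "fh_domain_error",
            "mutation_rate must be in [0, 1]")
  m <- nrow(map$markers)
  if (is.null(allele_freqs)) {
    H <- ifelse(is.na(map$markers$het), 0.75, map$markers$het)
    allele_freqs <- lapply(seq_len(m), function(j) {
      p <- allele_freqs_for_heterozygosity(H[j], k_alleles)
      labels <- 150L + 20L * ((j - 1L) %% 8L) + 2L * (seq_along(p) - 1L)
      setNames(p, labels)
    })
  }
  fh_assert(length(allele_freqs) == m, "fh_domain_error",
            "allele_freqs must have one element per marker")
  for (j in seq_len(m)) {
    fh_assert(abs(sum(allele_freqs[[j]]) - 1) <= 1e-9,
              "fh_domain_error",
              "allele frequencies at marker %s must sum to 1",
              map$markers$name[j])
    fh_assert(all(as.integer(names(allele_freqs[[j]])) > 0),
              "fh_domain_error", "allele labels must be positive integers")
  }
  if (is.null(founder_haplotype)) {
    set.seed(derive_seed(seed, 0L))
    founder_haplotype <- vapply(allele_freqs, function(f)
      as.integer(sample(names(f), 1L, prob = f)), 1L)
  }
  fh_assert(length(founder_haplotype) == m, "fh_domain_error",
            "founder_haplotype must have one allele per marker")
  for (j in seq_len(m))
    fh_assert(as.character(founder_haplotype[j]) %in%
                names(allele_freqs[[j]]), "fh_domain_error",
              "founder allele %d outside marker %s's allele set",
              founder_haplotype[j], map$markers$name[j])
  structure(list(map = map, generations = as.integer(generations),
                 lineages = as.integer(lineages),
                 n_families = as.integer(n_families),
                 allele_freqs = allele_freqs,
                 founder_haplotype = as.integer(founder_haplotype),
                 map_function = "haldane",
                 mutation_rate = mutation_rate,
                 mutation_step = as.integer(mutation_step),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

map_geometry <- function(map) {
  d <- (map$markers$pos_cM - map$focal$pos_cM) / 100  # signed Morgans
  list(d = d,
       span_left = max(0, -min(d)),
       span_right = max(0, max(d)))
}

# One lineage: founder-descent indicators per marker, contiguous retained
# extents (Morgans, censored at map ends), and the two allele rows.
# Assumes set.seed() has been called by the caller.
sim_one_lineage <- function(geom, config, g) {
  d <- geom$d
  m <- length(d)
  keep <- rep(TRUE, m)
  ext_l <- geom$span_left; ext_r <- geom$span_right
  if (g > 0L) {
    span <- geom$span_left + geom$span_right
    nX <- rpois(g, span)
    total <- sum(nX)
    if (total > 0L) {
      xs <- runif(total, -geom$span_left, geom$span_right)
      mid <- rep.int(seq_len(g), nX)
      for (j in seq_len(m)) {
        sel <- if (d[j] >= 0) xs > 0 & xs < d[j] else xs < 0 & xs > d[j]
        if (any(sel)) {
          cnt <- tabulate(mid[sel], nbins = g)
          if (any(cnt %% 2L == 1L)) keep[j] <- FALSE
        }
      }
      pos_x <- xs[xs > 0]; neg_x <- xs[xs < 0]
      if (length(pos_x)) ext_r <- min(pos_x)
      if (length(neg_x)) ext_l <- min(-neg_x)
    }
  }
  a1 <- integer(m); a2 <- integer(m)
  for (j in seq_len(m)) {
    f <- config$allele_freqs[[j]]
    a1[j] <- if (keep[j]) config$founder_haplotype[j] else
      as.integer(sample(names(f), 1L, prob = f))
    a2[j] <- as.integer(sample(names(f), 1L, prob = f))
  }
  if (config$mutation_rate > 0 && g > 0L) {
    steps <- rbinom(m, g, config$mutation_rate)
    for (j in which(steps > 0L & keep)) {
      drift <- sum(sample(c(-1L, 1L), steps[j], replace = TRUE))
      a1[j] <- a1[j] + drift * config$mutation_step
    }
  }
  list(keep = keep, ext_l = ext_l, ext_r = ext_r, a1 = a1, a2 = a2)
}

# Fast path shared with estimate_generations_mc(): genotype matrices only.
# With redraw_founder the founder haplotype is treated as a nuisance and
# re-drawn from the population frequencies (marginalized), as in each
# replicate of the generative model.
sim_genotype_matrices <- function(geom, config, g, lineages, seed,
                                  redraw_founder = FALSE) {
  m <- length(geom$d)
  if (redraw_founder) {
    set.seed(derive_seed(seed, 0L))
    config$founder_haplotype <- vapply(config$allele_freqs, function(f)
      as.integer(sample(names(f), 1L, prob = f)), 1L)
  }
  lins <- with_rng_streams(seed, lineages, function(i)
    sim_one_lineage(geom, config, g))
  list(a1 = do.call(rbind, lapply(lins, `[[`, "a1")),
       a2 = do.call(rbind, lapply(lins, `[[`, "a2")))
}

# Vectorized Monte-Carlo kernel for estimate_generations_mc(): simulates
# `reps` cohorts of `lineages` descendants at generation count g in one set
# of array operations and returns each cohort's minimal shared cM span
# (0 when a flank is discordant). Same generative model and sharing
# semantics as simulate_cohort() + delineate_shared_region() restricted to
# complete data (no missing genotypes, mutation_rate 0); the founder
# haplotype is redrawn per cohort (marginalized as a nuisance).
mc_minimal_spans <- function(map, config, g, lineages, reps, seed) {
  geom <- map_geometry(map)
  pos <- map$markers$pos_cM
  m <- length(pos)
  iL <- sum(pos < map$focal$pos_cM)
  k <- lineages; R <- reps
  set.seed(seed %% 2147483629)
  span <- geom$span_left + geom$span_right
  M <- R * k * g                       # total meioses, meiosis index fastest
  keep <- matrix(TRUE, R * k, m)
  if (g > 0L && span > 0) {
    nX <- rpois(M, span)
    tot <- sum(nX)
    if (tot > 0L) {
      xs <- runif(tot, -geom$span_left, geom$span_right)
      mid <- rep.int(seq_len(M), nX)
      for (j in seq_len(m)) {
        dj <- geom$d[j]
        sel <- if (dj >= 0) xs > 0 & xs < dj else xs < 0 & xs > dj
        odd <- tabulate(mid[sel], nbins = M) %% 2L == 1L
        # lineage loses marker j if any of its g meioses is odd
        keep[, j] <- colSums(matrix(odd, nrow = g)) == 0L
      }
    }
  }
  founder <- vapply(config$allele_freqs, function(f)
    as.integer(sample(names(f), R, replace = TRUE, prob = f)),
    integer(R))                         # R x m, one founder per cohort
  if (R == 1L) founder <- matrix(founder, 1L)
  pop_draw <- function() vapply(config$allele_freqs, function(f)
    as.integer(sample(names(f), R * k, replace = TRUE, prob = f)),
    integer(R * k))
  founder_rows <- founder[rep(seq_len(R), each = k), , drop = FALSE]
  p1 <- pop_draw()
  a1 <- ifelse(keep, founder_rows, p1)
  a2 <- pop_draw()
  # shared status per (cohort, marker): some allele of lineage 1 present in
  # every lineage's unordered pair
  lin1 <- (seq_len(R) - 1L) * k + 1L
  shared <- matrix(FALSE, R, m)
  for (cand_src in list(a1, a2)) {
    cand <- cand_src[lin1, , drop = FALSE]
    present <- matrix(TRUE, R, m)
    for (i in seq_len(k)) {
      ri <- (seq_len(R) - 1L) * k + i
      present <- present &
        (a1[ri, , drop = FALSE] == cand | a2[ri, , drop = FALSE] == cand)
    }
    shared <- shared | present
  }
  # minimal interval: maximal all-shared prefix outward on each side
  left_pos <- rep(NA_real_, R); right_pos <- rep(NA_real_, R)
  alive <- rep(TRUE, R)
  for (j in seq.int(iL, 1L, length.out = max(0L, iL))) {
    alive <- alive & shared[, j]
    left_pos[alive] <- pos[j]
  }
  alive <- rep(TRUE, R)
  for (j in seq.int(iL + 1L, m, length.out = max(0L, m - iL))) {
    alive <- alive & shared[, j]
    right_pos[alive] <- pos[j]
  }
  ifelse(is.na(left_pos) | is.na(right_pos), 0, right_pos - left_pos)
}

statuses_from_matrices <- function(a1, a2) {
  m <- ncol(a1)
  informative <- rep(TRUE, nrow(a1))
  vapply(seq_len(m), function(j)
    status_one_marker(a1[, j], a2[, j], informative)$status, "")
}

#' Simulate a cohort of founder-descendant carriers
#'
#' Runs the forward model described in [simulation_config()]: each lineage
#' is an unphased carrier genotype (founder-descent chromosome plus an
#' independent population chromosome). Identical config and seed give
#' bit-identical output.
#'
#' @param config a [simulation_config].
#' @return An object of class `simulated_cohort`: `genotypes` (an
#'   `str_genotypes` object, all carriers), `truth` (data.frame with the
#'   per-lineage contiguous retained extent left/right of the variant in
#'   cM), `founder_markers` (logical lineages x markers founder-descent
#'   indicator matrix) and `config`.
#' @examples
#' map <- genetic_map(
#'   data.frame(name = c("M1", "M2"), chromosome = "14",
#'              pos_cM = c(5, 15)), list(name = "V", pos_cM = 10))
#' sim <- simulate_cohort(simulation_config(map, generations = 5,
#'                                          lineages = 3, seed = 42))
#' @export
simulate_cohort <- function(config) {
  fh_assert(inherits(config, "simulation_config"), "fh_domain_error",
            "config must come from simulation_config()")
  geom <- map_geometry(config$map)
  k <- config$lineages
  m <- nrow(config$map$markers)
  lins <- with_rng_streams(config$seed, k, function(i)
    sim_one_lineage(geom, config, config$generations))
  a1 <- do.call(rbind, lapply(lins, `[[`, "a1"))
  a2 <- do.call(rbind, lapply(lins, `[[`, "a2"))
  keep <- do.call(rbind, lapply(lins, `[[`, "keep"))
  ext <- cbind(vapply(lins, `[[`, 0, "ext_l"),
               vapply(lins, `[[`, 0, "ext_r"))
  fam <- sprintf("SIMFAM%02d", ((seq_len(k) - 1L) %% config$n_families) + 1L)
  ind <- sprintf("SIM%03d", seq_len(k))
  geno <- new_str_genotypes(fam, ind, rep(TRUE, k), a1, a2,
                            config$map$markers$name)
  truth <- data.frame(lineage = seq_len(k), individual_id = ind,
                      left_cM = ext[, 1L] * 100, right_cM = ext[, 2L] * 100,
                      stringsAsFactors = FALSE)
  colnames(keep) <- config$map$markers$name
  structure(list(genotypes = geno, truth = truth, founder_markers = keep,
                 config = config),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated founder cohort: %d lineages, g = %d meioses, %d markers (seed %d)\n",
    x$config$lineages, x$config$generations, ncol(x$founder_markers),
    x$config$seed))
  invisible(x)
}

#' Write a simulated cohort as analysis-ready fixture files
#'
#' Emits the MAP-dialect map, PED-dialect genotypes and a truth TSV
#' (per-lineage retained extents plus founder-descent indicators). The map
#' and genotypes re-read exactly with [read_map()] / [read_genotypes()].
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"sim"`).
#' @return Named character vector of the paths written (`map`,
#'   `genotypes`, `truth`).
#' @export
write_fixture <- function(cohort, dir, prefix = "sim") {
  fh_assert(inherits(cohort, "simulated_cohort"), "fh_domain_error",
            "cohort must come from simulate_cohort()")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(map = file.path(dir, paste0(prefix, ".map")),
             genotypes = file.path(dir, paste0(prefix, ".ped")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  write_map(cohort$config$map, paths[["map"]])
  write_genotypes(cohort$genotypes, paths[["genotypes"]])
  truth <- cbind(cohort$truth,
                 as.data.frame(cohort$founder_markers * 1L))
  write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}
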