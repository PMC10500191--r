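test_that("heterozygosity solver hits the target exactly", {
  expect_equal(allele_freqs_for_heterozygosity(0.75, 4), rep(0.25, 4))
  expect_equal(allele_freqs_for_heterozygosity(1 - 1 / 6, 6), rep(1 / 6, 6))
  f <- allele_freqs_for_heterozygosity(0.63, 4)
  expect_equal(sum(f), 1)
  expect_equal(1 - sum(f^2), 0.63, tolerance = 1e-9)
  expect_gte(f[1], f[2])             # one major, equifrequent minors
  expect_equal(f[2], f[3])
  for (H in c(0.63, 0.7, 0.75, 0.83)) {
    fr <- allele_freqs_for_heterozygosity(H, 8)
    expect_equal(1 - sum(fr^2), H, tolerance = 1e-9)
  }
  expect_error(allele_freqs_for_heterozygosity(0.8, 4),
               class = "fh_infeasible_heterozygosity")
})

test_that("zero generations transmit the full founder haplotype", {
  map <- tgfb3_map()
  sim <- simulate_cohort(simulation_config(map, generations = 0,
                                           lineages = 4, seed = 3))
  expect_true(all(sim$founder_markers))
  expect_true(all(sim$genotypes$a1 ==
                    matrix(sim$config$founder_haplotype, 4, 11,
                           byrow = TRUE)))
  region <- delineate_shared_region(map, sim$genotypes)
  expect_identical(unname(region$minimal),
                   c("D14S1065", "D14S1044"))
  expect_true(all(region$sharing$status == "shared"))
})

test_that("founder-allele retention follows (1-theta)^g under the Haldane model", {
  map <- genetic_map(data.frame(name = "M1", chromosome = "14",
                                pos_cM = 20),
                     list(name = "V", pos_cM = 10))
  n <- 4000L; g <- 10L
  sim <- simulate_cohort(simulation_config(map, generations = g,
                                           lineages = n, seed = 17))
  theo <- (1 - cM_to_theta(10, "haldane"))^g
  se <- sqrt(theo * (1 - theo) / n)
  expect_lt(abs(mean(sim$founder_markers[, 1]) - theo), 3 * se)
})

test_that("retained segment lengths are exponential with mean 1/g Morgans", {
  map <- genetic_map(data.frame(name = c("L", "R"), chromosome = "14",
                                pos_cM = c(0, 100)),
                     list(name = "V", pos_cM = 50))
  n <- 4000L; g <- 20L
  sim <- simulate_cohort(simulation_config(map, generations = g,
                                           lineages = n, seed = 23))
  ext <- c(sim$truth$left_cM, sim$truth$right_cM)
  # censoring at 50 cM is negligible at g = 20 (P ~ 4.5e-5)
  se <- (100 / g) / sqrt(length(ext))
  expect_lt(abs(mean(ext) - 100 / g), 3 * se)
  expect_true(all(sim$truth$left_cM >= 0 & sim$truth$right_cM >= 0))
})

test_that("simulated genotypes are consistent with the recorded truth", {
  map <- tgfb3_map()
  sim <- simulate_cohort(simulation_config(map, generations = 8,
                                           lineages = 6, seed = 31))
  founder <- sim$config$founder_haplotype
  for (i in 1:6) {
    kept <- sim$founder_markers[i, ]
    expect_true(all(sim$genotypes$a1[i, kept] == founder[kept]))
    # markers inside the contiguous truth segment are always founder-descent
    d_cM <- map$markers$pos_cM - map$focal$pos_cM
    inside <- d_cM >= -sim$truth$left_cM[i] & d_cM <= sim$truth$right_cM[i]
    expect_true(all(sim$founder_markers[i, inside]))
  }
})

test_that("population chromosomes reproduce the configured heterozygosity", {
  map <- mk_map(c(10, 30), 20)
  cfg <- simulation_config(map, generations = 1, lineages = 3000, seed = 41,
                           allele_freqs = list(
                             setNames(allele_freqs_for_heterozygosity(0.63, 8),
                                      seq(150, by = 2, length.out = 8)),
                             setNames(allele_freqs_for_heterozygosity(0.83, 8),
                                      seq(150, by = 2, length.out = 8))))
  sim <- simulate_cohort(cfg)
  for (j in 1:2) {
    H <- c(0.63, 0.83)[j]
    draws <- sim$genotypes$a2[, j]              # pure population draws
    p_hat <- table(factor(draws, levels = seq(150, by = 2,
                                              length.out = 8))) /
      length(draws)
    H_hat <- 1 - sum(p_hat^2)
    se <- sqrt(2 * H * (1 - H)) / sqrt(length(draws))  # conservative
    expect_lt(abs(H_hat - H), 4 * se)
  }
})

test_that("identical config and seed give byte-identical fixtures; lineage streams are stable under k changes", {
  map <- tgfb3_map()
  cfg <- simulation_config(map, generations = 22, lineages = 6,
                           n_families = 5, seed = 42)
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1, sim2)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_fixture(sim1, d1); p2 <- write_fixture(sim2, d2)
  for (f in names(p1))
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])))

  # adding lineages never perturbs earlier lineages' draws
  cfg8 <- simulation_config(map, generations = 22, lineages = 8,
                            n_families = 5, seed = 42,
                            founder_haplotype = cfg$founder_haplotype)
  sim8 <- simulate_cohort(cfg8)
  expect_identical(sim8$genotypes$a1[1:6, ], sim1$genotypes$a1)
  expect_identical(sim8$genotypes$a2[1:6, ], sim1$genotypes$a2)

  # six lineages grouped into five families, like the genotyped cohort
  expect_equal(length(unique(sim1$genotypes$family_id)), 5L)
  expect_equal(n_individuals(sim1$genotypes), 6L)
})

test_that("fixtures round-trip through the readers and truth has one row per lineage", {
  map <- tgfb3_map()
  sim <- simulate_cohort(simulation_config(map, generations = 10,
                                           lineages = 5, seed = 7))
  dir <- tempfile()
  paths <- write_fixture(sim, dir)
  map_rt <- read_map(paths[["map"]])
  expect_equal(map_rt, map)
  geno_rt <- read_genotypes(paths[["genotypes"]], map_rt)
  expect_identical(geno_rt$a1, sim$genotypes$a1)
  expect_identical(geno_rt$a2, sim$genotypes$a2)
  truth <- read.delim(paths[["truth"]])
  expect_equal(nrow(truth), 5L)
})

test_that("stepwise mutation perturbs only transmitted founder alleles", {
  map <- tgfb3_map()
  cfg <- simulation_config(map, generations = 15, lineages = 10, seed = 13,
                           mutation_rate = 0.05)
  sim <- simulate_cohort(cfg)
  founder <- cfg$founder_haplotype
  drift <- sweep(sim$genotypes$a1, 2, founder)[sim$founder_markers]
  expect_true(all(drift %% 2 == 0))      # dinucleotide steps only
  expect_true(any(drift != 0))           # some mutation at this rate
})

test_that("the vectorized dating kernel matches the lineage-level simulator", {
  map <- tgfb3_map()
  g <- 12L; k <- 5L
  # distribution route 1: simulate_cohort + delineate_shared_region
  spans_loop <- vapply(1:300, function(s) {
    sim <- simulate_cohort(simulation_config(map, generations = g,
                                             lineages = k, seed = 5000 + s))
    r <- delineate_shared_region(map, sim$genotypes)
    if (is.na(r$sizes$cM_min)) 0 else r$sizes$cM_min
  }, 0)
  # distribution route 2: mc_minimal_spans kernel
  tmpl <- simulation_config(map, generations = g, lineages = k, seed = 1)
  spans_vec <- founderhap:::mc_minimal_spans(map, tmpl, g, k, 300L,
                                             seed = 77L)
  # same support and matching nonempty-span rate within binomial error
  cands <- c(0, as.vector(dist(map$markers$pos_cM)))
  expect_true(all(vapply(spans_vec, function(s)
    any(abs(s - cands) < 1e-9), TRUE)))
  p1 <- mean(spans_loop > 0); p2 <- mean(spans_vec > 0)
  se <- sqrt(p1 * (1 - p1) / 300 + p2 * (1 - p2) / 300)
  expect_lt(abs(p1 - p2), 4 * se)
  expect_lt(abs(mean(spans_loop) - mean(spans_vec)),
            4 * (sd(spans_loop) + sd(spans_vec)) / sqrt(300))
})
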