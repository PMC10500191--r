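test_that("per-marker sharing is the intersection of carrier allele sets", {
  map <- mk_map(c(1, 3), 2)
  g <- mk_genotypes(map, list(c(150, 152, 150, 152),
                              c(152, 154, 154, 156),
                              c(150, 152, 150, 152)))
  s <- marker_sharing_status(map, g, "M01")
  expect_identical(s$status, "shared")
  expect_identical(s$shared_alleles, 152L)
  s2 <- marker_sharing_status(map, g, "M02")
  expect_identical(s2$status, "discordant")
  expect_length(s2$shared_alleles, 0L)

  # identical homozygotes share their single allele
  hom <- mk_genotypes(map, list(c(151, 151, 151, 151),
                                c(151, 151, 151, 151)))
  expect_identical(marker_sharing_status(map, hom, "M01")$shared_alleles,
                   151L)

  # fewer than two informative carriers => uninformative, never an error
  miss <- mk_genotypes(map, list(c(0, 0, 150, 152),
                                 c(0, 0, 150, 154),
                                 c(151, 153, 0, 0)))
  expect_identical(marker_sharing_status(map, miss, "M01")$status,
                   "uninformative")
  expect_error(marker_sharing_status(map, g, "NOPE"),
               class = "fh_unknown_marker")
})

test_that("fixture delineation recovers the expected marker pairs and spans", {
  map <- tgfb3_map()
  region <- delineate_shared_region(map, tgfb3_genotypes(map))
  expect_identical(unname(region$minimal),
                   c("D14S1047", "D14S270"))
  expect_identical(unname(region$maximal),
                   c("D14S1028", "D14S983"))
  expect_false(any(region$maximal_open))
  expect_equal(region$sizes$cM_min, 2.13)
  expect_equal(region$sizes$cM_max, 6.54)
  expect_equal(region$sizes$bp_min, 1.92e6)
  expect_equal(region$sizes$bp_max, 4.14e6)
  expect_identical(region$status, "ok")
  st <- setNames(region$sharing$status, region$sharing$marker)
  expect_identical(unname(st[c("D14S1065", "D14S258", "D14S1047",
                               "D14S61", "D14S270")]),
                   rep("shared", 5L))
  expect_identical(unname(st[c("D14S1028", "D14S983", "D14S74")]),
                   rep("discordant", 3L))
})

test_that("all-shared panels extend to map ends with open maximal bounds", {
  map <- mk_map(c(1, 2, 4, 7), 3)
  g <- mk_genotypes(map, list(c(150, 152, 150, 150, 150, 154, 150, 150),
                              c(150, 150, 150, 156, 150, 150, 150, 152)))
  region <- delineate_shared_region(map, g)
  expect_identical(unname(region$minimal), c("M01", "M04"))
  expect_identical(unname(region$maximal), c("M01", "M04"))
  expect_true(all(region$maximal_open))
  expect_true(region$sizes$max_is_lower_bound)
  expect_equal(region$sizes$cM_min, 6)
})

test_that("uninformative markers bridge runs but cannot be endpoints; all-discordant flanks give an empty minimal region", {
  map <- mk_map(c(1, 2, 4, 7), 3)
  # M02 (left-adjacent) all-missing, M01 shared, M03 shared, M04 discordant
  g <- mk_genotypes(map, list(c(150, 152, 0, 0, 150, 150, 150, 152),
                              c(150, 150, 0, 0, 150, 154, 154, 156)))
  region <- delineate_shared_region(map, g)
  expect_identical(unname(region$minimal), c("M01", "M03"))
  expect_identical(unname(region$maximal), c("M01", "M04"))

  # discordant immediately both sides of the variant
  g2 <- mk_genotypes(map, list(c(150, 150, 150, 152, 154, 156, 150, 150),
                               c(150, 150, 154, 156, 150, 152, 150, 150)))
  region2 <- delineate_shared_region(map, g2)
  expect_identical(region2$status, "empty-minimal")
  expect_true(anyNA(region2$minimal))
  expect_true(is.na(region2$sizes$cM_min))
})

test_that("variant outside the marker span is delineated from the flanking side and flagged", {
  map <- mk_map(c(5, 6, 8), 2)   # variant left of all markers
  g <- mk_genotypes(map, list(c(150, 152, 150, 150, 154, 156),
                              c(150, 150, 150, 152, 150, 152)))
  region <- delineate_shared_region(map, g)
  expect_identical(region$status, "variant-terminal")
  expect_identical(unname(region$minimal), c("M01", "M02"))
  expect_identical(unname(region$maximal), c("M01", "M03"))
})

test_that("delineation matches the exhaustive oracle on random small instances", {
  set.seed(42)
  for (rep in 1:150) {
    inst <- random_instance(sample(2:4, 1L), sample(2:4, 1L))
    got <- delineate_shared_region(inst$map, inst$genotypes)
    want <- oracle_delineate(inst$map, inst$genotypes)
    expect_identical(got$sharing$status, want$status)
    expect_identical(got$minimal, want$minimal)
    expect_identical(got$maximal, want$maximal)
  }
})

test_that("adding carriers only shrinks the intervals; output is carrier-order invariant", {
  set.seed(7)
  idx_interval <- function(map, region) {
    p <- map$markers$name
    c(match(region$minimal["left"], p), match(region$minimal["right"], p),
      match(region$maximal["left"], p), match(region$maximal["right"], p))
  }
  for (rep in 1:40) {
    # complete data: with missing genotypes an added carrier could turn an
    # uninformative marker into a shared endpoint, legitimately growing the
    # minimal interval
    inst <- random_instance(4L, 4L, p_missing = 0)
    g_all <- inst$genotypes
    sub <- g_all
    keep <- 1:3
    sub$family_id <- sub$family_id[keep]
    sub$individual_id <- sub$individual_id[keep]
    sub$carrier <- sub$carrier[keep]
    sub$a1 <- sub$a1[keep, , drop = FALSE]
    sub$a2 <- sub$a2[keep, , drop = FALSE]
    r_sub <- delineate_shared_region(inst$map, sub)
    r_all <- delineate_shared_region(inst$map, g_all)
    i_sub <- idx_interval(inst$map, r_sub)
    i_all <- idx_interval(inst$map, r_all)
    # minimal interval of the larger cohort nested in the smaller cohort's
    if (!anyNA(i_all[1:2]) && !anyNA(i_sub[1:2])) {
      expect_gte(i_all[1], i_sub[1])
      expect_lte(i_all[2], i_sub[2])
    }
    # maximal bounds can only move inward when carriers are added
    expect_gte(i_all[3], i_sub[3])
    expect_lte(i_all[4], i_sub[4])

    # permutation invariance
    perm <- sample(4L)
    shuf <- g_all
    shuf$family_id <- shuf$family_id[perm]
    shuf$individual_id <- shuf$individual_id[perm]
    shuf$carrier <- shuf$carrier[perm]
    shuf$a1 <- shuf$a1[perm, , drop = FALSE]
    shuf$a2 <- shuf$a2[perm, , drop = FALSE]
    r_shuf <- delineate_shared_region(inst$map, shuf)
    expect_identical(r_shuf$minimal, r_all$minimal)
    expect_identical(r_shuf$maximal, r_all$maximal)
    expect_identical(r_shuf$sharing$status, r_all$sharing$status)
  }
})

test_that("region sizes degrade gracefully and reports serialize", {
  map <- mk_map(c(1, 3), 2)      # no bp positions
  g <- mk_genotypes(map, list(c(150, 152, 150, 150),
                              c(150, 150, 150, 152)))
  region <- delineate_shared_region(map, g)
  expect_equal(region$sizes$cM_min, 2)
  expect_true(is.na(region$sizes$bp_min))   # bp absent: omitted, no error

  tsv <- tempfile(fileext = ".tsv"); json <- tempfile(fileext = ".json")
  write_region_report(region, tsv, json)
  expect_true(file.exists(tsv))
  doc <- jsonlite::read_json(json)
  expect_identical(doc$minimal$left, "M01")
  expect_equal(doc$sizes$cM_min, 2)
})
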