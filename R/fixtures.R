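# Packaged fixtures: a reconstruction of the TGFB3 p.(Asp263His) founder
# study inputs. Marker coordinates, allele sizes and per-individual
# phenotype flags are synthetic stand-ins shaped to reproduce the published
# summary quantities (see the file headers under extdata/); published
# counts-only cohorts are carried as cohort_counts objects.

fh_extdata <- function(file) {
  path <- system.file("extdata", file, package = "founderhap")
  fh_assert(nzchar(path), "fh_io_error", "packaged file missing: %s", file)
  path
}

#' Packaged TGFB3 founder-study fixtures
#'
#' Loaders for the reconstructed study inputs shipped with the package:
#' the 11-marker chromosome-14 STR map bracketing the TGFB3 focal variant,
#' the unphased genotypes of the six genotyped carriers (five families),
#' and the 27-carrier phenotype cohort. Coordinates, allele sizes and
#' per-individual flags are synthetic reconstructions; only the published
#' summary quantities (marker order, sharing pattern, span sizes, cohort
#' composition) are faithful.
#'
#' @return `tgfb3_map()` a [genetic_map]; `tgfb3_genotypes()` an
#'   `str_genotypes`; `tgfb3_cohort()` a `phenotype_cohort`.
#' @examples
#' map <- tgfb3_map()
#' delineate_shared_region(map, tgfb3_genotypes(map))
#' @export
tgfb3_map <- function() read_map(fh_extdata("tgfb3_str_markers.map"))

#' @rdname tgfb3_map
#' @param map the genetic map the genotypes are typed on.
#' @export
tgfb3_genotypes <- function(map = tgfb3_map())
  read_genotypes(fh_extdata("tgfb3_carriers.ped"), map)

#' @rdname tgfb3_map
#' @export
tgfb3_cohort <- function() read_cohort(fh_extdata("tgfb3_cohort.tsv"))

#' Published literature cohort of TGFB3 variant carriers, as counts
#'
#' The 82-patient literature comparison cohort (35 probands, 47 relatives,
#' 46 male / 36 female) is available only as printed per-category totals:
#' TAAD 33, any arterial involvement 38, connective-tissue findings 76.
#' It is therefore packaged as a counts-only [cohort_counts] object.
#'
#' @return A `cohort_counts` object with `n_total = 82`.
#' @export
tgfb3_literature_counts <- function()
  cohort_counts(82L, c(taad = 33, arterial_any = 38, connective = 76),
                n_male = 46L, n_female = 36L)
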