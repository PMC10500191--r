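# Shared-haplotype delineation around the focal variant from unphased
# carrier genotypes.
#
# Sharing criterion: a marker is "shared" when one allele size is present
# in every informative carrier's unordered genotype (nonempty intersection
# of per-individual allele sets) — a necessary condition for a common
# founder haplotype; no phase inference is attempted, matching panels with
# one genotyped carrier per family.

SHARING_LEVELS <- c("shared", "discordant", "uninformative")

carrier_allele_sets <- function(genotypes, j) {
  keep <- genotypes$carrier
  a1 <- genotypes$a1[keep, j]
  a2 <- genotypes$a2[keep, j]
  informative <- a1 != MISSING_ALLELE   # both-missing enforced at read time
  list(a1 = a1, a2 = a2, informative = informative)
}

status_one_marker <- function(a1, a2, informative) {
  if (sum(informative) < 2L)
    return(list(status = "uninformative", shared = integer()))
  a1 <- a1[informative]; a2 <- a2[informative]
  cand <- unique(c(a1[1L], a2[1L]))
  for (i in seq_along(a1)[-1L]) {
    cand <- cand[cand == a1[i] | cand == a2[i]]
    if (!length(cand)) break
  }
  if (length(cand)) list(status = "shared", shared = sort(cand))
  else list(status = "discordant", shared = integer())
}

#' Sharing status of one marker across carriers
#'
#' A marker is `shared` when the intersection of the carriers'
#' per-individual allele sets (ignoring fully missing individuals) is
#' nonempty; `discordant` when the intersection is empty; `uninformative`
#' when fewer than two carriers are genotyped at the marker (never an
#' error). Several equally shared alleles are all retained.
#'
#' @param map a [genetic_map].
#' @param genotypes an `str_genotypes` object; only rows with
#'   `carrier = TRUE` are used.
#' @param marker marker name (must be in the map).
#' @return A list of class `marker_sharing` with `marker`, `status`
#'   (one of shared/discordant/uninformative) and `shared_alleles`
#'   (sorted integer vector, empty unless shared).
#' @examples
#' map <- genetic_map(data.frame(name = "M1", chromosome = "14",
#'                               pos_cM = 1), list(name = "V", pos_cM = 2))
#' @export
marker_sharing_status <- function(map, genotypes, marker) {
  j <- match(marker, map$markers$name)
  fh_assert(!is.na(j), "fh_unknown_marker", "marker not in map: %s", marker)
  fh_assert(sum(genotypes$carrier) >= 2L, "fh_too_few_carriers",
            "need at least 2 carrier records")
  s <- carrier_allele_sets(genotypes, j)
  st <- status_one_marker(s$a1, s$a2, s$informative)
  structure(list(marker = marker, status = st$status,
                 shared_alleles = st$shared),
            class = "marker_sharing")
}

all_marker_statuses <- function(map, genotypes) {
  m <- nrow(map$markers)
  status <- character(m)
  shared <- vector("list", m)
  for (j in seq_len(m)) {
    s <- carrier_allele_sets(genotypes, j)
    st <- status_one_marker(s$a1, s$a2, s$informative)
    status[j] <- st$status
    shared[[j]] <- st$shared
  }
  list(status = status, shared = shared)
}

# Core interval logic on a status vector; returns marker indices.
# iL = last marker left of the variant (0 if none), statuses in map order.
region_from_statuses <- function(status, iL) {
  m <- length(status)
  iR <- iL + 1L
  walk <- function(idx, step) {
    stop_at <- 0L
    while (idx >= 1L && idx <= m) {
      if (status[idx] == "discordant") { stop_at <- idx; break }
      idx <- idx + step
    }
    stop_at            # 0 => ran off the map end
  }
  stopL <- if (iL >= 1L) walk(iL, -1L) else 0L
  stopR <- if (iR <= m) walk(iR, +1L) else m + 1L
  if (iR > m) stopR <- m + 1L else if (stopR == 0L) stopR <- m + 1L
  run <- if (stopL + 1L > stopR - 1L) integer(0) else
    seq.int(stopL + 1L, stopR - 1L)
  run <- run[run >= 1L & run <= m]
  shared_run <- run[status[run] == "shared"]
  min_left  <- shared_run[shared_run <= iL]
  min_right <- shared_run[shared_run >= iR]
  # variant outside the marker span: both minimal endpoints come from the
  # single flanking side (nearest-marker delineation, flagged upstream)
  if (iL == 0L && length(shared_run)) min_left <- min(shared_run)
  if (iR > m && length(shared_run)) min_right <- max(shared_run)
  list(min_left = if (length(min_left)) min(min_left) else NA_integer_,
       min_right = if (length(min_right)) max(min_right) else NA_integer_,
       max_left = if (stopL >= 1L) stopL else NA_integer_,
       max_right = if (stopR <= m) stopR else NA_integer_)
}

#' Delineate the minimal and maximal shared interval around the variant
#'
#' Walks outward from the focal variant over the per-marker sharing pattern.
#' The *minimal* interval is the outermost run of consecutive shared (or
#' uninformative) markers containing the variant, reported by its terminal
#' *shared* markers — uninformative markers inside the run do not break it
#' but cannot serve as endpoints. The *maximal* interval is bounded by the
#' first discordant marker on each side; where none exists the map end acts
#' as an open sentinel and the corresponding span is a lower bound only.
#'
#' If every marker flanking the variant on one side is discordant the
#' minimal interval is reported as empty on that side (`status`
#' `"empty-minimal"`), never an error. A focal variant outside the marker
#' span is handled from the nearest flanking markers and flagged
#' `"variant-terminal"`.
#'
#' @param map a [genetic_map].
#' @param genotypes an `str_genotypes` object with at least two carriers.
#' @return An object of class `shared_region`: list with `minimal` and
#'   `maximal` (named character vectors `left`/`right`, NA where
#'   undefined), `maximal_open` (logical left/right map-end sentinels),
#'   `status`, `sharing` (per-marker data.frame with a `shared_alleles`
#'   list column) and `sizes` as returned by [region_sizes()].
#' @references The interval semantics follow standard founder-haplotype
#'   practice: the minimal region is certainly shared, the maximal region
#'   is the largest possibly shared one.
#' @export
delineate_shared_region <- function(map, genotypes) {
  fh_assert(sum(genotypes$carrier) >= 2L, "fh_too_few_carriers",
            "need at least 2 carrier records")
  fh_assert(identical(genotypes$markers, map$markers$name),
            "fh_marker_mismatch", "genotype markers do not match the map")
  st <- all_marker_statuses(map, genotypes)
  pos <- map$markers$pos_cM
  iL <- sum(pos < map$focal$pos_cM)
  idx <- region_from_statuses(st$status, iL)
  nm <- map$markers$name
  pick <- function(i) if (is.na(i)) NA_character_ else nm[i]
  m <- length(nm)
  minimal <- c(left = pick(idx$min_left), right = pick(idx$min_right))
  maximal <- c(left = if (is.na(idx$max_left)) nm[1L] else nm[idx$max_left],
               right = if (is.na(idx$max_right)) nm[m] else
                 nm[idx$max_right])
  status <- if (anyNA(minimal)) "empty-minimal"
            else if (map$variant_terminal) "variant-terminal"
            else "ok"
  region <- structure(
    list(minimal = minimal, maximal = maximal,
         maximal_open = c(left = is.na(idx$max_left),
                          right = is.na(idx$max_right)),
         status = status,
         sharing = data.frame(marker = nm, pos_cM = pos,
                              status = st$status,
                              stringsAsFactors = FALSE)),
    class = "shared_region")
  region$sharing$shared_alleles <- st$shared
  region$sizes <- region_sizes(region, map)
  region
}

#' Genetic and physical sizes of a shared region
#'
#' Spans are differences of the bound markers' positions: minimal span
#' between the outermost shared markers, maximal span between the first
#' discordant markers (or map ends). Physical (bp) sizes are reported only
#' when the map carries physical positions; map-end sentinel spans are
#' flagged as lower bounds.
#'
#' @param region a `shared_region`.
#' @param map the [genetic_map] it was delineated on.
#' @return List with `cM_min`, `cM_max`, `bp_min`, `bp_max` (NA where
#'   undefined or bp absent) and `max_is_lower_bound`.
#' @export
region_sizes <- function(region, map) {
  m <- map$markers
  span <- function(bounds, col) {
    if (anyNA(bounds)) return(NA_real_)
    i <- match(bounds, m$name)
    fh_assert(!anyNA(i), "fh_unknown_marker",
              "region bound not in map: %s", bounds[is.na(i)][1L])
    v <- m[[col]][i]
    if (anyNA(v)) NA_real_ else v[2L] - v[1L]
  }
  list(cM_min = span(region$minimal, "pos_cM"),
       cM_max = span(region$maximal, "pos_cM"),
       bp_min = span(region$minimal, "pos_bp"),
       bp_max = span(region$maximal, "pos_bp"),
       max_is_lower_bound = unname(any(region$maximal_open)))
}

#' @export
print.shared_region <- function(x, ...) {
  s <- x$sizes
  fmt <- function(v, unit, scale = 1)
    if (is.na(v)) "n/a" else sprintf("%.4g %s", v / scale, unit)
  cat("Shared haplotype region around the focal variant\n")
  cat(sprintf("  minimal: %s - %s (%s, %s)\n", x$minimal["left"],
              x$minimal["right"], fmt(s$cM_min, "cM"),
              fmt(s$bp_min, "Mb", 1e6)))
  cat(sprintf("  maximal: %s - %s (%s, %s)%s\n", x$maximal["left"],
              x$maximal["right"], fmt(s$cM_max, "cM"),
              fmt(s$bp_max, "Mb", 1e6),
              if (s$max_is_lower_bound) " [lower bound: map end]" else ""))
  cat(sprintf("  status: %s\n", x$status))
  invisible(x)
}

#' Serialize a shared region to a per-marker table and a JSON document
#'
#' Writes the per-marker sharing table (tab-delimited, with a one-line
#' region summary comment) and, optionally, a structured JSON mirror.
#'
#' @param region a `shared_region`.
#' @param tsv_path output path for the tab-delimited table.
#' @param json_path optional output path for the JSON document.
#' @return Invisibly, the paths written.
#' @export
write_region_report <- function(region, tsv_path, json_path = NULL) {
  s <- region$sizes
  summary_line <- sprintf(
    "# minimal %s-%s cM=%s bp=%s; maximal %s-%s cM=%s bp=%s; status=%s",
    region$minimal["left"], region$minimal["right"],
    format(s$cM_min), format(s$bp_min),
    region$maximal["left"], region$maximal["right"],
    format(s$cM_max), format(s$bp_max), region$status)
  tab <- region$sharing
  tab$shared_alleles <- vapply(tab$shared_alleles, paste, "", collapse = ",")
  con <- file(tsv_path, "w"); on.exit(close(con))
  writeLines(summary_line, con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    doc <- list(minimal = as.list(region$minimal),
                maximal = as.list(region$maximal),
                maximal_open = as.list(region$maximal_open),
                sizes = s, status = region$status,
                sharing = region$sharing[c("marker", "pos_cM", "status")])
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(c(tsv_path, json_path))
}
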