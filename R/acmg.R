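# ACMG/AMP evidence combining: classify a variant from its evidence codes
# by the published combining-rule table. Evidence strengths come from the
# code prefix (no upgrades/downgrades); codes are inputs, never derived
# from annotations here.

ACMG_VOCAB <- c("PVS1",
                paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
                "BA1", paste0("BS", 1:4), paste0("BP", 1:7))

#' Evidence strength of ACMG codes
#'
#' @param codes character vector of ACMG evidence codes (e.g. `"PS3"`).
#' @return Character vector of strengths: `pvs` (pathogenic very strong),
#'   `ps` (strong), `pm` (moderate), `pp` (supporting), `ba` (benign
#'   stand-alone), `bs` (benign strong), `bp` (benign supporting).
#' @export
acmg_strength <- function(codes) {
  bad <- setdiff(codes, ACMG_VOCAB)
  if (length(bad))
    fh_stop("fh_acmg_unknown_code", "unknown ACMG code: %s", bad[1L])
  tolower(sub("[0-9]+$", "", codes))
}

#' Classify a variant from ACMG evidence codes
#'
#' Applies the standard ACMG/AMP combining rules to the multiset of
#' evidence strengths (the classification depends on strengths only, never
#' on code identity beyond its prefix):
#'
#' * Pathogenic: PVS1 with (one strong, or two moderate, or one moderate
#'   plus one supporting, or two supporting); two strong; one strong with
#'   (three moderate, or two moderate plus two supporting, or one moderate
#'   plus four supporting).
#' * Likely pathogenic: PVS1 plus one moderate; one strong plus one or two
#'   moderate; one strong plus two supporting; three moderate; two
#'   moderate plus two supporting; one moderate plus four supporting.
#' * Benign: BA1 alone; two benign strong. Likely benign: one benign
#'   strong plus one benign supporting; two benign supporting.
#'
#' Evidence from both sides at once is conflicting: whenever pathogenic and
#' benign codes co-occur the call is VUS (`fired_rule = "conflict"` when a
#' side would otherwise classify). PP5 (reputable-source assertion) is
#' accepted despite its later deprecation; a note is attached to the
#' result.
#'
#' @param tags character vector of ACMG codes; duplicates are collapsed.
#' @return A list of class `acmg_classification`: `value` (one of
#'   `pathogenic`, `likely pathogenic`, `VUS`, `likely benign`, `benign`),
#'   `fired_rule`, `tags`, `notes`.
#' @examples
#' acmg_classify(c("PS3", "PM2", "PP3", "PP4", "PP5"))  # likely pathogenic
#' @export
acmg_classify <- function(tags) {
  tags <- unique(as.character(tags))
  s <- acmg_strength(tags)   # validates
  n <- function(level) sum(s == level)
  pvs <- n("pvs"); ps <- n("ps"); pm <- n("pm"); pp <- n("pp")
  ba <- n("ba"); bs <- n("bs"); bp <- n("bp")

  path_rule <-
    if (pvs >= 1 && ps >= 1) "P1a"
    else if (pvs >= 1 && pm >= 2) "P1b"
    else if (pvs >= 1 && pm >= 1 && pp >= 1) "P1c"
    else if (pvs >= 1 && pp >= 2) "P1d"
    else if (ps >= 2) "P2"
    else if (ps >= 1 && pm >= 3) "P3a"
    else if (ps >= 1 && pm >= 2 && pp >= 2) "P3b"
    else if (ps >= 1 && pm >= 1 && pp >= 4) "P3c"
    else if (pvs >= 1 && pm >= 1) "LP1"
    else if (ps >= 1 && pm >= 1) "LP2"
    else if (ps >= 1 && pp >= 2) "LP3"
    else if (pm >= 3) "LP4"
    else if (pm >= 2 && pp >= 2) "LP5"
    else if (pm >= 1 && pp >= 4) "LP6"
    else NA_character_
  benign_rule <-
    if (ba >= 1) "B1"
    else if (bs >= 2) "B2"
    else if (bs >= 1 && bp >= 1) "LB1"
    else if (bp >= 2) "LB2"
    else NA_character_

  has_path <- (pvs + ps + pm + pp) > 0
  has_benign <- (ba + bs + bp) > 0
  if (has_path && has_benign) {
    fired <- if (!is.na(path_rule) || !is.na(benign_rule)) "conflict"
             else "none"
    value <- "VUS"
  } else if (!is.na(path_rule)) {
    value <- if (grepl("^P", path_rule) && !grepl("^LP", path_rule))
      "pathogenic" else "likely pathogenic"
    fired <- path_rule
  } else if (!is.na(benign_rule)) {
    value <- if (grepl("^B", benign_rule) && !grepl("^LB", benign_rule))
      "benign" else "likely benign"
    fired <- benign_rule
  } else {
    value <- "VUS"; fired <- "none"
  }
  notes <- character()
  if ("PP5" %in% tags)
    notes <- c(notes,
               "PP5 is deprecated by later ACMG guidance; retained as supporting evidence")
  structure(list(value = value, fired_rule = fired, tags = sort(tags),
                 notes = notes),
            class = "acmg_classification")
}

#' @export
print.acmg_classification <- function(x, ...) {
  cat(sprintf("ACMG classification: %s (rule %s)\n  evidence: %s\n",
              x$value, x$fired_rule, paste(x$tags, collapse = ", ")))
  for (note in x$notes) cat("  note:", note, "\n")
  invisible(x)
}
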