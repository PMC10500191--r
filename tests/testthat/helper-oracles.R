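# Shared helpers: quick constructors, random instances, and independent
# oracles (brute-force delineation, ACMG rule table, chi-square tail).

# map with markers at given cM positions and the variant at `variant_cM`
mk_map <- function(pos_cM, variant_cM, pos_bp = NULL,
                   names = sprintf("M%02d", seq_along(pos_cM))) {
  markers <- data.frame(name = names, chromosome = "14", pos_cM = pos_cM)
  if (!is.null(pos_bp)) markers$pos_bp <- pos_bp
  genetic_map(markers, focal = list(name = "VAR", pos_cM = variant_cM))
}

# genotypes from per-individual allele-pair lists:
# pairs[[i]] is a 2 x m matrix (or length-2m vector) of alleles
mk_genotypes <- function(map, pairs, carrier = NULL) {
  m <- nrow(map$markers)
  n <- length(pairs)
  a1 <- matrix(0L, n, m); a2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    p <- matrix(as.integer(pairs[[i]]), nrow = 2L)
    a1[i, ] <- p[1L, ]; a2[i, ] <- p[2L, ]
  }
  if (is.null(carrier)) carrier <- rep(TRUE, n)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  rows <- vapply(seq_len(n), function(i)
    paste(c(sprintf("F%d", i), sprintf("I%d", i), as.integer(carrier[i]),
            as.vector(rbind(a1[i, ], a2[i, ]))), collapse = "\t"), "")
  writeLines(rows, tmp)
  read_genotypes(tmp, map)
}

# random unphased instance: alleles from {150,152,154,156}, optional missing
random_instance <- function(n_markers, n_carriers, p_missing = 0.1) {
  alleles <- c(150L, 152L, 154L, 156L)
  pairs <- lapply(seq_len(n_carriers), function(i) {
    p <- matrix(sample(alleles, 2L * n_markers, replace = TRUE), nrow = 2L)
    miss <- runif(n_markers) < p_missing
    p[, miss] <- 0L
    p
  })
  gap <- sample(seq_len(n_markers - 1L), 1L)
  map <- mk_map(pos_cM = seq_len(n_markers),
                variant_cM = gap + 0.5)
  list(map = map, genotypes = mk_genotypes(map, pairs))
}

# Brute-force delineation oracle: per marker, enumerates every choice of
# one allele per informative carrier (every haplotype assignment consistent
# with the unphased genotypes) and asks whether some single allele series
# can be shared by all; then rebuilds the intervals by direct scanning of
# discordant indices. Only feasible for small instances.
oracle_delineate <- function(map, genotypes) {
  m <- nrow(map$markers)
  keep <- genotypes$carrier
  status <- character(m)
  for (j in seq_len(m)) {
    a1 <- genotypes$a1[keep, j]; a2 <- genotypes$a2[keep, j]
    inf <- a1 != 0L
    if (sum(inf) < 2L) { status[j] <- "uninformative"; next }
    sets <- Map(c, a1[inf], a2[inf])
    found <- FALSE
    for (v in unique(unlist(sets)))        # candidate shared allele series
      if (all(vapply(sets, function(s) v %in% s, TRUE))) found <- TRUE
    status[j] <- if (found) "shared" else "discordant"
  }
  pos <- map$markers$pos_cM
  iL <- sum(pos < map$focal$pos_cM)
  disc <- which(status == "discordant")
  leftD <- disc[disc <= iL]; rightD <- disc[disc > iL]
  lo <- if (length(leftD)) max(leftD) else 0L
  hi <- if (length(rightD)) min(rightD) else m + 1L
  run <- if (lo + 1L > hi - 1L) integer(0) else seq.int(lo + 1L, hi - 1L)
  shared_run <- run[status[run] == "shared"]
  minL <- shared_run[shared_run <= iL]
  minR <- shared_run[shared_run > iL]
  if (iL == 0L && length(shared_run)) minL <- min(shared_run)
  if (iL == m && length(shared_run)) minR <- max(shared_run)
  nm <- map$markers$name
  list(status = status,
       minimal = c(left = if (length(minL)) nm[min(minL)] else NA_character_,
                   right = if (length(minR)) nm[max(minR)] else
                     NA_character_),
       maximal = c(left = if (lo >= 1L) nm[lo] else nm[1L],
                   right = if (hi <= m) nm[hi] else nm[m]))
}

# Independent ACMG oracle: rule table transcribed as data, scanned in order.
oracle_acmg <- function(tags) {
  tags <- unique(tags)
  pre <- sub("[0-9]+$", "", tags)
  cnt <- function(p) sum(pre == p)
  vs <- cnt("PVS"); st <- cnt("PS"); mo <- cnt("PM"); su <- cnt("PP")
  sa <- cnt("BA"); bst <- cnt("BS"); bsu <- cnt("BP")
  path_rules <- list(
    list(c(1, 1, 0, 0), "pathogenic"), list(c(1, 0, 2, 0), "pathogenic"),
    list(c(1, 0, 1, 1), "pathogenic"), list(c(1, 0, 0, 2), "pathogenic"),
    list(c(0, 2, 0, 0), "pathogenic"), list(c(0, 1, 3, 0), "pathogenic"),
    list(c(0, 1, 2, 2), "pathogenic"), list(c(0, 1, 1, 4), "pathogenic"),
    list(c(1, 0, 1, 0), "likely pathogenic"),
    list(c(0, 1, 1, 0), "likely pathogenic"),
    list(c(0, 1, 0, 2), "likely pathogenic"),
    list(c(0, 0, 3, 0), "likely pathogenic"),
    list(c(0, 0, 2, 2), "likely pathogenic"),
    list(c(0, 0, 1, 4), "likely pathogenic"))
  path_call <- NA_character_
  for (r in path_rules)
    if (all(c(vs, st, mo, su) >= r[[1]])) { path_call <- r[[2]]; break }
  benign_call <-
    if (sa >= 1 || bst >= 2) "benign"
    else if ((bst >= 1 && bsu >= 1) || bsu >= 2) "likely benign"
    else NA_character_
  if ((vs + st + mo + su) > 0 && (sa + bst + bsu) > 0) return("VUS")
  if (!is.na(path_call)) return(path_call)
  if (!is.na(benign_call)) return(benign_call)
  "VUS"
}

# chi-square(1) upper tail by numerical integration of the density
oracle_chisq1_tail <- function(q) {
  if (q <= 0) return(1)
  integrate(function(x) dchisq(x, df = 1), lower = q, upper = Inf,
            rel.tol = 1e-13, abs.tol = 1e-15)$value
}
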