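---
title: "Founder haplotypes from STR panels: delineation, dating, penetrance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder haplotypes from STR panels: delineation, dating, penetrance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderhap)
```

# The problem

A rare pathogenic variant found in several families from the same region
usually descends from a single ancestor. The classical evidence is a
haplotype of polymorphic markers around the variant that all carriers
share, and the classical clock is the recombination decay of that
haplotype: every meiosis has a chance θ of separating the variant from a
flanking marker, so the shared region shrinks at a predictable rate.
`founderhap` implements the three quantitative stages of such a study —
delineation of the shared region, dating of the most recent common
ancestor (MRCA), and penetrance comparison — plus a forward simulator that
generates data with exactly the statistical structure the analysis
assumes, so every stage can be validated without access to patient data.

# Sharing from unphased genotypes

STR genotypes are unphased, unordered pairs of fragment sizes (bp).
With one genotyped carrier per family there is no transmission information
to phase with, so `delineate_shared_region()` uses a deliberately weak but
assumption-free criterion: a marker is **shared** when a single allele size
occurs in every informative carrier's pair (a nonempty intersection of
allele sets) — a necessary condition for a common founder haplotype.
Because phase is free at each marker, an allele series over an interval
can be assembled exactly when each marker in it is individually shared;
the test suite verifies this equivalence against an exhaustive
enumeration of all haplotype assignments on small instances.

Interval semantics:

* **minimal** region: the outermost run of consecutive shared markers
  containing the variant, reported marker-to-marker. Uninformative
  markers (fewer than two genotyped carriers) interposed in a run do not
  break it — missing data is absence of evidence — but cannot serve as
  endpoints.
* **maximal** region: bounded by the first discordant marker on each
  side. If no discordant marker exists on a side the map end is an open
  sentinel and the span is reported as a lower bound.

Degenerate inputs are results, not errors: discordant markers immediately
on both sides of the variant give an empty minimal region with status
`"empty-minimal"`; a focal variant outside the marker span is delineated
from the nearest flanking markers and flagged `"variant-terminal"`.
Ties (several alleles shared at one marker) are all retained; no arbitrary
choice is made. Sharing by state rather than by descent is a known
limitation: with common alleles, an interval can appear shared by chance,
which biases the maximal region outward; the minimal region, built only on
demonstrated sharing, is the conservative quantity.

# Dating the MRCA

## Closed form

If the founder-marker association survives one meiosis with probability
1 − θ, after n generations a fraction (1 − θ)ⁿ of transmissions is intact.
`estimate_generations_formula()` solves (1 − θ)ⁿ = p:

n = log(p) / log(1 − θ)

Parameters, both exposed, never hard-coded: the probability term `p_term`
in (0, 1] (e.g. the observed fraction of non-recombinant haplotypes) and
θ in (0, 0.5]. With `p_term = 2/5` and `theta = 0.04` the solution is
22.45, reported rounded half-away-from-zero as 22 generations; the exact
value is always carried alongside. Calendar years are
`generations_exact × generation_time` with a default generation time of
20 years — a conventional historical-demography value; the conversion is
deliberately explicit because no single generation interval is canonical.
`cM_to_theta()` supplies the Haldane map function
θ = (1 − e^(−2d))/2 (d in Morgans) for simulation work, and a `direct`
reading (cM/100, capped at 0.5) for user-entered distances, which is how
small printed distances are usually meant.

## Monte-Carlo inversion

`estimate_generations_mc()` inverts the forward simulator: for each
candidate g on a grid it simulates cohorts of k founder descendants,
delineates them with the same sharing logic as the analysis, and scores
the fraction of simulations whose minimal shared span falls within a
relative tolerance band (default ±25%) of the observed span. The estimate
is the grid argmax; the reported interval covers every g whose score is
within a factor e² of the maximum — a likelihood-ratio-style cut, not a
calibrated confidence level. The founder haplotype is redrawn in every
simulated cohort: it is a nuisance parameter, and fixing it would bias the
score toward one allele-frequency class. Ties at the argmax resolve to the
smallest g. A fixed seed gives bit-identical results.

A structural feature of star genealogies deserves emphasis: a marker at
recombination fraction θ survives in *all* k lineages with probability
(1 − θ)^(k·g). At g = 20 with k = 5 that is (1 − θ)^100, so even markers
well under 1 cM from the variant are frequently lost in at least one
lineage, and the minimal region is then empty. An empty observed span
cannot be inverted; per the decay-limit rule the estimator returns the
grid maximum flagged `lower_bound`. In the package's own recovery
experiment (truth g = 20, k = 5, 11-marker panel, grid 2..60, 150
simulations per grid point, seeds 1..20 — sizes chosen to keep the
experiment comfortably re-runnable) the reported interval covered the
truth in 20 of 20 replicates, but about half the replicates were
lower-bound cases, and among the informative ones the point estimates
spread widely around the truth (long surviving segments estimate young).
The honest summary: with five lineages the minimal-span statistic dates an
old founder only coarsely; the interval, not the point estimate, is the
defensible output.

# Penetrance and cohort comparison

`summarize_cohort()` counts the phenotype categories — TAAD (thoracic
aortic aneurysm/dissection), other arterial involvement, non-aneurysmal
cardiovascular findings, connective-tissue findings — which are not
mutually exclusive; `unaffected` means all four flags false, and
`arterial_any` is TAAD or other arterial involvement.
`yates_proportion_test()` applies the 2×2 chi-square proportion test with
Yates continuity correction, clamping (|ad − bc| − n/2) at zero so that
identical proportions give exactly χ² = 0, p = 1 rather than a spurious
positive statistic. p-values are two-sided, from the closed-form χ²(1)
tail p = erfc(√(χ²/2)) (computed through the exact normal-tail identity);
the suite checks agreement with `stats::prop.test` to 1e−12 and with
numerical integration of the χ²(1) density to 1e−10. Zero marginals make
a comparison degenerate (χ² = 0, p = 1, flagged), never an error. No
multiple-testing adjustment is applied across comparisons, and no exact
(Fisher) test is offered — the implemented test is the one the workflow
standardizes on. Published comparison cohorts that exist only as printed
totals are carried as counts-only `cohort_counts` objects rather than
fabricated individual records.

# The simulator

`simulate_cohort()` draws, per lineage and per meiosis, crossovers as a
Poisson process with rate 1 per Morgan over the map span (Haldane model,
no interference — consistent with the map function used for θ, and
crossover interference is negligible at these scales). A marker keeps
founder descent iff every meiosis placed an even number of crossovers
between variant and marker, which makes the per-marker retention
probability exactly (1 − θ_Haldane)^g; the contiguous retained segment is
bounded by the nearest crossover over all meioses pooled, giving one-sided
lengths that are Exp(g) in Morgans, censored at the map ends. Both bridge
properties are verified by Monte Carlo in the tests (10,000 lineages,
3 binomial/normal SE), and they are what ties `estimate_generations_mc()`
to the closed-form estimator.

Defaults emulate the kind of dinucleotide STR panel used in founder
studies: 8 alleles per marker spaced 2 bp, frequencies solving the
marker's mapped expected heterozygosity (one major allele, equifrequent
minors, closed-form quadratic; H defaults to 0.75 where the map has no
value, and panel fixtures space heterozygosities evenly over
[0.63, 0.83]). Lineages are independent founder-descent chains — a star
genealogy, with family labels optionally spread over fewer families than
lineages. Each lineage draws from its own L'Ecuyer-CMRG substream, so
enlarging a cohort never perturbs the lineages already drawn. Optional
stepwise mutation (±1 repeat unit, default 2 bp, per transmitted founder
allele per meiosis, default rate 0) lets one probe the robustness of
sharing delineation: a mutated founder allele breaks sharing at that
marker and widens the reported maximal region.

What the simulator does *not* emulate, and what passing tests therefore do
not show about real data: background linkage disequilibrium between
panel markers (alleles off the founder haplotype are drawn i.i.d.),
a genuinely shared internal genealogy (real families share intermediate
ancestors, so their effective meiosis counts are dependent and smaller),
genotyping artifacts (stutter, allele dropout, half-calls are rejected at
parsing rather than modeled), and population growth or selection.

# Numerical and design choices

* Allele labels are integer fragment sizes in bp — the measurement a
  capillary sequencer actually reports — not repeat counts. Missing is
  coded 0, and half-missing genotypes are rejected at read time.
* Physical positions are 1-based; a region's bp size is the difference of
  its bound markers' positions.
* Map files carry the focal variant as a pseudo-locus row flagged by a
  `*` suffix on the chromosome label: one file, explicit flag. Maps are
  sorted on read; tied positions are an error.
* The packaged chromosome-14 fixtures are reconstructions: published
  founder studies print span sizes, not marker coordinates, so the
  fixture coordinates were chosen once to reproduce the published spans
  (2.13/6.54 cM, 1.92/4.14 Mb) and are labelled synthetic in the files.
* Evidence strengths in `acmg_classify()` come from the code prefix with
  no upgrades or downgrades; co-occurring pathogenic and benign evidence
  resolves to VUS; PP5 is accepted with a deprecation note.
* Test problem sizes (4,000–10,000 lineages for distributional checks,
  150 simulations per grid point, 20 recovery replicates) were fixed once
  as comfortable Monte-Carlo sizes for the asserted 3-SE tolerances.

# Limitations

Sharing is by state, not descent; the maximal region is anticonservative
under common alleles. The dating formula treats θ and p as known
constants and carries no sampling uncertainty; the Monte-Carlo interval
reflects simulation spread under a star genealogy only. Penetrance
comparisons against literature cohorts inherit the ascertainment bias of
published case series — symptomatic carriers are overrepresented — which
the test cannot correct, only quantify against.
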