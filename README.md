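# founderhap

Founder-variant analysis from microsatellite (STR) marker panels, in R.

When the same rare pathogenic variant turns up in several apparently
unrelated families, the classic way to demonstrate a common founder is to
genotype a panel of polymorphic STR markers flanking the variant and look
for a haplotype all carriers share. `founderhap` implements that workflow
end to end for clinical-genetics groups doing founder studies:

* **Shared-haplotype delineation** from unphased allele sizes: per-marker
  sharing status (nonempty intersection of carrier allele sets), the
  *minimal* shared interval (outermost shared markers around the variant)
  and the *maximal* interval (bounded by the first discordant marker on
  each side), with genetic (cM) and physical (bp) spans.
* **Dating the most recent common ancestor** from recombination decay.
  If a founder-marker association survives one meiosis with probability
  1 − θ, the number of generations solving (1 − θ)ⁿ = p is

      n = log(p) / log(1 − θ)

  There is also a Monte-Carlo inversion of the forward simulator
  (`estimate_generations_mc()`) that scores candidate generation counts by
  how often simulated cohorts reproduce the observed minimal span.
* **Penetrance tabulation and cohort comparison** with the chi-square
  proportion test with Yates continuity correction,
  χ² = n·(max(|ad−bc| − n/2, 0))² / ((a+b)(c+d)(a+c)(b+d)), two-sided
  p from the closed-form χ²(1) tail erfc(√(χ²/2)).
* **ACMG evidence combining** (`acmg_classify()`): the standard
  combining-rule table over PVS/PS/PM/PP/BA/BS/BP codes.
* **A forward simulator of founder-haplotype decay**
  (`simulate_cohort()`): carrier chromosomes descend from one founder
  through *g* meioses with Haldane (no-interference) crossovers;
  non-founder material draws from population allele frequencies with
  configurable expected heterozygosity. Every analysis stage is testable
  against it.

The package ships reconstructed fixtures shaped after a chromosome-14
*TGFB3* p.(Asp263His) founder cohort (11 dinucleotide STR markers, six
genotyped carriers from five families, a 27-carrier phenotype table and a
counts-only 82-patient literature cohort). Marker coordinates, allele
sizes and per-individual flags are synthetic stand-ins; the file headers
say exactly what is reconstructed.

## Worked example

```r
library(founderhap)

map    <- tgfb3_map()
region <- delineate_shared_region(map, tgfb3_genotypes(map))
region
#> Shared haplotype region around the focal variant
#>   minimal: D14S1047 - D14S270 (2.13 cM, 1.92 Mb)
#>   maximal: D14S1028 - D14S983 (6.54 cM, 4.14 Mb)
#>   status: ok

estimate_generations_formula(p_term = 2/5, theta = 0.04)
#> Founder age (formula): 22.45 generations (rounded 22) ~ 449 years (20 y/gen)

compare_cohorts(tgfb3_cohort(), tgfb3_literature_counts(), "taad")
#> Penetrance comparison, category 'taad'
#>   cohort A: 4/27 (15%)   cohort B: 33/82 (40%)
#>   chi2 = 4.779, df = 1, p = 0.02882 (Yates-corrected)
```

Reading: all six carriers share one allele at every marker from D14S1047
through D14S270, so the founder haplotype certainly spans those 2.13 cM
(1.92 Mb); the first discordant markers bound the largest possibly shared
interval at 6.54 cM (4.14 Mb). A haplotype surviving intact in 2 of 5
transmissions per θ = 0.04 of recombination dates the founder about 22
generations back. TAAD penetrance in the carrier cohort (15%) is
significantly below the literature cohort's 40% (p ≈ 0.029).

A command-line front end is installed as `exec/founderhap`
(`founderhap report --map ... --genotypes ... --cohort ... --out DIR`
chains the whole workflow and writes JSON + text reports with a
provenance block); `fh_cli_run()` exposes the same interface in-process.

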