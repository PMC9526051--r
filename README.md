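# trafficlines

Tools for genetic analysis with *Arabidopsis thaliana* "traffic lines" —
transgenic stocks carrying a pair of linked, seed-expressed fluorescent
reporters (*pNAP::eGFP* and *pNAP::DsRed*) in cis on one chromosome. Seed
fluorescence reports the inheritance of the marked chromosome segment, so a
traffic line works like a visual balancer: the genotype of a seed can be read
under a stereomicroscope before it is ever planted. The package is written
for plant geneticists planning or interpreting crosses with these stocks, and
for anyone who wants the underlying genetic calculus (testcross linkage
estimation, three-point gamete probabilities, dosage-coded seed
classification) in tested, scriptable form.

The package has four working parts:

- **Catalog.** A validated, queryable transcription of the published table of
  162 short-interval lines covering the five chromosomes (ABRC IDs, marker
  insertion coordinates on the Col reference, testcross seed-class counts,
  printed cM and cM/Mb). `check_integrity()` recomputes every derivable
  quantity and flags rows where the print contradicts itself;
  `find_spanning()` answers "which lines balance this locus?";
  `export_bed()` writes the intervals as BED.
- **Linkage.** The recombination fraction between the two reporters is
  estimated from the four fluorescence classes of a testcross: with markers
  in trans (repulsion), `r̂ = (n_both + n_none) / N` and `cM = 100 r̂` (the
  direct rule used throughout the printed table), with a Wilson score
  interval, exact 2×2 between-line comparison, and exact binomial
  segregation-distortion diagnostics.
- **Cross calculator.** Exact gamete and seed-class distributions for the
  schemes these lines support. For a three-point map with segment fractions
  r₁, r₂ and coincidence c, double-recombinant gametes arise at frequency
  c·r₁·r₂, and the probability that a nonfluorescent gamete secretly carries
  the marked chromosome's interior allele is
  c·r₁·r₂ / (1 − r₁ − r₂ + 2c·r₁·r₂) — the balancer-purity calculation.
  Seed genotyping posteriors, the lethal-rescue scheme, the linked-mutation
  separation screen and sample-size planning are built on the same engine.
- **Meiosis simulator.** A stationary gamma-renewal chiasma process (shape ν,
  2 chiasmata per Morgan, ½-thinning; ν = 1 recovers Poisson crossovers and
  Haldane's map) generates synthetic gametes, seed populations and testcross
  count tables, and serves as the brute-force oracle for every closed form in
  the cross calculator.

## Worked example

```r
library(trafficlines)

cat0 <- traffic_line_catalog()
row <- cat0[cat0$line_id == "1.30", ]
est <- estimate_r(count_table(row$n_red, row$n_green, row$n_both, row$n_none))
est
#> r = 0.0780 (33/423), 7.8 cM; 95% Wilson CI [0.0561, 0.1075]
recomb_rate(est, row$interval_nt)$cM_per_Mb
#> [1] 8.6

find_spanning(cat0, 3, 7230000)$line_id   # who balances Chr3:7,230,000?
#> [1] "3.31"

balancer_purity(0.035, 0.035)$contamination
#> [1] 0.001313743

rescue_scheme(0, 0, tau = 0)
#>                      fluorescent_viable                        fluorescent_dead
#>                                    0.75                                    0.00
#>                     nonfluorescent_dead       nonfluorescent_rescued_homozygote
#>                                    0.25                                    0.00
#> nonfluorescent_recombinant_heterozygote
#>                                    0.00
```

Line 1.30's 33 recombinant seeds among 423 give 7.8 cM across a 0.90-Mb
interval (8.6 cM/Mb), matching the printed catalog row. At the catalog's
average half-interval fractions (0.035 per side), about 1.3 nonfluorescent
chromosomes per thousand carry the marked chromosome's allele at the interval
midpoint — the residual risk when a line is used as a balancer. Selfing a
heterozygote that balances a recessive lethal gives three quarters
fluorescent viable seeds and one quarter nonfluorescent dead, the expectation
behind the transgene-rescue scheme.

A command-line wrapper is installed at `inst/scripts/tl`
(`tl catalog summary`, `tl estimate --counts FILE`,
`tl simulate testcross --r R --n N --seed S`, ...).

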