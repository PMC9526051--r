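---
title: "The genetic calculus of fluorescent traffic lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The genetic calculus of fluorescent traffic lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trafficlines)
```

## The system

A traffic line is an *Arabidopsis thaliana* stock carrying two linked
seed-expressed fluorescent transgenes — eGFP and DsRed under the seed-specific
Napin promoter — in cis on one chromosome of the Col accession. Because the
reporters are scored in dry seeds and their intensity is dosage-coded (0, 1
or 2 copies give none, moderate or strong fluorescence per channel), a seed's
genotype at the marked interval can be read by eye before planting. Held in
trans to an unmarked chromosome, the line acts as a balancer: a
nonfluorescent seed almost certainly carries two copies of the unmarked
homolog, failing only through double recombination inside the marked
interval. Held over a chromosome carrying mutations of interest, the same
dosage coding turns seed fluorescence into a genotyping, mapping, rescue or
recombinant-screening assay.

This package implements that calculus end to end: the catalog of 162
short-interval lines as validated data, linkage estimation from the
testcrosses that measured each line, an exact probability engine for the
crossing schemes, and a meiosis simulator that doubles as a brute-force
oracle for the closed forms.

## The catalog and its recomputation

Each catalog row records the two insertion positions, the physical interval,
and the four seed classes counted when the doubly marked heterozygote was
testcrossed to Col with the markers in trans: dsRed-only and GFP-only seeds
are parental, doubly fluorescent and nonfluorescent seeds are recombinant.

Two transcription-level conventions matter and are applied consistently:

- **The sample size is the class sum**, never the printed "Total" column.
  Several published rows print totals that contradict the class sum, and
  where they disagree the printed cM is consistent with the class sum (line
  1.70: classes sum to 153, total printed 321, printed 6.5 cM matches
  100 × 10/153). The printed totals are retained and flagged.
- **cM/Mb divides the 1-dp-rounded cM**, not the raw proportion. Line 3.49
  prints 16.5 = 2.0/0.121308; the raw 2.0339/0.121308 would print 16.8.

`check_integrity()` recomputes interval lengths, totals, cM and cM/Mb and
flags disagreements beyond ±0.1 cM and ±0.2 cM/Mb. The bands absorb the
table's mixed rounding conventions (some rows round half up, at least one
truncates). On the packaged catalog the flags are genuine features of the
printed table: cM mismatches (1.29, 2.17, 3.38, 5.21, 5.32 — 3.38's printed
5.7 against a recomputed 0.57 looks like a decimal slip), total mismatches
(1.70, 2.36, 5.21), one interval-length mismatch (1.42), and one duplicated
count vector (5.34/5.38). Every other row reproduces its printed values.

```{r integrity}
flags <- check_integrity(traffic_line_catalog())
table(flags$flag_kind)
```

Spanning queries treat positions as 1-based and intervals as closed; BED
export uses the standard 0-based half-open convention, so the two round-trip
exactly. The coverage summary reports the genome-average recombination rate
both as the column mean of printed cM/Mb and as the ratio of mean cM to mean
Mb; the two conventions disagree for this catalog (6.3 vs 5.5) and neither is
privileged.

## Linkage estimation

The recombination fraction is the pooled recombinant proportion R/N, and
distances follow the direct rule cM = 100 r — the row arithmetic of the
printed table shows no Haldane or Kosambi correction, so those map functions
exist here only to calibrate the simulator. The confidence interval is the
Wilson score interval at 95% by default: the recombinant counts in short
intervals are small (some rows have 4–6 recombinants), where the Wald
interval misbehaves and Wilson does not. Estimates above 0.5 are reported as
computed but flagged, since they usually mean the phase was mis-specified.

Two diagnostics accompany the estimator. `compare_lines()` is Fisher's exact
test on the 2×2 recombinant/parental table of two lines, for asking whether
two lines spanning the same region recombine at different rates.
`distortion_tests()` runs exact binomial tests of 1:1 within the parental
and recombinant pairs separately; a lopsided recombinant split (such as 18
recombinants on one flank against 6 on the other, p ≈ 0.023) is the
signature of an insertion-associated rearrangement suppressing recombination
on one side, while the pooled estimate stays unbiased.

## The exact engine

`gamete_distribution()` supports one, two or three linked loci with a scalar
coefficient of coincidence c applied to adjacent-segment doubles:
parental haplotypes at (1 − r₁ − r₂ + c·r₁·r₂)/2, single-region recombinants
at (rᵢ − c·r₁·r₂)/2, doubles at c·r₁·r₂/2. Interference in the literature on
this system is invoked only qualitatively, so a single scalar c is the
honest level of modelling; no closed-form bridge to the simulator's renewal
parameter is claimed. Maps with more than three linked loci are enumerated
exactly under independent segment crossovers (c = 1); combining more than
three loci *with* interference is delegated to the simulator rather than
inventing a multi-locus interference algebra. Unlinked groups combine by
independence, and structurally absent haplotypes (probability exactly zero)
are dropped from every distribution.

Seed classes are modelled on the diploid embryo: per channel, reporter
dosage 0/1/2 maps to none/moderate/strong. (Endosperm is triploid and could
in principle shift intensities for maternally vs paternally inherited
copies; the embryo-dosage model is the deliberate simplification and an
acknowledged limitation.) Misclassification is a per-seed, per-channel
probability ε of sliding to an adjacent intensity — moderate splits its ε
evenly between none and strong — independent between channels, default 0.
The observed 97% scoring concordance in the genotyping experiment motivates
offering ε as a free parameter; it is not fitted to anything. Lethality acts
after genotype formation and before observation, because dead (shrivelled)
seeds are still scored for fluorescence.

The scheme calculators are thin compositions of the engine:

- `balancer_purity()`: conditioning on a gamete showing neither marker, the
  probability it nonetheless carries the marked chromosome's interior allele
  is c·r₁·r₂/(1 − r₁ − r₂ + 2c·r₁·r₂); it peaks when the locus sits at the
  genetic midpoint and falls toward either marker.
- `rescue_scheme()`: a lethal allele balanced in trans, selfed after
  transformation at rate τ. With no recombination, ¾ of seeds are
  fluorescent and viable and ¼ nonfluorescent dead; rescued homozygotes
  enter at rate τ and double-recombination heterozygotes at the
  balancer-contamination rate. The tiny nonfluorescent +/+ class (both
  gametes doubly recombinant) is folded into the recombinant-heterozygote
  category.
- `separation_scheme()`: F2 seeds with a strong/moderate dosage asymmetry
  carry one fully marked chromosome and one single-marker recombinant; the
  recombinant's alleles at two interior mutations are classified by where
  the crossover fell. In the worked configuration (0.6 Mb / 45 kb / 0.6 Mb
  at a uniform local rate) the two major classes each take just under half
  of the selected mass and the mixed classes take ≈ 45/1245 of it. One
  reading note: the source text gives the mutation-to-marker distance as
  "ca. 600 Mb", which the marker coordinates show must mean 600 kb; the
  defaults here use 0.6 Mb.
- `required_sample_size()`: the geometric bound ⌈log(1 − confidence) /
  log(1 − p)⌉ for observing at least one seed of a target class.

Physical-to-genetic conversion, where a scheme is set up from coordinates,
assumes a uniform rate within the line's interval (fractions proportional to
physical length); callers can always pass explicit segment fractions.

## The simulator

Chiasmata on the four-strand bundle follow a stationary gamma renewal
process with shape ν and rate 2ν per Morgan, so the chiasma density is 2 per
Morgan for every ν; each chiasma involves the sampled chromatid with
probability ½ independently (no chromatid interference), giving a crossover
density of exactly 1 per Morgan. ν = 1 is the Poisson special case — no
interference, Haldane's map function — and is implemented by drawing segment
counts directly from the Poisson law, which is mathematically identical and
fast. For ν ≠ 1 the renewal points are simulated explicitly; stationarity is
reached by starting the process 5 Morgans (about ten mean inter-chiasma
gaps) before the region of interest, which is far beyond the renewal
process's relaxation length at the shapes of interest (ν ≤ ~20). Larger ν
spaces chiasmata more regularly, and the estimated coincidence ĉ falls
accordingly; the ν-to-c mapping is reported empirically per simulation, not
claimed in closed form.

Segment fractions are converted to Morgans through the inverse Haldane map
by default, which makes the ν = 1 simulator agree *exactly* with the c = 1
closed forms: under a Poisson process, crossovers in disjoint segments are
independent, so segment recombination probabilities multiply — precisely the
independence enumeration of the exact engine. That identity is what the
oracle-equivalence tests exploit: empirical haplotype frequencies at 10⁶
gametes are compared to the closed forms within 3 binomial standard errors
over a grid of segment fractions, and the balancer-purity closed form is
checked the same way. Obligate chiasma formation, gene conversion and
sex-specific map differences are not modelled (the source testcrosses used
the marked plant as the pollen parent; any male/female map difference is
silently absorbed into the per-line estimates).

`simulate_testcross_counts()` is a single multinomial draw over the four
seed classes and is what the estimator-calibration tests use: at r = 0.069
and N = 300 over 2000 replicates, the mean estimate is unbiased within Monte
Carlo error and the 95% Wilson interval covers the truth at close to its
nominal rate.

## What the synthetic data does and does not capture

The generator reproduces the *sampling* structure of the real experiments —
multinomial seed classes at a true recombination fraction, dosage-coded
intensities with adjacent-class confusion, lethal classes, interference via
the renewal process. It does not emulate transgene silencing (which removes
a marker entirely rather than misclassifying it), insertion-associated
rearrangements that suppress recombination locally (visible in the real
catalog as flagged outlier rows and lopsided recombinant splits), seed-lot
contamination, or segregation distortion from gametic or zygotic selection.
Passing tests therefore validate the calculus and its implementation, not
the biological cleanliness of any particular stock.

## Problem sizes and numerical choices

The test suite uses 10⁶ gametes for oracle-equivalence checks, 10⁵–2×10⁵
seeds for Monte Carlo posteriors, and 500–2000 replicates for calibration
experiments — sizes at which 3-standard-error bands are tight enough to
catch real defects while the whole suite runs in well under a minute.
Probabilities are exact rational arithmetic in double precision;
distributions are checked to sum to 1 within 10⁻¹²; comparisons against
printed table values use round-half-up at one decimal (the table's dominant
convention) with the ±0.1 cM / ±0.2 cM/Mb integrity bands; the BED score
field guards the ×10 truncation against binary representation slip with a
10⁻⁶ epsilon. All stochastic functions accept an explicit integer seed and
reproduce bit-for-bit.
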