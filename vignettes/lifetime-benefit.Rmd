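---
title: "Lifetime benefit of preemptive pharmacogenomic testing: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifetime benefit of preemptive pharmacogenomic testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxlifetime)
```

## The question

Pharmacogenomic testing is most valuable *before* an interacting drug is
prescribed. Given a cohort of deceased patients with genotypes and lifelong
prescription histories, `pgxlifetime` asks: at what candidate testing age
*x* would testing have changed the largest share of subsequent prescribing?
Because the cohort is fully deceased, every lifetime is observed completely
and the empirical survival curve S(x) is exact; no censoring adjustment is
needed or attempted.

## The panel and carrier model

The shipped panel contains 17 single-variant star-allele definitions across
nine pharmacogenes, each with the homozygote/heterozygote counts observed in
a 300-patient reference cohort. A patient is a *carrier* if they have at
least one heterozygous or homozygous QC-passed call at any panel variant.
No diplotype reconstruction is performed: compound heterozygotes are two
hits, not one named diplotype, and no metabolizer phenotype
(poor/intermediate/ultrarapid) is assigned. The only phenotype-like output
is the zygosity risk rule, shipped for SLCO1B1\*5 (heterozygote = moderate,
homozygote = high myopathy risk under simvastatin), and deliberately
configured as data (a panel column) rather than code.

Variant–call matching prefers exact (chrom, pos, ref, alt) identity and
falls back to rsID with a ±1 bp window. The fallback exists for the single
CYP2D6 \*6 deletion, whose left-anchored VCF representation shifts the
coordinate by one and prepends an anchor base; without the fallback the
variant would silently never match. A position match with a mismatched
reference allele is a warning, never a silent match.

## QC rules

Calls are excluded when read depth < 10, or when quality < 20 (homozygous)
or < 40 (heterozygous); all three boundaries are inclusive on the retained
side ("less than" is strict). The quality score is
`quality_score(p) = 10·log10(p/(1−p))` where `p` is the probability the
call is true. The orientation is chosen so that confident calls score
high — the only orientation consistent with "quality below 20/40 is
excluded" (the alternative sign convention would score a 99%-confident call
at −20 and exclude *everything* confident). Depth is checked before
quality, so a call failing both rules is tallied once, under depth, and the
three tallies always partition the input.

## Actionable incidences and impact statistics

An *actionable incidence* is a (patient, drug, gene) triple where the
patient carries a panel variant in the gene and the drug is linked to the
gene in the drug–gene map, stamped with the patient's earliest prescription
age for that drug. Only the first exposure matters for the benefit
question, so repeat prescriptions collapse to the earliest age.
Over-the-counter exposure is out of model: only records in the
prescriptions table count.

A "unique incidence" in `impact_stats()` is a distinct (patient, drug)
pair. A drug linked to two carried genes (warfarin with both VKORC1 and
CYP2C9, say) appears once per gene in the incidence table but counts once
as a pair; drugs-per-patient means and medians are computed over impacted
patients only. This convention makes the three summary outputs mutually
coherent (mean ≈ unique incidences / impacted patients).

The shipped drug–gene map covers the nine panel genes with their
best-known interacting drugs (clopidogrel–CYP2C19, codeine–CYP2D6,
simvastatin–SLCO1B1, warfarin–VKORC1/CYP2C9, fluorouracil and
capecitabine–DPYD, three thiopurines–TPMT, ivacaftor–CFTR, ethinyl
estradiol–F5). It is a documented minimal subset, not a transcription of
any full regulatory table; users with a richer map supply their own TSV.
Drug names are lower-cased and stripped of salt suffixes on both sides of
the join, and matching is exact on the normalized string — a deterministic,
testable rule in preference to fuzzy matching.

## The three benefit perspectives

With incidences I(p) = set of actionable first-prescription ages for
patient p, death ages D(p), and age grid x = 0…100 (integer years by
default; the grid is configurable and nothing in the method depends on its
resolution):

* **Fixed cohort**: numerator |{p : ∃a ∈ I(p), a ≥ x}|, denominator N
  always. At x = 0 this is the lifetime impacted fraction; it is
  non-increasing in x.
* **Living population**: same numerator restricted to patients alive at x,
  denominator |{p : D(p) > x}|. Undefined (reported missing) once nobody
  survives x.
* **Transient population**: living-population form with the numerator
  restricted to a ∈ [x, x + w), w ∈ {1, 3, 10} years by default —
  patients assumed lost to follow-up w years after testing.

Conventions, stated once and applied everywhere: testing at the age of a
prescription still counts (a ≥ x, boundary inclusive, since testing
precedes dispensing within the same age); "alive at x" is strict
(D(p) > x); windows are half-open to avoid double counting across adjacent
windows. Prescriptions can only occur in life, so the fixed-cohort
numerator needs no explicit alive condition — a ≥ x and a < D(p) imply
D(p) > x.

These definitions give the invariants the tests enforce: the transient
curves are non-decreasing in w and bounded by the living curve; a window
wider than the age span *equals* the living curve; and every curve equals a
brute-force per-patient set enumeration on small cohorts.

## The synthetic-cohort generator

The generator exists so the full pipeline — VCF in, curves out — runs
without access to any real cohort. It emulates three things:

**Genotypes.** Per-variant homozygote/heterozygote counts default to the
panel's reference counts (out of N = 300; they are rescaled
proportionally for other cohort sizes). Linkage structure matters for the
carrier fraction and is explicit configuration: the two VKORC1 variants
tag the same haplotype and are fully linked (carriers of the
smaller-count variant are a subset of the larger's), likewise the two
TPMT \*3A variants; CYP2C19 \*2B carriers are nested within \*2 carriers.
The relationship between CYP2D6 \*4 and \*10 is genuinely underdetermined
by marginal counts — independence and full nesting predict materially
different within-gene carrier unions — so it is a preset
(`cyp2d6_ld = "independent"` by default, `"nested"` available) rather
than an assumption baked into code. Two sampling modes: `exact_counts`
reproduces the configured marginals exactly and randomizes only the
assignment to patients (so a fixture cohort reproduces every reference
genotype cell); `hwe_binomial` draws each patient independently under
Hardy–Weinberg at the implied allele frequency, for frequency-level
statistical checks.

Under `exact_counts`, carrier status across effective loci (one per linked
group, one per nesting parent, one per remaining variant) is independent
by construction, so the expected carrier fraction has the closed form
1 − ∏ᵢ(1 − cᵢ/N) with cᵢ the locus carrier counts. With the shipped
counts this evaluates to 0.935, and the Monte Carlo mean over simulated
cohorts must agree with it within Monte Carlo error — a dual-route check
(sampler vs closed form) the test suite and acceptance script both
perform.

**Lifespans.** Truncated normal, mean 74, sd 12, support [20, 100] years,
sampled by inverse CDF. This is a pragmatic stand-in for an elderly
deceased cohort's age-at-death distribution, chosen for having the right
location and spread, not fitted to anything; any lifespan model can be
supplied.

**Prescriptions.** Per drug, a first-prescription age drawn from a
piecewise-constant yearly hazard by decade of age (inverted cumulative
hazard; no event by 100 means never prescribed), kept only if it precedes
death. The shipped hazards are clinically plausible shapes — statins and
anticoagulants ramping up after midlife, codeine roughly flat through
adulthood, oral contraceptives concentrated in reproductive ages, oncology
drugs rare — and are configuration, not estimates. Prescriptions are
genotype-independent by design: the analysis measures co-occurrence of
carrier status and exposure, and a generator that built in a
genotype→prescribing effect would beg the question it is used to test.

A single global seed drives the run; it is split (via one `sample.int`
draw) into independent per-stage seeds so the genotype stage and the
lifespan/prescription stage can each be regenerated alone. Identical
configuration and seed give byte-identical output files.

**What passing tests do and do not show.** The generator reproduces the
carrier-side statistics (genotype counts, linkage structure, carrier
prevalence) faithfully, so tests of annotation, linkage and curve logic on
synthetic cohorts transfer to real data. It does *not* emulate real
prescription-timing distributions, per-drug exposure prevalences,
comorbidity or polypharmacy correlation, within-gene LD beyond the declared
groups, or any genotype–prescribing dependence; consequently the *numeric
levels* of impact statistics and benefit curves on synthetic cohorts (64%
impacted in the README example, transient peaks of ~0.26) characterize the
generator's prescribing model, not any real population, and the curve
claims the package makes on synthetic data are structural (orderings,
monotonicity, limiting cases, oracle agreement), not numeric.

## Numerical and degenerate-input choices

* Empty call sets filter to empty; an empty cohort is a domain error for
  survival and fraction computations (division by zero has no sensible
  default).
* `cohort_summary` with N = 0 reports zero counts and missing allele
  frequencies; an allele frequency above 0.5 triggers a major/minor swap
  warning rather than silent renormalization.
* Curve denominators of zero (ages beyond the last death) yield missing
  fractions, never NaN propagation.
* Ties: a prescription exactly at a window edge belongs to the left-closed
  window; duplicate (patient, drug) prescriptions keep the earliest age
  deterministically after a stable sort.
* Problem sizes: the test suite simulates cohorts of 300 (the reference
  size) for pipeline checks, 10,000 for distributional closed-form checks,
  and ≤ 20 for brute-force oracle equality; the acceptance script uses
  1000 replicates of 300. These sizes give Monte Carlo standard errors an
  order of magnitude below the tolerances being checked.

## Known limitations

* Single-variant star-allele definitions only: no haplotype phasing, no
  CYP2D6 structural variation (deletions, duplications, hybrids), which is
  known to carry substantial actionable variation.
* The drug–gene map is a minimal curated subset; lifetime impact computed
  with it is a lower bound relative to a comprehensive regulatory map.
* Carrier prevalence depends on the declared linkage structure; for gene
  pairs whose joint distribution the marginal counts underdetermine, the
  package exposes the choice instead of resolving it.
* The deceased-cohort design makes survival exact but the cohort old:
  prescribing patterns of a contemporaneous younger population will
  differ.
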