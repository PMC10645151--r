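# pgxlifetime

Estimating when, over a lifetime, preemptive pharmacogenomic testing would
have mattered.

Common germline variants in pharmacogenes — *CYP2C19*, *CYP2D6*, *SLCO1B1*,
*VKORC1*, *DPYD*, *TPMT* and others — change how patients metabolize or
respond to widely prescribed drugs (clopidogrel, codeine, simvastatin,
warfarin, fluoropyrimidines, thiopurines). Most people carry at least one
such variant, yet testing is usually done, if at all, at the point of care.
`pgxlifetime` is for biostatisticians and pharmacogenomics researchers who
want to quantify, from a genotyped cohort with longitudinal prescription
records, how much of the population would have benefited from testing *before*
their actionable prescriptions — and at what age testing yields the broadest
benefit.

## What it computes

The pipeline has five stages, each an exported function group:

1. **Knowledge base** — `load_panel()` reads a TSV panel of actionable
   variants (shipped default: 17 variants in 9 pharmacogenes, with observed
   homozygote/heterozygote counts from a 300-patient reference cohort) and a
   drug–gene interaction map.
2. **Variant QC** — `read_vcf_calls()` + `filter_calls()` ingest VCF calls
   and apply the exclusion rules: homozygous calls with quality < 20,
   heterozygous calls with quality < 40, and any call with read depth < 10
   are dropped. `quality_score(p)` is the dB-like confidence
   10·log₁₀[p/(1−p)].
3. **Annotation** — `annotate_cohort()` intersects QC-passed calls with the
   panel; `cohort_summary()`, `carrier_fraction()` and `classify_risk()`
   summarize carrier status (minor-allele frequency = (2·hom + het)/2N) and
   zygosity-dependent risk (e.g. SLCO1B1\*5: heterozygote = moderate,
   \*5/\*5 = high myopathy risk on simvastatin).
4. **EHR linkage** — `actionable_incidences()` joins carriers to age-stamped
   first prescriptions of drugs linked to their carried genes;
   `impact_stats()` reports impacted-patient counts and drugs-per-patient.
5. **Benefit curves** — `lifetime_benefit()` returns, over an age grid *x*,
   three perspectives on "fraction who may benefit if tested at age *x*":
   - **fixed cohort**: |patients with an actionable first prescription at
     age ≥ x| / N (denominator constant);
   - **living population**: same numerator restricted to patients alive at
     *x*, divided by the number alive at *x*;
   - **transient population**: living-population benefit counting only
     prescriptions in the follow-up window [x, x+w), w ∈ {1, 3, 10} years,
   plus the exact empirical survival curve S(x) of the (fully deceased)
   cohort.

A seeded synthetic-cohort generator (`cohort_config()`, `simulate_cohort()`,
`simulate_carrier_fraction()`) produces genotypes at the panel's observed
genotype frequencies — with the fully linked VKORC1 and TPMT \*3A variant
pairs and the CYP2C19 \*2B-within-\*2 nesting preserved — alongside
truncated-normal lifespans and hazard-driven prescription ages, so the whole
pipeline runs end to end with no protected data.

## Worked example

```r
library(pgxlifetime)

panel  <- load_panel()                       # shipped 17-variant panel
cohort <- simulate_cohort(cohort_config(), seed = 42, dir = tempfile())

calls    <- filter_calls(read_vcf_calls(cohort$paths$vcf))
profiles <- annotate_cohort(calls, panel,
                            patients = cohort$demographics$patient_id)
carrier_fraction(profiles, 300)
inc <- actionable_incidences(profiles, cohort$prescriptions, panel)
impact_stats(inc, 300)
fit <- lifetime_benefit(inc, cohort$demographics)
fit
plot(fit)
```

which prints:

```
carrier fraction: 0.943
Impacted patients: 192 (64.0%)
Unique drug-patient incidences: 274 over 8 drugs
Drugs per impacted patient: mean 1.4, median 1.0, max 4
Lifetime benefit-of-testing curves
  cohort size: 300 | age grid: 0 - 100 | transient windows: 1, 3, 10 years
  lifetime impacted fraction (fixed model at age 0): 0.640
```

94.3% of this simulated cohort carries at least one actionable variant;
64% were prescribed at least one linked drug (the simulated prescribing
model is deliberately sparser than real lifetime EHR data — see the
vignette); and the fixed-cohort curve starts at that 64% and declines with
testing age, while the transient-population curves peak in later life when
prescribing is densest.

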