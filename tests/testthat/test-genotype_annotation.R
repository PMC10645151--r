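# Carrier profiling, cohort genotype summaries, risk classification.

panel <- load_panel()

test_that("annotate_patient matches panel sites and carries zygosity through", {
  call <- make_calls("P1", chrom = "12", pos = 21331549, ref = "T", alt = "C",
                     zygosity = "heterozygous", rsid = "rs4149056")
  pr <- annotate_patient(call, panel)
  expect_identical(nrow(pr$hits), 1L)
  expect_identical(pr$hits$gene, "SLCO1B1")
  expect_identical(pr$hits$star_allele, "*5")
  expect_identical(pr$hits$zygosity, "heterozygous")
  expect_identical(pr$carrier_genes, "SLCO1B1")

  none <- annotate_patient(make_calls("P2", chrom = "5", pos = 12345), panel)
  expect_identical(nrow(none$hits), 0L)
  expect_length(none$carrier_genes, 0)
})

test_that("indel matching falls back to rsID within a ±1 position window", {
  # left-anchored VCF representation of the single-base deletion: position is
  # one less than the panel coordinate and ref/alt do not match textually
  call <- make_calls("P1", chrom = "22", pos = 42525085, ref = "TA",
                     alt = "T", zygosity = "heterozygous", rsid = "rs5030655")
  pr <- annotate_patient(call, panel)
  expect_identical(pr$hits$rsid, "rs5030655")
  expect_identical(pr$carrier_genes, "CYP2D6")
  # same rsid but implausibly distant position: no match
  far <- make_calls("P1", chrom = "22", pos = 42525999, ref = "TA",
                    alt = "T", rsid = "rs5030655")
  expect_identical(nrow(annotate_patient(far, panel)$hits), 0L)
})

test_that("mismatched ref at a panel position warns and does not match", {
  call <- make_calls("P1", chrom = "12", pos = 21331549, ref = "G", alt = "C")
  expect_warning(pr <- annotate_patient(call, panel), "mismatched ref")
  expect_identical(nrow(pr$hits), 0L)
})

test_that("conflicting duplicate calls at one site are an error naming the site", {
  calls <- rbind(
    make_calls("P1", chrom = "12", pos = 21331549, ref = "T", alt = "C",
               zygosity = "heterozygous"),
    make_calls("P1", chrom = "12", pos = 21331549, ref = "T", alt = "C",
               zygosity = "homozygous_alt"))
  expect_error(annotate_patient(calls, panel), "rs4149056")
})

test_that("cohort_summary tallies hom/het and flags frequency anomalies", {
  profiles <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    rsid = c("rs6025", "rs6025", "rs4149056"),
    gene = c("F5", "F5", "SLCO1B1"),
    star_allele = c("Arg534Gln", "Arg534Gln", "*5"),
    zygosity = c("homozygous_alt", "heterozygous", "heterozygous"),
    stringsAsFactors = FALSE)
  cs <- cohort_summary(profiles, panel, N = 10)
  expect_identical(cs$n_hom[cs$rsid == "rs6025"], 1L)
  expect_identical(cs$n_het[cs$rsid == "rs6025"], 1L)
  expect_equal(cs$maf[cs$rsid == "rs6025"], 3 / 20)
  expect_true(all(cs$carrier_count == cs$n_hom + cs$n_het))

  # degenerate single-patient homozygote: MAF 1 with major/minor warning
  one <- profiles[1, , drop = FALSE]
  expect_warning(cs1 <- cohort_summary(one, panel, N = 1), "swapped")
  expect_equal(cs1$maf[cs1$rsid == "rs6025"], 1)

  # empty cohort: all counts zero, frequency missing
  cs0 <- cohort_summary(profiles[0, ], panel, N = 0)
  expect_true(all(cs0$carrier_count == 0L))
  expect_true(all(is.na(cs0$maf)))

  expect_error(cohort_summary(profiles, panel, N = 2), "smaller")
  bad <- profiles; bad$rsid[1] <- "rs000"
  expect_error(cohort_summary(bad, panel, N = 10), "rs000")
})

test_that("carrier_fraction counts distinct carriers and rejects N = 0", {
  profiles <- data.frame(patient_id = c("P1", "P1", "P2"),
                         rsid = "rs6025", gene = "F5",
                         star_allele = "x", zygosity = "heterozygous",
                         stringsAsFactors = FALSE)
  expect_equal(carrier_fraction(profiles, 4), 0.5)
  expect_equal(carrier_fraction(profiles[0, ], 4), 0)
  expect_error(carrier_fraction(profiles, 0), "positive")
  # invariance under row order / patient relabeling of the same profile set
  shuffled <- profiles[c(3, 1, 2), ]
  expect_equal(carrier_fraction(shuffled, 4), 0.5)
})

test_that("zygosity risk classification is none < moderate < high", {
  hom <- annotate_patient(
    make_calls("P1", chrom = "12", pos = 21331549, ref = "T", alt = "C",
               zygosity = "homozygous_alt"), panel)
  het <- annotate_patient(
    make_calls("P2", chrom = "12", pos = 21331549, ref = "T", alt = "C",
               zygosity = "heterozygous"), panel)
  non <- annotate_patient(make_calls("P3", chrom = "5", pos = 1), panel)
  expect_identical(as.character(classify_risk(hom, "SLCO1B1", panel = panel)),
                   "high")
  expect_identical(as.character(classify_risk(het, "SLCO1B1", panel = panel)),
                   "moderate")
  expect_identical(as.character(classify_risk(non, "SLCO1B1", panel = panel)),
                   "none")
  expect_true(classify_risk(non, "SLCO1B1", panel = panel) <
                classify_risk(het, "SLCO1B1", panel = panel))
  expect_error(classify_risk(het, "CYP2D6", panel = panel), "no zygosity-risk")
})

test_that("simulated cohorts agree with the analytic carrier-fraction product", {
  # closed-form oracle computed directly from the reference carrier counts
  analytic <- 1 - prod(1 - reference_effective_carriers() / 300)
  cfg <- cohort_config()
  expect_equal(carrier_fraction_analytic(cfg), analytic)
  sim <- simulate_carrier_fraction(cfg, n_reps = 200, seed = 909)
  expect_lt(abs(sim$mean - analytic), 3 * sim$se)
})
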