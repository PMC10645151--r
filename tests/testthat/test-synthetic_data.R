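# Seeded cohort generator: marginal recovery, linkage structure,
# reproducibility, structural validity.

test_that("exact-counts mode reproduces the configured genotype counts exactly", {
  cfg <- cohort_config()
  g <- simulate_genotypes(cfg, seed = 7)
  ref <- reference_genotype_counts()
  for (rsid in rownames(ref)) {
    z <- g$zygosity[g$rsid == rsid]
    expect_identical(sum(z == "homozygous_alt"), ref[rsid, "n_hom"][[1]],
                     info = rsid)
    expect_identical(sum(z == "heterozygous"), ref[rsid, "n_het"][[1]],
                     info = rsid)
  }
})

test_that("linkage structure holds in every generated cohort", {
  cfg <- cohort_config()
  for (seed in c(2, 12, 22)) {
    g <- simulate_genotypes(cfg, seed = seed)
    carriers <- function(rsid) g$patient_id[g$rsid == rsid]
    # fully linked pairs: secondary carriers within the primary's
    expect_true(all(carriers("rs9934438") %in% carriers("rs9923231")))
    expect_true(all(carriers("rs1800460") %in% carriers("rs1142345")))
    # nested child inside parent
    expect_true(all(carriers("rs17878459") %in% carriers("rs4244285")))
  }
  # the nested CYP2D6 preset adds *4 within *10
  cfg2 <- cohort_config(cyp2d6_ld = "nested")
  g2 <- simulate_genotypes(cfg2, seed = 5)
  expect_true(all(g2$patient_id[g2$rsid == "rs3892097"] %in%
                    g2$patient_id[g2$rsid == "rs1065852"]))
})

test_that("infeasible nestings and oversized counts are config errors", {
  gf <- data.frame(rsid = c("rsP", "rsC"), n_hom = c(0, 1), n_het = c(2, 5))
  expect_error(
    cohort_config(n_patients = 100, genotype_frequencies = gf,
                  ld_linked = list(),
                  ld_nested = list(list(parent = "rsP", child = "rsC")),
                  rx_model = list()),
    "infeasible nesting")
  gf2 <- data.frame(rsid = "rsA", n_hom = 60, n_het = 50)
  expect_error(
    cohort_config(n_patients = 100, genotype_frequencies = gf2,
                  ld_linked = list(), ld_nested = list(), rx_model = list()),
    "exceeds n_patients")
})

test_that("identical config and seed give byte-identical output files", {
  cfg <- cohort_config(n_patients = 60)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(cfg, seed = 31, dir = d1)
  simulate_cohort(cfg, seed = 31, dir = d2)
  for (f in c("genotypes.vcf", "demographics.tsv", "prescriptions.tsv",
              "provenance.yaml")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # a different seed must change the genotype assignment
  d3 <- withr::local_tempdir()
  simulate_cohort(cfg, seed = 32, dir = d3)
  expect_false(identical(readLines(file.path(d1, "genotypes.vcf")),
                         readLines(file.path(d3, "genotypes.vcf"))))
})

test_that("cohorts are structurally valid: deaths bound prescriptions, samples consistent", {
  co <- simulate_cohort(cohort_config(), seed = 8)
  rx <- merge(co$prescriptions, co$demographics, by = "patient_id")
  expect_true(all(rx$age_at_rx < rx$death_age))
  expect_true(all(co$genotypes$patient_id %in% co$demographics$patient_id))
  lm <- cohort_config()$lifespan_model
  expect_true(all(co$demographics$death_age >= lm$lower))
  expect_true(all(co$demographics$death_age <= lm$upper))
  # degenerate configs
  empty <- simulate_cohort(cohort_config(n_patients = 0), seed = 1)
  expect_identical(nrow(empty$genotypes), 0L)
  expect_identical(nrow(empty$demographics), 0L)
  zero_rx <- cohort_config(n_patients = 30,
                           rx_model = list(druga = rep(0, 10)))
  co0 <- simulate_lives_and_rx(zero_rx, seed = 3)
  expect_identical(nrow(co0$prescriptions), 0L)
})

test_that("hwe_binomial genotypes match binomial and exponential closed forms", {
  # het count for a rare allele over a large cohort: ~2p(1-p)N ± 3 SD
  gf <- data.frame(rsid = "rs6025", n_hom = 0, n_het = 14)
  cfg <- cohort_config(n_patients = 10000, genotype_frequencies =
                         data.frame(rsid = "rs6025",
                                    n_hom = 0, n_het = round(14 * 10000 / 300)),
                       sampling_mode = "hwe_binomial",
                       ld_linked = list(), ld_nested = list(),
                       rx_model = list())
  g <- simulate_genotypes(cfg, seed = 400)
  p <- (2 * 0 + round(14 * 10000 / 300)) / (2 * 10000)
  expected_het <- 2 * p * (1 - p) * 10000
  sd_het <- sqrt(10000 * 2 * p * (1 - p) * (1 - 2 * p * (1 - p)))
  n_het <- sum(g$zygosity == "heterozygous")
  expect_lt(abs(n_het - expected_het), 3 * sd_het)

  # constant-hazard first-prescription age: mean 1/lambda without mortality
  cfg_rx <- cohort_config(
    n_patients = 10000,
    genotype_frequencies = data.frame(rsid = "rs6025", n_hom = 0, n_het = 1),
    ld_linked = list(), ld_nested = list(),
    lifespan_model = list(mean = 1e5, sd = 1, lower = 9e4, upper = 2e5),
    rx_model = list(druga = rep(0.02, 10)))
  lr <- simulate_lives_and_rx(cfg_rx, seed = 401)
  ages <- lr$prescriptions$age_at_rx
  # truncation at age 100 censors the exponential; compare to its
  # conditional mean on [0, 100]
  lambda <- 0.02
  cond_mean <- 1 / lambda - 100 * exp(-lambda * 100) / (1 - exp(-lambda * 100))
  se <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - cond_mean), 3 * se)
})

test_that("hwe_binomial cohorts pass a Hardy-Weinberg goodness-of-fit check", {
  # one common variant, many replicates: chi-square GOF at alpha = 0.01
  # should reject in only a few percent of replicates
  gf <- data.frame(rsid = "rsX", n_hom = 40, n_het = 138)
  cfg <- cohort_config(n_patients = 300, genotype_frequencies = gf,
                       ld_linked = list(), ld_nested = list(),
                       rx_model = list())
  set.seed(500)
  n_reps <- 60
  rejected <- 0L
  for (i in seq_len(n_reps)) {
    g <- simulate_genotypes(cfg)
    n_hom <- sum(g$zygosity == "homozygous_alt")
    n_het <- sum(g$zygosity == "heterozygous")
    n_wt <- 300 - n_hom - n_het
    p <- (2 * n_hom + n_het) / 600
    expected <- 300 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((c(n_wt, n_het, n_hom) - expected)^2 / expected)
    if (stats::pchisq(stat, df = 1, lower.tail = FALSE) < 0.01) {
      rejected <- rejected + 1L
    }
  }
  expect_lte(rejected / n_reps, 0.05)
})

test_that("simulate_carrier_fraction tracks its analytic expectation", {
  # single variant covering everyone: fraction 1 in every replicate
  gf <- data.frame(rsid = "rsX", n_hom = 0, n_het = 300)
  cfg1 <- cohort_config(n_patients = 300, genotype_frequencies = gf,
                        ld_linked = list(), ld_nested = list(),
                        rx_model = list())
  sim1 <- simulate_carrier_fraction(cfg1, n_reps = 5, seed = 2)
  expect_true(all(sim1$fractions == 1))
  expect_equal(carrier_fraction_analytic(cfg1), 1)

  cfg <- cohort_config()
  sim <- simulate_carrier_fraction(cfg, n_reps = 300, seed = 77)
  expect_lt(abs(sim$mean - sim$analytic), 3 * sim$se)
  # reproducibility of the replicate stream
  sim2 <- simulate_carrier_fraction(cfg, n_reps = 300, seed = 77)
  expect_identical(sim$fractions, sim2$fractions)
})

test_that("VCF round trip preserves the generated genotypes", {
  cfg <- cohort_config(n_patients = 50)
  co <- simulate_cohort(cfg, seed = 13, dir = withr::local_tempdir())
  calls <- filter_calls(read_vcf_calls(co$paths$vcf))
  profiles <- annotate_cohort(calls, cfg$panel,
                              patients = co$demographics$patient_id)
  got <- profiles[order(profiles$patient_id, profiles$rsid),
                  c("patient_id", "rsid", "zygosity")]
  want <- co$genotypes[order(co$genotypes$patient_id, co$genotypes$rsid), ]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want[, c("patient_id", "rsid", "zygosity")])
})
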