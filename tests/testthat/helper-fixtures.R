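# Shared fixtures and independent brute-force oracles used across the suite.

make_calls <- function(patient_id, chrom = "1", pos = 100L, ref = "A",
                       alt = "G", zygosity = "heterozygous", quality = 99,
                       depth = 50, rsid = NA_character_) {
  data.frame(patient_id = patient_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, rsid = rsid, zygosity = zygosity,
             quality = quality, depth = depth, stringsAsFactors = FALSE)
}

# Hand-worked 3-patient toy used in the linkage and curve tests:
# P1 (dies 80): actionable rx at ages 40 and 60; P2 (dies 55): rx at 50;
# P3 (dies 90): none.
toy_demographics <- function() {
  data.frame(patient_id = c("P1", "P2", "P3"), death_age = c(80, 55, 90),
             stringsAsFactors = FALSE)
}

toy_incidences <- function() {
  data.frame(patient_id = c("P1", "P1", "P2"),
             drug = c("druga", "drugb", "drugc"),
             gene = c("G1", "G1", "G2"),
             age_at_rx = c(40, 60, 50), stringsAsFactors = FALSE)
}

# Brute-force incidence oracle: direct triple loop over
# (patient, drug, gene), independent of the join in actionable_incidences().
oracle_incidences <- function(profiles, rx, links) {
  rx <- rx[order(rx$patient_id, rx$drug, rx$age_at_rx), , drop = FALSE]
  rx <- rx[!duplicated(paste(rx$patient_id, rx$drug)), , drop = FALSE]
  rows <- list()
  for (p in unique(rx$patient_id)) {
    for (d in unique(rx$drug[rx$patient_id == p])) {
      for (g in unique(links$gene)) {
        carries <- any(profiles$patient_id == p & profiles$gene == g)
        linked <- any(links$drug == d & links$gene == g)
        if (carries && linked) {
          age <- rx$age_at_rx[rx$patient_id == p & rx$drug == d]
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = p, drug = d, gene = g, age_at_rx = age,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), drug = character(),
               gene = character(), age_at_rx = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$drug, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force curve oracle: explicit per-patient set enumeration at one age.
# model: "fixed", "living", "transient" (with window w).
oracle_benefit_at <- function(incidences, demographics, x, model,
                              w = NULL) {
  pairs <- unique(incidences[, c("patient_id", "drug", "age_at_rx")])
  qualifies <- function(p, lo, hi) {
    a <- pairs$age_at_rx[pairs$patient_id == p]
    any(a >= lo & a < hi)
  }
  all_ids <- demographics$patient_id
  alive <- all_ids[demographics$death_age > x]
  if (model == "fixed") {
    num <- sum(vapply(all_ids, qualifies, TRUE, lo = x, hi = Inf))
    return(num / length(all_ids))
  }
  if (length(alive) == 0L) return(NA_real_)
  hi <- if (model == "transient") x + w else Inf
  sum(vapply(alive, qualifies, TRUE, lo = x, hi = hi)) / length(alive)
}

# A small reproducible synthetic cohort run through the real pipeline
# (VCF round trip, QC, annotation, linkage).
small_cohort <- function(seed, n_patients = 300, ...) {
  cfg <- cohort_config(n_patients = n_patients, ...)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  co <- simulate_cohort(cfg, seed = seed, dir = dir)
  panel <- cfg$panel
  calls <- filter_calls(read_vcf_calls(co$paths$vcf))
  profiles <- annotate_cohort(calls, panel,
                              patients = co$demographics$patient_id)
  incidences <- actionable_incidences(profiles, co$prescriptions, panel)
  list(cfg = cfg, cohort = co, panel = panel, calls = calls,
       profiles = profiles, incidences = incidences)
}

# Table of reference genotype counts (the shipped panel's 17 hom/het cells),
# keyed by rsid, used wherever a test asserts fixture exactness.
reference_genotype_counts <- function() {
  counts <- rbind(
    rs75527207 = c(0, 1),   rs17878459 = c(0, 9),   rs4244285 = c(10, 75),
    rs1799853 = c(5, 56),   rs1057910 = c(3, 46),   rs3892097 = c(9, 45),
    rs5030655 = c(0, 4),    rs1065852 = c(12, 73),  rs67376798 = c(0, 5),
    rs3918290 = c(0, 5),    rs6025 = c(0, 14),      rs4149056 = c(7, 82),
    rs1142345 = c(2, 27),   rs1800460 = c(2, 26),   rs1800462 = c(0, 2),
    rs9934438 = c(40, 136), rs9923231 = c(40, 138))
  colnames(counts) <- c("n_hom", "n_het")
  storage.mode(counts) <- "integer"
  counts
}

# Effective-locus carrier counts implied by the reference counts under the
# default linkage structure (linked pairs collapsed, nested child absorbed).
reference_effective_carriers <- function() {
  c(1, 85, 61, 49, 54, 4, 85, 5, 5, 14, 89, 29, 2, 178)
}
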