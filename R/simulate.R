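# Seeded synthetic-cohort generator: panel genotypes with configurable
# linkage structure, lifespans, and age-stamped first prescriptions, so the
# whole pipeline runs end to end without protected health data.
#
# Prescriptions are deliberately independent of genotype: the analysis
# measures co-occurrence of carrier status and drug exposure, not a causal
# genotype -> prescribing effect, and the generator must not build one in.

#' Synthetic cohort configuration
#'
#' Bundles and validates everything the generator needs: cohort size,
#' per-variant genotype counts (defaults: the shipped panel's observed
#' homozygote/heterozygote counts in a 300-patient reference cohort), the
#' linkage structure among panel variants, the genotype sampling mode, the
#' lifespan distribution and the per-drug first-prescription hazard model.
#'
#' Linkage defaults: the two VKORC1 variants are fully linked, as are the two
#' TPMT *3A variants (they tag the same haplotype); CYP2C19 *2B carriers are
#' nested within *2 carriers. The relationship between the CYP2D6 *4 and *10
#' alleles is underdetermined by marginal genotype counts, so it is a preset:
#' \code{"independent"} (default) or \code{"nested"} (*4 within *10).
#'
#' @param n_patients cohort size (default 300).
#' @param genotype_frequencies data frame (\code{rsid}, \code{n_hom},
#'   \code{n_het}) of genotype counts out of \code{n_patients}; default taken
#'   from \code{panel}.
#' @param sampling_mode \code{"exact_counts"} (marginal counts reproduced
#'   exactly, assignment randomized) or \code{"hwe_binomial"} (independent
#'   per-patient genotype draws under Hardy-Weinberg at the implied allele
#'   frequency).
#' @param cyp2d6_ld \code{"independent"} or \code{"nested"}.
#' @param ld_linked list of character vectors of fully linked rsids (first
#'   element of each vector is the primary variant whose carriers contain the
#'   others').
#' @param ld_nested list of \code{list(parent=, child=)} nestings.
#' @param lifespan_model list \code{(mean, sd, lower, upper)} of a truncated
#'   normal age-at-death distribution in years (default mean 74, sd 12,
#'   truncated to [20, 100]).
#' @param rx_model named list: per drug, a vector of 10 piecewise-constant
#'   yearly first-prescription hazards, one per decade of age 0-100; default
#'   \code{\link{default_rx_model}}.
#' @param sex_prob probability that a patient is female (default 161/300, the
#'   reference cohort's composition).
#' @param panel \code{pgx_panel} supplying default genotype frequencies and
#'   the VCF site definitions.
#' @return validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 300,
                          genotype_frequencies = NULL,
                          sampling_mode = c("exact_counts", "hwe_binomial"),
                          cyp2d6_ld = c("independent", "nested"),
                          ld_linked = list(c("rs9923231", "rs9934438"),
                                           c("rs1142345", "rs1800460")),
                          ld_nested = list(list(parent = "rs4244285",
                                                child = "rs17878459")),
                          lifespan_model = list(mean = 74, sd = 12,
                                                lower = 20, upper = 100),
                          rx_model = default_rx_model(),
                          sex_prob = 161 / 300,
                          panel = load_panel()) {
  sampling_mode <- match.arg(sampling_mode)
  cyp2d6_ld <- match.arg(cyp2d6_ld)
  stopifnot(n_patients >= 0)
  if (is.null(genotype_frequencies)) {
    v <- panel$variants
    if (anyNA(v$n_hom) || anyNA(v$n_het)) {
      stop("panel carries no genotype counts; supply genotype_frequencies",
           call. = FALSE)
    }
    genotype_frequencies <- data.frame(rsid = v$rsid, n_hom = v$n_hom,
                                       n_het = v$n_het,
                                       stringsAsFactors = FALSE)
    # Counts are per 300; rescale proportionally for other cohort sizes.
    if (n_patients != 300) {
      genotype_frequencies$n_hom <-
        round(genotype_frequencies$n_hom * n_patients / 300)
      genotype_frequencies$n_het <-
        round(genotype_frequencies$n_het * n_patients / 300)
    }
  }
  gf <- genotype_frequencies
  stopifnot(all(c("rsid", "n_hom", "n_het") %in% names(gf)))
  if (any(gf$n_hom < 0) || any(gf$n_het < 0)) {
    stop("genotype counts must be ≥ 0", call. = FALSE)
  }
  if (n_patients > 0 && any(gf$n_hom + gf$n_het > n_patients)) {
    stop("config error: n_hom + n_het exceeds n_patients for: ",
         paste(gf$rsid[gf$n_hom + gf$n_het > n_patients], collapse = ", "),
         call. = FALSE)
  }
  if (cyp2d6_ld == "nested" &&
      all(c("rs1065852", "rs3892097") %in% gf$rsid)) {
    ld_nested <- c(ld_nested,
                   list(list(parent = "rs1065852", child = "rs3892097")))
  }
  cfg <- structure(list(
    n_patients = n_patients, genotype_frequencies = gf,
    sampling_mode = sampling_mode, cyp2d6_ld = cyp2d6_ld,
    ld_linked = ld_linked, ld_nested = ld_nested,
    lifespan_model = lifespan_model, rx_model = rx_model,
    sex_prob = sex_prob, panel = panel
  ), class = "cohort_config")
  .check_ld_feasible(cfg)
  for (h in rx_model) {
    if (length(h) != 10L || any(h < 0)) {
      stop("config error: each rx hazard must be 10 non-negative ",
           "per-decade rates", call. = FALSE)
    }
  }
  with(lifespan_model, stopifnot(sd > 0, lower < upper))
  cfg
}

.gf_row <- function(cfg, rsid) {
  i <- match(rsid, cfg$genotype_frequencies$rsid)
  if (is.na(i)) stop("config error: no genotype frequency for ", rsid,
                     call. = FALSE)
  cfg$genotype_frequencies[i, ]
}

.check_ld_feasible <- function(cfg) {
  gf <- cfg$genotype_frequencies
  present <- function(ids) all(ids %in% gf$rsid)
  for (pair in cfg$ld_linked) {
    if (!present(pair)) next
    prim <- .gf_row(cfg, pair[1])
    for (other in pair[-1]) {
      o <- .gf_row(cfg, other)
      if (o$n_hom > prim$n_hom || o$n_het > prim$n_het) {
        stop("config error: linked variant ", other,
             " has more homozygotes/heterozygotes than its primary ",
             pair[1], call. = FALSE)
      }
    }
  }
  for (nst in cfg$ld_nested) {
    if (!present(c(nst$parent, nst$child))) next
    p <- .gf_row(cfg, nst$parent); ch <- .gf_row(cfg, nst$child)
    if (ch$n_hom > p$n_hom || ch$n_het > p$n_het) {
      stop("config error: infeasible nesting, child ", nst$child,
           " counts exceed parent ", nst$parent, call. = FALSE)
    }
  }
  invisible(cfg)
}

# Partition the configured variants into effective loci: one per linked
# group (primary = first member), one per nesting (the parent; the child
# rides inside), one per remaining independent variant. Used by both the
# sampler and the analytic carrier-fraction formula.
.effective_loci <- function(cfg) {
  gf <- cfg$genotype_frequencies
  grouped <- character()
  loci <- list()
  nested_children <- vapply(cfg$ld_nested, function(n) n$child, "")
  for (pair in cfg$ld_linked) {
    if (!all(pair %in% gf$rsid)) next
    loci[[length(loci) + 1L]] <- list(primary = pair[1], linked = pair[-1],
                                      children = list())
    grouped <- c(grouped, pair)
  }
  for (nst in cfg$ld_nested) {
    if (!all(c(nst$parent, nst$child) %in% gf$rsid)) next
    hit <- which(vapply(loci, function(l) l$primary == nst$parent, TRUE))
    if (length(hit)) {
      loci[[hit]]$children <- c(loci[[hit]]$children, list(nst$child))
    } else {
      loci[[length(loci) + 1L]] <- list(primary = nst$parent,
                                        linked = character(),
                                        children = list(nst$child))
      grouped <- c(grouped, nst$parent)
    }
    grouped <- c(grouped, nst$child)
  }
  for (rsid in setdiff(gf$rsid, grouped)) {
    loci[[length(loci) + 1L]] <- list(primary = rsid, linked = character(),
                                      children = list())
  }
  loci
}

#' Analytic carrier fraction under the configured linkage structure
#'
#' Closed-form expected fraction of patients carrying at least one panel
#' variant: \eqn{1 - \prod_i (1 - c_i/N)} over effective loci, where
#' \eqn{c_i} is the carrier count of locus \eqn{i}'s primary variant (linked
#' partners share carriers; nested children add none). Exact for the
#' exact-counts sampler, whose loci are independent by construction.
#'
#' @param cfg a \code{\link{cohort_config}}.
#' @return expected carrier fraction in [0, 1].
#' @export
carrier_fraction_analytic <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  N <- cfg$n_patients
  if (N == 0) return(NA_real_)
  carriers <- vapply(.effective_loci(cfg), function(l) {
    r <- .gf_row(cfg, l$primary)
    r$n_hom + r$n_het
  }, 1)
  1 - prod(1 - carriers / N)
}

#' Simulate panel genotypes for a cohort
#'
#' Draws per-patient genotypes at the configured variants. In
#' \code{"exact_counts"} mode the marginal homozygote/heterozygote counts
#' equal the configured counts exactly and only the assignment to patients is
#' random; in \code{"hwe_binomial"} mode each patient's genotype at each
#' effective locus is an independent Hardy-Weinberg draw at the implied
#' allele frequency. Fully linked variants share carriers; a nested child's
#' carriers are a subset of its parent's.
#'
#' @param cfg a \code{\link{cohort_config}}.
#' @param seed optional integer seed.
#' @return data frame of carrier rows: \code{patient_id}, \code{rsid},
#'   \code{zygosity}; attribute \code{"patients"} holds all cohort ids.
#' @export
simulate_genotypes <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  N <- cfg$n_patients
  ids <- if (N > 0) sprintf("P%0*d", max(4L, nchar(N)), seq_len(N)) else
    character()
  rows <- list()
  add <- function(pids, rsid, zyg) {
    if (!length(pids)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      patient_id = pids, rsid = rsid, zygosity = zyg,
      stringsAsFactors = FALSE)
  }

  for (locus in .effective_loci(cfg)) {
    r <- .gf_row(cfg, locus$primary)
    if (cfg$sampling_mode == "exact_counts") {
      if (r$n_hom + r$n_het > length(ids)) {
        stop("config error: counts exceed cohort size for ", locus$primary,
             call. = FALSE)
      }
      picked <- sample(ids, r$n_hom + r$n_het)
      hom_ids <- picked[seq_len(r$n_hom)]
      het_ids <- setdiff(picked, hom_ids)
    } else {
      p <- (2 * r$n_hom + r$n_het) / (2 * N)
      g <- sample(0:2, N, replace = TRUE,
                  prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
      hom_ids <- ids[g == 2L]
      het_ids <- ids[g == 1L]
    }
    add(hom_ids, locus$primary, "homozygous_alt")
    add(het_ids, locus$primary, "heterozygous")

    for (other in locus$linked) {
      o <- .gf_row(cfg, other)
      if (cfg$sampling_mode == "exact_counts") {
        add(sample(hom_ids, o$n_hom), other, "homozygous_alt")
        add(sample(het_ids, o$n_het), other, "heterozygous")
      } else {
        # fully linked: identical carriers
        add(hom_ids, other, "homozygous_alt")
        add(het_ids, other, "heterozygous")
      }
    }
    for (child in locus$children) {
      ch <- .gf_row(cfg, child)
      if (cfg$sampling_mode == "exact_counts") {
        add(sample(hom_ids, ch$n_hom), child, "homozygous_alt")
        add(sample(het_ids, ch$n_het), child, "heterozygous")
      } else {
        p_hom <- if (r$n_hom > 0) ch$n_hom / r$n_hom else 0
        p_het <- if (r$n_het > 0) ch$n_het / r$n_het else 0
        add(hom_ids[stats::runif(length(hom_ids)) < p_hom], child,
            "homozygous_alt")
        add(het_ids[stats::runif(length(het_ids)) < p_het], child,
            "heterozygous")
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), rsid = character(),
               zygosity = character(), stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "patients") <- ids
  out
}

#' Default per-drug first-prescription hazard model
#'
#' Yearly first-prescription hazards by decade of age (10 values per drug,
#' ages 0-100) for the drugs of the default drug-gene map. The profiles are
#' chosen to be clinically plausible for a general adult population — statins
#' and anticoagulants ramp up after midlife, opioid analgesics are roughly
#' flat through adulthood, oral contraceptives concentrate in reproductive
#' ages, oncology and transplant drugs are rare — and are configuration, not
#' estimates from any real prescribing data.
#'
#' @return named list of 10-element hazard vectors.
#' @export
default_rx_model <- function() {
  list(
    simvastatin        = c(0, 0, 0, .002, .010, .030, .050, .050, .040, .020),
    warfarin           = c(0, 0, .001, .002, .005, .010, .020, .040, .050, .030),
    clopidogrel        = c(0, 0, 0, .001, .003, .008, .020, .030, .030, .020),
    codeine            = c(.002, .005, .010, .012, .012, .012, .012, .012, .010, .008),
    fluorouracil       = c(0, 0, 0, .001, .002, .004, .006, .006, .004, .002),
    capecitabine       = c(0, 0, 0, 0, .001, .002, .003, .003, .002, .001),
    azathioprine       = c(0, .001, .002, .002, .002, .002, .002, .001, .001, 0),
    mercaptopurine     = c(.001, .001, .001, .001, .001, .001, .001, 0, 0, 0),
    thioguanine        = c(0, 0, 0, 0, .0005, .0005, .0005, .0005, 0, 0),
    ivacaftor          = c(.0005, .0005, .0005, .0002, .0002, 0, 0, 0, 0, 0),
    `ethinyl estradiol` = c(0, .020, .030, .020, .005, 0, 0, 0, 0, 0)
  )
}

# First-event age under a piecewise-constant hazard (10 decades, 0-100), by
# inversion of the cumulative hazard; Inf if no event by age 100.
.sample_first_event_age <- function(hazards, n) {
  H <- cumsum(hazards * 10)
  E <- stats::rexp(n)
  ages <- rep(Inf, n)
  for (k in seq_along(hazards)) {
    H_prev <- if (k == 1L) 0 else H[k - 1L]
    hit <- is.infinite(ages) & E <= H[k] & hazards[k] > 0
    ages[hit] <- (k - 1L) * 10 + (E[hit] - H_prev) / hazards[k]
  }
  ages
}

#' Simulate lifespans and prescriptions
#'
#' Draws one age at death per patient from the configured truncated-normal
#' lifespan model (inverse-CDF sampling) and, independently, a first
#' prescription age per (patient, drug) from each drug's piecewise-constant
#' hazard; prescriptions at or after the patient's death are discarded, so a
#' prescription can only occur in life. Genotypes play no role.
#'
#' @param cfg a \code{\link{cohort_config}}.
#' @param patients character vector of patient ids (defaults to the ids the
#'   genotype stage generates for \code{cfg$n_patients}).
#' @param seed optional integer seed.
#' @return list with data frames \code{demographics} (\code{patient_id},
#'   \code{sex}, \code{death_age}) and \code{prescriptions}
#'   (\code{patient_id}, \code{drug}, \code{age_at_rx}).
#' @export
simulate_lives_and_rx <- function(cfg, patients = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  N <- cfg$n_patients
  if (is.null(patients)) {
    patients <- if (N > 0) sprintf("P%0*d", max(4L, nchar(N)), seq_len(N))
    else character()
  }
  lm <- cfg$lifespan_model
  u <- stats::runif(N, stats::pnorm(lm$lower, lm$mean, lm$sd),
                    stats::pnorm(lm$upper, lm$mean, lm$sd))
  death_age <- stats::qnorm(u, lm$mean, lm$sd)
  sex <- ifelse(stats::runif(N) < cfg$sex_prob, "F", "M")
  demographics <- data.frame(patient_id = patients, sex = sex,
                             death_age = death_age,
                             stringsAsFactors = FALSE)
  rx_rows <- list()
  for (drug in names(cfg$rx_model)) {
    age <- .sample_first_event_age(cfg$rx_model[[drug]], N)
    keep <- is.finite(age) & age < death_age
    if (any(keep)) {
      rx_rows[[length(rx_rows) + 1L]] <- data.frame(
        patient_id = patients[keep], drug = drug, age_at_rx = age[keep],
        stringsAsFactors = FALSE)
    }
  }
  prescriptions <- if (length(rx_rows)) do.call(rbind, rx_rows) else
    data.frame(patient_id = character(), drug = character(),
               age_at_rx = numeric(), stringsAsFactors = FALSE)
  prescriptions <- prescriptions[order(prescriptions$patient_id,
                                       prescriptions$drug), , drop = FALSE]
  rownames(prescriptions) <- NULL
  list(demographics = demographics, prescriptions = prescriptions)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the genotype and lifespan/prescription stages under a single global
#' seed (split into independent per-stage seeds, so each stage is
#' reproducible on its own) and optionally writes the cohort to disk as a
#' multi-sample VCFv4.2 genotype file, a demographics TSV, a prescriptions
#' TSV and a provenance YAML recording the seed and configuration summary.
#'
#' @param cfg a \code{\link{cohort_config}}.
#' @param seed integer seed driving both stages.
#' @param dir optional output directory (created if missing).
#' @return list with \code{genotypes}, \code{demographics},
#'   \code{prescriptions}, \code{seed}, and (if written) \code{paths}.
#' @export
simulate_cohort <- function(cfg, seed, dir = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(seed)
  stage_seeds <- base::sample.int(.Machine$integer.max, 2)
  genotypes <- simulate_genotypes(cfg, seed = stage_seeds[1])
  lives <- simulate_lives_and_rx(cfg, patients = attr(genotypes, "patients"),
                                 seed = stage_seeds[2])
  out <- list(genotypes = genotypes, demographics = lives$demographics,
              prescriptions = lives$prescriptions, seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                  demographics = file.path(dir, "demographics.tsv"),
                  prescriptions = file.path(dir, "prescriptions.tsv"),
                  provenance = file.path(dir, "provenance.yaml"))
    write_genotypes_vcf(genotypes, cfg$panel, paths$vcf,
                        patients = attr(genotypes, "patients"))
    utils::write.table(lives$demographics, paths$demographics, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(lives$prescriptions, paths$prescriptions, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(c(
      "generator: pgxlifetime::simulate_cohort",
      paste0("seed: ", seed),
      paste0("n_patients: ", cfg$n_patients),
      paste0("sampling_mode: ", cfg$sampling_mode),
      paste0("cyp2d6_ld: ", cfg$cyp2d6_ld),
      paste0("lifespan_model: {mean: ", cfg$lifespan_model$mean,
             ", sd: ", cfg$lifespan_model$sd,
             ", lower: ", cfg$lifespan_model$lower,
             ", upper: ", cfg$lifespan_model$upper, "}")
    ), paths$provenance)
    out$paths <- paths
  }
  out
}

#' Write panel genotypes as a multi-sample VCF
#'
#' Emits a VCFv4.2 file with one record per panel variant and one sample
#' column per patient (\code{GT:DP}; site QUAL fixed at a passing value).
#' The single-base deletion is written in left-anchored normalized form: the
#' anchor base one position upstream is synthetic (the file carries no real
#' sequence context) and matching recovers the variant through its rsID.
#'
#' @param genotypes carrier rows from \code{\link{simulate_genotypes}}.
#' @param panel a \code{pgx_panel}.
#' @param path output path.
#' @param patients all cohort sample ids (defaults to the genotypes'
#'   \code{"patients"} attribute).
#' @param qual site QUAL value (default 99).
#' @param depth per-sample DP value (default 50).
#' @export
write_genotypes_vcf <- function(genotypes, panel, path,
                                patients = attr(genotypes, "patients"),
                                qual = 99, depth = 50) {
  stopifnot(inherits(panel, "pgx_panel"))
  if (is.null(patients)) patients <- unique(genotypes$patient_id)
  v <- panel$variants
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pgxlifetime_synthetic_cohort",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", patients), collapse = "\t")
  )
  body <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    if (v$alt[i] == "-") {
      pos <- v$pos[i] - 1L
      ref <- paste0("T", v$ref[i])  # synthetic anchor base
      alt <- "T"
    } else {
      pos <- v$pos[i]; ref <- v$ref[i]; alt <- v$alt[i]
    }
    g <- genotypes[genotypes$rsid == v$rsid[i], , drop = FALSE]
    gt <- stats::setNames(rep("0/0", length(patients)), patients)
    gt[g$patient_id[g$zygosity == "heterozygous"]] <- "0/1"
    gt[g$patient_id[g$zygosity == "homozygous_alt"]] <- "1/1"
    body[i] <- paste(c(v$chrom[i], pos, v$rsid[i], ref, alt, qual, "PASS",
                       ".", "GT:DP", paste0(gt, ":", depth)),
                     collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Monte Carlo distribution of the cohort carrier fraction
#'
#' Repeatedly simulates genotypes under \code{cfg} and records the fraction
#' of patients carrying at least one panel variant in each replicate,
#' alongside the closed-form expectation
#' \code{\link{carrier_fraction_analytic}}.
#'
#' @param cfg a \code{\link{cohort_config}}.
#' @param n_reps number of replicate cohorts (≥ 1).
#' @param seed optional integer seed.
#' @return list of class \code{carrier_fraction_sim}: \code{fractions}
#'   (length \code{n_reps}), \code{mean}, \code{se}, \code{analytic},
#'   \code{n_patients}, \code{n_reps}.
#' @export
simulate_carrier_fraction <- function(cfg, n_reps = 1000, seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- cfg$n_patients
  fractions <- vapply(seq_len(n_reps), function(i) {
    g <- simulate_genotypes(cfg)
    length(unique(g$patient_id)) / N
  }, 1)
  structure(list(
    fractions = fractions,
    mean = mean(fractions),
    se = stats::sd(fractions) / sqrt(n_reps),
    analytic = carrier_fraction_analytic(cfg),
    n_patients = N, n_reps = n_reps
  ), class = "carrier_fraction_sim")
}

#' @export
print.carrier_fraction_sim <- function(x, ...) {
  cat(sprintf(
    "Carrier fraction over %d simulated cohorts of %d patients:\n  mean %.4f (SE %.4f); analytic expectation %.4f\n",
    x$n_reps, x$n_patients, x$mean, x$se, x$analytic))
  invisible(x)
}
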