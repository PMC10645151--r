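# Genotype annotation: intersect QC-passed calls with the panel to build
# carrier profiles, cohort genotype summaries and zygosity risk classes.

# Match calls against panel variants. Precedence: exact (chrom,pos,ref,alt),
# then rsID with a ±1 bp position window (needed for indels whose VCF
# left-anchored representation shifts the coordinate by one). A position match
# with a mismatched ref raises a warning and no match.
.match_panel <- function(calls, panel) {
  v <- panel$variants
  call_key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
  panel_key <- paste(v$chrom, v$pos, v$ref, v$alt)
  idx <- match(call_key, panel_key)

  if ("rsid" %in% names(calls)) {
    fb <- which(is.na(idx) & calls$rsid %in% v$rsid)
    for (i in fb) {
      j <- match(calls$rsid[i], v$rsid)
      if (calls$chrom[i] == v$chrom[j] && abs(calls$pos[i] - v$pos[j]) <= 1L) {
        idx[i] <- j
      }
    }
  }
  pos_only <- is.na(idx) &
    paste(calls$chrom, calls$pos) %in% paste(v$chrom, v$pos)
  if (any(pos_only)) {
    warning("call(s) at panel position(s) with mismatched ref/alt left ",
            "unmatched: ",
            paste(unique(paste0(calls$chrom[pos_only], ":",
                                calls$pos[pos_only])), collapse = ", "),
            call. = FALSE)
  }
  idx
}

#' Annotate one patient's calls against the panel
#'
#' Intersects a patient's QC-passed variant calls with the panel and returns a
#' carrier profile: the set of (panel variant, zygosity) hits and the derived
#' set of carrier genes. Calls at non-panel sites are ignored. Two calls by
#' the same patient at the same site with conflicting zygosity are an error.
#'
#' @param calls QC-passed calls for a single patient (see
#'   \code{\link{filter_calls}} for the schema).
#' @param panel a \code{pgx_panel}.
#' @return an object of class \code{carrier_profile}: list with
#'   \code{patient_id}, \code{hits} (data frame: rsid, gene, star_allele,
#'   zygosity), \code{carrier_genes}.
#' @export
annotate_patient <- function(calls, panel) {
  stopifnot(inherits(panel, "pgx_panel"))
  pid <- unique(calls$patient_id)
  if (length(pid) > 1L) {
    stop("annotate_patient expects calls for a single patient; got: ",
         paste(pid, collapse = ", "), call. = FALSE)
  }
  if (length(pid) == 0L) pid <- NA_character_
  if (nrow(calls)) .check_calls(calls)
  idx <- if (nrow(calls)) .match_panel(calls, panel) else integer()
  hit <- !is.na(idx)
  v <- panel$variants

  if (any(hit)) {
    site <- paste0(v$rsid[idx[hit]])
    zyg_by_site <- split(calls$zygosity[hit], site)
    bad <- names(zyg_by_site)[vapply(zyg_by_site,
                                     function(z) length(unique(z)) > 1L, TRUE)]
    if (length(bad)) {
      stop("conflicting duplicate calls for patient ", pid, " at site(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  keep <- which(hit)[!duplicated(idx[hit])]
  hits <- data.frame(
    rsid = v$rsid[idx[keep]], gene = v$gene[idx[keep]],
    star_allele = v$star_allele[idx[keep]],
    zygosity = calls$zygosity[keep], stringsAsFactors = FALSE
  )
  structure(list(patient_id = pid, hits = hits,
                 carrier_genes = sort(unique(hits$gene))),
            class = "carrier_profile")
}

#' @export
print.carrier_profile <- function(x, ...) {
  cat("Carrier profile for", x$patient_id, "-", nrow(x$hits), "panel hit(s)")
  if (nrow(x$hits)) cat(" in", paste(x$carrier_genes, collapse = ", "))
  cat("\n")
  if (nrow(x$hits)) print(x$hits)
  invisible(x)
}

#' Annotate a whole cohort of calls
#'
#' Convenience wrapper applying \code{\link{annotate_patient}} per patient and
#' binding the hits into the long carrier-profiles table used by the linkage
#' and summary functions.
#'
#' @param calls QC-passed calls for any number of patients.
#' @param panel a \code{pgx_panel}.
#' @param patients optional character vector of all cohort patient ids
#'   (including non-carriers); recorded as the \code{"patients"} attribute.
#' @return data frame with columns \code{patient_id}, \code{rsid},
#'   \code{gene}, \code{star_allele}, \code{zygosity}; one row per panel hit.
#' @export
annotate_cohort <- function(calls, panel, patients = NULL) {
  split_calls <- if (nrow(calls)) split(calls, calls$patient_id) else list()
  rows <- lapply(split_calls, function(cc) {
    pr <- annotate_patient(cc, panel)
    if (nrow(pr$hits) == 0L) return(NULL)
    cbind(patient_id = pr$patient_id, pr$hits, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), rsid = character(),
               gene = character(), star_allele = character(),
               zygosity = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (is.null(patients)) patients <- unique(calls$patient_id)
  attr(out, "patients") <- patients
  out
}

#' Per-variant genotype summary of a cohort
#'
#' Tallies homozygote and heterozygote carriers per panel variant over a set
#' of carrier profiles, together with the carrier count and minor-allele
#' frequency \eqn{(2 \cdot hom + het) / (2N)}. A frequency above 0.5 triggers
#' a major/minor-swap warning. With \code{N = 0} all counts are zero and the
#' frequency is reported missing.
#'
#' @param profiles long carrier-profiles table (see
#'   \code{\link{annotate_cohort}}).
#' @param panel a \code{pgx_panel}.
#' @param N cohort size (≥ number of distinct patients in \code{profiles}).
#' @return data frame with one row per panel variant: \code{rsid},
#'   \code{gene}, \code{star_allele}, \code{n_hom}, \code{n_het},
#'   \code{carrier_count}, \code{maf}.
#' @export
cohort_summary <- function(profiles, panel, N) {
  stopifnot(inherits(panel, "pgx_panel"), N >= 0)
  n_pat <- length(unique(profiles$patient_id))
  if (N < n_pat) {
    stop("N (", N, ") is smaller than the number of distinct patients (",
         n_pat, ")", call. = FALSE)
  }
  unknown <- setdiff(profiles$rsid, panel$variants$rsid)
  if (length(unknown)) {
    stop("profiles contain variant(s) not in the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  v <- panel$variants
  n_hom <- n_het <- integer(nrow(v))
  for (i in seq_len(nrow(v))) {
    z <- profiles$zygosity[profiles$rsid == v$rsid[i]]
    n_hom[i] <- sum(z == "homozygous_alt")
    n_het[i] <- sum(z == "heterozygous")
  }
  maf <- if (N > 0) (2 * n_hom + n_het) / (2 * N) else rep(NA_real_, nrow(v))
  if (any(!is.na(maf) & maf > 0.5)) {
    warning("allele frequency > 0.5 for: ",
            paste(v$rsid[!is.na(maf) & maf > 0.5], collapse = ", "),
            " (major/minor alleles may be swapped)", call. = FALSE)
  }
  data.frame(rsid = v$rsid, gene = v$gene, star_allele = v$star_allele,
             n_hom = n_hom, n_het = n_het, carrier_count = n_hom + n_het,
             maf = maf, stringsAsFactors = FALSE)
}

#' Fraction of the cohort carrying at least one panel variant
#'
#' @param profiles long carrier-profiles table.
#' @param N cohort size (must be ≥ 1).
#' @return numeric fraction in [0, 1].
#' @export
carrier_fraction <- function(profiles, N) {
  if (length(N) != 1L || is.na(N) || N < 1) {
    stop("N must be a positive cohort size", call. = FALSE)
  }
  length(unique(profiles$patient_id)) / N
}

#' Zygosity-dependent risk classification
#'
#' Classifies a patient's adverse-event risk for a gene under a
#' zygosity-dependent rule: no hit in the gene is \code{"none"}, heterozygous
#' hits only are the rule's het level, any homozygous hit is the rule's hom
#' level. The default rules are read from the panel's \code{ZygosityRisk}
#' column (shipped: SLCO1B1, het = moderate, hom = high, reflecting
#' statin-myopathy risk). Asking about a gene with no rule is an error, never
#' silently \code{"none"}.
#'
#' @param profile a \code{carrier_profile}.
#' @param gene gene symbol.
#' @param rules named list of rules, each \code{c(het = ..., hom = ...)};
#'   default derived from \code{panel}.
#' @param panel a \code{pgx_panel} used to derive default rules.
#' @return ordered factor with levels \code{none < moderate < high}.
#' @export
classify_risk <- function(profile, gene, rules = risk_rules(panel),
                          panel = load_panel()) {
  stopifnot(inherits(profile, "carrier_profile"))
  if (!gene %in% names(rules)) {
    stop("no zygosity-risk rule defined for gene: ", gene, call. = FALSE)
  }
  rule <- rules[[gene]]
  z <- profile$hits$zygosity[profile$hits$gene == gene]
  level <- if (length(z) == 0L) "none"
  else if (any(z == "homozygous_alt")) rule[["hom"]]
  else rule[["het"]]
  factor(level, levels = c("none", "moderate", "high"), ordered = TRUE)
}

#' @rdname classify_risk
#' @export
risk_rules <- function(panel) {
  stopifnot(inherits(panel, "pgx_panel"))
  v <- panel$variants[nzchar(panel$variants$risk_rule), , drop = FALSE]
  rules <- list()
  for (i in seq_len(nrow(v))) {
    parts <- strsplit(strsplit(v$risk_rule[i], ",", fixed = TRUE)[[1]], ":")
    rule <- vapply(parts, `[`, "", 2L)
    names(rule) <- vapply(parts, `[`, "", 1L)
    rules[[v$gene[i]]] <- rule
  }
  rules
}
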