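# EHR linkage: join carrier profiles with age-stamped prescriptions to
# produce actionable drug-gene incidences and cohort impact statistics.

#' Read and normalize a prescriptions table
#'
#' Reads a TSV of first-ever prescription events (\code{patient_id},
#' \code{drug}, \code{age_at_rx}), normalizes drug names with
#' \code{\link{normalize_drug}}, and collapses repeat (patient, drug) records
#' to the earliest age. Negative ages are an error.
#'
#' @param path path to the prescriptions TSV.
#' @return data frame with columns \code{patient_id}, \code{drug},
#'   \code{age_at_rx}, one row per (patient, drug).
#' @export
read_prescriptions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  req <- c("patient_id", "drug", "age_at_rx")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("prescriptions schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  normalize_prescriptions(raw)
}

#' @rdname read_prescriptions
#' @param rx data frame of prescription records.
#' @export
normalize_prescriptions <- function(rx) {
  if (any(rx$age_at_rx < 0)) {
    stop("age_at_rx must be ≥ 0", call. = FALSE)
  }
  rx$drug <- normalize_drug(rx$drug)
  rx <- rx[order(rx$patient_id, rx$drug, rx$age_at_rx), , drop = FALSE]
  rx <- rx[!duplicated(paste(rx$patient_id, rx$drug)), , drop = FALSE]
  rownames(rx) <- NULL
  rx[, c("patient_id", "drug", "age_at_rx")]
}

#' Actionable drug-gene incidences
#'
#' Joins carrier profiles against prescription records through the panel's
#' drug-gene map: a patient who carries a panel variant in gene G and was
#' prescribed a drug linked to G contributes one incidence per (patient, drug,
#' gene), stamped with the earliest prescription age of that drug. A drug
#' linked to two carried genes yields a row for each gene but counts once as a
#' (patient, drug) pair in \code{\link{impact_stats}}. Prescriptions for
#' patients outside the cohort are skipped with a warning.
#'
#' @param profiles long carrier-profiles table (see
#'   \code{\link{annotate_cohort}}).
#' @param prescriptions prescriptions table (see
#'   \code{\link{read_prescriptions}}); drug names are re-normalized and
#'   (patient, drug) pairs collapsed to earliest age.
#' @param panel a \code{pgx_panel}.
#' @param patients optional vector of cohort patient ids; defaults to the
#'   \code{"patients"} attribute of \code{profiles}, else to the union of ids
#'   seen in \code{profiles} and \code{prescriptions}.
#' @return data frame sorted by (patient_id, drug, gene) with columns
#'   \code{patient_id}, \code{drug}, \code{gene}, \code{age_at_rx}; attribute
#'   \code{"n_skipped_unknown_patient"} counts skipped prescription rows.
#' @export
actionable_incidences <- function(profiles, prescriptions, panel,
                                  patients = NULL) {
  stopifnot(inherits(panel, "pgx_panel"))
  rx <- normalize_prescriptions(prescriptions)
  if (is.null(patients)) patients <- attr(profiles, "patients")
  if (is.null(patients)) {
    patients <- union(unique(profiles$patient_id), unique(rx$patient_id))
  }
  unknown <- !(rx$patient_id %in% patients)
  if (any(unknown)) {
    warning(sum(unknown), " prescription record(s) for patient(s) not in ",
            "the cohort skipped", call. = FALSE)
    rx <- rx[!unknown, , drop = FALSE]
  }

  carried <- unique(profiles[, c("patient_id", "gene")])
  links <- panel$links
  rows <- list()
  for (i in seq_len(nrow(rx))) {
    genes <- links$gene[links$drug == rx$drug[i]]
    if (!length(genes)) next
    genes <- genes[paste(rx$patient_id[i], genes) %in%
                     paste(carried$patient_id, carried$gene)]
    for (g in genes) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = rx$patient_id[i], drug = rx$drug[i], gene = g,
        age_at_rx = rx$age_at_rx[i], stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), drug = character(),
               gene = character(), age_at_rx = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$drug, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped_unknown_patient") <- sum(unknown)
  attr(out, "patients") <- patients
  out
}

#' Cohort impact statistics
#'
#' Summarizes actionable incidences over a cohort of size \code{N}. A "unique
#' incidence" is a distinct (patient, drug) pair; the per-patient drug counts
#' (and their mean/median) are computed over impacted patients only, i.e. the
#' denominator is the number of patients with at least one incidence, not the
#' whole cohort.
#'
#' @param incidences output of \code{\link{actionable_incidences}}.
#' @param N cohort size (must be ≥ 1).
#' @return list of class \code{impact_stats}: \code{n_impacted},
#'   \code{pct_impacted}, \code{n_unique_incidences}, \code{n_unique_drugs},
#'   \code{drugs_per_impacted} (named integer vector),
#'   \code{mean_drugs}, \code{median_drugs}, \code{max_drugs_single_patient}.
#' @export
impact_stats <- function(incidences, N) {
  if (length(N) != 1L || is.na(N) || N < 1) {
    stop("N must be a positive cohort size", call. = FALSE)
  }
  pairs <- unique(incidences[, c("patient_id", "drug")])
  per_patient <- if (nrow(pairs)) table(pairs$patient_id) else table(character())
  counts <- as.integer(per_patient)
  names(counts) <- names(per_patient)
  n_impacted <- length(counts)
  structure(list(
    n_impacted = n_impacted,
    pct_impacted = n_impacted / N,
    n_unique_incidences = nrow(pairs),
    n_unique_drugs = length(unique(pairs$drug)),
    drugs_per_impacted = counts,
    mean_drugs = if (n_impacted) mean(counts) else NA_real_,
    median_drugs = if (n_impacted) stats::median(counts) else NA_real_,
    max_drugs_single_patient = if (n_impacted) max(counts) else NA_integer_
  ), class = "impact_stats")
}

#' @export
print.impact_stats <- function(x, ...) {
  cat(sprintf(
    "Impacted patients: %d (%.1f%%)\nUnique drug-patient incidences: %d over %d drugs\n",
    x$n_impacted, 100 * x$pct_impacted, x$n_unique_incidences,
    x$n_unique_drugs))
  if (x$n_impacted) {
    cat(sprintf("Drugs per impacted patient: mean %.1f, median %.1f, max %d\n",
                x$mean_drugs, x$median_drugs, x$max_drugs_single_patient))
  }
  invisible(x)
}
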