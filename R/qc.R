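# Variant-call QC: quality scoring, threshold filtering, VCF ingestion.

#' Variant-call confidence score
#'
#' Phred-like confidence score for a variant call,
#' \eqn{10 \log_{10}[P(\mathrm{true})/P(\mathrm{false})]} with
#' \eqn{P(\mathrm{false}) = 1 - P(\mathrm{true})}, oriented so that higher
#' scores mean higher confidence (a call that is true with probability 0.99
#' scores ~20; 0.9999 scores ~40). This orientation is the one consistent with
#' exclusion thresholds of the form "quality less than 20/40 is excluded".
#'
#' @param p_true probability in (0, 1) that the call is true. Vectorized.
#' @return numeric score(s) in dB-like units.
#' @examples
#' quality_score(0.5)     # 0
#' quality_score(0.99)    # 19.96
#' @export
quality_score <- function(p_true) {
  if (!is.numeric(p_true) || any(!is.finite(p_true)) ||
      any(p_true <= 0) || any(p_true >= 1)) {
    stop("p_true must lie strictly within (0, 1)", call. = FALSE)
  }
  10 * log10(p_true / (1 - p_true))
}

#' QC threshold configuration
#'
#' Exclusion thresholds for variant calls: homozygous calls with quality below
#' \code{min_quality_hom}, heterozygous calls with quality below
#' \code{min_quality_het}, and any call with read depth below
#' \code{min_depth} are excluded. "Below" is strict, so a call exactly at a
#' threshold is retained.
#'
#' @param min_quality_hom minimum quality for homozygous calls (default 20).
#' @param min_quality_het minimum quality for heterozygous calls (default 40).
#' @param min_depth minimum read depth (default 10).
#' @return a \code{qc_config} list.
#' @export
qc_config <- function(min_quality_hom = 20, min_quality_het = 40,
                      min_depth = 10) {
  stopifnot(min_quality_hom >= 0, min_quality_het >= 0, min_depth >= 0)
  structure(list(min_quality_hom = min_quality_hom,
                 min_quality_het = min_quality_het,
                 min_depth = min_depth),
            class = "qc_config")
}

.check_calls <- function(calls) {
  req <- c("patient_id", "chrom", "pos", "ref", "alt", "zygosity",
           "quality", "depth")
  missing_cols <- setdiff(req, names(calls))
  if (length(missing_cols)) {
    stop("calls missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ok <- calls$zygosity %in% c("heterozygous", "homozygous_alt")
  if (any(!ok)) {
    stop("invalid zygosity value(s): ",
         paste(unique(calls$zygosity[!ok]), collapse = ", "), call. = FALSE)
  }
  if (any(calls$depth < 0)) stop("depth must be ≥ 0", call. = FALSE)
  invisible(calls)
}

#' Filter variant calls on quality and depth
#'
#' Applies the exclusion rules of \code{\link{qc_config}}: depth is checked
#' first, then the zygosity-specific quality threshold, so a call failing both
#' is counted once under the depth reason. Input order is preserved; the
#' exclusion tally is attached as attribute \code{"qc_report"}.
#'
#' @param calls data frame of variant calls with columns \code{patient_id},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{zygosity}
#'   (\code{"heterozygous"} or \code{"homozygous_alt"}), \code{quality},
#'   \code{depth}.
#' @param cfg a \code{\link{qc_config}}.
#' @return the retained subset of \code{calls}, with a \code{qc_report}
#'   attribute listing \code{n_input}, \code{excluded_depth},
#'   \code{excluded_quality}, \code{retained}.
#' @export
filter_calls <- function(calls, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  if (nrow(calls) == 0L) {
    attr(calls, "qc_report") <- list(n_input = 0L, excluded_depth = 0L,
                                     excluded_quality = 0L, retained = 0L)
    return(calls)
  }
  .check_calls(calls)
  fail_depth <- calls$depth < cfg$min_depth
  qmin <- ifelse(calls$zygosity == "homozygous_alt",
                 cfg$min_quality_hom, cfg$min_quality_het)
  fail_quality <- !fail_depth & calls$quality < qmin
  keep <- !fail_depth & !fail_quality
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_report") <- list(
    n_input = nrow(calls),
    excluded_depth = sum(fail_depth),
    excluded_quality = sum(fail_quality),
    retained = sum(keep)
  )
  out
}

# -- VCF ingestion -------------------------------------------------------------

# Map a VCF GT string and an ALT-allele index to zygosity, or NA if the sample
# does not carry that ALT allele. Phased separators are accepted.
.gt_zygosity <- function(gt, alt_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_character_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  n_alt <- sum(alleles == as.character(alt_index))
  if (n_alt == 0L) return(NA_character_)
  if (n_alt >= 2L) "homozygous_alt" else "heterozygous"
}

#' Read per-sample variant calls from a VCF
#'
#' Reads a (possibly multi-sample, possibly bgzipped) VCFv4.x file via
#' \pkg{vcfR} and returns one row per sample per carried ALT allele.
#' Multi-allelic records are split: each ALT allele becomes its own call with
#' zygosity computed against that allele. Quality is the site \code{QUAL};
#' depth is the per-sample \code{DP} (NA if the format lacks DP).
#'
#' @param path path to a VCF file.
#' @return data frame of calls in the schema required by
#'   \code{\link{filter_calls}}, plus an \code{rsid} column from the VCF ID
#'   field.
#' @export
read_vcf_calls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_site <- nrow(fix)
  if (n_site == 0L) {
    return(data.frame(patient_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      rsid = character(), zygosity = character(),
                      quality = numeric(), depth = numeric(),
                      stringsAsFactors = FALSE))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- tryCatch(suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)),
    error = function(e) NULL)
  samples <- colnames(gt)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  rows <- vector("list", n_site)
  for (i in seq_len(n_site)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    site_rows <- list()
    for (a in seq_along(alts)) {
      for (s in seq_along(samples)) {
        zyg <- .gt_zygosity(gt[i, s], a)
        if (is.na(zyg)) next
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          patient_id = samples[s], chrom = fix[i, "CHROM"],
          pos = as.integer(fix[i, "POS"]), ref = fix[i, "REF"],
          alt = alts[a], rsid = fix[i, "ID"], zygosity = zyg,
          quality = qual[i],
          depth = if (is.null(dp)) NA_real_ else dp[i, s],
          stringsAsFactors = FALSE
        )
      }
    }
    rows[[i]] <- if (length(site_rows)) do.call(rbind, site_rows) else NULL
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      rsid = character(), zygosity = character(),
                      quality = numeric(), depth = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
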