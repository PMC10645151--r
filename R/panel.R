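# -- drug-name normalization ---------------------------------------------------

# Salt/ester suffixes stripped before matching. Matching is exact on the
# normalized string; no fuzzy matching.
.salt_suffixes <- c(
  "sodium", "potassium", "calcium", "hydrochloride", "hcl", "sulfate",
  "sulphate", "tartrate", "bitartrate", "phosphate", "maleate", "succinate",
  "mesylate", "besylate", "citrate", "acetate", "fumarate"
)

#' Normalize a drug name for matching
#'
#' Lower-cases, trims and collapses whitespace, and strips a trailing salt or
#' ester suffix (e.g. "Warfarin Sodium" -> "warfarin"). Prescription records
#' and drug-gene links are both passed through this function, so matching is
#' exact on the normalized string.
#'
#' @param drug character vector of drug names.
#' @return character vector of normalized names.
#' @examples
#' normalize_drug(c("Warfarin Sodium", "  Codeine  "))
#' @export
normalize_drug <- function(drug) {
  x <- tolower(trimws(as.character(drug)))
  x <- gsub("[[:space:]]+", " ", x)
  pat <- paste0(" (", paste(.salt_suffixes, collapse = "|"), ")$")
  gsub(pat, "", x)
}

# -- panel loading -------------------------------------------------------------

.panel_required_cols <- c("Gene", "Chr", "Position", "Nucleotide", "VariantID",
                          "Allele")
.links_required_cols <- c("drug", "gene", "source")

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character",
                    fill = TRUE, check.names = FALSE, quote = "")
}

# Parse "G > A" / "A > -" into ref/alt; "-" marks a single-base deletion.
.parse_nucleotide <- function(x) {
  parts <- strsplit(x, ">", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed Nucleotide field at panel row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  list(ref = trimws(vapply(parts, `[`, "", 1L)),
       alt = trimws(vapply(parts, `[`, "", 2L)))
}

#' Load and validate an actionable-variant panel and drug-gene map
#'
#' Reads a tab-separated variant panel (columns \code{Gene}, \code{Chr},
#' \code{Position}, \code{Nucleotide}, \code{VariantID}, \code{Allele},
#' optionally \code{Homozygotes}, \code{Heterozygotes}, \code{ZygosityRisk})
#' and a drug-gene link table (\code{drug}, \code{gene}, \code{source}),
#' validates both, and returns a \code{pgx_panel} object. Lines starting with
#' \code{#} are ignored. Drug names are normalized with
#' \code{\link{normalize_drug}} on load. Link genes that do not occur in the
#' panel are retained but reported in the \code{unmatched_genes} field.
#'
#' The shipped defaults (used when arguments are omitted) describe a panel of
#' 17 clinically significant variants across nine pharmacogenes, with genotype
#' counts observed in a 300-patient reference cohort.
#'
#' @param panel_path path to the variant panel TSV.
#' @param links_path path to the drug-gene links TSV.
#' @return an object of class \code{pgx_panel}: a list with data frames
#'   \code{variants} (gene, chrom, pos, ref, alt, rsid, star_allele, n_hom,
#'   n_het, risk_rule) and \code{links} (drug, gene, source), plus
#'   \code{unmatched_genes}.
#' @examples
#' panel <- load_panel()
#' n_panel_variants(panel)   # 17
#' n_panel_genes(panel)      # 9
#' @export
load_panel <- function(panel_path = default_panel_path(),
                       links_path = default_links_path()) {
  for (p in c(panel_path, links_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  raw <- .read_tsv(panel_path)
  missing_cols <- setdiff(.panel_required_cols, names(raw))
  if (length(missing_cols)) {
    stop("panel schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("panel must contain ≥1 variant", call. = FALSE)

  pos <- suppressWarnings(as.integer(raw$Position))
  if (anyNA(pos)) {
    stop("panel parse error: non-numeric Position at row(s): ",
         paste(which(is.na(pos)), collapse = ", "), call. = FALSE)
  }
  if (any(pos < 1L)) {
    stop("panel validation error: Position must be ≥ 1 at row(s): ",
         paste(which(pos < 1L), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(raw$Gene))) {
    stop("panel validation error: empty Gene at row(s): ",
         paste(which(!nzchar(raw$Gene)), collapse = ", "), call. = FALSE)
  }
  dup_rs <- unique(raw$VariantID[duplicated(raw$VariantID)])
  if (length(dup_rs)) {
    stop("panel validation error: duplicate rsID(s): ",
         paste(dup_rs, collapse = ", "), call. = FALSE)
  }
  nt <- .parse_nucleotide(raw$Nucleotide)
  key <- paste(raw$Chr, pos, nt$ref, nt$alt)
  if (anyDuplicated(key)) {
    stop("panel validation error: duplicate (chrom, pos, ref, alt) at row(s): ",
         paste(which(duplicated(key) | duplicated(key, fromLast = TRUE)),
               collapse = ", "), call. = FALSE)
  }

  n_hom <- if ("Homozygotes" %in% names(raw))
    suppressWarnings(as.integer(raw$Homozygotes)) else rep(NA_integer_, nrow(raw))
  n_het <- if ("Heterozygotes" %in% names(raw))
    suppressWarnings(as.integer(raw$Heterozygotes)) else rep(NA_integer_, nrow(raw))
  risk <- if ("ZygosityRisk" %in% names(raw)) {
    r <- raw$ZygosityRisk
    r[is.na(r)] <- ""
    r
  } else rep("", nrow(raw))

  variants <- data.frame(
    gene = raw$Gene, chrom = raw$Chr, pos = pos,
    ref = nt$ref, alt = nt$alt, rsid = raw$VariantID,
    star_allele = raw$Allele, n_hom = n_hom, n_het = n_het,
    risk_rule = risk, stringsAsFactors = FALSE
  )

  lraw <- .read_tsv(links_path)
  missing_cols <- setdiff(.links_required_cols, names(lraw))
  if (length(missing_cols)) {
    stop("links schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  links <- data.frame(
    drug = normalize_drug(lraw$drug), gene = lraw$gene,
    source = lraw$source, stringsAsFactors = FALSE
  )
  dup_link <- duplicated(paste(links$drug, links$gene))
  if (any(dup_link)) {
    stop("links validation error: duplicate (drug, gene) pair(s) at row(s): ",
         paste(which(dup_link), collapse = ", "), call. = FALSE)
  }
  unmatched <- sort(unique(setdiff(links$gene, variants$gene)))

  structure(
    list(variants = variants, links = links, unmatched_genes = unmatched),
    class = "pgx_panel"
  )
}

#' @rdname load_panel
#' @export
default_panel_path <- function() {
  system.file("extdata", "panel_variants.tsv", package = "pgxlifetime",
              mustWork = TRUE)
}

#' @rdname load_panel
#' @export
default_links_path <- function() {
  system.file("extdata", "drug_gene_links.tsv", package = "pgxlifetime",
              mustWork = TRUE)
}

#' @rdname load_panel
#' @param panel a \code{pgx_panel}.
#' @export
n_panel_variants <- function(panel) {
  stopifnot(inherits(panel, "pgx_panel"))
  nrow(panel$variants)
}

#' @rdname load_panel
#' @export
n_panel_genes <- function(panel) {
  stopifnot(inherits(panel, "pgx_panel"))
  length(unique(panel$variants$gene))
}

#' @export
print.pgx_panel <- function(x, ...) {
  cat("Pharmacogene variant panel:", n_panel_variants(x), "variants in",
      n_panel_genes(x), "genes;", nrow(x$links), "drug-gene links\n")
  if (length(x$unmatched_genes)) {
    cat("  link genes not in panel:",
        paste(x$unmatched_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Drugs linked to a pharmacogene
#'
#' Returns the (normalized, alphabetically sorted) drug names linked to a gene
#' in the panel's drug-gene map. A gene present in the panel but without links
#' yields an empty vector; a gene absent from both panel and link map is an
#' error, so that "no drugs" and "unknown gene" cannot be confused.
#'
#' @param panel a \code{pgx_panel} from \code{\link{load_panel}}.
#' @param gene gene symbol.
#' @return character vector of drug names (possibly empty).
#' @examples
#' drugs_for_gene(load_panel(), "SLCO1B1")  # "simvastatin"
#' @export
drugs_for_gene <- function(panel, gene) {
  stopifnot(inherits(panel, "pgx_panel"), length(gene) == 1L)
  known <- union(panel$variants$gene, panel$links$gene)
  if (!gene %in% known) {
    stop("gene not in panel: ", gene, call. = FALSE)
  }
  sort(unique(panel$links$drug[panel$links$gene == gene]))
}

#' Write a panel back to TSV
#'
#' Inverse of \code{\link{load_panel}}: writes the variant table and link table
#' in the same schema, so that reloading yields a field-by-field identical
#' panel.
#'
#' @param panel a \code{pgx_panel}.
#' @param panel_path,links_path output file paths.
#' @return invisibly, the panel.
#' @export
write_panel <- function(panel, panel_path, links_path) {
  stopifnot(inherits(panel, "pgx_panel"))
  v <- panel$variants
  out <- data.frame(
    Gene = v$gene, Chr = v$chrom, Position = v$pos,
    Nucleotide = paste(v$ref, ">", v$alt), VariantID = v$rsid,
    Allele = v$star_allele, Homozygotes = v$n_hom, Heterozygotes = v$n_het,
    ZygosityRisk = v$risk_rule, check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(out, panel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(panel$links, links_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(panel)
}
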