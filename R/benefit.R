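# Age-indexed benefit-of-testing curves under three population perspectives:
# fixed cohort (denominator always N), living population (denominator = those
# alive at the candidate testing age), and transient population (living, but
# only prescriptions within a follow-up window after testing count).
#
# Conventions, applied uniformly: a patient "benefits at age x" if some
# actionable first prescription occurs at age_at_rx >= x (testing precedes or
# coincides with prescribing; boundary inclusive); "alive at x" means
# death_age > x (strict); transient windows are half-open [x, x + w).

.check_demographics <- function(demographics) {
  req <- c("patient_id", "death_age")
  missing_cols <- setdiff(req, names(demographics))
  if (length(missing_cols)) {
    stop("demographics missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(demographics) == 0L) {
    stop("demographics must contain at least one patient", call. = FALSE)
  }
  if (anyDuplicated(demographics$patient_id)) {
    stop("duplicate patient_id in demographics", call. = FALSE)
  }
  invisible(demographics)
}

#' Empirical survival curve of a deceased cohort
#'
#' With every death age known (a fully deceased cohort, no censoring) the
#' empirical survivor function is exact: \eqn{S(x) = |\{death\_age > x\}|/N}.
#'
#' @param demographics data frame with columns \code{patient_id},
#'   \code{death_age}.
#' @param ages numeric evaluation grid (default integer years 0-100).
#' @return data frame with columns \code{age}, \code{n_alive},
#'   \code{fraction}.
#' @export
survival_curve <- function(demographics, ages = 0:100) {
  .check_demographics(demographics)
  n_alive <- vapply(ages, function(x) sum(demographics$death_age > x), 1L)
  data.frame(age = ages, n_alive = n_alive,
             fraction = n_alive / nrow(demographics))
}

# Earliest actionable first-prescription ages per patient (distinct drugs;
# a drug linked to several genes still contributes one age per drug).
.rx_ages_by_patient <- function(incidences) {
  pairs <- unique(incidences[, c("patient_id", "drug", "age_at_rx")])
  split(pairs$age_at_rx, pairs$patient_id)
}

.curve_frame <- function(model, window, ages, num, den) {
  data.frame(model = model, window = window, age = ages,
             numerator = num, denominator = den,
             fraction = ifelse(den > 0, num / den, NA_real_),
             stringsAsFactors = FALSE)
}

#' Fixed-cohort benefit curve
#'
#' Fraction of the whole cohort (denominator constant at \code{N}) that has
#' at least one actionable first prescription at or after each candidate
#' testing age. At age 0 this equals the lifetime impacted fraction; the
#' curve is non-increasing in age.
#'
#' @param incidences output of \code{\link{actionable_incidences}}.
#' @param demographics cohort demographics (used for \code{N} when omitted).
#' @param N cohort size.
#' @param ages evaluation grid.
#' @return data frame: \code{model}, \code{window}, \code{age},
#'   \code{numerator}, \code{denominator}, \code{fraction}.
#' @export
benefit_fixed <- function(incidences, demographics = NULL,
                          N = nrow(demographics), ages = 0:100) {
  if (is.null(N) || length(N) != 1L || is.na(N) || N < 1) {
    stop("cohort size N must be ≥ 1", call. = FALSE)
  }
  rx <- .rx_ages_by_patient(incidences)
  num <- vapply(ages, function(x) {
    sum(vapply(rx, function(a) any(a >= x), TRUE))
  }, 1L)
  .curve_frame("fixed_cohort", NA_real_, ages, num, rep(N, length(ages)))
}

#' Living-population benefit curve
#'
#' Among patients alive at each candidate testing age, the fraction with at
#' least one actionable first prescription at or after that age.
#'
#' @inheritParams benefit_fixed
#' @export
benefit_living <- function(incidences, demographics, ages = 0:100) {
  .check_demographics(demographics)
  rx <- .rx_ages_by_patient(incidences)
  death <- stats::setNames(demographics$death_age, demographics$patient_id)
  num <- den <- integer(length(ages))
  for (i in seq_along(ages)) {
    x <- ages[i]
    alive <- names(death)[death > x]
    den[i] <- length(alive)
    num[i] <- sum(vapply(alive, function(p) {
      a <- rx[[p]]
      !is.null(a) && any(a >= x)
    }, TRUE))
  }
  .curve_frame("living", NA_real_, ages, num, den)
}

#' Transient-population benefit curve
#'
#' Living-population benefit restricted to actionable first prescriptions in
#' the half-open follow-up window \eqn{[x, x + w)} after the testing age,
#' modelling patients lost to follow-up after \code{window} years.
#'
#' @inheritParams benefit_fixed
#' @param window follow-up window in years (> 0).
#' @export
benefit_transient <- function(incidences, demographics, ages = 0:100,
                              window) {
  if (length(window) != 1L || is.na(window) || window <= 0) {
    stop("window must be a positive number of years", call. = FALSE)
  }
  .check_demographics(demographics)
  rx <- .rx_ages_by_patient(incidences)
  death <- stats::setNames(demographics$death_age, demographics$patient_id)
  num <- den <- integer(length(ages))
  for (i in seq_along(ages)) {
    x <- ages[i]
    alive <- names(death)[death > x]
    den[i] <- length(alive)
    num[i] <- sum(vapply(alive, function(p) {
      a <- rx[[p]]
      !is.null(a) && any(a >= x & a < x + window)
    }, TRUE))
  }
  .curve_frame("transient", window, ages, num, den)
}

#' Benefit-of-testing curves over a lifetime
#'
#' Computes the empirical survival curve and the three benefit-of-testing
#' curve families (fixed cohort, living population, transient population at
#' each follow-up window) on a common age grid, and returns them as a single
#' classed object with print/summary/plot methods.
#'
#' @inheritParams benefit_fixed
#' @param windows follow-up windows (years) for the transient model.
#' @return object of class \code{lifetime_benefit}: list with \code{curves}
#'   (long data frame over all models), \code{survival}, \code{n},
#'   \code{ages}, \code{windows}.
#' @examples
#' demo <- data.frame(patient_id = c("P1", "P2", "P3"),
#'                    death_age = c(80, 55, 90))
#' inc <- data.frame(patient_id = c("P1", "P1", "P2"),
#'                   drug = c("a", "b", "c"),
#'                   gene = c("G1", "G1", "G2"),
#'                   age_at_rx = c(40, 60, 50))
#' fit <- lifetime_benefit(inc, demo, ages = 0:100)
#' summary(fit)
#' @export
lifetime_benefit <- function(incidences, demographics, ages = 0:100,
                             windows = c(1, 3, 10), N = nrow(demographics)) {
  .check_demographics(demographics)
  curves <- rbind(
    benefit_fixed(incidences, demographics, N = N, ages = ages),
    benefit_living(incidences, demographics, ages = ages)
  )
  for (w in sort(windows)) {
    curves <- rbind(curves,
                    benefit_transient(incidences, demographics, ages, w))
  }
  structure(list(
    curves = curves,
    survival = survival_curve(demographics, ages),
    n = N, ages = ages, windows = sort(windows)
  ), class = "lifetime_benefit")
}

#' @export
print.lifetime_benefit <- function(x, ...) {
  cat("Lifetime benefit-of-testing curves\n")
  cat("  cohort size:", x$n, "| age grid:", min(x$ages), "-", max(x$ages),
      "| transient windows:", paste(x$windows, collapse = ", "), "years\n")
  f0 <- x$curves$fraction[x$curves$model == "fixed_cohort" &
                            x$curves$age == min(x$ages)]
  cat(sprintf("  lifetime impacted fraction (fixed model at age %d): %.3f\n",
              min(x$ages), f0))
  invisible(x)
}

#' @export
summary.lifetime_benefit <- function(object, ...) {
  cv <- object$curves
  lab <- ifelse(is.na(cv$window), cv$model,
                paste0(cv$model, "_", cv$window, "y"))
  out <- do.call(rbind, lapply(split(cv, lab), function(d) {
    ok <- !is.na(d$fraction)
    data.frame(model = d$model[1], window = d$window[1],
               peak_fraction = max(d$fraction[ok]),
               peak_age = d$age[ok][which.max(d$fraction[ok])],
               fraction_at_min_age = d$fraction[which.min(d$age)])
  }))
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.lifetime_benefit <- function(x, ...) x$curves

#' @export
plot.lifetime_benefit <- function(x, ...) {
  cv <- x$curves
  graphics::plot(NA, xlim = range(x$ages), ylim = c(0, 1),
                 xlab = "Candidate testing age (years)",
                 ylab = "Fraction who may benefit", ...)
  graphics::lines(x$survival$age, x$survival$fraction, col = "grey50",
                  lty = 3)
  fx <- cv[cv$model == "fixed_cohort", ]
  graphics::lines(fx$age, fx$fraction, lty = 2)
  lv <- cv[cv$model == "living", ]
  graphics::lines(lv$age, lv$fraction, lty = 1)
  cols <- grDevices::hcl.colors(max(1L, length(x$windows)), "Dark 3")
  for (i in seq_along(x$windows)) {
    tr <- cv[cv$model == "transient" & cv$window == x$windows[i], ]
    graphics::lines(tr$age, tr$fraction, col = cols[i])
  }
  graphics::legend(
    "topright", bty = "n", cex = 0.8,
    legend = c("survival", "fixed cohort", "living",
               paste0("transient ", x$windows, "y")),
    lty = c(3, 2, 1, rep(1, length(x$windows))),
    col = c("grey50", "black", "black", cols)
  )
  invisible(x)
}

#' Write benefit curves to TSV
#'
#' @param x a \code{lifetime_benefit} object.
#' @param path output path.
#' @export
write_curves <- function(x, path) {
  stopifnot(inherits(x, "lifetime_benefit"))
  utils::write.table(x$curves, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
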