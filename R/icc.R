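# One-way random-effects intraclass correlation for test-retest designs.
# With two timepoints, ICC(1,1) = (BMS - WMS) / (BMS + WMS), where BMS and
# WMS are the between- and within-subject mean squares of a one-way ANOVA
# with k = 2 replicates per subject. Both sources of variability (between
# subjects, between scans within subject) are modelled as independent random
# effects.

icc_components <- function(x1, x2) {
  n <- length(x1)
  k <- 2
  m_i <- (x1 + x2) / 2
  grand <- mean(c(x1, x2))
  bms <- k * sum((m_i - grand)^2) / (n - 1)
  wms <- sum((x1 - m_i)^2 + (x2 - m_i)^2) / (n * (k - 1))
  list(bms = bms, wms = wms, n = n)
}

#' ICC(1,1) for paired test-retest measurements
#'
#' Estimates the one-way random-effects intraclass correlation from one
#' measurement pair per subject, with the F-based two-sided confidence
#' interval: with `F = BMS/WMS`,
#' `FL = F / qf(1 - alpha/2, n-1, n)`, `FU = F * qf(1 - alpha/2, n, n-1)`,
#' and each bound maps through `(F* - 1) / (F* + 1)` (the `k = 2` case).
#' Negative estimates are retained (the estimator's natural range is
#' `[-1, 1]`); truncating at zero would bias downstream rank analyses.
#' When all `2n` values are identical both mean squares vanish and the ICC
#' is undefined: the estimate is flagged missing.
#'
#' @param test,retest Numeric vectors of per-subject measurements at the two
#'   timepoints. Pairs with a missing value in either are dropped; at least
#'   two complete pairs are required.
#' @param alpha Two-sided significance level; the default 0.1 gives a 90%
#'   confidence interval.
#' @return An object of class `icc_fit` with fields `icc`, `bms`, `wms`,
#'   `ci_low`, `ci_high`, `alpha`, `n` (subjects used after pair deletion).
#'   Use [generics::tidy()] / [generics::glance()] for tibble output.
#' @examples
#' fit <- icc_1_1(c(1, 4, 7), c(2, 5, 9))
#' tidy(fit)
#' @export
icc_1_1 <- function(test, retest, alpha = 0.1) {
  stopifnot(length(test) == length(retest), alpha > 0, alpha < 1)
  ok <- is.finite(test) & is.finite(retest)
  x1 <- test[ok]
  x2 <- retest[ok]
  n <- length(x1)
  if (n < 2) stop("ICC needs at least 2 complete pairs", call. = FALSE)
  cmp <- icc_components(x1, x2)
  if (cmp$bms == 0 && cmp$wms == 0) {
    fit <- list(icc = NA_real_, bms = 0, wms = 0, ci_low = NA_real_,
                ci_high = NA_real_, alpha = alpha, n = n)
    return(structure(fit, class = "icc_fit"))
  }
  icc <- (cmp$bms - cmp$wms) / (cmp$bms + cmp$wms)
  if (cmp$wms == 0) {
    ci <- c(icc, icc)  # no within-subject variance: the interval degenerates
  } else {
    f <- cmp$bms / cmp$wms
    fl <- f / stats::qf(1 - alpha / 2, n - 1, n)
    fu <- f * stats::qf(1 - alpha / 2, n, n - 1)
    ci <- c((fl - 1) / (fl + 1), (fu - 1) / (fu + 1))
  }
  structure(
    list(icc = icc, bms = cmp$bms, wms = cmp$wms, ci_low = ci[1],
         ci_high = ci[2], alpha = alpha, n = n),
    class = "icc_fit"
  )
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %.4f  [%d%% CI %.4f, %.4f]  (n = %d, BMS = %.4g, WMS = %.4g)\n",
              x$icc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              x$n, x$bms, x$wms))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ICC fit
#'
#' @param x An `icc_fit` from [icc_1_1()].
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `conf.low`, `conf.high`, `bms`,
#'   `wms`, `n`.
#' @method tidy icc_fit
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(estimate = x$icc, conf.low = x$ci_low, conf.high = x$ci_high,
                 bms = x$bms, wms = x$wms, n = x$n)
}

#' @rdname tidy.icc_fit
#' @return `glance()`: one-row tibble with `icc`, `alpha`, `n`.
#' @method glance icc_fit
#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(icc = x$icc, alpha = x$alpha, n = x$n)
}

icc_key_cols <- c("roi", "image_type", "normalization", "filter",
                  "bin_width", "dim", "class", "feature")

#' Per-feature ICC table
#'
#' Computes one ICC(1,1) per feature key (`roi`, `image_type`,
#' `normalization`, `filter`, `bin_width`, `dim`, `class`, `feature`) from a
#' long feature table containing both timepoints. Subjects with a missing
#' value at either timepoint are dropped pairwise per key, and the retained
#' `n` is recorded. Keys where the ICC is undefined (all values identical, or
#' fewer than two complete pairs) get a missing estimate.
#'
#' @param features Feature table from [extract_cohort()] (long format, with
#'   `timepoint` in `c("test", "retest")`).
#' @param alpha Two-sided level for the confidence intervals (default 0.1).
#' @return Tibble with the key columns plus `n`, `icc`, `ci_low`, `ci_high`,
#'   `bms`, `wms`.
#' @export
icc_table <- function(features, alpha = 0.1) {
  stopifnot(all(c(icc_key_cols, "subject_id", "timepoint", "value") %in%
                  names(features)))
  wide <- tidyr::pivot_wider(features, names_from = "timepoint",
                             values_from = "value")
  if (!all(c("test", "retest") %in% names(wide))) {
    stop("feature table must contain both 'test' and 'retest' timepoints",
         call. = FALSE)
  }
  wide |>
    dplyr::group_by(dplyr::across(dplyr::all_of(icc_key_cols))) |>
    dplyr::summarise(
      {
        ok <- is.finite(.data$test) & is.finite(.data$retest)
        x1 <- .data$test[ok]
        x2 <- .data$retest[ok]
        if (length(x1) < 2) {
          tibble::tibble(n = length(x1), icc = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, bms = NA_real_, wms = NA_real_)
        } else {
          fit <- icc_1_1(x1, x2, alpha = alpha)
          tibble::tibble(n = fit$n, icc = fit$icc, ci_low = fit$ci_low,
                         ci_high = fit$ci_high, bms = fit$bms, wms = fit$wms)
        }
      },
      .groups = "drop"
    )
}
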