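# Plate-assay quantification: MTT viability, RBC hemolysis, autophagy
# activity, and interpolated IC50 from a dose-response curve.

#' Percent cell viability from MTT absorbances
#'
#' `100 * (A570_treated - A570_media) / (A570_untreated - A570_media)`:
#' background-corrected absorbance of treated wells relative to untreated.
#' Values outside \[0, 100\] are preserved (with a warning) rather than
#' clipped, so QC issues stay visible. The formula is invariant to adding a
#' constant to all three absorbances or scaling them by a positive factor.
#'
#' @param a570_treated,a570_untreated,a570_media Absorbance readings at
#'   570 nm (vectors recycle in the usual way).
#' @return Percent viability.
#' @examples
#' percent_viability(0.65, 1.05, 0.05)  # 60
#' @export
percent_viability <- function(a570_treated, a570_untreated, a570_media) {
  denom <- a570_untreated - a570_media
  if (any(denom == 0)) stop("untreated and media absorbances coincide (zero denominator)",
                            call. = FALSE)
  v <- 100 * (a570_treated - a570_media) / denom
  if (any(v < 0 | v > 100)) warning("viability outside [0, 100]% (reported as-is)",
                                    call. = FALSE)
  v
}

#' Percent hemolysis from 415 nm absorbances
#'
#' `100 * (A415_sample - A415_blank) / (A415_positive - A415_blank)`, where
#' the positive control is complete lysis (e.g. 1% Triton X-100) and the
#' blank is the untreated condition.
#'
#' @param a415_sample,a415_blank,a415_positive Absorbance readings at 415 nm.
#' @return Percent hemolysis (out-of-range values preserved with a warning).
#' @examples
#' percent_hemolysis(0.30, 0.10, 2.10)  # 10
#' @export
percent_hemolysis <- function(a415_sample, a415_blank, a415_positive) {
  denom <- a415_positive - a415_blank
  if (any(denom == 0)) stop("positive control equals blank (zero denominator)",
                            call. = FALSE)
  h <- 100 * (a415_sample - a415_blank) / denom
  if (any(h < 0 | h > 100)) warning("hemolysis outside [0, 100]% (reported as-is)",
                                    call. = FALSE)
  h
}

#' Autophagy activity fold-change
#'
#' Normalizes the autophagosome/autophagolysosome fluorescence signal
#' (ex480/em530) to the nuclear signal (ex340/em480) in each condition and
#' returns the treated/untreated ratio of those normalized signals.
#'
#' @param treated_autophagosome,treated_nuclear Fluorescence of the treated
#'   condition.
#' @param untreated_autophagosome,untreated_nuclear Fluorescence of the
#'   untreated (reference) condition.
#' @return Fold-change of autophagy activity relative to untreated.
#' @examples
#' autophagy_activity(0.30, 1, 0.20, 1)  # 1.5
#' @export
autophagy_activity <- function(treated_autophagosome, treated_nuclear,
                               untreated_autophagosome, untreated_nuclear) {
  if (any(treated_nuclear <= 0) || any(untreated_nuclear <= 0))
    stop("nuclear signals must be positive", call. = FALSE)
  ref <- untreated_autophagosome / untreated_nuclear
  if (any(ref == 0)) stop("untreated autophagosome signal is zero (undefined fold)",
                          call. = FALSE)
  (treated_autophagosome / treated_nuclear) / ref
}

#' Estimate IC50 by linear interpolation of a dose-response curve
#'
#' Replicate viabilities are averaged per dose first; the IC50 is the dose at
#' which the mean-viability curve first crosses 50%, linearly interpolated
#' between the bracketing doses (an exact 50% reading returns that dose).
#' No parametric (e.g. four-parameter logistic) model is fitted: the
#' interpolation is assumption-free and never extrapolates. If all means stay
#' above 50% the estimate is censored as "greater than the maximum tested
#' dose"; if all fall below, "less than the minimum tested dose".
#'
#' @param doses Numeric vector of concentrations (micromolar), at least two
#'   distinct values, strictly increasing after replicate aggregation.
#' @param viability Percent viability matched to `doses` (replicates allowed:
#'   repeat the dose value).
#' @return An object of class `"ic50_estimate"`: list with `value` (µM, `NA`
#'   when censored), `censored` (`"none"`, `"greater"`, `"less"`), `limit`
#'   (the censoring dose), and `method = "interpolation"`.
#' @examples
#' estimate_ic50(c(0, 100, 200, 400), c(100, 90, 60, 40))  # 300
#' @export
estimate_ic50 <- function(doses, viability) {
  stopifnot(is.numeric(doses), is.numeric(viability),
            length(doses) == length(viability))
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  means <- tapply(viability, doses, mean)
  d <- as.numeric(names(means))
  o <- order(d)
  d <- d[o]; m <- as.numeric(means)[o]
  if (length(d) < 2L) stop("need at least two distinct dose points", call. = FALSE)
  if (is.unsorted(d, strictly = TRUE)) stop("doses must be strictly increasing",
                                            call. = FALSE)

  res <- function(value, censored, limit) {
    structure(list(value = value, censored = censored, limit = limit,
                   method = "interpolation"), class = "ic50_estimate")
  }
  hit <- which(m == 50)
  if (length(hit)) return(res(d[hit[1L]], "none", NA_real_))
  cross <- which((m[-length(m)] - 50) * (m[-1L] - 50) < 0)
  if (length(cross)) {
    i <- cross[1L]
    value <- d[i] + (d[i + 1L] - d[i]) * (m[i] - 50) / (m[i] - m[i + 1L])
    return(res(value, "none", NA_real_))
  }
  if (all(m > 50)) return(res(NA_real_, "greater", max(d)))
  res(NA_real_, "less", min(d))
}

#' @export
print.ic50_estimate <- function(x, ...) {
  if (x$censored == "none") {
    cat(sprintf("IC50 = %.4g uM (linear interpolation)\n", x$value))
  } else {
    cat(sprintf("IC50 %s %.4g uM (censored at the tested range)\n",
                if (x$censored == "greater") ">" else "<", x$limit))
  }
  invisible(x)
}

#' Summarize replicate readings per condition
#'
#' Tidy mean, SD and n per condition, the reporting convention for plate
#' assays.
#'
#' @param readings Long-format data frame.
#' @param value Name of the numeric column (default `"absorbance"`).
#' @param group Name of the grouping column (default `"condition"`).
#' @return A data frame `(condition, mean, sd, n)`.
#' @export
summarize_replicates <- function(readings, value = "absorbance",
                                 group = "condition") {
  stopifnot(is.data.frame(readings), value %in% names(readings),
            group %in% names(readings))
  sp <- split(readings[[value]], readings[[group]])
  out <- data.frame(
    condition = names(sp),
    mean = vapply(sp, mean, numeric(1L)),
    sd = vapply(sp, sd, numeric(1L)),
    n = vapply(sp, length, integer(1L)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
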