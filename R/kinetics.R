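# R-squared without summary.lm (which warns on zero-residual fits)
rsq <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / sst
}

#' Fit a 4-methylumbelliferone calibration curve
#'
#' Least-squares line through (pmol MUB standard, fluorescence) pairs. The
#' fit converts raw fluorescence into picomoles of liberated MUB; a poor fit
#' (R-squared below `min_r2`) is an error because everything downstream is a
#' linear read-off of this curve.
#'
#' @param standards data.frame with columns `pmol` and `fluorescence` (>= 3
#'   rows spanning a non-zero range).
#' @param min_r2 R-squared gate, default 0.98.
#' @return An object of class `calibration_curve`: `slope`
#'   (fluorescence/pmol), `intercept`, `r_squared`, `n`.
#' @examples
#' fit_calibration(data.frame(pmol = 0:3, fluorescence = 2 * (0:3)))$slope # 2
#' @export
fit_calibration <- function(standards, min_r2 = 0.98) {
  if (!all(c("pmol", "fluorescence") %in% names(standards))) {
    stop("standards need columns 'pmol' and 'fluorescence'")
  }
  if (nrow(standards) < 3) stop("need >= 3 calibration standards")
  if (diff(range(standards$pmol)) <= 0) stop("degenerate standards: no pmol range")
  fit <- stats::lm(fluorescence ~ pmol, data = standards)
  r2 <- rsq(fit, standards$fluorescence)
  slope <- unname(stats::coef(fit)["pmol"])
  if (slope <= 0) stop("calibration slope must be positive")
  if (r2 < min_r2) {
    stop(sprintf("calibration R-squared %.4f below gate %.2f", r2, min_r2))
  }
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)["(Intercept)"]),
         r_squared = r2, n = nrow(standards)),
    class = "calibration_curve"
  )
}

#' An enzyme-assay time course
#'
#' @param time_h strictly increasing times in hours (>= 2 points).
#' @param fluorescence matching fluorescence readings.
#' @param enzyme label, e.g. `"GCase"`, `"NLGase"`, `"beta-gal"`.
#' @param condition `"none"`, `"CBE"` (lysosomal glucocerebrosidase
#'   inhibited) or `"AMP-DNM"` (non-lysosomal glucosylceramidase inhibited).
#' @param normalizer mg of cell protein (lysate assays) or millions of cells
#'   (live-cell assays); must be positive.
#' @param normalizer_unit `"mg"` or `"1e6cells"`.
#' @return An object of class `assay_record`.
#' @export
assay_record <- function(time_h, fluorescence, enzyme = "GCase",
                         condition = c("none", "CBE", "AMP-DNM"),
                         normalizer = 1, normalizer_unit = c("mg", "1e6cells")) {
  condition <- match.arg(condition)
  normalizer_unit <- match.arg(normalizer_unit)
  if (length(time_h) < 2) stop("need >= 2 time points")
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  if (length(fluorescence) != length(time_h)) stop("length mismatch")
  if (normalizer <= 0) stop("normalizer must be positive")
  structure(
    list(time_h = as.numeric(time_h), fluorescence = as.numeric(fluorescence),
         enzyme = enzyme, condition = condition,
         normalizer = normalizer, normalizer_unit = normalizer_unit),
    class = "assay_record"
  )
}

#' Enzyme activity from a fluorogenic time course
#'
#' Fluorescence is converted to pmol of product via the calibration curve;
#' the activity is the least-squares slope of pmol versus time divided by the
#' normalizer, i.e. pmol of product per hour per mg protein (or per 10^6
#' cells). With exactly two time points the slope degenerates to the
#' difference quotient. Negative slopes are clipped to zero with a warning;
#' a grossly saturating course (final pmol below half the maximum) triggers a
#' nonlinear-range warning.
#'
#' @param record an `assay_record`.
#' @param calib a `calibration_curve`.
#' @return An object of class `activity_result`: `activity`, `unit`,
#'   `r_squared` of the linear fit, `enzyme`, `condition`.
#' @examples
#' cal <- fit_calibration(data.frame(pmol = 0:3, fluorescence = 0:3))
#' rec <- assay_record(0:2, c(0, 10, 20))
#' compute_activity(rec, cal)$activity # 10
#' @export
compute_activity <- function(record, calib) {
  stopifnot(inherits(record, "assay_record"), inherits(calib, "calibration_curve"))
  pmol <- (record$fluorescence - calib$intercept) / calib$slope
  if (pmol[length(pmol)] < 0.5 * max(pmol) && max(pmol) > 0) {
    warning("nonlinear range: final product below 50% of maximum")
  }
  fit <- stats::lm(pmol ~ record$time_h)
  slope <- unname(stats::coef(fit)[2])
  r2 <- rsq(fit, pmol)
  if (slope < 0) {
    warning("negative product slope clipped to 0")
    slope <- 0
  }
  structure(
    list(
      activity = slope / record$normalizer,
      unit = paste0("pmol/h/",
                    if (record$normalizer_unit == "mg") "mg protein" else "10^6 cells"),
      r_squared = r2, enzyme = record$enzyme, condition = record$condition
    ),
    class = "activity_result"
  )
}

#' Resolve lysosomal vs non-lysosomal glucosylceramidase activity
#'
#' The two beta-glucosidases hydrolyse the same fluorogenic substrate
#' (MUB-beta-Glc) and are separated with inhibitors: CBE silences the
#' lysosomal enzyme (GCase), AMP-DNM silences the non-lysosomal enzyme
#' (NLGase). Hence GCase = activity measured with AMP-DNM, NLGase = activity
#' measured with CBE; their sum should reconstruct the uninhibited total.
#' `consistency` = |(GCase + NLGase) - total| / total, warned above
#' `max_inconsistency`.
#'
#' @param total,with_CBE,with_AMPDNM `activity_result`s (or bare numbers in
#'   the same unit) from the same substrate.
#' @param max_inconsistency warning threshold, default 0.2.
#' @return A list: `GCase`, `NLGase`, `consistency`.
#' @examples
#' resolve_glucosidases(100, 30, 70) # GCase 70, NLGase 30, consistency 0
#' @export
resolve_glucosidases <- function(total, with_CBE, with_AMPDNM,
                                 max_inconsistency = 0.2) {
  val <- function(x) if (inherits(x, "activity_result")) x$activity else as.numeric(x)
  tot <- val(total); cbe <- val(with_CBE); ampdnm <- val(with_AMPDNM)
  if (tot == 0 && (cbe > 0 || ampdnm > 0)) {
    stop("inconsistent input: zero total activity with non-zero inhibited conditions")
  }
  consistency <- if (tot > 0) abs((ampdnm + cbe) - tot) / tot else 0
  if (consistency > max_inconsistency) {
    warning(sprintf("inhibitor-resolved activities differ from total by %.0f%%",
                    100 * consistency))
  }
  list(GCase = ampdnm, NLGase = cbe, consistency = consistency)
}

#' Read a kinetics CSV
#'
#' Columns: `time_h`, `fluorescence`, optionally `condition`, `enzyme`,
#' `normalizer`, `normalizer_unit` (constant within a file). One record per
#' (enzyme, condition) combination is returned.
#'
#' @param path CSV file.
#' @return A list of `assay_record`.
#' @export
read_kinetics_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("time_h", "fluorescence") %in% names(tab))) {
    stop("kinetics CSV needs columns 'time_h' and 'fluorescence'")
  }
  if (!"condition" %in% names(tab)) tab$condition <- "none"
  if (!"enzyme" %in% names(tab)) tab$enzyme <- "GCase"
  key <- interaction(tab$enzyme, tab$condition, drop = TRUE)
  lapply(split(tab, key), function(g) {
    g <- g[order(g$time_h), ]
    assay_record(
      g$time_h, g$fluorescence, enzyme = g$enzyme[1], condition = g$condition[1],
      normalizer = if ("normalizer" %in% names(g)) g$normalizer[1] else 1,
      normalizer_unit = if ("normalizer_unit" %in% names(g)) g$normalizer_unit[1] else "mg"
    )
  })
}
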