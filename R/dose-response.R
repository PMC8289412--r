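#' Sweep agent doses and summarise plasmid topology
#'
#' Runs [batch_simulate()] at each dose (converted to density via the
#' calibration) and tabulates the topology fractions. Two read-outs of the
#' DSB signal are reported as percentages:
#'
#' * `linear_fraction`: `100 * linear / (linear + oc)` — the gel convention
#'   in which covalently closed molecules are excluded from the
#'   denominator (defined as 0 when no molecule is open or linear);
#' * `linear_of_total_pct`: `100 * linear / n` — the fraction of molecules
#'   carrying a DSB, the quantity that obeys the quadratic law exactly in
#'   the rare-event regime.
#'
#' The two coincide when nearly all molecules are relaxed (the regime of
#' the gel experiments) and diverge at low dose where the simulator leaves
#' an appreciable ccc fraction.
#'
#' @param doses_mM numeric vector of doses (mM), at least one.
#' @inheritParams batch_simulate
#' @param cal a [dose_calibration()].
#' @return a data.frame of class `dose_response_points` with columns
#'   dose_mM, nalkyl_density, n, ccc_fraction, oc_fraction,
#'   linear_fraction, se_linear, linear_of_total_pct, se_linear_total.
#' @export
sweep_doses <- function(doses_mM, plasmid, spectrum, params, n, seed = NULL,
                        cal = dose_calibration(),
                        method = c("vectorized", "molecule")) {
  if (!length(doses_mM)) stop_bad("doses_mM must contain at least one dose")
  check_number(n, "n", lower = 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(doses_mM, function(dose) {
    d <- dose_to_density(dose, cal)
    b <- batch_simulate(plasmid, d, spectrum, params, n,
                        method = method, keep_molecules = FALSE)
    m_open <- b$counts[["linear"]] + b$counts[["oc"]]
    p_open <- if (m_open > 0) b$counts[["linear"]] / m_open else 0
    data.frame(
      dose_mM = dose, nalkyl_density = d, n = b$n,
      ccc_fraction = b$fractions[["ccc"]], oc_fraction = b$fractions[["oc"]],
      linear_fraction = 100 * p_open,
      se_linear = if (m_open > 0)
        100 * sqrt(p_open * (1 - p_open) / m_open) else NA_real_,
      linear_of_total_pct = 100 * b$fractions[["linear"]],
      se_linear_total = 100 * b$se[["linear"]])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dose_response_points", "data.frame")
  out
}

#' Fit the linear fraction against the squared dose
#'
#' Ordinary least squares of the percent linear fraction on `dose^2` (mM^2),
#' the representation in which a two-hit mechanism gives a straight line.
#' Unweighted by default, matching the conventional three-point fit;
#' inverse-variance weights from `se_linear` are available.
#'
#' @param points a [sweep_doses()] result, or any data.frame with columns
#'   `dose_mM` and the chosen `measure`.
#' @param weighted use inverse-variance weights from `se_linear`.
#' @param measure column to fit (default `"linear_fraction"`).
#' @return list of class `quadratic_fit` with slope (% per mM^2),
#'   intercept (%), r_squared.
#' @export
#' @examples
#' pts <- data.frame(dose_mM = c(0, 1, 2),
#'                   linear_fraction = 1.4173 * c(0, 1, 4) - 0.0288)
#' fit_linear_fraction_vs_dose_squared(pts)
fit_linear_fraction_vs_dose_squared <- function(points, weighted = FALSE,
                                                measure = "linear_fraction") {
  if (!is.data.frame(points) || !all(c("dose_mM", measure) %in% names(points)))
    stop_bad("points must contain columns dose_mM and ", measure)
  if (nrow(points) < 2) stop_bad("at least two points are required")
  x <- points$dose_mM^2
  y <- points[[measure]]
  if (var(x) == 0) stop_bad("zero variance in dose^2; cannot fit")
  w <- if (weighted) {
    if (!"se_linear" %in% names(points) || any(!is.finite(points$se_linear)) ||
        any(points$se_linear <= 0))
      stop_bad("weighted fit requires finite positive se_linear")
    1 / points$se_linear^2
  } else NULL
  fit <- lm(y ~ x, weights = w)
  # suppress the "essentially perfect fit" note on noiseless input
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2),
            class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("<quadratic_fit> y = %.4f x %s %.4f (x = dose^2), R^2 = %.4f\n",
              x$slope, if (x$intercept < 0) "-" else "+", abs(x$intercept),
              x$r_squared))
  invisible(x)
}

#' Fold change of the linear fraction between two doses
#'
#' @param point_low,point_high single rows of a [sweep_doses()] result.
#' @param measure which percentage to ratio: `"linear_fraction"` (gel
#'   convention, default) or `"linear_of_total_pct"`.
#' @return list with `fold` and propagated standard error `se`.
#' @export
fold_change <- function(point_low, point_high, measure = "linear_fraction") {
  se_col <- if (measure == "linear_fraction") "se_linear" else
    "se_linear_total"
  for (p in list(point_low, point_high))
    if (!is.data.frame(p) || nrow(p) != 1 || !measure %in% names(p))
      stop_bad("points must be single rows containing ", measure)
  lo <- point_low[[measure]]; hi <- point_high[[measure]]
  if (lo <= 0) stop_bad("low-dose linear fraction is zero; fold undefined")
  fold <- hi / lo
  se <- NA_real_
  if (all(c(se_col) %in% names(point_low)) && se_col %in% names(point_high)) {
    slo <- point_low[[se_col]]; shi <- point_high[[se_col]]
    if (is.finite(slo) && is.finite(shi) && hi > 0)
      se <- fold * sqrt((slo / lo)^2 + (shi / hi)^2)
  }
  list(fold = fold, se = se)
}
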