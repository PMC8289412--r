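#' Closed-form expected linear (DSB-carrying) fraction
#'
#' Analytic twin of the Monte Carlo simulator for the rare-event regime.
#' The expected number of DSB-forming events per molecule is
#'
#' \deqn{E = E[\mathrm{O6mG}] \; p_\mathrm{engage,eff} \; p_\mathrm{gap}
#'        \left(1 - e^{-T d \, p_\mathrm{nick}}\right)}
#'
#' where `E[O6mG] = 2 L d / r` (`r` the N:O ratio of the spectrum), `T` the
#' excision track length, `d` the per-strand N-alkyl density and
#' `p_nick` the open-nick probability: an open gap of length `T` sees a
#' Poisson(`T d p_nick`) number of open nicks on the opposite strand. For
#' the exponential track model the bracket becomes `c T / (1 + c T)` with
#' `c = d p_nick`. The value is capped at 1, and carries the attribute
#' `rare_regime` (FALSE with a warning when the uncapped expectation
#' exceeds 0.2, where "expected events" stops approximating "fraction of
#' molecules broken").
#'
#' @inheritParams place_lesions
#' @param params a [repair_params()].
#' @return expected linear fraction (numeric scalar, attribute
#'   `rare_regime`).
#' @export
analytic_dsb_fraction <- function(plasmid, nalkyl_density, spectrum, params) {
  stopifnot(inherits(plasmid, "plasmid_spec"),
            inherits(spectrum, "adduct_spectrum"),
            inherits(params, "repair_params"))
  check_number(nalkyl_density, "nalkyl_density", lower = 0, upper = 0.5)
  d <- nalkyl_density
  e_o6 <- expected_counts(plasmid, d, spectrum)$o6mg
  p_eff <- effective_engagement(params, d)
  c_ <- d * params$p_nick_open
  tl <- params$track_length
  bracket <- switch(params$track_length_model,
                    fixed = 1 - exp(-tl * c_),
                    exponential = (tl * c_) / (1 + tl * c_))
  e <- e_o6 * p_eff * params$p_mmr_gap_open * bracket
  out <- min(e, 1)
  attr(out, "rare_regime") <- e <= 0.2
  if (e > 0.2)
    warning("expected DSB count per molecule exceeds 0.2; ",
            "outside the rare-event regime", call. = FALSE)
  out
}

# Effective MMR engagement probability at an O6mG:C site, marginalised over
# the presence of an N-alkyl adduct in the stimulation window (both strands
# of a window of `stimulation_window` nt centred on the site).
effective_engagement <- function(params, nalkyl_density) {
  if (!params$apply_stimulation) return(min(1, params$p_engage_base))
  p_near <- 1 - exp(-2 * params$stimulation_window * nalkyl_density)
  (1 - p_near) * min(1, params$p_engage_base) +
    p_near * min(1, params$p_engage_base * params$stimulation_factor)
}

#' Calibrate the open-nick probability to a target linear fraction
#'
#' Inverts [analytic_dsb_fraction()] for `p_nick_open` by bisection (the
#' fraction is monotone non-decreasing in `p_nick_open`).
#'
#' @param target_linear_fraction target fraction in `(0, 1)` (0 is allowed
#'   and returns 0).
#' @inheritParams analytic_dsb_fraction
#' @param params a [repair_params()]; its `p_nick_open` entry is ignored.
#' @param tol relative tolerance of the bisection.
#' @return the calibrated `p_nick_open`.
#' @export
#' @examples
#' calibrate_nick_availability(0.06, plasmid("pEL97"), 1 / 250,
#'                             spectrum_for_agent("MNU"), repair_params(p_nick_open = 0))
calibrate_nick_availability <- function(target_linear_fraction, plasmid,
                                        nalkyl_density, spectrum, params,
                                        tol = 1e-6) {
  check_number(target_linear_fraction, "target_linear_fraction", 0, 1)
  if (target_linear_fraction >= 1)
    stop_bad("target_linear_fraction must be < 1")
  if (target_linear_fraction == 0) return(0)
  f <- function(p) {
    params$p_nick_open <- p
    suppressWarnings(
      as.numeric(analytic_dsb_fraction(plasmid, nalkyl_density, spectrum,
                                       params)))
  }
  fmax <- f(1)
  if (target_linear_fraction > fmax)
    stop_bad("target linear fraction ", target_linear_fraction,
             " unreachable; maximum attainable with these parameters is ",
             format(fmax, digits = 6))
  lo <- 0; hi <- 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < target_linear_fraction) lo <- mid else hi <- mid
    if ((hi - lo) <= tol * max(hi, .Machine$double.eps)) break
  }
  (lo + hi) / 2
}
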