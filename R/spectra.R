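#' Adduct spectrum of an alkylating agent
#'
#' The spectrum gives the fraction of total alkyl adducts falling in each
#' class: 7mG (N7-methylguanine), 3mA (N3-methyladenine), O6mG
#' (O6-methylguanine) and a pooled "other" class (minor adducts such as
#' 1mA/3mC). Fractions must sum to 1. The derived N:O ratio,
#' `(frac_7mG + frac_3mA) / frac_O6mG`, is the number of BER-substrate
#' N-alkyl adducts per MMR-substrate O6mG; it is about 10 for MNU/TMZ-class
#' agents and > 250 for MMS.
#'
#' @param frac_7mG,frac_3mA,frac_O6mG,frac_other class fractions in `[0,1]`,
#'   summing to 1 within `1e-9`.
#' @param agent label for the agent (default `"custom"`).
#' @return an object of class `adduct_spectrum`.
#' @export
#' @examples
#' adduct_spectrum(0.725, 0.10, 0.085, 0.09, agent = "MNU")
adduct_spectrum <- function(frac_7mG, frac_3mA, frac_O6mG, frac_other,
                            agent = "custom") {
  for (nm in c("frac_7mG", "frac_3mA", "frac_O6mG", "frac_other"))
    check_number(get(nm), nm, lower = 0, upper = 1)
  s <- frac_7mG + frac_3mA + frac_O6mG + frac_other
  if (abs(s - 1) > 1e-9)
    stop_bad("adduct fractions must sum to 1 (got ", format(s, digits = 12), ")")
  structure(list(agent = agent, frac_7mG = frac_7mG, frac_3mA = frac_3mA,
                 frac_O6mG = frac_O6mG, frac_other = frac_other),
            class = "adduct_spectrum")
}

#' @export
print.adduct_spectrum <- function(x, ...) {
  cat(sprintf(paste0("<adduct_spectrum> %s: 7mG %.3f, 3mA %.3f, O6mG %.3f,",
                     " other %.3f (N:O ratio %.1f)\n"),
              x$agent, x$frac_7mG, x$frac_3mA, x$frac_O6mG, x$frac_other,
              no_ratio(x)))
  invisible(x)
}

#' N-alkyl to O-alkyl adduct ratio of a spectrum
#'
#' @param spectrum an [adduct_spectrum()].
#' @return `(frac_7mG + frac_3mA) / frac_O6mG` (Inf when `frac_O6mG` is 0).
#' @export
no_ratio <- function(spectrum) {
  stopifnot(inherits(spectrum, "adduct_spectrum"))
  (spectrum$frac_7mG + spectrum$frac_3mA) / spectrum$frac_O6mG
}

# Registered agent spectra. MNU: 7mG 70-75%, 3mA 8-12%, O6mG 8-9% of total
# adducts (midpoints); MMS: similar N-alkyl proportions but O6mG < 0.3%.
# ENU behaves like MNU in repair-synthesis assays and shares its spectrum.
.spectrum_registry <- function() {
  list(
    MNU = adduct_spectrum(0.725, 0.10, 0.085, 0.09, agent = "MNU"),
    MMS = adduct_spectrum(0.82, 0.105, 0.003, 0.072, agent = "MMS"),
    ENU = adduct_spectrum(0.725, 0.10, 0.085, 0.09, agent = "ENU")
  )
}

#' Look up the adduct spectrum of a registered agent
#'
#' Registered agents are `"MNU"`, `"MMS"` and `"ENU"` (ENU is modelled with
#' the MNU spectrum). Custom spectra can be built with [adduct_spectrum()].
#'
#' @param agent agent name.
#' @return an [adduct_spectrum()].
#' @export
#' @examples
#' spectrum_for_agent("MNU")$frac_O6mG # 0.085
spectrum_for_agent <- function(agent) {
  reg <- .spectrum_registry()
  if (!is.character(agent) || length(agent) != 1L || !agent %in% names(reg))
    stop_bad("unknown agent '", agent, "'; registered agents: ",
             paste(names(reg), collapse = ", "))
  reg[[agent]]
}

#' Dose-to-density calibration
#'
#' Lesion density is linear in dose. The default calibration anchors 1 mM of
#' agent to one N-alkyl adduct per 500 strand-nucleotides (density 0.002),
#' the level produced by the standard single-strength reaction; the
#' double-strength reaction (2 mM) then gives one adduct every 250 nt.
#'
#' @param density_per_mM N-alkyl adducts per strand-nucleotide per mM (> 0).
#' @return an object of class `dose_calibration`.
#' @export
dose_calibration <- function(density_per_mM = 1 / 500) {
  check_number(density_per_mM, "density_per_mM", lower = 0)
  if (density_per_mM <= 0) stop_bad("density_per_mM must be > 0")
  structure(list(density_per_mM = density_per_mM), class = "dose_calibration")
}

#' Convert an agent dose to an N-alkyl lesion density
#'
#' @param dose_mM dose in mM (>= 0).
#' @param cal a [dose_calibration()].
#' @return N-alkyl adducts per strand-nucleotide.
#' @export
#' @examples
#' dose_to_density(2) # 0.004, i.e. one adduct every 250 nt
dose_to_density <- function(dose_mM, cal = dose_calibration()) {
  stopifnot(inherits(cal, "dose_calibration"))
  if (!is.numeric(dose_mM) || any(is.na(dose_mM)) || any(dose_mM < 0))
    stop_bad("dose_mM must be non-negative")
  dose_mM * cal$density_per_mM
}
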