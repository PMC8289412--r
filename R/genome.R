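# Deterministic genome-scale extrapolation calculators. All arithmetic is
# exact; paper_round() gives the conventional 2-significant-figure print.
# Two genome sizes are carried deliberately: the lesion *density* estimate
# uses 6e9 nt (diploid strand-nucleotides), while the plasmid-to-genome DSB
# scaling uses 3e9 bp (haploid); the calculators reproduce that mixed usage
# rather than silently harmonising it (set both fields equal for a
# "consistent" mode).

#' Genome-wide alkylation lesion load
#'
#' Defaults correspond to a clinical 50 uM temozolomide dose: 5.2e4 O-alkyl
#' and 7.3e5 N-alkyl lesions per human genome, a 1000 nt excision window,
#' 6e9 nt used for density and 3e9 bp for DSB scaling.
#'
#' @param n_oalkyl O-alkyl (O6mG) lesions per genome.
#' @param n_nalkyl N-alkyl lesions per genome.
#' @param genome_nt_for_density genome size in strand-nucleotides used for
#'   the lesion-density calculation.
#' @param genome_bp_for_scaling genome size in bp used for plasmid-to-genome
#'   DSB scaling.
#' @param window_nt MMR excision window (nt) centred on an O6mG.
#' @return an object of class `genome_lesion_load`.
#' @export
genome_lesion_load <- function(n_oalkyl = 5.2e4, n_nalkyl = 7.3e5,
                               genome_nt_for_density = 6e9,
                               genome_bp_for_scaling = 3e9,
                               window_nt = 1000) {
  check_number(n_oalkyl, "n_oalkyl", 0, Inf)
  check_number(n_nalkyl, "n_nalkyl", 0, Inf)
  check_number(genome_nt_for_density, "genome_nt_for_density", 1, Inf)
  check_number(genome_bp_for_scaling, "genome_bp_for_scaling", 1, Inf)
  check_number(window_nt, "window_nt", 1, Inf)
  structure(list(n_oalkyl = n_oalkyl, n_nalkyl = n_nalkyl,
                 genome_nt_for_density = genome_nt_for_density,
                 genome_bp_for_scaling = genome_bp_for_scaling,
                 window_nt = window_nt),
            class = "genome_lesion_load")
}

#' At-risk lesion arrangements per genome
#'
#' A "lesion arrangement at-risk" is an O6mG with at least one N-alkyl
#' lesion inside its excision window. The probability that a given O6mG is
#' at risk is `window_nt * n_nalkyl / genome_nt_for_density` (a linear,
#' small-density approximation), and the expected at-risk count is
#' `n_oalkyl` times that probability.
#'
#' @param load a [genome_lesion_load()].
#' @return list with `at_risk_prob` and `at_risk_count`.
#' @export
#' @examples
#' at_risk(genome_lesion_load()) # prob 0.122, count 6327
at_risk <- function(load) {
  stopifnot(inherits(load, "genome_lesion_load"))
  prob <- load$window_nt * load$n_nalkyl / load$genome_nt_for_density
  if (prob > 1)
    stop_bad("window too large for density: at-risk probability ",
             format(prob, digits = 4), " exceeds 1")
  list(at_risk_prob = prob, at_risk_count = load$n_oalkyl * prob)
}

#' Scale a plasmid linear fraction to DSBs per genome
#'
#' @param linear_fraction fraction of plasmid molecules linearised, `[0,1]`.
#' @param plasmid_bp plasmid length (bp).
#' @param genome_bp genome size used for scaling (default haploid 3e9).
#' @return DSBs per genome, `genome_bp * linear_fraction / plasmid_bp`
#'   (exact; use [paper_round()] for the 2-significant-figure print).
#' @export
#' @examples
#' dsb_per_genome_from_plasmid(0.06, 11300) # 15929, prints as 16000
dsb_per_genome_from_plasmid <- function(linear_fraction, plasmid_bp,
                                        genome_bp = 3e9) {
  check_number(linear_fraction, "linear_fraction", 0, 1)
  check_number(plasmid_bp, "plasmid_bp", 1, Inf)
  check_number(genome_bp, "genome_bp", 1, Inf)
  genome_bp * linear_fraction / plasmid_bp
}

#' Quadratic dose scaling of a DSB estimate
#'
#' Under the two-hit mechanism the DSB yield scales with the square of the
#' dose: `dsb_ref * (dose_new / dose_ref)^2`.
#'
#' @param dsb_ref DSB count at the reference dose.
#' @param dose_ref_mM,dose_new_mM doses (> 0).
#' @return scaled DSB count.
#' @export
#' @examples
#' scale_dose_quadratic(16000, 2, 0.05) # 10
scale_dose_quadratic <- function(dsb_ref, dose_ref_mM, dose_new_mM) {
  check_number(dsb_ref, "dsb_ref", 0, Inf)
  check_number(dose_ref_mM, "dose_ref_mM", 0, Inf)
  check_number(dose_new_mM, "dose_new_mM", 0, Inf)
  if (dose_ref_mM <= 0 || dose_new_mM <= 0)
    stop_bad("doses must be > 0")
  dsb_ref * (dose_new_mM / dose_ref_mM)^2
}

#' Conversion rate of at-risk arrangements into DSBs
#'
#' @param dsb_count DSBs per genome.
#' @param at_risk_count at-risk arrangements per genome (> 0).
#' @return fraction `dsb_count / at_risk_count`.
#' @export
#' @examples
#' conversion_rate(10, 6240) # 0.0016, i.e. 0.16%
conversion_rate <- function(dsb_count, at_risk_count) {
  check_number(dsb_count, "dsb_count", 0, Inf)
  check_number(at_risk_count, "at_risk_count", 0, Inf)
  if (at_risk_count <= 0) stop_bad("at_risk_count must be > 0")
  dsb_count / at_risk_count
}

#' Repair patch sizes from UDS percentages
#'
#' Converts replication-equivalent UDS percentages into nucleotide patch
#' sizes. For the O6mG branch: total synthesis is
#' `uds_pct_o6mg / 100 * 2 * plasmid_bp` nt, the per-adduct patch divides by
#' `n_o6mg`, and the per-*engaged* patch further divides by
#' `engaged_fraction` (the fraction of O6mG sites actually processed by
#' MMR). The N-alkyl branch is analogous with no engagement correction.
#' Branches with `NULL` inputs are skipped (returned as `NA`).
#'
#' @param uds_pct_o6mg UDS attributable to O6mG:C repair, percent.
#' @param uds_pct_nalkyl UDS attributable to N-alkyl repair, percent.
#' @param plasmid_bp plasmid length (bp).
#' @param n_o6mg,n_nalkyl adduct counts per plasmid (> 0 where used).
#' @param engaged_fraction fraction of O6mG engaged by MMR, `(0, 1]`.
#' @return list of class `patch_size_estimate` with
#'   total_o6mg_synthesis_nt, per_o6mg_patch_nt, per_engaged_patch_nt,
#'   total_nalkyl_synthesis_nt, per_nalkyl_patch_nt.
#' @export
#' @examples
#' patch_size_estimates(uds_pct_o6mg = 3.1, plasmid_bp = 4363,
#'                      n_o6mg = 1.7, engaged_fraction = 0.30)
patch_size_estimates <- function(uds_pct_o6mg = NULL, uds_pct_nalkyl = NULL,
                                 plasmid_bp, n_o6mg = NULL, n_nalkyl = NULL,
                                 engaged_fraction = 1) {
  check_number(plasmid_bp, "plasmid_bp", 1, Inf)
  check_number(engaged_fraction, "engaged_fraction", 0, 1)
  if (engaged_fraction <= 0) stop_bad("engaged_fraction must be in (0, 1]")
  out <- list(total_o6mg_synthesis_nt = NA_real_,
              per_o6mg_patch_nt = NA_real_,
              per_engaged_patch_nt = NA_real_,
              total_nalkyl_synthesis_nt = NA_real_,
              per_nalkyl_patch_nt = NA_real_)
  if (!is.null(uds_pct_o6mg)) {
    check_number(uds_pct_o6mg, "uds_pct_o6mg", 0, Inf)
    if (is.null(n_o6mg) || n_o6mg <= 0)
      stop_bad("n_o6mg must be > 0 when uds_pct_o6mg is given")
    out$total_o6mg_synthesis_nt <- uds_pct_o6mg / 100 * 2 * plasmid_bp
    out$per_o6mg_patch_nt <- out$total_o6mg_synthesis_nt / n_o6mg
    out$per_engaged_patch_nt <- out$per_o6mg_patch_nt / engaged_fraction
  }
  if (!is.null(uds_pct_nalkyl)) {
    check_number(uds_pct_nalkyl, "uds_pct_nalkyl", 0, Inf)
    if (is.null(n_nalkyl) || n_nalkyl <= 0)
      stop_bad("n_nalkyl must be > 0 when uds_pct_nalkyl is given")
    out$total_nalkyl_synthesis_nt <- uds_pct_nalkyl / 100 * 2 * plasmid_bp
    out$per_nalkyl_patch_nt <- out$total_nalkyl_synthesis_nt / n_nalkyl
  }
  structure(out, class = "patch_size_estimate")
}

#' Stimulation factor from paired UDS increments
#'
#' Ratio of the O6mG-attributable UDS increment with N-alkyl co-damage to
#' the increment without it.
#'
#' @param delta_with_mms UDS increment (percent) with N-alkyl co-treatment.
#' @param delta_without_mms UDS increment (percent) without (> 0).
#' @return fold stimulation.
#' @export
#' @examples
#' stimulation_factor(1.85, 0.64) # about 2.9
stimulation_factor <- function(delta_with_mms, delta_without_mms) {
  check_number(delta_with_mms, "delta_with_mms", 0, Inf)
  check_number(delta_without_mms, "delta_without_mms", 0, Inf)
  if (delta_without_mms <= 0) stop_bad("delta_without_mms must be > 0")
  delta_with_mms / delta_without_mms
}

#' Full genome extrapolation chain
#'
#' Chains the calculators: at-risk probability and count from the lesion
#' load; DSBs per genome from the plasmid linear fraction at the reference
#' dose; quadratic scaling to a new (clinical) dose; and the conversion
#' rate of at-risk arrangements into DSBs at that dose.
#'
#' @param load a [genome_lesion_load()].
#' @param linear_fraction plasmid linear fraction at the reference dose.
#' @param plasmid_bp plasmid length (bp).
#' @param dose_ref_mM reference in-vitro dose (mM).
#' @param dose_new_mM target dose (mM); default 0.05 (clinical serum level).
#' @return list of class `genome_estimate` with exact values and a
#'   `rounded` twin at two significant figures.
#' @export
#' @examples
#' genome_estimate()
genome_estimate <- function(load = genome_lesion_load(),
                            linear_fraction = 0.06, plasmid_bp = 11300,
                            dose_ref_mM = 2, dose_new_mM = 0.05) {
  ar <- at_risk(load)
  dsb_ref <- dsb_per_genome_from_plasmid(linear_fraction, plasmid_bp,
                                         load$genome_bp_for_scaling)
  dsb_new <- scale_dose_quadratic(dsb_ref, dose_ref_mM, dose_new_mM)
  conv <- conversion_rate(dsb_new, ar$at_risk_count)
  exact <- list(at_risk_prob = ar$at_risk_prob,
                at_risk_count = ar$at_risk_count,
                dsb_ref_dose = dsb_ref, dsb_new_dose = dsb_new,
                conversion_rate = conv)
  structure(c(exact, list(rounded = lapply(exact, paper_round),
                          dose_ref_mM = dose_ref_mM,
                          dose_new_mM = dose_new_mM)),
            class = "genome_estimate")
}

#' @export
print.genome_estimate <- function(x, ...) {
  cat("<genome_estimate> (exact [2 significant figures])\n")
  cat(sprintf("  at-risk probability: %.4f [%g]\n",
              x$at_risk_prob, x$rounded$at_risk_prob))
  cat(sprintf("  at-risk arrangements/genome: %.1f [%g]\n",
              x$at_risk_count, x$rounded$at_risk_count))
  cat(sprintf("  DSBs/genome at %g mM: %.1f [%g]\n",
              x$dose_ref_mM, x$dsb_ref_dose, x$rounded$dsb_ref_dose))
  cat(sprintf("  DSBs/genome at %g mM: %.2f [%g]\n",
              x$dose_new_mM, x$dsb_new_dose, x$rounded$dsb_new_dose))
  cat(sprintf("  conversion rate: %.4f%% [%g%%]\n",
              100 * x$conversion_rate, 100 * x$rounded$conversion_rate))
  invisible(x)
}

#' Ionising-radiation reference constants
#'
#' Static reference values for context: a 2 Gy radiotherapy session induces
#' on the order of 2000 single-strand and 40 double-strand breaks per cell.
#' These are reported constants, not computed quantities.
#'
#' @return named numeric vector.
#' @export
ir_reference_constants <- function() {
  c(ssb_per_2Gy = 2000, dsb_per_2Gy = 40)
}
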