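#' Snapshot parameters of the two-pathway repair model
#'
#' The simulator does not follow repair kinetics in time. Instead it samples
#' one observation ("snapshot") of each molecule in which every potential
#' repair event is open with a stated probability, mirroring the end-point
#' gel states the model is read against:
#'
#' * every N-alkyl adduct (7mG/3mA) is a BER substrate; at the snapshot it
#'   carries an *open* nick with probability `p_nick_open` (nicks are
#'   transient, so this is small; the default is calibrated so that the
#'   6\% linear fraction anchor at the double-strength dose on the 11.3 kb
#'   plasmid is met, see [calibrate_nick_availability()]). Independently of
#'   nick state, every N-alkyl adduct contributes completed-BER synthesis:
#'   a 1 nt short patch, or with probability `ber_long_patch_fraction` a
#'   long patch of mean `ber_long_patch_mean` nt (support 2-8 nt).
#' * every O6mG:C site engages MMR with probability `p_engage_base`. The
#'   default 0.30 is the engagement measured in the presence of N-alkyl
#'   co-damage, so by default no further stimulation is applied
#'   (`apply_stimulation = FALSE`). When modelling the reconstitution
#'   scenario (a single O6mG with or without MMS co-treatment), set
#'   `apply_stimulation = TRUE` with an unstimulated `p_engage_base`; the
#'   engagement is then multiplied by `stimulation_factor` (capped at 1)
#'   whenever at least one N-alkyl adduct lies within
#'   `stimulation_window / 2` nt on either side of the O6mG.
#' * an engaged MMR event excises a track of `track_length` nt (fixed, or
#'   exponential with that mean) on a uniformly chosen strand, positioned
#'   per `track_placement`: `"uniform_cover"` places the track uniformly
#'   among intervals covering the O6mG (noncanonical MMR lacks
#'   directionality), `"centered"` centres it on the site. At the snapshot
#'   the track is an open single-stranded gap with probability
#'   `p_mmr_gap_open`; it always contributes `track_length` nt of synthesis
#'   on completion.
#'
#' A DSB is called when an open MMR gap spans an open BER nick on the
#' opposite strand (see [detect_dsb()]); optionally two opposite-strand
#' nicks closer than `nick_nick_dsb_threshold` also call a DSB (disabled by
#' default).
#'
#' @param p_engage_base probability an O6mG:C site initiates MMR.
#' @param stimulation_factor fold-increase of engagement by nearby N-alkyl
#'   processing (>= 1); used only when `apply_stimulation` is TRUE.
#' @param apply_stimulation apply the stimulation pathway (reconstitution
#'   scenario) rather than folding it into `p_engage_base`.
#' @param stimulation_window full width (nt) of the stimulation window
#'   centred on the O6mG.
#' @param track_length MMR excision track length (nt).
#' @param track_length_model `"fixed"` or `"exponential"`.
#' @param track_placement `"uniform_cover"` or `"centered"`.
#' @param p_nick_open probability an N-alkyl site carries an open BER nick
#'   at the snapshot. The default `NULL` resolves to the calibrated value
#'   (see Details).
#' @param p_mmr_gap_open probability an engaged MMR track is an open gap at
#'   the snapshot.
#' @param ber_long_patch_fraction fraction of BER events with a long patch.
#' @param ber_long_patch_mean mean long-patch size (nt), in `[2, 8]`.
#' @param nick_nick_dsb_threshold distance (nt) under which two open nicks
#'   on opposite strands directly call a DSB; 0 disables.
#' @return an object of class `repair_params`.
#' @export
#' @examples
#' repair_params()$p_nick_open # calibrated, about 0.0145
repair_params <- function(p_engage_base = 0.30,
                          stimulation_factor = 2.9,
                          apply_stimulation = FALSE,
                          stimulation_window = 1000,
                          track_length = 500,
                          track_length_model = c("fixed", "exponential"),
                          track_placement = c("uniform_cover", "centered"),
                          p_nick_open = NULL,
                          p_mmr_gap_open = 0.75,
                          ber_long_patch_fraction = 0.4,
                          ber_long_patch_mean = 5,
                          nick_nick_dsb_threshold = 0) {
  track_length_model <- match.arg(track_length_model)
  track_placement <- match.arg(track_placement)
  check_number(p_engage_base, "p_engage_base", 0, 1)
  check_number(stimulation_factor, "stimulation_factor", 1, Inf)
  check_flag(apply_stimulation, "apply_stimulation")
  check_number(stimulation_window, "stimulation_window", 1, Inf)
  check_number(track_length, "track_length", 1, Inf)
  check_number(p_mmr_gap_open, "p_mmr_gap_open", 0, 1)
  check_number(ber_long_patch_fraction, "ber_long_patch_fraction", 0, 1)
  check_number(ber_long_patch_mean, "ber_long_patch_mean", 2, 8)
  check_number(nick_nick_dsb_threshold, "nick_nick_dsb_threshold", 0, Inf)
  p <- structure(list(p_engage_base = p_engage_base,
                      stimulation_factor = stimulation_factor,
                      apply_stimulation = apply_stimulation,
                      stimulation_window = stimulation_window,
                      track_length = track_length,
                      track_length_model = track_length_model,
                      track_placement = track_placement,
                      p_nick_open = NA_real_,
                      p_mmr_gap_open = p_mmr_gap_open,
                      ber_long_patch_fraction = ber_long_patch_fraction,
                      ber_long_patch_mean = ber_long_patch_mean,
                      nick_nick_dsb_threshold = nick_nick_dsb_threshold),
                 class = "repair_params")
  if (is.null(p_nick_open)) {
    p$p_nick_open <- default_p_nick_open(p)
  } else {
    check_number(p_nick_open, "p_nick_open", 0, 1)
    p$p_nick_open <- p_nick_open
  }
  p
}

# The canonical anchor: at the double-strength dose (one N-alkyl adduct per
# 250 nt) the 11.3 kb plasmid shows ~6% linear molecules. p_nick_open is the
# value that makes the analytic DSB fraction hit that anchor with all other
# parameters at their defaults.
default_p_nick_open <- function(params) {
  calibrate_nick_availability(0.06, plasmid("pEL97"), 1 / 250,
                              spectrum_for_agent("MNU"), params)
}

#' @export
print.repair_params <- function(x, ...) {
  cat("<repair_params>\n")
  cat(sprintf("  MMR: engage %.3f%s, track %s %g nt (%s), gap open %.2f\n",
              x$p_engage_base,
              if (x$apply_stimulation)
                sprintf(" (x%.1f near N-alkyl, window %g nt)",
                        x$stimulation_factor, x$stimulation_window) else "",
              x$track_length_model, x$track_length, x$track_placement,
              x$p_mmr_gap_open))
  cat(sprintf("  BER: nick open %.4f, long patch %.2f (mean %g nt)\n",
              x$p_nick_open, x$ber_long_patch_fraction, x$ber_long_patch_mean))
  if (x$nick_nick_dsb_threshold > 0)
    cat(sprintf("  nick-nick DSB threshold: %g nt\n",
                x$nick_nick_dsb_threshold))
  invisible(x)
}
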