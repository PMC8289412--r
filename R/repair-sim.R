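# Single-molecule Monte Carlo of the two-pathway snapshot model.

draw_long_patch <- function(n, mean_nt) {
  # support {2,...,8}, mean = mean_nt: 2 + Binomial(6, (mean-2)/6)
  2L + rbinom(n, 6L, (mean_nt - 2) / 6)
}

draw_track_length <- function(n, params, length_bp) {
  len <- switch(params$track_length_model,
                fixed = rep(as.integer(round(params$track_length)), n),
                exponential = pmax(1L, as.integer(round(
                  rexp(n, rate = 1 / params$track_length)))))
  pmin(len, length_bp)
}

#' Simulate one snapshot of repair on a single molecule
#'
#' Samples the repair events active on one molecule under the snapshot model
#' described in [repair_params()], detects DSBs ([detect_dsb()]) and
#' classifies the resulting topology ([classify_topology()]).
#'
#' @param map a [lesion_map()].
#' @param params a [repair_params()].
#' @param seed optional integer seed.
#' @return a list with `events` (class `repair_event_set`: data.frame with
#'   kind, strand, start, length, open, synthesis_nt, origin_lesion, plus
#'   attribute `length_bp`) and `outcome` (class `plasmid_outcome`: list
#'   with topology, dsb_count, open_nicks_top/bottom, open_gaps,
#'   synthesized_nt, o6mg_attributed_nt, labeled_nt).
#' @export
simulate_repair <- function(map, params, seed = NULL) {
  stopifnot(inherits(map, "lesion_map"), inherits(params, "repair_params"))
  if (!is.null(seed)) set.seed(seed)
  plas <- attr(map, "plasmid")
  L <- plas$length_bp

  nal_idx <- which(map$adduct_class %in% .nalkyl_classes)
  o6_idx <- which(map$adduct_class == "O6mG")

  kind <- character(); strand <- character(); start <- integer()
  len <- integer(); open <- logical(); synth <- integer(); origin <- integer()

  # BER at N-alkyl adducts: transient nick geometry + completed-patch
  # synthesis accounting.
  if (length(nal_idx)) {
    n <- length(nal_idx)
    is_open <- runif(n) < params$p_nick_open
    is_long <- runif(n) < params$ber_long_patch_fraction
    patch <- ifelse(is_long, draw_long_patch(n, params$ber_long_patch_mean), 1L)
    kind <- c(kind, rep("BER_nick", n))
    strand <- c(strand, map$strand[nal_idx])
    start <- c(start, map$position[nal_idx])
    len <- c(len, ifelse(is_open, 0L, as.integer(patch)))
    open <- c(open, is_open)
    synth <- c(synth, as.integer(patch))
    origin <- c(origin, nal_idx)
  }

  # MMR at O6mG:C sites.
  if (length(o6_idx)) {
    for (i in o6_idx) {
      p_eng <- min(1, params$p_engage_base)
      if (params$apply_stimulation) {
        near <- length(nal_idx) > 0 &&
          any(circ_dist(map$position[nal_idx], map$position[i], L) <=
                params$stimulation_window / 2)
        if (near)
          p_eng <- min(1, params$p_engage_base * params$stimulation_factor)
      }
      if (runif(1) >= p_eng) next
      tl <- draw_track_length(1L, params, L)
      off <- switch(params$track_placement,
                    uniform_cover = sample.int(tl, 1L) - 1L,
                    centered = tl %/% 2L)
      kind <- c(kind, "MMR_gap")
      strand <- c(strand, sample(.strands, 1L))
      start <- c(start, (map$position[i] - off) %% L)
      len <- c(len, tl)
      open <- c(open, runif(1) < params$p_mmr_gap_open)
      synth <- c(synth, tl)
      origin <- c(origin, i)
    }
  }

  events <- data.frame(kind = kind, strand = strand, start = start,
                       length = len, open = open, synthesis_nt = synth,
                       origin_lesion = origin, stringsAsFactors = FALSE)
  attr(events, "length_bp") <- L
  class(events) <- c("repair_event_set", "data.frame")

  dsb <- detect_dsb(events, params)
  is_ber <- events$kind == "BER_nick"
  open_top <- sum(is_ber & events$open & events$strand == "top")
  open_bottom <- sum(is_ber & events$open & events$strand == "bottom")
  open_gaps <- sum(!is_ber & events$open)
  synth_total <- sum(events$synthesis_nt)
  o6_nt <- sum(events$synthesis_nt[!is_ber])
  # label-specific accounting: 1 nt patches at 7mG do not incorporate dATP
  short_7mg <- is_ber & events$synthesis_nt == 1L &
    map$adduct_class[events$origin_lesion] == "7mG"
  labeled <- synth_total - sum(events$synthesis_nt[short_7mg])

  outcome <- structure(
    list(topology = classify_topology(dsb$count,
                                      open_top + open_bottom + open_gaps),
         dsb_count = dsb$count,
         open_nicks_top = open_top, open_nicks_bottom = open_bottom,
         open_gaps = open_gaps,
         synthesized_nt = synth_total, o6mg_attributed_nt = o6_nt,
         labeled_nt = labeled),
    class = "plasmid_outcome")
  list(events = events, outcome = outcome)
}

#' Detect double-strand breaks in a set of repair events
#'
#' A DSB is called once for each open MMR gap whose circular interval
#' contains at least one open BER nick on the opposite strand, regardless of
#' nick multiplicity. When `params$nick_nick_dsb_threshold > 0`, every pair
#' of open nicks on opposite strands within that circular distance also
#' calls one DSB (disabled by default).
#'
#' @param events a `repair_event_set` from [simulate_repair()].
#' @param params a [repair_params()].
#' @param length_bp plasmid length; defaults to the event set's attribute.
#' @return list with `count` and `gap_hit` (logical per open gap).
#' @export
detect_dsb <- function(events, params, length_bp = attr(events, "length_bp")) {
  stopifnot(is.data.frame(events))
  if (is.null(length_bp)) stop_bad("length_bp is required")
  nicks <- events[events$kind == "BER_nick" & events$open, , drop = FALSE]
  gaps <- events[events$kind == "MMR_gap" & events$open, , drop = FALSE]
  gap_hit <- logical(nrow(gaps))
  if (nrow(gaps) && nrow(nicks)) {
    for (g in seq_len(nrow(gaps))) {
      opp <- nicks$strand != gaps$strand[g]
      gap_hit[g] <- any(circ_contains(gaps$start[g], gaps$length[g],
                                      nicks$start[opp], length_bp))
    }
  }
  count <- sum(gap_hit)
  thr <- params$nick_nick_dsb_threshold
  if (thr > 0 && nrow(nicks) > 1) {
    top <- nicks$start[nicks$strand == "top"]
    bot <- nicks$start[nicks$strand == "bottom"]
    if (length(top) && length(bot))
      count <- count + sum(outer(top, bot, function(a, b)
        circ_dist(a, b, length_bp) <= thr))
  }
  list(count = as.integer(count), gap_hit = gap_hit)
}

#' Classify plasmid topology from the snapshot state
#'
#' `"linear"` if at least one DSB; otherwise `"oc"` (open circular) if at
#' least one open nick or gap; otherwise `"ccc"` (covalently closed
#' circular).
#'
#' @param dsb_count number of DSBs.
#' @param n_open number of open nicks plus open gaps.
#' @return one of `"ccc"`, `"oc"`, `"linear"`.
#' @export
classify_topology <- function(dsb_count, n_open) {
  check_number(dsb_count, "dsb_count", 0, Inf)
  check_number(n_open, "n_open", 0, Inf)
  if (dsb_count >= 1) "linear" else if (n_open >= 1) "oc" else "ccc"
}

#' Repair synthesis (UDS) as percent of a replication round
#'
#' A full replication of an `L` bp plasmid synthesises `2 L` nt, so the UDS
#' read-out is `100 * mean(synthesized_nt) / (2 L)`. Mode
#' `"label_specific"` uses the `labeled_nt` tally, which excludes 1 nt
#' patches at 7mG (a dATP label only marks patches containing at least one
#' A, i.e. long patches and 3mA short patches).
#'
#' @param outcomes a list of `plasmid_outcome` objects, or the per-molecule
#'   data.frame from [batch_simulate()].
#' @param plasmid the [plasmid_spec()] the outcomes came from.
#' @param mode `"all"` (default) or `"label_specific"`.
#' @return percent of input-plasmid replication equivalent.
#' @export
uds_signal <- function(outcomes, plasmid, mode = c("all", "label_specific")) {
  mode <- match.arg(mode)
  stopifnot(inherits(plasmid, "plasmid_spec"))
  field <- if (mode == "all") "synthesized_nt" else "labeled_nt"
  if (is.data.frame(outcomes)) {
    if (!nrow(outcomes)) stop_bad("empty batch")
    synth <- outcomes[[field]]
  } else {
    if (!length(outcomes)) stop_bad("empty batch")
    synth <- vapply(outcomes, function(o) as.numeric(o[[field]]), numeric(1))
  }
  100 * mean(synth) / (2 * plasmid$length_bp)
}

#' Apportion repair synthesis to restriction fragments
#'
#' Cuts the circle at `cut_positions` and distributes each event's synthesis
#' across the resulting fragments pro rata of interval overlap; pure nicks
#' (length 0) count as 1 nt at their position. The specific activity of a
#' fragment is its signal divided by its length, mirroring the
#' radioactivity-per-ethidium quantification of restriction digests.
#'
#' @param events a `repair_event_set`.
#' @param cut_positions at least two distinct 0-based cut positions.
#' @param length_bp plasmid length; defaults to the event set's attribute.
#' @return data.frame with start, length, signal, specific_activity.
#' @export
fragment_specific_activity <- function(events, cut_positions,
                                       length_bp = attr(events, "length_bp")) {
  stopifnot(is.data.frame(events))
  if (is.null(length_bp)) stop_bad("length_bp is required")
  if (length(cut_positions) < 2)
    stop_bad("at least two cut positions are required")
  if (anyDuplicated(cut_positions))
    stop_bad("duplicate cut positions")
  if (any(cut_positions < 0 | cut_positions >= length_bp))
    stop_bad("cut positions must lie in [0, length_bp)")
  cuts <- sort(as.integer(cut_positions))
  k <- length(cuts)
  frag_start <- cuts
  frag_len <- as.integer(diff(c(cuts, cuts[1] + length_bp)))
  signal <- numeric(k)
  for (e in seq_len(nrow(events))) {
    elen <- max(events$length[e], 1L)
    for (f in seq_len(k)) {
      ov <- circ_overlap_len(events$start[e], elen, frag_start[f],
                             frag_len[f], length_bp)
      if (ov > 0)
        signal[f] <- signal[f] + events$synthesis_nt[e] * ov / elen
    }
  }
  data.frame(start = frag_start, length = frag_len, signal = signal,
             specific_activity = signal / frag_len)
}
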