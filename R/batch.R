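# Batch simulation. The default "vectorized" method samples, for each of n
# molecules, the same distributions as place_lesions() + simulate_repair()
# but draws per-molecule event *counts* first and positions only for the
# handful of geometric events (open nicks, open gaps), which keeps 1e5-1e6
# molecule batches tractable in pure R. Position collisions between the few
# geometric events of one molecule are neglected (probability O(k^2 / 2L)).
# method = "molecule" runs the literal per-molecule composition.

utils::globalVariables(c("mol", "gid", "nstr", "gstr", "npos", "gstart",
                         "glen", "hit", "a", "b", "N"))

#' Simulate a batch of molecules and summarise topology and synthesis
#'
#' @inheritParams place_lesions
#' @param params a [repair_params()].
#' @param n number of molecules (>= 1).
#' @param seed optional integer seed.
#' @param method `"vectorized"` (default) or `"molecule"`; the two are
#'   distributionally identical. `apply_stimulation = TRUE` requires all
#'   lesion positions per molecule and always uses the molecule path.
#' @param keep_molecules keep the per-molecule outcome table.
#' @return an object of class `batch_summary`: list with `n`, `fractions`
#'   (named ccc/oc/linear, summing to 1), `se` (binomial standard errors),
#'   `mean_dsb`, `mean_synthesized_nt`, `uds_percent_replication`,
#'   `linear_of_open` (linear / (linear + oc), NA if no open or linear
#'   molecules) and, when `keep_molecules`, a data.frame `molecules`.
#' @export
#' @examples
#' batch_simulate(plasmid("pBR322"), 1 / 500, spectrum_for_agent("MNU"),
#'                repair_params(), n = 100, seed = 1)
batch_simulate <- function(plasmid, nalkyl_density, spectrum, params, n,
                           seed = NULL,
                           method = c("vectorized", "molecule"),
                           keep_molecules = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(plasmid, "plasmid_spec"),
            inherits(spectrum, "adduct_spectrum"),
            inherits(params, "repair_params"))
  check_number(n, "n", lower = 1)
  n <- as.integer(n)
  check_number(nalkyl_density, "nalkyl_density", lower = 0, upper = 0.5)
  if (!is.null(seed)) set.seed(seed)
  if (params$apply_stimulation) method <- "molecule"

  mols <- if (method == "vectorized") {
    batch_vectorized(plasmid, nalkyl_density, spectrum, params, n)
  } else {
    batch_molecule(plasmid, nalkyl_density, spectrum, params, n)
  }
  summarise_batch(mols, plasmid, keep_molecules)
}

batch_molecule <- function(plasmid, nalkyl_density, spectrum, params, n) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    map <- place_lesions(plasmid, nalkyl_density, spectrum)
    o <- simulate_repair(map, params)$outcome
    rows[[i]] <- data.frame(
      molecule = i,
      n_nalkyl = sum(map$adduct_class %in% .nalkyl_classes),
      n_o6mg = sum(map$adduct_class == "O6mG"),
      open_nicks_top = o$open_nicks_top,
      open_nicks_bottom = o$open_nicks_bottom,
      open_gaps = o$open_gaps, dsb_count = o$dsb_count,
      topology = o$topology, synthesized_nt = o$synthesized_nt,
      o6mg_attributed_nt = o$o6mg_attributed_nt, labeled_nt = o$labeled_nt,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

batch_vectorized <- function(plasmid, nalkyl_density, spectrum, params, n) {
  L <- plasmid$length_bp
  fN <- spectrum$frac_7mG + spectrum$frac_3mA
  d <- nalkyl_density
  p_total <- if (d == 0) 0 else d / fN
  if (p_total > 1) stop_bad("total adduct density exceeds 1")

  # multinomial class split via sequential binomials
  n_tot <- rbinom(n, 2L * L, p_total)
  n_o6 <- rbinom(n, n_tot, spectrum$frac_O6mG)
  n_rem <- n_tot - n_o6
  p_other <- if (spectrum$frac_O6mG >= 1) 0 else
    spectrum$frac_other / (1 - spectrum$frac_O6mG)
  n_other <- rbinom(n, n_rem, p_other)
  n_nal <- n_rem - n_other
  n_7mg <- rbinom(n, n_nal, spectrum$frac_7mG / fN)

  # BER synthesis accounting
  k_long <- rbinom(n, n_nal, params$ber_long_patch_fraction)
  long_extra <- rbinom(n, 6L * k_long, (params$ber_long_patch_mean - 2) / 6)
  synth_ber <- (n_nal - k_long) + 2 * k_long + long_extra
  # short (1 nt) patches at 7mG are unlabeled; shorts are n_nal - k_long of
  # which each is at 7mG with prob frac_7mG / fN
  short_7mg <- rbinom(n, n_nal - k_long, spectrum$frac_7mG / fN)

  # open BER nicks with strands and positions
  k_open <- rbinom(n, n_nal, params$p_nick_open)
  K <- sum(k_open)
  nick_mol <- rep.int(seq_len(n), k_open)
  nick_str <- rbinom(K, 1L, 0.5)
  nick_pos <- as.integer(floor(runif(K) * L))

  # engaged MMR events and their open-gap subset
  k_eng <- rbinom(n, n_o6, min(1, params$p_engage_base))
  k_gap <- rbinom(n, k_eng, params$p_mmr_gap_open)
  synth_mmr <- if (params$track_length_model == "fixed") {
    k_eng * as.integer(round(params$track_length))
  } else {
    E <- sum(k_eng)
    tl_all <- draw_track_length(E, params, L)
    as.numeric(rowsum_safe(tl_all, rep.int(seq_len(n), k_eng), n))
  }

  G <- sum(k_gap)
  gap_mol <- rep.int(seq_len(n), k_gap)
  gap_len <- draw_track_length(G, params, L)
  gap_off <- switch(params$track_placement,
                    uniform_cover = as.integer(floor(runif(G) * gap_len)),
                    centered = gap_len %/% 2L)
  gap_start <- (as.integer(floor(runif(G) * L)) - gap_off) %% L
  gap_str <- rbinom(G, 1L, 0.5)

  # gap/nick overlap on opposite strands, joined per molecule
  dsb <- integer(n)
  if (G > 0 && K > 0) {
    nick_dt <- data.table::data.table(mol = nick_mol, nstr = nick_str,
                                      npos = nick_pos)
    gap_dt <- data.table::data.table(gid = seq_len(G), mol = gap_mol,
                                     gstr = gap_str, gstart = gap_start,
                                     glen = gap_len)
    pairs <- merge(gap_dt, nick_dt, by = "mol", allow.cartesian = TRUE)
    pairs <- pairs[nstr != gstr]
    if (nrow(pairs)) {
      pairs[, hit := ((npos - gstart) %% L) < glen]
      hits <- pairs[, list(hit = any(hit)), by = list(gid, mol)]
      hits <- hits[hit == TRUE]
      if (nrow(hits)) {
        tab <- hits[, .N, by = mol]
        dsb[tab$mol] <- tab$N
      }
    }
  }
  if (params$nick_nick_dsb_threshold > 0 && K > 1) {
    thr <- params$nick_nick_dsb_threshold
    nick_dt <- data.table::data.table(mol = nick_mol, nstr = nick_str,
                                      npos = nick_pos)
    top <- nick_dt[nstr == 0L]; bot <- nick_dt[nstr == 1L]
    pp <- merge(top[, list(mol, a = npos)], bot[, list(mol, b = npos)],
                by = "mol", allow.cartesian = TRUE)
    if (nrow(pp)) {
      pp <- pp[pmin(abs(a - b) %% L, L - abs(a - b) %% L) <= thr]
      if (nrow(pp)) {
        tab <- pp[, .N, by = mol]
        dsb[tab$mol] <- dsb[tab$mol] + tab$N
      }
    }
  }

  open_top <- as.integer(rowsum_safe(as.integer(nick_str == 0L), nick_mol, n))
  open_bottom <- k_open - open_top
  synth <- synth_ber + synth_mmr
  labeled <- synth - short_7mg
  topo <- ifelse(dsb >= 1L, "linear",
                 ifelse(k_open + k_gap >= 1L, "oc", "ccc"))
  data.frame(molecule = seq_len(n), n_nalkyl = n_nal, n_o6mg = n_o6,
             open_nicks_top = open_top, open_nicks_bottom = open_bottom,
             open_gaps = k_gap, dsb_count = dsb, topology = topo,
             synthesized_nt = synth, o6mg_attributed_nt = synth_mmr,
             labeled_nt = labeled, stringsAsFactors = FALSE)
}

# rowsum over groups 1..n returning a dense length-n vector
rowsum_safe <- function(x, group, n) {
  out <- numeric(n)
  if (length(x)) {
    rs <- rowsum(x, group)
    out[as.integer(rownames(rs))] <- rs[, 1L]
  }
  out
}

summarise_batch <- function(mols, plasmid, keep_molecules) {
  n <- nrow(mols)
  counts <- c(ccc = sum(mols$topology == "ccc"),
              oc = sum(mols$topology == "oc"),
              linear = sum(mols$topology == "linear"))
  fractions <- counts / n
  se <- sqrt(fractions * (1 - fractions) / n)
  n_open <- counts[["oc"]] + counts[["linear"]]
  out <- list(n = n, counts = counts, fractions = fractions, se = se,
              mean_dsb = mean(mols$dsb_count),
              mean_synthesized_nt = mean(mols$synthesized_nt),
              uds_percent_replication =
                100 * mean(mols$synthesized_nt) / (2 * plasmid$length_bp),
              linear_of_open = if (n_open > 0)
                counts[["linear"]] / n_open else NA_real_,
              plasmid = plasmid$name)
  if (keep_molecules) out$molecules <- mols
  structure(out, class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf("<batch_summary> %s, n = %d molecules\n", x$plasmid, x$n))
  cat(sprintf("  ccc %.4f  oc %.4f  linear %.4f (+/- %.4f)\n",
              x$fractions[["ccc"]], x$fractions[["oc"]],
              x$fractions[["linear"]], x$se[["linear"]]))
  cat(sprintf("  mean DSB %.4g; UDS %.3f%% of replication equivalent\n",
              x$mean_dsb, x$uds_percent_replication))
  invisible(x)
}
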