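# Independent oracles and small generators used across test files.

# Brute-force DSB caller: scans every strand-nucleotide of every open MMR
# gap and checks for an open BER nick at that position on the opposite
# strand. Intentionally naive; must agree with detect_dsb() exactly.
oracle_detect_dsb <- function(events, length_bp) {
  nicks <- events[events$kind == "BER_nick" & events$open, , drop = FALSE]
  gaps <- events[events$kind == "MMR_gap" & events$open, , drop = FALSE]
  count <- 0L
  if (nrow(gaps)) {
    for (g in seq_len(nrow(gaps))) {
      covered <- (gaps$start[g] + seq_len(gaps$length[g]) - 1L) %% length_bp
      opp <- nicks$start[nicks$strand != gaps$strand[g]]
      if (length(opp) && any(opp %in% covered)) count <- count + 1L
    }
  }
  count
}

# Random event set on a circle of length L.
random_event_set <- function(L, n_nicks, n_gaps, max_gap = 600L) {
  kind <- c(rep("BER_nick", n_nicks), rep("MMR_gap", n_gaps))
  n <- length(kind)
  ev <- data.frame(
    kind = kind,
    strand = sample(c("top", "bottom"), n, replace = TRUE),
    start = sample.int(L, n, replace = TRUE) - 1L,
    length = c(rep(0L, n_nicks),
               sample.int(max_gap, n_gaps, replace = TRUE)),
    open = rep(TRUE, n),
    synthesis_nt = c(rep(1L, n_nicks),
                     rep(0L, n_gaps)),
    origin_lesion = seq_len(n),
    stringsAsFactors = FALSE)
  ev$synthesis_nt[ev$kind == "MMR_gap"] <- ev$length[ev$kind == "MMR_gap"]
  attr(ev, "length_bp") <- L
  class(ev) <- c("repair_event_set", "data.frame")
  ev
}

# Kolmogorov distance between pooled cut-fragment lengths and the geometric
# law with per-site cut probability d.
ks_to_geometric <- function(lengths, d) {
  lengths <- sort(lengths)
  n <- length(lengths)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  theo <- 1 - (1 - d)^lengths
  max(abs(emp_hi - theo), abs(emp_lo - theo))
}

mnu <- function() spectrum_for_agent("MNU")
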