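test_that("repair_params validates and resolves the calibrated nick openness", {
  p <- repair_params()
  expect_equal(p$p_engage_base, 0.30)
  expect_equal(p$track_length, 500)
  expect_equal(p$p_mmr_gap_open, 0.75)
  # calibrated default: plugging it back into the closed form returns the
  # 6% anchor at the double-strength dose on pEL97
  a <- analytic_dsb_fraction(plasmid("pEL97"), 1 / 250, mnu(), p)
  expect_equal(as.numeric(a), 0.06, tolerance = 1e-4)
  expect_error(repair_params(p_engage_base = 1.2), "must be in")
  expect_error(repair_params(stimulation_factor = 0.5), "must be in")
  expect_error(repair_params(track_length = 0), "must be in")
})

test_that("detect_dsb calls gap/nick overlaps on opposite strands only", {
  L <- 4363
  p <- repair_params(p_nick_open = 0.1)
  ev <- function(gstart, glen, nstart, nstrand = "bottom") {
    e <- data.frame(kind = c("MMR_gap", "BER_nick"),
                    strand = c("top", nstrand),
                    start = c(gstart, nstart), length = c(glen, 0L),
                    open = TRUE, synthesis_nt = c(glen, 1L),
                    origin_lesion = 1:2, stringsAsFactors = FALSE)
    attr(e, "length_bp") <- L
    class(e) <- c("repair_event_set", "data.frame")
    e
  }
  expect_equal(detect_dsb(ev(1000, 500, 1200), p)$count, 1L)
  expect_equal(detect_dsb(ev(1000, 500, 1600), p)$count, 0L)
  expect_equal(detect_dsb(ev(1000, 500, 1200, "top"), p)$count, 0L)
  # half-open interval: start included, end excluded
  expect_equal(detect_dsb(ev(1000, 500, 1000), p)$count, 1L)
  expect_equal(detect_dsb(ev(1000, 500, 1500), p)$count, 0L)
  # wrap-around gap
  expect_equal(detect_dsb(ev(4000, 800, 100), p)$count, 1L)
  expect_equal(detect_dsb(ev(4000, 800, 500), p)$count, 0L)
})

test_that("detect_dsb equals the per-nucleotide brute-force oracle", {
  p <- repair_params(p_nick_open = 0.1)
  set.seed(21)
  for (i in 1:300) {
    L <- sample(200:2000, 1)
    ev <- random_event_set(L, n_nicks = sample(0:6, 1),
                           n_gaps = sample(0:4, 1),
                           max_gap = min(600L, L))
    expect_identical(detect_dsb(ev, p)$count, oracle_detect_dsb(ev, L))
  }
})

test_that("topology classification is deterministic", {
  expect_equal(classify_topology(0, 0), "ccc")
  expect_equal(classify_topology(0, 2), "oc")
  expect_equal(classify_topology(1, 0), "linear")
  expect_equal(classify_topology(2, 5), "linear")
})

test_that("a lesion-free molecule stays ccc with zero synthesis", {
  m <- lesion_map(plasmid("pBR322"))
  out <- simulate_repair(m, repair_params(), seed = 1)$outcome
  expect_equal(out$topology, "ccc")
  expect_equal(out$synthesized_nt, 0)
  expect_equal(out$dsb_count, 0L)
})

test_that("no DSBs form when either pathway is disabled", {
  plas <- plasmid_spec("toy", 3000)
  sp <- mnu()
  off <- list(repair_params(p_nick_open = 0),
              repair_params(p_engage_base = 0, p_nick_open = 0.5),
              repair_params(p_mmr_gap_open = 0, p_nick_open = 0.5))
  for (p in off) {
    b <- batch_simulate(plas, 0.02, sp, p, n = 400, seed = 17)
    expect_equal(sum(b$molecules$dsb_count), 0L)
    bm <- batch_simulate(plas, 0.02, sp, p, n = 100, seed = 18,
                         method = "molecule")
    expect_equal(sum(bm$molecules$dsb_count), 0L)
    expect_equal(analytic_dsb_fraction(plas, 0.02, sp, p), 0,
                 ignore_attr = TRUE)
  }
})

test_that("UDS accounting matches its closed form for MMR-only molecules", {
  plas <- plasmid_spec("c", 4363)
  p <- repair_params(p_nick_open = 0)
  m <- lesion_map(plas, c(500, 1500, 3000), rep("top", 3), rep("O6mG", 3))
  set.seed(31)
  o6nt <- replicate(4000, simulate_repair(m, p)$outcome$o6mg_attributed_nt)
  mu <- 3 * 0.30 * 500 # n_sites * p_engage * track_length
  expect_lt(abs(mean(o6nt) - mu), 3 * sd(o6nt) / sqrt(length(o6nt)))
  # and uds_signal converts synthesis to percent-replication correctly
  out <- data.frame(synthesized_nt = c(270, 270), labeled_nt = c(270, 270))
  expect_equal(uds_signal(out, plas), 100 * 270 / (2 * 4363))
  expect_equal(uds_signal(out, plas), 3.094, tolerance = 1e-3)
  expect_error(uds_signal(data.frame(synthesized_nt = numeric()), plas),
               "empty batch")
})

test_that("label-specific UDS excludes 1 nt patches at 7mG", {
  plas <- plasmid_spec("c", 2000)
  # all-7mG map, forced short patches: labeled signal must be zero
  m <- lesion_map(plas, c(100, 900), c("top", "bottom"), c("7mG", "7mG"))
  p <- repair_params(ber_long_patch_fraction = 0, p_nick_open = 0)
  out <- simulate_repair(m, p, seed = 2)$outcome
  expect_equal(out$synthesized_nt, 2)
  expect_equal(out$labeled_nt, 0)
  # 3mA short patches remain labeled
  m2 <- lesion_map(plas, 100, "top", "3mA")
  out2 <- simulate_repair(m2, p, seed = 3)$outcome
  expect_equal(out2$labeled_nt, 1)
})

test_that("fragment-specific activity apportions synthesis pro rata", {
  L <- 2114 # S (589) + L (1525) restriction fragments
  cuts <- c(0, 589)
  mk_gap <- function(start, len) {
    e <- data.frame(kind = "MMR_gap", strand = "top", start = start,
                    length = len, open = FALSE, synthesis_nt = len,
                    origin_lesion = 1L, stringsAsFactors = FALSE)
    attr(e, "length_bp") <- L
    class(e) <- c("repair_event_set", "data.frame")
    e
  }
  # track fully inside S: all signal in S
  fa <- fragment_specific_activity(mk_gap(44, 500), cuts)
  expect_equal(fa$signal[fa$start == 0], 500)
  expect_equal(fa$signal[fa$start == 589], 0)

  # spill-over grows as the site approaches the fragment boundary; a site
  # 200 nt into S with a centred 500 nt track spills exactly 10%
  site_spill <- function(site) {
    g <- mk_gap((site - 250) %% L, 500)
    fa <- fragment_specific_activity(g, cuts)
    fa$signal[fa$start == 589] / 500
  }
  expect_equal(site_spill(200), 0.10, tolerance = 1e-9)
  expect_equal(site_spill(175), 0.15, tolerance = 1e-9)
  spills <- vapply(seq(0, 588, by = 7), site_spill, numeric(1))
  expect_true(any(spills >= 0.10 & spills <= 0.15))
  expect_true(all(spills >= 0 & spills <= 1))

  # uniform background: equal specific activities by symmetry (exact for a
  # lattice of unit patches aligned with the cuts)
  n <- L / 2
  bg <- data.frame(kind = "BER_nick", strand = "top",
                   start = seq(0, L - 2, by = 2), length = 1L, open = FALSE,
                   synthesis_nt = 1L, origin_lesion = seq_len(n),
                   stringsAsFactors = FALSE)
  attr(bg, "length_bp") <- L
  class(bg) <- c("repair_event_set", "data.frame")
  fb <- fragment_specific_activity(bg, c(0, 600))
  expect_equal(fb$specific_activity[1], fb$specific_activity[2],
               tolerance = 1e-9)

  expect_error(fragment_specific_activity(mk_gap(0, 10), c(5, 5)),
               "duplicate")
  expect_error(fragment_specific_activity(mk_gap(0, 10), 5), "at least two")
})

test_that("analytic fraction obeys limits, quadratic scaling and monotonicity", {
  plas <- plasmid("pEL97")
  sp <- mnu()
  expect_equal(analytic_dsb_fraction(plas, 0.001, sp,
                                     repair_params(p_nick_open = 0)), 0,
               ignore_attr = TRUE)
  p <- repair_params()
  # doubling a small density quadruples the expectation (both factors linear)
  lo <- analytic_dsb_fraction(plas, 1e-5, sp, p)
  hi <- analytic_dsb_fraction(plas, 2e-5, sp, p)
  expect_equal(as.numeric(hi / lo), 4, tolerance = 0.01)
  expect_warning(analytic_dsb_fraction(plas, 0.02, sp,
                                       repair_params(p_nick_open = 0.5)),
                 "rare-event")
  # monotone in density, track length, openness and engagement
  grid <- expand.grid(d = c(0.001, 0.002), tl = c(250, 500),
                      pn = c(0.005, 0.02), pe = c(0.1, 0.3))
  vals <- apply(grid, 1, function(g)
    analytic_dsb_fraction(plas, g[["d"]], sp,
                          repair_params(track_length = g[["tl"]],
                                        p_nick_open = g[["pn"]],
                                        p_engage_base = g[["pe"]])))
  for (v in c("d", "tl", "pn", "pe")) {
    lo_m <- mean(vals[grid[[v]] == min(grid[[v]])])
    hi_m <- mean(vals[grid[[v]] == max(grid[[v]])])
    expect_gt(hi_m, lo_m)
  }
})

test_that("calibration inverts the closed form and flags unreachable targets", {
  p <- repair_params(p_nick_open = 0)
  got <- calibrate_nick_availability(0.06, plasmid("pEL97"), 1 / 250, mnu(), p)
  expect_equal(got, 0.014524, tolerance = 1e-3)
  p$p_nick_open <- got
  expect_equal(as.numeric(analytic_dsb_fraction(plasmid("pEL97"), 1 / 250,
                                                mnu(), p)),
               0.06, tolerance = 1e-5)
  expect_equal(calibrate_nick_availability(0, plasmid("pEL97"), 1 / 250,
                                           mnu(), p), 0)
  expect_error(calibrate_nick_availability(0.5, plasmid("pEL97"), 1e-4,
                                           mnu(), p), "unreachable")
})

test_that("batch summaries conserve fractions and reproduce under a seed", {
  plas <- plasmid("pBR322")
  p <- repair_params()
  b1 <- batch_simulate(plas, 1 / 500, mnu(), p, n = 1, seed = 1)
  expect_true(all(b1$fractions %in% c(0, 1)))
  b <- batch_simulate(plas, 1 / 500, mnu(), p, n = 2000, seed = 2)
  expect_equal(sum(b$fractions), 1, tolerance = 1e-12)
  expect_equal(b$se, sqrt(b$fractions * (1 - b$fractions) / b$n))
  b2 <- batch_simulate(plas, 1 / 500, mnu(), p, n = 2000, seed = 2)
  expect_identical(b$molecules, b2$molecules)
  expect_error(batch_simulate(plas, 1 / 500, mnu(), p, n = 0), "must be in")
})

test_that("vectorized and per-molecule paths agree statistically", {
  plas <- plasmid_spec("toy", 4000)
  p <- repair_params(p_nick_open = 0.08)
  n <- 3000
  bv <- batch_simulate(plas, 1 / 300, mnu(), p, n = n, seed = 101)
  bm <- batch_simulate(plas, 1 / 300, mnu(), p, n = n, seed = 102,
                       method = "molecule")
  for (col in c("dsb_count", "synthesized_nt", "n_nalkyl", "open_gaps")) {
    x <- bv$molecules[[col]]; y <- bm$molecules[[col]]
    se <- sqrt(var(x) / n + var(y) / n)
    expect_lt(abs(mean(x) - mean(y)), 4 * se)
  }
  expect_lt(abs(bv$fractions[["linear"]] - bm$fractions[["linear"]]),
            4 * sqrt(bv$se[["linear"]]^2 + bm$se[["linear"]]^2))
})

test_that("N-alkyl co-damage stimulates MMR engagement in the reconstitution setup", {
  # single O6mG:C construct, with or without random MMS adducts in cis;
  # unstimulated engagement 0.30/2.9, stimulated engagement 0.30
  plas <- plasmid_spec("mGC", 2114)
  p <- repair_params(p_engage_base = 0.30 / 2.9, apply_stimulation = TRUE,
                     p_nick_open = 0)
  n <- 4000
  set.seed(55)
  engaged_alone <- engaged_mms <- logical(n)
  for (i in seq_len(n)) {
    alone <- lesion_map(plas, 1000, "top", "O6mG")
    engaged_alone[i] <- simulate_repair(alone, p)$outcome$o6mg_attributed_nt > 0
    mms <- place_lesions(plas, 1 / 500, spectrum_for_agent("MMS"))
    mms <- mms[mms$adduct_class %in% c("7mG", "3mA") &
                 !(mms$position == 1000 & mms$strand == "top"), ]
    withm <- lesion_map(plas, c(mms$position, 1000),
                        c(mms$strand, "top"),
                        c(mms$adduct_class, "O6mG"))
    engaged_mms[i] <- simulate_repair(withm, p)$outcome$o6mg_attributed_nt > 0
  }
  fold <- mean(engaged_mms) / mean(engaged_alone)
  se <- fold * sqrt(1 / sum(engaged_mms) + 1 / sum(engaged_alone))
  expect_lt(abs(fold - 2.9), 3 * se + 0.15)
})
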