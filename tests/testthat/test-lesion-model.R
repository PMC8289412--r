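test_that("agent spectra are registered with the expected O-alkyl content", {
  expect_equal(spectrum_for_agent("MNU")$frac_O6mG, 0.085)
  expect_lte(spectrum_for_agent("MMS")$frac_O6mG, 0.003)
  # ENU is modelled with the MNU spectrum
  expect_equal(no_ratio(spectrum_for_agent("ENU")),
               no_ratio(spectrum_for_agent("MNU")))
  expect_error(spectrum_for_agent("XYZ"), "unknown agent")
  expect_error(adduct_spectrum(0.9, 0.2, 0.05, 0.05), "sum to 1")
  expect_error(adduct_spectrum(-0.1, 0.5, 0.3, 0.3), "must be in")
})

test_that("dose converts linearly to density and cross-checks the genome load", {
  expect_equal(dose_to_density(2), 0.004)
  expect_equal(dose_to_density(0), 0)
  expect_error(dose_to_density(-1), "non-negative")
  expect_equal(dose_to_density(1, dose_calibration(1 / 250)), 0.004)
  # the clinical 50 uM density agrees with the independently stated
  # genome-wide N-alkyl load (7.3e5 lesions over 6e9 nt) within 20%
  d_clinical <- dose_to_density(0.05)
  d_genome <- 7.3e5 / 6e9
  expect_lt(abs(d_clinical - d_genome) / d_genome, 0.20)
})

test_that("place_lesions respects geometry, seeding and degenerate inputs", {
  plas <- plasmid("pBR322")
  expect_equal(nrow(place_lesions(plas, 0, mnu())), 0L)
  expect_error(place_lesions(plas, 0.6, mnu()), "must be in")
  expect_error(place_lesions(plas, 1 / 500, mnu(), sequence_aware = TRUE),
               "requires a plasmid sequence")

  m1 <- place_lesions(plas, 1 / 100, mnu(), seed = 42)
  m2 <- place_lesions(plas, 1 / 100, mnu(), seed = 42)
  m3 <- place_lesions(plas, 1 / 100, mnu(), seed = 43)
  expect_identical(m1, m2)
  expect_false(identical(m1, m3))
  expect_true(all(m1$position >= 0 & m1$position < plas$length_bp))
  expect_equal(anyDuplicated(paste(m1$position, m1$strand)), 0L)
})

test_that("lesion counts are Poisson-consistent and classes follow the spectrum", {
  plas <- plasmid_spec("toy", 2000)
  d <- 1 / 500
  set.seed(7)
  n <- 10000
  counts <- integer(n)
  cls <- vector("list", n)
  for (i in seq_len(n)) {
    m <- place_lesions(plas, d, mnu())
    counts[i] <- sum(m$adduct_class %in% c("7mG", "3mA"))
    cls[[i]] <- m$adduct_class
  }
  mu <- 2 * plas$length_bp * d
  se <- sd(counts) / sqrt(n)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  expect_gt(var(counts) / mean(counts), 0.9)
  expect_lt(var(counts) / mean(counts), 1.1)

  tab <- table(factor(unlist(cls), levels = c("7mG", "3mA", "O6mG", "other")))
  props <- as.numeric(tab) / sum(tab)
  expected <- c(0.725, 0.10, 0.085, 0.09)
  se_bin <- sqrt(expected * (1 - expected) / sum(tab))
  expect_true(all(abs(props - expected) < 4 * se_bin))
})

test_that("sequence-aware placement puts classes on compatible bases", {
  set.seed(2)
  seqchars <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  plas <- plasmid_spec("seqtoy", 400, sequence = paste(seqchars, collapse = ""))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:20) {
    m <- place_lesions(plas, 0.05, mnu(), sequence_aware = TRUE)
    base <- ifelse(m$strand == "top", seqchars[m$position + 1],
                   comp[seqchars[m$position + 1]])
    expect_true(all(base[m$adduct_class %in% c("7mG", "O6mG")] == "G"))
    expect_true(all(base[m$adduct_class == "3mA"] == "A"))
    expect_equal(anyDuplicated(paste(m$position, m$strand)), 0L)
  }
})

test_that("expected_counts is the closed-form twin of placement", {
  sp10 <- adduct_spectrum(0.75, 0.15, 0.09, 0.01) # N:O ratio exactly 10
  ec <- expected_counts(plasmid("pEL97"), 1 / 250, sp10)
  expect_equal(ec$nalkyl, 90.4)
  expect_equal(ec$o6mg, 9.04)
  expect_equal(expected_counts(plasmid("pBR322"), 1 / 500, sp10)$o6mg, 1.72)
  z <- expected_counts(plasmid("pBR322"), 0, mnu())
  expect_equal(z$nalkyl, 0)
  expect_equal(unname(z$by_class), rep(0, 4))
  # large-sample mean of place_lesions matches within Monte Carlo error
  set.seed(11)
  tot <- replicate(4000, nrow(place_lesions(plasmid_spec("t", 1500), 0.01,
                                            mnu())))
  mu <- expected_counts(plasmid_spec("t", 1500), 0.01, mnu())$total
  expect_lt(abs(mean(tot) - mu), 3 * sd(tot) / sqrt(length(tot)))
})
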