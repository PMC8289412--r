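test_that("cleavage geometry on the circle is exact", {
  plas <- plasmid_spec("c", 4363)
  # O6mG alone does not cleave: both strands stay uncut and full length
  m <- lesion_map(plas, c(10, 20), c("top", "bottom"), c("O6mG", "other"))
  prof <- cleave_at_nalkyl(m)
  expect_true(all(prof$fragments$uncut))
  expect_equal(prof$fragments$length, c(4363, 4363))
  expect_equal(prof$mean_nicks_per_strand, 0)

  # a single 7mG linearises the top strand into one full-length fragment
  m1 <- lesion_map(plas, 100, "top", "7mG")
  prof1 <- cleave_at_nalkyl(m1)
  top <- prof1$fragments[prof1$fragments$strand == "top", ]
  expect_equal(top$length, 4363)
  expect_false(top$uncut)

  # known cut set: fragments are the circular gaps
  m3 <- lesion_map(plasmid_spec("s", 600), c(0, 100, 300),
                   rep("top", 3), c("7mG", "3mA", "7mG"))
  prof3 <- cleave_at_nalkyl(m3)
  expect_equal(sort(prof3$fragments$length[prof3$fragments$strand == "top"]),
               c(100, 200, 300))
  expect_equal(median_fragment_length(prof3), 200)
})

test_that("fragment lengths conserve strand length and match Poisson stats", {
  plas <- plasmid("pBR322")
  set.seed(5)
  maps <- replicate(2000, place_lesions(plas, 1 / 500, mnu()),
                    simplify = FALSE)
  prof <- cleave_at_nalkyl(maps)
  sums <- tapply(prof$fragments$length,
                 list(prof$fragments$molecule, prof$fragments$strand), sum)
  expect_true(all(sums == plas$length_bp))
  # mean nicks/strand ~ L * d = 8.726
  mu <- plas$length_bp / 500
  se <- sqrt(mu / (2 * 2000))
  expect_lt(abs(prof$mean_nicks_per_strand - mu), 3 * se)
  # median fragment length ~ ln(2)/d, within 5%
  med <- median_fragment_length(prof)
  expect_lt(abs(med - log(2) * 500) / (log(2) * 500), 0.05)
  # geometric-mode density recovery within 10%
  d_hat <- estimate_density_from_median(med, "geometric")
  expect_lt(abs(d_hat - 1 / 500) / (1 / 500), 0.10)
})

test_that("median inversion implements both conventions", {
  expect_equal(estimate_density_from_median(500), 0.002)
  expect_equal(estimate_density_from_median(500, "geometric"), log(2) / 500,
               tolerance = 1e-12)
  expect_error(estimate_density_from_median(0), "> 0")
  # an all-uncut batch has no median
  m <- lesion_map(plasmid_spec("c", 1000), 5, "top", "O6mG")
  expect_error(median_fragment_length(cleave_at_nalkyl(m)), "no fragments")
})

test_that("smear-centre nick estimator follows mean fragment arithmetic", {
  expect_equal(nicks_per_strand_from_smear(11300, 3000), 11300 / 3000)
  expect_equal(nicks_per_strand_from_smear(5000, 5000), 1)
  expect_error(nicks_per_strand_from_smear(5000, 0), "> 0")
  expect_error(nicks_per_strand_from_smear(5000, 6000), "cannot exceed")
  # internal consistency: estimator applied to the simulated mean fragment
  # length returns the simulated mean nick count by construction
  plas <- plasmid_spec("c", 8000)
  set.seed(9)
  maps <- replicate(500, place_lesions(plas, 1 / 400, mnu()),
                    simplify = FALSE)
  prof <- cleave_at_nalkyl(maps)
  cut <- prof$fragments[!prof$fragments$uncut, ]
  n_uncut_strands <- sum(prof$fragments$uncut)
  mean_frag <- mean(cut$length)
  nicks_est <- nicks_per_strand_from_smear(plas$length_bp, mean_frag)
  nicks_direct <- nrow(cut) / (2 * 500 - n_uncut_strands)
  expect_equal(nicks_est, nicks_direct, tolerance = 1e-12)
})

test_that("partial cleavage efficiency thins cuts binomially", {
  plas <- plasmid_spec("c", 2000)
  set.seed(13)
  maps <- replicate(800, place_lesions(plas, 0.01, mnu()), simplify = FALSE)
  full <- cleave_at_nalkyl(maps)
  half <- cleave_at_nalkyl(maps, efficiency = 0.5, seed = 1)
  ratio <- half$mean_nicks_per_strand / full$mean_nicks_per_strand
  expect_lt(abs(ratio - 0.5), 0.05)
})
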