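test_that("chemical shift deviations are observed minus reference", {
  ref <- random_coil_table()
  # observed equal to reference everywhere -> all zeros
  seqv <- c("L", "K", "R", "V")
  tab <- rbind(
    data.frame(residue = 1:4, residue_type = seqv, atom = "HA",
               shift_ppm = ref$HA[match(seqv, ref$residue_type)]),
    data.frame(residue = 1:4, residue_type = seqv, atom = "CA",
               shift_ppm = ref$CA[match(seqv, ref$residue_type)]))
  dev <- chemical_shift_deviation(tab)
  expect_equal(dev$d_ha, rep(0, 4))
  expect_equal(dev$d_ca, rep(0, 4))
  # synthetic helix offsets reproduced exactly
  tab$shift_ppm <- tab$shift_ppm + rep(c(-0.25, 2.0), each = 4)
  dev2 <- chemical_shift_deviation(tab)
  expect_equal(dev2$d_ha, rep(-0.25, 4))
  expect_equal(dev2$d_ca, rep(2.0, 4))
  # helix sign convention: negative Halpha, positive Calpha
  expect_true(all(dev2$d_ha < 0 & dev2$d_ca > 0))
})

test_that("secondary-structure calling matches the run-length oracle", {
  # supporting residues 1-21, break at 22, short tail 23-24
  n <- 24
  dev <- data.frame(residue = 1:n, residue_type = "A",
                    d_ha = c(rep(-0.25, 21), 0, -0.25, -0.25),
                    d_ca = c(rep(2, 21), 0, 2, 2))
  ss <- call_secondary_structure(dev, 0.1, 0.7, min_run = 4)
  expect_equal(nrow(ss$segments), 1)
  expect_equal(c(ss$segments$start, ss$segments$end), c(1, 21))
  oracle <- oracle_segments(ss$state$supporting, dev$residue, 4)
  expect_equal(lapply(seq_len(nrow(ss$segments)), function(k)
    c(ss$segments$start[k], ss$segments$end[k])), oracle)
  # all-zero deviations -> all coil
  dev0 <- data.frame(residue = 1:10, d_ha = 0, d_ca = 0)
  ss0 <- call_secondary_structure(dev0)
  expect_true(all(ss0$state$state == "coil"))
  expect_equal(nrow(ss0$segments), 0)
  # invariant to row order of the input
  ssr <- call_secondary_structure(dev[sample(n), ], 0.1, 0.7, 4)
  expect_equal(ssr$segments, ss$segments)
})

test_that("conflicting atom directions do not support helix", {
  # Halpha says helix, Calpha says (beyond threshold) the opposite
  dev <- data.frame(residue = 1:6, d_ha = -0.25, d_ca = -1.0)
  ss <- call_secondary_structure(dev)
  expect_true(all(!ss$state$supporting))
})

test_that("amide dispersion is the HN shift range", {
  tab <- data.frame(residue = 1:3, residue_type = "A", atom = "HN",
                    shift_ppm = c(8.0, 8.5, 8.88))
  expect_equal(amide_dispersion(tab), 0.88)
  tab$shift_ppm <- 8.1
  expect_equal(amide_dispersion(tab), 0)
  expect_error(amide_dispersion(tab[1, ]), "at least 2")
})

test_that("helical tables disperse amide shifts more than coil tables", {
  coil <- gen_shift_table("coil", seed = 5)
  helix <- gen_shift_table("helix", seed = 5)
  expect_gt(amide_dispersion(helix$data), amide_dispersion(coil$data))
})

test_that("PRE percentage loss and its linear error propagation are exact", {
  tab <- data.frame(residue = 1:3,
                    intensity_ref = c(100, 100, 100),
                    intensity_para = c(100, 50, 120),
                    noise_ref = c(0, 2, 2), noise_para = c(0, 2, 2))
  att <- pre_attenuation(tab)
  expect_equal(att$loss_pct, c(0, 50, -20))
  # B=100, C=50, dB=dC=2: A=0.5, loss 50%, error 100*0.5*(0.02+0.04)=3%
  expect_equal(att$loss_err_pct[1:2], c(0, 3))
  expect_equal(att$flag_negative, c(FALSE, FALSE, TRUE))
  expect_error(pre_attenuation(transform(tab, intensity_ref = 0)), "> 0")
})

test_that("PRE loss and error are invariant to a common intensity scale", {
  tab <- data.frame(residue = 1:5, intensity_ref = c(90, 110, 100, 95, 105),
                    intensity_para = c(30, 80, 55, 60, 20),
                    noise_ref = 2, noise_para = 3)
  a1 <- pre_attenuation(tab)
  tab2 <- tab
  tab2[, 2:5] <- tab2[, 2:5] * 7.3
  a2 <- pre_attenuation(tab2)
  expect_equal(a1$loss_pct, a2$loss_pct, tolerance = 1e-12)
  expect_equal(a1$loss_err_pct, a2$loss_err_pct, tolerance = 1e-12)
})

test_that("periodicity fit recovers a noiseless cosine exactly", {
  i <- 1:24
  y <- 50 + 30 * cos(2 * pi * (i - 1) / 3.6)
  fit <- fit_periodicity(y)
  expect_true(fit$periodic)
  expect_equal(fit$period, 3.6, tolerance = 0.01 / 3.6)
  expect_equal(fit$amplitude, 30, tolerance = 1e-3)
  expect_equal(fit$offset, 50, tolerance = 1e-3)
})

test_that("aperiodic profiles are flagged", {
  expect_false(fit_periodicity(rep(40, 12))$periodic)
  expect_true(is.na(fit_periodicity(rep(40, 12))$period))
  expect_error(fit_periodicity(1:5), "at least 8")
})

test_that("period recovery succeeds across periods and seeds", {
  # P in {3.2, 3.6, 4.0}, 20 seeds each, noise SD 10% of amplitude:
  # recovered within +/- 0.2 in >= 90% of runs
  for (P in c(3.2, 3.6, 4.0)) {
    hits <- 0
    for (s in 1:20) {
      set.seed(1000 + s)
      y <- 50 + 30 * cos(2 * pi * (1:24 - 1) / P) + rnorm(24, 0, 3)
      fit <- fit_periodicity(y)
      if (fit$periodic && abs(fit$period - P) <= 0.2) hits <- hits + 1
    }
    expect_gte(hits, 18)
  }
})

test_that("face classification separates cationic from other residues", {
  # identical losses -> no difference, p not significant
  prof <- data.frame(residue = 1:24, loss_pct = 40)
  fc <- classify_faces(prof, SAAP148)
  expect_equal(fc$difference, 0)
  expect_gt(fc$p_value, 0.05)
  expect_equal(fc$n_cationic, 11)
  # cationic set parsed from the sequence
  expect_equal(cationic_positions(SAAP148),
               c(2, 3, 6, 7, 10, 13, 14, 17, 20, 21, 24))
  # amphipathic profile: apolar face attenuated twice as much
  cat_pos <- cationic_positions(SAAP148)
  prof2 <- data.frame(residue = 1:24,
                      loss_pct = ifelse(1:24 %in% cat_pos, 30, 60))
  set.seed(3)
  prof2$loss_pct <- prof2$loss_pct + rnorm(24, 0, 3)
  fc2 <- classify_faces(prof2, SAAP148)
  expect_lt(fc2$mean_cationic, fc2$mean_other)
  expect_lt(fc2$p_value, 0.01)
  expect_error(classify_faces(prof2, "LLLL"), "non-empty")
})
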