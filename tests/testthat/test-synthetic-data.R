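test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(gen_bulk_specimens(seed = 5), gen_bulk_specimens(seed = 5))
  expect_identical(gen_aa_profiles(10, 1.7, seed = 5),
                   gen_aa_profiles(10, 1.7, seed = 5))
  s1 <- gen_incubation_series(-0.16, noise_sd = 0.05, seed = 5)
  s2 <- gen_incubation_series(-0.16, noise_sd = 0.05, seed = 5)
  expect_identical(s1$animal$concentrations, s2$animal$concentrations)
})

test_that("bulk generator honours group sizes and means", {
  recs <- gen_bulk_specimens(seed = 2)
  lb <- recs[recs$species == "Lembulus bicuspidatus" &
               recs$isotope == "N15", ]
  expect_equal(nrow(lb), 13)

  big <- gen_bulk_specimens(n_per_group = 1e4, seed = 3)
  gill_n <- big[big$tissue == "gill" & big$isotope == "N15", ]
  expect_lt(abs(mean(gill_n$value) - (-4.9)), 3 * 0.7 / sqrt(1e4))
  expect_error(gen_bulk_specimens(n_per_group = 0), ">= 1")
})

test_that("AA generator recovers the true TP", {
  # exact at zero noise
  prof <- gen_aa_profiles(5, true_tp = 2.6, baseline_phe = 6.4,
                          noise_sd = 0)
  expect_equal(estimate_tp(prof)$tp, rep(2.6, 5))

  # with 1 permil noise the mean of 400 estimates is within 0.05
  prof <- gen_aa_profiles(400, true_tp = 2.6, baseline_phe = 6.4,
                          noise_sd = 1.0, seed = 12)
  tps <- estimate_tp(prof)$tp
  expect_lt(abs(mean(tps) - 2.6), 0.05)
  # and their spread matches the propagated analytical SE within 20%
  expect_lt(abs(sd(tps) - sqrt(2) / 7.6), 0.2 * sqrt(2) / 7.6)
})

test_that("incubation generator round-trips through net_rate", {
  # noiseless, no drift: exact recovery
  sim <- gen_incubation_series(-0.16, afdw = 0.05, noise_sd = 0)
  expect_equal(net_rate(sim$animal, sim$blank, sim$afdw)$rate, -0.16)

  # noiseless with background drift: blank correction removes it exactly
  sim <- gen_incubation_series(-0.16, afdw = 0.05, noise_sd = 0,
                               blank_drift = 0.02)
  expect_equal(net_rate(sim$animal, sim$blank, sim$afdw)$rate, -0.16)

  # noisy replicates: mean recovered rate within 3 SE of the truth
  set.seed(77)
  rates <- replicate(100, {
    sim <- gen_incubation_series(0.14, analyte = "ammonium", afdw = 0.05,
                                 noise_sd = 0.05, blank_drift = 0.002)
    net_rate(sim$animal, sim$blank, sim$afdw)$rate
  })
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.14), 3 * se)
})

test_that("exhausted concentrations are floored at zero with a warning", {
  expect_warning(
    sim <- gen_incubation_series(-0.11, analyte = "oxygen", afdw = 0.05,
                                 noise_sd = 0),
    "floored")
  expect_true(all(sim$animal$concentrations >= 0))
})

test_that("a full synthetic study reproduces the study's conclusions", {
  study <- suppressWarnings(simulate_study(seed = 20))

  # gill bulk d15N mean attributes to ammonium, excluding N2 and nitrate
  gill <- summarize_groups(study$bulk)
  gill <- gill[gill$tissue == "gill" & gill$isotope == "N15", ]
  wins <- lapply(default_end_members(), expected_pon_window)
  verdicts <- attribute_nitrogen_source(gill$mean, gill$sd, wins)
  expect_equal(verdicts$verdict[verdicts$source == "ammonium"],
               "consistent")
  expect_equal(verdicts$verdict[verdicts$source == "dinitrogen"],
               "excluded")
  # pelagic nitrate is not asserted: its window (-4.3, 2.7) marginally
  # touches gill mean +/- 1 SD, and the source is excluded on habitat
  # grounds (surface water, not available to benthic symbionts)
  expect_equal(verdicts$verdict[verdicts$source == "nitrate_benthic"],
               "excluded")

  # the gastropod profiles classify as omnivory at the group mean
  est <- summary(estimate_tp(study$aa))
  nv <- est[est$species == "Nassarius vinctus", ]
  expect_equal(nv$trophic_class, "omnivory")
})

test_that("simulated tables round-trip losslessly through the file formats", {
  dir <- tempfile("sim")
  study <- suppressWarnings(simulate_study(seed = 4, dir = dir))
  bulk <- read_bulk_isotopes(file.path(dir, "bulk.csv"))
  expect_equal(bulk$value, study$bulk$value)
  aa <- read_aa_profiles(file.path(dir, "aa_profiles.csv"))
  expect_equal(aa$delta15n_glu, study$aa$delta15n_glu)
  inc <- read_incubations(file.path(dir, "incubations.csv"))
  expect_equal(inc$concentration, study$incubations$concentration)
  cfg <- yaml::read_yaml(file.path(dir, "sim_config.yaml"))
  expect_equal(cfg$seed, 4)
  unlink(dir, recursive = TRUE)
})
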