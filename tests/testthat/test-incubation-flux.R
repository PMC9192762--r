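vial <- function(conc, times = c(0, 50), analyte = "nitrate",
                 volume = 0.02, is_blank = FALSE, id = "v") {
  incubation_vial(id, analyte, times, conc, volume, is_blank = is_blank,
                  species = if (is_blank) "" else "sp")
}

test_that("net rate applies the blank-corrected flux equation", {
  # identical animal and blank series cancel exactly
  r <- net_rate(vial(c(20, 15)), vial(c(20, 15), is_blank = TRUE),
                afdw = 0.01)
  expect_equal(r$rate, 0)

  # a blank-corrected drop of 10 umol/l over 50 h in 0.02 l, 0.01 g AFDW
  r <- net_rate(vial(c(30, 20)), vial(c(30, 30), is_blank = TRUE),
                afdw = 0.01)
  expect_equal(r$rate, -0.4)
  expect_equal(r$units, "umol h-1 g-1 AFDW")

  # faster decline in the animal vial than the blank: net consumption
  r <- net_rate(vial(c(22, 10)), vial(c(22, 18), is_blank = TRUE),
                afdw = 0.05)
  expect_lt(r$rate, 0)
})

test_that("net rate rejects mismatched or mislabeled vials", {
  a <- vial(c(20, 10))
  b <- vial(c(20, 19), analyte = "ammonium", is_blank = TRUE)
  expect_error(net_rate(a, b, 0.01), "mismatch")
  expect_error(net_rate(a, vial(c(20, 19)), 0.01), "not flagged")
  expect_error(net_rate(vial(c(20, 19), is_blank = TRUE),
                        vial(c(20, 19), is_blank = TRUE), 0.01), "flagged")
  expect_error(net_rate(a, vial(c(20, 19), is_blank = TRUE), 0), "> 0")
})

test_that("net rate is linear in volume and inverse in AFDW", {
  a <- c(30, 18); b <- c(30, 28)
  base <- net_rate(vial(a), vial(b, is_blank = TRUE), afdw = 0.02)$rate
  doubled_v <- net_rate(vial(a, volume = 0.04),
                        vial(b, volume = 0.04, is_blank = TRUE),
                        afdw = 0.02)$rate
  expect_equal(doubled_v, 2 * base)
  halved_afdw <- net_rate(vial(a), vial(b, is_blank = TRUE),
                          afdw = 0.01)$rate
  expect_equal(halved_afdw, 2 * base)
})

test_that("a shared drift added to both vials leaves the rate unchanged", {
  times <- seq(0, 48, by = 8)
  animal <- 25 - 0.2 * times
  blank <- rep(25, length(times))
  base <- net_rate(vial(animal, times), vial(blank, times, is_blank = TRUE),
                   afdw = 0.03)$rate
  for (drift in c(-0.05, 0.02, 0.1)) {
    shifted <- net_rate(vial(animal + drift * times, times),
                        vial(blank + drift * times, times, is_blank = TRUE),
                        afdw = 0.03)$rate
    expect_equal(shifted, base)
  }
})

test_that("regression mode uses least-squares slopes of the full series", {
  times <- seq(0, 50, by = 5)
  set.seed(9)
  animal <- 20 - 0.1 * times + rnorm(length(times), 0, 0.01)
  blank <- 20 - 0.02 * times + rnorm(length(times), 0, 0.01)
  r <- net_rate(vial(animal, times), vial(blank, times, is_blank = TRUE),
                afdw = 0.02, method = "regression")
  slope_diff <- coef(lm(animal ~ times))[2] - coef(lm(blank ~ times))[2]
  expect_equal(r$rate, unname(slope_diff) * 0.02 / 0.02)
})

test_that("an oxygen vial ending at zero warns of anoxia", {
  a <- vial(c(0.73, 0), analyte = "oxygen")
  b <- vial(c(0.73, 0.7), analyte = "oxygen", is_blank = TRUE)
  expect_warning(net_rate(a, b, 0.01), "anoxia")
})

test_that("vial validation enforces the series invariants", {
  expect_error(incubation_vial("v", "nitrate", 0, 20, 0.02), "two time")
  expect_error(incubation_vial("v", "nitrate", c(0, 0), c(20, 19), 0.02),
               "increasing")
  expect_error(incubation_vial("v", "nitrate", c(0, 5), c(20, -1), 0.02),
               ">= 0")
  expect_error(incubation_vial("v", "nitrate", c(0, 5), c(20, 19), 0),
               "> 0")
  expect_error(incubation_vial("v", "water", c(0, 5), c(20, 19), 0.02),
               "analyte")
})

test_that("biomass conversions follow the allometric and AFDW models", {
  expect_equal(wet_weight_from_size(10, a = 0.005, b = 0), 0.005)
  expect_equal(wet_weight_from_size(2, a = 1, b = 1), 2)
  sizes <- seq(5, 20, by = 1)
  expect_true(all(diff(wet_weight_from_size(sizes, 0.001, 2.7)) > 0))
  expect_error(wet_weight_from_size(10, a = NA, b = 2), "supplied")
  expect_error(wet_weight_from_size(-1, 1, 1), "> 0")

  expect_equal(afdw_from_wet(1.0, 0.091), 0.091)
  expect_equal(afdw_from_wet(1.0, 0.081), 0.081)
  expect_equal(afdw_from_wet(0, 0.084), 0)
  expect_error(afdw_from_wet(1, 1.2), "0, 1")

  conv <- species_conversions()
  expect_equal(conv$afdw_factor[conv$species == "Lucinoma capensis"], 0.091)
  expect_equal(conv$afdw_factor[conv$species == "Nassarius vinctus"], 0.081)
  expect_equal(conv$afdw_factor[conv$species == "Lembulus bicuspidatus"],
               0.084)
})

test_that("flux_rates processes a long-format table end to end", {
  long <- data.frame(
    vial_id = rep(c("a1", "b1"), each = 2),
    species = rep(c("Lucinoma capensis", ""), each = 2),
    analyte = "nitrate",
    time_h = c(0, 50, 0, 50),
    concentration = c(30, 20, 30, 30),
    volume_l = 0.02,
    is_blank = rep(c(FALSE, TRUE), each = 2),
    wet_weight_g = c(0.1099, 0.1099, NA, NA),
    stringsAsFactors = FALSE
  )
  f <- tempfile(fileext = ".csv")
  write.csv(long, f, row.names = FALSE)
  tab <- flux_rates(read_incubations(f))
  unlink(f)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$afdw_g, 0.1099 * 0.091)
  expect_equal(tab$rate, (-10 / 50) * 0.02 / (0.1099 * 0.091))
  expect_error(flux_rates(long[long$is_blank, ]), "no animal")
})
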