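test_that("expected PON windows reproduce the published end-member bounds", {
  pelagic <- expected_pon_window(
    end_member("nitrate_pelagic", 5.7, 6.7, 4.0, 10.0))
  expect_equal(pelagic$delta_min, -4.3)
  expect_equal(pelagic$delta_max, 2.7)

  benthic <- expected_pon_window(
    end_member("nitrate_benthic", 5.9, 14.3, 0.4, 5.0))
  expect_equal(benthic$delta_min, 0.9)
  expect_equal(benthic$delta_max, 13.9)

  # dinitrogen: degenerate source interval, fixation fractionation 0-2.5
  n2 <- expected_pon_window(end_member("dinitrogen", 0.6, 0.6, 0, 2.5))
  expect_equal(n2$delta_min, -1.9)
  expect_equal(n2$delta_max, 0.6)

  # zero fractionation leaves the source interval untouched
  id <- expected_pon_window(end_member("custom", 2, 5, 0, 0))
  expect_equal(c(id$delta_min, id$delta_max), c(2, 5))

  expect_error(end_member("custom", 5, 2, 0, 1), "inverted")
  expect_error(end_member("custom", 2, 5, 3, 1), "inverted")
})

test_that("window algebra matches a brute-force grid oracle", {
  set.seed(101)
  grid <- seq(0, 1, length.out = 100)
  for (i in 1:50) {
    s <- sort(runif(2, -10, 15))
    e <- sort(runif(2, 0, 20))
    w <- expected_pon_window(end_member("custom", s[1], s[2], e[1], e[2]))
    # every source delta minus every epsilon, dense 100x100 grid
    combos <- outer(s[1] + grid * diff(s), e[1] + grid * diff(e), `-`)
    expect_equal(w$delta_min, min(combos))
    expect_equal(w$delta_max, max(combos))
    # exact interval-arithmetic identity: widths add
    expect_equal(w$delta_max - w$delta_min, diff(s) + diff(e))
  }
})

test_that("consumer enrichment windows add the trophic offset", {
  w <- consumer_enrichment_window(4.6, 10.0, 2.3, 3.4)
  expect_equal(c(w$delta_min, w$delta_max), c(6.9, 13.4))
  w <- consumer_enrichment_window(3, 7, 0, 0)
  expect_equal(c(w$delta_min, w$delta_max), c(3, 7))
  w <- consumer_enrichment_window(5.3, 5.3, 2.3, 3.4)
  expect_equal(c(w$delta_min, w$delta_max), c(7.6, 8.7))
  expect_error(consumer_enrichment_window(7, 3, 1, 2), "inverted")
})

test_that("composition of window operations equals direct arithmetic", {
  set.seed(202)
  for (i in 1:10) {
    s <- sort(runif(2, -5, 10)); e <- sort(runif(2, 0, 10))
    en <- sort(runif(2, 0, 4))
    base <- expected_pon_window(end_member("custom", s[1], s[2], e[1], e[2]))
    comp <- consumer_enrichment_window(base$delta_min, base$delta_max,
                                       en[1], en[2])
    expect_equal(comp$delta_min, s[1] - e[2] + en[1])
    expect_equal(comp$delta_max, s[2] - e[1] + en[2])
  }
})

test_that("ammonium inherits sediment PON delta-15N unchanged", {
  expect_equal(ammonium_delta_from_sediment_pon(5.6), 5.6)
  expect_equal(ammonium_delta_from_sediment_pon(4.3), 4.3)
  x <- runif(10, -5, 15)
  expect_equal(ammonium_delta_from_sediment_pon(x), x)
  expect_error(ammonium_delta_from_sediment_pon(NA_real_), "finite")
})

test_that("excreted ammonium is depleted by the excretion fractionation", {
  expect_equal(excreted_ammonium_delta(-2.5, 2.7), -5.2)
  expect_equal(excreted_ammonium_delta(4, 0), 4)
  expect_equal(excreted_ammonium_delta(0, 2.7), -2.7)
})

test_that("source attribution excludes what cannot explain the gills", {
  wins <- list(
    expected_pon_window(end_member("dinitrogen", 0.6, 0.6, 0, 2.5)),
    expected_pon_window(end_member("nitrate_benthic", 5.9, 14.3, 0.4, 5)),
    expected_pon_window(end_member("ammonium", 4.3, 5.6, 5, 20))
  )
  verdicts <- attribute_nitrogen_source(-4.9, 0.7, wins, k_sd = 1)
  expect_equal(verdicts$verdict, c("excluded", "excluded", "consistent"))
  # ammonium window from interval arithmetic: (-15.7, 0.6)
  expect_equal(verdicts$window_min[3], -15.7)
  expect_equal(verdicts$window_max[3], 0.6)
  expect_error(attribute_nitrogen_source(-4.9, 0.7, list()), "empty")
})

test_that("a mean inside a window is consistent at every k", {
  w <- pon_window(-2, 2, "custom")
  for (k in c(0, 0.5, 1, 3)) {
    expect_equal(attribute_nitrogen_source(0, 1, list(w), k)$verdict,
                 "consistent")
  }
})

test_that("attribution is monotone in k_sd and treats touching as overlap", {
  set.seed(303)
  for (i in 1:25) {
    m <- runif(1, -10, 10); s <- runif(1, 0, 3)
    b <- sort(runif(2, -10, 10))
    w <- pon_window(b[1], b[2])
    ks <- sort(runif(3, 0, 4))
    v <- vapply(ks, function(k) {
      attribute_nitrogen_source(m, s, list(w), k)$verdict
    }, character(1))
    # once consistent, stays consistent as k grows
    idx <- which(v == "consistent")
    expect_true(length(idx) == 0 || all(seq(min(idx), 3) %in% idx))
  }
  touch <- pon_window(1, 2)
  expect_equal(attribute_nitrogen_source(0, 1, list(touch), 1)$verdict,
               "consistent")
})

test_that("closed-system recycling check compares gill and excreted pools", {
  expect_true(recycling_consistency(-4.9, -5.2, 0.7))
  expect_true(recycling_consistency(-5.2, -5.2, 0.1))
  expect_false(recycling_consistency(-4.9, 5.0, 0.7))
  expect_error(recycling_consistency(-4.9, -5.2, 0), "> 0")
})

test_that("default end-members assemble from the study constants", {
  ems <- default_end_members()
  expect_named(ems, c("dinitrogen", "nitrate_pelagic", "nitrate_benthic",
                      "ammonium"))
  wins <- lapply(ems, expected_pon_window)
  expect_equal(wins$nitrate_pelagic$delta_min, -4.3)
  expect_equal(wins$ammonium$delta_min, 4.3 - 20)
})
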