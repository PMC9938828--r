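test_that("the contamination factor matches reported and boundary cases", {
  expect_equal(round(contamination_factor(0.36, 15), 2), -0.98)
  expect_equal(contamination_factor(50, 50), 0)
  expect_equal(contamination_factor(0, 7), -1)
  expect_error(contamination_factor(1, 0), "S must be")
  expect_error(contamination_factor(-1, 5), ">= 0")
})

test_that("contamination factor is monotone in M and antitone in S", {
  set.seed(11)
  m <- sort(runif(25, 0, 50))
  expect_true(all(diff(contamination_factor(m, 10)) > 0))
  s <- sort(runif(25, 1, 400))
  expect_true(all(diff(contamination_factor(5, s)) < 0))
})

test_that("degree of contamination reproduces the seasonal EPA values", {
  for (season in c("winter", "summer")) {
    conc <- vapply(epa_reg$metal, ref_mean, numeric(1), season = season)
    cd <- degree_of_contamination(contamination_factor(conc, epa_reg$standard))
    expect_equal(round(cd, 2), if (season == "winter") -3.74 else -3.82)
  }
  expect_equal(degree_of_contamination(rep(0, 4)), 0)
  expect_error(degree_of_contamination(numeric(0)), "empty")
})

test_that("degree of contamination equals a left-fold sum oracle", {
  set.seed(23)
  for (k in 1:20) {
    cf <- runif(sample(2:10, 1), -1, 5)
    fold <- 0
    for (v in cf) fold <- fold + v
    expect_equal(degree_of_contamination(cf), fold)
    expect_equal(degree_of_contamination(rev(cf)),
                 degree_of_contamination(cf))
  }
})

test_that("contamination classes are total, exclusive, and edge-assigned", {
  expect_equal(classify_cd(-3.74), "significantly_low")
  expect_equal(classify_cd(2), "moderate")
  expect_equal(classify_cd(3.5), "high")
  # band edges go to the lower-severity class
  expect_equal(classify_cd(1), "significantly_low")
  expect_equal(classify_cd(3), "moderate")
  set.seed(3)
  x <- runif(200, -5, 6)
  cls <- classify_cd(x)
  expect_true(all(cls %in% c("significantly_low", "moderate", "high")))
})

test_that("unit weights invert the standard", {
  expect_equal(unit_weight(2), 0.5)
  expect_equal(trunc_decimals(unit_weight(6), 4), 0.1666)
  expect_equal(unit_weight(1), 1)
  expect_equal(unit_weight(10, k = 2), 0.2)
  expect_error(unit_weight(0), "S must be")
  expect_error(unit_weight(10, k = -1), "k")
})

test_that("the sub-index uses absolute excursions from the ideal value", {
  # Mn has ideal 100 above its EPA standard 50: |M - I| / |S - I|
  expect_equal(round(sub_index(2.28, 50, 100), 2), 195.44)
  expect_equal(sub_index(0.32, 2, 0), 16)
  expect_equal(sub_index(50, 50, 0), 100)
  expect_error(sub_index(1, 10, 10), "ideal")
})

test_that("the pollution index is a bounded, scale-invariant weighted mean", {
  set.seed(17)
  for (k in 1:20) {
    n <- sample(2:8, 1)
    w <- runif(n, 0.001, 1)
    q <- runif(n, 0, 300)
    h <- hpi(w, q)
    expect_gte(h, min(q))
    expect_lte(h, max(q))
    # proportionality constant k cancels
    expect_equal(hpi(w * 7.3, q), h)
  }
  expect_equal(hpi(c(0.2, 0.5, 0.9), rep(42, 3)), 42)
  expect_error(hpi(c(a = 1, b = 2), c(a = 10, c = 20)), "differ")
})

test_that("full-precision and printed-table HPI evaluate the EPA winter case", {
  conc <- vapply(epa_reg$metal, ref_mean, numeric(1), season = "winter")
  w <- unit_weight(epa_reg$standard)
  q <- sub_index(conc, epa_reg$standard, epa_reg$ideal)
  expect_equal(hpi(w, q, rounding = "table"), 20.82, tolerance = 0.01 / 20.82)
  expect_equal(hpi(w, q, rounding = "full"), 20.47, tolerance = 0.02 / 20.47)
})

test_that("pollution-index classes partition the scale", {
  expect_equal(classify_hpi(20.82), "excellent")
  expect_equal(classify_hpi(75), "good")
  expect_equal(classify_hpi(150), "poor")
  expect_equal(classify_hpi(250), "very_poor")
  expect_equal(classify_hpi(310), "unsuitable")
  # edges belong to the upper band as stated by the band definitions
  expect_equal(classify_hpi(50), "good")
  expect_equal(classify_hpi(300), "unsuitable")
  expect_error(classify_hpi(-1), ">= 0")
})

test_that("compute_indices assembles the full chain per agency and season", {
  out <- compute_indices(ref_summary)
  expect_equal(nrow(out$indices), 4)
  expect_equal(nrow(out$metals), 16)
  # C_d equals the sum of the stored per-metal factors
  for (i in seq_len(nrow(out$indices))) {
    g <- out$indices[i, ]
    cf <- out$metals$cf[out$metals$agency == g$agency &
                          out$metals$season == g$season]
    expect_equal(g$cd, sum(cf))
  }
  expect_true(all(out$indices$cd_class == "significantly_low"))
  expect_true(all(out$indices$hpi_class == "excellent"))
  # weights are in (0, 1] for the default standards at k = 1
  expect_true(all(out$metals$w > 0 & out$metals$w <= 1))
})
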