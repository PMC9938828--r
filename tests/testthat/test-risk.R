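test_that("chronic daily intake reproduces reported child point estimates", {
  child <- profiles_def$children
  expect_equal(round(cdi(2.28, child), 5), 0.00025)
  expect_equal(round(cdi(8.72, child), 4), 0.0010)
  expect_equal(round(cdi(10.36, child), 4), 0.0012)
  expect_equal(cdi(0, child), 0)
})

test_that("cdi validates its exposure inputs", {
  child <- profiles_def$children
  expect_error(cdi(1, child, ef = 100), "EF range")
  expect_error(cdi(-1, child), ">= 0")
  expect_error(cdi(1, list(ir = 1)), "exposure_profile")
  bad <- profiles_def$children
  bad$lifetime_years <- 0
  expect_error(cdi(1, bad, endpoint = "carcinogenic"), "lifetime")
})

test_that("cdi is linear in C, IR, EF and inversely proportional to BW", {
  set.seed(31)
  for (k in 1:15) {
    C <- runif(1, 0, 20); ir <- runif(1, 0.5, 3); ef <- runif(1, 180, 365)
    ed <- runif(1, 1, 60); bw <- runif(1, 5, 90)
    p <- exposure_profile("x", ir, 180, ef, 365, ed, bw)
    # brute-force re-evaluation of the dose equation
    oracle <- C * ir * ef * ed / (1000 * bw * (ed * 365))
    expect_equal(cdi(C, p, ef = ef), oracle)
    expect_equal(cdi(2 * C, p, ef = ef), 2 * cdi(C, p, ef = ef))
    p2 <- exposure_profile("x", ir, 180, ef, 365, ed, 2 * bw)
    expect_equal(cdi(C, p2, ef = ef), cdi(C, p, ef = ef) / 2)
  }
})

test_that("the noncarcinogenic intake is independent of exposure duration", {
  for (ed in c(1, 6, 25, 50)) {
    p <- exposure_profile("x", 1.25, 180, 345, 365, ed, 10.64)
    expect_equal(cdi(5, p), cdi(5, profiles_def$children))
  }
})

test_that("hazard quotients divide by the configured safe dose", {
  child <- profiles_def$children
  expect_equal(hq(0.14, rfd = 0.14), 1)
  expect_equal(hq(cdi(0.32, child), rfd = 3e-4), 0.1184,
               tolerance = 5e-4 / 0.1184)
  expect_equal(hq(cdi(0.36, child), tdi = 0.0035), 0.01142,
               tolerance = 5e-4 / 0.01142)
  expect_error(hq(0.1, metal = "Xx"), "Xx")
})

test_that("the hazard index sums quotients and reproduces the child winter value", {
  child <- profiles_def$children
  conc <- vapply(epa_reg$metal, ref_mean, numeric(1), season = "winter")
  hqs <- mapply(hq, cdi(conc, child), epa_reg$rfd, epa_reg$tdi, epa_reg$metal)
  expect_equal(hi(hqs), 0.133, tolerance = 0.002 / 0.133)
  expect_gte(hi(hqs), max(hqs))
  expect_equal(hi(rep(0, 4)), 0)
  expect_error(hi(numeric(0)), "empty")
})

test_that("adult/child hazard ratio equals the intake-to-weight closed form", {
  child <- profiles_def$children
  adult <- profiles_def$adults
  conc <- c(3, 1, 0.5, 12)
  ratio <- hi(cdi(conc, adult) / c(1, 1, 1, 1)) /
    hi(cdi(conc, child) / c(1, 1, 1, 1))
  expect_equal(ratio, (adult$ir * child$bw) / (child$ir * adult$bw))
})

test_that("carcinogenic risk reproduces the reported seasonal range endpoints", {
  child <- profiles_def$children
  adult <- profiles_def$adults
  sf <- epa_reg$sf[epa_reg$metal == "Pb"]
  cr_at <- function(conc, prof) cr(cdi(conc, prof, "carcinogenic"), sf)
  expect_equal(cr_at(0.22, child), 1.78e-8, tolerance = 0.02)
  expect_equal(cr_at(3.80, adult), 6.90e-7, tolerance = 0.02)
  expect_equal(cr_at(0, child), 0)
  expect_error(cr(0.1, NA), "absent")
})

test_that("carcinogenic risk is monotone across min/mean/max concentrations", {
  out <- compute_risk(ref_summary)$cancer
  for (g in unique(out$group)) {
    for (s in unique(out$season)) {
      sub <- out[out$group == g & out$season == s, ]
      expect_lte(sub$cr[sub$statistic == "min"],
                 sub$cr[sub$statistic == "mean"])
      expect_lte(sub$cr[sub$statistic == "mean"],
                 sub$cr[sub$statistic == "max"])
    }
  }
  expect_true(all(out$cr_class == "negligible"))
})

test_that("risk classification bands are total with documented edges", {
  expect_equal(classify_cr(2.88e-8), "negligible")
  expect_equal(classify_cr(5e-5), "threshold")
  expect_equal(classify_cr(2e-4), "potent")
  expect_equal(classify_cr(1e-6), "threshold")
  expect_equal(classify_cr(1e-4), "threshold")
})

test_that("compute_risk returns consistent dose, hazard and cancer blocks", {
  out <- compute_risk(ref_summary)
  expect_true(all(out$doses$cdi >= 0))
  expect_true(all(out$doses$hq >= 0))
  # HI rows equal the sum of their group-season quotients
  for (g in c("children", "adults")) {
    for (s in c("winter", "summer")) {
      q <- out$doses$hq[out$doses$group == g & out$doses$season == s]
      h <- out$hazard$hi[out$hazard$group == g & out$hazard$season == s]
      expect_equal(h, sum(q))
    }
  }
  expect_true(all(out$hazard$hi_class == "acceptable"))
  # CR only for slope-factor metals
  expect_equal(unique(out$cancer$metal), "Pb")
})
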