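test_that("distribution specs sample their analytic moments", {
  expect_equal(draw_dist(dist_fixed(5), 100), rep(5, 100))

  set.seed(101)
  tri <- draw_dist(dist_triangular(180, 345, 365), 1e6)
  expect_equal(mean(tri), (180 + 345 + 365) / 3, tolerance = 0.5 / 296.7)
  expect_true(all(tri >= 180 & tri <= 365))

  set.seed(102)
  ln <- draw_dist(dist_lognormal(8.72, 6.35), 1e6)
  expect_equal(mean(ln), 8.72, tolerance = 0.05 / 8.72)
  expect_equal(sd(ln), 6.35, tolerance = 0.1 / 6.35)
  expect_true(all(ln > 0))

  set.seed(103)
  tn <- draw_dist(dist_normal(1.25, 0.25, min = 0), 1e5)
  expect_true(all(tn >= 0))
  expect_equal(mean(tn), 1.25, tolerance = 0.01)
})

test_that("mixture draws pool their components", {
  set.seed(104)
  mx <- draw_dist(dist_mixture(list(dist_fixed(1), dist_fixed(3))), 1e5)
  expect_setequal(unique(mx), c(1, 3))
  expect_equal(mean(mx), 2, tolerance = 0.02)
})

test_that("spec constructors reject invalid parameters", {
  expect_error(dist_normal(1, -0.1), "sd")
  expect_error(dist_triangular(10, 5, 20), "min <= mode <= max")
  expect_error(dist_lognormal(-1, 1), "mean")
  expect_error(dist_mixture(list()), "nonempty")
  expect_error(mcs_config(percentiles = c(0, 95)), "between 0 and 100")
})

test_that("a lognormal spec with zero sd degenerates to a constant", {
  expect_equal(draw_dist(dist_lognormal(3.3, 0), 10), rep(3.3, 10))
})

test_that("the engine is bit-reproducible and collapses under fixed specs", {
  child <- profiles_def$children
  conc <- vapply(epa_reg$metal, ref_mean, numeric(1), season = "winter")
  det <- hi(mapply(hq, cdi(conc, child), epa_reg$rfd, epa_reg$tdi,
                   epa_reg$metal))
  specs <- list(IR = dist_fixed(child$ir), EF = dist_fixed(345),
                ED = dist_fixed(child$ed), BW = dist_fixed(child$bw),
                f = dist_fixed(child$f))
  for (i in seq_len(nrow(epa_reg))) {
    m <- epa_reg$metal[i]
    specs[[paste0("C_", m)]] <- dist_fixed(conc[i])
    dose <- ifelse(is.na(epa_reg$rfd[i]), epa_reg$tdi[i], epa_reg$rfd[i])
    specs[[paste0("RfD_", m)]] <- dist_fixed(dose)
  }
  res <- run_mcs(hi_model(epa_reg$metal), specs,
                 mcs_config(n_iter = 200, seed = 5))
  expect_identical(unique(res$draws), det)
  expect_identical(res$mean, det)
  expect_identical(unname(res$percentiles), c(det, det))
  expect_true(all(is.na(res$sensitivity)))

  again <- run_mcs(hi_model(epa_reg$metal), specs,
                   mcs_config(n_iter = 200, seed = 5))
  expect_identical(res$draws, again$draws)

  full <- run_hi_mcs("children", mcs_config(n_iter = 500, seed = 9))
  full2 <- run_hi_mcs("children", mcs_config(n_iter = 500, seed = 9))
  expect_identical(full$draws, full2$draws)
  expect_identical(full$sensitivity, full2$sensitivity)
})

test_that("a linear model's Monte Carlo mean obeys the law of large numbers", {
  a <- 3.7
  specs <- list(X = dist_normal(10, 2))
  res <- run_mcs(function(x) a * mcs_input(x, "X"), specs,
                 mcs_config(n_iter = 1e5, seed = 21))
  se <- a * 2 / sqrt(1e5)
  expect_lt(abs(res$mean - a * 10), 3 * se)
  expect_equal(res$mean, mean(res$draws))
  expect_lte(res$percentiles[[1]], median(res$draws))
  expect_gte(res$percentiles[[2]], median(res$draws))
})

test_that("missing model inputs are reported by name", {
  expect_error(
    run_mcs(function(x) mcs_input(x, "Z"), list(X = dist_fixed(1)),
            mcs_config(n_iter = 10, seed = 1)),
    "`Z`")
})

test_that("sensitivity attributes variance through signed rank correlations", {
  set.seed(61)
  # single varying input takes all of the variance
  one <- list(X = rnorm(500), K = rep(2, 500))
  out <- one$X * 3
  s <- sensitivity_contribution(one, out)
  expect_equal(unname(s[["X"]]), 100)
  expect_equal(unname(s[["K"]]), 0)
  # inverse dependence is signed negative
  s_inv <- sensitivity_contribution(one, 1 / (one$X + 10))
  expect_equal(unname(s_inv[["X"]]), -100)

  # two independent standard normal addends split the variance evenly
  two <- list(A = rnorm(1e5), B = rnorm(1e5))
  s2 <- sensitivity_contribution(two, two$A + two$B)
  expect_equal(unname(s2[["A"]]), 50, tolerance = 5 / 50)
  expect_equal(unname(s2[["B"]]), 50, tolerance = 5 / 50)
  expect_equal(sum(abs(s2)), 100)

  expect_error(sensitivity_contribution(one, rep(1, 500)), "constant")
  expect_error(sensitivity_contribution(list(X = 1:3), 1:5), "equal lengths")
})

test_that("varying only body weight drives carcinogenic risk inversely", {
  child <- profiles_def$children
  specs <- cr_specs(child)
  specs$C <- dist_fixed(0.36)
  specs$IR <- dist_fixed(child$ir)
  specs$EF <- dist_fixed(345)
  res <- run_mcs(cr_model(), specs, mcs_config(n_iter = 2000, seed = 77))
  expect_equal(unname(res$sensitivity[["BW"]]), -100)
  expect_true(all(res$sensitivity[setdiff(names(res$sensitivity), "BW")]
                  == 0))
})

test_that("default risk Monte Carlo reflects the study's qualitative structure", {
  cfg <- mcs_config(n_iter = 4000, seed = 31)
  for (g in c("children", "adults")) {
    res_hi <- run_hi_mcs(g, cfg)
    res_cr <- run_cr_mcs(g, cfg)
    expect_lt(unname(res_hi$sensitivity[["BW"]]), 0)
    expect_lt(unname(res_cr$sensitivity[["BW"]]), 0)
    expect_true(all(res_hi$draws > 0))
    # hazard stays below the safety threshold across the distribution
    expect_lt(unname(res_hi$percentiles[["95%"]]), 1)
    expect_lt(unname(res_cr$percentiles[["95%"]]), 1e-6)
  }
  res_cr <- run_cr_mcs("children", cfg)
  expect_equal(names(which.max(abs(res_cr$sensitivity))), "C")
})
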