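test_that("probit fit recovers a known IC50 from a noiseless curve", {
  dr <- simulate_dose_response(ic50 = 0.165, slope = 2.2)
  fit <- probit_ic50(dr)
  expect_equal(fit$ic50, 0.165, tolerance = 0.01)
  expect_equal(fit$beta1, 2.2, tolerance = 0.01)
  expect_false(fit$extrapolated)
})

test_that("a dose grid symmetric around its midpoint pins IC50 there", {
  cstar <- 2.5
  conc <- cstar * 10^seq(-0.6, 0.6, length.out = 7)
  resp <- pnorm(1.5 * (log10(conc) - log10(cstar)))
  fit <- probit_ic50(dose_response(conc, resp))
  expect_equal(fit$ic50, cstar, tolerance = 1e-6)
})

test_that("IC50 is scale-equivariant in concentration units", {
  dr <- simulate_dose_response(ic50 = 0.4, slope = 1.8)
  f1 <- probit_ic50(dr)
  k <- 1000   # mg/mL -> ug/mL
  dr2 <- dose_response(dr$concentrations * k, dr$responses)
  f2 <- probit_ic50(dr2)
  expect_equal(f2$ic50 / (k * f1$ic50), 1, tolerance = 1e-8)
})

test_that("binomial-noise simulations recover IC50 with small median bias", {
  true_ic50 <- 0.165
  nsim <- 200
  est <- with_seed(99, replicate(nsim, {
    dr <- simulate_dose_response(true_ic50, slope = 2.2, n = 4)
    suppressWarnings(tryCatch(probit_ic50(dr)$ic50, error = function(e) NA))
  }))
  est <- est[!is.na(est)]
  expect_gt(length(est), 0.9 * nsim)
  expect_lt(abs(stats::median(est) / true_ic50 - 1), 0.05)
})

test_that("degenerate dose-response inputs are rejected or flagged", {
  expect_error(dose_response(c(1, 2, 2), c(0.1, 0.5, 0.9)), "increasing")
  expect_error(dose_response(c(-1, 2, 3), c(0.1, 0.5, 0.9)), "positive")
  expect_error(dose_response(c(1, 2, 3), c(0.1, 0.5, 1.2)), "\\[0, 1\\]")
  expect_error(probit_ic50(dose_response(c(1, 2, 3), c(0.4, 0.4, 0.4))),
               "flat")
  # responses never cross 50%: extrapolation warning
  conc <- c(1, 2, 4, 8)
  resp <- pnorm(2 * (log10(conc) - log10(50)))
  expect_warning(probit_ic50(dose_response(conc, resp)), "extrapolation")
})

test_that("linear calibration inverts exactly on noiseless standards", {
  cal <- linear_calibration(c(0, 1), c(0, 1))
  expect_equal(quantify(cal, 0.5), 0.5)
  cal2 <- linear_calibration(0:5, 2 * (0:5) + 1)
  expect_equal(quantify(cal2, 5), 2, tolerance = 1e-12)
  expect_equal(cal2$slope, 2)
  expect_equal(cal2$r_squared, 1)
  # quantifying a standard's own signal returns its concentration
  expect_equal(quantify(cal2, predict(cal2$fit)), 0:5, tolerance = 1e-9,
               ignore_attr = TRUE)
  flat <- linear_calibration(0:3, rep(2, 4))
  expect_error(quantify(flat, 2), "slope")
})

test_that("OLS slope estimates are well-calibrated under known noise", {
  true_slope <- 0.8
  x <- seq(0, 500, length.out = 9)   # Trolox-style standard grid
  hits <- with_seed(7, replicate(1000, {
    y <- 1.5 + true_slope * x + rnorm(9, sd = 20)
    cal <- linear_calibration(x, y)
    se <- summary(cal$fit)$coefficients["x", "Std. Error"]
    abs(cal$slope - true_slope) <= 3 * se
  }))
  expect_gt(mean(hits), 0.95)
})

test_that("inhibition percentages reproduce the control-relative arithmetic", {
  expect_equal(inhibition_percent(62.1, 33.4), 46.21578, tolerance = 1e-5)
  expect_equal(round(inhibition_percent(62.1, 33.4)), 46)
  expect_equal(round(inhibition_percent(62.1, 22.82)), 63)
  expect_equal(inhibition_percent(50, 50), 0)
  expect_error(inhibition_percent(0, 10), "control")
  expect_error(inhibition_percent(62, 110), "\\[0, 100\\]")
  # antitone in the treated value, bounded above by 100
  v <- inhibition_percent(60, c(50, 30, 10, 0))
  expect_true(!is.unsorted(v))
  expect_true(all(v <= 100))
})

test_that("the ROS table yields the published inhibition pattern", {
  tab <- inhibition_table(ros_cellrox(), control_label = "Control",
                          flag_threshold = 70)
  at <- function(trt, tp) tab[tab$treatment == trt & tab$timepoint == tp, ]
  expect_equal(at("PGAL 100", 24)$inhibition_rounded, 46)
  expect_equal(at("PGAL 200", 24)$inhibition_rounded, 63)
  expect_equal(at("PGAL-His 266", 24)$inhibition_rounded, 58)
  # 48-h polymer treatments all exceed 70% inhibition
  for (trt in c("PGAL 100", "PGAL 200", "PGAL-His 133", "PGAL-His 266")) {
    expect_gt(at(trt, 48)$inhibition, 70)
    expect_true(at(trt, 48)$flagged)
  }
  # free histidine barely moves ROS at 24 h
  expect_lt(at("His 33", 24)$inhibition, 10)
  expect_lt(at("His 66", 24)$inhibition, 10)
})

test_that("inhibition tables validate their control rows", {
  base <- data.frame(treatment = c("Control", "T1"), timepoint = 24,
                     percent_positive = c(50, 25))
  out <- inhibition_table(base)
  expect_equal(out$inhibition, 50)
  no_ctrl <- base[base$treatment != "Control", ]
  expect_error(inhibition_table(no_ctrl), "control")
  only_ctrl <- base[base$treatment == "Control", ]
  expect_equal(nrow(inhibition_table(only_ctrl)), 0)
})
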