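test_that("activity slope is the OLS slope over the initial read window", {
  t <- (0:7) * 15
  expect_equal(activity_slope(t, 3 * t + 7), 3)
  expect_equal(activity_slope(t, rep(42, 8)), 0)
  # only the first n_reads points enter: later curvature is ignored
  t_long <- (0:19) * 15
  y <- 2 * t_long
  y[t_long > 105] <- 2 * 105
  expect_equal(activity_slope(t_long, y, n_reads = 8), 2)
  expect_error(activity_slope(0, 5), "at least 2 points")
})

test_that("slope recovers the programmed rate from generated progress curves", {
  d <- kinetics_design(seed = 5)
  g <- gen_progress_curves(d)
  for (s in d$conc) {
    cur <- dplyr::filter(g$curves, .data$conc == s, .data$replicate == 1)
    v_true <- g$truth$v_true[g$truth$conc == s]
    # SE of an OLS slope with 8 reads at 15 s spacing and sd = noise_sd
    se <- d$noise_sd / sqrt(sum((cur$time - mean(cur$time))^2))
    expect_lt(abs(activity_slope(cur$time, cur$rfu) - v_true), 4 * se)
  }
})

test_that("Hill fit recovers Km, Vmax and the Hill exponent from noiseless data", {
  d1 <- kinetics_design(noise_sd = 0, km = 2.2, vmax = 50, hill = 1)
  g1 <- gen_progress_curves(d1)
  rates <- dplyr::summarise(dplyr::group_by(g1$curves, .data$conc, .data$replicate),
                            v = activity_slope(.data$time, .data$rfu),
                            .groups = "drop")
  fit <- fit_hill_kinetics(rates$conc, rates$v)
  expect_equal(fit$km, 2.2, tolerance = 1e-6)
  expect_equal(fit$hill, 1.0, tolerance = 1e-6)
  expect_equal(fit$vmax, 50, tolerance = 1e-6)

  d2 <- kinetics_design(noise_sd = 0, km = 5, vmax = 80, hill = 2)
  g2 <- gen_progress_curves(d2)
  fit2 <- fit_hill_kinetics(g2$truth$conc, g2$truth$v_true)
  expect_equal(fit2$hill, 2.0, tolerance = 1e-6)
  expect_equal(fit2$km, 5, tolerance = 1e-6)
})

test_that("doubling all rates doubles Vmax and leaves Km and the exponent alone", {
  g <- gen_progress_curves(kinetics_design(noise_sd = 0))
  f1 <- fit_hill_kinetics(g$truth$conc, g$truth$v_true)
  f2 <- fit_hill_kinetics(g$truth$conc, 2 * g$truth$v_true)
  expect_equal(f2$vmax, 2 * f1$vmax, tolerance = 1e-6)
  expect_equal(f2$km, f1$km, tolerance = 1e-6)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-6)
})

test_that("Michaelis-Menten mode pins the exponent and flags extrapolated Km", {
  g <- gen_progress_curves(kinetics_design(noise_sd = 0))
  fit <- fit_hill_kinetics(g$truth$conc, g$truth$v_true, fix_hill = 1)
  expect_identical(fit$hill, 1)
  expect_equal(fit$km, 2.2, tolerance = 1e-6)

  # nearly concentration-independent rates -> Km far outside the titration
  v_flat <- 50 * g$truth$conc / (50000 + g$truth$conc)
  flagged <- fit_hill_kinetics(g$truth$conc, v_flat, fix_hill = 1)
  expect_identical(flagged$flag, "extrapolated_km")
})

test_that("percent inhibition is relative slope loss, clamped with a warning", {
  expect_equal(percent_inhibition(0, 10), 100)
  expect_equal(percent_inhibition(10, 10), 0)
  expect_equal(percent_inhibition(5, 10), 50)
  expect_warning(p <- percent_inhibition(-3, 10), "clamped")
  expect_equal(p, 110)
  expect_error(percent_inhibition(5, 0), "positive")
})

test_that("three-parameter logistic recovers the generating IC50", {
  g <- gen_dose_response(inhibition_design(noise_sd = 0, ic50 = 1.2))
  fit <- fit_ic50(g$curve$conc, g$curve$inhibition)
  expect_equal(fit$ic50, 1.2, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-6)

  pinned <- fit_ic50(g$curve$conc, g$curve$inhibition, pin_limits = TRUE)
  expect_equal(pinned$ic50, 1.2, tolerance = 1e-6)
})

test_that("IC50 covaries exactly with the concentration unit", {
  g <- gen_dose_response(inhibition_design(noise_sd = 0, ic50 = 1.2))
  in_nM <- fit_ic50(g$curve$conc, g$curve$inhibition)
  in_uM <- fit_ic50(g$curve$conc / 1000, g$curve$inhibition)
  expect_equal(in_uM$ic50 * 1000, in_nM$ic50, tolerance = 1e-6)
})

test_that("flat inhibition data are flagged instead of yielding a finite IC50", {
  conc <- 0.078125 * 2^(0:12)
  flat <- fit_ic50(conc, rep(0, length(conc)))
  expect_false(flat$converged)
  expect_identical(flat$flag, "no_transition")
  expect_true(is.na(flat$ic50))
})

test_that("melt Tm sits at the derivative extremum of the transition", {
  g <- gen_melt_curve(melt_design(noise_sd = 0, tm = 51.6))
  res <- melt_tm(g$curve$temperature, g$curve$rfu)
  expect_lt(abs(res$tm - 51.6), 0.25)
  expect_true(is.na(res$flag))

  # uniform signal scaling leaves Tm unchanged
  res10 <- melt_tm(g$curve$temperature, 10 * g$curve$rfu)
  expect_equal(res10$tm, res$tm, tolerance = 1e-9)

  flat <- melt_tm(g$curve$temperature, rep(1000, nrow(g$curve)))
  expect_identical(flat$flag, "no_transition")
  expect_true(is.na(flat$tm))

  # transition pushed against the scan edge is flagged
  edge <- gen_melt_curve(melt_design(noise_sd = 0, tm = 93.5, width = 2))
  expect_false(is.na(melt_tm(edge$curve$temperature, edge$curve$rfu)$flag))
})

test_that("two comparable transitions raise the multimodality flag", {
  d <- melt_design(noise_sd = 0)
  t1 <- gen_melt_curve(melt_design(noise_sd = 0, tm = 45))$curve
  t2 <- gen_melt_curve(melt_design(noise_sd = 0, tm = 70))$curve
  res <- melt_tm(t1$temperature, t1$rfu + t2$rfu)
  expect_identical(res$flag, "multimodal")
})

test_that("Tm increments along a condition ladder and stabilization losses", {
  ladder <- c("apo", "NADH", "NADH+drug")
  tms <- tibble::tibble(
    variant = rep(c("WT", "DM"), each = 3),
    condition = rep(ladder, 2),
    tm = c(48.0, 53.25, 53.25 + 21.5,
           44.5, 47.25, 47.25 + 8.5)
  )
  inc <- delta_tm(tms, ladder)
  expect_equal(inc$increment[inc$variant == "WT"], c(5.25, 21.5))
  expect_equal(inc$increment[inc$variant == "DM"], c(2.75, 8.5))
  # increments along the ladder sum to the total Tm change
  for (v in c("WT", "DM")) {
    expect_equal(sum(inc$increment[inc$variant == v]),
                 tms$tm[tms$variant == v & tms$condition == "NADH+drug"] -
                   tms$tm[tms$variant == v & tms$condition == "apo"])
  }
  loss <- stabilization_loss(inc, reference = "WT")
  expect_equal(loss$loss[loss$condition == "NADH+drug"], 13.0)

  # identical Tm across the ladder -> all increments zero
  same <- tibble::tibble(variant = "WT", condition = ladder, tm = 50)
  expect_true(all(delta_tm(same, ladder)$increment == 0))

  # missing rung -> missing increment, not an error
  gap <- tms[tms$condition != "NADH" | tms$variant != "DM", ]
  inc_gap <- delta_tm(gap, ladder)
  expect_true(all(is.na(inc_gap$increment[inc_gap$variant == "DM"])))
})
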