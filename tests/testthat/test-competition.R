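test_that("rate extraction recovers an exact linear decay and flags flat traces", {
  tr <- make_line_trace(v = 1e-4, a0 = 0.343)
  r <- extract_rate(tr)
  expect_equal(r$v, 1e-4, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  expect_false(r$non_bleaching)
  # molar rate via the crocin coefficient
  expect_equal(r$v_molar, 1e-4 / 13726, tolerance = 1e-12)

  flat <- kinetic_trace("flat", "none", 0, 25, seq(0, 600, 10),
                        rep(0.343, 61))
  rf <- extract_rate(flat)
  expect_equal(rf$v, 0)
  expect_true(rf$non_bleaching)

  short <- kinetic_trace("s", "none", 0, 25, c(0, 100, 200, 300),
                         c(0.3, 0.29, 0.28, 0.27))
  expect_error(extract_rate(short), "insufficient data")
})

test_that("rate extraction is invariant to a constant absorbance offset", {
  set.seed(5)
  t <- seq(0, 600, 10)
  a <- 0.343 - 8e-5 * t + rnorm(length(t), 0, 0.002)
  tr1 <- kinetic_trace("a", "x", 5, 25, t, a)
  tr2 <- kinetic_trace("b", "x", 5, 25, t, a + 0.123)
  expect_equal(extract_rate(tr1)$v, extract_rate(tr2)$v, tolerance = 1e-12)
})

test_that("velocity ratio matches the competition equation plug-ins", {
  v0 <- 1e-4
  expect_equal(velocity_ratio(v0, v0), 1.0)
  # v = v0 / (1 + (ka/kc) [A]/[C])
  expect_equal(velocity_ratio(v0, v0 / (1 + 4.015 * 1)), 5.015)
  expect_equal(velocity_ratio(v0, v0 / (1 + 2.230 * 2)), 5.46)
  complete <- velocity_ratio(v0, 0)
  expect_true(is.infinite(complete))
  expect_true(attr(complete, "complete_inhibition"))
  expect_error(velocity_ratio(0, 1e-5), "v0")
})

test_that("competition slope regression recovers ka/kc with unit intercept", {
  x <- c(0.25, 0.5, 1, 2, 4)
  fit <- fit_competition_slope(data.frame(ratio_ac = x, v_ratio = 1 + 4.015 * x))
  expect_equal(fit$slope, 4.015, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)

  # zero-effect solute: v = v0 everywhere
  null_fit <- fit_competition_slope(data.frame(ratio_ac = x, v_ratio = rep(1, 5)))
  expect_equal(null_fit$slope, 0, tolerance = 1e-12)

  expect_error(fit_competition_slope(data.frame(ratio_ac = rep(1, 3),
                                                v_ratio = c(1, 2, 3))),
               "degenerate")
  expect_warning(fit_competition_slope(data.frame(ratio_ac = c(1, 1.5, 2),
                                                  v_ratio = c(5, 7, 9))),
                 "4-fold")
  expect_warning(fit_competition_slope(data.frame(ratio_ac = x,
                                                  v_ratio = 2 + 4 * x)),
                 "intercept")
})

test_that("Trolox equivalents are slope ratios", {
  x <- c(0.25, 0.5, 1, 2)
  mk <- function(s) fit_competition_slope(data.frame(ratio_ac = x,
                                                     v_ratio = 1 + s * x))
  trolox <- mk(2.230)
  expect_equal(trolox_equivalents(trolox, trolox)$trolox_equivalents, 1.0)
  expect_equal(trolox_equivalents(mk(4.015), trolox)$trolox_equivalents,
               1.80, tolerance = 0.005)
  expect_equal(trolox_equivalents(mk(0.023), trolox)$trolox_equivalents,
               0.0103, tolerance = 2e-3)
})

test_that("kinetic percent inhibition and its IC50 follow the closed form", {
  v0 <- 1e-4
  expect_equal(percent_inhibition_kinetic(v0, v0), 0)
  expect_equal(percent_inhibition_kinetic(v0, v0 / 2), 50)
  # %In = 50 exactly where (ka/kc) [A]/[C] = 1
  v <- v0 / (1 + 4.015 * (1 / 4.015))
  expect_equal(percent_inhibition_kinetic(v0, v), 50)
  expect_error(percent_inhibition_kinetic(0, 1), "degenerate")

  # noiseless series from ka/kc = 4.015 at [C] = 25: IC50 = 25/4.015
  conc <- 6.2267 * c(0.25, 0.5, 1, 2, 4)
  inh <- 100 * (1 - 1 / (1 + 4.015 * conc / 25))
  res <- ic50_from_kinetics(data.frame(conc = conc, inhibition = inh),
                            solute = "uric acid")
  expect_equal(res$value, 25 / 4.015, tolerance = 1e-3)
  expect_equal(res$assay_id, "CROCIN")

  # Trolox-like series
  conc_t <- (25 / 2.230) * c(0.25, 0.5, 1, 2, 4)
  inh_t <- 100 * (1 - 1 / (1 + 2.230 * conc_t / 25))
  res_t <- ic50_from_kinetics(data.frame(conc = conc_t, inhibition = inh_t))
  expect_equal(res_t$value, 25 / 2.230, tolerance = 1e-3)

  low <- ic50_from_kinetics(data.frame(conc = c(1, 2, 4),
                                       inhibition = c(5, 9, 16)))
  expect_true(low$censored)
})

test_that("simulated duplicate panel recovers slopes within 5% under default noise", {
  cfg <- simulation_config(seed = 77,
                           kinetic = list(ka_kc = c("uric acid" = 4.015,
                                                    "Trolox" = 2.230)))
  panel <- crocin_panel(simulate_kinetic_panel(cfg))
  expect_lt(abs(panel[["uric acid"]]$fit$slope - 4.015) / 4.015, 0.05)
  expect_lt(abs(panel[["Trolox"]]$fit$slope - 2.230) / 2.230, 0.05)
  expect_equal(panel[["uric acid"]]$fit$trolox_equivalents,
               4.015 / 2.230, tolerance = 0.1)
})

test_that("slope ranking equals 1/IC50 ranking on noiseless panels", {
  ka_kc <- c("uric acid" = 4.015, "Trolox" = 2.230, "phenol" = 0.023,
             "p-cresol" = 0.016)
  cfg <- simulation_config(seed = 9, kinetic = list(ka_kc = ka_kc, noise_sd = 0))
  panel <- crocin_panel(simulate_kinetic_panel(cfg))
  slopes <- vapply(panel, function(r) r$fit$slope, numeric(1))
  ic50s <- vapply(panel, function(r) r$ic50$value, numeric(1))
  expect_equal(order(-slopes), order(ic50s))
  # intercept -> 1 and closed-form IC50 = [C]/(ka/kc) in the noise-free limit
  for (sol in names(ka_kc)) {
    expect_equal(panel[[sol]]$fit$intercept, 1, tolerance = 1e-6)
    expect_equal(panel[[sol]]$ic50$value, 25 / ka_kc[[sol]],
                 tolerance = 1e-3 * 25 / ka_kc[[sol]])
  }
})
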