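test_that("endpoint simulation is exact at sigma = 0 and deterministic under a seed", {
  cfg0 <- simulation_config(seed = 1, true_ic50s = c(x = 20), noise_sd = 0,
                            n_replicates = 1L,
                            conc_grid = function(ic50) c(10, 20, 40))
  plate <- simulate_endpoint_assay(cfg0)
  s <- plate[plate$role == "sample", ]
  f <- s$conc_umol_L / (s$conc_umol_L + 20)
  expect_equal(s$absorbance, 0.750 * (1 - f), tolerance = 1e-12)
  # at c = IC50 the well sits exactly midway between control and blank
  expect_equal(s$absorbance[s$conc_umol_L == 20], 0.750 / 2)
  expect_equal(plate$absorbance[plate$role == "control"], 0.750)

  cfg <- simulation_config(seed = 33, true_ic50s = c(x = 20))
  expect_identical(simulate_endpoint_assay(cfg), simulate_endpoint_assay(cfg))
  cfg2 <- simulation_config(seed = 34, true_ic50s = c(x = 20))
  expect_false(identical(simulate_endpoint_assay(cfg)$absorbance,
                         simulate_endpoint_assay(cfg2)$absorbance))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_endpoint_assay(simulation_config(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("control-well noise has the configured standard deviation", {
  cfg <- simulation_config(seed = 8, true_ic50s = c(x = 20), noise_sd = 0.005,
                           n_replicates = 1L)
  draws <- vapply(1:2000, function(i) {
    cfg$seed <- i
    p <- simulate_endpoint_assay(cfg)
    p$absorbance[p$role == "control"]
  }, numeric(1))
  expect_lt(abs(sd(draws - 0.750) - 0.005) / 0.005, 0.15)
})

test_that("kinetic simulation follows the competition law exactly at sigma = 0", {
  cfg <- simulation_config(seed = 2, kinetic = list(noise_sd = 0))
  # [A] = 0: slope is -v0 after the lag
  tr0 <- simulate_kinetic_trace(cfg, "none", 0)
  r0 <- extract_rate(tr0)
  expect_equal(r0$r_squared, 1)
  v0 <- r0$v
  expect_gt(v0, 0)
  # start absorbance = epsilon * [C]: 13726 * 25e-6
  expect_equal(tr0$abs_443[1], 13726 * 25e-6, tolerance = 1e-12)

  # ka/kc = 4.015 at [A] = [C]: v = v0 / 5.015
  tr <- simulate_kinetic_trace(cfg, "uric acid", 25)
  expect_equal(extract_rate(tr)$v, v0 / 5.015, tolerance = 1e-9)
  expect_error(simulate_kinetic_trace(cfg, "uric acid", -1), ">= 0")

  # full panel round-trip recovers ka/kc exactly
  panel <- crocin_panel(simulate_kinetic_panel(cfg))
  expect_equal(panel[["uric acid"]]$fit$slope, 4.015, tolerance = 1e-9)
  expect_equal(panel[["Trolox"]]$fit$slope, 2.230, tolerance = 1e-9)
})

test_that("mixture simulation hits f = 1/2 at the Loewe point and responds to lambda", {
  spec <- design_stock(c(a = 10, b = 30), multiplier = 5, final_volume = 1000)
  v_star <- 1000 / (2 * 5) # S = 1
  cfg1 <- simulation_config(seed = 4, noise_sd = 0,
                            mixture = list(spec = spec, lambda = 1,
                                           volume_grid = c(25, 50, v_star, 200, 400)))
  p1 <- simulate_mixture_response(cfg1)
  s1 <- p1[p1$role == "sample" & p1$conc_umol_L == v_star, ]
  expect_equal(s1$absorbance, rep(0.750 / 2, nrow(s1)), tolerance = 1e-12)

  cfg2 <- simulation_config(seed = 4, noise_sd = 0,
                            mixture = list(spec = spec, lambda = 2))
  r1 <- mixture_report(spec, build_inhibition_curve(
    simulate_mixture_response(simulation_config(seed = 4, noise_sd = 0,
                                                mixture = list(spec = spec, lambda = 1))),
    "mixture"))
  r2 <- mixture_report(spec, build_inhibition_curve(simulate_mixture_response(cfg2),
                                                    "mixture"))
  expect_gt(r2$ic50_volume, r1$ic50_volume)
  expect_equal(r2$additivity_index, 2, tolerance = 1e-4)
  expect_match(attr(simulate_mixture_response(cfg2), "interaction_model"),
               "lambda = 2")
})

test_that("censored solutes are generated as a bound, not literal inertness", {
  cfg <- simulation_config(seed = 15,
                           true_ic50s = c("methylguanidine" = NA),
                           c_max_censored = c("methylguanidine" = 910))
  plate <- simulate_endpoint_assay(cfg)
  curve <- build_inhibition_curve(plate, "methylguanidine")
  expect_equal(max(curve$points$conc), 910)
  res <- fit_ic50(curve)
  expect_true(res$censored)
  cfg_bad <- simulation_config(seed = 15, true_ic50s = c(mg = NA))
  expect_error(simulate_endpoint_assay(cfg_bad), "c_max_censored")
})

test_that("fixture sets run the full pipeline and are byte-identical under a seed", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  generate_fixture_set(123, dir1, noise_sd = 0, kinetic_noise_sd = 0)
  generate_fixture_set(123, dir2, noise_sd = 0, kinetic_noise_sd = 0)
  files <- c("abts_plate.csv", "hocl_plate.csv", "crocin_traces.csv",
             "mixture_plate.csv", "mixture_config.json", "manifest.json")
  expect_true(all(file.exists(file.path(dir1, files))))
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }

  # noise-free fixtures invert to the ground truths recorded in the manifest
  manifest <- jsonlite::read_json(file.path(dir1, "manifest.json"),
                                  simplifyVector = TRUE)
  plate <- read_endpoint_csv(file.path(dir1, "abts_plate.csv"))
  for (sol in c("uric acid", "phenol", "p-cresol", "L-tyrosine")) {
    truth <- manifest$abts_true_ic50[[sol]]
    fit <- fit_ic50(build_inhibition_curve(plate, sol))
    expect_lt(abs(fit$value - truth) / truth, 1e-3)
  }
  mg <- fit_ic50(build_inhibition_curve(plate, "methylguanidine"))
  expect_true(mg$censored)

  panel <- crocin_panel(read_kinetic_csv(file.path(dir1, "crocin_traces.csv")))
  for (sol in names(manifest$crocin_ka_kc)) {
    truth <- manifest$crocin_ka_kc[[sol]]
    expect_lt(abs(panel[[sol]]$fit$slope - truth) / truth, 1e-3)
  }

  spec <- read_mixture_config(file.path(dir1, "mixture_config.json"))
  curve <- build_inhibition_curve(read_endpoint_csv(file.path(dir1, "mixture_plate.csv")),
                                  "mixture")
  mr <- mixture_report(spec, curve)
  expect_equal(mr$additivity_index, manifest$lambda, tolerance = 1e-3)
  expect_equal(mr$classification, "SUB_ADDITIVE")
})
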