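abts_ic50s <- c("uric acid" = 16.75, "phenol" = 12.98, "p-cresol" = 3.99,
                "L-tyrosine" = 5.23)

test_that("stock design reproduces the published stock concentrations exactly", {
  abts <- design_stock(abts_ic50s, multiplier = 2, final_volume = 300, "ABTS")
  expect_equal(setNames(abts$components$stock_conc, abts$components$solute),
               c("uric acid" = 33.5, "phenol" = 25.96, "p-cresol" = 7.98,
                 "L-tyrosine" = 10.46))

  hocl <- design_stock(c("uric acid" = 5.75, "phenol" = 8.95,
                         "p-cresol" = 15.75, "L-tyrosine" = 2.83),
                       multiplier = 10, final_volume = 1500, "HOCL")
  expect_equal(hocl$components$stock_conc, c(57.5, 89.5, 157.5, 28.3))

  crocin <- design_stock(c("uric acid" = 6.90, "phenol" = 1125.81,
                           "p-cresol" = 1162.31),
                         multiplier = 10, final_volume = 2000, "CROCIN")
  expect_equal(crocin$components$stock_conc, c(69.0, 11258.1, 11623.1))

  single <- design_stock(c(x = 7), multiplier = 1, final_volume = 100)
  expect_equal(single$components$stock_conc, 7)

  expect_error(design_stock(c(a = 5, b = NA), 2, 300), "censored")
})

test_that("dilution accounting matches the published worked rows", {
  abts <- design_stock(abts_ic50s, 2, 300, "ABTS")
  conc <- component_concentration(abts, 39.85)
  expect_equal(unname(conc[["uric acid"]]), 33.5 * 39.85 / 300)
  expect_equal(round_display(conc[["uric acid"]], 2, "half-up"), 4.45)

  hocl <- design_stock(c("uric acid" = 5.75), 10, 1500, "HOCL")
  c2 <- component_concentration(hocl, 41.70)
  expect_equal(unname(c2), 1.5985, tolerance = 1e-9)
  expect_equal(round_display(c2, 2, "half-up"), c("uric acid" = 1.60))

  expect_equal(unname(component_concentration(abts, 0)), rep(0, 4))
  expect_error(component_concentration(abts, 400), "within")
})

test_that("IC50 fractions are identical across components by construction", {
  abts <- design_stock(abts_ic50s, 2, 300, "ABTS")
  f <- ic50_fraction(abts, 39.85)
  expect_equal(unname(f), rep(2 * 39.85 / 300, 4))
  expect_equal(round_display(f[[1]], 2, "truncate"), 0.26)
  # at V = final/(n*multiplier), each component sits at 1/n of its IC50
  expect_equal(unname(ic50_fraction(abts, 300 / (4 * 2))), rep(0.25, 4))
  expect_equal(unname(ic50_fraction(abts, 0)), rep(0, 4))
  expect_equal(loewe_sum(abts, 37.5), 1)
})

test_that("additive projection is the mean of individual IC50s", {
  expect_equal(round_display(projected_ic50(c(6.90, 1125.81)), 2, "truncate"),
               566.35)
  expect_equal(round_display(projected_ic50(c(6.90, 1162.31)), 2, "truncate"),
               584.60)
  expect_equal(projected_ic50(c(1125.81, 1162.31)), 1144.06)
  expect_equal(projected_ic50(rep(42, 4)), 42)
  expect_error(projected_ic50(7), "at least 2")
  expect_error(projected_ic50(c(1, NA)), "positive")
})

test_that("additivity index classifies against the tau band", {
  sub <- additivity_index(851.22, 566.35)
  expect_equal(sub$index, 1.503, tolerance = 1e-3)
  expect_equal(sub$classification, "SUB_ADDITIVE")
  expect_equal(additivity_index(566.35, 566.35),
               list(index = 1, classification = "ADDITIVE"))
  sub2 <- additivity_index(739.52, 584.60)
  expect_equal(sub2$index, 1.265, tolerance = 1e-3)
  expect_equal(sub2$classification, "SUB_ADDITIVE")
  expect_equal(additivity_index(0.8, 1)$classification, "SUPRA_ADDITIVE")
  expect_equal(additivity_index(1.05, 1)$classification, "ADDITIVE")
  expect_equal(additivity_index(1.3, 1, tau = 0.5)$classification, "ADDITIVE")
})

test_that("additive capture shares are 50/n percentage points", {
  expect_equal(unname(additive_capture_shares(4)), rep(12.5, 4))
  expect_equal(unname(additive_capture_shares(2)), rep(25, 2))
  expect_equal(unname(additive_capture_shares(1)), 50)
  abts <- design_stock(abts_ic50s, 2, 300, "ABTS")
  expect_equal(additive_capture_shares(abts),
               setNames(rep(12.5, 4), names(abts_ic50s)))
})

test_that("published per-component concentrations sum to the published totals exactly", {
  expect_equal(5.18 + 846.04, 851.22)
  tab5 <- data.frame(
    mixture = c("uric+phenol", "uric+p-cresol", "phenol+p-cresol"),
    observed_total = c(sum(c(5.18, 846.04)), sum(c(4.36, 735.16)),
                       sum(c(858.43, 886.26))))
  expect_equal(tab5$observed_total, c(851.22, 739.52, 1744.69))
})

test_that("mixture report reassembles a binary crocin mixture row", {
  spec <- design_stock(c("uric acid" = 6.90, "phenol" = 1125.81),
                       multiplier = 10, final_volume = 2000, "CROCIN")
  # volume curve crossing 50% exactly at 150.3 uL
  pts <- data.frame(conc = c(50, 150.3, 500), inhibition = c(25, 50, 80),
                    replicate_id = 1L)
  curve <- inhibition_curve(pts, "CROCIN", "mixture", conc_unit = "uL")
  rep <- mixture_report(spec, curve, method = "interpolation")
  expect_equal(rep$ic50_volume, 150.3)
  expect_equal(unname(rep$component_conc_at_ic50),
               c(5.18, 846.04), tolerance = 1e-2)
  expect_equal(rep$observed_total, sum(rep$component_conc_at_ic50))
  expect_equal(rep$observed_total, 851.22, tolerance = 0.02)
  expect_equal(rep$projected_total, 566.355)
  expect_equal(rep$additivity_index, 1.503, tolerance = 1e-3)
  expect_equal(rep$classification, "SUB_ADDITIVE")
})

test_that("mixture report on the 4-solute design sums the component cells", {
  spec <- design_stock(abts_ic50s, 2, 300, "ABTS")
  pts <- data.frame(conc = c(10, 39.85, 150), inhibition = c(20, 50, 85),
                    replicate_id = 1L)
  curve <- inhibition_curve(pts, "ABTS", "mixture", conc_unit = "uL")
  rep <- mixture_report(spec, curve, method = "interpolation")
  cells <- round_display(as.numeric(rep$component_conc_at_ic50), 2, "half-up")
  expect_equal(sort(cells), sort(c(4.45, 3.45, 1.06, 1.39)))
  # sum of the displayed cells
  expect_equal(sum(cells), 10.35)
  expect_equal(rep$observed_total, sum(rep$component_conc_at_ic50))
})

test_that("an exactly additive simulated mixture reports index 1 and shares 50/n", {
  spec <- design_stock(abts_ic50s, 2, 300, "ABTS")
  cfg <- simulation_config(seed = 21, noise_sd = 0,
                           mixture = list(spec = spec, lambda = 1))
  curve <- build_inhibition_curve(simulate_mixture_response(cfg), "mixture")
  rep <- mixture_report(spec, curve)
  expect_equal(rep$ic50_volume, 300 / (4 * 2), tolerance = 1e-6)
  expect_equal(rep$additivity_index, 1, tolerance = 1e-6)
  expect_equal(unname(rep$ratio_to_individual_ic50), rep(0.25, 4),
               tolerance = 1e-6)
  expect_equal(unname(rep$capture_shares), rep(12.5, 4), tolerance = 1e-5)
  expect_equal(rep$classification, "ADDITIVE")
})

test_that("censored mixture curves yield a censored report and config round-trips", {
  spec <- design_stock(abts_ic50s, 2, 300, "ABTS")
  pts <- data.frame(conc = c(5, 10, 20), inhibition = c(5, 9, 15),
                    replicate_id = 1L)
  rep <- mixture_report(spec, inhibition_curve(pts, conc_unit = "uL"))
  expect_true(rep$censored)
  expect_true(is.na(rep$ic50_volume))

  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(assay = "ABTS",
                            components = data.frame(solute = names(abts_ic50s),
                                                    ic50_umol_L = unname(abts_ic50s)),
                            multiplier = 2, final_volume_uL = 300),
                       path, auto_unbox = TRUE, digits = NA)
  spec2 <- read_mixture_config(path)
  expect_equal(spec2$components$stock_conc, spec$components$stock_conc)
  expect_error(read_mixture_config({
    p <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(assay = "ABTS"), p, auto_unbox = TRUE)
    p
  }), "missing field")
})
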