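#' Reference serum concentrations of common uremic solutes
#'
#' Packaged table of mean uremic and upper-physiological serum concentrations
#' for nine low-molecular-weight uremic solutes. These anchor the default
#' concentration grids of the simulator (physiological, uremic and 10x uremic
#' levels are the customary test points for screening a solute panel).
#'
#' @param units `"mmol_L"` (as stored) or `"umol_L"` (the working unit of
#'   the analysis layer).
#'
#' @return A data frame with columns `solute`, `uremic`, `physiological`.
#' @export
#' @examples
#' reference_concentrations()
#' reference_concentrations("umol_L")
reference_concentrations <- function(units = c("mmol_L", "umol_L")) {
  units <- match.arg(units)
  tab <- data.frame(
    solute = c("L-arginine", "creatinine", "p-cresol", "hippuric acid",
               "methylguanidine", "phenol", "L-tyrosine", "urea", "uric acid"),
    uremic        = c(0.230, 0.880, 0.280, 1.700, 0.091, 0.110, 0.110, 33.000, 0.600),
    physiological = c(0.140, 0.120, 0.021, 0.028, 0.006, 0.015, 0.027,  6.700, 0.420),
    stringsAsFactors = FALSE
  )
  if (units == "umol_L") {
    tab$uremic <- tab$uremic * 1e3
    tab$physiological <- tab$physiological * 1e3
  }
  tab
}

#' Reference single-solute IC50 panel
#'
#' Published IC50 values (mean +/- SEM, umol/L) of the nine uremic solutes and
#' the Trolox standard across the five model systems. Censored entries
#' (no measurable 50% inhibition at the concentrations tested) carry
#' `censored = TRUE` and `ic50_umol_L = NA`. The hydrogen peroxide system is
#' censored for every solute; the assay itself is validated with catalase
#' (IC50 0.55 units/mL, i.e. 18.6 ug/mL or 77.5 nmol/L at MW 240,000 Da).
#'
#' These values serve as ground truth for the packaged simulation scenarios
#' and as inputs to the mixture designer.
#'
#' @param assay optional filter, one of `"ABTS"`, `"SUPEROXIDE"`, `"H2O2"`,
#'   `"HOCL"`, `"CROCIN"`.
#'
#' @return Data frame with columns `solute`, `assay`, `ic50_umol_L`, `sem`,
#'   `censored`.
#' @export
#' @examples
#' subset(reference_ic50s("ABTS"), !censored)
reference_ic50s <- function(assay = NULL) {
  row <- function(solute, assay, ic50, sem) {
    data.frame(solute = solute, assay = assay,
               ic50_umol_L = ic50, sem = sem,
               censored = is.na(ic50), stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row("L-arginine",      "ABTS", 61350.00, 562.56),
    row("creatinine",      "ABTS",   536.26,   3.32),
    row("p-cresol",        "ABTS",     3.99,   0.01),
    row("hippuric acid",   "ABTS",       NA,     NA),
    row("methylguanidine", "ABTS",       NA,     NA),
    row("phenol",          "ABTS",    12.98,   0.09),
    row("Trolox",          "ABTS",    16.45,   0.30),
    row("L-tyrosine",      "ABTS",     5.23,   0.02),
    row("urea",            "ABTS",       NA,     NA),
    row("uric acid",       "ABTS",    16.75,   0.14),

    row("Trolox",          "SUPEROXIDE", 2223.10, 0.17),
    row("L-arginine",      "SUPEROXIDE", NA, NA),
    row("creatinine",      "SUPEROXIDE", NA, NA),
    row("p-cresol",        "SUPEROXIDE", NA, NA),
    row("hippuric acid",   "SUPEROXIDE", NA, NA),
    row("methylguanidine", "SUPEROXIDE", NA, NA),
    row("phenol",          "SUPEROXIDE", NA, NA),
    row("L-tyrosine",      "SUPEROXIDE", NA, NA),
    row("urea",            "SUPEROXIDE", NA, NA),
    row("uric acid",       "SUPEROXIDE", NA, NA),

    row("L-arginine",      "HOCL", 92100.00, 0.10),
    row("creatinine",      "HOCL",  9130.00, 0.10),
    row("p-cresol",        "HOCL",    15.75, 0.12),
    row("hippuric acid",   "HOCL",  1600.00, 0.01),
    row("methylguanidine", "HOCL",       NA,   NA),
    row("phenol",          "HOCL",     8.95, 0.10),
    row("Trolox",          "HOCL",     8.65, 0.27),
    row("L-tyrosine",      "HOCL",     2.83, 0.04),
    row("urea",            "HOCL",  5600.00, 0.20),
    row("uric acid",       "HOCL",     5.75, 0.13),

    row("uric acid",       "CROCIN", 6.90,    NA),
    row("Trolox",          "CROCIN", 10.09,   NA),
    row("phenol",          "CROCIN", 1125.81, NA),
    row("p-cresol",        "CROCIN", 1162.31, NA),
    row("L-tyrosine",      "CROCIN", NA, NA),
    row("methylguanidine", "CROCIN", NA, NA),
    row("L-arginine",      "CROCIN", NA, NA),
    row("hippuric acid",   "CROCIN", NA, NA),
    row("creatinine",      "CROCIN", NA, NA),
    row("urea",            "CROCIN", NA, NA)
  )
  # H2O2: censored across the whole panel
  h2o2 <- tab[tab$assay == "ABTS", ]
  h2o2$assay <- "H2O2"
  h2o2$ic50_umol_L <- NA_real_
  h2o2$sem <- NA_real_
  h2o2$censored <- TRUE
  tab <- rbind(tab, h2o2)
  rownames(tab) <- NULL
  if (!is.null(assay)) {
    assay <- match.arg(assay, c("ABTS", "SUPEROXIDE", "H2O2", "HOCL", "CROCIN"))
    tab <- tab[tab$assay == assay, ]
    rownames(tab) <- NULL
  }
  tab
}

#' Reference crocin competition slopes (ka/kc)
#'
#' Published slopes of the v0/v vs [A]/[C] regression for the solute panel in
#' the crocin bleaching assay, in decreasing order of efficacy, together with
#' the kinetic IC50 where one was reached. The slope is the ratio ka/kc of the
#' peroxyl-radical rate constants of antioxidant and crocin; dividing by the
#' Trolox slope gives Trolox equivalents.
#'
#' @return Data frame with columns `solute`, `slope`, `ic50_umol_L`,
#'   `censored`.
#' @export
#' @examples
#' reference_crocin_slopes()
reference_crocin_slopes <- function() {
  data.frame(
    solute = c("uric acid", "Trolox", "phenol", "p-cresol", "L-tyrosine",
               "methylguanidine", "L-arginine", "hippuric acid",
               "creatinine", "urea"),
    slope = c(4.015, 2.230, 0.023, 0.016, 0.007,
              9.272e-4, 7.727e-4, 8.000e-5, 6.776e-5, 2.558e-6),
    ic50_umol_L = c(6.90, 10.09, 1125.81, 1162.31, NA, NA, NA, NA, NA, NA),
    censored = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}
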