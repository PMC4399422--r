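#' Molar extinction coefficient
#'
#' A light container for a species/wavelength/solvent-specific molar
#' absorptivity used in Beer-Lambert conversions between absorbance and
#' molar concentration.
#'
#' @param species character label of the absorbing species (e.g. `"crocin"`).
#' @param wavelength_nm wavelength of the measurement, nm (> 0).
#' @param epsilon_M_cm molar extinction coefficient, M^-1 cm^-1 (> 0).
#' @param solvent solvent the coefficient was determined in.
#' @param path_length_default default optical path length, cm.
#'
#' @return An object of class `extinction_coefficient`.
#' @export
#' @examples
#' crocin <- extinction_coefficient("crocin", 443, 13726, solvent = "DMSO")
#' absorbance_to_concentration(0.343, crocin) * 1e6  # ~25 umol/L
extinction_coefficient <- function(species, wavelength_nm, epsilon_M_cm,
                                   solvent = "aqueous buffer",
                                   path_length_default = 1) {
  stopifnot(is.character(species), length(species) == 1L)
  if (!is.numeric(epsilon_M_cm) || length(epsilon_M_cm) != 1L || epsilon_M_cm <= 0) {
    stop("`epsilon_M_cm` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(wavelength_nm) || length(wavelength_nm) != 1L || wavelength_nm <= 0) {
    stop("`wavelength_nm` must be a single positive number", call. = FALSE)
  }
  if (path_length_default <= 0) {
    stop("`path_length_default` must be positive", call. = FALSE)
  }
  structure(
    list(species = species, wavelength_nm = wavelength_nm,
         epsilon_M_cm = epsilon_M_cm, solvent = solvent,
         path_length_default = path_length_default),
    class = "extinction_coefficient"
  )
}

#' @export
print.extinction_coefficient <- function(x, ...) {
  cat(sprintf("<extinction coefficient> %s: epsilon = %s M^-1 cm^-1 at %g nm (%s)\n",
              x$species, format(x$epsilon_M_cm, big.mark = ","),
              x$wavelength_nm, x$solvent))
  invisible(x)
}

# chromophores used across the assay panel; epsilon in M^-1 cm^-1
.extinction_entries <- list(
  list("crocin",  443, 13726, "DMSO"),
  list("OCl-",    292,   350, "10 mmol/L NaOH"),
  list("TNB",     412, 13600, "50 mmol/L potassium phosphate pH 6.6"),
  list("H2O2",    230,    80, "aqueous")
)

#' Packaged extinction-coefficient registry
#'
#' Registry of the molar absorptivities used by the assay panel: crocin at
#' 443 nm (determined in DMSO), hypochlorite at 292 nm, TNB at 412 nm and
#' hydrogen peroxide at 230 nm. Lookup is unique by (species, wavelength).
#'
#' @param species optional species label; with `wavelength_nm` selects one entry.
#' @param wavelength_nm optional wavelength for the lookup.
#'
#' @return With no arguments, a data frame
#'   (`species`, `wavelength_nm`, `epsilon_M_cm`, `solvent`); with both
#'   arguments, the matching [extinction_coefficient()].
#' @export
#' @examples
#' extinction_registry()
#' extinction_registry("crocin", 443)
extinction_registry <- function(species = NULL, wavelength_nm = NULL) {
  tab <- do.call(rbind, lapply(.extinction_entries, function(e) {
    data.frame(species = e[[1]], wavelength_nm = e[[2]],
               epsilon_M_cm = e[[3]], solvent = e[[4]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(species) && is.null(wavelength_nm)) {
    return(tab)
  }
  hit <- tab$species == species & tab$wavelength_nm == wavelength_nm
  if (sum(hit) != 1L) {
    stop(sprintf("no unique registry entry for %s @ %s nm",
                 species, wavelength_nm), call. = FALSE)
  }
  row <- tab[hit, ]
  extinction_coefficient(row$species, row$wavelength_nm, row$epsilon_M_cm,
                         row$solvent)
}

#' Convert absorbance to molar concentration (Beer-Lambert)
#'
#' `absorbance_to_concentration()` returns `A / (epsilon * path)` in mol/L;
#' `concentration_to_absorbance()` is its exact inverse.
#'
#' @param absorbance absorbance, AU (>= 0); vectorised.
#' @param coeff an [extinction_coefficient()].
#' @param path optical path length in cm; defaults to the coefficient's
#'   default (1 cm unless stated otherwise). Microplate readings have an
#'   effective path set by fill volume, so the path is always explicit here.
#'
#' @return Concentration in mol/L (or absorbance in AU for the inverse).
#' @export
#' @examples
#' ocl <- extinction_registry("OCl-", 292)
#' absorbance_to_concentration(0.0105, ocl) # 3e-5 mol/L = 30 umol/L
absorbance_to_concentration <- function(absorbance, coeff,
                                        path = coeff$path_length_default) {
  stopifnot(inherits(coeff, "extinction_coefficient"))
  if (path <= 0) stop("`path` must be positive", call. = FALSE)
  if (any(absorbance < 0)) stop("`absorbance` must be >= 0", call. = FALSE)
  absorbance / (coeff$epsilon_M_cm * path)
}

#' @rdname absorbance_to_concentration
#' @param concentration concentration in mol/L (>= 0); vectorised.
#' @export
concentration_to_absorbance <- function(concentration, coeff,
                                        path = coeff$path_length_default) {
  stopifnot(inherits(coeff, "extinction_coefficient"))
  if (path <= 0) stop("`path` must be positive", call. = FALSE)
  if (any(concentration < 0)) stop("`concentration` must be >= 0", call. = FALSE)
  concentration * coeff$epsilon_M_cm * path
}

#' Convert a mass concentration to molar units
#'
#' Converts ug/mL to nmol/L given a molecular weight, e.g. for expressing an
#' enzyme IC50 (18.6 ug/mL of catalase, MW 240,000 Da, is 77.5 nmol/L).
#' `molar_to_mass()` is the inverse.
#'
#' @param mass_conc mass concentration, ug/mL.
#' @param molecular_weight molecular weight, Da (g/mol).
#' @param digits optional number of significant digits to round the result to
#'   (`NULL`, the default, leaves the value unrounded).
#'
#' @return Concentration in nmol/L (or ug/mL for the inverse).
#' @export
#' @examples
#' mass_to_molar(18.6, 240000) # 77.5 nmol/L
mass_to_molar <- function(mass_conc, molecular_weight, digits = NULL) {
  if (any(mass_conc <= 0) || molecular_weight <= 0) {
    stop("`mass_conc` and `molecular_weight` must be positive", call. = FALSE)
  }
  # ug/mL = mg/L; mg/L / (g/mol) = mmol/L * 1e-3 = umol/L; *1e3 -> nmol/L
  out <- mass_conc / molecular_weight * 1e6
  if (!is.null(digits)) out <- signif(out, digits)
  out
}

#' @rdname mass_to_molar
#' @param molar_conc concentration in nmol/L.
#' @export
molar_to_mass <- function(molar_conc, molecular_weight, digits = NULL) {
  if (any(molar_conc <= 0) || molecular_weight <= 0) {
    stop("`molar_conc` and `molecular_weight` must be positive", call. = FALSE)
  }
  out <- molar_conc * molecular_weight / 1e6
  if (!is.null(digits)) out <- signif(out, digits)
  out
}
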