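#' Design an IC50-proportioned mixture stock
#'
#' Builds a stock mixture in which each component's stock concentration is
#' the same multiple of its individual IC50 (`stock_i = multiplier *
#' IC50_i`). Adding any volume of such a stock delivers the same fraction of
#' every component's IC50, so under Loewe additivity the mixture behaves as a
#' single pseudo-compound and 50% inhibition is reached when the summed IC50
#' fractions equal 1.
#'
#' @param ic50s individual IC50s, umol/L: a named numeric vector or a data
#'   frame with columns `solute` and `ic50_umol_L`. All values must be
#'   uncensored (non-`NA`) and positive.
#' @param multiplier shared stock-to-IC50 ratio (> 0).
#' @param final_volume final reaction volume, uL.
#' @param assay_id assay label.
#'
#' @return An object of class `mixture_spec`.
#' @export
#' @examples
#' design_stock(c("uric acid" = 16.75, "phenol" = 12.98,
#'                "p-cresol" = 3.99, "L-tyrosine" = 5.23),
#'              multiplier = 2, final_volume = 300, assay_id = "ABTS")
design_stock <- function(ic50s, multiplier, final_volume, assay_id = NA_character_) {
  if (is.data.frame(ic50s)) {
    stopifnot(all(c("solute", "ic50_umol_L") %in% names(ic50s)))
    values <- setNames(ic50s$ic50_umol_L, ic50s$solute)
  } else {
    values <- ic50s
  }
  if (anyNA(values)) {
    stop("cannot design a stock from censored IC50s (components: ",
         paste(names(values)[is.na(values)], collapse = ", "),
         "); a censored potency gives no proportioning basis", call. = FALSE)
  }
  if (any(values <= 0) || multiplier <= 0 || final_volume <= 0) {
    stop("IC50s, `multiplier` and `final_volume` must be positive", call. = FALSE)
  }
  components <- data.frame(
    solute = names(values) %||% paste0("component_", seq_along(values)),
    individual_ic50 = as.numeric(values),
    stock_conc = multiplier * as.numeric(values),
    stringsAsFactors = FALSE
  )
  structure(
    list(components = components, multiplier = multiplier,
         final_volume = final_volume, assay_id = assay_id),
    class = "mixture_spec"
  )
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("<mixture spec> %s: %d components, multiplier %g, final volume %g uL\n",
              x$assay_id, nrow(x$components), x$multiplier, x$final_volume))
  print(x$components)
  invisible(x)
}

#' Component concentrations after adding stock volume
#'
#' Dilution accounting: `c_i = stock_i * added_volume / final_volume`.
#'
#' @param spec a [design_stock()] result.
#' @param added_volume stock volume added, uL, in `[0, final_volume]`.
#'
#' @return Named numeric vector of concentrations, umol/L.
#' @export
component_concentration <- function(spec, added_volume) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (added_volume < 0 || added_volume > spec$final_volume) {
    stop("`added_volume` must be within [0, final_volume]", call. = FALSE)
  }
  setNames(spec$components$stock_conc * added_volume / spec$final_volume,
           spec$components$solute)
}

#' IC50 fractions delivered by an added volume
#'
#' The fraction of each component's individual IC50 present after adding a
#' volume of stock: `f_i = c_i / IC50_i = multiplier * V / final_volume`.
#' Because the stock is IC50-proportioned the fraction is identical for all
#' components by construction; this is asserted to machine precision.
#'
#' @inheritParams component_concentration
#' @return Named numeric vector of (identical) IC50 fractions.
#' @export
ic50_fraction <- function(spec, added_volume) {
  conc <- component_concentration(spec, added_volume)
  f <- conc / spec$components$individual_ic50
  stopifnot(all(abs(f - f[1L]) <= 1e-12 * max(1, abs(f[1L]))))
  f
}

#' Additive (Loewe) projection of a mixture IC50
#'
#' For an IC50-proportioned mixture under Loewe additivity with a shared
#' Hill slope, the projected total concentration at 50% inhibition is the
#' arithmetic mean of the individual IC50s: each of the `n` components sits
#' at `1/n` of its own IC50, so the total is `(1/n) * sum(IC50_i)`.
#'
#' @param ic50s numeric vector of individual IC50s, umol/L (n >= 2).
#'
#' @return Projected mixture IC50 as total concentration, umol/L.
#' @export
#' @examples
#' projected_ic50(c(6.90, 1125.81)) # 566.355
projected_ic50 <- function(ic50s) {
  if (length(ic50s) < 2L) stop("need at least 2 components", call. = FALSE)
  if (any(!is.finite(ic50s) | ic50s <= 0)) {
    stop("all IC50s must be positive and uncensored", call. = FALSE)
  }
  mean(ic50s)
}

#' Additivity index and interaction call
#'
#' The ratio of the observed mixture IC50 (total concentration) to the
#' additive projection. An index of 1 is exact additivity; values above
#' `1 + tau` are sub-additive (more total mass needed than projected, i.e.
#' antagonism) and below `1 - tau` supra-additive (synergy).
#'
#' @param observed_total observed total concentration at the mixture IC50,
#'   umol/L.
#' @param projected_total additive projection from [projected_ic50()].
#' @param tau classification half-width around 1 (default 0.10).
#'
#' @return List with `index` and `classification` (one of `"ADDITIVE"`,
#'   `"SUB_ADDITIVE"`, `"SUPRA_ADDITIVE"`).
#' @export
#' @examples
#' additivity_index(851.22, 566.35) # 1.503, SUB_ADDITIVE
additivity_index <- function(observed_total, projected_total, tau = 0.10) {
  if (observed_total <= 0 || projected_total <= 0) {
    stop("totals must be positive", call. = FALSE)
  }
  index <- observed_total / projected_total
  classification <- if (abs(index - 1) <= tau) "ADDITIVE"
    else if (index > 1 + tau) "SUB_ADDITIVE" else "SUPRA_ADDITIVE"
  list(index = index, classification = classification)
}

#' Additive capture shares at the mixture IC50
#'
#' Under the exact-additive model every component of an IC50-proportioned
#' `n`-solute mixture contributes equally to the 50% capture at the mixture
#' IC50, i.e. `50/n` percentage points each (12.5% for four solutes, 25% for
#' two).
#'
#' @param spec a [design_stock()] result, or an integer number of components.
#'
#' @return Named numeric vector of per-component shares, percentage points.
#' @export
additive_capture_shares <- function(spec) {
  if (inherits(spec, "mixture_spec")) {
    n <- nrow(spec$components)
    names <- spec$components$solute
  } else {
    n <- as.integer(spec)
    names <- paste0("component_", seq_len(n))
  }
  if (n < 1L) stop("need at least one component", call. = FALSE)
  setNames(rep(50 / n, n), names)
}

#' Loewe sum of IC50 fractions at an added volume
#'
#' `S(V) = sum_i c_i(V) / IC50_i`; the additive model predicts 50%
#' inhibition at `S = 1`.
#'
#' @inheritParams component_concentration
#' @return The dimensionless Loewe sum.
#' @export
loewe_sum <- function(spec, added_volume) {
  sum(ic50_fraction(spec, added_volume))
}

#' Mixture report: observed vs additive IC50
#'
#' Fits the mixture IC50 on the added-volume axis, then assembles the full
#' accounting: component concentrations at the IC50 volume, their IC50
#' fractions, the observed total, the additive projection (mean of
#' individual IC50s), the additivity index and its classification, and each
#' component's capture share at the fitted point under the competition for
#' capture implied by the Loewe model.
#'
#' @param spec a [design_stock()] result.
#' @param curve an [inhibition_curve()] whose `conc` axis is the added stock
#'   volume in uL (e.g. from [build_inhibition_curve()] on a mixture plate,
#'   or [simulate_mixture_response()]).
#' @param tau classification threshold for [additivity_index()].
#' @param method fit method passed to [fit_ic50()].
#'
#' @return An object of class `mixture_report`; censored mixture curves give
#'   a censored report (`censored = TRUE`, volume/totals `NA`).
#' @export
mixture_report <- function(spec, curve, tau = 0.10, method = "auto") {
  stopifnot(inherits(spec, "mixture_spec"), inherits(curve, "inhibition_curve"))
  fit <- fit_ic50(curve, method = method)
  projected <- projected_ic50(spec$components$individual_ic50)
  if (fit$censored) {
    out <- list(spec = spec, censored = TRUE, ic50_volume = NA_real_,
                fit = fit, projected_total = projected)
    class(out) <- "mixture_report"
    return(out)
  }
  v50 <- fit$value
  conc <- component_concentration(spec, v50)
  frac <- ic50_fraction(spec, v50)
  s <- sum(frac)
  observed <- sum(conc)
  idx <- additivity_index(observed, projected, tau = tau)
  structure(
    list(spec = spec, censored = FALSE, ic50_volume = v50, fit = fit,
         component_conc_at_ic50 = conc,
         ratio_to_individual_ic50 = frac,
         observed_total = observed, projected_total = projected,
         additivity_index = idx$index, classification = idx$classification,
         # share of the 50% capture attributable to each component under the
         # capture-competition form f_i = (c_i/IC50_i)/(1+S)
         capture_shares = setNames(100 * frac / (1 + s), names(frac)),
         tau = tau),
    class = "mixture_report"
  )
}

#' @export
print.mixture_report <- function(x, ...) {
  if (x$censored) {
    cat("<mixture report> censored: mixture never reached 50% inhibition\n")
    return(invisible(x))
  }
  cat(sprintf("<mixture report> %s, %d components\n",
              x$spec$assay_id, nrow(x$spec$components)))
  cat(sprintf("  IC50 volume: %.4g uL of stock (final volume %g uL)\n",
              x$ic50_volume, x$spec$final_volume))
  tab <- data.frame(solute = x$spec$components$solute,
                    conc_at_ic50 = as.numeric(x$component_conc_at_ic50),
                    ic50_fraction = as.numeric(x$ratio_to_individual_ic50),
                    capture_share_pct = as.numeric(x$capture_shares))
  print(tab, digits = 4)
  cat(sprintf("  observed total %.4g vs projected %.4g umol/L; additivity index %.3f (%s, tau = %.2f)\n",
              x$observed_total, x$projected_total, x$additivity_index,
              x$classification, x$tau))
  invisible(x)
}

#' Read a mixture configuration file
#'
#' JSON configuration with fields `assay`, `components` (array of objects
#' with `solute` and `ic50_umol_L`), `multiplier` and `final_volume_uL`;
#' returns the corresponding [design_stock()] spec.
#'
#' @param path path to the JSON file.
#' @return A `mixture_spec`.
#' @export
read_mixture_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("assay", "components", "multiplier", "final_volume_uL")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("mixture config missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  design_stock(setNames(cfg$components$ic50_umol_L, cfg$components$solute),
               multiplier = cfg$multiplier,
               final_volume = cfg$final_volume_uL,
               assay_id = cfg$assay)
}
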