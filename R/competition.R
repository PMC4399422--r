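#' Extract the crocin bleaching rate from a kinetic trace
#'
#' Least-squares slope of absorbance at 443 nm vs time over a window,
#' sign-flipped to a positive bleaching rate `v` (AU/s). The default window
#' of 60-600 s skips the initial lag (the decay is linear after about one
#' minute) and covers the rest of a 10-minute monitoring run. The molar rate
#' `v_molar` ((mol/L)/s) is derived with the crocin extinction coefficient;
#' ratios of rates are taken on the AU/s scale, where the coefficient
#' cancels. A flat or rising trace is flagged as non-bleaching.
#'
#' @param trace a [kinetic_trace()].
#' @param window numeric `c(t_start, t_end)` in seconds.
#' @param epsilon_M_cm crocin molar absorptivity used for `v_molar`.
#' @param path optical path, cm.
#'
#' @return An object of class `bleaching_rate` with fields `sample_id`, `v`
#'   (AU/s), `window`, `r_squared`, `v_molar`, `non_bleaching`.
#' @export
extract_rate <- function(trace, window = c(60, 600),
                         epsilon_M_cm = extinction_registry("crocin", 443)$epsilon_M_cm,
                         path = 1) {
  stopifnot(inherits(trace, "kinetic_trace"), length(window) == 2L)
  keep <- trace$time_s >= window[1L] & trace$time_s <= window[2L]
  if (sum(keep) < 5L) {
    stop("insufficient data: need >= 5 points in the rate window", call. = FALSE)
  }
  t <- trace$time_s[keep]
  a <- trace$abs_443[keep]
  fit <- lm(a ~ t)
  slope <- coef(fit)[["t"]]
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- NA_real_
  # a numerically-zero slope (flat trace) counts as non-bleaching
  non_bleaching <- slope >= -1e-12
  v <- if (non_bleaching && abs(slope) <= 1e-12) 0 else max(0, -slope)
  structure(
    list(sample_id = trace$sample_id, solute = trace$solute,
         conc_umol_L = trace$conc_umol_L,
         crocin_umol_L = trace$crocin_umol_L,
         v = v, window = window, r_squared = r2,
         v_molar = v / (epsilon_M_cm * path),
         non_bleaching = non_bleaching),
    class = "bleaching_rate"
  )
}

#' @export
print.bleaching_rate <- function(x, ...) {
  cat(sprintf("<bleaching rate> %s: v = %.4g AU/s (%.4g (mol/L)/s), window %g-%g s, r2 = %s%s\n",
              x$sample_id, x$v, x$v_molar, x$window[1], x$window[2],
              format(x$r_squared, digits = 4),
              if (x$non_bleaching) " [non-bleaching]" else ""))
  invisible(x)
}

.rate_value <- function(x) {
  if (inherits(x, "bleaching_rate")) x$v else as.numeric(x)
}

#' Velocity ratio v0/v of the competition treatment
#'
#' In the competitive-kinetics model the uninhibited bleaching rate `v0`
#' relates to the inhibited rate `v` by
#' `v0/v = 1 + (ka/kc) * [A]/[C]`, so the ratio is the regression response of
#' [fit_competition_slope()]. Complete inhibition (`v = 0`) returns `Inf`
#' carrying attribute `complete_inhibition = TRUE` so callers can report it
#' distinctly rather than as a numeric artefact.
#'
#' @param v0 uninhibited rate (AU/s or a `bleaching_rate`).
#' @param v inhibited rate (same form).
#'
#' @return Dimensionless ratio `v0/v`.
#' @export
velocity_ratio <- function(v0, v) {
  v0 <- .rate_value(v0); v <- .rate_value(v)
  if (v0 <= 0) stop("`v0` must be positive", call. = FALSE)
  if (v < 0) stop("`v` must be >= 0", call. = FALSE)
  if (v == 0) {
    return(structure(Inf, complete_inhibition = TRUE))
  }
  v0 / v
}

#' Fit the competition slope ka/kc
#'
#' Ordinary least squares of `v0/v` on `[A]/[C]` with a free intercept. Under
#' the competition model the slope is the rate-constant ratio ka/kc (the
#' relative capacity of the antioxidant to intercept peroxyl radicals) and
#' the intercept is 1; an intercept deviating from 1 by more than
#' `intercept_tol` triggers a model-adequacy warning rather than being forced
#' away. Requires at least 3 points; a warning is issued when the positive
#' `[A]/[C]` values span less than a 4-fold range.
#'
#' @param points data frame with columns `ratio_ac` (`[A]/[C]`) and
#'   `v_ratio` (`v0/v`); infinite ratios (complete inhibition) are dropped
#'   with a warning.
#' @param intercept_tol tolerance on `|intercept - 1|` before warning.
#'
#' @return An object of class `competition_fit` with `slope`, `intercept`,
#'   `r_squared`, `points`, `trolox_equivalents` (NA until
#'   [trolox_equivalents()] is applied).
#' @export
#' @examples
#' x <- c(0.25, 0.5, 1, 2)
#' fit_competition_slope(data.frame(ratio_ac = x, v_ratio = 1 + 4.015 * x))
fit_competition_slope <- function(points, intercept_tol = 0.2) {
  stopifnot(is.data.frame(points),
            all(c("ratio_ac", "v_ratio") %in% names(points)))
  inf <- !is.finite(points$v_ratio)
  if (any(inf)) {
    warning("dropping ", sum(inf), " complete-inhibition point(s) from the regression")
    points <- points[!inf, ]
  }
  if (nrow(points) < 3L) {
    stop("insufficient data: need >= 3 finite points", call. = FALSE)
  }
  if (diff(range(points$ratio_ac)) == 0) {
    stop("degenerate [A]/[C] range: all x values identical", call. = FALSE)
  }
  pos <- points$ratio_ac[points$ratio_ac > 0]
  if (length(pos) >= 2L && max(pos) / min(pos) < 4) {
    warning("[A]/[C] spans less than a 4-fold range; slope may be poorly determined")
  }
  fit <- lm(v_ratio ~ ratio_ac, data = points)
  slope <- coef(fit)[["ratio_ac"]]
  intercept <- coef(fit)[["(Intercept)"]]
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- NA_real_
  if (abs(intercept - 1) > intercept_tol) {
    warning(sprintf("intercept %.3f deviates from 1 by more than %.2f; competition model may not hold",
                    intercept, intercept_tol))
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         points = points, trolox_equivalents = NA_real_),
    class = "competition_fit"
  )
}

#' @export
print.competition_fit <- function(x, ...) {
  cat(sprintf("<competition fit> ka/kc = %.4g, intercept = %.3f, r2 = %s, n = %d\n",
              x$slope, x$intercept, format(x$r_squared, digits = 4),
              nrow(x$points)))
  if (is.finite(x$trolox_equivalents)) {
    cat(sprintf("  Trolox equivalents: %.4g\n", x$trolox_equivalents))
  }
  invisible(x)
}

#' Trolox equivalents of a competition fit
#'
#' The ratio of a sample's ka/kc slope to the slope of the Trolox standard:
#' a relative antioxidant capacity on the Trolox scale.
#'
#' @param sample_fit a [fit_competition_slope()] result for the sample.
#' @param trolox_fit the same for Trolox (slope must be > 0).
#'
#' @return The sample [`competition_fit`][fit_competition_slope] with
#'   `trolox_equivalents` filled in.
#' @export
trolox_equivalents <- function(sample_fit, trolox_fit) {
  stopifnot(inherits(sample_fit, "competition_fit"),
            inherits(trolox_fit, "competition_fit"))
  if (trolox_fit$slope <= 0) {
    stop("Trolox slope must be positive", call. = FALSE)
  }
  sample_fit$trolox_equivalents <- sample_fit$slope / trolox_fit$slope
  sample_fit
}

#' Kinetic percent inhibition of crocin bleaching
#'
#' `%In = (1 - v/v0) * 100`, the kinetic analogue of endpoint percent
#' inhibition, used to convert bleaching rates into an IC50-ready series.
#'
#' @param v0 uninhibited rate (AU/s or `bleaching_rate`), must be > 0.
#' @param v inhibited rate (vectorised over plain numerics).
#'
#' @return Percent inhibition.
#' @export
percent_inhibition_kinetic <- function(v0, v) {
  v0 <- .rate_value(v0)
  v <- if (inherits(v, "bleaching_rate")) v$v else as.numeric(v)
  if (v0 <= 0) stop("degenerate assay: v0 must be positive", call. = FALSE)
  100 * (1 - v / v0)
}

#' IC50 from a kinetic percent-inhibition series
#'
#' Applies the [fit_ic50()] contract to crocin-bleaching percent inhibition:
#' for data generated exactly by the competition model the closed form is
#' `IC50 = [C] / (ka/kc)`, since `%In = 50` exactly when
#' `(ka/kc) [A]/[C] = 1`. Kinetic assays are customarily run in duplicate
#' rather than triplicate.
#'
#' @param series data frame with columns `conc` (umol/L) and `inhibition`
#'   (%, raw; clamped internally) and optionally `replicate_id`.
#' @param solute label.
#' @inheritParams fit_ic50
#'
#' @return An [ic50_result()] with `assay_id = "CROCIN"`.
#' @export
ic50_from_kinetics <- function(series, solute = NA_character_,
                               method = "auto") {
  stopifnot(is.data.frame(series),
            all(c("conc", "inhibition") %in% names(series)))
  if (is.null(series$replicate_id)) {
    series$replicate_id <- stats::ave(seq_len(nrow(series)), series$conc,
                                      FUN = seq_along)
  }
  pts <- data.frame(conc = series$conc,
                    inhibition = pmin(100, pmax(0, series$inhibition)),
                    inhibition_raw = series$inhibition,
                    replicate_id = series$replicate_id)
  fit_ic50(inhibition_curve(pts, assay_id = "CROCIN", solute = solute),
           method = method)
}

#' Analyse a panel of crocin bleaching traces
#'
#' Convenience pipeline over a list of [kinetic_trace()] objects: traces with
#' `[A] = 0` define the uninhibited rate `v0` (averaged if several); for each
#' solute the function extracts rates, builds the `(v0/v, [A]/[C])` points,
#' fits the competition slope, computes the kinetic percent-inhibition series
#' and its IC50, and (when a `"Trolox"` panel is present) Trolox equivalents.
#'
#' @param traces list of [kinetic_trace()] objects (e.g. from
#'   [read_kinetic_csv()]).
#' @param window rate window passed to [extract_rate()].
#'
#' @return Named list per solute: `fit` (`competition_fit`), `ic50`
#'   (`ic50_result`), `series` (the `%In` data frame), `v0` (AU/s).
#' @export
crocin_panel <- function(traces, window = c(60, 600)) {
  rates <- lapply(traces, extract_rate, window = window)
  is_v0 <- vapply(rates, function(r) r$conc_umol_L == 0, logical(1))
  if (!any(is_v0)) {
    stop("panel needs at least one [A] = 0 trace to define v0", call. = FALSE)
  }
  v0 <- mean(vapply(rates[is_v0], `[[`, numeric(1), "v"))
  sample_rates <- rates[!is_v0]
  solutes <- unique(vapply(sample_rates, `[[`, character(1), "solute"))
  out <- lapply(solutes, function(sol) {
    rs <- Filter(function(r) r$solute == sol, sample_rates)
    ratio_ac <- vapply(rs, function(r) r$conc_umol_L / r$crocin_umol_L, numeric(1))
    v <- vapply(rs, `[[`, numeric(1), "v")
    v_ratio <- vapply(v, function(vi) as.numeric(velocity_ratio(v0, vi)), numeric(1))
    fit <- fit_competition_slope(data.frame(ratio_ac = ratio_ac,
                                            v_ratio = v_ratio))
    series <- data.frame(conc = vapply(rs, `[[`, numeric(1), "conc_umol_L"),
                         inhibition = percent_inhibition_kinetic(v0, v))
    ic50 <- ic50_from_kinetics(series, solute = sol)
    list(fit = fit, ic50 = ic50, series = series, v0 = v0)
  })
  names(out) <- solutes
  if ("Trolox" %in% solutes) {
    tr <- out[["Trolox"]]$fit
    out <- lapply(out, function(res) {
      res$fit <- trolox_equivalents(res$fit, tr)
      res
    })
  }
  out
}
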