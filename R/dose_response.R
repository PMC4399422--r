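#' Percent inhibition of an endpoint reaction
#'
#' Inhibition relative to the uninhibited control (100% reaction) and the
#' reading blank: `100 * (control - sample) / (control - blank)`. The raw
#' value may fall outside \[0, 100\] (pro-oxidant appearance or noise); it is
#' reported alongside a clamped value, and only the clamped value feeds the
#' IC50 fit. The statistic is affine-invariant: adding a common offset to all
#' three readings leaves it unchanged.
#'
#' @param sample sample absorbance, AU (vectorised).
#' @param control control absorbance, AU.
#' @param blank reading-blank absorbance, AU (default 0).
#'
#' @return Data frame with columns `raw` and `clamped` (percent).
#' @export
#' @examples
#' percent_inhibition(0.375, control = 0.750, blank = 0) # 50%
percent_inhibition <- function(sample, control, blank = 0) {
  if (any(control == blank)) {
    stop("degenerate assay: control equals blank", call. = FALSE)
  }
  raw <- 100 * (control - sample) / (control - blank)
  data.frame(raw = raw, clamped = pmin(100, pmax(0, raw)))
}

#' Inhibition curve
#'
#' Concentration vs percent-inhibition points with replicate structure, the
#' input to [fit_ic50()]. Normally produced by [build_inhibition_curve()]
#' from an endpoint plate, or from kinetic percent inhibition by
#' [ic50_from_kinetics()].
#'
#' @param points data frame with columns `conc`, `inhibition` (clamped, %),
#'   `inhibition_raw` (optional) and `replicate_id`.
#' @param assay_id,solute labels carried into results.
#' @param conc_unit `"umol_L"` or `"uL"` (mixture volumes).
#'
#' @return An object of class `inhibition_curve`.
#' @export
inhibition_curve <- function(points, assay_id = NA_character_,
                             solute = NA_character_, conc_unit = "umol_L") {
  stopifnot(is.data.frame(points),
            all(c("conc", "inhibition", "replicate_id") %in% names(points)))
  if (!all(is.finite(points$inhibition))) {
    stop("inhibition values must be finite", call. = FALSE)
  }
  if (is.null(points$inhibition_raw)) points$inhibition_raw <- points$inhibition
  structure(
    list(assay_id = assay_id, solute = solute,
         points = points[c("conc", "inhibition", "inhibition_raw", "replicate_id")],
         n_replicates = length(unique(points$replicate_id)),
         conc_unit = conc_unit),
    class = "inhibition_curve"
  )
}

#' @export
print.inhibition_curve <- function(x, ...) {
  cat(sprintf("<inhibition curve> %s / %s: %d points, %d concentration(s), %d replicate(s)\n",
              x$assay_id, x$solute, nrow(x$points),
              length(unique(x$points$conc)), x$n_replicates))
  invisible(x)
}

#' Build an inhibition curve from an endpoint plate
#'
#' For each replicate, the replicate's own control and blank wells (averaged
#' if several) convert every sample absorbance of the requested solute into
#' percent inhibition via [percent_inhibition()].
#'
#' @param plate an [endpoint_plate()].
#' @param solute solute to extract.
#'
#' @return An [inhibition_curve()].
#' @export
build_inhibition_curve <- function(plate, solute) {
  stopifnot(inherits(plate, "endpoint_plate"))
  df <- as.data.frame(plate)
  if (!solute %in% df$solute[df$role == "sample"]) {
    stop("solute not found on plate: ", solute, call. = FALSE)
  }
  pieces <- lapply(unique(df$replicate_id), function(rep) {
    d <- df[df$replicate_id == rep, ]
    control <- mean(d$absorbance[d$role == "control"])
    blank <- mean(d$absorbance[d$role == "blank"])
    s <- d[d$role == "sample" & d$solute == solute, ]
    if (nrow(s) == 0L) return(NULL)
    pin <- percent_inhibition(s$absorbance, control, blank)
    data.frame(conc = s$conc_umol_L, inhibition = pin$clamped,
               inhibition_raw = pin$raw, replicate_id = rep)
  })
  points <- do.call(rbind, pieces)
  inhibition_curve(points, assay_id = df$assay_id[1L], solute = solute,
                   conc_unit = attr(plate, "conc_unit") %||% "umol_L")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' IC50 estimate
#'
#' Container for a potency estimate: value and SEM (same unit as the curve's
#' concentration axis), the fit method used, and a censoring flag for curves
#' that never reach 50% inhibition ("no effect up to `c_max_tested`").
#'
#' @param value IC50 (umol/L, or uL for mixture volume curves); `NA` when
#'   censored.
#' @param sem standard error of the estimate (`NA` if unavailable).
#' @param method `"FOUR_PARAM_LOGISTIC"` or `"MONOTONE_INTERPOLATION"`.
#' @param censored logical.
#' @param c_max_tested highest concentration tested.
#' @param assay_id,solute labels.
#' @param conc_unit concentration unit of `value`.
#' @param hill fitted Hill slope (logistic method only).
#'
#' @return An object of class `ic50_result`.
#' @export
ic50_result <- function(value, sem = NA_real_, method = NA_character_,
                        censored = FALSE, c_max_tested = NA_real_,
                        assay_id = NA_character_, solute = NA_character_,
                        conc_unit = "umol_L", hill = NA_real_) {
  if (!censored && (!is.finite(value) || value <= 0)) {
    stop("uncensored IC50 must be a positive number", call. = FALSE)
  }
  if (is.finite(sem) && sem < 0) stop("`sem` must be >= 0", call. = FALSE)
  structure(
    list(value = value, sem = sem, method = method, censored = censored,
         c_max_tested = c_max_tested, assay_id = assay_id, solute = solute,
         conc_unit = conc_unit, hill = hill),
    class = "ic50_result"
  )
}

#' @export
print.ic50_result <- function(x, ...) {
  unit <- if (identical(x$conc_unit, "uL")) "uL" else "umol/L"
  if (x$censored) {
    cat(sprintf("<IC50> %s / %s: censored, > %g %s (no 50%% effect at tested range)\n",
                x$assay_id, x$solute, x$c_max_tested, unit))
  } else {
    sem <- if (is.finite(x$sem)) sprintf(" +/- %.4g", x$sem) else ""
    cat(sprintf("<IC50> %s / %s: %.4g%s %s [%s]\n",
                x$assay_id, x$solute, x$value, sem, unit, x$method))
  }
  invisible(x)
}

#' Format an IC50 for a report table
#'
#' Censored results render as `"ND>c_max"`, uncensored as the number.
#'
#' @param x an [ic50_result()].
#' @param digits significant digits for uncensored values.
#' @return A character scalar.
#' @export
format_ic50 <- function(x, digits = 6) {
  stopifnot(inherits(x, "ic50_result"))
  if (x$censored) sprintf("ND>%g", x$c_max_tested) else
    format(signif(x$value, digits), scientific = FALSE)
}

# mean clamped inhibition per concentration, sorted by concentration
.mean_by_conc <- function(points) {
  agg <- stats::aggregate(inhibition ~ conc, data = points, FUN = mean)
  agg[order(agg$conc), ]
}

# lowest 50% crossing of the isotonic-smoothed mean curve
.interpolate_ic50 <- function(points) {
  agg <- .mean_by_conc(points)
  iso <- stats::isoreg(agg$conc, agg$inhibition)
  y <- iso$yf
  x <- agg$conc
  above <- which(y >= 50)
  if (!length(above)) return(NA_real_)
  i <- above[1L]
  if (y[i] == 50 || i == 1L) return(x[i])
  x0 <- x[i - 1L]; y0 <- y[i - 1L]
  x0 + (50 - y0) * (x[i] - x0) / (y[i] - y0)
}

#' Fit an IC50 to an inhibition curve
#'
#' The primary model is a constrained logistic with floor 0 and ceiling 100,
#' `inhibition(c) = 100 c^h / (c^h + IC50^h)`, fitted by Levenberg-Marquardt
#' least squares with the Hill slope `h >= 0.2` free. If the fit fails to
#' converge (or `method = "interpolation"` is requested) the estimator falls
#' back to the lowest 50% crossing of the isotonic-regression-smoothed mean
#' curve, linearly interpolated; the method actually used is recorded.
#' A curve whose mean inhibition never reaches 50% at any tested
#' concentration yields a censored result (`> c_max_tested`).
#'
#' @param curve an [inhibition_curve()] with at least 3 distinct
#'   concentrations.
#' @param method `"auto"` (logistic, interpolation fallback),
#'   `"logistic"`, or `"interpolation"`.
#'
#' @return An [ic50_result()].
#' @export
#' @examples
#' conc <- 16.75 * 2^seq(-3, 3)
#' pts <- data.frame(conc = conc,
#'                   inhibition = 100 * conc / (conc + 16.75),
#'                   replicate_id = 1L)
#' fit_ic50(inhibition_curve(pts, "ABTS", "uric acid"))
fit_ic50 <- function(curve, method = c("auto", "logistic", "interpolation")) {
  stopifnot(inherits(curve, "inhibition_curve"))
  method <- match.arg(method)
  pts <- curve$points
  if (length(unique(pts$conc)) < 3L) {
    stop("insufficient data: need >= 3 distinct concentrations", call. = FALSE)
  }
  c_max <- max(pts$conc)
  agg <- .mean_by_conc(pts)
  if (max(agg$inhibition) < 50) {
    return(ic50_result(NA_real_, censored = TRUE, c_max_tested = c_max,
                       assay_id = curve$assay_id, solute = curve$solute,
                       conc_unit = curve$conc_unit))
  }
  interp <- .interpolate_ic50(pts)
  if (method != "interpolation") {
    start_ic50 <- if (is.finite(interp) && interp > 0) interp else
      exp(mean(log(pts$conc[pts$conc > 0])))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        inhibition ~ 100 * conc^h / (conc^h + ic50^h),
        data = pts[pts$conc > 0, ],
        start = list(ic50 = start_ic50, h = 1),
        lower = c(ic50 = min(pts$conc[pts$conc > 0]) * 1e-6, h = 0.2),
        upper = c(ic50 = c_max * 1e6, h = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(fit)) {
      est <- coef(fit)
      se <- tryCatch(summary(fit)$coefficients["ic50", "Std. Error"],
                     error = function(e) NA_real_)
      if (is.finite(est[["ic50"]]) && est[["ic50"]] > 0) {
        return(ic50_result(est[["ic50"]], sem = se,
                           method = "FOUR_PARAM_LOGISTIC",
                           c_max_tested = c_max, assay_id = curve$assay_id,
                           solute = curve$solute, conc_unit = curve$conc_unit,
                           hill = est[["h"]]))
      }
    }
    if (method == "logistic") {
      stop("logistic IC50 fit failed to converge", call. = FALSE)
    }
  }
  if (!is.finite(interp)) {
    stop("no 50% crossing found for interpolation", call. = FALSE)
  }
  ic50_result(interp, method = "MONOTONE_INTERPOLATION", c_max_tested = c_max,
              assay_id = curve$assay_id, solute = curve$solute,
              conc_unit = curve$conc_unit)
}

#' Per-replicate IC50 estimates
#'
#' Splits a curve by replicate, fits each replicate separately, and returns
#' the individual estimates — the inputs for the mean +/- SEM summary of
#' [ic50_sem()]. Replicates that are censored on their own are returned as
#' `NA`.
#'
#' @inheritParams fit_ic50
#' @return Named numeric vector of per-replicate IC50s.
#' @export
fit_ic50_by_replicate <- function(curve, method = "auto") {
  stopifnot(inherits(curve, "inhibition_curve"))
  reps <- unique(curve$points$replicate_id)
  vapply(reps, function(rep) {
    sub <- curve$points[curve$points$replicate_id == rep, ]
    res <- tryCatch(
      fit_ic50(inhibition_curve(sub, curve$assay_id, curve$solute,
                                curve$conc_unit), method = method),
      error = function(e) NULL
    )
    if (is.null(res) || res$censored) NA_real_ else res$value
  }, numeric(1), USE.NAMES = FALSE) |>
    setNames(as.character(reps))
}

#' Mean and standard error over replicate IC50s
#'
#' Potency is summarised as the arithmetic mean of replicate-level IC50
#' estimates with the standard error of that mean (`sd / sqrt(n)`), the
#' customary "mean IC50 +/- SEM" of triplicate (or duplicate) assays.
#'
#' @param replicate_values numeric vector of per-replicate IC50s (>= 2
#'   non-missing values required for the SEM).
#'
#' @return List with `mean`, `sem`, `n`. With fewer than 2 values the SEM is
#'   `NA` and a warning flags it as undefined.
#' @export
#' @examples
#' ic50_sem(c(9, 10, 11)) # mean 10, sem 0.577
ic50_sem <- function(replicate_values) {
  v <- replicate_values[is.finite(replicate_values)]
  if (length(v) < 2L) {
    warning("SEM undefined with fewer than 2 replicate estimates")
    return(list(mean = if (length(v)) mean(v) else NA_real_,
                sem = NA_real_, n = length(v)))
  }
  list(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v))
}
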