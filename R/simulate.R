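# run code under a fixed seed without disturbing the caller's RNG stream
with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default log-spaced concentration grid around an expected IC50
#'
#' Eight points, log-spaced over roughly an 11-fold span either side of the
#' expected IC50 — wide enough to bracket the 50% crossing comfortably under
#' realistic absorbance noise.
#'
#' @param ic50 expected IC50, umol/L.
#' @param n number of points.
#' @param span half-width of the grid in log2 units.
#' @return Numeric vector of concentrations, umol/L.
#' @export
default_conc_grid <- function(ic50, n = 8, span = 3.5) {
  ic50 * 2^seq(-span, span, length.out = n)
}

#' Simulation configuration
#'
#' Collects everything the synthetic generators need. Endpoint defaults
#' mirror the ABTS-like setup: control absorbance 0.750 AU, reading blank 0,
#' Gaussian absorbance noise of 0.005 AU, triplicate plates, a hyperbolic
#' (Hill slope 1) scavenging response. The kinetic block describes the
#' crocin system: 25 umol/L crocin, molar absorptivity 13,726 M^-1 cm^-1 at
#' 443 nm, a constant radical generation term (AAPH thermolysis) entering as
#' the pseudo-first-order bleaching constant `radical_flux * kc_rel`, a 60 s
#' lag before the decay turns linear, 600 s of monitoring, 0.002 AU noise and
#' duplicate runs. Only the ratio `ka_rel/kc_rel` is identifiable from
#' competition data; both are housed here because the generator needs an
#' absolute rate scale while the analysis does not. The mixture block holds a
#' [design_stock()] spec, the shared Hill slope and the interaction
#' parameter `lambda` (`lambda = 1` exact Loewe additivity, `lambda > 1`
#' antagonism; see [simulate_mixture_response()]).
#'
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @param assay_id endpoint assay label.
#' @param true_ic50s named numeric vector of true IC50s, umol/L. `NA` marks a
#'   censored solute: its true IC50 is set to `100 * c_max` (a "no effect up
#'   to c_max" bound, not literal inertness), with `c_max` taken from
#'   `c_max_censored`.
#' @param hill_h shared Hill slope of the endpoint response.
#' @param control_abs,blank_abs control and reading-blank absorbances, AU.
#' @param noise_sd endpoint absorbance noise SD, AU.
#' @param n_replicates endpoint replicates.
#' @param conc_grid function mapping a true IC50 to its concentration grid;
#'   default [default_conc_grid()].
#' @param c_max_censored named vector of highest tested concentrations for
#'   censored solutes (their grids are log-spaced up to `c_max`).
#' @param kinetic named list overriding kinetic defaults: `crocin_umol_L`,
#'   `epsilon_M_cm`, `path`, `radical_flux` (s^-1), `kc_rel`, `ka_kc` (named
#'   vector of ka/kc ratios per solute), `t_lag`, `duration`, `dt`,
#'   `noise_sd`, `n_replicates`.
#' @param mixture named list overriding mixture defaults: `spec`
#'   (a [design_stock()]), `lambda`, `hill_h`, `volume_grid`, `noise_sd`,
#'   `n_replicates`.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, assay_id = "ABTS",
                              true_ic50s = c("uric acid" = 16.75),
                              hill_h = 1, control_abs = 0.750, blank_abs = 0,
                              noise_sd = 0.005, n_replicates = 3L,
                              conc_grid = default_conc_grid,
                              c_max_censored = numeric(),
                              kinetic = list(), mixture = list()) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (hill_h <= 0) stop("`hill_h` must be positive", call. = FALSE)
  if (control_abs == blank_abs) {
    stop("control and blank absorbance must differ", call. = FALSE)
  }
  kin <- modifyList(list(
    crocin_umol_L = 25, epsilon_M_cm = 13726, path = 1,
    radical_flux = 2.914e-4, kc_rel = 1,
    ka_kc = c("uric acid" = 4.015, "Trolox" = 2.230),
    t_lag = 60, duration = 600, dt = 5, noise_sd = 0.002, n_replicates = 2L
  ), kinetic)
  if (kin$duration <= kin$t_lag) {
    stop("kinetic duration must exceed t_lag", call. = FALSE)
  }
  mix <- modifyList(list(
    spec = NULL, lambda = 1, hill_h = 1, volume_grid = NULL,
    noise_sd = noise_sd, n_replicates = n_replicates
  ), mixture)
  if (mix$lambda <= 0) stop("mixture `lambda` must be positive", call. = FALSE)
  structure(
    list(seed = as.integer(seed), assay_id = assay_id,
         true_ic50s = true_ic50s, hill_h = hill_h,
         control_abs = control_abs, blank_abs = blank_abs,
         noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
         conc_grid = conc_grid, c_max_censored = c_max_censored,
         kinetic = kin, mixture = mix),
    class = "simulation_config"
  )
}

# resolve a solute's truth and grid, handling censored entries
.solute_truth <- function(cfg, solute) {
  ic50 <- cfg$true_ic50s[[solute]]
  if (is.na(ic50)) {
    if (!solute %in% names(cfg$c_max_censored)) {
      stop("censored solute ", solute, " needs an entry in `c_max_censored`",
           call. = FALSE)
    }
    c_max <- cfg$c_max_censored[[solute]]
    list(ic50 = 100 * c_max,
         grid = exp(seq(log(c_max / 100), log(c_max), length.out = 8)))
  } else {
    list(ic50 = ic50, grid = cfg$conc_grid(ic50))
  }
}

#' Simulate an endpoint assay plate
#'
#' Sample absorbance is
#' `blank + (control - blank) * (1 - f(c)) + N(0, noise_sd)` with
#' `f(c) = c^h / (c^h + IC50^h)`; control and blank wells are drawn with the
#' same noise. Censored solutes respond through the same model with their
#' true IC50 at `100 * c_max`, i.e. essentially flat over the tested range.
#' Output is deterministic given the seed.
#'
#' @param cfg a [simulation_config()].
#' @return An [endpoint_plate()].
#' @export
#' @examples
#' plate <- simulate_endpoint_assay(simulation_config(seed = 42))
#' fit_ic50(build_inhibition_curve(plate, "uric acid"))
simulate_endpoint_assay <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_rng_seed(cfg$seed, {
    rows <- list()
    span <- cfg$control_abs - cfg$blank_abs
    for (rep in seq_len(cfg$n_replicates)) {
      noise <- function(n) if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        assay_id = cfg$assay_id, replicate_id = rep, solute = "none",
        conc_umol_L = 0,
        absorbance = c(cfg$control_abs, cfg$blank_abs) + noise(2L),
        role = c("control", "blank"), stringsAsFactors = FALSE)
      for (solute in names(cfg$true_ic50s)) {
        truth <- .solute_truth(cfg, solute)
        grid <- truth$grid
        if (any(grid <= 0)) stop("invalid concentration grid", call. = FALSE)
        f <- grid^cfg$hill_h / (grid^cfg$hill_h + truth$ic50^cfg$hill_h)
        rows[[length(rows) + 1L]] <- data.frame(
          assay_id = cfg$assay_id, replicate_id = rep, solute = solute,
          conc_umol_L = grid,
          absorbance = cfg$blank_abs + span * (1 - f) + noise(length(grid)),
          role = "sample", stringsAsFactors = FALSE)
      }
    }
    endpoint_plate(do.call(rbind, rows))
  })
}

# deterministic kinetic trace given an explicit seed
.kinetic_trace_once <- function(cfg, solute, conc, seed, sample_id) {
  kin <- cfg$kinetic
  ratio <- if (conc == 0) 0 else {
    r <- kin$ka_kc[[solute]]
    if (is.null(r)) stop("no ka/kc ratio configured for ", solute, call. = FALSE)
    r
  }
  c_molar <- kin$crocin_umol_L * 1e-6
  a0 <- kin$epsilon_M_cm * kin$path * c_molar
  v0 <- kin$epsilon_M_cm * kin$path * kin$radical_flux * kin$kc_rel * c_molar
  v <- v0 / (1 + ratio * conc / kin$crocin_umol_L)
  t <- seq(0, kin$duration, by = kin$dt)
  with_rng_seed(seed, {
    eps <- if (kin$noise_sd > 0) rnorm(length(t), 0, kin$noise_sd) else 0
    a <- pmax(0, a0 - v * pmax(0, t - kin$t_lag) + eps)
    kinetic_trace(sample_id, if (conc == 0) "none" else solute,
                  conc, kin$crocin_umol_L, t, a)
  })
}

#' Simulate a crocin bleaching trace
#'
#' The uninhibited bleaching rate is `v0 = epsilon * path * radical_flux *
#' kc_rel * [C]` (AU/s); in the presence of an antioxidant the rate follows
#' the competition law `v = v0 / (1 + (ka/kc) [A]/[C])`. The absorbance
#' trace is `A(t) = epsilon * path * [C] - v * max(0, t - t_lag) +
#' N(0, noise_sd)`, floored at the blank level.
#'
#' @param cfg a [simulation_config()] with its kinetic block set.
#' @param solute solute name (must appear in `kinetic$ka_kc` unless
#'   `conc = 0`).
#' @param conc antioxidant concentration `[A]`, umol/L (>= 0).
#'
#' @return A [kinetic_trace()].
#' @export
simulate_kinetic_trace <- function(cfg, solute, conc) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (conc < 0) stop("`conc` must be >= 0", call. = FALSE)
  .kinetic_trace_once(cfg, solute, conc, cfg$seed,
                      sprintf("%s_c%g", if (conc == 0) "v0" else solute, conc))
}

#' Simulate a full crocin panel
#'
#' Generates, per replicate, one `[A] = 0` trace (defining v0) and one trace
#' per solute and concentration. Default concentrations place `[A]/[C]` at
#' 0.25, 0.5, 1, 2 and 4 times the solute's kinetic IC50 ratio, a 16-fold
#' span.
#'
#' @param cfg a [simulation_config()].
#' @param conc_factors multiples of the kinetic IC50 (`[C]/(ka/kc)`) at
#'   which to place the concentrations.
#' @return Named list of [kinetic_trace()] objects, ready for
#'   [crocin_panel()].
#' @export
simulate_kinetic_panel <- function(cfg, conc_factors = c(0.25, 0.5, 1, 2, 4)) {
  stopifnot(inherits(cfg, "simulation_config"))
  kin <- cfg$kinetic
  traces <- list()
  k <- 0L
  for (rep in seq_len(kin$n_replicates)) {
    k <- k + 1L
    id <- sprintf("v0_r%d", rep)
    traces[[id]] <- .kinetic_trace_once(cfg, "none", 0, cfg$seed + k, id)
    for (solute in names(kin$ka_kc)) {
      ic50_kin <- kin$crocin_umol_L / kin$ka_kc[[solute]]
      for (conc in ic50_kin * conc_factors) {
        k <- k + 1L
        id <- sprintf("%s_r%d_c%g", solute, rep, conc)
        traces[[id]] <- .kinetic_trace_once(cfg, solute, conc, cfg$seed + k, id)
      }
    }
  }
  traces
}

#' Simulate a mixture dose-volume response
#'
#' Produces an endpoint plate whose x-axis is the volume of an
#' IC50-proportioned stock added to the reaction. The capture fraction at a
#' Loewe sum `S` (see [loewe_sum()]) is `f = S^h / (lambda^h + S^h)`: at
#' `lambda = 1` this is the exactly-additive Loewe response `S/(1+S)` (for
#' `h = 1`), 50% capture falls at `S = lambda`, and the fitted additivity
#' index equals `lambda` in the noise-free limit — a single antagonism dial
#' that is exact at 1 and strictly monotone. The parameterization is
#' recorded in the plate's `interaction_model` attribute.
#'
#' @param cfg a [simulation_config()] whose mixture block has a `spec`.
#' @return An [endpoint_plate()] with `conc_unit = "uL"`.
#' @export
simulate_mixture_response <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  mix <- cfg$mixture
  if (is.null(mix$spec)) stop("mixture block has no `spec`", call. = FALSE)
  spec <- mix$spec
  if (anyNA(spec$components$individual_ic50)) {
    stop("cannot simulate a mixture with censored components", call. = FALSE)
  }
  n <- nrow(spec$components)
  v_star <- spec$final_volume / (n * spec$multiplier) # S = 1 volume
  volumes <- mix$volume_grid %||%
    pmin(spec$final_volume, v_star * mix$lambda * 2^seq(-3, 3, length.out = 9))
  with_rng_seed(cfg$seed, {
    rows <- list()
    span <- cfg$control_abs - cfg$blank_abs
    for (rep in seq_len(mix$n_replicates)) {
      noise <- function(n) if (mix$noise_sd > 0) rnorm(n, 0, mix$noise_sd) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        assay_id = spec$assay_id, replicate_id = rep, solute = "none",
        conc_umol_L = 0,
        absorbance = c(cfg$control_abs, cfg$blank_abs) + noise(2L),
        role = c("control", "blank"), stringsAsFactors = FALSE)
      s <- vapply(volumes, function(v) loewe_sum(spec, v), numeric(1))
      f <- s^mix$hill_h / (mix$lambda^mix$hill_h + s^mix$hill_h)
      rows[[length(rows) + 1L]] <- data.frame(
        assay_id = spec$assay_id, replicate_id = rep, solute = "mixture",
        conc_umol_L = volumes,
        absorbance = cfg$blank_abs + span * (1 - f) + noise(length(volumes)),
        role = "sample", stringsAsFactors = FALSE)
    }
    plate <- endpoint_plate(do.call(rbind, rows), conc_unit = "uL")
    attr(plate, "interaction_model") <-
      sprintf("f = S^h/(lambda^h + S^h), lambda = %g, h = %g",
              mix$lambda, mix$hill_h)
    plate
  })
}

#' Generate a complete fixture scenario on disk
#'
#' Writes a directory of CSV/JSON fixtures shaped like a full study: endpoint
#' plates for the ABTS and HOCl panels (effective solutes at their reference
#' IC50s plus a censored methylguanidine-like solute), a crocin kinetic panel
#' (uric acid, Trolox, phenol at their reference ka/kc slopes), a binary
#' crocin mixture response simulated with antagonism `lambda = 1.5`, the
#' mixture design config, and a manifest (JSON) recording the seed, ground
#' truths and `lambda`. Identical seeds produce byte-identical directories.
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param noise_sd endpoint noise SD (0 gives exactly invertible fixtures).
#' @param kinetic_noise_sd kinetic noise SD.
#' @param lambda antagonism parameter of the binary crocin mixture.
#'
#' @return `dir`, invisibly; files `abts_plate.csv`, `hocl_plate.csv`,
#'   `crocin_traces.csv`, `mixture_plate.csv`, `mixture_config.json`,
#'   `manifest.json`.
#' @export
generate_fixture_set <- function(seed, dir, noise_sd = 0.005,
                                 kinetic_noise_sd = 0.002, lambda = 1.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  abts <- c("uric acid" = 16.75, "phenol" = 12.98, "p-cresol" = 3.99,
            "L-tyrosine" = 5.23, "methylguanidine" = NA)
  hocl <- c("uric acid" = 5.75, "phenol" = 8.95, "p-cresol" = 15.75,
            "L-tyrosine" = 2.83, "methylguanidine" = NA)
  c_max <- c("methylguanidine" = 910) # 10x the mean uremic level
  cfg_abts <- simulation_config(seed = seed, assay_id = "ABTS",
                                true_ic50s = abts, noise_sd = noise_sd,
                                c_max_censored = c_max)
  cfg_hocl <- simulation_config(seed = seed + 1L, assay_id = "HOCL",
                                true_ic50s = hocl, noise_sd = noise_sd,
                                c_max_censored = c_max)
  write_endpoint_csv(simulate_endpoint_assay(cfg_abts),
                     file.path(dir, "abts_plate.csv"))
  write_endpoint_csv(simulate_endpoint_assay(cfg_hocl),
                     file.path(dir, "hocl_plate.csv"))

  ka_kc <- c("uric acid" = 4.015, "Trolox" = 2.230, "phenol" = 0.023)
  cfg_kin <- simulation_config(seed = seed + 2L,
                               kinetic = list(ka_kc = ka_kc,
                                              noise_sd = kinetic_noise_sd))
  write_kinetic_csv(simulate_kinetic_panel(cfg_kin),
                    file.path(dir, "crocin_traces.csv"))

  spec <- design_stock(c("uric acid" = 6.90, "phenol" = 1125.81),
                       multiplier = 10, final_volume = 2000,
                       assay_id = "CROCIN")
  cfg_mix <- simulation_config(seed = seed + 3L, noise_sd = noise_sd,
                               mixture = list(spec = spec, lambda = lambda))
  write_endpoint_csv(simulate_mixture_response(cfg_mix),
                     file.path(dir, "mixture_plate.csv"))
  jsonlite::write_json(
    list(assay = "CROCIN",
         components = data.frame(solute = spec$components$solute,
                                 ic50_umol_L = spec$components$individual_ic50),
         multiplier = spec$multiplier,
         final_volume_uL = spec$final_volume),
    file.path(dir, "mixture_config.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = seed, noise_sd = noise_sd, kinetic_noise_sd = kinetic_noise_sd,
         lambda = lambda,
         interaction_model = "f = S^h/(lambda^h + S^h)",
         abts_true_ic50 = as.list(abts), hocl_true_ic50 = as.list(hocl),
         censored_c_max = as.list(c_max), crocin_ka_kc = as.list(ka_kc)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
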