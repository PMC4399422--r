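#' Endpoint assay plate
#'
#' An `endpoint_plate` is a long-format table of endpoint absorbance readings
#' for one of the endpoint model systems, one row per well:
#' `assay_id`, `replicate_id`, `solute`, `conc_umol_L`, `absorbance`, `role`.
#' Each replicate must carry at least one `control` row (uninhibited, 100%
#' reaction) and one `blank` row (reading blank); `sample` rows must have a
#' positive concentration. For mixture response curves the x-axis is the
#' added stock volume rather than a concentration; `conc_unit` records which.
#'
#' @param df data frame with the columns above.
#' @param wavelength_nm measurement wavelength; defaults to the assay's
#'   standard wavelength (ABTS 734, HOCL 655, SUPEROXIDE 560, H2O2 412 nm).
#' @param conc_unit `"umol_L"` for solute concentrations, `"uL"` for mixture
#'   stock volumes.
#'
#' @return The validated data frame with class `endpoint_plate`.
#' @export
endpoint_plate <- function(df, wavelength_nm = NULL,
                           conc_unit = c("umol_L", "uL")) {
  conc_unit <- match.arg(conc_unit)
  df <- validate_endpoint_plate(df)
  assay <- df$assay_id[1L]
  if (is.null(wavelength_nm)) {
    wavelength_nm <- assay_wavelength(assay)
  }
  structure(df, class = c("endpoint_plate", "data.frame"),
            wavelength_nm = wavelength_nm, conc_unit = conc_unit)
}

assay_wavelength <- function(assay_id) {
  switch(assay_id,
         ABTS = 734, HOCL = 655, SUPEROXIDE = 560, H2O2 = 412,
         CROCIN = 443, NA_real_)
}

.endpoint_cols <- c("assay_id", "replicate_id", "solute", "conc_umol_L",
                    "absorbance", "role")

#' Validate an endpoint plate table
#'
#' Checks the schema and assay invariants of an endpoint plate table and
#' reports every violation with the offending row numbers.
#'
#' @param df candidate data frame.
#' @return The data frame, invisibly coerced to canonical column types.
#' @export
validate_endpoint_plate <- function(df) {
  missing <- setdiff(.endpoint_cols, names(df))
  if (length(missing)) {
    stop("endpoint plate is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[.endpoint_cols]
  problems <- character()
  num_abs <- suppressWarnings(as.numeric(df$absorbance))
  bad <- which(is.na(num_abs))
  if (length(bad)) {
    problems <- c(problems, paste0("non-numeric absorbance in row(s) ",
                                   paste(bad, collapse = ", ")))
  }
  num_conc <- suppressWarnings(as.numeric(df$conc_umol_L))
  bad <- which(is.na(num_conc) | num_conc < 0)
  if (length(bad)) {
    problems <- c(problems, paste0("missing or negative conc_umol_L in row(s) ",
                                   paste(bad, collapse = ", ")))
  }
  bad <- which(!df$role %in% c("control", "blank", "sample"))
  if (length(bad)) {
    problems <- c(problems,
                  paste0("role must be control/blank/sample; bad row(s) ",
                         paste(bad, collapse = ", ")))
  }
  bad <- which(df$role == "sample" & num_conc <= 0)
  if (length(bad)) {
    problems <- c(problems, paste0("sample rows need conc > 0; row(s) ",
                                   paste(bad, collapse = ", ")))
  }
  if (length(unique(df$assay_id)) > 1L) {
    problems <- c(problems, "a plate must hold a single assay_id")
  }
  for (rep in unique(df$replicate_id)) {
    roles <- df$role[df$replicate_id == rep]
    if (!any(roles == "control")) {
      problems <- c(problems, paste0("replicate ", rep, " has no control row"))
    }
    if (!any(roles == "blank")) {
      problems <- c(problems, paste0("replicate ", rep, " has no blank row"))
    }
  }
  if (length(problems)) {
    stop("invalid endpoint plate:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  df$absorbance <- num_abs
  df$conc_umol_L <- num_conc
  df
}

#' @export
print.endpoint_plate <- function(x, ...) {
  cat(sprintf("<endpoint plate> %s @ %g nm: %d wells, %d replicate(s), %d solute(s)\n",
              x$assay_id[1L], attr(x, "wavelength_nm"), nrow(x),
              length(unique(x$replicate_id)),
              length(unique(x$solute[x$role == "sample"]))))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Read or write an endpoint plate CSV
#'
#' The endpoint CSV dialect has exactly the columns
#' `assay_id,replicate_id,solute,conc_umol_L,absorbance,role` with
#' `role` one of `control`, `blank`, `sample`. Round-trips are lossless.
#'
#' @param path file path.
#' @return [read_endpoint_csv()] returns an [endpoint_plate()];
#'   [write_endpoint_csv()] returns `path` invisibly.
#' @export
read_endpoint_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("empty endpoint CSV: ", path, call. = FALSE)
  df$replicate_id <- suppressWarnings(as.integer(df$replicate_id))
  endpoint_plate(df)
}

#' @rdname read_endpoint_csv
#' @param plate an [endpoint_plate()].
#' @export
write_endpoint_csv <- function(plate, path) {
  stopifnot(inherits(plate, "endpoint_plate"))
  df <- as.data.frame(plate)[.endpoint_cols]
  df$conc_umol_L <- format(df$conc_umol_L, digits = 15, trim = TRUE,
                           scientific = FALSE)
  df$absorbance <- format(df$absorbance, digits = 15, trim = TRUE,
                          scientific = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Kinetic trace of crocin bleaching
#'
#' A `kinetic_trace` holds one absorbance-vs-time series at 443 nm for one
#' sample: the antioxidant concentration `[A]` (umol/L), the crocin
#' concentration `[C]` (umol/L), and strictly increasing time points.
#'
#' @param sample_id sample label.
#' @param solute solute name (`"none"` for the uninhibited v0 trace).
#' @param conc_umol_L antioxidant concentration `[A]`, umol/L (>= 0).
#' @param crocin_umol_L crocin concentration `[C]`, umol/L (> 0).
#' @param time_s numeric vector of times, s, strictly increasing.
#' @param abs_443 absorbances at 443 nm, AU, same length as `time_s`.
#' @param blank_corrected has the per-sample reaction blank (mixture without
#'   crocin) already been subtracted point-wise?
#'
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(sample_id, solute, conc_umol_L, crocin_umol_L,
                          time_s, abs_443, blank_corrected = TRUE) {
  if (length(time_s) != length(abs_443)) {
    stop("`time_s` and `abs_443` must have the same length", call. = FALSE)
  }
  if (any(diff(time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  if (crocin_umol_L <= 0) stop("crocin concentration must be > 0", call. = FALSE)
  if (conc_umol_L < 0) stop("`conc_umol_L` must be >= 0", call. = FALSE)
  structure(
    list(sample_id = sample_id, solute = solute,
         conc_umol_L = conc_umol_L, crocin_umol_L = crocin_umol_L,
         time_s = as.numeric(time_s), abs_443 = as.numeric(abs_443),
         blank_corrected = isTRUE(blank_corrected)),
    class = "kinetic_trace"
  )
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic trace> %s (%s, [A]=%g umol/L, [C]=%g umol/L): %d points, %g-%g s\n",
              x$sample_id, x$solute, x$conc_umol_L, x$crocin_umol_L,
              length(x$time_s), min(x$time_s), max(x$time_s)))
  invisible(x)
}

.kinetic_cols <- c("sample_id", "solute", "conc_umol_L", "crocin_umol_L",
                   "time_s", "abs_443")

#' Read or write kinetic trace CSVs
#'
#' The kinetic CSV dialect has one row per time point with columns
#' `sample_id,solute,conc_umol_L,crocin_umol_L,time_s,abs_443`.
#' [read_kinetic_csv()] splits the file into one [kinetic_trace()] per
#' `sample_id`, preserving file order.
#'
#' @param path file path.
#' @return A named list of [kinetic_trace()] objects.
#' @export
read_kinetic_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.kinetic_cols, names(df))
  if (length(missing)) {
    stop("kinetic CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("conc_umol_L", "crocin_umol_L", "time_s", "abs_443")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop("non-numeric ", col, " in row(s) ",
           paste(which(is.na(v)), collapse = ", "), call. = FALSE)
    }
    df[[col]] <- v
  }
  ids <- unique(df$sample_id)
  traces <- lapply(ids, function(id) {
    d <- df[df$sample_id == id, ]
    kinetic_trace(id, d$solute[1L], d$conc_umol_L[1L], d$crocin_umol_L[1L],
                  d$time_s, d$abs_443)
  })
  setNames(traces, ids)
}

#' @rdname read_kinetic_csv
#' @param traces a list of [kinetic_trace()] objects (or a single one).
#' @export
write_kinetic_csv <- function(traces, path) {
  if (inherits(traces, "kinetic_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(sample_id = tr$sample_id, solute = tr$solute,
               conc_umol_L = tr$conc_umol_L, crocin_umol_L = tr$crocin_umol_L,
               time_s = tr$time_s, abs_443 = tr$abs_443,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$abs_443 <- format(df$abs_443, digits = 15, trim = TRUE, scientific = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
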