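#' Round a value for display under an explicit convention
#'
#' Report tables support two display conventions for 2-decimal quantities:
#' `"half-up"` (arithmetic rounding, 4.4499 -> 4.45, 1.5985 -> 1.60) and
#' `"truncate"` (566.355 -> 566.35, 0.2657 -> 0.26). Published assay tables
#' mix both conventions, so the choice is explicit and recorded in output
#' metadata; raw values are always kept at full precision internally.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @param convention `"half-up"` or `"truncate"`.
#' @return Numeric vector rounded for display.
#' @export
#' @examples
#' round_display(4.4499, 2, "half-up")  # 4.45
#' round_display(566.355, 2, "truncate") # 566.35
round_display <- function(x, digits = 2, convention = c("half-up", "truncate")) {
  convention <- match.arg(convention)
  m <- 10^digits
  switch(convention,
         "half-up" = floor(x * m + 0.5) / m,
         "truncate" = trunc(x * m) / m)
}

# slopes below 1e-3 are customarily printed in scientific notation
format_slope <- function(x) {
  ifelse(abs(x) < 1e-3 & x != 0,
         sprintf("%.3e", x),
         sprintf("%.3f", x))
}

#' Assemble an IC50 panel table
#'
#' Long-to-wide summary of [ic50_result()] objects in the layout of a
#' published solute-by-assay IC50 panel: one row per solute, one column per
#' assay, censored cells rendered `"ND>c_max"`.
#'
#' @param results list of [ic50_result()] objects.
#' @param digits significant digits for uncensored entries.
#' @return Data frame with a `solute` column and one column per assay.
#' @export
ic50_table <- function(results, digits = 6) {
  stopifnot(all(vapply(results, inherits, logical(1), "ic50_result")))
  long <- do.call(rbind, lapply(results, function(r) {
    data.frame(solute = r$solute, assay = r$assay_id,
               cell = format_ic50(r, digits), stringsAsFactors = FALSE)
  }))
  solutes <- unique(long$solute)
  assays <- unique(long$assay)
  wide <- data.frame(solute = solutes, stringsAsFactors = FALSE)
  for (a in assays) {
    wide[[a]] <- vapply(solutes, function(s) {
      hit <- long$cell[long$solute == s & long$assay == a]
      if (length(hit)) hit[1L] else NA_character_
    }, character(1))
  }
  wide
}

#' Assemble a crocin competition table
#'
#' Summary of a [crocin_panel()] result in the layout of a published
#' competition-kinetics table: solute, ka/kc slope (scientific notation
#' below 1e-3), Trolox equivalents and kinetic IC50 (censored cells as
#' `"ND>c_max"`), ordered by decreasing slope.
#'
#' @param panel result of [crocin_panel()].
#' @return Data frame.
#' @export
crocin_table <- function(panel) {
  tab <- do.call(rbind, lapply(names(panel), function(sol) {
    res <- panel[[sol]]
    data.frame(solute = sol,
               slope = res$fit$slope,
               slope_display = format_slope(res$fit$slope),
               trolox_equivalents = res$fit$trolox_equivalents,
               ic50 = format_ic50(res$ic50, 6),
               stringsAsFactors = FALSE)
  }))
  tab[order(-tab$slope), , drop = FALSE]
}

#' Assemble a mixture accounting table
#'
#' Per-component table of a [mixture_report()] in the layout of a published
#' mixture-IC50 accounting: IC50 volume, concentration of each component at
#' the mixture IC50, its individual IC50 and the ratio between the two,
#' plus observed/projected totals and the additivity index as attributes.
#'
#' @param report a [mixture_report()].
#' @param digits decimal places for display columns.
#' @param convention display rounding convention (see [round_display()]).
#' @return Data frame with attributes `observed_total`, `projected_total`,
#'   `additivity_index`, `classification`, `convention`.
#' @export
mixture_table <- function(report, digits = 2,
                          convention = c("half-up", "truncate")) {
  stopifnot(inherits(report, "mixture_report"))
  convention <- match.arg(convention)
  if (report$censored) {
    stop("censored mixture report: no IC50 volume to tabulate", call. = FALSE)
  }
  tab <- data.frame(
    solute = report$spec$components$solute,
    ic50_volume_uL = round_display(report$ic50_volume, digits, convention),
    conc_at_ic50 = round_display(as.numeric(report$component_conc_at_ic50),
                                 digits, convention),
    individual_ic50 = report$spec$components$individual_ic50,
    ratio_to_ic50 = round_display(as.numeric(report$ratio_to_individual_ic50),
                                  digits, convention),
    stringsAsFactors = FALSE
  )
  attr(tab, "observed_total") <- report$observed_total
  attr(tab, "projected_total") <- report$projected_total
  attr(tab, "additivity_index") <- report$additivity_index
  attr(tab, "classification") <- report$classification
  attr(tab, "convention") <- convention
  tab
}

# md5 of an R object's canonical serialization, for config provenance lines
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Write a report table as TSV with embedded metadata
#'
#' Locale-independent TSV with `# key: value` header lines recording the
#' rounding convention and a hash of the generating configuration, so a
#' re-run with the same configuration is byte-identical and self-describing.
#'
#' @param tab data frame (e.g. from [ic50_table()], [crocin_table()],
#'   [mixture_table()]).
#' @param path output path.
#' @param convention rounding convention string recorded in the header.
#' @param config object hashed into the header (e.g. the run configuration).
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(tab, path, convention = "half-up",
                             config = NULL) {
  meta <- c(sprintf("# rounding: %s", convention),
            sprintf("# config_hash: %s",
                    if (is.null(config)) "none" else config_hash(config)))
  for (a in c("observed_total", "projected_total", "additivity_index",
              "classification")) {
    if (!is.null(attr(tab, a))) {
      meta <- c(meta, sprintf("# %s: %s", a, format(attr(tab, a), digits = 15)))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a report TSV written by [write_report_tsv()]
#'
#' @param path file path.
#' @return Data frame; header metadata in attribute `metadata`.
#' @export
read_report_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  tab <- read.csv(text = lines[!startsWith(lines, "# ")], sep = "\t",
                  stringsAsFactors = FALSE)
  attr(tab, "metadata") <- sub("^# ", "", meta)
  tab
}
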