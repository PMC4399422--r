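# shared fixture builders: everything is generated in code, no files

# minimal valid endpoint plate: 1 replicate, control + blank + n sample wells
make_plate_df <- function(assay = "ABTS", solute = "uric acid",
                          conc = c(5, 10, 20, 40), control = 0.750,
                          blank = 0, absorbance = NULL, replicate = 1L) {
  if (is.null(absorbance)) {
    f <- conc / (conc + 16.75)
    absorbance <- blank + (control - blank) * (1 - f)
  }
  rbind(
    data.frame(assay_id = assay, replicate_id = replicate, solute = "none",
               conc_umol_L = 0, absorbance = c(control, blank),
               role = c("control", "blank"), stringsAsFactors = FALSE),
    data.frame(assay_id = assay, replicate_id = replicate, solute = solute,
               conc_umol_L = conc, absorbance = absorbance, role = "sample",
               stringsAsFactors = FALSE)
  )
}

# exact hyperbolic inhibition curve (Hill slope h), optionally replicated
make_exact_curve <- function(ic50, conc = ic50 * 2^seq(-3, 3), h = 1,
                             reps = 1L, assay = "ABTS", solute = "x") {
  pts <- do.call(rbind, lapply(seq_len(reps), function(r) {
    data.frame(conc = conc,
               inhibition = 100 * conc^h / (conc^h + ic50^h),
               replicate_id = r)
  }))
  inhibition_curve(pts, assay_id = assay, solute = solute)
}

# exact linear bleaching trace A(t) = a0 - v * t over given times
make_line_trace <- function(v = 1e-4, a0 = 0.343, t = seq(0, 600, by = 10),
                            conc = 0, solute = "none", crocin = 25) {
  kinetic_trace(paste0(solute, "_line"), solute, conc, crocin, t, a0 - v * t)
}

# dense log-spaced grid-search oracle for the IC50 (fixed Hill slope h)
grid_search_ic50 <- function(points, h = 1, n_grid = 1e4) {
  grid <- exp(seq(log(min(points$conc) / 10), log(max(points$conc) * 10),
                  length.out = n_grid))
  sse <- vapply(grid, function(ic) {
    pred <- 100 * points$conc^h / (points$conc^h + ic^h)
    sum((points$inhibition - pred)^2)
  }, numeric(1))
  grid[which.min(sse)]
}
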