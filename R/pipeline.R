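#' Analysis configuration
#'
#' Declares the inputs of a full binary/ternary binding analysis: the
#' titrations per excitation wavelength (quenching and REES), per
#' synchronous offset, the RLS series, and the constants for the
#' quenching and Forster stages. Every titration slot is optional -
#' stages without inputs are skipped and marked absent in the report.
#'
#' @param label system label (e.g. `"binary"` or `"ternary-alphaCD"`).
#' @param ex280,ex295,ex305 emission [titration_series()] (or manifest
#'   paths) excited at 280, 295 and 305 nm.
#' @param sync15,sync60 synchronous-scan [titration_series()] at
#'   delta-lambda 15 / 60 nm.
#' @param rls RLS [titration_series()] (delta-lambda = 0 scans) or an
#'   [rls_curve()].
#' @param acceptor acceptor extinction [spectrum()] for the FRET stage,
#'   or `NULL` to skip it.
#' @param fret a [fret_constants()], required when `acceptor` is given.
#' @param tau0 fluorophore lifetime, s.
#' @param diffusion_limit dynamic-quenching ceiling, M^-1 s^-1.
#' @param two_regime fit two Stern-Volmer regimes?
#' @param readout `"peak"` or `"at"` (see [titration_intensities()]).
#' @param readout_wavelength wavelength for `readout = "at"`.
#' @param f_threshold hinge-acceptance F-ratio for [detect_cciac()].
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(label, ex280 = NULL, ex295 = NULL,
                            ex305 = NULL, sync15 = NULL, sync60 = NULL,
                            rls = NULL, acceptor = NULL, fret = NULL,
                            tau0 = 1e-8, diffusion_limit = 2e10,
                            two_regime = FALSE,
                            readout = c("peak", "at"),
                            readout_wavelength = NULL,
                            f_threshold = 4.0) {
  readout <- match.arg(readout)
  load_t <- function(x, kind) {
    if (is.null(x) || inherits(x, "titration_series") ||
        inherits(x, "rls_curve")) return(x)
    read_titration(x, kind = kind)
  }
  cfg <- list(label = label,
              ex280 = load_t(ex280, "emission"),
              ex295 = load_t(ex295, "emission"),
              ex305 = load_t(ex305, "emission"),
              sync15 = load_t(sync15, "synchronous"),
              sync60 = load_t(sync60, "synchronous"),
              rls = load_t(rls, "rls"),
              acceptor = acceptor, fret = fret, tau0 = tau0,
              diffusion_limit = diffusion_limit,
              two_regime = two_regime, readout = readout,
              readout_wavelength = readout_wavelength,
              f_threshold = f_threshold)
  slots <- c("ex280", "ex295", "ex305", "sync15", "sync60", "rls")
  if (all(vapply(slots, function(s) is.null(cfg[[s]]), logical(1))))
    stop("at least one titration must be supplied")
  if (tau0 <= 0 || diffusion_limit <= 0)
    stop("tau0 and diffusion_limit must be positive")
  if (!is.null(acceptor) && is.null(fret))
    stop("a FRET acceptor needs fret_constants (quantum yield!)")
  structure(cfg, class = "analysis_config")
}

#' Run the full binding analysis
#'
#' Orchestrates every stage for one system: Stern-Volmer, modified
#' Stern-Volmer and double-log quenching fits for each quenching
#' excitation (280 and 295 nm), mechanism classification, REES from the
#' 295/305 nm pair, synchronous slopes at both offsets, RLS
#' aggregation-onset detection, and the Forster analysis against the
#' supplied acceptor. Stages whose inputs are absent are skipped; by
#' default that is tolerated (`allow_missing = TRUE`) and recorded in
#' the report's `missing` field. The run is deterministic given its
#' inputs, and every decision (regime splits, unphysical-parameter
#' flags, exclusions) is appended to the report log.
#'
#' @param cfg an [analysis_config()].
#' @param allow_missing tolerate absent stages? If `FALSE`, any skipped
#'   stage is an error.
#' @return An object of class `"analysis_report"`: a list with
#'   `label`, per-stage results (`quenching`, `mechanism`, `rees`,
#'   `synchronous`, `rls`, `fret`), a `tables` list of data.frames, a
#'   `missing` character vector and a `log` character vector.
#' @export
run_analysis <- function(cfg, allow_missing = TRUE) {
  stopifnot(inherits(cfg, "analysis_config"))
  log <- character(0)
  missing <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  skip <- function(stage) {
    if (!allow_missing)
      stop("stage '", stage, "' has no input and allow_missing = FALSE")
    missing <<- c(missing, stage)
    note("stage %s: no input, skipped", stage)
    NULL
  }

  fit_block <- function(series, ex) {
    sv <- withCallingHandlers(
      stern_volmer_fit(series, readout = cfg$readout,
                       wavelength = cfg$readout_wavelength,
                       tau0 = cfg$tau0, two_regime = cfg$two_regime),
      warning = function(w) {
        note("ex%d Stern-Volmer: %s", ex, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    msv <- modified_stern_volmer_fit(series, readout = cfg$readout,
                                     wavelength = cfg$readout_wavelength,
                                     two_regime = cfg$two_regime)
    dl <- double_log_fit(series, readout = cfg$readout,
                         wavelength = cfg$readout_wavelength)
    if (cfg$two_regime)
      note("ex%d: two-regime split at [Q] = %.4g %s", ex,
           sv$regime_split, sv$unit)
    msv1 <- if (inherits(msv, "accessibility_fit2")) msv$low else msv
    if (isTRUE(msv1$unphysical))
      note("ex%d modified Stern-Volmer flagged unphysical: %s", ex,
           msv1$unphysical_reason)
    kq_molar <- per_conc_to_per_molar(sv$kq, sv$unit)
    mech <- classify_mechanism(kq_molar, "M", cfg$diffusion_limit)
    note("ex%d: kq = %.4g M^-1 s^-1 -> %s", ex, kq_molar, mech)
    list(excitation = ex, sv = sv, msv = msv, dl = dl,
         kq_molar = kq_molar, mechanism = mech)
  }

  quenching <- list()
  for (ex in c(280L, 295L)) {
    slot <- paste0("ex", ex)
    if (is.null(cfg[[slot]])) skip(slot)
    else quenching[[slot]] <- fit_block(cfg[[slot]], ex)
  }

  rees_res <- NULL
  if (!is.null(cfg$ex295) && !is.null(cfg$ex305)) {
    n295 <- length(cfg$ex295$concentrations)
    n305 <- length(cfg$ex305$concentrations)
    rees_res <- rees(cfg$ex295$spectra[[n295]],
                     cfg$ex305$spectra[[n305]], mode = "table")
    note("REES (highest-concentration pair): %g nm", rees_res$rees)
  } else skip("rees")

  synchronous <- list()
  for (slot in c("sync15", "sync60")) {
    if (is.null(cfg[[slot]])) skip(slot)
    else {
      synchronous[[slot]] <- synchronous_slope(cfg[[slot]])
      note("%s: slope %.4g per %s", slot, synchronous[[slot]]$slope,
           synchronous[[slot]]$unit)
    }
  }

  rls_res <- NULL
  if (!is.null(cfg$rls)) {
    curve <- if (inherits(cfg$rls, "rls_curve")) cfg$rls
             else extract_rls_curve(cfg$rls)
    rls_res <- detect_cciac(curve, f_threshold = cfg$f_threshold)
    note(if (rls_res$detected) "RLS: C_CIAC = %.4g %s"
         else "RLS: no onset detected (%.4g %s grid top)",
         if (rls_res$detected) rls_res$cciac
         else max(curve$concentrations), curve$unit)
  } else skip("rls")

  fret_res <- NULL
  if (!is.null(cfg$acceptor)) {
    donor_series <- if (!is.null(cfg$ex295)) cfg$ex295 else cfg$ex280
    if (is.null(donor_series)) skip("fret")
    else {
      n <- length(donor_series$concentrations)
      fint <- titration_intensities(donor_series, cfg$readout,
                                    cfg$readout_wavelength)
      fret_res <- fret_analysis(donor_series$spectra[[1L]],
                                cfg$acceptor, f = fint[n], f0 = fint[1L],
                                constants = cfg$fret)
      note("FRET: J = %.4g cm^3 M^-1, E = %.4g, R0 = %.4g nm, r = %.4g nm",
           fret_res$j, fret_res$e, fret_res$r0, fret_res$r)
    }
  } else skip("fret")

  report <- structure(
    list(label = cfg$label, quenching = quenching,
         rees = rees_res, synchronous = synchronous, rls = rls_res,
         fret = fret_res, missing = missing, log = log,
         config = cfg),
    class = "analysis_report")
  report$tables <- report_tables(report)
  report
}

# flatten a report into Table-style data.frames
report_tables <- function(rep) {
  qrows <- lapply(rep$quenching, function(b) {
    sv <- b$sv
    msv <- b$msv
    msv1 <- if (inherits(msv, "accessibility_fit2")) msv$low else msv
    msv2 <- if (inherits(msv, "accessibility_fit2")) msv$high else NULL
    data.frame(
      system = rep$label, excitation_nm = b$excitation,
      ksv1 = sv$ksv, ksv2 = sv$ksv2,
      kq1 = sv$kq, kq2 = sv$kq2,
      n1 = b$dl$n, n2 = NA_real_,
      f1 = msv1$fa, f2 = if (is.null(msv2)) NA_real_ else msv2$fa,
      r1 = sv$r, r2 = sv$r2,
      unit = sv$unit, mechanism = b$mechanism,
      unphysical = msv1$unphysical)
  })
  tables <- list()
  if (length(qrows))
    tables$quenching <- do.call(rbind, c(qrows, make.row.names = FALSE))
  if (!is.null(rep$rees))
    tables$rees <- data.frame(system = rep$label,
                              lam_max_295 = rep$rees$lam_max_295,
                              lam_max_305 = rep$rees$lam_max_305,
                              rees_nm = rep$rees$rees)
  if (length(rep$synchronous))
    tables$synchronous <- do.call(rbind, lapply(rep$synchronous,
      function(s) data.frame(system = rep$label,
                             delta_lambda = s$delta_lambda,
                             slope = s$slope,
                             residual_rms = s$residual_rms,
                             lam_max_shift = s$lam_max_shift)))
  if (!is.null(rep$rls))
    tables$rls <- data.frame(system = rep$label,
                             cciac = rep$rls$cciac,
                             detected = rep$rls$detected,
                             baseline = rep$rls$baseline,
                             slope_above = rep$rls$slope_above)
  if (!is.null(rep$fret))
    tables$fret <- data.frame(system = rep$label, j = rep$fret$j,
                              e = rep$fret$e, r0 = rep$fret$r0,
                              r = rep$fret$r)
  tables
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Binding analysis report: %s\n", x$label))
  for (nm in names(x$tables)) {
    cat("--", nm, "--\n")
    print(x$tables[[nm]], row.names = FALSE)
  }
  if (length(x$missing))
    cat("absent stages:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' One CSV per populated table plus a plain-text run log.
#'
#' @param report an `"analysis_report"` from [run_analysis()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$tables))
    utils::write.csv(report$tables[[nm]],
                     file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  writeLines(c(sprintf("system: %s", report$label),
               sprintf("absent stages: %s",
                       paste(report$missing, collapse = ", ")),
               report$log),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Compare analysis reports across systems
#'
#' Lines up the headline parameters of two or more systems (for
#' example the binary drug-protein system against the ternary systems
#' with different cyclodextrins): Stern-Volmer constants, regime
#' counts, binding-site exponents, accessible fractions and the RLS
#' aggregation onsets, with the C_CIAC ordering made explicit.
#'
#' @param reports list of `"analysis_report"`s (at least 2).
#' @return An object of class `"system_comparison"`: a list with a
#'   `table` data.frame (one row per system) and `cciac_order` (system
#'   labels sorted by ascending onset).
#' @export
compare_systems <- function(reports) {
  if (length(reports) < 2L)
    stop("need at least 2 reports to compare")
  stopifnot(all(vapply(reports, inherits, logical(1), "analysis_report")))
  units <- unlist(lapply(reports, function(r)
    if (!is.null(r$tables$quenching)) r$tables$quenching$unit else NULL))
  if (length(unique(units)) > 1L)
    stop("reports use incompatible concentration units: ",
         paste(unique(units), collapse = ", "))
  rows <- lapply(reports, function(r) {
    q <- r$tables$quenching
    q1 <- if (!is.null(q)) q[1L, ] else NULL
    data.frame(
      system = r$label,
      ksv1 = if (is.null(q1)) NA_real_ else q1$ksv1,
      ksv2 = if (is.null(q1)) NA_real_ else q1$ksv2,
      regimes = if (is.null(q1)) NA_integer_
                else if (is.na(q1$ksv2)) 1L else 2L,
      n1 = if (is.null(q1)) NA_real_ else q1$n1,
      f1 = if (is.null(q1)) NA_real_ else q1$f1,
      rees_nm = if (is.null(r$rees)) NA_real_ else r$rees$rees,
      cciac = if (is.null(r$rls)) NA_real_ else r$rls$cciac)
  })
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  ord <- order(tab$cciac)
  cciac_order <- tab$system[ord][!is.na(tab$cciac[ord])]
  structure(list(table = tab, cciac_order = cciac_order),
            class = "system_comparison")
}

#' @export
print.system_comparison <- function(x, ...) {
  cat("System comparison\n")
  print(x$table, row.names = FALSE)
  if (length(x$cciac_order))
    cat("C_CIAC ordering (ascending):",
        paste(x$cciac_order, collapse = " < "), "\n")
  invisible(x)
}
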