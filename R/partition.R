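# Analytes and partitioned samples ---------------------------------------

#' Analyte description for simulation
#'
#' Per-phase NMR properties of a fluorinated solute. Chemical shifts,
#' linewidths and relaxation times are *synthetic placeholders* chosen to
#' be physically plausible for small fluorinated molecules observed
#' without lock; they are inputs to the generator, not measured values.
#'
#' @param name text label.
#' @param n_fluorine equivalent 19F count per molecule contributing to the
#'   monitored signal (>= 1).
#' @param shift_oct,shift_aq chemical shift in the n-octanol / aqueous
#'   phase, ppm. A per-phase shift difference is what makes summed-mode
#'   quantification possible.
#' @param linewidth_oct,linewidth_aq Lorentzian FWHM per phase, Hz.
#' @param t1_oct,t1_aq longitudinal relaxation times, s.
#' @param t2_oct,t2_aq transverse relaxation times, s (T2 <= T1 per phase).
#' @param couplings optional list of `c(J_hz, multiplicity)` pairs applied
#'   to both phases (non-decoupled acquisition).
#' @param logp_lit literature log P associated with the analyte (NA if
#'   unknown); used only to label reports and to default simulations.
#' @return object of class `analyte`.
#' @export
analyte <- function(name, n_fluorine, shift_oct, shift_aq,
                    linewidth_oct, linewidth_aq,
                    t1_oct, t1_aq, t2_oct, t2_aq,
                    couplings = NULL, logp_lit = NA_real_) {
  if (n_fluorine < 1) slogp_stop("n_fluorine must be >= 1")
  if (linewidth_oct <= 0 || linewidth_aq <= 0) slogp_stop("linewidths must be positive")
  if (t2_oct > t1_oct || t2_aq > t1_aq)
    slogp_stop("T2 must not exceed T1 in either phase")
  if (any(c(t1_oct, t1_aq, t2_oct, t2_aq) <= 0))
    slogp_stop("relaxation times must be positive")
  if (!is.null(couplings)) {
    ok <- is.list(couplings) && all(vapply(couplings, function(cp)
      is.numeric(cp) && length(cp) == 2L && cp[2] >= 2, logical(1)))
    if (!ok) slogp_stop("couplings must be a list of c(J_hz, multiplicity) pairs")
  }
  structure(list(name = name, n_fluorine = n_fluorine,
                 shift_oct = shift_oct, shift_aq = shift_aq,
                 linewidth_oct = linewidth_oct, linewidth_aq = linewidth_aq,
                 t1_oct = t1_oct, t1_aq = t1_aq, t2_oct = t2_oct, t2_aq = t2_aq,
                 couplings = couplings, logp_lit = logp_lit),
            class = "analyte")
}

#' Built-in synthetic analyte fixtures
#'
#' Five fluorinated small molecules spanning the log P range the method
#' addresses. Shifts, linewidths and relaxation times are synthetic but
#' plausible; `logp_lit` carries the literature partition coefficient used
#' to default simulations (trifluorotoluene 3.01, 4-fluorophenol 1.77,
#' 1-fluoroethanol -0.68; the trifluoroethanol and hexafluoroisopropanol
#' values are placeholders of the same character).
#'
#' @param name optional single analyte to return; with no argument the
#'   full named list is returned.
#' @return an `analyte` or named list of them.
#' @export
#' @examples
#' builtin_analytes("trifluorotoluene")
builtin_analytes <- function(name = NULL) {
  lst <- list(
    trifluoroethanol = analyte("trifluoroethanol", 3, -76.8, -74.0, 6, 5,
                               2.5, 3.5, 0.6, 1.0, logp_lit = 0.41),
    hexafluoroisopropanol = analyte("hexafluoroisopropanol", 6, -76.2, -73.2, 6, 5,
                                    2.0, 3.0, 0.5, 0.9, logp_lit = 1.66),
    trifluorotoluene = analyte("trifluorotoluene", 3, -63.4, -60.4, 6, 5,
                               2.8, 3.8, 0.7, 1.1, logp_lit = 3.01),
    `4-fluorophenol` = analyte("4-fluorophenol", 1, -125.0, -122.0, 7, 5,
                               2.2, 3.2, 0.5, 0.9, logp_lit = 1.77),
    `1-fluoroethanol` = analyte("1-fluoroethanol", 1, -226.0, -223.0, 6, 5,
                                2.5, 3.5, 0.6, 1.0, logp_lit = -0.68)
  )
  if (is.null(name)) return(lst)
  a <- lst[[name]]
  if (is.null(a)) slogp_stop(sprintf("unknown built-in analyte '%s'", name))
  a
}

#' Equilibrium per-phase concentrations of a partitioned solute
#'
#' Solves the mass balance `c_oct*v_oct + c_aq*v_aq = n_total` (with the
#' three quantities in consistent units) together with the partition
#' equilibrium `c_oct = P * c_aq`, `P = 10^logp`. Amounts are taken in
#' mmol and volumes in uL; concentrations are reported in mol/L, so the
#' balance reads `(c_oct*v_oct + c_aq*v_aq) / 1000 = n_total`.
#'
#' @param logp true base-10 partition coefficient.
#' @param n_total total amount of solute, mmol.
#' @param v_oct,v_aq phase volumes, uL.
#' @return list with `c_oct` and `c_aq` in mol/L.
#' @export
#' @examples
#' partition_concentrations(0, 0.1, 270, 270)  # even split
partition_concentrations <- function(logp, n_total, v_oct, v_aq) {
  if (v_oct <= 0 || v_aq <= 0) slogp_stop("phase volumes must be positive")
  if (n_total < 0) slogp_stop("n_total must be non-negative")
  p <- 10^logp
  c_aq <- 1000 * n_total / (v_aq + p * v_oct)   # mmol/uL -> mol/L
  list(c_oct = p * c_aq, c_aq = c_aq)
}

#' Partitioned NMR sample
#'
#' An analyte equilibrated between n-octanol and water in a single NMR
#' tube. Default volumes follow the short-acquisition preparation
#' (270 uL of each solvent, no lock capillary).
#'
#' @param analyte an [analyte()].
#' @param logp_true ground-truth log P driving the per-phase
#'   concentrations; defaults to the analyte's `logp_lit`.
#' @param n_total total amount of solute, mmol (default 0.05).
#' @param v_oct,v_aq phase volumes, uL (default 270 each).
#' @return object of class `partition_sample` with resolved `c_oct`,
#'   `c_aq` (mol/L).
#' @export
partition_sample <- function(analyte, logp_true = analyte$logp_lit,
                             n_total = 0.05, v_oct = 270, v_aq = 270) {
  if (!inherits(analyte, "analyte")) slogp_stop("analyte must be an analyte object")
  if (is.na(logp_true)) slogp_stop("logp_true is NA and the analyte has no logp_lit")
  conc <- partition_concentrations(logp_true, n_total, v_oct, v_aq)
  structure(list(analyte = analyte, logp_true = logp_true, n_total = n_total,
                 v_oct = v_oct, v_aq = v_aq,
                 c_oct = conc$c_oct, c_aq = conc$c_aq),
            class = "partition_sample")
}

#' @export
print.partition_sample <- function(x, ...) {
  cat(sprintf("<partition sample: %s>\n", x$analyte$name))
  cat(sprintf("  true log P : %.3f\n", x$logp_true))
  cat(sprintf("  amount     : %.4f mmol in %g + %g uL\n", x$n_total, x$v_oct, x$v_aq))
  cat(sprintf("  c_oct      : %.4g M\n  c_aq       : %.4g M\n", x$c_oct, x$c_aq))
  invisible(x)
}
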