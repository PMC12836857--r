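# Nuclei and gradients ---------------------------------------------------

# gamma/2pi for 1H in MHz per tesla.
.gamma_bar_1h <- 42.577

# Frequency ratios (nucleus frequency / 1H frequency at the same field).
.builtin_nuclei <- list(
  "1H"  = 1.0,
  "19F" = 0.94094
)

#' Nucleus specification
#'
#' Bundles the gyromagnetic constant and frequency scaling of an NMR-active
#' nucleus. `gamma_bar` is the gyromagnetic ratio over 2*pi in MHz/T;
#' `xi_ratio` is the resonance frequency expressed as a fraction of the 1H
#' frequency at the same field. The two must be mutually consistent (the
#' basic frequency `xi_ratio * proton_freq` has to agree with
#' `gamma_bar * field` to within 0.2%), which holds by construction when
#' `gamma_bar` is derived from `xi_ratio`.
#'
#' @param name nucleus label, e.g. `"19F"`.
#' @param xi_ratio frequency ratio relative to 1H (dimensionless).
#' @param gamma_bar gyromagnetic ratio over 2*pi, MHz/T. Defaults to
#'   `xi_ratio * 42.577` (the 1H value), which reproduces all geometry
#'   numbers; override to use a different constant.
#' @return an object of class `nucleus_spec`.
#' @export
#' @examples
#' nucleus_spec("19F", 0.94094)
nucleus_spec <- function(name, xi_ratio, gamma_bar = .gamma_bar_1h * xi_ratio) {
  if (!is.character(name) || length(name) != 1L)
    slogp_stop("nucleus name must be a single string")
  if (!is.numeric(xi_ratio) || xi_ratio <= 0 || xi_ratio > 1.1)
    slogp_stop("xi_ratio must lie in (0, 1.1]")
  if (!is.numeric(gamma_bar) || gamma_bar <= 0)
    slogp_stop("gamma_bar must be positive")
  if (abs(gamma_bar - .gamma_bar_1h * xi_ratio) / (.gamma_bar_1h * xi_ratio) > 0.002)
    slogp_stop("gamma_bar and xi_ratio are inconsistent (> 0.2% apart)")
  structure(list(name = name, gamma_bar = gamma_bar, xi_ratio = xi_ratio),
            class = "nucleus_spec")
}

#' Look up a built-in nucleus
#'
#' @param name `"19F"` (default) or `"1H"`.
#' @param gamma_bar optional override of the gyromagnetic constant (MHz/T).
#' @return a [nucleus_spec()].
#' @export
nucleus <- function(name = "19F", gamma_bar = NULL) {
  xi <- .builtin_nuclei[[name]]
  if (is.null(xi))
    slogp_stop(sprintf("unknown nucleus '%s'; use nucleus_spec() for others", name))
  if (is.null(gamma_bar)) nucleus_spec(name, xi) else nucleus_spec(name, xi, gamma_bar)
}

#' @export
print.nucleus_spec <- function(x, ...) {
  cat(sprintf("<nucleus %s>  gamma_bar = %.4f MHz/T, xi = %.5f\n",
              x$name, x$gamma_bar, x$xi_ratio))
  invisible(x)
}

#' Basic (observe) frequency of a nucleus at a given 1H frequency
#'
#' @param nuc a [nucleus_spec()].
#' @param proton_freq 1H frequency of the magnet, MHz.
#' @return observe frequency in MHz.
#' @export
basic_frequency <- function(nuc, proton_freq) {
  if (proton_freq <= 0) slogp_stop("proton_freq must be positive")
  nuc$xi_ratio * proton_freq
}

#' Absolute gradient amplitude from a percent setting
#'
#' Spectrometers express z-gradient strength as a percentage of the
#' amplifier maximum; the geometry formulas need the absolute amplitude.
#'
#' @param percent gradient setting, percent of maximum (0 < percent <= 100).
#' @param g_max maximum z-gradient amplitude, G/cm.
#' @return absolute gradient, G/cm.
#' @export
#' @examples
#' gradient_abs(16, 55)  # 8.8 G/cm
gradient_abs <- function(percent, g_max) {
  if (!is.numeric(percent) || percent <= 0 || percent > 100)
    slogp_stop("gradient percent must lie in (0, 100]")
  if (!is.numeric(g_max) || g_max <= 0)
    slogp_stop("g_max must be positive")
  percent / 100 * g_max
}

#' Gradient specification
#'
#' @param percent percent of maximum gradient.
#' @param g_max maximum gradient amplitude, G/cm (default 55, sized so that
#'   a 16% setting corresponds to 8.8 G/cm).
#' @return object of class `gradient_spec` with the resolved absolute
#'   amplitude in `g_abs`.
#' @export
gradient_spec <- function(percent, g_max = 55) {
  structure(list(percent = percent, g_max = g_max,
                 g_abs = gradient_abs(percent, g_max)),
            class = "gradient_spec")
}

#' @export
print.gradient_spec <- function(x, ...) {
  cat(sprintf("<gradient %g%% of %g G/cm = %g G/cm>\n", x$percent, x$g_max, x$g_abs))
  invisible(x)
}

# Coerce numeric G/cm or gradient_spec to absolute G/cm.
as_gradient_abs <- function(gradient) {
  if (inherits(gradient, "gradient_spec")) return(gradient$g_abs)
  if (is.numeric(gradient) && length(gradient) == 1L) {
    if (gradient <= 0) slogp_stop("gradient must be positive")
    return(gradient)
  }
  slogp_stop("gradient must be a gradient_spec or a positive scalar (G/cm)")
}
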