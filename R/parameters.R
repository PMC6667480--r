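#' Pacemaker model parameters
#'
#' Assembles and validates the full parameter set of the limit-cycle
#' pacemaker: the oscillator constants, the dynamic light-processor (Process
#' L) constants, and the non-photic drive magnitude.  Defaults are the
#' standard published values for this model family.
#'
#' @param mu Stiffness of the Van der Pol nonlinearity (dimensionless).
#' @param tau_c Intrinsic circadian period in hours.
#' @param Lq,Lk Light-coupling constants of the complementary equation
#'   (dimensionless).
#' @param ls Light-sensitivity modulator constant (dimensionless, in (0,1)).
#' @param as_ Activity-sensitivity constant of the non-photic modulator
#'   (dimensionless).
#' @param alpha0 Photoreceptor activation rate at the reference illuminance,
#'   per minute.
#' @param beta Photoreceptor recovery rate, per minute.
#' @param G Photic drive gain (dimensionless).
#' @param p Lux-compression exponent (dimensionless, in (0,1]).
#' @param I0 Reference illuminance in photopic lux.
#' @param rho Non-photic drive magnitude (dimensionless); 0 disables the
#'   non-photic pathway entirely.
#'
#' @details The oscillator equations also involve two fixed constants that
#' are not free parameters: the angular scale pi/12 per hour and the period
#' correction 0.99729, which compensates the period lengthening caused by
#' the stiffness nonlinearity so that the simulated free-running period
#' equals `tau_c`.  Both are stored on the object for transparency but are
#' not meant to be changed.
#'
#' @return A list of class `circ_params`.
#' @examples
#' p <- circ_params()
#' p$tau_c
#' circ_params(tau_c = 24.6, rho = 0)
#' @export
circ_params <- function(mu = 0.13, tau_c = 24.2, Lq = 1 / 3, Lk = 0.55,
                        ls = 0.4, as_ = 10.0,
                        alpha0 = 0.05, beta = 0.0075, G = 33.75,
                        p = 0.5, I0 = 9500, rho = 0.032) {
  pars <- list(mu = mu, tau_c = tau_c, Lq = Lq, Lk = Lk, ls = ls, as_ = as_,
               alpha0 = alpha0, beta = beta, G = G, p = p, I0 = I0, rho = rho,
               period_correction = 0.99729, omega_scale = pi / 12)
  stopifnot(
    "tau_c must be positive" = tau_c > 0,
    "mu must be positive" = mu > 0,
    "ls must lie in (0, 1)" = ls > 0 && ls < 1,
    "as_ must be positive" = as_ > 0,
    "alpha0, beta, G, I0 must be positive" =
      alpha0 > 0 && beta > 0 && G > 0 && I0 > 0,
    "p must lie in (0, 1]" = p > 0 && p <= 1,
    "rho must be non-negative" = rho >= 0
  )
  class(pars) <- "circ_params"
  pars
}

#' @export
print.circ_params <- function(x, ...) {
  cat("Circadian pacemaker parameters\n")
  cat(sprintf("  oscillator: mu=%g  tau_c=%g h  Lq=%g  Lk=%g  ls=%g  as=%g\n",
              x$mu, x$tau_c, x$Lq, x$Lk, x$ls, x$as_))
  cat(sprintf("  light processor: alpha0=%g/min  beta=%g/min  G=%g  p=%g  I0=%g lux\n",
              x$alpha0, x$beta, x$G, x$p, x$I0))
  cat(sprintf("  non-photic: rho=%g\n", x$rho))
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' The configuration file holds flat `key: value` pairs.  Any key matching a
#' [circ_params()] argument overrides that parameter; the remaining
#' recognized keys are `mode` ("photic" or "pnp"), `init` ("midsleep" or
#' "oracle"), `substeps` (integration substeps per one-minute epoch) and
#' `cbtmin_offset_h` (fixed offset added when mapping CBTmin to a predicted
#' acrophase, hours).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `params` (a `circ_params`), `mode`, `init`,
#'   `substeps`, `cbtmin_offset_h`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must contain key: value pairs")
  par_names <- names(formals(circ_params))
  overrides <- raw[names(raw) %in% par_names]
  cfg <- list(
    params = do.call(circ_params, overrides),
    mode = if (!is.null(raw$mode)) match.arg(raw$mode, c("photic", "pnp")) else "pnp",
    init = if (!is.null(raw$init)) match.arg(raw$init, c("midsleep", "oracle")) else "midsleep",
    substeps = if (!is.null(raw$substeps)) as.integer(raw$substeps) else 1L,
    cbtmin_offset_h = if (!is.null(raw$cbtmin_offset_h)) as.numeric(raw$cbtmin_offset_h) else 0
  )
  cfg
}
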