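#' Parameters of the synthesis-diffusion-depletion (SDD) model
#'
#' Bundles the physical parameters of the one-dimensional SDD model in which
#' morphogen is injected at the left boundary with flux \code{jin}, diffuses
#' with diffusivity \code{D}, and is depleted everywhere at rate \code{kd}.
#' Two derived quantities are attached: the characteristic decay length
#' \code{lambda = sqrt(D/kd)} and the production scale
#' \code{nm = vcell*jin/(lcell*kd)}, the number of molecules produced per
#' depletion time, which sets the amplitude of the steady-state profile.
#'
#' Positions are continuous coordinates; cell discreteness enters only through
#' the cell length \code{lcell} (the spatial grid on which positional error is
#' defined) and the cell volume \code{vcell} (which converts concentration
#' fluctuations to molecule-count fluctuations).
#'
#' @param L system length.
#' @param lcell cell length (same length unit as \code{L}).
#' @param vcell cell volume.
#' @param D diffusivity (length^2/time).
#' @param kd depletion rate (1/time).
#' @param jin influx at the source boundary (concentration x length / time).
#' @return An object of class \code{"sdd_params"}: a list with the supplied
#'   fields plus derived \code{lambda} and \code{nm}.
#' @examples
#' p <- sdd_params(L = 50, lcell = 1, vcell = 1, D = 25, kd = 1, jin = 200)
#' p$lambda  # 5
#' p$nm      # 200
#' @export
sdd_params <- function(L, lcell = 1, vcell = 1, D, kd, jin) {
  vals <- c(L = L, lcell = lcell, vcell = vcell, D = D, kd = kd, jin = jin)
  if (!all(is.finite(vals))) {
    stop("invalid parameter: all SDD parameters must be finite, got ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (any(vals <= 0)) {
    stop("invalid parameter: all SDD parameters must be positive, got ",
         paste(names(vals)[vals <= 0], collapse = ", "))
  }
  lambda <- sqrt(D / kd)
  stopifnot(abs(lambda^2 * kd - D) <= 1e-12 * D)
  structure(
    list(L = L, lcell = lcell, vcell = vcell, D = D, kd = kd, jin = jin,
         lambda = lambda, nm = vcell * jin / (lcell * kd)),
    class = "sdd_params"
  )
}

#' @export
print.sdd_params <- function(x, ...) {
  cat("SDD model parameters\n")
  cat(sprintf("  L = %g, lcell = %g, vcell = %g\n", x$L, x$lcell, x$vcell))
  cat(sprintf("  D = %g, kd = %g, jin = %g\n", x$D, x$kd, x$jin))
  cat(sprintf("  derived: lambda = %g (L/lambda = %g), nm = %g\n",
              x$lambda, x$L / x$lambda, x$nm))
  invisible(x)
}

#' Per-molecule thermodynamic cost
#'
#' The proportionality constant \code{alpha_o} converts molecule counts into
#' thermodynamic cost: the ATP-equivalent cost of synthesizing and degrading
#' one morphogen molecule. For Bicoid (494 amino acids at ~4 ATP per peptide
#' bond) this is approximately 2e3 ATP.
#'
#' @param alpha_o per-molecule synthesis+degradation cost (ATP equivalents).
#' @return An object of class \code{"cost_params"}.
#' @export
cost_params <- function(alpha_o = 1) {
  if (!is.finite(alpha_o) || alpha_o <= 0) {
    stop("invalid parameter: alpha_o must be positive and finite")
  }
  structure(list(alpha_o = alpha_o), class = "cost_params")
}

#' Sensor geometry for the space-time-averaged measurement
#'
#' A cell at position x is assumed to read out the morphogen concentration
#' with a sensor covering the interval (x - a, x + a), averaging molecular
#' counts for a duration T.
#'
#' @param a sensor half-width (length).
#' @param T_avg averaging duration (time).
#' @return An object of class \code{"sensor_spec"}.
#' @export
sensor_spec <- function(a, T_avg) {
  if (!is.finite(a) || a <= 0) stop("invalid parameter: a must be positive")
  if (!is.finite(T_avg) || T_avg <= 0) stop("invalid parameter: T_avg must be positive")
  structure(list(a = a, T_avg = T_avg), class = "sensor_spec")
}

#' Parameters for the space-time-averaged measurement model
#'
#' In the space-time-averaged model the system is taken semi-infinite and the
#' influx \code{jin} is expressed in molecules/time (not concentration flux),
#' so that \code{jin * T} is the total number of molecules produced during a
#' measurement of duration T.
#'
#' @param jin influx (molecules/time).
#' @param kd depletion rate (1/time).
#' @param lam decay length (length).
#' @return An object of class \code{"spacetime_params"}.
#' @export
spacetime_params <- function(jin, kd, lam) {
  vals <- c(jin = jin, kd = kd, lam = lam)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("invalid parameter: jin, kd, lam must be positive and finite")
  }
  structure(list(jin = jin, kd = kd, lam = lam), class = "spacetime_params")
}

#' Read model parameters from a YAML configuration file
#'
#' Reads a YAML file whose top-level keys mirror the constructor arguments of
#' the parameter objects: a block \code{sdd} (fields of [sdd_params()]), an
#' optional block \code{cost} (\code{alpha_o}), optional blocks \code{sensor}
#' (\code{a}, \code{T_avg}) and \code{spacetime} (\code{jin}, \code{kd},
#' \code{lam}).
#'
#' @param path path to a YAML file.
#' @return A named list with any of \code{sdd}, \code{cost}, \code{sensor},
#'   \code{spacetime} that were present, as validated parameter objects, plus
#'   the raw parsed list under \code{raw}.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("malformed config '", path, "': ", conditionMessage(e))
  )
  out <- list(raw = raw)
  if (!is.null(raw$sdd)) out$sdd <- do.call(sdd_params, raw$sdd)
  if (!is.null(raw$cost)) out$cost <- do.call(cost_params, raw$cost)
  if (!is.null(raw$sensor)) out$sensor <- do.call(sensor_spec, raw$sensor)
  if (!is.null(raw$spacetime)) out$spacetime <- do.call(spacetime_params, raw$spacetime)
  out
}
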