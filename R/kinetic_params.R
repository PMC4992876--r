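# Kinetic parameter container and macro influx rate.

#' Two-tissue compartment model parameters
#'
#' Micro-parameters of the two-tissue compartment model together with the
#' fractional-volume weights of the weighted ROI signal:
#' \code{K1} (mL/g/min) plasma-to-tissue transport, \code{k2}, \code{k3},
#' \code{k4} (1/min) exchange and trapping rates (\code{k4 = 0} is the
#' irreversible model), \code{wp} fractional blood volume, \code{wd} and
#' \code{wa} the contributions of the diffusive and accumulative compartments
#' (weights sum to 1).
#'
#' @param K1,k2,k3,k4 Rate constants (all >= 0); units as above.
#' @param wp,wd,wa Weights in [0, 1] with \code{wp + wd + wa == 1} (within
#'   1e-9). \code{wa} defaults to \code{1 - wp - wd}.
#' @return An object of class \code{kinetic_params}.
#' @examples
#' p <- kinetic_params(K1 = 0.0255, k2 = 0.00286, k3 = 0.03314,
#'                     wp = 0.05, wd = 0.6)
#' macro_influx_rate(p)
#' @export
kinetic_params <- function(K1, k2, k3, k4 = 0, wp = 0.05, wd = 0.60,
                           wa = 1 - wp - wd) {
  for (nm in c("K1", "k2", "k3", "k4", "wp", "wd", "wa")) {
    v <- get(nm)
    fp_assert(is_scalar_num(v), "invalid_params", "%s must be a finite number", nm)
    fp_assert(v >= -1e-12, "invalid_params", "%s must be >= 0 (got %g)", nm, v)
  }
  fp_assert(wp <= 1 + 1e-9 && wd <= 1 + 1e-9 && wa <= 1 + 1e-9,
            "invalid_params", "weights must lie in [0, 1]")
  fp_assert(abs(wp + wd + wa - 1) <= 1e-9, "invalid_params",
            "weights must sum to 1 (got %g)", wp + wd + wa)
  structure(list(K1 = max(K1, 0), k2 = max(k2, 0), k3 = max(k3, 0),
                 k4 = max(k4, 0), wp = min(max(wp, 0), 1),
                 wd = min(max(wd, 0), 1), wa = min(max(wa, 0), 1)),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params> K1=%.4g mL/g/min, k2=%.4g, k3=%.4g, k4=%.4g 1/min; wp=%.3g wd=%.3g wa=%.3g\n",
    x$K1, x$k2, x$k3, x$k4, x$wp, x$wd, x$wa))
  invisible(x)
}

#' Macro (net) influx rate Ki
#'
#' For the irreversible model the net influx rate of trapped tracer is
#' \code{Ki = K1 * k3 / (k2 + k3)} (mL/g/min); it equals the asymptotic Patlak
#' slope of the total tissue concentration.
#'
#' @param params A \code{kinetic_params}.
#' @return Ki in mL/g/min.
#' @export
macro_influx_rate <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  fp_assert(params$k2 + params$k3 > 0, "undefined_macro",
            "Ki is undefined when k2 + k3 == 0")
  params$K1 * params$k3 / (params$k2 + params$k3)
}

#' Read / write kinetic parameters as JSON
#'
#' Fields \code{K1, k2, k3, k4, wp, wd, wa} in Table-style units
#' (mL/g/min and 1/min).
#'
#' @param path File path.
#' @export
read_kinetic_params <- function(path) {
  p <- jsonlite::fromJSON(path)
  need <- c("K1", "k2", "k3")
  fp_assert(all(need %in% names(p)), "format",
            "kinetic parameter JSON needs at least K1, k2, k3")
  kinetic_params(K1 = p$K1, k2 = p$k2, k3 = p$k3,
                 k4 = if (is.null(p$k4)) 0 else p$k4,
                 wp = if (is.null(p$wp)) 0.05 else p$wp,
                 wd = if (is.null(p$wd)) 0.60 else p$wd)
}

#' @rdname read_kinetic_params
#' @param params A \code{kinetic_params} to write.
#' @export
write_kinetic_params <- function(params, path) {
  stopifnot(inherits(params, "kinetic_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
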