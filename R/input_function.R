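# Plasma input function: sampled C_p(t) with piecewise-linear interpolation.
#
# The tracer is injected at acquisition start, so C_p is linearly ramped from
# (0, 0) when the first sample is later than t = 0. Evaluation beyond the last
# sample is an error (no extrapolation), because every downstream quantity is
# an integral over acquired frames.

#' Plasma input function
#'
#' @param times Sample times in seconds, strictly increasing, >= 0.
#' @param values Plasma activity concentration C_p(t) in Bq/mL, finite and
#'   >= 0.
#' @param unit Unit tag.
#' @return An object of class \code{input_function}.
#' @export
input_function <- function(times, values, unit = "Bq/mL") {
  fp_assert(is.numeric(times) && is.numeric(values) &&
              length(times) == length(values) && length(times) >= 2L,
            "invalid_spec", "input function needs >= 2 (time, value) samples")
  fp_assert(all(is.finite(times)) && all(is.finite(values)),
            "invalid_spec", "input function samples must be finite")
  fp_assert(all(diff(times) > 0), "invalid_spec",
            "input function times must be strictly increasing")
  fp_assert(times[1] >= 0, "invalid_spec", "input function starts at t >= 0")
  fp_assert(all(values >= 0), "invalid_spec", "C_p must be >= 0")
  if (times[1] > 0) {            # ramp from injection at (0, 0)
    times <- c(0, times)
    values <- c(0, values)
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 unit = unit, interpolation = "piecewise-linear"),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("<input_function> %d samples over [0, %g] s, peak %.4g %s\n",
              length(x$times), max(x$times), max(x$values), x$unit))
  invisible(x)
}

input_support_end <- function(cp) cp$times[length(cp$times)]

#' Evaluate the input function
#'
#' Piecewise-linear interpolation at arbitrary times within the sampled
#' support.
#'
#' @param cp An \code{input_function}.
#' @param t Times in seconds.
#' @return C_p(t).
#' @export
eval_input <- function(cp, t) {
  stopifnot(inherits(cp, "input_function"))
  fp_assert(all(t >= 0 - 1e-9) && all(t <= input_support_end(cp) + 1e-9),
            "extrapolation", "time outside input-function support [0, %g] s",
            input_support_end(cp))
  stats::approx(cp$times, cp$values, xout = pmin(pmax(t, 0), input_support_end(cp)),
                method = "linear", rule = 1)$y
}

#' Running integral of the input function
#'
#' Exact integral of the piecewise-linear C_p from 0 to each requested time
#' (trapezoid on the sample grid plus the exact partial segment).
#'
#' @param cp An \code{input_function}.
#' @param t Times in seconds within support.
#' @return Integral values in Bq/mL * s.
#' @export
input_cumint <- function(cp, t) {
  stopifnot(inherits(cp, "input_function"))
  fp_assert(all(t >= -1e-9) && all(t <= input_support_end(cp) + 1e-9),
            "extrapolation", "time outside input-function support")
  tt <- cp$times; vv <- cp$values
  cum <- c(0, cumsum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2))
  idx <- findInterval(t, tt, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(tt) - 1L)
  dt <- pmax(t - tt[idx], 0)
  v0 <- vv[idx]
  slope <- (vv[idx + 1L] - vv[idx]) / (tt[idx + 1L] - tt[idx])
  cum[idx] + v0 * dt + slope * dt^2 / 2
}
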