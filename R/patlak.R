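# Gjedde-Patlak graphical analysis of the influx constant Ki.
#
# For an irreversibly trapping tracer the transformed points
#   x(t) = int_0^t C_p ds / C_p(t)   (normalised time, minutes)
#   y(t) = C_t(t) / C_p(t)
# become linear once the reversible compartments equilibrate; the late-time
# slope is the net influx constant Ki.

#' Patlak transform of a tissue TAC
#'
#' Computes the normalised-time / tissue-ratio points at the frame midpoints.
#' The plasma integral is the exact integral of the piecewise-linear input.
#' Frames where C_p is below 1\% of its peak are flagged invalid (division
#' stability).
#'
#' @param tissue A \code{\link{tac}} (tissue concentration).
#' @param cp The plasma \code{\link{input_function}} (or the reference-tissue
#'   curve promoted to one).
#' @return An object of class \code{patlak_points}: data.frame with columns
#'   \code{frame}, \code{t_mid} (s), \code{x} (min), \code{y} (unitless),
#'   \code{valid}.
#' @export
patlak_transform <- function(tissue, cp) {
  stopifnot(inherits(tissue, "tac"), inherits(cp, "input_function"))
  mids <- frame_midpoints(tissue$schedule)
  fp_assert(max(mids) <= input_support_end(cp) + 1e-9, "extrapolation",
            "schedule midpoints extend beyond the input-function support")
  cpt <- eval_input(cp, mids)
  cum <- input_cumint(cp, mids)
  valid <- is.finite(cpt) & cpt > 0.01 * max(cp$values)
  x <- ifelse(valid, cum / cpt / 60, NA_real_)   # minutes
  y <- ifelse(valid, tissue$values / cpt, NA_real_)
  fp_assert(any(valid), "empty_transform", "no valid Patlak points")
  structure(data.frame(frame = seq_along(mids), t_mid = mids,
                       x = x, y = y, valid = valid),
            class = c("patlak_points", "data.frame"))
}

#' Fit the Patlak line
#'
#' Ordinary least-squares line through the valid transformed points with
#' midpoint time >= \code{t_star}. The slope estimates the net influx
#' constant Ki (mL/g/min for a plasma-driven transform), the intercept the
#' initial distribution volume V0.
#'
#' @param points A \code{\link{patlak_transform}} result.
#' @param t_star Linearity onset in minutes post injection (default 30,
#'   standard for FMISO and safely past the fast kinetics of this tracer).
#' @return List with \code{Ki}, \code{V0}, \code{r_squared}, \code{n_points},
#'   \code{t_star}.
#' @export
patlak_fit <- function(points, t_star = 30) {
  stopifnot(inherits(points, "patlak_points"))
  fp_assert(is_scalar_num(t_star) && t_star >= 0, "invalid_spec",
            "t_star must be a non-negative number of minutes")
  sel <- points$valid & points$t_mid >= t_star * 60
  fp_assert(sum(sel) >= 3, "insufficient_points",
            "need >= 3 valid points at t >= %g min (got %d)", t_star, sum(sel))
  fit <- stats::lm(y ~ x, data = points[sel, ])
  cf <- stats::coef(fit)
  # direct R^2 (summary.lm warns on the exact fits used in validation)
  yy <- points$y[sel]
  sst <- sum((yy - mean(yy))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  list(Ki = unname(cf[2]), V0 = unname(cf[1]), r_squared = r2,
       n_points = sum(sel), t_star = t_star)
}

#' Reference-tissue Patlak slope
#'
#' Same transform with a reference-tissue TAC (typically muscle) replacing
#' the plasma input; used for whole-body Ki-like mapping when a plasma curve
#' is unreliable. The reference curve is promoted to an input function by
#' piecewise-linear interpolation through its frame midpoints (ramped from 0
#' at injection).
#'
#' @param tissue Target-tissue \code{\link{tac}}.
#' @param reference Reference-tissue \code{\link{tac}} (strictly positive at
#'   late frames).
#' @param t_star Linearity onset in minutes (default 30).
#' @return As \code{\link{patlak_fit}}; the slope is in 1/min (per unit of
#'   reference exposure).
#' @export
reference_patlak <- function(tissue, reference, t_star = 30) {
  stopifnot(inherits(tissue, "tac"), inherits(reference, "tac"))
  ref_cp <- as_input_function(reference)
  patlak_fit(patlak_transform(tissue, ref_cp), t_star = t_star)
}

#' Promote a TAC to an input function
#'
#' Interprets the frame values as samples at the frame midpoints and builds a
#' piecewise-linear \code{\link{input_function}} (ramped from 0 at
#' injection). Negative noisy frames are clipped at 0. The support is
#' extended flat to the last frame end so that frame-spanning evaluations
#' remain inside it.
#'
#' @param x A \code{\link{tac}}.
#' @return An \code{\link{input_function}}.
#' @export
as_input_function <- function(x) {
  stopifnot(inherits(x, "tac"))
  mids <- frame_midpoints(x$schedule)
  ends <- x$schedule$frame_end
  v <- pmax(x$values, 0)
  input_function(c(mids, ends[length(ends)]), c(v, v[length(v)]),
                 unit = x$unit)
}

#' Export Patlak points as CSV
#'
#' @param points A \code{patlak_points} object.
#' @param path Output path.
#' @export
write_patlak_csv <- function(points, path) {
  stopifnot(inherits(points, "patlak_points"))
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}
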