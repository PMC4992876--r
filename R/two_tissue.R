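# Forward evaluation of the two-tissue compartment model.
#
# The system (rates converted from 1/min to 1/s internally) is
#   dC_d/dt = K1*C_p(t) - (k2 + k3)*C_d + k4*C_a
#   dC_a/dt = k3*C_d - k4*C_a
# with C_p piecewise linear between samples. The solution is computed exactly
# per input segment by convolution with the matrix-exponential kernel of the
# 2x2 system, expressed through its two eigen-rates alpha1 <= alpha2:
#   C_d = K1 [ (k4 - a1) y_{a1} + (a2 - k4) y_{a2} ] / (a2 - a1)
#   C_a = K1 k3 [ y_{a1} - y_{a2} ] / (a2 - a1)
# where y_a(t) = integral_0^t exp(-a (t - s)) C_p(s) ds is accumulated
# segment-by-segment in closed form. Results are therefore grid-independent:
# no ODE step-size is involved.

tt_eigen <- function(params) {
  k2s <- params$k2 / 60; k3s <- params$k3 / 60; b4 <- params$k4 / 60
  a <- k2s + k3s
  s <- a + b4
  disc <- (a - b4)^2 + 4 * k3s * b4      # == s^2 - 4*k2s*b4, cancellation-free
  sq <- sqrt(max(disc, 0))
  alpha2 <- (s + sq) / 2
  alpha1 <- if (alpha2 > 0) (k2s * b4) / alpha2 else 0  # product relation, stable
  if (params$k4 == 0) alpha1 <- 0
  if (alpha2 - alpha1 < 1e-14) alpha2 <- alpha1 + 1e-14  # confluent guard
  list(alpha1 = alpha1, alpha2 = alpha2, b4 = b4,
       K1s = params$K1 / 60, k3s = params$k3 / 60)
}

# y_i = d_i y_{i-1} + g_i with d_i = exp(x_i), x_i <= 0, via blocked rescaled
# cumulative sums (numerically safe for long decays, fully vectorised within
# blocks).
scan_decay <- function(x, g) {
  n <- length(x)
  y <- numeric(n)
  C <- cumsum(x)
  i0 <- 1L; y0 <- 0; C0 <- 0
  while (i0 <= n) {
    rel <- C[i0:n] - C0
    cross <- which(rel < -20)
    i1 <- if (length(cross)) i0 + cross[1] - 1L else n
    ii <- i0:i1
    relC <- C[ii] - C0
    z <- y0 + cumsum(g[ii] * exp(-relC))
    y[ii] <- exp(relC) * z
    y0 <- y[i1]; C0 <- C[i1]; i0 <- i1 + 1L
  }
  y
}

# Exponential-kernel convolution of a piecewise-linear curve and its running
# integral, both exact per segment. Returns y and I = integral_0^t y at the
# grid nodes.
conv_decay <- function(alpha, h, c0, c1) {
  n <- length(h)
  S <- (c0 + c1) * h / 2                      # exact segment integrals of C_p
  if (alpha <= 0) {
    y <- c(0, cumsum(S))                      # y_0(t) = running integral of C_p
    m <- (c1 - c0) / h
    segI <- utils::head(y, -1L) * h + c0 * h^2 / 2 + m * h^3 / 6
    return(list(y = y, I = c(0, cumsum(segI))))
  }
  x <- -alpha * h
  phi1 <- expm1(x) / (-alpha)                 # int_0^h exp(-alpha u) du
  small <- abs(x) < 1e-4                      # series where the closed form cancels
  phi2 <- ifelse(small,
                 h^2 / 2 * (1 + 2 * x / 3 + x^2 / 4),
                 (exp(x) * (x - 1) + 1) / alpha^2)
  m <- (c1 - c0) / h
  g <- c1 * phi1 - m * phi2
  y <- c(0, scan_decay(x, g))
  segI <- (S - diff(y)) / alpha               # from dy/dt = -alpha y + C_p
  list(y = y, I = c(0, cumsum(segI)))
}

# Evaluate compartment profiles (and running integrals) on the union of the
# input-function grid and the requested times.
tt_profiles <- function(params, cp, times_out) {
  fp_assert(all(times_out >= -1e-9), "extrapolation", "negative evaluation time")
  fp_assert(all(times_out <= input_support_end(cp) + 1e-9), "extrapolation",
            "evaluation time beyond input-function support [0, %g] s",
            input_support_end(cp))
  grid <- sort(unique(c(cp$times, pmax(times_out, 0))))
  cpv <- eval_input(cp, grid)
  h <- diff(grid)
  keep <- h > 0
  h <- h[keep]
  c0 <- cpv[-length(cpv)][keep]; c1 <- cpv[-1][keep]
  e <- tt_eigen(params)
  u1 <- conv_decay(e$alpha1, h, c0, c1)
  u2 <- conv_decay(e$alpha2, h, c0, c1)
  den <- e$alpha2 - e$alpha1
  w_d1 <- (e$b4 - e$alpha1) / den; w_d2 <- (e$alpha2 - e$b4) / den
  cd <- e$K1s * (w_d1 * u1$y + w_d2 * u2$y)
  ca <- e$K1s * e$k3s * (u1$y - u2$y) / den
  Id <- e$K1s * (w_d1 * u1$I + w_d2 * u2$I)
  Ia <- e$K1s * e$k3s * (u1$I - u2$I) / den
  Ip <- c(0, cumsum((c0 + c1) * h / 2))  # exact running integral of C_p
  idx <- match(round(pmax(times_out, 0), 9), round(grid, 9))
  fp_assert(!anyNA(idx), "grid", "internal grid lookup failed")
  list(grid = grid, idx = idx, cp = cpv, cd = cd, ca = ca,
       Ip = Ip, Id = Id, Ia = Ia)
}

#' Solve the two-tissue compartment model
#'
#' Exact solution of the compartment ODE system for a piecewise-linear plasma
#' input (see package vignette for the closed form). \code{k4 = 0} gives the
#' irreversible model, in which case the accumulative compartment C_a is
#' non-decreasing for a non-negative input.
#'
#' @param params A \code{\link{kinetic_params}}.
#' @param cp An \code{\link{input_function}} covering \code{[0,
#'   max(eval_times)]}.
#' @param eval_times Times in seconds at which to report the compartment
#'   concentrations.
#' @return An object of class \code{compartment_curves}: list with
#'   \code{times}, \code{C_d} (non-specific diffusive) and \code{C_a}
#'   (specific accumulative), in the input's concentration units.
#' @export
solve_two_tissue <- function(params, cp, eval_times) {
  stopifnot(inherits(params, "kinetic_params"), inherits(cp, "input_function"))
  fp_assert(is.numeric(eval_times) && length(eval_times) >= 1L &&
              all(is.finite(eval_times)), "invalid_spec",
            "eval_times must be finite numeric")
  pr <- tt_profiles(params, cp, eval_times)
  structure(list(times = as.numeric(eval_times),
                 C_d = pr$cd[pr$idx], C_a = pr$ca[pr$idx]),
            class = "compartment_curves")
}

#' Instantaneous weighted ROI signal
#'
#' \code{C_ROI(t) = wp*C_p(t) + wd*C_d(t) + wa*C_a(t)}: the measured PET
#' signal model with fractional blood volume \code{wp} and compartment
#' contributions \code{wd}, \code{wa}.
#'
#' @param params A \code{kinetic_params} (supplies the weights).
#' @param cp The \code{input_function}.
#' @param curves A \code{compartment_curves} evaluated within the input
#'   support.
#' @return Numeric vector of C_ROI at \code{curves$times}.
#' @export
roi_signal <- function(params, cp, curves) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(cp, "input_function"),
            inherits(curves, "compartment_curves"))
  fp_assert(all(curves$times <= input_support_end(cp) + 1e-9), "grid",
            "curve times extend beyond the input-function support")
  params$wp * eval_input(cp, curves$times) +
    params$wd * curves$C_d + params$wa * curves$C_a
}

# shared frame-averaging core: returns per-frame averages of
# wp*C_p + wd*C_d + wa*C_a for arbitrary weight triples
frame_average_weighted <- function(params, cp, schedule, wp, wd, wa) {
  bounds <- sort(unique(c(schedule$frame_start, schedule$frame_end)))
  pr <- tt_profiles(params, cp, bounds)
  FF <- wp * pr$Ip + wd * pr$Id + wa * pr$Ia
  Fb <- FF[pr$idx]
  i0 <- match(schedule$frame_start, bounds)
  i1 <- match(schedule$frame_end, bounds)
  (Fb[i1] - Fb[i0]) / frame_durations(schedule)
}

#' Frame-averaged model signal
#'
#' PET frames integrate counts, so the model prediction compared against a
#' measured TAC is the frame average \code{(1/dt) int_frame C_ROI(t) dt},
#' computed with the same per-segment closed form as
#' \code{\link{solve_two_tissue}} (no quadrature error).
#'
#' @inheritParams roi_signal
#' @param schedule A \code{\link{frame_schedule}} within the input support.
#' @return A \code{\link{tac}} of model frame averages.
#' @export
frame_average_signal <- function(params, cp, schedule) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(cp, "input_function"),
            inherits(schedule, "frame_schedule"))
  vals <- frame_average_weighted(params, cp, schedule,
                                 params$wp, params$wd, params$wa)
  tac(schedule, pmax(vals, 0), unit = cp$unit)
}

#' Frame-averaged total tissue concentration
#'
#' The tissue curve used by graphical (Patlak) analysis:
#' \code{C_t = (1 - vb) * (C_d + C_a) + vb * C_p}, frame-averaged. With
#' \code{vb = 0} this is the total tissue concentration whose asymptotic
#' Patlak slope equals \code{\link{macro_influx_rate}}. (The weighted ROI
#' signal of \code{\link{frame_average_signal}} instead yields an asymptotic
#' slope of \code{wa * Ki}; see the vignette.)
#'
#' @inheritParams frame_average_signal
#' @param vb Fractional blood volume in [0, 1), default 0.
#' @return A \code{\link{tac}}.
#' @export
frame_average_tissue <- function(params, cp, schedule, vb = 0) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(cp, "input_function"),
            inherits(schedule, "frame_schedule"))
  fp_assert(is_scalar_num(vb) && vb >= 0 && vb < 1, "invalid_spec",
            "vb must be in [0, 1)")
  vals <- frame_average_weighted(params, cp, schedule,
                                 vb, 1 - vb, 1 - vb)
  tac(schedule, pmax(vals, 0), unit = cp$unit)
}
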