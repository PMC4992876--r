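# Synthetic data generator: bolus input functions, noisy TACs, and 4D
# digital phantoms with ground truth, emulating a 2 h, 52-frame dynamic
# FMISO acquisition.

#' Canonical 2 h, 52-frame acquisition schedule
#'
#' 10 x 30 s, 10 x 60 s, 10 x 120 s, 10 x 150 s, 12 x 300 s.
#' @return A \code{\link{frame_schedule}} spanning [0, 7200] s.
#' @export
default_schedule <- function() {
  build_frame_schedule(list(c(10, 30), c(10, 60), c(10, 120),
                            c(10, 150), c(12, 300)))
}

#' Reference kinetic parameter presets
#'
#' Whole-tumour mean micro-parameters for the U87MG and MDA-MB-435 xenograft
#' scenarios at each imaging time point (pre-PDT and 1/6/24 h post PDT),
#' with the package's standard weights wp = 0.05, wd = 0.60, wa = 0.35
#' (weights are never reported for these scenarios, so plausible defaults
#' are used; recovery studies treat them as nuisance parameters).
#'
#' @param name One of \code{"U87MG-1h"}, \code{"U87MG-6h"},
#'   \code{"U87MG-24h"}, \code{"MDA-pre"}, \code{"MDA-1h"}, \code{"MDA-6h"},
#'   \code{"MDA-24h"}.
#' @return A \code{\link{kinetic_params}}.
#' @export
preset_params <- function(name) {
  tab <- list(
    "U87MG-1h"  = c(0.1095, 0.0602, 0.0109),
    "U87MG-6h"  = c(0.1241, 0.0535, 0.0085),
    "U87MG-24h" = c(0.0763, 0.0485, 0.0098),
    "MDA-pre"   = c(0.0115, 0.00123, 0.00149),
    "MDA-1h"    = c(0.0255, 0.00286, 0.03314),
    "MDA-6h"    = c(0.0264, 0.00259, 0.01678),
    "MDA-24h"   = c(0.0282, 0.00195, 0.00156))
  fp_assert(name %in% names(tab), "invalid_spec",
            "unknown preset '%s' (available: %s)", name,
            paste(names(tab), collapse = ", "))
  p <- tab[[name]]
  kinetic_params(K1 = p[1], k2 = p[2], k3 = p[3], wp = 0.05, wd = 0.60)
}

#' Named counting-noise levels
#'
#' Convenience sigma0 values for \code{\link{simulate_tac}}:
#' none = 0, low = 0.5, moderate = 3, high = 8 (in Bq/mL per
#' sqrt(Bq/mL/s)). With the default input function (peak 100 Bq/mL) these
#' give roughly 0 / 0.6 / 4 / 10 percent relative noise on late 300 s tumour
#' frames.
#'
#' @param level Character level name.
#' @export
noise_sigma <- function(level = c("none", "low", "moderate", "high")) {
  c(none = 0, low = 0.5, moderate = 3, high = 8)[[match.arg(level)]]
}

#' Bolus input-function specification
#'
#' A tri-exponential bolus: linear rise from (0, 0) to \code{peak_value} at
#' \code{peak_time}, then \code{sum_j A_j exp(-lambda_j (t - peak_time))}
#' with \code{lambda1 > lambda2 > lambda3} (1/min). The amplitudes are
#' \code{fractions * peak_value} so the curve is continuous at the peak; the
#' slow third component keeps a small positive plasma plateau at 2 h,
#' matching the long circulation of this tracer.
#'
#' @param peak_time Bolus peak time in seconds (default 30).
#' @param peak_value Peak plasma concentration in Bq/mL (default 100).
#' @param lambdas Decreasing decay constants in 1/min (default
#'   \code{c(4, 0.25, 0.005)}).
#' @param fractions Non-negative amplitude fractions summing to 1 (default
#'   \code{c(0.55, 0.25, 0.20)}).
#' @return An object of class \code{input_function_spec}.
#' @export
input_function_spec <- function(peak_time = 30, peak_value = 100,
                                lambdas = c(4, 0.25, 0.005),
                                fractions = c(0.55, 0.25, 0.20)) {
  fp_assert(is_scalar_num(peak_time) && peak_time > 0, "invalid_spec",
            "peak_time must be > 0 s")
  fp_assert(is_scalar_num(peak_value) && peak_value > 0, "invalid_spec",
            "peak_value must be > 0")
  fp_assert(is.numeric(lambdas) && length(lambdas) == 3L &&
              all(lambdas > 0) && all(diff(lambdas) < 0), "invalid_spec",
            "lambdas must be three positive decreasing rates (1/min)")
  fp_assert(is.numeric(fractions) && length(fractions) == 3L &&
              all(fractions >= 0) && abs(sum(fractions) - 1) < 1e-9,
            "invalid_spec", "fractions must be >= 0 and sum to 1")
  structure(list(peak_time = peak_time, peak_value = peak_value,
                 lambdas = lambdas, amplitudes = fractions * peak_value),
            class = "input_function_spec")
}

#' Generate a synthetic plasma input function
#'
#' Samples the bolus model of \code{\link{input_function_spec}} at
#' \code{dt}-second resolution over \code{[0, t_end]}.
#'
#' @param spec An \code{input_function_spec}.
#' @param t_end End of support in seconds (default 7200).
#' @param dt Sampling interval in seconds (default 1).
#' @return An \code{\link{input_function}}.
#' @export
make_input_function <- function(spec = input_function_spec(),
                                t_end = 7200, dt = 1) {
  stopifnot(inherits(spec, "input_function_spec"))
  fp_assert(t_end > spec$peak_time && dt > 0, "invalid_spec",
            "need t_end > peak_time and dt > 0")
  t <- seq(0, t_end, by = dt)
  if (t[length(t)] < t_end) t <- c(t, t_end)
  tp <- spec$peak_time
  rise <- spec$peak_value * pmin(t, tp) / tp
  tail_t <- pmax(t - tp, 0) / 60                 # minutes since peak
  decay <- sapply(seq_len(3), function(j)
    spec$amplitudes[j] * exp(-spec$lambdas[j] * tail_t))
  v <- ifelse(t <= tp, rise, rowSums(decay))
  input_function(t, v)
}

# closed-form integral of the bolus model over [0, T] (analytic oracle)
input_function_integral <- function(spec, T) {
  tp <- spec$peak_time
  if (T <= tp) return(0.5 * spec$peak_value * T^2 / tp)
  tri <- 0.5 * spec$peak_value * tp
  tail_min <- (T - tp) / 60
  tri + sum(spec$amplitudes * 60 / spec$lambdas *
              (1 - exp(-spec$lambdas * tail_min)))
}

#' Simulate a measured TAC with counting noise
#'
#' Frame-averaged model signal plus zero-mean Gaussian noise whose per-frame
#' standard deviation follows counting statistics:
#' \code{sd_i = sigma0 * sqrt(max(value_i, 0) / dt_i)} (variance
#' proportional to activity and inversely to frame duration, the standard
#' surrogate for reconstructed-PET noise).
#'
#' @param params \code{\link{kinetic_params}} of the simulated region.
#' @param cp Plasma \code{\link{input_function}}.
#' @param schedule Acquisition \code{\link{frame_schedule}}.
#' @param noise_sigma0 Noise scale (>= 0); 0 returns the exact model frame
#'   averages.
#' @param seed Seed for reproducibility (restored afterwards).
#' @param n_rep Number of replicate TACs.
#' @return A \code{\link{tac}} for \code{n_rep = 1}, else a list of
#'   \code{tac}s.
#' @export
simulate_tac <- function(params, cp, schedule, noise_sigma0 = 0,
                         seed = NULL, n_rep = 1) {
  fp_assert(is_scalar_num(noise_sigma0) && noise_sigma0 >= 0, "invalid_spec",
            "noise_sigma0 must be >= 0")
  fp_assert(n_rep >= 1 && n_rep == round(n_rep), "invalid_spec",
            "n_rep must be a whole number >= 1")
  model <- frame_average_signal(params, cp, schedule)
  if (noise_sigma0 == 0) {
    if (n_rep == 1) return(model)
    return(replicate(n_rep, model, simplify = FALSE))
  }
  sds <- noise_sigma0 * sqrt(pmax(model$values, 0) / frame_durations(schedule))
  nf <- n_frames(schedule)
  noise <- with_seed(seed, matrix(stats::rnorm(n_rep * nf, 0, 1),
                                  nrow = n_rep, byrow = TRUE))
  out <- lapply(seq_len(n_rep), function(r)
    tac(schedule, model$values + noise[r, ] * sds, unit = model$unit,
        allow_negative = TRUE))
  if (n_rep == 1) out[[1]] else out
}

#' Digital phantom specification
#'
#' Defines a voxelised scene with four disjoint regions -- a tumour sphere
#' split into a normoxic rim and a hypoxic core of a stated volume fraction,
#' a blood pool (pure plasma, wp = 1), and muscle filling the remainder --
#' each with its own kinetic parameters, plus a counting-noise level and a
#' seed.
#'
#' @param shape Integer grid dimensions (default \code{c(32, 32, 32)}).
#' @param voxel_mm Voxel size in mm (default 0.8 isotropic, small-animal
#'   PET).
#' @param preset Tumour-core scenario preset name (see
#'   \code{\link{preset_params}}); default \code{"MDA-1h"}.
#' @param hypoxic_fraction Fraction of tumour voxels in the hypoxic core, in
#'   [0, 1] (default 0.3).
#' @param rim_k3 Trapping rate of the normoxic rim in 1/min (default 0.002).
#' @param noise_sigma0 Counting-noise scale (default 1, low noise for a
#'   reconstructed frame).
#' @param seed Simulation seed (recorded in the output).
#' @param muscle,blood Optional \code{kinetic_params} overrides for the
#'   background regions.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(32, 32, 32), voxel_mm = c(0.8, 0.8, 0.8),
                         preset = "MDA-1h", hypoxic_fraction = 0.3,
                         rim_k3 = 0.002, noise_sigma0 = 1, seed = 1,
                         muscle = NULL, blood = NULL) {
  fp_assert(is.numeric(shape) && length(shape) == 3L && all(shape >= 8) &&
              all(shape == round(shape)), "invalid_spec",
            "shape must be three whole numbers >= 8")
  fp_assert(is_scalar_num(hypoxic_fraction) && hypoxic_fraction >= 0 &&
              hypoxic_fraction <= 1, "invalid_spec",
            "hypoxic_fraction must lie in [0, 1]")
  fp_assert(is_scalar_num(noise_sigma0) && noise_sigma0 >= 0, "invalid_spec",
            "noise_sigma0 must be >= 0")
  core <- preset_params(preset)
  rim <- kinetic_params(K1 = core$K1, k2 = core$k2, k3 = rim_k3,
                        wp = core$wp, wd = core$wd)
  if (is.null(muscle))
    muscle <- kinetic_params(K1 = 0.03, k2 = 0.06, k3 = 5e-4,
                             wp = 0.03, wd = 0.92)
  if (is.null(blood))
    blood <- kinetic_params(K1 = 0, k2 = 0, k3 = 0, wp = 1, wd = 0)
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 preset = preset, hypoxic_fraction = hypoxic_fraction,
                 params = list(core = core, rim = rim, muscle = muscle,
                               blood = blood),
                 noise_sigma0 = noise_sigma0, seed = seed),
            class = "phantom_spec")
}

#' Simulate a 4D dynamic PET phantom
#'
#' Places a tumour sphere (radius 0.2 x the smallest grid dimension) and a
#' separated blood-pool sphere (radius 0.11 x) in a muscle background; the
#' hypoxic core is the stated fraction of tumour voxels nearest the tumour
#' centre (exact by construction). Every voxel's series is the
#' frame-averaged model signal of its region plus seeded counting noise, as
#' in \code{\link{simulate_tac}}. Ground-truth masks and parameter maps are
#' returned for oracle comparisons: the truth Ki map stores the observable
#' asymptotic Patlak slope of the weighted voxel signal, \code{wa * K1 * k3 /
#' (k2 + k3)}, and the truth k3 map the generating k3.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param cp Plasma \code{\link{input_function}} (default: the standard
#'   synthetic bolus).
#' @param schedule Acquisition schedule (default:
#'   \code{\link{default_schedule}}).
#' @return List with \code{image} (4D array, Bq/mL), \code{masks} (logical
#'   3D arrays: tumor, core, rim, blood, muscle), \code{truth} (list:
#'   \code{ki}, \code{k3} arrays and the per-region \code{params}),
#'   \code{cp}, \code{schedule}, \code{spec}.
#' @export
simulate_dynamic_pet <- function(spec, cp = make_input_function(),
                                 schedule = default_schedule()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(cp, "input_function"),
            inherits(schedule, "frame_schedule"))
  dm <- spec$shape
  nf <- n_frames(schedule)
  rmin <- min(dm)
  centre_t <- dm * c(0.65, 0.65, 0.50)
  centre_b <- dm * c(0.25, 0.25, 0.30)
  r_t <- 0.20 * rmin
  r_b <- 0.11 * rmin
  fp_assert(sqrt(sum((centre_t - centre_b)^2)) > r_t + r_b + 1,
            "invalid_spec", "tumour and blood regions overlap")

  ax <- seq_len(dm[1]); ay <- seq_len(dm[2]); az <- seq_len(dm[3])
  dx2 <- outer(outer((ax - centre_t[1])^2, (ay - centre_t[2])^2, "+"),
               (az - centre_t[3])^2, "+")
  db2 <- outer(outer((ax - centre_b[1])^2, (ay - centre_b[2])^2, "+"),
               (az - centre_b[3])^2, "+")
  tumor <- dx2 <= r_t^2
  blood <- db2 <= r_b^2
  muscle <- !tumor & !blood

  tum_idx <- which(tumor)
  n_core <- round(spec$hypoxic_fraction * length(tum_idx))
  ord <- order(dx2[tum_idx], tum_idx)          # deterministic tie-break
  core <- array(FALSE, dm)
  core[tum_idx[ord[seq_len(n_core)]]] <- TRUE
  rim <- tumor & !core

  regions <- list(core = core, rim = rim, muscle = muscle, blood = blood)
  model_tacs <- lapply(spec$params, function(p)
    frame_average_signal(p, cp, schedule)$values)

  img <- matrix(0, nrow = prod(dm), ncol = nf)
  durs <- frame_durations(schedule)
  with_seed(spec$seed, {
    for (rg in names(regions)) {
      vox <- which(regions[[rg]])
      if (!length(vox)) next
      mv <- model_tacs[[rg]]
      img[vox, ] <- rep(mv, each = length(vox))
      if (spec$noise_sigma0 > 0) {
        sds <- spec$noise_sigma0 * sqrt(pmax(mv, 0) / durs)
        img[vox, ] <- img[vox, ] +
          matrix(stats::rnorm(length(vox) * nf), ncol = nf) *
            rep(sds, each = length(vox))
      }
    }
  })
  image4d <- array(img, c(dm, nf))
  attr(image4d, "pixdim") <- spec$voxel_mm

  ki_truth <- array(0, dm)
  k3_truth <- array(0, dm)
  for (rg in c("core", "rim", "muscle")) {
    p <- spec$params[[rg]]
    ki_truth[regions[[rg]]] <- p$wa * macro_influx_rate(p)
    k3_truth[regions[[rg]]] <- p$k3
  }

  list(image = image4d,
       masks = list(tumor = tumor, core = core, rim = rim,
                    blood = blood, muscle = muscle),
       truth = list(ki = ki_truth, k3 = k3_truth, params = spec$params),
       cp = cp, schedule = schedule, spec = spec)
}
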