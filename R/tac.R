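# Time-activity curves and unit conversions.

#' Time-activity curve (TAC)
#'
#' A TAC holds one frame-averaged activity concentration per frame of a
#' \code{\link{frame_schedule}}. Values are finite; negative values are only
#' admitted for measured/noisy data (\code{allow_negative = TRUE}), since
#' reconstructed PET frames can dip below zero while a model prediction
#' cannot.
#'
#' @param schedule A \code{frame_schedule}.
#' @param values Numeric vector, one value per frame.
#' @param unit Unit tag, typically \code{"Bq/mL"} or \code{"\%ID/g"}.
#' @param allow_negative Permit negative values (noisy data).
#' @return An object of class \code{tac}.
#' @export
tac <- function(schedule, values, unit = "Bq/mL", allow_negative = FALSE) {
  stopifnot(inherits(schedule, "frame_schedule"))
  fp_assert(is.numeric(values) && length(values) == n_frames(schedule),
            "invalid_spec", "values must have one entry per frame (%d)",
            n_frames(schedule))
  fp_assert(all(is.finite(values)), "invalid_spec", "TAC values must be finite")
  if (!allow_negative)
    fp_assert(all(values >= 0), "invalid_spec",
              "negative TAC values require allow_negative = TRUE")
  structure(list(schedule = schedule, values = as.numeric(values),
                 unit = unit, allow_negative = isTRUE(allow_negative)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d frames [%s], range %.4g - %.4g\n",
              n_frames(x$schedule), x$unit, min(x$values), max(x$values)))
  invisible(x)
}

#' Injection record
#'
#' Injected dose and tissue density used for %ID/g normalisation.
#'
#' @param injected_dose Injected activity in Bq (> 0).
#' @param injection_time Injection time in seconds (default 0, acquisition
#'   start).
#' @param tissue_density Tissue density in g/mL (default 1.0).
#' @export
injection_record <- function(injected_dose, injection_time = 0,
                             tissue_density = 1.0) {
  fp_assert(is_scalar_num(injected_dose) && injected_dose > 0,
            "invalid_record", "injected_dose must be a positive number (Bq)")
  fp_assert(is_scalar_num(tissue_density) && tissue_density > 0,
            "invalid_record", "tissue_density must be > 0 (g/mL)")
  fp_assert(is_scalar_num(injection_time), "invalid_record",
            "injection_time must be numeric (s)")
  structure(list(injected_dose = injected_dose,
                 injection_time = injection_time,
                 tissue_density = tissue_density),
            class = "injection_record")
}

#' Convert a TAC from Bq/mL to %ID/g
#'
#' \code{value_out = 100 * value_in / (injected_dose * tissue_density)}. The
#' inverse \code{from_percent_id_per_gram} restores Bq/mL.
#'
#' @param x A \code{tac} in Bq/mL (resp. \%ID/g for the inverse).
#' @param inj An \code{\link{injection_record}}.
#' @return A \code{tac} with the converted values and updated unit tag.
#' @export
to_percent_id_per_gram <- function(x, inj) {
  stopifnot(inherits(x, "tac"), inherits(inj, "injection_record"))
  tac(x$schedule, 100 * x$values / (inj$injected_dose * inj$tissue_density),
      unit = "%ID/g", allow_negative = x$allow_negative)
}

#' @rdname to_percent_id_per_gram
#' @export
from_percent_id_per_gram <- function(x, inj) {
  stopifnot(inherits(x, "tac"), inherits(inj, "injection_record"))
  tac(x$schedule, x$values * inj$injected_dose * inj$tissue_density / 100,
      unit = "Bq/mL", allow_negative = x$allow_negative)
}

#' Optional radioactive-decay correction
#'
#' Inputs are assumed to be decay-corrected already (the usual scanner
#' output); this utility is provided for uncorrected data and is never applied
#' implicitly. Values are multiplied by \code{2^(t_mid / half_life)} with the
#' frame midpoint as reference time.
#'
#' @param x A \code{tac}.
#' @param half_life_min Radionuclide half-life in minutes (default 109.77,
#'   fluorine-18).
#' @export
decay_correct <- function(x, half_life_min = 109.77) {
  stopifnot(inherits(x, "tac"))
  fp_assert(is_scalar_num(half_life_min) && half_life_min > 0,
            "invalid_spec", "half_life_min must be > 0")
  fac <- 2^(frame_midpoints(x$schedule) / (half_life_min * 60))
  tac(x$schedule, x$values * fac, unit = x$unit,
      allow_negative = x$allow_negative)
}

#' Read / write a TAC as CSV
#'
#' Columns (header required): \code{frame_start_s}, \code{frame_end_s},
#' \code{value}, \code{unit}.
#'
#' @param path CSV file path.
#' @export
read_tac_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_start_s", "frame_end_s", "value", "unit")
  fp_assert(all(need %in% names(d)), "format",
            "TAC CSV must have columns %s", paste(need, collapse = ", "))
  sched <- frame_schedule(d$frame_start_s, d$frame_end_s)
  tac(sched, d$value, unit = d$unit[1], allow_negative = TRUE)
}

#' @rdname read_tac_csv
#' @param x A \code{tac} to write.
#' @export
write_tac_csv <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  utils::write.csv(data.frame(frame_start_s = x$schedule$frame_start,
                              frame_end_s = x$schedule$frame_end,
                              value = x$values, unit = x$unit),
                   path, row.names = FALSE)
  invisible(path)
}
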