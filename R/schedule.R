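# Frame-schedule bookkeeping for dynamic PET acquisitions.
#
# A schedule is a set of contiguous, non-overlapping, half-open frames
# [start, end) in seconds from tracer injection (injection at t = 0).

#' Frame schedule constructor
#'
#' @param frame_start,frame_end Numeric vectors of frame start/end times in
#'   seconds. Frames must be contiguous (\code{frame_start[i+1] ==
#'   frame_end[i]}), non-empty, and start at or after 0.
#' @return An object of class \code{frame_schedule}.
#' @export
frame_schedule <- function(frame_start, frame_end) {
  fp_assert(is.numeric(frame_start) && is.numeric(frame_end) &&
              length(frame_start) == length(frame_end) &&
              length(frame_start) >= 1L,
            "invalid_spec", "frame_start and frame_end must be numeric vectors of equal positive length")
  fp_assert(all(is.finite(frame_start)) && all(is.finite(frame_end)),
            "invalid_spec", "frame times must be finite")
  fp_assert(frame_start[1] >= 0, "invalid_spec", "schedule must start at t >= 0")
  fp_assert(all(frame_end > frame_start), "invalid_spec",
            "every frame must have end > start")
  n <- length(frame_start)
  if (n > 1L)
    fp_assert(isTRUE(all.equal(frame_start[-1], frame_end[-n])) &&
                all(frame_start[-1] == frame_end[-n]),
              "invalid_spec", "frames must be contiguous and non-overlapping")
  structure(list(frame_start = as.numeric(frame_start),
                 frame_end = as.numeric(frame_end)),
            class = "frame_schedule")
}

#' Build a frame schedule from (count, duration) blocks
#'
#' The conventional shorthand for dynamic PET protocols, e.g. the 2 h,
#' 52-frame acquisition "10 x 30 s, 10 x 60 s, 10 x 120 s, 10 x 150 s,
#' 12 x 300 s" is \code{list(c(10, 30), c(10, 60), c(10, 120), c(10, 150),
#' c(12, 300))}.
#'
#' @param spec A list of length-2 numeric vectors \code{c(count,
#'   duration_seconds)}; counts must be whole numbers >= 1 and durations > 0.
#' @return A \code{\link{frame_schedule}} starting at 0 s.
#' @examples
#' sched <- build_frame_schedule(list(c(10, 30), c(10, 60), c(10, 120),
#'                                    c(10, 150), c(12, 300)))
#' n_frames(sched)  # 52
#' @export
build_frame_schedule <- function(spec) {
  fp_assert(is.list(spec) && length(spec) >= 1L, "invalid_spec",
            "spec must be a non-empty list of c(count, duration) pairs")
  durs <- unlist(lapply(spec, function(blk) {
    fp_assert(is.numeric(blk) && length(blk) == 2L && all(is.finite(blk)),
              "invalid_spec", "each block must be c(count, duration)")
    count <- blk[1]; duration <- blk[2]
    fp_assert(count >= 1 && count == round(count), "invalid_spec",
              "frame count must be a whole number >= 1 (got %g)", count)
    fp_assert(duration > 0, "invalid_spec",
              "frame duration must be > 0 s (got %g)", duration)
    rep(duration, count)
  }))
  ends <- cumsum(durs)
  frame_schedule(c(0, ends[-length(ends)]), ends)
}

#' @export
n_frames <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  length(schedule$frame_start)
}

#' Frame durations in seconds
#' @param schedule A \code{frame_schedule}.
#' @export
frame_durations <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$frame_end - schedule$frame_start
}

#' Frame midpoint times in seconds
#' @param schedule A \code{frame_schedule}.
#' @export
frame_midpoints <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  (schedule$frame_start + schedule$frame_end) / 2
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %g - %g s\n",
              n_frames(x), x$frame_start[1], x$frame_end[n_frames(x)]))
  invisible(x)
}

#' Read / write a frame schedule as JSON
#'
#' The on-disk form is a list of \code{{"count": n, "duration_s": d}} blocks.
#'
#' @param path File path.
#' @return \code{read_frame_schedule} returns a \code{frame_schedule}.
#' @export
read_frame_schedule <- function(path) {
  blocks <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  fp_assert(all(c("count", "duration_s") %in% names(blocks)), "format",
            "schedule JSON needs 'count' and 'duration_s' fields")
  build_frame_schedule(Map(c, blocks$count, blocks$duration_s))
}

#' @rdname read_frame_schedule
#' @param schedule A \code{frame_schedule} to serialise.
#' @export
write_frame_schedule <- function(schedule, path) {
  durs <- frame_durations(schedule)
  rle_d <- rle(durs)
  jsonlite::write_json(data.frame(count = rle_d$lengths,
                                  duration_s = rle_d$values),
                       path, digits = NA)
  invisible(path)
}
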