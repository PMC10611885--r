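#' Build a PET frame schedule from (count, duration) blocks
#'
#' Dynamic PET acquisitions are reconstructed into contiguous frames described
#' compactly as blocks, e.g. ten 15-s frames followed by three 60-s frames.
#' `frame_schedule()` expands such a block specification into a per-frame table.
#' Times are stored in seconds; kinetic fits work in minutes via `mid_min`.
#'
#' @param blocks A data frame (or tibble) with columns `count` and `duration_s`,
#'   or a list of `c(count, duration_s)` pairs.
#' @return A tibble of class `frame_schedule` with columns `frame`, `start_s`,
#'   `duration_s`, `end_s`, `mid_min`.
#' @examples
#' sched <- frame_schedule(list(c(10, 15), c(3, 60), c(5, 120), c(9, 300), c(1, 360)))
#' total_duration_min(sched) # 66.5
#' @export
frame_schedule <- function(blocks) {
  if (is.list(blocks) && !is.data.frame(blocks)) {
    blocks <- do.call(rbind, lapply(blocks, function(b) {
      if (length(b) != 2) stop("each block must be c(count, duration_s)", call. = FALSE)
      data.frame(count = b[[1]], duration_s = b[[2]])
    }))
  }
  if (!all(c("count", "duration_s") %in% names(blocks))) {
    stop("blocks needs columns `count` and `duration_s`", call. = FALSE)
  }
  count <- blocks$count
  dur <- blocks$duration_s
  if (any(!is.finite(count)) || any(count < 1) || any(count != round(count))) {
    stop("frame counts must be positive integers", call. = FALSE)
  }
  if (any(!is.finite(dur)) || any(dur <= 0)) {
    stop("frame durations must be strictly positive", call. = FALSE)
  }
  duration_s <- rep(dur, times = count)
  start_s <- cumsum(c(0, duration_s[-length(duration_s)]))
  out <- tibble::tibble(
    frame = seq_along(duration_s),
    start_s = start_s,
    duration_s = duration_s,
    end_s = start_s + duration_s,
    mid_min = (start_s + duration_s / 2) / 60
  )
  class(out) <- c("frame_schedule", class(out))
  out
}

#' @rdname frame_schedule
#' @param schedule A `frame_schedule`.
#' @export
total_duration_min <- function(schedule) {
  stopifnot(is_frame_schedule(schedule))
  sum(schedule$duration_s) / 60
}

#' @rdname frame_schedule
#' @export
frame_mid_times <- function(schedule) {
  stopifnot(is_frame_schedule(schedule))
  schedule$mid_min
}

#' @rdname frame_schedule
#' @param x Object to test.
#' @export
is_frame_schedule <- function(x) {
  inherits(x, "frame_schedule") ||
    (is.data.frame(x) && all(c("start_s", "duration_s", "mid_min") %in% names(x)))
}

#' Subset the trailing frames of a schedule
#'
#' @param schedule A `frame_schedule`.
#' @param n Number of trailing frames to keep.
#' @return A `frame_schedule` containing the last `n` frames (start times kept
#'   on the original clock).
#' @export
tail_frames <- function(schedule, n) {
  stopifnot(is_frame_schedule(schedule), n >= 1, n <= nrow(schedule))
  out <- schedule[seq.int(nrow(schedule) - n + 1, nrow(schedule)), ]
  class(out) <- unique(c("frame_schedule", class(out)))
  out
}

#' Default acquisition schedule used throughout the package
#'
#' 10 x 15 s, 3 x 60 s, 5 x 120 s, 9 x 300 s, 1 x 360 s: 28 frames, 66.5 min.
#' @return A `frame_schedule`.
#' @export
default_frame_schedule <- function() {
  frame_schedule(list(c(10, 15), c(3, 60), c(5, 120), c(9, 300), c(1, 360)))
}

validate_frame_schedule <- function(schedule) {
  if (any(schedule$duration_s <= 0)) stop("durations must be positive", call. = FALSE)
  if (is.unsorted(schedule$start_s)) stop("frame starts must be nondecreasing", call. = FALSE)
  gaps <- schedule$start_s[-1] - (schedule$start_s + schedule$duration_s)[-nrow(schedule)]
  if (any(abs(gaps) > 1e-6)) stop("schedule is not contiguous", call. = FALSE)
  invisible(schedule)
}
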