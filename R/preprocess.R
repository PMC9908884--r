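# Cleaning and smoothing of raw positional fixes.

#' Clean raw positional fixes
#'
#' Removes, in order: all fixes from the first monitored day (habituation to
#' the new pen), fixes inside censoring event intervals (human visits, sensor
#' swaps), and fixes whose coordinates fall outside the pen rectangle
#' (localisation error). Every removed row is accounted for in the returned
#' censor log.
#'
#' @param raw data.frame with `time_s`, `animal_id`, `x_m`, `y_m`.
#' @param pen Numeric `c(width_m, length_m)` of the pen rectangle.
#' @param events data.frame of half-open intervals `start_s`, `end_s` (and
#'   optionally `reason`); may be `NULL` or empty.
#' @param first_day_s Half-open interval `c(start, end)` of the first-day
#'   removal; defaults to the first 86,400 s. Use `NULL` to skip (e.g. when
#'   the first day is already absent from the input).
#' @param margin_m Tolerance margin (m) added around the pen before a fix
#'   counts as out-of-pen.
#' @return List with `positions` (the cleaned table) and `log`, a data.frame
#'   of per-reason removed-fix counts with attribute `intervals`.
#' @export
clean_positions <- function(raw, pen, events = NULL,
                            first_day_s = c(0, 86400), margin_m = 0) {
  stopifnot(all(c("time_s", "animal_id", "x_m", "y_m") %in% names(raw)),
            length(pen) == 2, all(pen > 0), margin_m >= 0)
  n0 <- nrow(raw)
  removed <- c(first_day = 0L, human_visit = 0L, sensor_swap = 0L,
               out_of_pen = 0L)
  keep <- rep(TRUE, n0)
  intervals <- data.frame(start_s = numeric(0), end_s = numeric(0),
                          reason = character(0))
  if (!is.null(first_day_s)) {
    fd <- raw$time_s >= first_day_s[1] & raw$time_s < first_day_s[2]
    removed["first_day"] <- sum(fd & keep)
    keep <- keep & !fd
    intervals <- rbind(intervals, data.frame(
      start_s = first_day_s[1], end_s = first_day_s[2], reason = "first_day"))
  }
  if (!is.null(events) && nrow(events) > 0) {
    if (is.null(events$reason)) events$reason <- "human_visit"
    for (r in seq_len(nrow(events))) {
      inside <- raw$time_s >= events$start_s[r] & raw$time_s < events$end_s[r]
      reason <- if (events$reason[r] %in% names(removed)) events$reason[r]
                else "human_visit"
      removed[reason] <- removed[reason] + sum(inside & keep)
      keep <- keep & !inside
    }
    intervals <- rbind(intervals, events[, c("start_s", "end_s", "reason")])
  }
  oob <- raw$x_m < -margin_m | raw$x_m > pen[1] + margin_m |
         raw$y_m < -margin_m | raw$y_m > pen[2] + margin_m
  removed["out_of_pen"] <- sum(oob & keep)
  keep <- keep & !oob
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  log <- data.frame(reason = names(removed), removed_fixes = as.integer(removed),
                    stringsAsFactors = FALSE)
  log$removed_fraction <- if (n0 > 0) log$removed_fixes / n0 else 0
  attr(log, "intervals") <- intervals
  attr(log, "input_rows") <- n0
  attr(log, "output_rows") <- nrow(out)
  list(positions = out, log = log)
}

#' Smooth cleaned fixes with a moving average
#'
#' Per animal, each coordinate is replaced by the mean of the available fixes
#' in a 10-s window (trailing by default). Only seconds that had a raw fix
#' get a smoothed fix: gaps are never imputed, and missing fixes inside the
#' window simply shrink the divisor.
#'
#' @param clean data.frame as returned by [clean_positions()].
#' @param window_s Window length in seconds (default 10).
#' @param align `"trailing"` (window ends at the current fix) or
#'   `"centered"`.
#' @return data.frame with the same rows and smoothed `x_m`, `y_m`.
#' @export
smooth_positions <- function(clean, window_s = 10, align = c("trailing", "centered")) {
  align <- match.arg(align)
  if (window_s < 1) stop("window_s must be >= 1")
  if (nrow(clean) == 0) return(clean)
  res <- clean[order(clean$animal_id, clean$time_s), , drop = FALSE]
  lo_off <- if (align == "trailing") window_s - 1 else floor((window_s - 1) / 2)
  hi_off <- if (align == "trailing") 0 else ceiling((window_s - 1) / 2)
  for (an in unique(res$animal_id)) {
    sel <- which(res$animal_id == an)
    tt <- res$time_s[sel]
    lo <- findInterval(tt - lo_off - 1e-9, tt) + 1
    hi <- findInterval(tt + hi_off + 1e-9, tt)
    cx <- cumsum(c(0, res$x_m[sel])); cy <- cumsum(c(0, res$y_m[sel]))
    cnt <- hi - lo + 1
    res$x_m[sel] <- (cx[hi + 1] - cx[lo]) / cnt
    res$y_m[sel] <- (cy[hi + 1] - cy[lo]) / cnt
  }
  rownames(res) <- NULL
  res
}
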