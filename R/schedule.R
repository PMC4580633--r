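#' GPS fix schedule
#'
#' Describes the collar's daily fix programme as a set of clock times.
#' The default is the 7-fix cougar programme (every 3 h at night, every
#' 4 h by day): 02:00, 05:00, 08:00, 12:00, 16:00, 19:00 and 21:00,
#' with 21:00, 02:00 and 05:00 treated as night slots.
#'
#' Slots are civil clock times; no daylight-saving arithmetic is applied
#' anywhere downstream (the collar programme is defined in clock time).
#'
#' @param slot_times character vector of "HH:MM" clock times, unique and
#'   non-empty.
#' @param night_slots subset of `slot_times` designated as night.
#' @return An object of class `fix_schedule`.
#' @examples
#' fix_schedule()
#' @export
fix_schedule <- function(slot_times = c("02:00", "05:00", "08:00", "12:00",
                                        "16:00", "19:00", "21:00"),
                         night_slots = c("21:00", "02:00", "05:00")) {
  if (!length(slot_times)) stop_kc("slot_times must be non-empty")
  if (anyDuplicated(slot_times)) stop_kc("slot_times must be unique")
  if (!all(night_slots %in% slot_times)) {
    stop_kc("night_slots must be a subset of slot_times")
  }
  mins <- slot_to_minutes(slot_times)
  ord <- order(mins)
  structure(
    list(
      slot_times = slot_times[ord],
      night_slots = night_slots,
      slot_minutes = mins[ord]
    ),
    class = "fix_schedule"
  )
}

#' @export
print.fix_schedule <- function(x, ...) {
  cat("<fix_schedule> ", length(x$slot_times), " slots/day: ",
      paste(x$slot_times, collapse = " "), "\n",
      "  night slots: ", paste(x$night_slots, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

slot_to_minutes <- function(slots) {
  parts <- strsplit(slots, ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), 0)
}

# Nearest-slot assignment for a vector of POSIXct times: each time is
# matched to the closest scheduled clock time (wrapping midnight) within
# `tol_min` minutes; otherwise NA (off-schedule).  Returns the slot
# label and the canonical scheduled timestamp it stands for.
assign_slots <- function(times, schedule, tol_min = 30) {
  stopifnot(inherits(schedule, "fix_schedule"))
  lt <- as.POSIXlt(times)
  mins <- lt$hour * 60 + lt$min + lt$sec / 60
  sm <- schedule$slot_minutes
  n <- length(times)
  slot <- character(n)
  slot_time <- as.POSIXct(rep(NA_real_, n), origin = "1970-01-01",
                          tz = attr(times, "tzone") %||% "UTC")
  day0 <- trunc(times, "days")
  for (i in seq_len(n)) {
    d <- abs(mins[i] - sm)
    d <- pmin(d, 1440 - d)                    # wrap midnight
    j <- which.min(d)
    if (d[j] <= tol_min) {
      slot[i] <- schedule$slot_times[j]
      offset <- sm[j]
      # place the canonical slot on the calendar day it belongs to
      if (mins[i] - sm[j] > 720) offset <- sm[j] + 1440
      if (sm[j] - mins[i] > 720) offset <- sm[j] - 1440
      slot_time[i] <- day0[i] + offset * 60
    } else {
      slot[i] <- NA_character_
    }
  }
  list(slot = slot, slot_time = slot_time)
}

# All scheduled slot timestamps for `schedule` whose value lies in
# [from, to] (closed).  Used for FIXRATE denominators and the S2
# missing-slot rule (callers restrict to strict interior as needed).
schedule_slot_times <- function(schedule, from, to) {
  stopifnot(inherits(schedule, "fix_schedule"))
  if (to < from) return(from[0])
  days <- seq(trunc(from, "days") - 86400, trunc(to, "days") + 86400,
              by = "1 day")
  out <- rep(days, each = length(schedule$slot_minutes)) +
    rep(schedule$slot_minutes * 60, times = length(days))
  sort(out[out >= from & out <= to])
}

# Number of scheduled slots strictly between two timestamps.
n_slots_between <- function(schedule, t1, t2) {
  s <- schedule_slot_times(schedule, t1, t2)
  sum(s > t1 & s < t2)
}
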