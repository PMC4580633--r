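# Tabular I/O for every format the pipeline touches: GPS fix tables,
# dual-axis activity logs, and the three cluster-table dialects
# (standard ground-truthing visits, the all-clusters table used for
# event-count prediction, and the double-observer experiment table).
# All files are RFC 4180 CSV, UTF-8, "." decimal separator.

#' Read a GPS fix table
#'
#' Reads collar fixes from CSV (columns `animal_id`, `timestamp` (ISO
#' 8601, local civil time), `x`, `y` in projected meters, optional
#' `downloaded` flag), assigns each fix to the nearest schedule slot
#' within +/- 30 minutes (off-schedule fixes get slot `NA`), sorts by
#' animal and time, and collapses duplicate (animal, slot, day) rows
#' keeping the first.
#'
#' Coordinates must arrive projected in meters: all distance rules of
#' the cluster detector (200 m radius, 200-500 m band) are metric, so
#' inputs that look geographic (every |x| <= 180 and |y| <= 90) are
#' rejected.
#'
#' @param path CSV file path.
#' @param schedule a [fix_schedule()].
#' @param tz timezone id applied to the whole dataset (default "UTC").
#'   Schedule slots are clock times in this zone.
#' @param slot_tol_min slot-matching tolerance in minutes (default 30).
#' @return A data.frame with columns `animal_id`, `time` (POSIXct), `x`,
#'   `y`, `downloaded` (logical; `TRUE` when the column is absent),
#'   `slot` (schedule label or `NA`), `slot_time` (canonical scheduled
#'   timestamp or `NA`). Empty input yields an empty (0-row) frame.
#' @export
read_gps_fixes <- function(path, schedule = fix_schedule(), tz = "UTC",
                           slot_tol_min = 30) {
  if (!file.exists(path)) stop_kc("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  assert_cols(raw, c("animal_id", "timestamp", "x", "y"), "gps_fixes")
  if (nrow(raw) == 0) {
    return(data.frame(
      animal_id = character(), time = as.POSIXct(character(), tz = tz),
      x = numeric(), y = numeric(), downloaded = logical(),
      slot = character(),
      slot_time = as.POSIXct(character(), tz = tz),
      stringsAsFactors = FALSE
    ))
  }
  time <- parse_time(raw$timestamp, tz, path)
  x <- parse_num(raw$x, "x", path)
  y <- parse_num(raw$y, "y", path)
  # lon/lat screens: values boxed in degree ranges with fractional parts
  # (projected-meter grids, even small test grids, are not)
  if (all(abs(x) <= 180) && all(abs(y) <= 90) &&
      any(x != round(x) | y != round(y))) {
    stop_kc(
      "gps_fixes: coordinates look geographic (degrees); ",
      "projected coordinates in meters are required"
    )
  }
  downloaded <- if ("downloaded" %in% names(raw)) {
    coerce_binary(raw$downloaded, "downloaded")
  } else {
    rep(TRUE, nrow(raw))
  }
  fixes <- data.frame(
    animal_id = as.character(raw$animal_id), time = time, x = x, y = y,
    downloaded = downloaded, stringsAsFactors = FALSE
  )
  fixes <- fixes[order(fixes$animal_id, fixes$time), , drop = FALSE]
  sl <- assign_slots(fixes$time, schedule, tol_min = slot_tol_min)
  fixes$slot <- sl$slot
  fixes$slot_time <- sl$slot_time
  # duplicate (animal, slot, day): keep the first occurrence
  key <- ifelse(
    is.na(fixes$slot), paste0("off_", seq_len(nrow(fixes))),
    paste(fixes$animal_id, format(fixes$slot_time, "%Y-%m-%d %H:%M"))
  )
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate (animal, slot, day) fix(es) dropped")
    fixes <- fixes[!dup, , drop = FALSE]
  }
  rownames(fixes) <- NULL
  fixes
}

parse_time <- function(x, tz, path) {
  t <- as.POSIXct(as.character(x), tz = tz,
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                 "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                 "%Y-%m-%d"),
                  optional = TRUE)
  bad <- which(is.na(t) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad)) {
    stop_kc(sprintf(
      "%s: unparseable timestamp at data line(s) %s (e.g. '%s')",
      path, paste(head(bad, 5), collapse = ", "), x[bad[1]]
    ))
  }
  if (anyNA(t)) {
    stop_kc(sprintf("%s: missing timestamp at data line(s) %s",
                    path, paste(head(which(is.na(t)), 5), collapse = ", ")))
  }
  t
}

parse_num <- function(x, field, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | !is.finite(v))
  if (length(bad)) {
    stop_kc(sprintf(
      "%s: non-numeric or non-finite '%s' at data line(s) %s",
      path, field, paste(head(bad, 5), collapse = ", ")
    ))
  }
  v
}

#' Write a GPS fix table
#'
#' Inverse of [read_gps_fixes()]: writes `animal_id`, `timestamp`, `x`,
#' `y`, `downloaded` columns.
#'
#' @param fixes data.frame as returned by [read_gps_fixes()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gps_fixes <- function(fixes, path) {
  out <- data.frame(
    animal_id = fixes$animal_id,
    timestamp = format(fixes$time, "%Y-%m-%d %H:%M:%S"),
    x = sprintf("%.17g", fixes$x),
    y = sprintf("%.17g", fixes$y),
    downloaded = as.integer(fixes$downloaded),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dual-axis activity log
#'
#' Reads 288-second activity-count records (columns `animal_id`,
#' `start`, `ax`, `ay`; counts accumulate 0-255 per axis per block).
#' Out-of-range counts are rejected (not clipped) with a row-level
#' error; overlapping intervals for one animal are an error naming both
#' rows. Output is sorted by (animal, start).
#'
#' @param path CSV file path.
#' @param tz timezone id (default "UTC").
#' @return data.frame with `animal_id`, `start` (POSIXct), `duration`
#'   (seconds, fixed 288), `ax`, `ay`.
#' @export
read_activity_log <- function(path, tz = "UTC") {
  if (!file.exists(path)) stop_kc("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  assert_cols(raw, c("animal_id", "start", "ax", "ay"), "activity")
  if (nrow(raw) == 0) {
    return(data.frame(
      animal_id = character(), start = as.POSIXct(character(), tz = tz),
      duration = numeric(), ax = numeric(), ay = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  start <- parse_time(raw$start, tz, path)
  ax <- parse_num(raw$ax, "ax", path)
  ay <- parse_num(raw$ay, "ay", path)
  bad <- which(ax < 0 | ax > 255 | ay < 0 | ay > 255)
  if (length(bad)) {
    stop_kc(sprintf(
      "%s: activity count outside [0,255] at data line(s) %s",
      path, paste(head(bad, 5), collapse = ", ")
    ))
  }
  rec <- data.frame(
    animal_id = as.character(raw$animal_id), start = start,
    duration = 288, ax = ax, ay = ay, stringsAsFactors = FALSE
  )
  ord <- order(rec$animal_id, rec$start)
  rec <- rec[ord, , drop = FALSE]
  same <- rec$animal_id[-1] == rec$animal_id[-nrow(rec)]
  gap <- as.numeric(difftime(rec$start[-1], rec$start[-nrow(rec)],
                             units = "secs"))
  ov <- which(same & gap < 288)
  if (length(ov)) {
    stop_kc(sprintf(
      "%s: overlapping activity intervals for animal %s (input rows %d and %d)",
      path, rec$animal_id[ov[1]], ord[ov[1]], ord[ov[1] + 1]
    ))
  }
  rownames(rec) <- NULL
  rec
}

#' Write a dual-axis activity log
#'
#' @param records data.frame as returned by [read_activity_log()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_log <- function(records, path) {
  out <- data.frame(
    animal_id = records$animal_id,
    start = format(records$start, "%Y-%m-%d %H:%M:%S"),
    ax = records$ax, ay = records$ay, stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Canonical column names per dialect; a user-supplied column_map
# (canonical -> file header) overrides entries, because supplementary
# layouts enumerate their headers only loosely.
dialect_fields <- function(dialect) {
  switch(dialect,
    standard_visits = list(
      mandatory = "FEEDING",
      known = c("CLUSTER_ID", "POSCOUNT", "TIMEBIN24", "NIGHTPROP",
                "CENTER", "ACCX", "ACCY", "ACCXYDIFF", "FIXRATE",
                "FIELDPROP", "SEARCH_LAG", "SEAS", "FEEDING")
    ),
    all_clusters = list(
      mandatory = character(),
      known = c("CLUSTER_ID", "POSCOUNT", "TIMEBIN24", "NIGHTPROP",
                "CENTER", "ACCX", "ACCY", "ACCXYDIFF", "FIXRATE",
                "FIELDPROP", "SEARCH_LAG", "SEAS")
    ),
    double_observer = list(
      mandatory = c("LargeSizedPrey", "WildUngulate", "Visit1FEEDING",
                    "Visit1SEARCH_LAG", "Visit2FEEDING",
                    "Visit2SEARCH_LAG"),
      known = c("CLUSTER_ID", "LargeSizedPrey", "WildUngulate",
                "Visit1FEEDING", "Visit1SEARCH_LAG", "Visit2FEEDING",
                "Visit2SEARCH_LAG")
    ),
    stop_kc("unknown dialect: ", dialect)
  )
}

#' Read a cluster / visit / observer-pair table
#'
#' Reads one of the three supplementary-style CSV dialects, mapping
#' column names case-insensitively onto the package's field names:
#'
#' * `standard_visits` - ground-truthed clusters with covariates and the
#'   binary response `FEEDING` (accepted encodings 1/0, TRUE/FALSE,
#'   Y/N); the input for the logistic feeding-prediction models.
#' * `all_clusters` - every cluster, visited or not; the input for
#'   feeding-event count prediction.
#' * `double_observer` - the double-observer experiment
#'   (`LargeSizedPrey`, `WildUngulate`, `Visit1FEEDING`,
#'   `Visit1SEARCH_LAG`, `Visit2FEEDING`, `Visit2SEARCH_LAG`), mapped to
#'   observer-pair fields `large_prey`, `wild_ungulate`,
#'   `visit1_feeding`, `visit1_lag_days`, `visit2_feeding`,
#'   `visit2_lag_days`.
#'
#' Unknown extra columns are preserved untouched. Row count is
#' preserved. A missing mandatory column is an error listing expected
#' versus found headers.
#'
#' @param path CSV file path.
#' @param dialect one of `"standard_visits"`, `"all_clusters"`,
#'   `"double_observer"`.
#' @param column_map optional named character vector mapping canonical
#'   field names to the file's actual headers, for files whose headers
#'   deviate from the defaults.
#' @return data.frame in the package's canonical column names.
#' @export
read_cluster_table <- function(path,
                               dialect = c("standard_visits",
                                           "all_clusters",
                                           "double_observer"),
                               column_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_kc("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fields <- dialect_fields(dialect)
  # resolve each canonical name to a file header (case-insensitive),
  # honouring the user map first
  lookup <- function(canon) {
    if (!is.null(column_map) && canon %in% names(column_map)) {
      return(column_map[[canon]])
    }
    hit <- which(tolower(names(raw)) == tolower(canon))
    if (length(hit)) names(raw)[hit[1]] else NA_character_
  }
  resolved <- vapply(fields$known, lookup, "")
  miss <- fields$mandatory[is.na(resolved[fields$mandatory])]
  if (length(miss)) {
    stop_kc(sprintf(
      "%s (%s): missing mandatory column(s) %s; expected headers include %s; found: %s",
      path, dialect, paste(miss, collapse = ", "),
      paste(fields$mandatory, collapse = ", "),
      paste(names(raw), collapse = ", ")
    ))
  }
  present <- resolved[!is.na(resolved)]
  out <- raw[, unname(present), drop = FALSE]
  names(out) <- names(present)
  # preserve unmapped extras untouched
  extras <- setdiff(names(raw), unname(present))
  for (e in extras) out[[e]] <- raw[[e]]

  if (dialect == "double_observer") {
    out2 <- data.frame(
      cluster_id = if ("CLUSTER_ID" %in% names(out)) {
        as.character(out$CLUSTER_ID)
      } else {
        as.character(seq_len(nrow(out)))
      },
      large_prey = coerce_binary(out$LargeSizedPrey, "LargeSizedPrey"),
      wild_ungulate = coerce_binary(out$WildUngulate, "WildUngulate"),
      visit1_feeding = coerce_binary(out$Visit1FEEDING, "Visit1FEEDING"),
      visit1_lag_days = parse_num(out$Visit1SEARCH_LAG, "Visit1SEARCH_LAG",
                                  path),
      visit2_feeding = coerce_binary(out$Visit2FEEDING, "Visit2FEEDING"),
      visit2_lag_days = parse_num(out$Visit2SEARCH_LAG, "Visit2SEARCH_LAG",
                                  path),
      stringsAsFactors = FALSE
    )
    if (any(out2$visit1_lag_days < 0) || any(out2$visit2_lag_days < 0)) {
      stop_kc(path, ": negative search lag in double_observer table")
    }
    keep <- setdiff(names(out), dialect_fields(dialect)$known)
    for (e in keep) out2[[e]] <- out[[e]]
    return(out2)
  }

  if ("FEEDING" %in% names(out)) {
    out$FEEDING <- as.integer(coerce_binary(out$FEEDING, "FEEDING"))
  }
  if ("TIMEBIN24" %in% names(out)) {
    out$TIMEBIN24 <- as.integer(coerce_binary(out$TIMEBIN24, "TIMEBIN24"))
  }
  if ("SEAS" %in% names(out)) out$SEAS <- toupper(as.character(out$SEAS))
  if ("CLUSTER_ID" %in% names(out)) {
    names(out)[names(out) == "CLUSTER_ID"] <- "cluster_id"
    out$cluster_id <- as.character(out$cluster_id)
  }
  num_fields <- intersect(
    c("POSCOUNT", "NIGHTPROP", "CENTER", "ACCX", "ACCY", "ACCXYDIFF",
      "FIXRATE", "FIELDPROP", "SEARCH_LAG"), names(out)
  )
  for (f in num_fields) {
    out[[f]] <- suppressWarnings(as.numeric(out[[f]]))
  }
  rownames(out) <- NULL
  out
}

#' Write a cluster / covariate table
#'
#' Writes with full (17 significant digit) numeric precision so that
#' re-reading reproduces the covariate matrix bit-for-bit.
#'
#' @param x data.frame (e.g. from [cluster_covariates()] or
#'   [read_cluster_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(x, path) {
  out <- x
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA, sprintf("%.17g", out[[nm]]))
    }
    if (is.logical(out[[nm]])) out[[nm]] <- as.integer(out[[nm]])
    if (inherits(out[[nm]], "POSIXct")) {
      out[[nm]] <- format(out[[nm]], "%Y-%m-%d %H:%M:%S")
    }
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
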