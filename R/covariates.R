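# Cluster covariates: the full vector (POSCOUNT ... SEAS) the
# feeding-prediction models consume, computed from member fixes,
# activity records, the fix schedule, download flags and visit metadata.

#' Covariate-computation parameters
#'
#' @param activity_halfwindow_h half-width in hours of the activity
#'   window around each member fix (default 1.5, i.e. records starting
#'   within +/- 1.5 h of the fix are averaged).
#' @param fixrate_window_h total width in hours of the centered moving
#'   window for the GPS acquisition success rate (default 96: +/- 48 h
#'   around each member fix, clipped to the deployment interval).
#' @param night_slots schedule slots counted as night for NIGHTPROP
#'   (default 21:00, 02:00, 05:00 - the slots in the 21:00-05:59 block).
#' @param season_breaks season definitions as month*100+day bounds;
#'   defaults: SUM Jun 1-Sep 30, FAL Oct 1-Jan 15, WIN Jan 16-May 31
#'   (tiles the year, no gap or overlap).
#' @return object of class `covariate_params`.
#' @export
covariate_params <- function(activity_halfwindow_h = 1.5,
                             fixrate_window_h = 96,
                             night_slots = c("21:00", "02:00", "05:00"),
                             season_breaks = NULL) {
  if (activity_halfwindow_h <= 0 || fixrate_window_h <= 0) {
    stop_kc("windows must be positive")
  }
  structure(
    list(activity_halfwindow_h = activity_halfwindow_h,
         fixrate_window_h = fixrate_window_h,
         night_slots = night_slots),
    class = "covariate_params"
  )
}

#' Assign calendar season
#'
#' Year-agnostic membership by calendar day: SUM = Jun 1 - Sep 30,
#' FAL = Oct 1 - Jan 15, WIN = Jan 16 - May 31. A cluster's season is
#' taken from its start date.
#'
#' @param date Date or POSIXct vector.
#' @return character vector of "SUM", "FAL", "WIN".
#' @examples
#' assign_season(as.Date(c("2011-07-04", "2011-01-15", "2011-01-16")))
#' @export
assign_season <- function(date) {
  lt <- as.POSIXlt(date)
  md <- (lt$mon + 1) * 100 + lt$mday
  ifelse(md >= 601 & md <= 930, "SUM",
         ifelse(md >= 1001 | md <= 115, "FAL", "WIN"))
}

#' Spatio-temporal covariates of one cluster
#'
#' POSCOUNT = member count; TIMEBIN24 = 1 when the cluster spans more
#' than 24 h (> 1 night on site); NIGHTPROP = fraction of members whose
#' schedule slot is a night slot; CENTER = mean Euclidean distance (m)
#' of members to the cluster centroid (0 iff all members coincide).
#'
#' @param members data.frame of the cluster's member fixes (rows of the
#'   fix table).
#' @param params [covariate_params()].
#' @return named list with POSCOUNT, TIMEBIN24, NIGHTPROP, CENTER.
#' @export
compute_spatiotemporal <- function(members, params = covariate_params()) {
  cx <- mean(members$x)
  cy <- mean(members$y)
  list(
    POSCOUNT = nrow(members),
    TIMEBIN24 = as.integer(
      as.numeric(difftime(max(members$time), min(members$time),
                          units = "hours")) > 24
    ),
    NIGHTPROP = mean(!is.na(members$slot) &
                       members$slot %in% params$night_slots),
    CENTER = mean(euclid(members$x, members$y, cx, cy))
  )
}

#' Activity covariates of one cluster
#'
#' Two-stage aggregation: for each member fix at time t, all activity
#' records starting within the +/- 1.5 h window are averaged per axis
#' (stage 1, matching the sensor stream to the GPS acquisition rate);
#' the per-fix means are then averaged over the members that had at
#' least one record (stage 2, matching time on site). ACCXYDIFF applies
#' the same two-stage mean to the per-record difference ax - ay, so it
#' equals ACCX - ACCY exactly under identical weights. All three are
#' `NA` when no member has any record in its window.
#'
#' @param members member fixes of one cluster.
#' @param records activity records of the cluster's animal (any order).
#' @param params [covariate_params()].
#' @return named list with ACCX, ACCY, ACCXYDIFF (possibly all `NA`).
#' @export
compute_activity <- function(members, records,
                             params = covariate_params()) {
  if (is.null(records) || nrow(records) == 0) {
    return(list(ACCX = NA_real_, ACCY = NA_real_, ACCXYDIFF = NA_real_))
  }
  records <- records[records$animal_id %in% members$animal_id[1], ,
                     drop = FALSE]
  if (nrow(records) == 0) {
    return(list(ACCX = NA_real_, ACCY = NA_real_, ACCXYDIFF = NA_real_))
  }
  st <- as.numeric(records$start)
  o <- order(st)
  st <- st[o]
  ax <- records$ax[o]
  ay <- records$ay[o]
  w <- params$activity_halfwindow_h * 3600
  tm <- as.numeric(members$time)
  lo <- findInterval(tm - w, st, left.open = TRUE) + 1
  hi <- findInterval(tm + w, st)
  mx <- my <- md <- rep(NA_real_, length(tm))
  for (i in seq_along(tm)) {
    if (hi[i] >= lo[i]) {
      r <- lo[i]:hi[i]
      mx[i] <- mean(ax[r])
      my[i] <- mean(ay[r])
      md[i] <- mean(ax[r] - ay[r])
    }
  }
  keep <- !is.na(mx)
  if (!any(keep)) {
    return(list(ACCX = NA_real_, ACCY = NA_real_, ACCXYDIFF = NA_real_))
  }
  list(ACCX = mean(mx[keep]), ACCY = mean(my[keep]),
       ACCXYDIFF = mean(md[keep]))
}

#' Ground-truthing error covariates of one cluster
#'
#' FIXRATE: for each member fix at time t, the acquisition success rate
#' over scheduled slots in the centered window \[t - 48 h, t + 48 h\]
#' intersected with the deployment interval (acquired scheduled fixes /
#' scheduled slots), averaged over members. FIELDPROP: fraction of
#' members whose fix had been downloaded via satellite before
#' ground-truthing. SEARCH_LAG: days from cluster initiation (first
#' member fix) to the visit, `NA` when unvisited; a visit before the
#' cluster start is an error.
#'
#' @param members member fixes of one cluster.
#' @param animal_fixes all acquired fixes of the same animal.
#' @param schedule [fix_schedule()].
#' @param deployment POSIXct length-2 vector (collar deployment
#'   interval); defaults to the range of `animal_fixes` times.
#' @param visit_time POSIXct visit time or `NULL` when unvisited.
#' @param params [covariate_params()].
#' @param grid optional precomputed slot grid (internal use; computed
#'   from `animal_fixes` when `NULL`).
#' @return named list with FIXRATE, FIELDPROP, SEARCH_LAG.
#' @export
compute_groundtruth_covs <- function(members, animal_fixes, schedule,
                                     deployment = NULL, visit_time = NULL,
                                     params = covariate_params(),
                                     grid = NULL) {
  if (is.null(deployment)) deployment <- range(animal_fixes$time)
  half <- params$fixrate_window_h / 2 * 3600
  if (is.null(grid)) grid <- fixrate_grid(animal_fixes, schedule, deployment)
  # inclusive counts on sorted numeric vectors
  count_in <- function(v, lo, hi) {
    findInterval(hi, v) - findInterval(lo, v, left.open = TRUE)
  }
  tm <- as.numeric(members$time)
  lo <- pmax(tm - half, as.numeric(deployment[1]))
  hi <- pmin(tm + half, as.numeric(deployment[2]))
  total <- count_in(grid$slots, lo, hi)
  got <- count_in(grid$acquired, lo, hi)
  rates <- ifelse(total > 0, got / pmax(total, 1), NA_real_)
  lag <- NA_real_
  if (!is.null(visit_time) && !is.na(visit_time)) {
    lag <- as.numeric(difftime(visit_time, min(members$time),
                               units = "days"))
    if (lag < 0) stop_kc("visit precedes cluster start (negative lag)")
  }
  list(
    FIXRATE = mean(rates, na.rm = TRUE),
    FIELDPROP = mean(members$downloaded),
    SEARCH_LAG = lag
  )
}

# Sorted numeric scheduled-slot grid over the deployment interval plus
# the animal's acquired canonical slot times; precomputed once per
# animal for FIXRATE.
fixrate_grid <- function(animal_fixes, schedule, deployment) {
  list(
    slots = as.numeric(
      schedule_slot_times(schedule, deployment[1], deployment[2])
    ),
    acquired = sort(unique(as.numeric(
      animal_fixes$slot_time[!is.na(animal_fixes$slot_time)]
    )))
  )
}

#' Full covariate table for a set of clusters
#'
#' Computes the complete covariate vector (POSCOUNT, TIMEBIN24,
#' NIGHTPROP, CENTER, ACCX, ACCY, ACCXYDIFF, FIXRATE, FIELDPROP,
#' SEARCH_LAG, SEAS) for every cluster, plus FEEDING when a visit table
#' is supplied. Clusters with no activity records in any member window
#' get `NA` activity covariates (a count is reported via `message()`).
#'
#' @param clusters output of [detect_clusters()]; its `member_idx` must
#'   index into `fixes`.
#' @param fixes the same fix table passed to [detect_clusters()].
#' @param activity optional activity record table
#'   ([read_activity_log()]).
#' @param visits optional visit table: data.frame(`cluster_id`,
#'   `visit_time` POSIXct, `feeding` logical/0-1, ...).
#' @param schedule [fix_schedule()].
#' @param params [covariate_params()].
#' @param deployment optional data.frame(`animal_id`, `start`, `end`)
#'   overriding the per-animal deployment interval (default: range of
#'   the animal's fixes).
#' @return data.frame with one row per cluster (cluster_id, animal_id,
#'   kind, start, the covariates, and FEEDING if visits are given).
#' @export
cluster_covariates <- function(clusters, fixes, activity = NULL,
                               visits = NULL, schedule = fix_schedule(),
                               params = covariate_params(),
                               deployment = NULL) {
  n <- nrow(clusters)
  if (n == 0) stop_kc("no clusters supplied")
  animals <- unique(clusters$animal_id)
  # per-animal sorted activity arrays with cumulative sums, so each
  # per-fix window mean is O(log m)
  act_by_animal <- NULL
  if (!is.null(activity) && nrow(activity)) {
    act_by_animal <- lapply(
      split(seq_len(nrow(activity)), activity$animal_id),
      function(ii) {
        o <- ii[order(activity$start[ii])]
        ax <- as.numeric(activity$ax[o])
        ay <- as.numeric(activity$ay[o])
        list(st = as.numeric(activity$start[o]),
             cax = cumsum(ax), cay = cumsum(ay))
      }
    )
  }
  fix_by_animal <- split(seq_len(nrow(fixes)), fixes$animal_id)
  dep_by_animal <- grid_by_animal <- list()
  for (an in animals) {
    dep_by_animal[[an]] <- if (!is.null(deployment)) {
      r <- deployment[deployment$animal_id == an, ]
      c(r$start[1], r$end[1])
    } else {
      range(fixes$time[fix_by_animal[[an]]])
    }
    grid_by_animal[[an]] <- fixrate_grid(
      fixes[fix_by_animal[[an]], , drop = FALSE], schedule,
      dep_by_animal[[an]]
    )
  }
  vt <- NULL
  if (!is.null(visits)) {
    vt <- visits[match(clusters$cluster_id, visits$cluster_id), ,
                 drop = FALSE]
  }
  cols <- c("POSCOUNT", "TIMEBIN24", "NIGHTPROP", "CENTER", "ACCX",
            "ACCY", "ACCXYDIFF", "FIXRATE", "FIELDPROP", "SEARCH_LAG")
  m <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  ftime <- as.numeric(fixes$time)
  fx <- fixes$x
  fy <- fixes$y
  fnight <- !is.na(fixes$slot) & fixes$slot %in% params$night_slots
  fdl <- fixes$downloaded
  aw <- params$activity_halfwindow_h * 3600
  half <- params$fixrate_window_h / 2 * 3600
  count_in <- function(v, lo, hi) {
    findInterval(hi, v) - findInterval(lo, v, left.open = TRUE)
  }
  for (i in seq_len(n)) {
    idx <- clusters$member_idx[[i]]
    an <- clusters$animal_id[i]
    tm <- ftime[idx]
    cx <- mean(fx[idx]); cy <- mean(fy[idx])
    poscount <- length(idx)
    timebin24 <- as.numeric(max(tm) - min(tm) > 86400)
    nightprop <- mean(fnight[idx])
    center <- mean(sqrt((fx[idx] - cx)^2 + (fy[idx] - cy)^2))
    accx <- accy <- accd <- NA_real_
    act <- act_by_animal[[an]]
    if (!is.null(act)) {
      lo <- findInterval(tm - aw, act$st, left.open = TRUE) + 1
      hi <- findInterval(tm + aw, act$st)
      got <- hi >= lo
      if (any(got)) {
        nrec <- hi[got] - lo[got] + 1
        sax <- act$cax[hi[got]] - c(0, act$cax)[lo[got]]
        say <- act$cay[hi[got]] - c(0, act$cay)[lo[got]]
        accx <- mean(sax / nrec)
        accy <- mean(say / nrec)
        accd <- mean((sax - say) / nrec)
      }
    }
    dep <- as.numeric(dep_by_animal[[an]])
    wlo <- pmax(tm - half, dep[1])
    whi <- pmin(tm + half, dep[2])
    grid <- grid_by_animal[[an]]
    tot <- count_in(grid$slots, wlo, whi)
    acq <- count_in(grid$acquired, wlo, whi)
    fixrate <- mean(ifelse(tot > 0, acq / pmax(tot, 1), NA_real_),
                    na.rm = TRUE)
    lag <- NA_real_
    if (!is.null(vt) && !is.na(vt$visit_time[i])) {
      lag <- (as.numeric(vt$visit_time[i]) - min(tm)) / 86400
      if (lag < 0) stop_kc("visit precedes cluster start (negative lag)")
    }
    m[i, ] <- c(poscount, timebin24, nightprop, center,
                accx, accy, accd, fixrate, mean(fdl[idx]), lag)
  }
  out <- data.frame(
    cluster_id = clusters$cluster_id, animal_id = clusters$animal_id,
    kind = clusters$kind, start = clusters$start,
    as.data.frame(m), SEAS = assign_season(clusters$start),
    stringsAsFactors = FALSE
  )
  out$TIMEBIN24 <- as.integer(out$TIMEBIN24)
  out$POSCOUNT <- as.integer(out$POSCOUNT)
  if (!is.null(vt)) {
    out$FEEDING <- as.integer(coerce_binary(vt$feeding, "feeding"))
  }
  n_noact <- sum(is.na(out$ACCX))
  if (!is.null(activity) && n_noact > 0) {
    message(n_noact, " cluster(s) with no activity records in window")
  }
  rownames(out) <- NULL
  out
}
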