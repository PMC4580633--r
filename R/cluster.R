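# Cluster detection: truncation of post-capture fixes, then grouping of
# GPS fixes into S1 (>= 2 fixes within radius_m / window_days) and S2
# (two consecutive fixes 200-500 m apart bracketing exactly one missed
# scheduled slot) candidate feeding clusters.

#' Cluster-detection parameters
#'
#' @param radius_m S1 cluster radius in meters (default 200): every
#'   member must lie within this distance of the cluster centroid.
#' @param window_days S1 temporal window in days (default 4): a joining
#'   fix must fall within this many days of the current member span.
#' @param s2_min_m,s2_max_m S2 distance band in meters (default
#'   (200, 500]): two consecutive fixes this far apart, with exactly one
#'   scheduled slot missed between them, form an S2 cluster.
#' @param capture_truncation_days days of data discarded after each
#'   capture event (default 7).
#' @return object of class `cluster_params`.
#' @export
cluster_params <- function(radius_m = 200, window_days = 4,
                           s2_min_m = 200, s2_max_m = 500,
                           capture_truncation_days = 7) {
  if (!(radius_m > 0 && radius_m <= s2_min_m && s2_min_m < s2_max_m)) {
    stop_kc("require 0 < radius_m <= s2_min_m < s2_max_m")
  }
  if (window_days <= 0) stop_kc("window_days must be positive")
  structure(
    list(radius_m = radius_m, window_days = window_days,
         s2_min_m = s2_min_m, s2_max_m = s2_max_m,
         capture_truncation_days = capture_truncation_days),
    class = "cluster_params"
  )
}

#' Truncate post-capture fixes and exclusion zones
#'
#' Removes fixes recorded within `capture_truncation_days` of the
#' matching animal's capture (captures perturb behaviour), and fixes
#' falling inside any user-supplied space-time exclusion box (e.g. known
#' natal dens). Counts of removals are reported via `message()`.
#'
#' @param fixes fix table from [read_gps_fixes()] or
#'   [simulate_dataset()].
#' @param capture_times optional data.frame(`animal_id`, `capture_time`
#'   POSIXct); may list several captures per animal. Captures for
#'   unknown animals produce a warning and are ignored.
#' @param params [cluster_params()].
#' @param exclusions optional data.frame with columns `xmin`, `xmax`,
#'   `ymin`, `ymax`, `tmin`, `tmax` (POSIXct) defining space-time boxes
#'   to drop.
#' @return the filtered fix table.
#' @export
truncate_fixes <- function(fixes, capture_times = NULL,
                           params = cluster_params(), exclusions = NULL) {
  drop <- rep(FALSE, nrow(fixes))
  if (!is.null(capture_times) && nrow(capture_times)) {
    unknown <- setdiff(unique(capture_times$animal_id),
                       unique(fixes$animal_id))
    if (length(unknown)) {
      warning("capture time(s) for unknown animal(s) ignored: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    lim <- params$capture_truncation_days * 86400
    for (i in seq_len(nrow(capture_times))) {
      dt <- as.numeric(fixes$time) - as.numeric(capture_times$capture_time[i])
      drop <- drop |
        (fixes$animal_id == capture_times$animal_id[i] & dt >= 0 & dt < lim)
    }
  }
  n_cap <- sum(drop)
  if (!is.null(exclusions) && nrow(exclusions)) {
    for (i in seq_len(nrow(exclusions))) {
      z <- exclusions[i, ]
      drop <- drop | (fixes$x >= z$xmin & fixes$x <= z$xmax &
                        fixes$y >= z$ymin & fixes$y <= z$ymax &
                        fixes$time >= z$tmin & fixes$time <= z$tmax)
    }
  }
  if (any(drop)) {
    message(n_cap, " fix(es) removed by capture truncation, ",
            sum(drop) - n_cap, " by exclusion zones")
  }
  out <- fixes[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect S1 and S2 candidate feeding clusters
#'
#' Each animal is processed independently, scanning chronologically.
#' S1 formation: a new cluster is seeded by the earliest unassigned pair
#' of fixes within `radius_m` and `window_days` of each other; further
#' unassigned fixes join when (a) they lie within `radius_m` of the
#' current centroid, (b) their time falls within `window_days` of the
#' current member time span, and (c) after recomputing the centroid with
#' them included, every member still lies within `radius_m` of it.
#' Joining repeats until no fix can be added, then the cluster closes.
#' S2 formation: among the remaining unassigned fixes, any pair that is
#' consecutive in the animal's acquired-fix sequence, separated by a
#' distance in (`s2_min_m`, `s2_max_m`], with exactly one scheduled slot
#' missing strictly between their times, forms a 2-member S2 cluster.
#' No fix belongs to more than one cluster; output is deterministic.
#'
#' @param fixes fix table sorted by (animal, time) (as produced by
#'   [read_gps_fixes()]); unsorted input is an error.
#' @param schedule [fix_schedule()] used for the S2 missing-slot rule.
#' @param params [cluster_params()].
#' @return data.frame with one row per cluster: `cluster_id`,
#'   `animal_id`, `kind` ("S1"/"S2"), `n_members`, `centroid_x`,
#'   `centroid_y`, `start`, `end`, and a list-column `member_idx` of row
#'   indices into `fixes`.
#' @export
detect_clusters <- function(fixes, schedule = fix_schedule(),
                            params = cluster_params()) {
  empty <- data.frame(
    cluster_id = character(), animal_id = character(), kind = character(),
    n_members = integer(), centroid_x = numeric(), centroid_y = numeric(),
    start = as.POSIXct(character()), end = as.POSIXct(character()),
    stringsAsFactors = FALSE
  )
  empty$member_idx <- list()
  if (nrow(fixes) < 2) return(empty)
  o <- order(fixes$animal_id, fixes$time)
  if (!identical(o, seq_len(nrow(fixes)))) {
    stop_kc("fixes must be sorted by (animal_id, time)")
  }
  res <- list()
  for (an in unique(fixes$animal_id)) {
    idx <- which(fixes$animal_id == an)
    res[[an]] <- detect_one_animal(fixes, idx, schedule, params)
  }
  out <- do.call(rbind, lapply(res, `[[`, "df"))
  if (is.null(out) || nrow(out) == 0) return(empty)
  out$member_idx <- do.call(c, lapply(res, `[[`, "members"))
  out$cluster_id <- paste0(out$animal_id, "_", out$kind, "_",
                           sequence(vapply(res, function(r) nrow(r$df), 0L)))
  rownames(out) <- NULL
  out[, c("cluster_id", "animal_id", "kind", "n_members", "centroid_x",
          "centroid_y", "start", "end", "member_idx")]
}

detect_one_animal <- function(fixes, idx, schedule, params) {
  n <- length(idx)
  t <- as.numeric(fixes$time[idx])
  x <- fixes$x[idx]
  y <- fixes$y[idx]
  win <- params$window_days * 86400
  rad <- params$radius_m
  assigned <- rep(FALSE, n)
  members_list <- list()
  kinds <- character()
  rad2 <- rad^2
  seed_from <- 1L

  repeat {
    seed <- find_seed(t, x, y, assigned, win, rad2, seed_from)
    if (is.null(seed)) break
    seed_from <- seed[1]
    mem <- seed
    assigned[mem] <- TRUE
    cx <- mean(x[mem]); cy <- mean(y[mem])
    tmin <- t[mem[1]]; tmax <- t[mem[2]]
    repeat {
      added <- FALSE
      for (k in which(!assigned)) {
        if (tmin - t[k] > win || t[k] - tmax > win) next
        if ((x[k] - cx)^2 + (y[k] - cy)^2 > rad2) next
        m2 <- c(mem, k)
        ncx <- mean(x[m2]); ncy <- mean(y[m2])
        if (any((x[m2] - ncx)^2 + (y[m2] - ncy)^2 > rad2)) next
        mem <- m2
        assigned[k] <- TRUE
        cx <- ncx; cy <- ncy
        if (t[k] < tmin) tmin <- t[k]
        if (t[k] > tmax) tmax <- t[k]
        added <- TRUE
      }
      if (!added) break
    }
    members_list[[length(members_list) + 1]] <- sort(mem)
    kinds <- c(kinds, "S1")
  }

  # S2: consecutive acquired fixes, both unassigned, 200-500 m apart,
  # exactly one scheduled slot missing strictly between them
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      j <- i + 1
      if (assigned[i] || assigned[j]) next
      d <- euclid(x[i], y[i], x[j], y[j])
      if (!(d > params$s2_min_m && d <= params$s2_max_m)) next
      t1 <- fixes$time[idx[i]]; t2 <- fixes$time[idx[j]]
      if (n_slots_between(schedule, t1, t2) != 1) next
      members_list[[length(members_list) + 1]] <- c(i, j)
      kinds <- c(kinds, "S2")
      assigned[c(i, j)] <- TRUE
    }
  }

  if (!length(members_list)) {
    df <- data.frame(
      animal_id = character(), kind = character(), n_members = integer(),
      centroid_x = numeric(), centroid_y = numeric(),
      start = as.POSIXct(character()), end = as.POSIXct(character()),
      stringsAsFactors = FALSE
    )
    return(list(df = df, members = list()))
  }
  starts <- vapply(members_list, function(m) min(t[m]), 0)
  ord <- order(starts)
  members_list <- members_list[ord]
  kinds <- kinds[ord]
  df <- data.frame(
    animal_id = fixes$animal_id[idx[1]],
    kind = kinds,
    n_members = vapply(members_list, length, 0L),
    centroid_x = vapply(members_list, function(m) mean(x[m]), 0),
    centroid_y = vapply(members_list, function(m) mean(y[m]), 0),
    start = as.POSIXct(vapply(members_list, function(m) min(t[m]), 0),
                       origin = "1970-01-01",
                       tz = attr(fixes$time, "tzone") %||% "UTC"),
    end = as.POSIXct(vapply(members_list, function(m) max(t[m]), 0),
                     origin = "1970-01-01",
                     tz = attr(fixes$time, "tzone") %||% "UTC"),
    stringsAsFactors = FALSE
  )
  list(df = df, members = lapply(members_list, function(m) idx[m]))
}

# Earliest unassigned pair within (radius, window); earliest first
# member, then earliest second member. Pair eligibility is static, so
# first indices already passed over in earlier calls (`from` pointer)
# can never seed a later cluster.
find_seed <- function(t, x, y, assigned, win, rad2, from = 1L) {
  un <- which(!assigned)
  un <- un[un >= from]
  if (length(un) < 2) return(NULL)
  for (a in seq_len(length(un) - 1)) {
    i <- un[a]
    for (b in (a + 1):length(un)) {
      j <- un[b]
      if (t[j] - t[i] > win) break
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= rad2) return(c(i, j))
    }
  }
  NULL
}
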