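# Synthetic biologging simulator: state-based movement (travel, day-bed,
# kill-handling), scheduled GPS fixes with stochastic acquisition and
# satellite-download failure, state-dependent dual-axis activity in
# 288-s blocks, and an imperfect ground-truthing observer whose success
# declines with search lag and improves with downloaded-fix coverage and
# prey mass. Ground truth (the kill ledger and per-cluster labels) is
# returned for parameter-recovery testing.

#' Simulator configuration
#'
#' Defaults describe a medium telemetry study: 30 collared animals
#' followed 120 days on the 7-fix/day schedule, a kill arriving roughly
#' every 1.25 weeks per animal (~400 kills in total, so roughly a
#' quarter of detected clusters are feeding sites), 81% fix acquisition
#' and 92% satellite download success, prey mass a small/large mixture,
#' handling time increasing with mass (1 + mass/30 days, capped at 8),
#' and ground-truthing visits lagged 2-60 days. Activity emissions give
#' feeding more x-axis (forward-backward) than y-axis motion, resting
#' low counts on both axes, and travel y-dominant.
#'
#' @param n_animals number of collared animals.
#' @param duration_days tracking duration per animal (days).
#' @param start study start timestamp (POSIXct or string, UTC).
#' @param schedule [fix_schedule()].
#' @param fix_success_p per-slot GPS acquisition probability.
#' @param download_success_p per-fix satellite download probability.
#' @param kill_rate_per_week kill arrival rate (Poisson; arrivals are
#'   suppressed while a previous kill is still being handled).
#' @param prey_small_range,prey_large_range,prey_small_weight prey-mass
#'   mixture: small mode U(5,20) kg, large mode U(40,80) kg, weight of
#'   the small mode.
#' @param handling_days increasing function mass (kg) -> handling days.
#' @param daybed_offset_m range of the day-bed offset from a kill site.
#' @param kill_site_sd_m SD (m) of night positions around the kill site.
#' @param daybed_sd_m SD (m) of positions around a day-bed.
#' @param travel_step_m range of per-slot-gap travel step lengths (m).
#' @param rest_day_p probability a non-handling day is spent at a
#'   day-bed (producing non-feeding clusters).
#' @param daybed_night_p probability a rest-day night slot is spent at
#'   the bed rather than travelling (night rests blur the day/night
#'   contrast between bed sites and kill sites).
#' @param handling_away_p probability a handling-period slot is a
#'   travel foray away from the carcass (short absences shorten and
#'   disperse feeding clusters).
#' @param daybed_reuse_p probability a rest day reuses the previous rest
#'   day's bed.
#' @param activity_emissions per-state list of `c(ax=, ay=, sd=)` means
#'   for the 288-s activity counts (truncated to \[0,255\]).
#' @param detection named coefficients `d0`, `d_lag`, `d_fieldprop`,
#'   `d_logmass` of the logistic ground-truth detection model.
#' @param visit_lag_range search-lag distribution (uniform, days).
#' @param visit_fraction fraction of detected clusters that get a
#'   ground-truthing visit.
#' @param seed integer seed; the whole simulation is reproducible.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_animals = 30, duration_days = 120,
                       start = "2011-04-15", schedule = fix_schedule(),
                       fix_success_p = 0.81, download_success_p = 0.92,
                       kill_rate_per_week = 0.8,
                       prey_small_range = c(5, 20),
                       prey_large_range = c(40, 80),
                       prey_small_weight = 0.45,
                       handling_days = function(mass) pmin(1 + mass / 30, 8),
                       daybed_offset_m = c(50, 150),
                       kill_site_sd_m = 30, daybed_sd_m = 20,
                       travel_step_m = c(500, 2000),
                       rest_day_p = 0.2, daybed_reuse_p = 0.3,
                       daybed_night_p = 0.25, handling_away_p = 0.1,
                       activity_emissions = list(
                         feeding = c(ax = 130, ay = 60, sd = 20),
                         resting = c(ax = 20, ay = 15, sd = 10),
                         travel = c(ax = 100, ay = 140, sd = 20)
                       ),
                       detection = c(d0 = 0.5, d_lag = -0.06,
                                     d_fieldprop = 1.5, d_logmass = 0.5),
                       visit_lag_range = c(2, 60),
                       visit_fraction = 0.8,
                       seed = 1) {
  probs <- c(fix_success_p, download_success_p, rest_day_p,
             daybed_reuse_p, daybed_night_p, handling_away_p,
             visit_fraction)
  if (any(probs < 0 | probs > 1)) stop_kc("probabilities must be in [0,1]")
  if (kill_rate_per_week < 0) stop_kc("kill_rate_per_week must be >= 0")
  max_handle <- handling_days(prey_large_range[2])
  if (max_handle >= duration_days) {
    stop_kc("infeasible config: handling longer than study duration")
  }
  if (handling_days(prey_large_range[2]) <
      handling_days(prey_small_range[1])) {
    stop_kc("handling_days must be increasing in mass")
  }
  structure(mget(names(formals(sim_config))), class = "sim_config")
}

rnorm2 <- function(n, sd) matrix(rnorm(2 * n, sd = sd), ncol = 2)

draw_mass <- function(n, cfg) {
  small <- runif(n) < cfg$prey_small_weight
  ifelse(small,
         runif(n, cfg$prey_small_range[1], cfg$prey_small_range[2]),
         runif(n, cfg$prey_large_range[1], cfg$prey_large_range[2]))
}

# kills for one animal: Poisson arrivals (exponential gaps) with
# arrivals suppressed during handling of the previous kill
draw_kills <- function(cfg) {
  rate_day <- cfg$kill_rate_per_week / 7
  t <- 0
  times <- masses <- handles <- numeric(0)
  if (rate_day > 0) repeat {
    t <- t + rexp(1, rate_day)
    if (t > cfg$duration_days) break
    m <- draw_mass(1, cfg)
    h <- cfg$handling_days(m)
    times <- c(times, t)
    masses <- c(masses, m)
    handles <- c(handles, h)
    t <- t + h
  }
  data.frame(time_d = times, mass_kg = masses, handling_days = handles)
}

simulate_animal <- function(an, cfg) {
  dur_s <- cfg$duration_days * 86400
  kills <- draw_kills(cfg)
  nk <- nrow(kills)
  k_start <- kills$time_d * 86400
  k_end <- (kills$time_d + kills$handling_days) * 86400

  slot_min <- cfg$schedule$slot_minutes
  nslot <- length(slot_min)
  days <- seq_len(cfg$duration_days) - 1
  slot_s <- as.vector(outer(slot_min * 60, days * 86400, `+`))
  slot_lab <- rep(cfg$schedule$slot_times, times = length(days))
  is_night <- slot_lab %in% cfg$schedule$night_slots
  ns <- length(slot_s)

  rest_day <- runif(cfg$duration_days) < cfg$rest_day_p
  reuse <- runif(cfg$duration_days) < cfg$daybed_reuse_p

  pos <- c(runif(1, 0, 1e5), runif(1, 0, 1e5))
  kill_xy <- matrix(NA_real_, nk, 2)
  bed_xy <- matrix(NA_real_, nk, 2)
  day_bed <- rep(NA_real_, 2)
  day_bed_day <- -10L
  x <- y <- numeric(ns)

  for (i in seq_len(ns)) {
    tt <- slot_s[i]
    d <- tt %/% 86400 + 1
    k <- if (nk) which(k_start <= tt & tt < k_end) else integer(0)
    if (length(k)) {
      k <- k[1]
      if (is.na(kill_xy[k, 1])) {
        kill_xy[k, ] <- pos
        ang <- runif(1, 0, 2 * pi)
        off <- runif(1, cfg$daybed_offset_m[1], cfg$daybed_offset_m[2])
        bed_xy[k, ] <- pos + off * c(cos(ang), sin(ang))
      }
      if (runif(1) < cfg$handling_away_p) {
        # short hunting/watering foray away from the carcass
        ang <- runif(1, 0, 2 * pi)
        step <- runif(1, cfg$travel_step_m[1], cfg$travel_step_m[2])
        pos <- kill_xy[k, ] + step * c(cos(ang), sin(ang))
      } else {
        anchor <- if (is_night[i]) kill_xy[k, ] else bed_xy[k, ]
        sdv <- if (is_night[i]) cfg$kill_site_sd_m else cfg$daybed_sd_m
        pos <- anchor + rnorm(2, sd = sdv)
      }
    } else if (rest_day[d] && (!is_night[i] || runif(1) < cfg$daybed_night_p)) {
      if (day_bed_day != d) {
        if (!(day_bed_day == d - 1 && reuse[d]) || is.na(day_bed[1])) {
          day_bed <- pos
        }
        day_bed_day <- d
      }
      pos <- day_bed + rnorm(2, sd = cfg$daybed_sd_m)
    } else {
      ang <- runif(1, 0, 2 * pi)
      step <- runif(1, cfg$travel_step_m[1], cfg$travel_step_m[2])
      pos <- pos + step * c(cos(ang), sin(ang))
    }
    x[i] <- pos[1]
    y[i] <- pos[2]
  }

  acquired <- runif(ns) < cfg$fix_success_p
  downloaded <- runif(ns) < cfg$download_success_p
  fixes <- data.frame(
    animal_id = an,
    time_s = slot_s[acquired],
    x = x[acquired], y = y[acquired],
    downloaded = downloaded[acquired],
    slot = slot_lab[acquired],
    stringsAsFactors = FALSE
  )

  # activity: 288-s blocks tiling [0, duration)
  nb <- dur_s %/% 288
  bs <- (seq_len(nb) - 1) * 288
  tod <- bs %% 86400
  bd <- bs %/% 86400 + 1
  night <- tod < 6 * 3600 | tod >= 19 * 3600
  handling <- rep(FALSE, nb)
  if (nk) {
    for (k in seq_len(nk)) {
      handling <- handling | (bs >= k_start[k] & bs < k_end[k])
    }
  }
  state <- ifelse(handling & night, "feeding",
                  ifelse(handling, "resting",
                         ifelse(rest_day[bd] & !night, "resting",
                                "travel")))
  em <- cfg$activity_emissions
  mu_x <- vapply(em, `[[`, 0, "ax")[state]
  mu_y <- vapply(em, `[[`, 0, "ay")[state]
  sdv <- vapply(em, `[[`, 0, "sd")[state]
  clamp <- function(v) pmin(pmax(round(v), 0), 255)
  activity <- data.frame(
    animal_id = an, time_s = bs,
    ax = clamp(rnorm(nb, mu_x, sdv)),
    ay = clamp(rnorm(nb, mu_y, sdv)),
    stringsAsFactors = FALSE
  )

  kills_out <- if (nk) {
    data.frame(
      animal_id = an, kill_id = paste0(an, "_K", seq_len(nk)),
      time_s = k_start, x = kill_xy[, 1], y = kill_xy[, 2],
      mass_kg = kills$mass_kg, handling_days = kills$handling_days,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(animal_id = character(), kill_id = character(),
               time_s = numeric(), x = numeric(), y = numeric(),
               mass_kg = numeric(), handling_days = numeric(),
               stringsAsFactors = FALSE)
  }
  list(fixes = fixes, activity = activity, kills = kills_out)
}

#' Simulate a complete biologging dataset
#'
#' Generates GPS fixes, activity records, a ground-truthing visit table
#' and the ground-truth kill ledger under a [sim_config()]. The observer
#' process visits a random subset of the detected clusters with uniform
#' search lags; a truly-feeding cluster is recorded as feeding with
#' probability `invlogit(d0 + d_lag*lag + d_fieldprop*fieldprop +
#' d_logmass*log(mass))` (observers never invent carcasses, so
#' non-feeding clusters are always recorded as absence). Identical seeds
#' give identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `fixes`, `activity`, `visits`, `truth`
#'   (list: `kills` ledger, `cluster_truth` per-cluster labels),
#'   `clusters` (the detected clusters the visits refer to), and
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  t0 <- as.POSIXct(config$start, tz = "UTC")
  with_seed(config$seed, {
    per <- lapply(seq_len(config$n_animals), function(i) {
      simulate_animal(sprintf("A%02d", i), config)
    })
    fixes <- do.call(rbind, lapply(per, `[[`, "fixes"))
    activity <- do.call(rbind, lapply(per, `[[`, "activity"))
    kills <- do.call(rbind, lapply(per, `[[`, "kills"))

    fixes <- data.frame(
      animal_id = fixes$animal_id,
      time = t0 + fixes$time_s,
      x = fixes$x, y = fixes$y, downloaded = fixes$downloaded,
      slot = fixes$slot,
      slot_time = t0 + fixes$time_s,
      stringsAsFactors = FALSE
    )
    fixes <- fixes[order(fixes$animal_id, fixes$time), , drop = FALSE]
    rownames(fixes) <- NULL
    activity <- data.frame(
      animal_id = activity$animal_id,
      start = t0 + activity$time_s,
      duration = 288, ax = activity$ax, ay = activity$ay,
      stringsAsFactors = FALSE
    )
    kills$time <- t0 + kills$time_s
    kills$time_s <- NULL

    clusters <- detect_clusters(fixes, config$schedule, cluster_params())
    ct <- truth_join(clusters, kills)

    n_visit <- floor(config$visit_fraction * nrow(clusters))
    vis_idx <- sort(sample(nrow(clusters), n_visit))
    lag <- runif(n_visit, config$visit_lag_range[1],
                 config$visit_lag_range[2])
    fieldprop <- vapply(vis_idx, function(i) {
      mean(fixes$downloaded[clusters$member_idx[[i]]])
    }, 0)
    truly <- ct$true_feeding[vis_idx]
    mass <- ct$mass_kg[vis_idx]
    dpar <- config$detection
    p_det <- invlogit(dpar["d0"] + dpar["d_lag"] * lag +
                        dpar["d_fieldprop"] * fieldprop +
                        dpar["d_logmass"] * log(ifelse(truly, mass, 1)))
    observed <- truly & (runif(n_visit) < p_det)
    visits <- data.frame(
      cluster_id = clusters$cluster_id[vis_idx],
      visit_time = clusters$start[vis_idx] + lag * 86400,
      feeding = observed,
      prey_mass_kg = ifelse(observed, mass, NA_real_),
      search_lag_days = lag,
      stringsAsFactors = FALSE
    )
    list(fixes = fixes, activity = activity, visits = visits,
         truth = list(kills = kills, cluster_truth = ct),
         clusters = clusters, config = config)
  })
}

#' Join detected clusters to the ground-truth kill ledger
#'
#' A cluster is truly feeding iff its space-time envelope overlaps a
#' kill's handling interval: same animal, time spans intersect, and the
#' cluster centroid lies within `radius_m` of the kill site.
#'
#' @param clusters output of [detect_clusters()].
#' @param kills kill ledger (`truth$kills` of [simulate_dataset()]):
#'   columns animal_id, kill_id, time, x, y, mass_kg, handling_days.
#' @param radius_m spatial match radius (default 200 m).
#' @return data.frame with `cluster_id`, `true_feeding`, `kill_id`,
#'   `mass_kg` (of the matched kill, `NA` otherwise).
#' @export
truth_join <- function(clusters, kills, radius_m = 200) {
  n <- nrow(clusters)
  out <- data.frame(
    cluster_id = clusters$cluster_id,
    true_feeding = rep(FALSE, n),
    kill_id = NA_character_,
    mass_kg = NA_real_,
    stringsAsFactors = FALSE
  )
  if (is.null(kills) || nrow(kills) == 0 || n == 0) return(out)
  for (i in seq_len(n)) {
    k <- kills[kills$animal_id == clusters$animal_id[i], , drop = FALSE]
    if (!nrow(k)) next
    ke <- as.numeric(k$time) + k$handling_days * 86400
    hit <- which(
      as.numeric(clusters$start[i]) <= ke &
        as.numeric(clusters$end[i]) >= as.numeric(k$time) &
        euclid(clusters$centroid_x[i], clusters$centroid_y[i],
               k$x, k$y) <= radius_m
    )
    if (length(hit)) {
      out$true_feeding[i] <- TRUE
      out$kill_id[i] <- k$kill_id[hit[1]]
      out$mass_kg[i] <- k$mass_kg[hit[1]]
    }
  }
  out
}

#' Simulate detection-model data directly
#'
#' Draws (search lag, downloaded-fix proportion, log prey mass) and a
#' Bernoulli detection outcome from the logistic observer model; a
#' lightweight generator for coefficient-recovery checks without running
#' the full movement simulator.
#'
#' @param n number of observations.
#' @param coefs named coefficients `d0`, `d_lag`, `d_fieldprop`,
#'   `d_logmass`.
#' @param seed integer seed.
#' @return data.frame with `SEARCH_LAG`, `FIELDPROP`, `LOGMASS`,
#'   `FEEDING` (the detection outcome) and the true probability `p`.
#' @export
simulate_detection_data <- function(n,
                                    coefs = c(d0 = 0.5, d_lag = -0.06,
                                              d_fieldprop = 1.5,
                                              d_logmass = 0.5),
                                    seed = 1) {
  with_seed(seed, {
    lag <- runif(n, 2, 60)
    fieldprop <- rbeta(n, 8, 1)
    logmass <- log(draw_mass(n, sim_config()))
    p <- invlogit(coefs["d0"] + coefs["d_lag"] * lag +
                    coefs["d_fieldprop"] * fieldprop +
                    coefs["d_logmass"] * logmass)
    data.frame(
      SEARCH_LAG = lag, FIELDPROP = fieldprop, LOGMASS = logmass,
      FEEDING = as.integer(runif(n) < p), p = as.numeric(p)
    )
  })
}
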