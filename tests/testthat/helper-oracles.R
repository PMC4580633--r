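# Independent oracles, written from the stated rules rather than from
# the package internals, plus fixture builders shared across tests.

# ---- fixture builders ------------------------------------------------

# Build a fix table by writing a CSV and reading it back through the
# package reader, so fixtures exercise the real I/O path.
make_fixes <- function(animal, time, x, y, downloaded = TRUE,
                       schedule = fix_schedule(), tz = "UTC") {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  df <- data.frame(
    animal_id = animal,
    timestamp = format(as.POSIXct(time, tz = tz), "%Y-%m-%d %H:%M:%S"),
    x = x, y = y, downloaded = as.integer(downloaded)
  )
  write.csv(df, f, row.names = FALSE)
  read_gps_fixes(f, schedule = schedule, tz = tz)
}

# Random slot-aligned track for clustering oracle comparisons: a random
# walk that lingers at a few sites, some slots missing.
random_track <- function(n_days = 5, p_fix = 0.75, seed = 1) {
  set.seed(seed)
  sched <- fix_schedule()
  t0 <- as.POSIXct("2011-06-01", tz = "UTC")
  slots <- as.vector(outer(sched$slot_minutes * 60,
                           (seq_len(n_days) - 1) * 86400, `+`))
  keep <- runif(length(slots)) < p_fix
  slots <- slots[keep][seq_len(min(sum(keep), 30))]
  pos <- c(0, 0)
  x <- y <- numeric(length(slots))
  site <- NULL
  for (i in seq_along(slots)) {
    if (!is.null(site) && runif(1) < 0.6) {
      pos <- site + rnorm(2, sd = 60)
    } else {
      if (runif(1) < 0.25) site <- pos
      pos <- pos + runif(1, 100, 1200) * c(cos(a <- runif(1, 0, 2 * pi)),
                                           sin(a))
    }
    x[i] <- pos[1]
    y[i] <- pos[2]
  }
  make_fixes("T1", t0 + slots, x, y)
}

# ---- clustering oracle ----------------------------------------------

# Literal replay of the documented S1/S2 rules by exhaustive scan.
oracle_clusters <- function(fixes, schedule = fix_schedule(),
                            params = cluster_params()) {
  out <- list()
  for (an in unique(fixes$animal_id)) {
    sub <- which(fixes$animal_id == an)
    tt <- as.numeric(fixes$time[sub])
    xx <- fixes$x[sub]
    yy <- fixes$y[sub]
    n <- length(sub)
    win <- params$window_days * 86400
    taken <- rep(FALSE, n)
    clusters <- list()
    repeat {
      seed_pair <- NULL
      for (i in seq_len(max(n - 1, 0))) {
        if (taken[i]) next
        for (j in (i + 1):n) {
          if (taken[j]) next
          if (tt[j] - tt[i] > win) next
          if (sqrt((xx[i] - xx[j])^2 + (yy[i] - yy[j])^2) <=
              params$radius_m) {
            seed_pair <- c(i, j)
            break
          }
        }
        if (!is.null(seed_pair)) break
      }
      if (is.null(seed_pair)) break
      mem <- seed_pair
      taken[mem] <- TRUE
      repeat {
        grew <- FALSE
        for (k in seq_len(n)) {
          if (taken[k]) next
          cx <- mean(xx[mem])
          cy <- mean(yy[mem])
          gap <- max(min(tt[mem]) - tt[k], tt[k] - max(tt[mem]), 0)
          if (gap > win) next
          if (sqrt((xx[k] - cx)^2 + (yy[k] - cy)^2) > params$radius_m) next
          trial <- c(mem, k)
          tcx <- mean(xx[trial])
          tcy <- mean(yy[trial])
          if (max(sqrt((xx[trial] - tcx)^2 + (yy[trial] - tcy)^2)) >
              params$radius_m) next
          mem <- trial
          taken[k] <- TRUE
          grew <- TRUE
        }
        if (!grew) break
      }
      clusters[[length(clusters) + 1]] <-
        list(kind = "S1", members = sort(sub[sort(mem)]))
    }
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        j <- i + 1
        if (taken[i] || taken[j]) next
        d <- sqrt((xx[i] - xx[j])^2 + (yy[i] - yy[j])^2)
        if (d <= params$s2_min_m || d > params$s2_max_m) next
        between <- schedule_slot_times_oracle(schedule, fixes$time[sub[i]],
                                              fixes$time[sub[j]])
        if (length(between) != 1) next
        taken[c(i, j)] <- TRUE
        clusters[[length(clusters) + 1]] <-
          list(kind = "S2", members = sub[c(i, j)])
      }
    }
    out <- c(out, clusters)
  }
  out
}

# scheduled slot clock times strictly between two timestamps, by brute
# enumeration over days
schedule_slot_times_oracle <- function(schedule, t1, t2) {
  days <- seq(as.Date(t1) - 1, as.Date(t2) + 1, by = "1 day")
  cand <- as.POSIXct(paste(rep(days, each = length(schedule$slot_times)),
                           schedule$slot_times), tz = "UTC")
  cand[cand > t1 & cand < t2]
}

# canonical form for comparing cluster memberships
membership_sets <- function(clusters_df) {
  s <- lapply(seq_len(nrow(clusters_df)), function(i) {
    list(kind = clusters_df$kind[i],
         members = sort(clusters_df$member_idx[[i]]))
  })
  s[order(vapply(s, function(e) min(e$members), 0))]
}

oracle_sets <- function(oracle_list) {
  s <- lapply(oracle_list, function(e) {
    list(kind = e$kind, members = sort(e$members))
  })
  s[order(vapply(s, function(e) min(e$members), 0))]
}

# ---- AUC oracle ------------------------------------------------------

auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# ---- logistic MLE oracle --------------------------------------------

# generic numerical optimizer of the binomial log-likelihood (BFGS with
# analytic gradient), independent of the IRLS path
logistic_optim <- function(y, X) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(b) {
    p <- 1 / (1 + exp(-drop(X %*% b)))
    -drop(crossprod(X, y - p))
  }
  opt <- optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  opt$par
}

# ---- shared simulated dataset ---------------------------------------

.shared <- new.env()

shared_sim <- function() {
  if (is.null(.shared$dat)) {
    cfg <- sim_config(seed = 101)
    dat <- simulate_dataset(cfg)
    covs <- cluster_covariates(dat$clusters, dat$fixes, dat$activity,
                               dat$visits, cfg$schedule)
    .shared$dat <- list(cfg = cfg, dat = dat, covs = covs,
                        visited = covs[!is.na(covs$FEEDING), ])
  }
  .shared$dat
}

# small fast dataset for cheaper tests
shared_sim_small <- function() {
  if (is.null(.shared$small)) {
    cfg <- sim_config(n_animals = 6, duration_days = 60, seed = 7)
    dat <- simulate_dataset(cfg)
    covs <- cluster_covariates(dat$clusters, dat$fixes, dat$activity,
                               dat$visits, cfg$schedule)
    .shared$small <- list(cfg = cfg, dat = dat, covs = covs,
                          visited = covs[!is.na(covs$FEEDING), ])
  }
  .shared$small
}
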