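t0 <- as.POSIXct("2011-06-01 02:00:00", tz = "UTC")

test_that("spatio-temporal covariates match geometry and hand computation", {
  # two members d meters apart: CENTER = d/2
  fx <- make_fixes("A", t0 + c(0, 3 * 3600), c(0, 120), c(0, 0))
  sp <- compute_spatiotemporal(fx)
  expect_equal(sp$CENTER, 60)
  expect_equal(sp$POSCOUNT, 2)
  expect_equal(sp$TIMEBIN24, 0L)
  expect_equal(sp$NIGHTPROP, 1)   # 02:00 and 05:00 are night slots

  # 5-member cluster, all four values against a hand calculation
  tt <- t0 + c(0, 3, 6, 27, 30) * 3600   # 02:00 05:00 08:00 05:00+1d 08:00+1d
  fx5 <- make_fixes("A", tt, c(0, 100, 50, 0, 100), c(0, 0, 80, 40, 40))
  sp5 <- compute_spatiotemporal(fx5)
  expect_equal(sp5$POSCOUNT, 5)
  expect_equal(sp5$TIMEBIN24, 1L)       # 30 h span
  expect_equal(sp5$NIGHTPROP, 3 / 5)    # 02:00, 05:00, 05:00
  cx <- mean(c(0, 100, 50, 0, 100))
  cy <- mean(c(0, 0, 80, 40, 40))
  expect_equal(sp5$CENTER,
               mean(sqrt((c(0, 100, 50, 0, 100) - cx)^2 +
                           (c(0, 0, 80, 40, 40) - cy)^2)))
})

test_that("activity covariates use the two-stage windowed mean", {
  fx <- make_fixes("A", t0 + c(0, 6 * 3600), c(0, 50), c(0, 0))
  # constant records: means equal the constant, difference zero
  rec <- data.frame(
    animal_id = "A",
    start = t0 + seq(-3600, 6 * 3600 + 3600, by = 288),
    ax = 100, ay = 100
  )
  ac <- compute_activity(fx, rec)
  expect_equal(ac$ACCX, 100)
  expect_equal(ac$ACCY, 100)
  expect_equal(ac$ACCXYDIFF, 0)

  # no records in any window: all missing
  far <- data.frame(animal_id = "A", start = t0 + 86400 * 10,
                    ax = 5, ay = 5)
  ac0 <- compute_activity(fx, far)
  expect_true(is.na(ac0$ACCX) && is.na(ac0$ACCY) && is.na(ac0$ACCXYDIFF))

  # hand-placed records: ax 10,20 around fix1; 30 around fix2
  rec2 <- data.frame(
    animal_id = "A",
    start = c(t0 - 1000, t0 + 1000, t0 + 6 * 3600),
    ax = c(10, 20, 30), ay = c(4, 6, 10)
  )
  ac2 <- compute_activity(fx, rec2)
  expect_equal(ac2$ACCX, mean(c(mean(c(10, 20)), 30)))  # 22.5
  expect_equal(ac2$ACCY, mean(c(5, 10)))
  expect_equal(ac2$ACCXYDIFF, ac2$ACCX - ac2$ACCY)
})

test_that("ground-truthing covariates count slots, downloads and lag", {
  # 4 days, all slots acquired except three hand-picked misses
  sched <- fix_schedule()
  all_t <- as.POSIXct(paste(
    rep(paste0("2011-06-0", 1:4), each = 7), rep(sched$slot_times, 4)
  ), tz = "UTC")
  miss <- c(5, 12, 20)
  fx <- make_fixes("A", all_t[-miss], seq_along(all_t[-miss]) * 1000, 0,
                   downloaded = rep(c(TRUE, FALSE), length.out = 25))
  members <- fx[10:11, ]
  gt <- compute_groundtruth_covs(members, fx, sched,
                                 deployment = range(all_t))
  # manual: per member, slots and acquisitions inside [t-48h, t+48h]
  acq <- all_t[-miss]
  manual <- vapply(members$time, function(tm) {
    lo <- max(tm - 48 * 3600, min(all_t))
    hi <- min(tm + 48 * 3600, max(all_t))
    sum(acq >= lo & acq <= hi) / sum(all_t >= lo & all_t <= hi)
  }, 0)
  expect_equal(gt$FIXRATE, mean(manual))
  expect_equal(gt$FIELDPROP, mean(members$downloaded))
  expect_true(is.na(gt$SEARCH_LAG))

  # complete acquisition gives FIXRATE exactly 1
  fxall <- make_fixes("A", all_t, seq_along(all_t) * 1000, 0)
  gt1 <- compute_groundtruth_covs(fxall[14:16, ], fxall, sched,
                                  deployment = range(all_t))
  expect_equal(gt1$FIXRATE, 1)

  # search lag in fractional days; negative lag is an error
  gt2 <- compute_groundtruth_covs(members, fx, sched,
                                  deployment = range(all_t),
                                  visit_time = members$time[1] + 1.5 * 86400)
  expect_equal(gt2$SEARCH_LAG, 1.5)
  expect_error(
    compute_groundtruth_covs(members, fx, sched,
                             deployment = range(all_t),
                             visit_time = members$time[1] - 3600),
    "negative lag"
  )
})

test_that("season assignment follows the calendar-day definitions", {
  expect_equal(assign_season(as.Date("2011-07-04")), "SUM")
  expect_equal(assign_season(as.Date("2011-01-15")), "FAL")
  expect_equal(assign_season(as.Date("2011-01-16")), "WIN")
  expect_equal(assign_season(as.Date("2011-12-31")), "FAL")
  expect_equal(assign_season(as.Date(c("2011-06-01", "2011-09-30",
                                       "2011-10-01", "2011-05-31"))),
               c("SUM", "SUM", "FAL", "WIN"))
  # the three ranges tile every day of the year
  days <- seq(as.Date("2011-01-01"), as.Date("2011-12-31"), by = "1 day")
  expect_true(all(assign_season(days) %in% c("SUM", "FAL", "WIN")))
})

test_that("covariate table honours the two-stage identity and input order", {
  sh <- shared_sim_small()
  covs <- sh$covs
  # ACCXYDIFF equals ACCX - ACCY exactly under identical weights
  ok <- !is.na(covs$ACCXYDIFF)
  expect_true(any(ok))
  expect_equal(covs$ACCXYDIFF[ok], (covs$ACCX - covs$ACCY)[ok])
  expect_true(all(covs$NIGHTPROP >= 0 & covs$NIGHTPROP <= 1))
  expect_true(all(covs$FIXRATE >= 0 & covs$FIXRATE <= 1))
  expect_true(all(covs$FIELDPROP >= 0 & covs$FIELDPROP <= 1))
  expect_true(all(covs$POSCOUNT >= 2))

  # outputs invariant to reordering of the activity record stream
  cl1 <- sh$dat$clusters[1:10, ]
  act <- sh$dat$activity
  set.seed(1)
  act_shuffled <- act[sample(nrow(act)), ]
  c_a <- cluster_covariates(cl1, sh$dat$fixes, act, sh$dat$visits,
                            sh$cfg$schedule)
  c_b <- cluster_covariates(cl1, sh$dat$fixes, act_shuffled,
                            sh$dat$visits, sh$cfg$schedule)
  expect_equal(c_a, c_b)
})

test_that("adding a night-slot member weakly increases NIGHTPROP", {
  # members at 02:00 (night), 05:00 (night), 08:00 (day), 21:00 (night)
  fx <- make_fixes("A", t0 + c(0, 3, 6, 19) * 3600,
                   c(0, 50, 100, 60), c(0, 0, 0, 50))
  base <- compute_spatiotemporal(fx[1:3, ])$NIGHTPROP
  expect_equal(base, 2 / 3)
  grown <- compute_spatiotemporal(fx)$NIGHTPROP
  expect_gte(grown, base)
  expect_equal(grown, 3 / 4)
})
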