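t0 <- as.POSIXct("2011-06-01 02:00:00", tz = "UTC")

test_that("capture truncation removes exactly the first week of data", {
  fx <- make_fixes("A", t0 + (0:99) * 10800, runif(100, 0, 1e4),
                   runif(100, 0, 1e4))
  expect_identical(truncate_fixes(fx, NULL), fx)  # no captures: identity

  cap <- data.frame(animal_id = "A", capture_time = t0)
  out <- truncate_fixes(fx, cap)
  expect_true(all(difftime(out$time, t0, units = "days") >= 7))
  # boundary: 6.9 days removed, 7.1 days retained
  fx2 <- make_fixes("B", t0 + c(6.9, 7.1) * 86400, c(1000, 2000), c(0, 0))
  out2 <- truncate_fixes(fx2, data.frame(animal_id = "B",
                                         capture_time = t0))
  expect_equal(nrow(out2), 1)
  expect_equal(out2$x, 2000)
  # brute-force per-row predicate on two animals
  both <- rbind(fx, fx2)
  both <- both[order(both$animal_id, both$time), ]
  caps <- data.frame(animal_id = c("A", "B"), capture_time = c(t0, t0))
  got <- truncate_fixes(both, caps)
  keep <- vapply(seq_len(nrow(both)), function(i) {
    ct <- caps$capture_time[caps$animal_id == both$animal_id[i]]
    dt <- as.numeric(difftime(both$time[i], ct, units = "days"))
    !(dt >= 0 & dt < 7)
  }, TRUE)
  expect_equal(got$time, both$time[keep])
  expect_warning(
    truncate_fixes(fx, data.frame(animal_id = "ZZ", capture_time = t0)),
    "unknown animal"
  )
})

test_that("exclusion zones drop fixes inside the space-time box", {
  fx <- make_fixes("A", t0 + (0:6) * 10800,
                   c(0, 500, 500, 5000, 500, 0, 0),
                   c(0, 500, 500, 5000, 500, 0, 0))
  zone <- data.frame(xmin = 400, xmax = 600, ymin = 400, ymax = 600,
                     tmin = t0, tmax = t0 + 4 * 10800)
  expect_message(out <- truncate_fixes(fx, exclusions = zone), "exclusion")
  expect_equal(nrow(out), 4)  # the three 500/500 fixes inside [t0, t0+4slots]
})

test_that("minimal S1 formation: a qualifying pair clusters at its midpoint", {
  expect_equal(nrow(detect_clusters(make_fixes("A", t0, 0, 0))), 0)

  fx <- make_fixes("A", t0 + c(0, 3 * 3600), c(0, 100), c(0, 0))
  cl <- detect_clusters(fx)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$kind, "S1")
  expect_equal(cl$n_members, 2L)
  expect_equal(cl$centroid_x, 50)
  expect_equal(cl$centroid_y, 0)
  # same pair beyond the 4-day window: no cluster
  fx2 <- make_fixes("A", t0 + c(0, 4.5 * 86400), c(0, 100), c(0, 0))
  expect_equal(nrow(detect_clusters(fx2)), 0)
})

test_that("S2 requires the 200-500 m band and exactly one missed slot", {
  # 02:00 and 08:00 fixes, 05:00 missing, 300 m apart -> S2
  fx <- make_fixes("A", t0 + c(0, 6 * 3600), c(0, 300), c(0, 0))
  cl <- detect_clusters(fx)
  expect_equal(cl$kind, "S2")
  expect_equal(cl$n_members, 2L)
  # with the intervening 05:00 fix acquired (all slots present): no cluster
  fx2 <- make_fixes("A", t0 + c(0, 3, 6) * 3600, c(0, 5000, 300),
                    c(0, 0, 0))
  expect_equal(nrow(detect_clusters(fx2)), 0)
  # two slots missing (02:00 then 12:00): no S2
  fx3 <- make_fixes("A", t0 + c(0, 10 * 3600), c(0, 300), c(0, 0))
  expect_equal(nrow(detect_clusters(fx3)), 0)
  # distance at exactly 200 m belongs to S1, not S2
  fx4 <- make_fixes("A", t0 + c(0, 6 * 3600), c(0, 200), c(0, 0))
  expect_equal(detect_clusters(fx4)$kind, "S1")
})

test_that("detected assignments match the brute-force oracle on random tracks", {
  for (s in 1:40) {
    fx <- random_track(n_days = 5, p_fix = 0.75, seed = s)
    got <- membership_sets(detect_clusters(fx))
    want <- oracle_sets(oracle_clusters(fx))
    expect_equal(got, want, info = paste("seed", s))
  }
})

test_that("cluster partition, radius and invariance properties hold", {
  for (s in c(3, 14, 25)) {
    fx <- random_track(n_days = 6, p_fix = 0.8, seed = s)
    cl <- detect_clusters(fx)
    mem <- unlist(cl$member_idx)
    expect_equal(anyDuplicated(mem), 0)            # partition
    expect_true(all(mem %in% seq_len(nrow(fx))))
    for (i in seq_len(nrow(cl))) {
      if (cl$kind[i] != "S1") next
      d <- sqrt((fx$x[cl$member_idx[[i]]] - cl$centroid_x[i])^2 +
                  (fx$y[cl$member_idx[[i]]] - cl$centroid_y[i])^2)
      expect_true(all(d <= 200 + 1e-9))            # radius after close
      gaps <- diff(sort(as.numeric(fx$time[cl$member_idx[[i]]])))
      expect_true(all(gaps <= 4 * 86400))          # consecutive gaps
    }
    # translation invariance
    sh <- fx
    sh$x <- sh$x + 12345
    sh$y <- sh$y - 999
    expect_equal(membership_sets(detect_clusters(sh)),
                 membership_sets(cl))
    # time-shift invariance (whole days keep the slot structure)
    ts <- fx
    ts$time <- ts$time + 5 * 86400
    ts$slot_time <- ts$slot_time + 5 * 86400
    expect_equal(membership_sets(detect_clusters(ts)),
                 membership_sets(cl))
  }
})

test_that("unsorted fix input is rejected", {
  fx <- make_fixes("A", t0 + c(0, 3 * 3600), c(0, 100), c(0, 0))
  expect_error(detect_clusters(fx[2:1, ]), "sorted")
})
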