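test_that("fixation-break masking uses a strict 100-pixel radius", {
  # three samples at distances 0, 100, 101 from the fixation center
  rec <- gaze_recording(xl = c(0, 100, 101), yl = c(0, 0, 0),
                        pl = c(1, 1, 1), xr = c(0, 0, 0), yr = c(0, 0, 0),
                        pr = c(1, 1, 1), sampling_rate = 1000)
  m <- mask_fixation_breaks(rec)
  expect_equal(m$valid_l, c(TRUE, TRUE, FALSE))
  expect_true(all(m$valid_r))
  # already-invalid samples stay missing even at the center
  rec$valid_l <- c(FALSE, TRUE, TRUE)
  m2 <- mask_fixation_breaks(rec)
  expect_equal(m2$valid_l, c(FALSE, TRUE, FALSE))
})

test_that("participant exclusion applies a strict > 50% rule", {
  mk <- function(frac) {
    n <- 1000
    v <- rep(TRUE, n)
    if (frac > 0) v[seq_len(round(frac * n))] <- FALSE
    gaze_recording(rep(0, n), rep(0, n), rep(1, n), rep(0, n), rep(0, n),
                   rep(1, n), valid_l = v, sampling_rate = 1000)
  }
  expect_true(participant_excluded(mk(0.6))$excluded)
  expect_false(participant_excluded(mk(0))$excluded)
  expect_false(participant_excluded(mk(0.5))$excluded)
  expect_equal(participant_excluded(mk(0.5))$missing_fraction, 0.5)
  expect_error(participant_excluded(gaze_recording()), "empty")
})

test_that("sparse epochs are discarded and clean epochs pass unchanged", {
  n <- 750
  data <- matrix(1, 4, n)
  missing <- matrix(FALSE, 4, n)
  missing[2, seq_len(ceiling(0.51 * n))] <- TRUE   # 51% missing -> dropped
  missing[3, seq_len(floor(0.50 * n))] <- TRUE     # exactly 50% -> kept
  ep <- make_epochs(data, condition = rep("HL", 4), missing = missing)
  cl <- clean_epochs(ep)
  expect_equal(cl$report$n_dropped_sparse, 1)
  expect_equal(cl$report$n_dropped_outlier, 0)
  expect_equal(nrow(cl$epochs$data), 3)
  # fully valid constant epochs: interpolation is the identity
  expect_true(all(cl$epochs$data == 1))
})

test_that("gaps are filled by linear interpolation with edge hold", {
  n <- 20
  x <- as.numeric(1:n)
  miss <- rep(FALSE, n)
  miss[c(1, 2, 8, 9, 10, n)] <- TRUE
  x[miss] <- NA
  ep <- epoch_set(matrix(x, 1), (0:(n - 1)) / 10, matrix(miss, 1),
                  condition = "HL")
  cl <- clean_epochs(ep)
  got <- cl$epochs$data[1, ]
  # oracle: approx() between valid neighbours, nearest-valid at edges
  ok <- which(!miss)
  want <- approx(ok, (1:n)[ok], xout = 1:n, rule = 2)$y
  expect_equal(got, want)
  # interior gap is the straight line between its neighbours
  expect_equal(got[8:10], c(8, 9, 10))
  # edge gaps hold the nearest valid value
  expect_equal(got[1:2], c(3, 3))
})

test_that("the outlier rule drops exactly the displaced trial", {
  set.seed(8)
  n <- 200
  base <- matrix(rnorm(20 * n), 20, n)
  bad <- base[1, ]
  idx <- seq_len(0.15 * n)          # 15% of samples displaced by +10 SD
  bad[idx] <- bad[idx] + 10
  data <- rbind(base, bad)
  ep <- make_epochs(data, condition = rep("HL", 21))
  cl <- clean_epochs(ep)
  expect_equal(cl$report$n_dropped_outlier, 1)
  expect_equal(nrow(cl$epochs$data), 20)
  # oracle: evaluate the rule directly on the interpolated data
  mu <- colMeans(data)
  sd_t <- apply(data, 2, sd)
  frac <- rowMeans(abs(sweep(data, 2, mu)) > 3 * sd_t)
  expect_equal(unname(which(frac >= 0.10)), 21L)
  # a displacement affecting < 10% of samples survives
  bad2 <- base[1, ]
  bad2[seq_len(0.05 * n)] <- bad2[seq_len(0.05 * n)] + 10
  cl2 <- clean_epochs(make_epochs(rbind(base, bad2),
                                  condition = rep("HL", 21)))
  expect_equal(cl2$report$n_dropped_outlier, 0)
})

test_that("a condition losing all trials is an error", {
  data <- matrix(1, 2, 100)
  missing <- matrix(FALSE, 2, 100)
  missing[2, 1:60] <- TRUE
  ep <- make_epochs(data, condition = c("HL", "LL"), missing = missing)
  expect_error(clean_epochs(ep), "LL")
})

test_that("participant z-scoring pools both conditions", {
  set.seed(4)
  a <- make_epochs(matrix(rnorm(5 * 100, mean = 2), 5, 100),
                   condition = rep("HL", 5))
  b <- make_epochs(matrix(rnorm(5 * 100, mean = 4), 5, 100),
                   condition = rep("LL", 5))
  z <- zscore_participant(list(a, b))
  pooled <- c(z[[1]]$data, z[[2]]$data)
  expect_equal(mean(pooled), 0, tolerance = 1e-9)
  expect_equal(sd(pooled), 1, tolerance = 1e-9)
  # brute-force oracle for the transformed condition-mean separation
  raw <- c(a$data, b$data)
  want_gap <- (mean(b$data) - mean(a$data)) / sd(raw)
  expect_equal(mean(z[[2]]$data) - mean(z[[1]]$data), want_gap,
               tolerance = 1e-12)
  expect_error(zscore_participant(make_epochs(matrix(1, 2, 10))),
               "distinct")
})

test_that("baseline correction zeroes the pre-onset window mean", {
  fs <- 100
  n <- 750
  time <- -2 + (0:(n - 1)) / fs
  # constant epochs go to zero
  ep <- epoch_set(matrix(5, 3, n), time, condition = rep("HL", 3))
  bc <- baseline_correct(ep)
  expect_true(all(bc$data == 0))
  # ramp x(t) = t: subtracts the discrete mean of t over [-0.2, 0)
  ramp <- epoch_set(matrix(time, 1, n, byrow = TRUE), time)
  bcr <- baseline_correct(ramp)
  win <- time[time >= -0.2 & time < 0]
  expect_equal(bcr$data[1, ], time - mean(win), tolerance = 1e-12)
  # and the window mean is the analytic midpoint of the sampled ramp
  expect_equal(mean(win), (-0.2 + -0.01) / 2, tolerance = 1e-12)
  # post-hoc baseline mean is 0 for every trial
  idx <- which(time >= -0.2 & time < 0)
  expect_lt(max(abs(rowMeans(bcr$data[, idx, drop = FALSE]))), 1e-12)
})

test_that("condition means match a direct summation oracle", {
  set.seed(6)
  data <- rbind(matrix(0, 2, 50), matrix(2, 2, 50),
                matrix(rnorm(3 * 50), 3, 50))
  cond <- c("A", "A", "B", "B", "C", "C", "C")
  ep <- make_epochs(data, condition = cond)
  cm <- condition_mean(ep)
  expect_equal(unname(cm["A", ]), rep(0, 50))
  expect_equal(unname(cm["B", ]), rep(2, 50))
  oracle <- colSums(data[5:7, ]) / 3
  expect_equal(unname(cm["C", ]), oracle, tolerance = 1e-12)
  expect_equal(attr(cm, "n")[["C"]], 3L)
  # two trials {0-trace, 2-trace} average to the constant 1
  half <- condition_mean(make_epochs(rbind(rep(0, 50), rep(2, 50)),
                                     condition = c("A", "A")))
  expect_equal(unname(half["A", ]), rep(1, 50))
})

test_that("group means average participants with equal weight", {
  t1 <- matrix(c(0, 0, 4, 4), 2, 2, byrow = TRUE,
               dimnames = list(c("HL", "LL"), NULL))
  t2 <- matrix(c(2, 2, 0, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("HL", "LL"), NULL))
  attr(t1, "time") <- attr(t2, "time") <- c(0, 0.001)
  g <- group_mean(list(t1, t2))
  expect_equal(unname(g["HL", ]), c(1, 1))
  expect_equal(unname(g["LL", ]), c(2, 2))
  # rows are aligned by label even when participants' row order differs
  # (counterbalanced block order)
  t3 <- t2[c("LL", "HL"), ]
  attr(t3, "time") <- c(0, 0.001)
  g2 <- group_mean(list(t1, t3))
  expect_equal(g2, g)
  expect_error(group_mean(list(t1, t1[1, , drop = FALSE])), "labels")
})

test_that("pd_peak finds the programmed bump and applies the tie rule", {
  fs <- 1000
  time <- -2 + (0:7499) / fs
  bump <- exp(-((time - 3.0)^2) / 0.5)
  pk <- pd_peak(bump, time, window = c(0, 5.4))
  expect_lt(abs(pk$latency - 3.0), 1.5 / fs)
  # monotone trace peaks at the window end
  mono <- pd_peak(time, time, window = c(0, 5))
  expect_equal(mono$latency, 5)
  # constant trace: earliest time wins
  flat <- pd_peak(rep(1, length(time)), time, window = c(1, 4))
  expect_equal(flat$latency, 1)
})

test_that("the load effect is the mean HL-LL difference over 2-5 s", {
  fs <- 1000
  time <- -2 + (0:7499) / fs
  ll <- rep(0.2, length(time))
  expect_equal(pd_load_effect(ll, ll, time), 0)
  expect_equal(pd_load_effect(ll + 0.4, ll, time), 0.4)
  # effect of 0.3 confined to [2, 4): direct summation oracle
  hl <- ll + 0.3 * (time >= 2 & time < 4)
  idx <- which(time >= 2 & time <= 5)
  oracle <- sum(hl[idx] - ll[idx]) / length(idx)
  expect_equal(pd_load_effect(hl, ll, time), oracle, tolerance = 1e-15)
  expect_equal(oracle, 0.3 * 2000 / 3001, tolerance = 1e-12)
})

test_that("missing-data incidence matches injected blink ground truth", {
  data <- matrix(0, 10, 100)
  missing <- matrix(FALSE, 10, 100)
  ep <- make_epochs(data, condition = rep("HL", 10), missing = missing)
  expect_true(all(blink_rate(ep) == 0))
  missing[c(2, 7), 40] <- TRUE
  ep2 <- make_epochs(data, condition = rep("HL", 10), missing = missing)
  expect_equal(unname(blink_rate(ep2)[40]), 0.2)
  # synthetic blinks: incidence peaks where the generator put them
  set.seed(12)
  cfg <- tiny_config(blink_rate = 60, n_trials_per_condition = 10)
  sim <- simulate_participant(cfg, "P01")
  rec <- mask_fixation_breaks(sim$recording)
  ep3 <- epoch_by_events(rec, sim$trials$onset_s,
                         condition = sim$trials$condition)
  inc <- blink_rate(ep3)
  gt <- sim$blinks
  rel_mid <- (gt$start + gt$end) / 2 -
    sim$trials$onset_s[match(gt$trial, sim$trials$trial)]
  rel_mid <- rel_mid[rel_mid >= -2 & rel_mid < 5.5]
  time <- attr(inc, "time")
  at_blinks <- vapply(rel_mid, function(t) inc[which.min(abs(time - t))],
                      numeric(1))
  expect_true(all(at_blinks >= 1 / nrow(ep3$data)))
})

test_that("the full chain equals a straight-line oracle on a small fixture", {
  set.seed(21)
  fs <- 100
  n <- 750
  nt <- 8
  data <- matrix(rnorm(nt * n, mean = 3), nt, n)
  missing <- matrix(runif(nt * n) < 0.05, nt, n)
  data[missing] <- NA
  cond <- rep(c("HL", "LL"), each = nt / 2)
  ep <- make_epochs(data, fs = fs, condition = cond, missing = missing)

  got <- clean_epochs(ep)$epochs
  got_z <- zscore_participant(got)
  got_bc <- baseline_correct(got_z)
  got_cm <- condition_mean(got_bc)

  # independently coded straight line: drop sparse, interpolate, drop
  # outliers, z-score, baseline, average
  keep <- rowMeans(missing) <= 0.5
  d <- data[keep, , drop = FALSE]
  m <- missing[keep, , drop = FALSE]
  cnd <- cond[keep]
  for (i in seq_len(nrow(d))) {
    ok <- which(!m[i, ])
    d[i, ] <- approx(ok, d[i, ok], xout = seq_len(n), rule = 2)$y
  }
  ofrac <- numeric(nrow(d))
  for (cc in unique(cnd)) {
    r <- which(cnd == cc)
    mu <- colMeans(d[r, , drop = FALSE])
    s <- apply(d[r, , drop = FALSE], 2, sd)
    for (i in r) ofrac[i] <- mean(abs(d[i, ] - mu) > 3 * s)
  }
  d <- d[ofrac < 0.10, , drop = FALSE]
  cnd <- cnd[ofrac < 0.10]
  d <- (d - mean(d)) / sd(d)
  tm <- -2 + (0:(n - 1)) / fs
  bwin <- which(tm >= -0.2 & tm < 0)
  d <- d - rowMeans(d[, bwin, drop = FALSE])
  for (cc in unique(cnd)) {
    expect_equal(unname(got_cm[cc, ]),
                 unname(colMeans(d[cnd == cc, , drop = FALSE])),
                 tolerance = 1e-12)
  }
})
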