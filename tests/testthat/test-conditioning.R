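make_ts <- function(data, tr = 2) roi_timeseries(data, "s1", tr_seconds = tr)

test_that("volume discarding removes leading time points and nothing else", {
  ts <- make_ts(matrix(seq_len(5 * 240), 5, 240))
  out <- discard_initial_volumes(ts, 4)
  expect_equal(ncol(out$data), 236)
  expect_identical(out$data, ts$data[, 5:240])
  expect_identical(out$node_ids, ts$node_ids)
  expect_identical(discard_initial_volumes(ts, 0), ts)
  short <- make_ts(matrix(rnorm(10), 2, 5))
  expect_error(discard_initial_volumes(short, 5), "discard")
})

test_that("framewise displacement follows the backward-difference definition", {
  m0 <- motion_params(matrix(0.5, 10, 6))
  expect_equal(framewise_displacement(m0), rep(0, 10))

  m <- matrix(0, 10, 6)
  m[6:10, 1] <- 1                       # single 1 mm x-translation step
  fd <- framewise_displacement(motion_params(m))
  expect_equal(fd[6], 1.0)
  expect_equal(fd[-6], rep(0, 9))

  m2 <- matrix(0, 10, 6)
  m2[4:10, 5] <- 0.02                   # 0.02 rad step about one axis
  fd2 <- framewise_displacement(motion_params(m2), head_radius_mm = 50)
  expect_equal(fd2[4], 1.0)             # 50 mm * 0.02 rad

  # invariance to a constant offset on all rows
  shift <- sweep(m, 2, c(3, -1, 2, 0.1, 0.2, -0.3), "+")
  expect_equal(framewise_displacement(motion_params(shift)), fd)
})

test_that("high-motion exclusion partitions the cohort at the mean-FD threshold", {
  man <- data.frame(subject_id = sprintf("s%02d", 1:62))
  fd <- setNames(rep(0.33, 62), man$subject_id)
  fd[c(5, 17, 40, 61)] <- c(1.2, 1.01, 2.5, 1.6)
  part <- exclude_high_motion(man, fd, threshold_mm = 1)
  expect_equal(nrow(part$retained), 58)
  expect_setequal(part$excluded$subject_id, c("s05", "s17", "s40", "s61"))
  expect_match(part$excluded$reason[1], "mean FD")

  all_in <- exclude_high_motion(man, fd, threshold_mm = Inf)
  expect_equal(nrow(all_in$retained), 62)

  expect_error(exclude_high_motion(man, fd[-3], threshold_mm = 1), "s03")
})

test_that("Friston-24 expansion has the documented layout", {
  set.seed(1)
  p <- matrix(rnorm(60), 10, 6)
  f <- friston24(motion_params(p))
  expect_equal(ncol(f), 24)
  expect_equal(unname(f[, 1:6]), p)
  expect_equal(unname(f[, 7:12]), p^2)
  expect_equal(unname(f[1, 13:24]), rep(0, 12))
  expect_equal(unname(f[2:10, 13:18]), p[1:9, ])
  expect_equal(unname(f[2:10, 19:24]), p[1:9, ]^2)
  expect_equal(friston24(motion_params(matrix(0, 8, 6))),
               matrix(0, 8, 24), ignore_attr = TRUE)
})

test_that("nuisance regression yields residuals orthogonal to the design", {
  set.seed(2)
  ts <- make_ts(matrix(rnorm(6 * 80), 6, 80))
  # intercept-only = demeaning
  demeaned <- nuisance_regress(ts, NULL)
  expect_equal(demeaned$data, sweep(ts$data, 1, rowMeans(ts$data)),
               tolerance = 1e-12)
  # a node equal to a regressor is annihilated
  reg <- matrix(rnorm(80 * 3), 80, 3)
  ts2 <- make_ts(rbind(reg[, 1], ts$data[-1, ]))
  out2 <- nuisance_regress(ts2, reg)
  expect_lt(max(abs(out2$data[1, ])), 1e-10)
  # orthogonality of residuals to every regressor column
  out <- nuisance_regress(ts, reg)
  ip <- crossprod(reg, t(out$data))
  expect_lt(max(abs(ip)) / max(abs(ts$data)), 1e-8)
  # idempotence
  out_again <- nuisance_regress(out, reg)
  expect_equal(out_again$data, out$data, tolerance = 1e-10)
  # rank-deficient design proceeds with a warning
  expect_warning(nuisance_regress(ts, cbind(reg, reg[, 1])), "rank deficient")
  expect_error(nuisance_regress(ts, reg[1:40, ]), "match")
})

test_that("band-pass keeps the passband and suppresses DC and the stopband", {
  tr <- 2
  t_sec <- (0:299) * tr
  const <- make_ts(matrix(5, 3, 300), tr)
  out_const <- bandpass(const, 0.01, 0.10)
  expect_lt(max(abs(out_const$data)), 1e-8)

  mid <- 101:200                         # avoid filter edge transients
  s_pass <- sin(2 * pi * 0.05 * t_sec)
  out_pass <- bandpass(make_ts(rbind(s_pass, s_pass), tr), 0.01, 0.10)
  amp_ratio <- max(abs(out_pass$data[1, mid])) / max(abs(s_pass[mid]))
  expect_gt(amp_ratio, 0.95)
  expect_lt(amp_ratio, 1.05)

  s_stop <- sin(2 * pi * 0.2 * t_sec)
  out_stop <- bandpass(make_ts(rbind(s_stop, s_stop), tr), 0.01, 0.10)
  expect_lt(max(abs(out_stop$data[1, mid])) / max(abs(s_stop[mid])), 0.2)

  expect_error(bandpass(const, 0.01, 0.3), "Nyquist")
  expect_error(bandpass(const, 0.2, 0.1), "invalid")
})

test_that("the conditioning chain preserves node count and order", {
  set.seed(3)
  ts <- roi_timeseries(matrix(rnorm(8 * 240), 8, 240), "s1", 2,
                       node_ids = sprintf("roi_%d", 8:1))
  mot <- motion_params(matrix(rnorm(240 * 6, 0, 0.01), 240, 6))
  nuis <- matrix(rnorm(240 * 3), 240, 3)
  out <- condition_timeseries(ts, motion = mot, nuisance = nuis)
  expect_equal(out$node_ids, ts$node_ids)
  expect_equal(nrow(out$data), 8)
  expect_equal(ncol(out$data), 236)
  out2 <- condition_timeseries(ts, motion = mot, nuisance = nuis,
                               order = "filter_first")
  expect_equal(out2$node_ids, ts$node_ids)
  expect_error(condition_timeseries(ts, motion = motion_params(
    matrix(0, 100, 6))), "match")
})
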