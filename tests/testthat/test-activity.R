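test_that("clock times map onto the circle", {
  expect_equal(event_times(c(0, 6, 12, 18)), c(0, pi / 2, pi, 3 * pi / 2))
  ts <- as.POSIXct("2014-07-01 06:00:00", tz = "UTC")
  expect_equal(event_times(ts), pi / 2)
  expect_true(all(event_times(runif(50, 0, 48)) < 2 * pi))
})

test_that("circular KDE integrates to one and respects symmetry", {
  set.seed(60)
  x <- rvonmises(400, pi, 2)
  f <- fit_circular_kde(x)
  h <- diff(f$grid)
  expect_equal(sum((f$values[-length(f$values)] + f$values[-1]) / 2 * h), 1,
               tolerance = 1e-6)
  expect_equal(f$values[1], f$values[length(f$values)])
  # a sample symmetric about pi gives a density symmetric about pi
  xs <- c(x, (2 * pi - x) %% (2 * pi))
  fs <- fit_circular_kde(xs, grid_n = 256)
  expect_equal(fs$values, rev(fs$values), tolerance = 1e-8)
  expect_error(fit_circular_kde(1.0), "at least 2")
})

test_that("the KDE is consistent for a von Mises target", {
  set.seed(61)
  x <- rvonmises(10000, pi, 2)
  f <- fit_circular_kde(x)
  true <- exp(2 * cos(f$grid - pi)) / (2 * pi * besselI(2, 0))
  expect_lt(max(abs(f$values - true)), 0.02)
})

test_that("self-overlap is one and disjoint clusters are near zero", {
  set.seed(62)
  x <- rvonmises(200, 1, 3)
  expect_equal(overlap_delta1(x, x), 1, tolerance = 1e-9)
  a <- rvonmises(300, 0, 200)
  b <- rvonmises(300, pi, 200)
  expect_lt(overlap_delta1(a, b), 0.05)
})

test_that("overlap is symmetric and rotation-invariant", {
  set.seed(63)
  a <- rvonmises(150, 0.7, 2)
  b <- rvonmises(180, 2.5, 1.5)
  expect_equal(overlap_delta1(a, b), overlap_delta1(b, a), tolerance = 1e-12)
  for (rot in c(0.5, 2, 4)) {
    expect_equal(overlap_delta1((a + rot) %% (2 * pi), (b + rot) %% (2 * pi)),
                 overlap_delta1(a, b), tolerance = 0.02)
  }
})

test_that("the estimator tracks the true overlap as separation grows", {
  seps <- c(0.5, 1.5, 2.8)
  true <- vapply(seps, function(d) oracle_vm_overlap(0, 4, d, 4), 0)
  expect_true(all(diff(true) < 0))
  set.seed(64)
  est <- vapply(seps, function(d) {
    overlap_delta1(rvonmises(3000, 0, 4), rvonmises(3000, d, 4))
  }, 0)
  expect_true(all(diff(est) < 0))
  expect_lt(max(abs(est - true)), 0.05)
})

test_that("overlap estimate is close to the quadrature oracle at large n", {
  set.seed(65)
  a <- rvonmises(5000, 0, 4)
  b <- rvonmises(5000, pi / 2, 4)
  expect_lt(abs(overlap_delta1(a, b) - oracle_vm_overlap(0, 4, pi / 2, 4)),
            0.03)
})

test_that("bootstrap intervals bracket the estimate and are seeded", {
  set.seed(66)
  a <- rvonmises(60, 0.5, 2)
  b <- rvonmises(80, 2.0, 2)
  e1 <- bootstrap_ci(a, b, n_boot = 150, seed = 3, grid_n = 128)
  e2 <- bootstrap_ci(a, b, n_boot = 150, seed = 3, grid_n = 128)
  expect_identical(e1[c("delta", "ci_low", "ci_high")],
                   e2[c("delta", "ci_low", "ci_high")])
  expect_lte(e1$ci_low, e1$delta)
  expect_gte(e1$ci_high, e1$delta)
  expect_true(e1$ci_low >= 0 && e1$ci_high <= 1)
  expect_equal(c(e1$n1, e1$n2), c(60, 80))
})

test_that("von Mises sampler concentrates at its mean direction", {
  set.seed(67)
  x <- rvonmises(4000, 2.2, 3)
  cm <- atan2(mean(sin(x)), mean(cos(x)))
  expect_lt(abs(cm - 2.2), 3 * 1 / sqrt(4000 * 0.8))
  # extreme concentration behaves as a point mass
  xx <- rvonmises(100, 1.0, 1e6)
  expect_lt(max(abs(xx - 1.0)), 0.01)
})

test_that("conditional overlap partitions sites and reports the table shape", {
  # history: conditioning species detected only at sites P1, P2
  sites <- c("P1", "P2", "A1", "A2")
  y <- array(0L, c(4, 2, 3), dimnames = list(sites, c("focal", "cond"), NULL))
  y[c(1, 2), 2, 1] <- 1L
  t0 <- as.POSIXct("2014-07-01 00:00:00", tz = "UTC")
  mk <- function(site, hours, cat) {
    data.frame(site_id = site, category = cat, timestamp = t0 + hours * 3600)
  }
  hrs <- c(5, 6, 7, 8, 9, 10, 18, 20)
  ev <- rbind(mk("P1", hrs, "focal"), mk("A1", hrs, "focal"),
              mk("P2", c(11, 13, 15, 17, 12, 14, 16, 19), "cond"))
  tab <- conditional_overlap(ev, y, "focal", "cond", "cond",
                             n_boot = 120, seed = 1, grid_n = 128)
  expect_identical(tab$subset, c("present", "absent"))
  expect_identical(names(tab), c("focal", "conditioning", "versus", "subset",
                                 "delta", "ci_low", "ci_high", "n"))
  expect_equal(tab$n, c(8, 8))
  # identical focal event times in both subsets: identical point estimates
  expect_equal(tab$delta[1], tab$delta[2], tolerance = 1e-12)
  # too-small subsets are reported as missing with their n
  ev2 <- ev[!(ev$site_id == "A1"), ]
  tab2 <- conditional_overlap(ev2, y, "focal", "cond", "cond",
                              n_boot = 120, seed = 1, grid_n = 128)
  expect_true(is.na(tab2$delta[tab2$subset == "absent"]))
  expect_equal(tab2$n[tab2$subset == "absent"], 0)
})

test_that("a planted activity shift at co-occupied sites lowers overlap there", {
  set.seed(68)
  sites <- c(sprintf("P%d", 1:6), sprintf("A%d", 1:6))
  y <- array(0L, c(12, 2, 3), dimnames = list(sites, c("focal", "cond"), NULL))
  y[1:6, 2, 1] <- 1L
  t0 <- as.POSIXct("2014-07-01 00:00:00", tz = "UTC")
  ref_hours <- (rvonmises(300, pi, 3)) / (2 * pi) * 24      # reference: midday
  shifted <- (rvonmises(120, 0, 3)) / (2 * pi) * 24         # focal flips to midnight
  aligned <- (rvonmises(120, pi, 3)) / (2 * pi) * 24
  ev <- rbind(
    data.frame(site_id = sample(sites[1:6], 120, TRUE), category = "focal",
               timestamp = t0 + shifted * 3600),
    data.frame(site_id = sample(sites[7:12], 120, TRUE), category = "focal",
               timestamp = t0 + aligned * 3600),
    data.frame(site_id = sample(sites, 300, TRUE), category = "cond",
               timestamp = t0 + ref_hours * 3600))
  tab <- conditional_overlap(ev, y, "focal", "cond", "cond",
                             n_boot = 120, seed = 2, grid_n = 128)
  expect_lt(tab$delta[tab$subset == "present"],
            tab$delta[tab$subset == "absent"])
})
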