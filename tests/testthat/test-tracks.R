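ballistic_tracks <- function(v = 3, dt = 0.5, n = 60, m = 4) {
  do.call(rbind, lapply(seq_len(m), function(i) {
    tt <- (0:(n - 1)) * dt
    th <- i  # arbitrary fixed direction per track
    data.frame(cell_id = i, time = tt, x = v * tt * cos(th),
               y = v * tt * sin(th), z = 0)
  }))
}

test_that("MSD is exact for ballistic and stationary motion", {
  tr <- ballistic_tracks(v = 3)
  m <- compute_msd(tr)
  expect_equal(m$msd, 9 * m$lag^2, tolerance = 1e-12)
  f <- suppressWarnings(fit_msd_exponent(m))
  expect_equal(f$alpha, 2, tolerance = 1e-3)
  expect_lt(f$se, 1e-3)
  still <- data.frame(cell_id = 1, time = 0:20, x = 2, y = 3, z = 0)
  expect_true(all(compute_msd(still)$msd == 0))
})

test_that("MSD slope of a lattice random walk is one", {
  set.seed(4)
  n <- 3000; m <- 100
  steps_x <- matrix(sample(c(-1, 0, 1), n * m, TRUE), n, m)
  steps_y <- matrix(sample(c(-1, 0, 1), n * m, TRUE), n, m)
  tr <- data.frame(cell_id = rep(1:m, each = n + 1),
                   time = rep(0:n, m),
                   x = as.vector(apply(rbind(0, steps_x), 2, cumsum)),
                   y = as.vector(apply(rbind(0, steps_y), 2, cumsum)),
                   z = 0)
  f <- fit_msd_exponent(compute_msd(tr, max_lag = n / 4))
  expect_equal(f$alpha, 1, tolerance = 0.05)
})

test_that("MSD is invariant under rigid motions and unit rescaling", {
  set.seed(8)
  tr <- gen_persistent_tracks(n_tracks = 5, n_frames = 80, seed = 8)
  m0 <- compute_msd(tr)
  th <- 0.83
  tr2 <- tr
  tr2$x <- cos(th) * tr$x - sin(th) * tr$y + 17
  tr2$y <- sin(th) * tr$x + cos(th) * tr$y - 5
  m2 <- compute_msd(tr2)
  expect_equal(m0$msd, m2$msd, tolerance = 1e-10)
  # rescaling time and space leaves the exponent unchanged
  tr3 <- tr
  tr3$time <- tr$time * 60; tr3$x <- tr$x * 1000; tr3$y <- tr$y * 1000
  f0 <- fit_msd_exponent(compute_msd(tr))
  f3 <- fit_msd_exponent(compute_msd(tr3))
  expect_equal(f0$alpha, f3$alpha, tolerance = 1e-9)
})

test_that("direction autocorrelation handles canonical geometries", {
  # straight line: 1 at every lag
  tr <- data.frame(cell_id = 1, time = 0:30, x = 2 * (0:30), y = 0, z = 0)
  pc <- direction_autocorr(tr, max_lag = 10)
  expect_true(all(abs(pc$cos_mean - 1) < 1e-12))
  # right-angle zig-zag: orthogonal headings at odd lags
  n <- 40
  dx <- rep(c(1, 0), n / 2); dy <- rep(c(0, 1), n / 2)
  tr <- data.frame(cell_id = 1, time = 0:n, x = cumsum(c(0, dx)),
                   y = cumsum(c(0, dy)), z = 0)
  pc <- direction_autocorr(tr, max_lag = 4)
  expect_equal(pc$cos_mean[pc$lag == 1], 0)
  expect_equal(pc$cos_mean[pc$lag == 2], 1)
  # isotropic headings: zero within sampling error, bounded by one
  set.seed(2)
  m <- 50; n <- 200
  th <- matrix(runif(n * m, 0, 2 * pi), n, m)
  tr <- data.frame(cell_id = rep(1:m, each = n + 1), time = rep(0:n, m),
                   x = as.vector(apply(rbind(0, cos(th)), 2, cumsum)),
                   y = as.vector(apply(rbind(0, sin(th)), 2, cumsum)), z = 0)
  pc <- direction_autocorr(tr, max_lag = 20)
  expect_equal(pc$cos_mean[pc$lag == 0], 1)
  expect_true(all(abs(pc$cos_mean[pc$lag > 0]) < 0.05))
  expect_true(all(abs(pc$cos_mean) <= 1 + 1e-12))
})

test_that("two-exponential fit inverts noise-free curves exactly", {
  tt <- seq(0.25, 25, by = 0.25)
  y <- 0.14 * exp(-tt / 4.56) + 0.64 * exp(-tt / 0.38)
  f <- fit_two_exponential(data.frame(lag = tt, cos_mean = y))
  expect_equal(f$A, 0.14, tolerance = 1e-6)
  expect_equal(f$tau, 4.56, tolerance = 1e-6)
  expect_equal(f$B, 0.64, tolerance = 1e-6)
  expect_equal(f$tau0, 0.38, tolerance = 1e-6)
  expect_false(f$flagged)
  # broad parameter grid
  set.seed(6)
  for (i in 1:10) {
    A <- runif(1, 0.05, 0.9); B <- runif(1, 0.05, 1 - A)
    tau0 <- runif(1, 0.2, 2); tau <- tau0 * runif(1, 2.2, 40)
    y <- A * exp(-tt / tau) + B * exp(-tt / tau0)
    f <- fit_two_exponential(data.frame(lag = tt, cos_mean = y))
    expect_equal(f$tau, tau, tolerance = 1e-6)
    expect_equal(f$tau0, tau0, tolerance = 1e-6)
  }
})

test_that("two-exponential fit degrades gracefully", {
  tt <- seq(0.25, 25, by = 0.25)
  # nested single-exponential data: B is driven to zero
  y <- 0.8 * exp(-tt / 5)
  f <- fit_two_exponential(data.frame(lag = tt, cos_mean = y))
  slow_amp <- if (f$A >= f$B) f$A else f$B
  expect_equal(slow_amp, 0.8, tolerance = 1e-4)
  expect_equal(f$tau, 5, tolerance = 1e-4)
  expect_lt(min(f$A, f$B), 1e-4)
  # pure noise around zero is flagged as unidentifiable
  set.seed(3)
  yn <- rnorm(length(tt), 0, 0.02)
  fn <- tryCatch(fit_two_exponential(data.frame(lag = tt, cos_mean = yn)),
                 error = function(e) NULL)
  expect_true(is.null(fn) || fn$flagged)
  expect_error(fit_two_exponential(data.frame(lag = 1:5, cos_mean = 1:5 / 10)),
               "at least 8")
})

test_that("radial velocity recovers drift towards a center", {
  # straight inward at 40 um/hr
  tt <- seq(0, 1, by = 0.1)
  tr <- data.frame(cell_id = 1, time = tt, x = 80 - 40 * tt, y = 0, z = 0)
  expect_equal(radial_velocity(tr, c(0, 0))$mean_v, 40, tolerance = 1e-9)
  # circular orbit: constant radius, zero radial velocity
  tr <- data.frame(cell_id = 1, time = tt, x = 50 * cos(tt), y = 50 * sin(tt),
                   z = 0)
  expect_lt(abs(radial_velocity(tr, c(0, 0))$mean_v), 1e-9)
  # noisy inward ensemble at the observed mean speed
  tr <- gen_radial_tracks(v_radial = 38.7, v_sd = 10, n_tracks = 50, seed = 2)
  expect_lt(abs(radial_velocity(tr, c(0, 0))$mean_v - 38.7), 3)
})

test_that("track-table IO validates and round-trips", {
  tr <- gen_persistent_tracks(n_tracks = 3, n_frames = 10, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path)
  tr2 <- read_tracks(path)
  expect_equal(tr2$x, tr$x, tolerance = 1e-9)
  # malformed inputs name the problem
  bad <- tr; bad$x[5] <- "oops"
  pb <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, pb, row.names = FALSE)
  expect_error(read_tracks(pb), "row 5")
  dup <- rbind(tr, tr[1, ])
  pd <- withr::local_tempfile(fileext = ".csv")
  write.csv(dup, pd, row.names = FALSE)
  expect_error(read_tracks(pd), "duplicate")
  nc <- tr[, c("cell_id", "time", "x")]
  pn <- withr::local_tempfile(fileext = ".csv")
  write.csv(nc, pn, row.names = FALSE)
  expect_error(read_tracks(pn), "missing columns")
})

test_that("non-uniform sampling errors or resamples as configured", {
  tr <- data.frame(cell_id = 1, time = c(0, 1, 2, 4, 5, 6, 8, 9),
                   x = 1:8, y = 0, z = 0)
  expect_error(compute_msd(tr), "uniformly")
  m <- compute_msd(tr, on_nonuniform = "resample")
  expect_gt(nrow(m), 3)  # resampled onto a uniform grid
})
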