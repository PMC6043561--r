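test_that("persistent-walk tracks move at exactly speed * dt per frame", {
  tr <- gen_persistent_tracks(speed = 30, dt = 0.25, n_tracks = 4,
                              n_frames = 50, seed = 2)
  for (id in 1:4) {
    sub <- tr[tr$cell_id == id, ]
    d <- sqrt(diff(sub$x)^2 + diff(sub$y)^2)
    expect_equal(d, rep(30 * 0.25, length(d)), tolerance = 1e-12)
  }
})

test_that("persistent-walk ensemble matches its target autocorrelation", {
  tr <- gen_persistent_tracks(A = 0.14, tau = 4.56, B = 0.64, tau0 = 0.38,
                              n_tracks = 250, n_frames = 500, seed = 5)
  pc <- direction_autocorr(tr, max_lag = 5 * 4.56)
  tgt <- 0.14 * exp(-pc$lag / 4.56) + 0.64 * exp(-pc$lag / 0.38)
  sel <- pc$lag > 0
  rms <- sqrt(mean((pc$cos_mean[sel] - tgt[sel])^2))
  expect_lt(rms, 0.03)
})

test_that("one-component and ballistic limits behave classically", {
  # B = 0, A = 1: no jitter, single population, plain persistent walk
  tr <- gen_persistent_tracks(A = 1, tau = 3, B = 0, tau0 = 0.5,
                              n_tracks = 300, n_frames = 300, seed = 7)
  pc <- direction_autocorr(tr, max_lag = 6)
  sel <- pc$lag > 0
  expect_lt(sqrt(mean((pc$cos_mean[sel] - exp(-pc$lag[sel] / 3))^2)), 0.03)
  # tau -> infinity: essentially straight tracks, MSD slope 2
  tr <- gen_persistent_tracks(A = 1, tau = 1e9, B = 0, tau0 = 0.5,
                              n_tracks = 10, n_frames = 100, seed = 3)
  f <- suppressWarnings(fit_msd_exponent(compute_msd(tr)))
  expect_equal(f$alpha, 2, tolerance = 1e-3)
})

test_that("generator parameter validation rejects impossible inputs", {
  expect_error(gen_persistent_tracks(A = 0.6, B = 0.6), "A \\+ B")
  expect_error(gen_persistent_tracks(tau = 0.1, tau0 = 0.4), "tau")
  expect_error(gen_fbm_tracks(H = 0), "H must")
  expect_error(gen_fbm_tracks(H = 1.2), "H must")
})

test_that("fGn increments carry the exact analytic autocovariance", {
  # the covariance the Cholesky construction realizes equals the
  # closed-form fGn autocovariance
  H <- 0.71; n <- 64
  G <- stats::toeplitz(sencluster:::fgn_autocov(0:(n - 1), H, 1.3))
  L <- t(chol(G))
  expect_lt(max(abs(L %*% t(L) - G)), 1e-8)
  expect_equal(sencluster:::fgn_autocov(1, 0.5), 0)   # Brownian: independent
  expect_equal(sencluster:::fgn_autocov(0, 0.5), 1)
  expect_equal(sencluster:::fgn_autocov(1, 0.71),
               0.5 * (2^1.42 - 2), tolerance = 1e-12)
})

test_that("fBm displacement variance scales as k^{2H}", {
  H <- 0.71
  tr <- gen_fbm_tracks(H, n_tracks = 150, n_frames = 600, seed = 4)
  x <- matrix(tr$x, nrow = 600)
  v1 <- var(as.vector(x[-1, ] - x[-600, ]))
  for (k in c(2, 4, 8)) {
    vk <- var(as.vector(x[-(1:k), ] - x[1:(600 - k), ]))
    expect_equal(vk / v1, k^(2 * H), tolerance = 0.05)
  }
  # Brownian special case recovers slope one
  tr <- gen_fbm_tracks(0.5, n_tracks = 100, n_frames = 400, seed = 4)
  f <- fit_msd_exponent(compute_msd(tr))
  expect_equal(f$alpha, 1, tolerance = 0.05)
})

test_that("generators are deterministic under a fixed seed", {
  a <- gen_persistent_tracks(n_tracks = 5, n_frames = 20, seed = 12)
  b <- gen_persistent_tracks(n_tracks = 5, n_frames = 20, seed = 12)
  expect_identical(a, b)
  c <- gen_persistent_tracks(n_tracks = 5, n_frames = 20, seed = 13)
  expect_false(identical(a, c))
  a <- gen_fbm_tracks(0.6, n_tracks = 3, n_frames = 50, seed = 1)
  b <- gen_fbm_tracks(0.6, n_tracks = 3, n_frames = 50, seed = 1)
  expect_identical(a, b)
})

test_that("initial lattice realizes the layout at both scales", {
  connected <- function(grid, id) {
    w <- which(grid == id, arr.ind = TRUE)
    if (nrow(w) == 1) return(TRUE)
    dims <- dim(grid)
    lin <- function(m) (m[, 3] - 1) * dims[1] * dims[2] +
      (m[, 2] - 1) * dims[1] + m[, 1]
    idx <- lin(w)
    seen <- rep(FALSE, length(idx))
    names(seen) <- idx
    queue <- idx[1]; seen[1] <- TRUE
    set <- new.env(parent = emptyenv())
    for (i in idx) assign(as.character(i), FALSE, envir = set)
    assign(as.character(idx[1]), TRUE, envir = set)
    count <- 1L
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      z <- (cur - 1) %/% (dims[1] * dims[2])
      rem <- (cur - 1) %% (dims[1] * dims[2])
      y <- rem %/% dims[1]; x <- rem %% dims[1]
      for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        xx <- (x + d[1]) %% dims[1]; yy <- (y + d[2]) %% dims[2]
        zz <- z + d[3]
        if (zz < 0 || zz >= dims[3]) next
        nb <- zz * dims[1] * dims[2] + yy * dims[1] + xx + 1
        key <- as.character(nb)
        ex <- mget(key, envir = set, ifnotfound = NA)[[1]]
        if (isFALSE(ex)) {
          assign(key, TRUE, envir = set)
          queue <- c(queue, nb)
          count <- count + 1L
        }
      }
    }
    count == nrow(w)
  }

  cfg <- reduced_config()
  set.seed(1)
  st <- gen_initial_lattice(cfg)
  tab <- table(st$cells$type)
  expect_equal(as.integer(tab[c("1", "2", "3", "4")]), c(1L, 12L, 6L, 1L))
  con <- st$cells$type %in% 1:3
  expect_true(all(abs(st$cells$vol[con] / st$cells$Vt[con] - 1) <= 0.1))
  # substrate floor intact and one site thick
  expect_true(all(st$grid[, , 1] == st$cells$id[st$cells$type == 4]))
  expect_true(all(st$grid[, , 2] != st$cells$id[st$cells$type == 4]))
  # every cell starts simply connected
  for (id in st$cells$id[st$cells$type %in% 1:3])
    expect_true(connected(st$grid, id))
  # founder clocks are strictly positive and asynchronous
  nd <- st$cells$next_div[st$cells$type == 3]
  expect_true(all(nd > 0) && length(unique(nd)) == 6)

  # full published scale: 1 core, 48 body, 20 tumor on 200 x 200 x 50
  set.seed(1)
  stf <- gen_initial_lattice(sim_config())
  tabf <- table(stf$cells$type)
  expect_equal(as.integer(tabf[c("1", "2", "3")]), c(1L, 48L, 20L))
  conf <- stf$cells$type %in% 1:3
  expect_true(all(abs(stf$cells$vol[conf] / stf$cells$Vt[conf] - 1) <= 0.1))

  # a layout that cannot fit errors out before any run
  tiny <- reduced_config(grid = list(Lx = 24L, Ly = 24L, Lz = 20L))
  expect_error({set.seed(1); gen_initial_lattice(tiny)}, "fit|place")
})
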