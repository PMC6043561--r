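#' Generate two-population persistent random-walk tracks
#'
#' Constant-speed 2D walkers whose ensemble heading autocorrelation
#' follows the two-tiered exponential `A exp(-t/tau) + B exp(-t/tau0)`.
#' The curve is realized as a population mixture: a fraction `A/(A+B)`
#' of tracks decorrelate with the slow constant `tau` and the rest with
#' `tau0` (headings evolve by Gaussian angular increments of variance
#' `2 dt / tau_i`), plus independent per-frame angular jitter whose
#' amplitude is solved from `1 - (A + B)` - the instantaneous
#' decorrelation implied by the fitted amplitudes summing below one.
#' The per-frame displacement magnitude is exactly `speed * dt`; only
#' the heading is ever jittered.
#'
#' @param A,tau,B,tau0 target autocorrelation parameters (`A + B <= 1`,
#'   `tau > tau0 > 0`); defaults are the fitted values for tumor cells
#'   percolating in a confluent monolayer (times in hours).
#' @param speed walker speed (um/hr).
#' @param dt frame interval (hr).
#' @param n_tracks,n_frames ensemble size and frames per track.
#' @param seed RNG seed.
#' @return A track table (`cell_id`, `time`, `x`, `y`, `z`), z = 0.
#' @export
gen_persistent_tracks <- function(A = 0.14, tau = 4.56, B = 0.64,
                                  tau0 = 0.38, speed = 30, dt = 0.25,
                                  n_tracks = 200, n_frames = 500,
                                  seed = 1) {
  if (A < 0 || B < 0 || A + B > 1) stop("need A, B >= 0 and A + B <= 1")
  if (!(tau > tau0 && tau0 > 0)) stop("need tau > tau0 > 0")
  if (speed <= 0 || dt <= 0) stop("speed and dt must be positive")
  set.seed(seed)
  nsteps <- n_frames - 1L
  slow <- runif(n_tracks) < A / (A + B)
  tau_i <- ifelse(slow, tau, tau0)
  # accumulated heading: Wiener angle with Var = 2 dt / tau_i per step
  dphi <- matrix(rnorm(nsteps * n_tracks), nsteps, n_tracks) *
    rep(sqrt(2 * dt / tau_i), each = nsteps)
  phi0 <- matrix(runif(n_tracks, 0, 2 * pi), nsteps, n_tracks, byrow = TRUE)
  phi <- apply(dphi, 2, cumsum) + phi0
  # per-frame jitter: E[cos eps] = sqrt(A + B) gives the lag-0+ drop
  sig_j <- sqrt(max(0, -log(A + B)))
  if (sig_j > 0)
    phi <- phi + matrix(rnorm(nsteps * n_tracks, sd = sig_j), nsteps, n_tracks)
  step <- speed * dt
  x <- apply(rbind(0, step * cos(phi)), 2, cumsum)
  y <- apply(rbind(0, step * sin(phi)), 2, cumsum)
  data.frame(cell_id = rep(seq_len(n_tracks), each = n_frames),
             time = rep((0:nsteps) * dt, n_tracks),
             x = as.vector(x), y = as.vector(y), z = 0)
}

# autocovariance of fractional Gaussian noise at integer lag k
fgn_autocov <- function(k, H, scale = 1) {
  k <- abs(k)
  scale^2 / 2 * (abs(k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
}

#' Generate fractional Brownian motion tracks
#'
#' Exact fractional Gaussian noise increments per axis from the
#' stationary increment covariance
#' `gamma(k) = scale^2/2 (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})`,
#' realized by multiplying i.i.d. Gaussians with the Cholesky factor of
#' the increment covariance matrix. The ensemble mean-squared
#' displacement grows exactly as `k^{2H}` in the frame lag, so the
#' anomalous exponent of the construction is `2H`: H = 0.5 is Brownian,
#' H = 0.71 reproduces the super-diffusive exponent 1.42 observed for
#' tumor cells in a confluent monolayer.
#'
#' @param H Hurst exponent in (0, 1).
#' @param n_tracks,n_frames ensemble size and frames per track.
#' @param dt frame interval (hr).
#' @param scale per-frame increment scale (um).
#' @param seed RNG seed.
#' @return A track table (`cell_id`, `time`, `x`, `y`, `z`), z = 0.
#' @export
gen_fbm_tracks <- function(H, n_tracks = 200, n_frames = 1000,
                           dt = 0.25, scale = 1, seed = 1) {
  if (!(H > 0 && H < 1)) stop("H must lie in (0, 1)")
  set.seed(seed)
  n <- n_frames - 1L
  L <- t(chol(stats::toeplitz(fgn_autocov(0:(n - 1), H, scale))))
  z <- matrix(rnorm(n * 2L * n_tracks), n, 2L * n_tracks)
  incr <- L %*% z
  x <- apply(rbind(0, incr[, seq_len(n_tracks), drop = FALSE]), 2, cumsum)
  y <- apply(rbind(0, incr[, n_tracks + seq_len(n_tracks), drop = FALSE]),
             2, cumsum)
  data.frame(cell_id = rep(seq_len(n_tracks), each = n_frames),
             time = rep((0:n) * dt, n_tracks),
             x = as.vector(x), y = as.vector(y), z = 0)
}

#' Generate noisy inward-drifting tracks
#'
#' Tracks drifting towards a center at a given mean radial speed with
#' Gaussian heading and speed noise - a construction for exercising
#' [radial_velocity()] on an ensemble with known ground truth.
#'
#' @param center attractor position (x, y).
#' @param v_radial mean inward speed (um/hr).
#' @param v_sd per-track sd of the inward speed (um/hr).
#' @param r0 starting radius (um).
#' @param dt frame interval (hr).
#' @param n_tracks,n_frames ensemble size and frames per track.
#' @param seed RNG seed.
#' @return A track table.
#' @export
gen_radial_tracks <- function(center = c(0, 0), v_radial = 38.7,
                              v_sd = 10, r0 = 80, dt = 0.1,
                              n_tracks = 50, n_frames = 15, seed = 1) {
  set.seed(seed)
  rows <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    th <- runif(1, 0, 2 * pi)
    v <- rnorm(1, v_radial, v_sd)
    tt <- (0:(n_frames - 1)) * dt
    r <- r0 - v * tt
    jit <- matrix(rnorm(2 * n_frames, sd = 0.5), ncol = 2)
    rows[[i]] <- data.frame(cell_id = i, time = tt,
                            x = center[1] + r * cos(th) + jit[, 1],
                            y = center[2] + r * sin(th) + jit[, 2],
                            z = 0)
  }
  do.call(rbind, rows)
}
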