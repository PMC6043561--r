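#' Read and write cell-track tables
#'
#' A track table is a CSV with header `cell_id,time,x,y,z`: time-stamped
#' 3D centroid positions, one row per cell per frame, uniformly sampled
#' within each track. `read_tracks()` validates the table and reports
#' the offending row on failure.
#'
#' @param path file path.
#' @return A data frame with columns `cell_id`, `time`, `x`, `y`, `z`.
#' @export
read_tracks <- function(path) {
  tr <- tryCatch(read.csv(path), error = function(e)
    stop("cannot parse track table '", path, "': ", conditionMessage(e)))
  needed <- c("cell_id", "time", "x", "y", "z")
  missing_cols <- setdiff(needed, names(tr))
  if (length(missing_cols))
    stop("track table is missing columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("time", "x", "y", "z")) {
    v <- suppressWarnings(as.numeric(tr[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("track table row ", bad[1], ": non-numeric '", col, "' value")
    tr[[col]] <- v
  }
  ord <- order(tr$cell_id, tr$time)
  tr <- tr[ord, , drop = FALSE]
  for (id in unique(tr$cell_id)) {
    tt <- tr$time[tr$cell_id == id]
    if (anyDuplicated(tt))
      stop("track ", id, ": duplicate time stamps")
    if (any(diff(tt) <= 0))
      stop("track ", id, ": times not strictly increasing")
  }
  rownames(tr) <- NULL
  tr
}

#' @rdname read_tracks
#' @param tracks a track table data frame.
#' @export
write_tracks <- function(tracks, path) {
  cols <- intersect(c("cell_id", "time", "x", "y", "z"), names(tracks))
  write.csv(tracks[, cols], path, row.names = FALSE)
  invisible(path)
}

# split a track table into per-track coordinate matrices after checking
# uniform sampling; returns list(dt, tracks = list of matrices [n x k])
prepare_tracks <- function(tracks, use_z = FALSE,
                           on_nonuniform = c("error", "resample")) {
  on_nonuniform <- match.arg(on_nonuniform)
  cols <- if (use_z) c("x", "y", "z") else c("x", "y")
  ids <- unique(tracks$cell_id)
  dts <- numeric(0)
  parts <- list()
  for (id in ids) {
    sub <- tracks[tracks$cell_id == id, , drop = FALSE]
    sub <- sub[order(sub$time), , drop = FALSE]
    if (nrow(sub) < 2) next
    d <- diff(sub$time)
    if (max(d) - min(d) > 1e-6 * max(d)) {
      if (on_nonuniform == "error")
        stop("track ", id, " is not uniformly sampled; ",
             "set on_nonuniform = \"resample\" to interpolate")
      dt0 <- median(d)
      tt <- seq(min(sub$time), max(sub$time), by = dt0)
      sub2 <- data.frame(time = tt)
      for (cl in cols) sub2[[cl]] <- approx(sub$time, sub[[cl]], tt)$y
      sub <- sub2
      d <- diff(tt)
    }
    dts <- c(dts, d[1])
    parts[[as.character(id)]] <- as.matrix(sub[, cols, drop = FALSE])
  }
  if (length(parts) == 0) stop("no track with at least 2 samples")
  if (max(dts) - min(dts) > 1e-6 * max(dts))
    stop("tracks have different sampling intervals")
  list(dt = dts[1], tracks = parts)
}

#' Ensemble mean-squared displacement
#'
#' Time-and-ensemble averaged squared displacement over all overlapping
#' sample pairs at each lag, pooled across tracks. By default only the
#' in-plane coordinates (x, y) enter, matching 2D phase-contrast
#' imaging; set `use_z = TRUE` for 3D tracks.
#'
#' @param tracks a track table (see [read_tracks()]).
#' @param max_lag largest lag (time units); default half the shortest
#'   track duration.
#' @param use_z include z displacements?
#' @param on_nonuniform `"error"` or `"resample"` for non-uniformly
#'   sampled tracks.
#' @return A data frame of class `msd_curve` with columns `lag`, `msd`,
#'   `sd` (per-lag spread of the pair samples) and `n` (pair count);
#'   attributes `dt`, `n_tracks` and `track_T` (shortest track
#'   duration).
#' @export
compute_msd <- function(tracks, max_lag = NULL, use_z = FALSE,
                        on_nonuniform = c("error", "resample")) {
  pr <- prepare_tracks(tracks, use_z, on_nonuniform)
  dt <- pr$dt
  lens <- vapply(pr$tracks, nrow, integer(1))
  track_T <- (min(lens) - 1) * dt
  if (is.null(max_lag)) max_lag <- track_T / 2
  kmax <- max(1L, min(as.integer(floor(max_lag / dt)), max(lens) - 1L))
  s1 <- s2 <- nn <- numeric(kmax)
  for (m in pr$tracks) {
    n <- nrow(m)
    for (k in seq_len(min(kmax, n - 1L))) {
      d2 <- rowSums((m[(1 + k):n, , drop = FALSE] -
                     m[1:(n - k), , drop = FALSE])^2)
      s1[k] <- s1[k] + sum(d2)
      s2[k] <- s2[k] + sum(d2^2)
      nn[k] <- nn[k] + length(d2)
    }
  }
  msd <- ifelse(nn > 0, s1 / nn, NA_real_)
  v <- ifelse(nn > 1, pmax(0, (s2 - nn * msd^2) / (nn - 1)), NA_real_)
  out <- data.frame(lag = c(0, seq_len(kmax) * dt),
                    msd = c(0, msd), sd = c(0, sqrt(v)), n = c(NA, nn))
  out <- out[!is.na(out$msd), , drop = FALSE]
  attr(out, "dt") <- dt
  attr(out, "n_tracks") <- length(pr$tracks)
  attr(out, "track_T") <- track_T
  class(out) <- c("msd_curve", class(out))
  out
}

#' Fit the anomalous-diffusion exponent
#'
#' Ordinary least squares of `log(msd)` on `log(lag)` within the fit
#' range. The slope is the anomalous exponent alpha: 1 for simple
#' diffusion, 2 for ballistic motion, between 1 and 2 for
#' super-diffusion.
#'
#' @param msd an `msd_curve` from [compute_msd()].
#' @param fit_range lag interval `c(lo, hi)`; the default is
#'   `[2 frames, T/4]`, avoiding short-lag noise and the
#'   statistics-starved long-lag tail.
#' @return A list with `alpha`, `se`, `intercept` (log prefactor),
#'   `n_lags` and `fit_range`.
#' @export
fit_msd_exponent <- function(msd, fit_range = NULL) {
  dt <- attr(msd, "dt") %||% min(msd$lag[msd$lag > 0])
  track_T <- attr(msd, "track_T") %||% max(msd$lag)
  if (is.null(fit_range)) fit_range <- c(2 * dt, track_T / 4)
  sel <- msd$lag >= fit_range[1] - 1e-9 & msd$lag <= fit_range[2] + 1e-9
  bad <- sel & msd$msd <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive MSD value(s) excluded from the fit")
    sel <- sel & msd$msd > 0
  }
  if (sum(sel) < 5) stop("fewer than 5 usable lags in the fit range")
  fit <- lm(log(msd$msd[sel]) ~ log(msd$lag[sel]))
  cf <- summary(fit)$coefficients
  list(alpha = unname(cf[2, 1]), se = unname(cf[2, 2]),
       intercept = unname(cf[1, 1]), n_lags = sum(sel),
       fit_range = fit_range)
}

#' Directional persistence autocorrelation
#'
#' The heading at time s is the unit vector of the displacement over
#' `[s, s + heading_step]`. The curve value at lag t is the mean, over
#' cells and start times, of the cosine of the angle between headings
#' separated by t; its per-lag spread is returned alongside. Headings of
#' zero-length displacements are undefined and those samples are
#' skipped.
#'
#' @param tracks a track table.
#' @param max_lag largest lag (time units); default one fifth of the
#'   shortest track duration.
#' @param heading_step displacement window defining a heading (time
#'   units); default one frame interval.
#' @param use_z include z in headings?
#' @param on_nonuniform see [compute_msd()].
#' @return A data frame of class `persistence_curve` with columns `lag`,
#'   `cos_mean`, `sd`, `n`; lag 0 is 1 by construction.
#' @export
direction_autocorr <- function(tracks, max_lag = NULL, heading_step = NULL,
                               use_z = FALSE,
                               on_nonuniform = c("error", "resample")) {
  pr <- prepare_tracks(tracks, use_z, on_nonuniform)
  dt <- pr$dt
  if (is.null(heading_step)) heading_step <- dt
  s <- max(1L, as.integer(round(heading_step / dt)))
  lens <- vapply(pr$tracks, nrow, integer(1))
  if (min(lens) <= s) stop("tracks too short for the heading step")
  track_T <- (min(lens) - 1) * dt
  if (is.null(max_lag)) max_lag <- track_T / 5
  kmax <- max(1L, min(as.integer(floor(max_lag / dt)),
                      max(lens) - s - 1L))
  headings <- lapply(pr$tracks, function(m) {
    n <- nrow(m)
    u <- m[(1 + s):n, , drop = FALSE] - m[1:(n - s), , drop = FALSE]
    len <- sqrt(rowSums(u^2))
    u <- u / len
    u[len == 0, ] <- NA_real_
    u
  })
  s1 <- s2 <- nn <- numeric(kmax + 1)
  for (u in headings) {
    n <- nrow(u)
    for (k in 0:min(kmax, n - 1L)) {
      cosv <- rowSums(u[1:(n - k), , drop = FALSE] *
                      u[(1 + k):n, , drop = FALSE])
      cosv <- cosv[!is.na(cosv)]
      s1[k + 1] <- s1[k + 1] + sum(cosv)
      s2[k + 1] <- s2[k + 1] + sum(cosv^2)
      nn[k + 1] <- nn[k + 1] + length(cosv)
    }
  }
  cm <- ifelse(nn > 0, s1 / nn, NA_real_)
  v <- ifelse(nn > 1, pmax(0, (s2 - nn * cm^2) / (nn - 1)), NA_real_)
  out <- data.frame(lag = (0:kmax) * dt, cos_mean = cm, sd = sqrt(v), n = nn)
  out <- out[!is.na(out$cos_mean), , drop = FALSE]
  attr(out, "dt") <- dt
  attr(out, "heading_step") <- s * dt
  attr(out, "n_tracks") <- length(pr$tracks)
  class(out) <- c("persistence_curve", class(out))
  out
}

#' Fit a two-tiered exponential to a persistence curve
#'
#' Nonlinear least squares of `A exp(-t/tau) + B exp(-t/tau0)` to the
#' heading autocorrelation at lags t > 0, under the constraints
#' `A, B >= 0` and `tau > tau0 > 0`. Fitting is multi-start (a fixed
#' grid of time-constant pairs plus data-adaptive starts); among
#' converged fits the best residual satisfying the identifiability
#' condition `tau >= 2 tau0` wins. When the curve extends far beyond the
#' slow time constant, a second pass refits on the signal-bearing window
#' `t <= window_factor * tau` of the first pass: beyond a few slow time
#' constants the model is below the sampling noise and those lags only
#' add noise-driven bias to `tau`. The reported directional persistence
#' time is `tau`, the slow component.
#'
#' @param curve a `persistence_curve` from [direction_autocorr()], or
#'   any data frame with `lag` and `cos_mean` columns.
#' @param window_factor self-consistent truncation of the fit window, in
#'   units of the fitted slow time constant; `Inf` disables the second
#'   pass.
#' @return A list of class `two_exp_fit` with `A`, `tau`, `B`, `tau0`,
#'   standard errors `se`, `resid_norm`, `converged` (any start
#'   converged), and `flagged` (TRUE when no identifiable fit was found
#'   or the slow time constant is not resolved, e.g. on pure noise).
#' @export
fit_two_exponential <- function(curve, window_factor = 2.5) {
  t0_all <- curve$lag
  y0_all <- curve$cos_mean
  keep <- t0_all > 0 & is.finite(y0_all)
  t0_all <- t0_all[keep]; y0_all <- y0_all[keep]
  if (length(t0_all) < 8) stop("need at least 8 positive-lag points to fit")
  first <- fit_two_exponential_once(t0_all, y0_all)
  win <- window_factor * first$p$tau
  sel <- t0_all <= win
  if (is.finite(win) && sum(sel) >= 8 && sum(!sel) > 0) {
    second <- tryCatch(fit_two_exponential_once(t0_all[sel], y0_all[sel]),
                       error = function(e) NULL)
    if (!is.null(second)) first <- second
  }
  finish_two_exp_fit(first)
}

fit_two_exponential_once <- function(t, y) {
  tmax <- max(t)
  tau0_starts <- unique(c(0.1, 0.5, 1, min(t), 0.05 * tmax))
  tau_starts <- unique(c(2, 5, 10, 0.25 * tmax, 0.5 * tmax))
  dat <- data.frame(t = t, y = y)
  best <- NULL; best_any <- NULL
  n_conv <- 0L
  for (t0s in tau0_starts) {
    for (ts in tau_starts) {
      if (ts <= t0s) next
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ A * exp(-t / tau) + B * exp(-t / tau0),
                          data = dat,
                          start = list(A = 0.5, B = 0.5, tau = ts, tau0 = t0s),
                          lower = c(A = 0, B = 0, tau = 1e-8, tau0 = 1e-8),
                          control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (is.null(fit)) next
      n_conv <- n_conv + 1L
      p <- as.list(coef(fit))
      if (p$tau < p$tau0) {  # enforce the slow/fast labelling
        p <- list(A = p$B, B = p$A, tau = p$tau0, tau0 = p$tau)
        swapped <- TRUE
      } else swapped <- FALSE
      rn <- sqrt(sum(residuals(fit)^2))
      cand <- list(p = p, rn = rn, fit = fit, swapped = swapped)
      if (is.null(best_any) || rn < best_any$rn) best_any <- cand
      if (p$tau >= 2 * p$tau0 && (is.null(best) || rn < best$rn))
        best <- cand
    }
  }
  if (n_conv == 0L)
    stop("two-exponential fit failed to converge from every start")
  use <- if (is.null(best)) best_any else best
  use$flagged <- is.null(best)
  use$n_conv <- n_conv
  use
}

finish_two_exp_fit <- function(use) {
  flagged <- use$flagged
  se <- tryCatch({
    s <- sqrt(diag(vcov(use$fit)))
    if (use$swapped) s <- s[c("B", "A", "tau0", "tau")]
    setNames(as.numeric(s), c("A", "B", "tau", "tau0"))
  }, error = function(e) setNames(rep(NA_real_, 4), c("A", "B", "tau", "tau0")))
  if (is.finite(se[["tau"]]) && se[["tau"]] > abs(use$p$tau)) flagged <- TRUE
  structure(list(A = use$p$A, tau = use$p$tau, B = use$p$B,
                 tau0 = use$p$tau0, se = se, resid_norm = use$rn,
                 converged = TRUE, flagged = flagged,
                 n_converged_starts = use$n_conv),
            class = "two_exp_fit")
}

#' @export
print.two_exp_fit <- function(x, ...) {
  cat(sprintf("two-tiered exponential fit: A e^(-t/tau) + B e^(-t/tau0)\n"))
  cat(sprintf("  A    = %.4f   tau  = %.4f (slow; persistence time)\n",
              x$A, x$tau))
  cat(sprintf("  B    = %.4f   tau0 = %.4f (fast)\n", x$B, x$tau0))
  cat(sprintf("  residual norm %.4g%s\n", x$resid_norm,
              if (x$flagged) "  [flagged: not identifiable]" else ""))
  invisible(x)
}

#' Mean radial velocity towards a center
#'
#' For each track, the radial distance to the center is regressed on
#' time; the track's radial velocity is minus the slope, so positive
#' values mean inward motion. Tracks with fewer than two samples are
#' skipped.
#'
#' @param tracks a track table.
#' @param center the attractor position, length 2 (x, y) or 3 (x, y, z) -
#'   typically the senescent-core centroid.
#' @return A list with `mean_v` (um per time unit) and a per-track data
#'   frame `per_track`.
#' @export
radial_velocity <- function(tracks, center) {
  if (!length(center) %in% c(2, 3)) stop("center must have length 2 or 3")
  ids <- unique(tracks$cell_id)
  vs <- numeric(0); used <- numeric(0)
  for (id in ids) {
    sub <- tracks[tracks$cell_id == id, , drop = FALSE]
    if (nrow(sub) < 2) next
    sub <- sub[order(sub$time), , drop = FALSE]
    r <- sqrt((sub$x - center[1])^2 + (sub$y - center[2])^2 +
                if (length(center) == 3) (sub$z - center[3])^2 else 0)
    slope <- coef(lm(r ~ sub$time))[2]
    vs <- c(vs, -unname(slope))
    used <- c(used, id)
  }
  if (length(vs) == 0) stop("no track with at least 2 samples")
  list(mean_v = mean(vs),
       per_track = data.frame(cell_id = used, v_radial = vs))
}
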