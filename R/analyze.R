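#' Run the full motility-statistics pipeline on a track table
#'
#' Computes the ensemble MSD and its anomalous exponent, the directional
#' persistence autocorrelation and its two-tiered exponential fit, and -
#' when an attractor center is supplied - the mean radial velocity
#' towards it.
#'
#' @param tracks a track table data frame, or a path to a track CSV.
#' @param center optional attractor position (x, y) or (x, y, z).
#' @param use_z include z in the displacement statistics?
#' @param heading_step heading window for [direction_autocorr()].
#' @param msd_fit_range lag interval for [fit_msd_exponent()].
#' @param max_lag largest autocorrelation lag.
#' @return A list of class `track_report` with elements `msd`,
#'   `msd_fit`, `persistence`, `persistence_fit`, `radial` (or NULL)
#'   and `n_tracks`.
#' @export
analyze_tracks <- function(tracks, center = NULL, use_z = FALSE,
                           heading_step = NULL, msd_fit_range = NULL,
                           max_lag = NULL) {
  if (is.character(tracks)) tracks <- read_tracks(tracks)
  msd <- compute_msd(tracks, use_z = use_z)
  msd_fit <- fit_msd_exponent(msd, fit_range = msd_fit_range)
  pers <- direction_autocorr(tracks, max_lag = max_lag,
                             heading_step = heading_step, use_z = use_z)
  pers_fit <- fit_two_exponential(pers)
  radial <- if (!is.null(center)) radial_velocity(tracks, center) else NULL
  structure(list(msd = msd, msd_fit = msd_fit, persistence = pers,
                 persistence_fit = pers_fit, radial = radial,
                 n_tracks = length(unique(tracks$cell_id))),
            class = "track_report")
}

#' @export
print.track_report <- function(x, ...) {
  cat(sprintf("track report (%d tracks)\n", x$n_tracks))
  cat(sprintf("  MSD exponent alpha = %.3f +/- %.3f (lags %.3g..%.3g)\n",
              x$msd_fit$alpha, x$msd_fit$se,
              x$msd_fit$fit_range[1], x$msd_fit$fit_range[2]))
  cat(sprintf("  persistence: A = %.3f, tau = %.3f, B = %.3f, tau0 = %.3f%s\n",
              x$persistence_fit$A, x$persistence_fit$tau,
              x$persistence_fit$B, x$persistence_fit$tau0,
              if (x$persistence_fit$flagged) " [flagged]" else ""))
  if (!is.null(x$radial))
    cat(sprintf("  mean radial velocity = %.2f (positive = inward)\n",
                x$radial$mean_v))
  invisible(x)
}

#' Write a track report to disk
#'
#' Exports the curves as CSV and the fitted parameters as JSON.
#'
#' @param report a `track_report` from [analyze_tracks()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_analysis <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(report$msd), file.path(dir, "msd.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(report$persistence),
            file.path(dir, "persistence.csv"), row.names = FALSE)
  fits <- list(
    msd = report$msd_fit,
    persistence = report$persistence_fit[c("A", "tau", "B", "tau0",
                                           "resid_norm", "flagged")],
    radial = if (!is.null(report$radial)) list(mean_v = report$radial$mean_v),
    n_tracks = report$n_tracks)
  jsonlite::write_json(fits, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
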