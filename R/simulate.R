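#' Run a full simulation
#'
#' Executes the complete loop from a configuration: build the initial
#' layout, pre-equilibrate the chemoattractant field for the configured
#' burn-in, then per Monte Carlo step run the copy attempts, advance the
#' field, and service the division clock (mitotic-rounding adhesion
#' updates and cell splits). Tumor-cell centroid tracks (periodic
#' coordinates unwrapped to continuous paths), division events, an
#' energy/acceptance log and cluster metrics of the final state are
#' returned and optionally written to a run directory.
#'
#' All randomness flows from `config$run$seed`: identical configurations
#' give identical outputs.
#'
#' @param config a [sim_config()] or [reduced_config()].
#' @param out_dir optional directory; when given, `tracks.csv`,
#'   `events.csv`, `energy.csv`, `metrics.json` and the resolved
#'   `config.yaml` are written there (and labelled TIFF snapshot stacks
#'   when snapshots were taken and the tiff package is installed).
#' @return A list with `state` (final [cpm_state()]), `tracks`,
#'   `events`, `energy`, `metrics` (see [cluster_metrics()]),
#'   `snapshots`, and the resolved `config`.
#' @export
run_simulation <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$run$seed)
  state <- gen_initial_lattice(config)
  if (config$field$burn_in > 0)
    state <- step_field(state, config$field, n_seconds = config$field$burn_in)
  res <- mcs_step(state, config$energy,
                  n_mcs = config$run$n_mcs, seed = config$run$seed,
                  cycle = config$cycle, field = config$field,
                  divisions = TRUE,
                  track_every = config$run$track_every,
                  snapshot_every = config$run$snapshot_every,
                  stop_after_events = config$run$stop_after_events %||% 0)
  tracks <- unwrap_tracks(res$tracks,
                          Lx = config$grid$Lx * config$grid$spacing,
                          Ly = config$grid$Ly * config$grid$spacing)
  metrics <- cluster_metrics(res$state)
  out <- list(state = res$state, tracks = tracks, events = res$events,
              energy = res$energy, metrics = metrics,
              snapshots = res$snapshots, config = config)
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unwrap periodic track coordinates
#'
#' Centroids logged on a periodic lattice jump by the box length when a
#' cell crosses the x or y boundary. This maps each track to a
#' continuous path by accumulating minimal-image frame-to-frame
#' displacements, which is what the displacement statistics require.
#'
#' @param tracks data frame with `cell_id`, `time`, `x`, `y` (and
#'   optionally more columns, preserved).
#' @param Lx,Ly physical box lengths (um).
#' @return The track table with `x` and `y` unwrapped.
#' @export
unwrap_tracks <- function(tracks, Lx, Ly) {
  if (nrow(tracks) == 0) return(tracks)
  unwrap1 <- function(v, L) {
    d <- diff(v)
    d <- (d + L / 2) %% L - L / 2
    v[1] + c(0, cumsum(d))
  }
  for (id in unique(tracks$cell_id)) {
    i <- which(tracks$cell_id == id)
    i <- i[order(tracks$time[i])]
    tracks$x[i] <- unwrap1(tracks$x[i], Lx)
    tracks$y[i] <- unwrap1(tracks$y[i], Ly)
  }
  tracks
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$tracks, file.path(out_dir, "tracks.csv"), row.names = FALSE)
  write.csv(run$events, file.path(out_dir, "events.csv"), row.names = FALSE)
  write.csv(run$energy, file.path(out_dir, "energy.csv"), row.names = FALSE)
  jsonlite::write_json(run$metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- rapply(unclass(run$config), unclass, how = "replace")
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  if (length(run$snapshots) > 0 && requireNamespace("tiff", quietly = TRUE)) {
    sidecar <- run$state$cells[, c("id", "type", "gen")]
    sidecar$type <- TYPE_NAMES[sidecar$type + 1L]
    jsonlite::write_json(sidecar, file.path(out_dir, "cells.json"),
                         auto_unbox = TRUE, digits = NA)
    for (k in seq_along(run$snapshots)) {
      sn <- run$snapshots[[k]]
      pages <- lapply(seq_len(dim(sn$grid)[3]),
                      function(z) sn$grid[, , z] / 65535)
      tiff::writeTIFF(pages,
                      file.path(out_dir, sprintf("grid_t%06d.tif", as.integer(sn$t))),
                      bits.per.sample = 16)
      om <- sn$omega
      den <- max(om, 1e-12)
      pages <- lapply(seq_len(dim(om)[3]), function(z) om[, , z] / den)
      tiff::writeTIFF(pages,
                      file.path(out_dir, sprintf("omega_t%06d.tif", as.integer(sn$t))),
                      bits.per.sample = 16)
    }
  }
  invisible(out_dir)
}

#' Inter-division intervals from a division-event log
#'
#' Computes the time between a cell's birth and its own division, for
#' every division event whose parent was itself born during the run.
#' Founder cells are excluded: their clocks start at uniformly random
#' phases (asynchronous seeding), so their first division times are not
#' full cycle lengths.
#'
#' @param events a division-event table with columns `time`, `parent`,
#'   `daughter` (as produced by [run_simulation()]).
#' @return Numeric vector of inter-division intervals (s).
#' @export
division_intervals <- function(events) {
  if (nrow(events) == 0) return(numeric(0))
  events <- events[order(events$time), , drop = FALSE]
  birth <- new.env(parent = emptyenv())
  out <- numeric(0)
  for (i in seq_len(nrow(events))) {
    p <- as.character(events$parent[i])
    d <- as.character(events$daughter[i])
    if (!is.null(birth[[p]])) out <- c(out, events$time[i] - birth[[p]])
    birth[[p]] <- events$time[i]
    birth[[d]] <- events$time[i]
  }
  out
}

#' Cluster metrics of a lattice state
#'
#' Quantifies 3D cluster formation on top of the senescent core: the
#' number of tumor cells whose centroid lies within the core's x-y
#' footprint and above the body's median top surface, the tallest
#' contiguous tumor-occupied z-extent over that footprint, and whether a
#' cluster has formed (at least two tumor cells on the core).
#'
#' @param state a [cpm_state()] containing exactly one core cell.
#' @return A list with `n_cells_on_core`, `max_stack_height` (in um),
#'   `cluster_formed`, and `body_top_median` (site units).
#' @export
cluster_metrics <- function(state) {
  cells <- state$cells
  core_ids <- cells$id[cells$type == TYPE_CODES[["core"]]]
  if (length(core_ids) != 1) stop("state must contain exactly one core cell")
  grid <- state$grid
  dims <- dim(grid)
  typev <- c(0L, cells$type)
  core_mask <- grid == core_ids
  footprint <- apply(core_mask, c(1, 2), any)
  body_ids <- cells$id[cells$type == TYPE_CODES[["body"]]]
  body_mask <- array(grid %in% body_ids, dims)
  body_cols <- apply(body_mask, c(1, 2), any)
  if (any(body_cols)) {
    top_z <- apply(body_mask, c(1, 2), function(col) {
      w <- which(col)
      if (length(w)) max(w) else NA_integer_
    })
    z_med <- median(top_z[body_cols], na.rm = TRUE)
  } else {
    z_med <- 1
  }
  tumor_ids <- cells$id[cells$type == TYPE_CODES[["tumor"]] & cells$vol > 0]
  n_on <- 0L
  for (id in tumor_ids) {
    ctr <- periodic_centroid(grid, id)
    cx <- ((round(ctr[1]) - 1) %% dims[1]) + 1
    cy <- ((round(ctr[2]) - 1) %% dims[2]) + 1
    if (footprint[cx, cy] && ctr[3] > z_med) n_on <- n_on + 1L
  }
  tumor_mask <- array(grid %in% tumor_ids, dims)
  max_stack <- 0L
  fp_idx <- which(footprint, arr.ind = TRUE)
  for (k in seq_len(nrow(fp_idx))) {
    col <- tumor_mask[fp_idx[k, 1], fp_idx[k, 2], ]
    if (any(col)) {
      r <- rle(col)
      max_stack <- max(max_stack, max(r$lengths[r$values]))
    }
  }
  list(n_cells_on_core = n_on,
       max_stack_height = max_stack * state$spacing,
       cluster_formed = n_on >= 2L,
       body_top_median = z_med)
}

# periodic (circular-mean) centroid of a cell, in 1-based site units
periodic_centroid <- function(grid, id) {
  dims <- dim(grid)
  w <- which(grid == id, arr.ind = TRUE)
  if (nrow(w) == 0) return(c(NA_real_, NA_real_, NA_real_))
  circ <- function(v, L) {
    a <- 2 * pi * (v - 1) / L
    m <- atan2(mean(sin(a)), mean(cos(a))) / (2 * pi) * L
    (m %% L) + 1
  }
  c(circ(w[, 1], dims[1]), circ(w[, 2], dims[2]), mean(w[, 3]))
}
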