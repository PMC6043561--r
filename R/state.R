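#' Construct a cellular Potts lattice state
#'
#' Bundles the integer cell-id grid, the per-cell records, and the
#' chemoattractant field into one state object. Site `(x, y, z)` of
#' `grid` holds the id of the cell occupying it; id 0 is the culture
#' medium. Cell ids must be the consecutive integers `1..nrow(cells)`.
#'
#' @param grid 3D integer array of cell ids.
#' @param cells data frame with columns `id`, `type` (code or name:
#'   medium/core/body/tumor/matrix), `Vt` (target volume, um^3), `Pt`
#'   (target surface, um^2), `t0` (division onset, s; -1 when never
#'   divided), `gen` (generation counter), `next_div` (scheduled division
#'   time, s; `Inf` for non-dividing types).
#' @param omega 3D numeric array of chemoattractant concentration, or
#'   `NULL` for a zero field.
#' @param spacing physical length of one lattice unit (um).
#' @param t current simulation time (s).
#' @return An object of class `cpm_state`. Cached per-cell volumes and
#'   surfaces (columns `vol`, `surf`) are computed from the grid.
#' @export
cpm_state <- function(grid, cells, omega = NULL, spacing = 1, t = 0) {
  if (length(dim(grid)) != 3) stop("grid must be a 3D array")
  storage.mode(grid) <- "integer"
  cells <- as.data.frame(cells)
  needed <- c("id", "type", "Vt", "Pt", "t0", "gen", "next_div")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols))
    stop("cells is missing columns: ", paste(missing_cols, collapse = ", "))
  cells$type <- type_code(cells$type)
  cells <- cells[order(cells$id), , drop = FALSE]
  if (!identical(as.integer(cells$id), seq_len(nrow(cells))))
    stop("cell ids must be the consecutive integers 1..n")
  ids_in_grid <- unique(as.integer(grid))
  if (any(!ids_in_grid %in% c(0L, cells$id)))
    stop("grid holds ids with no cell record")
  absent <- setdiff(cells$id, ids_in_grid)
  if (length(absent))
    stop("cell(s) in records absent from lattice: ", paste(absent, collapse = ", "))
  if (is.null(omega)) {
    omega <- array(0, dim(grid))
  } else {
    if (!identical(dim(omega), dim(grid))) stop("omega must match grid dims")
    if (any(omega < 0)) stop("omega must be non-negative")
  }
  state <- structure(list(grid = grid, cells = cells, omega = omega,
                          spacing = spacing, t = t),
                     class = "cpm_state")
  counts <- cpp_audit(state$grid, dim(state$grid), nrow(cells))
  state$cells$vol <- counts$vol[-1]
  state$cells$surf <- counts$surf[-1]
  state
}

#' @export
print.cpm_state <- function(x, ...) {
  d <- dim(x$grid)
  tn <- TYPE_NAMES[x$cells$type + 1L]
  cat(sprintf("cpm_state: %d x %d x %d lattice (spacing %g um), t = %g s\n",
              d[1], d[2], d[3], x$spacing, x$t))
  print(table(factor(tn, levels = TYPE_NAMES)))
  invisible(x)
}

# linear 1-based index of a 1-based (x, y, z) site
site_index <- function(dims, xyz) {
  xyz <- as.integer(xyz)
  if (length(xyz) != 3 || any(xyz < 1) || any(xyz > dims))
    stop("site out of grid: (", paste(xyz, collapse = ", "), ")")
  ((xyz[3] - 1L) * dims[2] + (xyz[2] - 1L)) * dims[1] + xyz[1]
}

# flatten per-cell records into the argument list the compiled core expects
cell_cols <- function(state) {
  cells <- state$cells
  list(type = as.integer(cells$type), Vt = as.numeric(cells$Vt),
       Pt = as.numeric(cells$Pt), t0 = as.numeric(cells$t0),
       gen = as.integer(cells$gen), next_div = as.numeric(cells$next_div))
}

# per-cell rounding factors exp(-(t - t0)/tau), zero outside the window
rounding_factors <- function(cells, t, cycle) {
  dt <- t - cells$t0
  active <- cells$type == TYPE_CODES[["tumor"]] & cells$t0 >= 0 &
    dt >= 0 & dt < cycle$rounding_window
  f_tt <- f_tm <- numeric(nrow(cells))
  f_tt[active] <- exp(-dt[active] / cycle$rounding_tau_tt)
  f_tm[active] <- exp(-dt[active] / cycle$rounding_tau_tm)
  list(tt = f_tt, tm = f_tm)
}

#' Total lattice energy (brute force)
#'
#' Full evaluation of the Hamiltonian: per-cell volume and surface
#' elastic penalties plus the type-pair interface energy summed over
#' every unordered order-2 neighbor pair of unlike cell ids. Volumes and
#' surfaces are recomputed from the grid (6-connectivity for surfaces),
#' never read from caches, so this function serves as the independent
#' oracle for the incremental [delta_h()]. The chemotactic term is a
#' move difference and has no total-energy counterpart.
#'
#' @param state a [cpm_state()].
#' @param params an [energy_params()].
#' @param cycle a [cycle_params()]; governs the mitotic-rounding adhesion
#'   override for tumor-tumor and tumor-matrix pairs.
#' @param t evaluation time (s), defaults to the state's clock.
#' @return Total energy (scalar).
#' @export
total_hamiltonian <- function(state, params, cycle = cycle_params(),
                              t = state$t) {
  grid <- state$grid
  dims <- dim(grid)
  cells <- state$cells
  n <- nrow(cells)
  # volumes and surfaces from scratch
  vol <- tabulate(grid, nbins = n)
  shift3 <- function(g, dx, dy, dz) {
    # periodic in x and y; beyond the z extent there is no site (NA)
    ix <- ((seq_len(dims[1]) - 1L + dx) %% dims[1]) + 1L
    iy <- ((seq_len(dims[2]) - 1L + dy) %% dims[2]) + 1L
    iz <- seq_len(dims[3]) + dz
    out_z <- iz < 1L | iz > dims[3]
    iz[out_z] <- 1L
    s <- g[ix, iy, iz, drop = FALSE]
    if (any(out_z)) s[, , out_z] <- NA_integer_
    s
  }
  face_offsets <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))
  surf <- numeric(n)
  for (off in face_offsets) {
    nb <- shift3(grid, off[1], off[2], off[3])
    exposed <- (is.na(nb) | nb != grid) & grid > 0L
    surf <- surf + tabulate(grid[exposed], nbins = n)
  }
  constrained <- cells$type %in% TYPE_CODES[c("core", "body", "tumor")]
  H <- sum(params$lambda_V * (vol[constrained] - cells$Vt[constrained])^2 +
           params$lambda_P * (surf[constrained] - cells$Pt[constrained])^2)
  # interface term: one representative offset per +/- pair of the 18-stencil
  pos_offsets <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                      c(1, 1, 0), c(1, -1, 0),
                      c(1, 0, 1), c(1, 0, -1),
                      c(0, 1, 1), c(0, 1, -1))
  rf <- rounding_factors(cells, t, cycle)
  sgn <- rounding_sign_code(cycle)
  amp <- cycle$rounding_amplitude
  typev <- c(0L, cells$type)          # id -> type, id 0 = medium
  f_tt <- c(0, rf$tt)
  f_tm <- c(0, rf$tm)
  for (off in pos_offsets) {
    nb <- shift3(grid, off[1], off[2], off[3])
    keep <- !is.na(nb) & nb != grid
    a <- grid[keep]
    b <- nb[keep]
    ta <- typev[a + 1L]
    tb <- typev[b + 1L]
    j <- params$J[cbind(ta + 1L, tb + 1L)]
    both_tumor <- ta == 3L & tb == 3L
    if (any(both_tumor)) {
      f <- pmax(f_tt[a[both_tumor] + 1L], f_tt[b[both_tumor] + 1L])
      j[both_tumor] <- j[both_tumor] + sgn * amp * f
    }
    tum_mat <- (ta == 3L & tb == 4L) | (ta == 4L & tb == 3L)
    if (any(tum_mat)) {
      tum_id <- ifelse(typev[a[tum_mat] + 1L] == 3L, a[tum_mat], b[tum_mat])
      j[tum_mat] <- j[tum_mat] + sgn * amp * f_tm[tum_id + 1L]
    }
    H <- H + sum(j)
  }
  H
}

#' Incremental energy change of one copy attempt
#'
#' Energy difference caused by copying `candidate_id` (the occupant of the
#' neighboring source site) into the target site, computed from the local
#' stencil only. Equals the difference of two [total_hamiltonian()]
#' evaluations for the constraint and interface parts, plus the
#' chemotactic term `mu * (omega(target) - omega(source))` when the
#' extending cell is tumor-typed.
#'
#' @param state a [cpm_state()].
#' @param params an [energy_params()].
#' @param site target site, 1-based `(x, y, z)`.
#' @param src source site (a neighbor of `site`), 1-based `(x, y, z)`.
#' @param candidate_id cell id proposed for the target site.
#' @param cycle a [cycle_params()].
#' @param t evaluation time (s).
#' @return Energy change (scalar); 0 when the candidate equals the
#'   current occupant.
#' @export
delta_h <- function(state, params, site, src, candidate_id,
                    cycle = cycle_params(), t = state$t) {
  dims <- dim(state$grid)
  cc <- cell_cols(state)
  cpp_delta_h(state$grid, state$omega, dims,
              cc$type, cc$Vt, cc$Pt, cc$t0, cc$gen, cc$next_div,
              params$J, params$lambda_V, params$lambda_P, params$mu,
              params$temp, rounding_sign_code(cycle),
              cycle$rounding_amplitude, cycle$rounding_tau_tt,
              cycle$rounding_tau_tm, cycle$rounding_window, t,
              site_index(dims, site), site_index(dims, src),
              as.integer(candidate_id))
}

#' Advance the lattice by Monte Carlo steps
#'
#' One Monte Carlo step (MCS) performs as many copy attempts as there are
#' lattice sites: each attempt draws a random site and a random order-2
#' neighbor, proposes copying the neighbor's cell id into the site, and
#' accepts with the Metropolis probability [p_copy()]. One MCS represents
#' one second of physical time. Substrate (matrix) sites and the fixed
#' top medium plane are never overwritten, substrate is never copied in,
#' and a copy that would erase a cell's last site is rejected. Per-cell
#' volume and surface caches are updated incrementally. Optionally each
#' MCS also advances the chemoattractant field and runs the division
#' clock.
#'
#' @param state a [cpm_state()].
#' @param params an [energy_params()]. `temp = 0` is accepted here as the
#'   zero-temperature limit (only non-positive energy changes accepted).
#' @param n_mcs number of steps.
#' @param seed integer seed for the simulation RNG; identical
#'   (state, seed) pairs give identical trajectories.
#' @param cycle a [cycle_params()].
#' @param field a [field_params()] or `NULL` to keep the field frozen.
#' @param divisions run the tumor division clock?
#' @param track_every log tumor-cell centroids and total energy every
#'   this many MCS (0 = only at start).
#' @param snapshot_every store full grid/field snapshots every this many
#'   MCS (0 = never).
#' @param stop_after_events stop early once this many division events
#'   have been logged (0 = never).
#' @return A list with the updated `state`, `tracks` (t, id, x, y, z,
#'   vol), `events` (t, parent, daughter, x, y, z), `energy` (t, H,
#'   acceptance rate) and `snapshots`.
#' @export
mcs_step <- function(state, params, n_mcs = 1, seed = 1,
                     cycle = cycle_params(), field = NULL,
                     divisions = FALSE, track_every = 0,
                     snapshot_every = 0, stop_after_events = 0) {
  dims <- dim(state$grid)
  cc <- cell_cols(state)
  field_enabled <- !is.null(field)
  if (field_enabled) {
    field <- validate_field(field, D_spacing = state$spacing)
    fp <- field$p; fd <- field$d; fD <- field$D; nsub <- field$n_substeps
  } else {
    fp <- 0; fd <- 0; fD <- 0; nsub <- 1L
  }
  if (params$temp < 0) stop("temperature must be >= 0")
  tumor_Vt <- 400
  tumor_Pt <- target_surface(400, 1.4)
  tum <- state$cells$type == TYPE_CODES[["tumor"]]
  if (any(tum)) {
    tumor_Vt <- state$cells$Vt[which(tum)[1]]
    tumor_Pt <- state$cells$Pt[which(tum)[1]]
  }
  res <- cpp_run(state$grid, state$omega, dims,
                 cc$type, cc$Vt, cc$Pt, cc$t0, cc$gen, cc$next_div,
                 params$J, params$lambda_V, params$lambda_P, params$mu,
                 params$temp, rounding_sign_code(cycle),
                 cycle$rounding_amplitude, cycle$rounding_tau_tt,
                 cycle$rounding_tau_tm, cycle$rounding_window,
                 field_enabled, fp, fd, fD, nsub, state$spacing,
                 cycle$tau_r_mean, cycle$tau_r_sd,
                 as.integer(n_mcs), state$t, as.numeric(seed),
                 as.integer(track_every), as.integer(snapshot_every),
                 isTRUE(divisions), as.integer(stop_after_events),
                 tumor_Vt, tumor_Pt)
  ncell <- length(res$cell_type)
  cells <- data.frame(id = seq_len(ncell), type = res$cell_type,
                      Vt = res$cell_Vt, Pt = res$cell_Pt,
                      t0 = res$cell_t0, gen = res$cell_gen,
                      next_div = res$cell_next_div,
                      vol = res$cell_vol, surf = res$cell_surf)
  new_state <- structure(list(grid = res$grid, cells = cells,
                              omega = res$omega, spacing = state$spacing,
                              t = res$t_end),
                         class = "cpm_state")
  tracks <- as.data.frame(res$tracks)
  names(tracks) <- c("time", "cell_id", "x", "y", "z", "vol")
  tracks <- tracks[, c("cell_id", "time", "x", "y", "z", "vol")]
  events <- as.data.frame(res$events)
  names(events) <- c("time", "parent", "daughter", "x", "y", "z")
  energy <- as.data.frame(res$energy)
  names(energy) <- c("time", "H", "acceptance")
  list(state = new_state, tracks = tracks, events = events,
       energy = energy, snapshots = res$snapshots, n_mcs = res$n_mcs)
}

#' Audit cached volume and surface bookkeeping
#'
#' Recomputes every cell's volume and 6-connectivity surface from the
#' grid and compares them with the cached values carried in the cell
#' records.
#'
#' @param state a [cpm_state()].
#' @return A list with `ok` (all caches exact), and the recomputed `vol`
#'   and `surf` vectors.
#' @export
audit_state <- function(state) {
  counts <- cpp_audit(state$grid, dim(state$grid), nrow(state$cells))
  vol <- counts$vol[-1]
  surf <- counts$surf[-1]
  list(ok = isTRUE(all.equal(vol, state$cells$vol)) &&
         isTRUE(all.equal(surf, state$cells$surf)),
       vol = vol, surf = surf)
}

#' Divide a tumor cell
#'
#' Splits the cell's sites by a vertical plane through its (periodic)
#' centroid whose normal is horizontal with the given azimuth (uniformly
#' random when omitted): the division axis is co-planar with the
#' substrate. One half keeps the parent id, the other becomes a new cell.
#' Both daughters keep the tumor target volume, receive fresh replication
#' clocks drawn with [draw_cycle_length()] (R RNG stream), rounding onset
#' `t0` set to the division time, and the generation counter incremented.
#'
#' @param state a [cpm_state()].
#' @param cell_id id of the dividing cell (must be tumor-typed).
#' @param cycle a [cycle_params()].
#' @param azimuth division-plane normal direction (radians), or `NULL`
#'   for a uniform draw.
#' @return A list with the updated `state`, `parent` and `daughter` ids,
#'   and `deferred = TRUE` when the cell had fewer than 2 sites and the
#'   division was postponed.
#' @export
divide_cell <- function(state, cell_id, cycle = cycle_params(),
                        azimuth = NULL) {
  cells <- state$cells
  if (cells$type[cell_id] != TYPE_CODES[["tumor"]])
    stop("only tumor cells divide")
  if (cells$vol[cell_id] < 2)
    return(list(state = state, parent = cell_id, daughter = NA_integer_,
                deferred = TRUE))
  if (is.null(azimuth)) azimuth <- runif(1, 0, 2 * pi)
  new_id <- nrow(cells) + 1L
  res <- cpp_divide(state$grid, dim(state$grid), as.integer(cell_id),
                    new_id, azimuth)
  daughter <- data.frame(id = new_id, type = TYPE_CODES[["tumor"]],
                         Vt = cells$Vt[cell_id], Pt = cells$Pt[cell_id],
                         t0 = state$t, gen = cells$gen[cell_id] + 1L,
                         next_div = state$t + draw_cycle_length(1, cycle),
                         vol = 0, surf = 0)
  cells$gen[cell_id] <- cells$gen[cell_id] + 1L
  cells$t0[cell_id] <- state$t
  cells$next_div[cell_id] <- state$t + draw_cycle_length(1, cycle)
  cells <- rbind(cells, daughter)
  state$grid <- res$grid
  state$cells <- cells
  counts <- cpp_audit(state$grid, dim(state$grid), nrow(cells))
  state$cells$vol <- counts$vol[-1]
  state$cells$surf <- counts$surf[-1]
  list(state = state, parent = cell_id, daughter = new_id,
       deferred = FALSE)
}
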