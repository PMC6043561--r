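#' Simulation configuration
#'
#' Assembles the full set of named defaults for a simulation run: grid
#' geometry, energy parameters, chemoattractant field, cell-cycle /
#' rounding schedule, initial layout, and run control. The defaults
#' reproduce the published full-scale setup: a 200 x 200 x 50 um grid
#' (1 um spacing, periodic in x and y, substrate bottom, fixed medium
#' top), one senescent core (target volume 1800 um^3, asperity 0.8), 48
#' thin body domains (600 um^3, asperity 0.8) tiling an annulus around
#' the core, 20 tumor cells (400 um^3, asperity 1.4) seeded outside the
#' body, field rates p = 2, d = 0.02, D = 2, temperature 100, and
#' replication period 5000 +/- 1000 s.
#'
#' @param ... named overrides merged (recursively) into the defaults,
#'   e.g. `sim_config(run = list(n_mcs = 100))`.
#' @return An object of class `sim_config`.
#' @seealso [reduced_config()] for the down-scaled scenario used
#'   throughout the tests and examples.
#' @export
sim_config <- function(...) {
  cfg <- list(
    grid = list(Lx = 200L, Ly = 200L, Lz = 50L, spacing = 1),
    energy = energy_params(),
    field = field_params(),
    cycle = cycle_params(rounding_sign = "weakening"),
    init = list(n_body = 48L, n_tumor = 20L,
                V_core = 1800, V_body = 600, V_tumor = 400,
                asp_core = 0.8, asp_body = 0.8, asp_tumor = 1.4,
                core_footprint = 12, body_thickness = 2L, tumor_gap = 2L),
    run = list(n_mcs = 8800L, seed = 1L, track_every = 20L,
               snapshot_every = 0L)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    if (inherits(overrides[[nm]], c("energy_params", "cycle_params",
                                    "field_params"))) {
      cfg[[nm]] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], overrides[[nm]])
    }
  }
  structure(cfg, class = "sim_config")
}

#' Reduced-grid scenario configuration
#'
#' The down-scaled counterpart of the full published setup, sized so a
#' run finishes in well under a minute: a 64 x 64 x 20 um grid with 12
#' body domains and 6 tumor cells (proportionally fewer than the
#' full-scale 48 and 20). All physical parameters - target volumes,
#' asperities, interaction energies, field rates, replication statistics -
#' keep their full-scale values; only the geometry and counts shrink.
#'
#' @param ... named overrides, as in [sim_config()].
#' @return An object of class `sim_config`.
#' @export
reduced_config <- function(...) {
  base <- sim_config(
    grid = list(Lx = 64L, Ly = 64L, Lz = 20L),
    init = list(n_body = 12L, n_tumor = 6L, core_footprint = 10,
                body_thickness = 4L)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(base)) stop("unknown config section: ", nm)
    if (inherits(overrides[[nm]], c("energy_params", "cycle_params",
                                    "field_params"))) {
      base[[nm]] <- overrides[[nm]]
    } else {
      base[[nm]] <- utils::modifyList(base[[nm]], overrides[[nm]])
    }
  }
  base
}

#' Read a simulation configuration from YAML
#'
#' Reconstructs a [sim_config()] from a YAML file of the form written to
#' a run directory by [run_simulation()] (`config.yaml`), so a run can be
#' reproduced or modified from its recorded configuration.
#'
#' @param path YAML file path.
#' @return An object of class `sim_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  needed <- c("grid", "energy", "field", "cycle", "init", "run")
  missing_s <- setdiff(needed, names(y))
  if (length(missing_s))
    stop("config file is missing sections: ", paste(missing_s, collapse = ", "))
  J <- matrix(unlist(y$energy$J), 5, 5,
              dimnames = list(TYPE_NAMES, TYPE_NAMES))
  en <- energy_params(J = J, lambda_V = y$energy$lambda_V,
                      lambda_P = y$energy$lambda_P, mu = y$energy$mu,
                      temp = y$energy$temp,
                      neighborhood_order = y$energy$neighborhood_order)
  cy <- cycle_params(tau_r_mean = y$cycle$tau_r_mean,
                     tau_r_sd = y$cycle$tau_r_sd,
                     rounding_amplitude = y$cycle$rounding_amplitude,
                     rounding_tau_tt = y$cycle$rounding_tau_tt,
                     rounding_tau_tm = y$cycle$rounding_tau_tm,
                     resting_J_tt = y$cycle$resting_J_tt,
                     resting_J_tm = y$cycle$resting_J_tm,
                     rounding_sign = y$cycle$rounding_sign,
                     rounding_window = y$cycle$rounding_window)
  fp <- field_params(p = y$field$p, d = y$field$d, D = y$field$D,
                     n_substeps = y$field$n_substeps,
                     burn_in = y$field$burn_in)
  sim_config(grid = y$grid, energy = en, field = fp, cycle = cy,
             init = y$init, run = y$run)
}

#' Build the initial lattice layout
#'
#' Constructs the starting configuration: a one-site-thick substrate
#' (matrix) floor; a centrally placed bulged senescent core (a
#' half-ellipsoid sized to its target volume); body domains tiling a
#' thin annular sheet around the core as equal angular wedges; and tumor
#' cells seeded as rectangular blocks in the medium outside the body,
#' preferring positions near the body's rim. Tumor replication clocks
#' start at uniformly random phases of a drawn cycle length
#' (asynchronous seeding), using R's RNG stream.
#'
#' @param config a [sim_config()] (or [reduced_config()]).
#' @return A [cpm_state()] at `t = 0`.
#' @export
gen_initial_lattice <- function(config) {
  g <- config$grid
  init <- config$init
  Lx <- g$Lx; Ly <- g$Ly; Lz <- g$Lz
  if (Lz < 8) stop("grid too shallow for the layout")
  grid <- array(0L, c(Lx, Ly, Lz))
  # substrate floor, one site thick, a single frozen cell
  grid[, , 1] <- 1L
  cxy <- c((Lx + 1) / 2, (Ly + 1) / 2)
  xs <- seq_len(Lx); ys <- seq_len(Ly)
  r2 <- outer((xs - cxy[1])^2, (ys - cxy[2])^2, `+`)
  a <- init$core_footprint

  # core: half-ellipsoid of footprint radius a standing on the floor;
  # its height is solved so the discrete site count matches the target
  core_count <- function(cc) {
    n <- 0L
    for (z in 2:Lz) {
      h <- (z - 2) / cc
      if (h > 1) break
      rz2 <- a^2 * (1 - h^2)
      n <- n + sum(r2 <= rz2)
    }
    n
  }
  c_grid <- seq(1, Lz - 3, by = 0.05)
  counts <- vapply(c_grid, core_count, integer(1))
  cc <- c_grid[which.min(abs(counts - init$V_core))]
  for (z in 2:Lz) {
    h <- (z - 2) / cc
    if (h > 1) break
    sl <- grid[, , z]
    sl[r2 <= a^2 * (1 - h^2)] <- 2L
    grid[, , z] <- sl
  }
  if (abs(core_count(cc) - init$V_core) / init$V_core > 0.1)
    stop("core layout does not fit the grid")

  # body: annular sheet of the given thickness split into equal wedges
  thk <- init$body_thickness
  if (1 + thk >= Lz) stop("body thickness exceeds grid height")
  target_body_sites <- init$n_body * init$V_body
  body_zs <- 2:(1 + thk)
  annulus_count <- function(rout) {
    n <- 0L
    for (z in body_zs) n <- n + sum(r2 > a^2 * 0 & r2 <= rout^2 &
                                      grid[, , z] == 0L)
    n
  }
  r_grid <- seq(a + 1, min(Lx, Ly) / 2 - 1, by = 0.05)
  bcounts <- vapply(r_grid, annulus_count, integer(1))
  if (max(bcounts) < 0.9 * target_body_sites)
    stop("body layout does not fit the grid")
  rout <- r_grid[which.min(abs(bcounts - target_body_sites))]
  ang <- outer(xs - cxy[1], ys - cxy[2],
               function(dx, dy) atan2(dy, dx))  # (-pi, pi]
  wedge <- pmin(init$n_body - 1L,
                as.integer(floor((ang + pi) / (2 * pi) * init$n_body)))
  for (z in body_zs) {
    sl <- grid[, , z]
    sel <- r2 <= rout^2 & sl == 0L
    sl[sel] <- 3L + wedge[sel]
    grid[, , z] <- sl
  }

  # tumor cells: near-cubic blocks on the floor outside the body,
  # greedily placed near the body rim with one site of clearance
  w <- max(3L, as.integer(floor(init$V_tumor^(1 / 3))))
  hgt <- max(2L, as.integer(round(init$V_tumor / w^2)))
  if (1 + hgt >= Lz) stop("tumor block height exceeds grid height")
  hw <- (w - 1L) %/% 2L
  mimg <- function(d, L) (d + L / 2) %% L - L / 2
  px <- rep(xs, times = Ly); py <- rep(ys, each = Lx)
  rr <- sqrt(mimg(px - cxy[1], Lx)^2 + mimg(py - cxy[2], Ly)^2)
  r_pref <- rout + w / 2 + init$tumor_gap
  ord <- order(abs(rr - r_pref), px, py)
  placed <- matrix(numeric(0), ncol = 2)
  first_tumor_id <- 3L + init$n_body
  n_placed <- 0L
  for (k in ord) {
    if (n_placed >= init$n_tumor) break
    pcx <- px[k]; pcy <- py[k]
    if (nrow(placed) > 0 &&
        any(sqrt(mimg(placed[, 1] - pcx, Lx)^2 +
                 mimg(placed[, 2] - pcy, Ly)^2) < w + 2)) next
    bx <- ((pcx - hw - 1 + 0:(w - 1)) %% Lx) + 1L
    by <- ((pcy - hw - 1 + 0:(w - 1)) %% Ly) + 1L
    gx <- ((pcx - hw - 2 + 0:(w + 1)) %% Lx) + 1L  # 1-dilated footprint
    gy <- ((pcy - hw - 2 + 0:(w + 1)) %% Ly) + 1L
    if (any(grid[gx, gy, 2:(1 + hgt)] != 0L)) next
    grid[bx, by, 2:(1 + hgt)] <- first_tumor_id + n_placed
    placed <- rbind(placed, c(pcx, pcy))
    n_placed <- n_placed + 1L
  }
  if (n_placed < init$n_tumor)
    stop("could not place ", init$n_tumor, " tumor cells on this grid")

  n_tum <- init$n_tumor
  cells <- data.frame(
    id = seq_len(2L + init$n_body + n_tum),
    type = c(TYPE_CODES[["matrix"]], TYPE_CODES[["core"]],
             rep(TYPE_CODES[["body"]], init$n_body),
             rep(TYPE_CODES[["tumor"]], n_tum)),
    Vt = c(0, init$V_core, rep(init$V_body, init$n_body),
           rep(init$V_tumor, n_tum)),
    Pt = c(0, target_surface(init$V_core, init$asp_core),
           rep(target_surface(init$V_body, init$asp_body), init$n_body),
           rep(target_surface(init$V_tumor, init$asp_tumor), n_tum)),
    t0 = -1, gen = 0L, next_div = Inf)
  # asynchronous replication phases for the founder tumor cells
  tum_rows <- cells$type == TYPE_CODES[["tumor"]]
  cells$next_div[tum_rows] <-
    runif(n_tum) * draw_cycle_length(n_tum, config$cycle)
  cpm_state(grid, cells, spacing = g$spacing, t = 0)
}
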