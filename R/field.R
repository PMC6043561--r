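#' Chemoattractant field parameters
#'
#' The chemoattractant concentration omega obeys the reaction-diffusion
#' equation `d omega/dt = p - d * omega + D * laplacian(omega)`, with
#' production `p` applied only at sites of the senescent-cell core,
#' decay and diffusion everywhere outside the substrate. It is advanced
#' by explicit forward-Euler substeps with a 7-point Laplacian; the
#' substep count is chosen from the stability bound
#' `D * dt / spacing^2 <= 1/6` unless given.
#'
#' @param p production rate at core sites (um^-3 s^-1).
#' @param d decay rate (s^-1).
#' @param D diffusion coefficient (um^2 s^-1).
#' @param n_substeps explicit substeps per second of physical time;
#'   `NULL` picks the smallest stable count.
#' @param burn_in seconds of field-only pre-equilibration before the
#'   lattice starts moving in [run_simulation()].
#' @return An object of class `field_params`.
#' @export
field_params <- function(p = 2, d = 0.02, D = 2, n_substeps = NULL,
                         burn_in = 500) {
  if (p < 0 || d < 0 || D < 0) stop("field rates must be non-negative")
  structure(list(p = p, d = d, D = D, n_substeps = n_substeps,
                 burn_in = burn_in),
            class = "field_params")
}

# resolve the substep count and enforce the explicit-scheme stability
# bound before any stepping starts
validate_field <- function(field, D_spacing = 1) {
  if (is.null(field$n_substeps)) {
    field$n_substeps <- max(1L, as.integer(ceiling(6 * field$D / D_spacing^2)))
  }
  dt <- 1 / field$n_substeps
  if (field$D * dt / D_spacing^2 > 1 / 6 + 1e-12)
    stop("field configuration unstable: D*dt/spacing^2 = ",
         signif(field$D * dt / D_spacing^2, 4), " exceeds 1/6")
  field
}

#' Advance the chemoattractant field
#'
#' Steps omega forward by `n_seconds` of physical time (the lattice is
#' held fixed). Production applies at core sites by default; substrate
#' (matrix) sites are no-flux boundaries with omega = 0, the x and y
#' boundaries are periodic, and the z faces are no-flux.
#'
#' @param state a [cpm_state()].
#' @param field a [field_params()].
#' @param n_seconds how much physical time to advance.
#' @param produce where the production term applies: at `"core"` sites
#'   (the secreting senescent core), `"everywhere"` (homogeneous test
#'   mode), or `"none"`.
#' @return The state with updated `omega`.
#' @export
step_field <- function(state, field = field_params(), n_seconds = 1,
                       produce = c("core", "everywhere", "none")) {
  produce <- match.arg(produce)
  field <- validate_field(field, D_spacing = state$spacing)
  typev <- c(0L, state$cells$type)
  site_type <- array(typev[state$grid + 1L], dim(state$grid))
  blocked <- site_type == TYPE_CODES[["matrix"]]
  prod_mask <- switch(produce,
                      core = site_type == TYPE_CODES[["core"]],
                      everywhere = !blocked,
                      none = array(FALSE, dim(state$grid)))
  total_sub <- as.integer(round(n_seconds * field$n_substeps))
  state$omega <- cpp_field_step(state$omega, dim(state$grid), blocked,
                                prod_mask, field$p, field$d, field$D,
                                1 / field$n_substeps, total_sub,
                                state$spacing)
  state
}

#' Concentration difference between two sites
#'
#' Exact lookup of `omega(x_prime) - omega(x)`, the quantity the
#' chemotactic energy term is built from.
#'
#' @param state a [cpm_state()] (or a plain 3D array of concentrations).
#' @param x,x_prime 1-based `(x, y, z)` site coordinates.
#' @return The scalar concentration difference.
#' @export
sample_gradient_pair <- function(state, x, x_prime) {
  omega <- if (inherits(state, "cpm_state")) state$omega else state
  dims <- dim(omega)
  omega[site_index(dims, x_prime)] - omega[site_index(dims, x)]
}
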