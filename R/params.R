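#' Default interface-energy matrix
#'
#' Builds the symmetric 5x5 type-pair interaction matrix over the types
#' `medium`, `core` (senescent-cell core), `body` (senescent-cell body
#' domains), `tumor` (non-senescent cells) and `matrix` (substrate).
#' Negative entries mean that contact between the pair lowers the energy.
#' The defaults are the model's eleven resting adhesion energies; pairs
#' never in contact in practice (e.g. medium-medium) are zero.
#'
#' @return A named, symmetric 5x5 numeric matrix.
#' @export
default_J <- function() {
  J <- matrix(0, 5, 5, dimnames = list(TYPE_NAMES, TYPE_NAMES))
  set <- function(a, b, v) {
    J[a, b] <<- v
    J[b, a] <<- v
  }
  set("core", "body", -170)
  set("core", "tumor", -10)
  set("core", "medium", 10)
  set("core", "matrix", -70)
  set("body", "medium", 4)
  set("body", "body", -120)
  set("body", "tumor", -2)
  set("tumor", "tumor", -6)
  set("tumor", "medium", -4)
  set("tumor", "matrix", -20)
  set("medium", "matrix", 10)
  J
}

#' Energy parameters for the lattice Hamiltonian
#'
#' @param J symmetric 5x5 type-pair interaction matrix (see [default_J()]).
#' @param lambda_V volume elasticity (energy per site^2 deviation).
#' @param lambda_P surface elasticity (energy per face^2 deviation).
#' @param mu chemotactic sensitivity. The move bias is
#'   `mu * (omega(target) - omega(source))` when a tumor cell extends into
#'   the target site, so `mu < 0` makes up-gradient extension favorable.
#' @param temp Metropolis temperature (must be positive; it sets the
#'   fuzziness of cell boundaries).
#' @param neighborhood_order neighborhood used for copy candidates and the
#'   interface sum; order 2 means the 18-site (face + edge) stencil.
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(J = default_J(), lambda_V = 1, lambda_P = 0.1,
                          mu = -150, temp = 100, neighborhood_order = 2) {
  J <- as.matrix(J)
  if (!isTRUE(all.equal(J, t(J)))) stop("J must be symmetric")
  if (!all(dim(J) == c(5, 5))) stop("J must be 5x5 (medium, core, body, tumor, matrix)")
  if (temp <= 0) stop("temperature must be positive")
  if (neighborhood_order != 2) stop("only neighborhood order 2 is implemented")
  structure(list(J = J, lambda_V = lambda_V, lambda_P = lambda_P,
                 mu = mu, temp = temp, neighborhood_order = neighborhood_order),
            class = "energy_params")
}

#' Cell-cycle and mitotic-rounding parameters
#'
#' Tumor cells replicate with normally distributed cycle lengths
#' (mean 5000 s, sd 1000 s by default, redrawn if non-positive). At each
#' division onset t0 the dividing cell's adhesion energies switch to a
#' transient schedule that relaxes exponentially back to the resting
#' values: tumor-tumor with time constant 100 s and tumor-substrate with
#' 500 s, both with amplitude 110.
#'
#' `rounding_sign` selects the direction of the transient. `"as_printed"`
#' subtracts the 110-amplitude term (contact energies become more
#' negative, i.e. stronger contact preference, during rounding);
#' `"weakening"` adds it, so adhesion weakens during rounding and a
#' freshly divided cell releases the substrate. See the methods vignette
#' for why the simulation scenarios default to `"weakening"` while this
#' function's evaluations default to `"as_printed"`.
#'
#' @param tau_r_mean,tau_r_sd mean and sd of the replication period (s).
#' @param rounding_amplitude transient amplitude (energy units).
#' @param rounding_tau_tt,rounding_tau_tm relaxation time constants (s)
#'   for the tumor-tumor and tumor-matrix schedules.
#' @param resting_J_tt,resting_J_tm resting interaction energies.
#' @param rounding_sign `"as_printed"` or `"weakening"`.
#' @param rounding_window duration (s) after which the schedule is
#'   truncated and the resting value used exactly; defaults to ten times
#'   the slower time constant.
#' @return An object of class `cycle_params`.
#' @export
cycle_params <- function(tau_r_mean = 5000, tau_r_sd = 1000,
                         rounding_amplitude = 110,
                         rounding_tau_tt = 100, rounding_tau_tm = 500,
                         resting_J_tt = -6, resting_J_tm = -20,
                         rounding_sign = c("as_printed", "weakening"),
                         rounding_window = 10 * rounding_tau_tm) {
  rounding_sign <- match.arg(rounding_sign)
  if (tau_r_mean <= 0 || tau_r_sd < 0) stop("invalid replication-period parameters")
  structure(list(tau_r_mean = tau_r_mean, tau_r_sd = tau_r_sd,
                 rounding_amplitude = rounding_amplitude,
                 rounding_tau_tt = rounding_tau_tt,
                 rounding_tau_tm = rounding_tau_tm,
                 resting_J_tt = resting_J_tt, resting_J_tm = resting_J_tm,
                 rounding_sign = rounding_sign,
                 rounding_window = rounding_window),
            class = "cycle_params")
}

rounding_sign_code <- function(params) {
  if (params$rounding_sign == "as_printed") -1L else 1L
}

#' Metropolis copy probability
#'
#' Probability that a copy attempt with energy change `deltaH` is accepted
#' at temperature `temp`: 1 when `deltaH < 0`, otherwise
#' `exp(-deltaH / temp)` (so a zero-cost move is always accepted).
#'
#' @param deltaH energy change of the proposed copy.
#' @param temp Metropolis temperature, must be positive.
#' @return Acceptance probability in `[0, 1]`, vectorized over `deltaH`.
#' @export
p_copy <- function(deltaH, temp) {
  if (!is.numeric(temp) || length(temp) != 1 || temp <= 0)
    stop("temperature must be a single positive number")
  ifelse(deltaH < 0, 1, exp(-deltaH / temp))
}

#' Time-dependent adhesion during mitotic rounding
#'
#' Evaluates the interaction-energy schedule of a cell that entered
#' division at time `t0`. For the tumor-tumor pair the schedule is
#' `-6 - 110 exp(-(t - t0)/100)` and for the tumor-matrix pair
#' `-20 - 110 exp(-(t - t0)/500)` (with the sign of the 110-term flipped
#' under `rounding_sign = "weakening"`). For `t < t0`, or beyond the
#' truncation window, the resting value is returned.
#'
#' @param t current time (s); vectorized.
#' @param t0 division onset time (s).
#' @param pair `"tumor-tumor"` or `"tumor-matrix"`.
#' @param params a [cycle_params()] object.
#' @return Interaction energy (energy units).
#' @export
adhesion_at <- function(t, t0, pair = c("tumor-tumor", "tumor-matrix"),
                        params = cycle_params()) {
  pair <- match.arg(pair)
  if (pair == "tumor-tumor") {
    rest <- params$resting_J_tt
    tau <- params$rounding_tau_tt
  } else {
    rest <- params$resting_J_tm
    tau <- params$rounding_tau_tm
  }
  dt <- t - t0
  active <- dt >= 0 & dt < params$rounding_window
  sgn <- if (params$rounding_sign == "as_printed") -1 else 1
  out <- rep(rest, length.out = length(dt))
  out[active] <- rest + sgn * params$rounding_amplitude * exp(-dt[active] / tau)
  out
}

#' Draw replication-period lengths
#'
#' Normal draws with the configured mean and sd, redrawn while
#' non-positive (truncated sampling). Uses R's RNG stream, so results are
#' reproducible under `set.seed()`.
#'
#' @param n number of draws.
#' @param params a [cycle_params()] object.
#' @return Numeric vector of `n` strictly positive durations (s).
#' @export
draw_cycle_length <- function(n = 1, params = cycle_params()) {
  if (params$tau_r_sd == 0) return(rep(params$tau_r_mean, n))
  out <- rnorm(n, params$tau_r_mean, params$tau_r_sd)
  bad <- out <= 0
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), params$tau_r_mean, params$tau_r_sd)
    bad <- out <= 0
  }
  out
}

# target surface from the dimensionless asperity: asperity times the
# surface area of the sphere with the target volume (asperity = 1 is
# sphere-like; > 1 allows a rougher, more deformable boundary)
target_surface <- function(V_target, asperity) {
  asperity * (36 * pi)^(1 / 3) * V_target^(2 / 3)
}
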