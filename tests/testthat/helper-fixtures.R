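# shared fixtures: all lattices are built in code at test time

# random 6x6x3 lattice with three tumor cells scattered through medium,
# plus a random chemoattractant field
rand_small_state <- function(seed, types = c(3L, 3L, 3L), with_t0 = FALSE) {
  set.seed(seed)
  grid <- array(sample(0:3, 6 * 6 * 3, replace = TRUE), c(6, 6, 3))
  for (id in 1:3) if (!any(grid == id)) grid[sample(length(grid), 1)] <- id
  cells <- data.frame(id = 1:3, type = types,
                      Vt = c(10, 12, 8), Pt = c(30, 28, 25),
                      t0 = if (with_t0) c(95, -1, 60) else -1,
                      gen = 0L, next_div = Inf)
  omega <- array(runif(6 * 6 * 3, 0, 5), c(6, 6, 3))
  cpm_state(grid, cells, omega = omega, t = 100)
}

# a single w x w x h box cell of the given type in medium
box_state <- function(dims = c(12, 12, 12), w = 4, h = 4, type = 3L,
                      Vt = w * w * h, Pt = NULL, origin = NULL) {
  grid <- array(0L, dims)
  if (is.null(origin)) origin <- floor((dims[1:2] - w) / 2) + 1
  ox <- origin[1]; oy <- origin[2]
  grid[ox:(ox + w - 1), oy:(oy + w - 1), 2:(1 + h)] <- 1L
  if (is.null(Pt)) Pt <- 2 * w * w + 4 * w * h
  cells <- data.frame(id = 1L, type = type, Vt = Vt, Pt = Pt,
                      t0 = -1, gen = 0L, next_div = Inf)
  cpm_state(grid, cells)
}

# two 2x2x2 tumor cells, either face-adjacent or separated by one medium
# layer, for interface-energy comparisons
pair_state <- function(gap = 0, t0 = c(-1, -1), t = 0) {
  grid <- array(0L, c(12, 8, 6))
  grid[3:4, 3:4, 3:4] <- 1L
  x2 <- 5 + gap
  grid[x2:(x2 + 1), 3:4, 3:4] <- 2L
  cells <- data.frame(id = 1:2, type = 3L, Vt = 8, Pt = 24,
                      t0 = t0, gen = 0L, next_div = Inf)
  cpm_state(grid, cells, t = t)
}

# random (target site, source neighbor) pair within the order-2 stencil
rand_move <- function(dims) {
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1),
                c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
                c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
                c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))
  repeat {
    s <- c(sample(dims[1], 1), sample(dims[2], 1), sample(dims[3], 1))
    src <- s + offs[sample(18, 1), ]
    src[1] <- ((src[1] - 1) %% dims[1]) + 1
    src[2] <- ((src[2] - 1) %% dims[2]) + 1
    if (src[3] >= 1 && src[3] <= dims[3]) return(list(s = s, src = src))
  }
}

# brute-force delta H: two full Hamiltonian evaluations plus the
# chemotactic term evaluated directly from the printed expression
oracle_delta_h <- function(state, params, cycle, s, src) {
  cand <- state$grid[src[1], src[2], src[3]]
  if (state$grid[s[1], s[2], s[3]] == cand) return(0)
  H0 <- total_hamiltonian(state, params, cycle = cycle)
  st2 <- state
  st2$grid[s[1], s[2], s[3]] <- cand
  st2 <- cpm_state(st2$grid, st2$cells[, 1:7], omega = st2$omega, t = state$t)
  H1 <- total_hamiltonian(st2, params, cycle = cycle)
  chemo <- if (cand > 0 && state$cells$type[cand] == 3L)
    params$mu * (state$omega[s[1], s[2], s[3]] -
                   state$omega[src[1], src[2], src[3]]) else 0
  H1 - H0 + chemo
}
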