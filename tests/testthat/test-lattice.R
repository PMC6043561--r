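test_that("copy probability follows the Metropolis rule", {
  expect_equal(p_copy(-5, 100), 1)
  expect_equal(p_copy(0, 100), 1)          # e^0 = 1: zero-cost moves accepted
  expect_equal(p_copy(100, 100), exp(-1))
  expect_equal(p_copy(c(-1, 0, 50, 200), 100),
               c(1, 1, exp(-0.5), exp(-2)))
  expect_error(p_copy(1, 0), "positive")
  expect_error(p_copy(1, -10), "positive")
})

test_that("total Hamiltonian matches hand-enumerated cases", {
  # empty lattice: no interfaces, the medium is unconstrained
  grid <- array(0L, c(5, 5, 4))
  grid[1, 1, 1] <- 1L  # one minimal cell so the state is valid
  st <- cpm_state(grid, data.frame(id = 1L, type = 3L, Vt = 1, Pt = 6,
                                   t0 = -1, gen = 0L, next_div = Inf))
  p0 <- energy_params(lambda_V = 0, lambda_P = 0, mu = 0)
  p0$J[] <- 0
  expect_equal(total_hamiltonian(st, p0), 0)

  # a 2x2x2 cell in medium: interface energy equals the enumerated count
  # of unlike order-2 neighbor pairs times J(tumor, medium)
  st <- box_state(dims = c(10, 10, 8), w = 2, h = 2, Vt = 8, Pt = 24)
  p1 <- energy_params(lambda_V = 1, lambda_P = 0, mu = 0)
  p1$J[] <- 0
  p1$J["tumor", "medium"] <- p1$J["medium", "tumor"] <- -4
  # independent enumeration over all site pairs within the stencil
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                c(0, 1, 1), c(0, 1, -1))
  dims <- dim(st$grid)
  n_pairs <- 0L
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3])
    for (k in 1:9) {
      xx <- ((x + offs[k, 1] - 1) %% dims[1]) + 1
      yy <- ((y + offs[k, 2] - 1) %% dims[2]) + 1
      zz <- z + offs[k, 3]
      if (zz < 1 || zz > dims[3]) next
      if (st$grid[x, y, z] != st$grid[xx, yy, zz]) n_pairs <- n_pairs + 1L
    }
  expect_equal(total_hamiltonian(st, p1), n_pairs * -4)
  # volume at target contributes nothing on top of the interface term
  expect_equal(total_hamiltonian(st, energy_params(lambda_V = 5,
                                                   lambda_P = 0, mu = 0)) -
                 total_hamiltonian(st, energy_params(lambda_V = 0,
                                                     lambda_P = 0, mu = 0)),
               0)
})

test_that("incremental delta H equals the brute-force oracle", {
  params <- energy_params(lambda_V = 2, lambda_P = 0.5, mu = -2, temp = 100)
  cyc <- cycle_params()
  worst <- 0
  for (rep in 1:15) {
    st <- rand_small_state(rep)
    for (k in 1:8) {
      mv <- rand_move(dim(st$grid))
      cand <- st$grid[mv$src[1], mv$src[2], mv$src[3]]
      dh <- delta_h(st, params, mv$s, mv$src, cand, cycle = cyc)
      worst <- max(worst, abs(dh - oracle_delta_h(st, params, cyc, mv$s, mv$src)))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("delta H oracle agreement holds with active rounding schedules", {
  params <- energy_params(lambda_V = 1, lambda_P = 0.2, mu = -5, temp = 100)
  for (sign in c("as_printed", "weakening")) {
    cyc <- cycle_params(rounding_sign = sign)
    worst <- 0
    for (rep in 1:8) {
      st <- rand_small_state(rep + 100, with_t0 = TRUE)  # rounding active at t = 100
      for (k in 1:6) {
        mv <- rand_move(dim(st$grid))
        cand <- st$grid[mv$src[1], mv$src[2], mv$src[3]]
        dh <- delta_h(st, params, mv$s, mv$src, cand, cycle = cyc)
        worst <- max(worst, abs(dh - oracle_delta_h(st, params, cyc, mv$s, mv$src)))
      }
    }
    expect_lt(worst, 1e-9)
  }
})

test_that("identical candidate yields zero energy change", {
  st <- rand_small_state(3)
  params <- energy_params()
  s <- c(2, 2, 2)
  cand <- st$grid[2, 2, 2]
  # source site holding the same id as the target
  w <- which(st$grid == cand, arr.ind = TRUE)
  expect_equal(delta_h(st, params, s, w[1, ], cand), 0)
})

test_that("kinetics are deterministic under a fixed seed", {
  st <- rand_small_state(7)
  params <- energy_params(lambda_V = 1, lambda_P = 0.1, mu = 0, temp = 100)
  r1 <- mcs_step(st, params, n_mcs = 10, seed = 42)
  r2 <- mcs_step(st, params, n_mcs = 10, seed = 42)
  expect_identical(r1$state$grid, r2$state$grid)
  expect_identical(r1$state$cells, r2$state$cells)
  r3 <- mcs_step(st, params, n_mcs = 10, seed = 43)
  expect_false(identical(r1$state$grid, r3$state$grid))
})

test_that("a single cell relaxes its volume to the target", {
  st <- box_state(dims = c(14, 14, 10), w = 3, h = 3, Vt = 60, Pt = 100)
  params <- energy_params(lambda_V = 2, lambda_P = 0, mu = 0, temp = 20)
  params$J[] <- 0
  res <- mcs_step(st, params, n_mcs = 300, seed = 1)
  expect_lt(abs(res$state$cells$vol[1] - 60) / 60, 0.15)
})

test_that("volume and surface caches survive a run with divisions", {
  cfg <- reduced_config(run = list(n_mcs = 120L))
  set.seed(5)
  st <- gen_initial_lattice(cfg)
  st$cells$next_div[st$cells$type == 3] <- c(10, 20, 30, 40, 50, 60)
  res <- mcs_step(st, cfg$energy, n_mcs = 120, seed = 5, cycle = cfg$cycle,
                  field = cfg$field, divisions = TRUE)
  expect_gt(nrow(res$events), 0)
  aud <- audit_state(res$state)
  expect_true(aud$ok)
  # no cell ever vanishes
  expect_true(all(res$state$cells$vol >= 1))
})

test_that("interface energies at rest and during rounding sort cell pairs", {
  params <- energy_params(lambda_V = 0, lambda_P = 0, mu = 0)
  cyc <- cycle_params()  # as printed
  # resting J: two tumor cells separated by medium are lower-energy than
  # in contact (J_tt = -6 vs 2 x J_tumor,medium = -8 per face pair)
  H_contact <- total_hamiltonian(pair_state(gap = 0), params, cycle = cyc)
  H_apart <- total_hamiltonian(pair_state(gap = 1), params, cycle = cyc)
  expect_lt(H_apart, H_contact)
  # during mitotic rounding (as printed, J_tt -> -116) contact wins:
  # freshly divided daughters stay bound as a dumbbell
  H_contact_r <- total_hamiltonian(pair_state(gap = 0, t0 = c(0, 0), t = 0),
                                   params, cycle = cyc)
  H_apart_r <- total_hamiltonian(pair_state(gap = 1, t0 = c(0, 0), t = 0),
                                 params, cycle = cyc)
  expect_lt(H_contact_r, H_apart_r)
})

test_that("state validation catches inconsistent records", {
  grid <- array(0L, c(4, 4, 4))
  grid[1, 1, 1] <- 1L
  cells2 <- data.frame(id = 1:2, type = 3L, Vt = 1, Pt = 6, t0 = -1,
                       gen = 0L, next_div = Inf)
  expect_error(cpm_state(grid, cells2), "absent from lattice")
  grid[2, 2, 2] <- 5L
  expect_error(cpm_state(grid, cells2[1, ]), "no cell record")
})
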