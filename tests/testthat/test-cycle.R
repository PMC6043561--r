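test_that("replication-period draws match the stated moments", {
  set.seed(1)
  x <- draw_cycle_length(1e5)
  expect_lt(abs(mean(x) - 5000), 15)
  expect_lt(abs(sd(x) - 1000), 15)
  expect_true(all(x > 0))
  set.seed(9); a <- draw_cycle_length(10)
  set.seed(9); b <- draw_cycle_length(10)
  expect_identical(a, b)
  expect_equal(draw_cycle_length(5, cycle_params(tau_r_sd = 0)),
               rep(5000, 5))
})

test_that("rounding adhesion schedule evaluates the printed formulas", {
  cyc <- cycle_params()  # as printed
  expect_equal(adhesion_at(0, 0, "tumor-tumor", cyc), -116)
  expect_equal(adhesion_at(100, 0, "tumor-tumor", cyc), -6 - 110 / exp(1))
  expect_equal(adhesion_at(500, 0, "tumor-matrix", cyc), -20 - 110 / exp(1))
  # long after onset both pairs recover their resting values
  expect_equal(adhesion_at(1e5, 0, "tumor-tumor", cyc), -6)
  expect_equal(adhesion_at(1e5, 0, "tumor-matrix", cyc), -20)
  # schedule not yet active
  expect_equal(adhesion_at(10, 50, "tumor-tumor", cyc), -6)
  # beyond the truncation window the resting value is exact
  expect_equal(adhesion_at(cyc$rounding_window + 1, 0, "tumor-matrix", cyc),
               -20)
  # weakening mode flips the transient
  wk <- cycle_params(rounding_sign = "weakening")
  expect_equal(adhesion_at(0, 0, "tumor-tumor", wk), -6 + 110)
  expect_equal(adhesion_at(0, 0, "tumor-matrix", wk), -20 + 110)
  expect_equal(adhesion_at(1e5, 0, "tumor-matrix", wk), -20)
})

test_that("moves involving a rounding cell use the scheduled adhesion", {
  params <- energy_params(lambda_V = 0, lambda_P = 0, mu = 0)
  cyc <- cycle_params()
  # two adjacent tumor cells; cell 1 fresh from division at t0 = 0
  st <- pair_state(gap = 0, t0 = c(0, -1), t = 0)
  mv <- list(s = c(5, 3, 3), src = c(4, 3, 3))  # cell 1 expands into cell 2
  cand <- st$grid[4, 3, 3]
  dh_round <- delta_h(st, params, mv$s, mv$src, cand, cycle = cyc, t = 0)
  st_rest <- pair_state(gap = 0, t0 = c(-1, -1), t = 0)
  dh_rest <- delta_h(st_rest, params, mv$s, mv$src, cand, cycle = cyc, t = 0)
  expect_false(isTRUE(all.equal(dh_round, dh_rest)))
  # ten fast time constants later the transient is tiny (110 e^-10 per
  # pair), and beyond the truncation window it vanishes exactly
  st_late <- pair_state(gap = 0, t0 = c(0, -1), t = 1000)
  dh_late <- delta_h(st_late, params, mv$s, mv$src, cand, cycle = cyc,
                     t = 1000)
  expect_lt(abs(dh_late - dh_rest), 0.1)
  st_done <- pair_state(gap = 0, t0 = c(0, -1), t = 5001)
  dh_done <- delta_h(st_done, params, mv$s, mv$src, cand, cycle = cyc,
                     t = 5001)
  expect_lt(abs(dh_done - dh_rest), 1e-12)
  # when two rounding cells touch, the more recent onset governs
  st2 <- pair_state(gap = 0, t0 = c(0, 40), t = 50)
  dh2 <- delta_h(st2, params, mv$s, mv$src, cand, cycle = cyc, t = 50)
  st3 <- pair_state(gap = 0, t0 = c(40, 40), t = 50)
  dh3 <- delta_h(st3, params, mv$s, mv$src, cand, cycle = cyc, t = 50)
  expect_equal(dh2, dh3)
})

test_that("division splits sites by a centroid plane and keeps the books", {
  # 2x2x2 cube split along a given azimuth: two equal daughters
  st <- box_state(dims = c(10, 10, 6), w = 2, h = 2, Vt = 8, Pt = 24)
  st$cells$type <- 3L
  st$t <- 1234
  res <- divide_cell(st, 1L, azimuth = 0)
  expect_false(res$deferred)
  st2 <- res$state
  expect_equal(nrow(st2$cells), 2)
  expect_equal(sum(st2$cells$vol), 8)             # sites conserved
  expect_equal(st2$cells$vol, c(4, 4))
  expect_equal(st2$cells$gen, c(1L, 1L))          # both daughters advance
  expect_equal(st2$cells$t0, c(1234, 1234))       # rounding onset = division
  expect_true(all(st2$cells$next_div > 1234))
  expect_true(all(st2$cells$type == 3L))
  # non-tumor cells never divide
  stc <- box_state(w = 2, h = 2, type = 1L, Vt = 8, Pt = 24)
  expect_error(divide_cell(stc, 1L), "tumor")
  # a 1-site cell defers
  g <- array(0L, c(4, 4, 4)); g[2, 2, 2] <- 1L
  st1 <- cpm_state(g, data.frame(id = 1L, type = 3L, Vt = 1, Pt = 6,
                                 t0 = -1, gen = 0L, next_div = Inf))
  expect_true(divide_cell(st1, 1L)$deferred)
})

test_that("centroid-plane splits of roughened cells are near-even", {
  # roughen a box by short Metropolis relaxation, then divide many times
  st <- box_state(dims = c(16, 16, 10), w = 6, h = 6, Vt = 216, Pt = 260)
  params <- energy_params(lambda_V = 1, lambda_P = 0.1, mu = 0, temp = 100)
  params$J[] <- 0
  st <- mcs_step(st, params, n_mcs = 30, seed = 2)$state
  set.seed(11)
  fr <- replicate(200, {
    r <- divide_cell(st, 1L)
    r$state$cells$vol[2] / sum(r$state$cells$vol)
  })
  expect_gte(mean(fr >= 0.3 & fr <= 0.7), 0.99)
})

test_that("only tumor cells ever appear in the division log", {
  cfg <- reduced_config(run = list(n_mcs = 150L))
  set.seed(3)
  st <- gen_initial_lattice(cfg)
  st$cells$next_div[st$cells$type == 3] <- seq(20, 120, length.out = 6)
  res <- mcs_step(st, cfg$energy, n_mcs = 150, seed = 3, cycle = cfg$cycle,
                  divisions = TRUE)
  expect_gt(nrow(res$events), 0)
  expect_true(all(res$state$cells$type[res$events$parent] == 3L))
  expect_true(all(res$state$cells$type[res$events$daughter] == 3L))
  # generation labelling distinguishes never-divided from replicated cells
  tum <- res$state$cells[res$state$cells$type == 3L, ]
  divided <- unique(c(res$events$parent, res$events$daughter))
  expect_true(all(tum$gen[tum$id %in% divided] >= 1))
  expect_true(all(tum$gen[!tum$id %in% divided] == 0))
})
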