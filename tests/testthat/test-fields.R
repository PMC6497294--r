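test_that("source maps reflect secretion and uptake per cell type", {
  p <- tiny_params()
  # all medium -> zero everywhere
  empty <- state_from_sigma(matrix(0L, 30, 30), integer(0), p)
  expect_true(all(source_map(empty, p, "A") == 0))
  expect_true(all(source_map(empty, p, "S") == 0))

  nc <- single_cell_state(p, type = 1L)
  sm <- source_map(nc, p, "A")
  expect_equal(sum(sm == 5), 25)       # S_A = 5 on each of the 25 NC sites
  expect_equal(sum(sm != 0), 25)
  expect_equal(sum(source_map(nc, p, "S") == -p$U_S), 25)  # uptake

  pl <- single_cell_state(p, type = 2L)
  expect_equal(sum(source_map(pl, p, "I") == 0.7), 25)
  expect_equal(sum(source_map(pl, p, "S") == 20), 25)
  expect_true(all(source_map(pl, p, "A") == 0))

  expect_error(source_map(nc, p, "X"), "unknown substance")
})

test_that("a uniform sourceless field decays by the closed form (1 - delta/n)^n", {
  p <- nc_params(lattice_width = 20, lattice_height = 20, halo = 0,
                 D_A = 1, D_S = 1, D_I = 1,
                 delta_A = 0.1, delta_S = 0.2, delta_I = 0,
                 field_substeps_per_MCS = 4, emt_enabled = FALSE)
  st <- state_from_sigma(matrix(0L, 20, 20), integer(0), p)
  st$fields$A[] <- 10; st$fields$S[] <- 3; st$fields$I[] <- 7
  st2 <- step_fields(st, p, n = 2)
  expect_equal(unique(as.vector(st2$fields$A)), 10 * (1 - 0.1 / 4)^8)
  expect_equal(unique(as.vector(st2$fields$S)), 3 * (1 - 0.2 / 4)^8)
  expect_equal(unique(as.vector(st2$fields$I)), 7)  # Laplacian of constant = 0
})

test_that("diffusion without decay or sources conserves mass under reflecting boundaries", {
  p <- nc_params(lattice_width = 24, lattice_height = 18, halo = 0,
                 D_A = 0.2, D_S = 0.2, D_I = 0.2,
                 delta_A = 0, delta_S = 0, delta_I = 0,
                 field_substeps_per_MCS = 1, emt_enabled = FALSE)
  st <- state_from_sigma(matrix(0L, 18, 24), integer(0), p)
  set.seed(42)
  st$fields$A[] <- runif(length(st$fields$A), 0, 5)
  m0 <- sum(st$fields$A)
  st2 <- step_fields(st, p, n = 100)
  expect_equal(sum(st2$fields$A), m0, tolerance = 1e-9)
  expect_true(all(st2$fields$A >= 0))
  # and the field homogenizes
  expect_lt(diff(range(st2$fields$A)), diff(range(st$fields$A)))
})

test_that("constant secretion over the whole lattice approaches the fixed point s/delta", {
  # placodes tile the full 20x20 lattice; with halo 0 and reflecting outer
  # boundaries there is no leakage and the spatial mean obeys the decay ODE
  p <- nc_params(lattice_width = 20, lattice_height = 20, halo = 0,
                 D_A = 0.1, D_S = 0.1, D_I = 0.1,
                 S_S = 20, delta_S = 0.01, S_I = 0.7, delta_I = 0.01,
                 field_substeps_per_MCS = 2, emt_enabled = FALSE)
  sigma <- matrix(0L, 20, 20)
  id <- 0L
  for (r in 0:3) for (cc in 0:3) {
    id <- id + 1L
    sigma[(r * 5 + 1):(r * 5 + 5), (cc * 5 + 1):(cc * 5 + 5)] <- id
  }
  st <- state_from_sigma(sigma, rep(2L, 16), p)
  st2 <- step_fields(st, p, n = 1200)     # 12 decay time constants
  expect_equal(mean(core_field(st2, "S")), 20 / 0.01, tolerance = 1e-3)
  expect_equal(mean(core_field(st2, "I")), 0.7 / 0.01, tolerance = 1e-3)
})

test_that("explicit substepping converges at first order in the substep size", {
  base <- nc_params(lattice_width = 16, lattice_height = 16, halo = 4,
                    D_A = 2, delta_A = 0.05, D_S = 0.01, D_I = 0.01,
                    emt_enabled = FALSE)
  st0 <- single_cell_state(base, x0 = 6, y0 = 6, type = 1L)
  sol <- function(n) {
    p <- set_params(base, field_substeps_per_MCS = n)
    core_field(step_fields(st0, p, n = 10), "A")
  }
  c1 <- sol(16); c2 <- sol(32); c4 <- sol(64)
  e12 <- max(abs(c1 - c2)); e24 <- max(abs(c2 - c4))
  expect_lt(e24, e12)                      # refining shrinks the difference
  expect_equal(e12 / e24, 2, tolerance = 0.35)  # ~ halves per refinement
})

test_that("field stepping rejects unstable substep settings", {
  p <- nc_params(D_S = 8, field_substeps_per_MCS = 4)
  st <- init_simulation(nc_params(), 1)
  expect_error(step_fields(st, p), "unstable")
})

test_that("decay length follows sqrt(D/delta) with sensible limits", {
  p <- nc_params()
  expect_equal(decay_length("I", p), sqrt(0.005 / 0.0006))
  expect_equal(decay_length("I", p), 2.887, tolerance = 1e-3)
  # inhibitor range ~ half the cell diameter d0 ~ 5.64
  expect_lt(decay_length("I", p), link_rest_length(p))
  expect_equal(decay_length("S", p), sqrt(8 / 0.006))
  expect_equal(decay_length("S", p), 36.5, tolerance = 1e-2)
  expect_equal(decay_length("A", nc_params(D_A = 0)), 0)
  expect_equal(decay_length("A", nc_params(delta_A = 0)), Inf)
  expect_error(decay_length("Q", p), "unknown substance")
})

test_that("concentrations stay non-negative under strong uptake", {
  p <- nc_params(lattice_width = 20, lattice_height = 20, halo = 0,
                 D_A = 0.1, D_S = 0.1, D_I = 0.1, U_S = 50,
                 field_substeps_per_MCS = 2, emt_enabled = FALSE)
  st <- single_cell_state(p, x0 = 8, y0 = 8, type = 1L)
  st$fields$S[] <- 1
  st2 <- step_fields(st, p, n = 20)
  expect_true(all(st2$fields$S >= 0))
  # the NC footprint was drained
  expect_lt(st2$fields$S[10 + 0, 10 + 0], 0.05)
})
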