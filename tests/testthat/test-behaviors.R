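test_that("polarity persistence follows p <- (1 - deltaP) p + dr", {
  p <- tiny_params()
  st <- single_cell_state(p, type = 1L)     # free NC: deltaP = 0.3
  st$cells$px <- 1; st$cells$py <- 0
  st2 <- update_polarity(st, p)             # zero displacement
  expect_equal(c(st2$cells$px, st2$cells$py), c(0.7, 0))
  # with a displacement
  st3 <- update_polarity(st, p, displacement = matrix(c(0.2, -0.1), 1))
  expect_equal(c(st3$cells$px, st3$cells$py), c(0.7 + 0.2, -0.1))
  # placode without contact: deltaP = 0.5
  stp <- single_cell_state(p, type = 2L)
  stp$cells$px <- 1
  expect_equal(update_polarity(stp, p)$cells$px, 0.5)
})

test_that("repeated zero-displacement updates shrink polarity geometrically", {
  p <- tiny_params()
  st <- single_cell_state(p, type = 1L)
  st$cells$px <- 2; st$cells$py <- -1
  for (k in 1:6) st <- update_polarity(st, p)
  expect_equal(st$cells$px, 2 * 0.7^6)
  expect_equal(st$cells$py, -1 * 0.7^6)
})

test_that("CIL adds -lambda_CIL times the unit vector toward the contact", {
  p <- tiny_params()
  st <- two_cell_state(p, types = c(1L, 1L), gap = 0)  # partner to the right
  st$cells$cil <- c(TRUE, FALSE)
  st2 <- update_polarity(st, p)
  # contacting NC: deltaP = 0.08, zero prior polarity; bias is -0.5 * (1, 0)
  expect_equal(st2$cells$px[1], -0.5)
  expect_equal(st2$cells$py[1], 0)
  expect_equal(st2$cells$px[2], 0)          # not in CIL state
  # with prior polarity the persistence part uses the contact decay rate
  st$cells$px <- c(1, 0)
  st3 <- update_polarity(st, p)
  expect_equal(st3$cells$px[1], (1 - 0.08) * 1 - 0.5)
})

test_that("placodes in CIL repolarize away from NC contacts only", {
  p <- tiny_params()
  # placode with an NC neighbor to the left and a placode neighbor right
  sigma <- matrix(0L, 30, 30)
  sigma[10:14, 1:5] <- 1L; sigma[10:14, 6:10] <- 2L; sigma[10:14, 11:15] <- 3L
  st <- state_from_sigma(sigma, c(1L, 2L, 2L), p)
  st$cells$cil <- c(FALSE, TRUE, FALSE)
  st2 <- update_polarity(st, p)
  # the placode-placode contact does not contribute: bias is away from the NC
  expect_equal(st2$cells$px[2], +p$lambda_CIL)
  expect_equal(st2$cells$py[2], 0)
})

test_that("CIL switching triggers on new NC contacts with the type's probability", {
  p <- tiny_params()
  st <- two_cell_state(p, types = c(1L, 1L), gap = 0)
  # certain switching: both NC enter the CIL state on a new contact
  set.seed(1)
  r <- update_cil(st, set_params(p, p_CIL_NC = 1))
  expect_true(all(r$state$cells$cil))
  expect_equal(r$entries, 2)
  # the same contact is no longer "new" on the next update
  r2 <- update_cil(r$state, set_params(p, p_CIL_NC = 1))
  expect_equal(r2$entries, 0)
  expect_true(all(r2$state$cells$cil))      # contact persists, state kept

  # zero probability: never
  set.seed(1)
  r0 <- update_cil(st, set_params(p, p_CIL_NC = 0))
  expect_false(any(r0$state$cells$cil))

  # placode-placode contacts never trigger, even at probability 1
  stp <- two_cell_state(p, types = c(2L, 2L), gap = 0)
  rp <- update_cil(stp, set_params(p, p_CIL_PL = 1))
  expect_false(any(rp$state$cells$cil))

  # an NC-placode contact triggers each side with its own probability
  sm <- two_cell_state(p, types = c(1L, 2L), gap = 0)
  rm <- update_cil(sm, set_params(p, p_CIL_NC = 1, p_CIL_PL = 0))
  expect_equal(rm$state$cells$cil, c(TRUE, FALSE))
})

test_that("cells leave the CIL state when triggering contacts end", {
  p <- tiny_params()
  st <- two_cell_state(p, types = c(1L, 1L), gap = 3)   # separated
  st$cells$cil <- c(TRUE, TRUE)
  r <- update_cil(st, p)
  expect_false(any(r$state$cells$cil))
  expect_equal(r$exits, 2)
  # isolated cells are never in CIL
  iso <- single_cell_state(p)
  expect_false(any(update_cil(iso, p)$state$cells$cil))
})

test_that("link formation, deterministic loss, and distance-dependent breakage", {
  p <- tiny_params()
  st <- two_cell_state(p, types = c(1L, 1L), gap = 0)
  # formation with certainty
  r <- update_links(st, set_params(p, p_link_form = 1))
  expect_equal(nrow(r$state$links), 1)
  expect_equal(r$formed, 1)
  # never formed at probability 0
  r0 <- update_links(st, set_params(p, p_link_form = 0))
  expect_equal(nrow(r0$state$links), 0)
  # losing lattice contact removes the link deterministically
  sep <- two_cell_state(p, types = c(1L, 1L), gap = 3)
  sep$links <- matrix(c(1L, 2L), 1, dimnames = list(NULL, c("i", "j")))
  r2 <- update_links(sep, set_params(p, p_link_form = 0))
  expect_equal(nrow(r2$state$links), 0)
  expect_equal(r2$broken, 1)
})

test_that("link breakage probability is (|r| - d0)/100 clamped to [0, 1]", {
  d0 <- link_rest_length(nc_params())
  expect_equal(link_break_prob(d0, d0), 0)
  expect_equal(link_break_prob(d0 + 2, d0), 0.02)
  expect_equal(link_break_prob(d0 - 3, d0), 0)      # compressed pairs hold
  expect_equal(link_break_prob(d0 + 500, d0), 1)
  # statistical check against the engine: touching 7x7 cells sit at centroid
  # distance 7 > d0, so linked pairs break with probability (7 - d0)/100
  p <- set_params(tiny_params(), p_link_form = 0)
  st <- two_cell_state(p, types = c(1L, 1L), gap = 0, w = 7)
  st$links <- matrix(c(1L, 2L), 1, dimnames = list(NULL, c("i", "j")))
  pb <- link_break_prob(7, d0)
  set.seed(99)
  broke <- vapply(1:4000, function(i) update_links(st, p)$broken, 0L)
  expect_lt(abs(mean(broke) - pb), 3 * sqrt(pb * (1 - pb) / 4000))
})

test_that("EMT inserts half-height NC cells into qualifying dorsal gaps", {
  p <- tiny_params()
  pe <- tiny_params(); pe$emt_enabled <- TRUE
  # fully occupied top strip: nothing inserted
  full <- single_cell_state(p, x0 = 1, y0 = 1, w = 30, h = 3, type = 2L)
  expect_equal(emt_insert(full, pe)$insertions, 0)

  # one clean 5x3 gap at the dorsal edge: exactly one new NC cell of area 15
  sigma <- matrix(0L, 30, 30)
  sigma[1:5, 11:30] <- 1L                 # blocks the right side
  st <- state_from_sigma(sigma, 2L, p)
  r <- emt_insert(st, pe)
  expect_gte(r$insertions, 1)
  new_ids <- which(r$state$cells$type == 1)
  expect_true(length(new_ids) >= 1)
  expect_true(all(r$state$cells$area[new_ids] == 15))
  expect_true(all(r$state$cells$px[new_ids] == 0))

  # two disjoint gaps separated by an occupied block: two distinct new ids
  sigma2 <- matrix(0L, 30, 30)
  sigma2[1:5, 8:12] <- 1L                 # occupied block splits the strip
  st2 <- state_from_sigma(sigma2, 2L, p)
  r2 <- emt_insert(st2, pe)
  expect_gte(r2$insertions, 2)
  expect_equal(anyDuplicated(r2$state$cells$id), 0)

  # inserted cells grow toward the target area under the volume constraint
  sigma3 <- matrix(0L, 30, 30)
  sigma3[1:3, 1:5] <- 1L                  # a fresh 5x3 NC cell
  p3 <- tiny_params()
  st3 <- state_from_sigma(sigma3, 1L, p3)
  set.seed(2)
  grown <- run_mcs(st3, p3, 60)$state
  expect_gt(grown$cells$area[1], 20)
  expect_lt(abs(grown$cells$area[1] - p3$V_T), 5)
})

test_that("cell count never decreases and grows only by EMT insertion", {
  p <- nc_params(lattice_width = 40, lattice_height = 95, halo = 10)
  sim <- run_simulation(p, 8, n_mcs = 60)
  n <- sim$metrics$n_cells
  expect_true(all(diff(n) >= 0))
  expect_equal(n[length(n)] - 8 * 15, sum(sim$metrics$emt_insertions))
})

test_that("with CIL switching disabled the repolarization strength is inert", {
  # no cell ever enters the CIL state, so lambda_CIL must not touch the
  # dynamics (exact regression guard for the no-CIL reduction)
  base <- nc_params(lattice_width = 40, lattice_height = 95, halo = 10,
                    p_CIL_NC = 0, p_CIL_PL = 0)
  a <- run_simulation(set_params(base, lambda_CIL = 0.5), 4, n_mcs = 20)
  b <- run_simulation(set_params(base, lambda_CIL = 0), 4, n_mcs = 20)
  expect_identical(a$state$sigma, b$state$sigma)
  expect_equal(a$state$cells$px, b$state$cells$px)
  expect_false(any(a$state$cells$cil))
})
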