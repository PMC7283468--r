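p <- fixture_params()

test_that("friction operator: structure, symmetry, positive definiteness", {
  st <- fixture_init()
  m <- st$mesh
  contact <- interface_flags(m, p)$nodes
  M <- assemble_friction(m, contact, p)
  # symmetric
  expect_lt(max(abs(M - Matrix::t(M))), 1e-15 * max(abs(M)))
  # diagonal block of a non-contact node: liquid drag plus its dashpot shares
  free <- which(!contact)[1]
  idx <- 3 * (free - 1) + 1:3
  blk <- as.matrix(M[idx, idx])
  expect_true(all(diag(blk) >= p$Gamma_liquid))
  # a node with no contact and (hypothetically) no edges would be pure drag:
  # subtracting the dashpot shares leaves Gamma_liquid exactly
  edges_i <- which(m$edges[, 1] == free | m$edges[, 2] == free)
  B <- matrix(0, 3, 3)
  for (e in edges_i) {
    d <- m$pos[m$edges[e, 2], ] - m$pos[m$edges[e, 1], ]
    nh <- d / sqrt(sum(d^2))
    B <- B + p$Lambda_d * (nh %o% nh)
  }
  expect_equal(blk - B, diag(p$Gamma_liquid, 3), tolerance = 1e-12)
  # positive definite on the spread fixture (dense eigensolve oracle)
  ev <- eigen(as.matrix(M), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("matrix-free friction application equals the assembled operator", {
  st <- fixture_init()
  m <- st$mesh
  contact <- interface_flags(m, p)$nodes
  M <- assemble_friction(m, contact, p)
  set.seed(4)
  v <- matrix(rnorm(3 * nrow(m$pos), sd = 1e-9), ncol = 3)
  mv <- mechamigr:::cpp_friction_matvec(m$pos, m$edges, as.integer(contact),
                                        p$Lambda_d, p$Gamma_subs,
                                        p$Gamma_liquid, v)
  ref <- matrix(as.vector(M %*% as.vector(t(v))), ncol = 3, byrow = TRUE)
  expect_lt(max(abs(mv - ref)) / max(abs(ref)), 1e-12)
  # and the solver inverts it
  F <- matrix(rnorm(3 * nrow(m$pos), sd = 1e-10), ncol = 3)
  v2 <- solve_velocities(m, F, contact, p)
  ref2 <- matrix(Matrix::solve(M, as.vector(t(F))), ncol = 3, byrow = TRUE)
  expect_lt(max(abs(v2 - ref2)) / max(abs(ref2)), 1e-6)
})

test_that("overdamped solve: single free node obeys v = F / Gamma exactly", {
  pos <- matrix(c(0, 0, 1e-5), 1, 3)
  edges <- matrix(integer(0), 0, 2)
  F <- matrix(c(2e-10, -1e-10, 5e-11), 1, 3)
  v <- mechamigr:::cpp_solve_velocities(pos, edges, 0L, p$Lambda_d,
                                        p$Gamma_subs, p$Gamma_liquid,
                                        F, matrix(0, 1, 3), 1e-14, 100)
  expect_equal(v, F / p$Gamma_liquid, tolerance = 1e-12)
  # zero force -> zero velocity -> zero displacement
  v0 <- mechamigr:::cpp_solve_velocities(pos, edges, 0L, p$Lambda_d,
                                         p$Gamma_subs, p$Gamma_liquid,
                                         matrix(0, 1, 3), matrix(0, 1, 3),
                                         1e-14, 100)
  expect_equal(max(abs(v0)), 0)
})

test_that("two-node Kelvin-Voigt element relaxes on the closed-form exponential", {
  # spring k + axis dashpot Lambda, liquid drag Gamma: the gap x = d - d*
  # decays with time constant (Gamma + 2 Lambda) / (2 k (1 + Gamma-term));
  # exactly: x' = -2 k x / (Gamma + 2 Lambda)
  k <- 1e-3; Lam <- 0.5; Gam <- 1e-3
  d_star <- 1e-5
  x0 <- 2e-6
  pos <- rbind(c(0, 0, 0), c(d_star + x0, 0, 0))
  edges <- matrix(c(1L, 2L), 1)
  vel <- matrix(0, 2, 3)
  dt <- 0.05
  nsteps <- 2000
  for (i in seq_len(nsteps)) {
    F <- mechamigr:::cpp_spring_forces(pos, edges, d_star, k)
    vel <- mechamigr:::cpp_solve_velocities(pos, edges, c(0L, 0L), Lam, 0,
                                            Gam, F, vel, 1e-13, 500)
    pos <- pos + vel * dt
  }
  tau <- (Gam + 2 * Lam) / (2 * k)
  x_expect <- x0 * exp(-nsteps * dt / tau)
  x_num <- pos[2, 1] - pos[1, 1] - d_star
  expect_lt(abs(x_num - x_expect) / x_expect, 0.01)
})

test_that("full-retraction detection uses a strict count in a trailing minute", {
  # 15 ruptures within 60 s fire the event
  res <- detect_full_retraction(seq(0, 59, length.out = 15), clock = 59, p)
  expect_true(res$fired)
  expect_length(res$remaining, 0)
  # 15 ruptures spread over 61 s do not
  res2 <- detect_full_retraction(seq(0, 61, length.out = 15), clock = 61, p)
  expect_false(res2$fired)
  expect_equal(length(res2$remaining), 14) # the oldest fell out of the window
  # 14 in a minute: no event
  expect_false(detect_full_retraction(seq(30, 59, length.out = 14), 59, p)$fired)
})

test_that("initialization is deterministic and satisfies its contract", {
  st <- fixture_init()
  fl <- interface_flags(st$mesh, p)
  expect_gt(sum(fl$tris), 0)
  lab <- demarcate_regions(st$raw$G, st$mesh, p)
  expect_gt(sum(lab == "Lp"), 0)
  expect_gt(sum(lab %in% c("frontLm", "rearLm")), 0)
  # volume within 5% of the reference
  expect_lt(abs(enclosed_volume(st$mesh) / st$mesh$ref_volume - 1), 0.05)
  # identical repeat (no RNG in initialization)
  st2 <- initialize_cell(p, subdivision = 2L)
  expect_identical(st2$mesh$pos, st$mesh$pos)
  expect_identical(st2$raw$G, st$raw$G)
})

test_that("short migration runs are reproducible from the seed", {
  st <- fixture_init()
  cnd <- mm_condition(4.16e-2, 5e-2)
  su <- mm_setup(TRUE, TRUE)
  sim1 <- simulate_cell(cnd, su, duration = 120, seed = 7, params = p,
                        subdivision = 2, save_every = 30, state = st)
  sim2 <- simulate_cell(cnd, su, duration = 120, seed = 7, params = p,
                        subdivision = 2, save_every = 30, state = st)
  expect_identical(sim1$metrics, sim2$metrics)
  expect_identical(sim1$state$raw$pos, sim2$state$raw$pos)
  sim3 <- simulate_cell(cnd, su, duration = 120, seed = 8, params = p,
                        subdivision = 2, save_every = 30, state = st)
  expect_false(identical(sim3$state$raw$pos, sim1$state$raw$pos))
  # duration 0: initialized state only, empty metrics
  sim0 <- simulate_cell(cnd, su, duration = 0, seed = 1, params = p,
                        subdivision = 2, state = st)
  expect_equal(nrow(sim0$metrics), 0)
})

test_that("force balance: internal forces cannot translate the cell", {
  # cortex + SF + protrusion + counter sum to zero; only substrate-coupled
  # terms (FA, contact, friction) move the center of mass
  st <- fixture_init()
  m <- st$mesh
  F <- cortex_forces(m, p)
  lab <- demarcate_regions(st$raw$G, m, p)
  pr <- protrusion_forces(st$raw$G, m, lab, p)
  cnt <- counter_force(pr, m)
  tot <- colSums(F) + colSums(pr$node_force) + colSums(cnt)
  # stress-fiber pair on two arbitrary nodes
  sf <- sf_force(m$pos[1, ], m$pos[80, ], 9e-6, 3, p)
  tot <- tot + sf$force_i + sf$force_j
  expect_lt(max(abs(tot)), 1e-12 * max(abs(F)))
})

test_that("state checkpoints round-trip through save/load", {
  st <- fixture_init()
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  save_state(st, f)
  st2 <- load_state(f)
  expect_identical(st2$mesh$pos, st$mesh$pos)
  expect_identical(st2$raw$G, st$raw$G)
  f2 <- tempfile(fileext = ".rds")
  on.exit(unlink(f2), add = TRUE)
  saveRDS(list(1), f2)
  expect_error(load_state(f2), "sim_state")
})
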