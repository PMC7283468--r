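p <- fixture_params()

test_that("adhesive contact has finite range and the exact Hertz limit", {
  # beyond the adhesive range: no force
  expect_equal(contact_force_normal(p$h0_adh * 1.01, 8e-6, p), 0)
  expect_equal(contact_force_normal(1e-6, 8e-6, p), 0)
  # zero adhesion energy reduces to the Hertz sphere-on-flat closed form
  p0 <- mm_params(w_adh = 1e-300)
  R <- 8e-6
  for (d in c(1e-9, 5e-9, 2e-8)) {
    FH <- 4 / 3 * p0$E_contact * sqrt(R) * d^1.5
    expect_lt(abs(contact_force_normal(-d, R, p0) - FH) / FH, 1e-6)
    expect_equal(contact_force_normal(d, R, p0), 0) # no pull without adhesion
  }
  # adhesive branch: constant-stress zone, continuous at contact
  gaps <- seq(0, p$h0_adh, length.out = 5)
  Fv <- contact_force_normal(gaps, R, p)
  expect_true(all(Fv <= 0))
  expect_true(all(diff(Fv) >= 0))                 # weakens with distance
  expect_equal(Fv[1], -2 * pi * R * p$w_adh)      # pull-off at zero gap
})

test_that("whole-mesh contact is equal and opposite between cell and substrate", {
  st <- fixture_init()
  ct <- maugis_dugdale_contact(st$mesh, p)
  expect_true(any(ct$tri_fz != 0))
  # node z-forces sum to the triangle normal forces (thirds)
  expect_equal(sum(ct$force[, 3]), sum(ct$tri_fz), tolerance = 1e-12)
  expect_true(all(ct$force[, 1] == 0) && all(ct$force[, 2] == 0))
})

test_that("two-spring FA force follows the series-spring law with no compression", {
  # at the combined rest length: zero force
  L0 <- p$L_FA0 + p$L_ECM0
  f0 <- fa_force(c(0, 0, L0), c(0, 0, 0), 0.5, p)
  expect_equal(f0$magnitude, 0)
  # compressed: still zero (the bond cannot push)
  expect_equal(fa_force(c(0, 0, L0 / 2), c(0, 0, 0), 0.5, p)$magnitude, 0)
  # the series stiffness is dominated by the soft ligand spring
  expect_equal(fa_series_stiffness(1e-3, p), 9.99999e-4, tolerance = 1e-10)
  # stretch of 15.4 nm beyond rest at k_ECM = 0.5 N/m reaches the rupture force
  ks <- fa_series_stiffness(0.5, p)
  stretch <- 7.7e-9 / ks
  f <- fa_force(c(0, 0, L0 + stretch), c(0, 0, 0), 0.5, p)
  expect_equal(f$magnitude, 7.7e-9, tolerance = 1e-12)
  expect_equal(stretch, 15.4e-9, tolerance = 1e-3)
  # force pulls the node toward the anchor
  expect_lt(f$force[3], 0)
})

test_that("disassembly rate: polarity, catch-bond exponential, and the outside factor", {
  s_on <- mm_setup(fa_mat = TRUE, sf_str = TRUE)
  s_off <- mm_setup(fa_mat = FALSE, sf_str = FALSE)
  cnd <- mm_condition(0.5, 5e-4)
  # zero force identity
  expect_equal(fa_disassembly_rate(0, "front", FALSE, s_on, cnd, p), 5e-4)
  # rear / front ratio is exactly beta_rear / beta_front = 2 at any force
  for (Fm in c(0, 1e-9, 7.7e-9)) {
    expect_equal(fa_disassembly_rate(Fm, "rear", FALSE, s_on, cnd, p) /
                 fa_disassembly_rate(Fm, "front", FALSE, s_on, cnd, p), 2)
  }
  # direct evaluation at the rupture force with the published sensitivity
  r <- fa_disassembly_rate(7.7e-9, "front", FALSE, s_on, cnd, p)
  expect_equal(r, 5e-4 * exp(-1.21 * 7.7), tolerance = 1e-6)
  expect_equal(r, 4.48e-8, tolerance = 1e-2)
  # strictly decreasing in force when maturation is on; flat when off
  Fs <- seq(0, 8e-9, length.out = 20)
  r_on <- vapply(Fs, fa_disassembly_rate, numeric(1), "front", FALSE, s_on, cnd, p)
  r_off <- vapply(Fs, fa_disassembly_rate, numeric(1), "front", FALSE, s_off, cnd, p)
  expect_true(all(diff(r_on) < 0))
  expect_true(all(r_off == 5e-4))
  # outside the lamellum the rate is multiplied by 10
  expect_equal(fa_disassembly_rate(0, "front", TRUE, s_on, cnd, p), 5e-3)
})

test_that("FA formation respects the distance gate, refractory state, and rate", {
  set.seed(1)
  # beyond the vertical binding distance: never forms
  for (i in 1:50)
    expect_null(attempt_fa_formation(c(0, 0, 1e-7), TRUE, FALSE, 0, 0, p))
  # refractory node: never forms
  for (i in 1:50)
    expect_null(attempt_fa_formation(c(0, 0, 1e-8), TRUE, FALSE, 10, 0, p))
  # adhered or non-lamellar nodes: never form
  expect_null(attempt_fa_formation(c(0, 0, 1e-8), TRUE, TRUE, 0, 0, p))
  expect_null(attempt_fa_formation(c(0, 0, 1e-8), FALSE, FALSE, 0, 0, p))
  # per-step probability 1 - exp(-r_on dt) = 2.4997e-4
  expect_equal(1 - exp(-p$r_on_FA * p$dt), 2.4997e-4, tolerance = 1e-4)
  # eligible node forms at the expected rate (binomial check)
  n <- 2e4
  set.seed(2)
  hits <- sum(vapply(seq_len(n), function(i)
    !is.null(attempt_fa_formation(c(0, 0, 1e-8), TRUE, FALSE, 0, 0, p)),
    logical(1)))
  pstep <- 1 - exp(-p$r_on_FA * p$dt)
  expect_lt(abs(hits - n * pstep), 3 * sqrt(n * pstep * (1 - pstep)) + 3)
  # anchor is the closest point on the plane
  set.seed(99)
  fa <- NULL
  while (is.null(fa)) fa <- attempt_fa_formation(c(1e-6, -2e-6, 1e-8),
                                                 TRUE, FALSE, 0, 5, p)
  expect_equal(fa$anchor, c(1e-6, -2e-6, 0))
})

test_that("rupture is a strict threshold and triggers the refractory period", {
  cnd <- mm_condition(0.5, 5e-4)
  s <- mm_setup(TRUE, TRUE)
  fas <- data.frame(node = 1:3,
                    F_mag = c(7.7e-9, 7.71e-9, 1e-10),
                    region = c("front", "front", "rear"),
                    outside_lm = FALSE)
  set.seed(3)
  res <- step_fa_population(fas, s, cnd, p)
  expect_false(1 %in% res$ruptured)   # exactly F_rup: no rupture
  expect_true(2 %in% res$ruptured)    # strictly above: rupture
  expect_equal(res$refractory_nodes, 2L)
  # rate zero and below threshold: always survives
  cnd0 <- mm_condition(0.5, 1e-12)
  for (i in 1:20) {
    r0 <- step_fa_population(fas[3, ], s, cnd0, p)
    expect_equal(r0$surviving, 1L)
  }
})

test_that("force-free FA survival matches the exponential law (1e4 samples)", {
  cnd <- mm_condition(0.5, 5e-2)
  s <- mm_setup(FALSE, FALSE)
  n <- 1e4
  set.seed(11)
  alive <- rep(TRUE, n)
  nsteps <- 200 # 10 s at dt = 0.05
  r <- fa_disassembly_rate(0, "rear", FALSE, s, cnd, p) # 2 * 0.05 = 0.1 per s
  pstep <- 1 - exp(-r * p$dt)
  for (i in seq_len(nsteps)) {
    u <- stats::runif(sum(alive))
    alive[alive] <- u >= pstep
  }
  expected <- exp(-r * nsteps * p$dt)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(alive) - expected), 3 * se)
})
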