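p <- fixture_params()

test_that("every cortex force category is the exact negative energy gradient", {
  m <- fixture_perturbed_mesh()
  expect_lt(fd_force_error(
    function(me) mechamigr:::cpp_spring_forces(me$pos, me$edges, me$edge_rest, p$k_cortex),
    function(me) mechamigr:::cpp_spring_energy(me$pos, me$edges, me$edge_rest, p$k_cortex),
    m), 1e-6)
  expect_lt(fd_force_error(
    function(me) mechamigr:::cpp_area_forces(me$pos, me$tris, me$tri_ref_area,
                                             me$ref_total_area, p$k_area_loc, p$k_area_glob),
    function(me) mechamigr:::cpp_area_energy(me$pos, me$tris, me$tri_ref_area,
                                             me$ref_total_area, p$k_area_loc, p$k_area_glob),
    m), 1e-6)
  expect_lt(fd_force_error(
    function(me) mechamigr:::cpp_volume_force(me$pos, me$tris, me$ref_volume, p$k_vol),
    function(me) mechamigr:::cpp_volume_energy(me$pos, me$tris, me$ref_volume, p$k_vol),
    m), 1e-6)
  expect_lt(fd_force_error(
    function(me) mechamigr:::cpp_bend_forces(me$pos, me$hinges, me$theta_ref, p$k_bend),
    function(me) mechamigr:::cpp_bend_energy(me$pos, me$hinges, me$theta_ref, p$k_bend),
    m), 1e-5)
})

test_that("the built sphere is the stress-free reference state", {
  m <- fixture_mesh()
  expect_equal(max(abs(edge_viscoelastic_forces(m, p)$spring)), 0)
  expect_equal(max(abs(edge_viscoelastic_forces(m, p)$dashpot)), 0) # zero velocities
  expect_equal(max(abs(area_conservation_forces(m, p))), 0)
  expect_equal(max(abs(volume_conservation_force(m, p))), 0)
  expect_lt(max(abs(bending_forces(m, p))), 1e-18) # theta == theta_ref
})

test_that("edge spring matches the direct evaluation and action-reaction", {
  # two connected nodes stretched by 1 um at the published cortex stiffness
  pos <- rbind(c(0, 0, 0), c(2e-6 + 1e-6, 0, 0))
  edges <- matrix(c(1L, 2L), 1)
  F <- mechamigr:::cpp_spring_forces(pos, edges, 2e-6, 2.9e-4)
  expect_equal(F[1, 1], 2.9e-4 * 1e-6)        # 2.9e-10 N toward the partner
  expect_equal(F[1, ], -F[2, ])
  expect_error(mechamigr:::cpp_spring_forces(rbind(c(0, 0, 0), c(0, 0, 0)),
                                             edges, 2e-6, 2.9e-4),
               "zero-length")
})

test_that("dashpot damps only the axial velocity component", {
  pos <- rbind(c(0, 0, 0), c(1e-6, 0, 0))
  edges <- matrix(c(1L, 2L), 1)
  vel <- rbind(c(1e-8, 2e-8, 0), c(0, 0, 0))
  F <- mechamigr:::cpp_dashpot_forces(pos, vel, edges, 0.5)
  expect_equal(F[1, ], c(-0.5 * 1e-8, 0, 0))  # axial only, opposing motion
  expect_equal(F[1, ], -F[2, ])
})

test_that("restoring directions: inflation pulls inward, compression pushes outward", {
  m <- fixture_mesh()
  ctr <- colMeans(m$pos)
  outward <- sweep(m$pos, 2, ctr)
  outward <- outward / sqrt(rowSums(outward^2))
  infl <- m; infl$pos <- sweep(sweep(m$pos, 2, ctr), 1, 1.05, `*`)
  infl$pos <- sweep(infl$pos, 2, ctr, `+`)
  Fa <- area_conservation_forces(infl, p)
  expect_lt(mean(rowSums(Fa * outward)), 0)   # inward on average
  comp <- m; comp$pos <- sweep(sweep(m$pos, 2, ctr), 1, 0.95, `*`)
  comp$pos <- sweep(comp$pos, 2, ctr, `+`)
  Fv <- volume_conservation_force(comp, p)
  expect_gt(mean(rowSums(Fv * outward)), 0)   # outward on average
})

test_that("cortex forces are internal: zero net force, zero net torque", {
  m <- fixture_perturbed_mesh()
  F <- cortex_forces(m, p)
  expect_lt(max(abs(colSums(F))), 1e-12 * max(abs(F)) * nrow(F) + 1e-25)
  tq <- colSums(cbind(
    m$pos[, 2] * F[, 3] - m$pos[, 3] * F[, 2],
    m$pos[, 3] * F[, 1] - m$pos[, 1] * F[, 3],
    m$pos[, 1] * F[, 2] - m$pos[, 2] * F[, 1]))
  expect_lt(max(abs(tq)), 1e-12 * max(abs(F)))
})

test_that("a perturbed sphere relaxes: cortex energy is non-increasing", {
  m <- fixture_perturbed_mesh()
  contact <- rep(FALSE, nrow(m$pos))
  E <- cortex_energy(m, p)
  for (i in 1:50) {
    F <- cortex_forces(m, p)
    v <- solve_velocities(m, F, contact = contact, params = p)
    m$pos <- m$pos + v * p$dt
    m$vel <- v
    E2 <- cortex_energy(m, p)
    expect_lte(E2, E * (1 + 1e-12))
    E <- E2
  }
})
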