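p <- fixture_params()

test_that("pure decay follows the closed form e^(-k_deg t)", {
  m <- fixture_icosahedron()
  pd <- mm_params(D_actin = 1e-30)   # diffusion switched off
  G <- rep(1, nrow(m$tris))
  n <- round((1 / pd$k_deg) / pd$dt) # advance to t = 1/k_deg = 62.5 s
  for (i in seq_len(n)) G <- step_actin_field(G, m, integer(0), pd$dt, pd)
  expect_equal(G[1], exp(-1), tolerance = 1e-3)
  expect_true(all(abs(G - G[1]) < 1e-15))
})

test_that("source triangles approach the balance k_gen / k_deg without diffusion", {
  m <- fixture_icosahedron()
  pd <- mm_params(D_actin = 1e-30)
  G <- numeric(nrow(m$tris))
  for (i in seq_len(round(400 / pd$dt))) G <- step_actin_field(G, m, 1:3, pd$dt, pd)
  expect_equal(G[1], pd$k_gen / pd$k_deg, tolerance = 2e-3)
  expect_lt(G[10], 1e-6 * pd$k_gen / pd$k_deg)  # sink triangles stay empty
})

test_that("explicit stepping preserves nonnegativity and enforces the bound", {
  m <- fixture_icosahedron()
  set.seed(7)
  G <- runif(nrow(m$tris)) * p$k_gen / p$k_deg
  for (i in 1:100) {
    G <- step_actin_field(G, m, c(2, 9), p$dt, p)
    expect_true(min(G) >= 0)
  }
  expect_error(step_actin_field(G, m, 1:2, dt = 1e5, p, subcycle = FALSE),
               "stability bound")
})

test_that("mesh diffusion matches a dense graph-Laplacian integrator", {
  m <- fixture_icosahedron()  # 20-triangle fixture
  W <- mechamigr:::cpp_fv_weights(m$pos, m$tris, m$tri_adj)
  A <- triangle_areas(m$pos, m$tris)
  nt <- nrow(m$tris)
  L <- matrix(0, nt, nt)
  for (t in seq_len(nt)) for (s in 1:3) {
    u <- m$tri_adj[t, s]
    if (u > 0) { L[t, u] <- L[t, u] + W[t, s] / A[t]
                 L[t, t] <- L[t, t] - W[t, s] / A[t] }
  }
  set.seed(1)
  G <- runif(nt) * 1e12
  src <- c(3, 11)
  sv <- numeric(nt); sv[src] <- p$k_gen
  for (i in 1:200) {
    Gc <- step_actin_field(G, m, src, p$dt, p)
    Gd <- G + p$dt * (sv - p$k_deg * G + p$D_actin * as.vector(L %*% G))
    expect_lt(max(abs(Gc - Gd)) / max(abs(Gd)), 1e-8)
    G <- Gc
  }
})

test_that("steady-state decay length from the periphery is sqrt(D/k_deg)", {
  # 1D strip of triangles: closed-form decay exp(-x / sqrt(D/k_deg))
  st <- fixture_init()
  G <- st$raw$G
  m <- st$mesh
  src <- identify_periphery(m, p)
  cen <- (m$pos[m$tris[, 1], ] + m$pos[m$tris[, 2], ] + m$pos[m$tris[, 3], ]) / 3
  ifl <- interface_flags(m, p)$tris
  # distance of each interface triangle to the nearest source centroid
  d <- vapply(which(ifl), function(t)
    min(sqrt(rowSums(sweep(cen[src, , drop = FALSE], 2, cen[t, ])^2))),
    numeric(1))
  g <- G[ifl]
  keep <- d > 1e-7 & g > 0
  lam_fit <- -1 / stats::coef(stats::lm(log(g[keep]) ~ d[keep]))[2]
  lam <- sqrt(p$D_actin / p$k_deg)
  expect_lt(abs(lam_fit - lam) / lam, 0.35) # coarse mesh; right length scale
})

test_that("periphery identification returns the interface boundary ring", {
  st <- fixture_init()
  m <- st$mesh
  src <- identify_periphery(m, p)
  ifl <- interface_flags(m, p)$tris
  expect_true(length(src) > 0)
  expect_true(all(ifl[src]))
  # every source triangle touches a non-interface neighbor
  for (t in src) {
    nb <- m$tri_adj[t, ]
    expect_true(any(!ifl[nb[nb > 0]]))
  }
  # a detached sphere has no sources
  sphere <- build_cell_mesh(8e-6, 2, center = c(0, 0, 5e-5))
  expect_warning(src0 <- identify_periphery(sphere, p), "no substrate interface")
  expect_length(src0, 0)
})

test_that("region demarcation has the banded threshold structure", {
  st <- fixture_init()
  m <- st$mesh
  G <- st$raw$G
  lab <- demarcate_regions(G, m, p)
  expect_setequal(levels(lab), c("Lp", "frontLm", "rearLm", "body", "top"))
  ifl <- interface_flags(m, p)$tris
  expect_true(all(lab[!ifl] == "top"))
  # Lp only on the leading front, above the Lp threshold (peak-normalized)
  gmax <- max(G)
  expect_true(all(G[lab == "Lp"] >= p$theta_Lp * gmax))
  cen_x <- (m$pos[m$tris[, 1], 1] + m$pos[m$tris[, 2], 1] + m$pos[m$tris[, 3], 1]) / 3
  expect_true(all(cen_x[lab == "Lp"] >= attr(lab, "com_x")))
  # Lm lies between the thresholds (rear Lm may absorb high-G rear periphery)
  expect_true(all(G[lab == "frontLm"] >= p$theta_Lm * gmax))
  expect_true(all(G[lab == "frontLm"] < p$theta_Lp * gmax))
  # an unreachable Lp threshold removes the lamellipodium but keeps the Lm
  p2 <- mm_params(theta_Lp = 1e6)
  lab2 <- suppressWarnings(demarcate_regions(G, m, p2))
  expect_equal(sum(lab2 == "Lp"), 0)
  expect_gt(sum(lab2 %in% c("frontLm", "rearLm")), 0)
  expect_no_error(suppressWarnings(
    demarcate_regions(G, m, mm_params(theta_Lp = 0.05, theta_Lm = 0.04))))
})

test_that("front/rear split is balanced, tie-broken to the front, and frame-invariant", {
  st <- fixture_init()
  m <- st$mesh
  sp <- split_front_rear(m, p)
  ifl <- interface_flags(m, p)
  nf <- sum(sp$node_front[ifl$nodes])
  nr <- sum(!sp$node_front[ifl$nodes])
  expect_lt(abs(nf - nr), 8) # near-symmetric spread cell
  # translation in x leaves the partition unchanged
  m2 <- m; m2$pos[, 1] <- m2$pos[, 1] + 5e-6
  sp2 <- split_front_rear(m2, p)
  expect_identical(sp$node_front, sp2$node_front)
  expect_equal(sp2$com_x - sp$com_x, 5e-6)
  # all nodes at the same x -> everything is front
  m3 <- m; m3$pos[, 1] <- 0
  expect_true(all(split_front_rear(m3, p)$node_front))
})

test_that("protrusion acts only on Lp triangles and is balanced by the counter force", {
  st <- fixture_init()
  m <- st$mesh
  G <- st$raw$G
  lab <- demarcate_regions(G, m, p)
  pr <- protrusion_forces(G, m, lab, p)
  expect_true(all(pr$tri_force[lab != "Lp", ] == 0))
  expect_true(all(pr$tri_force[, 3] == 0))  # substrate-tangent projection
  # uniform field -> zero gradient -> zero force (guarded)
  pr0 <- protrusion_forces(rep(1e12, length(G)), m, lab, p)
  expect_equal(max(abs(pr0$tri_force)), 0)
  # counter force balances protrusion exactly
  cnt <- counter_force(pr, m)
  expect_equal(colSums(pr$node_force) + colSums(cnt), c(0, 0, 0))
  expect_lt(max(abs(colSums(pr$node_force) + colSums(cnt))), 1e-24)
  # explicit division: total 1 nN over 162 nodes
  tf <- matrix(0, length(G), 3); tf[1, 1] <- 1e-9
  cnt2 <- counter_force(tf, m)
  expect_equal(cnt2[5, 1], -1e-9 / 162)
  # no Lp -> zero everywhere
  cnt3 <- counter_force(matrix(0, length(G), 3), m)
  expect_equal(max(abs(cnt3)), 0)
})
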