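# Shared fixtures, built in code and memoized for the session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_params <- function() mm_params()

# icosphere fixture at test resolution (162 nodes / 320 triangles)
fixture_mesh <- function() memo("mesh2", function() build_cell_mesh(8e-6, 2L))

# a gently perturbed copy for gradient checks (fixed seed, reproducible)
fixture_perturbed_mesh <- function() memo("mesh2_pert", function() {
  m <- build_cell_mesh(8e-6, 2L)
  set.seed(42)
  m$pos <- m$pos + matrix(rnorm(length(m$pos), sd = 2e-7), ncol = 3)
  m
})

# raw icosahedron (12 nodes / 20 triangles) for brute-force oracles
fixture_icosahedron <- function() memo("ico20", function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2)) * 8e-6
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mesh_from_triangulation(v, f)
})

# unit cube, outward-oriented, 12 triangles
fixture_cube <- function() memo("cube", function() {
  v <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
             c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  f <- rbind(c(1,3,2), c(1,4,3),   # bottom (-z)
             c(5,6,7), c(5,7,8),   # top (+z)
             c(1,2,6), c(1,6,5),   # front (-y)
             c(3,4,8), c(3,8,7),   # back (+y)
             c(1,5,8), c(1,8,4),   # left (-x)
             c(2,3,7), c(2,7,6))   # right (+x)
  list(pos = v, tris = f)
})

# initialized spread cell at test resolution; deterministic, reused widely
fixture_init <- function() memo("init2", function() initialize_cell(
  fixture_params(), subdivision = 2L))

# central finite-difference force check: max |F - (-dE/dx)| / max |dE/dx|
fd_force_error <- function(force_fun, energy_fun, mesh, h = 1e-10) {
  F <- force_fun(mesh)
  g <- matrix(0, nrow(mesh$pos), 3)
  for (i in seq_len(nrow(mesh$pos))) {
    for (c in 1:3) {
      mp <- mesh; mp$pos[i, c] <- mp$pos[i, c] + h
      mn <- mesh; mn$pos[i, c] <- mn$pos[i, c] - h
      g[i, c] <- -(energy_fun(mp) - energy_fun(mn)) / (2 * h)
    }
  }
  max(abs(F - g)) / max(abs(g))
}
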