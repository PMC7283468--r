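p <- fixture_params()

test_that("traction map: per-triangle normalization and the conservation identity", {
  g <- build_substrate_grid()
  # no FAs -> empty (all-zero) map, zero total traction
  empty <- traction_map(data.frame(anchor_x = numeric(), anchor_y = numeric(),
                                   Fx = numeric(), Fy = numeric(),
                                   Fz = numeric()), g)
  expect_equal(nrow(empty), 0)
  expect_equal(total_traction(empty), 0)
  # one FA of 1 nN on one triangle -> |T| = 1e-9 / 2.102e-12 = 475.7 Pa
  one <- traction_map(data.frame(anchor_x = 1e-7, anchor_y = 1e-7,
                                 Fx = 1e-9, Fy = 0, Fz = 0), g)
  expect_equal(nrow(one), 1)
  expect_equal(one$T_mag, 1e-9 / 2.102e-12, tolerance = 1e-12)
  expect_equal(total_traction(one), 475.7, tolerance = 1e-3)
  # conservation: sum_triangles A * T_vec = sum of FA force vectors, exactly
  set.seed(8)
  n <- 40
  fas <- data.frame(anchor_x = runif(n, -3e-5, 3e-5),
                    anchor_y = runif(n, -1.5e-5, 1.5e-5),
                    Fx = rnorm(n, sd = 1e-9), Fy = rnorm(n, sd = 1e-9),
                    Fz = rnorm(n, sd = 5e-10))
  tm <- traction_map(fas, g)
  expect_equal(colSums(cbind(tm$Tx, tm$Ty, tm$Tz)) * g$A_tri,
               colSums(cbind(fas$Fx, fas$Fy, fas$Fz)), tolerance = 1e-12)
  # sum of magnitudes bounds the magnitude of the sum
  expect_gte(total_traction(tm),
             sqrt(sum(colSums(cbind(tm$Tx, tm$Ty, tm$Tz))^2)))
  # anchor outside the grid is an error
  expect_error(traction_map(data.frame(anchor_x = 1, anchor_y = 0, Fx = 0,
                                       Fy = 0, Fz = 0), g), "outside")
})

test_that("center-of-mass displacement is the telescoped frame-to-frame sum", {
  m <- data.frame(time = 1:5, com_x = rep(2e-6, 5))
  expect_equal(com_displacement(m), rep(0, 5))
  m2 <- data.frame(time = 1:4, com_x = 2e-6 + (0:3) * 1e-7)
  expect_equal(com_displacement(m2), (0:3) * 1e-7)
  expect_equal(utils::tail(com_displacement(m2), 1), 3e-7)
  expect_length(com_displacement(data.frame()), 0)
})

test_that("mode classification follows the event/displacement rules", {
  t_h <- seq(0, 24 * 3600, by = 600)
  # any full-retraction event -> collective
  m <- data.frame(time = t_h, com_x = 0)
  expect_equal(classify_mode(m, n_retractions = 1), "collective")
  # monotone displacement to 8 um with no events -> progressive
  m2 <- data.frame(time = t_h, com_x = seq(0, 8e-6, length.out = length(t_h)))
  expect_equal(classify_mode(m2, n_retractions = 0), "progressive")
  # net negative displacement -> none
  m3 <- data.frame(time = t_h, com_x = seq(0, -2e-6, length.out = length(t_h)))
  expect_equal(classify_mode(m3, n_retractions = 0), "none")
  # large displacement that stalls for > 4 h is not progressive
  com <- c(seq(0, 8e-6, length.out = 60), rep(8e-6, length(t_h) - 60))
  m4 <- data.frame(time = t_h, com_x = com)
  expect_equal(classify_mode(m4, n_retractions = 0), "none")
  # below the 3-um threshold -> none
  m5 <- data.frame(time = t_h, com_x = seq(0, 2e-6, length.out = length(t_h)))
  expect_equal(classify_mode(m5, n_retractions = 0), "none")
  expect_error(classify_mode(m5), "n_retractions")
})

test_that("FA lifetimes are matched form-to-death per node", {
  ev <- data.frame(
    time = c(0, 10, 12, 50, 3, 40),
    node = c(1, 1, 1, 1, 2, 2),
    type = c("form", "disassemble", "form", "rupture", "form", "disassemble"))
  lt <- fa_lifetimes(ev)
  expect_setequal(lt, c(10, 38, 37))
  expect_length(fa_lifetimes(ev[0, ]), 0)
})

test_that("study aggregation: replicate means, SEM, and row structure", {
  # synthetic runs: deterministic metrics logs wrapped as cell_sim objects
  mk <- function(k, r0, disp_um, seed) {
    t <- seq(0, 7200, by = 600)
    m <- data.frame(time = t, com_x = seq(0, disp_um * 1e-6, length.out = length(t)),
                    n_fa = 10, n_sf = 4, cum_ruptures = 0, cum_disassembly = 5,
                    n_retractions = 0, traction = 100, mean_n_str = 1,
                    volume = 2e-15, n_interface_nodes = 60, mean_f_prot = 1e-10,
                    cum_formations = 15)
    structure(list(metrics = m,
                   events = data.frame(time = numeric(), node = integer(),
                                       type = character(), F = numeric(),
                                       region = character()),
                   state = list(raw = list(retract_times = numeric(0))),
                   condition = mm_condition(k, r0), setup = mm_setup(TRUE, TRUE),
                   duration = 7200, seed = seed),
              class = "cell_sim")
  }
  # five identical replicates -> SEM 0
  runs <- lapply(1:5, function(s) mk(0.5, 5e-4, 4, s))
  agg <- aggregate_study(runs)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$n_reps, 5)
  expect_equal(agg$displacement_sem, 0)
  expect_equal(agg$displacement_mean, 4e-6)
  # mean of {1..5} um -> 3 um, SEM = sd/sqrt(5) = 0.707 um
  runs2 <- lapply(1:5, function(s) mk(1e-3, 5e-4, s, s + 10))
  agg2 <- aggregate_study(runs2)
  expect_equal(agg2$displacement_mean, 3e-6)
  expect_equal(agg2$displacement_sem, 0.7071068e-6, tolerance = 1e-6)
  # one row per condition x setup
  agg3 <- aggregate_study(c(runs, runs2))
  expect_equal(nrow(agg3), 2)
})

test_that("metrics and manifests write readable CSV", {
  man <- enumerate_conditions(c(1e-3, 5e-1), c(5e-4), list(mm_setup()), reps = 2)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_manifest_csv(man, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(man))
  expect_equal(back$seed, man$seed)
})

test_that("VTK polydata export carries geometry and per-triangle fields", {
  m <- fixture_icosahedron()
  f <- tempfile(fileext = ".vtk")
  on.exit(unlink(f))
  write_vtk_polydata(m, f, cell_data = list(G = seq_len(nrow(m$tris))))
  txt <- readLines(f)
  expect_equal(txt[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS 12 double", txt)))
  expect_true(any(grepl("^POLYGONS 20 80", txt)))
  expect_true(any(grepl("^SCALARS G double 1", txt)))
})
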