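p <- fixture_params()

test_that("logistic weakening: phi ~ 1 at rest, exactly 1/2 at -dL50, to 0 in the limit", {
  expect_equal(sf_weakening_phi(0, p), 1 / (1 + exp(-p$mu * p$dL50)))
  expect_gt(sf_weakening_phi(0, p), 1 - 3e-8)     # mu * dL50 = 17.5
  expect_identical(sf_weakening_phi(-p$dL50, p), 0.5)
  expect_equal(sf_weakening_phi(-1, p), 0)
  # strictly increasing in dL
  dl <- seq(-6e-6, 2e-6, length.out = 40)
  expect_true(all(diff(sf_weakening_phi(dl, p)) > 0))
})

test_that("fiber force: one actomyosin unit when fresh, n_str units at the cap", {
  a <- c(0, 0, 0); b <- c(9e-6, 0, 0)
  fresh <- sf_force(a, b, L0 = 9e-6, n_str = 1, p)
  expect_equal(fresh$magnitude, 1e-9, tolerance = 3e-8)
  strong <- sf_force(a, b, L0 = 9e-6, n_str = 5, p)
  expect_equal(strong$magnitude, 5e-9, tolerance = 3e-8)
  # attraction along the axis, equal and opposite
  expect_gt(fresh$force_i[1], 0)
  expect_equal(fresh$force_i, -fresh$force_j)
  expect_warning(z <- sf_force(a, a, 9e-6, 1, p), "coincident")
  expect_equal(z$magnitude, 0)
})

test_that("fiber formation enforces the length and exclusivity conditions", {
  pos <- rbind(c(0, 0, 0), c(7.9e-6, 0, 0), c(9e-6, 0, 0), c(20e-6, 0, 0))
  pf <- mm_params(r_sf = 1e6)  # every eligible FA attempts each step
  # pair at 7.9 um is below the minimum initial length: never accepted
  set.seed(5)
  for (i in 1:20) {
    out <- form_stress_fibers(c(1L, 2L), pos, 0, pf)
    expect_equal(nrow(out), 0)
  }
  # valid pair: fiber carries n_str = 1 and the formation length
  set.seed(6)
  out <- form_stress_fibers(c(1L, 3L), pos, clock = 12, pf)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_str, 1L)
  expect_equal(out$L0, 9e-6)
  expect_equal(out$birth, 12)
  expect_identical(sf_weakening_phi(out$L0 - out$L0, p) > 0.999, TRUE)
  # bound FAs are excluded by the caller contract: nodes already used are
  # consumed within one call as pairs form
  set.seed(7)
  out2 <- form_stress_fibers(c(1L, 3L, 4L), pos, 0, pf)
  expect_lte(nrow(out2), 1)   # at most one pair can form among three FAs
  if (nrow(out2)) expect_false(anyDuplicated(c(out2$node_i, out2$node_j)) > 0)
})

test_that("stalling compares 10-s window means and strengthening caps at 5", {
  nblock <- round(p$ma_window / p$dt)
  fresh <- list(block_sum = 0, block_n = 0L, prev_avg = 0,
                prev_valid = FALSE, n_str = 1L)
  # constant length across two windows -> stall at the second comparison
  sf <- fresh
  stalls <- 0
  for (i in seq_len(2 * nblock)) {
    sf <- update_stall_and_strengthen(sf, 9e-6, TRUE, p)
    stalls <- stalls + sf$stalled
  }
  expect_equal(stalls, 1)
  expect_equal(sf$n_str, 2L)
  # shortening of 1 nm per window exceeds L_thr = 0.075 nm: no stall
  sf <- fresh
  L <- 9e-6
  for (w in 1:4) {
    for (i in seq_len(nblock)) {
      L <- L - 1e-9 / nblock
      sf <- update_stall_and_strengthen(sf, L, TRUE, p)
      expect_false(sf$stalled)
    }
  }
  expect_equal(sf$n_str, 1L)
  # the cap: stalls detected but n_str stays at n_str_max
  sf <- fresh; sf$n_str <- 5L
  for (i in seq_len(2 * nblock)) sf <- update_stall_and_strengthen(sf, 9e-6, TRUE, p)
  expect_equal(sf$n_str, 5L)
  # with strengthening off, stalls are detected but n_str stays 1
  sf <- fresh
  stalls <- 0
  for (i in seq_len(3 * nblock)) {
    sf <- update_stall_and_strengthen(sf, 9e-6, FALSE, p)
    stalls <- stalls + sf$stalled
  }
  expect_equal(stalls, 2)
  expect_equal(sf$n_str, 1L)
})

test_that("fibers persist on one adhesion and die when both are gone", {
  sfs <- data.frame(id = 1:3,
                    has_fa_i = c(TRUE, FALSE, FALSE),
                    has_fa_j = c(TRUE, TRUE, FALSE))
  kept <- prune_stress_fibers(sfs)
  expect_equal(kept$id, c(1L, 2L))
})

test_that("isolated two-spring experiment: staircase, F_am steps, plateau at the cap", {
  tr <- reduced_two_spring_experiment(4.16e-2, duration = 7200, params = p)
  # non-decreasing staircase
  expect_true(all(diff(tr$F_ECM) > -1e-15))
  expect_true(all(diff(tr$n_str) >= 0))
  # plateau at n_str_max units of the actomyosin force
  expect_equal(max(tr$n_str), 5)
  expect_equal(utils::tail(tr$F_ECM, 1), 5 * p$F_am, tolerance = 1e-3)
  # plateau levels sit at integer multiples of F_am: step height ~ F_am
  lev <- vapply(1:5, function(n) max(tr$F_ECM[tr$n_str == n]), numeric(1))
  expect_equal(lev / p$F_am, 1:5, tolerance = 2e-2)
  # strengthening is one-way and capped (invariant over the whole trace)
  expect_true(all(tr$n_str %in% 1:5))
})

test_that("time to first stall is non-increasing in ligand stiffness", {
  ks <- c(1.2e-2, 2.4e-2, 4.16e-2, 1.44e-1)  # spans the study range
  first_stall <- vapply(ks, function(k) {
    tr <- reduced_two_spring_experiment(k, duration = 2400, params = p)
    attr(tr, "stall_times")[1]
  }, numeric(1))
  expect_true(all(diff(first_stall) <= 0))
  # the stiff substrate reaches its second force plateau before the soft one
  t2 <- vapply(c(1.2e-2, 4.16e-2), function(k) {
    tr <- reduced_two_spring_experiment(k, duration = 2400, params = p)
    min(tr$time[tr$n_str >= 2])
  }, numeric(1))
  expect_lt(t2[2], t2[1])
})
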