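#' Assemble the friction operator as a sparse matrix
#'
#' The overdamped equation of motion is `M v = F` with a symmetric positive
#' definite friction operator `M` built from three sources: liquid (Stokes)
#' drag `Gamma_liquid` on every node, substrate contact friction
#' `Gamma_subs` on interface nodes, and the cortex dashpots, which couple
#' edge-connected nodes through the axis projector `Lambda_d n n^T`. The
#' engine applies this operator matrix-free; this explicit assembly is the
#' reference for symmetry/definiteness diagnostics and testing.
#'
#' @param mesh a `cell_mesh`.
#' @param contact logical vector (N): nodes in substrate contact.
#' @param params an `mm_params` object.
#' @return a symmetric sparse `Matrix::dgCMatrix` of size 3N x 3N
#'   (node-major: rows `3i-2, 3i-1, 3i` are node `i`).
#' @export
assemble_friction <- function(mesh, contact = NULL, params = mm_params()) {
  stopifnot(inherits(mesh, "cell_mesh"))
  n <- nrow(mesh$pos)
  if (is.null(contact)) contact <- interface_flags(mesh, params)$nodes
  stopifnot(length(contact) == n)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  # diagonal drag
  d <- rep(params$Gamma_liquid, n) + ifelse(contact, params$Gamma_subs, 0)
  ii <- c(ii, seq_len(3 * n)); jj <- c(jj, seq_len(3 * n))
  xx <- c(xx, rep(d, each = 3))
  # edge dashpots, axis-projected
  for (e in seq_len(nrow(mesh$edges))) {
    i <- mesh$edges[e, 1]; j <- mesh$edges[e, 2]
    dvec <- mesh$pos[j, ] - mesh$pos[i, ]
    len <- sqrt(sum(dvec^2))
    if (len <= 0) stop("zero-length edge", call. = FALSE)
    nh <- dvec / len
    B <- params$Lambda_d * (nh %o% nh)
    bi <- 3 * (i - 1); bj <- 3 * (j - 1)
    for (a in 1:3) for (b in 1:3) {
      ii <- c(ii, bi + a, bj + a, bi + a, bj + a)
      jj <- c(jj, bi + b, bj + b, bj + b, bi + b)
      xx <- c(xx, B[a, b], B[a, b], -B[a, b], -B[a, b])
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3 * n, 3 * n))
}

#' One overdamped velocity solve
#'
#' Solves `M v = F` for all node velocities with the matrix-free
#' preconditioned conjugate-gradient solver the engine uses.
#'
#' @param mesh a `cell_mesh`.
#' @param F N x 3 force matrix, N.
#' @param contact logical vector of contact nodes (default from interface).
#' @param params an `mm_params` object.
#' @param v0 warm-start velocities (default: the mesh velocities).
#' @return N x 3 velocity matrix, m/s.
#' @export
solve_velocities <- function(mesh, F, contact = NULL, params = mm_params(),
                             v0 = mesh$vel) {
  if (is.null(contact)) contact <- interface_flags(mesh, params)$nodes
  cpp_solve_velocities(mesh$pos, mesh$edges, as.integer(contact),
                       params$Lambda_d, params$Gamma_subs,
                       params$Gamma_liquid, F, v0, 1e-12, 5000)
}

#' Detect a full (collective) retraction
#'
#' Fires when at least `n_thr` FA ruptures fall within the trailing
#' `rupture_window` (60 s). After an event the window bookkeeping is reset,
#' so one cascade is never counted twice.
#'
#' @param rupture_times numeric vector of rupture timestamps, s.
#' @param clock current time, s.
#' @param params an `mm_params` object.
#' @return list `fired` (logical) and `remaining` (timestamps to carry
#'   forward: empty after an event).
#' @export
#' @examples
#' detect_full_retraction(seq(0, 59, length.out = 15), 59)$fired  # TRUE
detect_full_retraction <- function(rupture_times, clock,
                                   params = mm_params()) {
  keep <- rupture_times[rupture_times > clock - params$rupture_window]
  if (length(keep) >= params$n_thr) list(fired = TRUE, remaining = numeric(0))
  else list(fired = FALSE, remaining = keep)
}

## internal: fresh per-run state holder around a mesh
new_sim_state <- function(mesh, params) {
  n <- nrow(mesh$pos)
  list(
    pos = mesh$pos, vel = mesh$vel, G = numeric(nrow(mesh$tris)),
    refractory = numeric(n),
    fa_alive = integer(n), fa_ax = numeric(n), fa_ay = numeric(n),
    fa_birth = numeric(n), fa_sf = integer(n), fa_L0 = numeric(n),
    sf = matrix(0, 0, 13), clock = 0,
    cum_rupt = 0L, cum_dis = 0L, cum_form = 0L, n_retract = 0L,
    last_com = mean(mesh$pos[, 1]),
    rupture_times = numeric(0), retract_times = numeric(0)
  )
}

.mesh_clist <- function(mesh) {
  list(tris = mesh$tris, edges = mesh$edges, edge_rest = mesh$edge_rest,
       hinges = mesh$hinges, theta_ref = mesh$theta_ref,
       tri_adj = mesh$tri_adj, tri_opp = mesh$tri_opp,
       tri_ref_area = mesh$tri_ref_area,
       ref_total_area = mesh$ref_total_area, ref_volume = mesh$ref_volume,
       node_tri_ptr = mesh$node_tri_ptr, node_tri_idx = mesh$node_tri_idx)
}

.grid_clist <- function(grid) {
  list(x0 = grid$x0, y0 = grid$y0, l = grid$l, A_tri = grid$A_tri,
       nx = grid$nx, ny = grid$ny)
}

#' Initialize the cell on the substrate
#'
#' The attach-and-spread phase that precedes every migration run: the built
#' sphere is placed tangent to the plane and advanced under cortex, contact
#' and the uniform spreading load only - no FAs, no stress fibers, no
#' mechanosensing - in one-minute increments until the cell-substrate
#' interface area changes by less than 1% per minute (with `init_duration`
#' as the budget, whichever comes first). The spreading load is a standing
#' force of the model (it represents the active spreading machinery), so
#' the initialized shape is an equilibrium of forces that persist during
#' migration. The actin field is then advanced to steady state on the
#' settled geometry. The procedure is deterministic and identical for every
#' condition and setup.
#'
#' @param params an `mm_params` object.
#' @param subdivision mesh subdivision level (3 = production, 2 = fixtures).
#' @param grid a `substrate_grid` (default built to 80 x 40 um).
#' @return an object of class `sim_state` bundling the mesh, raw state,
#'   grid and parameters.
#' @export
initialize_cell <- function(params = mm_params(), subdivision = 3L,
                            grid = build_substrate_grid()) {
  mesh <- build_cell_mesh(params$R_c, subdivision,
                          center = c(0, 0, params$R_c + params$d_contact / 2))
  st <- new_sim_state(mesh, params)
  mc <- .mesh_clist(mesh)
  gc <- .grid_clist(grid)
  n_chunk <- max(1L, round(60 / params$dt))
  spread_f <- params$spread_pressure * mesh$ref_total_area / nrow(mesh$pos)
  area_prev <- 0
  t <- 0
  repeat {
    st <- cpp_simulate(st, mc, params, gc, FALSE, FALSE, 1e-3, 1e-3,
                       n_chunk, n_chunk, FALSE, FALSE, spread_f,
                       FALSE)
    t <- t + 60
    mesh$pos <- st$pos
    fl <- interface_flags(mesh, params)
    area <- sum(triangle_areas(mesh$pos, mesh$tris)[fl$tris])
    converged <- area > 0 && area_prev > 0 &&
      abs(area - area_prev) / area_prev < 0.01
    area_prev <- area
    if ((converged && t >= 180) || t >= params$init_duration) break
  }
  mesh$vel <- st$vel
  fl <- interface_flags(mesh, params)
  if (!any(fl$tris))
    stop("initialization failed: cell did not attach to the plane",
         call. = FALSE)
  # actin to steady state on the settled geometry
  st$G <- actin_steady_state(mesh, identify_periphery(mesh, params), params)
  structure(list(mesh = mesh, raw = st, grid = grid, params = params),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  fl <- interface_flags(x$mesh, x$params)
  cat(sprintf("<sim_state> t = %.1f s, %d interface nodes, %d FAs, %d live SFs\n",
              x$raw$clock, sum(fl$nodes), sum(x$raw$fa_alive),
              if (nrow(x$raw$sf)) sum(x$raw$sf[, 12] > 0) else 0L))
  invisible(x)
}

#' Advance a simulation state
#'
#' Runs the coupled migration loop for a span of simulated time: forces
#' (cortex, contact, FA, SF, protrusion + counter), implicit friction solve
#' for the velocities, position update, actin field and region update, then
#' the stochastic FA/SF sub-steps and full-retraction bookkeeping, in a
#' fixed documented order.
#'
#' @param state a `sim_state` from [initialize_cell()].
#' @param duration simulated time to advance, s.
#' @param setup an [mm_setup()].
#' @param condition an [mm_condition()].
#' @param save_every metrics sampling interval, s.
#' @param record_events log individual FA events?
#' @return the advanced `sim_state`, with a `metrics` data.frame and
#'   `events` data.frame accumulated under `$log`.
#' @export
step_simulation <- function(state, duration, setup, condition,
                            save_every = 10, record_events = TRUE) {
  stopifnot(inherits(state, "sim_state"))
  params <- state$params
  n_steps <- round(duration / params$dt)
  sv <- max(1L, round(save_every / params$dt))
  res <- cpp_simulate(state$raw, .mesh_clist(state$mesh), params,
                      .grid_clist(state$grid),
                      setup$fa_mat, setup$sf_str,
                      condition$k_ECM, condition$r_off0,
                      n_steps, sv, TRUE, TRUE,
                      params$spread_pressure * state$mesh$ref_total_area /
                        nrow(state$mesh$pos),
                      record_events)
  metrics <- as.data.frame(res$metrics)
  names(metrics) <- c("time", "com_x", "n_fa", "n_sf", "cum_ruptures",
                      "cum_disassembly", "n_retractions", "traction",
                      "mean_n_str", "volume", "n_interface_nodes",
                      "mean_f_prot", "cum_formations")
  events <- as.data.frame(res$events)
  if (nrow(events)) {
    names(events) <- c("time", "node", "type", "F", "region")
    events$type <- c("form", "disassemble", "rupture")[events$type]
    events$region <- c("front", "rear")[events$region]
  } else {
    events <- data.frame(time = numeric(), node = integer(),
                         type = character(), F = numeric(),
                         region = character())
  }
  state$mesh$pos <- res$pos
  state$mesh$vel <- res$vel
  state$raw <- res
  state$log$metrics <- rbind(state$log$metrics, metrics)
  state$log$events <- rbind(state$log$events, events)
  state
}

#' Run a full migration simulation
#'
#' Initialization (attach and spread, identical for all conditions) followed
#' by the migration loop for the requested duration under a given condition
#' and mechanosensing setup. Fully reproducible from the seed.
#'
#' @param condition an [mm_condition()] (ligand stiffness and zero-force FA
#'   disassembly rate).
#' @param setup an [mm_setup()] (mechanosensing switches).
#' @param duration simulated migration time, s (the 24-h study uses 86400).
#' @param seed integer RNG seed.
#' @param params an `mm_params` object.
#' @param subdivision mesh subdivision level.
#' @param save_every metrics sampling interval, s.
#' @param grid substrate grid (sized to contain the trajectory).
#' @param record_events keep the per-FA event log?
#' @param state optional pre-initialized `sim_state` to reuse (skips the
#'   attach-and-spread phase, e.g. when sweeping conditions).
#' @return an object of class `cell_sim`; see [classify_mode()],
#'   [com_displacement()], `print`, `summary` and `plot` methods.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_cell(mm_condition(0.5, 5e-4), mm_setup(TRUE, TRUE),
#'                      duration = 600, seed = 1, subdivision = 2)
#' summary(sim)
#' }
simulate_cell <- function(condition, setup, duration, seed = 1L,
                          params = mm_params(), subdivision = 3L,
                          save_every = 10, grid = build_substrate_grid(),
                          record_events = TRUE, state = NULL) {
  stopifnot(inherits(condition, "mm_condition"), inherits(setup, "mm_setup"))
  set.seed(seed)
  if (is.null(state)) {
    state <- initialize_cell(params, subdivision, grid)
  }
  if (duration > 0) {
    state <- step_simulation(state, duration, setup, condition,
                             save_every, record_events)
  }
  structure(list(state = state,
                 metrics = if (is.null(state$log$metrics))
                   data.frame() else state$log$metrics,
                 events = state$log$events,
                 condition = condition, setup = setup,
                 duration = duration, seed = seed, params = params),
            class = "cell_sim")
}

#' @export
print.cell_sim <- function(x, ...) {
  cat("<cell_sim> migration simulation\n")
  cat(sprintf("  condition: k_ECM = %g N/m, r_off0 = %g 1/s (<lambda> = %.1f min)\n",
              x$condition$k_ECM, x$condition$r_off0,
              expected_fa_lifetime(x$condition$r_off0)))
  cat(sprintf("  setup: FA maturation %s, SF strengthening %s\n",
              if (x$setup$fa_mat) "ON" else "OFF",
              if (x$setup$sf_str) "ON" else "OFF"))
  cat(sprintf("  duration %.2f h, seed %d, mode: %s\n", x$duration / 3600,
              x$seed, classify_mode(x)))
  invisible(x)
}

#' @export
summary.cell_sim <- function(object, ...) {
  m <- object$metrics
  disp <- com_displacement(m)
  out <- list(
    mode = classify_mode(object),
    displacement_um = if (length(disp)) utils::tail(disp, 1) * 1e6 else 0,
    n_retractions = if (nrow(m)) utils::tail(m$n_retractions, 1) else 0,
    cum_ruptures = if (nrow(m)) utils::tail(m$cum_ruptures, 1) else 0,
    mean_n_fa = if (nrow(m)) mean(m$n_fa) else 0,
    mean_traction_Pa = if (nrow(m)) mean(m$traction) else 0
  )
  class(out) <- "summary.cell_sim"
  out
}

#' @export
print.summary.cell_sim <- function(x, ...) {
  cat(sprintf("mode: %s | displacement %.2f um | retractions %d | ruptures %d\n",
              x$mode, x$displacement_um, x$n_retractions, x$cum_ruptures))
  cat(sprintf("mean FA count %.1f | mean traction %.1f Pa\n",
              x$mean_n_fa, x$mean_traction_Pa))
  invisible(x)
}

#' @export
plot.cell_sim <- function(x, ...) {
  m <- x$metrics
  if (!nrow(m)) { warning("no metrics to plot"); return(invisible(x)) }
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(m$time / 3600, com_displacement(m) * 1e6, type = "l",
                 xlab = "time [h]", ylab = "displacement [um]")
  graphics::abline(v = x$state$raw$retract_times / 3600, col = "red", lty = 3)
  graphics::plot(m$time / 3600, m$n_fa, type = "l",
                 xlab = "time [h]", ylab = "# FAs")
  graphics::plot(m$time / 3600, m$cum_ruptures, type = "l",
                 xlab = "time [h]", ylab = "cumulative ruptures")
  graphics::plot(m$time / 3600, m$traction, type = "l",
                 xlab = "time [h]", ylab = "total traction [Pa]")
  invisible(x)
}
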