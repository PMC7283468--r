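#' Interface flags for nodes and triangles
#'
#' A node belongs to the cell-substrate interface when it sits below the
#' height `z_interface`; a triangle belongs when all three of its nodes do.
#'
#' @param mesh a `cell_mesh`.
#' @param params an `mm_params` object.
#' @return list with logical vectors `nodes` (N) and `tris` (T).
#' @export
interface_flags <- function(mesh, params = mm_params()) {
  nodes <- mesh$pos[, 3] < params$z_interface
  tris <- nodes[mesh$tris[, 1]] & nodes[mesh$tris[, 2]] & nodes[mesh$tris[, 3]]
  list(nodes = nodes, tris = tris)
}

#' Identify the actin source triangles (cell periphery)
#'
#' The periphery of the cell-substrate interface is the source of the
#' globular-actin field: interface triangles adjacent to at least one
#' non-interface triangle form the boundary ring.
#'
#' @inheritParams interface_flags
#' @return integer vector of source triangle ids (possibly empty, with a
#'   warning, when the cell is detached).
#' @export
identify_periphery <- function(mesh, params = mm_params()) {
  fl <- interface_flags(mesh, params)
  ift <- fl$tris
  nbr_noniface <- matrix(TRUE, nrow(mesh$tris), 3)
  for (s in 1:3) {
    u <- mesh$tri_adj[, s]
    has <- u > 0
    nbr_noniface[has, s] <- !ift[u[has]]
  }
  src <- which(ift & (nbr_noniface[, 1] | nbr_noniface[, 2] | nbr_noniface[, 3]))
  if (!length(src)) warning("cell has no substrate interface: no actin sources")
  src
}

#' Advance the globular-actin surface field
#'
#' Explicit finite-volume step of
#' `dG/dt = k_gen 1[source] - k_deg G + D_actin lap(G)`
#' on the triangle mesh, with the surface Laplacian discretized over triangle
#' adjacency (flux weight = shared-edge length / centroid distance). When
#' `dt` exceeds the explicit stability bound the step is sub-cycled
#' (`subcycle = TRUE`, the default) or refused with the bound reported.
#'
#' @param G numeric vector, concentration per triangle (molecules/m^2).
#' @param mesh a `cell_mesh`.
#' @param sources integer vector of source triangle ids.
#' @param dt time step, s.
#' @param params an `mm_params` object.
#' @param subcycle logical; sub-cycle instead of failing above the bound.
#' @return updated concentration vector (nonnegative).
#' @export
step_actin_field <- function(G, mesh, sources, dt = NULL,
                             params = mm_params(), subcycle = TRUE) {
  stopifnot(inherits(mesh, "cell_mesh"), length(G) == nrow(mesh$tris))
  if (any(!is.finite(G)) || any(G < 0))
    stop("G must be finite and nonnegative", call. = FALSE)
  if (is.null(dt)) dt <- params$dt
  W <- cpp_fv_weights(mesh$pos, mesh$tris, mesh$tri_adj)
  areas <- triangle_areas(mesh$pos, mesh$tris)
  bound <- cpp_actin_stable_dt(mesh$tri_adj, W, areas, params$k_deg,
                               params$D_actin)
  nsub <- 1L
  if (dt > bound) {
    if (!subcycle)
      stop(sprintf("dt = %g s exceeds the explicit stability bound %g s",
                   dt, bound), call. = FALSE)
    nsub <- as.integer(ceiling(dt / bound))
  }
  src <- logical(nrow(mesh$tris))
  src[sources] <- TRUE
  cpp_actin_step(G, mesh$tri_adj, W, areas, src, params$k_gen, params$k_deg,
                 params$D_actin, dt, nsub)
}

#' Relax the actin field to steady state
#'
#' Repeated stepping until the maximum relative change per unit time falls
#' below `tol`, or `t_max` is reached.
#'
#' @inheritParams step_actin_field
#' @param tol relative change per second treated as converged.
#' @param t_max simulated-time budget, s.
#' @return concentration vector at (approximate) steady state.
#' @export
actin_steady_state <- function(mesh, sources, params = mm_params(),
                               tol = 1e-4, t_max = 1200) {
  G <- numeric(nrow(mesh$tris))
  dt <- 1 # coarse relaxation step, sub-cycled internally as needed
  t <- 0
  Gstar <- params$k_gen / params$k_deg
  while (t < t_max) {
    G2 <- step_actin_field(G, mesh, sources, dt, params)
    dmax <- max(abs(G2 - G)) / dt / Gstar
    G <- G2
    t <- t + dt
    if (t > 3 / params$k_deg && dmax < tol) break
  }
  G
}

#' Split the interface into front and rear
#'
#' Interface nodes and triangles with x-coordinate (centroid for triangles)
#' at or beyond the interface center of mass are the front; the rest are the
#' rear. Ties go to the front.
#'
#' @inheritParams interface_flags
#' @return list with `com_x`, logical `node_front` and `tri_front` vectors
#'   (defined for all entities, meaningful on the interface).
#' @export
split_front_rear <- function(mesh, params = mm_params()) {
  fl <- interface_flags(mesh, params)
  if (!any(fl$nodes)) stop("no interface: cell is detached", call. = FALSE)
  com_x <- mean(mesh$pos[fl$nodes, 1])
  cen <- triangle_centroids(mesh$pos, mesh$tris)
  list(com_x = com_x,
       node_front = mesh$pos[, 1] >= com_x,
       tri_front = cen[, 1] >= com_x)
}

#' Demarcate lamellipodium and lamella from the actin field
#'
#' Thresholds on the actin concentration, expressed as fractions
#' (`theta_Lp`, `theta_Lm`) of the current peak concentration (attained on
#' the source ring at steady state), partition the interface triangles: concentrations at or above the Lp
#' threshold on the leading front form the lamellipodium (the Lp fans out
#' the front only); concentrations between the two thresholds form the
#' lamellum, split into front and rear by the polarity axis; the remainder
#' of the interface is cell body, and off-interface triangles are the top
#' surface.
#'
#' @param G actin concentration per triangle.
#' @inheritParams interface_flags
#' @return factor of length T with levels `Lp`, `frontLm`, `rearLm`, `body`,
#'   `top`, plus attribute `com_x`.
#' @export
demarcate_regions <- function(G, mesh, params = mm_params()) {
  stopifnot(length(G) == nrow(mesh$tris))
  if (params$theta_Lm >= params$theta_Lp)
    stop("theta_Lm must be below theta_Lp", call. = FALSE)
  fl <- interface_flags(mesh, params)
  pol <- split_front_rear(mesh, params)
  gmax <- max(G)
  thLp <- params$theta_Lp * gmax
  thLm <- params$theta_Lm * gmax
  lab <- rep("top", length(G))
  ift <- fl$tris
  lab[ift] <- "body"
  lp <- ift & G >= thLp & pol$tri_front
  fr <- ift & !lp & G >= thLm & pol$tri_front
  rr <- ift & !lp & G >= thLm & !pol$tri_front
  # high-G rear triangles belong to the rear lamellum (no rear Lp)
  lab[lp] <- "Lp"; lab[fr] <- "frontLm"; lab[rr] <- "rearLm"
  if (!any(fr | rr)) warning("empty lamellum: thresholds may be miscalibrated")
  structure(factor(lab, levels = c("Lp", "frontLm", "rearLm", "body", "top")),
            com_x = pol$com_x)
}

#' Lamellipodial protrusion forces
#'
#' On each Lp triangle the protrusion force is `k_prot * G * ghat`, with
#' `ghat` the unit in-plane gradient of the actin field (pointing outward,
#' toward the periphery), projected onto the substrate-tangent plane.
#' Triangles with a vanishing gradient are skipped. Triangle forces are
#' distributed to nodes in equal thirds.
#'
#' @param G actin concentration per triangle.
#' @param labels region factor from [demarcate_regions()].
#' @inheritParams interface_flags
#' @return list with `tri_force` (T x 3, zero off the Lp), `node_force`
#'   (N x 3) and `mean_magnitude` (mean |F| per Lp triangle, N).
#' @export
protrusion_forces <- function(G, mesh, labels, params = mm_params()) {
  stopifnot(length(labels) == nrow(mesh$tris))
  gr <- cpp_tri_gradients(mesh$pos, mesh$tris, mesh$tri_adj, G)
  nt <- nrow(mesh$tris)
  tri_force <- matrix(0, nt, 3)
  lp <- which(labels == "Lp")
  gmin <- params$eps_grad * (params$k_gen / params$k_deg) / params$R_c
  mags <- numeric(length(lp))
  for (k in seq_along(lp)) {
    t <- lp[k]
    gn <- sqrt(sum(gr[t, ]^2))
    if (gn < gmin) next
    f <- params$k_prot * G[t] * gr[t, ] / gn
    f[3] <- 0 # substrate-tangent projection
    tri_force[t, ] <- f
    mags[k] <- sqrt(sum(f^2))
  }
  node_force <- matrix(0, nrow(mesh$pos), 3)
  for (t in lp) {
    for (s in 1:3) {
      v <- mesh$tris[t, s]
      node_force[v, ] <- node_force[v, ] + tri_force[t, ] / 3
    }
  }
  list(tri_force = tri_force, node_force = node_force,
       mean_magnitude = if (length(lp)) mean(mags) else 0)
}

#' Counter force balancing protrusion
#'
#' The total protrusion force is balanced by an equal and opposite force
#' spread uniformly over all cortex nodes, so protrusion is internally
#' force-balanced and cannot translate the cell by itself.
#'
#' @param prot result of [protrusion_forces()] (or a T x 3 triangle force
#'   matrix).
#' @param mesh a `cell_mesh`.
#' @return N x 3 matrix of per-node counter forces.
#' @export
counter_force <- function(prot, mesh) {
  tf <- if (is.list(prot)) prot$tri_force else prot
  tot <- colSums(tf)
  n <- nrow(mesh$pos)
  matrix(rep(-tot / n, each = n), n, 3)
}
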