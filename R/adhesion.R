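#' Adhesive sphere-plane contact force (Maugis-Dugdale contract)
#'
#' Normal contact force between a locally fitted sphere (radius `R_eff`) and
#' the rigid plane, in the Dugdale cohesive-zone form: a repulsive Hertzian
#' core for overlap, plus a constant adhesive stress `w_adh / h0_adh` acting
#' while the gap is below the finite range `h0_adh`. With the adhesion energy
#' set to zero the law is exactly the Hertz sphere-on-flat solution.
#'
#' @param gap signed gap, m: negative values are overlap.
#' @param R_eff effective sphere radius, m (the plane contributes an infinite
#'   radius, so the cell-side fitted sphere radius is the effective one).
#' @param params an `mm_params` object supplying `E_contact`, `w_adh`,
#'   `h0_adh`.
#' @return normal force on the sphere, N (positive pushes away from the
#'   plane; adhesive contributions are negative).
#' @export
#' @examples
#' p <- mm_params()
#' contact_force_normal(1e-6, 8e-6, p)   # beyond range: 0
contact_force_normal <- function(gap, R_eff, params = mm_params()) {
  vapply(gap, cpp_md_force, numeric(1), R_eff = R_eff,
         E_star = params$E_contact, w = params$w_adh, h0 = params$h0_adh)
}

#' Transient adhesive contact forces for a whole mesh
#'
#' Applies the sphere-plane law triangle by triangle: each cell triangle
#' within range of the plane is replaced by the sphere fitted to it and its
#' edge neighbors, the resulting normal force acts on the triangle's nodes in
#' equal thirds, and the reaction (equal and opposite) acts on the substrate.
#'
#' @param mesh a `cell_mesh`.
#' @param params an `mm_params` object.
#' @return list with `force` (N x 3 node forces) and `tri_fz` (per-triangle
#'   normal force on the cell, N; the substrate reaction is its negative).
#' @export
maugis_dugdale_contact <- function(mesh, params = mm_params()) {
  stopifnot(inherits(mesh, "cell_mesh"))
  cpp_contact_forces(mesh$pos, mesh$tris, mesh$tri_opp, params$E_contact,
                     params$w_adh, params$h0_adh, params$d_contact,
                     4 * params$R_c)
}

#' Focal adhesion two-spring force
#'
#' The FA is a stiff spring (`k_FA`) in series with the softer ligand spring
#' (`k_ECM`); because `k_FA >> k_ECM` the response is dictated by the ligand.
#' The bond carries force only when stretched beyond its rest length; it
#' cannot push. The default rest length is the sum of the two spring rest
#' lengths, `L_FA0 + L_ECM0`; a bond that assembled across a wider gap keeps
#' that formation gap as its rest length (clutches engage unstretched), which
#' the engine records per adhesion.
#'
#' @param node_pos length-3 node position, m.
#' @param anchor length-3 fixed substrate anchor, m.
#' @param k_ECM ligand stiffness, N/m.
#' @param params an `mm_params` object.
#' @param rest bond rest length, m (default `L_FA0 + L_ECM0`).
#' @return list with `force` (length-3 vector on the node, N), `magnitude`
#'   (N) and current `length` (m).
#' @export
#' @examples
#' p <- mm_params()
#' fa_force(c(0, 0, 2e-8), c(0, 0, 0), 0.5, p)$magnitude
fa_force <- function(node_pos, anchor, k_ECM, params = mm_params(),
                     rest = NULL) {
  k_ser <- 1 / (1 / params$k_FA + 1 / k_ECM)
  L0 <- if (is.null(rest)) params$L_FA0 + params$L_ECM0 else
    max(rest, params$L_FA0 + params$L_ECM0)
  d <- anchor - node_pos
  L <- sqrt(sum(d^2))
  if (L > L0 && L > 0) {
    fm <- k_ser * (L - L0)
    list(force = fm * d / L, magnitude = fm, length = L)
  } else {
    list(force = c(0, 0, 0), magnitude = 0, length = L)
  }
}

#' Series stiffness of the FA + ligand springs
#' @inheritParams fa_force
#' @return stiffness in N/m.
#' @export
fa_series_stiffness <- function(k_ECM, params = mm_params()) {
  1 / (1 / params$k_FA + 1 / k_ECM)
}

#' Force-dependent FA disassembly rate
#'
#' Catch-like stabilization: rate `beta * r_off0 * exp(-zeta_FA |F|)`, with
#' `beta = 1` at the front and `beta = 2` at the rear (polarity), multiplied
#' by 10 for adhesions that have slipped outside the lamellum. With FA
#' maturation switched off the force dependence is removed (the exponential
#' factor is 1).
#'
#' @param F_mag force carried by the FA, N (vectorized).
#' @param region `"front"` or `"rear"`.
#' @param outside_lm logical: is the FA outside the lamellum?
#' @param setup an [mm_setup()].
#' @param condition an [mm_condition()] supplying `r_off0`.
#' @param params an `mm_params` object.
#' @return disassembly rate, 1/s.
#' @export
#' @examples
#' s <- mm_setup(fa_mat = TRUE, sf_str = TRUE)
#' cnd <- mm_condition(0.5, 5e-4)
#' fa_disassembly_rate(0, "front", FALSE, s, cnd)         # r_off0
#' fa_disassembly_rate(7.7e-9, "front", FALSE, s, cnd)    # catch-stabilized
fa_disassembly_rate <- function(F_mag, region = c("front", "rear"),
                                outside_lm = FALSE, setup = mm_setup(),
                                condition, params = mm_params()) {
  region <- match.arg(region)
  beta <- if (region == "front") params$beta_front else params$beta_rear
  r <- beta * condition$r_off0
  r <- if (setup$fa_mat) r * exp(-params$zeta_FA * abs(F_mag)) else rep(r, length(F_mag))
  if (outside_lm) r <- r * params$outside_Lm_factor
  r
}

#' Attempt stochastic FA formation at a node
#'
#' A lamellar node forms an FA with per-step probability
#' `1 - exp(-r_on_FA dt)` provided it is within the vertical binding distance
#' of the plane, carries no FA already, and is not refractory. The anchor is
#' the instantaneous closest point on the plane and never moves afterwards.
#'
#' @param node_pos length-3 node position, m.
#' @param in_lm logical: node belongs to the lamellum.
#' @param has_fa logical: node already adhered.
#' @param refractory remaining refractory time, s.
#' @param clock current time, s.
#' @param params an `mm_params` object.
#' @return a list describing the new FA (`anchor`, `birth`) or `NULL`.
#' @export
attempt_fa_formation <- function(node_pos, in_lm, has_fa, refractory, clock,
                                 params = mm_params()) {
  if (!in_lm || has_fa || refractory > 0) return(NULL)
  if (abs(node_pos[3]) > params$bind_distance) return(NULL)
  p <- 1 - exp(-params$r_on_FA * params$dt)
  if (stats::runif(1) >= p) return(NULL)
  list(anchor = c(node_pos[1], node_pos[2], 0), birth = clock)
}

#' Advance an FA population by one step
#'
#' Pure bookkeeping form of the per-step FA update used by the engine:
#' adhesions carrying more than the rupture force `F_rup` (strictly) are
#' removed as ruptures and their nodes become refractory for `lambda_ref`;
#' the survivors disassemble stochastically with probability
#' `1 - exp(-r dt)` at the force-dependent rate of [fa_disassembly_rate()].
#' Disassembly and rupture are logged as distinct event types.
#'
#' @param fas data.frame with columns `node`, `F_mag`, `region`
#'   (`"front"`/`"rear"`), `outside_lm` (logical).
#' @param setup an [mm_setup()].
#' @param condition an [mm_condition()].
#' @param params an `mm_params` object.
#' @return list with `surviving` (row indices kept), `disassembled`,
#'   `ruptured` (row indices), and `refractory_nodes`.
#' @export
step_fa_population <- function(fas, setup, condition, params = mm_params()) {
  n <- nrow(fas)
  if (!n) return(list(surviving = integer(), disassembled = integer(),
                      ruptured = integer(), refractory_nodes = integer()))
  rupt <- which(fas$F_mag > params$F_rup)
  alive <- setdiff(seq_len(n), rupt)
  r <- vapply(alive, function(i)
    fa_disassembly_rate(fas$F_mag[i], fas$region[i], fas$outside_lm[i],
                        setup, condition, params), numeric(1))
  p <- 1 - exp(-r * params$dt)
  dis <- alive[stats::runif(length(alive)) < p]
  list(surviving = setdiff(alive, dis), disassembled = dis, ruptured = rupt,
       refractory_nodes = fas$node[rupt])
}
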