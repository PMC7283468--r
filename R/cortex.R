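#' Cortex edge viscoelastic forces
#'
#' Each cortex edge is a Kelvin-Voigt element: a linear spring of stiffness
#' `k_cortex` acting on the deviation of the edge length from its rest length,
#' in parallel with a dashpot of coefficient `Lambda_d` acting on the
#' projection of the relative node velocity onto the edge axis. The spring
#' contribution enters the force balance explicitly; the dashpot lives on the
#' friction side of the equation of motion and is exposed here as an explicit
#' force for testing.
#'
#' @param mesh a `cell_mesh`.
#' @param params an `mm_params` object.
#' @return list with N x 3 matrices `spring` and `dashpot` (N).
#' @export
edge_viscoelastic_forces <- function(mesh, params = mm_params()) {
  stopifnot(inherits(mesh, "cell_mesh"))
  list(
    spring = cpp_spring_forces(mesh$pos, mesh$edges, mesh$edge_rest,
                               params$k_cortex),
    dashpot = cpp_dashpot_forces(mesh$pos, mesh$vel, mesh$edges,
                                 params$Lambda_d)
  )
}

#' Local and global area conservation forces
#'
#' Negative gradient of the area energy
#' `E_A = k_loc/2 * sum_t (A_t - A_t,ref)^2 / A_t,ref
#'      + k_glob/2 * (A_tot - A_ref)^2 / A_ref`,
#' penalizing per-triangle and whole-cell area deviations from the built
#' reference state.
#'
#' @inheritParams edge_viscoelastic_forces
#' @return N x 3 force matrix (N).
#' @export
area_conservation_forces <- function(mesh, params = mm_params()) {
  stopifnot(inherits(mesh, "cell_mesh"))
  if (is.null(mesh$tri_ref_area)) stop("mesh has no reference areas", call. = FALSE)
  cpp_area_forces(mesh$pos, mesh$tris, mesh$tri_ref_area, mesh$ref_total_area,
                  params$k_area_loc, params$k_area_glob)
}

#' Volume conservation force
#'
#' Negative gradient of `E_V = k_vol/2 * (V - V_ref)^2 / V_ref` with the
#' enclosed volume from the divergence theorem.
#'
#' @inheritParams edge_viscoelastic_forces
#' @return N x 3 force matrix (N).
#' @export
volume_conservation_force <- function(mesh, params = mm_params()) {
  stopifnot(inherits(mesh, "cell_mesh"))
  enclosed_volume(mesh) # validates closedness/orientation
  cpp_volume_force(mesh$pos, mesh$tris, mesh$ref_volume, params$k_vol)
}

#' Bending resistance forces
#'
#' Discrete hinge bending: `E_B = k_bend * sum_h (1 - cos(theta_h -
#' theta_h,ref))` over all shared edges, with `theta` the signed dihedral
#' angle between the adjacent triangle planes and `theta_ref` recorded from
#' the built sphere (spontaneous curvature of the rest shape).
#'
#' @inheritParams edge_viscoelastic_forces
#' @return N x 3 force matrix (N).
#' @export
bending_forces <- function(mesh, params = mm_params()) {
  stopifnot(inherits(mesh, "cell_mesh"))
  cpp_bend_forces(mesh$pos, mesh$hinges, mesh$theta_ref, params$k_bend)
}

#' Total passive cortex elastic energy
#'
#' Spring + area + volume + bending energies of the current configuration;
#' the cortex force categories are exactly the negative gradient of this
#' quantity, which makes finite-difference verification and energy-descent
#' tests possible.
#'
#' @inheritParams edge_viscoelastic_forces
#' @return scalar energy, J.
#' @export
cortex_energy <- function(mesh, params = mm_params()) {
  stopifnot(inherits(mesh, "cell_mesh"))
  cpp_spring_energy(mesh$pos, mesh$edges, mesh$edge_rest, params$k_cortex) +
    cpp_area_energy(mesh$pos, mesh$tris, mesh$tri_ref_area,
                    mesh$ref_total_area, params$k_area_loc, params$k_area_glob) +
    cpp_volume_energy(mesh$pos, mesh$tris, mesh$ref_volume, params$k_vol) +
    cpp_bend_energy(mesh$pos, mesh$hinges, mesh$theta_ref, params$k_bend)
}

#' All passive cortex forces
#'
#' Sum of the spring, area, volume and bending contributions (the dashpot is
#' part of the friction operator).
#'
#' @inheritParams edge_viscoelastic_forces
#' @return N x 3 force matrix (N).
#' @export
cortex_forces <- function(mesh, params = mm_params()) {
  edge_viscoelastic_forces(mesh, params)$spring +
    area_conservation_forces(mesh, params) +
    volume_conservation_force(mesh, params) +
    bending_forces(mesh, params)
}
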