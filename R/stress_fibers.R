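#' Stress-fiber weakening factor
#'
#' Logistic dependence of the SF force on fiber shortening:
#' `phi = 1 / (1 + exp(-mu (dL + dL50)))` with `dL = L(t) - L0`. Near zero
#' shortening `phi ~ 1`; at a shortening of `dL50` the force is halved; far
#' beyond that the fiber carries almost no force, which promotes front-FA
#' disassembly after contraction.
#'
#' @param dL change in fiber length since formation, m (negative =
#'   shortening); vectorized.
#' @param params an `mm_params` object supplying `mu` and `dL50`.
#' @return weakening factor in (0, 1].
#' @export
#' @examples
#' sf_weakening_phi(0)                      # ~1
#' sf_weakening_phi(-mm_params()$dL50)      # exactly 0.5
sf_weakening_phi <- function(dL, params = mm_params()) {
  1 / (1 + exp(-params$mu * (dL + params$dL50)))
}

#' Stress-fiber contractile force pair
#'
#' The fiber pulls its two endpoint nodes together with magnitude
#' `n_str * F_am * phi(dL)`: equal and opposite forces, no spring behavior.
#'
#' @param pos_i,pos_j endpoint node positions, m.
#' @param L0 fiber length at formation, m.
#' @param n_str strengthening factor (integer 1..n_str_max).
#' @param params an `mm_params` object.
#' @return list with `force_i`, `force_j` (length-3 vectors, N), `magnitude`
#'   and the current `length`.
#' @export
sf_force <- function(pos_i, pos_j, L0, n_str = 1L, params = mm_params()) {
  d <- pos_j - pos_i
  L <- sqrt(sum(d^2))
  if (L <= 0) {
    warning("coincident stress-fiber endpoints: zero force")
    return(list(force_i = c(0, 0, 0), force_j = c(0, 0, 0),
                magnitude = 0, length = 0))
  }
  phi <- sf_weakening_phi(L - L0, params)
  fm <- n_str * params$F_am * phi
  list(force_i = fm * d / L, force_j = -fm * d / L, magnitude = fm, length = L)
}

#' Form stress fibers among unbound FAs
#'
#' Candidate pairs of FAs are drawn at random; a pair is accepted when
#' neither FA is already bound to a fiber and the separation of the two
#' nodes is at least the minimum initial fiber length `L_fib_min0`. Each
#' unbound FA attempts pairing with per-step probability
#' `1 - exp(-r_sf dt)`. New fibers start with `n_str = 1`, `phi = 1` and
#' record their formation length.
#'
#' @param fa_nodes integer vector of node ids carrying unbound FAs.
#' @param pos N x 3 node positions, m.
#' @param clock current time, s.
#' @param params an `mm_params` object.
#' @return data.frame of new fibers: `node_i`, `node_j`, `L0`, `n_str`,
#'   `birth`.
#' @export
form_stress_fibers <- function(fa_nodes, pos, clock = 0, params = mm_params()) {
  out <- data.frame(node_i = integer(), node_j = integer(), L0 = numeric(),
                    n_str = integer(), birth = numeric())
  unbound <- fa_nodes
  p <- 1 - exp(-params$r_sf * params$dt)
  for (i in fa_nodes) {
    if (!(i %in% unbound)) next
    if (stats::runif(1) >= p) next
    cand <- setdiff(unbound, i)
    if (!length(cand)) next
    j <- cand[sample.int(length(cand), 1)]
    L <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (L < params$L_fib_min0) next
    out <- rbind(out, data.frame(node_i = i, node_j = j, L0 = L,
                                 n_str = 1L, birth = clock))
    unbound <- setdiff(unbound, c(i, j))
  }
  out
}

#' Stall detection and stepwise strengthening
#'
#' The fiber length is averaged over a 10-s moving window; successive window
#' means (10 s apart, the first comparison 20 s after formation) are
#' compared, and when their difference falls below the threshold `L_thr` the
#' fiber has stalled. With SF strengthening on, each stall increments
#' `n_str` by one up to the cap `n_str_max`; with it off, stalls are
#' detected but the force stays at one unit.
#'
#' @param sf list-like fiber state with fields `block_sum`, `block_n`,
#'   `prev_avg`, `prev_valid`, `n_str`.
#' @param L current fiber length sample, m.
#' @param sf_str logical: strengthening mechanism active?
#' @param params an `mm_params` object.
#' @return updated fiber state, with logical field `stalled` set when a
#'   stall was detected at this sample.
#' @export
update_stall_and_strengthen <- function(sf, L, sf_str = TRUE,
                                        params = mm_params()) {
  nblock <- round(params$ma_window / params$dt)
  sf$block_sum <- sf$block_sum + L
  sf$block_n <- sf$block_n + 1L
  sf$stalled <- FALSE
  if (sf$block_n >= nblock) {
    avg <- sf$block_sum / sf$block_n
    if (isTRUE(sf$prev_valid) && abs(avg - sf$prev_avg) < params$L_thr) {
      sf$stalled <- TRUE
      if (sf_str && sf$n_str < params$n_str_max) sf$n_str <- sf$n_str + 1L
    }
    sf$prev_avg <- avg
    sf$prev_valid <- TRUE
    sf$block_sum <- 0
    sf$block_n <- 0L
  }
  sf
}

#' Prune stress fibers whose adhesions are gone
#'
#' A fiber persists, and keeps pulling, while at least one endpoint still
#' carries an FA; it is deleted (with its force pair) as soon as both
#' endpoint FAs have disassembled or ruptured.
#'
#' @param sfs data.frame with logical columns `has_fa_i`, `has_fa_j`.
#' @return the surviving subset of `sfs`.
#' @export
prune_stress_fibers <- function(sfs) {
  sfs[sfs$has_fa_i | sfs$has_fa_j, , drop = FALSE]
}

#' Isolated two-spring strengthening experiment
#'
#' The idealized system used to characterize stalling-driven strengthening:
#' a single node is bound to the plane through the FA + ligand springs in
#' series and pulled by one stress fiber (with stall detection and, when
#' `sf_str` is on, strengthening), detached from any cortex. The force
#' carried by the ligand spring rises in steps of about one actomyosin force
#' unit; the stiffer the ligand spring, the sooner each stall (and step)
#' occurs.
#'
#' @param k_ECM ligand stiffness, N/m.
#' @param duration simulated time, s.
#' @param params an `mm_params` object.
#' @param sf_str logical: strengthening active?
#' @param gamma drag on the node, N s/m (default: the cortex damping
#'   coefficient, standing in for the embedding the node normally has).
#' @return object of class `two_spring_trace`: data.frame with `time`,
#'   `F_ECM`, `n_str`, plus attribute `stall_times`.
#' @export
#' @examples
#' tr <- reduced_two_spring_experiment(4.16e-2, duration = 600)
#' max(tr$n_str)
reduced_two_spring_experiment <- function(k_ECM, duration = 7200,
                                          params = mm_params(),
                                          sf_str = TRUE,
                                          gamma = params$Lambda_d) {
  stopifnot(k_ECM > 0, duration > 0)
  res <- cpp_two_spring(k_ECM, duration, params, sf_str, gamma)
  out <- data.frame(time = res$time, F_ECM = res$F_ECM, n_str = res$n_str)
  attr(out, "stall_times") <- res$stall_times
  class(out) <- c("two_spring_trace", "data.frame")
  out
}

#' @export
plot.two_spring_trace <- function(x, ...) {
  graphics::plot(x$time / 60, x$F_ECM * 1e9, type = "l",
                 xlab = "time [min]", ylab = "|F_ECM| [nN]", ...)
  graphics::abline(h = seq_len(max(x$n_str)), lty = 3, col = "grey")
  invisible(x)
}
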