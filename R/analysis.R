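#' Table of live focal adhesions
#'
#' Extracts the current FA population of a simulation with the two-spring
#' force each adhesion carries, recomputed from the node and anchor
#' positions at the condition's ligand stiffness.
#'
#' @param sim a `cell_sim` (or a `sim_state` plus explicit `k_ECM`).
#' @param k_ECM ligand stiffness, N/m (taken from the simulation's condition
#'   when omitted).
#' @return data.frame: `node`, `anchor_x`, `anchor_y`, `Fx`, `Fy`, `Fz`,
#'   `F_mag`, `birth`.
#' @export
fa_table <- function(sim, k_ECM = NULL) {
  if (inherits(sim, "cell_sim")) {
    st <- sim$state
    if (is.null(k_ECM)) k_ECM <- sim$condition$k_ECM
  } else st <- sim
  if (is.null(k_ECM)) stop("k_ECM required", call. = FALSE)
  raw <- st$raw
  idx <- which(raw$fa_alive == 1L)
  out <- data.frame(node = idx, anchor_x = raw$fa_ax[idx],
                    anchor_y = raw$fa_ay[idx],
                    Fx = numeric(length(idx)), Fy = numeric(length(idx)),
                    Fz = numeric(length(idx)), F_mag = numeric(length(idx)),
                    birth = raw$fa_birth[idx])
  p <- st$params
  for (k in seq_along(idx)) {
    f <- fa_force(st$mesh$pos[idx[k], ],
                  c(raw$fa_ax[idx[k]], raw$fa_ay[idx[k]], 0), k_ECM, p,
                  rest = raw$fa_L0[idx[k]])
    out$Fx[k] <- f$force[1]; out$Fy[k] <- f$force[2]; out$Fz[k] <- f$force[3]
    out$F_mag[k] <- f$magnitude
  }
  out
}

#' Traction map on the substrate
#'
#' Per-substrate-triangle traction: the vector sum of the forces exerted by
#' the FAs anchored in each triangle, divided by the triangle area.
#' Triangles with no bound FA carry zero traction. The FA force on the
#' substrate is equal and opposite to the force on the cell node; only
#' magnitudes and sums enter the reported metrics, so the cell-side sign
#' convention is used.
#'
#' @param fas data.frame as from [fa_table()] (`anchor_x`, `anchor_y`, `Fx`,
#'   `Fy`, `Fz`).
#' @param grid a `substrate_grid`.
#' @return object of class `traction_map`: data.frame with `triangle`, `Tx`,
#'   `Ty`, `Tz`, `T_mag` (Pa) for the loaded triangles, with the grid as an
#'   attribute.
#' @export
traction_map <- function(fas, grid) {
  if (!nrow(fas)) {
    out <- data.frame(triangle = integer(), Tx = numeric(), Ty = numeric(),
                      Tz = numeric(), T_mag = numeric())
  } else {
    id <- locate_substrate_triangle(grid, fas$anchor_x, fas$anchor_y)
    sx <- tapply(fas$Fx, id, sum) / grid$A_tri
    sy <- tapply(fas$Fy, id, sum) / grid$A_tri
    sz <- tapply(fas$Fz, id, sum) / grid$A_tri
    out <- data.frame(triangle = as.integer(names(sx)),
                      Tx = as.numeric(sx), Ty = as.numeric(sy),
                      Tz = as.numeric(sz))
    out$T_mag <- sqrt(out$Tx^2 + out$Ty^2 + out$Tz^2)
  }
  attr(out, "grid") <- grid
  class(out) <- c("traction_map", "data.frame")
  out
}

#' Total cell traction
#'
#' Sum of the traction magnitudes over all substrate triangles (sum of
#' magnitudes, not the magnitude of the sum).
#'
#' @param map a `traction_map`.
#' @return total traction, Pa.
#' @export
total_traction <- function(map) {
  if (!nrow(map)) return(0)
  sum(map$T_mag)
}

#' Cumulative center-of-mass displacement
#'
#' Displacement is tracked through the x-position of the center of mass of
#' the interface nodes: the cumulative sum of its changes between
#' consecutive recorded time points. Frames with an empty interface carry
#' the previous center of mass forward (already handled in the metrics log).
#'
#' @param m a metrics data.frame (column `com_x`) or a `cell_sim`.
#' @return numeric vector of cumulative displacement, m (same length as the
#'   log; zero-length if the log is empty).
#' @export
com_displacement <- function(m) {
  if (inherits(m, "cell_sim")) m <- m$metrics
  if (!nrow(m)) return(numeric(0))
  cumsum(c(0, diff(m$com_x)))
}

#' Classify the migration mode of a run
#'
#' `collective` when at least one full-retraction event occurred;
#' otherwise `progressive` when the cell moved continuously forward through
#' the whole simulation (final displacement of at least 3 um and positive
#' displacement over every sliding 4-h window); otherwise `none` - in
#' particular runs with net negative displacement, which correspond to
#' contraction without migration.
#'
#' @param sim a `cell_sim`, or a metrics data.frame.
#' @param n_retractions number of full-retraction events (required when a
#'   bare data.frame is given).
#' @param min_displacement progressive-mode displacement threshold, m.
#' @param window sliding-window length for the forward-motion check, s.
#' @return one of `"collective"`, `"progressive"`, `"none"`.
#' @export
classify_mode <- function(sim, n_retractions = NULL,
                          min_displacement = 3e-6, window = 4 * 3600) {
  if (inherits(sim, "cell_sim")) {
    m <- sim$metrics
    n_retractions <- length(sim$state$raw$retract_times)
  } else {
    m <- sim
    if (is.null(n_retractions))
      stop("n_retractions required with a bare metrics log", call. = FALSE)
  }
  if (n_retractions >= 1) return("collective")
  if (!nrow(m)) return("none")
  disp <- com_displacement(m)
  final <- disp[length(disp)]
  if (final < min_displacement) return("none")
  span <- m$time[nrow(m)] - m$time[1]
  w <- min(window, span)
  idx_lo <- findInterval(m$time - w, m$time) + 1L
  ok <- TRUE
  for (k in seq_len(nrow(m))) {
    if (m$time[k] - m$time[1] < w) next
    if (disp[k] - disp[idx_lo[k]] <= 0) { ok <- FALSE; break }
  }
  if (ok) "progressive" else "none"
}

#' Lifetimes of completed focal adhesions
#'
#' Matches formation to disassembly/rupture events node by node and returns
#' the realized lifetimes.
#'
#' @param events event log data.frame (`time`, `node`, `type`).
#' @return numeric vector of lifetimes, s.
#' @export
fa_lifetimes <- function(events) {
  if (!nrow(events)) return(numeric(0))
  out <- numeric(0)
  for (nd in unique(events$node)) {
    ev <- events[events$node == nd, ]
    ev <- ev[order(ev$time), ]
    t_form <- NA_real_
    for (k in seq_len(nrow(ev))) {
      if (ev$type[k] == "form") t_form <- ev$time[k]
      else if (!is.na(t_form)) {
        out <- c(out, ev$time[k] - t_form)
        t_form <- NA_real_
      }
    }
  }
  out
}

## representative value of a time series over the stable interval:
## progressive/none -> mean over the trailing `stable` span; collective ->
## mean of the 10-min windows immediately preceding each retraction event
.stable_mean <- function(m, col, retract_times, stable = 800 * 60,
                         pre = 10 * 60) {
  if (!nrow(m)) return(NA_real_)
  if (length(retract_times)) {
    vals <- unlist(lapply(retract_times, function(tr) {
      sel <- m$time > tr - pre & m$time <= tr
      if (any(sel)) mean(m[[col]][sel]) else NA_real_
    }))
    mean(vals, na.rm = TRUE)
  } else {
    lo <- max(m$time) - min(stable, max(m$time) - min(m$time))
    mean(m[[col]][m$time >= lo])
  }
}

#' Aggregate a parameter study
#'
#' Summarizes a list of finished runs per condition x setup: mean and
#' standard error over replicates of the final displacement, FA count, FA
#' lifetime, strengthening factor, cumulative ruptures, retraction-event
#' count and total traction, plus the modal migration-mode label.
#' Time-varying metrics are averaged over the stable interval of each run
#' (trailing window for progressive runs, the 10 minutes preceding each
#' detachment for collective runs).
#'
#' @param runs list of `cell_sim` objects.
#' @param stable trailing stable window for progressive runs, s (the full
#'   study uses the last 800 min).
#' @return data.frame with one row per (fa_mat, sf_str, k_ECM, r_off0),
#'   columns `<metric>_mean` / `<metric>_sem`, `n_reps`, and `mode`.
#' @export
aggregate_study <- function(runs, stable = 800 * 60) {
  stopifnot(length(runs) >= 1)
  per <- lapply(runs, function(s) {
    m <- s$metrics
    rt <- s$state$raw$retract_times
    disp <- com_displacement(m)
    lt <- fa_lifetimes(s$events)
    data.frame(
      k_ECM = s$condition$k_ECM, r_off0 = s$condition$r_off0,
      fa_mat = s$setup$fa_mat, sf_str = s$setup$sf_str,
      displacement = if (length(disp)) utils::tail(disp, 1) else 0,
      n_fa = .stable_mean(m, "n_fa", rt, stable),
      fa_lifetime = if (length(lt)) mean(lt) else NA_real_,
      n_str = .stable_mean(m, "mean_n_str", rt, stable),
      ruptures = if (nrow(m)) utils::tail(m$cum_ruptures, 1) else 0,
      retractions = length(rt),
      traction = .stable_mean(m, "traction", rt, stable),
      mode = classify_mode(s), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per)
  key <- interaction(tab$fa_mat, tab$sf_str, tab$k_ECM, tab$r_off0, drop = TRUE)
  groups <- split(tab, key)
  sem <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(0)
    stats::sd(x) / sqrt(length(x))
  }
  rows <- lapply(groups, function(g) {
    num <- c("displacement", "n_fa", "fa_lifetime", "n_str", "ruptures",
             "retractions", "traction")
    out <- g[1, c("fa_mat", "sf_str", "k_ECM", "r_off0")]
    for (cn in num) {
      out[[paste0(cn, "_mean")]] <- mean(g[[cn]], na.rm = TRUE)
      out[[paste0(cn, "_sem")]] <- sem(g[[cn]])
    }
    out$n_reps <- nrow(g)
    md <- table(g$mode)
    out$mode <- names(md)[which.max(md)]
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fa_mat, out$sf_str, out$k_ECM, out$r_off0), ]
  rownames(out) <- NULL
  out
}
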