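#' Default model parameters
#'
#' Builds the full parameter set of the cell-migration model in SI units
#' (m, s, N, Pa). The defaults are the published working values of the model:
#' cortex stiffness and damping, actin source/decay/diffusion rates, the
#' two-spring focal-adhesion (FA) constants, the stress-fiber (SF) force scale
#' and its strengthening/weakening constants, and the time step. A second group
#' of parameters (area/volume/bending stiffnesses, friction coefficients,
#' lamellipodium/lamellum thresholds, contact constants, initialization
#' settings) is not part of the published table and carries documented
#' calibrated defaults; see the methods vignette.
#'
#' @param ... named overrides for any parameter, either numeric (SI) or a
#'   quantity string with a unit suffix, e.g. `F_am = "2 nN"`, `R_c = "10 um"`.
#' @return an object of class `mm_params`: a named list of numeric scalars.
#' @details Key defaults (SI): `R_c = 8e-6` m, `k_cortex = 2.9e-4` N/m,
#'   `Lambda_d = 0.5` N s/m, `k_gen = 1.18e11` molecules/m^2/s,
#'   `k_deg = 0.016` 1/s, `D_actin = 8e-14` m^2/s, `k_FA = 1e3` N/m,
#'   `r_on_FA = 5e-3` 1/s, `zeta_FA = 1.21e9` 1/N, `lambda_ref = 1800` s,
#'   `F_am = 1e-9` N, `F_rup = 7.7e-9` N, `L_thr = 7.5e-11` m, `mu = 5e6` 1/m,
#'   `dL50 = 3.5e-6` m, `n_thr = 15`, `n_str_max = 5`, `dt = 0.05` s.
#'   The SF weakening constants are interpreted on the meter scale (a fiber at
#'   least 8 um long weakens over micrometers of shortening, i.e. strains of
#'   order -0.25 to -0.4), so `dL50 = 3.5e-6` m and `mu = 5e6` 1/m.
#' @export
#' @examples
#' p <- mm_params()
#' p$F_rup            # 7.7e-9 N
#' mm_params(F_am = "2 nN")$F_am
mm_params <- function(...) {
  .apply_overrides(.mm_defaults, list(...), context = "mm_params")
}

.mm_defaults <- list(
    ## -- published parameter table ------------------------------------------
    R_c          = 8e-6,     # cell radius [m]
    L_fib_min0   = 8e-6,     # minimum initial stress-fiber length [m]
    k_cortex     = 2.9e-4,   # cortex edge spring stiffness [N/m]
    Lambda_d     = 5e-1,     # cortex edge dashpot [N s/m]
    k_gen        = 1.18e11,  # actin generation rate at source triangles [1/m^2/s]
    k_deg        = 0.016,    # actin degradation rate [1/s]
    D_actin      = 8e-14,    # actin surface diffusivity [m^2/s]
    k_FA         = 1e3,      # FA spring stiffness [N/m]
    L_FA0        = 1e-10,    # FA spring rest length [m]
    L_ECM0       = 1.4e-9,   # ligand spring rest length [m]
    r_on_FA      = 5e-3,     # FA binding rate [1/s]
    zeta_FA      = 1.21e9,   # FA mechanosensitivity [1/N] (1.21 per nN)
    lambda_ref   = 1800,     # refractory period [s]
    k_prot       = 1.355e-22, # protrusion gain [N per molecules/m^2], calibrated
    F_am         = 1e-9,     # reference actomyosin force [N]
    F_rup        = 7.7e-9,   # FA rupture force [N]
    L_thr        = 7.5e-11,  # SF stall threshold on 10-s mean length change [m]
    mu           = 5e6,      # slope of SF force drop with shortening [1/m]
    dL50         = 3.5e-6,   # shortening at which SF force is halved [m]
    n_thr        = 15,       # ruptures within 60 s that trigger full retraction
    n_str_max    = 5,        # strengthening cap
    beta_front   = 1,        # FA disassembly polarity factor, front
    beta_rear    = 2,        # FA disassembly polarity factor, rear
    outside_Lm_factor = 10,  # disassembly multiplier for FAs outside the Lm
    bind_distance = 7.5e-8,  # max vertical node-plane distance for FA formation [m]
    dt           = 0.05,     # time step [s]
    ma_window    = 10,       # SF moving-average window [s]
    rupture_window = 60,     # trailing window for the full-retraction count [s]
    ## -- calibrated extension parameters (not in the published table) -------
    k_area_loc   = 2.9e-4,   # local triangle area stiffness [N/m]
    k_area_glob  = 2.9e-4,   # global area stiffness [N/m]
    k_vol        = 5e3,      # volume stiffness [Pa]
    k_bend       = 1e-18,    # hinge bending modulus [J]
    Gamma_subs   = 5e-2,     # substrate contact friction per node [N s/m]
    Gamma_liquid = 1e-3,     # liquid drag per node [N s/m]
    theta_Lp     = 0.74,     # Lp threshold, fraction of the peak actin level
    theta_Lm     = 0.23,     # Lm threshold, fraction of the peak actin level
    init_duration = 1200,    # initialization (attach-and-spread) budget [s]
    ## -- contact (Maugis-Dugdale / Dugdale cohesive zone) --------------------
    E_contact    = 1e4,      # effective contact modulus [Pa]
    w_adh        = 1e-5,     # adhesion energy [J/m^2]
    h0_adh       = 5e-8,     # adhesive (Dugdale) range [m]
    d_contact    = 5e-8,     # contact offset (effective cortex thickness) [m]
    z_interface  = 1.5e-7,   # node height defining the cell-substrate interface [m]
    ## -- stochastic machinery -------------------------------------------------
    r_sf         = 3,        # SF formation attempt rate per unbound FA [1/s]
    eps_grad     = 1e-3,     # relative gradient cutoff for protrusion direction
    spread_pressure = 245    # standing spreading load (active spreading) [Pa]
)

.mm_int_params <- c("n_thr", "n_str_max")

.apply_overrides <- function(p, over, context) {
  if (length(over)) {
    nm <- names(over)
    if (is.null(nm) || any(!nzchar(nm)))
      stop(context, ": all overrides must be named", call. = FALSE)
    unknown <- setdiff(nm, names(p))
    if (length(unknown))
      stop(context, ": unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (k in nm) p[[k]] <- parse_quantity(over[[k]], k)
  }
  validate_params(p)
}

#' Parse a physical quantity
#'
#' Accepts a plain numeric (already SI) or a string of the form
#' `"<number> <unit>"`; the unit is converted to SI by a fixed multiplier
#' table covering the convenience units used in configs (um, nm, nN, pN,
#' min, h, kPa, ...).
#'
#' @param x numeric scalar or quantity string.
#' @param name parameter name, used in error messages.
#' @return numeric scalar in SI units.
#' @export
parse_quantity <- function(x, name = deparse(substitute(x))) {
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x))
      stop("parameter '", name, "' must be a finite scalar", call. = FALSE)
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L)
    stop("parameter '", name, "' must be numeric or a quantity string",
         call. = FALSE)
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*([^ ]*)\\s*$", x))[[1]]
  if (length(m) != 3L || is.na(suppressWarnings(as.numeric(m[2]))))
    stop("cannot parse quantity '", x, "' for parameter '", name, "'",
         call. = FALSE)
  val <- as.numeric(m[2])
  unit <- m[3]
  if (!nzchar(unit)) return(val)
  mult <- .unit_table[[unit]]
  if (is.null(mult))
    stop("unknown unit '", unit, "' for parameter '", name, "'", call. = FALSE)
  val * mult
}

.unit_table <- list(
  m = 1, um = 1e-6, "μm" = 1e-6, nm = 1e-9, mm = 1e-3,
  s = 1, min = 60, h = 3600, ms = 1e-3,
  N = 1, nN = 1e-9, pN = 1e-12, uN = 1e-6,
  "N/m" = 1, "nN/um" = 1e-3, "nN/nm" = 1, "pN/nm" = 1e-3,
  "1/s" = 1, "1/min" = 1 / 60, "1/h" = 1 / 3600,
  "1/N" = 1, "1/nN" = 1e9, "1/pN" = 1e12,
  "Pa" = 1, "kPa" = 1e3,
  "J" = 1, "J/m2" = 1, "N.s/m" = 1, "Ns/m" = 1,
  "m2/s" = 1, "um2/s" = 1e-12, "1/m" = 1, "1/um" = 1e6,
  "m2" = 1, "um2" = 1e-12
)

#' Validate a parameter set
#'
#' Checks positivity of all stiffnesses, rates, forces and lengths, the
#' polarity ordering `beta_rear > beta_front`, integer counts, and that the
#' moving-average and rupture windows are integer multiples of `dt`.
#'
#' @param p named list of parameters (as from [mm_params()]).
#' @return `p`, invisibly classed as `mm_params`.
#' @export
validate_params <- function(p) {
  required <- names(.mm_defaults)
  missing <- setdiff(required, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  positive <- setdiff(required, c("theta_Lp", "theta_Lm"))
  for (k in positive) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", k, "' must be a positive finite scalar", call. = FALSE)
  }
  for (k in c("theta_Lp", "theta_Lm"))
    if (!is.finite(p[[k]]) || p[[k]] <= 0)
      stop("parameter '", k, "' must be a positive finite scalar", call. = FALSE)
  if (p$theta_Lm >= p$theta_Lp)
    stop("theta_Lm must be smaller than theta_Lp", call. = FALSE)
  if (p$beta_rear <= p$beta_front)
    stop("beta_rear must exceed beta_front", call. = FALSE)
  for (k in .mm_int_params)
    if (abs(p[[k]] - round(p[[k]])) > 1e-9)
      stop("parameter '", k, "' must be an integer count", call. = FALSE)
  for (k in c("ma_window", "rupture_window")) {
    ratio <- p[[k]] / p$dt
    if (abs(ratio - round(ratio)) > 1e-6)
      stop("'", k, "' must be an integer multiple of dt", call. = FALSE)
  }
  structure(p, class = "mm_params")
}

#' @export
print.mm_params <- function(x, ...) {
  cat("<mm_params> ", length(x), " parameters (SI units)\n", sep = "")
  main <- c("R_c", "k_cortex", "k_FA", "r_on_FA", "F_am", "F_rup", "dt")
  for (k in main) cat(sprintf("  %-12s %g\n", k, x[[k]]))
  cat("  ... use unclass() for the full list\n")
  invisible(x)
}

#' Load parameters from a YAML configuration document
#'
#' Reads a YAML file (or an already-parsed list) of parameter overrides and
#' returns a validated parameter set in SI units. Values may be plain numbers
#' (interpreted as SI) or quantity strings such as `"2 nN"` or `"30 min"`.
#' Unknown keys are an error, never silently ignored.
#'
#' @param config path to a YAML file, or a named list.
#' @param overrides optional character vector of `key=value` strings applied
#'   after the document (mirrors a `--param key=value` command-line flag).
#' @return an `mm_params` object.
#' @export
load_params <- function(config = list(), overrides = character()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a file path or a named list", call. = FALSE)
  if (length(overrides)) {
    for (ov in overrides) {
      kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop("bad override '", ov, "': expected key=value", call. = FALSE)
      val <- suppressWarnings(as.numeric(kv[2]))
      config[[trimws(kv[1])]] <- if (is.na(val)) trimws(kv[2]) else val
    }
  }
  .apply_overrides(unclass(mm_params()), config, context = "load_params")
}

#' Serialize a parameter set to YAML
#'
#' Writes all parameters (SI values) so that
#' `load_params(serialize_params(p, f))` round-trips exactly.
#'
#' @param p an `mm_params` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
serialize_params <- function(p, file) {
  stopifnot(inherits(p, "mm_params"))
  yaml::write_yaml(lapply(unclass(p), function(v) v), file,
                   precision = 17L)
  invisible(file)
}

#' Mechanosensing setup
#'
#' A setup switches the two mechanosensing mechanisms on or off:
#' FA maturation (`fa_mat`, force-stabilized adhesion disassembly) and SF
#' strengthening (`sf_str`, stepwise force increase upon contraction stalling).
#'
#' @param fa_mat,sf_str logical flags.
#' @return a `mm_setup` list.
#' @export
#' @examples
#' mm_setup(TRUE, FALSE)
mm_setup <- function(fa_mat = TRUE, sf_str = TRUE) {
  stopifnot(is.logical(fa_mat), length(fa_mat) == 1L, !is.na(fa_mat),
            is.logical(sf_str), length(sf_str) == 1L, !is.na(sf_str))
  structure(list(fa_mat = fa_mat, sf_str = sf_str), class = "mm_setup")
}

#' All four mechanosensing setups
#' @return list of the four `mm_setup` combinations.
#' @export
all_setups <- function() {
  list(mm_setup(FALSE, FALSE), mm_setup(TRUE, FALSE),
       mm_setup(FALSE, TRUE), mm_setup(TRUE, TRUE))
}

#' Study condition
#'
#' A condition pairs the ligand spring stiffness `k_ECM` (N/m) with the
#' zero-force FA disassembly rate `r_off0` (1/s).
#'
#' @param k_ECM ligand stiffness, N/m (> 0).
#' @param r_off0 zero-force disassembly rate, 1/s, in (0, 1).
#' @return a `mm_condition` list.
#' @export
mm_condition <- function(k_ECM, r_off0) {
  stopifnot(is.numeric(k_ECM), length(k_ECM) == 1L, k_ECM > 0,
            is.numeric(r_off0), length(r_off0) == 1L)
  if (r_off0 <= 0 || r_off0 >= 1)
    stop("r_off0 must lie strictly between 0 and 1 per second", call. = FALSE)
  structure(list(k_ECM = k_ECM, r_off0 = r_off0), class = "mm_condition")
}

#' The published parameter-study grid
#'
#' Six ligand stiffnesses and four zero-force disassembly rates: the 6 x 4
#' condition grid of the study, crossed with four mechanosensing setups and
#' five replicates in the full design.
#'
#' @return list with elements `k_ECM` (N/m) and `r_off0` (1/s).
#' @export
study_grid <- function() {
  list(
    k_ECM  = c(1e-3, 3.5e-3, 1.2e-2, 4.16e-2, 1.44e-1, 5e-1),
    r_off0 = c(5e-2, 1.08e-2, 2.3e-3, 5e-4)
  )
}

#' Enumerate a run manifest
#'
#' Cross product of conditions x setups x replicates with a deterministic
#' ordering and a unique RNG seed per run.
#'
#' @param k_ECM vector of ligand stiffnesses, N/m.
#' @param r_off0 vector of zero-force disassembly rates, 1/s.
#' @param setups list of [mm_setup()] objects (default: all four).
#' @param reps replicates per condition x setup (>= 1).
#' @param base_seed integer; run `i` gets seed `base_seed + i - 1` unless
#'   `seeds` is given.
#' @param seeds optional explicit integer seed vector, one per run; must be
#'   unique.
#' @return data.frame with columns `run_id`, `k_ECM`, `r_off0`, `fa_mat`,
#'   `sf_str`, `rep`, `seed`.
#' @export
#' @examples
#' nrow(enumerate_conditions(study_grid()$k_ECM, study_grid()$r_off0,
#'                           all_setups(), reps = 5))  # 480
enumerate_conditions <- function(k_ECM, r_off0, setups = all_setups(),
                                 reps = 1L, base_seed = 1L, seeds = NULL) {
  stopifnot(length(k_ECM) >= 1L, length(r_off0) >= 1L, length(setups) >= 1L,
            reps >= 1L)
  if (anyDuplicated(k_ECM) || anyDuplicated(r_off0))
    stop("duplicate condition values", call. = FALSE)
  if (any(k_ECM <= 0)) stop("k_ECM values must be positive", call. = FALSE)
  if (any(r_off0 <= 0 | r_off0 >= 1))
    stop("r_off0 values must lie in (0, 1)", call. = FALSE)
  fa <- vapply(setups, function(s) s$fa_mat, logical(1))
  sf <- vapply(setups, function(s) s$sf_str, logical(1))
  if (anyDuplicated(paste(fa, sf))) stop("duplicate setups", call. = FALSE)
  g <- expand.grid(rep = seq_len(reps), r_off0 = r_off0, k_ECM = k_ECM,
                   setup = seq_along(setups), KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$setup, match(g$k_ECM, k_ECM), match(g$r_off0, r_off0), g$rep), ]
  n <- nrow(g)
  if (is.null(seeds)) seeds <- as.integer(base_seed) + seq_len(n) - 1L
  if (length(seeds) != n) stop("need exactly one seed per run", call. = FALSE)
  if (anyDuplicated(seeds)) stop("seeds must be unique across runs", call. = FALSE)
  out <- data.frame(
    run_id = sprintf("run%04d", seq_len(n)),
    k_ECM = g$k_ECM, r_off0 = g$r_off0,
    fa_mat = fa[g$setup], sf_str = sf[g$setup],
    rep = g$rep, seed = as.integer(seeds),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Convert ligand spring stiffness to an approximate Young's modulus
#'
#' Linear conversion `E = k_ECM / L_char` with characteristic length
#' `L_char = 4` um, which reproduces the published stiffness/modulus pairs
#' (0.001 N/m -> 0.25 kPa, ..., 0.5 N/m -> 125 kPa) to within 2%.
#'
#' @param k_ECM ligand stiffness, N/m (vectorized, > 0).
#' @param L_char characteristic length, m.
#' @return approximate Young's modulus in kPa.
#' @export
#' @examples
#' stiffness_to_modulus(c(1e-3, 5e-1))  # 0.25, 125 kPa
stiffness_to_modulus <- function(k_ECM, L_char = 4e-6) {
  if (any(!is.finite(k_ECM)) || any(k_ECM <= 0))
    stop("k_ECM must be positive", call. = FALSE)
  k_ECM / L_char / 1e3
}

#' Expected zero-force FA lifetime
#'
#' Treats stochastic FA disassembly as a Poisson process sampled once per
#' second: the expected lifetime is `-1 / log(1 - r)` seconds for per-second
#' disassembly probability `r`, returned in minutes.
#'
#' @param r_off0 zero-force disassembly rate, 1/s, in (0, 1); vectorized.
#' @return expected lifetime in minutes.
#' @export
#' @examples
#' round(expected_fa_lifetime(c(5e-2, 1.08e-2, 2.3e-3, 5e-4)), 1)
expected_fa_lifetime <- function(r_off0) {
  if (any(!is.finite(r_off0)) || any(r_off0 <= 0) || any(r_off0 >= 1))
    stop("r_off0 must lie strictly between 0 and 1", call. = FALSE)
  (-1 / log(1 - r_off0)) / 60
}
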