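#' Simulation configuration
#'
#' Collects every tunable parameter of the simulator: oxygen transport
#' constants, tumor growth/remodeling rates, boundary-condition curves,
#' scenario switches and domain geometry. Defaults are the values used for
#' the breast-tissue study conditions.
#'
#' @param scenario one of `"BASE"`, `"CMPR"`, `"METAB"`. `BASE` fixes the
#'   tumor consumption at four times normal with halved `P_M50`; `CMPR`
#'   additionally compresses tumor vessel radii by a factor `xi_cpr` drawn
#'   once per run from U(0.5, 1) and raises `r_max` from 10 to 14 um;
#'   `METAB` redraws the tumor `M0` per run from a lognormal with
#'   `meanlog = log(0.0149)` (ml O2/ml/min) and `sdlog = 0.3`.
#' @param geometry root-node geometry, `"RC1"` .. `"RC9"`.
#' @param L lateral domain size, um.
#' @param h tissue grid constant, um.
#' @param h_v vessel integration step, um.
#' @param h_gen generation lattice constant, um.
#' @param h_fine fine lattice constant for remodeling, um.
#' @param t_end end of tumor growth, hours.
#' @param dt remodeling time step, hours.
#' @param seed RNG seed (or `NULL` to leave the RNG state alone).
#' @param xi_cpr compression factor in (0.5, 1]; only used for `CMPR`. `NA`
#'   means "draw at run time".
#' @param ... overrides for any other field listed in the return value.
#' @return A list of class `sim_config`.
#'
#' @details Oxygen parameters (units as in the field's convention):
#' Hill exponent `n = 2.7`, half-saturation `P_S50 = 27` mmHg, solubilities
#' `alpha_p = 3.1e-5`, `alpha_t = 2.8e-5` mlO2/ml/mmHg, RBC oxygen capacity
#' `c0 = 0.5` mlO2/ml, diffusivities `D_p = 2750`, `D_t = 2410` um^2/s,
#' Michaelis-Menten `P_M50` 4 (normal) / 2 (tumor) mmHg, maximal consumption
#' `M0` 3.7 (normal) / 14.8 (tumor) ulO2/ml/min, Nusselt fit `p1 = 8` um,
#' `p2 = 4.7`, plasma viscosity 1.2 mPa s, inlet hematocrit 0.45, inlet PO2
#' curve `min(55 + 1*r, 100)` mmHg, fixed-point tolerance `eps = 0.1` mmHg.
#' Growth parameters: initial radius 250 um, expansion 2 um/h, shell
#' `R_g = 200` um, `t_switch = 12` h, `t_sprout = 2` h, `t_migr = 50` h,
#' `d_br_min = 80` um, `t_prol = 144` h, `r_sprout = 2.6` um, `r_max`
#' 10 um (14 for CMPR), `p_coll = 1`, `dw = 0.05` um/h, `f_coll = 0.25` Pa,
#' compression ramp width `w_cpr = 200` um.
#' @export
sim_config <- function(scenario = c("BASE", "CMPR", "METAB"),
                       geometry = "RC5", L = 8000, h = 40, h_v = 4,
                       h_gen = 130, h_fine = 10,
                       t_end = 600, dt = 1, seed = NULL,
                       xi_cpr = NA_real_, ...) {
  scenario <- match.arg(scenario)
  cfg <- list(
    scenario = scenario, geometry = geometry,
    L = L, h = h, h_v = h_v, h_gen = h_gen, h_fine = h_fine,
    t_end = t_end, dt = dt, seed = seed,
    # oxygen transport (Table-1-style constants)
    n = 2.7, P_S50 = 27,
    alpha_p = 3.1e-5, alpha_t = 2.8e-5, c0 = 0.5,
    D_t = 2410, D_p = 2750,
    P_M50_normal = 4, P_M50_tumor = 2,
    M0_normal = 3.7, M0_tumor = 14.8,    # ulO2 ml^-1 min^-1
    nu_p1 = 8, nu_p2 = 4.7,
    eta_plasma = 1.2,                    # mPa s
    H_bc = 0.45,
    P0_bc = 55, dP_bc = 1, Pc_bc = 100,  # inlet PO2 curve, mmHg / mmHg/um
    eps = 0.1, max_outer = 2000,
    # tumor growth / remodeling
    R_tum0 = 250, v_tum = 2, R_g = 200,
    t_switch = 12, t_sprout = 2, t_migr = 50,
    d_br_min = 80, t_prol = 144,
    r_sprout = 2.6, r_max = if (scenario == "CMPR") 14 else 10,
    p_coll = 1, dw = 0.05, f_coll = 0.25,
    # compression (CMPR)
    xi_cpr = xi_cpr, w_cpr = 200,
    # METAB lognormal for tumor M0 in mlO2/ml/min
    metab_meanlog = log(0.0149), metab_sdlog = 0.3,
    # initial network generation (netgen)
    p_tripod = 0.5, alpha_murray = 3, mix_bias = 0,
    f0_shear = NA_real_, k_shear = 0.5, act_rate = 0.5, f_rem_frac = 0.3,
    cull_rate = 0.2,
    plateau_window = 5, plateau_tol = 0.02, max_sweeps = 30,
    # root pressure curve p_bc(r) (see pressure_bc)
    p_cap = 31, p_art_max = 89, p_ven_min = 14, p_r_scale = 6,
    # hemodynamics iteration
    H_damping = 0.5, H_tol = 1e-4, max_hemo_iter = 60
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg)))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (scenario == "CMPR" && !is.na(cfg$xi_cpr) &&
      (cfg$xi_cpr < 0.5 || cfg$xi_cpr > 1)) {
    stop("xi_cpr must lie in [0.5, 1]")
  }
  if (scenario != "CMPR" && !is.na(cfg$xi_cpr)) {
    stop("xi_cpr is only meaningful for scenario CMPR")
  }
  stopifnot(cfg$L > 0, cfg$h > 0, cfg$h_v > 0, cfg$h_gen > 0,
            cfg$eps > 0, cfg$M0_normal > 0, cfg$M0_tumor > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> scenario %s, geometry %s, L = %g um, t_end = %g h\n",
              x$scenario, x$geometry, x$L, x$t_end))
  invisible(x)
}

#' Michaelis-Menten parameters for a tissue region
#'
#' @param cfg a `sim_config`
#' @param tumor logical: tumor tissue?
#' @return list with `M0` (mlO2 ml^-1 s^-1) and `P_M50` (mmHg)
#' @export
mm_params <- function(cfg, tumor = FALSE) {
  M0 <- if (tumor) cfg$M0_tumor else cfg$M0_normal
  list(M0 = M0 * 1e-3 / 60,  # ul/ml/min -> mlO2/ml/s
       P_M50 = if (tumor) cfg$P_M50_tumor else cfg$P_M50_normal)
}
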