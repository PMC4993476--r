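#' Per-run scenario random draws
#'
#' BASE is fully deterministic (tumor consumption fixed at four times
#' normal). CMPR draws the compression factor `xi_cpr ~ U(0.5, 1)` once
#' per run. METAB draws the tumor maximal consumption rate from a
#' lognormal with `meanlog = log(0.0149)` ml O2/ml/min and `sdlog = 0.3`
#' (median equal to BASE, spread about 32% of the median); the
#' normal-tissue rate is unchanged.
#'
#' @param scenario `"BASE"`, `"CMPR"` or `"METAB"`
#' @param cfg a `sim_config`
#' @return named list with `xi_cpr` (or `NA`) and `M0_tumor`
#'   (ulO2 ml^-1 min^-1)
#' @export
draw_scenario_randoms <- function(scenario, cfg = sim_config(scenario)) {
  switch(scenario,
         BASE = list(xi_cpr = NA_real_, M0_tumor = cfg$M0_tumor),
         CMPR = list(xi_cpr = stats::runif(1, 0.5, 1),
                     M0_tumor = cfg$M0_tumor),
         METAB = list(xi_cpr = NA_real_,
                      M0_tumor = stats::rlnorm(1, cfg$metab_meanlog,
                                               cfg$metab_sdlog) * 1e3),
         stop("unknown scenario ", scenario))
}

#' Cohort plan
#'
#' @param geometries character vector of RC schemes
#' @param replicates networks per geometry
#' @param scenarios scenario labels to run on each tumor
#' @param base_seed integer; each run's seed is derived deterministically
#'   from (geometry, replicate, base_seed)
#' @param L,h,t_end,h_fine reduced-scale profile (um, um, hours, um)
#' @return object of class `cohort_plan`
#' @export
cohort_plan <- function(geometries = paste0("RC", 1:9), replicates = 2,
                        scenarios = c("BASE"), base_seed = 1,
                        L = 4000, h = 40, t_end = 600, h_fine = 65) {
  stopifnot(replicates >= 1)
  structure(list(geometries = geometries, replicates = replicates,
                 scenarios = scenarios, base_seed = base_seed,
                 L = L, h = h, t_end = t_end, h_fine = h_fine),
            class = "cohort_plan")
}

.run_seed <- function(plan, geometry, replicate) {
  (plan$base_seed * 1009L +
   match(geometry, paste0("RC", 1:9)) * 131L + replicate * 7L) %% 2147483647L
}

#' Run a cohort of simulations
#'
#' For each (geometry, replicate): generate the initial network, solve
#' hemodynamics and oxygen at t = 0 (normal record), remodel to `t_end`
#' under each scenario, and solve again (tumor record over the tumor
#' sphere). Returns the observable table, one row per (run, state).
#' Individual run failures are caught, logged and excluded.
#'
#' @param plan a [cohort_plan()]
#' @param include_tumor run the remodeling stage (set `FALSE` for
#'   t = 0-only ensembles)
#' @param progress print one line per run
#' @return data.frame of observable records with run metadata columns
#' @export
run_cohort <- function(plan, include_tumor = TRUE, progress = FALSE) {
  rows <- list()
  for (geo in plan$geometries) {
    for (rep_i in seq_len(plan$replicates)) {
      seed <- .run_seed(plan, geo, rep_i)
      out <- tryCatch(
        .run_one(plan, geo, rep_i, seed, include_tumor, progress),
        error = function(e) {
          warning(sprintf("run %s/%d failed: %s", geo, rep_i,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (!is.null(out)) rows[[length(rows) + 1]] <- out
    }
  }
  do.call(rbind, rows)
}

.run_one <- function(plan, geo, rep_i, seed, include_tumor, progress) {
  cfg0 <- sim_config(scenario = "BASE", geometry = geo, L = plan$L,
                     h = plan$h, t_end = plan$t_end, h_fine = plan$h_fine)
  set.seed(seed)
  net <- generate_network(cfg0)
  hs <- solve_hemodynamics(net, cfg0)
  ox <- solve_coupled(hs$net, hs$flow, cfg0)
  rec0 <- observable_record(hs$net, hs$flow, ox, cfg0)
  rec0$geometry <- geo; rec0$replicate <- rep_i; rec0$seed <- seed
  rec0$scenario <- "initial"; rec0$t <- 0; rec0$xi_cpr <- NA_real_
  rec0$M0_tumor <- NA_real_
  baseH <- mean_hematocrit(hs$net)
  rec0$core_H_ratio <- NA_real_; rec0$rim_H_ratio <- NA_real_
  rows <- list(rec0)
  if (progress) message(sprintf("%s/%d t=0 done (Y=%.2f c_Hb=%.1f)",
                                geo, rep_i, rec0$Y, rec0$c_Hb))
  if (include_tumor) {
    center <- rep(plan$L / 2, 3)
    for (sc in plan$scenarios) {
      cfg <- sim_config(scenario = sc, geometry = geo, L = plan$L,
                        h = plan$h, t_end = plan$t_end,
                        h_fine = plan$h_fine)
      set.seed(seed + 1L)
      draws <- draw_scenario_randoms(sc, cfg)
      tg <- run_tumor_growth(net, cfg, xi_cpr = draws$xi_cpr)
      hs2 <- solve_hemodynamics(tg$net, cfg)
      ox2 <- solve_coupled(hs2$net, hs2$flow, cfg,
                           center = center, R_tum = tg$tumor$R_tum,
                           M0_tumor_override = if (sc == "METAB")
                             draws$M0_tumor else NULL)
      sphere <- list(center = center, R = tg$tumor$R_tum)
      # scaled tumor perfusion: rBF_norm * rBF_tum / rBF_sph_norm
      rbf_norm <- perfusion(hs$net, hs$flow, "whole")
      rbf_sph_norm <- perfusion(hs$net, hs$flow, sphere)
      rbf_tum <- perfusion(hs2$net, hs2$flow, sphere)
      rbf_scaled <- if (rbf_sph_norm > 0)
        rbf_norm * rbf_tum / rbf_sph_norm else NA_real_
      rec <- observable_record(hs2$net, hs2$flow, ox2, cfg, region = sphere,
                               tag = "tumor_sphere")
      rec$rBF_scaled <- rbf_scaled
      hr <- regional_hematocrit_ratio(hs2$net, tg$tumor, baseH)
      rec$core_H_ratio <- hr$core_ratio; rec$rim_H_ratio <- hr$rim_ratio
      rec$geometry <- geo; rec$replicate <- rep_i; rec$seed <- seed
      rec$scenario <- sc; rec$t <- tg$tumor$t
      rec$xi_cpr <- tg$xi_cpr
      rec$M0_tumor <- draws$M0_tumor
      rows[[length(rows) + 1]] <- rec
      if (progress) message(sprintf("%s/%d %s done (Y=%.2f c_Hb=%.1f)",
                                    geo, rep_i, sc, rec$Y, rec$c_Hb))
    }
  }
  for (i in seq_along(rows)) {
    miss <- setdiff(c("rBF_scaled"), names(rows[[i]]))
    for (m in miss) rows[[i]][[m]] <- NA_real_
  }
  common <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) { r[setdiff(common, names(r))] <- NA; r[common] })
  do.call(rbind, rows)
}

#' Summarize a cohort table as ensemble means and standard deviations
#'
#' @param tab output of [run_cohort()]
#' @return data.frame with one row per (scenario, quantity)
#' @export
summarize_cohort <- function(tab) {
  num <- names(tab)[vapply(tab, is.numeric, logical(1))]
  num <- setdiff(num, c("replicate", "seed", "t"))
  out <- list()
  for (sc in unique(tab$scenario)) {
    sub <- tab[tab$scenario == sc, ]
    for (q in num) {
      v <- sub[[q]]
      v <- v[is.finite(v)]
      if (!length(v)) next
      out[[length(out) + 1]] <- data.frame(
        scenario = sc, quantity = q, mean = mean(v), sd = stats::sd(v),
        n = length(v))
    }
  }
  do.call(rbind, out)
}
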