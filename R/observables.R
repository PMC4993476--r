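#' Region selectors for observables
#'
#' A region is either the whole domain or a sphere; segments belong to a
#' region if their midpoint does (radial profiles clip by shells instead).
#'
#' @param net a `vessel_network`
#' @param region `"whole"` or a list `list(center = c(x, y, z), R = r)`
#' @return list with logical `seg_mask`, region volume `V` (um^3), and the
#'   region description
#' @keywords internal
.region_select <- function(net, region = "whole") {
  if (identical(region, "whole")) {
    list(seg_mask = rep(TRUE, nrow(net$segments)), V = net$L^3,
         region = region)
  } else {
    d <- .dist_center(.seg_mid(net), region$center)
    if (region$R > net$L / 2 * sqrt(3) + 1e-9)
      stop("region sphere exceeds the domain")
    list(seg_mask = d <= region$R, V = 4 / 3 * pi * region$R^3,
         region = region)
  }
}

#' Tissue total hemoglobin concentration
#'
#' `c_Hb = MCHC * rRBCV = MCHC / |Omega| * sum pi r~^2 l H`, converted to
#' umol/l with the hemoglobin tetramer molar mass (64,500 g/mol).
#'
#' @param net a `vessel_network` with hematocrit assigned
#' @param region see [.region_select()]
#' @param MCHC mean corpuscular hemoglobin concentration, g/ml
#' @return c_Hb in umol/l
#' @export
tissue_hemoglobin <- function(net, region = "whole",
                              MCHC = vasox_units$MCHC) {
  rs <- .region_select(net, region)
  if (!any(rs$seg_mask)) stop("tissue_hemoglobin: empty region")
  sg <- net$segments[rs$seg_mask, ]
  rrbcv <- sum(pi * sg$r_tilde^2 * sg$l * sg$H) / rs$V
  MCHC * rrbcv / vasox_units$hb_molar_mass * 1e9
}

#' Tissue blood oxygen saturation
#'
#' `Y = c_HbO / c_Hb`: the RBC-volume-weighted mean of the per-segment
#' length-averaged blood oxygen saturation.
#'
#' @param net a `vessel_network`
#' @param Sbar per-segment mean saturation (from an `oxygen_solution`)
#' @param region see [.region_select()]
#' @return Y in [0, 1]
#' @export
tissue_blood_oxygen_saturation <- function(net, Sbar, region = "whole") {
  rs <- .region_select(net, region)
  sg <- net$segments[rs$seg_mask, ]
  wt <- pi * sg$r_tilde^2 * sg$l * sg$H
  if (sum(wt) <= 0) stop("tissue_blood_oxygen_saturation: zero RBC volume in region")
  sum(wt * Sbar[rs$seg_mask]) / sum(wt)
}

#' Length-weighted mean vascular oxygen saturation
#'
#' `<S> = sum l S / sum l`: every vessel contributes by its length alone,
#' making this measure insensitive to vessel caliber (in contrast to Y).
#'
#' @inheritParams tissue_blood_oxygen_saturation
#' @return `<S>` in [0, 1]
#' @export
length_weighted_saturation <- function(net, Sbar, region = "whole") {
  rs <- .region_select(net, region)
  if (!any(rs$seg_mask)) stop("length_weighted_saturation: empty region")
  sg <- net$segments[rs$seg_mask, ]
  sum(sg$l * Sbar[rs$seg_mask]) / sum(sg$l)
}

#' Vascular morphology densities
#'
#' Line density `L_D` (total centerline length per volume, mm^-2), the
#' relative blood volume `rBV` (%), surface density `S_D` (mm^-1), the
#' ratio `S_D/rBV` (um^-1), and the mean radius (um). Compressed radii are
#' used where compression is active.
#'
#' @param net a `vessel_network`
#' @param region see [.region_select()]
#' @return named list `L_D`, `rBV`, `S_D`, `SD_over_rBV`, `mean_r`
#' @export
vascular_densities <- function(net, region = "whole") {
  rs <- .region_select(net, region)
  sg <- net$segments[rs$seg_mask, ]
  L_D <- sum(sg$l) / rs$V * 1e6              # um/um^3 -> mm/mm^3
  rBV <- sum(pi * sg$r_tilde^2 * sg$l) / rs$V
  S_D <- sum(2 * pi * sg$r_tilde * sg$l) / rs$V * 1e3   # um^-1 -> mm^-1
  list(L_D = L_D, rBV = 100 * rBV, S_D = S_D,
       SD_over_rBV = ifelse(rBV > 0, S_D / 1e3 / rBV, NA_real_),
       mean_r = if (nrow(sg)) mean(sg$r_tilde) else NA_real_)
}

#' Perfusion (regional blood flow)
#'
#' Whole-domain perfusion is the summed arterial-root inflow divided by
#' the domain volume. For a sphere, the inward blood flux through its
#' surface (vessels crossing the surface with flow directed inward)
#' divided by the sphere volume. Unit conversion assumes tissue density
#' 1 g/ml, giving ml g^-1 min^-1.
#'
#' @param net a `vessel_network`
#' @param flow a `flow_state`
#' @param region `"whole"` or `list(center=, R=)`
#' @return perfusion, ml g^-1 min^-1
#' @export
perfusion <- function(net, flow, region = "whole") {
  nd <- net$nodes; sg <- net$segments
  ia <- match(sg$a, nd$id); ib <- match(sg$b, nd$id)
  if (identical(region, "whole")) {
    # net injection per arterial root node (a root can both feed the
    # network and locally re-collect flow; only the net counts)
    art <- which(nd$role == "arterial_root")
    inj <- numeric(length(art))
    for (t in seq_along(art)) {
      v <- art[t]
      inj[t] <- sum(flow$q[ia == v]) - sum(flow$q[ib == v])
    }
    return(sum(inj) / net$L^3 * 60)
  }
  if (region$R > net$L / 2 * sqrt(3) + 1e-9)
    stop("perfusion: sphere exceeds the domain")
  da <- .dist_center(cbind(nd$x[ia], nd$y[ia], nd$z[ia]), region$center)
  db <- .dist_center(cbind(nd$x[ib], nd$y[ib], nd$z[ib]), region$center)
  # crossing segments; inward flow contribution
  a_in <- da <= region$R & db > region$R
  b_in <- db <= region$R & da > region$R
  qin <- sum(pmax(-flow$q[a_in], 0)) + sum(pmax(flow$q[b_in], 0))
  qin / (4 / 3 * pi * region$R^3) * 60
}

#' Flow-weighted inlet oxygen saturation
#'
#' `<S_in>_q`: saturation of blood entering at arterial roots weighted by
#' the root flows.
#'
#' @param net a `vessel_network`
#' @param flow a `flow_state`
#' @param ox an `oxygen_solution`
#' @param cfg a `sim_config`
#' @return fraction in [0, 1]
#' @export
inlet_saturation <- function(net, flow, ox, cfg) {
  nd <- net$nodes; sg <- net$segments
  ia <- match(sg$a, nd$id); ib <- match(sg$b, nd$id)
  art_a <- nd$role[ia] == "arterial_root" & flow$q > 0
  art_b <- nd$role[ib] == "arterial_root" & flow$q < 0
  q <- c(flow$q[art_a], -flow$q[art_b])
  P <- c(ox$P_up[art_a], ox$P_up[art_b])
  if (sum(q) <= 0) return(NA_real_)
  sum(q * hill_saturation(P, cfg$n, cfg$P_S50)) / sum(q)
}

#' Oxygen metabolic observables
#'
#' `MRO2`: volume mean of the Michaelis-Menten consumption over the
#' region's grid sites (ulO2 ml^-1 min^-1). `rJ_in`: oxygen supply at
#' input, `c0 H <S_in>_q rBF`. `OEF = MRO2 / rJ_in`. Mean vascular PO2 is
#' length-weighted; mean tissue PO2 is the grid mean over the region.
#'
#' @param net a `vessel_network`
#' @param flow a `flow_state`
#' @param ox an `oxygen_solution`
#' @param cfg a `sim_config`
#' @param region `"whole"` or `list(center=, R=)`
#' @param rBF optionally override the perfusion used for `rJ_in` (e.g. a
#'   scaled tumor perfusion), ml g^-1 min^-1
#' @return named list `MRO2`, `rJ_in`, `OEF`, `mean_P`, `mean_Pt`,
#'   `S_in_q`
#' @export
oxygen_metabolics <- function(net, flow, ox, cfg, region = "whole",
                              rBF = NULL) {
  grid <- ox$grid
  site_mask <- if (identical(region, "whole")) {
    rep(TRUE, prod(grid$dims))
  } else {
    xyz <- grid_coords(grid)
    .dist_center(xyz, region$center) <= region$R
  }
  M <- mm_consumption(grid$P, ox$M0_site, ox$P_M50_site)
  MRO2 <- mean(M[site_mask]) * 60 * 1e3    # mlO2/ml/s -> ulO2/ml/min
  if (is.null(rBF)) rBF <- perfusion(net, flow, region)
  Sin <- inlet_saturation(net, flow, ox, cfg)
  rJ_in <- cfg$c0 * cfg$H_bc * Sin * rBF * 1e3   # ulO2 ml^-1 min^-1
  if (is.na(rJ_in) || rJ_in <= 0) stop("oxygen_metabolics: zero oxygen supply")
  rs <- .region_select(net, region)
  sg <- net$segments[rs$seg_mask, ]
  mean_P <- sum(sg$l * ox$Pbar[rs$seg_mask]) / sum(sg$l)
  list(MRO2 = MRO2, rJ_in = rJ_in, OEF = MRO2 / rJ_in,
       mean_P = mean_P, mean_Pt = mean(grid$P[site_mask]), S_in_q = Sin)
}

#' Zeroth-order estimate of the maximal oxygen consumption rate
#'
#' Assuming zeroth-order kinetics, the oxygen extracted per unit tissue
#' volume and time equals the oxygen carried in per unit time times the
#' extraction fraction: `M0 = huefner * c_Hb_blood * OEF * rBF` (the mean
#' transit time `rBV/rBF` cancels against the blood volume).
#'
#' @param rBV fractional blood volume (dimensionless, e.g. 0.008);
#'   accepted for completeness, it cancels out of the estimate
#' @param rBF perfusion, 1/min
#' @param c_Hb_blood blood hemoglobin concentration, g/dl
#' @param huefner oxygen binding capacity, mlO2 per g Hb
#' @param OEF oxygen extraction fraction
#' @return M0 in ulO2 ml^-1 min^-1
#' @export
estimate_M0_zeroth_order <- function(rBV = 0.008, rBF = 0.06,
                                     c_Hb_blood = 14,
                                     huefner = vasox_units$huefner,
                                     OEF = 0.32) {
  if (rBF <= 0) stop("estimate_M0_zeroth_order: rBF must be positive")
  huefner * (c_Hb_blood / 100) * OEF * rBF * 1e3  # g/dl -> g/ml; ml -> ul
}

#' Radial profiles in concentric shells
#'
#' Divides the domain into concentric shells of the given width about the
#' center and reports per-shell vascular line density, relative blood
#' volume, mean hematocrit, and (when a tissue grid is supplied) mean
#' tissue PO2. Segments are clipped to shells by their midpoint.
#'
#' @param net a `vessel_network`
#' @param center 3-vector, um
#' @param width shell thickness, um
#' @param grid optional `tissue_grid` for PO2 means
#' @param r_max outer radius; default half the domain size
#' @return data.frame with one row per shell
#' @export
radial_profiles <- function(net, center = rep(net$L / 2, 3), width = 100,
                            grid = NULL, r_max = net$L / 2) {
  stopifnot(width > 0)
  edges <- seq(0, r_max + width, by = width)
  d <- .dist_center(.seg_mid(net), center)
  sh <- findInterval(d, edges, rightmost.closed = TRUE)
  out <- data.frame(r_inner = edges[-length(edges)],
                    r_outer = edges[-1])
  vol <- 4 / 3 * pi * (out$r_outer^3 - out$r_inner^3)
  sg <- net$segments
  agg <- function(x) {
    v <- rep(0, nrow(out))
    s <- rowsum(x, sh)
    idx <- as.integer(rownames(s))
    ok <- idx >= 1 & idx <= nrow(out)
    v[idx[ok]] <- s[ok, 1]
    v
  }
  out$L_D <- agg(sg$l) / vol * 1e6
  out$rBV <- 100 * agg(pi * sg$r_tilde^2 * sg$l) / vol
  lw <- agg(sg$l)
  out$mean_H <- ifelse(lw > 0, agg(sg$l * sg$H) / lw, NA_real_)
  if (!is.null(grid)) {
    xyz <- grid_coords(grid)
    dg <- .dist_center(xyz, center)
    shg <- findInterval(dg, edges, rightmost.closed = TRUE)
    mp <- rep(NA_real_, nrow(out))
    s <- rowsum(grid$P, shg)
    cnt <- rowsum(rep(1, length(shg)), shg)
    idx <- as.integer(rownames(s))
    ok <- idx >= 1 & idx <= nrow(out)
    mp[idx[ok]] <- s[ok, 1] / cnt[ok, 1]
    out$mean_Pt <- mp
  }
  out
}

#' Core and rim hematocrit relative to baseline
#'
#' Length-weighted mean hematocrit over the tumor core (more than 100 um
#' inside the invasive edge) and over a 50 um thick shell at the edge,
#' both relative to a baseline hematocrit (the mean of the t = 0
#' network).
#'
#' @param net tumor-stage `vessel_network`
#' @param tumor a `tumor_state`
#' @param baseline_H baseline mean hematocrit (length-weighted)
#' @return list `core_ratio`, `rim_ratio`
#' @export
regional_hematocrit_ratio <- function(net, tumor, baseline_H) {
  d <- .dist_center(.seg_mid(net), tumor$center)
  sg <- net$segments
  lw_mean <- function(mask) {
    if (!any(mask)) stop("regional_hematocrit_ratio: empty region")
    sum(sg$l[mask] * sg$H[mask]) / sum(sg$l[mask])
  }
  core <- lw_mean(d < tumor$R_tum - 100)
  rim <- lw_mean(d >= tumor$R_tum - 50 & d <= tumor$R_tum)
  list(core_ratio = core / baseline_H, rim_ratio = rim / baseline_H)
}

#' Length-weighted mean hematocrit of a network
#' @param net a `vessel_network`
#' @return fraction
#' @export
mean_hematocrit <- function(net) {
  sum(net$segments$l * net$segments$H) / sum(net$segments$l)
}

#' Collect the full observable record for one network state
#'
#' One row with every tissue-level quantity: morphology (`L_D`, `rBV`,
#' `S_D`, mean radius), perfusion, hemoglobin (`c_Hb`, `c_HbO`),
#' saturations (`Y`, `S_mean`), and oxygen metabolics (`MRO2`, `rJ_in`,
#' `OEF`, mean PO2s).
#'
#' @param net a `vessel_network`
#' @param flow a `flow_state`
#' @param ox an `oxygen_solution`
#' @param cfg a `sim_config`
#' @param region `"whole"` or `list(center=, R=)`
#' @param tag character label for the row
#' @param rBF_override optional perfusion to use for `rJ_in`
#' @return one-row data.frame
#' @export
observable_record <- function(net, flow, ox, cfg, region = "whole",
                              tag = "whole_domain", rBF_override = NULL) {
  vd <- vascular_densities(net, region)
  cHb <- tissue_hemoglobin(net, region)
  Y <- tissue_blood_oxygen_saturation(net, ox$Sbar, region)
  Sm <- length_weighted_saturation(net, ox$Sbar, region)
  rbf <- perfusion(net, flow, region)
  om <- oxygen_metabolics(net, flow, ox, cfg, region, rBF = rBF_override)
  data.frame(region = tag, L_D = vd$L_D, rBV = vd$rBV, S_D = vd$S_D,
             SD_over_rBV = vd$SD_over_rBV, mean_r = vd$mean_r,
             rBF = rbf, c_Hb = cHb, c_HbO = Y * cHb, Y = Y, S_mean = Sm,
             MRO2 = om$MRO2, rJ_in = om$rJ_in, OEF = om$OEF,
             mean_P = om$mean_P, mean_Pt = om$mean_Pt,
             S_in_q = om$S_in_q)
}
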