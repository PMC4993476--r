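#' Relative apparent blood viscosity (Fahraeus-Lindqvist effect)
#'
#' Empirical dependence of the apparent viscosity of blood on vessel
#' diameter and hematocrit, after Pries and Secomb. Two parameterizations
#' are provided: the in vivo law (default), which includes the
#' endothelial-surface-layer factor and is the one used for all network
#' hemodynamics here, and the classic in vitro (glass tube) law.
#'
#' @param r vessel radius, um (vectorized)
#' @param H discharge hematocrit in [0, 1]
#' @param law `"invivo"` or `"invitro"`
#' @return dimensionless relative viscosity `eta_rel`; multiply by the
#'   plasma viscosity to obtain the apparent viscosity.
#' @references Pries AR, Secomb TW (2005) Am J Physiol 289:H2657.
#'   Pries AR et al. (1992) Am J Physiol 263:H1770.
#' @export
relative_viscosity <- function(r, H, law = c("invivo", "invitro")) {
  law <- match.arg(law)
  D <- 2 * r
  H <- pmin(pmax(H, 0), 1)
  eta45 <- if (law == "invivo") {
    6 * exp(-0.085 * D) + 3.2 - 2.44 * exp(-0.06 * D^0.645)
  } else {
    220 * exp(-1.3 * D) + 3.2 - 2.44 * exp(-0.06 * D^0.645)
  }
  Dc <- 1 / (1 + 1e-11 * D^12)
  C <- (0.8 + exp(-0.075 * D)) * (-1 + Dc) + Dc
  frac <- ifelse(abs(H - 0) < 1e-300, 0,
                 ((1 - H)^C - 1) / ((1 - 0.45)^C - 1))
  if (law == "invivo") {
    esl <- (D / (D - 1.1))^2
    (1 + (eta45 - 1) * frac * esl) * esl
  } else {
    1 + (eta45 - 1) * frac
  }
}

#' Hydraulic conductance of a vessel segment
#'
#' Hagen-Poiseuille conductance `g = pi r^4 / (8 eta l)` expressed in
#' um^3 s^-1 mmHg^-1, using the compressed radius when compression is
#' active. Flow follows as `q = g * (p_a - p_b)` with nodal pressures in
#' mmHg.
#'
#' @param r effective (possibly compressed) radius, um
#' @param l length, um
#' @param eta apparent viscosity, mPa s
#' @return conductance, um^3 s^-1 mmHg^-1
#' @export
segment_conductance <- function(r, l, eta) {
  if (any(l <= 0)) stop("segment_conductance: zero or negative length")
  # eta [mPa s] = 1e-3 Pa s; pi r^4/(8 eta l) is um^3/(Pa s); x133.322 -> per mmHg
  pi * r^4 / (8 * (eta * 1e-3) * l) * vasox_units$mmHg_to_Pa
}

#' Root pressure boundary curve
#'
#' Monotone radius-to-pressure curves for arterial and venous root nodes.
#' Arterial pressures rise with root radius from the capillary plateau
#' `p_cap` towards `p_art_max`; venous pressures fall towards `p_ven_min`.
#' The shape is a saturating exponential in the radius excess over the
#' capillary radius; the amplitude/scale defaults are calibrated once so
#' that the t = 0 network ensemble reproduces a normal-tissue perfusion of
#' about 0.05 ml g^-1 min^-1 (see `scripts/calibrate_bc.R`).
#'
#' @param r root segment radius, um
#' @param type `"arterial_root"` or `"venous_root"`
#' @param cfg a `sim_config`
#' @return pressure, mmHg
#' @export
pressure_bc <- function(r, type, cfg) {
  s <- 1 - exp(-pmax(r - 2.5, 0) / cfg$p_r_scale)
  ifelse(type == "arterial_root",
         cfg$p_cap + (cfg$p_art_max - cfg$p_cap) * s,
         cfg$p_cap - (cfg$p_cap - cfg$p_ven_min) * s)
}

.incidence_lists <- function(net) {
  ia <- match(net$segments$a, net$nodes$id)
  ib <- match(net$segments$b, net$nodes$id)
  n <- nrow(net$nodes)
  inc <- vector("list", n)
  ord <- order(c(ia, ib))
  allv <- c(ia, ib)[ord]
  segv <- c(seq_len(nrow(net$segments)), seq_len(nrow(net$segments)))[ord]
  split(segv, factor(allv, levels = seq_len(n)))
}

#' Solve nodal blood pressures and segment flows
#'
#' Assembles the node mass-balance system (sum of Poiseuille flows zero at
#' every interior node) with Dirichlet pressures at root nodes and solves
#' the sparse SPD system by a direct Cholesky factorization. Derives
#' signed flows, wall shear stresses `f = r |dp| / (2 l)` and apparent
#' viscosities.
#'
#' @param net a `vessel_network` with hematocrit assigned per segment
#' @param cfg a `sim_config` (boundary curve, plasma viscosity)
#' @param root_pressure optional named override: numeric vector of
#'   pressures (mmHg) aligned with root nodes in node order; default uses
#'   [pressure_bc()] with the radius of the widest segment at each root.
#' @return list of class `flow_state`: `pressure` (per node, mmHg), `q`
#'   (per segment, um^3/s, signed a->b), `f` (Pa), `eta` (mPa s),
#'   `g` (conductance), `root_pressure`.
#' @export
solve_pressures <- function(net, cfg, root_pressure = NULL) {
  nd <- net$nodes; sg <- net$segments
  n <- nrow(nd)
  ia <- match(sg$a, nd$id); ib <- match(sg$b, nd$id)
  eta <- cfg$eta_plasma * relative_viscosity(sg$r_tilde, sg$H)
  g <- segment_conductance(sg$r_tilde, sg$l, eta)
  is_root <- nd$role != "interior"
  if (!any(nd$role == "arterial_root") || !any(nd$role == "venous_root"))
    stop("solve_pressures: need at least one arterial and one venous root")
  # connectivity: every node must reach a root through the graph
  gph <- igraph::graph_from_edgelist(cbind(ia, ib), directed = FALSE)
  if (igraph::vcount(gph) < n) gph <- igraph::add_vertices(gph, n - igraph::vcount(gph))
  comp <- igraph::components(gph)$membership
  rooted <- unique(comp[is_root])
  orphan <- which(!(comp %in% rooted) & tabulate(comp, max(comp))[comp] >= 1)
  orphan <- orphan[orphan %in% c(ia, ib)]
  if (length(orphan)) {
    stop(sprintf("solve_pressures: component without boundary condition (e.g. node %d)",
                 nd$id[orphan[1]]))
  }
  if (is.null(root_pressure)) {
    pr <- numeric(n)
    widest <- rep(2.5, n)
    agg <- tapply(c(sg$r_tilde, sg$r_tilde), c(ia, ib), max)
    widest[as.integer(names(agg))] <- agg
    pr[is_root] <- pressure_bc(widest[is_root], nd$role[is_root], cfg)
  } else {
    pr <- numeric(n)
    pr[is_root] <- root_pressure
  }
  deg <- tabulate(c(ia, ib), n)
  free <- which(!is_root & deg > 0)   # isolated nodes carry no pressure
  idx_free <- integer(n); idx_free[free] <- seq_along(free)
  p <- numeric(n)
  p[is_root] <- pr[is_root]
  p[!is_root & deg == 0] <- NA_real_
  if (length(free)) {
    fa <- idx_free[ia]; fb <- idx_free[ib]
    ii <- c(fa[fa > 0], fb[fb > 0])
    jj <- c(fa[fa > 0], fb[fb > 0])
    xx <- c(g[fa > 0], g[fb > 0])
    both <- which(fa > 0 & fb > 0)
    A <- Matrix::sparseMatrix(
      i = c(ii, fa[both], fb[both]),
      j = c(jj, fb[both], fa[both]),
      x = c(xx, -g[both], -g[both]),
      dims = c(length(free), length(free)), symmetric = FALSE)
    rhs <- numeric(length(free))
    bdry_a <- which(fa > 0 & fb == 0)
    bdry_b <- which(fb > 0 & fa == 0)
    if (length(bdry_a))
      rhs <- rhs + unname(tapply2(fa[bdry_a], g[bdry_a] * p[ib[bdry_a]],
                                  length(free)))
    if (length(bdry_b))
      rhs <- rhs + unname(tapply2(fb[bdry_b], g[bdry_b] * p[ia[bdry_b]],
                                  length(free)))
    sol <- Matrix::solve(Matrix::forceSymmetric(A), rhs)
    p[free] <- as.numeric(sol)
  }
  q <- g * (p[ia] - p[ib])
  dp <- abs(p[ia] - p[ib])
  f <- sg$r_tilde * dp * vasox_units$mmHg_to_Pa / (2 * sg$l)
  structure(list(pressure = p, q = q, f = f, eta = eta, g = g,
                 root_pressure = pr),
            class = "flow_state")
}

# dense "scatter-add": sums values into bins 1..n
tapply2 <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Hematocrit split at an arterial bifurcation (phase separation)
#'
#' Empirical red-blood-cell partitioning at a diverging bifurcation after
#' Pries et al.: the fractional RBC flux into a daughter is a logistic
#' function of its fractional blood flow, with parameters depending on the
#' parent hematocrit and the daughter diameters. RBC flux is conserved
#' exactly; daughter hematocrits are capped at 1 with the excess assigned
#' to the sister branch.
#'
#' @param q_parent parent flow magnitude, um^3/s
#' @param H_parent parent (discharge) hematocrit
#' @param q1,q2 daughter flow magnitudes
#' @param r1,r2 daughter radii, um
#' @param rf feeding (parent) radius, um
#' @param law `"invivo"` (2005 parameters, default) or `"classic"` (1990)
#' @return c(H1, H2)
#' @references Pries AR et al. (1990) Am J Physiol 258:H1829.
#'   Pries AR, Secomb TW (2005) Am J Physiol 289:H2657.
#' @export
phase_separation_split <- function(q_parent, H_parent, q1, q2, r1, r2, rf,
                                   law = c("invivo", "classic")) {
  law <- match.arg(law)
  if (q_parent <= 0 || (q1 + q2) <= 0) return(c(H_parent, H_parent))
  Df <- 2 * rf; D1 <- 2 * r1; D2 <- 2 * r2
  FQB <- q1 / (q1 + q2)
  if (law == "invivo") {
    X0 <- 0.964 * (1 - H_parent) / Df
    A <- -13.29 * ((D1^2 / D2^2 - 1) / (D1^2 / D2^2 + 1)) * (1 - H_parent) / Df
    B <- 1 + 6.98 * (1 - H_parent) / Df
  } else {
    X0 <- 0.4 / Df
    A <- -6.96 * log(D1 / D2) / Df
    B <- 1 + 6.98 * (1 - H_parent) / Df
  }
  FQE <- if (FQB <= X0) 0 else if (FQB >= 1 - X0) 1 else {
    xl <- (FQB - X0) / (1 - 2 * X0)
    z <- A + B * log(xl / (1 - xl))
    1 / (1 + exp(-z))
  }
  rbc <- H_parent * q_parent
  H1 <- if (q1 > 0) FQE * rbc / q1 else 0
  H2 <- if (q2 > 0) (1 - FQE) * rbc / q2 else 0
  if (H1 > 1) { H2 <- H2 + (H1 - 1) * q1 / q2; H1 <- 1 }
  if (H2 > 1) { H1 <- H1 + (H2 - 1) * q2 / q1; H2 <- 1 }
  c(H1, H2)
}

#' Propagate hematocrit through the network along flow directions
#'
#' Nodes are processed in order of decreasing pressure (a valid topological
#' order of the flow digraph, since Poiseuille flow runs strictly downhill
#' in pressure and therefore admits no flow-directed cycles). Diverging
#' arterial bifurcations apply the phase-separation law; merging nodes mix
#' RBC flux-conservatively. Inlet segments at source nodes receive the
#' boundary hematocrit. Unperfused segments keep their previous hematocrit.
#'
#' @param net a `vessel_network`
#' @param flow a `flow_state` from [solve_pressures()]
#' @param cfg a `sim_config` (`H_bc`)
#' @param phase_sep use the phase separation law (TRUE) or pure
#'   flow-weighted mixing everywhere (FALSE)
#' @return numeric vector of per-segment hematocrits
#' @export
propagate_hematocrit <- function(net, flow, cfg, phase_sep = TRUE) {
  nd <- net$nodes; sg <- net$segments
  n <- nrow(nd); m <- nrow(sg)
  ia <- match(sg$a, nd$id); ib <- match(sg$b, nd$id)
  q <- flow$q
  qtol <- 1e-12 * max(abs(q), 1)
  H <- sg$H
  inc <- .incidence_lists(net)
  ord <- order(flow$pressure, decreasing = TRUE)
  for (ni in ord) {
    segs <- inc[[ni]]
    if (!length(segs)) next
    away <- ia[segs] == ni            # TRUE: segment points away via a-end
    qs <- ifelse(away, q[segs], -q[segs])  # positive = outflow from ni
    outs <- segs[qs > qtol]
    ins  <- segs[qs < -qtol]
    if (!length(outs)) next
    qout <- abs(q[outs])
    if (!length(ins)) {
      H[outs] <- cfg$H_bc          # source node (root acting as inlet)
      next
    }
    rbc_in <- sum(abs(q[ins]) * H[ins])
    qin_tot <- sum(abs(q[ins]))
    # at root nodes part of the blood drains externally; network outflows
    # then carry the flow-weighted mixture, not the full RBC flux
    drain <- nd$role[ni] != "interior" && qin_tot > sum(qout) + qtol
    if (drain) {
      H[outs] <- min(1, rbc_in / qin_tot)
    } else if (length(outs) == 1) {
      H[outs] <- min(1, rbc_in / max(qout, qin_tot))
    } else if (length(outs) == 2 && length(ins) == 1 && phase_sep) {
      hs <- phase_separation_split(abs(q[ins]), H[ins],
                                   qout[1], qout[2],
                                   sg$r_tilde[outs[1]], sg$r_tilde[outs[2]],
                                   sg$r_tilde[ins])
      H[outs] <- hs
    } else {
      # flow-weighted equal-hematocrit split
      H[outs] <- min(1, rbc_in / sum(qout))
    }
  }
  H
}

#' Self-consistent hemodynamics solve
#'
#' Alternates pressure solves (viscosity depends on hematocrit) with
#' hematocrit propagation (which depends on flows) under under-relaxation
#' until the largest per-segment hematocrit change falls below `cfg$H_tol`
#' and flow directions are stable.
#'
#' @param net a `vessel_network`
#' @param cfg a `sim_config`
#' @param phase_sep passed to [propagate_hematocrit()]
#' @return list with `net` (updated pressures, `q`, `H`) and `flow`
#'   (`flow_state` with `f`, `eta`, `converged`, `iterations`).
#' @export
solve_hemodynamics <- function(net, cfg, phase_sep = TRUE) {
  net$segments$H[is.na(net$segments$H)] <- cfg$H_bc
  fs <- NULL
  converged <- FALSE
  it <- 0
  prev_sign <- NULL
  for (it in seq_len(cfg$max_hemo_iter)) {
    fs <- solve_pressures(net, cfg)
    Hnew <- propagate_hematocrit(net, fs, cfg, phase_sep = phase_sep)
    d <- cfg$H_damping
    Hd <- (1 - d) * net$segments$H + d * Hnew
    dH <- max(abs(Hd - net$segments$H))
    net$segments$H <- Hd
    sgn <- sign(fs$q)
    stable <- !is.null(prev_sign) && all(sgn == prev_sign)
    prev_sign <- sgn
    if (dH < cfg$H_tol && (stable || it == 1)) { converged <- TRUE; break }
    if (!phase_sep && it >= 1) { converged <- TRUE; break }
  }
  # accepted iterate: flows from the final pressure solve, hematocrit
  # propagated (undamped) under exactly those flows, so that blood and
  # RBC conservation hold at machine precision at every node
  fs <- solve_pressures(net, cfg)
  net$segments$H <- propagate_hematocrit(net, fs, cfg, phase_sep = phase_sep)
  fs$converged <- converged
  fs$iterations <- it
  net$nodes$pressure <- fs$pressure
  net$segments$q <- fs$q
  list(net = net, flow = fs)
}
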