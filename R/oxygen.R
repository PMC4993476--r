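#' Hill oxyhemoglobin saturation curve
#'
#' `S(P) = P^n / (P^n + P_S50^n)`: fraction of hemoglobin binding sites
#' occupied at plasma partial pressure `P`.
#'
#' @param P partial oxygen pressure, mmHg (vectorized)
#' @param n Hill exponent
#' @param P_S50 half-saturation pressure, mmHg
#' @return saturation in [0, 1)
#' @export
hill_saturation <- function(P, n = 2.7, P_S50 = 27) {
  t <- ifelse(P <= 0, 0, (P / P_S50)^n)
  t / (1 + t)
}

#' Derivative of the Hill curve with respect to P
#' @inheritParams hill_saturation
#' @return dS/dP, per mmHg
#' @export
hill_saturation_slope <- function(P, n = 2.7, P_S50 = 27) {
  ifelse(P <= 0, 0, {
    t <- (P / P_S50)^n
    n * t / (P * (1 + t)^2)
  })
}

#' Total oxygen content of blood
#'
#' `c = alpha_p P + H c0 S(P)`: dissolved plus hemoglobin-bound oxygen per
#' unit volume of blood.
#'
#' @param P plasma PO2, mmHg
#' @param H hematocrit
#' @param cfg a `sim_config` (or any list with `alpha_p`, `c0`, `n`, `P_S50`)
#' @return mlO2 per ml blood
#' @export
blood_o2_content <- function(P, H, cfg = sim_config()) {
  cfg$alpha_p * P + H * cfg$c0 * hill_saturation(P, cfg$n, cfg$P_S50)
}

#' Transvascular mass-transfer coefficient
#'
#' From the Nusselt-number fit `Nu(r) = p2 (1 - exp(-r/p1))` and the
#' definition `Nu = 2 r gamma / (D_p alpha_p)`, so
#' `gamma = Nu(r) D_p alpha_p / (2 r)`, monotonically decreasing in the
#' radius.
#'
#' @param r vessel radius, um
#' @param cfg a `sim_config` (`nu_p1`, `nu_p2`, `D_p`, `alpha_p`)
#' @return gamma in um^3 O2 um^-2 s^-1 mmHg^-1
#' @export
mass_transfer_coefficient <- function(r, cfg = sim_config()) {
  nu <- cfg$nu_p2 * (1 - exp(-r / cfg$nu_p1))
  nu * cfg$D_p * cfg$alpha_p / (2 * r)
}

#' Inlet PO2 boundary curve at arterial roots
#'
#' `P_bc(r) = min(P0 + dP * r, Pc)`: larger feeding arterioles carry blood
#' closer to systemic arterial oxygenation, capped at `Pc`.
#'
#' @param r arteriolar radius, um
#' @param cfg a `sim_config`
#' @return PO2, mmHg
#' @export
inlet_po2 <- function(r, cfg = sim_config()) {
  pmin(cfg$P0_bc + cfg$dP_bc * r, cfg$Pc_bc)
}

#' Michaelis-Menten oxygen consumption rate
#'
#' `M(P) = M0 P / (P + P_M50)`; saturates at `M0` and vanishes linearly at
#' low PO2.
#'
#' @param P tissue PO2, mmHg
#' @param M0 maximal rate (any rate unit; returned in the same unit)
#' @param P_M50 half-maximum pressure, mmHg
#' @return consumption rate in units of `M0`
#' @export
mm_consumption <- function(P, M0, P_M50) {
  M0 * pmax(P, 0) / (pmax(P, 0) + P_M50)
}

#' One-dimensional zeroth-order oxygen diffusion length
#'
#' Distance over which tissue PO2 falls from `P0` to zero under constant
#' consumption `M0` in one dimension: `l_diff = sqrt(2 D alpha_t P0 / M0)`.
#'
#' @param P0 boundary PO2, mmHg
#' @param M0 consumption rate, mlO2 ml^-1 s^-1
#' @param D diffusivity, um^2/s
#' @param alpha_t tissue solubility, mlO2 ml^-1 mmHg^-1
#' @return length, um
#' @export
diffusion_length <- function(P0, M0, D = 2410, alpha_t = 2.8e-5) {
  if (any(M0 <= 0)) stop("diffusion_length: M0 must be positive")
  sqrt(2 * D * alpha_t * P0 / M0)
}

#' Peclet number
#' @param v velocity, um/s
#' @param L length scale, um
#' @param D diffusivity, um^2/s
#' @return dimensionless `v L / D`
#' @export
peclet <- function(v, L, D) {
  if (any(D <= 0)) stop("peclet: D must be positive")
  v * L / D
}

#' Regular tissue PO2 grid
#'
#' Cubic grid of tissue oxygen partial pressure over the domain `(0, L)^3`
#' with lattice constant `h`; grid sites sit at `(i h, j h, k h)`,
#' `i = 0..L/h`.
#'
#' @param L domain size, um
#' @param h lattice constant, um
#' @param value initial PO2, mmHg
#' @return object of class `tissue_grid` with `dims`, `h`, `L`, `P`
#'   (numeric vector in x-fastest order)
#' @export
tissue_grid <- function(L, h, value = 0) {
  nside <- floor(L / h + 1e-9) + 1
  structure(list(dims = c(nside, nside, nside), h = h, L = L,
                 P = rep(value, nside^3)),
            class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat(sprintf("<tissue_grid> %d^3 sites, h = %g um, mean P_t = %.2f mmHg\n",
              x$dims[1], x$h, mean(x$P)))
  invisible(x)
}

#' Grid site coordinates
#' @param grid a `tissue_grid`
#' @return matrix with columns x, y, z (um)
#' @export
grid_coords <- function(grid) {
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  i <- (seq_len(nx) - 1)
  cbind(x = rep(i, times = ny * nz) * grid$h,
        y = rep(rep((seq_len(ny) - 1), each = nx), times = nz) * grid$h,
        z = rep((seq_len(nz) - 1), each = nx * ny) * grid$h)
}

#' Oxygen flux balance at a junction
#'
#' Red cells meeting at a junction are assumed to equilibrate instantly to
#' a common partial pressure `P~` that conserves the total oxygen flux:
#' `sum_in q_i c(P_i) = [sum_out H_j q_j] c0 S(P~) + [sum_out q_j] alpha_p P~`,
#' solved by bisection.
#'
#' @param q_in,H_in,P_in inflow segment flows (positive), hematocrits, PO2s
#' @param q_out,H_out outflow flows (positive) and hematocrits
#' @param cfg a `sim_config`
#' @param tol bisection tolerance, mmHg
#' @return equilibrium PO2 `P~`, mmHg
#' @export
junction_mix_po2 <- function(q_in, H_in, P_in, q_out, H_out,
                             cfg = sim_config(), tol = 1e-8) {
  if (sum(q_in) <= 0) stop("junction_mix_po2: total inflow is zero")
  iota <- sum(q_in * blood_o2_content(P_in, H_in, cfg))
  qa <- sum(q_out) * cfg$alpha_p
  qh <- sum(q_out * H_out)
  gfun <- function(P) qa * P + qh * cfg$c0 * hill_saturation(P, cfg$n, cfg$P_S50) - iota
  hi <- max(P_in, 1e-6)
  while (gfun(hi) < 0) hi <- hi * 2
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gfun(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Integrate intravascular PO2 along one perfused segment
#'
#' Implicit-Euler integration of the axial oxygen advection equation with
#' transvascular diffusive loss `j_tv = gamma (P - P_t)` in conservative
#' form: `q c(P_{k+1}) + dx 2 pi r gamma (P_{k+1} - P_t(x_{k+1})) = q c(P_k)`.
#' Integration points are spaced `~h_v` with the last point coinciding with
#' the segment end (`ceiling(l/h_v) + 1` points).
#'
#' @param P_in upstream PO2, mmHg
#' @param r radius, um
#' @param l length, um
#' @param H hematocrit
#' @param q flow magnitude, um^3/s (must be > 0)
#' @param P_t tissue PO2 at the integration points: scalar, vector of
#'   length `ceiling(l/h_v)+1`, or function of arc length
#' @param cfg a `sim_config`
#' @param gamma mass-transfer coefficient; default from the Nusselt fit
#' @return list with `x` (arc length), `P` (PO2 samples), `exchange`
#'   (per-point transvascular loss `w_k gamma 2 pi r (P_k - P_t_k)`,
#'   trapezoid weights, mlO2/s), `S` (saturation samples)
#' @export
integrate_vessel_po2 <- function(P_in, r, l, H, q, P_t, cfg = sim_config(),
                                 gamma = mass_transfer_coefficient(r, cfg)) {
  if (q <= 0) stop("integrate_vessel_po2: flow must be positive along the direction of integration")
  np <- max(2L, as.integer(ceiling(l / cfg$h_v)) + 1L)
  dx <- l / (np - 1)
  x <- (seq_len(np) - 1) * dx
  Pt <- if (is.function(P_t)) P_t(x) else rep_len(P_t, np)
  P <- numeric(np)
  P[1] <- P_in
  A <- dx * 2 * pi * r * gamma
  cont <- function(p) q * blood_o2_content(p, H, cfg)
  for (k in 2:np) {
    rhs <- cont(P[k - 1]) + A * Pt[k]
    gfun <- function(p) cont(p) + A * p - rhs
    lo <- min(P[k - 1], Pt[k]); hi <- max(P[k - 1], Pt[k])
    if (hi - lo < 1e-12) { P[k] <- lo; next }
    if (gfun(lo) > 0) { P[k] <- lo; next }
    if (gfun(hi) < 0) { P[k] <- hi; next }
    P[k] <- stats::uniroot(gfun, c(lo, hi), tol = 1e-10)$root
  }
  wlen <- rep(dx, np); wlen[c(1, np)] <- dx / 2
  list(x = x, P = P,
       exchange = wlen * 2 * pi * r * gamma * (P - Pt),
       S = hill_saturation(P, cfg$n, cfg$P_S50))
}

.role_code <- function(role) {
  match(role, c("interior", "arterial_root", "venous_root")) - 1L
}

#' Tumor region mask on a tissue grid
#' @param grid a `tissue_grid`
#' @param center tumor center (3-vector, um)
#' @param R_tum tumor radius, um (0 for none)
#' @return logical vector over grid sites
#' @export
grid_tumor_mask <- function(grid, center, R_tum) {
  if (R_tum <= 0) return(rep(FALSE, prod(grid$dims)))
  xyz <- grid_coords(grid)
  sqrt((xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
       (xyz[, 3] - center[3])^2) <= R_tum
}

.sweep_network <- function(net, flow, grid, cfg) {
  nd <- net$nodes; sg <- net$segments
  ia <- match(sg$a, nd$id) - 1L
  ib <- match(sg$b, nd$id) - 1L
  role <- .role_code(nd$role)
  # inlet PO2 per node from the widest attached segment (anatomical radius)
  widest <- rep(2.5, nrow(nd))
  agg <- tapply(c(sg$r, sg$r), c(ia + 1L, ib + 1L), max)
  widest[as.integer(names(agg))] <- agg
  inletP <- inlet_po2(widest, cfg)
  gam <- mass_transfer_coefficient(sg$r_tilde, cfg)
  qtol <- 1e-12 * max(abs(flow$q), 1e-30)
  press <- flow$pressure
  press[!is.finite(press)] <- -1e300   # isolated nodes sort last
  cpp_vessel_sweep(ia, ib, nd$x, nd$y, nd$z, press, role, inletP,
                   sg$r_tilde, sg$l, sg$H, flow$q, gam,
                   as.integer(grid$dims), grid$h, grid$P,
                   cfg$n, cfg$P_S50, cfg$alpha_p, cfg$c0, cfg$h_v, qtol,
                   cfg$H_bc)
}

#' Assemble the linearized tissue oxygen system
#'
#' Builds the sparse symmetric system
#' `[alpha_t D_t Lap_h - MB I - QB] P_t = MA - QA` for one fixed-point
#' iteration: 7-point Neumann Laplacian, Michaelis-Menten consumption
#' linearized about the previous iterate, and transvascular line sources
#' accumulated over vessel integration points with trilinear weights (the
#' exchange matrix is diagonalized, i.e. tissue PO2 under the vessel is
#' taken from the owning site).
#'
#' @param sweep result of a vessel sweep (internal; `QA`, `QB` per site,
#'   already divided by nothing — raw mlO2/s/mmHg weights times h^-3 applied
#'   here)
#' @param grid a `tissue_grid` (previous iterate in `grid$P`)
#' @param M0,P_M50 per-site Michaelis-Menten parameters (mlO2 ml^-1 s^-1,
#'   mmHg)
#' @param cfg a `sim_config`
#' @return list with sparse matrix `A` (negated, SPD), right-hand side
#'   `b` such that `A P_t = b`, and the diagonal pieces.
#' @export
assemble_tissue_system <- function(sweep, grid, M0, P_M50, cfg) {
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  n <- nx * ny * nz
  h <- grid$h
  kappa <- cfg$alpha_t * cfg$D_t / h^2
  Pt <- grid$P
  MB <- M0 * P_M50 / (pmax(Pt, 0) + P_M50)^2
  MA <- mm_consumption(Pt, M0, P_M50) - MB * Pt
  QBd <- sweep$QB / h^3
  QAv <- sweep$QA / h^3
  # negated system: (kappa * (-Lap) + MB + QB) Pt = QA - MA  (SPD)
  idx <- seq_len(n)
  i3 <- (idx - 1) %% nx
  j3 <- ((idx - 1) %/% nx) %% ny
  k3 <- (idx - 1) %/% (nx * ny)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (d in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    ok <- (i3 + d[1] < nx) & (j3 + d[2] < ny) & (k3 + d[3] < nz)
    from <- idx[ok]
    to <- from + d[1] + d[2] * nx + d[3] * nx * ny
    ii <- c(ii, from, to); jj <- c(jj, to, from)
    xx <- c(xx, rep(-kappa, 2 * length(from)))
  }
  nbrs <- tabulate(ii, n)
  A <- Matrix::sparseMatrix(i = c(ii, idx), j = c(jj, idx),
                            x = c(xx, nbrs * kappa + MB + QBd),
                            dims = c(n, n))
  list(A = A, b = QAv - MA, MB = MB, MA = MA, QB = QBd, QA = QAv,
       kappa = kappa)
}

#' Solve the coupled intravascular/tissue oxygen problem to a fixed point
#'
#' Alternates a network sweep (junction mixing + implicit-Euler axial
#' integration in topological order) with a linearized tissue diffusion
#' solve until the maximum change of both the tissue field and the
#' per-segment upstream PO2s falls below `cfg$eps` (0.1 mmHg by default).
#' The tissue system is solved by Jacobi-preconditioned conjugate
#' gradients on the 7-point stencil.
#'
#' @param net a `vessel_network` with flow solved (`q`, `H`, pressures)
#' @param flow a `flow_state`
#' @param cfg a `sim_config`
#' @param grid optional `tissue_grid`; default spans the network domain at
#'   `cfg$h`
#' @param center,R_tum tumor sphere for region-dependent consumption
#'   (default: no tumor)
#' @param Pt_init initial tissue PO2; default `P_root,max / 2`
#' @param M0_tumor_override optional tumor M0 (ulO2 ml^-1 min^-1), e.g. a
#'   METAB draw
#' @return object of class `oxygen_solution`: `grid` (converged tissue
#'   PO2), per-segment `Sbar`, `Pbar`, `P_up`, `P_down`, `exchange`
#'   (mlO2/s), `influx`/`outflux` (root oxygen fluxes, mlO2/s),
#'   `consumption` (mlO2/s), `iterations`, `converged`.
#' @export
solve_coupled <- function(net, flow, cfg, grid = NULL, center = NULL,
                          R_tum = 0, Pt_init = NULL,
                          M0_tumor_override = NULL) {
  if (is.null(grid)) grid <- tissue_grid(net$L, cfg$h)
  if (is.null(center)) center <- rep(net$L / 2, 3)
  mask <- grid_tumor_mask(grid, center, R_tum)
  mmN <- mm_params(cfg, tumor = FALSE)
  mmT <- mm_params(cfg, tumor = TRUE)
  if (!is.null(M0_tumor_override)) mmT$M0 <- M0_tumor_override * 1e-3 / 60
  M0 <- ifelse(mask, mmT$M0, mmN$M0)
  P_M50 <- ifelse(mask, mmT$P_M50, mmN$P_M50)
  if (is.null(Pt_init)) {
    Pt_init <- max(inlet_po2(net$segments$r, cfg)) / 2
  }
  grid$P <- rep_len(Pt_init, prod(grid$dims))
  h <- grid$h
  kappa <- cfg$alpha_t * cfg$D_t / h^2
  P_up_prev <- NULL
  sweep <- NULL
  converged <- FALSE
  it <- 0
  for (it in seq_len(cfg$max_outer)) {
    sweep <- .sweep_network(net, flow, grid, cfg)
    MB <- M0 * P_M50 / (pmax(grid$P, 0) + P_M50)^2
    MA <- mm_consumption(grid$P, M0, P_M50) - MB * grid$P
    diagv <- MB + sweep$QB / h^3
    rhs <- sweep$QA / h^3 - MA
    sol <- cpp_tissue_cg(as.integer(grid$dims), kappa, diagv, rhs, grid$P,
                         1e-9, 5000L)
    Pt_new <- pmax(sol$x, 0)
    dPt <- max(abs(Pt_new - grid$P))
    dPv <- if (is.null(P_up_prev)) Inf else
      max(abs(sweep$P_up - P_up_prev), na.rm = TRUE)
    grid$P <- Pt_new
    P_up_prev <- sweep$P_up
    if (dPt < cfg$eps && dPv < cfg$eps) { converged <- TRUE; break }
  }
  sweep <- .sweep_network(net, flow, grid, cfg)
  consumption <- sum(mm_consumption(grid$P, M0, P_M50)) * h^3
  structure(list(grid = grid, Sbar = sweep$Sbar, Pbar = sweep$Pbar,
                 P_up = sweep$P_up, P_down = sweep$P_down,
                 exchange = sweep$exchange,
                 influx = sweep$influx, outflux = sweep$outflux,
                 consumption = consumption, M0_site = M0, P_M50_site = P_M50,
                 iterations = it, converged = converged),
            class = "oxygen_solution")
}

#' @export
print.oxygen_solution <- function(x, ...) {
  cat(sprintf(
    "<oxygen_solution> %s after %d iterations; mean P_t = %.1f mmHg, mean S = %.3f\n",
    if (x$converged) "converged" else "NOT converged", x$iterations,
    mean(x$grid$P), mean(x$Sbar, na.rm = TRUE)))
  invisible(x)
}

#' Line-source exchange weights for a prescribed vascular PO2
#'
#' Accumulates the transvascular source terms (`QA`, diagonal `QB`, and
#' optionally the full exchange matrix with basis-product off-diagonals)
#' for a fixed per-segment intravascular PO2, using the same integration
#' points and trilinear weights as the coupled solver. Used by the
#' simplified constant-PO2 solver mode and by the check that the
#' diagonalized exchange matrix is an adequate approximation.
#'
#' @param net a `vessel_network`
#' @param grid a `tissue_grid`
#' @param cfg a `sim_config`
#' @param P_seg intravascular PO2 per segment (recycled), mmHg
#' @param full also assemble the full sparse exchange matrix `QBfull`
#' @return list with `QA`, `QBdiag` (both un-normalized, i.e. in
#'   um^3 O2 s^-1 mmHg^-1 units as accumulated; divide by h^3 for the
#'   per-site system) and optionally `QBfull` (sparse, same scaling)
#' @export
line_source_weights <- function(net, grid, cfg, P_seg, full = FALSE) {
  nd <- net$nodes; sg <- net$segments
  ia <- match(sg$a, nd$id); ib <- match(sg$b, nd$id)
  P_seg <- rep_len(P_seg, nrow(sg))
  n <- prod(grid$dims)
  QA <- numeric(n); QB <- numeric(n)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  nx <- grid$dims[1]; ny <- grid$dims[2]
  gam <- mass_transfer_coefficient(sg$r_tilde, cfg)
  for (e in seq_len(nrow(sg))) {
    np <- max(2L, as.integer(ceiling(sg$l[e] / cfg$h_v)) + 1L)
    dx <- sg$l[e] / (np - 1)
    tt <- (seq_len(np) - 1) / (np - 1)
    px <- nd$x[ia[e]] + tt * (nd$x[ib[e]] - nd$x[ia[e]])
    py <- nd$y[ia[e]] + tt * (nd$y[ib[e]] - nd$y[ia[e]])
    pz <- nd$z[ia[e]] + tt * (nd$z[ib[e]] - nd$z[ia[e]])
    wlen <- rep(dx, np); wlen[c(1, np)] <- dx / 2
    coef <- wlen * 2 * pi * sg$r_tilde[e] * gam[e]
    fx <- px / grid$h; fy <- py / grid$h; fz <- pz / grid$h
    i0 <- pmin(pmax(floor(fx), 0), nx - 2)
    j0 <- pmin(pmax(floor(fy), 0), ny - 2)
    k0 <- pmin(pmax(floor(fz), 0), grid$dims[3] - 2)
    ax <- fx - i0; ay <- fy - j0; az <- fz - k0
    for (c in 0:7) {
      di <- c %% 2; dj <- (c %/% 2) %% 2; dk <- c %/% 4
      w <- (if (di) ax else 1 - ax) * (if (dj) ay else 1 - ay) *
           (if (dk) az else 1 - az)
      site <- 1 + (i0 + di) + nx * ((j0 + dj) + ny * (k0 + dk))
      QA <- QA + tapply2(site, coef * w * P_seg[e], n)
      QB <- QB + tapply2(site, coef * w, n)
      if (full) {
        for (c2 in 0:7) {
          di2 <- c2 %% 2; dj2 <- (c2 %/% 2) %% 2; dk2 <- c2 %/% 4
          w2 <- (if (di2) ax else 1 - ax) * (if (dj2) ay else 1 - ay) *
                (if (dk2) az else 1 - az)
          site2 <- 1 + (i0 + di2) + nx * ((j0 + dj2) + ny * (k0 + dk2))
          ti <- c(ti, site); tj <- c(tj, site2)
          tx <- c(tx, coef * w * w2)
        }
      }
    }
  }
  out <- list(QA = QA, QBdiag = QB)
  if (full) {
    out$QBfull <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                                       dims = c(n, n))
  }
  out
}

#' Tissue oxygen field for a prescribed vascular PO2 (simplified mode)
#'
#' Solves the tissue diffusion/consumption problem treating the
#' intravascular PO2 as a fixed input (constant per segment) instead of
#' coupling it to axial transport — the classic simplification when the
#' vascular side is taken as a boundary condition. Iterates the
#' Michaelis-Menten linearization to the same `eps` fixed point.
#'
#' @param net a `vessel_network`
#' @param cfg a `sim_config`
#' @param vessel_po2 per-segment PO2 (scalar recycled), mmHg
#' @param grid optional `tissue_grid`
#' @param center,R_tum tumor sphere for region-dependent consumption
#' @param full_qb use the full exchange matrix instead of the
#'   diagonalized one
#' @return object of class `oxygen_solution` (vascular fields are the
#'   prescribed constants; no flux bookkeeping)
#' @export
solve_tissue_fixed_po2 <- function(net, cfg, vessel_po2, grid = NULL,
                                   center = NULL, R_tum = 0,
                                   full_qb = FALSE) {
  if (is.null(grid)) grid <- tissue_grid(net$L, cfg$h)
  if (is.null(center)) center <- rep(net$L / 2, 3)
  mask <- grid_tumor_mask(grid, center, R_tum)
  mmN <- mm_params(cfg, FALSE); mmT <- mm_params(cfg, TRUE)
  M0 <- ifelse(mask, mmT$M0, mmN$M0)
  P_M50 <- ifelse(mask, mmT$P_M50, mmN$P_M50)
  P_seg <- rep_len(vessel_po2, nrow(net$segments))
  ws <- line_source_weights(net, grid, cfg, P_seg, full = full_qb)
  h <- grid$h
  kappa <- cfg$alpha_t * cfg$D_t / h^2
  n <- prod(grid$dims)
  grid$P <- rep(max(P_seg) / 2, n)
  converged <- FALSE
  it <- 0
  for (it in seq_len(cfg$max_outer)) {
    MB <- M0 * P_M50 / (pmax(grid$P, 0) + P_M50)^2
    MA <- mm_consumption(grid$P, M0, P_M50) - MB * grid$P
    rhs <- ws$QA / h^3 - MA
    if (full_qb) {
      idx <- seq_len(n)
      i3 <- (idx - 1) %% grid$dims[1]
      j3 <- ((idx - 1) %/% grid$dims[1]) %% grid$dims[2]
      k3 <- (idx - 1) %/% (grid$dims[1] * grid$dims[2])
      ii <- jj <- integer(0); xx <- numeric(0)
      for (d in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
        ok <- (i3 + d[1] < grid$dims[1]) & (j3 + d[2] < grid$dims[2]) &
              (k3 + d[3] < grid$dims[3])
        from <- idx[ok]
        to <- from + d[1] + d[2] * grid$dims[1] +
              d[3] * grid$dims[1] * grid$dims[2]
        ii <- c(ii, from, to); jj <- c(jj, to, from)
        xx <- c(xx, rep(-kappa, 2 * length(from)))
      }
      nbrs <- tabulate(ii, n)
      A <- Matrix::sparseMatrix(i = c(ii, idx), j = c(jj, idx),
                                x = c(xx, nbrs * kappa + MB),
                                dims = c(n, n)) + ws$QBfull / h^3
      Pt_new <- pmax(as.numeric(Matrix::solve(A, rhs)), 0)
    } else {
      sol <- cpp_tissue_cg(as.integer(grid$dims), kappa,
                           MB + ws$QBdiag / h^3, rhs, grid$P, 1e-9, 5000L)
      Pt_new <- pmax(sol$x, 0)
    }
    dPt <- max(abs(Pt_new - grid$P))
    grid$P <- Pt_new
    if (dPt < cfg$eps) { converged <- TRUE; break }
  }
  m <- nrow(net$segments)
  structure(list(grid = grid, Sbar = hill_saturation(P_seg, cfg$n, cfg$P_S50),
                 Pbar = P_seg, P_up = P_seg, P_down = P_seg,
                 exchange = rep(NA_real_, m),
                 influx = NA_real_, outflux = NA_real_,
                 consumption = sum(mm_consumption(grid$P, M0, P_M50)) * h^3,
                 M0_site = M0, P_M50_site = P_M50,
                 iterations = it, converged = converged),
            class = "oxygen_solution")
}
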