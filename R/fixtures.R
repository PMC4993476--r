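#' Single perfused tube fixture with analytic references
#'
#' An axis-aligned tube through the center of a cubic box, with an
#' arterial root at the upstream end and a venous root downstream.
#' Returned together with closed-form reference profiles:
#' \itemize{
#'   \item `expo_profile(x, P_in, P_t, q)`: the plasma-only (`H = 0`)
#'     intravascular profile
#'     `P(x) = P_t + (P_in - P_t) exp(-2 pi r gamma x / (q alpha_p))`
#'     for constant tissue PO2.
#'   \item `krogh_profile(rho, P_wall, M0)`: the classical radial tissue
#'     profile around a single capillary supplying a concentric cylinder
#'     of radius `R_k` under zeroth-order consumption:
#'     `P(rho) = P_wall + M0/(4 D alpha_t) (rho^2 - r^2)
#'       - M0 R_k^2/(2 D alpha_t) log(rho/r)`.
#' }
#'
#' @param r tube radius, um
#' @param l tube length, um
#' @param box_L box size, um (tube centered; `l <= box_L`)
#' @param cfg a `sim_config`
#' @param H hematocrit assigned to the tube
#' @param R_k Krogh cylinder radius for the reference closure, um
#' @return list with `net`, `gamma`, `expo_profile`, `krogh_profile`
#' @export
make_single_tube <- function(r = 3, l = 1000, box_L = 1000,
                             cfg = sim_config(), H = 0.45,
                             R_k = 100) {
  c0 <- box_L / 2
  nodes <- data.frame(id = 1:2,
                      x = c(c0 - l / 2, c0 + l / 2),
                      y = c0, z = c0,
                      role = c("arterial_root", "venous_root"))
  segs <- data.frame(id = 1L, a = 1L, b = 2L, r = r, H = H,
                     type = "capillary")
  net <- vessel_network(nodes, segs, h_gen = l, h_fine = cfg$h_fine,
                        L = box_L)
  gam <- mass_transfer_coefficient(r, cfg)
  expo_profile <- function(x, P_in, P_t, q) {
    P_t + (P_in - P_t) * exp(-2 * pi * r * gam * x / (q * cfg$alpha_p))
  }
  krogh_profile <- function(rho, P_wall, M0) {
    P_wall + M0 / (4 * cfg$D_t * cfg$alpha_t) * (rho^2 - r^2) -
      M0 * R_k^2 / (2 * cfg$D_t * cfg$alpha_t) * log(rho / r)
  }
  list(net = net, gamma = gam, expo_profile = expo_profile,
       krogh_profile = krogh_profile)
}

#' Symmetric bifurcation fixture
#'
#' One arterial root feeding a junction that splits into two daughter
#' branches draining at two venous roots. Daughter radii and lengths can
#' be made asymmetric.
#'
#' @param r_parent,r1,r2 radii, um
#' @param l segment length, um
#' @param box_L box size, um
#' @param cfg a `sim_config`
#' @return a `vessel_network`
#' @export
make_bifurcation <- function(r_parent = 10, r1 = 8, r2 = 8, l = 400,
                             box_L = 1600, cfg = sim_config()) {
  c0 <- box_L / 2
  nodes <- data.frame(
    id = 1:4,
    x = c(c0 - l, c0, c0 + l / sqrt(2), c0 + l / sqrt(2)),
    y = c(c0, c0, c0 + l / sqrt(2), c0 - l / sqrt(2)),
    z = c0,
    role = c("arterial_root", "interior", "venous_root", "venous_root"))
  segs <- data.frame(id = 1:3, a = c(1L, 2L, 2L), b = c(2L, 3L, 4L),
                     r = c(r_parent, r1, r2),
                     type = c("artery", "vein", "vein"), H = cfg$H_bc)
  vessel_network(nodes, segs, h_gen = l, h_fine = cfg$h_fine, L = box_L)
}

#' Random perfused tree fixture for solver oracles
#'
#' A small random arterio-venous chain/tree with arbitrary radii used to
#' compare the sparse pressure solver against a dense oracle. All nodes
#' lie in the box; roots are the first and last nodes.
#'
#' @param n_seg number of segments (chain plus random shortcuts never
#'   exceeding degree 3)
#' @param box_L box size, um
#' @param cfg a `sim_config`
#' @param seed RNG seed
#' @return a `vessel_network`
#' @export
make_random_fixture <- function(n_seg = 10, box_L = 2000,
                                cfg = sim_config(), seed = 1) {
  set.seed(seed)
  n <- n_seg + 1
  nodes <- data.frame(id = seq_len(n),
                      x = stats::runif(n, 0.1, 0.9) * box_L,
                      y = stats::runif(n, 0.1, 0.9) * box_L,
                      z = stats::runif(n, 0.1, 0.9) * box_L,
                      role = "interior")
  nodes$role[1] <- "arterial_root"
  nodes$role[n] <- "venous_root"
  segs <- data.frame(id = seq_len(n_seg), a = seq_len(n_seg),
                     b = seq_len(n_seg) + 1L,
                     r = stats::runif(n_seg, 2.5, 12),
                     type = "capillary", H = cfg$H_bc)
  vessel_network(nodes, segs, h_gen = 130, h_fine = cfg$h_fine, L = box_L)
}

#' Miniature end-to-end lattice network
#'
#' A small RC1-style network (full pipeline at reduced domain size) with
#' guaranteed arterio-venous connectivity, for smoke tests of the whole
#' solver chain.
#'
#' @param L domain size, um
#' @param seed RNG seed
#' @param cfg base `sim_config`; geometry is forced to RC1 and `L`
#'   overridden
#' @return a `vessel_network`
#' @export
make_mini_lattice <- function(L = 1200, seed = 1, cfg = sim_config()) {
  cfg$L <- L
  cfg$geometry <- "RC1"
  generate_network(cfg, seed = seed)
}
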