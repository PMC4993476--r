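#' Tumor state
#'
#' Spherical tumor expanding linearly: `R_tum(t) = R_tum(0) + v_tum * t`.
#'
#' @param R_tum current radius, um
#' @param t time, hours
#' @param center 3-vector, um
#' @return object of class `tumor_state`
#' @export
tumor_state <- function(R_tum = 250, t = 0, center = c(0, 0, 0)) {
  structure(list(R_tum = R_tum, t = t, center = center),
            class = "tumor_state")
}

.seg_mid <- function(net) {
  ia <- match(net$segments$a, net$nodes$id)
  ib <- match(net$segments$b, net$nodes$id)
  cbind((net$nodes$x[ia] + net$nodes$x[ib]) / 2,
        (net$nodes$y[ia] + net$nodes$y[ib]) / 2,
        (net$nodes$z[ia] + net$nodes$z[ib]) / 2)
}

.dist_center <- function(xyz, center) {
  sqrt((xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
       (xyz[, 3] - center[3])^2)
}

#' Resample a network onto the fine lattice spacing
#'
#' Subdivides every segment into sub-segments of approximately `h_fine`
#' length (the remodeling resolution), placing the new interior nodes on
#' the segment axis. All per-segment attributes are inherited.
#'
#' @param net a `vessel_network`
#' @param h_fine target sub-segment length, um (default from the network)
#' @return the resampled `vessel_network`
#' @export
subdivide_segments <- function(net, h_fine = net$h_fine) {
  nd <- net$nodes; sg <- net$segments
  ia <- match(sg$a, nd$id); ib <- match(sg$b, nd$id)
  nsub <- pmax(1L, as.integer(round(sg$l / h_fine)))
  keep <- nsub == 1L
  new_nodes <- list(nd)
  new_segs <- list(sg[keep, , drop = FALSE])
  next_node <- max(nd$id) + 1L
  next_seg <- if (nrow(sg)) max(sg$id) + 1L else 1L
  for (e in which(!keep)) {
    n <- nsub[e]
    frac <- seq_len(n - 1) / n
    ids <- next_node + seq_len(n - 1) - 1L
    next_node <- next_node + n - 1L
    new_nodes[[length(new_nodes) + 1]] <- data.frame(
      id = ids,
      x = nd$x[ia[e]] + frac * (nd$x[ib[e]] - nd$x[ia[e]]),
      y = nd$y[ia[e]] + frac * (nd$y[ib[e]] - nd$y[ia[e]]),
      z = nd$z[ia[e]] + frac * (nd$z[ib[e]] - nd$z[ia[e]]),
      role = "interior", pressure = NA_real_)
    chain <- c(sg$a[e], ids, sg$b[e])
    part <- sg[rep(e, n), , drop = FALSE]
    part$id <- next_seg + seq_len(n) - 1L
    next_seg <- next_seg + n
    part$a <- chain[-length(chain)]
    part$b <- chain[-1]
    part$l <- sg$l[e] / n
    new_segs[[length(new_segs) + 1]] <- part
  }
  nd2 <- do.call(rbind, new_nodes)
  if (is.null(nd2$pressure)) nd2$pressure <- NA_real_
  sg2 <- do.call(rbind, new_segs)
  rownames(nd2) <- rownames(sg2) <- NULL
  vessel_network(nd2, sg2, h_gen = net$h_gen, h_fine = h_fine, L = net$L,
                 meta = net$meta)
}

#' Initial wall stability
#'
#' Healthy vessels start with a wall stability proportional to a
#' radius-dependent wall thickness, `w0(r) = min(r/2, 10)` um by default.
#' Only the decay rate and the `w = 0` collapse condition matter for the
#' remodeling dynamics.
#'
#' @param r radius, um
#' @return wall stability, um
#' @export
initial_wall_stability <- function(r) {
  pmin(r / 2, 10)
}

# path distance (um) from every node to the nearest branching point
.branch_distances <- function(net) {
  deg <- node_degrees(net)
  branch <- which(deg >= 3L)
  n <- nrow(net$nodes)
  if (!length(branch)) return(rep(Inf, n))
  ia <- match(net$segments$a, net$nodes$id)
  ib <- match(net$segments$b, net$nodes$id)
  g <- igraph::graph_from_edgelist(cbind(ia, ib), directed = FALSE)
  if (igraph::vcount(g) < n + 1) g <- igraph::add_vertices(g, n + 1 - igraph::vcount(g))
  # virtual source node n+1 linked to all branch points with weight 0
  g <- igraph::add_edges(g, as.vector(rbind(n + 1L, branch)))
  wts <- c(net$segments$l, rep(0, length(branch)))
  d <- igraph::distances(g, v = n + 1L, weights = wts)
  as.numeric(d)[seq_len(n)]
}

#' Angiogenic sprout initiation
#'
#' Nodes in tissue inside the angiogenic shell
#' (`R_tum < |x - center| < R_tum + R_g`), with spare degree and no
#' branching point within `d_br_min` um of network path, spawn a sprout
#' segment of radius `r_sprout` in a uniformly random lattice direction
#' with probability `dt / t_sprout` per step.
#'
#' @param net a `vessel_network` (fine-lattice resolution)
#' @param tumor a `tumor_state`
#' @param cfg a `sim_config`
#' @return the updated network
#' @export
step_sprout_init <- function(net, tumor, cfg) {
  nd <- net$nodes
  dists <- .dist_center(cbind(nd$x, nd$y, nd$z), tumor$center)
  deg <- node_degrees(net)
  dbr <- .branch_distances(net)
  eligible <- which(dists > tumor$R_tum & dists < tumor$R_tum + cfg$R_g &
                    deg <= 2L & deg >= 1L & dbr >= cfg$d_br_min &
                    nd$role == "interior")
  if (!length(eligible)) return(net)
  fire <- eligible[stats::runif(length(eligible)) < cfg$dt / cfg$t_sprout]
  if (!length(fire)) return(net)
  dirs <- .fcc_offsets / sqrt(2)   # unit vectors
  # occupancy hash: sprouts may not be spawned on top of existing vessels
  occ_key <- function(x, y, z) paste(round(x / (net$h_fine / 2)),
                                     round(y / (net$h_fine / 2)),
                                     round(z / (net$h_fine / 2)))
  occ <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(nd))) assign(occ_key(nd$x[i], nd$y[i], nd$z[i]),
                                      TRUE, envir = occ)
  next_node <- max(nd$id) + 1L
  next_seg <- max(net$segments$id) + 1L
  add_nd <- list(); add_sg <- list()
  for (v in fire) {
    d <- dirs[sample.int(nrow(dirs), 1L), ]
    pos <- c(nd$x[v], nd$y[v], nd$z[v]) + d * net$h_fine
    if (any(pos < 0 | pos > net$L)) next
    k <- occ_key(pos[1], pos[2], pos[3])
    if (isTRUE(mget(k, envir = occ, ifnotfound = list(NULL))[[1]])) next
    assign(k, TRUE, envir = occ)
    add_nd[[length(add_nd) + 1]] <- data.frame(
      id = next_node, x = pos[1], y = pos[2], z = pos[3],
      role = "interior", pressure = NA_real_)
    add_sg[[length(add_sg) + 1]] <- data.frame(
      id = next_seg, a = nd$id[v], b = next_node, r = cfg$r_sprout,
      r_tilde = cfg$r_sprout, l = net$h_fine, H = 0, q = 0,
      w = initial_wall_stability(cfg$r_sprout), type = "capillary",
      tumor = FALSE, sprout = TRUE, boundary = FALSE, tau = 1, tin = 0)
    next_node <- next_node + 1L
    next_seg <- next_seg + 1L
  }
  if (!length(add_nd)) return(net)
  net$nodes <- rbind(nd, do.call(rbind, add_nd))
  net$segments <- rbind(net$segments, do.call(rbind, add_sg))
  net
}

#' Sprout migration, connection, and ageing
#'
#' Active sprout tips extend by one fine-lattice bond with probability
#' `dt / t_sprout`; a tip landing within half a bond of an existing node
#' connects to it (rejected if that would create a degree-4 junction).
#' Sprout ages `tau` are incremented globally; sprouts that never became
#' perfused within `t_migr` hours are removed (with their whole chain).
#'
#' @param net a `vessel_network`
#' @param cfg a `sim_config`
#' @return the updated network
#' @export
step_sprout_migrate <- function(net, cfg) {
  sg <- net$segments
  nd <- net$nodes
  sg$tau[sg$sprout] <- sg$tau[sg$sprout] + cfg$dt
  net$segments <- sg
  deg <- node_degrees(net)
  # spatial hash for contact detection
  key <- function(x, y, z) paste(round(x / (net$h_fine / 2)),
                                 round(y / (net$h_fine / 2)),
                                 round(z / (net$h_fine / 2)))
  hash <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(nd))) assign(key(nd$x[i], nd$y[i], nd$z[i]),
                                      i, envir = hash)
  # active tips: degree-1 endpoints of live sprout segments
  sprout_seg <- which(sg$sprout & sg$tau <= cfg$t_migr)
  tips <- integer(0); tip_seg <- integer(0)
  for (e in sprout_seg) {
    for (endp in c(sg$a[e], sg$b[e])) {
      vi <- match(endp, nd$id)
      if (deg[vi] == 1L) { tips <- c(tips, vi); tip_seg <- c(tip_seg, e) }
    }
  }
  dirs <- .fcc_offsets / sqrt(2)
  next_node <- max(nd$id) + 1L
  next_seg <- max(sg$id) + 1L
  for (t in seq_along(tips)) {
    if (stats::runif(1) >= cfg$dt / cfg$t_sprout) next
    vi <- tips[t]
    d <- dirs[sample.int(nrow(dirs), 1L), ]
    pos <- c(nd$x[vi], nd$y[vi], nd$z[vi]) + d * net$h_fine
    if (any(pos < 0 | pos > net$L)) next
    hit <- mget(key(pos[1], pos[2], pos[3]), envir = hash,
                ifnotfound = list(NULL))[[1]]
    tau_now <- sg$tau[tip_seg[t]]
    if (!is.null(hit)) {
      # connection to an existing vessel; reject degree-4 junctions
      if (node_degrees(net)[hit] >= 3L || hit == vi) next
      seg_new <- data.frame(
        id = next_seg, a = nd$id[vi], b = nd$id[hit], r = cfg$r_sprout,
        r_tilde = cfg$r_sprout,
        l = sqrt(sum((c(nd$x[hit], nd$y[hit], nd$z[hit]) -
                      c(nd$x[vi], nd$y[vi], nd$z[vi]))^2)),
        H = 0, q = 0, w = initial_wall_stability(cfg$r_sprout),
        type = "capillary", tumor = FALSE, sprout = TRUE, boundary = FALSE,
        tau = tau_now, tin = 0)
      net$segments <- rbind(net$segments, seg_new)
      next_seg <- next_seg + 1L
    } else {
      nd_new <- data.frame(id = next_node, x = pos[1], y = pos[2],
                           z = pos[3], role = "interior",
                           pressure = NA_real_)
      seg_new <- data.frame(
        id = next_seg, a = nd$id[vi], b = next_node, r = cfg$r_sprout,
        r_tilde = cfg$r_sprout, l = net$h_fine, H = 0, q = 0,
        w = initial_wall_stability(cfg$r_sprout), type = "capillary",
        tumor = FALSE, sprout = TRUE, boundary = FALSE, tau = tau_now,
        tin = 0)
      net$nodes <- rbind(net$nodes, nd_new)
      net$segments <- rbind(net$segments, seg_new)
      assign(key(pos[1], pos[2], pos[3]), nrow(net$nodes), envir = hash)
      next_node <- next_node + 1L
      next_seg <- next_seg + 1L
    }
    nd <- net$nodes
    sg <- net$segments
  }
  # expire never-circulated sprouts; pruning also removes anything this
  # stranded (e.g. a younger sprout that had connected into the dead one)
  expired <- net$segments$sprout & net$segments$tau > cfg$t_migr
  if (any(expired)) {
    net$segments <- net$segments[!expired, , drop = FALSE]
    net <- .drop_isolated_nodes(net)
    net <- prune_dead_ends(net, cfg)
  }
  net
}

.drop_isolated_nodes <- function(net) {
  used <- net$nodes$id %in% c(net$segments$a, net$segments$b) |
          net$nodes$role != "interior"
  net$nodes <- net$nodes[used, , drop = FALSE]
  net
}

#' Mark newly perfused sprouts as normal vessels
#'
#' Sprouts that carry flow after a hemodynamics update become permanent
#' vessels (the sprout flag is cleared).
#'
#' @param net a `vessel_network`
#' @param flow a `flow_state`
#' @return the updated network
#' @export
circulate_sprouts <- function(net, flow) {
  qtol <- 1e-12 * max(abs(flow$q), 1e-30)
  newly <- net$segments$sprout & abs(flow$q) > qtol
  net$segments$sprout[newly] <- FALSE
  net
}

#' Circumferential growth of tumor vessels
#'
#' Vessel segments resident inside the tumor sphere for at least
#' `t_switch` hours dilate: the endothelial cells lining the wall double
#' every `t_prol` hours, so the radius grows exponentially,
#' `dr/dt = ln(2) r / t_prol`, capped at `r_max`. Residence clocks `tin`
#' and the tumor flag are updated here.
#'
#' @param net a `vessel_network`
#' @param tumor a `tumor_state`
#' @param cfg a `sim_config`
#' @return the updated network
#' @export
step_circumferential_growth <- function(net, tumor, cfg) {
  sg <- net$segments
  mids <- .seg_mid(net)
  inside <- .dist_center(mids, tumor$center) <= tumor$R_tum
  sg$tumor <- sg$tumor | inside
  sg$tin[inside] <- sg$tin[inside] + cfg$dt
  grow <- inside & sg$tin >= cfg$t_switch
  sg$r[grow] <- pmin(sg$r[grow] * exp(log(2) * cfg$dt / cfg$t_prol),
                     pmax(cfg$r_max, sg$r[grow]))
  net$segments <- sg
  net
}

#' Degradation of tumor vessel wall stability
#'
#' Tumor segments lose wall stability at the constant rate `dw` um/h,
#' clamped at zero; non-tumor segments are untouched.
#'
#' @param net a `vessel_network`
#' @param cfg a `sim_config`
#' @return the updated network
#' @export
step_wall_degrade <- function(net, cfg) {
  tum <- net$segments$tumor
  net$segments$w[tum] <- pmax(0, net$segments$w[tum] - cfg$dw * cfg$dt)
  net
}

#' Vessel collapse and regression
#'
#' Segments with fully degenerate walls (`w = 0`) and wall shear stress
#' below `f_coll` are removed with probability `p_coll`; the dead-end
#' chains this strands are then pruned back to the nearest junction that
#' still connects (through the graph) to both an arterial and a venous
#' root. Active sprout tips are spared from dead-end pruning.
#'
#' @param net a `vessel_network`
#' @param flow a `flow_state` with up-to-date wall shear stresses
#' @param cfg a `sim_config`
#' @return the updated network
#' @export
step_collapse_regress <- function(net, flow, cfg) {
  sg <- net$segments
  victim <- sg$w <= 0 & flow$f < cfg$f_coll & sg$tumor
  if (any(victim)) {
    fire <- victim & stats::runif(nrow(sg)) < cfg$p_coll
    sg <- sg[!fire, , drop = FALSE]
    net$segments <- sg
  }
  prune_dead_ends(net, cfg)
}

#' Prune dead-end branches
#'
#' Iteratively removes degree-1 segments whose endpoint is neither a root
#' nor an active sprout tip, then drops connected components that lack
#' either an arterial or a venous root.
#'
#' @param net a `vessel_network`
#' @param cfg a `sim_config` (`t_migr` to recognize active sprouts)
#' @return the pruned network
#' @export
prune_dead_ends <- function(net, cfg) {
  repeat {
    deg <- node_degrees(net)
    nd <- net$nodes; sg <- net$segments
    ia <- match(sg$a, nd$id); ib <- match(sg$b, nd$id)
    active_sprout <- sg$sprout & sg$tau <= cfg$t_migr
    leaf_a <- deg[ia] == 1L & nd$role[ia] == "interior"
    leaf_b <- deg[ib] == 1L & nd$role[ib] == "interior"
    kill <- (leaf_a | leaf_b) & !active_sprout
    if (!any(kill)) break
    net$segments <- sg[!kill, , drop = FALSE]
    net <- .drop_isolated_nodes(net)
    if (!nrow(net$segments)) break
  }
  # drop components without both root types
  if (nrow(net$segments)) {
    nd <- net$nodes; sg <- net$segments
    ia <- match(sg$a, nd$id); ib <- match(sg$b, nd$id)
    g <- igraph::graph_from_edgelist(cbind(ia, ib), directed = FALSE)
    if (igraph::vcount(g) < nrow(nd)) g <- igraph::add_vertices(g, nrow(nd) - igraph::vcount(g))
    comp <- igraph::components(g)$membership
    ok_art <- unique(comp[nd$role == "arterial_root"])
    ok_ven <- unique(comp[nd$role == "venous_root"])
    good <- intersect(ok_art, ok_ven)
    keep <- comp[ia] %in% good
    if (!all(keep)) {
      net$segments <- sg[keep, , drop = FALSE]
      net <- .drop_isolated_nodes(net)
    }
  }
  net
}

#' Solid-stress compression of tumor vessels
#'
#' Sets the compressed radius `r_tilde = psi(|x - center|) * r` with
#' `psi = xi_cpr` deep inside the tumor (`|x| < R - w_cpr`), 1 outside
#' (`|x| > R + w_cpr`) and a linear ramp across the rim. The compressed
#' radius feeds every subsequent flow and oxygen computation.
#'
#' @param net a `vessel_network`
#' @param tumor a `tumor_state`
#' @param xi_cpr compression factor in [0.5, 1]
#' @param w_cpr ramp half-width, um
#' @return the updated network
#' @export
apply_compression <- function(net, tumor, xi_cpr, w_cpr = 200) {
  if (is.na(xi_cpr)) stop("apply_compression: xi_cpr not set")
  if (xi_cpr < 0.5 || xi_cpr > 1) stop("xi_cpr must lie in [0.5, 1]")
  d <- .dist_center(.seg_mid(net), tumor$center)
  psi <- compression_factor(d, tumor$R_tum, xi_cpr, w_cpr)
  net$segments$r_tilde <- psi * net$segments$r
  net
}

#' @rdname apply_compression
#' @param dist distance from tumor center, um
#' @param R tumor radius, um
#' @export
compression_factor <- function(dist, R, xi_cpr, w_cpr = 200) {
  ifelse(dist < R - w_cpr, xi_cpr,
         ifelse(dist > R + w_cpr, 1,
                xi_cpr - (dist - R + w_cpr) / (2 * w_cpr) * (xi_cpr - 1)))
}

#' Simulate tumor growth and vascular remodeling
#'
#' Runs the full remodeling loop from `t = 0` to `cfg$t_end` in steps of
#' `cfg$dt` hours: sprout initiation, sprout migration, circumferential
#' growth, wall degradation, collapse/regression with dead-end pruning,
#' compression (CMPR), and a hemodynamics update per step, while the
#' tumor radius expands linearly.
#'
#' @param net initial (t = 0) `vessel_network` at generation resolution;
#'   it is resampled to the fine lattice here
#' @param cfg a `sim_config`
#' @param seed optional RNG seed
#' @param xi_cpr compression factor (CMPR); `NA` draws one from U(0.5, 1)
#' @param progress print a line every 50 steps
#' @return list with `net` (final network), `tumor` (final state),
#'   `xi_cpr`, and `log` (per-step event counts)
#' @export
run_tumor_growth <- function(net, cfg, seed = NULL, xi_cpr = cfg$xi_cpr,
                             progress = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (cfg$scenario == "CMPR" && is.na(xi_cpr)) xi_cpr <- stats::runif(1, 0.5, 1)
  center <- rep(net$L / 2, 3)
  tumor <- tumor_state(cfg$R_tum0, 0, center)
  net <- subdivide_segments(net, cfg$h_fine)
  net$segments$w <- initial_wall_stability(net$segments$r)
  res <- solve_hemodynamics(net, cfg)
  net <- res$net; flow <- res$flow
  steps <- as.integer(round(cfg$t_end / cfg$dt))
  log <- data.frame(t = numeric(0), segments = integer(0),
                    sprouts = integer(0), R_tum = numeric(0))
  for (s in seq_len(steps)) {
    net <- step_sprout_init(net, tumor, cfg)
    net <- step_sprout_migrate(net, cfg)
    net <- step_circumferential_growth(net, tumor, cfg)
    net <- step_wall_degrade(net, cfg)
    if (cfg$scenario == "CMPR") {
      net <- apply_compression(net, tumor, xi_cpr, cfg$w_cpr)
    }
    res <- solve_hemodynamics(net, cfg)
    net <- res$net; flow <- res$flow
    net <- circulate_sprouts(net, flow)
    net <- step_collapse_regress(net, flow, cfg)
    if (nrow(net$segments) == 0)
      stop("run_tumor_growth: network fully regressed")
    tumor$t <- tumor$t + cfg$dt
    tumor$R_tum <- cfg$R_tum0 + cfg$v_tum * tumor$t
    log <- rbind(log, data.frame(t = tumor$t, segments = nrow(net$segments),
                                 sprouts = sum(net$segments$sprout),
                                 R_tum = tumor$R_tum))
    if (progress && s %% 50 == 0)
      message(sprintf("t = %g h: %d segments, R_tum = %g um",
                      tumor$t, nrow(net$segments), tumor$R_tum))
  }
  if (cfg$scenario == "CMPR") {
    net <- apply_compression(net, tumor, xi_cpr, cfg$w_cpr)
  }
  res <- solve_hemodynamics(net, cfg)  # flow consistent with the final state
  net <- res$net
  list(net = net, tumor = tumor, xi_cpr = xi_cpr, log = log)
}
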