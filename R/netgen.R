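#' Root-node geometry for initial network generation
#'
#' Describes where feeding arterioles and draining venules attach to the
#' boundary of the cubic domain. Nine schemes are available:
#' \itemize{
#'   \item RC1/RC2/RC3: every boundary site of one, two opposing, or four
#'     lateral faces is occupied, alternating arterial/venous.
#'   \item RC4/RC5/RC6: isolated nodes at 33\% and 66\% of the face
#'     diagonal; one face with both nodes (RC4), two opposing faces with
#'     one node each (RC5), four faces with one node each (RC6).
#'   \item RC7/RC8: fixed parent vessels protrude along x to 60\% of the
#'     domain; every site they occupy seeds further growth, with the
#'     boundary condition applied at the true inlet/outlet on the domain
#'     face. RC7 uses one arterial and one venous parent at opposite face
#'     centers; RC8 uses two antiparallel pairs at the diagonal thirds.
#'   \item RC9: every boundary site (all faces) is occupied independently
#'     with probability `p_root`, type chosen at random; configurations
#'     without at least one root of each type are redrawn.
#' }
#'
#' @param scheme `"RC1"` .. `"RC9"`
#' @param p_root occupation probability for RC9; `NULL` draws it from
#'   U(0, 1) at generation time
#' @return object of class `root_geometry`
#' @export
root_geometry <- function(scheme, p_root = NULL) {
  stopifnot(scheme %in% paste0("RC", 1:9))
  if (!is.null(p_root) && (p_root <= 0 || p_root > 1))
    stop("p_root must lie in (0, 1]")
  structure(list(scheme = scheme, p_root = p_root), class = "root_geometry")
}

# FCC lattice bookkeeping ---------------------------------------------------
# Sites are integer triples (i, j, k) with i + j + k even, at coordinates
# offset + (i, j, k) * s where s = h_gen / sqrt(2); nearest neighbours are
# the 12 offsets (+-1, +-1, 0), (+-1, 0, +-1), (0, +-1, +-1) at distance
# h_gen.
.fcc_offsets <- local({
  o <- rbind(
    c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
    c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
    c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))
  storage.mode(o) <- "integer"
  o
})

.lattice_init <- function(L, h_gen) {
  s <- h_gen / sqrt(2)
  m <- as.integer(floor(L / s + 1e-9))
  offset <- (L - m * s) / 2
  list(s = s, m = m, offset = offset, n1 = m + 1L)
}

.lat_key <- function(lat, ijk) {
  1L + ijk[, 1] + lat$n1 * (ijk[, 2] + lat$n1 * ijk[, 3])
}

.lat_valid <- function(lat, ijk) {
  (ijk[, 1] >= 0L) & (ijk[, 1] <= lat$m) &
  (ijk[, 2] >= 0L) & (ijk[, 2] <= lat$m) &
  (ijk[, 3] >= 0L) & (ijk[, 3] <= lat$m) &
  ((ijk[, 1] + ijk[, 2] + ijk[, 3]) %% 2L == 0L)
}

.face_sites <- function(lat, axis, side) {
  fix <- if (side == 0) 0L else lat$m
  uv <- expand.grid(u = 0:lat$m, v = 0:lat$m)
  ijk <- switch(axis,
                x = cbind(fix, uv$u, uv$v),
                y = cbind(uv$u, fix, uv$v),
                z = cbind(uv$u, uv$v, fix))
  storage.mode(ijk) <- "integer"
  ijk[.lat_valid(lat, ijk), , drop = FALSE]
}

.diag_site <- function(lat, axis, side, frac) {
  fix <- if (side == 0) 0L else lat$m
  u <- as.integer(round(frac * lat$m))
  offs <- expand.grid(du = -1:1, dv = -1:1)
  offs <- offs[order(abs(offs$du) + abs(offs$dv)), ]
  for (t in seq_len(nrow(offs))) {
    uu <- u + offs$du[t]; vv <- u + offs$dv[t]
    ijk <- switch(axis,
                  x = matrix(c(fix, uu, vv), 1),
                  y = matrix(c(uu, fix, vv), 1),
                  z = matrix(c(uu, vv, fix), 1))
    storage.mode(ijk) <- "integer"
    if (.lat_valid(lat, ijk)) return(ijk)
  }
  stop("no valid lattice site near diagonal fraction")
}

.shuffle <- function(x) if (length(x) <= 1L) x else sample(x)

#' Place root nodes for a given geometry
#'
#' @param geometry a [root_geometry()]
#' @param L domain size, um
#' @param h_gen generation lattice constant, um
#' @return data.frame with lattice indices `i`, `j`, `k`, `role`, logical
#'   `seed_only` (TRUE for interior sites of RC7/RC8 parent vessels, which
#'   seed growth but carry no boundary condition) and `chain` (parent
#'   vessel id, 0 otherwise); the lattice description is attached as
#'   attribute `"lattice"`.
#' @export
place_roots <- function(geometry, L, h_gen) {
  lat <- .lattice_init(L, h_gen)
  sc <- geometry$scheme
  alt_roles <- function(n) rep(c("arterial_root", "venous_root"),
                               length.out = n)
  mk <- function(ijk, role, seed_only = FALSE, chain = 0L) {
    data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3], role = role,
               seed_only = seed_only, chain = chain)
  }
  out <- NULL
  if (sc %in% c("RC1", "RC2", "RC3")) {
    faces <- switch(sc,
                    RC1 = list(c("x", 0)),
                    RC2 = list(c("x", 0), c("x", 1)),
                    RC3 = list(c("x", 0), c("x", 1), c("y", 0), c("y", 1)))
    out <- do.call(rbind, lapply(faces, function(f) {
      st <- .face_sites(lat, f[1], as.integer(f[2]))
      st <- st[order(st[, 2], st[, 3], st[, 1]), , drop = FALSE]
      mk(st, alt_roles(nrow(st)))
    }))
  } else if (sc == "RC4") {
    out <- rbind(mk(.diag_site(lat, "x", 0, 1 / 3), "arterial_root"),
                 mk(.diag_site(lat, "x", 0, 2 / 3), "venous_root"))
  } else if (sc == "RC5") {
    out <- rbind(mk(.diag_site(lat, "x", 0, 1 / 3), "arterial_root"),
                 mk(.diag_site(lat, "x", 1, 2 / 3), "venous_root"))
  } else if (sc == "RC6") {
    out <- rbind(mk(.diag_site(lat, "x", 0, 1 / 3), "arterial_root"),
                 mk(.diag_site(lat, "x", 1, 2 / 3), "venous_root"),
                 mk(.diag_site(lat, "y", 0, 1 / 3), "arterial_root"),
                 mk(.diag_site(lat, "y", 1, 2 / 3), "venous_root"))
  } else if (sc %in% c("RC7", "RC8")) {
    mk_parent <- function(j0, k0, side, role, chain) {
      i0 <- if (side == 0) 0L else lat$m
      di <- if (side == 0) 1L else -1L
      if ((i0 + j0 + k0) %% 2L != 0L) j0 <- j0 + 1L  # parity of the entry site
      nstep <- as.integer(round(0.6 * lat$m))
      ijk <- t(vapply(0:nstep, function(t)
        c(i0 + di * t, if (t %% 2 == 0) j0 else j0 + 1L, k0), integer(3)))
      ijk <- ijk[.lat_valid(lat, ijk), , drop = FALSE]
      mk(ijk, role, seed_only = c(FALSE, rep(TRUE, nrow(ijk) - 1L)),
         chain = chain)
    }
    even <- function(u) u + u %% 2L
    ctr <- even(as.integer(round(lat$m / 2)))
    if (sc == "RC7") {
      out <- rbind(mk_parent(ctr, ctr, 0, "arterial_root", 1L),
                   mk_parent(ctr, ctr, 1, "venous_root", 2L))
    } else {
      t1 <- even(as.integer(round(lat$m / 3)))
      t2 <- even(as.integer(round(2 * lat$m / 3)))
      out <- rbind(mk_parent(t1, t1, 0, "arterial_root", 1L),
                   mk_parent(t2, t2, 0, "venous_root", 2L),
                   mk_parent(t1, t1, 1, "venous_root", 3L),
                   mk_parent(t2, t2, 1, "arterial_root", 4L))
    }
  } else { # RC9
    faces <- list(c("x", 0), c("x", 1), c("y", 0), c("y", 1),
                  c("z", 0), c("z", 1))
    all_sites <- unique(do.call(rbind, lapply(faces, function(f)
      .face_sites(lat, f[1], as.integer(f[2])))))
    for (try in 1:100) {
      pp <- if (is.null(geometry$p_root)) stats::runif(1) else geometry$p_root
      sel <- stats::runif(nrow(all_sites)) < pp
      if (!any(sel)) next
      roles <- sample(c("arterial_root", "venous_root"), sum(sel),
                      replace = TRUE)
      if (any(roles == "arterial_root") && any(roles == "venous_root")) {
        out <- mk(all_sites[sel, , drop = FALSE], roles)
        break
      }
    }
    if (is.null(out)) stop("RC9: could not draw a configuration with both root types")
  }
  out <- out[!duplicated(out[, c("i", "j", "k")]), ]
  rownames(out) <- NULL
  attr(out, "lattice") <- lat
  out
}

# mutable generation state --------------------------------------------------
.gen_state <- function(lat, roots) {
  st <- new.env(parent = emptyenv())
  st$lat <- lat
  nmax <- 1024L
  st$ni <- integer(nmax); st$nj <- integer(nmax); st$nk <- integer(nmax)
  st$tree <- integer(nmax); st$role <- character(nmax)
  st$alive_n <- logical(nmax)
  st$nn <- 0L
  st$key2node <- integer(lat$n1^3)
  emax <- 1024L
  st$ea <- integer(emax); st$eb <- integer(emax); st$alive_e <- logical(emax)
  st$ne <- 0L
  st$deg <- integer(nmax)
  st$inc <- vector("list", nmax)

  st$add_node <- function(i, j, k, tree, role = "interior") {
    if (st$nn == length(st$ni)) {
      gr <- function(v) c(v, vector(mode = mode(v), length = length(v)))
      st$ni <- gr(st$ni); st$nj <- gr(st$nj); st$nk <- gr(st$nk)
      st$tree <- gr(st$tree); st$role <- gr(st$role)
      st$alive_n <- gr(st$alive_n); st$deg <- gr(st$deg)
      st$inc <- c(st$inc, vector("list", length(st$inc)))
    }
    st$nn <- st$nn + 1L
    id <- st$nn
    st$ni[id] <- i; st$nj[id] <- j; st$nk[id] <- k
    st$tree[id] <- tree; st$role[id] <- role
    st$alive_n[id] <- TRUE
    st$key2node[.lat_key(st$lat, cbind(i, j, k))] <- id
    id
  }

  st$add_edge <- function(a, b) {
    if (st$ne == length(st$ea)) {
      st$ea <- c(st$ea, integer(length(st$ea)))
      st$eb <- c(st$eb, integer(length(st$eb)))
      st$alive_e <- c(st$alive_e, logical(length(st$alive_e)))
    }
    st$ne <- st$ne + 1L
    e <- st$ne
    st$ea[e] <- a; st$eb[e] <- b; st$alive_e[e] <- TRUE
    st$deg[a] <- st$deg[a] + 1L; st$deg[b] <- st$deg[b] + 1L
    st$inc[[a]] <- c(st$inc[[a]], e); st$inc[[b]] <- c(st$inc[[b]], e)
    e
  }

  st$remove_edge <- function(e) {
    a <- st$ea[e]; b <- st$eb[e]
    st$alive_e[e] <- FALSE
    st$deg[a] <- st$deg[a] - 1L; st$deg[b] <- st$deg[b] - 1L
    st$inc[[a]] <- setdiff(st$inc[[a]], e)
    st$inc[[b]] <- setdiff(st$inc[[b]], e)
    for (v in c(a, b)) {
      if (st$deg[v] == 0L && st$role[v] == "interior") {
        st$alive_n[v] <- FALSE
        st$key2node[.lat_key(st$lat, cbind(st$ni[v], st$nj[v], st$nk[v]))] <- 0L
      }
    }
  }

  for (r in seq_len(nrow(roots))) {
    st$add_node(roots$i[r], roots$j[r], roots$k[r], tree = r,
                role = if (isTRUE(roots$seed_only[r])) "interior"
                       else roots$role[r])
  }
  st$tree_role <- roots$role  # tree id == root row id
  # parent chains (RC7/RC8): connect consecutive sites, unify tree ids
  if (any(roots$chain > 0L)) {
    for (ch in unique(roots$chain[roots$chain > 0L])) {
      run <- which(roots$chain == ch)
      for (t in seq_along(run)[-1]) st$add_edge(run[t - 1L], run[t])
      st$tree[run] <- run[1L]
    }
  }
  st
}

.free_neighbors <- function(st, v) {
  nb <- cbind(st$ni[v] + .fcc_offsets[, 1],
              st$nj[v] + .fcc_offsets[, 2],
              st$nk[v] + .fcc_offsets[, 3])
  nb <- nb[.lat_valid(st$lat, nb), , drop = FALSE]
  if (!nrow(nb)) return(nb)
  nb[st$key2node[.lat_key(st$lat, nb)] == 0L, , drop = FALSE]
}

#' Grow interdigitating vascular trees on the generation lattice
#'
#' Starting from the root nodes, structural elements (linear: one bond;
#' tripod: a new branching site with up to two onward bonds) are attached
#' to randomly selected open terminal branches until no element can be
#' added without occupying an already-used lattice site; overlap is
#' forbidden, which also keeps every tree acyclic and the trees mutually
#' disjoint.
#'
#' @param roots data.frame from [place_roots()] (with its lattice attribute)
#' @param cfg a `sim_config` (`p_tripod`)
#' @return generation-state environment (internal representation consumed
#'   by [connect_capillaries()] and [shear_guided_refinement()])
#' @export
.grow_phase <- function(st, cfg, seeds) {
  # attach structural elements (linear bond / tripod) to randomly chosen
  # open ends until no element can be added without overlap
  stack <- integer(max(1024L, 2L * length(seeds)))
  slen <- length(seeds)
  stack[seq_len(slen)] <- seeds
  push <- function(v) {
    if (slen == length(stack)) stack <<- c(stack, integer(length(stack)))
    slen <<- slen + 1L
    stack[slen] <<- v
  }
  while (slen > 0L) {
    idx <- if (slen == 1L) 1L else sample.int(slen, 1L)
    pick <- stack[idx]
    stack[idx] <- stack[slen]
    slen <- slen - 1L
    if (!st$alive_n[pick] || st$deg[pick] >= 3L) next
    fn <- .free_neighbors(st, pick)
    if (!nrow(fn)) next
    row <- fn[sample.int(nrow(fn), 1L), ]
    v <- st$add_node(row[1], row[2], row[3], tree = st$tree[pick])
    st$add_edge(pick, v)
    if (stats::runif(1) < cfg$p_tripod) {
      fn2 <- .free_neighbors(st, v)
      nadd <- min(2L, nrow(fn2))
      if (nadd > 0L) {
        sel <- fn2[sample.int(nrow(fn2), nadd), , drop = FALSE]
        for (t in seq_len(nadd)) {
          w <- st$add_node(sel[t, 1], sel[t, 2], sel[t, 3],
                           tree = st$tree[pick])
          st$add_edge(v, w)
          push(w)
        }
      } else {
        push(v)
      }
    } else {
      push(v)
    }
    # roots and parent-vessel seeds may sprout further branches
    if (st$role[pick] != "interior" && st$deg[pick] < 3L) push(pick)
  }
  invisible(st)
}

grow_trees <- function(roots, cfg) {
  st <- .gen_state(attr(roots, "lattice"), roots)
  .grow_phase(st, cfg, seeds = seq_len(st$nn))
  st
}

#' Identify capillary links between nearby opposite-type open ends
#'
#' Open ends are degree-1 interior nodes. An arterial and a venous open
#' end one generation-lattice bond apart are linked by a direct capillary
#' segment; ends two bonds apart are linked through one free intermediate
#' lattice site. Each open end accepts at most one capillary link.
#'
#' @param st generation state from [grow_trees()]
#' @return list with `direct` (two-column matrix of node pairs: arterial
#'   end, venous end), `via` (data.frame `a`, `v`, `mi`, `mj`, `mk` with
#'   the intermediate site), and `n_links` (total capillary count)
#' @export
connect_capillaries <- function(st) {
  empty <- list(direct = matrix(integer(0), 0, 2),
                via = data.frame(a = integer(0), v = integer(0),
                                 mi = integer(0), mj = integer(0),
                                 mk = integer(0)),
                n_links = 0L)
  alive <- which(st$alive_n[seq_len(st$nn)])
  leaves <- alive[st$deg[alive] == 1L & st$role[alive] == "interior"]
  if (!length(leaves)) return(empty)
  is_art <- st$tree_role[st$tree[leaves]] == "arterial_root"
  art <- leaves[is_art]; ven <- leaves[!is_art]
  # capillaries sprout from arterial open ends and drain into the terminal
  # region of venules: a venous open end or any venous node within two
  # bonds of one, degree permitting (terminal venules collect several
  # capillaries). Total node degree never exceeds 3.
  is_ven_leaf <- logical(st$nn); is_ven_leaf[ven] <- TRUE
  ven_target <- logical(st$nn); ven_target[ven] <- TRUE
  frontier_v <- ven
  for (d in 1:2) {
    nxt <- integer(0)
    for (v in frontier_v) {
      for (e in st$inc[[v]]) {
        u <- if (st$ea[e] == v) st$eb[e] else st$ea[e]
        if (!ven_target[u] && st$role[u] == "interior" &&
            st$deg[u] <= 2L) {
          ven_target[u] <- TRUE
          nxt <- c(nxt, u)
        }
      }
    }
    frontier_v <- nxt
  }
  cap_slots <- integer(st$nn)
  cap_slots[which(ven_target)] <- pmax(0L, 3L - st$deg[which(ven_target)])
  cap_slots[art] <- 2L
  is_ven_leaf <- ven_target
  pairs_a <- integer(0); pairs_v <- integer(0)
  neigh_ids <- function(i, j, k) {
    nb <- cbind(i + .fcc_offsets[, 1], j + .fcc_offsets[, 2],
                k + .fcc_offsets[, 3])
    nb[.lat_valid(st$lat, nb), , drop = FALSE]
  }
  art_sh <- .shuffle(art)
  for (pass in 1:2) {
    for (aL in art_sh) {
      if (cap_slots[aL] <= 0L) next
      nb <- neigh_ids(st$ni[aL], st$nj[aL], st$nk[aL])
      ids <- st$key2node[.lat_key(st$lat, nb)]
      cand <- ids[ids > 0L]
      cand <- cand[is_ven_leaf[cand] & cap_slots[cand] > 0L]
      cand <- setdiff(cand, pairs_v[pairs_a == aL])  # no parallel duplicates
      if (length(cand)) {
        vL <- if (length(cand) == 1L) cand else sample(cand, 1L)
        cap_slots[vL] <- cap_slots[vL] - 1L
        cap_slots[aL] <- cap_slots[aL] - 1L
        pairs_a <- c(pairs_a, aL); pairs_v <- c(pairs_v, vL)
      }
    }
  }
  # second pass: straight capillary chords to venous targets within two
  # bond lengths (capillaries are not confined to lattice bonds; a 2.5 um
  # capillary threads freely between the much coarser generation vessels)
  shells <- local({
    g <- as.matrix(expand.grid(di = -2:2, dj = -2:2, dk = -2:2))
    d2 <- rowSums(g^2)
    keep <- d2 > 0 & d2 <= 8 & (rowSums(g) %% 2 == 0)
    g <- g[keep, , drop = FALSE]
    g[order(d2[keep]), , drop = FALSE]
  })
  for (aL in art_sh) {
    if (cap_slots[aL] <= 0L) next
    nb <- cbind(st$ni[aL] + shells[, 1], st$nj[aL] + shells[, 2],
                st$nk[aL] + shells[, 3])
    ok <- .lat_valid(st$lat, nb)
    ids <- st$key2node[.lat_key(st$lat, nb[ok, , drop = FALSE])]
    cand <- ids[ids > 0L]
    cand <- cand[is_ven_leaf[cand] & cap_slots[cand] > 0L]
    cand <- setdiff(cand, pairs_v[pairs_a == aL])
    if (length(cand)) {
      vL <- cand[1]   # nearest shell first (shells pre-sorted by distance)
      cap_slots[vL] <- cap_slots[vL] - 1L
      cap_slots[aL] <- cap_slots[aL] - 1L
      pairs_a <- c(pairs_a, aL); pairs_v <- c(pairs_v, vL)
    }
  }
  list(direct = cbind(pairs_a, pairs_v), via = list(),
       n_links = length(pairs_a))
}

# materialize the generation state (+ capillary pairs) as a vessel_network;
# returns the network and the state-edge -> segment-row map
.state_to_network <- function(st, caps, L, h_gen, cfg) {
  alive <- which(st$alive_n[seq_len(st$nn)])
  remap <- integer(st$nn); remap[alive] <- seq_along(alive)
  s <- st$lat$s; off <- st$lat$offset
  nodes <- data.frame(id = seq_along(alive),
                      x = off + st$ni[alive] * s,
                      y = off + st$nj[alive] * s,
                      z = off + st$nk[alive] * s,
                      role = st$role[alive])
  ee <- which(st$alive_e[seq_len(st$ne)])
  a <- remap[st$ea[ee]]; b <- remap[st$eb[ee]]
  type <- ifelse(st$tree_role[st$tree[st$ea[ee]]] == "arterial_root",
                 "artery", "vein")
  if (nrow(caps$direct)) {
    a <- c(a, remap[caps$direct[, 1]]); b <- c(b, remap[caps$direct[, 2]])
    type <- c(type, rep("capillary", nrow(caps$direct)))
  }
  for (lnk in caps$via) {
    nm <- nrow(lnk$mids)
    mid_id <- nrow(nodes) + seq_len(nm)
    nodes <- rbind(nodes,
                   data.frame(id = mid_id,
                              x = off + lnk$mids[, 1] * s,
                              y = off + lnk$mids[, 2] * s,
                              z = off + lnk$mids[, 3] * s,
                              role = "interior"))
    chain <- c(remap[lnk$a], mid_id, remap[lnk$v])
    a <- c(a, chain[-length(chain)])
    b <- c(b, chain[-1])
    type <- c(type, rep("capillary", length(chain) - 1))
  }
  segs <- data.frame(id = seq_along(a), a = a, b = b, r = 2.5, type = type,
                     H = cfg$H_bc)
  net <- vessel_network(nodes, segs, h_gen = h_gen, h_fine = cfg$h_fine,
                        L = L)
  net <- assign_radii_murray(net, alpha = cfg$alpha_murray,
                             r_leaf_artery = 2.5, r_leaf_vein = 3.8,
                             r_capillary = 2.5)
  edge2seg <- integer(st$ne)
  edge2seg[ee] <- seq_along(ee)
  list(net = net, edge2seg = edge2seg)
}

#' Assign radii by Murray's law
#'
#' Sets terminal segment radii (2.5 um arterial, 3.8 um venous, 2.5 um
#' capillaries by default) and propagates radii from the leaves towards
#' each root via `r_parent^alpha = r_1^alpha + r_2^alpha`. Pass-through
#' (single-child) nodes copy the child radius. Capillary segments are not
#' part of the trees.
#'
#' @param net a `vessel_network` whose non-capillary segments form trees
#'   rooted at the root nodes (an error is raised if a cycle is found)
#' @param alpha Murray exponent (3 by default)
#' @param r_leaf_artery,r_leaf_vein,r_capillary terminal radii, um; `NA`
#'   keeps the radii already stored on the leaf/capillary segments
#' @return the network with updated radii
#' @export
assign_radii_murray <- function(net, alpha = 3, r_leaf_artery = NA,
                                r_leaf_vein = NA, r_capillary = NA) {
  sg <- net$segments
  if (!is.na(r_capillary)) sg$r[sg$type == "capillary"] <- r_capillary
  tree_seg <- which(sg$type != "capillary")
  n <- nrow(net$nodes)
  ia <- match(sg$a, net$nodes$id); ib <- match(sg$b, net$nodes$id)
  adj <- vector("list", n)
  for (e in tree_seg) {
    adj[[ia[e]]] <- c(adj[[ia[e]]], e)
    adj[[ib[e]]] <- c(adj[[ib[e]]], e)
  }
  roots <- which(net$nodes$role != "interior")
  depth <- rep(NA_integer_, n)
  parent_edge <- integer(n)
  queue <- integer(n); queue[seq_along(roots)] <- roots
  qlen <- length(roots); head <- 1L
  depth[roots] <- 0L
  while (head <= qlen) {
    u <- queue[head]; head <- head + 1L
    for (e in adj[[u]]) {
      v <- if (ia[e] == u) ib[e] else ia[e]
      if (is.na(depth[v])) {
        depth[v] <- depth[u] + 1L
        parent_edge[v] <- e
        qlen <- qlen + 1L
        queue[qlen] <- v
      } else if (parent_edge[u] != e) {
        stop("assign_radii_murray: cycle detected among tree segments")
      }
    }
  }
  order_nodes <- queue[seq_len(qlen)]
  for (u in rev(order_nodes)) {
    e <- parent_edge[u]
    if (e == 0L) next
    kids <- setdiff(adj[[u]], e)
    if (!length(kids)) {
      rl <- if (sg$type[e] == "artery") r_leaf_artery else r_leaf_vein
      if (!is.na(rl)) sg$r[e] <- rl
    } else {
      sg$r[e] <- sum(sg$r[kids]^alpha)^(1 / alpha)
    }
  }
  sg$r_tilde <- sg$r
  net$segments <- sg
  net
}

#' Capillary-count plateau criterion
#'
#' @param counts capillary counts per refinement sweep
#' @param window number of trailing sweeps examined
#' @param tol relative range tolerance
#' @return TRUE when the range of the last `window` counts is within
#'   `tol` of their mean
#' @export
plateau_reached <- function(counts, window = 5, tol = 0.02) {
  if (length(counts) < window) return(FALSE)
  tail_c <- utils::tail(counts, window)
  (max(tail_c) - min(tail_c)) <= tol * mean(tail_c)
}

#' Shear-stress-guided refinement of the initial network
#'
#' Iterative pruning/extension loop. Per sweep: capillaries are connected
#' and blood flow with wall shear stress is computed on the temporary
#' network (uniform inlet hematocrit); capillary-connected terminals whose
#' shear falls far below the median terminal shear are stochastically
#' retracted (probability logistic in shear); unconnected dead-end chains
#' are pruned; and the trees regrow from every node with spare degree into
#' the freed space. The sweep repeats until the capillary count reaches a
#' plateau. Pruning and regrowth let arterial and venous trees invade each
#' other's territory, producing the fine interdigitation and homogeneous
#' capillary distribution of the final network.
#'
#' @param st generation state from [grow_trees()]
#' @param L,h_gen domain/lattice geometry, um
#' @param cfg a `sim_config` (`f0_shear`, `k_shear`, `act_rate`,
#'   `cull_rate`, `f_rem_frac`, `plateau_window`, `plateau_tol`,
#'   `max_sweeps`)
#' @return list with the final `vessel_network` and the per-sweep capillary
#'   `counts`
#' @export
shear_guided_refinement <- function(st, L, h_gen, cfg) {
  counts <- integer(0)
  capped_of <- function(caps) {
    capped <- logical(st$nn)
    capped[caps$direct] <- TRUE
    capped
  }
  prune_dead <- function(caps) {
    repeat {
      capped <- capped_of(caps)
      alive <- which(st$alive_n[seq_len(st$nn)])
      dead <- alive[st$deg[alive] == 1L & st$role[alive] == "interior" &
                    !capped[alive]]
      if (!length(dead)) return(caps)
      for (v in dead) st$remove_edge(st$inc[[v]][1])
      caps <- connect_capillaries(st)
    }
  }
  caps <- connect_capillaries(st)
  for (sweep in seq_len(cfg$max_sweeps)) {
    mat <- .state_to_network(st, caps, L, h_gen, cfg)
    fs <- tryCatch(solve_pressures(mat$net, cfg),
                   error = function(e)
                     stop("shear_guided_refinement: flow solve failed: ",
                          conditionMessage(e)))
    alive <- which(st$alive_n[seq_len(st$nn)])
    leaves <- alive[st$deg[alive] == 1L & st$role[alive] == "interior"]
    if (!length(leaves)) break
    capped <- capped_of(caps)
    leaf_f <- fs$f[mat$edge2seg[vapply(leaves, function(v) st$inc[[v]][1], 0L)]]
    f0 <- if (is.na(cfg$f0_shear)) {
      stats::median(leaf_f[leaf_f > 0])
    } else cfg$f0_shear
    if (!is.finite(f0) || f0 <= 0) f0 <- 1e-6
    k_f <- cfg$k_shear * f0
    f_rem <- cfg$f_rem_frac * f0
    # shear-gated retraction of weakly perfused capillary terminals
    for (v in .shuffle(leaves[capped[leaves]])) {
      e <- st$inc[[v]][1]
      f <- fs$f[mat$edge2seg[e]]
      p_cull <- cfg$act_rate * stats::plogis(-(f - f_rem) / k_f)
      if (stats::runif(1) < cfg$cull_rate * p_cull) st$remove_edge(e)
    }
    # dead ends carry no flow and collapse entirely
    caps <- prune_dead(connect_capillaries(st))
    # regrowth into the freed space from every node with spare degree
    alive <- which(st$alive_n[seq_len(st$nn)])
    seeds <- alive[st$deg[alive] < 3L]
    .grow_phase(st, cfg, seeds = .shuffle(seeds))
    caps <- connect_capillaries(st)
    counts <- c(counts, caps$n_links)
    if (plateau_reached(counts, cfg$plateau_window, cfg$plateau_tol)) break
  }
  # closure: every terminal branch ends in a capillary link or a root
  caps <- prune_dead(caps)
  mat <- .state_to_network(st, caps, L, h_gen, cfg)
  list(net = mat$net, counts = counts)
}

#' Generate an initial (t = 0) arterio-venous network
#'
#' Full pipeline: root placement, stochastic tree growth, capillary
#' connection, Murray radius assignment, and shear-guided refinement until
#' the capillary count plateaus.
#'
#' @param cfg a `sim_config` (geometry, L, h_gen, netgen tuning)
#' @param seed optional RNG seed
#' @return a `vessel_network`
#' @export
generate_network <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geo <- root_geometry(cfg$geometry)
  roots <- place_roots(geo, cfg$L, cfg$h_gen)
  st <- grow_trees(roots, cfg)
  res <- shear_guided_refinement(st, cfg$L, cfg$h_gen, cfg)
  net <- res$net
  net$meta$capillary_counts <- res$counts
  net$meta$geometry <- cfg$geometry
  net
}
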