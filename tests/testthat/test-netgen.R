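test_that("root placement matches each scheme's pattern", {
  L <- 1500; hg <- 130
  # RC4: exactly two nodes, one of each type, on one face
  r4 <- place_roots(root_geometry("RC4"), L, hg)
  expect_equal(nrow(r4), 2)
  expect_setequal(r4$role, c("arterial_root", "venous_root"))
  expect_true(all(r4$i == 0))
  # RC5: two nodes on opposing faces
  r5 <- place_roots(root_geometry("RC5"), L, hg)
  expect_equal(nrow(r5), 2)
  expect_equal(sort(unique(r5$i)), c(0, attr(r5, "lattice")$m))
  # RC6: exactly four nodes
  r6 <- place_roots(root_geometry("RC6"), L, hg)
  expect_equal(nrow(r6), 4)
  expect_equal(sum(r6$role == "arterial_root"), 2)
  # RC1-RC3 alternate types over whole faces
  r1 <- place_roots(root_geometry("RC1"), L, hg)
  expect_true(all(r1$i == 0))
  expect_gt(nrow(r1), 10)
  expect_equal(abs(sum(r1$role == "arterial_root") -
                   sum(r1$role == "venous_root")) <= 1, TRUE)
  # RC9 with p_root = 1 occupies every boundary site
  set.seed(1)
  r9 <- place_roots(root_geometry("RC9", p_root = 1), L, hg)
  lat <- attr(r9, "lattice")
  expect_true(all(r9$i == 0 | r9$i == lat$m | r9$j == 0 | r9$j == lat$m |
                  r9$k == 0 | r9$k == lat$m))
  n_boundary <- sum(with(expand.grid(i = 0:lat$m, j = 0:lat$m, k = 0:lat$m),
    (i + j + k) %% 2 == 0 &
    (i == 0 | i == lat$m | j == 0 | j == lat$m | k == 0 | k == lat$m)))
  expect_equal(nrow(r9), n_boundary)
  expect_true(any(r9$role == "arterial_root") &&
              any(r9$role == "venous_root"))
  # RC7: parent vessels protrude to 60% of the domain
  r7 <- place_roots(root_geometry("RC7"), L, hg)
  expect_true(any(r7$seed_only))
  expect_equal(sum(!r7$seed_only), 2)
  expect_gte(max(r7$i[r7$chain == 1]), floor(0.6 * lat$m) - 1)
})

test_that("tree growth occupies each lattice site at most once", {
  cfg <- sim_config(L = 1300, geometry = "RC1")
  set.seed(5)
  roots <- place_roots(root_geometry("RC1"), cfg$L, cfg$h_gen)
  st <- grow_trees(roots, cfg)
  alive <- which(st$alive_n[1:st$nn])
  keys <- 1 + st$ni[alive] + (st$lat$n1) * (st$nj[alive] +
                                            st$lat$n1 * st$nk[alive])
  expect_equal(anyDuplicated(keys), 0)
  # no duplicated bonds
  ee <- which(st$alive_e[1:st$ne])
  bond <- paste(pmin(st$ea[ee], st$eb[ee]), pmax(st$ea[ee], st$eb[ee]))
  expect_equal(anyDuplicated(bond), 0)
  # trees never share a site: every node carries exactly one tree id
  expect_true(all(st$tree[alive] > 0))
})

test_that("Murray's law propagates radii from the terminals upward", {
  # hand-built Y tree: two leaves into one parent
  nodes <- data.frame(id = 1:4,
                      x = c(0, 200, 400, 400), y = c(0, 0, 150, -150),
                      z = 0, role = c("arterial_root", rep("interior", 3)))
  segs <- data.frame(id = 1:3, a = c(1L, 2L, 2L), b = c(2L, 3L, 4L),
                     r = 1, type = "artery", H = 0.45)
  net <- vessel_network(nodes, segs, L = 1000)
  out <- assign_radii_murray(net, alpha = 3, r_leaf_artery = 2.5,
                             r_leaf_vein = 3.8)
  expect_equal(out$segments$r[2], 2.5)
  expect_equal(out$segments$r[3], 2.5)
  expect_equal(out$segments$r[1], 2.5 * 2^(1 / 3), tolerance = 1e-12)
  # linear case alpha = 1: radii add
  out1 <- assign_radii_murray(net, alpha = 1, r_leaf_artery = NA,
                              r_leaf_vein = NA)
  out1$segments$r[2:3] <- c(1, 2)
  out1 <- assign_radii_murray(out1, alpha = 1)
  expect_equal(out1$segments$r[1], 3)
  # chain node passes the radius through unchanged
  nodes2 <- data.frame(id = 1:3, x = c(0, 100, 200), y = 0, z = 0,
                       role = c("arterial_root", "interior", "interior"))
  segs2 <- data.frame(id = 1:2, a = 1:2, b = 2:3, r = 1, type = "artery",
                      H = 0.45)
  ch <- assign_radii_murray(vessel_network(nodes2, segs2, L = 500),
                            alpha = 3, r_leaf_artery = 2.5)
  expect_equal(ch$segments$r[1], ch$segments$r[2])
  # cycles among tree segments are rejected
  segs3 <- rbind(segs, data.frame(id = 4L, a = 3L, b = 4L, r = 1,
                                  type = "artery", H = 0.45))
  expect_error(assign_radii_murray(vessel_network(nodes, segs3, L = 1000)),
               "cycle")
})

test_that("capillary-count plateau detector", {
  expect_true(plateau_reached(c(100, 101, 100, 100, 101), 5, 0.02))
  expect_false(plateau_reached(c(100, 101, 100, 100), 5, 0.02))
  expect_false(plateau_reached(c(150, 140, 120, 105, 100), 5, 0.02))
})

test_that("generated networks satisfy the structural invariants", {
  net <- cached_mini_net()
  expect_identical(validate_network(net), character(0))
  # Murray consistency at every arterial/venous bifurcation
  sg <- net$segments
  nd <- net$nodes
  ia <- match(sg$a, nd$id); ib <- match(sg$b, nd$id)
  deg <- node_degrees(net)
  tree <- sg$type != "capillary"
  # recompute radii; residual should vanish where two children meet a parent
  viol <- 0; checked <- 0
  adj <- split(c(seq_len(nrow(sg)), seq_len(nrow(sg))), c(ia, ib))
  for (v in which(deg == 3 & nd$role == "interior")) {
    es <- adj[[as.character(v)]]
    es <- es[tree[es]]
    if (length(es) != 3) next
    rr <- sort(sg$r[es])
    checked <- checked + 1
    if (abs(rr[3]^3 - rr[1]^3 - rr[2]^3) / rr[3]^3 > 1e-9) viol <- viol + 1
  }
  expect_gt(checked, 10)
  expect_equal(viol, 0)
  # closure: every degree-1 node is a root (capillaried ends have degree 2+)
  leaves <- which(node_degrees(net) == 1)
  expect_true(all(nd$role[leaves] != "interior"))
})

test_that("capillary spatial distribution is homogeneous across octants", {
  net <- cached_mini_net()
  sg <- net$segments[net$segments$type == "capillary", ]
  nd <- net$nodes
  ia <- match(sg$a, nd$id)
  mid <- net$L / 2
  oct <- paste(nd$x[ia] > mid, nd$y[ia] > mid, nd$z[ia] > mid)
  counts <- table(oct)
  expect_equal(length(counts), 8)
  expect_lt((max(counts) - min(counts)) / mean(counts), 0.6)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(L = 1300, geometry = "RC1")
  n1 <- generate_network(cfg, seed = 123)
  n2 <- generate_network(cfg, seed = 123)
  expect_identical(n1$nodes, n2$nodes)
  expect_identical(n1$segments, n2$segments)
  n3 <- generate_network(cfg, seed = 124)
  expect_false(identical(n1$segments, n3$segments))
})
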