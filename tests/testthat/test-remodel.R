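# a straight perfused vessel crossing the domain, at fine resolution,
# with the tumor sphere centered on it
remodel_fixture <- function(L = 1200, h_fine = 60, r = 6) {
  nodes <- data.frame(id = 1:2, x = c(0, L), y = L / 2, z = L / 2,
                      role = c("arterial_root", "venous_root"))
  segs <- data.frame(id = 1L, a = 1L, b = 2L, r = r, type = "artery",
                     H = 0.45)
  net <- vessel_network(nodes, segs, h_gen = L, h_fine = h_fine, L = L)
  subdivide_segments(net, h_fine)
}

test_that("tumor radius grows linearly at v_tum", {
  tum <- tumor_state(250, 0, c(0, 0, 0))
  expect_equal(250 + 2 * 600, 1450)   # R_tum at t_end under Table values
  cfg <- sim_config(L = 1200, t_end = 5, h_fine = 60)
  net <- remodel_fixture()
  # subdivision preserves geometry and attributes
  expect_identical(validate_network(net), character(0))
  expect_equal(sum(net$segments$l), 1200)
  expect_true(all(net$segments$r == 6))
})

test_that("sprout initiation respects region and branch-distance gates", {
  cfg <- sim_config(L = 1200, h_fine = 60, t_sprout = 1, dt = 1,
                    d_br_min = 80)
  net <- remodel_fixture()
  # tumor occupying the center: nodes inside the sphere never sprout
  tum <- tumor_state(R_tum = 200, t = 0, center = c(600, 600, 600))
  set.seed(1)
  out <- step_sprout_init(net, tum, cfg)
  if (nrow(out$segments) > nrow(net$segments)) {
    new_seg <- out$segments[(nrow(net$segments) + 1):nrow(out$segments), ]
    an <- match(new_seg$a, out$nodes$id)
    d <- sqrt((out$nodes$x[an] - 600)^2 + (out$nodes$y[an] - 600)^2 +
              (out$nodes$z[an] - 600)^2)
    expect_true(all(d > tum$R_tum - 1e-9))
    expect_true(all(d < tum$R_tum + cfg$R_g + 1e-9))
    expect_true(all(new_seg$r == cfg$r_sprout))
    expect_true(all(new_seg$tau == 1))
  }
  # d_br gate: make the mid node a branch point, then no sprout within 80 um
  cfg2 <- sim_config(L = 1200, h_fine = 60, t_sprout = 1, dt = 1,
                     d_br_min = 1e9)  # gate everything
  set.seed(2)
  out2 <- step_sprout_init(net, tum, cfg2)
  # the straight chain has no branch point at all -> distances are Inf
  expect_gt(nrow(out2$segments), nrow(net$segments))
  # with a branching point everywhere within reach, nothing fires
  net3 <- out2
  cfg3 <- sim_config(L = 1200, h_fine = 60, t_sprout = 1, dt = 1,
                     d_br_min = 1e9)
  deg3 <- node_degrees(net3)
  expect_true(any(deg3 >= 3))
  set.seed(3)
  out3 <- step_sprout_init(net3, tum, cfg3)
  dbr <- vasox:::.branch_distances(net3)
  eligible_far <- which(is.finite(dbr) & dbr < 1e9)
  # nodes close to the new branch points are gated out
  new_cnt <- nrow(out3$segments) - nrow(net3$segments)
  expect_lte(new_cnt, sum(!is.finite(dbr)) + sum(dbr >= 1e9))
})

test_that("sprout counts follow the binomial law of firing probability", {
  cfg <- sim_config(L = 2400, h_fine = 60, t_sprout = 2, dt = 1,
                    R_g = 1e6)
  # long chain: every interior node eligible (no branch points)
  nodes <- data.frame(id = 1:2, x = c(0, 2400), y = 1200, z = 1200,
                      role = c("arterial_root", "venous_root"))
  segs <- data.frame(id = 1L, a = 1L, b = 2L, r = 6, type = "artery",
                     H = 0.45)
  net <- subdivide_segments(vessel_network(nodes, segs, L = 2400,
                                           h_fine = 60), 60)
  tum <- tumor_state(R_tum = 1e-6, t = 0, center = c(1200, 1200, 0))
  n_elig <- sum(node_degrees(net) <= 2 & net$nodes$role == "interior")
  set.seed(42)
  draws <- 0; trials <- 0
  for (rep in 1:40) {
    out <- step_sprout_init(net, tum, cfg)
    draws <- draws + (nrow(out$segments) - nrow(net$segments))
    trials <- trials + n_elig
  }
  # binomial(trials, 1/2): stay within 4 sigma (boundary rejections are
  # impossible here because the chain is far from the walls)
  p <- cfg$dt / cfg$t_sprout
  expect_lt(abs(draws - trials * p), 4 * sqrt(trials * p * (1 - p)))
})

test_that("circumferential growth doubles the radius over t_prol and caps", {
  cfg <- sim_config(L = 1200, h_fine = 60, t_prol = 144, t_switch = 12,
                    r_max = 1e9)
  net <- remodel_fixture(r = 5)
  tum <- tumor_state(R_tum = 1e9, t = 0, center = c(600, 600, 600))
  # warm-up: residence clock below t_switch leaves radii unchanged
  for (i in 1:11) net <- step_circumferential_growth(net, tum, cfg)
  expect_true(all(net$segments$r == 5))
  # 144 further hours of growth double the radius
  for (i in 1:144) net <- step_circumferential_growth(net, tum, cfg)
  expect_equal(net$segments$r[1], 10, tolerance = 1e-9)
  # cap at r_max
  cfgc <- sim_config(L = 1200, h_fine = 60, r_max = 10)
  netc <- remodel_fixture(r = 10)
  netc$segments$tin <- 100
  netc <- step_circumferential_growth(netc, tum, cfgc)
  expect_true(all(netc$segments$r <= 10 + 1e-12))
})

test_that("wall degradation clamps at zero and spares normal tissue", {
  cfg <- sim_config(L = 1200, h_fine = 60)
  net <- remodel_fixture()
  net$segments$w <- 1
  net$segments$tumor <- c(TRUE, rep(FALSE, nrow(net$segments) - 1))
  for (i in 1:10) net <- step_wall_degrade(net, cfg)
  expect_equal(net$segments$w[1], 0.5)
  expect_true(all(net$segments$w[-1] == 1))
  net$segments$w[1] <- 0.03
  net <- step_wall_degrade(net, cfg)
  expect_equal(net$segments$w[1], 0)
})

test_that("collapse removes degenerate low-shear segments and prunes dead ends", {
  cfg <- sim_config(L = 1200, h_fine = 300)
  # T-shape: main perfused channel plus a side branch ending blind
  nodes <- data.frame(id = 1:5,
                      x = c(0, 600, 1200, 600, 600),
                      y = c(600, 600, 600, 900, 1200), z = 600,
                      role = c("arterial_root", "interior", "venous_root",
                               "interior", "interior"))
  segs <- data.frame(id = 1:4, a = c(1L, 2L, 2L, 4L), b = c(2L, 3L, 4L, 5L),
                     r = 6, type = "artery", H = 0.45)
  net <- vessel_network(nodes, segs, L = 1200, h_fine = 300)
  res <- solve_hemodynamics(net, cfg)
  # the blind branch (segments 3, 4) carries no flow
  expect_lt(abs(res$flow$q[4]), 1e-9 * max(abs(res$flow$q)))
  net2 <- res$net
  net2$segments$tumor <- TRUE
  net2$segments$w <- c(1, 1, 1, 0)     # only the blind tip is degenerate
  out <- step_collapse_regress(net2, res$flow, cfg)
  # the tip collapses; the stranded side branch is pruned entirely
  expect_equal(sort(out$segments$id), c(1L, 2L))
  # degenerate but high-shear segments survive
  net3 <- res$net
  net3$segments$tumor <- TRUE
  net3$segments$w <- 0
  f_high <- res$flow; f_high$f <- rep(10, 4)
  out3 <- step_collapse_regress(net3, f_high, cfg)
  expect_equal(sort(out3$segments$id), c(1L, 2L))  # blind arm still pruned
  expect_true(all(c(1L, 2L) %in% out3$segments$id))
})

test_that("compression profile follows the linear ramp over the rim", {
  expect_equal(compression_factor(0, 1000, 0.6, 200), 0.6)
  expect_equal(compression_factor(1000 - 300, 1000, 0.6, 200), 0.6)
  expect_equal(compression_factor(1000 + 300, 1000, 0.6, 200), 1)
  expect_equal(compression_factor(1000, 1000, 0.6, 200), 0.8)  # midpoint
  net <- remodel_fixture()
  tum <- tumor_state(400, 0, c(600, 600, 600))
  out <- apply_compression(net, tum, 0.7, 200)
  expect_true(all(out$segments$r_tilde <= out$segments$r + 1e-12))
  expect_error(apply_compression(net, tum, 0.3), "0.5")
})

test_that("a short tumor growth run is deterministic and well-formed", {
  cfg <- sim_config(L = 1200, h = 60, h_fine = 130, t_end = 30,
                    R_tum0 = 150, geometry = "RC1", max_hemo_iter = 10)
  net <- make_mini_lattice(L = 1200, seed = 31, cfg = cfg)
  r1 <- run_tumor_growth(net, cfg, seed = 5)
  r2 <- run_tumor_growth(net, cfg, seed = 5)
  expect_identical(r1$net$segments, r2$net$segments)
  expect_equal(r1$tumor$R_tum, cfg$R_tum0 + cfg$v_tum * cfg$t_end)
  expect_identical(validate_network(r1$net), character(0))
  # tumor radii never exceed the dilatation cap
  expect_true(all(r1$net$segments$r[r1$net$segments$tumor] <=
                  cfg$r_max + 1e-9))
  # wall stability is non-negative and non-increasing for tumor segments
  expect_true(all(r1$net$segments$w >= 0))
  # no degree-4 nodes were ever created
  expect_true(all(node_degrees(r1$net) <= 3))
})
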