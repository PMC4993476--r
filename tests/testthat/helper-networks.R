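# Shared fixtures built in code. Kept deliberately small so the whole
# suite stays fast; the mini lattice is cached per session.

two_node_net <- function(r = 5, l = 500, L = 1000, H = 0.45) {
  nodes <- data.frame(id = 1:2, x = c(L / 2 - l / 2, L / 2 + l / 2),
                      y = L / 2, z = L / 2,
                      role = c("arterial_root", "venous_root"))
  segs <- data.frame(id = 1L, a = 1L, b = 2L, r = r, H = H,
                     type = "capillary")
  vessel_network(nodes, segs, h_gen = l, L = L)
}

# merge fixture: two inflows joining into one outflow
merge_net <- function(L = 1000) {
  nodes <- data.frame(
    id = 1:4,
    x = c(100, 100, 400, 800), y = c(200, 600, 400, 400), z = 400,
    role = c("arterial_root", "arterial_root", "interior", "venous_root"))
  segs <- data.frame(id = 1:3, a = c(1L, 2L, 3L), b = c(3L, 3L, 4L),
                     r = c(10, 8, 12), type = c("artery", "artery", "vein"),
                     H = 0.45)
  vessel_network(nodes, segs, h_gen = 400, L = L)
}

cached_mini_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_mini_lattice(L = 1300, seed = 99)
    }
    cache
  }
})

expect_close <- function(x, y, rel = 1e-8) {
  testthat::expect_lt(max(abs(x - y)) / max(abs(y), 1e-300), rel)
}
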