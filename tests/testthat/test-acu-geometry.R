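# Constrained-Voronoi mesh construction, volume bookkeeping, N-calibration
# and boundary attachment.

hex_sk <- function(side = 150, seed = 1, ...) {
  generate_acu_skeleton(6, side, 0, seed = seed, ...)
}

test_that("degenerate point counts give the expected meshes", {
  sk <- hex_sk()
  m1 <- build_septal_mesh(sk, 1, seed = 2)
  expect_equal(sum(m1$edges$kind == "septal"), 0)
  m2 <- build_septal_mesh(sk, 2, seed = 2)
  expect_equal(sum(m2$edges$kind == "septal"), 1)
  # the single interior ridge meets the boundary in two new junctions
  expect_equal(nrow(m2$nodes), 8)
})

test_that("meshes are connected planar graphs with interior septal edges", {
  for (seed in 1:4) {
    N <- c(20, 50, 35, 80)[seed]
    sk <- generate_acu_skeleton(6, 273, 50, seed = seed)
    net <- build_septal_mesh(sk, N, seed = seed + 10)
    # Euler characteristic of the planar subdivision: V - E + F = 2,
    # F = N cells + outer face
    expect_equal(nrow(net$nodes) - nrow(net$edges) + N + 1, 2)
    pos <- as.matrix(net$nodes[, c("x_um", "y_um")])
    se <- net$edges[net$edges$kind == "septal", ]
    mids <- (pos[match(se$from, net$nodes$id), ] + pos[match(se$to, net$nodes$id), ]) / 2
    expect_true(all(points_in_polygon(mids, net$polygon, tol = 0)))
    expect_true(all(se$diameter_um >= 5 & se$diameter_um <= 8))
    ig <- igraph::graph_from_data_frame(
      data.frame(from = net$edges$from, to = net$edges$to), directed = FALSE)
    expect_equal(igraph::components(ig)$no, 1)
  }
})

test_that("mesh construction is deterministic in the seed", {
  sk <- hex_sk(seed = 3)
  a <- build_septal_mesh(sk, 40, seed = 9)
  b <- build_septal_mesh(sk, 40, seed = 9)
  expect_identical(a$edges, b$edges)
  expect_identical(a$nodes, b$nodes)
})

test_that("capillary volume is the cylinder-volume sum over septal edges", {
  nodes <- tibble::tibble(id = 1:2, x_um = c(0, 100), y_um = 0,
                          kind = "septal_junction")
  edges <- tibble::tibble(id = 1L, from = 1L, to = 2L, kind = "septal",
                          diameter_um = 6, length_um = 100)
  net <- acu_network(nodes, edges, inlets = 1L, outlets = 2L)
  expect_equal(capillary_volume(net), pi / 4 * 36 * 100, tolerance = 1e-12)
  expect_equal(capillary_volume(make_tube(2)), 0)
  msh <- build_septal_mesh(hex_sk(seed = 5), 60, seed = 6)
  expect_equal(capillary_volume(msh), oracle_capillary_volume(msh), tolerance = 1e-12)
})

test_that("interstitial volume is the barrier slab minus the capillary volume", {
  sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  nodes <- tibble::tibble(id = 1:4, x_um = sq[, 1], y_um = sq[, 2],
                          kind = "corner_junction")
  edges <- tibble::tibble(id = 1:4, from = 1:4, to = c(2, 3, 4, 1), kind = "corner",
                          diameter_um = 20, length_um = 100)
  net <- acu_network(nodes, edges, inlets = 1L, outlets = 3L, polygon = sq,
                     barrier_um = 6)
  expect_equal(interstitial_volume(net), 60000, tolerance = 1e-12)
  msh <- build_septal_mesh(hex_sk(seed = 7), 50, seed = 8)
  expect_equal(interstitial_volume(msh),
               polygon_area(msh$polygon) * msh$barrier_um - oracle_capillary_volume(msh),
               tolerance = 1e-12)
  dense <- msh
  dense$barrier_um <- 0.001
  expect_error(interstitial_volume(dense), "over-dense")
})

test_that("doubling the barrier thickness roughly halves the volume ratio", {
  msh <- build_septal_mesh(hex_sk(seed = 9), 60, seed = 10)
  r1 <- volume_ratio(msh)
  msh2 <- msh
  msh2$barrier_um <- 2 * msh$barrier_um
  r2 <- volume_ratio(msh2)
  expect_equal(r2, r1 / 2, tolerance = 0.2)
})

test_that("N-calibration reaches the 1.54 band and is monotone in expectation", {
  sk <- hex_sk(side = 120, seed = 21)
  cal <- calibrate_n_points(sk, target_ratio = 1.54, tol = 0.05, replicates = 3,
                            seed = 2)
  expect_gte(cal$achieved_ratio, 1.49)
  expect_lte(cal$achieved_ratio, 1.59)
  expect_error(calibrate_n_points(sk, target_ratio = 0), "infeasible")
  ratio_at <- function(N) mean(vapply(1:3, function(r)
    volume_ratio(build_septal_mesh(sk, N, seed = r)), numeric(1)))
  rs <- vapply(c(10, 40, 160), ratio_at, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("boundary attachment snaps accesses to opposite sides and validates", {
  sk <- hex_sk(seed = 30)
  v1 <- as.numeric(sk$nodes[1, c("x_um", "y_um")])
  v4 <- as.numeric(sk$nodes[4, c("x_um", "y_um")])
  ctr <- polygon_centroid(sk$polygon)
  out_of <- function(v) v + 80 * (v - ctr) / sqrt(sum((v - ctr)^2))
  net <- attach_boundary(sk, rbind(out_of(v1)), rbind(out_of(v4)), validate = FALSE)
  # graph distance between the anchor corner nodes along corner edges is 3
  ce <- net$edges[net$edges$kind == "corner", ]
  g <- igraph::graph_from_data_frame(data.frame(from = ce$from, to = ce$to),
                                     directed = FALSE)
  stubs <- net$edges[net$edges$kind == "distribution", ]
  anchors <- stubs$to
  expect_equal(as.numeric(igraph::distances(g, as.character(anchors[1]),
                                            as.character(anchors[2]))), 3)
  expect_error(attach_boundary(sk, rbind(out_of(v1)), rbind(out_of(v1))), "equals|same")
  # a calibrated-density mesh with opposed accesses perfuses every septal edge
  msh <- build_septal_mesh(hex_sk(seed = 31), 60, seed = 32)
  expect_no_warning(
    full <- attach_boundary(msh, rbind(out_of(v1)), rbind(out_of(v4)), validate = TRUE)
  )
  sol <- perfuse(full, pressure_boundary())
  se <- sol$edges[sol$edges$kind == "septal", ]
  expect_true(all(abs(se$flow_m3s) > 0))
})

test_that("network JSON serialisation round-trips byte-identically", {
  msh <- build_septal_mesh(hex_sk(seed = 33), 25, seed = 34)
  js1 <- write_acu_network(msh)
  back <- read_acu_network(js1)
  js2 <- write_acu_network(back)
  expect_identical(js1, js2)
  expect_equal(back$edges$length_um, msh$edges$length_um, tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".json")
  write_acu_network(msh, path)
  expect_identical(write_acu_network(read_acu_network(path)), js1)
})
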