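# Poiseuille conductances, Laplacian pressure solves, patency updates and the
# de-recruitment fixed point.

test_that("edge conductance follows the Hagen-Poiseuille closed form", {
  g <- edge_conductance(50, 1000, viscosity = 2e-3)
  expect_equal(g, pi * (5e-5)^4 / (128 * 2e-3 * 1e-3), tolerance = 1e-12)
  expect_equal(edge_conductance(100, 1000) / edge_conductance(50, 1000), 16,
               tolerance = 1e-12)
  expect_equal(edge_conductance(50, 2000) / edge_conductance(50, 1000), 0.5,
               tolerance = 1e-12)
  expect_equal(edge_conductance(50, 1000, patent = FALSE), 0)
  expect_equal(edge_conductance(0, 1000), 0)
})

test_that("a single tube reproduces the analytic flow and midpoint pressure", {
  tube <- make_tube(2, d = 40, L = 800)
  bc <- pressure_boundary(16, 6, -10)
  sol <- perfuse(tube, bc)
  p <- stats::setNames(sol$node_pressures$pressure_cmH2O, sol$node_pressures$id)
  expect_equal(unname(p["2"]), 11, tolerance = 1e-12)
  q_analytic <- pi * (4e-5)^4 * (10 * 98.0665) / (128 * 2e-3 * 1.6e-3)
  expect_equal(sol$acu_flow_m3s, q_analytic, tolerance = 1e-12)
})

test_that("parallel tubes split flow by the fourth power of diameter", {
  eq <- perfuse(make_parallel(30, 30), pressure_boundary())
  expect_equal(eq$edges$flow_m3s[1], eq$acu_flow_m3s / 2, tolerance = 1e-12)
  expect_equal(eq$edges$flow_m3s[2], eq$acu_flow_m3s / 2, tolerance = 1e-12)
  mixed <- perfuse(make_parallel(30, 6, kinds = c("corner", "septal")),
                   pressure_boundary())
  expect_true(all(mixed$edges$patent))
  expect_equal(mixed$edges$flow_m3s[2] / mixed$edges$flow_m3s[1], (6 / 30)^4,
               tolerance = 1e-12)
})

test_that("mesh pressure solves match a dense direct-solve oracle", {
  for (seed in 1:5) {
    net <- random_mesh(seed, n_points = 5)
    expect_lte(nrow(net$nodes), 30)
    bc <- pressure_boundary()
    p <- solve_pressures(net, bc)
    o <- oracle_solve(net, bc)
    expect_equal(unname(p), unname(o$pressures[names(p)]), tolerance = 1e-10)
    sol <- perfuse(net, bc)
    expect_equal(sol$edges$flow_m3s, o$flows, tolerance = 1e-10)
  }
})

test_that("flow is conserved at interior nodes and across the boundary", {
  for (seed in 1:20) {
    net <- random_mesh(seed, n_points = sample(4:12, 1))
    sol <- perfuse(net, pressure_boundary())
    expect_lt(max(kirchhoff_residuals(sol, net)), 1e-9 * abs(sol$acu_flow_m3s))
    inflow <- sol$acu_flow_m3s
    e <- sol$edges
    sgn_out <- as.integer(e$to %in% net$outlets) - as.integer(e$from %in% net$outlets)
    outflow <- sum(e$flow_m3s * sgn_out)
    expect_equal(outflow, inflow, tolerance = 1e-9)
    # the mid-pressure cut decomposition is exact
    expect_equal(sol$corner_flow_m3s + sol$septal_flow_m3s + sol$distribution_cut_flow_m3s,
                 sol$acu_flow_m3s, tolerance = 1e-9)
  }
})

test_that("patency follows the signed transmural rule and spares corner vessels", {
  net <- make_parallel(30, 6, kinds = c("corner", "septal"))
  p <- stats::setNames(c(14, 8), net$nodes$id)   # mean luminal pressure 11
  pat <- update_patency(net, p, pressure_boundary(P_i = -10))
  expect_true(all(pat))
  # stagnant region at mean pressure 2 with P_i = 3: transmural -1, closed
  p2 <- stats::setNames(c(2, 2), net$nodes$id)
  pat2 <- update_patency(net, p2, pressure_boundary(16, 6, 3))
  expect_false(pat2[2])
  expect_true(pat2[1])  # corner edges never close
})

test_that("raising interstitial pressure de-recruits monotonically to full closure", {
  net <- random_mesh(3, n_points = 25, n_inlets = 2, n_outlets = 2)
  # the edema path of the boundary table, then into the closure regime
  sweep_pi <- c(-10, -6, 3, 13, 20)
  patent_count <- surface <- ratio <- numeric(0)
  for (pi_val in sweep_pi) {
    sol <- perfuse(net, pressure_boundary(16, 6, pi_val))
    patent_count <- c(patent_count, sum(sol$edges$patent[sol$edges$kind == "septal"]))
    surface <- c(surface, filtration_surface(net, sol$edges$patent))
    ratio <- c(ratio, sol$septal_to_corner_ratio)
  }
  expect_true(all(diff(patent_count) <= 0))
  expect_true(all(diff(surface) <= 1e-15))
  expect_true(all(diff(ratio) <= 1e-12))
  # P_i >= P_art: every septal capillary closes, flow survives on corner paths
  limit <- perfuse(net, pressure_boundary(16, 6, 20))
  expect_equal(sum(limit$edges$patent[limit$edges$kind == "septal"]), 0)
  expect_gt(limit$acu_flow_m3s, 0)
  expect_equal(limit$septal_flow_m3s, 0)
})

test_that("a septal-only path fully de-recruits when P_i exceeds luminal pressure", {
  nodes <- tibble::tibble(id = 1:2, x_um = c(0, 100), y_um = 0,
                          kind = c("inlet", "outlet"))
  edges <- tibble::tibble(id = 1L, from = 1L, to = 2L, kind = "septal",
                          diameter_um = 6, length_um = 100)
  net <- acu_network(nodes, edges, inlets = 1L, outlets = 2L)
  sol <- perfuse(net, pressure_boundary(16, 6, 20))
  expect_true(sol$fully_derecruited)
  expect_equal(sol$acu_flow_m3s, 0)
  expect_false(any(sol$edges$patent))
})

test_that("flows are invariant to expressing pressures in pascals", {
  net <- random_mesh(8, n_points = 10)
  c_pa <- 98.0665
  sol_cm <- perfuse(net, pressure_boundary(16, 6, -10))
  sol_pa <- perfuse(net, pressure_boundary(16 * c_pa, 6 * c_pa, -10 * c_pa))
  expect_equal(sol_pa$edges$flow_m3s / c_pa, sol_cm$edges$flow_m3s, tolerance = 1e-12)
})
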