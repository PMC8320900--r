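# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the package's solver/summation code paths.

# Dense direct solve of the Dirichlet network problem with base R only.
oracle_solve <- function(net, bc, patent = rep(TRUE, nrow(net$edges)), viscosity = 2e-3) {
  e <- net$edges
  ids <- net$nodes$id
  n <- length(ids)
  d <- e$diameter_um * 1e-6
  L <- e$length_um * 1e-6
  g <- pi * d^4 / (128 * viscosity * L)
  g[!patent | d <= 0] <- 0
  A <- matrix(0, n, n)
  iu <- match(e$from, ids); iv <- match(e$to, ids)
  for (k in seq_along(g)) {
    A[iu[k], iu[k]] <- A[iu[k], iu[k]] + g[k]
    A[iv[k], iv[k]] <- A[iv[k], iv[k]] + g[k]
    A[iu[k], iv[k]] <- A[iu[k], iv[k]] - g[k]
    A[iv[k], iu[k]] <- A[iv[k], iu[k]] - g[k]
  }
  bnd <- match(c(net$inlets, net$outlets), ids)
  pb <- c(rep(bc$P_art, length(net$inlets)), rep(bc$P_ven, length(net$outlets)))
  free <- setdiff(seq_len(n), bnd)
  p <- numeric(n)
  p[bnd] <- pb
  keep <- free[rowSums(abs(A[free, , drop = FALSE])) > 0]
  if (length(keep) > 0) {
    p[keep] <- solve(A[keep, keep, drop = FALSE], -A[keep, bnd, drop = FALSE] %*% pb)
  }
  iso <- setdiff(free, keep)
  p[iso] <- bc$P_i
  q <- unname(g * (p[iu] - p[iv]) * 98.0665)
  list(pressures = stats::setNames(p, ids), flows = q)
}

# Brute-force per-edge summations.
oracle_capillary_volume <- function(net) {
  v <- 0
  for (k in seq_len(nrow(net$edges))) {
    if (net$edges$kind[k] == "septal")
      v <- v + pi / 4 * net$edges$diameter_um[k]^2 * net$edges$length_um[k]
  }
  as.numeric(v)
}

oracle_filtration_surface <- function(net, patent) {
  s <- 0
  for (k in seq_len(nrow(net$edges))) {
    if (net$edges$kind[k] == "septal" && patent[k])
      s <- s + pi * net$edges$diameter_um[k] * 1e-6 * net$edges$length_um[k] * 1e-6
  }
  as.numeric(s)
}

oracle_jv <- function(solution, params) {
  tot <- 0
  e <- solution$edges
  for (k in seq_len(nrow(e))) {
    if (e$kind[k] == "septal" && e$patent[k]) {
      S <- pi * e$diameter_um[k] * 1e-6 * e$length_um[k] * 1e-6
      tot <- tot + params$Lp * S *
        ((e$mean_pressure_cmH2O[k] - solution$bc$P_i) - params$sigma * (params$pi_c - params$pi_i))
    }
  }
  as.numeric(tot)
}

# Hand-built tiny networks ----------------------------------------------------

# A straight chain inlet - interior... - outlet of `n_seg` equal segments.
make_tube <- function(n_seg = 2, d = 50, L = 1000, kind = "corner") {
  n <- n_seg + 1
  nodes <- tibble::tibble(
    id = seq_len(n), x_um = seq(0, by = L, length.out = n), y_um = 0,
    kind = c("inlet", rep("corner_junction", n - 2), "outlet")
  )
  edges <- tibble::tibble(
    id = seq_len(n_seg), from = seq_len(n_seg), to = seq_len(n_seg) + 1,
    kind = kind, diameter_um = d, length_um = L
  )
  acu_network(nodes, edges, inlets = 1L, outlets = n, polygon = NULL)
}

# Two parallel edges between one inlet and one outlet.
make_parallel <- function(d1, d2, L = 1000, kinds = c("corner", "corner")) {
  nodes <- tibble::tibble(id = 1:2, x_um = c(0, L), y_um = 0,
                          kind = c("inlet", "outlet"))
  edges <- tibble::tibble(id = 1:2, from = 1L, to = 2L, kind = kinds,
                          diameter_um = c(d1, d2), length_um = L)
  acu_network(nodes, edges, inlets = 1L, outlets = 2L, polygon = NULL)
}

# A small random meshed ACU with attached inlet/outlet stubs.
random_mesh <- function(seed, n_junctions = 6, mean_len = 150, sd_len = 20,
                        n_points = 8, n_inlets = 1, n_outlets = 1) {
  sk <- generate_acu_skeleton(n_junctions, mean_len, sd_len,
                              n_inlets = n_inlets, n_outlets = n_outlets, seed = seed)
  net <- build_septal_mesh(sk, n_points, seed = seed + 1)
  ctr <- c(mean(sk$polygon[, 1]), mean(sk$polygon[, 2]))
  stub <- function(ids) {
    p <- as.matrix(sk$nodes[match(ids, sk$nodes$id), c("x_um", "y_um")])
    dirv <- sweep(p, 2, ctr)
    p + 60 * dirv / sqrt(rowSums(dirv^2))
  }
  attach_boundary(net, stub(sk$inlets), stub(sk$outlets), validate = FALSE)
}

# Kirchhoff residuals at interior (non-boundary) nodes of a solution.
kirchhoff_residuals <- function(sol, net) {
  e <- sol$edges
  resid <- tapply(c(-e$flow_m3s, e$flow_m3s), c(e$from, e$to), sum)
  interior <- setdiff(net$nodes$id, c(net$inlets, net$outlets))
  abs(resid[as.character(interior)])
}

table1_bcs <- function() {
  pt <- pressure_table()
  lapply(seq_len(nrow(pt)), function(i)
    pressure_boundary(pt$P_art[i], pt$P_ven[i], pt$P_i[i], pt$label[i]))
}
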