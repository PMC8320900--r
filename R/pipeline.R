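# End-to-end study orchestration: corner skeleton -> calibrated septal mesh ->
# boundary attachment -> per-timepoint diameters -> perfusion -> filtration ->
# a Table-2-style study report. Topology is frozen at baseline; only diameters
# (corner, distribution) and patency vary across timepoints.

#' Study configuration
#'
#' @param pressures Tibble of boundary pressures per timepoint (defaults to
#'   [pressure_table()]); must contain timepoint 0.
#' @param target_ratio Capillary-to-interstitial volume ratio for mesh
#'   calibration (1.54, the fully extended rabbit capillary network).
#' @param calibration_tol,calibration_replicates Calibration search settings.
#' @param barrier_um Alveolar barrier thickness (μm) of the 2D-to-volume
#'   bridge.
#' @param corner_scale Named per-timepoint multiplier applied to corner
#'   diameters (names = minutes). Default emulates the observed corner
#'   vasomotion: mild (~25%) constriction at 30 min, moderate dilation at
#'   120 min.
#' @param distribution_pattern Time-course pattern for the feeding
#'   distribution vessels (see [generate_diameter_timecourse()]); the default
#'   `"constrict_reopen"` halves them at 30 min with recovery by 120 min.
#' @param starling A [starling_params()].
#' @param physio A [physio_params()].
#' @param distribution_diameter Baseline distribution stub diameter (μm).
#' @param seed Master seed; all stage seeds derive from it.
#' @return An `acu_study_config` list.
#' @export
acu_study_config <- function(pressures = pressure_table(), target_ratio = 1.54,
                             calibration_tol = 0.05, calibration_replicates = 5,
                             barrier_um = 6.5,
                             corner_scale = c(`0` = 1, `30` = 0.75, `120` = 1.15),
                             distribution_pattern = "constrict_reopen",
                             starling = starling_params(), physio = physio_params(),
                             distribution_diameter = 50, seed = 1L) {
  pressures <- as_tibble(pressures)
  if (is.unsorted(pressures$timepoint_min)) abort("timepoints must be sorted")
  if (!0 %in% pressures$timepoint_min) abort("pressure table must contain the baseline timepoint 0")
  structure(list(pressures = pressures, target_ratio = target_ratio,
                 calibration_tol = calibration_tol,
                 calibration_replicates = calibration_replicates,
                 barrier_um = barrier_um, corner_scale = corner_scale,
                 distribution_pattern = distribution_pattern,
                 starling = starling, physio = physio,
                 distribution_diameter = distribution_diameter,
                 seed = as.integer(seed)),
            class = "acu_study_config")
}

# Per-timepoint copy of the network with scaled corner / distribution
# diameters (septal diameters frozen at baseline).
scale_diameters <- function(net, corner_factor, distribution_factor) {
  e <- net$edges
  e$diameter_um[e$kind == "corner"] <- e$diameter_um[e$kind == "corner"] * corner_factor
  e$diameter_um[e$kind == "distribution"] <-
    e$diameter_um[e$kind == "distribution"] * distribution_factor
  net$edges <- e
  net
}

# Build one synthetic ACU ready for perfusion: skeleton -> calibrated mesh ->
# inlet/outlet stubs placed radially outside the designated junctions.
build_synthetic_acu <- function(spec, config, n_points = NULL) {
  sk <- generate_acu_skeleton(
    n_corner_junctions = spec$n_junctions %||% 8,
    mean_corner_length = spec$mean_corner_length,
    corner_length_sd = spec$corner_length_sd %||% 0,
    n_inlets = spec$n_inlets %||% 2,
    n_outlets = spec$n_outlets %||% 2,
    seed = spec$seed %||% config$seed
  )
  sk$barrier_um <- config$barrier_um
  if (is.null(n_points)) {
    cal <- calibrate_n_points(sk, target_ratio = config$target_ratio,
                              tol = config$calibration_tol,
                              replicates = config$calibration_replicates,
                              seed = child_seed(config$seed, 11))
    n_points <- cal$n_points
  } else {
    cal <- NULL
  }
  net <- build_septal_mesh(sk, n_points, seed = child_seed(spec$seed %||% config$seed, 13))
  ctr <- polygon_centroid(sk$polygon)
  stub_pos <- function(ids) {
    p <- as.matrix(sk$nodes[match(ids, sk$nodes$id), c("x_um", "y_um")])
    dir <- sweep(p, 2, ctr)
    dir <- dir / sqrt(rowSums(dir^2))
    p + 100 * dir
  }
  net <- attach_boundary(net, stub_pos(sk$inlets), stub_pos(sk$outlets),
                         distribution_diameter = config$distribution_diameter,
                         bc = boundary_at(config, 0), params = config$physio,
                         validate = FALSE)
  list(network = net, skeleton = sk, calibration = cal)
}

boundary_at <- function(config, tp) {
  row <- config$pressures[config$pressures$timepoint_min == tp, ]
  if (nrow(row) != 1) abort(sprintf("no pressure row for timepoint %s", tp))
  pressure_boundary(row$P_art, row$P_ven, row$P_i, label = row$label)
}

#' Run a full multi-timepoint ACU study
#'
#' For each ACU (synthetic spec or prebuilt network) the baseline topology is
#' built once, then per timepoint the corner and distribution diameters are
#' rescaled, perfusion is solved under that timepoint's boundary pressures,
#' and Starling filtration is reported against baseline.
#'
#' @param acus Either a list of synthetic ACU specs (lists with
#'   `mean_corner_length`, optional `corner_length_sd`, `n_junctions`,
#'   `n_inlets`, `n_outlets`, `seed`, `name`, `n_points`) or a named list of
#'   ready `acu_network`s with attached inlets/outlets.
#' @param config An [acu_study_config()].
#' @return An `acu_study`: list with `report` (tibble, one row per ACU x
#'   timepoint, units following the reference table: flows in 1e-12 m³/s,
#'   surface in 1e-7 m², Jv/S in 1e-10 m/s), `networks`, `solutions`, and a
#'   provenance block (config hash, seeds, package version).
#' @export
run_study <- function(acus = list(
                        list(name = "ACU1", mean_corner_length = 273, corner_length_sd = 76),
                        list(name = "ACU2", mean_corner_length = 195, corner_length_sd = 58)
                      ),
                      config = acu_study_config()) {
  stopifnot(inherits(config, "acu_study_config"))
  tps <- config$pressures$timepoint_min
  dist_course <- generate_diameter_timecourse(1, config$distribution_pattern,
                                              timepoints = tps, jitter = 0)
  rows <- list()
  networks <- list(); solutions <- list()
  for (a in seq_along(acus)) {
    item <- acus[[a]]
    if (inherits(item, "acu_network")) {
      net <- item
      name <- names(acus)[a] %||% paste0("ACU", a)
      cal <- NULL
    } else {
      name <- item$name %||% paste0("ACU", a)
      built <- build_synthetic_acu(item, config, n_points = item$n_points %||% NULL)
      net <- built$network
      cal <- built$calibration
    }
    mcl <- mean_corner_length(net)
    base_filt <- NULL
    for (tp in tps) {
      cf <- config$corner_scale[as.character(tp)]
      if (is.na(cf)) cf <- 1
      df <- dist_course$diameter_um[dist_course$timepoint_min == tp]
      net_tp <- scale_diameters(net, cf, df)
      sol <- perfuse(net_tp, boundary_at(config, tp), config$physio)
      filt <- filtration_report(sol, config$starling, baseline = base_filt)
      if (tp == 0) base_filt <- filt
      solutions[[paste(name, tp)]] <- sol
      rows[[length(rows) + 1L]] <- tibble(
        acu = name, timepoint_min = tp,
        mean_corner_length_um = mcl$mean_um,
        corner_length_sd_um = mcl$sd_um,
        n_septal_patent = sum(sol$edges$patent[sol$edges$kind == "septal"]),
        acu_flow_1e12_m3s = sol$acu_flow_m3s / 1e-12,
        septal_corner_ratio = sol$septal_to_corner_ratio,
        filtration_surface_1e7_m2 = filt$surface_m2 / 1e-7,
        jv_per_surface_1e10_ms = filt$jv_per_surface_ms / 1e-10,
        pct_surface = filt$pct_surface,
        pct_jv_per_surface = filt$pct_jv_per_surface,
        n_points = if (!is.null(cal)) cal$n_points else NA_integer_,
        achieved_ratio = if (!is.null(cal)) cal$achieved_ratio else volume_ratio(net)
      )
    }
    networks[[name]] <- net
  }
  report <- bind_rows(rows) |>
    group_by(.data$acu) |>
    mutate(
      pct_acu_flow = 100 * (.data$acu_flow_1e12_m3s / .data$acu_flow_1e12_m3s[.data$timepoint_min == 0] - 1),
      pct_septal_corner_ratio = 100 * (.data$septal_corner_ratio / .data$septal_corner_ratio[.data$timepoint_min == 0] - 1)
    ) |>
    ungroup()
  structure(list(
    report = report,
    networks = networks,
    solutions = solutions,
    config = config,
    provenance = list(
      config_hash = rlang::hash(config),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("acuflow"))
    )
  ), class = "acu_study")
}

#' @export
print.acu_study <- function(x, ...) {
  cat("<acu_study> ", length(x$networks), " ACU network(s) x ",
      length(unique(x$report$timepoint_min)), " timepoints (seed ",
      x$provenance$seed, ")\n", sep = "")
  print(x$report[, c("acu", "timepoint_min", "acu_flow_1e12_m3s", "septal_corner_ratio",
                     "filtration_surface_1e7_m2", "jv_per_surface_1e10_ms",
                     "pct_jv_per_surface")])
  invisible(x)
}
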