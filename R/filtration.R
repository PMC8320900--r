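# Starling-law transcapillary filtration over the patent septal network.
#
# Jv_e = Lp * S_e * [(Pc - P_i) - sigma * (pi_c - pi_i)], with S_e the lateral
# cylinder surface pi*d*L of a patent septal edge and Pc the mean of its
# endpoint pressures. Corner and distribution vessels do not filter here: the
# septal wall is the exchange surface.

#' Starling filtration parameters
#'
#' The source study uses, but never prints, its permeability values; these
#' defaults are declared assumptions: a reflection coefficient near the tight
#' continuous endothelium, an oncotic gradient of 15 cmH₂O, and a hydraulic
#' conductivity placing baseline Jv/S in the 1e-10 m/s decade. Absolute
#' filtration numbers are calibration-dependent; relative (timepoint vs
#' baseline) comparisons are the meaningful output.
#'
#' @param Lp Hydraulic conductivity in m/(s·cmH₂O).
#' @param sigma Protein reflection coefficient (0-1).
#' @param pi_c Plasma oncotic pressure (cmH₂O).
#' @param pi_i Interstitial oncotic pressure (cmH₂O).
#' @return A `starling_params` list.
#' @export
starling_params <- function(Lp = 4e-11, sigma = 0.9, pi_c = 34, pi_i = 19) {
  if (Lp <= 0) abort("Lp must be positive")
  if (sigma < 0 || sigma > 1) abort("sigma must lie in [0, 1]")
  structure(list(Lp = Lp, sigma = sigma, pi_c = pi_c, pi_i = pi_i),
            class = "starling_params")
}

#' Filtration surface of the patent septal network
#'
#' Sum of lateral cylinder surfaces \eqn{\pi d L} over patent septal edges,
#' in SI units.
#'
#' @param net An `acu_network`.
#' @param patent Logical patency vector over edges (default all patent), e.g.
#'   from an [perfuse()] solution.
#' @return Surface in m².
#' @export
filtration_surface <- function(net, patent = NULL) {
  e <- net$edges
  patent <- patent %||% rep(TRUE, nrow(e))
  sel <- e$kind == "septal" & patent
  sum(pi * e$diameter_um[sel] * 1e-6 * e$length_um[sel] * 1e-6)
}

#' Starling filtration flow of one capillary segment
#'
#' @param surface_m2 Exchange surface of the segment (m²).
#' @param Pc Mean capillary (luminal) pressure of the segment (cmH₂O).
#' @param P_i Interstitial pressure (cmH₂O).
#' @param params A [starling_params()].
#' @return Filtration flow in m³/s (negative = re-absorption), vectorised.
#' @export
edge_filtration <- function(surface_m2, Pc, P_i, params = starling_params()) {
  params$Lp * surface_m2 * ((Pc - P_i) - params$sigma * (params$pi_c - params$pi_i))
}

#' Filtration report for a perfusion solution
#'
#' Aggregates filtration surface S, total Starling flow Jv and the
#' surface-normalised flow Jv/S over the patent septal edges of a perfusion
#' solution, with percent changes against an optional baseline report.
#'
#' @param solution An `acu_perfusion` from [perfuse()].
#' @param params A [starling_params()].
#' @param baseline Optional baseline `acu_filtration` for percent changes.
#' @return An `acu_filtration`: per-edge tibble plus `surface_m2`, `jv_m3s`,
#'   `jv_per_surface_ms` and `pct_*` fields (NA without / with a degenerate
#'   baseline).
#' @export
filtration_report <- function(solution, params = starling_params(), baseline = NULL) {
  stopifnot(inherits(solution, "acu_perfusion"))
  e <- solution$edges
  sep <- e[e$kind == "septal", ]
  S_e <- ifelse(sep$patent, pi * sep$diameter_um * 1e-6 * sep$length_um * 1e-6, 0)
  jv_e <- ifelse(sep$patent,
                 edge_filtration(S_e, sep$mean_pressure_cmH2O, solution$bc$P_i, params),
                 0)
  S <- sum(S_e)
  jv <- sum(jv_e)
  pct <- function(x, x0) if (is.null(x0) || !is.finite(x0) || x0 == 0) NA_real_ else 100 * (x - x0) / x0
  jvs <- if (S > 0) jv / S else 0
  structure(list(
    edges = tibble(id = sep$id, patent = sep$patent, surface_m2 = S_e,
                   Pc_cmH2O = sep$mean_pressure_cmH2O, jv_m3s = jv_e),
    surface_m2 = S,
    jv_m3s = jv,
    jv_per_surface_ms = jvs,
    pct_surface = pct(S, baseline$surface_m2),
    pct_jv = pct(jv, baseline$jv_m3s),
    pct_jv_per_surface = pct(jvs, baseline$jv_per_surface_ms),
    bc = solution$bc,
    params = params
  ), class = "acu_filtration")
}

#' @export
print.acu_filtration <- function(x, ...) {
  cat(sprintf("<acu_filtration> %s: S = %.3g m^2, Jv = %.3g m^3/s, Jv/S = %.3g m/s",
              x$bc$label, x$surface_m2, x$jv_m3s, x$jv_per_surface_ms))
  if (is.finite(x$pct_jv_per_surface))
    cat(sprintf(" (Jv/S %+.0f%% vs baseline)", x$pct_jv_per_surface))
  cat("\n")
  invisible(x)
}
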