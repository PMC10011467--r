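#' Monte Carlo sensitivity of the pressure match to (R1norm, Cnorm)
#'
#' Draws `n` independent parameter pairs uniformly over `ranges`, simulates
#' the normalized pressure response to the reference flow for each pair,
#' and records the cost — the sum of squared differences to the reference
#' pressure over the dimensionless 0.01 grid. The reference waveforms are
#' typically per-artery ensemble means of normalized measured waveforms.
#' The full draw set is evaluated (no early stopping) and the minimum is
#' reported; results are deterministic given `seed`.
#'
#' @param flow_norm Reference normalized flow (`wk_nwaveform`).
#' @param pressure_norm Reference normalized pressure (`wk_nwaveform`).
#' @param n Number of draws (default 1500).
#' @param ranges List with elements `r1norm` and `cnorm`, each `c(lo, hi)`.
#'   Defaults cover the plausible normalized plane:
#'   r1norm in (0.001, 0.6], cnorm in (0.01, 3].
#' @param seed Integer RNG seed (recorded in the output).
#' @param settings A [solver_settings()].
#' @return A `wk3_sensitivity` object: a tibble of samples
#'   (`r1norm`, `cnorm`, `cost`) with attributes `ranges`, `n`, `seed`,
#'   `reference_flow`, `reference_pressure`.
#' @export
monte_carlo_sensitivity <- function(flow_norm, pressure_norm, n = 1500L,
                                    ranges = list(r1norm = c(0.001, 0.6),
                                                  cnorm = c(0.01, 3.0)),
                                    seed = 1L,
                                    settings = solver_settings()) {
  check_nwaveform(flow_norm, "flow")
  check_nwaveform(pressure_norm, "pressure")
  if (n < 1) abort("`n` must be at least 1")
  for (nm in c("r1norm", "cnorm")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || r[1] >= r[2]) {
      abort(sprintf("`ranges$%s` must be c(lo, hi) with lo < hi", nm))
    }
  }
  if (ranges$r1norm[1] <= 0 || ranges$r1norm[2] >= 1 ||
      ranges$cnorm[1] <= 0) {
    abort("r1norm range must lie in (0,1); cnorm range must be positive")
  }
  set.seed(seed)
  r1 <- runif(n, ranges$r1norm[1], ranges$r1norm[2])
  cn <- runif(n, ranges$cnorm[1], ranges$cnorm[2])
  g <- solver_grid(1, settings)
  qhalf <- nwf_splinefun(flow_norm)(g$t_half)
  pref <- pressure_norm$value
  cost <- vapply(seq_len(n), function(i) {
    sensitivity_cost_core(qhalf, flow_norm$value, r1[i], cn[i], pref,
                          settings)
  }, numeric(1))
  out <- tibble(r1norm = r1, cnorm = cn, cost = cost)
  structure(out, ranges = ranges, n = as.integer(n), seed = as.integer(seed),
            reference_flow = flow_norm, reference_pressure = pressure_norm,
            class = c("wk3_sensitivity", class(out)))
}

sensitivity_cost_core <- function(qhalf, qgrid, r1norm, cnorm, pref,
                                  settings) {
  p <- forward_normalized_core(qhalf, qgrid, wk3_nparams(r1norm, cnorm),
                               settings)
  p <- p / mean(p)
  sum((p - pref)^2)
}

#' Cost of a single normalized parameter pair against reference waveforms
#'
#' The same cost the Monte Carlo map records, evaluated at one point —
#' useful for querying the cost at, e.g., the cohort medians.
#'
#' @inheritParams monte_carlo_sensitivity
#' @param nparams A `wk3_nparams`.
#' @return Scalar dimensionless cost (sum of squared differences over the
#'   0.01 grid).
#' @export
sensitivity_cost <- function(flow_norm, pressure_norm, nparams,
                             settings = solver_settings()) {
  check_nwaveform(flow_norm, "flow")
  check_nwaveform(pressure_norm, "pressure")
  g <- solver_grid(1, settings)
  qhalf <- nwf_splinefun(flow_norm)(g$t_half)
  sensitivity_cost_core(qhalf, flow_norm$value, nparams$r1norm,
                        nparams$cnorm, pressure_norm$value, settings)
}

#' Grid a Monte Carlo sensitivity map for contour plotting
#'
#' Bins the scattered samples onto a regular (r1norm, cnorm) grid, keeping
#' the minimum cost per cell (empty cells take the value of the nearest
#' non-empty cell), so the surface minimum equals the sample minimum
#' exactly. Also reports the arg-min sample and, optionally, the
#' independently recomputed cost at a reference parameter pair (e.g. the
#' cohort medians).
#'
#' @param map A `wk3_sensitivity`.
#' @param grid_resolution Number of cells per axis (default 40, minimum 2).
#' @param reference Optional `wk3_nparams` at which to recompute the cost.
#' @param settings A [solver_settings()] (for the reference query).
#' @return A `wk3_surface` tibble (`r1norm`, `cnorm`, `cost`) with
#'   attributes `argmin` (one-row tibble) and `reference_cost`.
#' @export
grid_contour <- function(map, grid_resolution = 40L, reference = NULL,
                         settings = solver_settings()) {
  if (!inherits(map, "wk3_sensitivity")) abort("expected `wk3_sensitivity`")
  if (nrow(map) < 1) abort("empty sensitivity map")
  if (grid_resolution < 2) abort("`grid_resolution` must be at least 2")
  ranges <- attr(map, "ranges")
  gx <- seq(ranges$r1norm[1], ranges$r1norm[2],
            length.out = grid_resolution)
  gy <- seq(ranges$cnorm[1], ranges$cnorm[2],
            length.out = grid_resolution)
  ix <- pmin(pmax(findInterval(map$r1norm, gx, all.inside = TRUE), 1L),
             grid_resolution)
  iy <- pmin(pmax(findInterval(map$cnorm, gy, all.inside = TRUE), 1L),
             grid_resolution)
  cost_mat <- matrix(NA_real_, grid_resolution, grid_resolution)
  for (k in seq_len(nrow(map))) {
    cur <- cost_mat[ix[k], iy[k]]
    if (is.na(cur) || map$cost[k] < cur) cost_mat[ix[k], iy[k]] <- map$cost[k]
  }
  # fill empty cells from the nearest non-empty cell
  filled <- which(!is.na(cost_mat), arr.ind = TRUE)
  empty <- which(is.na(cost_mat), arr.ind = TRUE)
  if (nrow(empty) > 0) {
    for (k in seq_len(nrow(empty))) {
      d2 <- (filled[, 1] - empty[k, 1])^2 + (filled[, 2] - empty[k, 2])^2
      nearest <- filled[which.min(d2), , drop = FALSE]
      cost_mat[empty[k, 1], empty[k, 2]] <- cost_mat[nearest]
    }
  }
  surf <- tidyr::expand_grid(r1norm = gx, cnorm = gy)
  surf$cost <- as.vector(t(cost_mat))  # row-major matches expand_grid order
  argmin <- map[which.min(map$cost), , drop = FALSE]
  ref_cost <- if (!is.null(reference)) {
    sensitivity_cost(attr(map, "reference_flow"),
                     attr(map, "reference_pressure"), reference, settings)
  } else {
    NA_real_
  }
  structure(as_tibble(surf),
            argmin = as_tibble(argmin), reference_cost = ref_cost,
            resolution = as.integer(grid_resolution),
            class = c("wk3_surface", class(surf)))
}

#' @export
tidy.wk3_sensitivity <- function(x, ...) as_tibble(x)

#' @export
glance.wk3_sensitivity <- function(x, ...) {
  i <- which.min(x$cost)
  tibble(n = attr(x, "n"), seed = attr(x, "seed"),
         min_cost = x$cost[i],
         r1norm_at_min = x$r1norm[i], cnorm_at_min = x$cnorm[i])
}

#' Write sensitivity samples to CSV
#'
#' @param map A `wk3_sensitivity` (or `wk3_surface`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
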