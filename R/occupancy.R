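#' Default buffered-metal grid
#'
#' 61 log-spaced concentrations over 1e-16 to 1e-3 M, the range the buffer
#' sweep is designed to cover.
#'
#' @param n Number of points; default 61.
#' @param from,to Grid bounds in molar.
#' @return Increasing numeric vector of concentrations (molar).
#' @export
default_metal_grid <- function(n = 61, from = 1e-16, to = 1e-3) {
  if (n < 1) return(numeric(0))
  10^seq(log10(from), log10(to), length.out = n)
}

build_sensor_network <- function(sensor, metal, metal_kd, holo_kd,
                                 buffered_metal, cell,
                                 metal_total = 0.01, buffer_total = 0.1) {
  p_tot <- copies_to_concentration(sensor$abundance, cell)
  d_tot <- copies_to_concentration(sensor$dna_targets, cell)
  k1 <- 1 / metal_kd
  k3 <- 1 / sensor$apo_dna_kd$kd
  k4 <- 1 / holo_kd
  if (buffered_metal == 0) {
    reaction_network(
      list(reaction(c("P", "D"), "PD", k3)),
      c(P = p_tot, D = d_tot))
  } else {
    k5 <- k5_for_target(buffered_metal, metal_total, buffer_total)
    reaction_network(
      list(reaction(c("P", "M"), "PM", k1),
           reaction(c("P", "D"), "PD", k3),
           reaction(c("PM", "D"), "PMD", k4),
           reaction(c("M", "B"), "MB", k5)),
      c(P = p_tot, M = metal_total, D = d_tot, B = buffer_total))
  }
}

#' Fractional operator-promoter occupancy at one buffered metal concentration
#'
#' Builds and solves the coupled four-equilibrium network for one sensor:
#' P + M <-> PM (association constant 1/metal Kd), P + D <-> PD (1/apo DNA
#' Kd), PM + D <-> PMD (1/holo DNA Kd) and M + B <-> MB (buffer constant
#' chosen to realise \code{buffered_metal}). Metal binding to the PD state
#' is not an independent equilibrium: it is implied by thermodynamic-cycle
#' closure, so the network carries only the four constants. Occupancy is
#' (PD + PMD)/D_total for repressor-type sensors; for activators only the
#' metalated complex counts, PMD/D_total, since the metalated sensor is the
#' transcriptionally active species.
#'
#' @param sensor A \code{\link{sensor_params}}.
#' @param metal Metal name with constants in the sensor (\code{"Co"},
#'   \code{"Zn"}).
#' @param buffered_metal Buffered free-metal concentration (molar, >= 0;
#'   must be < \code{metal_total}).
#' @param cell A \code{\link{cell_context}}.
#' @param metal_total,buffer_total Buffer construction totals (molar).
#' @param response \code{"total_bound"} or \code{"metalated_bound"};
#'   defaults by regulatory mode (activators use the metalated complex).
#' @return Fractional occupancy in [0, 1].
#' @export
promoter_occupancy <- function(sensor, metal, buffered_metal,
                               cell = cell_context(),
                               metal_total = 0.01, buffer_total = 0.1,
                               response = NULL) {
  stopifnot(inherits(sensor, "sensor_params"))
  if (!is.numeric(buffered_metal) || buffered_metal < 0)
    stop("`buffered_metal` must be >= 0")
  mk <- sensor$metal_kd[[metal]]
  hk <- sensor$holo_dna_kd[[metal]]
  if (is.null(mk) || is.null(hk))
    stop(sprintf("sensor %s has no usable constants for metal %s",
                 sensor$name, metal))
  if (is.null(response))
    response <- if (sensor$mode == "activator") "metalated_bound"
                else "total_bound"
  response <- match.arg(response, c("total_bound", "metalated_bound"))
  if (sensor$abundance == 0) return(0)
  d_tot <- copies_to_concentration(sensor$dna_targets, cell)
  net <- build_sensor_network(sensor, metal, mk$kd, hk$kd, buffered_metal,
                              cell, metal_total, buffer_total)
  st <- solve_network(net)
  if (!st$converged)
    stop(sprintf("speciation solver failed for %s/%s at %.3g M buffered metal",
                 sensor$name, metal, buffered_metal))
  cc <- st$concentrations
  bound <- if (buffered_metal == 0) {
    if (response == "metalated_bound") 0 else cc[["PD"]]
  } else if (response == "metalated_bound") {
    cc[["PMD"]]
  } else {
    cc[["PD"]] + cc[["PMD"]]
  }
  min(max(bound / d_tot, 0), 1)
}

#' Occupancy response curve over a buffered-metal grid
#'
#' @inheritParams promoter_occupancy
#' @param grid Strictly increasing buffered-metal concentrations (molar).
#' @return An \code{occupancy_curve}: sensor, metal, grid, occupancy,
#'   response type, and (after \code{\link{normalise_curve}}) normalised
#'   values.
#' @export
#' @examples
#' reg <- apply_modelling_rules(load_sensor_registry())
#' rc <- response_curve(reg$RcnR, "Co", default_metal_grid(13))
response_curve <- function(sensor, metal, grid = default_metal_grid(),
                           cell = cell_context(),
                           metal_total = 0.01, buffer_total = 0.1,
                           response = NULL) {
  stopifnot(inherits(sensor, "sensor_params"))
  if (length(grid) && any(diff(grid) <= 0))
    stop("`grid` must be strictly increasing")
  occ <- vapply(grid, function(m) {
    promoter_occupancy(sensor, metal, m, cell, metal_total, buffer_total,
                       response)
  }, numeric(1))
  if (is.null(response))
    response <- if (sensor$mode == "activator") "metalated_bound"
                else "total_bound"
  structure(list(sensor = sensor$name, metal = metal, mode = sensor$mode,
                 grid = grid, occupancy = occ, normalised = NULL,
                 response = response),
            class = "occupancy_curve")
}

#' @export
print.occupancy_curve <- function(x, ...) {
  cat(sprintf("<occupancy_curve> %s / %s (%s, %s), %d points\n",
              x$sensor, x$metal, x$mode, x$response, length(x$grid)))
  if (length(x$grid))
    cat(sprintf("  occupancy range [%.4g, %.4g]%s\n", min(x$occupancy),
                max(x$occupancy),
                if (is.null(x$normalised)) "" else " (normalised)"))
  invisible(x)
}

#' Convert an occupancy curve to a data.frame
#'
#' @param x An \code{occupancy_curve}.
#' @param ... Unused.
#' @export
as.data.frame.occupancy_curve <- function(x, ...) {
  df <- data.frame(sensor = x$sensor, metal = x$metal,
                   buffered_metal_M = x$grid, occupancy = x$occupancy,
                   stringsAsFactors = FALSE)
  if (!is.null(x$normalised)) df$normalised <- x$normalised
  df
}

#' Normalise an occupancy curve to [0, 1]
#'
#' Affine rescaling by the minimum and maximum occupancy. With
#' \code{reference} curves supplied, the joint min/max across all of them is
#' used instead (shared-scale mode, used to put FrmR and FrmR^E64H on the
#' same scale so their maxima remain comparable).
#'
#' @param curve An \code{occupancy_curve}.
#' @param reference Optional list of \code{occupancy_curve}s (usually
#'   including \code{curve}) defining the joint scale.
#' @return The curve with its \code{normalised} field filled.
#' @export
normalise_curve <- function(curve, reference = NULL) {
  stopifnot(inherits(curve, "occupancy_curve"))
  if (!length(curve$grid)) stop("cannot normalise an empty curve")
  vals <- if (is.null(reference)) curve$occupancy else {
    unlist(lapply(reference, function(cv) {
      stopifnot(inherits(cv, "occupancy_curve")); cv$occupancy
    }))
  }
  lo <- min(vals); hi <- max(vals)
  if (hi - lo <= .Machine$double.eps * max(hi, 1))
    stop("degenerate curve: occupancy is constant, cannot normalise")
  curve$normalised <- (curve$occupancy - lo) / (hi - lo)
  curve
}

#' Half-response set point of a sensor
#'
#' The buffered metal concentration at which the normalised occupancy
#' crosses 0.5, interpolated linearly in log10 concentration. The curve
#' must cross 0.5 exactly once; curves are normalised on their own scale
#' first if needed.
#'
#' @param curve An \code{occupancy_curve} (normalised or not).
#' @return A list of class \code{set_point_result}: \code{sensor},
#'   \code{metal}, \code{set_point} (molar) and \code{direction}
#'   (\code{"rising"} or \code{"falling"}).
#' @export
set_point <- function(curve) {
  stopifnot(inherits(curve, "occupancy_curve"))
  if (is.null(curve$normalised)) curve <- normalise_curve(curve)
  y <- curve$normalised - 0.5
  idx <- which(y[-length(y)] * y[-1] < 0)
  hits <- which(y == 0)
  n_cross <- length(idx) + length(hits)
  if (n_cross == 0L)
    stop(sprintf("set point undefined for %s/%s: curve never crosses 0.5",
                 curve$sensor, curve$metal))
  if (n_cross > 1L)
    stop(sprintf("set point undefined for %s/%s: multiple 0.5 crossings",
                 curve$sensor, curve$metal))
  if (length(hits)) {
    sp <- curve$grid[hits]
    dir <- if (curve$normalised[length(y)] > curve$normalised[1]) "rising"
           else "falling"
  } else {
    i <- idx
    lx <- log10(curve$grid)
    sp <- 10^(lx[i] + (0 - y[i]) / (y[i + 1] - y[i]) * (lx[i + 1] - lx[i]))
    dir <- if (y[i + 1] > y[i]) "rising" else "falling"
  }
  structure(list(sensor = curve$sensor, metal = curve$metal,
                 set_point = sp, direction = dir),
            class = "set_point_result")
}

#' @export
print.set_point_result <- function(x, ...) {
  cat(sprintf("%s / %s: set point %.3g M (%s)\n", x$sensor, x$metal,
              x$set_point, x$direction))
  invisible(x)
}

#' Rank sensors by their set points and report specificity margins
#'
#' Orders a set of same-metal occupancy curves by ascending set point, the
#' order in which the sensors respond to a rising buffered metal
#' concentration. Consecutive set-point ratios are the specificity margins;
#' sensors less than twofold apart are flagged as overlapping (their
#' modelled responses are not distinguishable).
#'
#' @param curves List of \code{occupancy_curve}s sharing grid and metal.
#' @return data.frame ordered by set point: \code{rank}, \code{sensor},
#'   \code{metal}, \code{set_point_M}, \code{direction},
#'   \code{fold_vs_previous}, \code{overlaps_previous}.
#' @export
rank_sensors <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  metals <- vapply(curves, `[[`, character(1), "metal")
  if (length(unique(metals)) != 1L)
    stop("all curves must share the same metal")
  grids <- lapply(curves, `[[`, "grid")
  if (!all(vapply(grids, function(g) identical(g, grids[[1]]), logical(1))))
    stop("all curves must share the same grid")
  sps <- lapply(curves, set_point)
  df <- data.frame(
    sensor = vapply(sps, `[[`, character(1), "sensor"),
    metal = metals,
    set_point_M = vapply(sps, `[[`, numeric(1), "set_point"),
    direction = vapply(sps, `[[`, character(1), "direction"),
    stringsAsFactors = FALSE)
  df <- df[order(df$set_point_M), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$fold_vs_previous <- c(NA, df$set_point_M[-1] /
                             df$set_point_M[-nrow(df)])
  df$overlaps_previous <- !is.na(df$fold_vs_previous) &
    df$fold_vs_previous < 2
  rownames(df) <- NULL
  df[, c("rank", "sensor", "metal", "set_point_M", "direction",
         "fold_vs_previous", "overlaps_previous")]
}
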