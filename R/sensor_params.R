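#' Affinity constant with bound flag and uncertainty
#'
#' Dissociation constants in the sensor registry are sometimes only bounds
#' (e.g. the apo-Zur DNA affinity is a lower bound on Kd, printed ">=").
#' The flag is carried through reporting but the value itself is used as a
#' point estimate in downstream computation.
#'
#' @param kd Dissociation constant in molar; must be positive.
#' @param bound One of \code{"exact"}, \code{"lower"} (true Kd >= value) or
#'   \code{"upper"} (true Kd <= value).
#' @param sd Optional standard deviation in molar.
#' @return An object of class \code{affinity_constant}.
#' @export
affinity_constant <- function(kd, bound = "exact", sd = NULL) {
  if (!is.numeric(kd) || length(kd) != 1L || !is.finite(kd) || kd <= 0)
    stop("`kd` must be a single positive finite number (molar)")
  bound <- match.arg(bound, c("exact", "lower", "upper"))
  if (!is.null(sd)) {
    if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
      stop("`sd` must be a single non-negative number (molar)")
  }
  structure(list(kd = kd, bound = bound, sd = sd),
            class = "affinity_constant")
}

#' @export
print.affinity_constant <- function(x, ...) {
  pfx <- switch(x$bound, exact = "", lower = ">= ", upper = "<= ")
  sd <- if (!is.null(x$sd)) sprintf(" (+/- %.2g)", x$sd) else ""
  cat(sprintf("Kd = %s%.3g%s M\n", pfx, x$kd, sd))
  invisible(x)
}

# Accept either an affinity_constant or a bare positive number.
as_kd <- function(x, what = "Kd") {
  if (inherits(x, "affinity_constant")) return(x$kd)
  if (is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0) return(x)
  stop(sprintf("%s must be a positive number or an affinity_constant", what))
}

kd_bound <- function(x) {
  if (inherits(x, "affinity_constant")) x$bound else "exact"
}

#' Full thermodynamic description of one metal sensor
#'
#' Bundles everything the occupancy model needs for one sensor: its
#' functional assembly (the non-dissociable unit that binds DNA), cellular
#' abundance in assemblies per cell, number of operator-promoter targets per
#' cell, regulatory mode, metal dissociation constants (1/K1 side), the
#' apo-sensor DNA dissociation constant (1/K3 side) and the metalated-sensor
#' DNA dissociation constants per metal (1/K4 side).
#'
#' @param name Sensor identifier, e.g. \code{"RcnR"}.
#' @param assembly \code{"dimer"} or \code{"tetramer"}.
#' @param abundance Assemblies per cell (non-negative).
#' @param abundance_sd Optional standard deviation of \code{abundance}.
#' @param dna_targets Operator-promoter copies per cell (>= 1).
#' @param mode \code{"co_repressor"}, \code{"de_repressor"} or
#'   \code{"activator"}.
#' @param metal_kd Named list of \code{\link{affinity_constant}}s, metal ->
#'   combined metal dissociation constant. Entries may be \code{NULL} when a
#'   DNA affinity exists for a metal-loading state whose metal affinity was
#'   not determined (such entries are excluded from occupancy modelling).
#' @param apo_dna_kd \code{\link{affinity_constant}} for the apo sensor.
#' @param holo_dna_kd Named list of \code{\link{affinity_constant}}s (or
#'   \code{NULL} where not determined), metal -> metalated-sensor DNA
#'   dissociation constant.
#' @return An object of class \code{sensor_params}.
#' @export
sensor_params <- function(name, assembly, abundance, dna_targets, mode,
                          metal_kd, apo_dna_kd, holo_dna_kd,
                          abundance_sd = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string")
  assembly <- match.arg(assembly, c("dimer", "tetramer"))
  mode <- match.arg(mode, c("co_repressor", "de_repressor", "activator"))
  if (!is.numeric(abundance) || abundance < 0)
    stop(sprintf("sensor %s: `abundance` must be >= 0", name))
  if (!is.numeric(dna_targets) || dna_targets < 1)
    stop(sprintf("sensor %s: `dna_targets` must be >= 1", name))
  if (!inherits(apo_dna_kd, "affinity_constant"))
    stop(sprintf("sensor %s: `apo_dna_kd` must be an affinity_constant", name))
  stopifnot(is.list(metal_kd), is.list(holo_dna_kd))
  for (m in names(holo_dna_kd)) {
    h <- holo_dna_kd[[m]]
    if (!is.null(h) && !inherits(h, "affinity_constant"))
      stop(sprintf("sensor %s: holo_dna_kd[%s] invalid", name, m))
  }
  for (m in names(metal_kd)) {
    k <- metal_kd[[m]]
    if (!is.null(k) && !inherits(k, "affinity_constant"))
      stop(sprintf("sensor %s: metal_kd[%s] invalid", name, m))
  }
  structure(list(name = name, assembly = assembly,
                 abundance = abundance, abundance_sd = abundance_sd,
                 dna_targets = dna_targets, mode = mode,
                 metal_kd = metal_kd, apo_dna_kd = apo_dna_kd,
                 holo_dna_kd = holo_dna_kd),
            class = "sensor_params")
}

#' @export
print.sensor_params <- function(x, ...) {
  cat(sprintf("<sensor_params> %s (%s, %s)\n", x$name, x$assembly, x$mode))
  cat(sprintf("  abundance: %g assemblies/cell; DNA targets: %g/cell\n",
              x$abundance, x$dna_targets))
  cat(sprintf("  apo DNA Kd: %s%.3g M\n",
              switch(x$apo_dna_kd$bound, exact = "", lower = ">= ",
                     upper = "<= "), x$apo_dna_kd$kd))
  for (m in union(names(x$metal_kd), names(x$holo_dna_kd))) {
    mk <- x$metal_kd[[m]]
    hk <- x$holo_dna_kd[[m]]
    cat(sprintf("  %s: metal Kd %s; holo DNA Kd %s\n", m,
                if (is.null(mk)) "n.a." else sprintf("%.3g M", mk$kd),
                if (is.null(hk)) "n.d." else sprintf("%.3g M", hk$kd)))
  }
  invisible(x)
}

parse_affinity <- function(x, sensor, field) {
  if (is.null(x)) return(NULL)
  if (is.null(x$kd_M))
    stop(sprintf("sensor %s: field %s is missing kd_M", sensor, field))
  kd <- x$kd_M
  if (!is.numeric(kd) || kd <= 0)
    stop(sprintf("sensor %s: field %s has non-positive Kd", sensor, field))
  affinity_constant(kd, bound = if (is.null(x$bound)) "exact" else x$bound,
                    sd = x$sd_M)
}

#' Load a sensor parameter registry from JSON
#'
#' The registry is a JSON array with one object per sensor holding the
#' fields of \code{\link{sensor_params}}; affinities are serialised as
#' \code{{"kd_M": <molar>, "bound": "exact|lower|upper", "sd_M": <molar>|null}}.
#' The packaged registry (\code{system.file("extdata",
#' "sensor_registry.json", package = "metalsens")}) holds the measured
#' constants for Zur, ZntR, RcnR, FrmR and FrmR^E64H.
#'
#' @param source Path to the registry JSON file. Defaults to the packaged
#'   registry.
#' @return A named list of \code{\link{sensor_params}} objects.
#' @export
#' @examples
#' reg <- load_sensor_registry()
#' reg$RcnR$metal_kd$Co$kd   # 5.1e-10 M
load_sensor_registry <- function(source = system.file(
    "extdata", "sensor_registry.json", package = "metalsens")) {
  if (!file.exists(source))
    stop(sprintf("registry file not found: %s", source))
  raw <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  if (!is.list(raw) || length(raw) == 0L)
    stop("registry file is empty or not a JSON array of sensor objects")
  sensors <- lapply(raw, function(s) {
    for (f in c("name", "assembly", "abundance", "dna_targets", "mode",
                "apo_dna_kd", "metals")) {
      if (is.null(s[[f]]))
        stop(sprintf("sensor %s: required field `%s` missing",
                     if (is.null(s$name)) "<unnamed>" else s$name, f))
    }
    metal_kd <- list(); holo <- list()
    for (m in names(s$metals)) {
      e <- s$metals[[m]]
      metal_kd[[m]] <- parse_affinity(e$metal_kd, s$name,
                                      paste0("metals.", m, ".metal_kd"))
      h <- parse_affinity(e$holo_dna_kd, s$name,
                          paste0("metals.", m, ".holo_dna_kd"))
      if (!is.null(h)) holo[[m]] <- h
    }
    sensor_params(
      name = s$name, assembly = s$assembly,
      abundance = s$abundance$count, abundance_sd = s$abundance$sd,
      dna_targets = s$dna_targets, mode = s$mode,
      metal_kd = metal_kd,
      apo_dna_kd = parse_affinity(s$apo_dna_kd, s$name, "apo_dna_kd"),
      holo_dna_kd = holo)
  })
  names(sensors) <- vapply(sensors, `[[`, character(1), "name")
  sensors
}

#' Allosteric coupling free energy between metal and DNA binding
#'
#' DeltaG_C = RT ln(Kd_holo / Kd_apo), the free energy linking metal
#' binding to DNA binding. Negative values mean the metal tightens DNA
#' binding (co-repression, as for Zur); positive values mean the metal
#' weakens it (de-repression, as for RcnR and FrmR).
#'
#' Bound flags propagate: if the apo Kd is a lower bound (true value could
#' be weaker still), the computed coupling energy is an upper bound, and
#' vice versa; the flag is attached as attribute \code{"bound"}.
#'
#' @param apo_dna_kd Apo-sensor DNA dissociation constant (molar), a number
#'   or \code{\link{affinity_constant}}.
#' @param holo_dna_kd Metalated-sensor DNA dissociation constant, likewise.
#' @param temperature Kelvin; default 298.15.
#' @return Coupling free energy in kcal mol^-1 (numeric scalar, with a
#'   \code{"bound"} attribute of \code{"exact"}, \code{"upper"} or
#'   \code{"lower"}).
#' @export
#' @examples
#' coupling_free_energy(2.7e-5, 5.4e-8)   # ~ -3.7 kcal/mol, Zn(II)-Zur
coupling_free_energy <- function(apo_dna_kd, holo_dna_kd,
                                 temperature = 298.15) {
  ka <- as_kd(apo_dna_kd, "apo_dna_kd")
  kh <- as_kd(holo_dna_kd, "holo_dna_kd")
  if (!is.numeric(temperature) || temperature <= 0)
    stop("`temperature` must be positive (kelvin)")
  dg <- RGAS_KCAL * temperature * log(kh / ka)
  ba <- kd_bound(apo_dna_kd); bh <- kd_bound(holo_dna_kd)
  # apo is a lower bound on Kd => ratio (holo/apo) is an upper bound => dG <=
  bound <- if (ba == "lower" || bh == "upper") {
    if (bh == "lower" || ba == "upper") "exact" else "upper"
  } else if (bh == "lower" || ba == "upper") "lower" else "exact"
  attr(dg, "bound") <- bound
  dg
}

#' Average of dissociation constants
#'
#' Arithmetic mean, used where the standard deviations of the Co(II)- and
#' Zn(II)-sensor DNA affinities overlap and a single combined 1/K4 value is
#' carried into the occupancy model.
#'
#' @param kds Numeric vector (or list of \code{\link{affinity_constant}}s)
#'   of positive dissociation constants in molar.
#' @return The arithmetic mean (molar).
#' @export
#' @examples
#' average_affinity(c(3.1e-8, 4.1e-8))   # 3.6e-8, Zur
average_affinity <- function(kds) {
  if (is.list(kds)) kds <- vapply(kds, as_kd, numeric(1))
  if (length(kds) == 0L) stop("`kds` must contain at least one value")
  if (!is.numeric(kds) || any(!is.finite(kds)) || any(kds <= 0))
    stop("all dissociation constants must be positive and finite")
  mean(kds)
}

#' Estimate a missing metalated-sensor DNA affinity by a fold-ratio rule
#'
#' Where a weak metal affinity precluded direct measurement of a
#' metalated-sensor DNA affinity (Co(II)-FrmR), the value is estimated from
#' the same sensor's affinity for the other metal scaled by the
#' fold-difference observed in a related variant:
#' \code{base_kd * ratio_numerator_kd / ratio_denominator_kd}.
#'
#' @param base_kd Known DNA Kd to scale (molar), e.g. Zn(II)-FrmR.
#' @param ratio_numerator_kd,ratio_denominator_kd The Kd pair whose ratio
#'   supplies the fold-difference, e.g. Co(II)- and Zn(II)-FrmR^E64H.
#' @return Estimated dissociation constant (molar).
#' @export
#' @examples
#' estimate_missing_holo_dna_kd(3.1e-6, 2.3e-6, 3.5e-6)  # ~2.0e-6 M
estimate_missing_holo_dna_kd <- function(base_kd, ratio_numerator_kd,
                                         ratio_denominator_kd) {
  b <- as_kd(base_kd, "base_kd")
  n <- as_kd(ratio_numerator_kd, "ratio_numerator_kd")
  d <- as_kd(ratio_denominator_kd, "ratio_denominator_kd")
  b * n / d
}

#' Table of coupling free energies for a sensor registry
#'
#' Recomputes DeltaG_C for every sensor/metal pair with both an apo- and a
#' metalated-sensor DNA affinity.
#'
#' @param registry A list of \code{\link{sensor_params}} from
#'   \code{\link{load_sensor_registry}}.
#' @param temperature Kelvin; default 298.15.
#' @return data.frame with columns \code{sensor}, \code{metal},
#'   \code{apo_kd_M}, \code{holo_kd_M}, \code{dG_kcal}, \code{bound}.
#' @export
coupling_energy_table <- function(registry, temperature = 298.15) {
  rows <- list()
  for (s in registry) {
    for (m in names(s$holo_dna_kd)) {
      dg <- coupling_free_energy(s$apo_dna_kd, s$holo_dna_kd[[m]],
                                 temperature)
      rows[[length(rows) + 1L]] <- data.frame(
        sensor = s$name, metal = m,
        apo_kd_M = s$apo_dna_kd$kd, holo_kd_M = s$holo_dna_kd[[m]]$kd,
        dG_kcal = as.numeric(dg), bound = attr(dg, "bound"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Apply the parameter-combination rules used for occupancy modelling
#'
#' Transforms a raw registry (measured constants) into the parameter set the
#' occupancy model consumes:
#' \itemize{
#'   \item Zur and RcnR metalated-DNA affinities are replaced by the
#'     across-metal averages (3.6e-8 and 1.4e-5 M respectively from the
#'     packaged registry), because their Co(II) and Zn(II) values agree
#'     within error.
#'   \item The undetermined Co(II)-FrmR DNA affinity is estimated from
#'     Zn(II)-FrmR and the Co/Zn fold-difference of FrmR^E64H
#'     (\code{\link{estimate_missing_holo_dna_kd}}), giving ~2.0e-6 M.
#'   \item ZntR is controlled by \code{zntr_k4}: \code{"per_metal"}
#'     (default) keeps the per-metal values; \code{"printed_average"} uses
#'     4.7e-7 M; \code{"computed_average"} averages the per-metal values.
#' }
#' Entries without a metal affinity (e.g. the four-Zn(II) Zur DNA affinity,
#' retained only for the coupling-energy table) are dropped from occupancy
#' modelling.
#'
#' @param registry Output of \code{\link{load_sensor_registry}}.
#' @param zntr_k4 See above.
#' @return A registry (named list of \code{\link{sensor_params}}) ready for
#'   \code{\link{response_curve}}.
#' @export
apply_modelling_rules <- function(registry,
                                  zntr_k4 = c("per_metal", "printed_average",
                                              "computed_average")) {
  zntr_k4 <- match.arg(zntr_k4)
  out <- registry

  avg_pair <- function(s) {
    k <- average_affinity(list(s$holo_dna_kd$Co, s$holo_dna_kd$Zn))
    s$holo_dna_kd$Co <- affinity_constant(k, bound = s$holo_dna_kd$Co$bound)
    s$holo_dna_kd$Zn <- affinity_constant(k, bound = s$holo_dna_kd$Zn$bound)
    s
  }
  if (!is.null(out$Zur)) out$Zur <- avg_pair(out$Zur)
  if (!is.null(out$RcnR)) out$RcnR <- avg_pair(out$RcnR)

  if (!is.null(out$ZntR)) {
    if (zntr_k4 == "printed_average") {
      out$ZntR$holo_dna_kd$Co <- affinity_constant(4.7e-7)
      out$ZntR$holo_dna_kd$Zn <- affinity_constant(4.7e-7)
    } else if (zntr_k4 == "computed_average") {
      out$ZntR <- avg_pair(out$ZntR)
    }
  }

  if (!is.null(out$FrmR) && is.null(out$FrmR$holo_dna_kd$Co) &&
      !is.null(out$`FrmR_E64H`)) {
    est <- estimate_missing_holo_dna_kd(
      out$FrmR$holo_dna_kd$Zn,
      out$`FrmR_E64H`$holo_dna_kd$Co,
      out$`FrmR_E64H`$holo_dna_kd$Zn)
    out$FrmR$holo_dna_kd$Co <- affinity_constant(est)
  }

  # drop DNA-affinity entries with no matching metal affinity (not modellable)
  for (nm in names(out)) {
    keep <- names(out[[nm]]$holo_dna_kd)[
      !vapply(out[[nm]]$metal_kd[names(out[[nm]]$holo_dna_kd)], is.null,
              logical(1))]
    out[[nm]]$holo_dna_kd <- out[[nm]]$holo_dna_kd[keep]
  }
  out
}
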