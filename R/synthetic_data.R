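#' Noise specification for synthetic titrations
#'
#' @param kind \code{"relative_gaussian"} (level is a fraction of the
#'   noise-free signal) or \code{"absolute_gaussian"} (level in signal
#'   units).
#' @param level Noise level (>= 0). Default 0.01 (1 percent relative), a
#'   realistic scatter for equilibrium optical titrations.
#' @param seed Integer seed; every generator is bit-reproducible for a
#'   fixed seed.
#' @return An object of class \code{noise_spec}.
#' @export
noise_spec <- function(kind = c("relative_gaussian", "absolute_gaussian"),
                       level = 0.01, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(level) || level < 0) stop("`level` must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1L) stop("`seed` must be scalar")
  structure(list(kind = kind, level = level, seed = as.integer(seed)),
            class = "noise_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

apply_noise <- function(signal, noise) {
  if (noise$level == 0) return(signal)
  with_seed(noise$seed, {
    eps <- stats::rnorm(length(signal))
    if (noise$kind == "relative_gaussian") signal * (1 + noise$level * eps)
    else signal + noise$level * eps
  })
}

#' Generate a seeded synthetic chelator-competition dataset
#'
#' Simulates the exact-speciation competition curve over a metal grid from
#' zero to 1.2 x (probe + protein site) totals and adds seeded Gaussian
#' noise. The generating truth is recorded in the curve's \code{meta}.
#'
#' @param design A \code{\link{competition_model}}.
#' @param truth_kd True protein metal Kd (molar).
#' @param n_points Number of titration points (>= 6); default 24.
#' @param noise A \code{\link{noise_spec}}.
#' @return A \code{\link{titration_curve}} with
#'   \code{meta = list(model, truth_kd, noise)}.
#' @export
generate_competition_dataset <- function(design, truth_kd, n_points = 24L,
                                         noise = noise_spec()) {
  stopifnot(inherits(design, "competition_model"),
            inherits(noise, "noise_spec"))
  if (!is.numeric(n_points) || n_points < 6)
    stop("`n_points` must be >= 6")
  top <- 1.2 * (design$probe_total +
                  design$protein_total * design$equivalents)
  grid <- seq(0, top, length.out = n_points)
  clean <- simulate_competition(design, truth_kd, grid)
  titration_curve(grid, apply_noise(clean$signal, noise),
                  titrant = "metal",
                  meta = list(model = design, truth_kd = truth_kd,
                              noise = noise))
}

#' Generate a seeded synthetic anisotropy dataset
#'
#' Protein grid is log-spaced (monomer basis) from Kd/100 to 100 x Kd
#' around the assembly-basis truth, with a zero-protein baseline point.
#'
#' @param design A \code{\link{dna_binding_model}}.
#' @param truth_kd True per-event DNA Kd (molar, assembly basis).
#' @param n_points Number of points (>= 6); default 24.
#' @param noise A \code{\link{noise_spec}}.
#' @return A \code{\link{titration_curve}} with truth in \code{meta}.
#' @export
generate_anisotropy_dataset <- function(design, truth_kd, n_points = 24L,
                                        noise = noise_spec()) {
  stopifnot(inherits(design, "dna_binding_model"),
            inherits(noise, "noise_spec"))
  if (!is.numeric(n_points) || n_points < 6)
    stop("`n_points` must be >= 6")
  centre <- truth_kd * design$assembly_size   # monomer basis
  grid <- c(0, 10^seq(log10(centre) - 2, log10(centre) + 2,
                      length.out = n_points - 1L))
  clean <- simulate_anisotropy(design, truth_kd, grid)
  titration_curve(grid, apply_noise(clean$signal, noise),
                  titrant = "protein",
                  meta = list(model = design, truth_kd = truth_kd,
                              noise = noise))
}

#' Packaged chelator-competition experimental designs
#'
#' The competition experiments from which the sensors' metal affinities
#' were determined, with probe and protein concentrations as performed and
#' the determined affinity as \code{truth_kd}:
#' \itemize{
#'   \item \code{fura2_zntr}: fura-2 (15.4 uM) vs ZntR (9.8 uM, 1 Co(II)
#'     equivalent per monomer), Kd 9.5e-8 M.
#'   \item \code{fura2_zur}: fura-2 (14.6 uM) vs Zur (9.8 uM, 2
#'     equivalents), Kd 1.5e-8 M.
#'   \item \code{egta_zur}: EGTA (50 uM) vs Zur (52 uM, 2 equivalents),
#'     protein-complex absorbance readout, Kd 1.5e-8 M.
#'   \item \code{quin2_rcnr}: quin-2 (18.0 uM) vs RcnR (14.9 uM, 1 Zn(II)
#'     equivalent), Kd 9.4e-12 M.
#'   \item \code{magfura2_rcnr}: magfura-2 (22.6 uM) vs RcnR (16.9 uM).
#'     With RcnR ~2000-fold tighter than the probe this design only bounds
#'     the affinity (the protein withholds a full equivalent regardless of
#'     the exact Kd), so it is flagged \code{identifiable = FALSE} and used
#'     for simulation and envelopes, not quantitative recovery.
#' }
#'
#' @return Named list; each element has \code{model} (a
#'   \code{\link{competition_model}}), \code{truth_kd} (molar) and
#'   \code{identifiable}.
#' @export
competition_designs <- function() {
  list(
    fura2_zntr = list(
      model = competition_model("fura-2", 8.64e-9, 15.4e-6, 9.8e-6,
                                equivalents = 1),
      truth_kd = 9.5e-8, identifiable = TRUE),
    fura2_zur = list(
      model = competition_model("fura-2", 8.64e-9, 14.6e-6, 9.8e-6,
                                equivalents = 2),
      truth_kd = 1.5e-8, identifiable = TRUE),
    egta_zur = list(
      model = competition_model("EGTA", 7.89e-9, 50e-6, 52e-6,
                                equivalents = 2,
                                signal_source = "protein_metal_complex",
                                signal_direction = "increasing"),
      truth_kd = 1.5e-8, identifiable = TRUE),
    quin2_rcnr = list(
      model = competition_model("quin-2", 3.7e-12, 18.0e-6, 14.9e-6,
                                equivalents = 1),
      truth_kd = 9.4e-12, identifiable = TRUE),
    magfura2_rcnr = list(
      model = competition_model("magfura-2", 2e-8, 22.6e-6, 16.9e-6,
                                equivalents = 1),
      truth_kd = 9.4e-12, identifiable = FALSE))
}

#' Packaged fluorescence-anisotropy experimental designs
#'
#' \itemize{
#'   \item \code{zur_znua}: two Zur dimers binding the znuA
#'     operator-promoter sequentially (10 nM DNA), Kd 5.4e-8 M.
#'   \item \code{zntr_znta}: one ZntR dimer on the zntA operator-promoter
#'     (10 nM DNA), delta_r fixed at 0.025, fitted range truncated at
#'     1500 nM monomer (above which ternary complexes form), Kd 1.1e-6 M.
#'   \item \code{rcnr_rcna}: two RcnR tetramers on the rcnA
#'     operator-promoter (10 nM DNA), Zn(II)-RcnR Kd 1.3e-5 M.
#' }
#'
#' @return Named list; each element has \code{model}, \code{truth_kd} and
#'   optionally \code{max_titrant}.
#' @export
anisotropy_designs <- function() {
  list(
    zur_znua = list(
      model = dna_binding_model("two_sequential_assemblies_per_dna",
                                dna_total = 10e-9, assembly_size = 2),
      truth_kd = 5.4e-8),
    zntr_znta = list(
      model = dna_binding_model("one_assembly_per_dna", dna_total = 10e-9,
                                assembly_size = 2,
                                delta_r_per_event = 0.025,
                                fit_delta_r = FALSE),
      truth_kd = 1.1e-6, max_titrant = 1500e-9),
    rcnr_rcna = list(
      model = dna_binding_model("two_sequential_assemblies_per_dna",
                                dna_total = 10e-9, assembly_size = 4),
      truth_kd = 1.3e-5))
}

#' Write the packaged fixture set to a directory
#'
#' Copies the sensor registry, writes the chelator constant records, and
#' generates one seeded example dataset per experimental design (CSV with a
#' JSON truth sidecar).
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the example datasets.
#' @return Invisibly, the vector of files written.
#' @export
packaged_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  reg_src <- system.file("extdata", "sensor_registry.json",
                         package = "metalsens")
  reg_dst <- file.path(dir, "sensor_registry.json")
  file.copy(reg_src, reg_dst, overwrite = TRUE)
  written <- c(written, reg_dst)

  chel <- file.path(dir, "chelator_constants.csv")
  utils::write.csv(chelator_constants(), chel, row.names = FALSE)
  written <- c(written, chel)

  dump_curve <- function(curve, stem, truth) {
    csv <- file.path(dir, paste0(stem, ".csv"))
    df <- as.data.frame(curve)
    utils::write.csv(df, csv, row.names = FALSE)
    side <- file.path(dir, paste0(stem, "_truth.json"))
    jsonlite::write_json(list(design = stem, truth_kd_M = truth,
                              seed = seed),
                         side, auto_unbox = TRUE, digits = NA)
    c(csv, side)
  }
  i <- 0L
  for (nm in names(competition_designs())) {
    d <- competition_designs()[[nm]]
    i <- i + 1L
    cv <- generate_competition_dataset(d$model, d$truth_kd,
                                       noise = noise_spec(seed = seed + i))
    written <- c(written, dump_curve(cv, paste0("competition_", nm),
                                     d$truth_kd))
  }
  for (nm in names(anisotropy_designs())) {
    d <- anisotropy_designs()[[nm]]
    i <- i + 1L
    cv <- generate_anisotropy_dataset(d$model, d$truth_kd,
                                      noise = noise_spec(seed = seed + i))
    written <- c(written, dump_curve(cv, paste0("anisotropy_", nm),
                                     d$truth_kd))
  }
  invisible(written)
}
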