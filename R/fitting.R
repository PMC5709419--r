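# Titration fitting: bounded 1-D least squares on log10(Kd) with the
# nuisance signal parameters profiled out linearly at each candidate Kd.
# The affine structure of the signal model makes the profile exact, so the
# optimisation is one-dimensional and robust; multi-start guards against
# the flat shoulders of weakly identifiable designs.

profile_ssr <- function(y, x, design_extra = NULL) {
  # least squares of y on [1, x] (or [1] with x fixed already in y)
  X <- cbind(1, x)
  fit <- stats::lm.fit(X, y)
  list(ssr = sum(fit$residuals^2), coef = fit$coefficients,
       fitted = fit$fitted.values)
}

optimise_log_kd <- function(ssr_fun, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, ssr_fun, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 1e4))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish with golden-section around the best point
  w <- 0.5
  o2 <- stats::optimize(ssr_fun, lower = max(lower, best$par - w),
                        upper = min(upper, best$par + w), tol = 1e-10)
  if (o2$objective < best$value) list(par = o2$minimum, value = o2$objective)
  else list(par = best$par, value = best$value)
}

kd_sd_from_curvature <- function(ssr_fun, log_kd, ssr, n, n_par) {
  # local quadratic model of the residual surface in log10(Kd)
  h <- 0.05
  d2 <- (ssr_fun(log_kd + h) - 2 * ssr + ssr_fun(log_kd - h)) / h^2
  if (!is.finite(d2) || d2 <= 0) return(NA_real_)
  sigma2 <- ssr / max(n - n_par, 1)
  sd_log <- sqrt(2 * sigma2 / d2)
  10^log_kd * log(10) * sd_log   # delta method back to molar
}

fit_result <- function(kd, kd_sd, residual_rms, converged, envelope = NULL,
                       fitted = NULL, signal_coef = NULL, log_kd = NA) {
  structure(list(kd = kd, kd_sd = kd_sd, residual_rms = residual_rms,
                 converged = converged, envelope = envelope,
                 fitted = fitted, signal_coef = signal_coef,
                 log_kd = log_kd),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<fit_result> Kd = %.3g M", x$kd))
    if (is.finite(x$kd_sd)) cat(sprintf(" (+/- %.2g)", x$kd_sd))
    cat(sprintf(", residual RMS %.3g\n", x$residual_rms))
  } else {
    cat("<fit_result> not converged (Kd not identifiable from these data)\n")
  }
  invisible(x)
}

#' Fit a protein metal affinity from a chelator-competition titration
#'
#' Least-squares estimate of the protein's metal dissociation constant,
#' with the exact-speciation forward model of
#' \code{\link{simulate_competition}} and the two affine signal parameters
#' profiled out. The fit is bounded on log10(Kd), multi-started from
#' probe_kd x {1e-2, 1, 1e2}, and reports tenfold tighter/weaker envelope
#' curves (the dashed-line convention of the competition figures).
#'
#' @param curve A \code{\link{titration_curve}} (metal titrant).
#' @param model The \code{\link{competition_model}} describing the design.
#' @param lower,upper Bounds on Kd (molar); default probe_kd x 1e-5 and
#'   probe_kd x 1e5.
#' @return A \code{fit_result}: \code{kd}, \code{kd_sd} (local curvature),
#'   \code{residual_rms}, \code{converged}, \code{envelope} (curves at
#'   Kd/10 and Kd x 10) and the fitted signal.
#' @export
fit_metal_affinity <- function(curve, model, lower = model$probe_kd * 1e-5,
                               upper = model$probe_kd * 1e5) {
  stopifnot(inherits(curve, "titration_curve"),
            inherits(model, "competition_model"))
  y <- curve$signal
  mt <- curve$titrant_total
  if (length(y) < 6L)
    stop("at least 6 titration points are required")
  if (stats::sd(y) == 0)
    return(fit_result(NA_real_, NA_real_, 0, FALSE))

  ssr_of <- function(lk) {
    cx <- competition_complex(model, 10^lk, mt)
    profile_ssr(y, cx)$ssr
  }
  llo <- log10(lower); lhi <- log10(upper)
  starts <- log10(model$probe_kd) + c(-2, 0, 2)
  starts <- pmin(pmax(starts, llo), lhi)
  opt <- optimise_log_kd(ssr_of, starts, llo, lhi)

  kd <- 10^opt$par
  cx <- competition_complex(model, kd, mt)
  pr <- profile_ssr(y, cx)
  rms <- sqrt(pr$ssr / length(y))

  # identifiability: the fit must beat the protein-free null and sit away
  # from the bounds with positive curvature
  null_ssr <- profile_ssr(y, competition_complex(
    competition_model(model$probe, model$probe_kd, model$probe_total,
                      0, model$equivalents, model$signal_source,
                      model$signal_direction), model$probe_kd, mt))$ssr
  at_bound <- opt$par - llo < 0.05 || lhi - opt$par < 0.05
  kd_sd <- kd_sd_from_curvature(ssr_of, opt$par, pr$ssr, length(y), 3)
  converged <- !at_bound && is.finite(kd_sd) &&
    (model$protein_total == 0 || pr$ssr < null_ssr * (1 - 1e-6) ||
       pr$ssr < 1e-20)
  if (!converged)
    return(fit_result(NA_real_, NA_real_, rms, FALSE))

  # envelope uses the fitted affine map directly
  env_curve <- function(kfac) {
    cxe <- competition_complex(model, kd * kfac, mt)
    titration_curve(mt, pr$coef[1] + pr$coef[2] * cxe, titrant = "metal",
                    meta = model)
  }
  env <- list(tighter = env_curve(0.1), weaker = env_curve(10))
  fit_result(kd, kd_sd, rms, TRUE, envelope = env,
             fitted = pr$fitted, signal_coef = pr$coef, log_kd = opt$par)
}

#' Fit a DNA affinity from a fluorescence-anisotropy titration
#'
#' Least-squares estimate of the per-event DNA dissociation constant under
#' the model's stoichiometry. When \code{model$fit_delta_r} is TRUE the
#' baseline and anisotropy change per event are both profiled out; when
#' FALSE (the ZntR convention, delta_r fixed at 0.025) only the baseline
#' is. Points above \code{max_titrant} can be excluded, mirroring fits
#' truncated below the onset of ternary-complex formation.
#'
#' @param curve A \code{\link{titration_curve}} (protein titrant, monomer
#'   basis).
#' @param model The \code{\link{dna_binding_model}}.
#' @param max_titrant Optional truncation of the fitted range (molar,
#'   monomer basis).
#' @param lower,upper Bounds on Kd (molar); defaults 1e-12 and 1e-2.
#' @return A \code{fit_result} (envelope at Kd/10 and Kd x 10).
#' @export
fit_dna_affinity <- function(curve, model, max_titrant = NULL,
                             lower = 1e-12, upper = 1e-2) {
  stopifnot(inherits(curve, "titration_curve"),
            inherits(model, "dna_binding_model"))
  keep <- if (is.null(max_titrant)) seq_along(curve$titrant_total)
          else which(curve$titrant_total <= max_titrant)
  y <- curve$signal[keep]
  pt <- curve$titrant_total[keep]
  if (length(y) < 6L)
    stop("at least 6 titration points are required (after truncation)")
  if (stats::sd(y) == 0)
    return(fit_result(NA_real_, NA_real_, 0, FALSE))

  n_events <- if (model$stoichiometry == "one_assembly_per_dna") 1 else 2
  ssr_of <- function(lk) {
    b <- anisotropy_bound(model, 10^lk, pt)
    if (model$fit_delta_r) {
      profile_ssr(y, b)$ssr
    } else {
      r0 <- mean(y - model$delta_r_per_event * b)
      sum((y - r0 - model$delta_r_per_event * b)^2)
    }
  }
  llo <- log10(lower); lhi <- log10(upper)
  start0 <- log10(model$dna_total * n_events)
  starts <- pmin(pmax(start0 + c(-2, 0, 2), llo), lhi)
  opt <- optimise_log_kd(ssr_of, starts, llo, lhi)

  kd <- 10^opt$par
  b <- anisotropy_bound(model, kd, pt)
  if (model$fit_delta_r) {
    pr <- profile_ssr(y, b)
    coef <- pr$coef; ssr <- pr$ssr; fitted <- pr$fitted; n_par <- 3
  } else {
    r0 <- mean(y - model$delta_r_per_event * b)
    fitted <- r0 + model$delta_r_per_event * b
    ssr <- sum((y - fitted)^2)
    coef <- c(r0, model$delta_r_per_event); n_par <- 2
  }
  rms <- sqrt(ssr / length(y))
  at_bound <- opt$par - llo < 0.05 || lhi - opt$par < 0.05
  kd_sd <- kd_sd_from_curvature(ssr_of, opt$par, ssr, length(y), n_par)
  if (at_bound || !is.finite(kd_sd))
    return(fit_result(NA_real_, NA_real_, rms, FALSE))

  env_curve <- function(kfac) {
    be <- anisotropy_bound(model, kd * kfac, pt)
    titration_curve(pt, coef[1] + coef[2] * be, titrant = "protein",
                    meta = model)
  }
  fit_result(kd, kd_sd, rms, TRUE,
             envelope = list(tighter = env_curve(0.1),
                             weaker = env_curve(10)),
             fitted = fitted, signal_coef = coef, log_kd = opt$par)
}
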