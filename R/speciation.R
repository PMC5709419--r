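#' Binding reaction A + B <-> AB
#'
#' One association step of a binding-equilibrium network. Reactants may be
#' base species (which carry total concentrations) or complexes produced by
#' earlier reactions; the product must be unique in the network.
#'
#' @param reactants Character vector of exactly two species names.
#' @param product Name of the complex formed.
#' @param k_assoc Association constant in M^-1 (>= 0; zero short-circuits
#'   to "no binding").
#' @return An object of class \code{reaction}.
#' @export
reaction <- function(reactants, product, k_assoc) {
  if (!is.character(reactants) || length(reactants) != 2L)
    stop("`reactants` must be two species names")
  if (!is.character(product) || length(product) != 1L || !nzchar(product))
    stop("`product` must be a single species name")
  if (product %in% reactants)
    stop("`product` may not be one of its own reactants")
  if (!is.numeric(k_assoc) || length(k_assoc) != 1L || !is.finite(k_assoc) ||
      k_assoc < 0)
    stop("`k_assoc` must be a single finite number >= 0 (per molar)")
  structure(list(reactants = reactants, product = product,
                 k_assoc = k_assoc), class = "reaction")
}

#' Binding-equilibrium network under total-concentration mass balances
#'
#' A set of association reactions together with total concentrations for the
#' base species. Every reactant must be either a base species (with a total)
#' or the product of another reaction, and the product dependency graph must
#' be acyclic.
#'
#' @param reactions List of \code{\link{reaction}} objects.
#' @param totals Named numeric vector, base species -> total concentration
#'   (molar, >= 0).
#' @return An object of class \code{reaction_network} (with the topological
#'   complex order, per-complex base-species stoichiometries and mass-action
#'   coefficients precomputed).
#' @export
#' @examples
#' net <- reaction_network(
#'   list(reaction(c("M", "B"), "MB", 10)),
#'   c(M = 0.01, B = 0.1))
#' solve_network(net)$concentrations
reaction_network <- function(reactions, totals) {
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  stopifnot(is.list(reactions), length(reactions) >= 1L)
  for (r in reactions) if (!inherits(r, "reaction"))
    stop("`reactions` must be a list of reaction objects")
  if (is.null(names(totals)) || any(!nzchar(names(totals))))
    stop("`totals` must be a named numeric vector")
  if (any(!is.finite(totals)) || any(totals < 0))
    stop("all totals must be finite and >= 0")
  base <- names(totals)
  products <- vapply(reactions, `[[`, character(1), "product")
  if (anyDuplicated(products))
    stop("each complex may be produced by only one reaction")
  if (any(products %in% base))
    stop("a reaction product may not also carry a total (base species)")
  all_reactants <- unique(unlist(lapply(reactions, `[[`, "reactants")))
  unknown <- setdiff(all_reactants, c(base, products))
  if (length(unknown))
    stop(sprintf("species without a total or producing reaction: %s",
                 paste(unknown, collapse = ", ")))

  # topological order of complexes; also detects cycles
  placed <- character(0)
  order <- integer(0)
  remaining <- seq_along(reactions)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      all(reactions[[i]]$reactants %in% c(base, placed))
    }, logical(1))]
    if (!length(ready)) stop("cyclic complex definitions in network")
    order <- c(order, ready)
    placed <- c(placed, products[ready])
    remaining <- setdiff(remaining, ready)
  }
  reactions <- reactions[order]
  products <- products[order]

  # stoichiometry of each complex in base species, and mass-action coefficient
  nb <- length(base)
  stoich <- matrix(0, nrow = length(reactions), ncol = nb,
                   dimnames = list(products, base))
  coef <- numeric(length(reactions))
  unit <- function(sp) {
    v <- numeric(nb)
    if (sp %in% base) { v[match(sp, base)] <- 1; return(list(s = v, c = 1)) }
    i <- match(sp, products)
    list(s = stoich[i, ], c = coef[i])
  }
  for (i in seq_along(reactions)) {
    r1 <- unit(reactions[[i]]$reactants[1])
    r2 <- unit(reactions[[i]]$reactants[2])
    stoich[i, ] <- r1$s + r2$s
    coef[i] <- reactions[[i]]$k_assoc * r1$c * r2$c
  }
  structure(list(reactions = reactions, totals = totals, base = base,
                 complexes = products, stoich = stoich, coef = coef),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d base species, %d complexes\n",
              length(x$base), length(x$complexes)))
  for (r in x$reactions)
    cat(sprintf("  %s + %s <-> %s   K = %.4g /M\n", r$reactants[1],
                r$reactants[2], r$product, r$k_assoc))
  cat("  totals (M):",
      paste(sprintf("%s = %.4g", x$base, x$totals), collapse = ", "), "\n")
  invisible(x)
}

#' Solve a two-component binding equilibrium exactly
#'
#' A + B <-> AB with association constant \code{k_assoc}, solved by the
#' numerically stable root of the ligand-depletion quadratic
#' \code{k x^2 - (k (A_t + B_t) + 1) x + k A_t B_t = 0} lying in
#' \code{[0, min(A_t, B_t)]}.
#'
#' @param k_assoc Association constant (per molar, >= 0).
#' @param total_a,total_b Total concentrations (molar, >= 0).
#' @return A \code{speciation_state} with species \code{A}, \code{B},
#'   \code{AB}.
#' @export
#' @examples
#' solve_two_component(10, 0.01, 0.1)$concentrations[["A"]]  # ~5.12e-3 M
solve_two_component <- function(k_assoc, total_a, total_b) {
  if (any(!is.finite(c(k_assoc, total_a, total_b))) ||
      any(c(k_assoc, total_a, total_b) < 0))
    stop("all inputs must be finite and >= 0")
  if (k_assoc == 0 || total_a == 0 || total_b == 0) {
    conc <- c(A = total_a, B = total_b, AB = 0)
    x <- 0
  } else {
    # each free concentration from its own quadratic
    # k a^2 + a (1 + k (B_t - A_t)) - A_t = 0, taking the branch that
    # avoids cancellation, so tight binding (free << total) stays accurate
    free_root <- function(tx, ty) {
      s <- 1 + k_assoc * (ty - tx)
      if (s >= 0) 2 * tx / (s + sqrt(s * s + 4 * k_assoc * tx))
      else (-s + sqrt(s * s + 4 * k_assoc * tx)) / (2 * k_assoc)
    }
    a <- free_root(total_a, total_b)
    b <- free_root(total_b, total_a)
    x <- k_assoc * a * b
    conc <- c(A = a, B = b, AB = x)
  }
  res <- c(A = if (total_a > 0) (conc[["A"]] + x - total_a) / total_a else 0,
           B = if (total_b > 0) (conc[["B"]] + x - total_b) / total_b else 0)
  structure(list(concentrations = conc, residuals = res,
                 converged = TRUE, iterations = 0L),
            class = "speciation_state")
}

#' @export
print.speciation_state <- function(x, ...) {
  cat("<speciation_state>",
      if (x$converged) "converged" else "NOT CONVERGED",
      sprintf("(max |rel. residual| %.2e)\n", max(abs(x$residuals), 0)))
  print(signif(x$concentrations, 6))
  invisible(x)
}

#' Solve a binding-equilibrium network
#'
#' Finds non-negative equilibrium concentrations satisfying every
#' mass-action relation exactly (complexes are evaluated from the free
#' base-species concentrations) and every mass balance to within
#' \code{tolerance}. The solver works in log free-concentration space of the
#' base species -- concentrations in these networks span ~1e-16 to 1e-1 M,
#' so linear-space iteration is ill-conditioned -- using a damped Newton
#' iteration with an analytic Jacobian, falling back on per-coordinate
#' bisection sweeps (each single-species mass balance is monotone in its own
#' free concentration) whenever a Newton step fails to reduce the residual.
#' Base species with zero total, and complexes with zero association
#' constant, are eliminated analytically.
#'
#' @param net A \code{\link{reaction_network}}.
#' @param tolerance Maximum relative mass-balance error; default 1e-12.
#' @param max_iter Iteration cap; default 500.
#' @return A \code{speciation_state}: named concentrations for every species
#'   and relative mass-balance residuals for every base species.
#' @export
solve_network <- function(net, tolerance = 1e-12, max_iter = 500L) {
  stopifnot(inherits(net, "reaction_network"))
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("`tolerance` must be positive")
  base <- net$base; totals <- net$totals
  nb <- length(base)

  # species fixed at zero: zero totals and complexes containing them or with
  # zero coefficient
  zero_base <- totals == 0
  cx_zero <- (net$coef == 0) |
    (if (any(zero_base)) rowSums(net$stoich[, zero_base, drop = FALSE] > 0) > 0
     else rep(FALSE, length(net$coef)))
  act <- which(!zero_base)
  na <- length(act)
  cx_act <- which(!cx_zero)

  conc_complex <- function(u) {
    # u: log free conc of active base species
    if (!length(cx_act)) return(numeric(0))
    drop(exp(log(net$coef[cx_act]) +
               net$stoich[cx_act, act, drop = FALSE] %*% u))
  }

  if (na == 0L || length(cx_act) == 0L) {
    free <- ifelse(zero_base, 0, totals)
    cx <- rep(0, length(net$complexes))
    names(cx) <- net$complexes
    conc <- c(free, cx)
    res <- rep(0, nb); names(res) <- base
    return(structure(list(concentrations = conc, residuals = res,
                          converged = TRUE, iterations = 0L),
                     class = "speciation_state"))
  }

  Ta <- totals[act]
  S <- net$stoich[cx_act, act, drop = FALSE]

  resid <- function(u) {
    cc <- conc_complex(u)
    (exp(u) + drop(crossprod(S, cc)) - Ta) / Ta
  }
  jac <- function(u, cc) {
    # d f_s / d u_t = (delta_st free_s + sum_c S_cs S_ct conc_c) / T_s
    J <- crossprod(S * cc, S)   # sum_c S_cs S_ct conc_c
    diag(J) <- diag(J) + exp(u)
    J / Ta
  }
  bisect_coord <- function(u, s) {
    # solve f_s = 0 in u_s with the other coordinates fixed
    lo <- log(Ta[s]) - 90; hi <- log(Ta[s])
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      u[s] <- mid
      if (resid(u)[s] > 0) hi <- mid else lo <- mid
      if (hi - lo < 1e-14) break
    }
    u[s] <- (lo + hi) / 2
    u
  }

  u <- log(Ta)           # initial guess: free = total
  f <- resid(u)
  iter <- 0L
  while (max(abs(f)) > tolerance && iter < max_iter) {
    iter <- iter + 1L
    cc <- conc_complex(u)
    step <- tryCatch(solve(jac(u, cc), f), error = function(e) NULL)
    improved <- FALSE
    if (!is.null(step) && all(is.finite(step))) {
      lambda <- 1
      for (h in 1:40) {
        u_new <- u - lambda * step
        u_new <- pmin(u_new, log(Ta) + 1e-12)  # free cannot exceed total
        f_new <- resid(u_new)
        if (all(is.finite(f_new)) && max(abs(f_new)) < max(abs(f))) {
          u <- u_new; f <- f_new; improved <- TRUE
          break
        }
        lambda <- lambda / 2
      }
    }
    if (!improved) {
      # Gauss-Seidel sweep of per-coordinate bisections
      for (s in seq_len(na)) u <- bisect_coord(u, s)
      f <- resid(u)
    }
  }

  converged <- max(abs(f)) <= tolerance
  if (!converged)
    warning(sprintf(
      "solve_network: not converged after %d iterations (max residual %.2e)",
      iter, max(abs(f))))

  free <- numeric(nb); names(free) <- base
  free[act] <- exp(u)
  cx <- numeric(length(net$complexes)); names(cx) <- net$complexes
  cx[cx_act] <- conc_complex(u)
  res <- numeric(nb); names(res) <- base
  res[act] <- f
  structure(list(concentrations = c(free, cx), residuals = res,
                 converged = converged, iterations = iter),
            class = "speciation_state")
}
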