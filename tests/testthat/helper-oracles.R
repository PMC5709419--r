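# Independent equilibrium oracle: nested 1-D root finding on the mass
# balances, in log free-concentration space. Shares no code with the
# package solver (which uses a damped Newton iteration); used to validate
# solve_network on small networks.
#
# `reactions` is a list of list(reactants = c(a, b), product, k), in
# dependency order; `totals` a named vector over base species.
oracle_network <- function(reactions, totals) {
  base <- names(totals)

  conc_all <- function(free) {
    conc <- as.list(free)
    for (r in reactions)
      conc[[r$product]] <- r$k * conc[[r$reactants[1]]] *
        conc[[r$reactants[2]]]
    conc
  }
  count_in <- function(species, b) {
    if (species == b) return(1)
    for (r in reactions) if (r$product == species)
      return(count_in(r$reactants[1], b) + count_in(r$reactants[2], b))
    0
  }
  balance <- function(free, b) {
    conc <- conc_all(free)
    tot <- conc[[b]]
    for (r in reactions)
      tot <- tot + count_in(r$product, b) * conc[[r$product]]
    tot - totals[[b]]
  }
  solve_level <- function(free, idx) {
    if (idx > length(base)) return(free)
    b <- base[idx]
    if (totals[[b]] == 0) {
      free[b] <- 0
      return(solve_level(free, idx + 1))
    }
    f <- function(u) {
      free[b] <- exp(u)
      free <- solve_level(free, idx + 1)
      balance(free, b)
    }
    # pad the upper bracket by 1e-9 in log space: exp(log(T)) is off by an
    # ulp, which can leave f(upper) marginally negative when binding of
    # this species is negligible
    u <- stats::uniroot(f, lower = log(totals[[b]]) - 70,
                        upper = log(totals[[b]]) + 1e-9, tol = 1e-13)$root
    free[b] <- exp(u)
    solve_level(free, idx + 1)
  }
  free <- stats::setNames(rep(0, length(base)), base)
  unlist(conc_all(solve_level(free, 1)))
}

# bisection oracle for the single A + B <-> AB mass balance, used against
# the closed-form quadratic
oracle_two_component_free_a <- function(k, ta, tb) {
  f <- function(u) {
    a <- exp(u)
    ab_over_a <- k * tb / (1 + k * a)   # free B = tb - ab; solve exactly:
    # solve ab from b-balance given a: ab = k*a*(tb-ab) => ab = k a tb/(1+k a)
    a + a * ab_over_a - ta
  }
  exp(stats::uniroot(f, lower = log(ta) - 70, upper = log(ta),
                     tol = 1e-14)$root)
}

expect_close <- function(x, y, rel) {
  expect_lt(abs(x - y), rel * max(abs(y), .Machine$double.xmin))
}

table1_registry <- function() apply_modelling_rules(load_sensor_registry())
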