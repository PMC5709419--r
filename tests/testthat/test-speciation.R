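test_that("two-component quadratic matches the worked buffer example", {
  st <- solve_two_component(10, 0.01, 0.1)
  expect_equal(unname(st$concentrations["A"]), 5.12e-3, tolerance = 1e-3)
  expect_true(all(abs(st$residuals) < 1e-14))
})

test_that("two-component solution agrees with a bisection oracle", {
  cases <- list(c(1e9, 1e-6, 1e-3), c(10, 0.01, 0.1), c(1e12, 1e-8, 1e-8),
                c(5e4, 2e-5, 1.5e-5), c(1e15, 1e-11, 1e-7))
  for (cs in cases) {
    st <- solve_two_component(cs[1], cs[2], cs[3])
    expect_close(unname(st$concentrations["A"]),
                 oracle_two_component_free_a(cs[1], cs[2], cs[3]), 1e-10)
  }
  # tight-binding limit: free A = total_a / (1 + K * free B), B in excess
  st <- solve_two_component(1e9, 1e-6, 1e-3)
  expect_equal(unname(st$concentrations["A"]), 1.0e-12, tolerance = 1e-2)
})

test_that("degenerate two-component inputs short-circuit", {
  st <- solve_two_component(0, 0.01, 0.1)
  expect_equal(unname(st$concentrations), c(0.01, 0.1, 0))
  st <- solve_two_component(1e9, 0, 0.1)
  expect_equal(unname(st$concentrations["AB"]), 0)
  expect_error(solve_two_component(-1, 1, 1), ">= 0")
})

test_that("network validation rejects malformed networks", {
  expect_error(reaction(c("A", "B"), "A", 1), "own reactants")
  expect_error(reaction_network(
    list(reaction(c("A", "B"), "AB", 1)), c(A = 1e-6)),
    "without a total")
  expect_error(reaction_network(
    list(reaction(c("A", "B"), "AB", 1),
         reaction(c("A", "B"), "AB", 2)), c(A = 1e-6, B = 1e-6)),
    "only one reaction")
  # cyclic definitions are impossible to order
  expect_error(reaction_network(
    list(reaction(c("X", "Y"), "Z", 1),
         reaction(c("Z", "W"), "X", 1)),
    c(Y = 1e-6, W = 1e-6)), "cyclic|without a total")
})

test_that("single-reaction network matches the closed form", {
  net <- reaction_network(list(reaction(c("M", "B"), "MB", 10)),
                          c(M = 0.01, B = 0.1))
  st <- solve_network(net)
  cf <- solve_two_component(10, 0.01, 0.1)
  expect_close(st$concentrations[["M"]], cf$concentrations[["A"]], 1e-12)
  expect_close(st$concentrations[["MB"]], cf$concentrations[["AB"]], 1e-12)
})

test_that("all-zero totals give the all-zero solution", {
  net <- reaction_network(list(reaction(c("A", "B"), "AB", 1e8)),
                          c(A = 0, B = 0))
  st <- solve_network(net)
  expect_equal(unname(st$concentrations), c(0, 0, 0))
  expect_true(st$converged)
})

test_that("network solver agrees with the nested-root oracle", {
  set.seed(42)
  for (rep in 1:12) {
    k1 <- 10^stats::runif(1, 2, 10)
    k2 <- 10^stats::runif(1, 2, 10)
    k3 <- 10^stats::runif(1, 2, 10)
    t3 <- 10^stats::runif(3, -9, -4)
    # branched: A binds B and C independently
    rx <- list(list(reactants = c("A", "B"), product = "AB", k = k1),
               list(reactants = c("A", "C"), product = "AC", k = k2))
    net <- reaction_network(
      list(reaction(c("A", "B"), "AB", k1),
           reaction(c("A", "C"), "AC", k2)),
      c(A = t3[1], B = t3[2], C = t3[3]))
    st <- solve_network(net)
    orc <- oracle_network(rx, c(A = t3[1], B = t3[2], C = t3[3]))
    for (sp in names(orc))
      expect_close(st$concentrations[[sp]], orc[[sp]], 1e-2)
    expect_true(all(abs(st$residuals) < 1e-10))

    # chained: AB further binds C
    rx2 <- c(rx[1], list(list(reactants = c("AB", "C"), product = "ABC",
                              k = k3)))
    net2 <- reaction_network(
      list(reaction(c("A", "B"), "AB", k1),
           reaction(c("AB", "C"), "ABC", k3)),
      c(A = t3[1], B = t3[2], C = t3[3]))
    st2 <- solve_network(net2)
    orc2 <- oracle_network(rx2, c(A = t3[1], B = t3[2], C = t3[3]))
    for (sp in names(orc2))
      expect_close(st2$concentrations[[sp]], orc2[[sp]], 1e-2)
    expect_true(all(abs(st2$residuals) < 1e-10))
  }
})

test_that("mass is conserved on the coupled sensor network", {
  reg <- table1_registry()
  s <- reg$Zur
  p_tot <- copies_to_concentration(s$abundance)
  d_tot <- copies_to_concentration(s$dna_targets)
  net <- reaction_network(
    list(reaction(c("P", "M"), "PM", 1 / s$metal_kd$Zn$kd),
         reaction(c("P", "D"), "PD", 1 / s$apo_dna_kd$kd),
         reaction(c("PM", "D"), "PMD", 1 / s$holo_dna_kd$Zn$kd),
         reaction(c("M", "B"), "MB", k5_for_target(1e-12))),
    c(P = p_tot, M = 0.01, D = d_tot, B = 0.1))
  st <- solve_network(net)
  cc <- st$concentrations
  expect_true(st$converged)
  expect_close(cc[["P"]] + cc[["PM"]] + cc[["PD"]] + cc[["PMD"]], p_tot,
               1e-10)
  expect_close(cc[["D"]] + cc[["PD"]] + cc[["PMD"]], d_tot, 1e-10)
  expect_close(cc[["M"]] + cc[["PM"]] + cc[["PMD"]] + cc[["MB"]], 0.01,
               1e-10)
  # sensors are a small metal sink: free M matches the buffer-only
  # two-component solution up to the sink fraction P_total/M_total
  expect_close(cc[["M"]],
               solve_two_component(k5_for_target(1e-12), 0.01,
                                   0.1)$concentrations[["A"]],
               2 * p_tot / 0.01)
})

test_that("raising an association constant never lowers its product", {
  set.seed(7)
  for (rep in 1:6) {
    tot <- c(A = 10^stats::runif(1, -8, -5), B = 10^stats::runif(1, -8, -5))
    ks <- 10^seq(4, 9, length.out = 6)
    ab <- vapply(ks, function(k) {
      solve_network(reaction_network(
        list(reaction(c("A", "B"), "AB", k)), tot))$concentrations[["AB"]]
    }, numeric(1))
    expect_true(all(diff(ab) >= -1e-18))
  }
})
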