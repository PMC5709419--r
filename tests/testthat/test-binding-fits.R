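designs_c <- competition_designs()
designs_a <- anisotropy_designs()

test_that("competition forward model has the right structure and limits", {
  d <- designs_c$fura2_zntr$model
  grid <- seq(0, 4e-5, length.out = 15)

  # no competitor: pure probe saturation, and the half-signal point sits at
  # the depletion quadratic's solution, not at the probe Kd (probe total is
  # far above its Kd in these designs)
  solo <- competition_model(d$probe, d$probe_kd, d$probe_total, 0)
  cv <- simulate_competition(solo, 1e-7, grid)
  expect_true(all(diff(cv$signal) <= 0))
  half_target <- d$probe_total / 2
  mt_half <- half_target + d$probe_kd * half_target /
    (d$probe_total - half_target)   # exact inversion of the 1:1 isotherm
  sig_at_half <- simulate_competition(solo, 1e-7, mt_half)$signal
  expect_equal(sig_at_half, 0.5, tolerance = 1e-6)
  expect_gt(mt_half / d$probe_kd, 100)   # depletion regime indeed

  # a hopelessly weak competitor is invisible (< 0.5% of signal)
  weak <- simulate_competition(d, d$probe_kd * 1e5, grid)
  expect_lt(max(abs(weak$signal - cv$signal)), 0.005)

  # competition from the protein shifts signal toward higher metal
  comp <- simulate_competition(d, designs_c$fura2_zntr$truth_kd, grid)
  expect_true(all(comp$signal >= cv$signal - 1e-12))
})

test_that("competition speciation equals the generic network solution", {
  d <- designs_c$fura2_zur$model
  kd <- 1.5e-8
  for (mt in c(1e-6, 1.5e-5, 4e-5)) {
    st <- solve_network(reaction_network(
      list(reaction(c("Pr", "M"), "PrM", 1 / d$probe_kd),
           reaction(c("S", "M"), "SM", 1 / kd)),
      c(Pr = d$probe_total, S = d$protein_total * d$equivalents, M = mt)))
    fast <- simulate_competition(d, kd, mt)
    expect_equal(1 - fast$signal, st$concentrations[["PrM"]] / d$probe_total,
                 tolerance = 1e-9)
  }
})

test_that("anisotropy forward model covers both stoichiometries", {
  m1 <- designs_a$zntr_znta$model
  m2 <- designs_a$zur_znua$model

  expect_equal(simulate_anisotropy(m1, 1e-6, 0)$signal, m1$r0)
  # saturation: one event for 1:1, two events for sequential
  expect_equal(simulate_anisotropy(m1, 1e-6, 1)$signal,
               m1$r0 + m1$delta_r_per_event, tolerance = 1e-4)
  expect_equal(simulate_anisotropy(m2, 5.4e-8, 1)$signal,
               m2$r0 + 2 * m2$delta_r_per_event, tolerance = 1e-4)

  # 1:1, no depletion: half-maximal anisotropy at assemblies = Kd
  kd <- 1e-5   # far above the 10 nM DNA
  half <- simulate_anisotropy(m1, kd, kd * m1$assembly_size)$signal
  expect_equal(half, m1$r0 + m1$delta_r_per_event / 2, tolerance = 1e-3)

  # sequential model equals the generic network solution
  st <- solve_network(reaction_network(
    list(reaction(c("D", "A"), "DA", 1 / 5.4e-8),
         reaction(c("DA", "A"), "DA2", 1 / 5.4e-8)),
    c(D = m2$dna_total, A = 2e-7)))
  fast <- simulate_anisotropy(m2, 5.4e-8, 2e-7 * m2$assembly_size)
  expect_equal((fast$signal - m2$r0) / m2$delta_r_per_event,
               (st$concentrations[["DA"]] + 2 * st$concentrations[["DA2"]]) /
                 m2$dna_total, tolerance = 1e-9)

  # monotone rising in titrant
  grid <- 10^seq(-8, -4, length.out = 12)
  expect_true(all(diff(simulate_anisotropy(m2, 5.4e-8, grid)$signal) > 0))
})

test_that("noise-free fits recover the generating Kd", {
  d <- designs_c$fura2_zntr
  cv <- generate_competition_dataset(d$model, d$truth_kd,
                                     noise = noise_spec(level = 0))
  f <- fit_metal_affinity(cv, d$model)
  expect_true(f$converged)
  expect_equal(f$kd, d$truth_kd, tolerance = 5e-4)

  a <- designs_a$zntr_znta
  cva <- generate_anisotropy_dataset(a$model, a$truth_kd,
                                     noise = noise_spec(level = 0))
  fa <- fit_dna_affinity(cva, a$model, max_titrant = a$max_titrant)
  expect_true(fa$converged)
  expect_equal(fa$kd, a$truth_kd, tolerance = 5e-4)
  # the fixed delta-r convention pins the span
  expect_equal(unname(fa$signal_coef[2]), 0.025)
})

test_that("tenfold envelopes bracket the fitted curve pointwise", {
  d <- designs_c$fura2_zur
  cv <- generate_competition_dataset(d$model, d$truth_kd,
                                     noise = noise_spec(level = 0))
  f <- fit_metal_affinity(cv, d$model)
  # tighter competitor withholds more metal from the probe -> higher signal
  expect_true(all(f$envelope$tighter$signal >= f$fitted - 1e-12))
  expect_true(all(f$envelope$weaker$signal <= f$fitted + 1e-12))

  a <- designs_a$zur_znua
  cva <- generate_anisotropy_dataset(a$model, a$truth_kd,
                                     noise = noise_spec(level = 0))
  fa <- fit_dna_affinity(cva, a$model)
  expect_true(all(fa$envelope$tighter$signal >= fa$fitted - 1e-12))
  expect_true(all(fa$envelope$weaker$signal <= fa$fitted + 1e-12))
})

test_that("degenerate or uninformative data are flagged, not fitted", {
  d <- designs_c$fura2_zntr$model
  flat <- titration_curve(seq(0, 4e-5, length.out = 10), rep(1, 10),
                          titrant = "metal")
  expect_false(fit_metal_affinity(flat, d)$converged)

  a <- designs_a$zur_znua$model
  flat_a <- titration_curve(10^seq(-8, -5, length.out = 10), rep(0.15, 10),
                            titrant = "protein")
  expect_false(fit_dna_affinity(flat_a, a)$converged)

  expect_error(fit_metal_affinity(
    titration_curve(c(0, 1e-6), c(1, 0.9), titrant = "metal"), d),
    "at least 6")
})
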