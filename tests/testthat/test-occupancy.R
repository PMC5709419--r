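# occupancy tests use a coarser grid than the default 61 points; the
# curves are smooth sigmoids and 21-31 points resolve every property
reg <- table1_registry()
grid21 <- default_metal_grid(21)

test_that("single-point occupancies match closed-form limits", {
  zur <- reg$Zur
  p_tot <- copies_to_concentration(zur$abundance)
  d_tot <- copies_to_concentration(zur$dna_targets)

  # no sensor -> no occupancy
  zur0 <- zur; zur0$abundance <- 0
  expect_equal(promoter_occupancy(zur0, "Zn", 1e-9), 0)

  # vanishing metal: DNA competition at the effective apo/holo-weighted
  # affinity (the trace of metalated sensor still contributes through the
  # much tighter holo DNA constant)
  m <- 1e-16
  occ <- promoter_occupancy(zur, "Zn", m)
  k1m <- m / zur$metal_kd$Zn$kd
  keff <- (1 / zur$apo_dna_kd$kd + k1m / zur$holo_dna_kd$Zn$kd) / (1 + k1m)
  cf <- solve_two_component(keff, d_tot, p_tot)
  expect_equal(occ, cf$concentrations[["AB"]] / d_tot, tolerance = 1e-3)
  expect_equal(occ, 1.3e-3, tolerance = 0.1)

  # saturating metal: single-site competition at the holo affinity
  occ_sat <- promoter_occupancy(zur, "Zn", 1e-4)
  cf_sat <- solve_two_component(1 / zur$holo_dna_kd$Zn$kd, d_tot, p_tot)
  expect_equal(occ_sat, cf_sat$concentrations[["AB"]] / d_tot,
               tolerance = 1e-2)

  expect_error(promoter_occupancy(zur, "Ni", 1e-9), "no usable constants")
})

test_that("occupancy equals the fixed-free-metal closed form in the deep-buffer limit", {
  # with the buffer pinning free metal at m, the sensor partitions between
  # apo and holo by 1/(1 + K1 m); DNA then sees a two-site competition
  s <- reg$RcnR
  p_tot <- copies_to_concentration(s$abundance)
  d_tot <- copies_to_concentration(s$dna_targets)
  for (m in c(1e-11, 1e-9, 1e-7)) {
    k1 <- 1 / s$metal_kd$Co$kd
    # effective single-species DNA competition: total bound complex =
    # P_free * D_free * (K3 + K4 K1 m)/(1 + K1 m)
    keff <- (1 / s$apo_dna_kd$kd + (1 / s$holo_dna_kd$Co$kd) * k1 * m) /
      (1 + k1 * m)
    cf <- solve_two_component(keff, d_tot, p_tot)
    occ <- promoter_occupancy(s, "Co", m)
    expect_equal(occ, cf$concentrations[["AB"]] / d_tot, tolerance = 1e-3)
  }
})

test_that("response curves are monotone in the expected direction", {
  rcn <- response_curve(reg$RcnR, "Co", grid21)
  expect_true(all(diff(rcn$occupancy) < 0))       # de-repression: falling
  zur <- response_curve(reg$Zur, "Co", grid21)
  expect_true(all(diff(zur$occupancy) > 0))       # co-repression: rising
  znt <- response_curve(reg$ZntR, "Co", grid21)
  expect_equal(znt$response, "metalated_bound")   # activator counts PMD
  expect_true(all(diff(znt$occupancy) > 0))
  expect_true(all(rcn$occupancy >= 0 & rcn$occupancy <= 1))

  empty <- response_curve(reg$RcnR, "Co", numeric(0))
  expect_length(empty$occupancy, 0)
  expect_error(response_curve(reg$RcnR, "Co", c(1e-9, 1e-9)),
               "strictly increasing")
})

test_that("normalisation rescales to [0,1] and supports a shared scale", {
  cv <- normalise_curve(response_curve(reg$RcnR, "Co", grid21))
  expect_equal(min(cv$normalised), 0)
  expect_equal(max(cv$normalised), 1)
  # idempotence
  expect_equal(normalise_curve(cv)$normalised, cv$normalised)

  # FrmR_E64H never reaches FrmR's occupancy on the joint scale
  frm <- response_curve(reg$FrmR, "Co", grid21)
  e64 <- response_curve(reg$FrmR_E64H, "Co", grid21)
  joint <- normalise_curve(e64, reference = list(frm, e64))
  expect_lt(max(joint$normalised), 0.6)
  expect_equal(max(normalise_curve(frm,
                                   reference = list(frm, e64))$normalised), 1)

  flat <- cv; flat$occupancy <- rep(0.5, length(grid21)); flat$normalised <- NULL
  expect_error(normalise_curve(flat), "degenerate")
})

test_that("set points interpolate the half-response in log space", {
  # symmetric synthetic sigmoid centred at 1e-9 M
  g <- 10^seq(-12, -6, length.out = 25)
  sig <- structure(list(sensor = "synthetic", metal = "Co", mode = "de_repressor",
                        grid = g, occupancy = 1 / (1 + (g / 1e-9)),
                        normalised = NULL, response = "total_bound"),
                   class = "occupancy_curve")
  sp <- set_point(sig)
  expect_equal(sp$set_point, 1e-9, tolerance = 1e-2)
  expect_equal(sp$direction, "falling")

  # tightening the metal affinity tenfold lowers the set point
  rcn <- reg$RcnR
  sp0 <- set_point(response_curve(rcn, "Co", grid21))
  rcn$metal_kd$Co <- affinity_constant(rcn$metal_kd$Co$kd / 10)
  sp1 <- set_point(response_curve(rcn, "Co", grid21))
  expect_lt(sp1$set_point, sp0$set_point)

  flat <- sig; flat$occupancy <- rep(1, 25)
  flat$normalised <- rep(0, 25)
  expect_error(set_point(flat), "never crosses")
})

test_that("sensor ranking orders set points and flags near-ties", {
  c1 <- normalise_curve(response_curve(reg$RcnR, "Co", grid21))
  c2 <- normalise_curve(response_curve(reg$Zur, "Co", grid21))
  rk <- rank_sensors(list(c1, c2))
  expect_equal(rk$sensor, c("RcnR", "Zur"))
  expect_false(any(rk$overlaps_previous, na.rm = TRUE))

  # identical sensors tie and overlap
  c2b <- c1; c2b$sensor <- "RcnR-copy"
  rk2 <- rank_sensors(list(c1, c2b))
  expect_true(rk2$overlaps_previous[2])

  zn <- normalise_curve(response_curve(reg$RcnR, "Zn", grid21))
  expect_error(rank_sensors(list(c1, zn)), "same metal")
})

test_that("RcnR is markedly more sensitive to zinc than to cobalt", {
  sp_co <- set_point(response_curve(reg$RcnR, "Co", grid21))
  sp_zn <- set_point(response_curve(reg$RcnR, "Zn", grid21))
  ratio <- sp_co$set_point / sp_zn$set_point
  expect_gt(ratio, 10)
  expect_lt(ratio, 100)
})
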