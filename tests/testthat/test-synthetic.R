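test_that("oscillator trajectory realizes its schedule and validates dt", {
  sched <- frequency_schedule(data.frame(start = 0, end = 10000, freq = 1600))
  tr <- gen_oscillator_trajectory(sched, dt = 0.5, seed = 1)
  b <- bond_length_series(tr, "C2=O2")
  sp <- power_spectrum(b, 0.5, depth = 4096)
  expect_lt(abs(peak_position(sp, c(1500, 1700)) - 1600), sp$resolution)
  ## zero amplitude: flat band
  tr0 <- gen_oscillator_trajectory(
    frequency_schedule(data.frame(start = 0, end = 5000, freq = 1600),
                       amplitude = 0, noise_sd = 0), dt = 0.5, seed = 1)
  expect_equal(stats::sd(bond_length_series(tr0, "C2=O2")), 0)
  ## undersampling is rejected with the required dt in the message
  expect_error(gen_oscillator_trajectory(sched, dt = 5, seed = 1), "dt")
  ## window-wise recovery of a three-segment schedule
  tr3 <- gen_oscillator_trajectory(alal_frequency_schedule(), dt = 0.5, seed = 2)
  b3 <- bond_length_series(tr3, "C2=O2")
  wins <- list(c(8000, 16000), c(16000, 36000), c(40000, 50000))
  expected <- c(1600, 1594, 1584)
  for (i in seq_along(wins)) {
    sel <- tr3$times >= wins[[i]][1] & tr3$times < wins[[i]][2]
    sp <- power_spectrum(b3[sel], 0.5, depth = 4096)
    expect_lt(abs(peak_position(sp, c(1500, 1700)) - expected[i]),
              sp$resolution)
  }
})

test_that("generators are deterministic given the seed", {
  s <- alal_hydration_schedule()
  s$segments <- s$segments[1, , drop = FALSE]
  s$segments$end <- 2000
  a <- gen_hydration_trajectory(s, dt = 2, seed = 7)
  b <- gen_hydration_trajectory(s, dt = 2, seed = 7)
  expect_identical(a$coords, b$coords)
  c_ <- gen_hydration_trajectory(s, dt = 2, seed = 8)
  expect_false(identical(a$coords, c_$coords))
  expect_identical(gen_correlated_series(100, 0.3, 5),
                   gen_correlated_series(100, 0.3, 5))
})

test_that("hydration generator hits targets and exchanges identities", {
  sched <- hydration_schedule(data.frame(
    start = c(0, 4000, 8000), end = c(4000, 8000, 12000),
    target = c(1, 1.5, 2), rate = 1 / 800))
  tr <- gen_hydration_trajectory(sched, dt = 2, seed = 5)
  hb <- hbond_count_series(tr, "C2=O2")
  wins <- list(c(0, 4000), c(4000, 8000), c(8000, 12000))
  for (i in 1:3)
    expect_lt(abs(hbond_window_stats(hb, wins[[i]])["mean"] -
                  sched$segments$target[i]), 0.1)
  ## constant target 1.0 throughout
  tr1 <- gen_hydration_trajectory(
    hydration_schedule(data.frame(start = 0, end = 3000, target = 1,
                                  rate = 1 / 800)), dt = 2, seed = 5)
  expect_lt(abs(mean(hbond_count_series(tr1, "C2=O2")$counts) - 1), 0.1)
  ## identity changes: the bonded-water id set changes within each segment
  gt <- attr(tr, "ground_truth")
  expect_true(length(gt$events) >= 3)
  ids <- hb$ids
  for (w in wins) {
    sel <- which(tr$times >= w[1] & tr$times < w[2])
    idsets <- unique(lapply(ids[sel], sort))
    expect_gt(length(idsets), 1)
  }
  ## background waters stay outside 4.5 A of the acceptor oxygen
  geo <- amideshell:::.group_water_geometry(tr, "C2=O2")
  gt_roles <- gt$role_series
  for (m in seq_along(geo)) {
    bg_frames <- gt_roles[, m] > gt$n_slots
    if (any(bg_frames)) expect_true(all(geo[[m]]$d_oo[bg_frames] > 4.5))
  }
})

test_that("correlated series reach their target correlation", {
  g <- gen_correlated_series(10000, 0.4, seed = 2148)
  r <- cor(g$x, g$y)
  expect_gte(r, 0.37); expect_lte(r, 0.43)
  g1 <- gen_correlated_series(100, 1, seed = 1)
  expect_equal(cor(g1$x, g1$y), 1)
  gm <- gen_correlated_series(100, -1, seed = 1)
  expect_equal(cor(gm$x, gm$y), -1)
  g0 <- gen_correlated_series(20000, 0, seed = 3)
  expect_lt(abs(cor(g0$x, g0$y)), 0.03)
  expect_error(gen_correlated_series(100, 1.2), "target_r")
})

test_that("interaction records carry recoverable zone structure", {
  zp <- data.frame(mean_E = c(-5.5, -2.5, -0.5), sd_E = 0.3,
                   mean_r = c(1.9, 3.2, 4.5), mean_theta = c(10, 50, 110),
                   n = c(120, 100, 80))
  rec <- gen_interaction_records(zp, seed = 9)
  expect_equal(nrow(rec), 300)
  expect_false(attr(rec, "ground_truth")$degenerate)
  ## single zone flags degenerate
  rec1 <- gen_interaction_records(zp[1, ], seed = 9)
  expect_true(attr(rec1, "ground_truth")$degenerate)
  ## zero-count zone leaves a two-zone structure
  zp0 <- zp; zp0$n[2] <- 0
  rec0 <- gen_interaction_records(zp0, seed = 9)
  expect_setequal(unique(rec0$zone_truth), c(1, 3))
})

test_that("torsion series visit states with the planted weights", {
  states <- data.frame(phi = c(-130, -130, -57), psi = c(140, -47, 140),
                       weight = c(0.7, 0.2, 0.1), kappa = 50)
  g <- gen_torsion_series(states, n = 10000, seed = 2148)
  freq <- as.numeric(table(factor(g$state, levels = 1:3))) / 10000
  expect_lt(max(abs(freq - states$weight)), 0.03)
  ## single state maps to beta everywhere
  one <- gen_torsion_series(data.frame(phi = -130, psi = 140, weight = 1,
                                       kappa = 200), n = 500, seed = 1)
  expect_true(all(assign_backbone_state(one$phi, one$psi) == "beta"))
  ## infinite concentration freezes the angles at the centers
  frozen <- gen_torsion_series(data.frame(phi = 80, psi = 70, weight = 1,
                                          kappa = Inf), n = 50, seed = 1)
  expect_equal(frozen$phi, rep(80, 50))
  expect_equal(frozen$psi, rep(70, 50))
  expect_error(gen_torsion_series(data.frame(phi = 0, psi = 0, weight = 0.5,
                                             kappa = 1), 10), "sum to 1")
})
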