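make_hydrated_frame <- function(rads = c(1.8, 2.5, 3.7, 4.1),
                                theta = c(5, 20, 60, 80)) {
  fx <- peptide_fixture()
  O2 <- fx$positions[3, ]; C2 <- fx$positions[2, ]
  u <- (O2 - C2) / sqrt(sum((O2 - C2)^2))
  dirs <- list(u, c(0, 0.35, 0.94), c(0, -0.2, 0.98), c(0.4, 0.2, 0.89))
  ws <- Map(function(d, r, th) donating_water(O2, d / sqrt(sum(d^2)), r, th),
            dirs, rads, theta)
  fixture_with_waters(ws)
}

test_that("capped fragments have the CONH composition and collinear caps", {
  tr <- make_hydrated_frame()
  frag <- extract_capped_fragment(tr, 1, "C2=O2")
  expect_equal(frag$elements, c("C", "O", "N", "H", "H", "H"))
  expect_equal(nrow(frag$xyz), 6)
  p <- frame_positions(tr, 1)
  ## caps lie along the former bond vectors at the stated lengths
  vC <- frag$xyz[5, ] - p[2, ]           # C cap, along C2 -> CA1
  bC <- p[1, ] - p[2, ]
  expect_equal(sqrt(sum(vC^2)), 1.09, tolerance = 1e-9)
  cosang <- sum(vC * bC) / sqrt(sum(vC^2) * sum(bC^2))
  expect_lt(acos(pmin(cosang, 1)), 1e-6)
  vN <- frag$xyz[6, ] - p[4, ]           # N cap, along N2 -> CA2
  expect_equal(sqrt(sum(vN^2)), 1.01, tolerance = 1e-9)
  expect_error(extract_capped_fragment(tr, 1, "C9=O9"), "C9=O9")
})

test_that("attach_water counts atoms, minimum-images, and flags overlap", {
  tr <- make_hydrated_frame()
  frag <- extract_capped_fragment(tr, 1, "C2=O2")
  comb <- attach_water(frag, tr, 1, 1)
  expect_equal(nrow(comb$xyz), 9)
  expect_equal(comb$molecule, c(rep(1L, 6), rep(2L, 3)))
  expect_null(attr(comb, "overlap"))
  ## periodic image: water stored on the far side of a box is pulled back
  trb <- make_hydrated_frame()
  trb$box <- c(20, 20, 20)
  p <- frame_positions(trb, 1)
  w <- water_molecules(trb$topology)[[1]]
  trb$coords[1, w, ] <- p[w, ] + matrix(c(20, 0, 0), 3, 3, byrow = TRUE)
  fragb <- extract_capped_fragment(trb, 1, "C2=O2")
  combb <- attach_water(fragb, trb, 1, 1)
  expect_equal(combb$xyz[7:9, ], comb$xyz[7:9, ], tolerance = 1e-9)
  ## overlap injection is flagged, not silently accepted
  trc <- make_hydrated_frame(rads = c(0.5, 2.5, 3.7, 4.1))
  fragc <- extract_capped_fragment(trc, 1, "C2=O2")
  expect_true(isTRUE(attr(attach_water(fragc, trc, 1, 1), "overlap")))
})

test_that("toy backend physics: well depth, wall, separation, invariance", {
  tr <- make_hydrated_frame()
  frag <- extract_capped_fragment(tr, 1, "C2=O2")
  be <- toy_energy_backend()
  fx <- peptide_fixture()
  O2 <- fx$positions[3, ]; C2 <- fx$positions[2, ]
  u <- (O2 - C2) / sqrt(sum((O2 - C2)^2))
  e_at <- function(r) {
    t2 <- fixture_with_waters(list(donating_water(O2, u, r, 0)))
    f2 <- extract_capped_fragment(t2, 1, "C2=O2")
    interaction_energy(suppressWarnings(attach_water(f2, t2, 1, 1)), be)
  }
  rs <- seq(1.2, 3.0, by = 0.1)
  es <- vapply(rs, e_at, 0)
  rmin <- rs[which.min(es)]
  expect_gte(rmin, 1.6); expect_lte(rmin, 2.2)     # single physical minimum
  expect_equal(sum(diff(es) < 0 & c(diff(es)[-1] > 0, FALSE)), 1)
  expect_lt(min(es), 0)
  expect_lte(abs(min(es)), 8)                      # H-bond scale, kcal/mol
  expect_gt(e_at(1.0), 0)                          # repulsive wall
  expect_lt(abs(e_at(50)), 0.05)                   # separation limit
  ## dipole-dipole falloff: |E| drops by ~2^3 per doubling of distance
  e10 <- e_at(10); e20 <- e_at(20); e40 <- e_at(40)
  expect_gt(abs(e10 / e20), 4); expect_lt(abs(e10 / e20), 12)
  expect_gt(abs(e20 / e40), 4); expect_lt(abs(e20 / e40), 12)
  ## rigid rotation + translation invariance
  comb <- attach_water(frag, tr, 1, 1)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  comb2 <- comb
  comb2$xyz <- comb$xyz %*% t(R) + matrix(c(3, -2, 5), 9, 3, byrow = TRUE)
  expect_equal(interaction_energy(comb2, be), interaction_energy(comb, be),
               tolerance = 1e-9)
})

test_that("far-separated waters contribute additively", {
  fx <- peptide_fixture()
  O2 <- fx$positions[3, ]; C2 <- fx$positions[2, ]
  u <- (O2 - C2) / sqrt(sum((O2 - C2)^2))
  wA <- donating_water(O2, u, 1.8, 5)
  wB <- donating_water(O2, c(0, 0, 1), 2.1, 10)
  wB <- wB + matrix(c(0, 0, 8), 3, 3, byrow = TRUE)   # > 8 A from wA
  tr <- fixture_with_waters(list(wA, wB))
  frag <- extract_capped_fragment(tr, 1, "C2=O2")
  be <- toy_energy_backend()
  eA <- interaction_energy(attach_water(frag, tr, 1, 1), be)
  eB <- interaction_energy(attach_water(frag, tr, 1, 2), be)
  ## pair interaction of the fragment with both waters at once
  both <- attach_water(frag, tr, 1, 1)
  p <- frame_positions(tr, 1)
  w2 <- water_molecules(tr$topology)[[2]]
  both$elements <- c(both$elements, "O", "H", "H")
  both$xyz <- rbind(both$xyz, p[w2, ])
  both$types <- c(both$types, "O_water", "H_water", "H_water")
  both$molecule <- c(both$molecule, rep(2L, 3))
  eAB <- interaction_energy(both, be)
  ## E(frag <-> {A, B}) includes the A-B coupling, which is tiny at > 8 A
  expect_lt(abs(eAB - (eA + eB)) / abs(eA + eB), 0.05)
})

test_that("k-means zones recover planted labels and honor k = 2, 3, 4", {
  zp <- data.frame(mean_E = c(-5.5, -2.5, -0.5), sd_E = 0.3,
                   mean_r = c(1.9, 3.2, 4.5), mean_theta = c(10, 50, 110),
                   n = c(150, 120, 100))
  rec <- gen_interaction_records(zp, seed = 2148)
  zm <- kmeans_zones(rec, k = 3, seed = 2148)
  ## perfect agreement with ground truth (adjusted agreement 1.0)
  map <- c(strong = 1, moderate = 2, weak = 3)
  expect_equal(unname(map[as.character(zm$assignment)]), rec$zone_truth)
  expect_equal(zm$labels, c("strong", "moderate", "weak"))
  expect_true(all(diff(zm$centers) > 0))
  ## k = 2: hydrogen-bonded vs not
  zm2 <- kmeans_zones(rec, k = 2, seed = 1)
  expect_equal(zm2$labels, c("strong", "weak"))
  expect_true(all(zm2$assignment[rec$zone_truth == 1] == "strong"))
  ## k = 4 splits the strong zone, keeping moderate/weak intact
  zp4 <- rbind(data.frame(mean_E = -7.5, sd_E = 0.3, mean_r = 1.7,
                          mean_theta = 5, n = 80), zp)
  rec4 <- gen_interaction_records(zp4, seed = 3)
  zm4 <- kmeans_zones(rec4, k = 4, seed = 3)
  expect_equal(zm4$labels, c("very strong", "strong", "moderate", "weak"))
  expect_true(all(zm4$assignment[rec4$zone_truth == 1] == "very strong"))
  expect_true(all(zm4$assignment[rec4$zone_truth == 4] == "weak"))
  ## determinism under fixed seed + restarts
  expect_identical(kmeans_zones(rec, k = 3, seed = 5, restarts = 50),
                   kmeans_zones(rec, k = 3, seed = 5, restarts = 50))
  ## degenerate identical records are rejected
  bad <- rec; bad$energy <- -3; bad$r <- 2; bad$theta <- 10
  expect_error(kmeans_zones(bad, k = 3, seed = 1), "degenerate")
})

test_that("geometric H-bonds concentrate in the strong zone", {
  ## strong zone planted at H-bond geometry: records passing the geometric
  ## criteria should nearly all cluster strong
  zp <- data.frame(mean_E = c(-5.5, -2.0, -0.3), sd_E = c(0.8, 0.6, 0.3),
                   mean_r = c(1.85, 3.2, 4.6), mean_theta = c(10, 55, 110),
                   n = c(200, 150, 120))
  rec <- gen_interaction_records(zp, seed = 11)
  zm <- kmeans_zones(rec, k = 3, seed = 11)
  geom_ok <- rec$r <= 2.5 & rec$theta <= 45
  frac <- mean(zm$assignment[geom_ok] == "strong")
  expect_gte(frac, 0.95)
})

test_that("zone occupancy counts strong/moderate waters per frame", {
  zp <- data.frame(mean_E = c(-5.5, -5.3, -2.4, -0.4),
                   sd_E = 0.2, mean_r = c(1.8, 1.9, 3.3, 4.8),
                   mean_theta = c(8, 12, 50, 120), n = 60)
  rec <- gen_interaction_records(zp, seed = 6)
  rec$zone_truth[rec$zone_truth == 2] <- 1     # two strong waters per frame
  zm <- kmeans_zones(rec, k = 3, seed = 6)
  occ <- zone_occupancy(rec, zm)
  expect_equal(mean(occ$strong), 2, tolerance = 0.05)
  expect_equal(mean(occ$moderate), 1, tolerance = 0.05)
  expect_error(zone_occupancy(rec[1:10, ], zm), "different record set")
})

test_that("energy-frequency correlation matches the two-pass oracle", {
  g <- gen_correlated_series(10000, 0.4, seed = 2148)
  r <- correlate_energy_frequency(g$x, g$y)
  expect_gte(r, 0.37); expect_lte(r, 0.43)
  expect_equal(r, oracle_pearson(g$x, g$y), tolerance = 1e-12)
  set.seed(14)
  for (i in 1:5) {
    x <- rnorm(200); y <- 0.3 * x + rnorm(200)
    expect_equal(correlate_energy_frequency(x, y), oracle_pearson(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(correlate_energy_frequency(g$x, g$x), 1)
  expect_equal(correlate_energy_frequency(g$x, -g$x), -1)
  expect_error(correlate_energy_frequency(rep(1, 100), rnorm(100)),
               "zero-variance")
  expect_error(correlate_energy_frequency(1:5, 1:5 + 0), "10 valid")
})
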