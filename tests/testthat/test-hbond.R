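test_that("is_hbonded applies inclusive distance/angle criteria", {
  crit <- hbond_criteria()
  mk <- function(r, dev) {
    H <- c(0, 0, 0)
    A <- c(r, 0, 0)
    th <- dev * pi / 180
    D <- H + 0.96 * c(-cos(th), sin(th), 0)   # deviation measured at H
    list(D = D, H = H, A = A)
  }
  g <- mk(1.8, 10)
  expect_true(is_hbonded(g$D, g$H, g$A, crit))
  g <- mk(2.5, 45)                            # inclusive boundary
  expect_true(is_hbonded(g$D, g$H, g$A, crit))
  g <- mk(2.6, 0)
  expect_false(is_hbonded(g$D, g$H, g$A, crit))
  g <- mk(1.8, 46)
  expect_false(is_hbonded(g$D, g$H, g$A, crit))
  expect_error(is_hbonded(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0), crit),
               "coincide")
  ## periodic image: acceptor across the box boundary (image at x = -0.8,
  ## donor on the opposite side of the hydrogen)
  box <- c(10, 10, 10)
  expect_true(is_hbonded(c(0.96, 0, 0), c(0, 0, 0), c(9.2, 0, 0), crit, box))
})

test_that("count series, distribution, and conservation on built frames", {
  fx <- peptide_fixture()
  O2 <- fx$positions[3, ]; C2 <- fx$positions[2, ]
  u <- (O2 - C2) / sqrt(sum((O2 - C2)^2))
  w_in <- donating_water(O2, u, r = 1.8, theta_deg = 10)
  w_in2 <- donating_water(O2, c(0.2, 0.3, 0.93), r = 2.0, theta_deg = 25)
  w_out <- donating_water(O2, c(0, 0, 1), r = 4.2, theta_deg = 100)
  tr <- fixture_with_waters(list(w_in, w_in2, w_out))
  hb <- hbond_count_series(tr, "C2=O2")
  expect_equal(hb$counts, 2L)
  expect_setequal(hb$ids[[1]], c(1L, 2L))
  ## no waters at all
  hb0 <- hbond_count_series(fixture_with_waters(list()), "C2=O2")
  expect_equal(hb0$counts, 0L)
  ## distribution of a hand-made series
  s <- hb; s$counts <- c(1L, 1L, 2L, 2L)
  d <- hbond_state_distribution(s)
  expect_equal(unname(d[c("1", "2")]), c(0.5, 0.5))
  expect_equal(sum(d), 1)
  ## conservation: mean of distribution equals series mean
  expect_equal(sum(as.numeric(names(d)) * d), mean(s$counts))
  ## point mass for a constant series
  s$counts <- rep(3L, 5)
  expect_equal(unname(hbond_state_distribution(s)["3"]), 1)
})

test_that("count means follow the hydration schedule windows", {
  sched <- hydration_schedule(data.frame(
    start = c(0, 2000, 6000), end = c(2000, 6000, 8000),
    target = c(1, 1.5, 2), rate = 1 / 800))
  tr <- gen_hydration_trajectory(sched, dt = 2, seed = 42)
  hb <- hbond_count_series(tr, "C2=O2")
  m <- sapply(list(c(0, 2000), c(2000, 6000), c(6000, 8000)),
              function(w) hbond_window_stats(hb, w)["mean"])
  expect_equal(unname(m), c(1, 1.5, 2), tolerance = 0.1)
  expect_true(all(diff(m) > 0))
  expect_error(hbond_window_stats(hb, c(9e5, 9.1e5)), "empty")
})

test_that("distance-angle histogram localizes placement modes", {
  fx <- peptide_fixture()
  O2 <- fx$positions[3, ]; C2 <- fx$positions[2, ]
  u <- (O2 - C2) / sqrt(sum((O2 - C2)^2))
  set.seed(7)
  n <- 200
  frames <- lapply(seq_len(n), function(i)
    donating_water(O2, u, r = rnorm(1, 1.9, 0.05),
                   theta_deg = pmax(rnorm(1, 10, 2), 0)))
  tr <- fixture_with_waters(list(frames[[1]]))
  coords <- tr$coords[rep(1, n), , , drop = FALSE]
  for (i in seq_len(n)) coords[i, 12:14, ] <- frames[[i]]
  tr <- trajectory(coords, dt = 0.5, top = tr$topology)
  h <- dist_angle_histogram(tr, "C2=O2")
  ij <- which(h$counts == max(h$counts), arr.ind = TRUE)[1, ]
  expect_lt(abs(mean(h$r_edges[ij[1] + 0:1]) - 1.9), 0.15)
  expect_lt(abs(mean(h$theta_edges[ij[2] + 0:1]) - 10), 5)
  ## marginals integrate to the same mass as the grid
  expect_equal(sum(h$g_r) * h$bins[1], sum(h$counts) / h$n_frames,
               tolerance = 1e-9)
  ## empty water set -> zero grid
  h0 <- dist_angle_histogram(fixture_with_waters(list()), "C2=O2")
  expect_equal(sum(h0$counts), 0)
})

test_that("running integral steps at the shell radius and is monotone", {
  fx <- peptide_fixture()
  O2 <- fx$positions[3, ]; C2 <- fx$positions[2, ]
  u <- (O2 - C2) / sqrt(sum((O2 - C2)^2))
  w1 <- donating_water(O2, u, r = 1.8, theta_deg = 5)
  w2 <- donating_water(O2, c(0, 0, 1), r = 2.4, theta_deg = 8)
  tr <- fixture_with_waters(list(w1, w2), nframes = 3)
  h <- dist_angle_histogram(tr, "C2=O2")
  expect_equal(running_integral(h, 1.0), 0)
  expect_equal(running_integral(h, 2.0), 1)
  expect_equal(running_integral(h, 2.5), 2)          # two-water shell
  expect_equal(running_integral(h, 2.5, "hbond"), 2)
  rs <- seq(0.5, 5, by = 0.25)
  vals <- sapply(rs, running_integral, hist = h)
  expect_true(all(diff(vals) >= 0))
  ## normalization: full-range integral equals mean waters in range
  expect_equal(running_integral(h, 5), 2)
})

test_that("water ranking orders by O-O distance with index tie-break", {
  fx <- peptide_fixture()
  O2 <- fx$positions[3, ]; C2 <- fx$positions[2, ]
  u <- (O2 - C2) / sqrt(sum((O2 - C2)^2))
  dirs <- list(u, c(0, 0, 1), c(0, 1, 0.4), c(0.5, -0.1, 0.86))
  rads <- c(1.8, 2.5, 3.7, 4.1)
  ws <- Map(function(d, r) donating_water(O2, d / sqrt(sum(d^2)), r, 10),
            dirs, rads)
  tr <- fixture_with_waters(ws[c(3, 1, 4, 2)])   # scrambled storage order
  rk <- rank_waters(tr, 1, "C2=O2")
  expect_equal(rk$rank, paste0("W", 1:4))
  expect_equal(rk$water, c(2L, 4L, 1L, 3L))
  expect_equal(rk$r, rads, tolerance = 0.05)
  ## identity swap across frames changes W1
  tr2 <- fixture_with_waters(list(ws[[1]], ws[[2]]), nframes = 2)
  tr2$coords[2, 12:14, ] <- ws[[2]]
  tr2$coords[2, 15:17, ] <- ws[[1]]
  expect_equal(rank_waters(tr2, 1, "C2=O2", n = 2)$water[1], 1L)
  expect_equal(rank_waters(tr2, 2, "C2=O2", n = 2)$water[1], 2L)
  ## exact tie: lower molecule index first
  tr3 <- fixture_with_waters(list(ws[[2]], ws[[2]]))
  expect_equal(rank_waters(tr3, 1, "C2=O2", n = 2)$water, c(1L, 2L))
  ## short flag
  expect_true(isTRUE(attr(rank_waters(tr3, 1, "C2=O2", n = 4), "short")))
})

test_that("criteria monotonicity: looser cutoffs never lower counts", {
  sched <- hydration_schedule(data.frame(start = 0, end = 1000,
                                         target = 2, rate = 1 / 400))
  tr <- gen_hydration_trajectory(sched, dt = 2, seed = 13)
  base <- hbond_count_series(tr, "C2=O2", hbond_criteria(2.5, 45))$counts
  for (crit in list(hbond_criteria(3.0, 45), hbond_criteria(2.5, 60),
                    hbond_criteria(3.5, 90))) {
    expect_true(all(hbond_count_series(tr, "C2=O2", crit)$counts >= base))
  }
})

test_that("a constructed three-water chain is found as one order-3 bridge", {
  fx <- peptide_fixture()
  O2 <- fx$positions[3, ]; O3 <- fx$positions[8, ]
  nodes <- arc_nodes(O2, O3, m = 4)            # 3 intermediate oxygens
  ws <- chain_waters(O2, nodes, endB = O3)
  tr <- fixture_with_waters(ws)
  br <- find_water_bridges(tr, 1, "C2=O2", "C3=O3")
  expect_length(br, 1)
  expect_equal(br[[1]]$order, 3)
  expect_equal(br[[1]]$path, 1:3)
  expect_equal(br[[1]]$endpoints, c("C2=O2", "C3=O3"))
})

test_that("bridge search agrees with the oracle on random 12-water frames", {
  fx <- peptide_fixture()
  O2 <- fx$positions[3, ]
  crit <- hbond_criteria()
  set.seed(99)
  for (rep_ in 1:6) {
    ws <- lapply(1:12, function(i) {
      cen <- O2 + runif(3, -4, 4)
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      donating_water(cen + 1.8 * d, d, r = runif(1, 1.5, 2.4),
                     theta_deg = runif(1, 0, 60))
    })
    tr <- fixture_with_waters(ws)
    br <- find_water_bridges(tr, 1, "C2=O2", "C3=O3", crit, max_order = 7)
    p <- frame_positions(tr, 1)
    waters <- water_molecules(tr$topology)
    nw <- length(waters)
    acceptors <- c(list(list(idx = 3, water = NA), list(idx = 8, water = NA)),
                   lapply(seq_len(nw), function(i) list(idx = waters[[i]][1],
                                                        water = i)))
    prs <- oracle_hbond_pairs(p, waters, acceptors)
    adj <- matrix(FALSE, nw, nw); gA <- logical(nw); gB <- logical(nw)
    for (e in prs) {
      if (e$acceptor == 1) gA[e$water] <- TRUE
      else if (e$acceptor == 2) gB[e$water] <- TRUE
      else { adj[e$water, e$acceptor - 2] <- TRUE
             adj[e$acceptor - 2, e$water] <- TRUE }
    }
    ob <- oracle_bridges(gA, gB, adj, nw)
    expect_equal(length(br), length(ob))
    if (length(ob)) expect_setequal(lapply(br, `[[`, "path"), ob)
    ## production per-frame H-bond count equals the oracle's direct count
    hb <- hbond_count_series(tr, "C2=O2", crit)
    expect_equal(hb$counts[1], sum(gA))
  }
})

test_that("order cap and disconnected graphs give empty bridge lists", {
  fx <- peptide_fixture()
  O2 <- fx$positions[3, ]; O3 <- fx$positions[8, ]
  w_far <- donating_water(O2 + c(0, 0, 20), c(0, 0, 1), r = 1.8)
  tr <- fixture_with_waters(list(w_far))
  expect_equal(find_water_bridges(tr, 1, "C2=O2", "C3=O3"), list())
  ## a genuine 8-water chain exceeds the default order cap of 7
  ws <- chain_waters(O2, arc_nodes(O2, O3, m = 9), endB = O3)
  tr8 <- fixture_with_waters(ws)
  expect_equal(find_water_bridges(tr8, 1, "C2=O2", "C3=O3", max_order = 7),
               list())
  br8 <- find_water_bridges(tr8, 1, "C2=O2", "C3=O3", max_order = 8)
  expect_length(br8, 1)
  expect_equal(br8[[1]]$order, 8)
})
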