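## Synthetic trajectory / signal / record generators with known ground truth.
##
## These emulate the statistical structure of a solvated-peptide simulation:
## a C=O oscillator whose frequency follows a piecewise-constant schedule
## (amide I band, ~1580-1610 cm^-1), water molecules entering and leaving the
## carbonyl's first hydration shell on a few-ps residence timescale, capped-
## fragment interaction-energy records drawn from separated zones, correlated
## scalar series, and metastable backbone-torsion series. Every generator is
## deterministic given (parameters, seed), and ground truth travels with the
## data as the "ground_truth" attribute.

.check_segments <- function(seg, valcol, what) {
  if (!nrow(seg)) .stopf("empty %s schedule", what)
  if (any(seg$end <= seg$start)) .stopf("%s schedule: segment end <= start", what)
  if (nrow(seg) > 1 && any(abs(seg$start[-1] - seg$end[-nrow(seg)]) > 1e-9))
    .stopf("%s schedule: segments must be contiguous", what)
  if (any(seg[[valcol]] < 0)) .stopf("%s schedule: negative values", what)
  seg
}

#' Piecewise-constant frequency schedule for the C=O oscillator
#'
#' @param segments data.frame with columns `start`, `end` (fs) and `freq`
#'   (cm^-1); segments must be contiguous and non-overlapping
#' @param amplitude oscillation amplitude, Angstrom (default 0.05)
#' @param noise_sd additive Gaussian noise on the bond length, Angstrom
#' @param r0 equilibrium bond length, Angstrom (default 1.23)
#' @return object of class `frequency_schedule`
#' @export
frequency_schedule <- function(segments, amplitude = 0.05, noise_sd = 0.005,
                               r0 = 1.23) {
  segments <- .check_segments(segments, "freq", "frequency")
  if (any(segments$freq <= 0)) .stopf("frequencies must be > 0")
  structure(list(segments = segments, amplitude = amplitude,
                 noise_sd = noise_sd, r0 = r0),
            class = "frequency_schedule")
}

#' Hydration schedule: target H-bond counts with exchange kinetics
#'
#' @param segments data.frame with columns `start`, `end` (fs), `target`
#'   (mean H-bond count) and `rate` (exchange events per fs; water residence
#'   is about `1/rate`)
#' @param r_mean,r_sd hydrogen-acceptor distance of bonded waters, Angstrom
#'   (default 1.85 +/- 0.08, the center of the observed first-shell band)
#' @param theta_mean,theta_sd deviation-from-linearity of bonded waters, deg
#' @return object of class `hydration_schedule`
#' @export
hydration_schedule <- function(segments, r_mean = 1.85, r_sd = 0.08,
                               theta_mean = 12, theta_sd = 6) {
  segments <- .check_segments(segments, "target", "hydration")
  if (r_mean <= 0 || theta_mean < 0 || theta_mean > 180)
    .stopf("invalid bonded-water geometry")
  structure(list(segments = segments, r_mean = r_mean, r_sd = r_sd,
                 theta_mean = theta_mean, theta_sd = theta_sd),
            class = "hydration_schedule")
}

#' The three-window scenario schedules
#'
#' The stated world of the analysis: a 50 ps run whose one-water window
#' (up to 16 ps), mixed window (16-36 ps) and two-water window (from 36 ps)
#' carry carbonyl frequencies 1600 / 1594 / 1584 cm^-1 and hydration targets
#' 1.0 / 1.5 / 2.0, with a 2.5 ps water-exchange timescale.
#'
#' @return a [frequency_schedule()] / [hydration_schedule()]
#' @export
alal_frequency_schedule <- function() {
  frequency_schedule(data.frame(start = c(0, 16000, 36000),
                                end = c(16000, 36000, 50000),
                                freq = c(1600, 1594, 1584)))
}

#' @rdname alal_frequency_schedule
#' @export
alal_hydration_schedule <- function() {
  hydration_schedule(data.frame(start = c(0, 16000, 36000),
                                end = c(16000, 36000, 50000),
                                target = c(1.0, 1.5, 2.0),
                                rate = 1 / 2500))
}

## piecewise bond-length series with per-segment phase reset
.bond_series <- function(schedule, dt, n) {
  t <- (seq_len(n) - 1) * dt
  b <- rep(schedule$r0, n)
  for (i in seq_len(nrow(schedule$segments))) {
    s <- schedule$segments[i, ]
    sel <- t >= s$start & t < s$end
    b[sel] <- schedule$r0 +
      schedule$amplitude * cos(2 * pi * .c_cm_fs * s$freq * (t[sel] - s$start))
  }
  if (schedule$noise_sd > 0) b <- b + stats::rnorm(n, sd = schedule$noise_sd)
  b
}

#' Two-atom C=O oscillator trajectory
#'
#' Bond length `r0 + A cos(2 pi c nu (t - t_segment))` plus Gaussian noise,
#' with the phase reset at segment boundaries. The carbon sits at the origin
#' and the oxygen oscillates along x.
#'
#' @param schedule a [frequency_schedule()]
#' @param dt timestep, fs; must resolve the highest frequency with at least
#'   10 samples per period
#' @param seed RNG seed
#' @return a [trajectory()] with group `"C2=O2"`; ground truth in
#'   `attr(, "ground_truth")`
#' @export
gen_oscillator_trajectory <- function(schedule, dt = 0.5, seed = 1) {
  fmax <- max(schedule$segments$freq)
  if (dt > .period_fs(fmax) / 10)
    .stopf("dt = %g fs undersamples %g cm^-1; need dt <= %.3g fs",
           dt, fmax, .period_fs(fmax) / 10)
  set.seed(seed)
  n <- round((max(schedule$segments$end) - min(schedule$segments$start)) / dt)
  b <- .bond_series(schedule, dt, n)
  coords <- array(0, dim = c(n, 2, 3))
  coords[, 2, 1] <- b
  top <- topology(labels = c("C2", "O2"), elements = c("C", "O"),
                  groups = list("C2=O2" = 1:2, peptide = 1:2,
                                water = integer(0)))
  traj <- trajectory(coords, dt = dt, top = top)
  attr(traj, "ground_truth") <- list(schedule = schedule, bond = b)
  traj
}

.rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.rownorm <- function(a) a / sqrt(rowSums(a^2))

## duty-cycle occupancy + exchange events for one hydration segment
.segment_occupancy <- function(frames, target, rate, dt) {
  nseg <- length(frames)
  base <- floor(target + 1e-9)
  frac <- target - base
  occ <- matrix(FALSE, nseg, 0)
  events <- integer(0)
  cycle <- if (rate > 0) max(2L, round(1 / (rate * dt))) else nseg
  if (frac > 1e-9) {
    on_len <- round(frac * cycle)
    pattern <- rep(c(TRUE, FALSE), c(on_len, cycle - on_len))
    occ_frac <- rep_len(pattern, nseg)
  } else occ_frac <- NULL
  if (rate > 0) {
    events <- frames[seq(1L, nseg, by = cycle)]
    if (!length(events)) events <- frames[ceiling(nseg / 2)]
  }
  list(base = base, occ_frac = occ_frac, events = events)
}

#' Hydration trajectory: scheduled waters around a carbonyl acceptor
#'
#' Places water molecules around the `"C2=O2"` acceptor of the peptide
#' fixture so the per-segment mean geometric hydrogen-bond count matches the
#' schedule target. Integer parts of the target are persistently bonded
#' waters; a fractional part is realized by one water duty-cycling between
#' the bonded geometry and a parked position outside the criteria, with a
#' cycle length of `1/rate` fs. At exchange events the occupying water swaps
#' identity with a background water (which otherwise stays outside 4.5 A),
#' so rank labels can map to changing water identities as in a real shell.
#' Optionally the C=O bond length follows a [frequency_schedule()].
#'
#' @param schedule a [hydration_schedule()]
#' @param peptide fixture list with `topology` and `positions`
#'   (default [peptide_fixture()])
#' @param dt timestep, fs
#' @param seed RNG seed
#' @param freq_schedule optional [frequency_schedule()] modulating the C=O
#'   bond of the acceptor group
#' @param n_background number of background (shell 4.5-6.5 A) waters
#' @param box optional cubic box edge, Angstrom
#' @return a [trajectory()]; ground truth (occupancy, identities, schedules)
#'   in `attr(, "ground_truth")`
#' @export
gen_hydration_trajectory <- function(schedule, peptide = peptide_fixture(),
                                     dt = 0.5, seed = 1,
                                     freq_schedule = NULL,
                                     n_background = 3, box = NULL) {
  set.seed(seed)
  seg <- schedule$segments
  n <- round((max(seg$end) - min(seg$start)) / dt)
  t <- (seq_len(n) - 1) * dt
  top_p <- peptide$topology
  if (!"C2=O2" %in% names(top_p$groups)) .stopf("peptide fixture lacks a C2=O2 group")
  acc <- select_group(top_p, "C2=O2")          # (C, O)
  pC <- peptide$positions[acc[1], ]
  pO <- peptide$positions[acc[2], ]
  u <- (pO - pC) / sqrt(sum((pO - pC)^2))      # C=O axis
  ## occupancy and identity bookkeeping -------------------------------------
  n_slots <- max(ceiling(seg$target - 1e-9))
  occ <- matrix(FALSE, n, max(n_slots, 1))
  events <- list()
  for (i in seq_len(nrow(seg))) {
    fr <- which(t >= seg$start[i] & t < seg$end[i])
    so <- .segment_occupancy(fr, seg$target[i], seg$rate[i], dt)
    if (so$base > 0) occ[fr, seq_len(so$base)] <- TRUE
    if (!is.null(so$occ_frac)) occ[fr, so$base + 1L] <- so$occ_frac
    events[[i]] <- so$events
  }
  events <- sort(unique(unlist(events)))
  n_waters <- n_slots + n_background
  ## role_of[m] = role occupied by molecule m; roles 1..n_slots are bonded
  ## slots, the rest are parked shell positions. Swap at exchange events.
  role_series <- matrix(0L, n, n_waters)
  role_of <- seq_len(n_waters)
  ev_ptr <- 1L; bg_rot <- 0L
  for (i in seq_len(n)) {
    while (ev_ptr <= length(events) && events[ev_ptr] == i) {
      if (n_background > 0 && n_slots > 0) {
        slot <- 1L + (ev_ptr %% n_slots)
        bg_rot <- bg_rot %% n_background + 1L
        park <- n_slots + bg_rot
        m_slot <- which(role_of == slot); m_park <- which(role_of == park)
        role_of[m_slot] <- park; role_of[m_park] <- slot
      }
      ev_ptr <- ev_ptr + 1L
    }
    role_series[i, ] <- role_of
  }
  ## positions per role ------------------------------------------------------
  ## local frame perpendicular to the C=O axis
  helper <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- helper - sum(helper * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross3(u, e1)
  d_oh <- 0.9572; hoh <- 104.52 * pi / 180
  base_az <- (seq_len(max(n_slots, 1)) - 1) * 2 * pi / max(n_slots, 1)
  role_xyz <- vector("list", n_waters)   # each: list(O, H1, H2) n x 3
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  for (k in seq_len(n_slots)) {
    r <- clip(stats::rnorm(n, schedule$r_mean, schedule$r_sd), 1.5, 2.45)
    th <- clip(stats::rnorm(n, schedule$theta_mean, schedule$theta_sd), 0, 44) * pi / 180
    alpha <- clip(stats::rnorm(n, 50, 8), 25, 75) * pi / 180   # off-axis polar angle
    phi <- base_az[k] + stats::rnorm(n, 0, 0.15)
    d <- outer(cos(alpha), u) +
         sin(alpha) * (cos(phi) %o% e1 + sin(phi) %o% e2)
    ## parked geometry when the slot is unoccupied
    r_eff <- ifelse(occ[, k], r, 4.2)
    H1 <- matrix(pO, n, 3, byrow = TRUE) + r_eff * d
    a <- -d                                       # unit H -> acceptor
    p1 <- .rownorm(.rowcross(a, matrix(u, n, 3, byrow = TRUE)))
    p2 <- .rowcross(a, p1)
    psi <- stats::rnorm(n, 0, 0.3)
    perp <- cos(psi) * p1 + sin(psi) * p2
    th_eff <- ifelse(occ[, k], th, 100 * pi / 180)  # parked: pointing away
    vOH <- -cos(th_eff) * a + sin(th_eff) * perp    # unit H -> O_w
    Ow <- H1 + d_oh * vOH
    v1 <- -vOH                                      # unit O_w -> H1
    q <- .rownorm(.rowcross(v1, perp))
    v2 <- cos(hoh) * v1 + sin(hoh) * q
    H2 <- Ow + d_oh * v2
    role_xyz[[k]] <- list(O = Ow, H1 = H1, H2 = H2)
  }
  for (k in seq_len(n_background)) {
    ## mostly out of the peptide plane so background waters never crowd the
    ## other polar groups
    dir0 <- c(stats::rnorm(2, 0, 0.4), sample(c(-1, 1), 1) * stats::runif(1, 0.8, 1.2))
    dir0 <- dir0 / sqrt(sum(dir0^2))
    dist <- pmax(stats::runif(1, 5.0, 6.5) + stats::rnorm(n, 0, 0.15), 4.6)
    Ow <- matrix(pO, n, 3, byrow = TRUE) + dist * matrix(dir0, n, 3, byrow = TRUE)
    ## hydrogens pointing outward (never toward the acceptor)
    H1 <- Ow + d_oh * matrix(dir0, n, 3, byrow = TRUE)
    vperp <- .cross3(dir0, if (abs(dir0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0))
    vperp <- vperp / sqrt(sum(vperp^2))
    v2 <- cos(hoh) * dir0 + sin(hoh) * vperp
    H2 <- Ow + d_oh * matrix(v2, n, 3, byrow = TRUE)
    role_xyz[[n_slots + k]] <- list(O = Ow, H1 = H1, H2 = H2)
  }
  ## assemble ----------------------------------------------------------------
  np <- nrow(peptide$positions)
  natoms <- np + 3 * n_waters
  coords <- array(0, dim = c(n, natoms, 3))
  for (a_ in seq_len(np))
    coords[, a_, ] <- matrix(peptide$positions[a_, ], n, 3, byrow = TRUE)
  if (!is.null(freq_schedule)) {
    b <- .bond_series(freq_schedule, dt, n)
    coords[, acc[2], ] <- matrix(pC, n, 3, byrow = TRUE) + b %o% u
  }
  for (m in seq_len(n_waters)) {
    base <- np + 3 * (m - 1)
    for (i_part in 1:3) {
      part <- c("O", "H1", "H2")[i_part]
      ## gather this molecule's role positions frame by frame (vectorized
      ## over roles: molecules swap roles only at sparse events)
      xyz <- matrix(0, n, 3)
      for (role in unique(role_series[, m])) {
        sel <- role_series[, m] == role
        xyz[sel, ] <- role_xyz[[role]][[part]][sel, , drop = FALSE]
      }
      coords[, base + i_part, ] <- xyz
    }
  }
  wlab <- as.vector(t(outer(seq_len(n_waters), c("OW", "HW1", "HW2"),
                            function(i, s) paste0(s, i))))
  labels <- c(top_p$labels, wlab)
  elements <- c(top_p$elements, rep(c("O", "H", "H"), n_waters))
  groups <- top_p$groups
  groups$water <- np + seq_len(3 * n_waters)
  groups$peptide <- seq_len(np)
  top <- topology(labels, elements, bonds = top_p$bonds, groups = groups,
                  peptide_bonds = top_p$peptide_bonds)
  top$masses[top$elements == "H"] <- 2.014   # heavy water / deuterated amides
  traj <- trajectory(coords, dt = dt, top = top, box = box)
  attr(traj, "ground_truth") <- list(
    schedule = schedule, freq_schedule = freq_schedule,
    occupancy = occ, role_series = role_series, n_slots = n_slots,
    events = events)
  traj
}

#' Pair of series with a prescribed population correlation
#'
#' `y = r x + sqrt(1 - r^2) z` with independent standard-normal `x`, `z`.
#'
#' @param n series length (>= 3)
#' @param target_r population Pearson correlation, in `[-1, 1]`
#' @param seed RNG seed
#' @return list with `x`, `y` and `attr(, "ground_truth")` = target
#' @export
gen_correlated_series <- function(n, target_r, seed = 1) {
  if (abs(target_r) > 1) .stopf("|target_r| must be <= 1")
  if (n < 3) .stopf("n must be >= 3")
  set.seed(seed)
  x <- stats::rnorm(n)
  z <- stats::rnorm(n)
  y <- target_r * x + sqrt(1 - target_r^2) * z
  out <- list(x = x, y = y)
  attr(out, "ground_truth") <- target_r
  out
}

#' Interaction-energy records drawn from labeled zones
#'
#' Draws per-water interaction records from Gaussian zones (strong /
#' moderate / weak in the intended use), with the true zone labels stored so
#' clustering can be scored. Zones whose energy means are separated by less
#' than 3 pooled standard deviations are flagged degenerate.
#'
#' @param zone_params data.frame with columns `mean_E`, `sd_E` (kcal/mol),
#'   `mean_r` (Angstrom), `mean_theta` (deg), `n` (record count per zone)
#' @param seed RNG seed
#' @return data.frame of class `interaction_records` with columns `frame`,
#'   `water`, `r`, `theta`, `energy`, `zone_truth`
#' @export
gen_interaction_records <- function(zone_params, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (z in seq_len(nrow(zone_params))) {
    zp <- zone_params[z, ]
    if (zp$n == 0) next
    rows[[z]] <- data.frame(
      frame = seq_len(zp$n),
      water = z,
      r = pmax(stats::rnorm(zp$n, zp$mean_r, 0.15), 1.2),
      theta = pmin(pmax(stats::rnorm(zp$n, zp$mean_theta, 8), 0), 180),
      energy = stats::rnorm(zp$n, zp$mean_E, zp$sd_E),
      zone_truth = z)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("interaction_records", "data.frame")
  means <- zone_params$mean_E[zone_params$n > 0]
  pooled <- sqrt(mean(zone_params$sd_E[zone_params$n > 0]^2))
  degen <- length(means) < 2 || min(diff(sort(means))) < 3 * pooled
  attr(out, "ground_truth") <- list(zone_params = zone_params,
                                    degenerate = degen)
  out
}

#' Backbone-torsion series with metastable states
#'
#' Markov switching between wrapped-normal states on the (phi, psi) plane.
#' The transition kernel jumps to the stationary distribution with
#' probability `trans_prob`, so the planted weights are exactly the
#' stationary state probabilities.
#'
#' @param states data.frame with columns `phi`, `psi` (deg), `weight`
#'   (sums to 1) and `kappa` (concentration; angular sd is
#'   `(180/pi)/sqrt(kappa)` degrees, `Inf` = frozen at the center)
#' @param n number of frames
#' @param trans_prob per-frame switching probability (default 0.1)
#' @param seed RNG seed
#' @return list with `phi`, `psi`, `state` (integer series) and ground truth
#' @export
gen_torsion_series <- function(states, n, trans_prob = 0.1, seed = 1) {
  if (abs(sum(states$weight) - 1) > 1e-9) .stopf("state weights must sum to 1")
  set.seed(seed)
  ns <- nrow(states)
  st <- integer(n)
  st[1] <- sample.int(ns, 1, prob = states$weight)
  if (n > 1) {
    jump <- stats::runif(n - 1) < trans_prob
    targets <- sample.int(ns, n - 1, replace = TRUE, prob = states$weight)
    for (i in 2:n) st[i] <- if (jump[i - 1]) targets[i - 1] else st[i - 1]
  }
  sd_deg <- ifelse(is.finite(states$kappa), (180 / pi) / sqrt(states$kappa), 0)
  phi <- wrap_angle(states$phi[st] + stats::rnorm(n, 0, sd_deg[st]))
  psi <- wrap_angle(states$psi[st] + stats::rnorm(n, 0, sd_deg[st]))
  out <- list(phi = phi, psi = psi, state = st)
  attr(out, "ground_truth") <- list(states = states, trans_prob = trans_prob)
  out
}
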