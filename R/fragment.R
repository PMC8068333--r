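## Capped CONH fragments, supermolecular interaction energies through a
## pluggable backend, interaction-zone clustering, and energy-frequency
## correlation.
##
## The supermolecular interaction energy is E(fragment+water) - E(fragment)
## - E(water), all three from the same backend. The built-in backend is a
## fixed-point-charge Coulomb + Lennard-Jones toy model: it reproduces the
## qualitative physics (attractive hydrogen-bond well between 1.6 and 2.2 A,
## repulsive wall at short range, ~r^-3 multipole falloff) but not
## quantum-chemical magnitudes.

#' Extract a hydrogen-capped CONH fragment
#'
#' Copies the C, O, N and amide-H atoms of the chosen peptide bond and caps
#' the broken C(alpha)-C and N-C(alpha) bonds with hydrogens placed along the
#' former bond vectors (C-H 1.09 A, N-H 1.01 A), preserving the valency of
#' the peptide-bond unit. Atom order: C, O, N, H(amide), H(cap at C),
#' H(cap at N).
#'
#' @param traj a [trajectory()] whose topology defines `peptide_bonds`
#' @param frame frame index
#' @param bond_id peptide-bond name (e.g. `"C2=O2"`)
#' @return object of class `fragment_geometry`: `elements`, `xyz` (6 x 3),
#'   `types` (charge/LJ type per atom), `molecule` (all 1), provenance fields
#' @export
extract_capped_fragment <- function(traj, frame, bond_id) {
  pb <- traj$topology$peptide_bonds[[bond_id]]
  if (is.null(pb)) .stopf("no peptide bond '%s' in topology (have: %s)", bond_id,
                          paste(names(traj$topology$peptide_bonds), collapse = ", "))
  p <- frame_positions(traj, frame)
  cap <- function(from, to, len) {
    v <- p[to, ] - p[from, ]
    p[from, ] + len * v / sqrt(sum(v^2))
  }
  xyz <- rbind(p[pb$C, ], p[pb$O, ], p[pb$N, ], p[pb$H, ],
               cap(pb$C, pb$ca_prev, 1.09),
               cap(pb$N, pb$ca_next, 1.01))
  structure(list(elements = c("C", "O", "N", "H", "H", "H"),
                 xyz = xyz,
                 types = c("C_carbonyl", "O_carbonyl", "N_amide", "H_amide",
                           "H_cap", "H_cap"),
                 molecule = rep(1L, 6),
                 frame = frame, bond_id = bond_id,
                 cut_bonds = list(c(pb$ca_prev, pb$C), c(pb$N, pb$ca_next))),
            class = "fragment_geometry")
}

#' @export
print.fragment_geometry <- function(x, ...) {
  cat(sprintf("<fragment_geometry> %d atoms (%s), %d molecule(s)\n",
              nrow(x$xyz), paste(x$elements, collapse = ""),
              max(x$molecule)))
  invisible(x)
}

#' Attach one water molecule to a fragment
#'
#' The water's coordinates are taken unchanged except for minimum imaging
#' relative to the fragment's carbonyl oxygen (the whole molecule is shifted
#' by the image offset of its oxygen). Any intermolecular pair closer than
#' 0.8 A flags the geometry with `attr(, "overlap") = TRUE`.
#'
#' @param fragment a `fragment_geometry`
#' @param traj the source [trajectory()]
#' @param frame frame index
#' @param water water molecule index (into [water_molecules()])
#' @return combined `fragment_geometry` (9 atoms, molecules 1 and 2)
#' @export
attach_water <- function(fragment, traj, frame, water) {
  w <- water_molecules(traj$topology)[[water]]
  if (is.null(w)) .stopf("no water molecule %d", water)
  p <- frame_positions(traj, frame)
  wxyz <- p[w, , drop = FALSE]
  if (!is.null(traj$box)) {
    o_acc <- fragment$xyz[2, ]
    shift <- minimum_image(wxyz[1, ] - o_acc, traj$box) - (wxyz[1, ] - o_acc)
    wxyz <- sweep(wxyz, 2, shift, `+`)
  }
  out <- fragment
  out$elements <- c(fragment$elements, "O", "H", "H")
  out$xyz <- rbind(fragment$xyz, wxyz)
  out$types <- c(fragment$types, "O_water", "H_water", "H_water")
  out$molecule <- c(fragment$molecule, rep(2L, 3))
  dmin <- min(as.matrix(stats::dist(out$xyz))[out$molecule == 1, out$molecule == 2])
  if (dmin < 0.8) attr(out, "overlap") <- TRUE
  out
}

## frozen toy-model parameters: TIP3P-like water, amide charges rounded from
## common fixed-charge force fields, caps absorbing the residual so the
## fragment is neutral. Chosen once; tests depend on these being bit-stable.
.toy_params <- list(
  q = c(C_carbonyl = 0.51, O_carbonyl = -0.51, N_amide = -0.47,
        H_amide = 0.31, H_cap = 0.08, O_water = -0.834, H_water = 0.417),
  sigma = c(C_carbonyl = 3.40, O_carbonyl = 2.96, N_amide = 3.25,
            H_amide = 1.07, H_cap = 2.50, O_water = 3.1507, H_water = 0),
  eps = c(C_carbonyl = 0.086, O_carbonyl = 0.21, N_amide = 0.17,
          H_amide = 0.0157, H_cap = 0.0157, O_water = 0.1521, H_water = 0))

#' Toy electrostatics + Lennard-Jones energy backend
#'
#' Deterministic all-pairs fixed-point-charge Coulomb plus Lennard-Jones
#' (Lorentz-Berthelot combining) evaluator satisfying the energy-backend
#' contract: `evaluate(geometry)` returns a total energy in kcal/mol.
#' Intramolecular terms cancel exactly in supermolecular differences because
#' the monomer coordinates are identical in both evaluations. A stand-in for
#' an external quantum-chemistry engine, reproducing trends only.
#'
#' @return object of class `energy_backend` with fields `evaluate`, `name`,
#'   `deterministic`
#' @export
toy_energy_backend <- function() {
  pars <- .toy_params
  evaluate <- function(geometry) {
    xyz <- geometry$xyz
    types <- geometry$types
    n <- nrow(xyz)
    if (n < 2) return(0)
    q <- pars$q[types]; sg <- pars$sigma[types]; ep <- pars$eps[types]
    if (anyNA(q)) .stopf("unknown atom type(s): %s",
                         paste(unique(types[is.na(q)]), collapse = ", "))
    e <- 0
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      d <- sqrt(colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2))
      e <- e + sum(.coulomb_kcal * q[i] * q[j] / d)
      sij <- (sg[i] + sg[j]) / 2
      eij <- sqrt(ep[i] * ep[j])
      lj <- eij > 0
      if (any(lj)) {
        sr6 <- (sij[lj] / d[lj])^6
        e <- e + sum(4 * eij[lj] * (sr6^2 - sr6))
      }
    }
    e
  }
  structure(list(evaluate = evaluate, name = "toy-coulomb-lj",
                 deterministic = TRUE),
            class = "energy_backend")
}

#' Supermolecular interaction energy of a fragment-water pair
#'
#' `E(fragment + water) - E(fragment) - E(water)`, each term from the same
#' backend.
#'
#' @param combined a two-molecule `fragment_geometry` from [attach_water()]
#' @param backend an `energy_backend` (default [toy_energy_backend()])
#' @return interaction energy in kcal/mol
#' @export
interaction_energy <- function(combined, backend = toy_energy_backend()) {
  if (max(combined$molecule) != 2) .stopf("geometry must contain exactly two molecules")
  sub <- function(m) {
    g <- combined
    keep <- combined$molecule == m
    g$elements <- g$elements[keep]; g$xyz <- g$xyz[keep, , drop = FALSE]
    g$types <- g$types[keep]; g$molecule <- g$molecule[keep]
    g
  }
  backend$evaluate(combined) - backend$evaluate(sub(1)) - backend$evaluate(sub(2))
}

#' Per-frame interaction records for the ranked closest waters
#'
#' Samples the trajectory every `every` fs, ranks waters by oxygen distance
#' to the acceptor oxygen, and records distance, angle and supermolecular
#' interaction energy for the `n_waters` closest ones, plus each water's
#' closest-hydrogen distance to the fragment's N-D group.
#'
#' @param traj a [trajectory()]
#' @param bond_id peptide-bond name (default `"C2=O2"`)
#' @param backend an `energy_backend`
#' @param every sampling interval in fs (default 50)
#' @param n_waters ranks to keep (default 4)
#' @return data.frame of class `interaction_records`: `frame`, `time`,
#'   `rank`, `water`, `d_oo`, `r`, `theta`, `energy`, `nd_dist`
#' @export
collect_interaction_records <- function(traj, bond_id = "C2=O2",
                                        backend = toy_energy_backend(),
                                        every = 50, n_waters = 4) {
  step <- max(1L, round(every / traj$dt))
  frames <- seq(1L, n_frames(traj), by = step)
  waters <- water_molecules(traj$topology)
  pb <- traj$topology$peptide_bonds[[bond_id]]
  if (is.null(pb)) .stopf("no peptide bond '%s'", bond_id)
  geo <- .group_water_geometry(traj, bond_id)   # once, vectorized over frames
  nw <- length(geo)
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    frag <- extract_capped_fragment(traj, f, bond_id)
    d_oo <- vapply(geo, function(w) w$d_oo[f], 0)
    ord <- order(d_oo, seq_len(nw))[seq_len(min(n_waters, nw))]
    rk <- data.frame(rank = paste0("W", seq_along(ord)), water = ord,
                     d_oo = d_oo[ord],
                     r = vapply(geo[ord], function(w) w$r[f], 0),
                     theta = vapply(geo[ord], function(w) w$theta[f], 0))
    p <- frame_positions(traj, f)
    hD <- p[pb$H, ]
    e <- numeric(nrow(rk)); nd <- numeric(nrow(rk))
    for (k in seq_len(nrow(rk))) {
      comb <- attach_water(frag, traj, f, rk$water[k])
      e[k] <- interaction_energy(comb, backend)
      w <- waters[[rk$water[k]]]
      nd[k] <- min(sqrt(colSums((t(p[w[2:3], , drop = FALSE]) - hD)^2)))
    }
    rows[[fi]] <- data.frame(frame = f, time = traj$times[f], rank = rk$rank,
                             water = rk$water, d_oo = rk$d_oo, r = rk$r,
                             theta = rk$theta, energy = e, nd_dist = nd)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("interaction_records", "data.frame")
  out
}

.zone_labels <- function(k) {
  switch(as.character(k),
         "2" = c("strong", "weak"),
         "3" = c("strong", "moderate", "weak"),
         "4" = c("very strong", "strong", "moderate", "weak"),
         paste0("zone", seq_len(k)))
}

#' Cluster interaction records into interaction zones
#'
#' k-means over the interaction energy (default) or jointly over
#' standardized (energy, r, theta), best of `restarts` random starts.
#' Clusters are relabeled by ascending mean energy, so the most negative
#' cluster is the "strong" (hydrogen-bonded) zone.
#'
#' @param records an `interaction_records` data.frame
#' @param k number of zones (2, 3 or 4; default 3)
#' @param seed RNG seed for the restarts
#' @param restarts number of k-means restarts (default 50)
#' @param features `"energy"` (1D, default) or `"joint"` (energy, r, theta)
#' @return object of class `zone_model`: `centers` (kcal/mol, ascending),
#'   `labels`, `assignment` (factor per record), `k`, `features`
#' @export
kmeans_zones <- function(records, k = 3, seed = 1, restarts = 50,
                         features = c("energy", "joint")) {
  features <- match.arg(features)
  if (nrow(records) < k) .stopf("need at least k = %d records", k)
  x <- if (features == "energy") matrix(records$energy, ncol = 1)
       else scale(cbind(records$energy, records$r, records$theta))
  if (all(apply(x, 2, stats::sd) < 1e-12)) .stopf("degenerate records: zero variance")
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100)
  mean_e <- tapply(records$energy, km$cluster, mean)
  ord <- order(mean_e)                     # ascending: most negative first
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labs <- .zone_labels(k)
  assignment <- factor(labs[relabel[km$cluster]], levels = labs)
  structure(list(centers = as.numeric(mean_e[ord]), labels = labs,
                 assignment = assignment, k = k, features = features),
            class = "zone_model")
}

#' @export
print.zone_model <- function(x, ...) {
  cat(sprintf("<zone_model> k = %d on %s: %s\n", x$k, x$features,
              paste(sprintf("%s = %.2f", x$labels, x$centers), collapse = ", ")))
  invisible(x)
}

#' Per-frame occupancy of the strong and moderate zones
#'
#' @param records an `interaction_records` data.frame
#' @param zones a fitted `zone_model` (assignment aligned with `records`)
#' @return data.frame with `frame`, `time` (if present), `strong`, `moderate`
#' @export
zone_occupancy <- function(records, zones) {
  if (length(zones$assignment) != nrow(records))
    .stopf("zone model was fitted on a different record set")
  strong_lvls <- intersect(c("very strong", "strong"), zones$labels)
  fr <- unique(records$frame)
  s <- vapply(fr, function(f) sum(records$frame == f &
                                  zones$assignment %in% strong_lvls), 0)
  m <- vapply(fr, function(f) sum(records$frame == f &
                                  zones$assignment == "moderate"), 0)
  out <- data.frame(frame = fr, strong = s, moderate = m)
  if ("time" %in% names(records))
    out$time <- records$time[match(fr, records$frame)]
  out
}

#' Pearson correlation between interaction energies and instantaneous
#' frequencies
#'
#' Computed over frames where both series are valid (finite energy, valid
#' frequency); at least 10 overlapping frames are required.
#'
#' @param energy numeric vector, one value per frame of `freq`
#' @param freq an `instfreq_series`, or a numeric vector
#' @return Pearson correlation coefficient
#' @export
correlate_energy_frequency <- function(energy, freq) {
  f <- if (inherits(freq, "instfreq_series")) {
    v <- freq$frequency; v[!freq$valid] <- NA; v
  } else freq
  if (length(energy) != length(f)) .stopf("series lengths differ")
  ok <- is.finite(energy) & is.finite(f)
  if (sum(ok) < 10) .stopf("fewer than 10 valid overlapping frames")
  if (stats::sd(energy[ok]) < 1e-12 || stats::sd(f[ok]) < 1e-12)
    .stopf("zero-variance input")
  stats::cor(energy[ok], f[ok])
}
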