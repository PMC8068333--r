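## Backbone torsions, histogram free-energy surfaces, and backbone-state
## assignment on the Ramachandran plane.

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention, result wrapped into (-180, 180]. The syn (cis,
#' eclipsed) planar arrangement is 0 degrees; anti (trans) is 180.
#'
#' @param p1,p2,p3,p4 length-3 positions
#' @return angle in degrees
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    .stopf("collinear points: dihedral undefined")
  ang <- atan2(sum(.cross3(n1, n2) * b2) / sqrt(sum(b2^2)),
               sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

#' Wrap angles into (-180, 180]
#'
#' @param x angles in degrees
#' @return wrapped angles
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w <= -180] <- w[w <= -180] + 360   # guard the open boundary
  w
}

#' Torsion time series from a trajectory
#'
#' @param traj a [trajectory()]
#' @param idx length-4 atom indices defining the torsion
#' @return numeric vector of angles in degrees, one per frame
#' @export
torsion_series <- function(traj, idx) {
  if (length(idx) != 4) .stopf("idx must name four atoms")
  vapply(seq_len(n_frames(traj)), function(i) {
    p <- frame_positions(traj, i)
    dihedral(p[idx[1], ], p[idx[2], ], p[idx[3], ], p[idx[4], ])
  }, 0)
}

#' Two-dimensional free-energy surface from torsion histograms
#'
#' `F = -kB T ln(H / H_max)` over the binned (phi, psi) plane; the most
#' populated bin defines F = 0 and empty bins are reported as `NA`
#' (undefined), not infinities.
#'
#' @param phi,psi equal-length angle series, degrees in (-180, 180]
#' @param bins number of bins per axis (default 72, i.e. 5-degree bins)
#' @param temperature temperature in K (default 300)
#' @return object of class `free_energy_surface`: `F` grid (kcal/mol),
#'   `phi_edges`, `psi_edges`, `counts`, `temperature`
#' @export
free_energy_2d <- function(phi, psi, bins = 72, temperature = 300) {
  if (!length(phi) || length(phi) != length(psi)) .stopf("phi and psi must be equal-length, non-empty")
  if (temperature <= 0) .stopf("temperature must be > 0")
  edges <- seq(-180, 180, length.out = bins + 1)
  pi_ <- findInterval(wrap_angle(phi), edges, rightmost.closed = TRUE)
  si_ <- findInterval(wrap_angle(psi), edges, rightmost.closed = TRUE)
  counts <- matrix(0L, bins, bins)
  for (i in seq_along(pi_)) counts[pi_[i], si_[i]] <- counts[pi_[i], si_[i]] + 1L
  fmat <- matrix(NA_real_, bins, bins)
  nz <- counts > 0
  fmat[nz] <- -.kB_kcal * temperature * log(counts[nz] / max(counts))
  structure(list(F = fmat, counts = counts, phi_edges = edges,
                 psi_edges = edges, temperature = temperature),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("<free_energy_surface> %d x %d bins at %g K, max F %.2f kcal/mol\n",
              nrow(x$F), ncol(x$F), x$temperature, max(x$F, na.rm = TRUE)))
  invisible(x)
}

.backbone_centers <- data.frame(
  state = c("alpha", "beta", "L"),
  phi = c(-57, -130, 80),
  psi = c(-47, 140, 70))

#' Assign backbone states on the Ramachandran plane
#'
#' Rectangular windows of half-width `width` degrees (wrap-aware) around the
#' canonical centers: alpha-helix (-57, -47), beta-sheet (-130, +140),
#' left-handed helix (+80, +70). Points outside every window are `"other"`.
#'
#' @param phi,psi angle vectors in degrees
#' @param width window half-width in degrees (default 30)
#' @return factor with levels `alpha`, `beta`, `L`, `other`
#' @export
assign_backbone_state <- function(phi, psi, width = 30) {
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  lab <- rep("other", length(phi))
  angdiff <- function(a, b) abs(wrap_angle(a - b))
  for (k in seq_len(nrow(.backbone_centers))) {
    hit <- angdiff(phi, .backbone_centers$phi[k]) <= width &
           angdiff(psi, .backbone_centers$psi[k]) <= width
    lab[hit] <- .backbone_centers$state[k]
  }
  factor(lab, levels = c("alpha", "beta", "L", "other"))
}

#' Joint distribution of backbone states for two peptide bonds
#'
#' @param labels1,labels2 equal-length state factors (from
#'   [assign_backbone_state()])
#' @return matrix of joint probabilities (rows = first bond) summing to 1
#' @export
state_probabilities <- function(labels1, labels2) {
  if (length(labels1) != length(labels2)) .stopf("label series differ in length")
  tab <- table(labels1, labels2)
  tab / sum(tab)
}
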