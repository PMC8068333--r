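## Geometric hydrogen-bond detection, hydrogen-bonded-state time series,
## combined distance-angle distributions, water ranking, and water-bridge
## graph search.
##
## The angle convention throughout is the *deviation from linearity* of the
## donor-hydrogen-acceptor arrangement: 0 deg means perfectly linear D-H...A.
## This follows the common geometric criterion (max 2.5 A hydrogen-acceptor
## distance, max 45 deg deviation), with both boundaries inclusive.

#' Geometric hydrogen-bond criteria
#'
#' @param r_max maximal hydrogen-acceptor distance, Angstrom (default 2.5)
#' @param ang_max maximal deviation from linearity, degrees (default 45)
#' @return object of class `hbond_criteria`
#' @export
hbond_criteria <- function(r_max = 2.5, ang_max = 45) {
  if (r_max <= 0) .stopf("r_max must be > 0")
  if (ang_max <= 0 || ang_max > 180) .stopf("ang_max must be in (0, 180]")
  structure(list(r_max = r_max, ang_max = ang_max), class = "hbond_criteria")
}

## vectorized deviation-from-linearity at H, rows = observations
.deviation_deg <- function(u, v) {
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  cosang <- rowSums(u * v) / (nu * nv)
  180 - acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Test one donor-hydrogen-acceptor triple for a hydrogen bond
#'
#' True iff the hydrogen-acceptor distance is at most `r_max` and the
#' deviation from linearity of D-H...A is at most `ang_max` (both inclusive).
#' The intermolecular H...A vector is minimum-imaged when a box is given.
#'
#' @param donor,hydrogen,acceptor length-3 positions, Angstrom
#' @param criteria an [hbond_criteria()]
#' @param box orthorhombic box edges or `NULL`
#' @return logical
#' @export
is_hbonded <- function(donor, hydrogen, acceptor,
                       criteria = hbond_criteria(), box = NULL) {
  ha <- acceptor - hydrogen
  if (!is.null(box)) ha <- minimum_image(ha, box)
  r <- sqrt(sum(ha^2))
  if (r < 1e-9) .stopf("hydrogen and acceptor coincide: angle undefined")
  dev <- .deviation_deg(matrix(donor - hydrogen, ncol = 3), matrix(ha, ncol = 3))
  r <= criteria$r_max && dev <= criteria$ang_max
}

## Per-water geometry relative to a two-atom polar group, vectorized over
## frames. Acceptor groups (second atom O, e.g. "C2=O2"): waters donate, both
## water hydrogens are tested, the histogram coordinate is the closest
## hydrogen. Donor groups (second atom H, e.g. "N2-D2"): the group donates to
## the water oxygen.
.group_water_geometry <- function(traj, group, criteria = hbond_criteria()) {
  g <- select_group(traj$topology, group)
  if (length(g) != 2) .stopf("group '%s' must have two atoms (heavy, partner)", group)
  mode <- if (traj$topology$elements[g[2]] == "H") "donor" else "acceptor"
  waters <- water_molecules(traj$topology)
  nf <- n_frames(traj)
  box <- traj$box
  at <- function(i) matrix(traj$coords[, i, , drop = FALSE], ncol = 3)
  mi <- function(d) if (is.null(box)) d else minimum_image(d, box)
  out <- vector("list", length(waters))
  if (mode == "acceptor") {
    acc <- at(g[2])
    for (k in seq_along(waters)) {
      w <- waters[[k]]
      ow <- at(w[1])
      rr <- matrix(NA_real_, nf, 2); dv <- matrix(NA_real_, nf, 2)
      for (h in 1:2) {
        hw <- at(w[1 + h])
        ha <- mi(acc - hw)
        rr[, h] <- sqrt(rowSums(ha^2))
        dv[, h] <- .deviation_deg(ow - hw, ha)
      }
      closest <- (rr[, 2] < rr[, 1]) + 1L
      sel <- cbind(seq_len(nf), closest)
      doo <- sqrt(rowSums(mi(acc - ow)^2))
      out[[k]] <- list(r = rr[sel], theta = dv[sel],
                       bonded = (rr[, 1] <= criteria$r_max & dv[, 1] <= criteria$ang_max) |
                                (rr[, 2] <= criteria$r_max & dv[, 2] <= criteria$ang_max),
                       d_oo = doo)
    }
  } else {
    don <- at(g[1]); hyd <- at(g[2])
    for (k in seq_along(waters)) {
      w <- waters[[k]]
      ow <- at(w[1])
      ha <- mi(ow - hyd)
      r <- sqrt(rowSums(ha^2))
      dev <- .deviation_deg(don - hyd, ha)
      out[[k]] <- list(r = r, theta = dev,
                       bonded = r <= criteria$r_max & dev <= criteria$ang_max,
                       d_oo = r)
    }
  }
  out
}

#' Hydrogen-bond count time series for a polar group
#'
#' Per-frame number (and identities) of water molecules hydrogen-bonded to
#' the group. The hydrogen-bonded state of the group in a frame is this
#' count; its distribution over frames defines the first solvation shell
#' statistics.
#'
#' @param traj a [trajectory()] whose topology defines a `"water"` group
#' @param group polar-group name (e.g. `"C2=O2"`)
#' @param criteria an [hbond_criteria()]
#' @return object of class `hbond_series` with `counts` (integer per frame),
#'   `ids` (list of bonded water molecule indices per frame), `times`
#' @export
hbond_count_series <- function(traj, group, criteria = hbond_criteria()) {
  geo <- .group_water_geometry(traj, group, criteria)
  nf <- n_frames(traj)
  if (!length(geo)) {
    bonded <- matrix(FALSE, nf, 0)
  } else {
    bonded <- vapply(geo, `[[`, logical(nf), "bonded")
    if (nf == 1) bonded <- matrix(bonded, nrow = 1)
  }
  counts <- as.integer(rowSums(bonded))
  ids <- apply(bonded, 1, which, simplify = FALSE)
  structure(list(counts = counts, ids = ids, times = traj$times,
                 group = group, criteria = criteria),
            class = "hbond_series")
}

#' @export
print.hbond_series <- function(x, ...) {
  cat(sprintf("<hbond_series> '%s', %d frames, mean %.2f +/- %.2f\n",
              x$group, length(x$counts), mean(x$counts), stats::sd(x$counts)))
  invisible(x)
}

#' Mean and standard deviation of the H-bond count over a time window
#'
#' @param series an `hbond_series`
#' @param window length-2 fs interval (start inclusive, end exclusive), or
#'   `NULL` for the full series
#' @return named vector `c(mean, sd, n)`
#' @export
hbond_window_stats <- function(series, window = NULL) {
  sel <- if (is.null(window)) rep(TRUE, length(series$counts))
         else series$times >= window[1] & series$times < window[2]
  if (!any(sel)) .stopf("empty window")
  x <- series$counts[sel]
  c(mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Probability distribution of the hydrogen-bonded state
#'
#' @param series an `hbond_series`
#' @return named numeric vector of probabilities per count (sums to 1)
#' @export
hbond_state_distribution <- function(series) {
  if (!length(series$counts)) .stopf("empty series")
  tab <- table(factor(series$counts, levels = 0:max(series$counts)))
  p <- as.numeric(tab) / length(series$counts)
  names(p) <- names(tab)
  p
}

#' Combined distance-angle distribution of water around a polar group
#'
#' Two-dimensional density over (closest water hydrogen to acceptor distance,
#' deviation-from-linearity angle) for all waters within `r_range`,
#' normalized per frame: the grid integrates to the mean number of waters per
#' frame inside the range. Marginals `g_r` and `g_theta` are the standard
#' combined radial / angular distribution functions.
#'
#' @param traj a [trajectory()]
#' @param group polar-group name
#' @param r_range distance range, Angstrom (default `c(0, 5)`)
#' @param theta_range angle range, degrees (default `c(0, 180)`)
#' @param bins bin widths `c(dr, dtheta)` (default `c(0.05, 1)`)
#' @return object of class `dist_angle_histogram`
#' @export
dist_angle_histogram <- function(traj, group, r_range = c(0, 5),
                                 theta_range = c(0, 180), bins = c(0.05, 1)) {
  if (any(bins <= 0)) .stopf("bin widths must be > 0")
  geo <- .group_water_geometry(traj, group)
  nf <- n_frames(traj)
  r_edges <- seq(r_range[1], r_range[2], by = bins[1])
  t_edges <- seq(theta_range[1], theta_range[2], by = bins[2])
  grid <- matrix(0, nrow = length(r_edges) - 1, ncol = length(t_edges) - 1)
  for (w in geo) {
    ok <- w$r >= r_range[1] & w$r <= r_range[2] &
          w$theta >= theta_range[1] & w$theta <= theta_range[2]
    if (!any(ok)) next
    ri <- findInterval(w$r[ok], r_edges, rightmost.closed = TRUE)
    ti <- findInterval(w$theta[ok], t_edges, rightmost.closed = TRUE)
    for (i in seq_along(ri)) grid[ri[i], ti[i]] <- grid[ri[i], ti[i]] + 1
  }
  counts <- grid
  density <- grid / (nf * bins[1] * bins[2])
  structure(list(r_edges = r_edges, theta_edges = t_edges,
                 counts = counts, density = density, n_frames = nf,
                 g_r = rowSums(density) * bins[2],
                 g_theta = colSums(density) * bins[1],
                 bins = bins),
            class = "dist_angle_histogram")
}

#' @export
print.dist_angle_histogram <- function(x, ...) {
  cat(sprintf("<dist_angle_histogram> %d x %d bins, %d frames, integral %.2f waters/frame\n",
              nrow(x$counts), ncol(x$counts), x$n_frames,
              sum(x$counts) / x$n_frames))
  invisible(x)
}

#' Running integral of the water distribution
#'
#' Cumulative mean number of water molecules with (closest-hydrogen) distance
#' at most `r`; with `restrict = "hbond"` only waters also satisfying the
#' angle criterion are counted. Non-decreasing in `r`.
#'
#' @param hist a [dist_angle_histogram()]
#' @param r upper integration bound, Angstrom
#' @param restrict `"all"` or `"hbond"` (angle-restricted)
#' @param ang_max angle cutoff used when `restrict = "hbond"` (default 45)
#' @return mean water count (per frame)
#' @export
running_integral <- function(hist, r, restrict = c("all", "hbond"), ang_max = 45) {
  restrict <- match.arg(restrict)
  if (r < hist$r_edges[1] || r > hist$r_edges[length(hist$r_edges)])
    .stopf("r = %g outside histogram range", r)
  rbins <- which(hist$r_edges[-1] <= r + 1e-12)
  if (!length(rbins)) return(0)
  tsel <- if (restrict == "hbond") hist$theta_edges[-1] <= ang_max + 1e-12
          else rep(TRUE, ncol(hist$counts))
  sum(hist$counts[rbins, tsel, drop = FALSE]) / hist$n_frames
}

#' Rank the closest water molecules around a carbonyl group
#'
#' Waters are sorted by their oxygen's distance to the group's acceptor
#' oxygen and relabeled W1, W2, ... per frame, so a rank can map to
#' different water identities over time. Exact distance ties break toward
#' the lower water index.
#'
#' @param traj a [trajectory()]
#' @param frame frame index
#' @param group acceptor group name
#' @param n number of ranks (default 4)
#' @return data.frame with columns `rank`, `water` (molecule index), `d_oo`,
#'   `r` (closest H to acceptor, Angstrom), `theta` (deg). If fewer than `n`
#'   waters exist all are returned with `attr(, "short") = TRUE`.
#' @export
rank_waters <- function(traj, frame, group, n = 4) {
  geo <- .group_water_geometry(traj, group)
  nw <- length(geo)
  short <- nw < n
  d_oo <- vapply(geo, function(w) w$d_oo[frame], 0)
  ord <- order(d_oo, seq_len(nw))[seq_len(min(n, nw))]
  out <- data.frame(rank = paste0("W", seq_along(ord)),
                    water = ord,
                    d_oo = d_oo[ord],
                    r = vapply(geo[ord], function(w) w$r[frame], 0),
                    theta = vapply(geo[ord], function(w) w$theta[frame], 0))
  if (short) attr(out, "short") <- TRUE
  out
}

## hydrogen-bond adjacency among waters (+ two polar groups) for one frame
.hbond_graph_edges <- function(traj, frame, groups, criteria) {
  waters <- water_molecules(traj$topology)
  nw <- length(waters)
  p <- frame_positions(traj, frame)
  box <- traj$box
  edges <- character(0)
  wnode <- function(i) paste0("w", i)
  ## group-water edges
  for (gname in groups) {
    sub <- trajectory(array(p, dim = c(1, nrow(p), 3)), dt = traj$dt,
                      top = traj$topology, box = box)
    geo <- .group_water_geometry(sub, gname, criteria)
    for (k in seq_len(nw))
      if (geo[[k]]$bonded[1]) edges <- c(edges, gname, wnode(k))
  }
  ## water-water edges (either water donating)
  mi <- function(d) if (is.null(box)) d else minimum_image(d, box)
  for (i in seq_len(nw)) for (j in seq_len(nw)) {
    if (i == j) next
    wi <- waters[[i]]; wj <- waters[[j]]
    acc <- p[wj[1], ]
    for (h in 2:3) {
      hw <- p[wi[h], ]
      ha <- mi(acc - hw)
      r <- sqrt(sum(ha^2))
      if (r <= criteria$r_max &&
          .deviation_deg(matrix(p[wi[1], ] - hw, ncol = 3),
                         matrix(ha, ncol = 3)) <= criteria$ang_max) {
        if (i < j) edges <- c(edges, wnode(i), wnode(j))
        else edges <- c(edges, wnode(j), wnode(i))
        break
      }
    }
  }
  edges
}

#' Water bridges between two polar groups
#'
#' Finds all minimal-length chains of hydrogen-bonded water molecules
#' connecting `groupA` and `groupB`, treating hydrogen bonds as undirected
#' edges (breadth-first shortest paths). The order of a bridge is its number
#' of intermediate waters; bridges longer than `max_order` are discarded.
#'
#' @param traj a [trajectory()]
#' @param frame frame index
#' @param groupA,groupB polar-group names
#' @param criteria an [hbond_criteria()]
#' @param max_order maximal number of bridging waters (default 7)
#' @return list of bridges, each `list(endpoints, path, order)` where `path`
#'   holds water molecule indices; empty list when no bridge exists
#' @export
find_water_bridges <- function(traj, frame, groupA, groupB,
                               criteria = hbond_criteria(), max_order = 7) {
  edges <- .hbond_graph_edges(traj, frame, c(groupA, groupB), criteria)
  nodes <- unique(c(groupA, groupB, edges))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(edges)) g <- igraph::add_edges(g, match(edges, nodes))
  ## dedupe parallel edges from bidirectional water-water detection
  g <- igraph::simplify(g)
  if (igraph::distances(g, groupA, groupB) == Inf) return(list())
  ps <- igraph::all_shortest_paths(g, from = groupA, to = groupB)$res
  out <- list()
  for (pth in ps) {
    nm <- igraph::V(g)$name[as.integer(pth)]
    inner <- nm[-c(1, length(nm))]
    if (!length(inner) || length(inner) > max_order) next
    if (!all(grepl("^w", inner))) next   # paths through the other group node
    out[[length(out) + 1]] <- list(endpoints = c(groupA, groupB),
                                   path = as.integer(sub("^w", "", inner)),
                                   order = length(inner))
  }
  out
}
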