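# Independent oracles and fixture builders. Everything here is deliberately
# naive (O(n^2) sums, exhaustive enumeration, closed-form formulas) and
# shares no code path with the production implementations it checks.

c_cm_fs <- 2.99792458e-5

## direct evaluation of the discretized wavelet transform
oracle_cwt <- function(x, dt, scales, params = wavelet_params()) {
  x <- x - mean(x)
  n <- length(x)
  W <- matrix(0i, length(scales), n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    for (k in seq_len(n)) {
      arg <- (seq_len(n) - k) * dt / s
      W[j, k] <- sum(x * Conj(morlet_gabor(arg, params))) / sqrt(s)
    }
  }
  W
}

## two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## dihedral via the alternative two-plane-normal formula
oracle_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cr(n1, n2) * b2) / sqrt(sum(b2^2))
  a <- atan2(y, x) * 180 / pi
  if (a <= -180) a + 360 else a
}

## exhaustive hydrogen-bond enumeration for one frame: every water hydrogen
## against every acceptor oxygen (group O or another water's O)
oracle_hbond_pairs <- function(p, waters, acceptors, r_max = 2.5, ang_max = 45,
                               box = NULL) {
  dev <- function(d_, h_, a_) {
    u <- d_ - h_; v <- a_ - h_
    180 - acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  mi <- function(v) if (is.null(box)) v else v - box * floor(v / box + 0.5)
  out <- list()
  for (wi in seq_along(waters)) {
    w <- waters[[wi]]
    for (h in 2:3) {
      for (ai in seq_along(acceptors)) {
        a <- acceptors[[ai]]
        if (identical(a$water, wi)) next
        ha <- mi(p[a$idx, ] - p[w[h], ])
        r <- sqrt(sum(ha^2))
        if (r <= r_max &&
            dev(p[w[1], ], p[w[h], ], p[w[h], ] + ha) <= ang_max)
          out[[length(out) + 1]] <- list(water = wi, acceptor = ai)
      }
    }
  }
  out
}

## exhaustive bridge search: all simple water paths between two group nodes,
## keep the minimal length <= max_order
oracle_bridges <- function(adj_gw_a, adj_gw_b, adj_ww, nw, max_order = 7) {
  paths <- list()
  best <- Inf
  recur <- function(node, visited, path) {
    if (length(path) > max_order || length(path) > best) return()
    for (nxt in seq_len(nw)) {
      if (nxt %in% visited) next
      if (!adj_ww[node, nxt]) next
      p2 <- c(path, nxt)
      if (adj_gw_b[nxt]) {
        if (length(p2) < best) { best <<- length(p2); paths <<- list() }
        if (length(p2) == best) paths[[length(paths) + 1]] <<- p2
      }
      recur(nxt, c(visited, nxt), p2)
    }
  }
  for (w0 in which(adj_gw_a)) {
    if (adj_gw_b[w0]) {
      if (1 < best) { best <- 1; paths <- list() }
      if (best == 1) paths[[length(paths) + 1]] <- w0
    }
    recur(w0, w0, w0)
  }
  unique(paths[vapply(paths, length, 1L) == best])
}

## ---- fixture builders ------------------------------------------------------

## trajectory from the peptide fixture plus explicit water coordinates;
## `waters` is a list of 3x3 matrices (rows O, H1, H2), one per frame-set or
## shared across `nframes` frames
fixture_with_waters <- function(waters, nframes = 1, box = NULL) {
  fx <- peptide_fixture()
  np <- nrow(fx$positions)
  nw <- length(waters)
  coords <- array(0, dim = c(nframes, np + 3 * nw, 3))
  for (i in seq_len(nframes)) {
    coords[i, 1:np, ] <- fx$positions
    for (k in seq_len(nw)) coords[i, np + 3 * (k - 1) + 1:3, ] <- waters[[k]]
  }
  g <- fx$topology$groups
  g$water <- np + seq_len(3 * nw)
  top <- topology(c(fx$topology$labels,
                    paste0(rep(c("OW", "HW1", "HW2"), nw), rep(seq_len(nw), each = 3))),
                  c(fx$topology$elements, rep(c("O", "H", "H"), nw)),
                  bonds = fx$topology$bonds, groups = g,
                  peptide_bonds = fx$topology$peptide_bonds)
  trajectory(coords, dt = 0.5, top = top, box = box)
}

## water donating one hydrogen toward a target point: H at distance r from
## `target`, displaced outward along `dir` (the direction away from the
## solute), deviation `theta_deg` from linearity at the hydrogen
donating_water <- function(target, dir, r, theta_deg = 0, perp = NULL) {
  dir <- dir / sqrt(sum(dir^2))
  if (is.null(perp)) {
    perp <- c(-dir[2], dir[1], 0)
    if (sum(perp^2) < 1e-9) perp <- c(1, 0, 0)
  }
  perp <- perp / sqrt(sum(perp^2))
  H1 <- target + r * dir
  th <- theta_deg * pi / 180
  vOH <- cos(th) * dir + sin(th) * perp     # from H toward the water O
  Ow <- H1 + 0.9572 * vOH
  v1 <- -vOH
  q <- c(v1[2] * perp[3] - v1[3] * perp[2],
         v1[3] * perp[1] - v1[1] * perp[3],
         v1[1] * perp[2] - v1[2] * perp[1])
  q <- q / sqrt(sum(q^2))
  hoh <- 104.52 * pi / 180
  H2 <- Ow + 0.9572 * (cos(hoh) * v1 + sin(hoh) * q)
  rbind(Ow, H1, H2)
}

## exact hydrogen-bonded water chain: water k's oxygen sits at nodes[k];
## H1 donates to the previous element (endA or the previous water's O) with
## r = spacing - 0.9572 and zero deviation; the last water's H2 donates to
## endB; other H2s point away from the chain
chain_waters <- function(endA, nodes, endB = NULL) {
  unitv <- function(v) v / sqrt(sum(v^2))
  nw <- length(nodes)
  out <- vector("list", nw)
  for (k in seq_len(nw)) {
    Ow <- nodes[[k]]
    prev <- if (k == 1) endA else nodes[[k - 1]]
    H1 <- Ow + 0.9572 * unitv(prev - Ow)
    if (k == nw && !is.null(endB)) {
      H2 <- Ow + 0.9572 * unitv(endB - Ow)
    } else {
      nxt <- if (k == nw) Ow + (Ow - prev) else nodes[[k + 1]]
      H2 <- Ow + 0.9572 * unitv(Ow - (prev + nxt) / 2)
    }
    out[[k]] <- rbind(Ow, H1, H2)
  }
  out
}

## points on a circular arc from a to b split into m equal chords of given
## length (the chain scaffold); arc lies in the plane spanned by (b - a) and
## the z axis
arc_nodes <- function(a, b, m, chord = 2.76) {
  d <- sqrt(sum((b - a)^2))
  th <- uniroot(function(th) sin(th / 2) / sin(th / (2 * m)) - d / chord,
                c(1e-6, 2 * pi - 1e-6))$root
  R <- chord / (2 * sin(th / (2 * m)))
  u <- (b - a) / d
  w <- c(0, 0, 1)
  w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
  mid <- (a + b) / 2
  cen <- mid - sqrt(max(R^2 - (d / 2)^2, 0)) * w
  a0 <- atan2(sum((a - cen) * w), sum((a - cen) * u))
  b0 <- atan2(sum((b - cen) * w), sum((b - cen) * u))
  if (b0 < a0) b0 <- b0 + 2 * pi
  lapply(seq_len(m - 1), function(k) {
    phi <- a0 + (b0 - a0) * k / m
    cen + R * (cos(phi) * u + sin(phi) * w)
  })
}

## tone helper
tone <- function(nu_cm, n, dt, amp = 1, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  amp * cos(2 * pi * c_cm_fs * nu_cm * (seq_len(n) - 1) * dt) +
    (if (noise > 0) rnorm(n, 0, noise) else 0)
}
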