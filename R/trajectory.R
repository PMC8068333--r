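## Trajectory and topology containers + multi-frame XYZ IO.
## Units: positions in Angstrom, time in fs. Atom indices are 1-based.

.element_masses <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007,
                     O = 15.999, S = 32.06)

#' Build a topology
#'
#' A topology names the atoms of the system, their elements and masses, the
#' covalent bonds, and named atom groups (polar groups such as `"C2=O2"`,
#' the `"water"` selection, ...). Deuteration is expressed as a mass override
#' (mass 2.014 amu on a hydrogen) so that geometric analyses are unaffected.
#'
#' @param labels character vector of atom labels
#' @param elements character vector of element symbols (same length)
#' @param masses numeric masses in amu; defaults looked up from the element
#' @param bonds two-column integer matrix of bonded atom index pairs
#' @param groups named list of integer index vectors
#' @param peptide_bonds named list describing peptide bonds; each entry holds
#'   indices `C`, `O`, `N`, `H`, `ca_prev`, `ca_next` (flanking alpha carbons)
#' @return an object of class `topology`
#' @export
topology <- function(labels, elements, masses = NULL,
                     bonds = matrix(integer(0), ncol = 2),
                     groups = list(), peptide_bonds = list()) {
  n <- length(labels)
  if (length(elements) != n) .stopf("labels and elements differ in length")
  if (is.null(masses)) {
    masses <- unname(.element_masses[elements])
    if (anyNA(masses)) .stopf("no default mass for element(s): %s",
                              paste(unique(elements[is.na(masses)]), collapse = ", "))
  }
  if (any(masses <= 0)) .stopf("masses must be > 0")
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (any(bonds < 1) || any(bonds > n)))
    .stopf("bond index outside 1..%d", n)
  for (g in names(groups)) {
    gi <- groups[[g]]
    if (any(gi < 1) || any(gi > n)) .stopf("group '%s' has index outside 1..%d", g, n)
  }
  structure(list(labels = labels, elements = elements, masses = masses,
                 bonds = bonds, groups = groups, peptide_bonds = peptide_bonds),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d bonds, groups: %s\n",
              length(x$labels), nrow(x$bonds),
              paste(names(x$groups), collapse = ", ")))
  invisible(x)
}

#' Set deuterium masses on selected hydrogens
#'
#' @param top a [topology()]
#' @param indices atom indices to deuterate (must be hydrogens)
#' @return the modified topology
#' @export
deuterate <- function(top, indices) {
  if (any(top$elements[indices] != "H"))
    .stopf("deuteration applies to hydrogen atoms only")
  top$masses[indices] <- .element_masses[["D"]]
  top
}

#' Build a trajectory
#'
#' @param coords numeric array `[frames, atoms, 3]` in Angstrom
#' @param dt uniform timestep in fs
#' @param top a [topology()] (atom count must match)
#' @param box orthorhombic box edge lengths in Angstrom, or `NULL`
#' @param times optional frame times in fs (defaults to `0, dt, 2 dt, ...`)
#' @return an object of class `trajectory`
#' @export
trajectory <- function(coords, dt, top, box = NULL, times = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    .stopf("coords must be an [frames, atoms, 3] array")
  if (dim(coords)[2] != length(top$labels))
    .stopf("coords has %d atoms but topology has %d",
           dim(coords)[2], length(top$labels))
  if (dt <= 0) .stopf("dt must be > 0")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(box <= 0)) .stopf("box must be 3 positive edge lengths")
  }
  n <- dim(coords)[1]
  if (is.null(times)) times <- (seq_len(n) - 1) * dt
  if (n > 1 && any(abs(diff(times) - dt) > 1e-6))
    .stopf("frame times are not uniformly spaced by dt")
  structure(list(coords = coords, dt = dt, topology = top, box = box,
                 times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, dt = %g fs%s\n",
              n_frames(x), n_atoms(x), x$dt,
              if (is.null(x$box)) "" else sprintf(", box = %s A",
                                                  paste(signif(x$box, 6), collapse = " x "))))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a trajectory
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame's positions
#'
#' @param traj a trajectory
#' @param i frame index
#' @return an atoms-by-3 matrix of positions (Angstrom)
#' @export
frame_positions <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) .stopf("frame index %d out of range", i)
  matrix(traj$coords[i, , ], ncol = 3)
}

## ---- minimum image ---------------------------------------------------------

#' Minimum-image convention for an orthorhombic box
#'
#' Wraps each displacement component into `[-edge/2, edge/2)`. With no box the
#' displacement is returned unchanged with a warning (non-periodic analysis).
#'
#' @param delta displacement vector(s): length-3 vector or n-by-3 matrix, Angstrom
#' @param box orthorhombic edge lengths (length 3), or `NULL`
#' @return wrapped displacement, same shape as `delta`
#' @export
minimum_image <- function(delta, box) {
  if (is.null(box)) {
    .warnf("minimum_image: no box given; displacement passed through")
    return(delta)
  }
  if (any(box <= 0)) .stopf("box edges must be > 0")
  if (is.matrix(delta)) {
    for (k in 1:3) delta[, k] <- delta[, k] - box[k] * floor(delta[, k] / box[k] + 0.5)
    delta
  } else {
    delta - box * floor(delta / box + 0.5)
  }
}

## ---- selections ------------------------------------------------------------

#' Look up a named atom group
#'
#' @param top a [topology()]
#' @param name registered group name
#' @return integer vector of atom indices
#' @export
select_group <- function(top, name) {
  if (!name %in% names(top$groups))
    .stopf("unknown group '%s'; available: %s", name,
           paste(names(top$groups), collapse = ", "))
  top$groups[[name]]
}

#' Water molecules of a topology
#'
#' Waters are stored as consecutive O,H,H triples inside the `"water"` group.
#'
#' @param top a [topology()]
#' @return list of integer triples `c(O, H1, H2)`, one per water molecule
#' @export
water_molecules <- function(top) {
  w <- top$groups[["water"]]
  if (is.null(w) || !length(w)) return(list())
  if (length(w) %% 3 != 0) .stopf("water group size not divisible by 3")
  split(w, rep(seq_len(length(w) / 3), each = 3))
}

## ---- XYZ IO ----------------------------------------------------------------

.parse_xyz_box <- function(comment) {
  m <- regmatches(comment, regexpr('Lattice="[^"]+"', comment))
  if (length(m)) {
    nums <- as.numeric(strsplit(gsub('Lattice="|"', "", m), "\\s+")[[1]])
    if (length(nums) == 9) return(nums[c(1, 5, 9)])
    if (length(nums) == 3) return(nums)
  }
  nums <- suppressWarnings(as.numeric(strsplit(trimws(comment), "\\s+")[[1]]))
  if (length(nums) == 3 && !anyNA(nums) && all(nums > 0)) return(nums)
  NULL
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ dialect: an atom-count line, a comment line (optionally
#' carrying the box as `Lattice="..."` or three floats), then one
#' `element x y z` line per atom. All frames must have the same atom count.
#'
#' @param path file path
#' @param dt uniform timestep between stored frames, fs
#' @param top optional [topology()]; if omitted a minimal one is built from
#'   the element column (no bonds or groups)
#' @param box optional box override (edge lengths, Angstrom)
#' @return a [trajectory()]
#' @export
read_xyz <- function(path, dt, top = NULL, box = NULL) {
  lines <- readLines(path)
  pos <- 1L; nl <- length(lines)
  frames <- list(); elements <- NULL; frame <- 0L
  while (pos <= nl && nzchar(trimws(lines[pos]))) {
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat)) .stopf("frame %d: bad atom-count line %d", frame, pos)
    if (pos + 1L + nat > nl)
      .stopf("frame %d: truncated (expected %d atoms)", frame, nat)
    comment <- lines[pos + 1L]
    if (is.null(box) && frame == 1L) box <- .parse_xyz_box(comment)
    block <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    bad_n <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad_n))
      .stopf("frame %d: malformed coordinate line %d", frame, pos + 1L + bad_n[1])
    el <- vapply(toks, `[`, "", 1L)
    xyz <- vapply(toks, function(t) suppressWarnings(as.numeric(t[2:4])), numeric(3))
    if (anyNA(xyz)) {
      badline <- pos + 1L + which(apply(is.na(xyz), 2, any))[1]
      .stopf("frame %d: non-numeric coordinate at line %d", frame, badline)
    }
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements))
      .stopf("frame %d: atom count %d differs from frame 1 (%d)",
             frame, length(el), length(elements))
    frames[[frame]] <- t(xyz)
    pos <- pos + 2L + nat
  }
  if (!frame) .stopf("no frames in '%s'", path)
  coords <- array(0, dim = c(frame, length(elements), 3))
  for (i in seq_len(frame)) coords[i, , ] <- frames[[i]]
  if (is.null(top)) {
    top <- topology(labels = paste0(elements, seq_along(elements)),
                    elements = elements)
  } else if (length(top$labels) != length(elements)) {
    .stopf("topology has %d atoms, file has %d", length(top$labels), length(elements))
  }
  trajectory(coords, dt = dt, top = top, box = box)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj a [trajectory()]
#' @param path output file
#' @param digits coordinate decimals (default 6)
#' @return `path`, invisibly
#' @export
write_xyz <- function(traj, path, digits = 6) {
  con <- file(path, "w"); on.exit(close(con))
  nat <- n_atoms(traj)
  el <- traj$topology$elements
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df", digits, digits, digits)
  boxline <- if (!is.null(traj$box))
    sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g"', traj$box[1], traj$box[2], traj$box[3])
  for (i in seq_len(n_frames(traj))) {
    p <- frame_positions(traj, i)
    writeLines(as.character(nat), con)
    writeLines(if (is.null(boxline)) sprintf("frame %d t= %g fs", i, traj$times[i])
               else sprintf("frame %d t= %g fs %s", i, traj$times[i], boxline), con)
    writeLines(sprintf(fmt, el, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

## ---- built-in peptide fixture ---------------------------------------------

#' Stylized di-amide peptide fixture
#'
#' A planar, trans-configured backbone fragment with two peptide bonds,
#' mimicking the central portion of a tetrapeptide: alpha carbons CA1-CA3 and
#' two CONH units whose carbonyls are registered as groups `"C2=O2"` and
#' `"C3=O3"` (amide deuteriums carry mass 2.014 amu). Geometry uses standard
#' bond lengths (C=O 1.23, C-N 1.33, N-H 1.01, C-C 1.52 Angstrom); it is a
#' synthetic stand-in for solute coordinates, not an optimized structure.
#'
#' @return list with elements `topology` and `positions` (11 x 3 matrix)
#' @export
peptide_fixture <- function() {
  pos <- rbind(
    CA1 = c(-1.52,  0.00, 0),
    C2  = c( 0.00,  0.00, 0),
    O2  = c( 0.56,  1.10, 0),
    N2  = c( 0.66, -1.15, 0),
    D2  = c( 1.11, -2.05, 0),
    CA2 = c( 2.07, -0.76, 0),
    C3  = c( 3.59, -0.76, 0),
    O3  = c( 4.15,  0.34, 0),
    N3  = c( 4.25, -1.91, 0),
    D3  = c( 4.70, -2.81, 0),
    CA3 = c( 5.66, -1.52, 0))
  top <- topology(
    labels   = rownames(pos),
    elements = c("C", "C", "O", "N", "H", "C", "C", "O", "N", "H", "C"),
    bonds    = cbind(c(1, 2, 2, 4, 4, 6, 7, 7, 9, 9),
                     c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11)),
    groups   = list("C2=O2" = c(2L, 3L), "C3=O3" = c(7L, 8L),
                    "N2-D2" = c(4L, 5L), "N3-D3" = c(9L, 10L),
                    peptide = 1:11, water = integer(0)),
    peptide_bonds = list(
      "C2=O2" = list(C = 2L, O = 3L, N = 4L, H = 5L, ca_prev = 1L, ca_next = 6L),
      "C3=O3" = list(C = 7L, O = 8L, N = 9L, H = 10L, ca_prev = 6L, ca_next = 11L)))
  top <- deuterate(top, c(5L, 10L))
  list(topology = top, positions = unname(pos))
}

#' Bond-length time series of a two-atom group
#'
#' For an acceptor group such as `"C2=O2"` (atom order heavy, partner) the
#' per-frame bond length |r2 - r1| is returned, minimum-imaged when the
#' trajectory has a box.
#'
#' @param traj a [trajectory()]
#' @param group two-atom group name
#' @return numeric vector, one value per frame (Angstrom)
#' @export
bond_length_series <- function(traj, group) {
  g <- select_group(traj$topology, group)
  if (length(g) != 2) .stopf("group '%s' is not a two-atom group", group)
  d <- traj$coords[, g[2], , drop = FALSE] - traj$coords[, g[1], , drop = FALSE]
  d <- matrix(d, ncol = 3)
  if (!is.null(traj$box)) d <- minimum_image(d, traj$box)
  sqrt(rowSums(d^2))
}
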