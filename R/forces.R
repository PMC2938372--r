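#' Force of a single Kelvin-Voigt element
#'
#' The element joining points `a` and `b` exerts on `a` the force
#' \deqn{f_a = [k (|r_{ab}| - L_0) + \eta\, (v_b - v_a)\cdot\hat u]\,\hat u}
#' with \eqn{\hat u} the unit axis from `a` to `b`; the force on `b` is
#' exactly `-f_a`.  The dashpot acts on the relative velocity component
#' projected on the element axis, keeping the pair central and
#' torque-free.
#'
#' @param pa,pb endpoint positions (length-2, um).
#' @param va,vb endpoint velocities (length-2, um/s).
#' @param k spring constant, nN/um.
#' @param eta viscosity, nN.s/um.
#' @param L0 rest length, um.
#' @return list with `f_a` and `f_b` (each length-2, nN).
#' @examples
#' voigt_force(c(0, 0), c(3, 0), k = 2, L0 = 1)$f_a  # (4, 0)
#' @export
voigt_force <- function(pa, pb, va = c(0, 0), vb = c(0, 0),
                        k, eta = 0, L0) {
  d <- pb - pa
  len <- sqrt(sum(d * d))
  if (len <= 0) stop("degenerate element axis: coincident endpoints")
  u <- d / len
  fmag <- k * (len - L0) + eta * sum((vb - va) * u)
  f <- fmag * u
  list(f_a = f, f_b = -f)
}

# Vectorized Voigt forces on the A endpoints of M elements (M x 2 matrix);
# forces on B endpoints are the exact negation.
voigt_forces_vec <- function(pa, pb, va, vb, k, eta, L0) {
  dx <- pb[, 1] - pa[, 1]; dy <- pb[, 2] - pa[, 2]
  len <- sqrt(dx * dx + dy * dy)
  if (any(len <= 0)) stop("degenerate element axis: coincident endpoints")
  ux <- dx / len; uy <- dy / len
  vrel <- (vb[, 1] - va[, 1]) * ux + (vb[, 2] - va[, 2]) * uy
  fmag <- k * (len - L0) + eta * vrel
  cbind(fmag * ux, fmag * uy, deparse.level = 0)
}

get_cell <- function(world, cell) {
  if (is.list(cell)) cell else world$cells[[as.character(cell)]]
}

#' Cytoskeletal (radial-element) forces on a cell's membrane nodes
#'
#' Each membrane node receives the force of its one radial Voigt element
#' to the paired nucleus node.
#'
#' @param world a `cell_world`.
#' @param cell cell record or id.
#' @return n x 2 force matrix (nN), rows in membrane ring order.
#' @export
cytoskeleton_forces <- function(world, cell) {
  cell <- get_cell(world, cell)
  if (length(cell$mem) != length(cell$nuc))
    stop("mismatched membrane/nucleus ring lengths")
  voigt_forces_vec(world$pos[cell$mem, , drop = FALSE],
                   world$pos[cell$nuc, , drop = FALSE],
                   world$vel[cell$mem, , drop = FALSE],
                   world$vel[cell$nuc, , drop = FALSE],
                   cell$k_rad, cell$eta_rad, cell$L0_rad)
}

#' Forces on a cell's nucleus nodes
#'
#' Each nucleus node receives its radial element's reaction, its one or
#' two diametral chord contributions, and its two nuclear-membrane ring
#' element contributions.
#'
#' @inheritParams cytoskeleton_forces
#' @return n x 2 force matrix, rows in nucleus ring order.
#' @export
nucleus_forces <- function(world, cell) {
  cell <- get_cell(world, cell)
  n <- cell$n
  f <- -cytoskeleton_forces(world, cell)       # radial reaction
  f <- f + ring_element_forces(world, cell, "nuc")
  if (length(cell$k_chord)) {
    partner <- chord_partner(0:(n - 1L), n) + 1L
    fa <- voigt_forces_vec(world$pos[cell$nuc, , drop = FALSE],
                           world$pos[cell$nuc[partner], , drop = FALSE],
                           world$vel[cell$nuc, , drop = FALSE],
                           world$vel[cell$nuc[partner], , drop = FALSE],
                           cell$k_chord, cell$eta_chord, cell$L0_chord)
    f <- f + fa
    # reaction on the partner endpoints
    f[partner, ] <- f[partner, ] - fa
  }
  f
}

# Forces from a closed ring of consecutive Voigt elements on its own
# nodes (membrane or nuclear membrane): node i feels elements (i-1,i)
# and (i,i+1); pairwise cancellation makes the ring sum exactly zero.
ring_element_forces <- function(world, cell, ring = c("mem", "nuc")) {
  ring <- match.arg(ring)
  ids <- cell[[ring]]
  n <- length(ids)
  nxt <- c(2:n, 1L)
  kk <- cell[[if (ring == "mem") "k_mem" else "k_nucmem"]]
  ee <- cell[[if (ring == "mem") "eta_mem" else "eta_nucmem"]]
  ll <- cell[[if (ring == "mem") "L0_mem" else "L0_nucmem"]]
  fa <- voigt_forces_vec(world$pos[ids, , drop = FALSE],
                         world$pos[ids[nxt], , drop = FALSE],
                         world$vel[ids, , drop = FALSE],
                         world$vel[ids[nxt], , drop = FALSE],
                         kk, ee, ll)
  f <- fa
  f[nxt, ] <- f[nxt, ] - fa
  f
}

#' Membrane ring element forces on a cell's membrane nodes
#'
#' Each membrane node receives the forces of its two adjacent ring
#' elements; the total over the closed ring cancels pairwise to exactly
#' zero.
#'
#' @inheritParams cytoskeleton_forces
#' @return n x 2 force matrix in membrane ring order.
#' @export
membrane_forces <- function(world, cell) {
  cell <- get_cell(world, cell)
  ring_element_forces(world, cell, "mem")
}

#' Osmotic pressure forces on a cell's membrane nodes
#'
#' The pressure differential `P_in - P_env` loads each membrane node with
#' force `(P_in - P_env) * l_i * n_i` where `l_i` is half the length of
#' the chord joining the node's two ring neighbors (the lumped supported
#' length) and `n_i` the outward unit normal to that chord.  Chord
#' vectors telescope around the ring, so the net force on any closed
#' ring is exactly zero.
#'
#' @inheritParams cytoskeleton_forces
#' @param P_env environmental pressure; defaults to the world's.
#' @return n x 2 force matrix in membrane ring order.
#' @export
pressure_forces <- function(world, cell, P_env = world$P_env) {
  cell <- get_cell(world, cell)
  xy <- cell_ring_xy(world, cell, "mem")
  dP <- cell$P_in - P_env
  if (dP == 0) return(matrix(0, cell$n, 2))
  n <- nrow(xy)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  cx <- xy[nxt, 1] - xy[prv, 1]; cy <- xy[nxt, 2] - xy[prv, 2]
  0.5 * dP * cbind(cy, -cx, deparse.level = 0)  # outward chord normal x half chord
}

#' Total intra-cellular forces on one cell
#'
#' Membrane nodes: cytoskeleton + membrane ring + pressure.  Nucleus
#' nodes: radial reaction + chords + nuclear-membrane ring.  With no
#' pressure differential the vector sum over all nodes of an isolated
#' cell is zero to rounding.
#'
#' @inheritParams pressure_forces
#' @return list with `mem` and `nuc` force matrices (n x 2 each).
#' @export
total_inner_force <- function(world, cell, P_env = world$P_env) {
  cell <- get_cell(world, cell)
  list(mem = cytoskeleton_forces(world, cell) +
         membrane_forces(world, cell) +
         pressure_forces(world, cell, P_env),
       nuc = nucleus_forces(world, cell))
}

# Outward normals for ALL membrane nodes at once (rows aligned with the
# world node table; non-membrane rows are zero).  Cached per step by the
# engine; reused by pressure and repulsion.
all_membrane_normals <- function(world) {
  nor <- matrix(0, n_nodes(world), 2)
  for (cell in world$cells) {
    xy <- cell_ring_xy(world, cell, "mem")
    nor[cell$mem, ] <- outward_normal(xy)
  }
  nor
}

# Pressure forces for all cells accumulated into an N x 2 matrix.
all_pressure_forces <- function(world, normals) {
  f <- matrix(0, n_nodes(world), 2)
  for (cell in world$cells) {
    dP <- cell$P_in - world$P_env
    if (dP == 0) next
    xy <- cell_ring_xy(world, cell, "mem")
    n <- nrow(xy)
    nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
    cx <- xy[nxt, 1] - xy[prv, 1]; cy <- xy[nxt, 2] - xy[prv, 2]
    f[cell$mem, ] <- f[cell$mem, ] + 0.5 * dP * cbind(cy, -cx, deparse.level = 0)
  }
  f
}
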