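# Cell-cell / cell-ECM coupling: ECM chains, adhesion bond lifecycle with
# rupture hysteresis, and short-range elastic repulsion.

# sample points along a piecewise-linear path at roughly 'spacing',
# keeping every vertex exactly (notch corners must survive).
path_points <- function(verts, spacing, close = FALSE) {
  out <- list(); p <- 0L
  nseg <- nrow(verts) - 1L + as.integer(close)
  for (s in seq_len(nseg)) {
    a <- verts[s, ]
    b <- verts[if (s == nrow(verts)) 1L else s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    m <- max(1L, round(len / spacing))
    tt <- (0:(m - 1L)) / m
    p <- p + 1L
    out[[p]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }
  pts <- do.call(rbind, out)
  if (!close) pts <- rbind(pts, verts[nrow(verts), , drop = FALSE])
  pts
}

#' Add an extracellular-matrix chain to a world
#'
#' The ECM is a series chain of Voigt elements (an open line or a closed
#' ring) whose nodes interact with cell membrane nodes through the same
#' adhesion and repulsion machinery as cells.  A rigid chain has all
#' nodes fixed; a deformable chain moves under drag like any node.
#'
#' @param world a `cell_world`.
#' @param geometry one of `"line"`, `"ring"`, `"line_with_gap"`,
#'   `"ring_with_hole"`.
#' @param spacing target node spacing, um.
#' @param length line length, um (line geometries).
#' @param center length-2 center of the geometry.
#' @param radius ring radius, um (ring geometries).
#' @param gap_width,gap_depth rectangular notch width and depth, um
#'   (`line_with_gap`); width must be positive.
#' @param hole_angle angular width of the removed arc, radians
#'   (`ring_with_hole`).
#' @param rigid fix all chain nodes.
#' @param drag per-node drag: scalar, vector, or `function(x, y)`
#'   (spatial profiles such as a thinned low-drag center).
#' @param k,eta chain element spring constant and viscosity.
#' @param adh adhesion template of the chain (list `k`, `eta`, `L0`).
#' @return updated world; the chain id is in `attr(, "ecm_id")`.
#' @export
build_ecm <- function(world, geometry = c("line", "ring", "line_with_gap",
                                          "ring_with_hole"),
                      spacing = 2, length = 100, center = c(0, 0),
                      radius = 20, gap_width = NULL, gap_depth = NULL,
                      hole_angle = NULL, rigid = FALSE, drag = 50,
                      k = 10, eta = 1,
                      adh = list(k = 4, eta = 0.4, L0 = 0.5)) {
  geometry <- match.arg(geometry)
  closed <- FALSE
  if (geometry == "line") {
    verts <- rbind(c(center[1] - length / 2, center[2]),
                   c(center[1] + length / 2, center[2]))
    pts <- path_points(verts, spacing)
  } else if (geometry == "line_with_gap") {
    if (is.null(gap_width) || gap_width <= 0) stop("gap width W must be positive")
    if (is.null(gap_depth) || gap_depth <= 0) stop("gap depth must be positive")
    xl <- center[1] - gap_width / 2; xr <- center[1] + gap_width / 2
    y <- center[2]
    verts <- rbind(c(center[1] - length / 2, y),
                   c(xl, y), c(xl, y - gap_depth),
                   c(xr, y - gap_depth), c(xr, y),
                   c(center[1] + length / 2, y))
    pts <- path_points(verts, spacing)
  } else if (geometry == "ring") {
    m <- max(8L, round(2 * pi * radius / spacing))
    th <- 2 * pi * (0:(m - 1L)) / m
    pts <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
    closed <- TRUE
  } else { # ring_with_hole
    if (is.null(hole_angle) || hole_angle <= 0 || hole_angle >= 2 * pi)
      stop("hole_angle must be in (0, 2*pi)")
    span <- 2 * pi - hole_angle
    m <- max(8L, round(radius * span / spacing)) + 1L
    th <- hole_angle / 2 + span * (0:(m - 1L)) / (m - 1L)
    pts <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
  }
  id <- world$next_ecm_id
  if (is.function(drag)) drag <- drag(pts[, 1], pts[, 2])
  drag <- rep_len(drag, nrow(pts))
  base <- n_nodes(world)
  world <- append_nodes(world, pos = pts,
                        ring = rep(RING_ECM, nrow(pts)),
                        owner = rep(id, nrow(pts)),
                        idx = 0:(nrow(pts) - 1L),
                        drag = drag, mass = rep(0, nrow(pts)),
                        fixed = rep(isTRUE(rigid), nrow(pts)))
  nodes <- base + seq_len(nrow(pts))
  ne <- if (closed) nrow(pts) else nrow(pts) - 1L
  nx <- pts[c(seq_len(ne - 1L) + 1L, if (closed) 1L else ne + 1L), , drop = FALSE]
  L0 <- sqrt(rowSums((nx - pts[seq_len(ne), , drop = FALSE])^2))
  world$ecm[[as.character(id)]] <- list(
    id = id, nodes = nodes, closed = closed, rigid = isTRUE(rigid),
    k = rep(k, ne), eta = rep(eta, ne), L0 = L0, adh = adh)
  world$next_ecm_id <- id - 1L
  world$cache <- NULL
  attr(world, "ecm_id") <- id
  world
}

# adhesion template of an owner id (cell > 0, ECM chain < 0)
owner_adh_template <- function(world, id) {
  if (id > 0) world$cells[[as.character(id)]]$adh else world$ecm[[as.character(id)]]$adh
}

bond_key <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  lo * 1e7 + hi
}

#' Update the adhesion bond set
#'
#' Node pairs of different owners closer than `d_a` gain a Voigt bond
#' whose stiffness and viscosity combine the two owners' adhesion
#' templates in series and whose rest length is the mean of their
#' template rest lengths.  Existing bonds rupture only beyond `d_r`
#' (`d_a < d_r`: hysteresis).  Bonds of apoptotic cells are removed
#' unconditionally, and apoptotic cells form no new bonds.
#'
#' @param world a `cell_world`.
#' @param rule an [adhesion_rule()]; defaults to the world's.
#' @return updated world; `attr(, "created")` and `attr(, "ruptured")`
#'   are 2-column matrices of node-index pairs.
#' @export
update_adhesions <- function(world, rule = world$rule) {
  b <- world$bonds
  ruptured <- matrix(integer(0), 0, 2)
  apop <- vapply(world$cells, function(cl) cl$state == "apoptotic", logical(1))
  apop_ids <- live_cell_ids(world)[apop]
  if (length(b$a)) {
    d <- sqrt(rowSums((world$pos[b$a, , drop = FALSE] -
                       world$pos[b$b, , drop = FALSE])^2))
    drop <- d > rule$d_r |
      world$owner[b$a] %in% apop_ids | world$owner[b$b] %in% apop_ids
    if (any(drop)) {
      ruptured <- cbind(b$a[drop], b$b[drop])
      world$bonds <- b <- lapply(b, function(v) v[!drop])
    }
  }
  # candidates: membrane nodes of live non-apoptotic cells + ECM nodes
  ok_owner <- setdiff(live_cell_ids(world), apop_ids)
  cand <- which((world$ring == RING_MEMBRANE & world$owner %in% ok_owner) |
                  world$ring == RING_ECM)
  created <- matrix(integer(0), 0, 2)
  if (length(cand) > 1L) {
    pairs <- cpp_grid_pairs(world$pos, cand, world$owner, rule$d_a)
    if (nrow(pairs)) {
      if (rule$one_bond_per_pair && length(world$bonds$a)) {
        have <- bond_key(world$bonds$a, world$bonds$b)
        new <- !(bond_key(pairs[, 1], pairs[, 2]) %in% have)
        pairs <- pairs[new, , drop = FALSE]
      }
      if (nrow(pairs)) {
        oa <- world$owner[pairs[, 1]]; ob <- world$owner[pairs[, 2]]
        ks <- numeric(nrow(pairs)); es <- numeric(nrow(pairs)); ls <- numeric(nrow(pairs))
        okey <- paste(oa, ob)
        for (u in unique(okey)) {
          m <- okey == u
          ta <- owner_adh_template(world, oa[which(m)[1]])
          tb <- owner_adh_template(world, ob[which(m)[1]])
          cmb <- combine_adhesion_params(ta, tb)
          ks[m] <- cmb$k; es[m] <- cmb$eta; ls[m] <- (ta$L0 + tb$L0) / 2
        }
        world$bonds$a <- c(world$bonds$a, pairs[, 1])
        world$bonds$b <- c(world$bonds$b, pairs[, 2])
        world$bonds$k <- c(world$bonds$k, ks)
        world$bonds$eta <- c(world$bonds$eta, es)
        world$bonds$L0 <- c(world$bonds$L0, ls)
        created <- pairs
      }
    }
  }
  attr(world, "created") <- created
  attr(world, "ruptured") <- ruptured
  world
}

#' Adhesion bond forces
#'
#' Voigt forces of every live adhesion bond, accumulated per node;
#' pairwise antisymmetric, so the world total is exactly zero.
#'
#' @param world a `cell_world`.
#' @return N x 2 force matrix over all world nodes.
#' @export
adhesion_forces <- function(world) {
  b <- world$bonds
  if (!length(b$a)) return(matrix(0, n_nodes(world), 2))
  if (any(b$a > n_nodes(world)) || any(b$b > n_nodes(world)))
    stop("dangling adhesion bond endpoint")
  cpp_voigt_accumulate(world$pos, world$vel, b$a, b$b, b$k, b$eta, b$L0)$full
}

# polyline (node-index vector + closed flag) of an owner id
owner_polyline <- function(world, id) {
  if (id > 0) list(nodes = world$cells[[as.character(id)]]$mem, closed = TRUE)
  else {
    ch <- world$ecm[[as.character(id)]]
    list(nodes = ch$nodes, closed = ch$closed)
  }
}

#' Short-range elastic repulsion forces
#'
#' A membrane node whose nearest distance `d` to another owner's membrane
#' polyline (or ECM chain) is below `d_rep` receives magnitude
#' `k_rep * (d_rep - d)` along its own membrane's inward normal; the
#' reaction is distributed onto the nearest foreign segment's endpoints
#' by barycentric weights, so total momentum is conserved.  The force is
#' continuous (zero) at `d = d_rep`.
#'
#' @param world a `cell_world`.
#' @param rule an [adhesion_rule()].
#' @param normals optional precomputed outward membrane normals
#'   (N x 2, as from the engine's per-step cache).
#' @return N x 2 force matrix over all world nodes.
#' @export
repulsion_forces <- function(world, rule = world$rule, normals = NULL) {
  F0 <- matrix(0, n_nodes(world), 2)
  mem <- membrane_nodes(world)
  if (!length(mem)) return(F0)
  cand <- c(mem, ecm_nodes(world))
  # node-node prefilter must reach any node whose distance to a foreign
  # *segment* could be < d_rep: pad by the longest current segment.
  elem <- world_elements(world)
  seg_cat <- elem$cat == CAT_MEMBRANE | elem$cat == CAT_ECM_CHAIN
  if (!any(seg_cat)) return(F0)
  seg_len <- sqrt(rowSums((world$pos[elem$b[seg_cat], , drop = FALSE] -
                           world$pos[elem$a[seg_cat], , drop = FALSE])^2))
  cutoff <- rule$d_rep + max(seg_len)
  pairs <- cpp_grid_pairs(world$pos, cand, world$owner, cutoff)
  if (!nrow(pairs)) return(F0)
  pr <- rbind(pairs, pairs[, 2:1, drop = FALSE])
  sel <- world$ring[pr[, 1]] == RING_MEMBRANE
  pr <- pr[sel, , drop = FALSE]
  if (!nrow(pr)) return(F0)
  qo <- world$owner[pr[, 1]]; fo <- world$owner[pr[, 2]]
  gkey <- paste0(qo, "|", fo)
  keep <- !duplicated(paste0(pr[, 1], "_", gkey))
  qnode <- pr[keep, 1]; qg <- factor(gkey[keep])
  lev <- levels(qg)
  fid <- as.integer(sub(".*\\|", "", lev))
  polys <- lapply(fid, function(id) owner_polyline(world, id))
  polyflat <- unlist(lapply(polys, `[[`, "nodes"))
  polylen <- vapply(polys, function(p) length(p$nodes), integer(1))
  polyoff <- cumsum(c(1L, polylen[-length(polylen)]))
  polyclosed <- vapply(polys, `[[`, logical(1), "closed")
  if (is.null(normals)) normals <- all_membrane_normals(world)
  cpp_repulsion(world$pos, qnode, as.integer(qg), -normals,
                as.integer(polyflat), as.integer(polyoff),
                as.integer(polylen), polyclosed,
                rule$d_rep, rule$k_rep)
}

#' Substrate drag at a node (2D-culture mode)
#'
#' In 2D-culture mode the adhesion intensity between cell and substrate
#' is represented by the drag coefficient: this returns the configured
#' substrate field's value at a node's position, used as that node's drag
#' in the overdamped update.
#'
#' @param world a `cell_world` with a configured substrate field.
#' @param node node row index (vectorized).
#' @return drag value(s), nN.s/um.
#' @export
substrate_drag <- function(world, node) {
  if (is.null(world$substrate))
    stop("no substrate drag field configured (not in 2D-culture mode)")
  if (is.function(world$substrate))
    world$substrate(world$pos[node, 1], world$pos[node, 2])
  else rep_len(world$substrate, length(node))
}

# engine helper: refresh membrane drags of non-motile cells from the
# substrate field (motile cells manage their own drag cycle)
apply_substrate <- function(world) {
  if (is.null(world$substrate)) return(world)
  for (cell in world$cells) {
    if (cell$motile) next
    world$drag[cell$mem] <- substrate_drag(world, cell$mem)
  }
  world
}
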