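# Rule-based cellular processes: growth gating and node insertion,
# mitosis mechanics and topology surgery, apoptosis, polarization, and
# crawling-motility parameter cycling.

#' Volume-gate region of a cell
#'
#' The growth rules are gated by the current area relative to the rest
#' area: `"stop"` at or below `c_s * V_rest` (growth ends), `"growth"` at
#' or above `c_g * V_rest` (growth may continue), `"intermediate"`
#' between the two bounds, where the cell's previous regime is retained
#' (hysteresis; the engine keeps that memory).
#'
#' @param world a `cell_world`.
#' @param cell cell record or id.
#' @return one of `"stop"`, `"growth"`, `"intermediate"`.
#' @export
growth_state <- function(world, cell) {
  cell <- get_cell(world, cell)
  V <- cell_area(world, cell)
  if (V <= cell$c_s * cell$V_rest) "stop"
  else if (V >= cell$c_g * cell$V_rest) "growth"
  else "intermediate"
}

# Insert one membrane node and the paired nucleus node into local edge e
# (between ring positions e and e+1, 1-based).  Element spring/viscosity
# parameters of the two new half-edges average the first neighboring
# homogeneous elements; rest lengths split the old edge evenly (callers
# rescale).  Returns the world with the updated cell stored.
insert_paired_nodes <- function(world, cell, e) {
  n <- cell$n
  e2 <- (e %% n) + 1L
  ep <- ((e - 2L) %% n) + 1L
  for (rg in c("mem", "nuc")) {
    ids <- cell[[rg]]
    mid <- (world$pos[ids[e], ] + world$pos[ids[e2], ]) / 2
    vmid <- (world$vel[ids[e], ] + world$vel[ids[e2], ]) / 2
    world <- append_nodes(
      world, pos = matrix(mid, 1, 2),
      ring = if (rg == "mem") RING_MEMBRANE else RING_NUCLEUS,
      owner = cell$id, idx = 0L,
      drag = (world$drag[ids[e]] + world$drag[ids[e2]]) / 2,
      mass = world$mass[ids[e]],
      fixed = FALSE, label = world$label[ids[e]],
      group = world$group[ids[e]])
    world$vel[n_nodes(world), ] <- vmid
    new_id <- n_nodes(world)
    cell[[rg]] <- append(ids, new_id, after = e)
    pk <- if (rg == "mem") "k_mem" else "k_nucmem"
    pe <- if (rg == "mem") "eta_mem" else "eta_nucmem"
    pl <- if (rg == "mem") "L0_mem" else "L0_nucmem"
    # edge e splits into two; k/eta from flanking neighbors e-1 and e+1
    kv <- cell[[pk]]; ev <- cell[[pe]]; lv <- cell[[pl]]
    k1 <- (kv[ep] + kv[e]) / 2; k2 <- (kv[e] + kv[e2]) / 2
    e1 <- (ev[ep] + ev[e]) / 2; e2v <- (ev[e] + ev[e2]) / 2
    half <- lv[e] / 2
    cell[[pk]] <- append(kv, k2, after = e); cell[[pk]][e] <- k1
    cell[[pe]] <- append(ev, e2v, after = e); cell[[pe]][e] <- e1
    cell[[pl]] <- append(lv, half, after = e); cell[[pl]][e] <- half
  }
  # radial element for the new node: averages of its flanking radials
  kr <- (cell$k_rad[e] + cell$k_rad[e2]) / 2
  er <- (cell$eta_rad[e] + cell$eta_rad[e2]) / 2
  lr <- (cell$L0_rad[e] + cell$L0_rad[e2]) / 2
  cell$k_rad <- append(cell$k_rad, kr, after = e)
  cell$eta_rad <- append(cell$eta_rad, er, after = e)
  cell$L0_rad <- append(cell$L0_rad, lr, after = e)
  cell$n <- n + 1L
  world$idx[cell$mem] <- 0:(cell$n - 1L)
  world$idx[cell$nuc] <- 0:(cell$n - 1L)
  world$mass[cell$mem] <- cell$params$mass / cell$n
  world$mass[cell$nuc] <- cell$params$mass_nuc / cell$n
  world$cells[[as.character(cell$id)]] <- cell
  world$cache <- NULL
  world
}

rebuild_chords <- function(cell) {
  n <- cell$n
  kc <- if (length(cell$k_chord)) mean(cell$k_chord) else cell$params$k_chord
  ec <- if (length(cell$eta_chord)) mean(cell$eta_chord) else cell$params$eta_chord
  # effective nucleus radius from the nuclear-membrane rest perimeter
  r_eff <- mean(cell$L0_nucmem) / (2 * sin(pi / n))
  cell$k_chord <- rep(kc, n)
  cell$eta_chord <- rep(ec, n)
  cell$L0_chord <- rep(2 * r_eff * sin(pi * (n %/% 2L) / n), n)
  cell
}

#' Grow a cell by one node insertion
#'
#' Draws a uniform random ring position, inserts one membrane node and
#' the paired nucleus node at the flanking midpoints, and adds four Voigt
#' elements (membrane, nuclear membrane, radial, and a chord re-pairing)
#' with parameters averaged from the first neighboring homogeneous
#' elements.  Rest lengths rescale so the total membrane rest perimeter
#' grows by (n+1)/n, radial rest lengths by (n+1)/n, and the rest area by
#' ((n+1)/n)^2.
#'
#' @param world a `cell_world`.
#' @param cell cell record or id (must not be mitotic or apoptotic).
#' @param at optional 1-based edge index overriding the random draw
#'   (used by tests).
#' @return updated world.
#' @export
add_growth_point <- function(world, cell, at = NULL) {
  cell <- get_cell(world, cell)
  if (cell$state %in% c("mitotic", "apoptotic"))
    stop("cell ", cell$id, " cannot grow in state ", cell$state)
  n <- cell$n
  e <- if (is.null(at)) sample.int(n, 1L) else as.integer(at)
  grow <- (n + 1) / n
  tot_mem <- sum(cell$L0_mem); tot_nucmem <- sum(cell$L0_nucmem)
  world <- insert_paired_nodes(world, cell, e)
  cell <- world$cells[[as.character(cell$id)]]
  # the split edge's two halves share the perimeter increment equally, so
  # the total rest perimeter scales by exactly (n+1)/n
  old_edge_mem <- 2 * cell$L0_mem[e]
  add <- tot_mem * grow - tot_mem
  cell$L0_mem[c(e, e + 1L)] <- (old_edge_mem + add) / 2
  old_edge_nm <- 2 * cell$L0_nucmem[e]
  addn <- tot_nucmem * grow - tot_nucmem
  cell$L0_nucmem[c(e, e + 1L)] <- (old_edge_nm + addn) / 2
  cell$L0_rad <- cell$L0_rad * grow
  cell$V_rest <- cell$V_rest * grow^2
  cell$scale <- cell$scale * grow
  cell <- rebuild_chords(cell)
  world$cells[[as.character(cell$id)]] <- cell
  world$cache <- NULL
  attr(world, "event") <- list(type = "growth", cell = cell$id, n = cell$n)
  world
}

rot90 <- function(v) c(-v[2], v[1])

#' Select the division axis of a mitotic cell
#'
#' An unpolarized cell divides along the minor principal axis of its
#' membrane-node second-moment tensor (perpendicular to the elongation
#' direction), through the nucleus center of mass; a degenerate
#' (isotropic) tensor is tie-broken by the axis through membrane node 1.
#' A polarized cell divides orthogonally to the ECM-contacting (basal)
#' membrane stretch.
#'
#' @param world a `cell_world`.
#' @param cell cell record or id.
#' @return list with unit `dir` and `anchor` (nucleus center of mass).
#' @export
select_division_axis <- function(world, cell) {
  cell <- get_cell(world, cell)
  anchor <- colMeans(world$pos[cell$nuc, , drop = FALSE])
  mem <- cell_ring_xy(world, cell, "mem")
  if (cell$polarized && any(world$label[cell$mem] == LABEL_BASAL)) {
    bas <- mem[world$label[cell$mem] == LABEL_BASAL, , drop = FALSE]
    if (nrow(bas) >= 2L) {
      stretch <- bas[nrow(bas), ] - bas[1, ]
      cc <- colMeans(bas)
      if (nrow(bas) > 2L) {
        ev <- eigen(crossprod(sweep(bas, 2, cc)), symmetric = TRUE)
        stretch <- ev$vectors[, 1]
      }
      dir <- rot90(stretch / sqrt(sum(stretch^2)))
      return(list(dir = dir, anchor = anchor))
    }
  }
  cc <- colMeans(mem)
  M <- crossprod(sweep(mem, 2, cc)) / nrow(mem)
  ev <- eigen(M, symmetric = TRUE)
  rel <- (ev$values[1] - ev$values[2]) / max(ev$values[1], .Machine$double.eps)
  if (rel < 1e-6) {
    d <- mem[1, ] - anchor
    dir <- d / sqrt(sum(d^2))
  } else {
    dir <- ev$vectors[, 2]  # minor principal axis
  }
  list(dir = dir / sqrt(sum(dir^2)), anchor = anchor)
}

# node-group assignment for a division axis: side of the division line,
# falling back to an index half-ring when the line crosses the membrane
# more than twice
mitotic_groups <- function(world, cell, axis) {
  n <- cell$n
  mem <- cell_ring_xy(world, cell, "mem")
  rel <- sweep(mem, 2, axis$anchor)
  side <- rel[, 1] * axis$dir[2] - rel[, 2] * axis$dir[1]
  grp <- ifelse(side >= 0, 1L, 2L)
  runs <- rle(grp)
  n_runs <- length(runs$values) - as.integer(length(runs$values) > 1L &&
    runs$values[1] == runs$values[length(runs$values)])
  if (n_runs != 2L || sum(grp == 1L) < 3L || sum(grp == 2L) < 3L) {
    k0 <- which.min(abs(side))
    nA <- (n + 1L) %/% 2L
    locA <- ((k0 - 1L + 0:(nA - 1L)) %% n) + 1L
    grp <- rep(2L, n); grp[locA] <- 1L
  }
  grp
}

# area share of the smaller prospective daughter (sub-polygons closed
# through the two interface midpoints); used to postpone divisions whose
# cut would be badly off-center
division_balance <- function(world, cell, axis = select_division_axis(world, cell)) {
  grp <- mitotic_groups(world, cell, axis)
  n <- cell$n
  nxt <- c(2:n, 1L)
  iface <- which(grp != grp[nxt])
  if (length(iface) != 2L) return(0)
  mem <- cell_ring_xy(world, cell, "mem")
  areas <- vapply(c(1L, 2L), function(g) {
    start <- which(grp == g & grp[c(n, 1:(n - 1L))] != g)[1]
    loc <- ((start - 1L + 0:(sum(grp == g) - 1L)) %% n) + 1L
    prev_idx <- ((loc[1] - 2L) %% n) + 1L
    next_idx <- (loc[length(loc)] %% n) + 1L
    ring <- rbind((mem[prev_idx, ] + mem[loc[1], ]) / 2,
                  mem[loc, , drop = FALSE],
                  (mem[loc[length(loc)], ] + mem[next_idx, ]) / 2)
    abs(polygon_area(ring, signed = TRUE))
  }, numeric(1))
  min(areas) / sum(areas)
}

#' Partition a cell into the two mitotic groups
#'
#' Finds the membrane node nearest to the division axis, assigns the
#' contiguous half-ring starting there (and the matching nucleus nodes)
#' to group A and the rest to B, and eliminates the nucleoskeletal chords
#' (the nuclear structure collapses during mitosis).  The cell enters the
#' mitotic state.
#'
#' @param world a `cell_world`.
#' @param cell cell record or id.
#' @param axis list with `dir` and `anchor` as from
#'   [select_division_axis()].
#' @return updated world; the cell's `mito` block holds the axis, group
#'   assignment and force magnitudes.
#' @export
partition_cell <- function(world, cell, axis = select_division_axis(world, cell)) {
  cell <- get_cell(world, cell)
  n <- cell$n
  # split by the side of the division line each node lies on: through the
  # nucleus center of mass this cuts the cell into two approximately
  # equal parts even when growth has made the node spacing uneven
  grp <- mitotic_groups(world, cell, axis)
  world$group[cell$mem] <- grp
  world$group[cell$nuc] <- grp
  # chords are eliminated during mitosis
  cell$k_chord <- numeric(0); cell$eta_chord <- numeric(0); cell$L0_chord <- numeric(0)
  # orient the pull direction towards group A's current nucleus centroid
  u <- rot90(axis$dir)
  comA <- colMeans(world$pos[cell$nuc[grp == 1L], , drop = FALSE])
  comB <- colMeans(world$pos[cell$nuc[grp == 2L], , drop = FALSE])
  if (sum((comA - comB) * u) < 0) u <- -u
  cell$mito <- list(dir = axis$dir, anchor = axis$anchor, u = u, grp = grp,
                    F_div_n = cell$params$F_div_n,
                    F_div_m = cell$params$F_div_m,
                    L_div = cell$params$L_div)
  cell$state <- "mitotic"
  world$cells[[as.character(cell$id)]] <- cell
  world$cache <- NULL
  world
}

nucleus_group_separation <- function(world, cell) {
  grp <- cell$mito$grp
  comA <- colMeans(world$pos[cell$nuc[grp == 1L], , drop = FALSE])
  comB <- colMeans(world$pos[cell$nuc[grp == 2L], , drop = FALSE])
  sqrt(sum((comA - comB)^2))
}

#' Mitotic forces on one cell
#'
#' Spindle shortening pulls the two nucleus groups apart orthogonally to
#' the division axis (equal and opposite group totals), while the
#' contractile ring squeezes the two A/B membrane interfaces toward each
#' other along the axis.  Both are ramped to zero as the nucleus
#' separation approaches the division threshold, avoiding an impulsive
#' release.  The total over the cell is zero.
#'
#' @param world a `cell_world`.
#' @param cell a mitotic cell record or id.
#' @return list with `mem` and `nuc` n x 2 force matrices.
#' @export
mitosis_forces <- function(world, cell) {
  cell <- get_cell(world, cell)
  if (is.null(cell$mito)) stop("cell ", cell$id, " is not mitotic")
  n <- cell$n
  st <- cell$mito
  fm <- matrix(0, n, 2); fn <- matrix(0, n, 2)
  sep <- nucleus_group_separation(world, cell)
  # full pull until 0.8 L_div, fading linearly to zero at 1.1 L_div, so
  # the threshold is crossed decisively without an impulsive release
  ramp <- min(1, max(0, (1.1 * st$L_div - sep) / (0.3 * st$L_div)))
  if (ramp == 0) return(list(mem = fm, nuc = fn))
  grp <- st$grp
  nh <- n %/% 2L
  totA <- st$F_div_n * nh * ramp
  fn[grp == 1L, ] <- matrix(st$u * (totA / sum(grp == 1L)), sum(grp == 1L), 2, byrow = TRUE)
  fn[grp == 2L, ] <- matrix(-st$u * (totA / sum(grp == 2L)), sum(grp == 2L), 2, byrow = TRUE)
  # A/B interfaces: ring positions where the group changes
  nxt <- c(2:n, 1L)
  iface <- which(grp != grp[nxt])   # two edges (i, i+1) crossing groups
  if (length(iface) == 2L) {
    p1 <- colMeans(world$pos[cell$mem[c(iface[1], nxt[iface[1]])], , drop = FALSE])
    p2 <- colMeans(world$pos[cell$mem[c(iface[2], nxt[iface[2]])], , drop = FALSE])
    d12 <- p2 - p1
    nd <- sqrt(sum(d12^2))
    if (nd > 1e-9) {
      d12 <- d12 / nd
      h <- st$F_div_m * ramp / 2
      i1 <- c(iface[1], nxt[iface[1]]); i2 <- c(iface[2], nxt[iface[2]])
      fm[i1, ] <- fm[i1, ] + matrix(d12 * h, 2, 2, byrow = TRUE)
      fm[i2, ] <- fm[i2, ] - matrix(d12 * h, 2, 2, byrow = TRUE)
    }
  }
  list(mem = fm, nuc = fn)
}

# Build one daughter from a parent arc.  The daughter ring is the arc
# plus two fresh nodes at the midpoints of the two group-crossing edges
# (the furrow interfaces), so the two daughters tile the parent along a
# common cut line and the split conserves area.  Each daughter's copies
# of the cut nodes are offset slightly towards its own side so the two
# freshly separated membranes never coincide exactly.
daughter_from_arc <- function(world, parent, loc, offset = 0.15) {
  n <- parent$n
  q <- length(loc)
  prev_idx <- ((loc[1] - 2L) %% n) + 1L     # last node of the other group
  next_idx <- (loc[q] %% n) + 1L            # first node of the other group
  prev_edge <- prev_idx                     # edge prev -> loc[1]
  last_edge <- loc[q]                       # edge loc[q] -> next
  arc_mem <- parent$mem[loc]
  arc_nuc <- parent$nuc[loc]
  mid <- function(i, j) (world$pos[i, ] + world$pos[j, ]) / 2
  m_start <- mid(parent$mem[prev_idx], arc_mem[1])
  m_end <- mid(arc_mem[q], parent$mem[next_idx])
  n_start <- mid(parent$nuc[prev_idx], arc_nuc[1])
  n_end <- mid(arc_nuc[q], parent$nuc[next_idx])
  ctr <- colMeans(world$pos[arc_mem, , drop = FALSE])
  pull <- function(p) {
    d <- ctr - p; L <- sqrt(sum(d * d))
    if (L < 1e-9) p else p + offset * d / L
  }
  # ring order: m_start, arc nodes, m_end (counterclockwise preserved)
  new_xy_mem <- rbind(pull(m_start), pull(m_end))
  new_xy_nuc <- rbind(n_start, n_end)       # nuclei are re-seated after the split
  half <- function(v, e) v[e] / 2
  mean2 <- function(v) (v[prev_edge] + v[last_edge]) / 2
  edges <- loc[-q]                          # intra-arc edges
  # edges: m_start->arc1, arc edges, arcq->m_end, cut m_end->m_start
  build <- function(kv, lv = NULL) {
    if (is.null(lv))
      c(mean2(kv), kv[edges], mean2(kv), mean2(kv))
    else
      c(half(lv, prev_edge), lv[edges], half(lv, last_edge), mean2(lv))
  }
  list(
    arc_mem = arc_mem, arc_nuc = arc_nuc,
    new_xy_mem = new_xy_mem, new_xy_nuc = new_xy_nuc,
    k_mem = build(parent$k_mem), eta_mem = build(parent$eta_mem),
    L0_mem = build(NULL, parent$L0_mem),
    k_nucmem = build(parent$k_nucmem), eta_nucmem = build(parent$eta_nucmem),
    L0_nucmem = build(NULL, parent$L0_nucmem),
    k_rad = c(mean2(parent$k_rad), parent$k_rad[loc], mean2(parent$k_rad)),
    eta_rad = c(mean2(parent$eta_rad), parent$eta_rad[loc], mean2(parent$eta_rad)),
    L0_rad = c(mean2(parent$L0_rad), parent$L0_rad[loc], mean2(parent$L0_rad))
  )
}

#' Split a mitotic cell into two daughters
#'
#' Performs the topology surgery once the nucleus groups have separated
#' past `L_div`: group-crossing ring elements are deleted and the ring
#' endpoints re-joined within each group, producing two closed cells.
#' Each daughter is then repopulated by midpoint insertion between the
#' farthest consecutive node pair until it regains the founder node
#' count, its rest geometry is reset to the founder template
#' (`V_rest` = the parent's initial rest area) and its nucleoskeletal
#' chords are rebuilt.  The daughters adhere to each other at the next
#' bond update.
#'
#' @param world a `cell_world`.
#' @param cell a mitotic cell record or id with separated nuclei.
#' @return updated world; `attr(, "daughters")` holds the two new ids.
#' @export
split_cell <- function(world, cell) {
  parent <- get_cell(world, cell)
  if (is.null(parent$mito)) stop("cell ", parent$id, " is not mitotic")
  grp <- parent$mito$grp
  n <- parent$n
  if (sum(grp == 1L) < 3L || sum(grp == 2L) < 3L)
    stop("non-manifold surgery: a mitotic group has fewer than 3 nodes")
  # contiguous local index runs for each group (A starts where B ends)
  nxt <- c(2:n, 1L)
  startA <- which(grp == 1L & grp[c(n, 1:(n - 1L))] == 2L)[1]
  locA <- ((startA - 1L + 0:(sum(grp == 1L) - 1L)) %% n) + 1L
  startB <- which(grp == 2L & grp[c(n, 1:(n - 1L))] == 1L)[1]
  locB <- ((startB - 1L + 0:(sum(grp == 2L) - 1L)) %% n) + 1L
  pid <- parent$id
  daughters <- integer(0)
  for (loc in list(locA, locB)) {
    d <- daughter_from_arc(world, parent, loc)
    id <- world$next_cell_id
    world$next_cell_id <- id + 1L
    pr <- parent$params
    grp_here <- world$group[d$arc_mem[1]]
    # append the daughter's two cut nodes on each ring
    world <- append_nodes(world, pos = d$new_xy_mem,
                          ring = rep(RING_MEMBRANE, 2L), owner = c(id, id),
                          idx = c(0L, 0L),
                          drag = rep(pr$drag_mem, 2L),
                          mass = rep(pr$mass / (length(loc) + 2L), 2L),
                          fixed = c(FALSE, FALSE),
                          group = rep(grp_here, 2L))
    mem_new <- n_nodes(world) - 1:0
    world <- append_nodes(world, pos = d$new_xy_nuc,
                          ring = rep(RING_NUCLEUS, 2L), owner = c(id, id),
                          idx = c(0L, 0L),
                          drag = rep(pr$drag_nuc, 2L),
                          mass = rep(pr$mass_nuc / (length(loc) + 2L), 2L),
                          fixed = c(FALSE, FALSE),
                          group = rep(grp_here, 2L))
    nuc_new <- n_nodes(world) - 1:0
    d$mem <- c(mem_new[1], d$arc_mem, mem_new[2])
    d$nuc <- c(nuc_new[1], d$arc_nuc, nuc_new[2])
    celld <- list(
      id = id, mem = d$mem, nuc = d$nuc, n = length(loc) + 2L, n0 = parent$n0,
      R = parent$R, r_n = parent$r_n, scale = 1,
      k_mem = d$k_mem, eta_mem = d$eta_mem, L0_mem = d$L0_mem,
      k_nucmem = d$k_nucmem, eta_nucmem = d$eta_nucmem, L0_nucmem = d$L0_nucmem,
      k_rad = d$k_rad, eta_rad = d$eta_rad, L0_rad = d$L0_rad,
      k_chord = numeric(0), eta_chord = numeric(0), L0_chord = numeric(0),
      V_rest = parent$V_rest0, V_rest0 = parent$V_rest0,
      c_s = parent$c_s, c_g = parent$c_g, P_in = parent$P_in,
      adh = parent$adh, state = "quiescent", gstate = "growth",
      polarized = FALSE, motile = FALSE, motility = NULL, mito = NULL,
      params = pr, t_next_growth = world$t + pr$tau_g,
      growth_suppressed = parent$growth_suppressed
    )
    world$owner[celld$mem] <- id
    world$owner[celld$nuc] <- id
    world$group[celld$mem] <- 0L
    world$group[celld$nuc] <- 0L
    world$idx[celld$mem] <- 0:(celld$n - 1L)
    world$idx[celld$nuc] <- 0:(celld$n - 1L)
    world$cells[[as.character(id)]] <- celld
    # repopulate to the founder count at the farthest consecutive pair
    while (world$cells[[as.character(id)]]$n < parent$n0) {
      cd <- world$cells[[as.character(id)]]
      xy <- cell_ring_xy(world, cd, "mem")
      m <- nrow(xy)
      gap <- sqrt(rowSums((xy[c(2:m, 1L), , drop = FALSE] - xy)^2))
      world <- insert_paired_nodes(world, cd, which.max(gap))
    }
    cd <- world$cells[[as.character(id)]]
    # reset to the founder rest template; a daughter that inherited more
    # than n0 nodes (area-balanced cuts need not split node counts
    # evenly) keeps them, carrying the matching growth scale
    m <- cd$n
    s <- m / cd$n0
    tpl <- rest_template(cd$R, cd$r_n, m, s)
    cd$L0_mem <- rep(tpl$L0_mem, m)
    cd$L0_nucmem <- rep(tpl$L0_nucmem, m)
    cd$L0_rad <- rep(tpl$L0_rad, m)
    cd$k_mem <- rep(pr$k_mem, m); cd$eta_mem <- rep(pr$eta_mem, m)
    cd$k_nucmem <- rep(pr$k_nucmem, m); cd$eta_nucmem <- rep(pr$eta_nucmem, m)
    cd$k_rad <- rep(pr$k_rad, m); cd$eta_rad <- rep(pr$eta_rad, m)
    cd$scale <- s
    cd$V_rest <- tpl$V_rest
    cd <- rebuild_chords(cd)
    # place the daughter's new nucleus: a fresh regular ring around the
    # membrane centroid, angularly aligned with its paired membrane nodes
    # (the parent's nuclear structure collapsed during mitosis)
    mem_xy <- world$pos[cd$mem, , drop = FALSE]
    cc <- colMeans(mem_xy)
    ang <- atan2(mem_xy[, 2] - cc[2], mem_xy[, 1] - cc[1])
    world$pos[cd$nuc, ] <- cbind(cc[1] + cd$r_n * cos(ang),
                                 cc[2] + cd$r_n * sin(ang))
    world$vel[cd$nuc, ] <- 0
    world$cells[[as.character(id)]] <- cd
    world$drag[cd$mem] <- pr$drag_mem
    world$drag[cd$nuc] <- pr$drag_nuc
    world$label[c(cd$mem, cd$nuc)] <- LABEL_NONE
    daughters <- c(daughters, id)
  }
  world$cells[[as.character(pid)]] <- NULL
  world$cache <- NULL
  attr(world, "daughters") <- daughters
  attr(world, "event") <- list(type = "division", cell = pid,
                               daughters = daughters)
  world
}

#' Start, advance and complete apoptosis
#'
#' `start_apoptosis()` disassembles the cell's adherens junctions
#' unilaterally, divides every element rest length by the apoptotic
#' shrink factor (5), and removes the inner pressure, after which the
#' dynamics collapse the cell; calling it again is a no-op.
#' `apoptosis_step()` is deliberately inert (shrinkage is purely
#' mechanical).  `reap()` deletes apoptotic cells whose area has fallen
#' below the prescribed minimal area.
#'
#' @param world a `cell_world`.
#' @param cell cell record or id.
#' @param factor rest-length reduction factor.
#' @return updated world.
#' @export
start_apoptosis <- function(world, cell, factor = 5) {
  cell <- get_cell(world, cell)
  if (cell$state == "apoptotic") return(world)
  cell$state <- "apoptotic"
  cell$L0_mem <- cell$L0_mem / factor
  cell$L0_nucmem <- cell$L0_nucmem / factor
  cell$L0_rad <- cell$L0_rad / factor
  if (length(cell$L0_chord)) cell$L0_chord <- cell$L0_chord / factor
  cell$P_in <- world$P_env
  cell$mito <- NULL
  world$cells[[as.character(cell$id)]] <- cell
  nodes <- c(cell$mem, cell$nuc)
  drop <- world$bonds$a %in% nodes | world$bonds$b %in% nodes
  if (any(drop)) world$bonds <- lapply(world$bonds, function(v) v[!drop])
  world$cache <- NULL
  attr(world, "event") <- list(type = "apoptosis_start", cell = cell$id)
  world
}

#' @rdname start_apoptosis
#' @export
apoptosis_step <- function(world, cell) world

#' @rdname start_apoptosis
#' @export
reap <- function(world) {
  reaped <- integer(0)
  for (cell in world$cells) {
    if (cell$state != "apoptotic") next
    if (cell_area(world, cell) < cell$params$A_min_frac * cell$V_rest0) {
      reaped <- c(reaped, cell$id)
    }
  }
  for (id in reaped) {
    cell <- world$cells[[as.character(id)]]
    world <- remove_nodes(world, c(cell$mem, cell$nuc))
    world$cells[[as.character(id)]] <- NULL
  }
  world$cache <- NULL
  attr(world, "reaped") <- reaped
  world
}

# Local 2-opt ring untangling.  Crossing of two nearby membrane edges
# (a transient fold created by crowding or division surgery) is removed
# by reversing the ring slots between them -- membrane and nucleus slots
# together, so the index-to-index radial pairing is preserved.  Folds
# must be removed promptly: the pressure load on an inverted sub-path
# points into the cell and would otherwise feed the fold.
untangle_cell <- function(world, cell, window = 8L, max_pass = 8L) {
  cell <- get_cell(world, cell)
  if (cell$state == "mitotic") return(world)   # groups must stay contiguous
  n <- cell$n
  changed <- FALSE
  # a fully inverted (clockwise) ring flips the pressure load inward and
  # would collapse the cell: restore the counterclockwise convention
  if (polygon_area(world$pos[cell$mem, , drop = FALSE], signed = TRUE) < 0) {
    cell$mem <- rev(cell$mem)
    cell$nuc <- rev(cell$nuc)
    changed <- TRUE
  }
  for (pass in seq_len(max_pass)) {
    xy <- world$pos[cell$mem, , drop = FALSE]
    nxt <- c(2:n, 1L)
    ax <- xy[, 1]; ay <- xy[, 2]; bx <- xy[nxt, 1]; by <- xy[nxt, 2]
    hit <- NULL
    for (off in 2:window) {
      if (off >= n - 1L) break
      j <- ((seq_len(n) + off - 1L) %% n) + 1L
      cx <- ax[j]; cy <- ay[j]; dx <- bx[j]; dy <- by[j]
      d1 <- (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
      d2 <- (by - ay) * (dx - ax) - (bx - ax) * (dy - ay)
      d3 <- (dy - cy) * (ax - cx) - (dx - cx) * (ay - cy)
      d4 <- (dy - cy) * (bx - cx) - (dx - cx) * (by - cy)
      cross <- ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
        ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
      cross[is.na(cross)] <- FALSE
      if (any(cross)) { i0 <- which(cross)[1]; hit <- c(i0, j[i0]); break }
    }
    if (is.null(hit)) break
    i <- hit[1]; j <- hit[2]
    span_len <- (j - i) %% n
    span <- ((i + seq_len(span_len) - 1L) %% n) + 1L   # ring slots i+1 .. j
    cell$mem[span] <- rev(cell$mem[span])
    cell$nuc[span] <- rev(cell$nuc[span])
    changed <- TRUE
  }
  if (changed) {
    world$idx[cell$mem] <- 0:(n - 1L)
    world$idx[cell$nuc] <- 0:(n - 1L)
    world$cells[[as.character(cell$id)]] <- cell
    world$cache <- NULL
  }
  world
}

# membrane nodes of a cell within eps of any ECM chain
ecm_contact_map <- function(world, cell, eps = world$rule$d_a) {
  cell <- get_cell(world, cell)
  contact <- rep(FALSE, cell$n)
  if (!length(world$ecm)) return(contact)
  pts <- cell_ring_xy(world, cell, "mem")
  for (ch in world$ecm) {
    poly <- world$pos[ch$nodes, , drop = FALSE]
    if (nrow(poly) < 2L) next
    d <- cpp_point_polyline(pts, poly, ch$closed)$dist
    contact <- contact | (d < eps)
  }
  contact
}

ang_dist <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Polarize a cell from its ECM contacts
#'
#' ECM-contacting membrane nodes become basal, nodes in the angular
#' sector opposite the basal centroid become apical, and the remainder
#' lateral.  The cell is polarized iff the basal set is nonempty; an
#' unpolarized cell keeps all labels at none.
#'
#' @param world a `cell_world`.
#' @param cell cell record or id.
#' @param contact optional logical vector over membrane nodes flagging
#'   ECM contact; defaults to nodes within the bond-creation distance of
#'   any ECM chain.
#' @return updated world.
#' @export
polarize <- function(world, cell, contact = NULL) {
  cell <- get_cell(world, cell)
  if (is.null(contact)) contact <- ecm_contact_map(world, cell)
  lab <- rep(LABEL_NONE, cell$n)
  if (any(contact)) {
    xy <- cell_ring_xy(world, cell, "mem")
    cc <- colMeans(xy)
    th <- atan2(xy[, 2] - cc[2], xy[, 1] - cc[1])
    thb <- atan2(mean(sin(th[contact])), mean(cos(th[contact])))
    w <- max(max(ang_dist(th[contact], thb)), pi / 6)
    w <- min(w, pi / 2)
    lab[] <- LABEL_LATERAL
    lab[ang_dist(th, thb + pi) <= w] <- LABEL_APICAL
    lab[contact] <- LABEL_BASAL
    cell$polarized <- TRUE
  } else {
    cell$polarized <- FALSE
  }
  world$label[cell$mem] <- lab
  world$cells[[as.character(cell$id)]] <- cell
  world
}

#' Make a cell motile
#'
#' Assigns anterior/posterior membrane labels by the sign of the
#' projection on `direction` and installs the crawling parameter cycle:
#' radial rest lengths and membrane drags of each region oscillate
#' between their initial and threshold values at frequency `omega`, the
#' two regions in antiphase.
#'
#' @param world a `cell_world`.
#' @param cell cell record or id.
#' @param direction length-2 crawl direction.
#' @param omega cycle frequency, rad/s.
#' @param L0_ant_factor,L0_post_factor threshold-to-initial ratios for
#'   the anterior (protrusion, > 1) and posterior (contraction, < 1)
#'   radial rest lengths.
#' @param drag_factor threshold-to-initial drag ratio of the active
#'   region (< 1: the protruding/retracting side de-adheres).
#' @return updated world.
#' @export
set_motile <- function(world, cell, direction = c(1, 0), omega = 2 * pi / 60,
                       L0_ant_factor = 1.5, L0_post_factor = 0.6,
                       drag_factor = 0.05) {
  cell <- get_cell(world, cell)
  xy <- cell_ring_xy(world, cell, "mem")
  cc <- colMeans(xy)
  dirn <- direction / sqrt(sum(direction^2))
  ant <- as.vector((sweep(xy, 2, cc) %*% dirn) > 0)
  world$label[cell$mem[ant]] <- LABEL_ANTERIOR
  world$label[cell$mem[!ant]] <- LABEL_POSTERIOR
  D0 <- if (!is.null(world$substrate) && !is.function(world$substrate))
    world$substrate else cell$params$drag_mem
  L0r <- mean(cell$L0_rad)
  cell$motile <- TRUE
  cell$motility <- list(
    omega = omega, dir = dirn,
    L0a0 = L0r, L0at = L0r * L0_ant_factor,
    L0p0 = L0r, L0pt = L0r * L0_post_factor,
    Da0 = D0, Dat = D0 * drag_factor,
    Dp0 = D0, Dpt = D0 * drag_factor)
  world$cells[[as.character(cell$id)]] <- cell
  world
}

# rectified half-cycle ramp: a region is active for half the period,
# rising from its initial value to its threshold and back (sin^2, C1 at
# the junctions), then rests at the initial value; period 2*pi/omega.
motility_wave <- function(init, thr, omega, t, phase) {
  ph <- (omega * t + phase) %% (2 * pi)
  if (ph < pi) init + (thr - init) * sin(ph)^2 else init
}

# drag dips only during the first quarter of the region's stroke (while
# its rest length is moving away from rest), so the region slides during
# protrusion/contraction but is re-anchored before the return stroke --
# the drag asymmetry that rectifies the cycle into net crawling.
motility_drag_wave <- function(init, thr, omega, t, phase) {
  ph <- (omega * t + phase) %% (2 * pi)
  if (ph < pi / 2) init + (thr - init) * sin(2 * ph)^2 else init
}

#' Advance a motile cell's parameter cycle
#'
#' Writes the instantaneous anterior/posterior radial rest lengths and
#' membrane drags for time `t`.  Anterior leads (phase 0), posterior is
#' in antiphase; after each full period all parameters are exactly back
#' at their initial values.
#'
#' @param world a `cell_world`.
#' @param cell a motile cell record or id.
#' @param t simulation time, s.
#' @return updated world.
#' @export
motility_update <- function(world, cell, t = world$t) {
  cell <- get_cell(world, cell)
  if (!isTRUE(cell$motile) || is.null(cell$motility))
    stop("cell ", cell$id, " is not motile")
  lab <- world$label[cell$mem]
  if (!any(lab == LABEL_ANTERIOR) || !any(lab == LABEL_POSTERIOR))
    stop("motile cell lacks anterior/posterior labels")
  mo <- cell$motility
  La <- motility_wave(mo$L0a0, mo$L0at, mo$omega, t, 0)
  Lp <- motility_wave(mo$L0p0, mo$L0pt, mo$omega, t, pi)
  Da <- motility_drag_wave(mo$Da0, mo$Dat, mo$omega, t, 0)
  Dp <- motility_drag_wave(mo$Dp0, mo$Dpt, mo$omega, t, pi)
  cell$L0_rad[lab == LABEL_ANTERIOR] <- La
  cell$L0_rad[lab == LABEL_POSTERIOR] <- Lp
  world$drag[cell$mem[lab == LABEL_ANTERIOR]] <- Da
  world$drag[cell$mem[lab == LABEL_POSTERIOR]] <- Dp
  world$cells[[as.character(cell$id)]] <- cell
  world$cache <- NULL
  world
}
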