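#' Create an empty simulation world
#'
#' A world holds the flat node table (positions, velocities, drag, ring
#' membership), per-cell structural records, ECM chains, the live adhesion
#' bond set, the environmental pressure, an optional substrate drag field
#' and an optional external force field, plus the clock.
#'
#' @param P_env environmental pressure, nN/um.
#' @param substrate `NULL`, a single number (uniform 2D-culture drag
#'   applied to membrane nodes), or a `function(x, y)` returning the local
#'   drag.
#' @param external_force `NULL` or `function(pos, t)` returning an
#'   N x 2 force matrix (nN).
#' @param rule an [adhesion_rule()].
#' @return object of class `cell_world`.
#' @export
new_world <- function(P_env = 0, substrate = NULL, external_force = NULL,
                      rule = adhesion_rule()) {
  w <- list(
    pos = matrix(numeric(0), 0, 2),
    vel = matrix(numeric(0), 0, 2),
    drag = numeric(0),
    mass = numeric(0),
    ring = integer(0),
    owner = integer(0),
    idx = integer(0),
    label = integer(0),
    group = integer(0),   # mitosis group: 0 none, 1 A, 2 B
    fixed = logical(0),
    cells = list(),
    ecm = list(),
    bonds = empty_bonds(),
    P_env = P_env,
    substrate = substrate,
    external_force = external_force,
    rule = rule,
    t = 0,
    next_cell_id = 1L,
    next_ecm_id = -1L,
    cache = NULL,
    config = list()
  )
  class(w) <- "cell_world"
  w
}

empty_bonds <- function() {
  list(a = integer(0), b = integer(0), k = numeric(0), eta = numeric(0),
       L0 = numeric(0))
}

n_nodes <- function(world) nrow(world$pos)

#' Number of live cells in a world
#' @param world a `cell_world`.
#' @export
n_cells <- function(world) length(world$cells)

live_cell_ids <- function(world) as.integer(names(world$cells))

# Rest-geometry template for a cell discretized into n nodes per ring at
# growth scale s (s = 1 for a fresh cell; each insertion multiplies the
# linear scale by (n+1)/n so s = n/n0).
rest_template <- function(R, r_n, n, s = 1) {
  list(
    L0_mem = 2 * R * s * sin(pi / n),
    L0_nucmem = 2 * r_n * s * sin(pi / n),
    L0_rad = (R - r_n) * s,
    L0_chord = 2 * r_n * s * sin(pi * (n %/% 2L) / n),
    V_rest = 0.5 * n * (R * s)^2 * sin(2 * pi / n)
  )
}

# chord partner of local 0-based index i in an n-ring: (i + n %/% 2) mod n
chord_partner <- function(i, n) (i + n %/% 2L) %% n

#' Add a cell to a world
#'
#' The cell is initialized as two concentric regular n-gons (membrane
#' radius `R`, nucleus radius `r_n`, counterclockwise) with every element
#' at its rest length, so an isolated freshly added cell is a mechanical
#' fixed point when `P_in == P_env`.
#'
#' @param world a `cell_world`.
#' @param center length-2 center position, um.
#' @param params a [cell_params()] list.
#' @param phase rotation of the first node, radians.
#' @return the updated world; the new cell id is in
#'   `attr(, "cell_id")`.
#' @export
add_cell <- function(world, center = c(0, 0), params = cell_params(),
                     phase = 0) {
  n <- as.integer(params$n)
  id <- world$next_cell_id
  theta <- phase + 2 * pi * (0:(n - 1L)) / n
  mem_xy <- cbind(center[1] + params$R * cos(theta),
                  center[2] + params$R * sin(theta))
  nuc_xy <- cbind(center[1] + params$r_n * cos(theta),
                  center[2] + params$r_n * sin(theta))
  base <- n_nodes(world)
  world <- append_nodes(
    world,
    pos = rbind(mem_xy, nuc_xy),
    ring = rep(c(RING_MEMBRANE, RING_NUCLEUS), each = n),
    owner = rep(id, 2L * n),
    idx = c(0:(n - 1L), 0:(n - 1L)),
    drag = c(rep(params$drag_mem, n), rep(params$drag_nuc, n)),
    mass = c(rep(params$mass / n, n), rep(params$mass_nuc / n, n)),
    fixed = rep(FALSE, 2L * n))
  tpl <- rest_template(params$R, params$r_n, n)
  cell <- list(
    id = id,
    mem = base + 1:n,
    nuc = base + n + 1:n,
    n = n, n0 = n,
    R = params$R, r_n = params$r_n, scale = 1,
    k_mem = rep(params$k_mem, n), eta_mem = rep(params$eta_mem, n),
    L0_mem = rep(tpl$L0_mem, n),
    k_nucmem = rep(params$k_nucmem, n), eta_nucmem = rep(params$eta_nucmem, n),
    L0_nucmem = rep(tpl$L0_nucmem, n),
    k_rad = rep(params$k_rad, n), eta_rad = rep(params$eta_rad, n),
    L0_rad = rep(tpl$L0_rad, n),
    k_chord = rep(params$k_chord, n), eta_chord = rep(params$eta_chord, n),
    L0_chord = rep(tpl$L0_chord, n),
    V_rest = tpl$V_rest, V_rest0 = tpl$V_rest,
    c_s = params$c_s, c_g = params$c_g,
    P_in = params$P_in,
    adh = list(k = params$adh_k, eta = params$adh_eta, L0 = params$adh_L0),
    state = "quiescent",
    gstate = "growth",       # hysteresis memory of the volume gate
    polarized = FALSE,
    motile = FALSE,
    motility = NULL,
    mito = NULL,
    params = params,
    t_next_growth = params$tau_g,
    growth_suppressed = FALSE
  )
  world$cells[[as.character(id)]] <- cell
  world$next_cell_id <- id + 1L
  world$cache <- NULL
  attr(world, "cell_id") <- id
  world
}

append_nodes <- function(world, pos, ring, owner, idx, drag, mass, fixed,
                         label = NULL, group = NULL) {
  m <- nrow(pos)
  world$pos <- rbind(world$pos, pos)
  world$vel <- rbind(world$vel, matrix(0, m, 2))
  world$ring <- c(world$ring, as.integer(ring))
  world$owner <- c(world$owner, as.integer(owner))
  world$idx <- c(world$idx, as.integer(idx))
  world$drag <- c(world$drag, drag)
  world$mass <- c(world$mass, mass)
  world$fixed <- c(world$fixed, fixed)
  world$label <- c(world$label, if (is.null(label)) rep(LABEL_NONE, m) else as.integer(label))
  world$group <- c(world$group, if (is.null(group)) rep(0L, m) else as.integer(group))
  world$cache <- NULL
  world
}

# Coordinates of a cell's membrane / nucleus ring in ring order.
cell_ring_xy <- function(world, cell, ring = c("mem", "nuc")) {
  ring <- match.arg(ring)
  world$pos[cell[[ring]], , drop = FALSE]
}

#' Current area of a cell
#' @param world a `cell_world`.
#' @param cell a cell record or cell id.
#' @export
cell_area <- function(world, cell) {
  if (!is.list(cell)) cell <- world$cells[[as.character(cell)]]
  abs(polygon_area(cell_ring_xy(world, cell), signed = TRUE))
}

# Flat structural element table (radial, chords, membrane rings, ECM
# chains) -- everything except adhesion bonds, which churn and are kept
# separately.  Cached until the topology changes.
world_elements <- function(world) {
  if (!is.null(world$cache$elem)) return(world$cache$elem)
  as_ <- list(); bs <- list(); ks <- list(); es <- list(); ls <- list(); cs <- list()
  p <- 0L
  for (cell in world$cells) {
    n <- cell$n
    nxt <- c(2:n, 1L)
    # membrane ring
    p <- p + 1L
    as_[[p]] <- cell$mem; bs[[p]] <- cell$mem[nxt]
    ks[[p]] <- cell$k_mem; es[[p]] <- cell$eta_mem; ls[[p]] <- cell$L0_mem
    cs[[p]] <- rep(CAT_MEMBRANE, n)
    # nuclear membrane ring
    p <- p + 1L
    as_[[p]] <- cell$nuc; bs[[p]] <- cell$nuc[nxt]
    ks[[p]] <- cell$k_nucmem; es[[p]] <- cell$eta_nucmem; ls[[p]] <- cell$L0_nucmem
    cs[[p]] <- rep(CAT_NUC_MEMBRANE, n)
    # radial cytoskeleton, membrane i <-> nucleus i
    p <- p + 1L
    as_[[p]] <- cell$mem; bs[[p]] <- cell$nuc
    ks[[p]] <- cell$k_rad; es[[p]] <- cell$eta_rad; ls[[p]] <- cell$L0_rad
    cs[[p]] <- rep(CAT_RADIAL, n)
    # nucleoskeletal chords i <-> (i + n/2) mod n (absent during mitosis)
    if (length(cell$k_chord)) {
      p <- p + 1L
      partner <- chord_partner(0:(n - 1L), n) + 1L
      as_[[p]] <- cell$nuc; bs[[p]] <- cell$nuc[partner]
      ks[[p]] <- cell$k_chord; es[[p]] <- cell$eta_chord; ls[[p]] <- cell$L0_chord
      cs[[p]] <- rep(CAT_CHORD, n)
    }
  }
  for (ch in world$ecm) {
    m <- length(ch$nodes)
    ne <- if (ch$closed) m else m - 1L
    if (ne < 1L) next
    p <- p + 1L
    as_[[p]] <- ch$nodes[seq_len(ne)]
    bs[[p]] <- ch$nodes[c(seq_len(ne - 1L) + 1L, if (ch$closed) 1L else ne + 1L)]
    ks[[p]] <- ch$k; es[[p]] <- ch$eta; ls[[p]] <- ch$L0
    cs[[p]] <- rep(CAT_ECM_CHAIN, ne)
  }
  elem <- list(a = as.integer(unlist(as_)), b = as.integer(unlist(bs)),
               k = as.numeric(unlist(ks)), eta = as.numeric(unlist(es)),
               L0 = as.numeric(unlist(ls)), cat = as.integer(unlist(cs)))
  world$cache$elem  # no-op; caller caches via set_elem_cache
  elem
}

# run-time cache helpers (list semantics: caller must reassign the world)
with_elem_cache <- function(world) {
  if (is.null(world$cache$elem)) world$cache$elem <- world_elements(world)
  world
}

#' Validate world structural invariants
#'
#' Checks ring closure, equal ring lengths, counterclockwise orientation,
#' simplicity, nonnegative drag, bond endpoint sanity.  Returns the world
#' invisibly, stopping on violation.
#' @param world a `cell_world`.
#' @param check_simple also run the O(n^2) self-intersection test.
#' @export
validate_world <- function(world, check_simple = TRUE) {
  N <- n_nodes(world)
  stopifnot(length(world$drag) == N, length(world$ring) == N,
            length(world$owner) == N, all(world$drag >= 0),
            all(world$mass >= 0))
  if (any(world$fixed & (abs(world$vel[, 1]) > 0 | abs(world$vel[, 2]) > 0)))
    stop("fixed nodes must have zero velocity")
  for (cell in world$cells) {
    stopifnot(length(cell$mem) == cell$n, length(cell$nuc) == cell$n)
    if (length(unique(world$idx[cell$mem])) != cell$n)
      stop("duplicate membrane indices in cell ", cell$id)
    mem <- cell_ring_xy(world, cell, "mem")
    nuc <- cell_ring_xy(world, cell, "nuc")
    if (polygon_area(mem, signed = TRUE) <= 0)
      stop("membrane ring of cell ", cell$id, " is not counterclockwise")
    if (polygon_area(nuc, signed = TRUE) <= 0)
      stop("nucleus ring of cell ", cell$id, " is not counterclockwise")
    if (check_simple && !ring_is_simple(mem))
      stop("membrane ring of cell ", cell$id, " self-intersects")
    stopifnot(cell$V_rest > 0, cell$c_s > 0, cell$c_s <= cell$c_g)
  }
  if (length(world$bonds$a)) {
    stopifnot(all(world$bonds$a >= 1L), all(world$bonds$a <= N),
              all(world$bonds$b >= 1L), all(world$bonds$b <= N))
    if (any(world$owner[world$bonds$a] == world$owner[world$bonds$b]))
      stop("adhesion bond joins nodes of the same owner")
  }
  invisible(world)
}

# Remove node rows (e.g. a reaped cell) and remap every stored index.
remove_nodes <- function(world, rows) {
  if (!length(rows)) return(world)
  N <- n_nodes(world)
  keep <- setdiff(seq_len(N), rows)
  map <- integer(N)
  map[keep] <- seq_along(keep)
  world$pos <- world$pos[keep, , drop = FALSE]
  world$vel <- world$vel[keep, , drop = FALSE]
  for (f in c("drag", "mass", "ring", "owner", "idx", "label", "group", "fixed"))
    world[[f]] <- world[[f]][keep]
  world$cells <- lapply(world$cells, function(cell) {
    cell$mem <- map[cell$mem]; cell$nuc <- map[cell$nuc]; cell
  })
  world$ecm <- lapply(world$ecm, function(ch) { ch$nodes <- map[ch$nodes]; ch })
  bk <- !(world$bonds$a %in% rows | world$bonds$b %in% rows)
  world$bonds <- lapply(world$bonds, function(v) v[bk])
  world$bonds$a <- map[world$bonds$a]
  world$bonds$b <- map[world$bonds$b]
  world$cache <- NULL
  world
}

# membrane node rows of all live cells (bond / repulsion candidates)
membrane_nodes <- function(world) which(world$ring == RING_MEMBRANE)
ecm_nodes <- function(world) which(world$ring == RING_ECM)
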