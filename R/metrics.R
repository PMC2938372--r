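# Tissue-geometry statistics: internal boundary classification, cell
# edge density rho = lambda / A_T, form factor Gamma = rho *
# sqrt(A_T / n_c), and neighbor graphs.

# list of membrane polygons keyed by cell id; a plain list of n x 2
# matrices passes through so the metrics are testable on hand geometry.
world_polys <- function(world) {
  if (inherits(world, "cell_world"))
    lapply(world$cells, function(cell) cell_ring_xy(world, cell, "mem"))
  else if (is.list(world)) world
  else stop("expected a cell_world or a list of polygon matrices")
}

# for each cell: per-segment lengths, internal flags (midpoint within
# eps of another cell's polyline) and the nearest foreign cell.
classify_segments <- function(polys, eps) {
  nc <- length(polys)
  cents <- t(vapply(polys, colMeans, numeric(2)))
  rads <- vapply(seq_len(nc), function(i)
    max(sqrt(rowSums(sweep(polys[[i]], 2, cents[i, ])^2))), numeric(1))
  out <- vector("list", nc)
  for (i in seq_len(nc)) {
    p <- polys[[i]]
    m <- nrow(p)
    nxt <- c(2:m, 1L)
    mid <- (p + p[nxt, , drop = FALSE]) / 2
    len <- sqrt(rowSums((p[nxt, , drop = FALSE] - p)^2))
    best <- rep(Inf, m); who <- rep(NA_integer_, m)
    for (j in seq_len(nc)) {
      if (j == i) next
      if (sqrt(sum((cents[i, ] - cents[j, ])^2)) > rads[i] + rads[j] + eps) next
      d <- cpp_point_polyline(mid, polys[[j]], TRUE)$dist
      upd <- d < best
      best[upd] <- d[upd]; who[upd] <- j
    }
    internal <- best < eps
    out[[i]] <- list(len = len, internal = internal,
                     neighbor = ifelse(internal, who, NA_integer_))
  }
  out
}

#' Internal cell-cell boundary lengths
#'
#' Classifies every membrane segment of every cell as internal (its
#' midpoint lies within `eps` of another cell's membrane polyline) or
#' external (contributing to the patch perimeter).  Each physical
#' interface is counted once: the two sides' detected lengths are
#' averaged.
#'
#' @param world a `cell_world` or a plain list of polygon matrices.
#' @param eps contact tolerance, um; defaults to the adhesion creation
#'   distance so mechanical and metric adjacency agree.
#' @return list with `pairs` (data frame `i`, `j`, `length` per cell
#'   pair, each pair once with i < j), `internal` and `external`
#'   per-cell totals, and `interior` (logical: no external perimeter).
#' @export
shared_boundaries <- function(world, eps = NULL) {
  if (is.null(eps))
    eps <- if (inherits(world, "cell_world")) world$rule$d_a else 0.05
  polys <- world_polys(world)
  nc <- length(polys)
  cls <- classify_segments(polys, eps)
  internal <- vapply(cls, function(x) sum(x$len[x$internal]), numeric(1))
  external <- vapply(cls, function(x) sum(x$len[!x$internal]), numeric(1))
  names(internal) <- names(external) <- names(polys)
  # one-sided detected lengths per ordered pair
  key <- list()
  for (i in seq_len(nc)) {
    x <- cls[[i]]
    if (!any(x$internal)) next
    tab <- tapply(x$len[x$internal], x$neighbor[x$internal], sum)
    for (j in names(tab)) {
      a <- min(i, as.integer(j)); b <- max(i, as.integer(j))
      kk <- paste(a, b)
      key[[kk]] <- c(key[[kk]], tab[[j]])
    }
  }
  pairs <- if (length(key)) {
    ij <- do.call(rbind, strsplit(names(key), " "))
    data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
               length = vapply(key, function(v) sum(v) / 2, numeric(1)),
               row.names = NULL)
  } else data.frame(i = integer(0), j = integer(0), length = numeric(0))
  list(pairs = pairs, internal = internal, external = external,
       interior = external <= 1e-12)
}

# occupied area: sum of cell areas minus pairwise overlaps of near cells
occupied_area <- function(polys) {
  areas <- vapply(polys, function(p) abs(polygon_area(p, signed = TRUE)), numeric(1))
  A <- sum(areas)
  nc <- length(polys)
  if (nc > 1L) {
    cents <- t(vapply(polys, colMeans, numeric(2)))
    rads <- vapply(seq_len(nc), function(i)
      max(sqrt(rowSums(sweep(polys[[i]], 2, cents[i, ])^2))), numeric(1))
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        if (sqrt(sum((cents[i, ] - cents[j, ])^2)) > rads[i] + rads[j]) next
        A <- A - polygon_overlap_area(polys[[i]], polys[[j]])
      }
    }
  }
  A
}

#' Cell edge density
#'
#' \eqn{\rho = \lambda / A_T} where \eqn{\lambda} is the sum of all
#' internal cell boundary lengths plus half the patch perimeter (the
#' external edges are shared with a mirror-image patch) and \eqn{A_T}
#' the total occupied area.
#'
#' @inheritParams shared_boundaries
#' @return list with `lambda`, `A_T`, `rho`.
#' @export
edge_density <- function(world, eps = NULL) {
  polys <- world_polys(world)
  if (!length(polys)) stop("empty world: no cells to measure")
  sb <- shared_boundaries(world, eps)
  lambda <- sum(sb$pairs$length) + sum(sb$external) / 2
  A_T <- occupied_area(polys)
  list(lambda = lambda, A_T = A_T, rho = lambda / A_T)
}

#' Form factor of a culture
#'
#' \eqn{\Gamma = \rho \sqrt{A_T / n_c}}, dimensionless; minimal
#' (\eqn{\sqrt\pi}) for circular cells, larger for polygonal or
#' dendritic cultures.
#'
#' @inheritParams shared_boundaries
#' @return the form factor (numeric scalar).
#' @export
form_factor <- function(world, eps = NULL) {
  polys <- world_polys(world)
  if (!length(polys)) stop("form factor undefined for zero cells")
  ed <- edge_density(world, eps)
  ed$rho * sqrt(ed$A_T / length(polys))
}

#' Cell adjacency graph and neighbor statistics
#'
#' Cells are adjacent iff they share internal boundary length (or, for a
#' world, hold at least one adhesion bond).  Reports per-cell degree,
#' the mean over all cells, and the mean over interior cells (no
#' external perimeter); the interior mean tends to 6 in large
#' monolayers.
#'
#' @inheritParams shared_boundaries
#' @return list with `adjacency` (symmetric 0/1 matrix), `degree`,
#'   `mean`, `interior` (logical), `mean_interior`.
#' @export
neighbor_graph <- function(world, eps = NULL) {
  polys <- world_polys(world)
  nc <- length(polys)
  adj <- matrix(0L, nc, nc)
  if (nc == 0L)
    return(list(adjacency = adj, degree = integer(0), mean = NaN,
                interior = logical(0), mean_interior = NaN))
  sb <- shared_boundaries(world, eps)
  if (nrow(sb$pairs))
    for (r in seq_len(nrow(sb$pairs)))
      adj[sb$pairs$i[r], sb$pairs$j[r]] <- adj[sb$pairs$j[r], sb$pairs$i[r]] <- 1L
  if (inherits(world, "cell_world") && length(world$bonds$a)) {
    ids <- live_cell_ids(world)
    oa <- world$owner[world$bonds$a]; ob <- world$owner[world$bonds$b]
    cc <- oa > 0 & ob > 0
    ia <- match(oa[cc], ids); ib <- match(ob[cc], ids)
    ok <- !is.na(ia) & !is.na(ib)
    adj[cbind(ia[ok], ib[ok])] <- 1L
    adj[cbind(ib[ok], ia[ok])] <- 1L
  }
  dimnames(adj) <- list(names(polys), names(polys))
  deg <- rowSums(adj)
  list(adjacency = adj, degree = deg, mean = mean(deg),
       interior = sb$interior,
       mean_interior = if (any(sb$interior)) mean(deg[sb$interior]) else NaN)
}

#' Summary statistics of a culture
#'
#' Total occupied area, cell count, edge length \eqn{\lambda}, edge
#' density \eqn{\rho}, form factor \eqn{\Gamma}, and neighbor-count
#' means, plus per-cell areas.
#'
#' @inheritParams shared_boundaries
#' @return list of class `culture_summary`.
#' @export
culture_summary <- function(world, eps = NULL) {
  polys <- world_polys(world)
  if (!length(polys)) stop("empty world: no cells to measure")
  ed <- edge_density(world, eps)
  ng <- neighbor_graph(world, eps)
  areas <- vapply(polys, function(p) abs(polygon_area(p, signed = TRUE)), numeric(1))
  structure(list(
    A_T = ed$A_T, n_c = length(polys), lambda = ed$lambda, rho = ed$rho,
    gamma = ed$rho * sqrt(ed$A_T / length(polys)),
    mean_neighbors = ng$mean, mean_neighbors_interior = ng$mean_interior,
    n_interior = sum(ng$interior), degree = ng$degree, areas = areas),
    class = "culture_summary")
}

#' @export
print.culture_summary <- function(x, ...) {
  cat(sprintf("culture: %d cells (%d interior), A_T = %.1f um^2\n",
              x$n_c, x$n_interior, x$A_T))
  cat(sprintf("  lambda = %.1f um, rho = %.4f /um, Gamma = %.3f\n",
              x$lambda, x$rho, x$gamma))
  cat(sprintf("  mean neighbors: %.2f (all), %.2f (interior)\n",
              x$mean_neighbors, x$mean_neighbors_interior))
  invisible(x)
}

# free (neither cell- nor ECM-contacting) perimeter fraction per cell;
# used by scenario rules (acinus differentiation predicate).
free_perimeter_fraction <- function(world, eps = world$rule$d_a) {
  polys <- world_polys(world)
  nc <- length(polys)
  if (!nc) return(numeric(0))
  cls <- classify_segments(polys, eps)
  out <- numeric(nc)
  for (i in seq_len(nc)) {
    covered <- cls[[i]]$internal
    p <- polys[[i]]
    m <- nrow(p)
    mid <- (p + p[c(2:m, 1L), , drop = FALSE]) / 2
    for (ch in world$ecm) {
      poly <- world$pos[ch$nodes, , drop = FALSE]
      if (nrow(poly) < 2L) next
      covered <- covered | (cpp_point_polyline(mid, poly, ch$closed)$dist < eps)
    }
    out[i] <- sum(cls[[i]]$len[!covered]) / sum(cls[[i]]$len)
  }
  names(out) <- names(polys)
  out
}
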