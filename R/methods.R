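# S3 methods for worlds and simulation results.

#' @export
print.cell_world <- function(x, ...) {
  states <- table(vapply(x$cells, `[[`, character(1), "state"))
  cat(sprintf("<cell_world> t = %.2f s, %d cells, %d nodes, %d bonds, %d ECM chain(s)\n",
              x$t, n_cells(x), n_nodes(x), length(x$bonds$a), length(x$ecm)))
  if (length(states))
    cat("  states:", paste(names(states), states, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cell_world <- function(object, ...) {
  print(object)
  if (n_cells(object) > 0) print(culture_summary(object))
  invisible(object)
}

#' Plot a world
#'
#' Draws membrane and nucleus polygons, ECM chains and (optionally)
#' adhesion bonds with base graphics.
#'
#' @param x a `cell_world`.
#' @param bonds draw adhesion bonds.
#' @param ... passed to `plot.default`.
#' @export
plot.cell_world <- function(x, bonds = FALSE, ...) {
  if (n_nodes(x) == 0L) stop("empty world")
  rx <- range(x$pos[, 1]); ry <- range(x$pos[, 2])
  graphics::plot(NA, xlim = rx, ylim = ry, asp = 1, xlab = "x [um]",
                 ylab = "y [um]", ...)
  for (ch in x$ecm) {
    p <- x$pos[ch$nodes, , drop = FALSE]
    if (ch$closed) p <- rbind(p, p[1, ])
    graphics::lines(p, col = "brown", lwd = 2)
  }
  cols <- c(quiescent = "grey30", growing = "forestgreen",
            mitotic = "orange", apoptotic = "red")
  for (cell in x$cells) {
    mem <- cell_ring_xy(x, cell, "mem")
    nuc <- cell_ring_xy(x, cell, "nuc")
    graphics::polygon(mem, border = cols[[cell$state]],
                      col = grDevices::adjustcolor("lightblue", 0.3))
    graphics::polygon(nuc, border = "navy",
                      col = grDevices::adjustcolor("navy", 0.2))
  }
  if (bonds && length(x$bonds$a))
    graphics::segments(x$pos[x$bonds$a, 1], x$pos[x$bonds$a, 2],
                       x$pos[x$bonds$b, 1], x$pos[x$bonds$b, 2],
                       col = "grey60")
  invisible(x)
}

#' @export
print.cell_sim <- function(x, ...) {
  cat(sprintf("<cell_sim> %d steps run, final t = %.2f s, %d cells\n",
              x$steps_run, x$world$t, n_cells(x$world)))
  if (nrow(x$events)) {
    tab <- table(x$events$event)
    cat("  events:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.cell_sim <- function(object, ...) {
  print(object)
  if (n_cells(object$world) > 0) print(culture_summary(object$world))
  invisible(object)
}

#' Plot a simulation result
#'
#' `type = "world"` draws the final configuration; `type = "metrics"`
#' plots the recorded cell count and form factor against time.
#'
#' @param x a `cell_sim`.
#' @param type `"world"` or `"metrics"`.
#' @param ... passed on.
#' @export
plot.cell_sim <- function(x, type = c("world", "metrics"), ...) {
  type <- match.arg(type)
  if (type == "world") return(plot(x$world, ...))
  m <- x$metrics
  if (!nrow(m)) stop("no metrics recorded (record_every = 0?)")
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(m$t, m$n_c, type = "s", xlab = "t [s]", ylab = "cells", ...)
  if (!is.null(m$gamma) && any(!is.na(m$gamma)))
    graphics::plot(m$t, m$gamma, type = "l", xlab = "t [s]",
                   ylab = expression(Gamma), ...)
  invisible(x)
}
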