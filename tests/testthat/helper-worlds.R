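# Small worlds built in code for the unit tests.

# a free node tethered to a fixed anchor by one Voigt element
toy_element_world <- function(k = 2, eta = 1.5, D = 0.5, L0 = 1, x0 = 1) {
  w <- new_world()
  w$pos <- rbind(c(0, 0), c(L0 + x0, 0))
  w$vel <- matrix(0, 2, 2)
  w$drag <- c(1, D); w$mass <- c(0, 0)
  w$ring <- c(3L, 3L); w$owner <- c(-1L, -1L); w$idx <- c(0L, 1L)
  w$label <- c(0L, 0L); w$group <- c(0L, 0L)
  w$fixed <- c(TRUE, FALSE)
  w$ecm[["-1"]] <- list(id = -1L, nodes = 1:2, closed = FALSE, rigid = FALSE,
                        k = k, eta = eta, L0 = L0,
                        adh = list(k = 1, eta = 1, L0 = 0.5))
  w
}

single_cell_world <- function(n = 40, P_in = 0, R = 7.5, r_n = 2.5, ...) {
  w <- new_world()
  add_cell(w, c(0, 0), cell_params(n = n, P_in = P_in, R = R, r_n = r_n, ...))
}

two_cell_world <- function(gap = 0.7, n = 20, ...) {
  p <- cell_params(n = n, ...)
  w <- new_world(substrate = p$drag_mem)
  w <- add_cell(w, c(-(p$R + gap / 2), 0), p)
  add_cell(w, c(p$R + gap / 2, 0), p)
}

regular_ring <- function(n, R = 1, center = c(0, 0), phase = 0) {
  th <- phase + 2 * pi * (0:(n - 1)) / n
  cbind(center[1] + R * cos(th), center[2] + R * sin(th))
}

unit_square <- function(x0 = 0, y0 = 0)
  rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1))
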