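# Scenario constructors for the case studies: single cell, monolayer
# culture at varying substrate adhesion, epithelium on an ECM line,
# cysts, ECM gap, tensegrity bud, hollow acinus, and a crawling cell.

SCENARIO_NAMES <- c("single_cell", "monolayer", "ecm_line_epithelium",
                    "ecm_hole_cyst", "inverted_cyst", "ecm_gap",
                    "tensegrity_bud", "acinus", "crawling_cell")

#' List the named scenarios
#' @return character vector of scenario names.
#' @export
list_scenarios <- function() SCENARIO_NAMES

#' Scenario specification
#'
#' Bundles the geometry, biology and run parameters that fully determine
#' a constructible world for one of the named case studies.
#'
#' @param name scenario name; see [list_scenarios()].
#' @param n membrane nodes per cell (population scenarios default to 20
#'   for tractable culture sizes; a single cell defaults to 40).
#' @param drag_mult substrate drag as a multiple of the reference D0
#'   (e.g. 1e-4 for the low-adhesion culture).
#' @param target_cells stop the run once this many cells exist
#'   (`NULL`: run the full step budget).
#' @param W_over_R ECM gap width in units of the free cell radius.
#' @param ... further overrides stored in the spec (cell parameter
#'   overrides via `params`, ECM drag via `ecm_drag`, acinus ring radius
#'   via `ring_radius`, apoptosis delay via `T_apop`, ...).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, n = NULL, drag_mult = 1, target_cells = NULL,
                          W_over_R = 2, ...) {
  name <- match.arg(name, SCENARIO_NAMES)
  if (is.null(n)) n <- if (name %in% c("single_cell", "crawling_cell")) 40L else 20L
  structure(c(list(name = name, n = as.integer(n), drag_mult = drag_mult,
                   target_cells = target_cells, W_over_R = W_over_R),
              list(...)),
            class = "scenario_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hook factory: continuous polarization against the ECM plus apoptosis
# of cells detached from the ECM for longer than T_apop seconds
epithelial_hooks <- function(T_apop = 60, every = 10L) {
  list(function(world, step) {
    if (step %% every != 0L) return(world)
    for (id in live_cell_ids(world)) {
      cell <- world$cells[[as.character(id)]]
      if (cell$state == "apoptotic") next
      contact <- ecm_contact_map(world, cell)
      world <- polarize(world, cell, contact)
      cell <- world$cells[[as.character(id)]]
      if (any(contact)) {
        cell$last_contact_t <- world$t
        world$cells[[as.character(id)]] <- cell
      } else {
        since <- cell$last_contact_t %||% world$t
        if (world$t - since > T_apop)
          world <- start_apoptosis(world, cell)
      }
    }
    world
  })
}

# hook factory for the acinus program: proliferate until the colony's
# exposed rim is fully on the ECM, then differentiate (polarized outer
# layer stops proliferating, inner cells enter apoptosis)
acinus_hooks <- function(min_cells = 8L, every = 20L, free_tol = 0.12,
                         t_diff = 1000) {
  list(function(world, step) {
    if (step %% every != 0L) return(world)
    ids <- live_cell_ids(world)
    if (!length(ids)) return(world)
    contact <- lapply(ids, function(id)
      ecm_contact_map(world, world$cells[[as.character(id)]]))
    names(contact) <- as.character(ids)
    for (id in ids)
      world <- polarize(world, id, contact[[as.character(id)]])
    if (!isTRUE(world$config$differentiated)) {
      if (length(ids) >= min_cells) {
        touching <- vapply(contact, any, logical(1))
        if (any(touching)) {
          free <- free_perimeter_fraction(world)
          exposed <- free > free_tol
          # outer layer fully on the matrix -- or the colony has reached
          # the differentiation age
          if (all(touching[exposed]) || world$t >= t_diff)
            world$config$differentiated <- TRUE
        }
      }
    }
    if (isTRUE(world$config$differentiated)) {
      for (id in live_cell_ids(world)) {
        cell <- world$cells[[as.character(id)]]
        if (cell$state == "apoptotic") next
        if (any(contact[[as.character(id)]] %||% FALSE) && cell$polarized) {
          cell$growth_suppressed <- TRUE
          world$cells[[as.character(id)]] <- cell
        } else {
          world <- start_apoptosis(world, cell)
        }
      }
    }
    world
  })
}

#' Build the initial world of a named scenario
#'
#' Cells start as concentric regular n-gons with every element at rest;
#' the monolayer begins from two founder cells, cysts and the acinus
#' from one.  Scenario-specific ECM geometry, substrate drag, hooks
#' (polarization, apoptosis predicates) and stop rules are attached to
#' `world$config`.
#'
#' @param spec a [scenario_spec()] (or a scenario name, for defaults).
#' @return a `cell_world` ready for [run_simulation()].
#' @export
make_world <- function(spec) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  pov <- spec$params %||% list()
  pov$n <- spec$n
  params <- do.call(cell_params, pov)
  R <- params$R
  D0 <- params$drag_mem
  hooks <- list()
  stop_when <- NULL
  if (!is.null(spec$target_cells)) {
    tc <- spec$target_cells
    stop_when <- function(world) n_cells(world) >= tc
  }
  w <- new_world(substrate = D0 * spec$drag_mult)

  if (spec$name == "single_cell") {
    w <- add_cell(w, c(0, 0), params)
  } else if (spec$name == "monolayer") {
    gap <- spec$founder_gap %||% 1
    w <- add_cell(w, c(-(R + gap / 2), 0), params)
    w <- add_cell(w, c(R + gap / 2, 0), params)
  } else if (spec$name == "crawling_cell") {
    w <- add_cell(w, c(0, 0), params)
    w <- set_motile(w, 1L, direction = spec$direction %||% c(1, 0),
                    omega = spec$omega %||% (2 * pi / 60))
    # a motility assay: the crawling cell runs its protrusion cycle, not
    # the proliferation program
    w$cells[[1]]$growth_suppressed <- TRUE
  } else if (spec$name == "ecm_line_epithelium") {
    w <- build_ecm(w, "line", spacing = spec$ecm_spacing %||% 2,
                   length = spec$ecm_length %||% 12 * R,
                   center = c(0, 0), drag = spec$ecm_drag %||% 50)
    w <- add_cell(w, c(0, R + 0.5), params)
    hooks <- epithelial_hooks(T_apop = spec$T_apop %||% 60)
  } else if (spec$name == "ecm_hole_cyst") {
    W <- (spec$W_over_R %||% 3) * R
    w <- build_ecm(w, "line_with_gap", spacing = spec$ecm_spacing %||% 2,
                   length = spec$ecm_length %||% 16 * R,
                   gap_width = W, gap_depth = spec$gap_depth %||% 1.5 * R,
                   center = c(0, 0), drag = spec$ecm_drag %||% 50)
    w <- add_cell(w, c(0, 0.2 * R), params)
    hooks <- epithelial_hooks(T_apop = spec$T_apop %||% 120)
  } else if (spec$name == "inverted_cyst") {
    rr <- spec$ring_radius %||% 2 * R
    w <- build_ecm(w, "ring", spacing = spec$ecm_spacing %||% 2,
                   radius = rr, center = c(0, 0),
                   drag = spec$ecm_drag %||% 50)
    w <- add_cell(w, c(rr + R + 0.5, 0), params)
    hooks <- epithelial_hooks(T_apop = spec$T_apop %||% 120)
  } else if (spec$name == "ecm_gap") {
    W <- spec$W_over_R * R
    w <- build_ecm(w, "line_with_gap", spacing = spec$ecm_spacing %||% 2,
                   length = spec$ecm_length %||% 20 * R,
                   gap_width = W, gap_depth = spec$gap_depth %||% 3 * R,
                   center = c(0, 0), rigid = TRUE)
    w <- add_cell(w, c(-6 * R, R + 0.5), params)
    w$config$gap <- list(xc = 0, y = 0, W = W,
                         depth = spec$gap_depth %||% 3 * R)
    hooks <- epithelial_hooks(T_apop = spec$T_apop %||% 120)
  } else if (spec$name == "tensegrity_bud") {
    len <- spec$ecm_length %||% 16 * R
    dip <- spec$dip_depth %||% 0.95
    sigma <- spec$dip_sigma %||% 1.5 * R
    base_drag <- spec$ecm_drag %||% 50
    dragf <- function(x, y) base_drag * (1 - dip * exp(-x^2 / (2 * sigma^2)))
    w <- build_ecm(w, "line", spacing = spec$ecm_spacing %||% 2,
                   length = len, center = c(0, 0), drag = dragf)
    ncell <- spec$n_cells %||% 5L
    xs <- seq(-(ncell - 1) / 2, (ncell - 1) / 2) * (2 * R + 0.5)
    for (x in xs) w <- add_cell(w, c(x, R + 0.5), params)
    hooks <- epithelial_hooks(T_apop = spec$T_apop %||% 1e9)
  } else if (spec$name == "acinus") {
    # a narrower growth-recovery band lets rim cells resume growing after
    # transient compression, so the colony reliably reaches the ECM ring
    if (is.null(pov$c_g)) {
      pov$c_g <- 0.72
      params <- do.call(cell_params, pov)
    }
    rr <- spec$ring_radius %||% 28
    w <- build_ecm(w, "ring", spacing = spec$ecm_spacing %||% 2,
                   radius = rr, center = c(0, 0),
                   drag = spec$ecm_drag %||% 50)
    w <- add_cell(w, c(0, 0), params)
    hooks <- acinus_hooks(min_cells = spec$min_cells %||% 8L,
                          t_diff = spec$t_diff %||% 1000)
  }
  w$config$scenario <- spec
  w$config$hooks <- hooks
  w$config$stop_when <- stop_when
  validate_world(w)
}

#' Run a named scenario
#'
#' Convenience wrapper: builds the world with [make_world()] and runs it
#' with the scenario's hooks and stop rule installed.
#'
#' @param spec a [scenario_spec()], a scenario name, or a prebuilt
#'   `cell_world` from [make_world()].
#' @param n_steps step budget.
#' @param dt time step, s.
#' @param seed RNG seed.
#' @param record_every metrics cadence (steps).
#' @param record_metrics compute tissue metrics while recording.
#' @return a `cell_sim`.
#' @export
run_scenario <- function(spec, n_steps = 1000L, dt = 0.05, seed = 1L,
                         record_every = 100L, record_metrics = FALSE) {
  world <- if (inherits(spec, "cell_world")) spec else make_world(spec)
  cfg <- engine_config(dt = dt, n_steps = n_steps, seed = seed,
                       record_every = record_every,
                       record_metrics = record_metrics,
                       stop_when = world$config$stop_when,
                       hooks = world$config$hooks)
  run_simulation(world, cfg)
}

#' Classify the outcome of an ECM-gap run
#'
#' Structural classification of the final configuration around a
#' rectangular ECM notch of width `W`: `not_lined` (no cell entered the
#' gap mouth), `entry_blocked` (a single cell wedged in the mouth while
#' the monolayer continues above), `entrapped` (cells inside but the
#' notch floor is not covered), or `lined` (walls and floor covered by
#' cell contacts).
#'
#' @param world final `cell_world` of an `ecm_gap` run (its
#'   `config$gap` holds the notch geometry; override via `gap`).
#' @param W gap width, um.
#' @param R free cell radius, um.
#' @param gap optional list(xc, y, depth) replacing `world$config$gap`.
#' @param eps contact distance for coverage, um.
#' @return one of `"not_lined"`, `"entry_blocked"`, `"entrapped"`,
#'   `"lined"`.
#' @export
gap_regime_classifier <- function(world, W, R, gap = world$config$gap,
                                  eps = NULL) {
  if (is.null(gap)) stop("no gap geometry available")
  if (is.null(eps)) eps <- world$rule$d_a + 0.5
  polys <- world_polys(world)
  if (!length(polys)) return("not_lined")
  cents <- t(vapply(polys, colMeans, numeric(2)))
  inside <- cents[, 2] < gap$y & abs(cents[, 1] - gap$xc) < W / 2 + R / 2
  if (!any(inside)) return("not_lined")
  # sample the notch walls and floor and measure cell coverage
  xl <- gap$xc - W / 2; xr <- gap$xc + W / 2; yb <- gap$y - gap$depth
  smp <- rbind(
    cbind(xl, seq(yb, gap$y, by = 1)),
    cbind(xr, seq(yb, gap$y, by = 1)),
    cbind(seq(xl, xr, by = 1), yb))
  covered <- rep(FALSE, nrow(smp))
  for (p in polys)
    covered <- covered | (cpp_point_polyline(smp, p, TRUE)$dist < eps)
  cov <- mean(covered)
  if (cov >= 0.85) return("lined")
  if (sum(inside) <= 2 && cov < 0.5) return("entry_blocked")
  "entrapped"
}
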