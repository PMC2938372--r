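# Force accumulation, overdamped time integration, and the per-step
# scheduler ordering mechanics, bond updates and biological events.

#' Engine configuration
#'
#' @param dt time step, s.  Must satisfy the element-wise stability bound
#'   `dt < min((D_min + eta) / k)` over all elements, with `D_min` the
#'   smallest drag of a non-fixed node (checked at startup).
#' @param n_steps number of steps to run.
#' @param seed integer seed; every random choice (growth insertion
#'   positions, tie-breaks) draws from this stream, so equal seeds give
#'   identical runs.
#' @param forces named logical toggles: `pressure`, `adhesion`,
#'   `repulsion`, `external`, `mitosis`.
#' @param record_every cadence (steps) of the metrics time series; set
#'   `0` to disable.
#' @param record_metrics compute the tissue-geometry summary at each
#'   recording step (otherwise only time and cell count are logged).
#' @param stop_when optional `function(world)`; the run ends when it
#'   returns `TRUE`.
#' @param hooks list of `function(world, step)` scenario rules executed
#'   after the biological events of each step.
#' @param biology enable growth/division/apoptosis event processing.
#' @return an `engine_config` list.
#' @export
engine_config <- function(dt = 0.05, n_steps = 1000L, seed = 1L,
                          forces = list(), record_every = 50L,
                          record_metrics = TRUE,
                          stop_when = NULL, hooks = list(),
                          biology = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  tog <- list(pressure = TRUE, adhesion = TRUE, repulsion = TRUE,
              external = TRUE, mitosis = TRUE)
  tog[names(forces)] <- forces
  structure(list(dt = dt, n_steps = as.integer(n_steps), seed = as.integer(seed),
                 forces = tog, record_every = as.integer(record_every),
                 record_metrics = isTRUE(record_metrics),
                 stop_when = stop_when, hooks = hooks,
                 biology = isTRUE(biology)),
            class = "engine_config")
}

check_stability <- function(world, dt) {
  elem <- world_elements(world)
  if (!length(elem$a)) return(invisible(TRUE))
  Dmin <- suppressWarnings(min(world$drag[!world$fixed]))
  if (!is.finite(Dmin)) return(invisible(TRUE))
  bound <- min((Dmin + elem$eta) / elem$k)
  if (dt >= bound)
    stop(sprintf("dt = %g violates the stability bound %g = min (D_min + eta)/k",
                 dt, bound))
  invisible(TRUE)
}

# internal: all force terms; returns full (antisymmetric bookkeeping),
# semi (own-node axial dashpot moved to the denominator) and H (sum of
# incident element viscosities per node).
compute_forces <- function(world, toggles = NULL, normals = NULL) {
  if (is.null(toggles))
    toggles <- list(pressure = TRUE, adhesion = TRUE, repulsion = TRUE,
                    external = TRUE, mitosis = TRUE)
  N <- n_nodes(world)
  if (N == 0L)
    return(list(full = matrix(0, 0, 2), semi = matrix(0, 0, 2), H = numeric(0)))
  elem <- world_elements(world)
  a <- elem$a; b <- elem$b; k <- elem$k; eta <- elem$eta; L0 <- elem$L0
  if (toggles$adhesion && length(world$bonds$a)) {
    a <- c(a, world$bonds$a); b <- c(b, world$bonds$b)
    k <- c(k, world$bonds$k); eta <- c(eta, world$bonds$eta)
    L0 <- c(L0, world$bonds$L0)
  }
  if (length(a)) {
    acc <- cpp_voigt_accumulate(world$pos, world$vel, a, b, k, eta, L0)
    full <- acc$full; semi <- acc$semi; H <- acc$H
  } else {
    full <- matrix(0, N, 2); semi <- matrix(0, N, 2); H <- numeric(N)
  }
  if (is.null(normals)) normals <- all_membrane_normals(world)
  if (toggles$pressure) {
    fp <- all_pressure_forces(world, normals)
    full <- full + fp; semi <- semi + fp
  }
  if (toggles$repulsion) {
    fr <- repulsion_forces(world, normals = normals)
    full <- full + fr; semi <- semi + fr
  }
  if (toggles$external && !is.null(world$external_force)) {
    fe <- world$external_force(world$pos, world$t)
    full <- full + fe; semi <- semi + fe
  }
  if (toggles$mitosis) {
    for (cell in world$cells) {
      if (cell$state != "mitotic") next
      fm <- mitosis_forces(world, cell)
      full[cell$mem, ] <- full[cell$mem, ] + fm$mem
      full[cell$nuc, ] <- full[cell$nuc, ] + fm$nuc
      semi[cell$mem, ] <- semi[cell$mem, ] + fm$mem
      semi[cell$nuc, ] <- semi[cell$nuc, ] + fm$nuc
    }
  }
  list(full = full, semi = semi, H = H)
}

#' Total force on every node
#'
#' The per-node total is the five-term decomposition: intra-cellular
#' forces (cytoskeleton, membrane, pressure), cell-cell interaction
#' (adhesion + repulsion), cell-ECM interaction (same machinery against
#' ECM chains), external field, and mitotic forces.  Forces on fixed
#' nodes are computed but never applied.
#'
#' @param world a `cell_world`.
#' @param forces named logical toggles as in [engine_config()].
#' @return N x 2 matrix of total forces, nN.
#' @export
accumulate_forces <- function(world, forces = list()) {
  tog <- list(pressure = TRUE, adhesion = TRUE, repulsion = TRUE,
              external = TRUE, mitosis = TRUE)
  tog[names(forces)] <- forces
  compute_forces(world, tog)$full
}

#' Advance node positions by one overdamped step
#'
#' First-order overdamped update `v = F / (D + H)`, `x <- x + v dt`,
#' where `D` is the node drag and `H` the summed viscosity of its
#' incident elements (the node's own axial dashpot term, treated
#' implicitly for stability; neighbor dashpot terms enter `F` explicitly
#' at the previous step's velocities).  Fixed nodes do not move.
#'
#' @param world a `cell_world`.
#' @param dt time step, s.
#' @param forces optional precomputed force list from the internal
#'   accumulator; recomputed when missing.
#' @return updated world (positions, velocities, time).
#' @export
integrate_step <- function(world, dt, forces = NULL) {
  if (is.null(forces)) forces <- compute_forces(world)
  free <- !world$fixed
  if (any(world$drag[free] <= 0))
    stop("non-fixed node with zero drag: configure the substrate or node drag")
  denom <- world$drag + forces$H
  v <- forces$semi / denom
  v[!free, ] <- 0
  world$vel <- v
  world$pos[free, ] <- world$pos[free, ] + v[free, , drop = FALSE] * dt
  world$t <- world$t + dt
  world
}

# total elastic energy stored in springs (stability diagnostics/tests)
spring_potential <- function(world) {
  elem <- world_elements(world)
  a <- c(elem$a, world$bonds$a); b <- c(elem$b, world$bonds$b)
  k <- c(elem$k, world$bonds$k); L0 <- c(elem$L0, world$bonds$L0)
  if (!length(a)) return(0)
  len <- sqrt(rowSums((world$pos[b, , drop = FALSE] -
                       world$pos[a, , drop = FALSE])^2))
  sum(0.5 * k * (len - L0)^2)
}

# one biological-event pass; returns list(world, events)
biology_step <- function(world, step) {
  events <- list()
  ids <- live_cell_ids(world)
  for (id in ids) {
    cell <- world$cells[[as.character(id)]]
    if (is.null(cell)) next
    if (cell$state == "apoptotic") next
    if (cell$state == "mitotic") {
      if (nucleus_group_separation(world, cell) > cell$mito$L_div) {
        world <- split_cell(world, cell)
        events[[length(events) + 1L]] <-
          list(step = step, t = world$t, cell = id, event = "division",
               detail = paste(attr(world, "daughters"), collapse = "+"))
      }
      next
    }
    region <- growth_state(world, cell)
    if (region != "intermediate") cell$gstate <- region
    cell$state <- if (cell$gstate == "growth") "growing" else "quiescent"
    world$cells[[as.character(id)]] <- cell
    if (world$t >= cell$t_next_growth) {
      cell$t_next_growth <- world$t + cell$params$tau_g
      world$cells[[as.character(id)]] <- cell
      if (cell$gstate == "growth" && !isTRUE(cell$growth_suppressed)) {
        if (cell$V_rest >= 2 * cell$V_rest0) {
          # divide only when the cut is reasonably centered; a deformed
          # cell postpones mitosis until its geometry allows a near-equal
          # split (divisions yield approximately equal daughters)
          ax <- select_division_axis(world, cell)
          if (division_balance(world, cell, ax) >= 0.3) {
            world <- partition_cell(world, cell, ax)
            events[[length(events) + 1L]] <-
              list(step = step, t = world$t, cell = id,
                   event = "mitosis_start", detail = "")
          }
        } else {
          world <- add_growth_point(world, cell)
          events[[length(events) + 1L]] <-
            list(step = step, t = world$t, cell = id, event = "growth",
                 detail = as.character(world$cells[[as.character(id)]]$n))
        }
      }
    }
  }
  world <- reap(world)
  for (id in attr(world, "reaped"))
    events[[length(events) + 1L]] <-
      list(step = step, t = world$t, cell = id, event = "reaped", detail = "")
  list(world = world, events = events)
}

#' Run a simulation
#'
#' Per step, in order: motility parameter cycling, substrate drag
#' refresh, adhesion bond update, force accumulation, overdamped
#' integration, biological events (growth attempts, division trigger and
#' surgery, apoptosis reaping, scenario hooks), scheduled outputs.
#' Deterministic for a fixed seed.
#'
#' @param world a `cell_world`.
#' @param config an [engine_config()].
#' @return a `cell_sim` object: final `world`, `events` and `metrics`
#'   data frames, the config, and the number of steps run.
#' @export
run_simulation <- function(world, config = engine_config()) {
  set.seed(config$seed)
  check_stability(world, config$dt)
  events <- list()
  metrics <- list()
  maxR <- if (length(world$cells))
    max(vapply(world$cells, `[[`, numeric(1), "R")) else 10
  steps_run <- 0L
  for (step in seq_len(config$n_steps)) {
    for (cell in world$cells)
      if (isTRUE(cell$motile)) world <- motility_update(world, cell)
    world <- apply_substrate(world)
    if (config$forces$adhesion) world <- update_adhesions(world)
    world <- with_elem_cache(world)
    normals <- all_membrane_normals(world)
    forces <- compute_forces(world, config$forces, normals)
    world <- integrate_step(world, config$dt, forces)
    disp <- max(abs(world$vel)) * config$dt
    if (disp > maxR)
      stop(sprintf(
        "instability: step %d moved a node %.3g um (> one cell radius); reduce dt",
        step, disp))
    if (config$biology) {
      bs <- biology_step(world, step)
      world <- bs$world
      events <- c(events, bs$events)
      if (step %% 5L == 0L)
        for (id in live_cell_ids(world)) world <- untangle_cell(world, id)
    }
    for (h in config$hooks) world <- h(world, step)
    steps_run <- step
    if (config$record_every > 0L && step %% config$record_every == 0L) {
      row <- list(step = step, t = world$t, n_c = n_cells(world))
      if (config$record_metrics && n_cells(world) > 0L) {
        cs <- culture_summary(world)
        row <- c(row, list(A_T = cs$A_T, lambda = cs$lambda, rho = cs$rho,
                           gamma = cs$gamma,
                           mean_neighbors = cs$mean_neighbors,
                           mean_neighbors_interior = cs$mean_neighbors_interior))
      }
      metrics[[length(metrics) + 1L]] <- row
    }
    if (!is.null(config$stop_when) && isTRUE(config$stop_when(world))) break
  }
  ev <- if (length(events)) do.call(rbind, lapply(events, function(e)
    data.frame(step = e$step, t = e$t, cell = e$cell, event = e$event,
               detail = e$detail, stringsAsFactors = FALSE)))
  else data.frame(step = integer(0), t = numeric(0), cell = integer(0),
                  event = character(0), detail = character(0))
  mt <- if (length(metrics)) {
    nm <- unique(unlist(lapply(metrics, names)))
    do.call(rbind, lapply(metrics, function(m) {
      m[setdiff(nm, names(m))] <- NA_real_
      as.data.frame(m[nm])
    }))
  } else data.frame()
  structure(list(world = world, events = ev, metrics = mt, config = config,
                 steps_run = steps_run),
            class = "cell_sim")
}
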