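test_that("volume gate regions follow the stop/growth rule", {
  w <- single_cell_world(n = 20)
  cl <- w$cells[[1]]
  # at rest the area equals V_rest: growth region (c_g < 1)
  expect_identical(growth_state(w, 1L), "growth")
  # shrink the membrane uniformly below c_s: stop
  w2 <- w
  sc <- sqrt(cl$c_s * 0.9)
  w2$pos[cl$mem, ] <- w2$pos[cl$mem, ] * sc
  expect_identical(growth_state(w2, 1L), "stop")
  # between the bounds: intermediate (engine retains the previous regime)
  w3 <- w
  sc3 <- sqrt((cl$c_s + cl$c_g) / 2)
  w3$pos[cl$mem, ] <- w3$pos[cl$mem, ] * sc3
  expect_identical(growth_state(w3, 1L), "intermediate")
})

test_that("growth insertion adds one paired node and four elements with scaling", {
  w <- single_cell_world(n = 40)
  cl0 <- w$cells[[1]]
  Vr0 <- cl0$V_rest
  rad0 <- mean(cl0$L0_rad)
  mem_tot0 <- sum(cl0$L0_mem)
  n_elem0 <- length(viscocell:::world_elements(w)$a)
  w <- add_growth_point(w, 1L, at = 7L)
  cl <- w$cells[[1]]
  expect_identical(cl$n, 41L)
  expect_identical(length(cl$mem), 41L)
  expect_identical(length(cl$nuc), 41L)
  # +4 elements: membrane, nuclear membrane, radial, chord re-pairing
  expect_identical(length(viscocell:::world_elements(w)$a), n_elem0 + 4L)
  # stated proportionalities
  expect_equal(cl$V_rest, Vr0 * (41 / 40)^2, tolerance = 1e-12)
  expect_equal(mean(cl$L0_rad), rad0 * 41 / 40, tolerance = 1e-12)
  expect_equal(sum(cl$L0_mem), mem_tot0 * 41 / 40, tolerance = 1e-12)
  # repeated insertions until the rest area doubles: n = ceil(40 sqrt 2)
  while (w$cells[[1]]$V_rest < 2 * Vr0)
    w <- add_growth_point(w, 1L, at = 1L)
  expect_identical(w$cells[[1]]$n, 57L)
  # growth is forbidden during mitosis/apoptosis
  w2 <- single_cell_world(n = 20)
  w2 <- partition_cell(w2, 1L)
  expect_error(add_growth_point(w2, 1L), "cannot grow")
})

test_that("division axis is perpendicular to the elongation direction", {
  # ellipse with major axis along x: divide along y
  w <- single_cell_world(n = 40)
  cl <- w$cells[[1]]
  w$pos[cl$mem, 1] <- w$pos[cl$mem, 1] * 1.6
  w$pos[cl$nuc, 1] <- w$pos[cl$nuc, 1] * 1.6
  ax <- select_division_axis(w, 1L)
  expect_lt(abs(ax$dir[1]), 1e-9)
  expect_equal(abs(ax$dir[2]), 1)
  expect_equal(ax$anchor, colMeans(w$pos[cl$nuc, ]), tolerance = 1e-12)
  # circle: degenerate tensor resolved deterministically through node 1
  w2 <- single_cell_world(n = 40)
  ax2 <- select_division_axis(w2, 1L)
  ax2b <- select_division_axis(w2, 1L)
  expect_equal(ax2$dir, ax2b$dir)
  d <- w2$pos[w2$cells[[1]]$mem[1], ] - ax2$anchor
  expect_equal(abs(sum(ax2$dir * d / sqrt(sum(d^2)))), 1, tolerance = 1e-9)
  # polarized cell with basal nodes along the bottom: vertical axis
  w3 <- single_cell_world(n = 40)
  cl3 <- w3$cells[[1]]
  bottom <- w3$pos[cl3$mem, 2] < -0.6 * cl3$R
  w3 <- polarize(w3, 1L, contact = bottom)
  ax3 <- select_division_axis(w3, 1L)
  expect_gt(abs(ax3$dir[2]), 0.98)
})

test_that("partition halves the ring and eliminates the nuclear chords", {
  w <- single_cell_world(n = 40)
  w <- partition_cell(w, 1L)
  cl <- w$cells[[1]]
  expect_identical(cl$state, "mitotic")
  expect_identical(length(cl$k_chord), 0L)
  grp <- cl$mito$grp
  expect_lte(abs(sum(grp == 1L) - sum(grp == 2L)), 1L)
  expect_identical(sort(unique(grp)), c(1L, 2L))
  # group A is contiguous along the ring
  runs <- rle(grp[order(seq_along(grp))])$values
  expect_lte(length(rle(c(grp, grp[1]))$values), 4L)
})

test_that("mitotic forces are equal-and-opposite with increasing separation", {
  w <- single_cell_world(n = 40)
  w <- partition_cell(w, 1L)
  cl <- w$cells[[1]]
  fm <- mitosis_forces(w, 1L)
  expect_equal(colSums(fm$mem) + colSums(fm$nuc), c(0, 0), tolerance = 1e-9)
  # nuclear centroid separation strictly increases under the pulls
  sep0 <- viscocell:::nucleus_group_separation(w, cl)
  cfg <- engine_config(dt = 0.05, n_steps = 60, record_every = 0,
                       biology = FALSE)
  sim <- run_simulation(w, cfg)
  sep1 <- viscocell:::nucleus_group_separation(sim$world, sim$world$cells[[1]])
  expect_gt(sep1, sep0)
})

test_that("split restores daughter node counts and conserves area", {
  w <- single_cell_world(n = 40)
  Vr0 <- w$cells[[1]]$V_rest
  # grow to doubling, then divide under the engine
  w$substrate <- 20
  cfg <- engine_config(dt = 0.05, n_steps = 8000, seed = 3, record_every = 0,
                       stop_when = function(wd) n_cells(wd) >= 2)
  sim <- run_simulation(w, cfg)
  expect_identical(n_cells(sim$world), 2L)
  for (cl in sim$world$cells) {
    expect_identical(cl$n, 40L)
    expect_identical(length(cl$mem), 40L)
    expect_identical(length(cl$nuc), 40L)
    expect_identical(length(cl$k_chord), 40L)
    expect_true(viscocell:::ring_is_simple(cell_ring_xy(sim$world, cl, "mem")))
    expect_equal(cl$V_rest, Vr0, tolerance = 1e-9)
  }
  # daughters adhere to each other at the next bond update
  wb <- update_adhesions(sim$world)
  expect_gt(length(wb$bonds$a), 0)
})

test_that("apoptosis collapses the cell and reaping removes it", {
  w <- two_cell_world(gap = 0.5)
  w <- update_adhesions(w)
  expect_gt(length(w$bonds$a), 0)
  L0_before <- w$cells[[1]]$L0_mem
  w <- start_apoptosis(w, 1L)
  cl <- w$cells[[1]]
  expect_identical(cl$state, "apoptotic")
  expect_identical(length(w$bonds$a), 0L)            # unilateral disruption
  expect_equal(cl$L0_mem, L0_before / 5)             # five-fold reduction
  expect_equal(cl$P_in, w$P_env)
  # idempotent restart
  w2 <- start_apoptosis(w, 1L)
  expect_equal(w2$cells[[1]]$L0_mem, L0_before / 5)
  # area decreases monotonically (sampled) until the cell is reaped
  cfg <- engine_config(dt = 0.05, n_steps = 2000, record_every = 0)
  areas <- c()
  wd <- w
  for (i in 1:40) {
    for (j in 1:25) wd <- integrate_step(wd, 0.05)
    if (is.null(wd$cells[["1"]])) break
    areas <- c(areas, cell_area(wd, 1L))
    wd <- reap(wd)
  }
  expect_true(all(diff(areas) < 0))
  expect_null(wd$cells[["1"]])
  expect_identical(n_cells(wd), 1L)
})

test_that("polarization labels basal, apical and lateral sectors", {
  w <- single_cell_world(n = 40)
  # no ECM contact: unpolarized, all labels none
  w0 <- polarize(w, 1L, contact = rep(FALSE, 40))
  expect_false(w0$cells[[1]]$polarized)
  expect_true(all(w0$label[w0$cells[[1]]$mem] == 0L))
  # bottom third contacting: bottom basal, top apical, sides lateral
  cl <- w$cells[[1]]
  ang <- atan2(w$pos[cl$mem, 2], w$pos[cl$mem, 1])
  contact <- abs(ang + pi / 2) < pi / 3
  w1 <- polarize(w, 1L, contact = contact)
  lab <- w1$label[cl$mem]
  expect_true(w1$cells[[1]]$polarized)
  expect_true(all(lab[contact] == 4L))                       # basal
  top <- abs(ang - pi / 2) < pi / 6
  expect_true(all(lab[top] == 3L))                           # apical
  expect_true(all(lab %in% c(3L, 4L, 5L)))                   # full partition
})

test_that("motility cycle is periodic, antiphase, and drives crawling", {
  w <- new_world(substrate = 20)
  w <- add_cell(w, c(0, 0), cell_params(n = 40))
  w <- set_motile(w, 1L, direction = c(1, 0), omega = 2 * pi / 30)
  cl <- w$cells[[1]]
  mo <- cl$motility
  # t = 0: everything at its initial value
  w0 <- motility_update(w, 1L, t = 0)
  expect_equal(mean(w0$cells[[1]]$L0_rad), mo$L0a0, tolerance = 1e-9)
  expect_equal(unname(w0$drag[cl$mem[1]]), mo$Da0)
  # quarter period: anterior at threshold, posterior at initial
  Tq <- (2 * pi / mo$omega) / 4
  w1 <- motility_update(w, 1L, t = Tq)
  lab <- w1$label[w1$cells[[1]]$mem]
  expect_equal(unique(w1$cells[[1]]$L0_rad[lab == 1L]), mo$L0at, tolerance = 1e-9)
  expect_equal(unique(w1$cells[[1]]$L0_rad[lab == 2L]), mo$L0p0, tolerance = 1e-9)
  # full period: exactly back to initial values (no drift)
  w2 <- motility_update(w, 1L, t = 2 * pi / mo$omega)
  expect_equal(w2$cells[[1]]$L0_rad, w$cells[[1]]$L0_rad, tolerance = 1e-9)
  # a full cycle on a uniform substrate yields net forward displacement
  sim <- run_scenario(scenario_spec("crawling_cell", n = 20,
                                    omega = 2 * pi / 30),
                      n_steps = 600, dt = 0.05, seed = 1, record_every = 0)
  cc0 <- c(0, 0)
  cc1 <- colMeans(sim$world$pos[sim$world$cells[[1]]$mem, ])
  expect_gt(cc1[1] - cc0[1], 0)
  # missing labels error
  wq <- single_cell_world(n = 20)
  expect_error(motility_update(wq, 1L), "not motile")
})

test_that("apoptosis is absorbing: no growth, division, or new bonds", {
  w <- two_cell_world(gap = 0.5)
  w <- start_apoptosis(w, 1L)
  expect_error(add_growth_point(w, 1L), "cannot grow")
  w <- update_adhesions(w)
  expect_identical(length(w$bonds$a), 0L)
  # engine never schedules growth/division for it
  cfg <- engine_config(dt = 0.05, n_steps = 100, record_every = 0)
  sim <- run_simulation(w, cfg)
  ev <- sim$events[sim$events$cell == 1L & sim$events$event %in%
                     c("growth", "mitosis_start"), ]
  expect_identical(nrow(ev), 0L)
})
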