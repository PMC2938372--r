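test_that("adhesion templates combine in series, symmetrically", {
  expect_equal(combine_adhesion_params(list(k = 2, eta = 1),
                                       list(k = 2, eta = 1))$k, 1)
  set.seed(2)
  for (i in 1:10) {
    a <- list(k = runif(1, 0.1, 9), eta = runif(1, 0.1, 9))
    b <- list(k = runif(1, 0.1, 9), eta = runif(1, 0.1, 9))
    expect_equal(combine_adhesion_params(a, b), combine_adhesion_params(b, a))
  }
  # stiff limit: series combination tends to the softer spring
  expect_equal(combine_adhesion_params(list(k = 1e9, eta = 1),
                                       list(k = 2, eta = 1))$k,
               2, tolerance = 1e-6)
  expect_error(combine_adhesion_params(list(k = -1, eta = 1),
                                       list(k = 2, eta = 1)), "positive")
})

test_that("adhesion rule validates its hysteresis band", {
  expect_error(adhesion_rule(d_a = 2, d_r = 1), "d_a < d_r")
  expect_error(adhesion_rule(d_rep = 0), "d_rep")
})

test_that("bonds form under d_a, persist in the band, rupture past d_r", {
  w <- two_cell_world(gap = 0.7)
  rule <- w$rule
  w <- update_adhesions(w)
  expect_gt(length(w$bonds$a), 0)
  expect_gt(nrow(attr(w, "created")), 0)
  shift2 <- function(w, dx) {
    cl <- w$cells[["2"]]
    w$pos[c(cl$mem, cl$nuc), 1] <- w$pos[c(cl$mem, cl$nuc), 1] + dx
    w
  }
  # distance cycling d_a-eps -> (d_a+d_r)/2 -> d_a-eps keeps the bond
  nb0 <- length(w$bonds$a)
  mid <- (rule$d_a + rule$d_r) / 2
  w2 <- update_adhesions(shift2(w, mid - 0.7))
  expect_gt(length(w2$bonds$a), 0)
  w3 <- update_adhesions(shift2(w2, 0.7 - mid))
  expect_gte(length(w3$bonds$a), nb0)
  # crossing d_r ruptures
  w4 <- update_adhesions(shift2(w3, rule$d_r + 5))
  expect_identical(length(w4$bonds$a), 0L)
  expect_gt(nrow(attr(w4, "ruptured")), 0)
})

test_that("same-owner nodes and apoptotic cells never bond", {
  w <- single_cell_world(n = 20)   # many same-cell nodes under d_a
  w <- update_adhesions(w, adhesion_rule(d_a = 5, d_r = 6))
  expect_identical(length(w$bonds$a), 0L)
  w2 <- two_cell_world(gap = 0.7)
  w2 <- start_apoptosis(w2, 1L)
  w2 <- update_adhesions(w2)
  expect_identical(length(w2$bonds$a), 0L)
})

test_that("adhesion forces are pairwise antisymmetric Voigt forces", {
  w <- two_cell_world(gap = 0.7)
  expect_equal(max(abs(adhesion_forces(w))), 0)  # no bonds yet
  w <- update_adhesions(w)
  # stretch the pair so bonds exceed rest length: mutual attraction
  cl <- w$cells[["2"]]
  w$pos[c(cl$mem, cl$nuc), 1] <- w$pos[c(cl$mem, cl$nuc), 1] + 0.8
  f <- adhesion_forces(w)
  expect_equal(colSums(f), c(0, 0), tolerance = 1e-12)
  b <- w$bonds
  f1 <- f[b$a[1], ]
  expected <- voigt_force(w$pos[b$a[1], ], w$pos[b$b[1], ],
                          k = b$k[1], eta = b$eta[1], L0 = b$L0[1])$f_a
  # node may hold several bonds; single-bond case matches exactly
  if (sum(b$a == b$a[1]) == 1) expect_equal(f1, expected, tolerance = 1e-12)
  # attraction: force on the left cell's node points right (+x)
  expect_gt(sum(f[b$a, 1]), 0)
})

test_that("point-segment distance clamps to endpoints", {
  r <- point_segment_distance(c(0, 1), c(-1, 0), c(1, 0))
  expect_equal(r$dist, 1); expect_equal(r$closest, c(0, 0))
  r2 <- point_segment_distance(c(2, 0), c(-1, 0), c(1, 0))
  expect_equal(r2$dist, 1); expect_equal(r2$closest, c(1, 0))
  expect_equal(point_segment_distance(c(0.3, 0), c(-1, 0), c(1, 0))$dist, 0)
  expect_error(point_segment_distance(c(0, 0), c(1, 1), c(1, 1)), "degenerate")
})

test_that("repulsion ramps linearly, vanishes at range, conserves momentum", {
  rule <- adhesion_rule(d_a = 1.5, d_r = 3, d_rep = 1, k_rep = 5)
  # far cells: zero
  w <- two_cell_world(gap = 5)
  expect_equal(max(abs(repulsion_forces(w, rule))), 0)
  # overlap at d ~ d_rep/2: magnitude k_rep * d_rep/2 on the closest node
  w2 <- two_cell_world(gap = rule$d_rep / 2)
  f <- repulsion_forces(w2, rule)
  expect_equal(colSums(f), c(0, 0), tolerance = 1e-9)
  cl1 <- w2$cells[["1"]]
  tip <- cl1$mem[which.max(w2$pos[cl1$mem, 1])]
  # the tip feels its own inward push k_rep*(d_rep - d) at d = d_rep/2,
  # plus the reaction of the facing cell's query landing on its segment
  expect_gte(sqrt(sum(f[tip, ]^2)), rule$k_rep * rule$d_rep / 2 * 0.95)
  expect_lte(sqrt(sum(f[tip, ]^2)), rule$k_rep * rule$d_rep * 1.05)
  expect_lt(f[tip, 1], 0)   # pushed back into its own cell
  # continuity at d = d_rep: gap exactly at range gives ~zero force
  w3 <- two_cell_world(gap = rule$d_rep * 1.0001)
  expect_lt(max(abs(repulsion_forces(w3, rule))), 1e-2)
})

test_that("ECM chains build with the stated node and element counts", {
  w <- new_world()
  w <- build_ecm(w, "line", spacing = 1, length = 100)
  ch <- w$ecm[[1]]
  expect_identical(length(ch$nodes), 101L)
  expect_identical(length(ch$k), 100L)
  expect_false(ch$closed)
  # closed ring: node count equals element count
  w2 <- build_ecm(new_world(), "ring", spacing = 1, radius = 20)
  ch2 <- w2$ecm[[1]]
  expect_identical(length(ch2$nodes), length(ch2$k))
  expect_true(ch2$closed)
  # gap: notch corner vertices at +/- W/2
  R <- 7.5; W <- 2 * R
  w3 <- build_ecm(new_world(), "line_with_gap", spacing = 2, length = 100,
                  gap_width = W, gap_depth = 10)
  xs <- w3$pos[w3$ecm[[1]]$nodes, 1]
  ys <- w3$pos[w3$ecm[[1]]$nodes, 2]
  expect_true(any(abs(xs - W / 2) < 1e-9 & abs(ys) < 1e-9))
  expect_true(any(abs(xs + W / 2) < 1e-9 & abs(ys) < 1e-9))
  expect_true(any(abs(ys + 10) < 1e-9))
  expect_error(build_ecm(new_world(), "line_with_gap", gap_width = 0,
                         gap_depth = 5), "positive")
  # rigid chains have fixed nodes
  w4 <- build_ecm(new_world(), "line", rigid = TRUE)
  expect_true(all(w4$fixed[w4$ecm[[1]]$nodes]))
  # drag profile function is evaluated at node positions
  w5 <- build_ecm(new_world(), "line", length = 40,
                  drag = function(x, y) 50 * (1 - 0.9 * exp(-x^2 / 50)))
  dv <- w5$drag[w5$ecm[[1]]$nodes]
  expect_lt(min(dv), 10)
  expect_gt(max(dv), 45)
})

test_that("substrate drag returns the field value at the node position", {
  w <- new_world(substrate = 20)
  w <- add_cell(w, c(0, 0), cell_params(n = 12))
  expect_equal(substrate_drag(w, w$cells[[1]]$mem),
               rep(20, 12))
  # the low-adhesion culture setting
  w$substrate <- 0.0001 * 20
  expect_equal(substrate_drag(w, 1L), 0.002)
  # gradient field: monotone along its axis
  w$substrate <- function(x, y) 1 + 0.1 * x
  d <- substrate_drag(w, w$cells[[1]]$mem)
  ord <- order(w$pos[w$cells[[1]]$mem, 1])
  expect_true(all(diff(d[ord]) >= 0))
  w$substrate <- NULL
  expect_error(substrate_drag(w, 1L), "substrate")
})

test_that("interaction forces conserve momentum over a bonded two-cell world", {
  w <- two_cell_world(gap = 0.5)
  w <- update_adhesions(w)
  f <- adhesion_forces(w) + repulsion_forces(w)
  expect_lt(max(abs(colSums(f))), 1e-9 * max(1, max(abs(f))))
})

test_that("overlapping rest cells released separate to non-overlap", {
  w <- two_cell_world(gap = -2)   # pushed into overlap
  cfg <- engine_config(dt = 0.05, n_steps = 2500, record_every = 0,
                       biology = FALSE)
  sim <- run_simulation(w, cfg)
  polys <- lapply(sim$world$cells, function(cl)
    cell_ring_xy(sim$world, cl, "mem"))
  ov <- viscocell:::polygon_overlap_area(polys[[1]], polys[[2]])
  area1 <- polygon_area(polys[[1]])
  expect_lt(ov / area1, 0.01)
})
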