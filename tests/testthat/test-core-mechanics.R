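test_that("Voigt element force matches the analytic spring and dashpot laws", {
  # pure Hooke: k (|r| - L0) along the axis, equal and opposite
  f <- voigt_force(c(0, 0), c(3, 0), k = 2, L0 = 1)
  expect_equal(f$f_a, c(4, 0))
  expect_identical(f$f_b, -f$f_a)
  # rest state: zero
  f0 <- voigt_force(c(0, 0), c(0, 2), k = 5, eta = 3, L0 = 2)
  expect_equal(f0$f_a, c(0, 0))
  # dashpot only: closing speed 0.5 along the axis at rest length
  fd <- voigt_force(c(0, 0), c(1, 0), va = c(0.25, 0), vb = c(-0.25, 0),
                    k = 1, eta = 2, L0 = 1)
  expect_equal(sqrt(sum(fd$f_a^2)), 1.0)
  expect_lt(fd$f_a[1], 0)  # resists the approach
  # off-axis element, random velocities: exact antisymmetry
  set.seed(7)
  for (i in 1:10) {
    pa <- rnorm(2); pb <- rnorm(2); va <- rnorm(2); vb <- rnorm(2)
    if (sum((pa - pb)^2) < 1e-6) next
    fr <- voigt_force(pa, pb, va, vb, k = runif(1, 0.1, 5),
                      eta = runif(1, 0, 3), L0 = runif(1, 0.1, 2))
    expect_identical(fr$f_b, -fr$f_a)
  }
  expect_error(voigt_force(c(1, 1), c(1, 1), k = 1, L0 = 1), "degenerate")
})

test_that("polygon area follows the shoelace formula and orientation contract", {
  expect_equal(polygon_area(unit_square()), 1.0)
  # regular 40-gon of radius 7.5: closed form n R^2 sin(2 pi/n)/2
  expect_equal(polygon_area(regular_ring(40, 7.5)),
               0.5 * 40 * 7.5^2 * sin(2 * pi / 40), tolerance = 1e-12)
  expect_error(polygon_area(unit_square()[4:1, ]), "clockwise")
  expect_error(polygon_area(matrix(c(0, 0, 1, 1), 2, 2)), "at least 3")
})

test_that("outward normals are unit, chord-perpendicular, and outward", {
  # regular polygon: normal at a node is its radial direction
  ring <- regular_ring(12, 3)
  nor <- outward_normal(ring)
  expect_equal(nor, ring / 3, tolerance = 1e-12)
  # unit square CCW, node (1,0): chord (0,0)->(1,1), normal (1,-1)/sqrt(2)
  expect_equal(drop(outward_normal(unit_square(), 2L)),
               c(1, -1) / sqrt(2))
  # degenerate: coincident neighbors
  bad <- rbind(c(0, 0), c(1, 0), c(0, 0))
  expect_error(outward_normal(bad, 2L), "degenerate")
})

test_that("cytoskeleton forces act through the paired radial elements", {
  w <- single_cell_world(n = 40)
  # concentric rest: all zero
  expect_equal(max(abs(cytoskeleton_forces(w, 1L))), 0, tolerance = 1e-12)
  # nucleus displaced +0.1 in x: net membrane force towards +x, equal and
  # opposite to the net radial force on the nucleus (brute-force oracle)
  w2 <- w
  cl <- w2$cells[[1]]
  w2$pos[cl$nuc, 1] <- w2$pos[cl$nuc, 1] + 0.1
  fm <- cytoskeleton_forces(w2, 1L)
  brute <- t(vapply(seq_len(cl$n), function(i)
    voigt_force(w2$pos[cl$mem[i], ], w2$pos[cl$nuc[i], ],
                k = cl$k_rad[i], eta = cl$eta_rad[i], L0 = cl$L0_rad[i])$f_a,
    numeric(2)))
  expect_equal(fm, brute, tolerance = 1e-12)
  expect_gt(colSums(fm)[1], 0)
  fn_rad <- -fm
  expect_equal(colSums(fm), -colSums(fn_rad))
  # one radial element stretched by delta: only that node reacts, k*delta
  w3 <- w
  cl <- w3$cells[[1]]
  dirn <- w3$pos[cl$mem[5], ] - w3$pos[cl$nuc[5], ]
  dirn <- dirn / sqrt(sum(dirn^2))
  w3$pos[cl$mem[5], ] <- w3$pos[cl$mem[5], ] + 0.2 * dirn
  f3 <- cytoskeleton_forces(w3, 1L)
  expect_equal(sqrt(sum(f3[5, ]^2)), cl$k_rad[5] * 0.2, tolerance = 1e-9)
  expect_equal(max(abs(f3[-5, ])), 0, tolerance = 1e-12)
})

test_that("nucleus forces combine radial, chord and ring contributions", {
  w <- single_cell_world(n = 40)
  expect_equal(max(abs(nucleus_forces(w, 1L))), 0, tolerance = 1e-10)
  # uniform nuclear dilation: chords stretched, all forces point inward,
  # net zero by symmetry
  w2 <- w
  cl <- w2$cells[[1]]
  w2$pos[cl$nuc, ] <- w2$pos[cl$nuc, ] * 1.1
  # isolate the chord contribution: dilate a copy where only chords resist
  fn <- nucleus_forces(w2, 1L)
  expect_equal(colSums(fn), c(0, 0), tolerance = 1e-10)
  inward <- -w2$pos[cl$nuc, ] / sqrt(rowSums(w2$pos[cl$nuc, ]^2))
  expect_true(all(rowSums(fn * inward) > 0))
})

test_that("membrane ring forces cancel pairwise over the closed ring", {
  w <- single_cell_world(n = 40)
  expect_equal(max(abs(membrane_forces(w, 1L))), 0, tolerance = 1e-12)
  # one node displaced outward: restoring force on that node
  w2 <- w
  cl <- w2$cells[[1]]
  p <- w2$pos[cl$mem[3], ]
  w2$pos[cl$mem[3], ] <- p * 1.1
  f <- membrane_forces(w2, 1L)
  expect_lt(sum(f[3, ] * p), 0)  # pulls back towards the center
  expect_equal(colSums(f), c(0, 0), tolerance = 1e-12)
  # uniform dilation: all inward, equal magnitudes
  w3 <- w
  w3$pos[cl$mem, ] <- w3$pos[cl$mem, ] * 1.2
  f3 <- membrane_forces(w3, 1L)
  mags <- sqrt(rowSums(f3^2))
  expect_equal(max(mags) - min(mags), 0, tolerance = 1e-9)
  expect_true(all(rowSums(f3 * w3$pos[cl$mem, ]) < 0))
})

test_that("pressure load uses lumped supported lengths and closes to zero", {
  w <- single_cell_world(n = 40, P_in = 1, R = 1, r_n = 0.3)
  f <- pressure_forces(w, 1L, P_env = 0)
  # unit-radius regular 40-gon, dP = 1: per-node magnitude ~ 2*pi/40
  # (half the neighbor chord length, sin(2 pi/40) = 0.1564)
  expect_equal(sqrt(sum(f[1, ]^2)), sin(2 * pi / 40), tolerance = 1e-12)
  expect_equal(sqrt(sum(f[1, ]^2)), 2 * pi / 40, tolerance = 5e-3)
  expect_equal(colSums(f), c(0, 0), tolerance = 1e-12)
  # P_in = P_env: all zero
  expect_equal(max(abs(pressure_forces(w, 1L, P_env = 1))), 0)
  # irregular ring still closes exactly (chord vectors telescope)
  w2 <- single_cell_world(n = 23, P_in = 2)
  cl <- w2$cells[[1]]
  set.seed(3)
  w2$pos[cl$mem, ] <- w2$pos[cl$mem, ] * (1 + runif(23, -0.05, 0.05))
  f2 <- pressure_forces(w2, 1L, P_env = 0)
  expect_lt(max(abs(colSums(f2))), 1e-12)
})

test_that("total inner force of an isolated cell sums to zero", {
  # rest configuration, dP = 0: identically zero
  w <- single_cell_world(n = 40)
  f <- total_inner_force(w, 1L)
  expect_lt(max(abs(f$mem)), 1e-12)
  expect_lt(max(abs(f$nuc)), 1e-12)
  # randomly perturbed configuration: Newton's-third-law bookkeeping
  set.seed(11)
  w2 <- w
  w2$pos <- w2$pos + matrix(rnorm(nrow(w2$pos) * 2, 0, 0.1), ncol = 2)
  w2$vel <- matrix(rnorm(nrow(w2$pos) * 2, 0, 0.05), ncol = 2)
  f2 <- total_inner_force(w2, 1L)
  tot <- colSums(f2$mem) + colSums(f2$nuc)
  expect_lt(max(abs(tot)), 1e-9 * max(abs(rbind(f2$mem, f2$nuc))))
  # dP > 0 on the rest shape: purely radial outward forces, membrane only
  w3 <- single_cell_world(n = 40, P_in = 0.5)
  f3 <- total_inner_force(w3, 1L)
  cl <- w3$cells[[1]]
  outward <- w3$pos[cl$mem, ] / sqrt(rowSums(w3$pos[cl$mem, ]^2))
  expect_true(all(rowSums(f3$mem * outward) > 0))
  cross <- f3$mem[, 1] * outward[, 2] - f3$mem[, 2] * outward[, 1]
  expect_lt(max(abs(cross)), 1e-12)
  expect_lt(max(abs(f3$nuc)), 1e-12)
})

test_that("engine force accumulation equals the per-operation decomposition", {
  set.seed(5)
  w <- single_cell_world(n = 24, P_in = 0.3)
  w$pos <- w$pos + matrix(rnorm(nrow(w$pos) * 2, 0, 0.15), ncol = 2)
  w$vel <- matrix(rnorm(nrow(w$pos) * 2, 0, 0.1), ncol = 2)
  f_engine <- accumulate_forces(w)
  f_ops <- total_inner_force(w, 1L)
  cl <- w$cells[[1]]
  expect_equal(f_engine[cl$mem, ], f_ops$mem, tolerance = 1e-12)
  expect_equal(f_engine[cl$nuc, ], f_ops$nuc, tolerance = 1e-12)
})

test_that("a cell at rest geometry is a mechanical fixed point", {
  w <- single_cell_world(n = 40)
  p0 <- w$pos
  for (i in 1:1000) w <- integrate_step(w, 0.02)
  expect_lt(max(abs(w$pos - p0)), 1e-8)
})

test_that("single-element relaxation matches x0 exp(-k t/(D+eta)) within 1% RMS", {
  k <- 2; eta <- 1.5; D <- 0.5; x0 <- 1
  dt <- 0.005 * (D + eta) / k
  w <- toy_element_world(k, eta, D, L0 = 1, x0 = x0)
  ts <- seq_len(2000) * dt
  xs <- numeric(length(ts))
  for (i in seq_along(ts)) { w <- integrate_step(w, dt); xs[i] <- w$pos[2, 1] - 1 }
  ref <- x0 * exp(-k * ts / (D + eta))
  expect_lt(sqrt(mean((xs - ref)^2)) / x0, 0.01)
})
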