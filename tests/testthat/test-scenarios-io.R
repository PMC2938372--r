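test_that("scenario constructors build the stated initial conditions", {
  # single cell: 2n nodes, n elements in each of 4 categories
  w <- make_world(scenario_spec("single_cell", n = 40))
  expect_identical(n_nodes(w), 80L)
  elem <- viscocell:::world_elements(w)
  expect_identical(as.integer(table(elem$cat)[as.character(1:4)]),
                   rep(40L, 4))
  # monolayer starts from exactly two founder cells
  wm <- make_world(scenario_spec("monolayer"))
  expect_identical(n_cells(wm), 2L)
  # gap geometry: notch of width W = 2R present
  wg <- make_world(scenario_spec("ecm_gap", W_over_R = 2))
  R <- wg$cells[[1]]$R
  xs <- wg$pos[wg$ecm[[1]]$nodes, 1]
  ys <- wg$pos[wg$ecm[[1]]$nodes, 2]
  expect_true(any(abs(xs - R) < 1e-9 & abs(ys) < 1e-9))
  expect_true(any(abs(xs + R) < 1e-9 & abs(ys) < 1e-9))
  # crawling cell is labeled and motile
  wc <- make_world(scenario_spec("crawling_cell", n = 20))
  expect_true(wc$cells[[1]]$motile)
  expect_true(any(wc$label[wc$cells[[1]]$mem] == 1L))
  expect_true(any(wc$label[wc$cells[[1]]$mem] == 2L))
})

test_that("every named scenario constructs and survives a 100-step smoke run", {
  for (nm in list_scenarios()) {
    spec <- scenario_spec(nm, n = 12)
    w <- make_world(spec)
    expect_s3_class(w, "cell_world")
    sim <- run_scenario(w, n_steps = 100, dt = 0.05, seed = 1,
                        record_every = 0)
    expect_identical(sim$steps_run, 100L)
    expect_silent(validate_world(sim$world, check_simple = FALSE))
  }
})

test_that("frames round-trip the full world state", {
  w <- two_cell_world(gap = 0.5, n = 14)
  w <- build_ecm(w, "line", spacing = 3, length = 30, center = c(0, -12))
  w <- update_adhesions(w)
  # make the state rich: one mitotic cell with groups and axis
  w <- partition_cell(w, 1L)
  f <- tempfile(fileext = ".tsv")
  write_frame(w, f)
  w2 <- read_frame(f)
  expect_identical(n_nodes(w2), n_nodes(w))
  expect_equal(w2$pos, unname(w$pos), tolerance = 1e-15)
  expect_equal(w2$drag, w$drag, tolerance = 1e-15)
  expect_identical(w2$ring, w$ring)
  expect_identical(w2$owner, w$owner)
  expect_identical(length(w2$bonds$a), length(w$bonds$a))
  c1 <- w$cells[["1"]]; c2 <- w2$cells[["1"]]
  expect_equal(c2$L0_mem, c1$L0_mem, tolerance = 1e-15)
  expect_identical(c2$state, "mitotic")
  expect_equal(c2$mito$dir, c1$mito$dir, tolerance = 1e-15)
  expect_identical(c2$mito$grp, c1$mito$grp)
  expect_equal(c2$V_rest, c1$V_rest, tolerance = 1e-15)
  ch1 <- w$ecm[[1]]; ch2 <- w2$ecm[[1]]
  expect_equal(ch2$L0, ch1$L0, tolerance = 1e-15)
  expect_identical(ch2$closed, ch1$closed)
  # a frame read back can be advanced
  sim <- run_simulation(w2, engine_config(dt = 0.05, n_steps = 5,
                                          record_every = 0))
  expect_identical(sim$steps_run, 5L)
  # truncated file: loud parse error, not a silent partial load
  lines <- readLines(f)
  writeLines(lines[1:(length(lines) %/% 2)], f)
  expect_error(read_frame(f), "truncated|parse|missing")
  unlink(f)
})

test_that("the CLI lists scenarios, runs one, and rejects bad usage", {
  expect_output(code <- run_scenario_cli("--list-scenarios"),
                "monolayer")
  expect_identical(code, 0L)
  # unknown scenario: usage error, exit code 2
  suppressMessages(capture.output(
    code1 <- run_scenario_cli(c("--scenario", "nope", "--steps", "5",
                                "--out", tempdir()))))
  expect_identical(code1, 2L)
  # missing --out is a usage error
  expect_output(code2 <- run_scenario_cli(c("--scenario", "single_cell",
                                            "--steps", "5")), "usage")
  expect_identical(code2, 2L)
  # a real (tiny) run writes frames, metrics, events, manifest
  out <- file.path(tempdir(), "vc-cli-test")
  unlink(out, recursive = TRUE)
  code3 <- run_scenario_cli(c("--scenario", "single_cell", "--steps", "20",
                              "--seed", "3", "--out", out,
                              "--param", "n=12", "--frame-every", "10"))
  expect_identical(code3, 0L)
  expect_true(file.exists(file.path(out, "final.tsv")))
  expect_true(file.exists(file.path(out, "metrics.tsv")))
  expect_true(file.exists(file.path(out, "events.tsv")))
  expect_true(file.exists(file.path(out, "manifest.txt")))
  expect_true(length(list.files(file.path(out, "frames"))) >= 1)
  wf <- read_frame(file.path(out, "final.tsv"))
  expect_identical(n_cells(wf), 1L)
  unlink(out, recursive = TRUE)
})

test_that("gap regimes classify from structural geometry", {
  # synthetic final worlds around a notch at the origin
  gap <- list(xc = 0, y = 0, depth = 20)
  mk <- function(centers, R = 5) {
    w <- new_world()
    for (i in seq_len(nrow(centers)))
      w <- add_cell(w, centers[i, ], cell_params(n = 16, R = R, r_n = 2))
    w$config$gap <- gap
    w
  }
  # empty notch, cells only above the line: not lined
  w1 <- mk(rbind(c(-15, 6), c(-4, 6), c(7, 6)))
  expect_identical(gap_regime_classifier(w1, W = 8, R = 5), "not_lined")
  # a single cell wedged in the mouth, monolayer passing above
  w2 <- mk(rbind(c(-12, 6), c(0, -2), c(12, 6)))
  expect_identical(gap_regime_classifier(w2, W = 8, R = 5), "entry_blocked")
  # several cells inside a deep notch, floor uncovered: entrapped
  w3 <- mk(rbind(c(0, -2), c(0, -9), c(-10, 6), c(10, 6)))
  expect_identical(gap_regime_classifier(w3, W = 9, R = 5), "entrapped")
  # wide shallow notch fully covered: lined
  gap2 <- list(xc = 0, y = 0, depth = 8)
  w4 <- mk(rbind(c(-9, -4), c(-3, -4), c(3, -4), c(9, -4)))
  w4$config$gap <- gap2
  expect_identical(gap_regime_classifier(w4, W = 26, R = 5), "lined")
  # no cells at all
  w5 <- new_world(); w5$config$gap <- gap
  expect_identical(gap_regime_classifier(w5, W = 8, R = 5), "not_lined")
})

test_that("scenario runs honor seeds: different seeds, different histories", {
  spec <- scenario_spec("monolayer", n = 12, drag_mult = 1e-4,
                        target_cells = 4)
  a <- run_scenario(spec, n_steps = 1200, dt = 0.05, seed = 1, record_every = 0)
  b <- run_scenario(spec, n_steps = 1200, dt = 0.05, seed = 99, record_every = 0)
  expect_false(identical(a$events, b$events))
})
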