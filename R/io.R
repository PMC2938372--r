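# Plain-text frame I/O (versioned, delimiter-separated, diffable) and
# the command-line scenario runner.

FRAME_MAGIC <- "#viscocell-frame v1"

fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' Write a world snapshot to a plain-text frame
#'
#' The frame holds the node table (owner, ring, ring index, position,
#' velocity, drag, mass, label, mitotic group, fixed flag), the element
#' table (endpoints, category, k, eta, L0 -- including live adhesion
#' bonds), the cell state table (including mitosis axis and motility
#' block), and the ECM chain table, at full floating-point precision, so
#' `read_frame(write_frame(w))` round-trips the state.  Scenario hooks
#' (closures) and functional substrate fields are not serialized.
#'
#' @param world a `cell_world`.
#' @param file path or connection.
#' @return `file`, invisibly.
#' @export
write_frame <- function(world, file) {
  con <- if (inherits(file, "connection")) file else base::file(file, "w")
  if (!inherits(file, "connection")) on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl(FRAME_MAGIC)
  wl("#t\t", fmt(world$t))
  wl("#P_env\t", fmt(world$P_env))
  subst <- if (is.numeric(world$substrate)) fmt(world$substrate) else "NA"
  wl("#substrate\t", subst)
  r <- world$rule
  wl("#rule\t", paste(fmt(c(r$d_a, r$d_r, r$d_rep, r$k_rep)), collapse = "\t"),
     "\t", as.integer(r$one_bond_per_pair))
  wtab <- function(tag, df) {
    wl("[", tag, "]")
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  N <- n_nodes(world)
  wtab("nodes", data.frame(
    id = seq_len(N), owner = world$owner, ring = world$ring, idx = world$idx,
    x = fmt(world$pos[, 1]), y = fmt(world$pos[, 2]),
    vx = fmt(world$vel[, 1]), vy = fmt(world$vel[, 2]),
    drag = fmt(world$drag), mass = fmt(world$mass),
    label = world$label, group = world$group,
    fixed = as.integer(world$fixed)))
  elem <- world_elements(world)
  ea <- c(elem$a, world$bonds$a); eb <- c(elem$b, world$bonds$b)
  wtab("elements", data.frame(
    a = ea, b = eb,
    cat = c(elem$cat, rep(CAT_ADHESION, length(world$bonds$a))),
    k = fmt(c(elem$k, world$bonds$k)),
    eta = fmt(c(elem$eta, world$bonds$eta)),
    L0 = fmt(c(elem$L0, world$bonds$L0))))
  if (length(world$cells)) {
    rows <- lapply(world$cells, function(cl) {
      mito <- cl$mito
      mo <- cl$motility
      pd <- setNames(as.list(unlist(cl$params)), paste0("p_", names(unlist(cl$params))))
      c(list(id = cl$id, n = cl$n, n0 = cl$n0, R = cl$R, r_n = cl$r_n,
             scale = fmt(cl$scale), V_rest = fmt(cl$V_rest),
             V_rest0 = fmt(cl$V_rest0), c_s = cl$c_s, c_g = cl$c_g,
             P_in = fmt(cl$P_in), state = cl$state, gstate = cl$gstate,
             polarized = as.integer(cl$polarized),
             motile = as.integer(cl$motile),
             growth_suppressed = as.integer(isTRUE(cl$growth_suppressed)),
             t_next_growth = fmt(cl$t_next_growth),
             last_contact_t = fmt(cl$last_contact_t %||% NA_real_),
             adh_k = fmt(cl$adh$k), adh_eta = fmt(cl$adh$eta),
             adh_L0 = fmt(cl$adh$L0),
             mito_dirx = fmt(if (is.null(mito)) NA_real_ else mito$dir[1]),
             mito_diry = fmt(if (is.null(mito)) NA_real_ else mito$dir[2]),
             mito_ux = fmt(if (is.null(mito)) NA_real_ else mito$u[1]),
             mito_uy = fmt(if (is.null(mito)) NA_real_ else mito$u[2]),
             mito_ax = fmt(if (is.null(mito)) NA_real_ else mito$anchor[1]),
             mito_ay = fmt(if (is.null(mito)) NA_real_ else mito$anchor[2]),
             mot = if (is.null(mo)) "NA" else
               paste(fmt(c(mo$omega, mo$dir, mo$L0a0, mo$L0at, mo$L0p0,
                           mo$L0pt, mo$Da0, mo$Dat, mo$Dp0, mo$Dpt)),
                     collapse = ",")),
        pd)
    })
    wtab("cells", do.call(rbind, lapply(rows, function(x)
      as.data.frame(x, stringsAsFactors = FALSE))))
  }
  if (length(world$ecm)) {
    wtab("ecm", do.call(rbind, lapply(world$ecm, function(ch)
      data.frame(id = ch$id, closed = as.integer(ch$closed),
                 rigid = as.integer(ch$rigid),
                 adh_k = fmt(ch$adh$k), adh_eta = fmt(ch$adh$eta),
                 adh_L0 = fmt(ch$adh$L0)))))
  }
  wl("[end]")
  invisible(file)
}

read_section <- function(lines, tag) {
  start <- which(lines == paste0("[", tag, "]"))
  if (!length(start)) return(NULL)
  start <- start[1] + 1L
  ends <- which(startsWith(lines, "["))
  stop_at <- min(ends[ends > start - 1L & ends != start - 1L] - 1L)
  block <- lines[start:stop_at]
  if (!length(block)) stop("frame parse error: empty section [", tag,
                           "] (truncated file?)")
  read.table(text = block, header = TRUE, sep = "\t",
             stringsAsFactors = FALSE)
}

#' Read a world back from a frame file
#'
#' @param file path to a frame written by [write_frame()].
#' @return a `cell_world`.
#' @export
read_frame <- function(file) {
  lines <- readLines(file)
  if (!length(lines) || lines[1] != FRAME_MAGIC)
    stop("not a viscocell frame (bad magic line): ", file)
  if (!any(lines == "[end]"))
    stop("frame parse error: missing [end] marker (truncated file)")
  hdr <- function(tag) {
    ln <- lines[startsWith(lines, paste0("#", tag, "\t"))]
    if (!length(ln)) stop("frame parse error: missing header #", tag)
    strsplit(ln[1], "\t")[[1]][-1]
  }
  rl <- as.numeric(hdr("rule"))
  world <- new_world(P_env = as.numeric(hdr("P_env")),
                     rule = adhesion_rule(rl[1], rl[2], rl[3], rl[4], rl[5] > 0))
  sub <- hdr("substrate")
  world$substrate <- if (sub == "NA") NULL else as.numeric(sub)
  world$t <- as.numeric(hdr("t"))
  nd <- read_section(lines, "nodes")
  world$pos <- cbind(nd$x, nd$y)
  world$vel <- cbind(nd$vx, nd$vy)
  world$drag <- nd$drag; world$mass <- nd$mass
  world$ring <- nd$ring; world$owner <- nd$owner; world$idx <- nd$idx
  world$label <- nd$label; world$group <- nd$group
  world$fixed <- nd$fixed > 0
  el <- read_section(lines, "elements")
  ct <- read_section(lines, "cells")
  if (!is.null(ct)) {
    for (r in seq_len(nrow(ct))) {
      cr <- ct[r, ]
      id <- cr$id
      mem <- which(world$owner == id & world$ring == RING_MEMBRANE)
      mem <- mem[order(world$idx[mem])]
      nuc <- which(world$owner == id & world$ring == RING_NUCLEUS)
      nuc <- nuc[order(world$idx[nuc])]
      pn <- startsWith(names(ct), "p_")
      params <- as.list(cr[pn])
      names(params) <- sub("^p_", "", names(params))
      params$n <- as.integer(params$n)
      ecat <- function(cat, idxv) {
        sel <- el$cat == cat & el$a %in% idxv
        sub <- el[sel, ]
        sub[order(world$idx[sub$a]), ]
      }
      em <- ecat(CAT_MEMBRANE, mem)
      en <- ecat(CAT_NUC_MEMBRANE, nuc)
      er <- ecat(CAT_RADIAL, mem)
      ec <- ecat(CAT_CHORD, nuc)
      grp <- world$group[mem]
      mito <- NULL
      if (!is.na(cr$mito_dirx))
        mito <- list(dir = c(cr$mito_dirx, cr$mito_diry),
                     anchor = c(cr$mito_ax, cr$mito_ay),
                     u = c(cr$mito_ux, cr$mito_uy), grp = grp,
                     F_div_n = params$F_div_n, F_div_m = params$F_div_m,
                     L_div = params$L_div)
      mo <- NULL
      if (!identical(cr$mot, "NA") && !is.na(cr$mot)) {
        mv <- as.numeric(strsplit(cr$mot, ",")[[1]])
        mo <- list(omega = mv[1], dir = mv[2:3], L0a0 = mv[4], L0at = mv[5],
                   L0p0 = mv[6], L0pt = mv[7], Da0 = mv[8], Dat = mv[9],
                   Dp0 = mv[10], Dpt = mv[11])
      }
      cell <- list(
        id = id, mem = mem, nuc = nuc, n = cr$n, n0 = cr$n0,
        R = cr$R, r_n = cr$r_n, scale = cr$scale,
        k_mem = em$k, eta_mem = em$eta, L0_mem = em$L0,
        k_nucmem = en$k, eta_nucmem = en$eta, L0_nucmem = en$L0,
        k_rad = er$k, eta_rad = er$eta, L0_rad = er$L0,
        k_chord = ec$k, eta_chord = ec$eta, L0_chord = ec$L0,
        V_rest = cr$V_rest, V_rest0 = cr$V_rest0,
        c_s = cr$c_s, c_g = cr$c_g, P_in = cr$P_in,
        adh = list(k = cr$adh_k, eta = cr$adh_eta, L0 = cr$adh_L0),
        state = cr$state, gstate = cr$gstate,
        polarized = cr$polarized > 0, motile = cr$motile > 0,
        motility = mo, mito = mito, params = params,
        t_next_growth = cr$t_next_growth,
        growth_suppressed = cr$growth_suppressed > 0)
      if (!is.na(cr$last_contact_t)) cell$last_contact_t <- cr$last_contact_t
      world$cells[[as.character(id)]] <- cell
    }
  }
  et <- read_section(lines, "ecm")
  if (!is.null(et)) {
    for (r in seq_len(nrow(et))) {
      id <- et$id[r]
      nodes <- which(world$owner == id & world$ring == RING_ECM)
      nodes <- nodes[order(world$idx[nodes])]
      sel <- el$cat == CAT_ECM_CHAIN & el$a %in% nodes
      ee <- el[sel, ]
      ee <- ee[order(world$idx[ee$a]), ]
      world$ecm[[as.character(id)]] <- list(
        id = id, nodes = nodes, closed = et$closed[r] > 0,
        rigid = et$rigid[r] > 0, k = ee$k, eta = ee$eta, L0 = ee$L0,
        adh = list(k = et$adh_k[r], eta = et$adh_eta[r], L0 = et$adh_L0[r]))
    }
  }
  ad <- el[el$cat == CAT_ADHESION, ]
  world$bonds <- list(a = ad$a, b = ad$b, k = ad$k, eta = ad$eta, L0 = ad$L0)
  world$next_cell_id <- if (length(world$cells))
    max(vapply(world$cells, `[[`, integer(1), "id")) + 1L else 1L
  world$next_ecm_id <- if (length(world$ecm))
    min(vapply(world$ecm, `[[`, integer(1), "id")) - 1L else -1L
  world$cache <- NULL
  world
}

#' Command-line scenario runner
#'
#' Usage:
#' \preformatted{
#'   run-scenario.R --scenario NAME --steps N --dt X --seed S --out DIR
#'                  [--param key=value]... [--frame-every K]
#'   run-scenario.R --list-scenarios
#' }
#' Writes frames at the requested cadence, the metrics time series and
#' the event log under `--out`.  Returns (invisibly) the process exit
#' code: 0 on success, 1 on runtime failure (e.g. instability abort),
#' 2 on usage errors.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
run_scenario_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: run-scenario.R --scenario NAME --steps N --out DIR",
        "[--dt X] [--seed S] [--frame-every K] [--param key=value]...\n",
        "       run-scenario.R --list-scenarios\n")
  }
  if ("--list-scenarios" %in% args) {
    cat(list_scenarios(), sep = "\n")
    return(invisible(0L))
  }
  opt <- list(dt = 0.05, seed = 1L, frame_every = 500L, params = list())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    val <- function() { if (i + 1L > length(args)) stop("missing value for ", a); args[i + 1L] }
    ok <- TRUE
    switch(a,
      "--scenario" = { opt$scenario <- val(); i <- i + 2L },
      "--steps" = { opt$steps <- as.integer(val()); i <- i + 2L },
      "--dt" = { opt$dt <- as.numeric(val()); i <- i + 2L },
      "--seed" = { opt$seed <- as.integer(val()); i <- i + 2L },
      "--out" = { opt$out <- val(); i <- i + 2L },
      "--frame-every" = { opt$frame_every <- as.integer(val()); i <- i + 2L },
      "--param" = {
        kv <- strsplit(val(), "=", fixed = TRUE)[[1]]
        if (length(kv) != 2L) { ok <- FALSE } else {
          v <- suppressWarnings(as.numeric(kv[2]))
          opt$params[[kv[1]]] <- if (is.na(v)) kv[2] else v
        }
        i <- i + 2L
      },
      { ok <- FALSE; i <- i + 1L })
    if (!ok) { message("bad argument: ", a); usage(); return(invisible(2L)) }
  }
  if (is.null(opt$scenario) || is.null(opt$steps) || is.null(opt$out)) {
    usage(); return(invisible(2L))
  }
  if (!opt$scenario %in% list_scenarios()) {
    message("unknown scenario: ", opt$scenario); usage(); return(invisible(2L))
  }
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
  spec <- do.call(scenario_spec, c(list(name = opt$scenario), opt$params))
  world <- make_world(spec)
  frames_dir <- file.path(opt$out, "frames")
  dir.create(frames_dir, showWarnings = FALSE)
  fe <- opt$frame_every
  frame_hook <- function(w, step) {
    if (fe > 0L && step %% fe == 0L)
      write_frame(w, file.path(frames_dir, sprintf("frame_%06d.tsv", step)))
    w
  }
  cfg <- engine_config(dt = opt$dt, n_steps = opt$steps, seed = opt$seed,
                       record_every = max(1L, opt$steps %/% 50L),
                       record_metrics = TRUE,
                       stop_when = world$config$stop_when,
                       hooks = c(world$config$hooks, list(frame_hook)))
  sim <- tryCatch(run_simulation(world, cfg), error = function(e) e)
  if (inherits(sim, "error")) {
    message("run failed: ", conditionMessage(sim))
    return(invisible(1L))
  }
  write_frame(sim$world, file.path(opt$out, "final.tsv"))
  write.table(sim$metrics, file.path(opt$out, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$events, file.path(opt$out, "events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- c(paste0("package: viscocell ",
                       as.character(utils::packageVersion("viscocell"))),
                paste0("scenario: ", opt$scenario),
                paste0("steps: ", opt$steps), paste0("dt: ", opt$dt),
                paste0("seed: ", opt$seed),
                paste0("params: ", paste(names(opt$params),
                                         unlist(opt$params),
                                         sep = "=", collapse = " ")))
  writeLines(manifest, file.path(opt$out, "manifest.txt"))
  invisible(0L)
}
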