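# recorder machinery driven directly, without a full simulation

make_ctx <- function(M, gids, dir, dt = 0.1, nsteps = 10) {
  out <- file.path(dir, "out"); tmp <- file.path(dir, "tmp")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  list(dt = dt, nsteps = nsteps, partition = make_partition(gids, M),
       gids = gids, out_dir = out, tmp_dir = tmp)
}

test_that("buffers flush every N steps (pattern 4, 4, 2 for 10 steps, N = 4)", {
  d <- tempfile("rep")
  ctx <- make_ctx(1, 0:2, d)
  rec <- make_report(list(variable = "v_soma", file = "v.h5", node_ids = "all",
                          buffer_steps = 4), ctx)
  rec$begin()
  for (s in 1:10)
    rec$step(list(t = s * 0.1, v_soma = rep(s, 3)), s)
  rec$end()
  expect_equal(rec$flush_log, c(4L, 4L, 2L))
  v <- read_h5(file.path(ctx$out_dir, "v.h5"), "report/data")
  expect_equal(dim(v), c(10L, 3L))
  expect_equal(v[, 1], as.numeric(1:10))
})

test_that("a mid-run reader sees exactly the flushed prefix", {
  d <- tempfile("rep")
  ctx <- make_ctx(1, 0:1, d)
  rec <- make_report(list(variable = "v_soma", file = "v.h5", node_ids = "all",
                          buffer_steps = 2), ctx)
  rec$begin()
  for (s in 1:5) rec$step(list(t = s * 0.1, v_soma = c(s, -s)), s)
  # 5 steps with N = 2: flushes after steps 2 and 4; step 5 still buffered
  mid <- read_h5(file.path(ctx$tmp_dir, "v_soma_rank0.h5"), "data")
  expect_equal(dim(mid), c(4L, 2L))
  expect_equal(mid[, 1], as.numeric(1:4))
  rec$end()
  fin <- read_h5(file.path(ctx$out_dir, "v.h5"), "report/data")
  expect_equal(nrow(fin), 5L)
})

test_that("rank spike files merge sorted by (time, gid)", {
  d <- tempfile("rep")
  ctx <- make_ctx(2, 0:9, d)
  rec <- make_report(list(variable = "spikes", file = "spikes.h5",
                          buffer_steps = 1000), ctx)
  rec$begin()
  # gid 4 (rank 0) spikes at 1.0 ms; gid 1 (rank 1) spikes at 0.5 ms
  rec$step(list(t = 0.5, spike_gids = 1L), 1)
  rec$step(list(t = 1.0, spike_gids = 4L), 2)
  rec$end()
  f <- file.path(ctx$out_dir, "spikes.h5")
  expect_equal(as.vector(read_h5(f, "spikes/timestamps")), c(0.5, 1.0))
  expect_equal(as.vector(read_h5(f, "spikes/gids")), c(1L, 4L))
  # temp files are deleted on success
  expect_length(list.files(ctx$tmp_dir), 0)
})

test_that("simultaneous spikes are all kept, never deduplicated", {
  d <- tempfile("rep")
  ctx <- make_ctx(3, 0:5, d)
  rec <- make_report(list(variable = "spikes", file = "s.h5",
                          buffer_steps = 1), ctx)
  rec$begin()
  rec$step(list(t = 0.1, spike_gids = c(0L, 1L, 2L, 5L)), 1)
  rec$step(list(t = 0.2, spike_gids = c(1L, 1L)), 2)  # burst in one step
  rec$end()
  f <- file.path(ctx$out_dir, "s.h5")
  expect_equal(as.vector(read_h5(f, "spikes/gids")),
               c(0L, 1L, 2L, 5L, 1L, 1L))
})

test_that("a missing rank temp file aborts the merge", {
  d <- tempfile("rep")
  ctx <- make_ctx(2, 0:3, d)
  rec <- make_report(list(variable = "spikes", file = "s.h5",
                          buffer_steps = 1000), ctx)
  rec$begin()
  rec$step(list(t = 0.1, spike_gids = 0L), 1)
  for (w in rec$writers) lfpnet:::.h5_stream_close(w)
  file.remove(file.path(ctx$tmp_dir, "spikes_rank1.h5"))
  rec$writers <- list()       # already closed
  rec$steps_in_buf <- 0L      # suppress the final flush
  expect_error(rec$end(), "missing rank temp file.*rank1")
})

test_that("extracellular merge sums per-rank contributions elementwise", {
  d <- tempfile("rep")
  el <- file.path(d, "el.csv")
  dir.create(d)
  linear_electrode_layout(el, n_sites = 3)
  ctx <- make_ctx(2, 0:3, d, nsteps = 4)
  rec <- make_report(list(variable = "extracellular", file = "lfp.h5",
                          electrode_file = el, buffer_steps = 2, sigma = 0.3),
                     ctx)
  rec$begin()
  for (s in 1:4) {
    phi <- rbind(rep(s, 3), rep(10 * s, 3))  # rank 0 and rank 1 partials
    rec$step(list(t = s * 0.1, phi_by_rank = phi), s)
  }
  rec$end()
  out <- read_h5(file.path(ctx$out_dir, "lfp.h5"), "report/data")
  expect_equal(out, matrix(11 * (1:4), 4, 3))
})

test_that("configs are validated with defaults and unknown-key rejection", {
  d <- tempfile("cfg"); dir.create(d)
  write_component_files(file.path(d, "components"))
  net <- create_network("v1"); add_nodes(net, 1, pop_name = "a",
                                         model_type = "intfire",
                                         model_template = "lif",
                                         dynamics_params = "lif_exc.json")
  save_network(net, file.path(d, "network"))
  base <- list(
    run = list(tstop = 10),
    components = list(morphologies_dir = "components/morphologies",
                      dynamics_params_dir = "components/dynamics_params"),
    networks = list(list(name = "v1", dir = "network")),
    output = list(dir = "out"))
  write_cfg <- function(cfg) {
    f <- file.path(d, "c.json")
    jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
    f
  }
  cfg <- parse_config(write_cfg(base))
  expect_equal(cfg$run$dt, 0.1)     # documented defaults
  expect_equal(cfg$run$nranks, 1)
  expect_equal(cfg$run$seed, 0)

  bad <- base; bad$run$dtt <- 0.2   # typo -> caught
  expect_error(parse_config(write_cfg(bad)), "unknown key.*dtt")
  bad2 <- base; bad2$run$tstop <- NULL
  expect_error(parse_config(write_cfg(bad2)), "tstop")
  bad3 <- base; bad3$networks[[1]]$dir <- "no_such_dir"
  expect_error(parse_config(write_cfg(bad3)), "does not exist")
  bad4 <- base
  bad4$reports <- list(list(variable = "calcium", file = "c.h5"))
  expect_error(parse_config(write_cfg(bad4)), "variable")
})

test_that("the CLI runs, validates, and fails loudly", {
  d <- tempfile("cli")
  cfgp <- single_lif_fixture(d, syn_weight = 0.1)

  expect_equal(suppressMessages(cli_main(c("run", cfgp))), 0L)
  expect_true(file.exists(file.path(d, "out", "v.h5")))
  v1 <- read_h5(file.path(d, "out", "v.h5"), "report/data")

  # rerun with the same config and seeds: identical outputs
  expect_equal(suppressMessages(cli_main(c("run", cfgp))), 0L)
  expect_identical(read_h5(file.path(d, "out", "v.h5"), "report/data"), v1)

  expect_equal(suppressMessages(cli_main(c("validate", cfgp))), 0L)
  expect_equal(suppressMessages(cli_main(character(0))), 2L)
  expect_equal(suppressMessages(cli_main(c("run"))), 1L)
  expect_equal(suppressMessages(cli_main(c("run", "no_such_config.json"))), 1L)

  # build subcommand drives the fixture registry
  spec <- file.path(d, "spec.json")
  jsonlite::write_json(list(generator = "layer4_composition",
                            params = list(scale = 0.002, seed = 1)),
                       spec, auto_unbox = TRUE, digits = NA)
  bd <- file.path(d, "built")
  expect_equal(suppressMessages(cli_main(c("build", spec, "--output-dir", bd))), 0L)
  expect_true(file.exists(file.path(bd, "l4_nodes.h5")))

  # the installed exec script exists and is a thin wrapper
  script <- system.file("exec", "lfpnet", package = "lfpnet")
  if (!nzchar(script)) script <- file.path(find.package("lfpnet"), "exec", "lfpnet")
  expect_true(file.exists(script))
})
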