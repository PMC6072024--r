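# JSON run configuration.
#
# Unknown keys are rejected at every level: silent typos in a config are the
# dominant user error, and a misspelled optional key would otherwise quietly
# fall back to its default.

.CONFIG_KEYS <- list(
  top = c("run", "components", "networks", "inputs", "reports", "output"),
  run = c("dt", "tstop", "seed", "nranks", "max_seg_len"),
  components = c("morphologies_dir", "dynamics_params_dir"),
  network = c("name", "dir", "external"),
  input = c("network", "spikes_file"),
  report = c("variable", "file", "node_ids", "buffer_steps", "electrode_file",
             "sigma"),
  output = c("dir"))

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")))
  invisible(TRUE)
}

.resolve_path <- function(p, base) {
  if (is.null(p)) return(NULL)
  if (grepl("^(/|~)", p)) p else file.path(base, p)
}

#' Parse and validate a run configuration
#'
#' Reads the JSON configuration (run parameters, component directories,
#' network file sets, external inputs, reports, output directory), applies
#' documented defaults (`dt = 0.1` ms, `buffer_steps = 1000`, `nranks = 1`,
#' `max_seg_len = 20` um, `seed = 0`, `sigma = 0.3` S/m) and verifies that
#' every referenced path exists.  Relative paths are resolved against the
#' config file's directory.
#'
#' @param path path to the JSON config.
#' @return validated config list of class `lfpnet_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  base <- dirname(normalizePath(path))
  .check_keys(cfg, .CONFIG_KEYS$top, "config")
  if (is.null(cfg$run)) stop("config is missing mandatory section: run")
  .check_keys(cfg$run, .CONFIG_KEYS$run, "run")
  if (is.null(cfg$run$tstop)) stop("config is missing mandatory key: run.tstop")
  run <- list(dt = cfg$run$dt %||% 0.1, tstop = cfg$run$tstop,
              seed = cfg$run$seed %||% 0, nranks = cfg$run$nranks %||% 1,
              max_seg_len = cfg$run$max_seg_len %||% 20)
  if (run$dt <= 0 || run$tstop <= 0) stop("run.dt and run.tstop must be > 0")

  comp <- cfg$components %||% list()
  .check_keys(comp, .CONFIG_KEYS$components, "components")
  comp$morphologies_dir <- .resolve_path(comp$morphologies_dir, base)
  comp$dynamics_params_dir <- .resolve_path(comp$dynamics_params_dir, base)
  for (d in c(comp$morphologies_dir, comp$dynamics_params_dir))
    if (!dir.exists(d)) stop("components directory does not exist: ", d)

  if (is.null(cfg$networks) || !length(cfg$networks))
    stop("config is missing mandatory section: networks")
  networks <- lapply(cfg$networks, function(nw) {
    .check_keys(nw, .CONFIG_KEYS$network, "networks[]")
    if (is.null(nw$name) || is.null(nw$dir))
      stop("each networks[] entry needs `name` and `dir`")
    nw$dir <- .resolve_path(nw$dir, base)
    nw$external <- isTRUE(nw$external)
    fs <- network_fileset(nw$dir, nw$name)
    for (f in c(fs$nodes_file, fs$node_types_file, fs$edges_file,
                fs$edge_types_file))
      if (!file.exists(f)) stop("network file does not exist: ", f)
    nw$fileset <- fs
    nw
  })
  if (sum(!vapply(networks, `[[`, logical(1), "external")) != 1)
    stop("exactly one network must be non-external (the simulated network)")

  inputs <- lapply(cfg$inputs %||% list(), function(inp) {
    .check_keys(inp, .CONFIG_KEYS$input, "inputs[]")
    if (is.null(inp$network) || is.null(inp$spikes_file))
      stop("each inputs[] entry needs `network` and `spikes_file`")
    inp$spikes_file <- .resolve_path(inp$spikes_file, base)
    if (!file.exists(inp$spikes_file))
      stop("spikes file does not exist: ", inp$spikes_file)
    inp
  })

  reports <- lapply(cfg$reports %||% list(), function(rp) {
    .check_keys(rp, .CONFIG_KEYS$report, "reports[]")
    v <- rp$variable
    if (is.null(v) || !v %in% .report_variables())
      stop("reports[].variable must be one of: ",
           paste(.report_variables(), collapse = ", "))
    if (is.null(rp$file)) stop("reports[] entry needs `file`")
    rp$buffer_steps <- rp$buffer_steps %||% 1000
    if (rp$buffer_steps < 1) stop("buffer_steps must be >= 1")
    rp$node_ids <- rp$node_ids %||% "all"
    if (v == "extracellular") {
      if (is.null(rp$electrode_file))
        stop("extracellular report needs `electrode_file`")
      rp$electrode_file <- .resolve_path(rp$electrode_file, base)
      if (!file.exists(rp$electrode_file))
        stop("electrode file does not exist: ", rp$electrode_file)
      rp$sigma <- rp$sigma %||% 0.3
      if (rp$sigma <= 0) stop("sigma must be > 0")
    }
    rp
  })

  out <- cfg$output %||% list()
  .check_keys(out, .CONFIG_KEYS$output, "output")
  if (is.null(out$dir)) stop("config is missing mandatory key: output.dir")
  out$dir <- .resolve_path(out$dir, base)

  res <- list(run = run, components = comp, networks = networks,
              inputs = inputs, reports = reports, output = out)
  class(res) <- "lfpnet_config"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
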