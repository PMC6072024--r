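# Shared fixtures built in code at test time.

# write an SWC file from inline text
write_swc <- function(text) {
  f <- tempfile(fileext = ".swc")
  writeLines(text, f)
  f
}

# soma (r = 10 um) plus one straight 100 um basal dendrite sampled every 20 um
simple_swc <- function() write_swc(c(
  "# soma + straight dendrite",
  "1 1 0 0 0 10 -1",
  "2 3 0 20 0 1 1",
  "3 3 0 40 0 1 2",
  "4 3 0 60 0 1 3",
  "5 3 0 80 0 1 4",
  "6 3 0 100 0 1 5"))

# one-point soma only
soma_swc <- function(radius = 10) write_swc(c(
  sprintf("1 1 0 0 0 %g -1", radius)))

# a tiny single-LIF-cell simulation driven by one external spike; returns the
# config path.  `edit` can rewrite files before the config is parsed.
single_lif_fixture <- function(dir, syn_weight = 0.1, spike_times = 20,
                               tstop = 60, nsyns = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_component_files(file.path(dir, "components"))
  sim <- create_network("v1")
  add_nodes(sim, 1, pop_name = "cell", model_type = "intfire",
            model_template = "lif", dynamics_params = "lif_exc.json")
  ext <- create_network("ext")
  add_nodes(ext, 1, pop_name = "src", model_type = "virtual")
  force(nsyns)
  add_edges(sim, NULL, NULL, function(source, target) nsyns,
            syn_weight = syn_weight, delay = 1,
            model_template = "current_exp", dynamics_params = "ExtToInh.json",
            source_network = ext)
  build_edges(sim, 0)
  nd <- file.path(dir, "network")
  save_network(sim, nd); save_network(ext, nd)
  write_spike_file(file.path(dir, "spk.h5"),
                   rep(0L, length(spike_times)), spike_times)
  cfg <- list(
    run = list(dt = 0.1, tstop = tstop, seed = 0),
    components = list(morphologies_dir = "components/morphologies",
                      dynamics_params_dir = "components/dynamics_params"),
    networks = list(list(name = "v1", dir = "network"),
                    list(name = "ext", dir = "network", external = TRUE)),
    inputs = list(list(network = "ext", spikes_file = "spk.h5")),
    reports = list(list(variable = "v_soma", file = "v.h5")),
    output = list(dir = "out"))
  cp <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cp, auto_unbox = TRUE, digits = NA)
  cp
}

read_h5 <- function(path, name) {
  suppressWarnings(rhdf5::h5read(path, name))
}

file_md5 <- function(path) unname(tools::md5sum(path))

line_point_distance <- function(a, b, site) {
  u <- (b - a) / sqrt(sum((b - a)^2))
  dx <- site - a
  t <- sum(dx * u)
  sqrt(max(sum(dx^2) - t^2, 0))
}

# numerical quadrature oracle: potential of uniform-current line a -> b at
# `site`, integrating point sources along the segment
quadrature_line_resistance <- function(sigma, a, b, site) {
  stats::integrate(function(s) {
    p <- outer(1 - s, a) + outer(s, b)
    1 / (4 * pi * sigma * sqrt(rowSums(sweep(p, 2, site)^2)))
  }, 0, 1, rel.tol = 1e-12)$value
}
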