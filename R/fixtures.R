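# Synthetic fixture generators: morphologies, spike trains, example network
# compositions, electrode layouts and ready-to-run configurations.  All
# generators are deterministic under a fixed seed and emit the same standard
# files the main modules consume.

#' Write a ball-and-stick SWC morphology
#'
#' One somatic sample at the origin plus a straight dendrite along +y with
#' `n_samples` evenly spaced samples, so the dendritic section (which starts
#' at the soma attachment) has total length exactly `dend_length`.
#'
#' @param path output SWC path.
#' @param soma_radius soma radius, um.
#' @param dend_length total dendritic length, um.
#' @param n_samples number of dendritic samples (>= 1).
#' @param dend_radius dendrite radius, um.
#' @return the path, invisibly.
#' @export
ball_and_stick_swc <- function(path, soma_radius = 10, dend_length = 500,
                               n_samples = 50, dend_radius = 1) {
  stopifnot(soma_radius > 0, dend_length > 0, n_samples >= 1, dend_radius > 0)
  y <- seq_len(n_samples) * dend_length / n_samples
  lines <- c("# ball-and-stick synthetic morphology",
             sprintf("1 1 0.000000 0.000000 0.000000 %.6f -1", soma_radius),
             sprintf("%d 3 0.000000 %.6f 0.000000 %.6f %d",
                     seq_len(n_samples) + 1L, y, dend_radius,
                     c(1L, seq_len(n_samples - 1L) + 1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Fixed-probability connection rule
#'
#' Connects every pair independently with probability `p`; connected pairs
#' draw a uniform integer synapse count in `nsyns_range`.  Distance-blind
#' companion to [distance_tapered_probability()].
#'
#' @inheritParams distance_tapered_probability
#' @param p connection probability in [0, 1].
#' @return integer synapse counts.
#' @export
fixed_probability <- local({
  f <- function(source, target, p, nsyns_range = c(1, 1), stream) {
    if (p < 0 || p > 1) stop("p must be in [0, 1]")
    lo <- nsyns_range[1]; hi <- nsyns_range[2]
    connected <- stream(0) < p
    n <- as.integer(lo + floor(stream(1) * (hi - lo + 1)))
    ifelse(connected, n, 0L)
  }
  attr(f, "vectorized") <- TRUE
  f
})

# positions uniform in a disc (x, z), fixed y; counter-based per node
.disc_positions <- function(n, radius, y, seed, salt) {
  u1 <- rng_uniform(seed, salt, seq_len(n) - 1, 0, 0)
  u2 <- rng_uniform(seed, salt, seq_len(n) - 1, 0, 1)
  r <- radius * sqrt(u1); th <- 2 * pi * u2
  cbind(r * cos(th), rep(y, n), r * sin(th))
}

# positions uniform in a cylinder or cylindrical annulus
.cylinder_positions <- function(n, r_inner, r_outer, height, seed, salt) {
  u1 <- rng_uniform(seed, salt, seq_len(n) - 1, 0, 0)
  u2 <- rng_uniform(seed, salt, seq_len(n) - 1, 0, 1)
  u3 <- rng_uniform(seed, salt, seq_len(n) - 1, 0, 2)
  r <- sqrt(r_inner^2 + u1 * (r_outer^2 - r_inner^2))
  th <- 2 * pi * u2
  cbind(r * cos(th), height * (u3 - 0.5), r * sin(th))
}

#' Build the two-population example network
#'
#' A recurrently connected model with one excitatory population of
#' biophysical ball-and-stick cells and one inhibitory population of LIF
#' point cells, somata placed uniformly in a disc, and all four connection
#' classes (E-E, E-I, I-E, I-I) wired with the distance-tapered rule.
#'
#' @param n_exc,n_inh population sizes (both >= 1).
#' @param seed build seed.
#' @param radius disc radius, um.
#' @return a built `lfpnet_network` named "v1" whose component file names
#'   reference the files written by [two_pop_fixture()].
#' @export
two_pop_network <- function(n_exc = 20, n_inh = 5, seed = 0, radius = 100) {
  stopifnot(n_exc >= 1, n_inh >= 1)
  net <- create_network("v1")
  add_nodes(net, n_exc, pop_name = "exc", ei = "e",
            model_type = "biophysical", model_template = "passive_cable",
            morphology_file = "ball_stick.swc", dynamics_params = "pas_exc.json",
            per_node = list(positions = .disc_positions(n_exc, radius, 0, seed, 1),
                            rotation_angle_yaxis =
                              2 * pi * rng_uniform(seed, 3, seq_len(n_exc) - 1)))
  add_nodes(net, n_inh, pop_name = "inh", ei = "i",
            model_type = "intfire", model_template = "lif",
            dynamics_params = "lif_inh.json",
            per_node = list(positions = .disc_positions(n_inh, radius, 0, seed, 2)))

  rule <- distance_tapered_probability
  add_edges(net, list(pop_name = "exc"), list(pop_name = "exc"), rule,
            list(p0 = 0.3, sigma = 120, nsyns_range = c(1, 3)),
            syn_weight = 5e-4, delay = 1.5, model_template = "exp2syn",
            dynamics_params = "AMPA_ExcToExc.json",
            target_sections = "basal", distance_range = c(30, 300))
  add_edges(net, list(pop_name = "exc"), list(pop_name = "inh"), rule,
            list(p0 = 0.4, sigma = 120, nsyns_range = c(1, 2)),
            syn_weight = 2e-3, delay = 1.5, model_template = "current_exp",
            dynamics_params = "ExcToInh.json")
  add_edges(net, list(pop_name = "inh"), list(pop_name = "exc"), rule,
            list(p0 = 0.6, sigma = 120, nsyns_range = c(1, 2)),
            syn_weight = 2e-3, delay = 1.0, model_template = "exp2syn",
            dynamics_params = "GABA_InhToExc.json",
            target_sections = "somatic", distance_range = c(0, 30))
  add_edges(net, list(pop_name = "inh"), list(pop_name = "inh"), rule,
            list(p0 = 0.4, sigma = 120, nsyns_range = c(1, 1)),
            syn_weight = 1e-3, delay = 1.0, model_template = "current_exp",
            dynamics_params = "InhToInh.json")
  build_edges(net, seed)
  net
}

.DEFAULT_DYNAMICS <- list(
  "pas_exc.json" = list(cm = 1, g_pas = 1e-4, e_pas = -70, ra = 100,
                        spike_threshold = -45),
  "pas_inh.json" = list(cm = 1, g_pas = 1.5e-4, e_pas = -70, ra = 100,
                        spike_threshold = -45),
  "lif_exc.json" = list(tau_m = 10, v_rest = -70, v_thresh = -50,
                        v_reset = -70, r_m = 100, t_ref = 2),
  "lif_inh.json" = list(tau_m = 8, v_rest = -70, v_thresh = -50,
                        v_reset = -70, r_m = 120, t_ref = 1),
  "AMPA_ExcToExc.json" = list(kind = "conductance_biexp", tau1 = 0.5,
                              tau2 = 3, e_rev = 0),
  "GABA_InhToExc.json" = list(kind = "conductance_biexp", tau1 = 1,
                              tau2 = 8, e_rev = -80),
  "ExcToInh.json" = list(kind = "current_exp", tau = 2),
  "InhToInh.json" = list(kind = "current_exp", tau = 3),
  "AMPA_ExtToExc.json" = list(kind = "conductance_biexp", tau1 = 0.3,
                              tau2 = 2, e_rev = 0),
  "ExtToInh.json" = list(kind = "current_exp", tau = 2))

#' Write the standard component files
#'
#' Emits the ball-and-stick morphology and the default cell/synapse
#' dynamics-parameter JSON files referenced by the fixture networks.
#'
#' @param dir components directory (created if needed); morphologies go to
#'   `dir/morphologies`, parameters to `dir/dynamics_params`.
#' @return list with the two subdirectory paths.
#' @export
write_component_files <- function(dir) {
  mdir <- file.path(dir, "morphologies")
  pdir <- file.path(dir, "dynamics_params")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  ball_and_stick_swc(file.path(mdir, "ball_stick.swc"),
                     soma_radius = 10, dend_length = 400, n_samples = 40)
  for (nm in names(.DEFAULT_DYNAMICS))
    jsonlite::write_json(.DEFAULT_DYNAMICS[[nm]], file.path(pdir, nm),
                         auto_unbox = TRUE, digits = NA)
  invisible(list(morphologies_dir = mdir, dynamics_params_dir = pdir))
}

#' Write a linear electrode layout
#'
#' @param path output CSV (columns id, x, y, z in um).
#' @param n_sites number of sites.
#' @param pitch inter-site spacing, um.
#' @param x,z lateral position of the (vertical) probe shank, um.
#' @param y0 depth of the first site, um.
#' @return the path, invisibly.
#' @export
linear_electrode_layout <- function(path, n_sites = 6, pitch = 40,
                                    x = 0, z = 0, y0 = -60) {
  el <- data.frame(id = seq_len(n_sites) - 1L, x = x,
                   y = y0 + pitch * (seq_len(n_sites) - 1L), z = z)
  utils::write.csv(el, path, row.names = FALSE)
  invisible(path)
}

#' Generate and save an external population's Poisson spike trains
#'
#' Firing rates are converted to spikes by an (inhomogeneous) Poisson
#' process, one counter-based stream per cell, and written as a spike file.
#'
#' @param n_cells number of source cells (gids 0..n_cells-1).
#' @param rate rate in Hz: scalar or step profile `data.frame(time, rate)`
#'   (see [poisson_spike_train()]); helpers: [rate_profile_on_off()],
#'   [rate_profile_gray_then_stim()].
#' @param t_stop duration, ms.
#' @param seed stream seed.
#' @param path output spike file.
#' @return the path, invisibly.
#' @export
external_population_spikes <- function(n_cells, rate, t_stop, seed, path) {
  pseed <- .derive_seed(seed, .SEED_POISSON)
  all_t <- list(); all_g <- list()
  for (gid in seq_len(n_cells) - 1L) {
    stream <- function(counters) rng_uniform(pseed, gid, 0, 0, counters)
    ts <- poisson_spike_train(rate, t_stop, stream)
    if (length(ts)) {
      all_t[[length(all_t) + 1L]] <- ts
      all_g[[length(all_g) + 1L]] <- rep.int(gid, length(ts))
    }
  }
  write_spike_file(path, unlist(all_g) %||% integer(0),
                   unlist(all_t) %||% numeric(0))
}

#' Alternating ON/OFF rate profile
#'
#' Two-state profile loosely representing switching brain states: the rate
#' alternates between `off_rate` and `on_rate` every `period` ms, starting
#' OFF.
#'
#' @param on_rate,off_rate rates in Hz.
#' @param period state duration, ms.
#' @param t_stop total duration covered, ms.
#' @return step profile `data.frame(time, rate)`.
#' @export
rate_profile_on_off <- function(on_rate = 20, off_rate = 2, period = 500,
                                t_stop = 3000) {
  edges <- seq(0, t_stop, by = period)
  data.frame(time = edges,
             rate = rep(c(off_rate, on_rate), length.out = length(edges)))
}

#' Gray-screen-then-stimulus rate profile
#'
#' Timing skeleton of a visual-response protocol: a low spontaneous rate for
#' the first `gray_ms` (gray screen), then an elevated rate for the remainder
#' (drifting-grating presentation).  No visual model is implied, only the
#' timing.
#'
#' @param gray_rate,stim_rate rates in Hz.
#' @param gray_ms gray-screen duration, ms.
#' @return step profile `data.frame(time, rate)`.
#' @export
rate_profile_gray_then_stim <- function(gray_rate = 4, stim_rate = 15,
                                        gray_ms = 500) {
  data.frame(time = c(0, gray_ms), rate = c(gray_rate, stim_rate))
}

#' Layer-4 composition example network (nodes)
#'
#' Builds the composition of a cortical layer-4 model: a biophysical "core"
#' cylinder (radius 400 um, height 100 um) of 10,000 cells across 5 cell
#' types — three excitatory (Scnn1a 3400, Rorb 3300, Nr5a1 1800; 85% of the
#' core) and two inhibitory PV types (750 each; 15%) — surrounded by a
#' "periphery" annulus (outer radius 845 um) of 35,000 LIF cells across one
#' excitatory and one inhibitory type (85%/15% split), so border cells see on
#' average as many neighbours as central ones.  Counts scale by `scale` with
#' rounding.  By default only nodes are created; `with_edges` adds
#' distance-tapered recurrent rules with desk-scale connection
#' probabilities.
#'
#' @param scale fraction of the full size, in (0, 1].
#' @param seed build seed (positions, rotations, tuning angles).
#' @param with_edges also register and build recurrent edges (intended for
#'   small `scale` only).
#' @return a built `lfpnet_network` named "l4".
#' @export
layer4_composition_spec <- function(scale = 1, seed = 0, with_edges = FALSE) {
  if (!is.numeric(scale) || scale <= 0 || scale > 1)
    stop("`scale` must be in (0, 1]")
  core <- list(
    list(pop = "Scnn1a", n = 3400, ei = "e"),
    list(pop = "Rorb",   n = 3300, ei = "e"),
    list(pop = "Nr5a1",  n = 1800, ei = "e"),
    list(pop = "PV1",    n = 750,  ei = "i"),
    list(pop = "PV2",    n = 750,  ei = "i"))
  periph <- list(
    list(pop = "LIF_exc", n = 29750, ei = "e"),
    list(pop = "LIF_inh", n = 5250,  ei = "i"))

  net <- create_network("l4")
  salt <- 10L
  for (ct in core) {
    n <- max(1L, round(ct$n * scale))
    pos <- .cylinder_positions(n, 0, 400, 100, seed, salt)
    pn <- list(positions = pos,
               rotation_angle_yaxis = 2 * pi * rng_uniform(seed, salt + 1,
                                                           seq_len(n) - 1))
    if (ct$ei == "e")
      pn$tuning_angle <- 360 * rng_uniform(seed, salt + 2, seq_len(n) - 1)
    add_nodes(net, n, pop_name = ct$pop, ei = ct$ei, location = "core",
              model_type = "biophysical", model_template = "passive_cable",
              morphology_file = "ball_stick.swc",
              dynamics_params = if (ct$ei == "e") "pas_exc.json" else "pas_inh.json",
              per_node = pn)
    salt <- salt + 3L
  }
  for (ct in periph) {
    n <- max(1L, round(ct$n * scale))
    pos <- .cylinder_positions(n, 400, 845, 100, seed, salt)
    add_nodes(net, n, pop_name = ct$pop, ei = ct$ei, location = "periphery",
              model_type = "intfire", model_template = "lif",
              dynamics_params = if (ct$ei == "e") "lif_exc.json" else "lif_inh.json",
              per_node = list(positions = pos))
    salt <- salt + 3L
  }
  if (with_edges) {
    rule <- distance_tapered_probability
    add_edges(net, list(ei = "e"), list(ei = "e"), rule,
              list(p0 = 0.05, sigma = 150, nsyns_range = c(1, 3)),
              syn_weight = 5e-4, delay = 2, model_template = "exp2syn",
              dynamics_params = "AMPA_ExcToExc.json",
              target_sections = "basal", distance_range = c(30, 300),
              weight_function = "gaussian_tuning")
    add_edges(net, list(ei = "i"), list(ei = "e"), rule,
              list(p0 = 0.15, sigma = 150, nsyns_range = c(1, 2)),
              syn_weight = 2e-3, delay = 1, model_template = "exp2syn",
              dynamics_params = "GABA_InhToExc.json",
              target_sections = "somatic", distance_range = c(0, 30))
    build_edges(net, seed)
  }
  net
}

#' Write a complete ready-to-run two-population fixture
#'
#' Generates everything a simulation needs under one directory: component
#' files, the built two-population network and an external Poisson input
#' population (saved as relational file sets), the input spike file, a linear
#' electrode layout, and a JSON run configuration wiring them together.
#'
#' @param dir fixture directory (created).
#' @param n_exc,n_inh recurrent population sizes.
#' @param n_ext external source count.
#' @param ext_rate external Poisson rate, Hz.
#' @param tstop simulated duration, ms.
#' @param dt step, ms.
#' @param seed master seed (build, placement, inputs).
#' @param buffer_steps report buffer size N.
#' @return path to the written config file.
#' @export
two_pop_fixture <- function(dir, n_exc = 20, n_inh = 5, n_ext = 10,
                            ext_rate = 40, tstop = 200, dt = 0.1, seed = 0,
                            buffer_steps = 1000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comp <- write_component_files(file.path(dir, "components"))

  net <- two_pop_network(n_exc, n_inh, seed)
  ext <- create_network("ext")
  add_nodes(ext, n_ext, pop_name = "ext", model_type = "virtual",
            per_node = list(positions = .disc_positions(n_ext, 100, 0, seed, 7)))
  add_edges(net, NULL, list(pop_name = "exc"), fixed_probability,
            list(p = 0.6, nsyns_range = c(1, 2)),
            syn_weight = 1.5e-3, delay = 1.0, model_template = "exp2syn",
            dynamics_params = "AMPA_ExtToExc.json",
            target_sections = c("basal", "somatic"), distance_range = c(0, 200),
            source_network = ext)
  add_edges(net, NULL, list(pop_name = "inh"), fixed_probability,
            list(p = 0.6, nsyns_range = c(1, 1)),
            syn_weight = 0.12, delay = 1.0, model_template = "current_exp",
            dynamics_params = "ExtToInh.json",
            source_network = ext)
  build_edges(net, seed)

  netdir <- file.path(dir, "network")
  save_network(net, netdir)
  save_network(ext, netdir)

  inputs_dir <- file.path(dir, "inputs")
  dir.create(inputs_dir, showWarnings = FALSE)
  spikes_path <- file.path(inputs_dir, "ext_spikes.h5")
  external_population_spikes(n_ext, ext_rate, tstop, seed, spikes_path)

  el_path <- file.path(dir, "electrodes.csv")
  linear_electrode_layout(el_path, n_sites = 6, pitch = 40, y0 = -60)

  cfg <- list(
    run = list(dt = dt, tstop = tstop, seed = seed, nranks = 1,
               max_seg_len = 40),
    components = list(morphologies_dir = "components/morphologies",
                      dynamics_params_dir = "components/dynamics_params"),
    networks = list(list(name = "v1", dir = "network"),
                    list(name = "ext", dir = "network", external = TRUE)),
    inputs = list(list(network = "ext", spikes_file = "inputs/ext_spikes.h5")),
    reports = list(
      list(variable = "spikes", file = "spikes.h5", buffer_steps = buffer_steps),
      list(variable = "v_soma", file = "v_soma.h5", node_ids = "all",
           buffer_steps = buffer_steps),
      list(variable = "extracellular", file = "lfp.h5",
           electrode_file = "electrodes.csv", buffer_steps = buffer_steps,
           sigma = 0.3)),
    output = list(dir = "output"))
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_path
}

# ---- fixture-spec registry (used by the CLI build command) -------------------

.fixture_registry <- list(
  two_pop_fixture = function(params, out_dir) {
    do.call(two_pop_fixture, c(list(dir = out_dir), params))
  },
  layer4_composition = function(params, out_dir) {
    net <- do.call(layer4_composition_spec, params)
    save_network(net, out_dir)
    out_dir
  },
  ball_and_stick_swc = function(params, out_dir) {
    do.call(ball_and_stick_swc,
            c(list(path = file.path(out_dir, "ball_stick.swc")), params))
  })

#' Run a named fixture generator from a JSON spec
#'
#' The spec is `{"generator": <name>, "params": {...}}`; available
#' generators: `two_pop_fixture`, `layer4_composition`, `ball_and_stick_swc`.
#' Identical spec + seed produce identical outputs.
#'
#' @param spec_path path to the JSON fixture spec.
#' @param out_dir output directory.
#' @return generator return value (typically a path).
#' @export
run_fixture_spec <- function(spec_path, out_dir) {
  spec <- jsonlite::fromJSON(spec_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  gen <- spec$generator
  if (is.null(gen) || !gen %in% names(.fixture_registry))
    stop("unknown fixture generator: ", gen %||% "<missing>",
         " (available: ", paste(names(.fixture_registry), collapse = ", "), ")")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .fixture_registry[[gen]](spec$params %||% list(), out_dir)
}
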