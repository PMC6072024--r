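# Simulation orchestration: load networks, instantiate cells and synapses,
# wire external inputs, run the fixed-step loop firing report hooks at begin,
# each step, and end.
#
# Ranks are a logical contract: the whole network is advanced in one process,
# and the round-robin partition only decides which rank's temporary file each
# cell reports to.  Because all randomness is counter-based and keyed by gid,
# every output is identical for any rank count.

.load_dynamics_params <- function(dir, file, cache) {
  if (is.null(file) || is.na(file)) stop("missing dynamics_params reference")
  key <- file
  if (!is.null(cache[[key]])) return(cache[[key]])
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("dynamics_params file not found: ", path)
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cache[[key]] <- p
  p
}

.syn_kind_from <- function(model_template, target_model_type, json) {
  k <- json$kind %||% model_template
  if (!is.null(k) && !is.na(k)) {
    k <- switch(as.character(k),
                exp2syn = , conductance_biexp = "conductance_biexp",
                expsyn_current = , current_exp = "current_exp",
                stop("unknown synapse model_template: ", k))
    return(k)
  }
  if (identical(target_model_type, "intfire")) "current_exp" else "conductance_biexp"
}

#' Run a simulation described by a configuration
#'
#' Executes the full workflow: load the network file sets, instantiate cell
#' models (LIF point neurons and passive cable cells) and synapses, place
#' synapses on morphologies under the edge types' section/distance
#' constraints, wire precomputed external spike trains, and advance the
#' network with fixed-step integration while the configured reports record
#' spikes, somatic voltages and extracellular potentials.  Outputs are
#' identical for any logical rank count and any report buffer size.
#'
#' @param config an `lfpnet_config` from [parse_config()], or a path to a
#'   JSON config file.
#' @param nranks,seed,output_dir optional overrides of the config values.
#' @return list with `report_files` (named by variable), `n_spikes`, and the
#'   step count, invisibly.
#' @export
run_simulation <- function(config, nranks = NULL, seed = NULL,
                           output_dir = NULL) {
  if (is.character(config)) config <- parse_config(config)
  stopifnot(inherits(config, "lfpnet_config"))
  run <- config$run
  if (!is.null(nranks)) run$nranks <- nranks
  if (!is.null(seed)) run$seed <- seed
  out_dir <- output_dir %||% config$output$dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tmp_dir <- file.path(out_dir, "tmp")
  dir.create(tmp_dir, recursive = TRUE, showWarnings = FALSE)

  dt <- run$dt
  nsteps <- as.integer(floor(run$tstop / dt + 1e-9))
  pseed <- .derive_seed(run$seed, .SEED_PLACEMENT)

  # ---- networks --------------------------------------------------------------
  nets <- list()
  for (nw in config$networks) nets[[nw$name]] <- load_network(nw$fileset)
  external <- vapply(config$networks, `[[`, logical(1), "external")
  names(external) <- vapply(config$networks, `[[`, character(1), "name")
  sim_name <- names(external)[!external]
  sim_net <- nets[[sim_name]]
  for (nm in names(external)[external])
    if (length(nets[[nm]]$edges$target_node_id))
      stop("external population '", nm,
           "' has incoming edges; feed-forward contract violated")

  node_tables <- lapply(nets, .node_table)
  df <- node_tables[[sim_name]]
  n_cells <- nrow(df)
  gids <- df$node_id
  partition <- make_partition(gids, run$nranks)

  # ---- cell models -----------------------------------------------------------
  dyn_cache <- new.env(parent = emptyenv())
  morph_cache <- new.env(parent = emptyenv())
  get_morph <- function(file) {
    if (is.null(morph_cache[[file]])) {
      path <- file.path(config$components$morphologies_dir, file)
      morph_cache[[file]] <- discretize(load_swc(path), run$max_seg_len)
    }
    morph_cache[[file]]
  }

  type_ids <- vapply(sim_net$node_types, `[[`, integer(1), "node_type_id")
  cell_model <- vector("list", length(sim_net$node_types))
  for (ti in seq_along(sim_net$node_types)) {
    tp <- sim_net$node_types[[ti]]$props
    if (is.null(tp$model_type))
      stop("node type ", type_ids[ti], " lacks model_type")
    pj <- .load_dynamics_params(config$components$dynamics_params_dir,
                                tp$dynamics_params, dyn_cache)
    if (tp$model_type == "intfire") {
      cell_model[[ti]] <- list(
        kind = "lif",
        params = lif_params(tau_m = pj$tau_m, v_rest = pj$v_rest,
                            v_thresh = pj$v_thresh, v_reset = pj$v_reset,
                            r_m = pj$r_m, t_ref = pj$t_ref %||% 0))
    } else if (tp$model_type == "biophysical") {
      if (is.null(tp$morphology_file))
        stop("node type ", type_ids[ti], " lacks morphology_file")
      m <- get_morph(tp$morphology_file)
      cp <- cable_params(cm = pj$cm, g_pas = pj$g_pas, e_pas = pj$e_pas,
                         ra = pj$ra, v_init = pj$v_init %||% pj$e_pas,
                         spike_threshold = pj$spike_threshold %||% -20)
      cell_model[[ti]] <- list(kind = "cable", cell = build_cable_cell(m, cp),
                               morph = m)
    } else stop("node type ", type_ids[ti], " has unsupported model_type: ",
                tp$model_type)
  }
  model_of_node <- match(df$node_type_id, type_ids)
  kind_of_node <- vapply(cell_model, `[[`, character(1), "kind")[model_of_node]

  lif_cells <- which(kind_of_node == "lif")          # row indices into df
  bio_cells <- which(kind_of_node == "cable")
  lif_index <- match(seq_len(n_cells), lif_cells)    # per node: index in lif block
  bio_index <- match(seq_len(n_cells), bio_cells)

  # LIF state grouped by node type (same params within a group)
  lif_groups <- split(seq_along(lif_cells), model_of_node[lif_cells])
  lif_v <- numeric(length(lif_cells)); lif_refr <- integer(length(lif_cells))
  for (g in names(lif_groups)) {
    p <- cell_model[[as.integer(g)]]$params
    lif_v[lif_groups[[g]]] <- p$v_rest
  }

  # cable state + segment slot offsets
  bio_proto <- lapply(bio_cells, function(i) cell_model[[model_of_node[i]]]$cell)
  bio_nseg <- vapply(bio_proto, `[[`, integer(1), "n")
  seg_off <- c(0L, cumsum(bio_nseg))
  n_slots <- if (length(bio_nseg)) seg_off[length(seg_off)] else 0L
  bio_v <- lapply(bio_proto, function(cl) rep(cl$params$v_init, cl$n))
  bio_thr <- vapply(bio_proto, function(cl) cl$params$spike_threshold, numeric(1))

  # ---- extracellular setup ---------------------------------------------------
  lfp_reports <- Filter(function(r) r$variable == "extracellular", config$reports)
  need_lfp <- length(lfp_reports) > 0
  R_cells <- NULL; nsites <- 0L; el <- NULL
  if (need_lfp) {
    if (length(lfp_reports) > 1)
      stop("at most one extracellular report is supported per run")
    el <- read_electrode_layout(lfp_reports[[1]]$electrode_file)
    nsites <- nrow(el)
    sigma <- lfp_reports[[1]]$sigma
    R_cells <- lapply(seq_along(bio_cells), function(ci) {
      i <- bio_cells[ci]
      pos <- c(df$x[i] %||% 0, df$y[i] %||% 0, df$z[i] %||% 0)
      pos[is.na(pos)] <- 0
      rot <- df$rotation_angle_yaxis[i] %||% 0
      if (is.na(rot)) rot <- 0
      segs <- .transform_segments(cell_model[[model_of_node[i]]]$morph$segments,
                                  pos, rot)
      build_transfer_matrix(sigma, el, segs)
    })
  }

  # ---- synapses --------------------------------------------------------------
  syn <- .instantiate_synapses(sim_net, nets, node_tables, sim_name, df,
                               cell_model, model_of_node, lif_index, bio_index,
                               seg_off, dt, pseed,
                               config$components$dynamics_params_dir, dyn_cache)

  # routing: source key -> synapse rows
  out_rows <- split(seq_len(syn$n), syn$src_key)
  pend <- vector("list", nsteps + 1L)

  # external inputs: schedule activations up front
  for (inp in config$inputs) {
    trains <- load_external_spikes(inp$spikes_file)
    for (gid_chr in names(trains)) {
      key <- paste0(inp$network, ":", gid_chr)
      rows <- out_rows[[key]]
      if (is.null(rows)) next
      for (ts in trains[[gid_chr]]) {
        dstep <- as.integer(floor((ts + syn$delay_ms[rows]) / dt + 0.5))
        for (ri in seq_along(rows)) {
          s <- dstep[ri]
          if (s >= 1L && s <= nsteps)
            pend[[s]] <- c(pend[[s]], rows[ri])
        }
      }
    }
  }

  # aggregation operators (plain lists of target slots; sums via rowsum-style
  # accumulation using precomputed index vectors)
  agg <- .build_aggregators(syn, length(lif_cells), n_slots)

  # ---- reports ---------------------------------------------------------------
  ctx <- list(dt = dt, nsteps = nsteps, partition = partition, gids = gids,
              out_dir = out_dir, tmp_dir = tmp_dir)
  recorders <- lapply(config$reports, make_report, ctx = ctx)
  for (rec in recorders) rec$begin()

  rank_of_bio <- partition$rank[bio_cells]
  v_soma <- numeric(n_cells)
  n_spikes_total <- 0L

  # ---- main loop -------------------------------------------------------------
  for (s in seq_len(nsteps)) {
    t_now <- s * dt
    # synaptic state decay + queued activations
    syn$A <- syn$A * syn$dA
    syn$B <- syn$B * syn$dB
    rows <- pend[[s]]
    if (!is.null(rows) && length(rows)) {
      inc <- rowsum(cbind(syn$incA[rows], syn$incB[rows]), rows)
      ri <- as.integer(rownames(inc))
      syn$A[ri] <- syn$A[ri] + inc[, 1]
      syn$B[ri] <- syn$B[ri] + inc[, 2]
      pend[s] <- list(NULL)
    }
    g_row <- syn$B - syn$A          # biexp conductance rows (cur rows: B=A=0 there)

    spiking <- integer(0)

    # LIF cells
    if (length(lif_cells)) {
      i_syn <- .agg_sum(agg$lif_cur, syn$A, length(lif_cells)) +
        .agg_sum(agg$lif_ge, g_row, length(lif_cells)) -
        lif_v * .agg_sum(agg$lif_g, g_row, length(lif_cells))
      for (g in names(lif_groups)) {
        idx <- lif_groups[[g]]
        p <- cell_model[[as.integer(g)]]$params
        st <- step_lif(list(v = lif_v[idx], refr = lif_refr[idx]), p,
                       i_syn[idx], dt)
        lif_v[idx] <- st$state$v; lif_refr[idx] <- st$state$refr
        if (any(st$spiked))
          spiking <- c(spiking, gids[lif_cells[idx[st$spiked]]])
      }
      v_soma[lif_cells] <- lif_v
    }

    # cable cells
    if (length(bio_cells)) {
      g_all <- .agg_sum(agg$bio_g, g_row, n_slots)
      ge_all <- .agg_sum(agg$bio_ge, g_row, n_slots)
      icur_all <- .agg_sum(agg$bio_cur, syn$A, n_slots)
      phi_by_rank <- if (need_lfp) matrix(0, partition$M, nsites)
      for (ci in seq_along(bio_cells)) {
        sl <- (seg_off[ci] + 1L):seg_off[ci + 1L]
        cl <- bio_proto[[ci]]
        res <- step_passive_cable(cl, list(v = bio_v[[ci]]), dt,
                                  i_inj = icur_all[sl], g_syn = g_all[sl],
                                  g_syn_e = ge_all[sl])
        v_old <- bio_v[[ci]][cl$soma_segment]
        bio_v[[ci]] <- res$state$v
        v_new <- res$state$v[cl$soma_segment]
        if (v_old < bio_thr[ci] && v_new >= bio_thr[ci])
          spiking <- c(spiking, gids[bio_cells[ci]])
        if (need_lfp)
          phi_by_rank[rank_of_bio[ci] + 1L, ] <-
            accumulate_lfp(phi_by_rank[rank_of_bio[ci] + 1L, ],
                           R_cells[[ci]], res$currents)
        v_soma[bio_cells[ci]] <- v_new
      }
    } else phi_by_rank <- if (need_lfp) matrix(0, partition$M, nsites)

    # recurrent spike delivery
    if (length(spiking)) {
      spiking <- sort(spiking)
      n_spikes_total <- n_spikes_total + length(spiking)
      for (gid in spiking) {
        rows <- out_rows[[paste0(sim_name, ":", gid)]]
        if (is.null(rows)) next
        dstep <- s + syn$delay_steps[rows]
        ok <- dstep <= nsteps
        for (ri in which(ok)) pend[[dstep[ri]]] <- c(pend[[dstep[ri]]], rows[ri])
      }
    }

    data <- list(t = t_now, step = s, spike_gids = spiking, v_soma = v_soma,
                 phi_by_rank = if (need_lfp) phi_by_rank)
    for (rec in recorders) rec$step(data, s)
  }

  files <- lapply(recorders, function(rec) rec$end())
  names(files) <- vapply(config$reports, `[[`, character(1), "variable")
  invisible(list(report_files = files, n_spikes = n_spikes_total,
                 nsteps = nsteps, n_cells = n_cells))
}

# expand edges into synapse rows with placements, weights and kinetics
.instantiate_synapses <- function(sim_net, nets, node_tables, sim_name, df,
                                  cell_model, model_of_node, lif_index,
                                  bio_index, seg_off, dt, pseed, dyn_dir,
                                  dyn_cache) {
  ed <- sim_net$edges
  n_edges <- length(ed$source_node_id)
  et_ids <- vapply(sim_net$edge_types, `[[`, integer(1), "edge_type_id")
  type_ids <- vapply(sim_net$node_types, `[[`, integer(1), "node_type_id")

  cols <- list(src_key = character(0), tclass = integer(0), tidx = integer(0),
               slot = integer(0), kind = integer(0), w = numeric(0),
               tau1 = numeric(0), tau2 = numeric(0), e_rev = numeric(0),
               delay_ms = numeric(0), delay_steps = integer(0))
  warned_lif_sections <- FALSE

  # resolve per edge type once
  et_info <- lapply(sim_net$edge_types, function(t) {
    p <- t$props
    if (is.null(p$syn_weight)) stop("edge type ", t$edge_type_id,
                                    " lacks syn_weight")
    if (is.null(p$delay)) stop("edge type ", t$edge_type_id, " lacks delay")
    pj <- .load_dynamics_params(dyn_dir, p$dynamics_params, dyn_cache)
    wf <- .get_weight_function(p$weight_function)
    list(props = p, json = pj, wf = wf,
         src_net = p$source_network %||% sim_name)
  })
  names(et_info) <- as.character(et_ids)

  out <- vector("list", n_edges)
  for (i in seq_len(n_edges)) {
    tinfo <- et_info[[as.character(ed$edge_type_id[i])]]
    p <- tinfo$props
    sgid <- ed$source_node_id[i]; tgid <- ed$target_node_id[i]
    nsyns <- ed$nsyns[i]
    src_tab <- node_tables[[tinfo$src_net]]
    if (is.null(src_tab)) stop("edge type references unknown source network: ",
                               tinfo$src_net)
    srow <- match(sgid, src_tab$node_id)
    if (is.na(srow)) stop("edge source gid ", sgid, " missing in network ",
                          tinfo$src_net)
    trow <- tgid + 1L
    tmodel <- model_of_node[trow]
    tkind <- cell_model[[tmodel]]$kind
    skind <- .syn_kind_from(p$model_template, if (tkind == "lif") "intfire"
                            else "biophysical", tinfo$json)
    tau1 <- tinfo$json$tau1 %||% tinfo$json$tau
    tau2 <- tinfo$json$tau2
    e_rev <- tinfo$json$e_rev %||% 0
    if (skind == "conductance_biexp" && (is.null(tau2) || tau2 <= tau1))
      stop("edge type ", ed$edge_type_id[i], ": biexp requires tau2 > tau1")
    w0 <- p$syn_weight * tinfo$wf(p, as.list(src_tab[srow, , drop = FALSE]),
                                  as.list(df[trow, , drop = FALSE]))
    dstep <- delay_steps(p$delay, dt)
    src_key <- paste0(tinfo$src_net, ":", sgid)

    if (tkind == "lif") {
      if (!is.null(p$target_sections) && !warned_lif_sections) {
        warning("target_sections/distance_range ignored for point-neuron targets",
                call. = FALSE)
        warned_lif_sections <- TRUE
      }
      out[[i]] <- data.frame(
        src_key = src_key, tclass = 1L, tidx = lif_index[trow], slot = lif_index[trow],
        kind = if (skind == "current_exp") 1L else 2L,
        w = w0 * nsyns, tau1 = tau1, tau2 = tau2 %||% NA_real_, e_rev = e_rev,
        delay_ms = p$delay, delay_steps = dstep)
    } else {
      m <- cell_model[[tmodel]]$morph
      ts <- p$target_sections
      if (is.null(ts)) stop("edge type ", ed$edge_type_id[i],
                            " targets biophysical cells but has no target_sections")
      dr <- p$distance_range %||% c(0, Inf)
      stream <- function(counter) rng_uniform(pseed, tgid, i, counter,
                                              seq_len(nsyns) - 1)
      pl <- place_synapses(m, ts, dr, nsyns, stream)
      bi <- bio_index[trow]
      out[[i]] <- data.frame(
        src_key = src_key, tclass = 2L, tidx = bi,
        slot = seg_off[bi] + pl$segment,
        kind = if (skind == "current_exp") 1L else 2L,
        w = w0, tau1 = tau1, tau2 = tau2 %||% NA_real_, e_rev = e_rev,
        delay_ms = p$delay, delay_steps = dstep)
    }
  }
  tab <- if (n_edges) do.call(rbind, out) else
    data.frame(src_key = character(0), tclass = integer(0), tidx = integer(0),
               slot = integer(0), kind = integer(0), w = numeric(0),
               tau1 = numeric(0), tau2 = numeric(0), e_rev = numeric(0),
               delay_ms = numeric(0), delay_steps = integer(0))

  n <- nrow(tab)
  dA <- exp(-dt / tab$tau1)
  dB <- numeric(n); norm <- rep(1, n)
  is_biexp <- tab$kind == 2L
  dB[is_biexp] <- exp(-dt / tab$tau2[is_biexp])
  norm[is_biexp] <- .biexp_norm(tab$tau1[is_biexp], tab$tau2[is_biexp])
  incA <- ifelse(is_biexp, tab$w * norm, tab$w)
  incB <- ifelse(is_biexp, tab$w * norm, 0)
  c(as.list(tab), list(n = n, dA = dA, dB = dB, incA = incA, incB = incB,
                       A = numeric(n), B = numeric(n)))
}

# index-vector accumulators: sum x over rows into target slots
.build_aggregators <- function(syn, n_lif, n_slots) {
  pick <- function(tclass, kind) which(syn$tclass == tclass & syn$kind == kind)
  list(
    lif_cur = list(rows = pick(1L, 1L), slot = syn$slot[pick(1L, 1L)], wmul = NULL),
    lif_g = list(rows = pick(1L, 2L), slot = syn$slot[pick(1L, 2L)], wmul = NULL),
    lif_ge = list(rows = pick(1L, 2L), slot = syn$slot[pick(1L, 2L)],
                  wmul = syn$e_rev[pick(1L, 2L)]),
    bio_g = list(rows = pick(2L, 2L), slot = syn$slot[pick(2L, 2L)], wmul = NULL),
    bio_ge = list(rows = pick(2L, 2L), slot = syn$slot[pick(2L, 2L)],
                  wmul = syn$e_rev[pick(2L, 2L)]),
    bio_cur = list(rows = pick(2L, 1L), slot = syn$slot[pick(2L, 1L)], wmul = NULL))
}

.agg_sum <- function(a, x, n_out) {
  out <- numeric(n_out)
  if (!length(a$rows)) return(out)
  v <- x[a$rows]
  if (!is.null(a$wmul)) v <- v * a$wmul
  s <- rowsum(v, a$slot)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
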