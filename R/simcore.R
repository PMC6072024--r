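# Simulation primitives: round-robin partitioning, leaky integrate-and-fire
# point neurons, passive multi-compartment cables (backward Euler), synapse
# kinetics, Poisson spike trains and external spike files.
#
# Units throughout: ms, mV, nA, uS, nF, MOhm, um.  Fixed-step integration
# only; determinism and partition invariance rule out adaptive steps.

#' Round-robin partition of cell gids over logical ranks
#'
#' Rank `k` of `M` hosts the cells with gids `k, k+M, k+2M, ...` (gid mod M),
#' so per-rank counts differ by at most one and the assignment is a pure
#' function of the gid.
#'
#' @param gids integer vector of cell gids.
#' @param M number of ranks (>= 1).
#' @return object of class `lfpnet_partition` with `$M`, `$gids`, `$rank`
#'   (rank per gid).
#' @export
make_partition <- function(gids, M) {
  if (!is.numeric(M) || length(M) != 1 || M < 1 || M != floor(M))
    stop("`M` must be a positive integer")
  p <- list(M = as.integer(M), gids = as.integer(gids),
            rank = as.integer(gids %% M))
  class(p) <- "lfpnet_partition"
  p
}

#' @export
print.lfpnet_partition <- function(x, ...) {
  cat(sprintf("<partition: %d gids over %d ranks (%s per rank)>\n",
              length(x$gids), x$M,
              paste(range(tabulate(x$rank + 1L, x$M)), collapse = "-")))
  invisible(x)
}

# ---- leaky integrate-and-fire ------------------------------------------------

#' Leaky integrate-and-fire parameters
#'
#' @param tau_m membrane time constant, ms (> 0).
#' @param v_rest,v_thresh,v_reset resting, threshold and reset potentials,
#'   mV (`v_thresh > v_reset`).
#' @param r_m input resistance, MOhm (> 0).
#' @param t_ref absolute refractory period, ms (>= 0).
#' @return validated parameter list of class `lfpnet_lif_params`.
#' @export
lif_params <- function(tau_m = 10, v_rest = -70, v_thresh = -50,
                       v_reset = -70, r_m = 100, t_ref = 2) {
  stopifnot(tau_m > 0, r_m > 0, t_ref >= 0, v_thresh > v_reset)
  p <- list(tau_m = tau_m, v_rest = v_rest, v_thresh = v_thresh,
            v_reset = v_reset, r_m = r_m, t_ref = t_ref)
  class(p) <- "lfpnet_lif_params"
  p
}

#' Initial LIF state
#' @param n number of cells.
#' @param params LIF parameters (initial voltage = `v_rest`).
#' @return list with voltage vector `v` (mV) and refractory step counters.
#' @export
lif_state <- function(n, params) {
  list(v = rep(params$v_rest, n), refr = integer(n))
}

#' Advance LIF cells by one time step
#'
#' Exponential-Euler update of `dV/dt = (-(V - v_rest) + r_m I) / tau_m` with
#' the synaptic current held constant over the step (exact for constant
#' input).  A cell at or above threshold at the step end emits a spike, is
#' reset, and is clamped at `v_reset` for `t_ref` ms (`ceil(t_ref/dt)`
#' steps).  Equality with threshold counts as a crossing.
#'
#' @param state from [lif_state()].
#' @param params from [lif_params()].
#' @param i_syn synaptic/injected current per cell, nA.
#' @param dt time step, ms (> 0).
#' @return list with updated `state` and logical vector `spiked`.
#' @export
step_lif <- function(state, params, i_syn, dt) {
  stopifnot(dt > 0)
  v_inf <- params$v_rest + params$r_m * i_syn
  decay <- exp(-dt / params$tau_m)
  v <- v_inf + (state$v - v_inf) * decay
  refr <- state$refr
  clamped <- refr > 0L
  v[clamped] <- params$v_reset
  refr[clamped] <- refr[clamped] - 1L
  spiked <- !clamped & v >= params$v_thresh
  v[spiked] <- params$v_reset
  refr[spiked] <- as.integer(ceiling(params$t_ref / dt))
  list(state = list(v = v, refr = refr), spiked = spiked)
}

# ---- passive cable -----------------------------------------------------------

#' Passive membrane and cable parameters
#'
#' @param cm specific membrane capacitance, uF/cm^2.
#' @param g_pas passive (leak) conductance density, S/cm^2.
#' @param e_pas leak reversal potential, mV.
#' @param ra axial resistivity, Ohm cm.
#' @param v_init initial voltage, mV (defaults to `e_pas`).
#' @param spike_threshold somatic voltage whose upward crossing is recorded
#'   as a spike, mV.
#' @return validated parameter list of class `lfpnet_cable_params`.
#' @export
cable_params <- function(cm = 1, g_pas = 1e-4, e_pas = -70, ra = 100,
                         v_init = e_pas, spike_threshold = -20) {
  stopifnot(cm > 0, g_pas > 0, ra > 0)
  p <- list(cm = cm, g_pas = g_pas, e_pas = e_pas, ra = ra,
            v_init = v_init, spike_threshold = spike_threshold)
  class(p) <- "lfpnet_cable_params"
  p
}

# Axial topology of a discretized morphology: for every segment, the index of
# the segment it couples to towards the soma (0 for the root/soma segment).
.segment_parents <- function(m) {
  segs <- m$segments
  n <- nrow(segs)
  parent <- integer(n)
  first_of_sec <- match(seq_along(m$sections), segs$section)
  nseg_of_sec <- tabulate(segs$section, length(m$sections))
  for (i in seq_len(n)) {
    sec <- segs$section[i]
    k <- i - first_of_sec[sec] + 1L  # position within section
    if (k > 1L) { parent[i] <- i - 1L; next }
    if (segs$type[i] == 1L) { parent[i] <- 0L; next }  # soma segment = root
    att <- m$sections[[sec]]$attach_row
    if (is.na(att)) { parent[i] <- 0L; next }
    ps <- m$sections[[sec]]$parent_section
    if (is.na(ps) || m$sections[[ps]]$type == 1L) {
      parent[i] <- first_of_sec[1L]  # attach to the soma segment
    } else {
      # locate the parent's sub-segment containing the attachment arc position
      arc <- m$sections[[sec]]$attach_arc
      Lp <- m$sections[[ps]]$length
      np <- nseg_of_sec[ps]
      j <- min(np, max(1L, ceiling(arc / (Lp / np))))
      parent[i] <- first_of_sec[ps] + j - 1L
    }
  }
  parent
}

#' Build a passive multi-compartment cell from a discretized morphology
#'
#' Converts geometry to electrical quantities: membrane area `2 pi r L` per
#' segment (the one-point soma segment spans its diameter, so its cylinder
#' area equals the sphere area `4 pi r^2`), capacitance `cm * A`, leak
#' `g_pas * A`, and axial conductances from `ra` via half-segment series
#' resistances `R = ra (L/2) / (pi r^2)` between coupled segment midpoints.
#'
#' @param m a discretized morphology ([discretize()]).
#' @param params from [cable_params()].
#' @return object of class `lfpnet_cable_cell` holding the conductance
#'   structure; per-cell voltage state lives outside (see
#'   [step_passive_cable()]).
#' @export
build_cable_cell <- function(m, params) {
  stopifnot(inherits(m, "lfpnet_morphology"), inherits(params, "lfpnet_cable_params"))
  if (is.null(m$segments)) stop("morphology is not discretized")
  segs <- m$segments
  n <- nrow(segs)
  area <- 2 * pi * segs$radius * segs$length            # um^2
  C <- params$cm * area * 1e-5                          # nF
  g_leak <- params$g_pas * area * 1e-2                  # uS
  half_r <- params$ra * (segs$length / 2) / (pi * segs$radius^2) * 1e-2  # MOhm
  parent <- .segment_parents(m)
  G <- matrix(0, n, n)
  for (i in which(parent > 0L)) {
    j <- parent[i]
    g <- 1 / (half_r[i] + half_r[j])                    # uS
    G[i, i] <- G[i, i] + g; G[j, j] <- G[j, j] + g
    G[i, j] <- G[i, j] - g; G[j, i] <- G[j, i] - g
  }
  if (n > 1) {
    # connectivity check: the axial graph must span all segments
    seen <- logical(n); seen[parent == 0L] <- TRUE
    for (rep in seq_len(n)) seen <- seen | (parent > 0L & seen[pmax(parent, 1L)])
    if (!all(seen)) stop("disconnected morphology: axial system is singular")
  }
  cell <- list(n = n, C = C, g_leak = g_leak, G_ax = G, params = params,
               segments = segs, soma_segment = match(1L, segs$type))
  class(cell) <- "lfpnet_cable_cell"
  cell
}

#' Initial cable state
#' @param cell from [build_cable_cell()].
#' @return list with per-segment voltage vector `v` (mV).
#' @export
cable_state <- function(cell) list(v = rep(cell$params$v_init, cell$n))

#' Advance a passive cable cell by one backward-Euler step
#'
#' Solves `(C/dt + G_leak + G_syn + G_axial) V' = (C/dt) V + g_leak e_pas +
#' sum g_syn e_rev + I_inj` and returns the per-segment transmembrane
#' currents `I_n = C dV/dt + g_leak (V' - e_pas) + g_syn (V' - e_rev)`
#' (outward positive, axial currents excluded).  By Kirchhoff's law the
#' currents sum to the injected current exactly (to solver roundoff), which
#' is what makes them valid sources for the extracellular forward model.
#'
#' @param cell from [build_cable_cell()].
#' @param state from [cable_state()].
#' @param dt time step, ms.
#' @param i_inj injected current per segment, nA (scalar 0 or vector).
#' @param g_syn summed synaptic conductance per segment, uS.
#' @param g_syn_e summed `g * e_rev` per segment, uS mV.
#' @return list with updated `state` and `currents` (nA per segment).
#' @export
step_passive_cable <- function(cell, state, dt, i_inj = 0, g_syn = 0,
                               g_syn_e = 0) {
  stopifnot(dt > 0)
  n <- cell$n
  i_inj <- rep_len(i_inj, n); g_syn <- rep_len(g_syn, n)
  g_syn_e <- rep_len(g_syn_e, n)
  cdt <- cell$C / dt
  A <- cell$G_ax
  diag(A) <- diag(A) + cdt + cell$g_leak + g_syn
  rhs <- cdt * state$v + cell$g_leak * cell$params$e_pas + g_syn_e + i_inj
  v_new <- solve(A, rhs)
  currents <- cdt * (v_new - state$v) + cell$g_leak * (v_new - cell$params$e_pas) +
    g_syn * v_new - g_syn_e
  list(state = list(v = v_new), currents = currents)
}

# ---- synapse kinetics --------------------------------------------------------

#' Synapse parameters
#'
#' Two kinds are built in: `"conductance_biexp"`, a difference-of-exponentials
#' conductance normalized so its peak equals the synaptic weight (uS), with
#' reversal potential `e_rev`; and `"current_exp"`, a single-exponential
#' current pulse whose peak equals the weight (nA).
#'
#' @param kind `"conductance_biexp"` or `"current_exp"`.
#' @param tau1 rise time constant (biexp) or decay time constant
#'   (current_exp), ms.
#' @param tau2 decay time constant, ms (biexp only, `tau2 > tau1`).
#' @param e_rev reversal potential, mV (biexp only).
#' @return validated list of class `lfpnet_syn_params`.
#' @export
syn_params <- function(kind, tau1, tau2 = NULL, e_rev = 0) {
  kind <- match.arg(kind, c("conductance_biexp", "current_exp"))
  stopifnot(tau1 > 0)
  if (kind == "conductance_biexp") {
    if (is.null(tau2) || tau2 <= tau1)
      stop("conductance_biexp requires tau2 > tau1")
  }
  p <- list(kind = kind, tau1 = tau1, tau2 = tau2, e_rev = e_rev)
  class(p) <- "lfpnet_syn_params"
  p
}

# peak-normalization factor for the biexponential g(t) = w * k *
# (exp(-t/tau2) - exp(-t/tau1)), peak at t_p = tau1 tau2 / (tau2 - tau1) *
# log(tau2/tau1)
.biexp_norm <- function(tau1, tau2) {
  tp <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  1 / (exp(-tp / tau2) - exp(-tp / tau1))
}

#' Conduction-delay step count
#'
#' Delays are rounded to the nearest integer number of steps, with exact
#' half-step ties rounding up.
#'
#' @param delay delay in ms (>= 0).
#' @param dt step, ms.
#' @return integer step count.
#' @export
delay_steps <- function(delay, dt) {
  stopifnot(all(delay >= 0), dt > 0)
  as.integer(floor(delay / dt + 0.5))
}

# ---- Poisson spike trains ----------------------------------------------------

#' Generate a (possibly inhomogeneous) Poisson spike train
#'
#' Uses thinning against the profile maximum; candidate arrivals come in
#' (gap, accept) pairs from the counter-based `stream`, so the train is a
#' pure function of the stream key and independent of internal chunk sizes.
#'
#' @param rate firing rate in Hz: a scalar, or a step profile as a
#'   `data.frame(time, rate)` whose `time` column (ms) gives the left edge of
#'   each constant-rate interval.
#' @param t_stop train duration, ms.
#' @param stream `function(counters)` returning one uniform per counter.
#' @return sorted spike times in (0, t_stop], ms.
#' @export
poisson_spike_train <- function(rate, t_stop, stream) {
  stopifnot(t_stop > 0)
  if (is.data.frame(rate)) {
    if (!all(c("time", "rate") %in% names(rate)) || any(rate$rate < 0))
      stop("rate profile needs nonnegative `rate` and `time` columns")
    rmax <- max(rate$rate)
    rate_at <- function(t) rate$rate[pmax(findInterval(t, rate$time), 1L)]
  } else {
    if (!is.numeric(rate) || length(rate) != 1 || rate < 0)
      stop("rate must be a nonnegative scalar or a profile data.frame")
    rmax <- rate
    rate_at <- function(t) rep(rate, length(t))
  }
  if (rmax == 0) return(numeric(0))
  times <- numeric(0)
  t <- 0; i <- 0L
  chunk <- max(64L, ceiling(1.5 * rmax * t_stop / 1000))
  repeat {
    idx <- i + seq_len(chunk) - 1L
    gaps <- -log(stream(2 * idx)) / rmax * 1000  # ms
    cand <- t + cumsum(gaps)
    keep <- stream(2 * idx + 1) < rate_at(cand) / rmax
    times <- c(times, cand[keep & cand <= t_stop])
    i <- i + chunk
    t <- cand[chunk]
    if (t > t_stop) break
  }
  times[times <= t_stop]
}

# ---- external spike files ----------------------------------------------------

#' Write a spike file
#'
#' HDF5 layout: datasets `/spikes/gids` and `/spikes/timestamps` (ms), rows
#' sorted by (time, gid).
#'
#' @param path output file.
#' @param gids integer gid per spike.
#' @param timestamps spike times, ms.
#' @export
write_spike_file <- function(path, gids, timestamps) {
  stopifnot(length(gids) == length(timestamps))
  o <- order(timestamps, gids)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "spikes")
  rhdf5::h5write(as.double(timestamps[o]), path, "spikes/timestamps")
  rhdf5::h5write(as.integer(gids[o]), path, "spikes/gids")

  invisible(path)
}

#' Load external spike trains
#'
#' External populations are feed-forward sources: their trains are
#' precomputed and loaded; they can never receive simulated input.
#'
#' @param path spike file from [write_spike_file()].
#' @return named list mapping gid (as character) to a sorted numeric vector
#'   of spike times in ms.
#' @export
load_external_spikes <- function(path) {
  if (!file.exists(path)) stop("spike file not found: ", path)
  ts <- as.double(rhdf5::h5read(path, "spikes/timestamps"))
  gids <- as.integer(rhdf5::h5read(path, "spikes/gids"))

  if (any(ts < 0)) {
    bad <- unique(gids[ts < 0])
    stop("negative spike times for gid(s): ", paste(bad, collapse = ", "))
  }
  out <- split(ts, gids)
  unsorted <- names(out)[vapply(out, is.unsorted, logical(1))]
  if (length(unsorted))
    stop("unsorted spike times for gid(s): ", paste(unsorted, collapse = ", "))
  out
}
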