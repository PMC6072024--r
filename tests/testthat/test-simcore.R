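test_that("round-robin partition matches gid mod M and balances load", {
  p <- make_partition(0:9, 4)
  expect_equal(which(p$rank == 0) - 1L, c(0, 4, 8))
  expect_equal(which(p$rank == 1) - 1L, c(1, 5, 9))
  expect_equal(which(p$rank == 2) - 1L, c(2, 6))
  expect_equal(which(p$rank == 3) - 1L, c(3, 7))

  expect_true(all(make_partition(0:99, 1)$rank == 0))
  expect_error(make_partition(0:3, 0), "positive")

  for (N in c(1, 7, 10, 23)) for (M in c(1, 2, 3, 5, 8)) {
    counts <- tabulate(make_partition(0:(N - 1), M)$rank + 1L, M)
    expect_lte(max(counts) - min(counts), 1)
  }
})

test_that("LIF threshold crossing matches the closed form", {
  p <- lif_params(tau_m = 10, v_rest = -70, v_thresh = -50, v_reset = -70,
                  r_m = 100, t_ref = 2)
  dt <- 0.1
  first_spike <- function(i_syn, steps = 4000) {
    st <- lif_state(1, p)
    for (s in seq_len(steps)) {
      r <- step_lif(st, p, i_syn, dt)
      st <- r$state
      if (r$spiked[1]) return(s * dt)
    }
    NA_real_
  }
  # t* = tau ln(RI / (RI - (Vth - Vrest)))
  t_star <- 10 * log(30 / (30 - 20))
  expect_lte(abs(first_spike(0.3) - t_star), dt)

  # I = 0: resting potential is a fixed point
  st <- lif_state(1, p)
  for (s in 1:100) st <- step_lif(st, p, 0, dt)$state
  expect_equal(st$v, -70)

  # subthreshold drive (RI < Vth - Vrest) never spikes; asymptote = -51 mV
  expect_true(is.na(first_spike(0.19, steps = 10000)))
  st <- lif_state(1, p)
  for (s in 1:10000) st <- step_lif(st, p, 0.19, dt)$state
  expect_equal(st$v, -70 + 19, tolerance = 1e-6)

  # refractory clamp holds for t_ref after a spike
  st <- lif_state(1, p)
  repeat { r <- step_lif(st, p, 0.5, dt); st <- r$state; if (r$spiked[1]) break }
  for (s in seq_len(as.integer(p$t_ref / dt))) {
    r <- step_lif(st, p, 0.5, dt); st <- r$state
    expect_equal(st$v[1], p$v_reset)
  }
})

test_that("single-compartment cable matches RC charging to 0.5%", {
  m <- discretize(load_swc(soma_swc(10)), 100)
  p <- cable_params(cm = 1, g_pas = 1e-4, e_pas = -70, ra = 100)
  cell <- build_cable_cell(m, p)
  dt <- 0.025; I <- 0.1
  R_in <- 1 / cell$g_leak
  tau <- R_in * cell$C
  st <- cable_state(cell)
  nst <- 4000
  v <- numeric(nst)
  for (s in seq_len(nst)) {
    r <- step_passive_cable(cell, st, dt, i_inj = I)
    st <- r$state
    v[s] <- st$v
  }
  tt <- dt * seq_len(nst)
  v_exact <- p$e_pas + R_in * I * (1 - exp(-tt / tau))
  expect_lt(max(abs(v - v_exact)) / (R_in * I), 0.005)
})

test_that("transmembrane currents obey Kirchhoff's law per step", {
  m <- discretize(load_swc(simple_swc()), 15)
  cell <- build_cable_cell(m, cable_params())
  nseg <- cell$n
  dt <- 0.025

  # no stimulus: sum of currents = 0
  st <- cable_state(cell)
  for (s in 1:50) {
    r <- step_passive_cable(cell, st, dt)
    st <- r$state
    expect_lt(abs(sum(r$currents)), 1e-9 * nseg)
  }

  # somatic injection: sum of currents = injected current, with synaptic
  # conductances active on the dendrite
  inj <- numeric(nseg); inj[cell$soma_segment] <- 0.1
  g <- numeric(nseg); g[nseg] <- 2e-4
  st <- cable_state(cell)
  for (s in 1:200) {
    r <- step_passive_cable(cell, st, dt, i_inj = inj, g_syn = g,
                            g_syn_e = g * 0)
    st <- r$state
    expect_lt(abs(sum(r$currents) - 0.1), 1e-9 * nseg)
  }
})

test_that("conduction delays round to the nearest step, half-steps up", {
  expect_equal(delay_steps(2.0, 0.1), 20L)
  expect_equal(delay_steps(0.25, 0.1), 3L)  # 2.5 steps -> up
  expect_equal(delay_steps(0.24, 0.1), 2L)
  expect_equal(delay_steps(0, 0.1), 0L)
  expect_error(delay_steps(-1, 0.1), ">= 0")
})

test_that("biexp conductance peaks at the synaptic weight and is linear", {
  tau1 <- 0.5; tau2 <- 3; dt <- 0.01; w <- 2e-3
  k <- lfpnet:::.biexp_norm(tau1, tau2)
  tt <- seq(dt, 50, by = dt)
  g <- w * k * (exp(-tt / tau2) - exp(-tt / tau1))
  tp <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  expect_equal(max(g), w, tolerance = 1e-4)
  expect_equal(tt[which.max(g)], tp, tolerance = 1e-2)
  # doubling the weight doubles the whole conductance waveform
  g2 <- (2 * w) * k * (exp(-tt / tau2) - exp(-tt / tau1))
  expect_equal(g2, 2 * g)
})

test_that("Poisson trains have the right mean and exponential intervals", {
  # rate 0: empty
  expect_length(poisson_spike_train(0, 1000, function(ctr) rng_uniform(1, 0, 0, 0, ctr)), 0)

  # 10 Hz for 100 s over 200 independent streams: pooled total ~ Poisson(2e5)
  counts <- vapply(0:199, function(gid) {
    length(poisson_spike_train(10, 1e5,
                               function(ctr) rng_uniform(42, gid, 0, 0, ctr)))
  }, numeric(1))
  total <- sum(counts)
  expect_lt(abs(total - 2e5), 3 * sqrt(2e5))

  # ISIs at constant rate are exponential (KS at alpha = 0.01 on 1e4 ISIs)
  isis <- unlist(lapply(0:9, function(gid) {
    diff(poisson_spike_train(20, 51000,
                             function(ctr) rng_uniform(7, gid, 0, 0, ctr)))
  }))
  expect_gt(length(isis), 1e4)
  ks <- suppressWarnings(stats::ks.test(isis, "pexp", rate = 20 / 1000))
  expect_gt(ks$p.value, 0.01)

  # inhomogeneous profile: per-phase rates within 3 SD
  prof <- data.frame(time = c(0, 500), rate = c(5, 50))
  ts <- poisson_spike_train(prof, 1000,
                            function(ctr) rng_uniform(3, 1, 0, 0, ctr))
  n1 <- sum(ts <= 500); n2 <- sum(ts > 500)
  expect_lt(abs(n1 - 2.5), 3 * sqrt(2.5) + 1)
  expect_lt(abs(n2 - 25), 3 * sqrt(25))
  expect_error(poisson_spike_train(-1, 100, identity), "nonnegative")
})

test_that("spike files round-trip and reject invalid trains", {
  f <- tempfile(fileext = ".h5")
  write_spike_file(f, c(3L, 1L, 2L), c(5.5, 1.0, 3.0))
  tr <- load_external_spikes(f)
  expect_equal(tr[["1"]], 1.0)
  expect_equal(tr[["3"]], 5.5)

  # empty file is valid
  f0 <- tempfile(fileext = ".h5")
  write_spike_file(f0, integer(0), numeric(0))
  expect_length(load_external_spikes(f0), 0)

  # negative times are rejected, naming the gid
  fneg <- tempfile(fileext = ".h5")
  write_spike_file(fneg, c(0L, 1L), c(1, 2))
  rhdf5::h5write(c(-1, 2), fneg, "spikes/timestamps")
  rhdf5::h5closeAll()
  expect_error(load_external_spikes(fneg), "negative.*0")
})
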