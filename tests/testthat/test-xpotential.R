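test_that("point-source transfer resistance has the right value and scaling", {
  # sigma = 0.3 S/m at 10 um: 1/(4 pi 0.3 S/m 10 um) = 0.026526 MOhm,
  # so 1 nA produces 26.53 uV
  R <- point_transfer_resistance(0.3, c(10, 0, 0), c(0, 0, 0))
  expect_equal(R, 1 / (4 * pi * 0.3 * 10), tolerance = 1e-12)
  expect_equal(R * 1 * 1000, 26.53, tolerance = 1e-3)  # uV per nA

  # 1/d: doubling the distance halves the resistance
  R2 <- point_transfer_resistance(0.3, c(20, 0, 0), c(0, 0, 0))
  expect_equal(R2, R / 2)

  expect_error(point_transfer_resistance(0.3, c(0, 0, 0), c(0, 0, 0)),
               "coincides")
})

test_that("line-source resistance equals quadrature of point sources", {
  set.seed(101)  # geometry sampling only; the quantity checked is deterministic
  worst <- 0
  for (i in 1:300) {
    a <- runif(3, -50, 50)
    b <- a + runif(3, -30, 30)
    L <- sqrt(sum((b - a)^2))
    if (L < 0.5) next
    site <- runif(3, -200, 200)
    # keep the site off the segment axis so the unclamped forms agree
    if (line_point_distance(a, b, site) < 1) next
    R <- line_transfer_resistance(0.3, a, b, site)
    Q <- quadrature_line_resistance(0.3, a, b, site)
    worst <- max(worst, abs(R - Q) / Q)
    # endpoint swap symmetry
    expect_equal(line_transfer_resistance(0.3, b, a, site), R,
                 tolerance = 1e-12)
  }
  expect_lt(worst, 1e-6)
})

test_that("line source converges to the point source in the far field", {
  a <- c(0, 0, 0); b <- c(0, 10, 0)  # 10 um segment
  mid <- (a + b) / 2
  for (d in c(1000, 2000, 5000)) {  # >= 100x segment length
    site <- mid + c(d, 0, 0)
    Rl <- line_transfer_resistance(0.3, a, b, site)
    Rp <- point_transfer_resistance(0.3, site, mid)
    expect_lt(abs(Rl - Rp) / Rp, 0.001)
  }
})

test_that("the near-field clamp keeps the potential finite", {
  a <- c(0, 0, 0); b <- c(0, 20, 0)
  on_axis <- c(0, 10, 0)          # on the segment axis
  R <- line_transfer_resistance(0.3, a, b, on_axis, radius = 1)
  expect_true(is.finite(R) && R > 0)
  grazing <- c(0.01, 10, 0)       # closer than the membrane radius
  expect_true(is.finite(line_transfer_resistance(0.3, a, b, grazing, radius = 1)))
  expect_error(line_transfer_resistance(0.3, a, a, on_axis), "degenerate")
})

test_that("transfer matrices are rigid-motion invariant and decay with distance", {
  m <- discretize(load_swc(simple_swc()), 20)
  el <- data.frame(id = 0:4, x = 50, y = seq(-40, 120, length.out = 5), z = 0)
  R0 <- build_transfer_matrix(0.3, el, m$segments)
  expect_equal(dim(R0), c(5L, nrow(m$segments)))

  # translating cell and electrodes together changes nothing
  shift <- c(300, -40, 120)
  segs_t <- lfpnet:::.transform_segments(m$segments, position = shift)
  el_t <- transform(el, x = x + shift[1], y = y + shift[2], z = z + shift[3])
  expect_equal(build_transfer_matrix(0.3, el_t, segs_t), R0, tolerance = 1e-12)

  # a 1x1 matrix is just the line-source resistance
  one <- build_transfer_matrix(0.3, el[1, ], m$segments[1, ])
  expect_equal(one[1, 1],
               line_transfer_resistance(
                 0.3, unlist(m$segments[1, c("ax", "ay", "az")]),
                 unlist(m$segments[1, c("bx", "by", "bz")]),
                 unlist(el[1, c("x", "y", "z")]),
                 radius = m$segments$radius[1]))

  # along a collinear array, entries fall off with distance from the segment
  el_line <- data.frame(id = 0:5, x = 100 * 2^(0:5), y = 0, z = 0)
  Rline <- build_transfer_matrix(0.3, el_line, m$segments[1, , drop = FALSE])
  expect_true(all(diff(Rline[, 1]) < 0))
})

test_that("potentials superpose exactly over cells and currents", {
  m <- discretize(load_swc(simple_swc()), 20)
  el <- data.frame(id = 0:2, x = c(40, 80, 160), y = 10, z = 0)
  RA <- build_transfer_matrix(0.3, el, m$segments)
  RB <- build_transfer_matrix(0.3, el,
                              lfpnet:::.transform_segments(m$segments,
                                                           c(30, 0, 0)))
  IA <- seq_len(ncol(RA)) * 0.01
  IB <- rev(IA)
  phi_joint <- accumulate_lfp(accumulate_lfp(numeric(3), RA, IA), RB, IB)
  phi_sep <- accumulate_lfp(numeric(3), RA, IA) +
    accumulate_lfp(numeric(3), RB, IB)
  expect_identical(phi_joint, phi_sep)
  expect_identical(accumulate_lfp(numeric(3), RA, numeric(ncol(RA))),
                   numeric(3))
  expect_equal(accumulate_lfp(numeric(3), RA, 2 * IA),
               2 * accumulate_lfp(numeric(3), RA, IA))
  expect_error(accumulate_lfp(numeric(2), RA, IA), "shape")
})

test_that("a driven one-compartment cell reproduces the monopole closed form", {
  m <- discretize(load_swc(soma_swc(10)), 100)
  cell <- build_cable_cell(m, cable_params())
  d <- 500
  site <- c(d, 0, 0)
  Rp <- point_transfer_resistance(0.3, site, c(0, 0, 0))
  Rl <- build_transfer_matrix(0.3, data.frame(id = 0, x = d, y = 0, z = 0),
                              m$segments)
  dt <- 0.025
  st <- cable_state(cell)
  tt <- dt * seq_len(2000)
  inj <- 0.05 * sin(2 * pi * tt / 20)
  phi <- numeric(length(tt))
  for (s in seq_along(tt)) {
    r <- step_passive_cable(cell, st, dt, i_inj = inj[s])
    st <- r$state
    # one compartment: net transmembrane current equals the injected current
    expect_lt(abs(r$currents - inj[s]), 1e-12)
    phi[s] <- accumulate_lfp(0, Rl, r$currents)
  }
  expect_lt(max(abs(phi - inj * Rp)), max(abs(inj)) * Rp * 0.005)
})

test_that("a current dipole decays faster than a monopole", {
  # two close segments carrying opposite currents: zero net current
  segs <- data.frame(ax = 0, ay = c(0, 20), az = 0,
                     bx = 0, by = c(10, 30), bz = 0,
                     radius = 1, length = 10, type = 3L, section = 1L,
                     path_dist = 0)
  I <- c(1, -1)
  # probe off the dipole's symmetry plane (where the potential vanishes)
  phi_at <- function(d) {
    R <- build_transfer_matrix(0.3, data.frame(id = 0, x = d, y = -10, z = 0),
                               segs)
    abs(accumulate_lfp(0, R, I))
  }
  d0 <- 400  # > 10x the cell extent (~30 um)
  expect_lt(phi_at(2 * d0) / phi_at(d0), 0.5)
})
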