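# Extracellular potential forward model.
#
# The medium is a homogeneous isotropic volume conductor with conductivity
# sigma.  Each morphological segment is a finite line source carrying its
# transmembrane current uniformly along its length; the potential at an
# electrode site is phi_m = sum_n R_mn * I_n, with transfer resistances R_mn
# computed once per cell at setup.  Units: micrometers, nA, MOhm, mV.  Note
# 1 S/m = 1 uS/um, so with sigma in S/m and distances in um the resistances
# come out in MOhm directly (MOhm x nA = mV).

#' Point-source transfer resistance
#'
#' `R = 1 / (4 pi sigma d)` for a monopolar point source — the far-field limit
#' of the line-source model, used mainly as a cross-check.
#'
#' @param sigma medium conductivity, S/m (> 0).
#' @param site electrode position, 3-vector or m x 3 matrix, micrometers.
#' @param point source position, 3-vector, micrometers.
#' @return transfer resistance(s) in MOhm.
#' @export
point_transfer_resistance <- function(sigma, site, point) {
  stopifnot(sigma > 0)
  site <- unname(rbind(site))
  d <- sqrt((site[, 1] - point[1])^2 + (site[, 2] - point[2])^2 +
              (site[, 3] - point[3])^2)
  if (any(d == 0)) stop("electrode site coincides with the source point")
  as.vector(1 / (4 * pi * sigma * d))
}

#' Line-source transfer resistance
#'
#' Potential per unit current of a finite line segment carrying its current
#' uniformly along its length:
#' `R = 1/(4 pi sigma L) * [asinh((L - t)/r) - asinh(-t/r)]`,
#' where `t` is the longitudinal coordinate of the site's projection measured
#' from endpoint `a` and `r` its radial distance to the segment's axis.  The
#' expression is the exact integral of point sources along the segment and is
#' symmetric under endpoint swap.  `r` is clamped from below to the segment
#' radius: the logarithmic singularity on the axis is unphysical (an
#' electrode cannot sit inside the membrane).
#'
#' @inheritParams point_transfer_resistance
#' @param a,b segment endpoints, 3-vectors, micrometers.
#' @param radius segment radius used as the near-field clamp, micrometers.
#' @return transfer resistance(s) in MOhm, finite and positive.
#' @export
line_transfer_resistance <- function(sigma, a, b, site, radius = 0) {
  stopifnot(sigma > 0)
  L <- sqrt(sum((b - a)^2))
  if (L <= 0) stop("degenerate segment (zero length)")
  site <- unname(rbind(site))
  u <- (b - a) / L
  dx <- sweep(site, 2, a)
  t <- as.vector(dx %*% u)
  r2 <- pmax(rowSums(dx^2) - t^2, 0)
  r <- pmax(sqrt(r2), radius, 1e-9)
  as.vector((asinh((L - t) / r) - asinh(-t / r)) / (4 * pi * sigma * L))
}

#' Read an electrode layout
#'
#' @param path CSV with header columns `id, x, y, z` (positions in
#'   micrometers).
#' @return data.frame with unique ids and finite coordinates.
#' @export
read_electrode_layout <- function(path) {
  el <- utils::read.csv(path)
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(el)))
    stop("electrode file must have columns id, x, y, z: ", path)
  if (anyDuplicated(el$id)) stop("electrode ids must be unique")
  if (any(!is.finite(as.matrix(el[, c("x", "y", "z")]))))
    stop("electrode coordinates must be finite")
  el[need]
}

# rigid placement of a cell's local segment geometry: rotation about the
# y-axis (cortical depth axis) by `rotation` radians, then translation to the
# soma position
.transform_segments <- function(segments, position = c(0, 0, 0), rotation = 0) {
  rot <- function(x, z) {
    cs <- cos(rotation); sn <- sin(rotation)
    list(x = x * cs + z * sn, z = -x * sn + z * cs)
  }
  a <- rot(segments$ax, segments$az)
  b <- rot(segments$bx, segments$bz)
  segments$ax <- a$x + position[1]; segments$az <- a$z + position[3]
  segments$bx <- b$x + position[1]; segments$bz <- b$z + position[3]
  segments$ay <- segments$ay + position[2]
  segments$by <- segments$by + position[2]
  segments
}

#' Transfer-resistance matrix for one cell
#'
#' Computes `R_mn` between every electrode site m and every segment n of a
#' placed cell, once per cell at setup; during a run the per-step potential
#' contribution is just `R %*% I`.
#'
#' @param sigma medium conductivity, S/m.
#' @param electrodes data.frame from [read_electrode_layout()] (or any frame
#'   with x, y, z columns).
#' @param segments discretized segment table in absolute coordinates.
#' @return `m x n` matrix in MOhm.
#' @export
build_transfer_matrix <- function(sigma, electrodes, segments) {
  sites <- as.matrix(electrodes[, c("x", "y", "z")])
  n <- nrow(segments)
  R <- matrix(0, nrow(sites), n)
  for (j in seq_len(n)) {
    R[, j] <- line_transfer_resistance(
      sigma,
      a = c(segments$ax[j], segments$ay[j], segments$az[j]),
      b = c(segments$bx[j], segments$by[j], segments$bz[j]),
      site = sites, radius = segments$radius[j])
  }
  R
}

#' Accumulate one cell's contribution to the extracellular potential
#'
#' `phi <- phi + R %*% I`: superposition over cells is exact, so the total
#' recorded potential is the sum of independently computed per-cell (or
#' per-rank) contributions.
#'
#' @param phi numeric vector, mV per electrode site.
#' @param R the cell's transfer matrix, MOhm.
#' @param currents per-segment transmembrane currents at this step, nA
#'   (outward positive).
#' @return updated potential vector, mV.
#' @export
accumulate_lfp <- function(phi, R, currents) {
  if (length(currents) != ncol(R) || length(phi) != nrow(R))
    stop("shape mismatch between potential vector, transfer matrix and currents")
  phi + as.vector(R %*% currents)
}
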