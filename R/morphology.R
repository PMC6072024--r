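# SWC morphologies: tree reading, section extraction, discretization into
# line segments, and synapse placement under section-type / path-distance
# constraints.
#
# Conventions: coordinates and radii in micrometers; section types follow the
# SWC codes somatic = 1, axonal = 2, basal (dendrite) = 3, apical = 4; path
# distance is measured from the soma center (the first type-1 sample) along
# the tree, and a segment's eligibility is judged by its midpoint distance.

.SWC_TYPES <- c(somatic = 1L, axonal = 2L, basal = 3L, apical = 4L)

.section_name <- function(code) names(.SWC_TYPES)[match(code, .SWC_TYPES)]

#' Load an SWC morphology file
#'
#' Reads a standard 7-column SWC file ('#' comments), validates the tree
#' (unique ids, a single root, parents preceding children, known type codes)
#' and extracts unbranched sections.
#'
#' @param path path to the SWC file.
#' @return an object of class `lfpnet_morphology` with `$points` (the SWC
#'   samples), `$sections` (unbranched chains with type, polyline point
#'   indices, start path distance and length), and `$segments = NULL` until
#'   [discretize()] is called.
#' @export
load_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  if (!any(keep)) stop("SWC file has no samples: ", path)
  tab <- utils::read.table(text = raw[keep], col.names =
    c("id", "type", "x", "y", "z", "radius", "parent"))
  lines <- which(keep)

  if (anyDuplicated(tab$id))
    stop("duplicate sample id at line ", lines[which(duplicated(tab$id))[1]])
  bad_type <- which(!tab$type %in% .SWC_TYPES)
  if (length(bad_type))
    stop("unknown SWC type code ", tab$type[bad_type[1]], " at line ",
         lines[bad_type[1]])
  roots <- which(tab$parent == -1)
  if (length(roots) != 1)
    stop("SWC tree must have exactly one root, found ", length(roots))
  pos_in_file <- match(tab$parent, tab$id)
  bad_parent <- which(tab$parent != -1 &
                        (is.na(pos_in_file) | pos_in_file >= seq_len(nrow(tab))))
  if (length(bad_parent))
    stop("parent id ", tab$parent[bad_parent[1]],
         " missing or not defined before line ", lines[bad_parent[1]])

  pts <- tab
  pts$parent_row <- pos_in_file  # NA for root
  if (!any(pts$type == 1L)) stop("SWC file has no somatic (type 1) sample")

  m <- list(points = pts, sections = .extract_sections(pts), segments = NULL)
  class(m) <- "lfpnet_morphology"
  m
}

# Maximal unbranched chains.  A new section starts at the root, where the
# parent sample has more than one child, or where the type code changes; the
# chain's polyline is prefixed with its attachment point so geometry is
# continuous.  All type-1 samples form the single somatic section.
.extract_sections <- function(pts) {
  n <- nrow(pts)
  nchildren <- tabulate(pts$parent_row[!is.na(pts$parent_row)], nbins = n)
  soma_rows <- which(pts$type == 1L)

  sec_of <- integer(n)  # section index per sample row
  sections <- list()
  add_section <- function(type, rows_polyline, attach_row) {
    sections[[length(sections) + 1L]] <<-
      list(type = type, rows = rows_polyline, attach_row = attach_row)
    length(sections)
  }
  soma_sec <- add_section(1L, soma_rows, NA_integer_)
  sec_of[soma_rows] <- soma_sec

  for (i in seq_len(n)) {
    if (pts$type[i] == 1L) next
    p <- pts$parent_row[i]
    starts <- is.na(p) || pts$type[p] != pts$type[i] || nchildren[p] > 1
    if (starts) {
      rows <- if (!is.na(p)) c(p, i) else i
      sec_of[i] <- add_section(pts$type[i], rows, p)
    } else {
      s <- sec_of[p]
      sections[[s]]$rows <- c(sections[[s]]$rows, i)
      sec_of[i] <- s
    }
  }

  xyz <- as.matrix(pts[, c("x", "y", "z")])
  for (s in seq_along(sections)) {
    rows <- sections[[s]]$rows
    if (length(rows) >= 2) {
      d <- sqrt(rowSums((xyz[rows[-1], , drop = FALSE] -
                           xyz[rows[-length(rows)], , drop = FALSE])^2))
    } else d <- numeric(0)
    sections[[s]]$cum <- c(0, cumsum(d))
    sections[[s]]$length <- sum(d)
  }
  # one-point soma: extent taken as the sample diameter
  if (length(soma_rows) == 1)
    sections[[soma_sec]]$length <- 2 * pts$radius[soma_rows]

  # path distance at each section's start, walking from the soma outwards;
  # sections attaching on (or inside) the soma start at distance 0
  dist_end_of_row <- rep(NA_real_, n)
  dist_end_of_row[soma_rows] <- 0
  order_rows <- seq_len(n)  # parents precede children by construction
  for (s in seq_along(sections)) sections[[s]]$dist_start <- NA_real_
  sections[[soma_sec]]$dist_start <- 0
  for (i in order_rows) {
    if (pts$type[i] == 1L) next
    s <- sec_of[i]
    rows <- sections[[s]]$rows
    if (is.na(sections[[s]]$dist_start)) {
      a <- sections[[s]]$attach_row
      sections[[s]]$dist_start <- if (!is.na(a) && !is.na(dist_end_of_row[a]))
        dist_end_of_row[a] else 0
    }
    k <- match(i, rows)
    dist_end_of_row[i] <- sections[[s]]$dist_start + sections[[s]]$cum[k]
  }
  # attachment topology, used by the cable builder for axial coupling
  for (s in seq_along(sections)) {
    a <- sections[[s]]$attach_row
    if (is.na(a)) {
      sections[[s]]$parent_section <- NA_integer_
      sections[[s]]$attach_arc <- NA_real_
    } else {
      ps <- sec_of[a]
      sections[[s]]$parent_section <- ps
      sections[[s]]$attach_arc <- sections[[ps]]$cum[match(a, sections[[ps]]$rows)]
    }
  }
  lapply(sections, function(s)
    s[c("type", "rows", "cum", "length", "dist_start", "attach_row",
        "parent_section", "attach_arc")])
}

#' @export
print.lfpnet_morphology <- function(x, ...) {
  types <- vapply(x$sections, `[[`, integer(1), "type")
  cat(sprintf("<morphology: %d samples, %d sections (%s)%s>\n",
              nrow(x$points), length(x$sections),
              paste(sprintf("%d %s", tabulate(types, 4)[unique(types)],
                            .section_name(unique(types))), collapse = ", "),
              if (is.null(x$segments)) "" else
                sprintf(", %d segments", nrow(x$segments))))
  invisible(x)
}

#' Total length of non-somatic sections, by type name
#' @param m a morphology.
#' @return named numeric vector of section lengths in micrometers.
#' @export
section_lengths <- function(m) {
  types <- vapply(m$sections, `[[`, integer(1), "type")
  lens <- vapply(m$sections, `[[`, numeric(1), "length")
  out <- tapply(lens, .section_name(types), sum)
  c(out)
}

#' Discretize a morphology into line segments
#'
#' Splits every section into `ceil(length / max_seg_len)` equal-length line
#' segments whose endpoints and radii interpolate the SWC samples linearly.
#' Membrane current is later assumed uniform over each segment, which is why
#' equal-length splitting is used.  The soma is always rendered as a single
#' segment spanning its extent (a one-point soma spans its diameter along y).
#'
#' @param m a morphology from [load_swc()].
#' @param max_seg_len maximum segment length in micrometers (> 0).
#' @return the morphology with `$segments`: a data.frame with endpoint
#'   columns ax..bz, `radius`, `length`, `type`, `section`, and `path_dist`
#'   (midpoint path distance from the soma center).
#' @export
discretize <- function(m, max_seg_len = 20) {
  stopifnot(inherits(m, "lfpnet_morphology"))
  if (!is.numeric(max_seg_len) || max_seg_len <= 0)
    stop("`max_seg_len` must be > 0")
  pts <- m$points
  xyz <- as.matrix(pts[, c("x", "y", "z")])
  segs <- list()
  for (si in seq_along(m$sections)) {
    sec <- m$sections[[si]]
    if (sec$type == 1L) {
      soma_rows <- sec$rows
      if (length(soma_rows) == 1) {
        c0 <- xyz[soma_rows, ]
        r <- pts$radius[soma_rows]
        a <- c0 - c(0, r, 0); b <- c0 + c(0, r, 0)
        len <- 2 * r
      } else {
        a <- xyz[soma_rows[1], ]; b <- xyz[soma_rows[length(soma_rows)], ]
        r <- mean(pts$radius[soma_rows])
        len <- max(sec$length, sqrt(sum((b - a)^2)))
        if (len <= 0) { a <- a - c(0, r, 0); b <- b + c(0, r, 0); len <- 2 * r }
      }
      segs[[length(segs) + 1L]] <- data.frame(
        ax = a[1], ay = a[2], az = a[3], bx = b[1], by = b[2], bz = b[3],
        radius = r, length = len, type = 1L, section = si, path_dist = 0)
      next
    }
    L <- sec$length
    if (L <= 0) next
    nseg <- ceiling(L / max_seg_len)
    breaks <- seq(0, L, length.out = nseg + 1)
    rows <- sec$rows
    interp <- function(s) {  # arc length -> (x, y, z, radius)
      k <- findInterval(s, sec$cum, rightmost.closed = TRUE)
      k <- pmin(pmax(k, 1L), length(rows) - 1L)
      f <- (s - sec$cum[k]) / pmax(sec$cum[k + 1] - sec$cum[k], .Machine$double.eps)
      f <- pmin(pmax(f, 0), 1)
      cbind(xyz[rows[k], , drop = FALSE] * (1 - f) +
              xyz[rows[k + 1], , drop = FALSE] * f,
            pts$radius[rows[k]] * (1 - f) + pts$radius[rows[k + 1]] * f)
    }
    pa <- interp(breaks[-length(breaks)])
    pb <- interp(breaks[-1])
    mid <- interp((breaks[-1] + breaks[-length(breaks)]) / 2)
    segs[[length(segs) + 1L]] <- data.frame(
      ax = pa[, 1], ay = pa[, 2], az = pa[, 3],
      bx = pb[, 1], by = pb[, 2], bz = pb[, 3],
      radius = mid[, 4], length = L / nseg, type = sec$type, section = si,
      path_dist = sec$dist_start + (breaks[-1] + breaks[-length(breaks)]) / 2)
  }
  m$segments <- do.call(rbind, segs)
  rownames(m$segments) <- NULL
  m$max_seg_len <- max_seg_len
  m
}

#' Segments eligible for synapse placement
#'
#' @param m a discretized morphology.
#' @param target_sections character subset of
#'   `c("somatic", "axonal", "basal", "apical")`.
#' @param distance_range `[d_min, d_max]` band of path distance from the soma
#'   center, micrometers; a segment qualifies if its midpoint distance lies in
#'   the band.
#' @return integer vector of qualifying segment row indices (possibly empty).
#' @export
candidate_segments <- function(m, target_sections, distance_range = c(0, Inf)) {
  stopifnot(inherits(m, "lfpnet_morphology"))
  if (is.null(m$segments)) stop("morphology is not discretized; call discretize()")
  if (!length(target_sections) || !all(target_sections %in% names(.SWC_TYPES)))
    stop("`target_sections` must be a nonempty subset of: ",
         paste(names(.SWC_TYPES), collapse = ", "))
  if (length(distance_range) != 2 || distance_range[1] > distance_range[2] ||
      distance_range[1] < 0)
    stop("`distance_range` must be ordered and nonnegative")
  codes <- .SWC_TYPES[target_sections]
  which(m$segments$type %in% codes &
          m$segments$path_dist >= distance_range[1] &
          m$segments$path_dist <= distance_range[2])
}

#' Place synapses on a morphology
#'
#' Draws `n` placements independently: the segment is chosen with probability
#' proportional to its length among the candidates, the offset uniformly in
#' [0, 1] along it.  Randomness comes from the supplied counter-based stream,
#' so placements are reproducible and independent of evaluation order.
#'
#' @param m a discretized morphology.
#' @inheritParams candidate_segments
#' @param n number of synapses to place (>= 1).
#' @param stream `function(counter)` returning `n` uniforms per counter value.
#' @return data.frame with columns `segment` (row index into `m$segments`)
#'   and `offset`.
#' @export
place_synapses <- function(m, target_sections, distance_range, n, stream) {
  cand <- candidate_segments(m, target_sections, distance_range)
  if (!length(cand))
    stop(sprintf("no candidate segments for sections [%s], distance range [%g, %g]",
                 paste(target_sections, collapse = ", "),
                 distance_range[1], distance_range[2]))
  stopifnot(n >= 1)
  lens <- m$segments$length[cand]
  cum <- cumsum(lens) / sum(lens)
  pick <- findInterval(stream(0), cum) + 1L
  pick <- pmin(pick, length(cand))
  data.frame(segment = cand[pick], offset = stream(1))
}
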