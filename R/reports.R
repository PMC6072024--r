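# Buffered simulation recorders.
#
# Each report accumulates step data in memory and flushes to a per-rank
# temporary HDF5 file every `buffer_steps` steps, so long runs never hold the
# full recording in RAM and the flushed prefix of a temp file is readable
# while the simulation is still going.  At the end of a run the per-rank
# files are merged: spikes are concatenated and sorted by (time, gid),
# voltage traces are concatenated by gid, extracellular contributions are
# summed elementwise.  Final file content is independent of both the buffer
# size and the rank count.
#
# A report class provides three hooks — begin, step, end — registered under
# its variable name; user-defined classes can be plugged in the same way.

.report_registry <- new.env(parent = emptyenv())

.report_variables <- function() ls(.report_registry)

#' Register a report class
#'
#' @param variable name used in `reports[].variable` config entries.
#' @param constructor `function(cfg, ctx)` returning an environment with
#'   function fields `begin()`, `step(data, step)` and `end()`; `ctx` carries
#'   `dt`, `nsteps`, the partition, gid list, and output/temp directories.
#' @export
register_report_class <- function(variable, constructor) {
  stopifnot(is.character(variable), is.function(constructor))
  assign(variable, constructor, envir = .report_registry)
  invisible(variable)
}

#' Instantiate a report recorder
#' @param cfg one validated `reports[]` config entry.
#' @param ctx simulation context (see [register_report_class()]).
#' @return recorder environment.
#' @export
make_report <- function(cfg, ctx) {
  ctor <- get(cfg$variable, envir = .report_registry, inherits = FALSE)
  ctor(cfg, ctx)
}

# ---- extendible HDF5 stream writers -------------------------------------------
#
# Appends happen on every buffer flush, which with buffer_steps = 1 means
# every time step; the writer therefore keeps low-level file/dataset handles
# open for the whole run and extends + hyperslab-writes through them, with an
# explicit H5Fflush after each append so the flushed prefix is readable by
# other processes mid-run.

.h5_stream_open <- function(path, names, ncols, modes) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  for (i in seq_along(names)) {
    if (is.na(ncols[i])) {
      rhdf5::h5createDataset(path, names[i], dims = 0,
                             maxdims = rhdf5::H5Sunlimited(),
                             storage.mode = modes[i], chunk = 1024)
    } else {
      rhdf5::h5createDataset(path, names[i], dims = c(0, ncols[i]),
                             maxdims = c(rhdf5::H5Sunlimited(), ncols[i]),
                             storage.mode = modes[i],
                             chunk = c(1024, max(ncols[i], 1)))
    }
  }

  w <- new.env(parent = emptyenv())
  w$path <- path
  w$fid <- rhdf5::H5Fopen(path)
  w$did <- lapply(names, function(nm) rhdf5::H5Dopen(w$fid, nm))
  names(w$did) <- names
  w$ncols <- ncols; names(w$ncols) <- names
  w$nrow <- numeric(length(names)); names(w$nrow) <- names
  w
}

.h5_stream_append <- function(w, name, x) {
  did <- w$did[[name]]
  nc <- w$ncols[[name]]
  n0 <- w$nrow[[name]]
  if (is.na(nc)) {              # 1-D dataset
    k <- length(x)
    if (k > 0) {
      rhdf5::H5Dset_extent(did, n0 + k)
      sid <- rhdf5::H5Dget_space(did)
      rhdf5::H5Sselect_hyperslab(sid, start = n0 + 1, count = k)
      msid <- rhdf5::H5Screate_simple(k)
      rhdf5::H5Dwrite(did, x, h5spaceMem = msid, h5spaceFile = sid)
      rhdf5::H5Sclose(sid); rhdf5::H5Sclose(msid)
    }
  } else {
    k <- nrow(x)
    if (k > 0) {
      rhdf5::H5Dset_extent(did, c(n0 + k, nc))
      sid <- rhdf5::H5Dget_space(did)
      rhdf5::H5Sselect_hyperslab(sid, start = c(n0 + 1, 1), count = c(k, nc))
      msid <- rhdf5::H5Screate_simple(c(k, nc))
      rhdf5::H5Dwrite(did, x, h5spaceMem = msid, h5spaceFile = sid)
      rhdf5::H5Sclose(sid); rhdf5::H5Sclose(msid)
    }
  }
  w$nrow[[name]] <- n0 + k
  rhdf5::H5Fflush(w$fid)
  invisible(w)
}

.h5_stream_close <- function(w) {
  for (d in w$did) rhdf5::H5Dclose(d)
  rhdf5::H5Fclose(w$fid)
  invisible(w$path)
}

# ---- spike report ------------------------------------------------------------

.spike_report <- function(cfg, ctx) {
  rec <- new.env(parent = emptyenv())
  rec$cfg <- cfg; rec$ctx <- ctx
  M <- ctx$partition$M
  rank_of_gid <- ctx$partition$rank
  tmp <- function(k) file.path(ctx$tmp_dir, sprintf("spikes_rank%d.h5", k))
  rec$flush_log <- integer(0)

  rec$begin <- function() {
    rec$buf_t <- vector("list", M); rec$buf_g <- vector("list", M)
    rec$steps_in_buf <- 0L
    rec$writers <- lapply(seq_len(M) - 1L, function(k)
      .h5_stream_open(tmp(k), c("timestamps", "gids"), c(NA, NA),
                      c("double", "integer")))
  }
  flush <- function() {
    for (k in seq_len(M)) {
      ts <- unlist(rec$buf_t[[k]]); g <- unlist(rec$buf_g[[k]])
      if (is.null(ts)) { ts <- numeric(0); g <- integer(0) }
      .h5_stream_append(rec$writers[[k]], "timestamps", as.double(ts))
      .h5_stream_append(rec$writers[[k]], "gids", as.integer(g))
      rec$buf_t[[k]] <- list(); rec$buf_g[[k]] <- list()
    }
    rec$flush_log <- c(rec$flush_log, rec$steps_in_buf)
    rec$steps_in_buf <- 0L
  }
  rec$step <- function(data, step) {
    g <- data$spike_gids
    if (length(g)) {
      rk <- rank_of_gid[g + 1L] + 1L
      for (k in unique(rk)) {
        sel <- rk == k
        rec$buf_t[[k]] <- c(rec$buf_t[[k]], list(rep(data$t, sum(sel))))
        rec$buf_g[[k]] <- c(rec$buf_g[[k]], list(g[sel]))
      }
    }
    rec$steps_in_buf <- rec$steps_in_buf + 1L
    if (rec$steps_in_buf >= cfg$buffer_steps) flush()
  }
  rec$end <- function() {
    if (rec$steps_in_buf > 0L) flush()
    for (w in rec$writers) .h5_stream_close(w)
    ts <- numeric(0); g <- integer(0)
    for (k in seq_len(M)) {
      f <- tmp(k - 1L)
      if (!file.exists(f)) stop("missing rank temp file: ", f)
      ts <- c(ts, as.double(rhdf5::h5read(f, "timestamps")))
      g <- c(g, as.integer(rhdf5::h5read(f, "gids")))

    }
    final <- file.path(ctx$out_dir, cfg$file)
    write_spike_file(final, g, ts)
    for (k in seq_len(M)) file.remove(tmp(k - 1L))
    final
  }
  rec
}

# ---- timeseries reports (somatic voltage, extracellular potential) -----------

# shared machinery: a steps x channels matrix buffered per rank
.timeseries_report <- function(cfg, ctx, channels_of_rank, row_fn, merge_fn) {
  rec <- new.env(parent = emptyenv())
  rec$cfg <- cfg; rec$ctx <- ctx
  M <- ctx$partition$M
  tmp <- function(k) file.path(ctx$tmp_dir,
                               sprintf("%s_rank%d.h5", cfg$variable, k))
  nch <- vapply(seq_len(M), function(k) channels_of_rank(k - 1L), integer(1))
  rec$flush_log <- integer(0)

  rec$begin <- function() {
    rec$buf <- lapply(seq_len(M), function(k)
      matrix(0, cfg$buffer_steps, nch[k]))
    rec$fill <- 0L
    rec$total_rows <- 0L
    rec$writers <- lapply(seq_len(M), function(k)
      if (nch[k] > 0) .h5_stream_open(tmp(k - 1L), "data", nch[k], "double"))
  }
  flush <- function() {
    for (k in seq_len(M)) {
      if (nch[k] == 0) next
      block <- rec$buf[[k]][seq_len(rec$fill), , drop = FALSE]
      .h5_stream_append(rec$writers[[k]], "data", block)
    }
    rec$total_rows <- rec$total_rows + rec$fill
    rec$flush_log <- c(rec$flush_log, rec$fill)
    rec$fill <- 0L
  }
  rec$step <- function(data, step) {
    rec$fill <- rec$fill + 1L
    for (k in seq_len(M))
      if (nch[k] > 0) rec$buf[[k]][rec$fill, ] <- row_fn(data, k - 1L)
    if (rec$fill >= cfg$buffer_steps) flush()
  }
  rec$end <- function() {
    if (rec$fill > 0L) flush()
    for (w in rec$writers) if (!is.null(w)) .h5_stream_close(w)
    per_rank <- lapply(seq_len(M), function(k) {
      if (nch[k] == 0) return(matrix(0, rec$total_rows, 0))
      f <- tmp(k - 1L)
      if (!file.exists(f)) stop("missing rank temp file: ", f)
      d <- matrix(rhdf5::h5read(f, "data"), ncol = nch[k])

      d
    })
    final <- file.path(ctx$out_dir, cfg$file)
    merge_fn(final, per_rank)
    for (k in seq_len(M)) if (nch[k] > 0) file.remove(tmp(k - 1L))
    final
  }
  rec
}

.write_timeseries_file <- function(path, data, time, extra = list()) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "report")
  rhdf5::h5write(data, path, "report/data")
  rhdf5::h5write(as.double(time), path, "report/time")
  for (nm in names(extra)) rhdf5::h5write(extra[[nm]], path,
                                          paste0("report/", nm))

  invisible(path)
}

.vsoma_report <- function(cfg, ctx) {
  sel <- if (identical(cfg$node_ids, "all")) ctx$gids
         else as.integer(unlist(cfg$node_ids))
  sel <- sort(sel)
  rank_of <- ctx$partition$rank[match(sel, ctx$partition$gids)]
  gids_of_rank <- function(k) sel[rank_of == k]
  rec <- .timeseries_report(
    cfg, ctx,
    channels_of_rank = function(k) length(gids_of_rank(k)),
    row_fn = function(data, k) data$v_soma[match(gids_of_rank(k), ctx$gids)],
    merge_fn = function(final, per_rank) {
      nsteps <- nrow(per_rank[[1]])
      out <- matrix(0, nsteps, length(sel))
      for (k in seq_along(per_rank)) {
        cols <- match(gids_of_rank(k - 1L), sel)
        if (length(cols)) out[, cols] <- per_rank[[k]]
      }
      .write_timeseries_file(final, out, ctx$dt * seq_len(nsteps),
                             list(gids = as.integer(sel)))
    })
  rec
}

.extracellular_report <- function(cfg, ctx) {
  el <- read_electrode_layout(cfg$electrode_file)
  nsites <- nrow(el)
  rec <- .timeseries_report(
    cfg, ctx,
    channels_of_rank = function(k) nsites,
    # engine supplies per-rank partial potentials: sum over the rank's cells
    row_fn = function(data, k) data$phi_by_rank[k + 1L, ],
    merge_fn = function(final, per_rank) {
      out <- Reduce(`+`, per_rank)
      .write_timeseries_file(final, out, ctx$dt * seq_len(nrow(out)),
                             list(channel_id = as.integer(el$id)))
    })
  rec$electrodes <- el
  rec$sigma <- cfg$sigma
  rec
}

.init_report_classes <- function() {
  register_report_class("spikes", .spike_report)
  register_report_class("v_soma", .vsoma_report)
  register_report_class("extracellular", .extracellular_report)
}
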