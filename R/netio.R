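# Persistence of the type-instance relational network description.
#
# Per network <name>, four files: <name>_nodes.h5 and <name>_edges.h5 hold
# the per-instance columns (ids plus per-instance arrays, nothing shared);
# <name>_node_types.csv and <name>_edge_types.csv hold one row per type with
# every shared property.  Editing a type-level value (say a synapse weight)
# therefore never touches the binary instance tables.

#' File set of a persisted network
#'
#' @param directory directory holding the files.
#' @param name network name.
#' @return object of class `lfpnet_fileset` with the four file paths.
#' @export
network_fileset <- function(directory, name) {
  fs <- list(
    name = name,
    nodes_file = file.path(directory, paste0(name, "_nodes.h5")),
    node_types_file = file.path(directory, paste0(name, "_node_types.csv")),
    edges_file = file.path(directory, paste0(name, "_edges.h5")),
    edge_types_file = file.path(directory, paste0(name, "_edge_types.csv")))
  class(fs) <- "lfpnet_fileset"
  fs
}

.VECTOR_TYPE_PROPS <- c("target_sections", "distance_range")

.encode_csv_value <- function(v, prop) {
  if (is.null(v)) return(NA)
  if (is.function(v) || is.environment(v) || (is.list(v) && !is.null(dim(v))))
    stop("unserializable property value: ", prop)
  if (is.list(v)) v <- unlist(v)
  if (!is.atomic(v)) stop("unserializable property value: ", prop)
  if (length(v) > 1) paste(v, collapse = ",") else v
}

.types_to_csv_table <- function(types, id_col) {
  all_names <- unique(unlist(lapply(types, function(t) names(t$props))))
  rows <- lapply(types, function(t) {
    row <- list()
    row[[id_col]] <- t[[id_col]]
    for (nm in all_names) row[[nm]] <- .encode_csv_value(t$props[[nm]], nm)
    row
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

.csv_table_to_types <- function(df, id_col) {
  lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, setdiff(names(df), id_col), drop = FALSE])
    props <- props[!vapply(props, function(v) length(v) == 1 && is.na(v), logical(1))]
    for (nm in intersect(names(props), .VECTOR_TYPE_PROPS)) {
      parts <- strsplit(as.character(props[[nm]]), ",", fixed = TRUE)[[1]]
      props[[nm]] <- if (nm == "distance_range") as.numeric(parts) else parts
    }
    out <- list(props = props)
    out[[id_col]] <- as.integer(df[[id_col]][i])
    out
  })
}

.write_column_group <- function(path, group, cols) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  parts <- strsplit(group, "/", fixed = TRUE)[[1]]
  for (i in seq_along(parts))
    rhdf5::h5createGroup(path, paste(parts[seq_len(i)], collapse = "/"))
  id_cols <- intersect(c("node_id", "node_type_id", "source_node_id",
                         "target_node_id", "edge_type_id", "nsyns"), names(cols))
  for (nm in c(id_cols, sort(setdiff(names(cols), id_cols)))) {
    v <- cols[[nm]]
    if (is.logical(v)) v <- as.integer(v)
    if (is.character(v)) v[is.na(v)] <- ""
    rhdf5::h5write(v, path, paste0(group, "/", nm))
  }

  invisible(path)
}

.read_column_group <- function(path, group) {
  info <- rhdf5::h5ls(path)
  names_in <- info$name[info$group == paste0("/", group) & info$otype == "H5I_DATASET"]
  out <- lapply(names_in, function(nm) {
    v <- rhdf5::h5read(path, paste0(group, "/", nm))
    if (is.array(v)) v <- as.vector(v)
    v
  })

  names(out) <- names_in
  out
}

#' Save a network to its relational file set
#'
#' Instance tables go to HDF5 (one dataset per column, node/edge ids sorted
#' deterministically), shared type-level properties to small editable CSVs.
#'
#' @param net a network (nodes added; edges built or absent).
#' @param directory output directory (created if needed).
#' @return the [network_fileset()] written.
#' @export
save_network <- function(net, directory) {
  stopifnot(inherits(net, "lfpnet_network"))
  .check_integrity(net)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  fs <- network_fileset(directory, net$name)

  node_cols <- c(list(node_id = seq_len(net$n_nodes) - 1L,
                      node_type_id = as.integer(net$nodes$node_type_id)),
                 net$nodes$props)
  for (nm in names(net$nodes$props)) {
    v <- net$nodes$props[[nm]]
    if (!is.atomic(v)) stop("unserializable property value: ", nm)
  }
  .write_column_group(fs$nodes_file, paste0("nodes/", net$name), node_cols)

  nt <- .types_to_csv_table(net$node_types, "node_type_id")
  if (is.null(nt)) nt <- data.frame(node_type_id = integer(0))
  utils::write.csv(nt, fs$node_types_file, row.names = FALSE, na = "")

  ed <- net$edges
  o <- order(ed$edge_type_id, ed$target_node_id, ed$source_node_id)
  .write_column_group(fs$edges_file, paste0("edges/", net$name), list(
    source_node_id = ed$source_node_id[o], target_node_id = ed$target_node_id[o],
    edge_type_id = ed$edge_type_id[o], nsyns = ed$nsyns[o]))

  et <- .types_to_csv_table(net$edge_types, "edge_type_id")
  if (is.null(et)) et <- data.frame(edge_type_id = integer(0))
  utils::write.csv(et, fs$edge_types_file, row.names = FALSE, na = "")
  invisible(fs)
}

.check_integrity <- function(net) {
  ed <- net$edges
  nt_ids <- vapply(net$node_types, `[[`, integer(1), "node_type_id")
  if (length(net$nodes$node_type_id) && !all(net$nodes$node_type_id %in% nt_ids))
    stop("dangling node_type_id in node table")
  et_ids <- vapply(net$edge_types, function(t) t$edge_type_id, integer(1))
  if (length(ed$edge_type_id) && !all(ed$edge_type_id %in% et_ids))
    stop("dangling edge_type_id in edge table")
  if (length(ed$target_node_id) &&
      (any(ed$target_node_id < 0) || any(ed$target_node_id >= net$n_nodes)))
    stop("edge target gid out of range")
  if (any(ed$nsyns < 1)) stop("edge with nsyns < 1")
  invisible(TRUE)
}

#' Load a network from its relational file set
#'
#' Reconstructs the in-memory network (equal to the saved one up to
#' provenance) without re-executing any connection rule; cost is proportional
#' to the table sizes.
#'
#' @param fileset a [network_fileset()].
#' @return an `lfpnet_network`.
#' @export
load_network <- function(fileset) {
  stopifnot(inherits(fileset, "lfpnet_fileset"))
  for (f in c(fileset$nodes_file, fileset$node_types_file,
              fileset$edges_file, fileset$edge_types_file))
    if (!file.exists(f)) stop("missing network file: ", f)

  net <- create_network(fileset$name)
  node_cols <- .read_column_group(fileset$nodes_file, paste0("nodes/", fileset$name))
  ntypes <- utils::read.csv(fileset$node_types_file, na.strings = "")
  net$node_types <- .csv_table_to_types(ntypes, "node_type_id")
  n <- length(node_cols$node_id)
  net$n_nodes <- n
  net$nodes$node_type_id <- as.integer(node_cols$node_type_id)
  net$nodes$props <- node_cols[setdiff(names(node_cols),
                                       c("node_id", "node_type_id"))]
  nt_ids <- vapply(net$node_types, `[[`, integer(1), "node_type_id")
  dangling <- setdiff(unique(net$nodes$node_type_id), nt_ids)
  if (length(dangling))
    stop("dangling node_type_id(s) in node table: ",
         paste(dangling, collapse = ", "))

  edge_cols <- .read_column_group(fileset$edges_file, paste0("edges/", fileset$name))
  etypes <- utils::read.csv(fileset$edge_types_file, na.strings = "")
  net$edge_types <- .csv_table_to_types(etypes, "edge_type_id")
  net$edges <- list(source_node_id = as.integer(edge_cols$source_node_id),
                    target_node_id = as.integer(edge_cols$target_node_id),
                    edge_type_id = as.integer(edge_cols$edge_type_id),
                    nsyns = as.integer(edge_cols$nsyns))
  et_ids <- vapply(net$edge_types, `[[`, integer(1), "edge_type_id")
  dangling <- setdiff(unique(net$edges$edge_type_id), et_ids)
  if (length(dangling))
    stop("dangling edge_type_id(s) in edge table: ",
         paste(dangling, collapse = ", "))
  net
}

.MANDATORY_NODE_KEYS <- list(
  biophysical = c("model_template", "dynamics_params", "morphology_file"),
  intfire = c("model_template", "dynamics_params"),
  virtual = character(0))
.MANDATORY_EDGE_KEYS <- c("syn_weight", "delay", "dynamics_params")

#' Validate a persisted network file set
#'
#' Collects (rather than stops on) findings: missing files, dangling type
#' ids, missing mandatory simulator keys, malformed distance ranges, negative
#' delays.  An empty report means the file set is loadable and simulatable.
#'
#' @param fileset a [network_fileset()].
#' @return data.frame with columns `where` and `message`; zero rows if clean.
#' @export
validate_fileset <- function(fileset) {
  findings <- list()
  note <- function(where, message)
    findings[[length(findings) + 1L]] <<- data.frame(where = where, message = message)

  missing <- !vapply(c(fileset$nodes_file, fileset$node_types_file,
                       fileset$edges_file, fileset$edge_types_file),
                     file.exists, logical(1))
  if (any(missing)) {
    for (f in c(fileset$nodes_file, fileset$node_types_file,
                fileset$edges_file, fileset$edge_types_file)[missing])
      note("files", paste("missing file:", f))
    return(do.call(rbind, findings))
  }
  net <- tryCatch(load_network(fileset), error = function(e) {
    note("load", conditionMessage(e)); NULL
  })
  if (is.null(net)) return(do.call(rbind, findings))

  type_of_node <- net$nodes$node_type_id
  nt_ids <- vapply(net$node_types, `[[`, integer(1), "node_type_id")
  for (t in net$node_types) {
    mt <- t$props$model_type
    wh <- paste0("node_type ", t$node_type_id)
    if (is.null(mt)) { note(wh, "missing model_type"); next }
    if (!mt %in% names(.MANDATORY_NODE_KEYS)) {
      note(wh, paste("unknown model_type:", mt)); next
    }
    for (k in .MANDATORY_NODE_KEYS[[mt]])
      if (is.null(t$props[[k]])) note(wh, paste("missing", k))
  }

  bio_types <- nt_ids[vapply(net$node_types, function(t)
    identical(t$props$model_type, "biophysical"), logical(1))]
  for (t in net$edge_types) {
    wh <- paste0("edge_type ", t$edge_type_id)
    for (k in .MANDATORY_EDGE_KEYS)
      if (is.null(t$props[[k]])) note(wh, paste("missing", k))
    if (!is.null(t$props$delay) && t$props$delay < 0)
      note(wh, "negative delay")
    dr <- t$props$distance_range
    if (!is.null(dr) && (length(dr) != 2 || anyNA(dr) || dr[1] < 0 || dr[1] > dr[2]))
      note(wh, "malformed distance_range")
    ts <- t$props$target_sections
    if (!is.null(ts) && !all(ts %in% .SECTION_NAMES))
      note(wh, "unknown target_sections")
    member <- net$edges$edge_type_id == t$edge_type_id
    if (any(member)) {
      tgt_types <- type_of_node[net$edges$target_node_id[member] + 1L]
      if (any(tgt_types %in% bio_types) && (is.null(ts) || !length(ts)))
        note(wh, "biophysical targets but no target_sections")
    }
  }
  out <- do.call(rbind, findings)
  if (is.null(out)) out <- data.frame(where = character(0), message = character(0))
  out
}
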