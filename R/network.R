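# Rule-based network builder.
#
# A network is built in two passes: node populations are appended with
# add_nodes(), each call defining one node type (the properties shared by all
# members) plus per-instance arrays; connection rules are registered with
# add_edges() and only instantiated by build_edges().  Properties therefore
# live in a type-instance relational model: anything shared sits once in the
# type table, per-cell/per-connection values sit in columnar instance tables.

#' Create an empty network
#'
#' @param name nonempty string identifying the network (also used to
#'   namespace cell gids when several networks are simulated together).
#' @return an object of class `lfpnet_network` (environment-backed, so
#'   `add_nodes()`/`add_edges()` modify it in place).
#' @export
create_network <- function(name) {
  if (!is.character(name) || length(name) != 1 || is.na(name) || !nzchar(name))
    stop("network `name` must be a nonempty string")
  net <- new.env(parent = emptyenv())
  net$name <- name
  net$node_types <- list()
  net$nodes <- list(node_type_id = integer(0), props = list())
  net$n_nodes <- 0L
  net$edge_types <- list()
  net$edge_rules <- list()
  net$edges <- .empty_edges()
  net$built_seed <- NULL
  class(net) <- "lfpnet_network"
  net
}

.empty_edges <- function() {
  list(source_node_id = integer(0), target_node_id = integer(0),
       edge_type_id = integer(0), nsyns = integer(0))
}

.RESERVED_NODE_KEYS <- c("node_id", "node_type_id")
# "virtual" marks source-only populations (external inputs): never simulated,
# so they carry no dynamics
.MODEL_TYPES <- c("biophysical", "intfire", "virtual")
.SECTION_NAMES <- c("somatic", "axonal", "basal", "apical")

#' @export
print.lfpnet_network <- function(x, ...) {
  cat(sprintf("<lfpnet network '%s': %d nodes (%d types), %d edges (%d types, %d rules)>\n",
              x$name, x$n_nodes, length(x$node_types),
              length(x$edges$source_node_id), length(x$edge_types),
              length(x$edge_rules)))
  invisible(x)
}

#' Add a population of nodes
#'
#' Each call creates one node type holding the shared properties given in
#' `...`, and appends `N` node instances with contiguous gids continuing from
#' the current maximum.  Per-instance values go in `per_node`: vectors of
#' length `N`, or an `N x 3` matrix for `positions` (stored as x, y, z in
#' micrometers).
#'
#' @param net a network from [create_network()].
#' @param N number of nodes to add (>= 1).
#' @param ... shared (type-level) properties as name = scalar pairs.  For
#'   simulation, `model_type` must be "biophysical" or "intfire" ("virtual"
#'   marks source-only external populations),
#'   `model_template` names the cell model, and `dynamics_params` (plus
#'   `morphology_file` for biophysical types) reference component files.
#' @param per_node named list of per-instance arrays.
#' @return the new `node_type_id` (invisibly).
#' @export
add_nodes <- function(net, N, ..., per_node = list()) {
  stopifnot(inherits(net, "lfpnet_network"))
  if (!is.numeric(N) || length(N) != 1 || is.na(N) || N < 1 || N != floor(N))
    stop("`N` must be a positive integer")
  N <- as.integer(N)
  shared <- list(...)
  if (length(shared) && (is.null(names(shared)) || any(!nzchar(names(shared)))))
    stop("all shared properties must be named")
  per_node <- .normalize_per_node(per_node, N)
  bad <- intersect(c(names(shared), names(per_node)), .RESERVED_NODE_KEYS)
  if (length(bad))
    stop("reserved property name(s): ", paste(bad, collapse = ", "))
  clash <- intersect(names(shared), names(per_node))
  if (length(clash))
    stop("property name(s) in both shared and per-node sets: ",
         paste(clash, collapse = ", "))
  if (!is.null(shared$model_type) && !shared$model_type %in% .MODEL_TYPES)
    stop("model_type must be one of: ", paste(.MODEL_TYPES, collapse = ", "))
  # collisions with properties used by other node types are allowed (that is
  # the point of heterogeneous populations); collisions within one call are not

  type_id <- length(net$node_types)  # 0-based sequential
  net$node_types[[length(net$node_types) + 1L]] <-
    list(node_type_id = type_id, props = shared)

  net$nodes$node_type_id <- c(net$nodes$node_type_id, rep.int(type_id, N))
  old_n <- net$n_nodes
  for (nm in union(names(net$nodes$props), names(per_node))) {
    have <- net$nodes$props[[nm]]
    if (is.null(have)) have <- rep(NA, old_n)
    add <- per_node[[nm]]
    if (is.null(add)) add <- rep(NA, N)
    net$nodes$props[[nm]] <- c(have, add)
  }
  net$n_nodes <- old_n + N
  invisible(type_id)
}

.normalize_per_node <- function(per_node, N) {
  if (!is.list(per_node)) stop("`per_node` must be a named list")
  if (length(per_node) && (is.null(names(per_node)) || any(!nzchar(names(per_node)))))
    stop("all per-node properties must be named")
  out <- list()
  for (nm in names(per_node)) {
    v <- per_node[[nm]]
    if (nm == "positions") {
      v <- as.matrix(v)
      if (nrow(v) != N || ncol(v) != 3)
        stop("`positions` must be an N x 3 matrix")
      if (any(!is.finite(v))) stop("positions must be finite")
      out$x <- as.numeric(v[, 1]); out$y <- as.numeric(v[, 2])
      out$z <- as.numeric(v[, 3])
    } else {
      if (!is.atomic(v) || length(v) != N)
        stop(sprintf("per-node property '%s' has length %d, expected N = %d",
                     nm, length(v), N))
      out[[nm]] <- v
    }
  }
  out
}

# Merged (type + instance) property table; instance columns win on collision,
# which add_nodes() forbids anyway.  NA marks properties a node lacks.
.node_table <- function(net) {
  n <- net$n_nodes
  df <- data.frame(node_id = seq_len(n) - 1L,
                   node_type_id = net$nodes$node_type_id)
  type_of <- match(net$nodes$node_type_id,
                   vapply(net$node_types, `[[`, integer(1), "node_type_id"))
  type_props <- unique(unlist(lapply(net$node_types, function(t) names(t$props))))
  for (nm in setdiff(type_props, names(net$nodes$props))) {
    vals <- lapply(net$node_types, function(t) {
      v <- t$props[[nm]]
      if (is.null(v) || length(v) != 1 || !is.atomic(v)) NA else v
    })
    df[[nm]] <- unlist(vals)[type_of]
  }
  for (nm in names(net$nodes$props)) df[[nm]] <- net$nodes$props[[nm]]
  df
}

#' Query nodes by property predicate
#'
#' The predicate sees type-level and instance-level properties in one merged
#' namespace.  A node lacking a referenced property is a non-match, never an
#' error, so heterogeneous populations stay queryable.
#'
#' @param net a network.
#' @param predicate `NULL` (match all), a named list of property = value
#'   pairs (all must match), or a function taking the named list of one
#'   node's properties and returning `TRUE` to match.
#' @return `data.frame` of matching nodes in ascending gid order, with the
#'   merged property columns.
#' @export
query_nodes <- function(net, predicate = NULL) {
  df <- .node_table(net)
  df[.query_mask(df, predicate), , drop = FALSE]
}

.query_mask <- function(df, predicate) {
  n <- nrow(df)
  if (is.null(n)) n <- 0L
  if (is.null(predicate)) return(rep(TRUE, n))
  if (is.list(predicate) && !is.function(predicate)) {
    keep <- rep(TRUE, n)
    for (nm in names(predicate)) {
      col <- df[[nm]]
      if (is.null(col)) return(rep(FALSE, n))
      keep <- keep & !is.na(col) & col %in% predicate[[nm]]
    }
    return(keep)
  }
  if (is.function(predicate)) {
    vapply(seq_len(n), function(i) {
      props <- as.list(df[i, , drop = FALSE])
      props <- props[!vapply(props, function(v) length(v) == 1 && is.na(v), logical(1))]
      isTRUE(tryCatch(predicate(props), error = function(e) FALSE))
    }, logical(1))
  } else stop("predicate must be NULL, a named list, or a function")
}

#' Register a connection rule between two node selections
#'
#' Registration is deferred: no pairs are enumerated until [build_edges()].
#' Each call defines one edge type carrying the shared connection properties
#' in `...` (for simulation: `syn_weight`, `delay` in ms, `model_template`,
#' `dynamics_params`, and for biophysical targets `target_sections` and
#' `distance_range` in micrometers; `weight_function` optionally names a
#' registered modulation function).
#'
#' @param net target network (owns the created edges).
#' @param source_query,target_query node predicates as in [query_nodes()].
#' @param connection_rule function `(source, target, ...params, stream)`
#'   returning an integer number of synapses (0 = unconnected) for one pair,
#'   or a vectorized builder rule such as [distance_tapered_probability()].
#'   `stream`, when accepted, is `function(counter)` yielding uniforms from
#'   the pair's own counter-based stream.
#' @param connection_params named list passed to the rule.
#' @param ... shared edge-type properties.
#' @param source_network source population; defaults to `net` itself.  Use an
#'   external population's network to wire feed-forward inputs.
#' @return the new `edge_type_id` (invisibly).
#' @export
add_edges <- function(net, source_query = NULL, target_query = NULL,
                      connection_rule, connection_params = list(), ...,
                      source_network = NULL) {
  stopifnot(inherits(net, "lfpnet_network"))
  if (!is.function(connection_rule)) stop("`connection_rule` must be a function")
  props <- list(...)
  .validate_edge_type_props(props)
  if (is.null(source_network)) source_network <- net
  stopifnot(inherits(source_network, "lfpnet_network"))
  props$source_network <- source_network$name

  edge_type_id <- length(net$edge_types)
  net$edge_types[[length(net$edge_types) + 1L]] <-
    list(edge_type_id = edge_type_id, props = props)
  net$edge_rules[[length(net$edge_rules) + 1L]] <- list(
    edge_type_id = edge_type_id,
    source_query = source_query, target_query = target_query,
    rule = connection_rule, params = connection_params,
    source_network = source_network)
  invisible(edge_type_id)
}

.validate_edge_type_props <- function(props) {
  if (!is.null(props$delay) && (!is.numeric(props$delay) || props$delay < 0))
    stop("`delay` must be >= 0 ms")
  dr <- props$distance_range
  if (!is.null(dr)) {
    if (!is.numeric(dr) || length(dr) != 2 || any(is.na(dr)) ||
        dr[1] < 0 || dr[1] > dr[2])
      stop("`distance_range` must be [d_min, d_max] with 0 <= d_min <= d_max")
  }
  ts <- props$target_sections
  if (!is.null(ts) && !all(ts %in% .SECTION_NAMES))
    stop("`target_sections` must be a subset of: ",
         paste(.SECTION_NAMES, collapse = ", "))
  wf <- props$weight_function
  if (!is.null(wf) && !.weight_function_exists(wf))
    stop("unknown weight_function: ", wf)
  invisible(TRUE)
}

#' Instantiate all registered connection rules
#'
#' Every (source, target) pair in each rule's query cross-product is passed
#' to the rule, which returns the synapse count `nsyns` for that pair; pairs
#' with `nsyns >= 1` become edge records.  All randomness inside rules draws
#' from counter-based streams keyed by `(seed, edge_type_id, source_gid,
#' target_gid)`, so the resulting edge table is independent of iteration
#' order and of any parallel chunking, and a rerun with the same seed is
#' identical.
#'
#' @param net a network with at least one registered rule.
#' @param seed integer build seed.
#' @return total edge count (invisibly).
#' @export
build_edges <- function(net, seed = 0) {
  stopifnot(inherits(net, "lfpnet_network"))
  if (!length(net$edge_rules)) stop("no edge rules registered")
  bseed <- .derive_seed(seed, .SEED_BUILD)
  cols <- list(source_node_id = list(), target_node_id = list(),
               edge_type_id = list(), nsyns = list())
  for (r in net$edge_rules) {
    src_df <- query_nodes(r$source_network, r$source_query)
    tgt_df <- query_nodes(net, r$target_query)
    if (!nrow(src_df) || !nrow(tgt_df)) next
    res <- .run_rule(r, src_df, tgt_df, bseed)
    keep <- res$nsyns >= 1L
    cols$source_node_id[[length(cols$source_node_id) + 1L]] <- res$sgid[keep]
    cols$target_node_id[[length(cols$target_node_id) + 1L]] <- res$tgid[keep]
    cols$edge_type_id[[length(cols$edge_type_id) + 1L]] <-
      rep.int(r$edge_type_id, sum(keep))
    cols$nsyns[[length(cols$nsyns) + 1L]] <- res$nsyns[keep]
  }
  net$edges <- lapply(cols, function(x) as.integer(unlist(x)))
  names(net$edges) <- c("source_node_id", "target_node_id",
                        "edge_type_id", "nsyns")
  net$built_seed <- seed
  invisible(length(net$edges$source_node_id))
}

# Pair iteration is target-major (target gid ascending, then source gid
# ascending); with counter-based streams the order only fixes the row order
# of the output table, not its content.
.run_rule <- function(r, src_df, tgt_df, bseed) {
  e <- r$edge_type_id
  sgid_all <- src_df$node_id
  tgid_all <- tgt_df$node_id
  src_hash <- .hash_string(r$source_network$name)
  grid <- list(
    s = rep(seq_along(sgid_all), times = length(tgid_all)),
    t = rep(seq_along(tgid_all), each = length(sgid_all)))
  sgid <- sgid_all[grid$s]
  tgid <- tgid_all[grid$t]
  # namespace source gids by network (exact 32-bit arithmetic: a plain double
  # product would round away the gid)
  key2 <- .u32(sgid + .mul32(2654435761, src_hash))

  if (isTRUE(attr(r$rule, "vectorized"))) {
    stream <- function(counter = 0) rng_uniform(bseed, e, key2, tgid, counter)
    nsyns <- do.call(r$rule, c(list(source = src_df[grid$s, , drop = FALSE],
                                    target = tgt_df[grid$t, , drop = FALSE],
                                    stream = stream), r$params))
  } else {
    takes_stream <- "stream" %in% names(formals(r$rule))
    nsyns <- vapply(seq_along(sgid), function(i) {
      args <- c(list(source = as.list(src_df[grid$s[i], , drop = FALSE]),
                     target = as.list(tgt_df[grid$t[i], , drop = FALSE])),
                r$params)
      if (takes_stream)
        args$stream <- local({
          k2 <- key2[i]; tg <- tgid[i]
          function(counter = 0) rng_uniform(bseed, e, k2, tg, counter)
        })
      as.numeric(do.call(r$rule, args))
    }, numeric(1))
  }
  bad <- which(!is.finite(nsyns) | nsyns < 0 | nsyns != floor(nsyns))
  if (length(bad)) {
    i <- bad[1]
    stop(sprintf(
      "connection rule for edge type %d returned invalid nsyns (%s) for pair source=%d target=%d",
      e, format(nsyns[i]), sgid[i], tgid[i]))
  }
  list(sgid = sgid, tgid = tgid, nsyns = as.integer(nsyns))
}

#' Distance-tapered connection probability rule
#'
#' Connects a pair with probability `p = p0 * exp(-d^2 / (2 sigma^2))` where
#' `d` is the planar (x, z) Euclidean distance between somata in micrometers;
#' connected pairs receive a uniform integer synapse count in `nsyns_range`.
#' Draws come from the per-pair counter-based stream, so builds are
#' order-independent.  Pass as `connection_rule` to [add_edges()] with
#' `connection_params = list(p0 = , sigma = , nsyns_range = )`.
#'
#' @param source,target node property tables (rows paired).
#' @param p0 peak connection probability at distance 0, in [0, 1].
#' @param sigma lateral falloff scale, micrometers (> 0).
#' @param nsyns_range integer `[lo, hi]`, `1 <= lo <= hi`.
#' @param stream per-pair uniform stream (supplied by the builder).
#' @return integer vector of synapse counts (0 = unconnected).
#' @export
distance_tapered_probability <- local({
  f <- function(source, target, p0, sigma, nsyns_range = c(1, 1), stream) {
    if (p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
    if (sigma <= 0) stop("sigma must be > 0")
    lo <- nsyns_range[1]; hi <- nsyns_range[2]
    if (lo < 1 || lo > hi) stop("nsyns_range must satisfy 1 <= lo <= hi")
    need <- c("x", "z")
    if (!all(need %in% names(source)) || !all(need %in% names(target)) ||
        anyNA(source$x) || anyNA(source$z) || anyNA(target$x) || anyNA(target$z))
      stop("distance_tapered_probability requires node positions")
    d2 <- (source$x - target$x)^2 + (source$z - target$z)^2
    p <- p0 * exp(-d2 / (2 * sigma^2))
    connected <- stream(0) < p
    n <- as.integer(lo + floor(stream(1) * (hi - lo + 1)))
    ifelse(connected, pmin(n, hi), 0L)
  }
  attr(f, "vectorized") <- TRUE
  f
})

# ---- weight-function registry -----------------------------------------------

.wf_registry <- new.env(parent = emptyenv())

#' Register a synaptic weight-modulation function
#'
#' Weight functions scale an edge type's `syn_weight` per connection at
#' simulation setup, e.g. to implement tuning-dependent weights.  The
#' function receives the edge-type property list and the source and target
#' node property lists and returns a nonnegative multiplier.
#'
#' @param name registry name referenced by `weight_function` edge properties.
#' @param fn `function(edge_props, source, target)` returning a scalar
#'   multiplier.
#' @export
register_weight_function <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name), is.function(fn))
  assign(name, fn, envir = .wf_registry)
  invisible(name)
}

.weight_function_exists <- function(name) {
  exists(name, envir = .wf_registry, inherits = FALSE)
}

.get_weight_function <- function(name) {
  if (is.null(name)) return(function(edge_props, source, target) 1)
  if (!.weight_function_exists(name)) stop("unknown weight_function: ", name)
  get(name, envir = .wf_registry, inherits = FALSE)
}

# identity default plus a tuning-difference example used in fixtures
.init_weight_functions <- function() {
  register_weight_function("identity", function(edge_props, source, target) 1)
  register_weight_function("gaussian_tuning", function(edge_props, source, target) {
    if (is.null(source$tuning_angle) || is.null(target$tuning_angle)) return(1)
    dth <- abs(source$tuning_angle - target$tuning_angle) %% 360
    dth <- pmin(dth, 360 - dth)
    exp(-(dth / 90)^2)
  })
}
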