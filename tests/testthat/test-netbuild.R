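test_that("networks start empty and names are validated", {
  net <- create_network("V1")
  expect_equal(net$n_nodes, 0L)
  expect_length(net$edges$source_node_id, 0)
  expect_length(net$node_types, 0)
  other <- create_network("LGN")
  expect_false(identical(net, other))
  expect_error(create_network(""), "nonempty")
  expect_error(create_network(NULL), "nonempty")
})

test_that("add_nodes appends contiguous gids and one node type per call", {
  net <- create_network("n")
  t1 <- add_nodes(net, 3, pop_name = "a")
  t2 <- add_nodes(net, 2, pop_name = "b")
  expect_equal(net$n_nodes, 5L)
  expect_length(net$node_types, 2)
  expect_false(t1 == t2)
  df <- query_nodes(net)
  expect_equal(df$node_id, 0:4)

  # per-node arrays must match N exactly
  expect_error(add_nodes(net, 4, per_node = list(v = 1:5)), "length 5")
  expect_error(add_nodes(net, 0), "positive")
  expect_error(add_nodes(net, 2, node_id = 7), "reserved")
  expect_error(add_nodes(net, 2, x = 1, per_node = list(x = c(1, 2))), "both")
  expect_error(add_nodes(net, 2, model_type = "hoc"), "model_type")
  expect_error(
    add_nodes(net, 2, per_node = list(positions = matrix(0, 3, 3))), "N x 3")
})

test_that("queries use a merged namespace and missing properties never error", {
  net <- create_network("fig3")
  add_nodes(net, 4, pop_name = "exc", model_type = "biophysical",
            model_template = "passive_cable", morphology_file = "m.swc",
            dynamics_params = "p.json",
            per_node = list(positions = matrix(seq_len(12), 4, 3)))
  add_nodes(net, 2, pop_name = "inh", model_type = "intfire",
            model_template = "lif", dynamics_params = "l.json")

  expect_equal(nrow(query_nodes(net)), 6)
  exc <- query_nodes(net, list(pop_name = "exc"))
  expect_equal(exc$node_id, 0:3)
  # predicate over a property the LIF nodes lack matches only biophysical
  has_morph <- query_nodes(net, function(p) !is.null(p$morphology_file))
  expect_equal(has_morph$node_id, 0:3)
  # brute-force cross-check of the list-query against the merged table
  tab <- query_nodes(net)
  expect_equal(query_nodes(net, list(model_type = "intfire"))$node_id,
               tab$node_id[tab$model_type == "intfire" & !is.na(tab$model_type)])
  # function predicate referencing nothing sensible is a non-match, not error
  expect_equal(nrow(query_nodes(net, function(p) p$absent > 1)), 0)
})

test_that("add_edges registers deferred rules and fails fast on bad props", {
  net <- create_network("n")
  add_nodes(net, 3, pop_name = "a")
  e1 <- add_edges(net, NULL, NULL, function(source, target) 1L,
                  syn_weight = 1, delay = 1, dynamics_params = "d.json")
  e2 <- add_edges(net, NULL, NULL, function(source, target) 1L,
                  syn_weight = 1, delay = 1, dynamics_params = "d.json")
  expect_false(e1 == e2)
  expect_length(net$edge_rules, 2)
  expect_length(net$edges$source_node_id, 0)  # nothing instantiated yet

  expect_error(add_edges(net, NULL, NULL, function(s, t) 1,
                         weight_function = "no_such_fn"), "weight_function")
  expect_error(add_edges(net, NULL, NULL, function(s, t) 1,
                         distance_range = c(500, 400)), "distance_range")
  expect_error(add_edges(net, NULL, NULL, function(s, t) 1, delay = -1),
               "delay")
  expect_error(add_edges(net, NULL, NULL, function(s, t) 1,
                         target_sections = "dendrite"), "target_sections")
})

test_that("build_edges enumerates the query cross-product", {
  net <- create_network("n")
  add_nodes(net, 3, pop_name = "src")
  add_nodes(net, 2, pop_name = "tgt")
  add_edges(net, list(pop_name = "src"), list(pop_name = "tgt"),
            function(source, target) 1L,
            syn_weight = 1, delay = 1, dynamics_params = "d.json")
  expect_equal(build_edges(net, 0), 6L)
  # pair iteration is target-major, gids ascending
  expect_equal(net$edges$target_node_id, rep(3:4, each = 3))
  expect_equal(net$edges$source_node_id, rep(0:2, 2))

  # rule returning zero connects nothing; empty selection is fine
  net2 <- create_network("n2")
  add_nodes(net2, 3, pop_name = "a")
  add_edges(net2, NULL, NULL, function(source, target) 0L)
  add_edges(net2, list(pop_name = "ghost"), NULL, function(source, target) 1L)
  expect_equal(build_edges(net2, 0), 0L)

  # invalid nsyns is an error naming the offending pair
  net3 <- create_network("n3")
  add_nodes(net3, 2, pop_name = "a")
  add_edges(net3, NULL, NULL, function(source, target) -1)
  expect_error(build_edges(net3, 0), "source=0 target=0")
  net4 <- create_network("n4")
  add_nodes(net4, 1, pop_name = "a")
  add_edges(net4, NULL, NULL, function(source, target) 0.5)
  expect_error(build_edges(net4, 0), "invalid nsyns")
})

test_that("builds are reproducible under a seed and seed-sensitive", {
  build_tab <- function(seed) {
    net <- two_pop_network(12, 4, seed = seed)
    net$edges
  }
  expect_identical(build_tab(5), build_tab(5))
  a <- build_tab(5); b <- build_tab(6)
  expect_false(identical(a, b))
})

test_that("rebuilding with an added rule leaves earlier edge types unchanged", {
  make <- function(two_rules) {
    net <- create_network("n")
    add_nodes(net, 6, pop_name = "a",
              per_node = list(positions = cbind(seq_len(6) * 10, 0, 0)))
    add_edges(net, NULL, NULL, distance_tapered_probability,
              list(p0 = 0.7, sigma = 50, nsyns_range = c(1, 2)),
              syn_weight = 1, delay = 1, dynamics_params = "d.json")
    if (two_rules)
      add_edges(net, NULL, NULL, fixed_probability, list(p = 0.5),
                syn_weight = 1, delay = 1, dynamics_params = "d.json")
    build_edges(net, 3)
    net$edges
  }
  one <- make(FALSE); two <- make(TRUE)
  keep <- two$edge_type_id == 0L
  expect_identical(one$source_node_id, two$source_node_id[keep])
  expect_identical(one$target_node_id, two$target_node_id[keep])
  expect_identical(one$nsyns, two$nsyns[keep])
})

test_that("distance-tapered rule matches its closed-form connection rate", {
  # 100 x 100 pairs all at planar distance 100 um
  net <- create_network("mc")
  add_nodes(net, 100, pop_name = "src",
            per_node = list(positions = cbind(0, seq_len(100), 0)))
  add_nodes(net, 100, pop_name = "tgt",
            per_node = list(positions = cbind(100, seq_len(100), 0)))
  add_edges(net, list(pop_name = "src"), list(pop_name = "tgt"),
            distance_tapered_probability,
            list(p0 = 0.5, sigma = 100, nsyns_range = c(1, 1)),
            syn_weight = 1, delay = 1, dynamics_params = "d.json")
  n_edges <- build_edges(net, 17)
  p_expect <- 0.5 * exp(-0.5)
  n_pairs <- 1e4
  expect_lt(abs(n_edges / n_pairs - p_expect),
            3 * sqrt(p_expect * (1 - p_expect) / n_pairs))

  # degenerate probabilities
  net0 <- create_network("p0")
  add_nodes(net0, 5, pop_name = "a",
            per_node = list(positions = matrix(0, 5, 3)))
  add_edges(net0, NULL, NULL, distance_tapered_probability,
            list(p0 = 0, sigma = 10))
  expect_equal(build_edges(net0, 1), 0L)
  net1 <- create_network("p1")
  add_nodes(net1, 5, pop_name = "a",
            per_node = list(positions = matrix(0, 5, 3)))
  add_edges(net1, NULL, NULL, distance_tapered_probability,
            list(p0 = 1, sigma = 10))
  expect_equal(build_edges(net1, 1), 25L)  # d = 0, p = 1: all pairs

  # missing positions is an error
  netp <- create_network("nopos")
  add_nodes(netp, 2, pop_name = "a")
  add_edges(netp, NULL, NULL, distance_tapered_probability,
            list(p0 = 0.5, sigma = 10))
  expect_error(build_edges(netp, 1), "positions")
})

test_that("referential integrity holds after building", {
  net <- two_pop_network(10, 4, seed = 1)
  ed <- net$edges
  expect_true(all(ed$target_node_id %in% 0:13))
  expect_true(all(ed$source_node_id %in% 0:13))
  expect_true(all(ed$edge_type_id %in%
                    vapply(net$edge_types, `[[`, integer(1), "edge_type_id")))
  expect_true(all(ed$nsyns >= 1))
})
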