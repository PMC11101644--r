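triangle_map <- function() {
  edges_map(data.frame(source = c("a", "b", "c"), sign = "activation",
                       target = c("b", "c", "a")))
}

star_map <- function(leaves) {
  edges_map(data.frame(source = "hub", sign = "activation",
                       target = paste0("leaf", seq_len(leaves))))
}

test_that("hand-computable graphs give exact metric values", {
  tri <- topology_report(triangle_map(), "undirected")
  expect_equal(tri$clustering_coefficient, 1)
  expect_equal(tri$diameter, 1)
  expect_equal(tri$n_connected_components, 1)
  expect_equal(tri$density, 1)

  path3 <- topology_report(edges_map(data.frame(
    source = c("a", "b"), sign = "activation", target = c("b", "c"))),
    "undirected")
  expect_equal(path3$diameter, 2)
  expect_equal(path3$characteristic_path_length, 4 / 3)
  expect_equal(path3$radius, 1)
  expect_equal(path3$avg_neighbours, 4 / 3)

  expect_error(topology_report(empty_map(character(0))),
               class = "emtmap_contract_error")
})

test_that("multi-edge pairs, self-loops and modes are accounted separately", {
  edf <- data.frame(source = c("a", "b", "a", "c", "c"),
                    sign = c("activation", "inhibition", "activation",
                             "activation", "activation"),
                    target = c("b", "a", "b", "c", "d"))
  map <- edges_map(edf)
  rep_d <- topology_report(map, "directed")
  expect_equal(rep_d$n_self_loops, 1)
  expect_equal(rep_d$multi_edge_node_pairs, 1)  # the a/b pair (3 edges)
  expect_equal(rep_d$n_edges, 4)                # self-loop excluded
  rep_u <- topology_report(map, "undirected")
  expect_equal(rep_u$n_edges_simple, 2)
  expect_lte(rep_u$n_edges_simple, rep_d$n_edges_simple)
  expect_equal(rep_u$n_connected_components,
               rep_d$n_connected_components)
})

test_that("path statistics match a brute-force BFS oracle on random graphs", {
  for (seed in c(3, 11, 27, 44, 61, 78)) {
    map <- random_test_map(seed)
    want <- oracle_path_stats(map)
    got <- topology_report(map, "undirected")
    expect_equal(got$diameter, want$diameter, info = sprintf("seed %d", seed))
    expect_equal(got$radius, want$radius, info = sprintf("seed %d", seed))
    expect_equal(got$characteristic_path_length, want$cpl,
                 info = sprintf("seed %d", seed))
  }
})

test_that("MCC scores are exact on canonical graphs and random graphs", {
  tri <- mcc_scores(triangle_map())
  expect_equal(unname(tri$scores[c("a", "b", "c")]), rep(2, 3))

  star <- mcc_scores(star_map(3))
  expect_equal(unname(star$scores["hub"]), 3)
  expect_equal(unname(star$scores["leaf1"]), 1)

  k4 <- edges_map(data.frame(
    source = c("a", "a", "a", "b", "b", "c"), sign = "activation",
    target = c("b", "c", "d", "c", "d", "d")))
  expect_equal(unname(mcc_scores(k4)$scores), rep(6, 4))

  for (seed in c(2, 16, 58)) {
    map <- random_test_map(seed, n_max = 10)
    expect_equal(mcc_scores(map)$scores, oracle_mcc(map),
                 info = sprintf("seed %d", seed))
  }
})

test_that("MCC ranking is deterministic and permutation-equivariant", {
  map <- random_test_map(7)
  r1 <- mcc_scores(map)
  expect_equal(r1$ranked_ids,
               r1$ranked_ids[order(-r1$scores[r1$ranked_ids],
                                   r1$ranked_ids, method = "radix")])
  # relabel nodes: scores must follow the relabelling
  perm <- stats::setNames(paste0("x", rev(seq_len(n_species(map)))),
                          map$species$id)
  map2 <- map
  map2$species$id <- unname(perm[map$species$id])
  map2$species$name <- map2$species$id
  map2$interactions$target <- unname(perm[map$interactions$target])
  map2$interactions$sources <- lapply(map$interactions$sources,
                                      function(s) unname(perm[s]))
  r2 <- mcc_scores(map2)
  expect_equal(unname(r2$scores[unname(perm[names(r1$scores)])]),
               unname(r1$scores))
})

test_that("top-k subnetworks are induced sub-maps preserving signs", {
  map <- emt_core_fixture()
  ranking <- mcc_scores(map)
  whole <- top_k_subnetwork(ranking, n_species(map), map)
  expect_equal(n_interactions(whole), n_interactions(map))

  star <- star_map(3)
  top1 <- top_k_subnetwork(mcc_scores(star), 1, star)
  expect_equal(n_species(top1), 1)
  expect_equal(n_interactions(top1), 0)
  expect_equal(top1$species$id, "hub")

  sub <- top_k_subnetwork(ranking, 8, map)
  se <- interaction_edges(sub)
  fe <- interaction_edges(map)
  for (i in seq_len(nrow(se))) {
    match_row <- fe[fe$source == se$source[i] & fe$target == se$target[i], ]
    expect_equal(se$sign[i], match_row$sign[1])
  }
  expect_error(top_k_subnetwork(ranking, 0, map),
               class = "emtmap_contract_error")
})

test_that("degree distributions count every node and power-law fits work", {
  star <- star_map(10)
  dd <- degree_distribution(star, "undirected")
  expect_equal(sum(dd$counts$n_nodes), 11)
  expect_equal(dd$counts$degree, c(1, 10))
  expect_error(fit_power_law(dd), class = "emtmap_fit_error")

  # preferential-attachment graph: exponent in the scale-free range
  set.seed(404)
  g <- igraph::sample_pa(2000, m = 2, directed = TRUE)
  el <- igraph::as_edgelist(g)
  pa_map <- edges_map(data.frame(source = paste0("v", el[, 1]),
                                 sign = "activation",
                                 target = paste0("v", el[, 2])),
                      ids = paste0("v", seq_len(2000)))
  fit <- fit_power_law(degree_distribution(pa_map, "undirected"))
  expect_gt(fit$exponent, 2)
  expect_lt(fit$exponent, 3.5)
  expect_gt(fit$r_squared, 0.7)
})
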