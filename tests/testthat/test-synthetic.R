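test_that("random map generation is seed-deterministic and spec-exact", {
  spec <- synthetic_map_spec(n_nodes = 50, n_edges = 100,
                             inhibition_fraction = 0.3, seed = 7)
  m1 <- generate_random_map(spec)
  m2 <- generate_random_map(spec)
  expect_identical(m1$species, m2$species)
  expect_identical(m1$interactions, m2$interactions)
  expect_equal(n_species(m1), 50)
  expect_equal(n_interactions(m1), 100)
  edges <- interaction_edges(m1)
  expect_false(any(edges$source == edges$target))
  expect_false(any(duplicated(paste(edges$source, edges$target))))
  expect_equal(nrow(validate_map(m1)), 0)

  # zero inhibition fraction means zero inhibitory edges
  m0 <- generate_random_map(synthetic_map_spec(20, 40,
                                               inhibition_fraction = 0,
                                               seed = 3))
  expect_false(any(interaction_edges(m0)$sign == "inhibition"))

  # input nodes are never targets
  mi <- generate_random_map(synthetic_map_spec(15, 30, input_nodes = 3,
                                               seed = 5))
  inputs <- synthetic_node_ids <- sprintf("n%02d", 1:3)
  expect_false(any(interaction_edges(mi)$target %in% inputs))

  expect_error(synthetic_map_spec(4, 40), class = "emtmap_spec_error")
})

test_that("motif injection is verbatim, idempotent and conflict-checked", {
  spec <- synthetic_map_spec(
    n_nodes = 10, n_edges = 12, seed = 11,
    motifs = list(list(kind = "mutual_inhibition", nodes = c("n09", "n10"))))
  map <- generate_random_map(spec)
  edges <- interaction_edges(map)
  expect_true(any(edges$source == "n09" & edges$target == "n10" &
                    edges$sign == "inhibition"))
  expect_true(any(edges$source == "n10" & edges$target == "n09" &
                    edges$sign == "inhibition"))
  # motif nodes are isolated from the random wiring
  other <- edges[!(edges$source %in% c("n09", "n10") &
                     edges$target %in% c("n09", "n10")), ]
  expect_false(any(c(other$source, other$target) %in% c("n09", "n10")))

  base <- empty_map(c("a", "b"))
  nf <- inject_motif(base, list(kind = "negative_feedback",
                                nodes = c("a", "b")))
  e <- interaction_edges(nf)
  expect_equal(e$sign[e$source == "a"], "activation")
  expect_equal(e$sign[e$source == "b"], "inhibition")
  # input map untouched, repeat injection is a no-op
  expect_equal(n_interactions(base), 0)
  again <- inject_motif(nf, list(kind = "negative_feedback",
                                 nodes = c("a", "b")))
  expect_equal(n_interactions(again), n_interactions(nf))

  expect_error(inject_motif(nf, list(kind = "mutual_inhibition",
                                     nodes = c("a", "b"))),
               class = "emtmap_conflict_error")
})

test_that("the EMT-core fixture matches its shipped manifest exactly", {
  map <- emt_core_fixture()
  manifest <- jsonlite::fromJSON(system.file("extdata",
                                             "emt_core_manifest.json",
                                             package = "emtmap"),
                                 simplifyVector = FALSE)
  expect_equal(n_species(map), manifest$n_species)
  expect_equal(n_interactions(map), manifest$n_interactions)
  sm <- summarize_map(map)
  expect_equal(as.list(sm$species_by_kind), manifest$species_by_kind)
  edges <- interaction_edges(map)
  for (me in manifest$edges) {
    hit <- edges$source == me$source & edges$target == me$target &
      edges$sign == me$sign
    expect_true(any(hit),
                info = sprintf("%s -%s-> %s", me$source, me$sign, me$target))
  }
  # the shipped edge table reproduces the in-code fixture
  csv <- read_edge_table(
    system.file("extdata", "emt_core_edges.csv", package = "emtmap"),
    dialect = list(source = "source", sign = "sign", target = "target",
                   id = "id", category = "category",
                   source_kind = "source_kind", target_kind = "target_kind"))
  expect_setequal(csv$species$id, map$species$id)
  expect_equal(n_interactions(csv), n_interactions(map))
})

test_that("the fixture wires the curated feedback architecture", {
  edges <- interaction_edges(emt_core_fixture())
  has <- function(s, sg, t) any(edges$source == s & edges$sign == sg &
                                  edges$target == t)
  # miR-200/ZEB and miR-34/SNAIL mutual inhibition
  expect_true(has("miR200", "inhibition", "ZEB"))
  expect_true(has("ZEB", "inhibition", "miR200"))
  expect_true(has("miR34", "inhibition", "SNAIL"))
  expect_true(has("SNAIL", "inhibition", "miR34"))
  # NF-kB/NKILA negative feedback
  expect_true(has("NFKB", "activation", "NKILA"))
  expect_true(has("NKILA", "inhibition", "NFKB"))
  # AKT/TWIST double-positive feedback and the GSK-3beta brake
  expect_true(has("AKT", "activation", "TWIST"))
  expect_true(has("TWIST", "activation", "AKT"))
  expect_true(has("AKT", "inhibition", "GSK3B"))
  expect_true(has("GSK3B", "inhibition", "SNAIL"))
  # logic inference yields exactly one input: the TGFB stimulus
  expect_equal(infer_rules(emt_core_fixture())$inputs, "TGFB")
})

test_that("planted negative feedback oscillates; mutual inhibition does not", {
  flags <- function(kind, seeds) {
    vapply(seeds, function(s) {
      spec <- synthetic_map_spec(
        n_nodes = 12, n_edges = 18, inhibition_fraction = 0.3,
        motifs = list(list(kind = kind, nodes = c("n11", "n12"))), seed = s)
      model <- infer_rules(generate_random_map(spec))
      prof <- activity_profile(model,
                               sim_config(n_steps = 3000, initial = "random",
                                          seed = s + 1000),
                               window = 100, ensemble = 3)
      detect_oscillation(prof, "n11")$oscillating
    }, logical(1))
  }
  seeds <- 1:15
  expect_gt(mean(flags("negative_feedback", seeds)), 0.9)
  expect_lt(mean(flags("mutual_inhibition", seeds + 100)), 0.1)
})
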