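two_node_negfb <- function() {
  # A activates B, B inhibits A; A additionally has rule NOT B (no input)
  infer_rules(edges_map(data.frame(source = c("A", "B"),
                                   sign = c("activation", "inhibition"),
                                   target = c("B", "A"))))
}

test_that("synchronous steps apply every rule simultaneously", {
  model <- infer_rules(edges_map(data.frame(
    source = c("A", "I"), sign = c("activation", "inhibition"),
    target = c("T", "T"))))
  s <- state_vec(model, c(A = 1, I = 0, T = 0)[model$node_order])
  nxt <- sync_step(model, s)
  expect_true(nxt[["T"]])
  # a fixed point maps to itself
  expect_equal(sync_step(model, nxt), nxt)
  # incomplete states violate the contract
  expect_error(sync_step(model, c(A = 1)), class = "emtmap_contract_error")
})

test_that("the 2-node negative feedback has the period-4 synchronous orbit", {
  model <- two_node_negfb()
  s <- state_vec(model, c(A = TRUE, B = FALSE)[model$node_order])
  orbit <- list(s)
  for (i in 1:4) orbit[[i + 1]] <- sync_step(model, orbit[[i]])
  get <- function(i) unname(orbit[[i]][c("A", "B")])
  expect_equal(get(2), c(TRUE, TRUE))
  expect_equal(get(3), c(FALSE, TRUE))
  expect_equal(get(4), c(FALSE, FALSE))
  expect_equal(get(5), get(1))
})

test_that("simulation is reproducible and honours clamps", {
  model <- infer_rules(emt_core_fixture())
  mk <- emt_marker_config()
  cfg <- sim_config(n_steps = 400, clamps = c(TGFB = 1),
                    initial = "epithelial", seed = 42, markers = mk)
  t1 <- simulate_model(model, cfg)
  t2 <- simulate_model(model, cfg)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$updated_node_log, t2$updated_node_log)
  expect_true(all(t1$states[, "TGFB"]))
  expect_true(all(t1$states %in% c(TRUE, FALSE)))

  cfg0 <- sim_config(n_steps = 400, clamps = c(TGFB = 0),
                     initial = "epithelial", seed = 42, markers = mk)
  expect_false(any(simulate_model(model, cfg0)$states[-1, "TGFB"]))
  expect_error(sim_config(n_steps = 0), class = "emtmap_config_error")
  expect_error(simulate_model(model, sim_config(initial = "mesenchymal",
                                                n_steps = 10)),
               class = "emtmap_config_error")
})

test_that("a fractional clamp matches its probability within binomial error", {
  model <- infer_rules(edges_map(data.frame(source = "X", sign = "activation",
                                            target = "Y")))
  p <- 0.3
  n <- 4000
  cfg <- sim_config(n_steps = n, clamps = c(X = p), initial = "random",
                    seed = 99)
  tr <- simulate_model(model, cfg)
  frac <- mean(tr$states[-1, "X"])
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("activity profiles echo clamps and decay of unsupported nodes", {
  model <- infer_rules(edges_map(data.frame(source = "X", sign = "activation",
                                            target = "Y")))
  cfg <- sim_config(n_steps = 500, clamps = c(X = 1), initial = "random",
                    seed = 3)
  prof <- activity_profile(model, cfg, window = 50, ensemble = 10)
  expect_equal(unname(prof$values[, "X"]), rep(1, 10))
  expect_true(all(prof$values >= 0 & prof$values <= 1))
  # identical base seed, identical profile (cross-module reproducibility)
  prof2 <- activity_profile(model, cfg, window = 50, ensemble = 10)
  expect_identical(prof$values, prof2$values)
  expect_error(activity_profile(model, cfg, window = 501),
               class = "emtmap_config_error")
})

test_that("exhaustive attractors match the hand-enumerated small cases", {
  # single self-activator: both constant states are fixed points
  self_act <- infer_rules(edges_map(data.frame(source = "A",
                                               sign = "activation",
                                               target = "A")))
  aset <- attractors_exhaustive(self_act, "asynchronous")
  expect_length(aset$attractors, 2)
  expect_true(all(vapply(aset$attractors, `[[`, character(1), "type") ==
                    "fixed_point"))

  # mutual inhibition: exactly the two opposite fixed points
  mut <- infer_rules(edges_map(data.frame(source = c("A", "B"),
                                          sign = "inhibition",
                                          target = c("B", "A"))))
  aset <- attractors_exhaustive(mut, "asynchronous")
  expect_length(aset$attractors, 2)
  states <- do.call(rbind, lapply(aset$attractors, `[[`, "states"))
  expect_setequal(paste(states[, "A"], states[, "B"]),
                  c("TRUE FALSE", "FALSE TRUE"))

  # negative feedback: one cyclic attractor containing all four states
  aset <- attractors_exhaustive(two_node_negfb(), "asynchronous")
  expect_length(aset$attractors, 1)
  expect_equal(aset$attractors[[1]]$type, "cycle")
  expect_equal(nrow(aset$attractors[[1]]$states), 4)

  big <- infer_rules(generate_random_map(synthetic_map_spec(25, 40, seed = 1)))
  expect_error(attractors_exhaustive(big), class = "emtmap_size_error")
})

test_that("asynchronous attractors equal the reachability-closure oracle", {
  for (seed in c(6, 21, 35, 52, 80)) {
    model <- infer_rules(random_test_map(seed, n_min = 3, n_max = 7))
    got <- attractor_index_sets(attractors_exhaustive(model, "asynchronous"),
                                model)
    want <- oracle_async_attractors(model)
    want <- want[order(vapply(want, `[`, integer(1), 1))]
    expect_equal(got, want, info = sprintf("seed %d", seed))
  }
})

test_that("oscillation detection follows its definition", {
  fake <- structure(list(values = cbind(const = rep(1, 10),
                                        osc = rep(c(0.3, 0.7), 5),
                                        drift = seq(0.1, 0.9, length.out = 10))),
                    class = "activity_profile")
  expect_false(detect_oscillation(fake, "const")$oscillating)
  expect_true(detect_oscillation(fake, "osc")$oscillating)
  expect_false(detect_oscillation(fake, "drift")$oscillating)
  expect_error(detect_oscillation(fake, "ghost"),
               class = "emtmap_contract_error")
  tiny <- structure(list(values = cbind(x = c(0.4, 0.6))),
                    class = "activity_profile")
  expect_error(detect_oscillation(tiny, "x"),
               class = "emtmap_contract_error")
})
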