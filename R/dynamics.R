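# Simulation engine for Boolean logical models: synchronous and general
# asynchronous (uniform random single-node) updates, clamp resampling for
# externally controlled inputs, ensemble activity-level readouts, exhaustive
# attractor analysis on small models, and an oscillation detector.

#' Simulation configuration
#'
#' @param scheme `"asynchronous"` (one uniformly chosen node updated per
#'   step) or `"synchronous"` (all nodes updated together).
#' @param n_steps number of update steps; asynchronous steps count single-node
#'   updates.
#' @param clamps named numeric vector of ON-probabilities for input nodes;
#'   a clamped input is resampled Bernoulli(p) at every step.
#' @param initial `"epithelial"`, `"random"`, or a named 0/1 vector covering
#'   every model node. The epithelial preset needs `markers`.
#' @param seed integer seed making the trajectory reproducible.
#' @param markers a [marker_config()] used to resolve the epithelial preset:
#'   epithelial markers start ON, mesenchymal markers OFF, every other
#'   non-input node OFF, inputs at their clamp.
#' @return a `sim_config` object.
#' @export
sim_config <- function(scheme = c("asynchronous", "synchronous"),
                       n_steps = 5000, clamps = numeric(0),
                       initial = "epithelial", seed = 1L, markers = NULL) {
  scheme <- match.arg(scheme)
  if (n_steps < 1) stop_fmt("emtmap_config_error", "n_steps must be >= 1")
  if (length(clamps) > 0) {
    if (is.null(names(clamps)) || any(names(clamps) == ""))
      stop_fmt("emtmap_config_error", "clamps must be a named vector")
    if (any(clamps < 0 | clamps > 1))
      stop_fmt("emtmap_config_error", "clamp probabilities must lie in [0,1]")
  }
  structure(list(scheme = scheme, n_steps = as.integer(n_steps),
                 clamps = clamps, initial = initial, seed = as.integer(seed),
                 markers = markers),
            class = "sim_config")
}

check_state <- function(model, state) {
  missing <- setdiff(model$node_order, names(state))
  if (length(missing) > 0)
    stop_fmt("emtmap_contract_error", "state is missing node '%s'",
             missing[1])
  s <- as.logical(state[model$node_order])
  if (any(is.na(s)) || any(!state[model$node_order] %in% c(0, 1, TRUE, FALSE)))
    stop_fmt("emtmap_contract_error", "state values must be binary")
  names(s) <- model$node_order
  s
}

# Resolve the initial state; consumes RNG for "random" and for Bernoulli
# clamp initialisation, so call inside with_seed().
resolve_initial <- function(model, config) {
  nodes <- model$node_order
  init <- config$initial
  if (is.character(init) && length(init) == 1) {
    if (init == "random") {
      s <- stats::runif(length(nodes)) < 0.5
    } else if (init == "epithelial") {
      mk <- config$markers
      if (is.null(mk))
        stop_fmt("emtmap_config_error",
                 "epithelial preset requires a marker_config in `markers`")
      s <- rep(FALSE, length(nodes))
      names(s) <- nodes
      s[intersect(mk$epithelial_markers, nodes)] <- TRUE
      s[intersect(mk$mesenchymal_markers, nodes)] <- FALSE
    } else {
      stop_fmt("emtmap_config_error", "unknown initial preset '%s'", init)
    }
    names(s) <- nodes
  } else {
    s <- check_state(model, init)
  }
  if (length(config$clamps) > 0) {
    unknown <- setdiff(names(config$clamps), nodes)
    if (length(unknown) > 0)
      stop_fmt("emtmap_config_error", "clamped node '%s' not in model",
               unknown[1])
    s[names(config$clamps)] <- stats::runif(length(config$clamps)) <
      config$clamps
  }
  s
}

#' One synchronous update step
#'
#' Every node is simultaneously set to its rule evaluated on the input state;
#' clamped nodes keep their current value.
#'
#' @param model a `logic_model`.
#' @param state named binary vector over all model nodes.
#' @param clamps named clamp vector; clamped nodes are left unchanged.
#' @return the successor state (named logical vector).
#' @export
sync_step <- function(model, state, clamps = numeric(0)) {
  s <- check_state(model, state)
  M <- matrix(s, nrow = 1, dimnames = list(NULL, model$node_order))
  nxt <- as.logical(eval_model_matrix(model, M)[1, ])
  names(nxt) <- model$node_order
  if (length(clamps) > 0) nxt[names(clamps)] <- s[names(clamps)]
  nxt
}

#' Simulate a logical model
#'
#' Asynchronous scheme: at each step the clamped inputs are resampled
#' Bernoulli(p), then one node chosen uniformly at random is updated.
#' Synchronous scheme: all nodes are updated together, after which clamp
#' draws overwrite the clamped inputs. Identical configurations (including
#' the seed) give identical trajectories.
#'
#' @param model a `logic_model`.
#' @param config a [sim_config()].
#' @return a `trajectory`: binary state matrix of `n_steps + 1` rows, the
#'   per-step updated node (asynchronous only) and the config echo.
#' @export
simulate_model <- function(model, config) {
  stopifnot(inherits(config, "sim_config"))
  funs <- compile_rules(model)
  nodes <- model$node_order
  nn <- length(nodes)
  n_steps <- config$n_steps
  clamp_idx <- match(names(config$clamps), nodes)
  kcl <- length(clamp_idx)

  with_seed(config$seed, {
    s <- unname(resolve_initial(model, config))
    upd <- if (config$scheme == "asynchronous")
      sample.int(nn, n_steps, replace = TRUE) else integer(0)
    clamp_draws <- if (kcl > 0)
      matrix(stats::runif(n_steps * kcl), n_steps, kcl) <
        rep(config$clamps, each = n_steps)
    else NULL

    states <- matrix(FALSE, n_steps + 1, nn)
    states[1, ] <- s
    if (config$scheme == "asynchronous") {
      for (t in seq_len(n_steps)) {
        if (kcl > 0) s[clamp_idx] <- clamp_draws[t, ]
        i <- upd[t]
        s[i] <- funs[[i]](s)
        states[t + 1, ] <- s
      }
    } else {
      M <- matrix(s, nrow = 1, dimnames = list(NULL, nodes))
      for (t in seq_len(n_steps)) {
        M[1, ] <- s
        s <- as.logical(eval_model_matrix(model, M)[1, ])
        if (kcl > 0) s[clamp_idx] <- clamp_draws[t, ]
        states[t + 1, ] <- s
      }
    }
    colnames(states) <- nodes
    structure(list(states = states, updated_node_log = nodes[upd],
                   config = config),
              class = "trajectory")
  })
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d nodes, %d steps (%s, seed %d)\n",
              ncol(x$states), nrow(x$states) - 1, x$config$scheme,
              x$config$seed))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  st <- x$states
  data.frame(step = rep(seq_len(nrow(st)) - 1L, ncol(st)),
             node = rep(colnames(st), each = nrow(st)),
             value = as.integer(st), stringsAsFactors = FALSE)
}

#' Ensemble activity levels in sliding windows
#'
#' Runs `ensemble` seeded simulations (seeds `seed, seed+1, ...`) and reports,
#' for every node, the fraction of time it was ON within consecutive
#' non-overlapping windows, averaged across the ensemble. This is the
#' activity-level readout used to compare simulated dynamics against
#' qualitative activity plots.
#'
#' @param model a `logic_model`.
#' @param config a [sim_config()] (its seed is the ensemble base seed).
#' @param window window width in update steps.
#' @param ensemble number of runs.
#' @return an `activity_profile` with a `values` matrix (windows x nodes).
#' @export
activity_profile <- function(model, config, window = 50, ensemble = 100) {
  if (window < 1) stop_fmt("emtmap_config_error", "window must be >= 1")
  if (ensemble < 1) stop_fmt("emtmap_config_error", "ensemble must be >= 1")
  if (window > config$n_steps)
    stop_fmt("emtmap_config_error", "window (%d) exceeds n_steps (%d)",
             window, config$n_steps)
  n_windows <- config$n_steps %/% window
  nodes <- model$node_order
  acc <- matrix(0, n_windows, length(nodes))
  for (e in seq_len(ensemble) - 1L) {
    cfg <- config
    cfg$seed <- config$seed + e
    tr <- simulate_model(model, cfg)
    st <- tr$states[-1, , drop = FALSE]  # post-update states only
    for (w in seq_len(n_windows)) {
      rows <- ((w - 1) * window + 1):(w * window)
      acc[w, ] <- acc[w, ] + colMeans(st[rows, , drop = FALSE])
    }
  }
  values <- acc / ensemble
  colnames(values) <- nodes
  structure(list(values = values, window_size = as.integer(window),
                 ensemble_size = as.integer(ensemble),
                 scheme = config$scheme, base_seed = config$seed,
                 config = config),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf(
    "activity_profile: %d windows x %d nodes (window %d, ensemble %d, %s)\n",
    nrow(x$values), ncol(x$values), x$window_size, x$ensemble_size,
    x$scheme))
  invisible(x)
}

#' @export
as.data.frame.activity_profile <- function(x, ...) {
  v <- x$values
  data.frame(window = rep(seq_len(nrow(v)), ncol(v)),
             node = rep(colnames(v), each = nrow(v)),
             value = as.numeric(v), stringsAsFactors = FALSE)
}

#' Exhaustive attractor analysis of a small model
#'
#' Enumerates the full state space (at most 20 nodes). Synchronous attractors
#' are the cycles of the deterministic update map; asynchronous attractors
#' are the terminal strongly connected components of the nondeterministic
#' single-node-update state-transition graph. Every reported fixed point
#' satisfies `f(s) = s` by construction.
#'
#' @param model a `logic_model`.
#' @param scheme update scheme.
#' @return an `attractor_set`: list of attractors, each with a `type`
#'   (`fixed_point`, `cycle` or `complex`) and a state matrix.
#' @export
attractors_exhaustive <- function(model,
                                  scheme = c("asynchronous", "synchronous")) {
  scheme <- match.arg(scheme)
  nodes <- model$node_order
  n <- length(nodes)
  if (n > 20)
    stop_fmt("emtmap_size_error",
             "%d nodes: exhaustive enumeration supports at most 20; use simulate_model()",
             n)
  n_states <- bitwShiftL(1L, n)
  pow2 <- 2^(seq_len(n) - 1)
  idx <- seq_len(n_states) - 1
  M <- vapply(seq_len(n), function(j) bitwAnd(idx, as.integer(pow2[j])) > 0,
              logical(n_states))
  if (n_states == 1) M <- matrix(M, nrow = 1)
  colnames(M) <- nodes
  Fm <- eval_model_matrix(model, M)

  if (scheme == "synchronous") {
    to <- as.integer(Fm %*% pow2) + 1L
    from <- seq_len(n_states)
  } else {
    diff <- Fm != M
    from <- integer(0); to <- integer(0)
    for (j in seq_len(n)) {
      rows <- which(diff[, j])
      if (length(rows) == 0) next
      from <- c(from, rows)
      to <- c(to, rows + ifelse(M[rows, j], -1L, 1L) * as.integer(pow2[j]))
    }
  }
  g <- igraph::make_empty_graph(n = n_states, directed = TRUE)
  if (length(from) > 0)
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g, mode = "strong")$membership
  terminal <- rep(TRUE, max(memb))
  if (length(from) > 0) {
    cross <- memb[from] != memb[to]
    terminal[unique(memb[from][cross])] <- FALSE
  }
  attractors <- list()
  for (comp in which(terminal)) {
    states_idx <- which(memb == comp)
    sm <- M[states_idx, , drop = FALSE]
    if (length(states_idx) == 1) {
      type <- "fixed_point"
      # safety: a singleton terminal SCC must be a fixed point
      stopifnot(all(Fm[states_idx, ] == M[states_idx, ]))
    } else if (scheme == "synchronous") {
      type <- "cycle"
    } else {
      sel <- memb[from] == comp & memb[to] == comp
      outdeg <- tabulate(from[sel], nbins = n_states)[states_idx]
      type <- if (all(outdeg == 1)) "cycle" else "complex"
    }
    attractors[[length(attractors) + 1]] <- list(type = type, states = sm)
  }
  structure(list(attractors = attractors, scheme = scheme, n_nodes = n),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("attractor_set (%s): %d attractor(s)\n", x$scheme,
              length(x$attractors)))
  for (a in x$attractors)
    cat(sprintf("  %s with %d state(s)\n", a$type, nrow(a$states)))
  invisible(x)
}

#' Flag sustained oscillation in a node's activity profile
#'
#' A node oscillates when, after a burn-in, its window means stay strictly
#' inside `(eps, 1 - eps)` and the sequence is non-monotone (has both rises
#' and falls). Nodes pinned at 0/1 or converging monotonically are not
#' flagged.
#'
#' @param profile an [activity_profile()] with at least 3 windows.
#' @param node species id.
#' @param eps boundary tolerance (default 0.05).
#' @param burnin fraction of initial windows to discard (default 0.2).
#' @return list with `oscillating` flag and a summary of the thresholds used.
#' @export
detect_oscillation <- function(profile, node, eps = 0.05, burnin = 0.2) {
  if (!node %in% colnames(profile$values))
    stop_fmt("emtmap_contract_error", "unknown node id '%s'", node)
  v <- profile$values[, node]
  if (length(v) < 3)
    stop_fmt("emtmap_contract_error",
             "profile must have at least 3 windows (has %d)", length(v))
  skip <- floor(length(v) * burnin)
  vv <- v[(skip + 1):length(v)]
  interior <- all(vv > eps & vv < 1 - eps)
  d <- diff(vv)
  nonmono <- any(d > 0) && any(d < 0)
  list(node = node, oscillating = interior && nonmono,
       interior = interior, non_monotone = nonmono,
       eps = eps, burnin = burnin, windows_used = length(vv),
       range = range(vv))
}
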