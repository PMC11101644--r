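# Independent brute-force oracles and small builders shared across tests.
# The oracles deliberately avoid the code paths they check: BFS distances by
# hand, clique enumeration over all vertex subsets, attractors via a
# reachability-closure matrix.

# --- builders ---------------------------------------------------------------

empty_map <- function(ids) {
  regulatory_map(data.frame(id = ids, stringsAsFactors = FALSE),
                 data.frame(id = character(), target = character(),
                            category = character(), sign = character(),
                            stringsAsFactors = FALSE))
}

edges_map <- function(edf, ids = NULL) {
  # edf: data.frame(source, sign, target)
  ids <- ids %||% unique(c(edf$source, edf$target))
  ints <- data.frame(id = sprintf("e%03d", seq_len(nrow(edf))),
                     target = edf$target, category = "state_transition",
                     sign = edf$sign, stringsAsFactors = FALSE)
  ints$sources <- as.list(edf$source)
  regulatory_map(data.frame(id = ids, stringsAsFactors = FALSE), ints)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_test_map <- function(seed, n_min = 4, n_max = 12) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  m <- sample(n:(min(3 * n, n * (n - 1))), 1)
  generate_random_map(synthetic_map_spec(
    n_nodes = n, n_edges = m, inhibition_fraction = 0.3, seed = seed))
}

state_vec <- function(model, bits) {
  stats::setNames(as.logical(bits), model$node_order)
}

# --- graph oracles ----------------------------------------------------------

# undirected adjacency matrix of the simple projection (no self-loops)
oracle_adjacency <- function(map) {
  ids <- map$species$id
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  e <- interaction_edges(map)
  e <- e[e$source != e$target, , drop = FALSE]
  for (i in seq_len(nrow(e))) {
    A[e$source[i], e$target[i]] <- TRUE
    A[e$target[i], e$source[i]] <- TRUE
  }
  A
}

# all-pairs BFS distances on an adjacency matrix
oracle_bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ]))))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

oracle_path_stats <- function(map) {
  A <- oracle_adjacency(map)
  D <- oracle_bfs_distances(A)
  diag(D) <- Inf
  finite <- is.finite(D)
  ecc <- apply(D, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f) == 0) NA_real_ else max(f)
  })
  list(diameter = if (any(finite)) max(D[finite]) else 0,
       radius = if (any(finite)) min(ecc, na.rm = TRUE) else 0,
       cpl = if (any(finite)) mean(D[finite]) else 0)
}

# exact MCC by enumerating every vertex subset and keeping maximal cliques
oracle_mcc <- function(map) {
  A <- oracle_adjacency(map)
  ids <- rownames(A)
  n <- length(ids)
  scores <- stats::setNames(numeric(n), ids)
  is_clique <- function(idx) all(A[idx, idx][upper.tri(diag(length(idx)))])
  subsets <- lapply(seq_len(2^n - 1), function(code)
    which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0))
  cliques <- Filter(function(idx) length(idx) >= 2 && is_clique(idx), subsets)
  for (cl in cliques) {
    outside <- setdiff(seq_len(n), cl)
    maximal <- !any(vapply(outside, function(v) all(A[v, cl]), logical(1)))
    if (maximal) scores[cl] <- scores[cl] + factorial(length(cl) - 1)
  }
  scores
}

# --- attractor oracle -------------------------------------------------------

# asynchronous attractors as sets of mutually reachable states with no
# escape, computed from the boolean reachability closure of the full
# single-node-update transition relation (use for <= 8 nodes)
oracle_async_attractors <- function(model) {
  nodes <- model$node_order
  n <- length(nodes)
  stopifnot(n <= 8)
  ns <- 2^n
  pow2 <- 2^(seq_len(n) - 1)
  M <- vapply(seq_len(n),
              function(j) bitwAnd(seq_len(ns) - 1, as.integer(pow2[j])) > 0,
              logical(ns))
  colnames(M) <- nodes
  R <- diag(ns) > 0
  for (s in seq_len(ns)) {
    st <- stats::setNames(M[s, ], nodes)
    for (j in seq_len(n)) {
      nx <- st
      nx[j] <- eval_expr(model$rules[[j]]$expr, st)
      R[s, sum(pow2[nx]) + 1] <- TRUE
    }
  }
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  attractor_state <- vapply(seq_len(ns), function(s) {
    reach <- which(R[s, ])
    all(R[reach, s])
  }, logical(1))
  comps <- list()
  seen <- rep(FALSE, ns)
  for (s in which(attractor_state)) {
    if (seen[s]) next
    members <- which(R[s, ] & R[, s] & attractor_state)
    seen[members] <- TRUE
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps
}

# canonical representation of an attractor_set's state sets for comparison
attractor_index_sets <- function(aset, model) {
  pow2 <- 2^(seq_along(model$node_order) - 1)
  sets <- lapply(aset$attractors, function(a)
    sort(as.integer(a$states %*% pow2) + 1L))
  sets[order(vapply(sets, `[`, integer(1), 1))]
}
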