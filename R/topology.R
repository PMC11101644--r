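# Topological analysis of regulatory maps: the standard metric battery on
# directed and undirected views, degree distributions with a log-log
# power-law fit, and maximal clique centrality (MCC) hub ranking.
#
# Conventions (documented because several tools differ silently):
# * Shortest-path statistics (diameter, radius, characteristic path length)
#   are computed over connected node pairs only, so maps with many
#   components still get finite values; nodes that reach no other node are
#   excluded from the radius.
# * Self-loops are excluded from clustering and neighbour counts and
#   reported separately.
# * The clustering coefficient is the mean Watts-Strogatz local coefficient
#   on the simple undirected projection, with degree < 2 nodes contributing
#   0. In directed mode the numerator counts directed links among the
#   (undirected) neighbours over k(k-1) ordered pairs.
# * Density is e/(n(n-1)) in directed mode and 2e/(n(n-1)) in undirected
#   mode, with e the simple-projection edge count of that mode.

# igraph view of a map; one edge per (source, target) of every interaction.
map_to_igraph <- function(map, mode = c("directed", "undirected"),
                          include_degradation = FALSE, simplify = TRUE) {
  mode <- match.arg(mode)
  sp <- map$species
  if (!include_degradation) sp <- sp[sp$kind != "degradation", , drop = FALSE]
  edges <- interaction_edges(map)
  keep <- edges$source %in% sp$id & edges$target %in% sp$id
  edges <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "sign")], directed = TRUE,
    vertices = sp$id)
  if (mode == "undirected")
    g <- igraph::as_undirected(g, mode = "each")
  if (simplify) g <- igraph::simplify(g, remove.multiple = TRUE,
                                      remove.loops = TRUE)
  g
}

#' Topology report for a regulatory map
#'
#' Computes node/edge counts, average neighbour count, diameter, radius,
#' characteristic path length (all over connected pairs only), mean local
#' clustering coefficient, density, connected components, multi-edge node
#' pairs and self-loop count, on the directed or undirected view of the map.
#' Degradation sink species are excluded by default.
#'
#' @param map a non-empty `regulatory_map`.
#' @param mode `"directed"` or `"undirected"`.
#' @param include_degradation include degradation sink species.
#' @return a `topology_report` (list of named metrics).
#' @export
topology_report <- function(map, mode = c("directed", "undirected"),
                            include_degradation = FALSE) {
  mode <- match.arg(mode)
  if (n_species(map) == 0)
    stop_fmt("emtmap_contract_error", "map has no species")
  raw <- map_to_igraph(map, mode = "directed",
                       include_degradation = include_degradation,
                       simplify = FALSE)
  n <- igraph::vcount(raw)
  self_loops <- sum(igraph::which_loop(raw))
  # multi-edge node pairs: unordered pairs joined by more than one edge
  # (direction and parallels both count), before any merging
  el <- igraph::as_edgelist(raw, names = FALSE)
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  pair_key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  multi_pairs <- sum(table(pair_key) > 1)

  g <- map_to_igraph(map, mode = mode,
                     include_degradation = include_degradation,
                     simplify = TRUE)
  n_edges_raw <- igraph::ecount(raw) - self_loops
  e_simple <- igraph::ecount(g)

  # undirected simple projection used for neighbours and clustering
  gu <- if (mode == "undirected") g else
    igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  avg_neighbours <- mean(igraph::degree(gu))

  # local clustering (Watts-Strogatz), degree < 2 contributes 0
  deg_u <- igraph::degree(gu)
  ids_u <- igraph::V(gu)$name
  local_cc <- rep(0, n)
  if (any(deg_u >= 2)) {
    which2 <- which(deg_u >= 2)
    adj <- igraph::adjacent_vertices(gu, which2)
    k <- deg_u[which2]
    links <- vapply(adj, function(nb) {
      sub <- igraph::induced_subgraph(if (mode == "directed") g else gu,
                                      ids_u[as.integer(nb)])
      igraph::ecount(sub)
    }, numeric(1))
    denom <- if (mode == "directed") k * (k - 1) else k * (k - 1) / 2
    local_cc[which2] <- links / denom
  }
  clustering <- mean(local_cc)

  # shortest paths over connected pairs only
  d <- igraph::distances(g, mode = "out")
  diag(d) <- Inf
  finite <- is.finite(d)
  if (any(finite)) {
    cpl <- mean(d[finite])
    diameter <- max(d[finite])
    ecc <- apply(d, 1, function(r) {
      f <- r[is.finite(r)]
      if (length(f) == 0) NA_real_ else max(f)
    })
    radius <- min(ecc, na.rm = TRUE)
  } else {
    cpl <- 0; diameter <- 0; radius <- 0
  }

  density <- if (mode == "directed") e_simple / (n * (n - 1)) else
    2 * e_simple / (n * (n - 1))
  comps <- igraph::components(g, mode = "weak")$no

  structure(list(
    mode = mode,
    n_nodes = n,
    n_edges = n_edges_raw,
    n_edges_simple = e_simple,
    avg_neighbours = avg_neighbours,
    diameter = diameter,
    radius = radius,
    characteristic_path_length = cpl,
    clustering_coefficient = clustering,
    density = density,
    n_connected_components = comps,
    multi_edge_node_pairs = multi_pairs,
    n_self_loops = self_loops
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("topology_report (%s view)\n", x$mode))
  for (k in setdiff(names(x), "mode"))
    cat(sprintf("  %-28s %s\n", k,
                format(x[[k]], digits = 4, scientific = FALSE)))
  invisible(x)
}

#' Degree distribution of a map
#'
#' @param map a `regulatory_map`.
#' @param mode `"directed"` or `"undirected"` (simple projection).
#' @param direction `"total"`, `"in"` or `"out"` (directed mode only).
#' @param include_degradation include degradation sink species.
#' @return a `degree_distribution`: data frame of per-degree node counts.
#' @export
degree_distribution <- function(map, mode = c("directed", "undirected"),
                                direction = c("total", "in", "out"),
                                include_degradation = FALSE) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  g <- map_to_igraph(map, mode = mode,
                     include_degradation = include_degradation)
  igr_mode <- switch(direction, total = "all", `in` = "in", out = "out")
  deg <- igraph::degree(g, mode = igr_mode)
  tab <- table(deg)
  structure(list(
    counts = data.frame(degree = as.integer(names(tab)),
                        n_nodes = as.integer(tab)),
    mode = mode, direction = direction, n_nodes = length(deg)
  ), class = "degree_distribution")
}

#' Power-law fit on a degree distribution
#'
#' Least-squares line fitted on the log-log binned histogram: with
#' `binning = "log"` (default) per-degree counts are aggregated into
#' powers-of-two degree bins and converted to count densities (count divided
#' by bin width) before the fit on log10(bin centre) vs log10(density), which
#' removes the flattening caused by sparse single-occupancy tail degrees;
#' `binning = "raw"` fits log10(count) against log10(degree) per occupied
#' degree. The exponent is the negative slope. At least 3 occupied non-zero
#' degrees (and 3 occupied bins) are required.
#'
#' @param dd a [degree_distribution()].
#' @param binning `"log"` or `"raw"`.
#' @return a `power_law_fit` with `exponent`, `intercept`, `r_squared`.
#' @export
fit_power_law <- function(dd, binning = c("log", "raw")) {
  binning <- match.arg(binning)
  counts <- dd$counts[dd$counts$degree > 0 & dd$counts$n_nodes > 0, ]
  if (nrow(counts) < 3)
    stop_fmt("emtmap_fit_error",
             "need at least 3 occupied non-zero degrees, have %d",
             nrow(counts))
  if (binning == "raw") {
    x <- log10(counts$degree)
    y <- log10(counts$n_nodes)
  } else {
    lo <- 2^(0:ceiling(log2(max(counts$degree))))
    hi <- 2 * lo
    cnt <- vapply(seq_along(lo), function(b)
      sum(counts$n_nodes[counts$degree >= lo[b] & counts$degree < hi[b]]),
      numeric(1))
    keep <- cnt > 0
    if (sum(keep) < 3)
      stop_fmt("emtmap_fit_error",
               "need at least 3 occupied logarithmic bins, have %d",
               sum(keep))
    x <- log10(sqrt(lo * hi))[keep]
    y <- log10(cnt[keep] / (hi - lo)[keep])
  }
  fit <- stats::lm(y ~ x)
  structure(list(exponent = -unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_bins = length(x), binning = binning),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit: exponent %.3f, r^2 %.3f (%d bins)\n",
              x$exponent, x$r_squared, x$n_bins))
  invisible(x)
}

# factorials up to 20 are exact in double; clique sizes here are far smaller
factorial_int <- function(k) factorial(k)

#' Maximal clique centrality (MCC) hub ranking
#'
#' MCC(v) is the sum of (|C| - 1)! over all maximal cliques C containing v on
#' the simple undirected projection of the map. For a node whose only maximal
#' cliques are single edges this reduces to its edge count, matching the
#' CytoHubba convention; isolated nodes score 0. Cliques are enumerated
#' exactly (Bron-Kerbosch with pivoting). Ranking is deterministic:
#' descending score, then lexicographic id.
#'
#' @param map a non-empty `regulatory_map`.
#' @param include_degradation include degradation sink species.
#' @return a `hub_ranking`: named score vector and ranked ids.
#' @export
mcc_scores <- function(map, include_degradation = FALSE) {
  if (n_species(map) == 0)
    stop_fmt("emtmap_contract_error", "map has no species")
  g <- map_to_igraph(map, mode = "undirected",
                     include_degradation = include_degradation)
  ids <- igraph::V(g)$name
  scores <- stats::setNames(numeric(length(ids)), ids)
  cliques <- igraph::max_cliques(g, min = 2)
  for (cl in cliques) {
    members <- ids[as.integer(cl)]
    scores[members] <- scores[members] + factorial_int(length(members) - 1)
  }
  ord <- order(-scores, ids, method = "radix")
  structure(list(scores = scores, ranked_ids = ids[ord]),
            class = "hub_ranking")
}

#' @export
print.hub_ranking <- function(x, ...) {
  k <- min(10, length(x$ranked_ids))
  cat(sprintf("hub_ranking: %d nodes; top %d:\n", length(x$ranked_ids), k))
  for (id in x$ranked_ids[seq_len(k)])
    cat(sprintf("  %-20s %g\n", id, x$scores[[id]]))
  invisible(x)
}

#' Induced sub-map on the top-k hub nodes
#'
#' @param ranking a [mcc_scores()] result.
#' @param k number of top-ranked nodes to keep.
#' @param map the map the ranking was computed from.
#' @return a `regulatory_map` induced on the k top-ranked nodes: interactions
#'   are kept when all their endpoints are ranked in the top k.
#' @export
top_k_subnetwork <- function(ranking, k, map) {
  n <- length(ranking$ranked_ids)
  if (k < 1 || k > n)
    stop_fmt("emtmap_contract_error", "k must lie in [1, %d], got %s", n,
             format(k))
  keep <- ranking$ranked_ids[seq_len(k)]
  sp <- map$species[map$species$id %in% keep, , drop = FALSE]
  ints <- map$interactions
  sel <- vapply(seq_len(nrow(ints)), function(i)
    ints$target[[i]] %in% keep && all(ints$sources[[i]] %in% keep),
    logical(1))
  regulatory_map(sp, ints[sel, , drop = FALSE],
                 provenance = sprintf("top-%d subnetwork of %s", k,
                                      map$provenance))
}
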