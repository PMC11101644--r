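# Seeded random signed regulatory maps with controllable structure, plus the
# curated EMT-core fixture: a ~20-node abstraction of TGFbeta-driven EMT
# signalling in metastatic breast cancer whose every edge is backed by a
# documented interaction statement (see the manifest shipped in extdata).

MOTIF_KINDS <- c("mutual_inhibition", "negative_feedback",
                 "double_positive_feedback")

#' Specification for a seeded random regulatory map
#'
#' @param n_nodes number of nodes.
#' @param n_edges number of distinct directed edges (no self-loops).
#' @param inhibition_fraction expected fraction of inhibitory edges; the
#'   exact count is drawn deterministically from the seed.
#' @param motifs list of motifs, each `list(kind = <one of mutual_inhibition,
#'   negative_feedback, double_positive_feedback>, nodes = c(a, b))`. Motif
#'   nodes are kept out of the random wiring so that their dynamics are
#'   attributable to the planted motif.
#' @param input_nodes number of nodes reserved as inputs (never targets).
#' @param seed integer seed; the generated map is fully reproducible.
#' @return a `synthetic_map_spec`.
#' @export
synthetic_map_spec <- function(n_nodes, n_edges, inhibition_fraction = 0.3,
                               motifs = list(), input_nodes = 0, seed = 1L) {
  if (inhibition_fraction < 0 || inhibition_fraction > 1)
    stop_fmt("emtmap_spec_error", "inhibition_fraction must lie in [0,1]")
  if (n_edges > n_nodes * (n_nodes - 1))
    stop_fmt("emtmap_spec_error",
             "n_edges (%d) exceeds n_nodes*(n_nodes-1) = %d", n_edges,
             n_nodes * (n_nodes - 1))
  for (m in motifs) {
    if (!m$kind %in% MOTIF_KINDS)
      stop_fmt("emtmap_spec_error", "unknown motif kind '%s'", m$kind)
    if (length(m$nodes) != 2)
      stop_fmt("emtmap_spec_error", "motifs require exactly 2 node ids")
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 n_edges = as.integer(n_edges),
                 inhibition_fraction = inhibition_fraction,
                 motifs = motifs, input_nodes = as.integer(input_nodes),
                 seed = as.integer(seed)),
            class = "synthetic_map_spec")
}

synthetic_node_ids <- function(n) {
  sprintf("n%0*d", max(2L, nchar(as.character(n))), seq_len(n))
}

#' Generate a seeded random signed regulatory map
#'
#' Draws exactly `n_edges` distinct directed edges without self-loops among
#' the non-motif nodes (input nodes are never targets), assigns an
#' inhibitory sign to a binomially drawn number of them, then injects the
#' requested motifs verbatim. Fully reproducible from the spec seed.
#'
#' @param spec a [synthetic_map_spec()].
#' @return a `regulatory_map` with all species of kind `protein`.
#' @export
generate_random_map <- function(spec) {
  stopifnot(inherits(spec, "synthetic_map_spec"))
  ids <- synthetic_node_ids(spec$n_nodes)
  motif_nodes <- unique(unlist(lapply(spec$motifs, `[[`, "nodes")))
  if (length(setdiff(motif_nodes, ids)) > 0)
    stop_fmt("emtmap_spec_error", "motif node '%s' outside id range",
             setdiff(motif_nodes, ids)[1])
  inputs <- ids[seq_len(spec$input_nodes)]
  free <- setdiff(ids, motif_nodes)
  sources <- free
  targets <- setdiff(free, inputs)
  pairs <- expand.grid(source = sources, target = targets,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  if (spec$n_edges > nrow(pairs))
    stop_fmt("emtmap_spec_error",
             "cannot place %d edges among %d admissible node pairs",
             spec$n_edges, nrow(pairs))
  map <- with_seed(spec$seed, {
    sel <- pairs[sample.int(nrow(pairs), spec$n_edges), , drop = FALSE]
    n_inh <- stats::rbinom(1, spec$n_edges, spec$inhibition_fraction)
    sign <- rep("activation", spec$n_edges)
    if (n_inh > 0) sign[seq_len(n_inh)] <- "inhibition"
    species <- data.frame(id = ids, name = ids, kind = "protein",
                          compartment = "cytoplasm", notes = "",
                          stringsAsFactors = FALSE)
    ints <- data.frame(id = sprintf("e%04d", seq_len(spec$n_edges)),
                       target = sel$target, category = "state_transition",
                       sign = sign, note = "", stringsAsFactors = FALSE)
    ints$sources <- as.list(sel$source)
    regulatory_map(species, ints,
                   provenance = sprintf("synthetic(seed=%d)", spec$seed))
  })
  for (m in spec$motifs) map <- inject_motif(map, m)
  map
}

motif_edges <- function(motif) {
  a <- motif$nodes[1]; b <- motif$nodes[2]
  switch(motif$kind,
         mutual_inhibition = data.frame(
           source = c(a, b), target = c(b, a),
           sign = c("inhibition", "inhibition"), stringsAsFactors = FALSE),
         negative_feedback = data.frame(
           source = c(a, b), target = c(b, a),
           sign = c("activation", "inhibition"), stringsAsFactors = FALSE),
         double_positive_feedback = data.frame(
           source = c(a, b), target = c(b, a),
           sign = c("activation", "activation"), stringsAsFactors = FALSE),
         stop_fmt("emtmap_spec_error", "unknown motif kind '%s'", motif$kind))
}

#' Inject a two-node feedback motif into a map
#'
#' Returns a new map with the motif edges added (the input map is not
#' mutated). Re-injecting an already present motif is a no-op; an existing
#' edge between the same endpoints with the opposite sign is a conflict
#' error. Motif endpoints missing from the map are added as species.
#'
#' @param map a `regulatory_map`.
#' @param motif `list(kind, nodes = c(a, b))`.
#' @param seed unused; accepted for interface uniformity with the generator.
#' @return a `regulatory_map`.
#' @export
inject_motif <- function(map, motif, seed = NULL) {
  new_edges <- motif_edges(motif)
  sp <- map$species
  missing <- setdiff(unique(c(new_edges$source, new_edges$target)), sp$id)
  if (length(missing) > 0)
    sp <- rbind(sp, data.frame(id = missing, name = missing,
                               kind = "protein", compartment = "cytoplasm",
                               notes = "", stringsAsFactors = FALSE))
  ints <- map$interactions
  existing <- interaction_edges(map)
  add <- list()
  for (i in seq_len(nrow(new_edges))) {
    s <- new_edges$source[i]; t <- new_edges$target[i]
    sg <- new_edges$sign[i]
    prior <- existing[existing$source == s & existing$target == t, ,
                      drop = FALSE]
    if (nrow(prior) > 0) {
      if (any(prior$sign != sg))
        stop_fmt("emtmap_conflict_error",
                 "edge %s -> %s already present with sign '%s'", s, t,
                 prior$sign[1])
      next  # identical edge already there: idempotent
    }
    add[[length(add) + 1]] <- data.frame(
      id = sprintf("motif_%s_%s_%s_%d", motif$kind, motif$nodes[1],
                   motif$nodes[2], i),
      target = t, category = "state_transition", sign = sg,
      note = sprintf("injected %s motif", motif$kind),
      stringsAsFactors = FALSE)
    add[[length(add)]]$sources <- list(s)
  }
  if (length(add) > 0) {
    ints <- rbind(ints, do.call(rbind, add))
  }
  regulatory_map(sp, ints, provenance = map$provenance)
}

# The curated EMT-core interaction table. Each note states, in the package's
# own words, the mechanistic claim supporting the edge; the one deliberately
# abstracted edge (SMAD -> MDM2) is flagged as such in its note.
emt_core_edge_table <- function() {
  e <- function(source, sign, target, category, note)
    data.frame(source = source, sign = sign, target = target,
               category = category, note = note, stringsAsFactors = FALSE)
  rbind(
    e("TGFB", "activation", "TGFBR", "state_transition",
      "TGFbeta ligand binding assembles and activates the TGFbetaRII/RI receptor complex"),
    e("TGFBR", "activation", "SMAD", "state_transition",
      "the active receptor complex phosphorylates R-SMADs, which trimerise with SMAD4 and translocate to the nucleus"),
    e("SMAD", "activation", "SNAIL", "state_transition",
      "TGFbeta/SMAD signalling drives transcription of SNAIL family factors"),
    e("NFKB", "activation", "SNAIL", "state_transition",
      "NF-kB signalling amplifies SNAIL activity"),
    e("GSK3B", "inhibition", "SNAIL", "state_transition",
      "GSK-3beta targets SNAIL for degradation, suppressing EMT"),
    e("miR34", "inhibition", "SNAIL", "state_transition",
      "miR-34 and SNAIL form a mutually inhibitory feedback loop"),
    e("SNAIL", "inhibition", "miR34", "state_transition",
      "SNAIL represses miR-34 in the mutually inhibitory loop"),
    e("ZEB", "inhibition", "miR34", "state_transition",
      "ZEB contributes to downregulation of the epithelial miRNAs"),
    e("SNAIL", "inhibition", "miR200", "state_transition",
      "SNAIL contributes to downregulation of the miR-200 family"),
    e("ZEB", "inhibition", "miR200", "state_transition",
      "ZEB and miR-200 form a mutually inhibitory feedback loop"),
    e("miR200", "inhibition", "ZEB", "state_transition",
      "miR-200 represses ZEB in the mutually inhibitory loop"),
    e("SNAIL", "activation", "ZEB", "state_transition",
      "ZEB expression is primarily driven by SNAIL"),
    e("GRHL2", "inhibition", "ZEB", "state_transition",
      "GRHL2 and ZEB form a mutually inhibitory loop stabilising hybrid states"),
    e("ZEB", "inhibition", "GRHL2", "state_transition",
      "ZEB represses GRHL2 in the mutually inhibitory loop"),
    e("OVOL2", "inhibition", "ZEB", "state_transition",
      "OVOL2 and ZEB form a mutually inhibitory loop"),
    e("ZEB", "inhibition", "OVOL2", "state_transition",
      "ZEB represses OVOL2 in the mutually inhibitory loop"),
    e("SNAIL", "inhibition", "GRHL2", "state_transition",
      "EMT transcription factors repress epithelial phenotype-stability genes"),
    e("SNAIL", "inhibition", "OVOL2", "state_transition",
      "EMT transcription factors repress epithelial phenotype-stability genes"),
    e("SNAIL", "inhibition", "ECadherin", "state_transition",
      "SNAIL represses E-cadherin through its E-boxes"),
    e("SNAIL", "inhibition", "ZO1", "state_transition",
      "TGFbeta-driven SNAIL suppresses the tight-junction protein ZO-1"),
    e("TGFBR", "activation", "AKT", "state_transition",
      "the receptor complex activates PI3K/AKT independently of SMADs"),
    e("TWIST", "activation", "AKT", "state_transition",
      "TWIST and AKT form a double-positive feedback loop"),
    e("AKT", "activation", "TWIST", "state_transition",
      "AKT induces TWIST in the double-positive feedback loop"),
    e("AKT", "inhibition", "GSK3B", "state_transition",
      "AKT stabilises SNAIL by blocking GSK-3beta"),
    e("AKT", "activation", "NFKB", "state_transition",
      "AKT signalling activates NF-kB"),
    e("NFKB", "activation", "NKILA", "state_transition",
      "NF-kB induces the lncRNA NKILA"),
    e("NKILA", "inhibition", "NFKB", "state_transition",
      "NKILA feeds back negatively on NF-kB, yielding oscillations"),
    e("SNAIL", "activation", "Goosecoid", "state_transition",
      "SNAIL drives the mesenchymal marker Goosecoid"),
    e("SNAIL", "activation", "NCadherin", "state_transition",
      "EMT transcription factors promote mesenchymal phenotype-associated genes"),
    e("ZEB", "activation", "NCadherin", "state_transition",
      "EMT transcription factors promote mesenchymal phenotype-associated genes"),
    e("p53", "activation", "miR200", "state_transition",
      "p53 sustains epithelial miRNAs that preserve E-cadherin expression"),
    e("p53", "activation", "miR34", "state_transition",
      "p53 sustains epithelial miRNAs that preserve E-cadherin expression"),
    e("MDM2", "inhibition", "p53", "state_transition",
      "MDM2 targets p53 for degradation"),
    e("SMAD", "activation", "MDM2", "state_transition",
      "abstraction: TGFbeta/SMAD signalling is taken to induce MDM2, relieving p53 control of the epithelial miRNAs"),
    e("SNAIL", "activation", "EMT", "logical_activation",
      "EMT onset requires the core mesenchymal regulators"),
    e("ZEB", "activation", "EMT", "logical_activation",
      "EMT onset requires the core mesenchymal regulators"),
    e("TWIST", "activation", "EMT", "logical_activation",
      "EMT onset requires the core mesenchymal regulators"),
    e("ECadherin", "inhibition", "EMT", "logical_activation",
      "intact E-cadherin junctions oppose the EMT phenotype")
  )
}

emt_core_species_table <- function() {
  s <- function(id, name, kind, compartment)
    data.frame(id = id, name = name, kind = kind, compartment = compartment,
               notes = "", stringsAsFactors = FALSE)
  rbind(
    s("TGFB", "TGFbeta", "protein", "extracellular"),
    s("TGFBR", "TGFbeta receptor complex", "complex", "membrane"),
    s("SMAD", "SMAD2/3-SMAD4 complex", "complex", "nucleus"),
    s("SNAIL", "SNAIL/SLUG", "protein", "nucleus"),
    s("ZEB", "ZEB1/2", "protein", "nucleus"),
    s("TWIST", "TWIST1/2", "protein", "nucleus"),
    s("miR200", "miR-200 family", "rna", "cytoplasm"),
    s("miR34", "miR-34 family", "rna", "cytoplasm"),
    s("GRHL2", "GRHL2", "protein", "nucleus"),
    s("OVOL2", "OVOL2", "protein", "nucleus"),
    s("ECadherin", "E-cadherin", "protein", "membrane"),
    s("ZO1", "ZO-1", "protein", "membrane"),
    s("AKT", "AKT", "protein", "cytoplasm"),
    s("GSK3B", "GSK-3beta", "protein", "cytoplasm"),
    s("NFKB", "NF-kB", "protein", "nucleus"),
    s("NKILA", "lncRNA NKILA", "rna", "cytoplasm"),
    s("Goosecoid", "Goosecoid", "protein", "nucleus"),
    s("NCadherin", "N-cadherin", "protein", "membrane"),
    s("p53", "p53", "protein", "nucleus"),
    s("MDM2", "MDM2", "protein", "nucleus"),
    s("EMT", "EMT", "phenotype", "cytoplasm")
  )
}

#' The EMT-core fixture map
#'
#' A deterministic 21-node, 38-interaction abstraction of TGFbeta-induced
#' EMT signalling: receptor activation collapsed to
#' TGFB -> receptor complex -> SMAD complex; SNAIL/SLUG and ZEB1/ZEB2 merged
#' into family nodes; the mutually inhibitory miRNA/TF switches
#' (miR-34-SNAIL, miR-200-ZEB), the phenotype-stability factors GRHL2 and
#' OVOL2, the AKT-TWIST double-positive loop, the GSK-3beta brake on SNAIL,
#' the NF-kB-NKILA negative feedback oscillator, the p53-MDM2 control of the
#' epithelial miRNAs, and an EMT phenotype node driven by the core
#' mesenchymal regulators and opposed by E-cadherin. Every interaction
#' carries a mechanistic provenance note; the same table ships as a
#' plain-text edge table plus JSON manifest under `extdata`.
#'
#' @return a `regulatory_map`.
#' @export
emt_core_fixture <- function() {
  edges <- emt_core_edge_table()
  ints <- data.frame(id = sprintf("emt%02d", seq_len(nrow(edges))),
                     target = edges$target, category = edges$category,
                     sign = edges$sign, note = edges$note,
                     stringsAsFactors = FALSE)
  ints$sources <- as.list(edges$source)
  regulatory_map(emt_core_species_table(), ints,
                 provenance = "emt_core_fixture")
}

#' Write the EMT-core fixture and its manifest to a directory
#'
#' Emits `emt_core_edges.csv` (the edge table, re-readable with
#' [read_edge_table()]) and `emt_core_manifest.json` (species/interaction
#' counts, census, marker sets and per-edge provenance notes). Used to
#' regenerate the copies shipped under `extdata`.
#'
#' @param dir output directory.
#' @return paths of the two files, invisibly.
#' @export
write_emt_core_fixture <- function(dir = ".") {
  map <- emt_core_fixture()
  csv <- file.path(dir, "emt_core_edges.csv")
  write_edge_table(map, csv)
  sm <- summarize_map(map)
  mk <- emt_marker_config()
  edges <- emt_core_edge_table()
  manifest <- list(
    name = "emt_core_fixture",
    n_species = sm$n_species,
    n_interactions = sm$n_interactions,
    species_by_kind = as.list(sm$species_by_kind),
    interactions_by_category = as.list(sm$interactions_by_category),
    input_nodes = list("TGFB"),
    epithelial_markers = mk$epithelial_markers,
    mesenchymal_markers = mk$mesenchymal_markers,
    phenotype_node = mk$phenotype_node,
    edges = lapply(seq_len(nrow(edges)), function(i)
      list(source = edges$source[i], sign = edges$sign[i],
           target = edges$target[i], note = edges$note[i]))
  )
  js <- file.path(dir, "emt_core_manifest.json")
  jsonlite::write_json(manifest, js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv, js))
}
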