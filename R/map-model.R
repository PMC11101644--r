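# Data model and I/O for SBGN-style disease maps.
#
# A regulatory map is the package's central container: a species table, an
# interaction table (signed, possibly multi-source reactions) and a
# provenance descriptor. Species identity is the map-file id, never the
# display name, so the same molecule curated in two compartments stays two
# nodes.

SPECIES_KINDS <- c("protein", "gene", "rna", "complex", "phenotype",
                   "degradation", "unknown")
COMPARTMENTS <- c("cytoplasm", "nucleus", "extracellular", "membrane")
INTERACTION_CATEGORIES <- c("state_transition", "complex_association",
                            "dissociation", "transport",
                            "unknown_transition", "logical_activation")
INTERACTION_SIGNS <- c("activation", "inhibition", "neutral")

# Documented mapping from sign tokens found in edge tables and SBML
# annotations to the canonical sign vocabulary. Unknown tokens fail loudly:
# a silently flipped sign corrupts every downstream rule.
SIGN_TOKENS <- c(
  "activation" = "activation", "activate" = "activation",
  "activates" = "activation", "positive" = "activation",
  "positive_influence" = "activation", "stimulation" = "activation",
  "catalysis" = "activation", "trigger" = "activation", "->" = "activation",
  "1" = "activation", "+1" = "activation",
  "inhibition" = "inhibition", "inhibit" = "inhibition",
  "inhibits" = "inhibition", "negative" = "inhibition",
  "negative_influence" = "inhibition", "repression" = "inhibition",
  "-|" = "inhibition", "-1" = "inhibition",
  "neutral" = "neutral", "transport" = "neutral", "unknown" = "neutral"
)

#' Construct a regulatory map
#'
#' @param species data frame with columns `id`, `name`, `kind`,
#'   `compartment`, `notes` (missing optional columns are filled with
#'   defaults: `name = id`, `kind = "unknown"`, `compartment = "cytoplasm"`,
#'   empty notes).
#' @param interactions data frame with columns `id`, `sources` (list column
#'   of character vectors, or a plain character column for single-source
#'   interactions), `target`, `category`, `sign` and optional `note`.
#' @param provenance short description of where the map came from.
#' @return an object of class `regulatory_map`.
#' @export
regulatory_map <- function(species, interactions, provenance = "in-memory") {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  nsp <- nrow(species)
  if (is.null(species$name)) species$name <- species$id
  if (is.null(species$kind)) species$kind <- rep("unknown", nsp)
  if (is.null(species$compartment))
    species$compartment <- rep("cytoplasm", nsp)
  if (is.null(species$notes)) species$notes <- rep("", nsp)
  species <- species[, c("id", "name", "kind", "compartment", "notes")]

  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  if (nrow(interactions) > 0 && !is.list(interactions$sources)) {
    interactions$sources <- as.list(as.character(interactions$sources))
  }
  if (nrow(interactions) == 0) {
    interactions <- data.frame(id = character(), target = character(),
                               category = character(), sign = character(),
                               note = character(), stringsAsFactors = FALSE)
    interactions$sources <- list()
  }
  if (is.null(interactions$note))
    interactions$note <- rep("", nrow(interactions))
  interactions <- interactions[, c("id", "sources", "target", "category",
                                   "sign", "note")]
  structure(list(species = species, interactions = interactions,
                 provenance = provenance),
            class = "regulatory_map")
}

#' @export
print.regulatory_map <- function(x, ...) {
  cat(sprintf("regulatory_map: %d species, %d interactions (%s)\n",
              n_species(x), n_interactions(x), x$provenance))
  invisible(x)
}

#' Number of species in a map
#' @param map a `regulatory_map`.
#' @export
n_species <- function(map) nrow(map$species)

#' Number of interactions in a map
#' @param map a `regulatory_map`.
#' @export
n_interactions <- function(map) nrow(map$interactions)

#' Flatten interactions into one row per (source, target) edge
#'
#' Multi-source interactions (complex associations) contribute one edge per
#' source, all carrying the interaction's sign and id.
#' @param map a `regulatory_map`.
#' @return data frame with columns `interaction_id`, `source`, `target`,
#'   `sign`, `category`.
#' @export
interaction_edges <- function(map) {
  ints <- map$interactions
  if (nrow(ints) == 0) {
    return(data.frame(interaction_id = character(), source = character(),
                      target = character(), sign = character(),
                      category = character(), stringsAsFactors = FALSE))
  }
  k <- lengths(ints$sources)
  data.frame(interaction_id = rep(ints$id, k),
             source = unlist(ints$sources, use.names = FALSE),
             target = rep(ints$target, k),
             sign = rep(ints$sign, k),
             category = rep(ints$category, k),
             stringsAsFactors = FALSE)
}

#' Validate a regulatory map
#'
#' Checks the structural invariants of the data model and reports (never
#' raises on) content problems.
#'
#' @param map a `regulatory_map`.
#' @return data frame of issues with columns `rule`, `id`, `message`;
#'   zero rows for a valid map.
#' @export
validate_map <- function(map) {
  issues <- list()
  add <- function(rule, id, message) {
    issues[[length(issues) + 1]] <<- data.frame(
      rule = rule, id = id, message = message, stringsAsFactors = FALSE)
  }
  sp <- map$species
  ints <- map$interactions

  if (any(is.na(sp$id) | sp$id == "")) add("species_id_nonempty", "<NA>",
                                           "species with empty id")
  dup <- sp$id[duplicated(sp$id)]
  for (d in unique(dup)) add("species_id_unique", d, "duplicate species id")
  bad_kind <- sp$id[!sp$kind %in% SPECIES_KINDS]
  for (d in bad_kind) add("species_kind", d, "unknown species kind")
  bad_comp <- sp$id[!sp$compartment %in% COMPARTMENTS]
  for (d in bad_comp) add("species_compartment", d, "unknown compartment")

  dup_i <- ints$id[duplicated(ints$id)]
  for (d in unique(dup_i)) add("interaction_id_unique", d,
                               "duplicate interaction id")
  for (i in seq_len(nrow(ints))) {
    srcs <- ints$sources[[i]]
    iid <- ints$id[[i]]
    missing <- setdiff(c(srcs, ints$target[[i]]), sp$id)
    for (m in missing) add("referential_integrity", iid,
                           sprintf("endpoint '%s' not a species in the map", m))
    if (!ints$category[[i]] %in% INTERACTION_CATEGORIES)
      add("interaction_category", iid, "unknown interaction category")
    if (!ints$sign[[i]] %in% INTERACTION_SIGNS)
      add("interaction_sign", iid, "unknown interaction sign")
    if (identical(ints$category[[i]], "complex_association") && length(srcs) < 2)
      add("complex_association_sources", iid,
          "complex_association requires at least 2 sources")
    if (identical(ints$category[[i]], "dissociation") && length(srcs) != 1)
      add("dissociation_sources", iid, "dissociation requires exactly 1 source")
    if (identical(ints$sign[[i]], "neutral") &&
        !ints$category[[i]] %in% c("transport", "dissociation"))
      add("neutral_sign_scope", iid,
          "sign 'neutral' only allowed for transport/dissociation")
  }
  # phenotype nodes are terminal read-outs of the curated map
  pheno <- sp$id[sp$kind == "phenotype"]
  if (length(pheno) > 0 && nrow(ints) > 0) {
    out_src <- unique(unlist(ints$sources, use.names = FALSE))
    for (p in intersect(pheno, out_src))
      add("phenotype_terminal", p, "phenotype node has outgoing interactions")
  }
  if (length(issues) == 0) {
    return(data.frame(rule = character(), id = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Census summary of a regulatory map
#'
#' Tallies species by kind and interactions by category, including zero
#' entries for unused categories, so the counts always sum to the map totals.
#'
#' @param map a `regulatory_map`.
#' @return an object of class `map_summary`.
#' @export
summarize_map <- function(map) {
  by_kind <- table(factor(map$species$kind, levels = SPECIES_KINDS))
  by_cat <- table(factor(map$interactions$category,
                         levels = INTERACTION_CATEGORIES))
  structure(list(
    n_species = n_species(map),
    n_interactions = n_interactions(map),
    species_by_kind = stats::setNames(as.integer(by_kind), names(by_kind)),
    interactions_by_category = stats::setNames(as.integer(by_cat),
                                               names(by_cat)),
    n_compartments = length(unique(map$species$compartment))
  ), class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf("map_summary: %d species / %d interactions / %d compartments\n",
              x$n_species, x$n_interactions, x$n_compartments))
  kinds <- x$species_by_kind[x$species_by_kind > 0]
  cats <- x$interactions_by_category[x$interactions_by_category > 0]
  if (length(kinds)) cat("  species:",
                         paste(names(kinds), kinds, sep = "=", collapse = ", "),
                         "\n")
  if (length(cats)) cat("  interactions:",
                        paste(names(cats), cats, sep = "=", collapse = ", "),
                        "\n")
  invisible(x)
}

#' Export a map summary as JSON
#' @param summary a `map_summary`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @export
map_summary_json <- function(summary, path = NULL) {
  x <- unclass(summary)
  x$species_by_kind <- as.list(x$species_by_kind)
  x$interactions_by_category <- as.list(x$interactions_by_category)
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
  }
}

canonical_sign <- function(token, row = NA_integer_) {
  key <- tolower(trimws(token))
  out <- unname(SIGN_TOKENS[key])
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    where <- if (is.na(row[bad[1]])) "" else sprintf(" at row %d", row[bad[1]])
    stop_fmt("emtmap_format_error",
             "unresolvable sign token '%s'%s", token[bad[1]], where)
  }
  out
}

#' Read a SIF-like edge table into a regulatory map
#'
#' Expects a delimited UTF-8 text file with a header row and (configurably
#' named) columns for source, sign and target; optional columns give the
#' interaction id (rows sharing an id are grouped into one multi-source
#' interaction), category, and per-endpoint kind/compartment.
#'
#' @param path file path.
#' @param dialect named list of column names:
#'   `source`, `sign`, `target` (mandatory), `id`, `category`,
#'   `source_kind`, `target_kind`, `source_compartment`,
#'   `target_compartment`, `note` (optional).
#' @param sep field separator; `","` by default, use `"\t"` for TSV.
#' @return a `regulatory_map`.
#' @export
read_edge_table <- function(path,
                            dialect = list(source = "source", sign = "sign",
                                           target = "target"),
                            sep = ",") {
  if (!file.exists(path))
    stop_fmt("emtmap_io_error", "file not found: %s", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      comment.char = "", stringsAsFactors = FALSE,
                      check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop_fmt("emtmap_format_error",
                                 "cannot parse edge table %s: %s",
                                 path, conditionMessage(e)))
  for (col in c("source", "sign", "target")) {
    name <- dialect[[col]] %||% col
    if (!name %in% names(df))
      stop_fmt("emtmap_format_error",
               "missing mandatory column '%s' in %s", name, path)
  }
  get_col <- function(role, default = NULL) {
    nm <- dialect[[role]] %||% role
    if (nm %in% names(df)) df[[nm]] else default
  }
  src <- as.character(get_col("source"))
  tgt <- as.character(get_col("target"))
  if (nrow(df) > 0 && any(is.na(src) | trimws(src) == ""))
    stop_fmt("emtmap_format_error", "blank source at row %d",
             which(is.na(src) | trimws(src) == "")[1])
  if (nrow(df) > 0 && any(is.na(tgt) | trimws(tgt) == ""))
    stop_fmt("emtmap_format_error", "blank target at row %d",
             which(is.na(tgt) | trimws(tgt) == "")[1])
  sign <- canonical_sign(as.character(get_col("sign")), row = seq_len(nrow(df)))
  iid <- as.character(get_col("id", sprintf("i%04d", seq_len(nrow(df)))))
  category <- as.character(get_col("category", rep("state_transition",
                                                   nrow(df))))
  note <- as.character(get_col("note", rep("", nrow(df))))

  # species: first occurrence wins for kind/compartment annotations
  kind_src <- get_col("source_kind")
  kind_tgt <- get_col("target_kind")
  comp_src <- get_col("source_compartment")
  comp_tgt <- get_col("target_compartment")
  ids <- c(src, tgt)
  kinds <- c(if (is.null(kind_src)) rep("unknown", length(src)) else kind_src,
             if (is.null(kind_tgt)) rep("unknown", length(tgt)) else kind_tgt)
  comps <- c(if (is.null(comp_src)) rep("cytoplasm", length(src)) else comp_src,
             if (is.null(comp_tgt)) rep("cytoplasm", length(tgt)) else comp_tgt)
  first <- !duplicated(ids)
  species <- data.frame(id = ids[first], name = ids[first],
                        kind = kinds[first], compartment = comps[first],
                        notes = "", stringsAsFactors = FALSE)

  # group rows sharing an interaction id into one multi-source interaction
  grp <- split(seq_len(nrow(df)), factor(iid, levels = unique(iid)))
  ints <- data.frame(id = names(grp), stringsAsFactors = FALSE)
  ints$sources <- lapply(grp, function(rows) src[rows])
  ints$target <- vapply(grp, function(rows) tgt[rows[1]], character(1))
  ints$category <- vapply(grp, function(rows) category[rows[1]], character(1))
  ints$sign <- vapply(grp, function(rows) sign[rows[1]], character(1))
  ints$note <- vapply(grp, function(rows) note[rows[1]], character(1))
  regulatory_map(species, ints, provenance = path)
}

#' Write a regulatory map as an edge table
#'
#' Rows are sorted by interaction id (then source) so two writes of the same
#' map are byte-identical; a read-back reproduces species labels, endpoints
#' and signs.
#'
#' @param map a `regulatory_map`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(map, path, sep = ",") {
  edges <- interaction_edges(map)
  sp <- map$species
  idx_t <- match(edges$target, sp$id)
  idx_s <- match(edges$source, sp$id)
  out <- data.frame(id = edges$interaction_id,
                    source = edges$source,
                    sign = edges$sign,
                    target = edges$target,
                    category = edges$category,
                    source_kind = sp$kind[idx_s],
                    target_kind = sp$kind[idx_t],
                    source_compartment = sp$compartment[idx_s],
                    target_compartment = sp$compartment[idx_t],
                    stringsAsFactors = FALSE)
  out <- out[order(out$id, out$source, method = "radix"), , drop = FALSE]
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop_fmt("emtmap_io_error",
                                               "cannot write %s: %s", path,
                                               conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
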