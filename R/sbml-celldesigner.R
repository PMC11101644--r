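# Reader for CellDesigner-dialect SBML (process-description disease maps).
#
# CellDesigner stores the SBGN class of each species and the type of each
# reaction inside its extension annotations; plain SBML (no extension) is
# accepted with degraded kind information (every species becomes "unknown").

CD_NS <- "http://www.sbml.org/2001/ns/celldesigner"

# CellDesigner species class -> map kind
CD_CLASS_KIND <- c(
  "PROTEIN" = "protein", "RECEPTOR" = "protein", "ION_CHANNEL" = "protein",
  "TRUNCATED" = "protein", "GENERIC" = "protein",
  "GENE" = "gene",
  "RNA" = "rna", "ANTISENSE_RNA" = "rna",
  "COMPLEX" = "complex",
  "PHENOTYPE" = "phenotype",
  "DEGRADED" = "degradation",
  "UNKNOWN" = "unknown", "SIMPLE_MOLECULE" = "unknown", "ION" = "unknown",
  "DRUG" = "unknown"
)

# CellDesigner reaction type -> (category, sign)
CD_REACTION_TYPE <- list(
  "STATE_TRANSITION" = c("state_transition", "activation"),
  "TRANSCRIPTION" = c("state_transition", "activation"),
  "TRANSLATION" = c("state_transition", "activation"),
  "POSITIVE_INFLUENCE" = c("state_transition", "activation"),
  "REDUCED_PHYSICAL_STIMULATION" = c("state_transition", "activation"),
  "NEGATIVE_INFLUENCE" = c("state_transition", "inhibition"),
  "REDUCED_INHIBITION" = c("state_transition", "inhibition"),
  "INHIBITION" = c("state_transition", "inhibition"),
  "HETERODIMER_ASSOCIATION" = c("complex_association", "activation"),
  "DISSOCIATION" = c("dissociation", "neutral"),
  "TRUNCATION" = c("dissociation", "neutral"),
  "TRANSPORT" = c("transport", "neutral"),
  "KNOWN_TRANSITION_OMITTED" = c("unknown_transition", "activation"),
  "UNKNOWN_TRANSITION" = c("unknown_transition", "activation"),
  "REDUCED_TRIGGER" = c("logical_activation", "activation"),
  "BOOLEAN_LOGIC_GATE" = c("logical_activation", "activation")
)

# CellDesigner modification type -> sign of the modifier arc
CD_MODIFIER_SIGN <- c(
  "CATALYSIS" = "activation", "UNKNOWN_CATALYSIS" = "activation",
  "PHYSICAL_STIMULATION" = "activation", "TRIGGER" = "activation",
  "MODULATION" = "activation", "TRANSCRIPTIONAL_ACTIVATION" = "activation",
  "TRANSLATIONAL_ACTIVATION" = "activation",
  "INHIBITION" = "inhibition", "UNKNOWN_INHIBITION" = "inhibition",
  "TRANSCRIPTIONAL_INHIBITION" = "inhibition",
  "TRANSLATIONAL_INHIBITION" = "inhibition"
)

map_compartment <- function(name) {
  n <- tolower(name)
  out <- rep("cytoplasm", length(n))
  out[grepl("nucl", n)] <- "nucleus"
  out[grepl("extra", n)] <- "extracellular"
  out[grepl("membrane", n)] <- "membrane"
  out
}

xml_find_local <- function(node, name) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
}

#' Read a CellDesigner SBML disease map
#'
#' Parses an SBML Level 2/3 file, using CellDesigner extension annotations
#' (species class, reaction type, modification type) when present to assign
#' species kinds and interaction categories/signs. Each SBML reaction yields
#' one interaction from its reactants to its product; each modifier yields an
#' additional interaction onto the same product, signed by its modification
#' type (unannotated modifiers count as activators). Reactions without a
#' product are treated as degradations and target a synthetic sink species.
#'
#' @param path path to an SBML file.
#' @return a `regulatory_map`.
#' @export
read_celldesigner_sbml <- function(path) {
  if (!file.exists(path))
    stop_fmt("emtmap_io_error", "file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_fmt(
                    "emtmap_parse_error", "malformed XML in %s: %s",
                    path, conditionMessage(e)))
  model <- xml_find_local(doc, "model")
  if (length(model) == 0)
    stop_fmt("emtmap_format_error", "no SBML model element in %s", path)
  model <- model[[1]]

  comp_nodes <- xml_find_local(model, "compartment")
  comp_names <- stats::setNames(
    vapply(comp_nodes, function(n)
      xml2::xml_attr(n, "name") %||% xml2::xml_attr(n, "id"), character(1)),
    vapply(comp_nodes, function(n) xml2::xml_attr(n, "id"), character(1)))

  sp_nodes <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(sp_nodes) == 0)
    stop_fmt("emtmap_format_error", "SBML model in %s declares no species",
             path)
  sp_id <- vapply(sp_nodes, function(n) xml2::xml_attr(n, "id"), character(1))
  sp_name <- vapply(sp_nodes, function(n)
    xml2::xml_attr(n, "name") %||% xml2::xml_attr(n, "id"), character(1))
  sp_comp <- vapply(sp_nodes, function(n)
    xml2::xml_attr(n, "compartment") %||% "", character(1))
  sp_kind <- vapply(sp_nodes, function(n) {
    cls <- xml_find_local(n, "class")
    if (length(cls) == 0) return("unknown")
    unname(CD_CLASS_KIND[xml2::xml_text(cls[[1]])] %||% "unknown")
  }, character(1))
  sp_kind[is.na(sp_kind)] <- "unknown"
  comp_label <- ifelse(sp_comp %in% names(comp_names),
                       comp_names[sp_comp], sp_comp)
  species <- data.frame(id = sp_id, name = sp_name, kind = sp_kind,
                        compartment = map_compartment(comp_label),
                        notes = "", stringsAsFactors = FALSE)

  rxn_nodes <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  ints <- list()
  extra_species <- list()
  for (rx in rxn_nodes) {
    rid <- xml2::xml_attr(rx, "id")
    rtype_node <- xml_find_local(rx, "reactionType")
    rtype <- if (length(rtype_node)) xml2::xml_text(rtype_node[[1]]) else
      "STATE_TRANSITION"
    cat_sign <- CD_REACTION_TYPE[[rtype]] %||% c("unknown_transition",
                                                 "activation")
    reactants <- vapply(xml2::xml_find_all(
      rx, ".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']"),
      function(n) xml2::xml_attr(n, "species"), character(1))
    products <- vapply(xml2::xml_find_all(
      rx, ".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']"),
      function(n) xml2::xml_attr(n, "species"), character(1))
    if (length(products) == 0) {
      sink <- paste0(rid, "_deg")
      extra_species[[sink]] <- data.frame(
        id = sink, name = sink, kind = "degradation",
        compartment = "cytoplasm", notes = "synthetic degradation sink",
        stringsAsFactors = FALSE)
      products <- sink
    }
    if (length(reactants) == 0) reactants <- character(0)
    for (pi in seq_along(products)) {
      iid <- if (length(products) == 1) rid else sprintf("%s_p%d", rid, pi)
      if (length(reactants) > 0) {
        ints[[length(ints) + 1]] <- list(
          id = iid, sources = reactants, target = products[pi],
          category = cat_sign[1], sign = cat_sign[2], note = rtype)
      }
      # modifier arcs: one signed interaction per modifier
      mods <- xml2::xml_find_all(
        rx, ".//*[local-name()='listOfModifiers']/*[local-name()='modifierSpeciesReference']")
      mod_types <- xml_find_local(rx, "modification")
      type_by_species <- stats::setNames(
        vapply(mod_types, function(n) xml2::xml_attr(n, "type"), character(1)),
        vapply(mod_types, function(n) xml2::xml_attr(n, "modifiers"),
               character(1)))
      for (mi in seq_along(mods)) {
        msp <- xml2::xml_attr(mods[[mi]], "species")
        mtype <- type_by_species[msp]
        msign <- if (!is.na(mtype)) CD_MODIFIER_SIGN[mtype] %||% "activation"
                 else "activation"
        if (is.na(msign)) msign <- "activation"
        ints[[length(ints) + 1]] <- list(
          id = sprintf("%s_m%d", iid, mi), sources = msp,
          target = products[pi], category = "state_transition",
          sign = unname(msign),
          note = sprintf("modifier(%s)", if (is.na(mtype)) "?" else mtype))
      }
    }
  }
  if (length(extra_species) > 0)
    species <- rbind(species, do.call(rbind, unname(extra_species)))
  if (length(ints) == 0) {
    interactions <- data.frame(id = character(), target = character(),
                               category = character(), sign = character(),
                               note = character(), stringsAsFactors = FALSE)
    interactions$sources <- list()
  } else {
    interactions <- data.frame(
      id = vapply(ints, `[[`, character(1), "id"),
      target = vapply(ints, `[[`, character(1), "target"),
      category = vapply(ints, `[[`, character(1), "category"),
      sign = vapply(ints, `[[`, character(1), "sign"),
      note = vapply(ints, `[[`, character(1), "note"),
      stringsAsFactors = FALSE)
    interactions$sources <- lapply(ints, `[[`, "sources")
  }
  regulatory_map(species, interactions, provenance = path)
}
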