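# SBML-qual (Level 3 Version 1) import/export for binary logical models.
#
# One qualitative species per rule target (maxLevel 1) and one transition per
# non-input rule; inputs are encoded as qualitative species without a
# transition. Rules are stored as MathML over eq-comparisons against level 1,
# the convention used by logical-model translators in this ecosystem.

QUAL_NS <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

expr_to_mathml <- function(e) {
  switch(e$op,
         lit = sprintf(
           "<apply><eq/><ci>%s</ci><cn type=\"integer\">1</cn></apply>",
           xml_escape(e$id)),
         not = sprintf("<apply><not/>%s</apply>", expr_to_mathml(e$arg)),
         and = sprintf("<apply><and/>%s</apply>",
                       paste(vapply(e$args, expr_to_mathml, character(1)),
                             collapse = "")),
         or = sprintf("<apply><or/>%s</apply>",
                      paste(vapply(e$args, expr_to_mathml, character(1)),
                            collapse = "")))
}

#' Write a logical model as SBML-qual
#'
#' @param model a `logic_model`.
#' @param path output file path.
#' @param model_id id recorded on the SBML model element.
#' @return `path`, invisibly.
#' @export
write_sbml_qual <- function(model, path, model_id = "logic_model") {
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "level=\"3\" version=\"1\" xmlns:qual=\"", QUAL_NS,
           "\" qual:required=\"true\">"),
    sprintf("  <model id=\"%s\">", xml_escape(model_id)),
    "    <listOfCompartments>",
    "      <compartment id=\"default\" constant=\"true\"/>",
    "    </listOfCompartments>",
    "    <qual:listOfQualitativeSpecies>")
  for (t in model$node_order) {
    lines <- c(lines, sprintf(
      paste0("      <qual:qualitativeSpecies qual:id=\"%s\" ",
             "qual:compartment=\"default\" qual:constant=\"false\" ",
             "qual:maxLevel=\"1\"/>"), xml_escape(t)))
  }
  lines <- c(lines, "    </qual:listOfQualitativeSpecies>",
             "    <qual:listOfTransitions>")
  for (t in model$node_order) {
    rule <- model$rules[[t]]
    if (rule$is_input) next
    regs <- c_sort(expr_literals(rule$expr))
    lines <- c(lines, sprintf("      <qual:transition qual:id=\"tr_%s\">",
                              xml_escape(t)),
               "        <qual:listOfInputs>")
    for (r in regs) {
      lines <- c(lines, sprintf(
        paste0("          <qual:input qual:id=\"tr_%s_in_%s\" ",
               "qual:qualitativeSpecies=\"%s\" ",
               "qual:transitionEffect=\"none\"/>"),
        xml_escape(t), xml_escape(r), xml_escape(r)))
    }
    lines <- c(lines,
               "        </qual:listOfInputs>",
               "        <qual:listOfOutputs>",
               sprintf(paste0("          <qual:output qual:qualitativeSpecies",
                              "=\"%s\" qual:transitionEffect=",
                              "\"assignmentLevel\"/>"), xml_escape(t)),
               "        </qual:listOfOutputs>",
               "        <qual:listOfFunctionTerms>",
               "          <qual:defaultTerm qual:resultLevel=\"0\"/>",
               "          <qual:functionTerm qual:resultLevel=\"1\">",
               sprintf("            <math xmlns=\"%s\">%s</math>", MATHML_NS,
                       expr_to_mathml(rule$expr)),
               "          </qual:functionTerm>",
               "        </qual:listOfFunctionTerms>",
               "      </qual:transition>")
  }
  lines <- c(lines, "    </qual:listOfTransitions>", "  </model>", "</sbml>")
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop_fmt("emtmap_io_error",
                                               "cannot write %s: %s", path,
                                               conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

mathml_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1)
      stop_fmt("emtmap_format_error", "math element must have one child")
    return(mathml_to_expr(kids[[1]]))
  }
  if (name == "ci") return(lx_lit(trimws(xml2::xml_text(node))))
  if (name != "apply")
    stop_fmt("emtmap_format_error", "unsupported MathML element '%s'", name)
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  args <- kids[-1]
  if (op == "eq") {
    ci <- trimws(xml2::xml_text(args[[1]]))
    level <- suppressWarnings(as.numeric(xml2::xml_text(args[[2]])))
    if (is.na(level) || !level %in% c(0, 1))
      stop_fmt("emtmap_multilevel_error",
               "comparison against level %s: only binary models supported",
               xml2::xml_text(args[[2]]))
    e <- lx_lit(ci)
    return(if (level == 1) e else lx_not(e))
  }
  sub <- lapply(args, mathml_to_expr)
  switch(op,
         not = lx_not(sub[[1]]),
         and = lx_nary("and", sub),
         or = lx_nary("or", sub),
         stop_fmt("emtmap_format_error", "unsupported MathML operator '%s'",
                  op))
}

#' Read an SBML-qual file into a logical model
#'
#' Only binary models are supported: a qualitative species declaring
#' `maxLevel > 1` raises an unsupported-multilevel error. Species without a
#' transition become inputs with identity rules.
#'
#' @param path path to an SBML-qual file.
#' @return a `logic_model`.
#' @export
read_sbml_qual <- function(path) {
  if (!file.exists(path))
    stop_fmt("emtmap_io_error", "file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_fmt(
                    "emtmap_parse_error", "malformed XML in %s: %s", path,
                    conditionMessage(e)))
  qs <- xml_find_local(doc, "qualitativeSpecies")
  if (length(qs) == 0)
    stop_fmt("emtmap_format_error", "no qualitative species in %s", path)
  get_qattr <- function(node, attr) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) v <- xml2::xml_attr(node, paste0("qual:", attr))
    v
  }
  ids <- vapply(qs, get_qattr, character(1), "id")
  max_levels <- vapply(qs, get_qattr, character(1), "maxLevel")
  ml <- suppressWarnings(as.numeric(max_levels))
  if (any(!is.na(ml) & ml > 1))
    stop_fmt("emtmap_multilevel_error",
             "qualitative species '%s' has maxLevel %s: only binary models supported",
             ids[which(!is.na(ml) & ml > 1)[1]],
             max_levels[which(!is.na(ml) & ml > 1)[1]])

  rules <- stats::setNames(vector("list", length(ids)), ids)
  for (tr in xml_find_local(doc, "transition")) {
    outs <- xml_find_local(tr, "output")
    if (length(outs) == 0) next
    target <- get_qattr(outs[[1]], "qualitativeSpecies")
    if (!target %in% ids)
      stop_fmt("emtmap_format_error",
               "transition output references undeclared species '%s'", target)
    terms <- xml_find_local(tr, "functionTerm")
    expr <- NULL
    for (ft in terms) {
      lvl <- suppressWarnings(as.numeric(get_qattr(ft, "resultLevel")))
      if (is.na(lvl)) next
      if (lvl > 1)
        stop_fmt("emtmap_multilevel_error",
                 "function term with resultLevel %s: only binary models supported",
                 get_qattr(ft, "resultLevel"))
      if (lvl == 1) {
        math <- xml_find_local(ft, "math")
        if (length(math) == 0)
          stop_fmt("emtmap_format_error",
                   "function term for '%s' has no math element", target)
        expr <- mathml_to_expr(math[[1]])
      }
    }
    if (is.null(expr))
      stop_fmt("emtmap_format_error",
               "transition for '%s' has no resultLevel-1 function term",
               target)
    undeclared <- setdiff(expr_literals(expr), ids)
    if (length(undeclared) > 0)
      stop_fmt("emtmap_format_error",
               "transition for '%s' references undeclared species '%s'",
               target, undeclared[1])
    rules[[target]] <- new_logic_rule(target, expr)
  }
  for (t in ids) {
    if (is.null(rules[[t]])) rules[[t]] <- new_logic_rule(t, lx_lit(t),
                                                          is_input = TRUE)
  }
  inputs <- ids[vapply(rules, `[[`, logical(1), "is_input")]
  structure(list(rules = rules, node_order = ids, inputs = inputs),
            class = "logic_model")
}
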