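# Phenotype calling: classify Boolean states and simulated time courses as
# epithelial, mesenchymal or hybrid from configured marker node sets.

#' Marker configuration for phenotype calling
#'
#' @param epithelial_markers,mesenchymal_markers disjoint, non-empty species
#'   id vectors.
#' @param phenotype_node optional dedicated phenotype read-out node (e.g. an
#'   EMT node); recorded for downstream reporting, not used by the
#'   classification rule.
#' @param majority_threshold fraction in (0.5, 1] of markers of one class
#'   that must be ON to call that class.
#' @return a `marker_config`.
#' @export
marker_config <- function(epithelial_markers, mesenchymal_markers,
                          phenotype_node = NULL,
                          majority_threshold = 0.75) {
  if (length(epithelial_markers) == 0 || length(mesenchymal_markers) == 0)
    stop_fmt("emtmap_config_error", "marker lists must be non-empty")
  if (length(intersect(epithelial_markers, mesenchymal_markers)) > 0)
    stop_fmt("emtmap_config_error", "marker lists must be disjoint")
  if (majority_threshold <= 0.5 || majority_threshold > 1)
    stop_fmt("emtmap_config_error",
             "majority_threshold must lie in (0.5, 1]")
  structure(list(epithelial_markers = epithelial_markers,
                 mesenchymal_markers = mesenchymal_markers,
                 phenotype_node = phenotype_node,
                 majority_threshold = majority_threshold),
            class = "marker_config")
}

#' Default marker configuration for the EMT-core fixture
#'
#' Epithelial side: E-cadherin, ZO-1, miR-200, GRHL2, OVOL2; mesenchymal
#' side: SNAIL, ZEB, TWIST, Goosecoid, N-cadherin; dedicated phenotype node
#' EMT; majority threshold 0.75.
#' @return a `marker_config`.
#' @export
emt_marker_config <- function() {
  marker_config(
    epithelial_markers = c("ECadherin", "ZO1", "miR200", "GRHL2", "OVOL2"),
    mesenchymal_markers = c("SNAIL", "ZEB", "TWIST", "Goosecoid",
                            "NCadherin"),
    phenotype_node = "EMT",
    majority_threshold = 0.75)
}

#' Classify a single network state
#'
#' With threshold `t`: epithelial if the epithelial ON-fraction is at least
#' `t` and the mesenchymal ON-fraction at most `1 - t`; mesenchymal under the
#' mirror condition; otherwise hybrid when at least one marker is ON on each
#' side (marker coexistence); undetermined when either side is fully OFF and
#' no majority label applies. Exactly one label is assigned.
#'
#' @param state named binary vector covering all marker ids.
#' @param config a [marker_config()].
#' @return a `phenotype_call`: label plus the two exact marker fractions.
#' @export
classify_state <- function(state, config) {
  need <- c(config$epithelial_markers, config$mesenchymal_markers)
  missing <- setdiff(need, names(state))
  if (length(missing) > 0)
    stop_fmt("emtmap_contract_error", "state is missing marker '%s'",
             missing[1])
  e_on <- sum(as.logical(state[config$epithelial_markers]))
  m_on <- sum(as.logical(state[config$mesenchymal_markers]))
  ef <- e_on / length(config$epithelial_markers)
  mf <- m_on / length(config$mesenchymal_markers)
  thr <- config$majority_threshold
  label <- if (ef >= thr && mf <= 1 - thr) "epithelial"
  else if (mf >= thr && ef <= 1 - thr) "mesenchymal"
  else if (e_on >= 1 && m_on >= 1) "hybrid"
  else "undetermined"
  structure(list(label = label, epithelial_fraction = ef,
                 mesenchymal_fraction = mf),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf("phenotype: %s (E %.2f / M %.2f)\n", x$label,
              x$epithelial_fraction, x$mesenchymal_fraction))
  invisible(x)
}

#' Phenotype time course of a trajectory or activity profile
#'
#' Classifies every state of a trajectory, or every window of an activity
#' profile after binarising window means at `binarize` (default 0.5), and
#' summarises label transitions (first index at which each new label
#' appears).
#'
#' @param x a `trajectory` or `activity_profile`.
#' @param config a [marker_config()].
#' @param binarize cut point applied to window means of a profile.
#' @return data frame with columns `index`, `label`,
#'   `epithelial_fraction`, `mesenchymal_fraction`; the transition summary is
#'   attached as attribute `"transitions"`.
#' @export
phenotype_course <- function(x, config, binarize = 0.5) {
  if (inherits(x, "trajectory")) {
    states <- x$states
  } else if (inherits(x, "activity_profile")) {
    states <- x$values >= binarize
  } else {
    stop_fmt("emtmap_contract_error",
             "x must be a trajectory or an activity_profile")
  }
  if (is.null(dim(states)) || nrow(states) == 0)
    stop_fmt("emtmap_contract_error", "empty trajectory")
  calls <- lapply(seq_len(nrow(states)), function(i)
    classify_state(states[i, ], config))
  out <- data.frame(
    index = seq_len(nrow(states)),
    label = vapply(calls, `[[`, character(1), "label"),
    epithelial_fraction = vapply(calls, `[[`, numeric(1),
                                 "epithelial_fraction"),
    mesenchymal_fraction = vapply(calls, `[[`, numeric(1),
                                  "mesenchymal_fraction"),
    stringsAsFactors = FALSE)
  change <- c(TRUE, out$label[-1] != out$label[-nrow(out)])
  attr(out, "transitions") <- out[change, c("index", "label")]
  out
}
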