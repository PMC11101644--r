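# End-to-end orchestration: read/validate/summarise a map, infer the logical
# model, simulate the stimulus-off and stimulus-on scenarios, call
# phenotypes, run the topology battery and hub ranking, and export a
# reproducible report bundle with checksummed artefacts.

#' Pipeline configuration
#'
#' @param map a `regulatory_map`, a path to an edge table (.csv/.tsv) or
#'   SBML (.xml/.sbml) file, or `"fixture"` for the packaged EMT core.
#' @param stimulus input node clamped to 0 and 1 in the two canonical
#'   scenarios.
#' @param n_steps,window,ensemble simulation settings (asynchronous updates).
#' @param markers a [marker_config()]; defaults to the EMT fixture markers.
#' @param hub_k size of the hub subnetwork.
#' @param seed base seed for all stochastic stages.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(map = "fixture", stimulus = "TGFB",
                            n_steps = 5000, window = 50, ensemble = 100,
                            markers = emt_marker_config(), hub_k = 25,
                            seed = 1L) {
  if (hub_k < 1) stop_fmt("emtmap_config_error", "hub_k must be >= 1")
  structure(list(map = map, stimulus = stimulus,
                 n_steps = as.integer(n_steps), window = as.integer(window),
                 ensemble = as.integer(ensemble), markers = markers,
                 hub_k = as.integer(hub_k), seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_fmt("emtmap_pipeline_error", "stage '%s' failed: %s", name,
             conditionMessage(e))
  })
}

load_pipeline_map <- function(map) {
  if (inherits(map, "regulatory_map")) return(map)
  if (identical(map, "fixture")) return(emt_core_fixture())
  if (!is.character(map) || length(map) != 1)
    stop_fmt("emtmap_config_error", "map must be a regulatory_map, a path, or 'fixture'")
  if (!file.exists(map))
    stop_fmt("emtmap_io_error", "map file not found: %s", map)
  if (grepl("\\.(xml|sbml)$", map, ignore.case = TRUE))
    read_celldesigner_sbml(map)
  else if (grepl("\\.tsv$", map, ignore.case = TRUE))
    read_edge_table(map, sep = "\t")
  else read_edge_table(map)
}

#' Run the full analysis pipeline
#'
#' Executes read -> validate -> summarise -> infer rules -> simulate the
#' stimulus-off and stimulus-on scenarios (asynchronous ensemble activity
#' profiles) -> phenotype courses -> topology reports (both modes) -> MCC
#' ranking -> top-k hub subnetwork. Any stage error propagates with the
#' stage name.
#'
#' @param config a [pipeline_config()].
#' @return a `report_bundle` with all artefacts plus run metadata.
#' @export
run_paper_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  map <- stage("read", load_pipeline_map(config$map))
  issues <- stage("validate", validate_map(map))
  if (nrow(issues) > 0)
    stop_fmt("emtmap_pipeline_error",
             "stage 'validate' failed: %d issue(s), first: %s [%s]",
             nrow(issues), issues$message[1], issues$id[1])
  summary <- stage("summarize", summarize_map(map))
  model <- stage("infer_rules", infer_rules(map))
  scenario <- function(clamp_value, seed_offset) {
    clamps <- stats::setNames(clamp_value, config$stimulus)
    cfg <- sim_config(scheme = "asynchronous", n_steps = config$n_steps,
                      clamps = clamps, initial = "epithelial",
                      seed = config$seed + seed_offset,
                      markers = config$markers)
    activity_profile(model, cfg, window = config$window,
                     ensemble = config$ensemble)
  }
  profile_off <- stage("simulate_off", scenario(0, 0L))
  profile_on <- stage("simulate_on", scenario(1, config$ensemble))
  course_off <- stage("phenotype_off",
                      phenotype_course(profile_off, config$markers))
  course_on <- stage("phenotype_on",
                     phenotype_course(profile_on, config$markers))
  topo_dir <- stage("topology_directed", topology_report(map, "directed"))
  topo_und <- stage("topology_undirected",
                    topology_report(map, "undirected"))
  ranking <- stage("hubs", mcc_scores(map))
  k <- min(config$hub_k, length(ranking$ranked_ids))
  submap <- stage("hub_subnetwork", top_k_subnetwork(ranking, k, map))
  structure(list(
    map = map, summary = summary, model = model,
    profile_off = profile_off, profile_on = profile_on,
    course_off = course_off, course_on = course_on,
    topology = list(directed = topo_dir, undirected = topo_und),
    ranking = ranking, hub_subnetwork = submap,
    metadata = list(seed = config$seed, n_steps = config$n_steps,
                    window = config$window, ensemble = config$ensemble,
                    stimulus = config$stimulus, hub_k = k,
                    package_version = as.character(
                      utils::packageVersion("emtmap")))
  ), class = "report_bundle")
}

write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
}

#' Export a report bundle to a directory
#'
#' Writes CSV/JSON artefacts with stable names plus a `MANIFEST` listing each
#' file with its MD5 checksum; [verify_report()] re-checks the checksums.
#' Exports are deterministic: re-exporting the same bundle reproduces
#' identical checksums.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
export_report <- function(bundle, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop_fmt("emtmap_io_error", "cannot create directory %s", dir)
  files <- character(0)
  out <- function(name) { files <<- c(files, name); file.path(dir, name) }

  map_summary_json(bundle$summary, out("map_summary.json"))
  writeLines(sprintf("%s = %s", names(model_rules_text(bundle$model)),
                     model_rules_text(bundle$model)),
             out("logic_rules.txt"))
  write_profile_csv(bundle$profile_off, out("activity_stimulus_off.csv"))
  write_profile_csv(bundle$profile_on, out("activity_stimulus_on.csv"))
  utils::write.csv(bundle$course_off, out("phenotype_stimulus_off.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$course_on, out("phenotype_stimulus_on.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(lapply(bundle$topology, unclass),
                       out("topology.json"), auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  hubs <- data.frame(rank = seq_along(bundle$ranking$ranked_ids),
                     id = bundle$ranking$ranked_ids,
                     mcc = unname(
                       bundle$ranking$scores[bundle$ranking$ranked_ids]))
  utils::write.table(hubs, out("hub_ranking.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_edge_table(bundle$hub_subnetwork, out("hub_subnetwork.csv"))
  jsonlite::write_json(bundle$metadata, out("run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  sums <- tools::md5sum(file.path(dir, files))
  manifest <- data.frame(file = files, md5 = unname(sums),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "MANIFEST"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Verify an exported report bundle against its MANIFEST
#'
#' @param dir directory written by [export_report()].
#' @return list with `ok` flag and a data frame of mismatching/missing files.
#' @export
verify_report <- function(dir) {
  mpath <- file.path(dir, "MANIFEST")
  if (!file.exists(mpath))
    stop_fmt("emtmap_io_error", "no MANIFEST in %s", dir)
  manifest <- utils::read.table(mpath, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  actual <- tools::md5sum(file.path(dir, manifest$file))
  bad <- manifest[is.na(actual) | actual != manifest$md5, , drop = FALSE]
  list(ok = nrow(bad) == 0, mismatches = bad)
}
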