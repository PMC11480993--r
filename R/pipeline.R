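# End-to-end pipeline orchestration.
#
# run_pipeline() chains curation -> fragmentation -> tally -> network ->
# shared-scaffold analysis for a target pair, writing every stage output
# plus a machine-readable summary of the filter cascade (records in,
# records surviving each filter, scaffolds before/after the support
# filter, shared scaffolds).

.an_default_config <- function() {
  list(
    bioactivity = NULL, pdb_evidence = NULL, columns = NULL,
    targets = c("CHEMBL3105", "CHEMBL1163125"),
    ppot_threshold = 5.0, min_support = 5L, allowed_rings = c(2L, 3L),
    seed = 1L, out = "amidenet_run", format = "graphml"
  )
}

#' Assemble a pipeline run configuration
#'
#' @param config optional named list or path to a YAML file; entries
#'   override the defaults (`targets`, `ppot_threshold = 5`,
#'   `min_support = 5`, `allowed_rings = c(2, 3)`, `seed`, `out`,
#'   `format`, input paths `bioactivity`, `pdb_evidence`, and a `columns`
#'   mapping for [read_bioactivity()]).
#' @param ... individual overrides applied after `config`.
#' @return the merged configuration list.
#' @export
run_config <- function(config = NULL, ...) {
  cfg <- .an_default_config()
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  for (src in list(config, list(...))) {
    for (nm in names(src)) cfg[[nm]] <- src[[nm]]
  }
  cfg$targets <- as.character(cfg$targets)
  if (length(cfg$targets) != 2) {
    stop("the pipeline analyses a target pair; got ",
         length(cfg$targets), " target(s)", call. = FALSE)
  }
  cfg
}

#' Run the merged-pharmacophore pipeline
#'
#' Executes curate -> fragment -> tally -> network -> shared for the
#' configured target pair and writes all stage outputs to the output
#' directory: potency annotations, drop log, scaffold rows, per-target
#' frequency tables, the network (in the configured format), the shared
#' scaffold ranking, and a JSON summary of the filter cascade.
#'
#' @param config a configuration from [run_config()] (or anything it
#'   accepts).
#' @param bioactivity optional in-memory measurement table (canonical
#'   schema), used instead of reading `config$bioactivity` from disk.
#' @param pdb_evidence optional in-memory evidence table.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = NULL, bioactivity = NULL,
                         pdb_evidence = NULL) {
  cfg <- run_config(config)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out, "run.log")
  logcon <- file(logf, open = "wt")
  on.exit(close(logcon))
  say <- function(...) writeLines(sprintf(...), logcon)

  if (is.null(bioactivity)) {
    if (is.null(cfg$bioactivity)) {
      stop("no bioactivity input configured", call. = FALSE)
    }
    bioactivity <- read_bioactivity(cfg$bioactivity, cfg$columns)
  }
  if (is.null(pdb_evidence) && !is.null(cfg$pdb_evidence)) {
    pdb_evidence <- read.csv(cfg$pdb_evidence, stringsAsFactors = FALSE)
  }
  if (nrow(bioactivity) == 0) stop("empty bioactivity input", call. = FALSE)
  say("records in: %d", nrow(bioactivity))

  actives <- curate_activities(bioactivity, targets = cfg$targets,
                               threshold = cfg$ppot_threshold)
  dl <- attr(actives, "drop_log")
  for (r in unique(dl$reason)) {
    say("dropped (%s): %d", r, sum(dl$reason == r))
  }
  say("active annotations: %d", nrow(actives))
  write.csv(actives, file.path(cfg$out, "potency_annotations.csv"),
            row.names = FALSE)
  write_drop_log(actives, file.path(cfg$out, "drop_log.tsv"))

  summary <- list(records_in = nrow(bioactivity),
                  active_annotations = nrow(actives),
                  per_target = list())
  tallies <- list()
  scaffold_rows <- list()
  for (tid in cfg$targets) {
    act <- actives[actives$target_id == tid, , drop = FALSE]
    cpds <- unique(data.frame(compound_id = act$compound_id,
                              smiles = act$standardized_smiles))
    rows <- fragment_molecules(cpds, allowed_rings = cfg$allowed_rings)
    scaffold_rows[[tid]] <- rows
    tally <- tally_scaffolds(rows, actives, tid)
    n_before <- length(tally$support)
    tally <- apply_min_support(tally, cfg$min_support)
    tallies[[tid]] <- tally
    say("%s: %d actives, %d scaffolds, %d with support >= %d",
        tid, nrow(act), n_before, length(tally$support), cfg$min_support)
    summary$per_target[[tid]] <- list(
      actives = nrow(act),
      scaffolds = n_before,
      scaffolds_supported = length(tally$support),
      coverage = if (length(tally$support)) coverage_fraction(tally) else 0,
      compound_to_core_ratio = if (length(tally$support))
        compound_to_core_ratio(tally) else NA)
    write.csv(rows, file.path(cfg$out, paste0("scaffolds_", tid, ".csv")),
              row.names = FALSE)
    write.csv(scaffold_frequency_table(tally),
              file.path(cfg$out, paste0("frequency_", tid, ".csv")),
              row.names = FALSE)
  }

  if (!is.null(pdb_evidence)) {
    # re-key evidence rows onto post-deduplication representative ids
    id_map <- attr(actives, "id_map")
    hit <- match(pdb_evidence$compound_id, id_map$original)
    pdb_evidence$compound_id[!is.na(hit)] <-
      id_map$representative[hit[!is.na(hit)]]
  }
  net <- build_scaffold_network(tallies, pdb_evidence)
  ext <- switch(cfg$format, graphml = "graphml", sif = "sif", csv = "")
  export_network(net, file.path(cfg$out, paste0("network",
                 if (nzchar(ext)) paste0(".", ext) else "")), cfg$format)
  shared <- shared_scaffolds(net, cfg$targets)
  write.csv(shared, file.path(cfg$out, "shared_scaffolds.csv"),
            row.names = FALSE)
  say("shared scaffolds: %d", nrow(shared))
  summary$shared_scaffolds <- shared$scaffold_key

  jsonlite::write_json(summary, file.path(cfg$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
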