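# Scaffold-target network analysis.
#
# Scaffold tallies map each scaffold key to the set of active compounds
# supporting it for one target; after a minimum-support filter the tallies
# for two (or more) targets are organized into a bipartite network whose
# edges carry the support count and a crystallographic-evidence flag.
# Scaffolds adjacent to both targets of a pair are the shared pharmacophore
# candidates.

#' Tally scaffold support for one target
#'
#' @param scaffold_rows output of [fragment_molecules()] for the target's
#'   active compounds.
#' @param actives potency annotations from [curate_activities()].
#' @param target_id target identifier.
#' @return an object of class `scaffold_tally`: target id plus a map
#'   scaffold key -> character vector of supporting compound ids (each
#'   compound counted once per scaffold).
#' @export
tally_scaffolds <- function(scaffold_rows, actives, target_id) {
  act <- actives[actives$target_id == target_id, , drop = FALSE]
  unknown <- setdiff(unique(scaffold_rows$compound_id), act$compound_id)
  if (length(unknown)) {
    stop("scaffold rows reference compounds not active against ", target_id,
         ": ", paste(head(unknown, 10), collapse = ", "), call. = FALSE)
  }
  support <- lapply(split(scaffold_rows$compound_id,
                          scaffold_rows$scaffold_key),
                    function(x) sort(unique(as.character(x))))
  structure(list(target_id = target_id, support = support,
                 n_actives = nrow(act),
                 active_ids = act$compound_id),
            class = "scaffold_tally")
}

#' @export
print.scaffold_tally <- function(x, ...) {
  cat(sprintf("<scaffold_tally %s: %d scaffolds over %d active compounds>\n",
              x$target_id, length(x$support), x$n_actives))
  invisible(x)
}

#' Apply the minimum-support filter to a tally
#'
#' Keeps scaffolds supported by at least `min_support` active compounds
#' (inclusive; the default of five mirrors the reliability criterion used
#' to retain scaffolds with interpretable SAR).
#'
#' @param tally a `scaffold_tally`.
#' @param min_support inclusive support threshold.
#' @return the filtered `scaffold_tally`.
#' @export
apply_min_support <- function(tally, min_support = 5L) {
  stopifnot(inherits(tally, "scaffold_tally"))
  keep <- vapply(tally$support, length, integer(1)) >= min_support
  tally$support <- tally$support[keep]
  tally
}

#' Fraction of active compounds covered by retained scaffolds
#'
#' @param tally a (filtered) `scaffold_tally`.
#' @return fraction in `[0, 1]` of the target's active compounds that
#'   support at least one retained scaffold.
#' @export
coverage_fraction <- function(tally) {
  stopifnot(inherits(tally, "scaffold_tally"))
  if (tally$n_actives == 0) {
    stop("coverage undefined: no active compounds for ", tally$target_id,
         call. = FALSE)
  }
  covered <- unique(unlist(tally$support, use.names = FALSE))
  length(intersect(covered, tally$active_ids)) / tally$n_actives
}

#' Compound-to-core ratio of a tally
#'
#' Number of distinct compounds supporting any retained scaffold divided by
#' the number of retained scaffolds.
#'
#' @param tally a (filtered) `scaffold_tally`.
#' @return numeric ratio.
#' @export
compound_to_core_ratio <- function(tally) {
  stopifnot(inherits(tally, "scaffold_tally"))
  if (length(tally$support) == 0) {
    stop("ratio undefined: no scaffolds retained", call. = FALSE)
  }
  n_cpd <- length(unique(unlist(tally$support, use.names = FALSE)))
  n_cpd / length(tally$support)
}

#' Build the bipartite scaffold-target network
#'
#' One node per target and per scaffold; a scaffold is connected to a
#' target when it was retained in that target's tally. Edges carry the
#' support count and a logical `pdb_evidence` flag that is TRUE when at
#' least one supporting compound appears in the structural-evidence table
#' for that target.
#'
#' @param tallies list of (filtered) `scaffold_tally` objects, one per
#'   target.
#' @param pdb_evidence optional data.frame with columns `compound_id`,
#'   `target_id`, `pdb_code`; malformed rows are skipped with a warning.
#' @return an igraph object with vertex attributes `name` and `kind`
#'   (`"scaffold"`/`"target"`) and edge attributes `support_count` and
#'   `pdb_evidence`.
#' @export
build_scaffold_network <- function(tallies, pdb_evidence = NULL) {
  stopifnot(length(tallies) >= 1,
            all(vapply(tallies, inherits, logical(1), "scaffold_tally")))
  ev <- data.frame(compound_id = character(), target_id = character())
  if (!is.null(pdb_evidence)) {
    need <- c("compound_id", "target_id", "pdb_code")
    if (!all(need %in% names(pdb_evidence))) {
      stop("pdb_evidence must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    bad <- !stats::complete.cases(pdb_evidence[, need]) |
      pdb_evidence$compound_id == "" | pdb_evidence$pdb_code == ""
    if (any(bad)) {
      warning(sum(bad), " malformed evidence row(s) skipped", call. = FALSE)
    }
    ev <- pdb_evidence[!bad, , drop = FALSE]
  }
  edges <- list()
  for (ta in tallies) {
    ev_cpds <- ev$compound_id[ev$target_id == ta$target_id]
    for (key in names(ta$support)) {
      cpds <- ta$support[[key]]
      edges[[length(edges) + 1]] <- data.frame(
        from = key, to = ta$target_id,
        support_count = length(cpds),
        pdb_evidence = any(cpds %in% ev_cpds),
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(),
               support_count = integer(), pdb_evidence = logical())
  targets <- vapply(tallies, function(t) t$target_id, character(1))
  scaffolds <- sort(unique(edges$from))
  verts <- data.frame(
    name = c(scaffolds, targets),
    kind = c(rep("scaffold", length(scaffolds)),
             rep("target", length(targets))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  igraph::V(g)$type <- igraph::V(g)$kind == "target"
  g
}

#' Shared scaffolds of a target pair
#'
#' Scaffold nodes adjacent to both targets, ranked by crystallographic
#' evidence (either edge), then by the smaller of the two per-target
#' supports (descending), then lexicographically by canonical key.
#'
#' @param network a network from [build_scaffold_network()].
#' @param targets optional character vector of the two target ids; defaults
#'   to all target nodes of the network (which must then be exactly two).
#' @return data.frame with `scaffold_key`, `support` per target,
#'   `min_support`, `pdb_evidence`, in rank order.
#' @export
shared_scaffolds <- function(network, targets = NULL) {
  kind <- igraph::V(network)$kind
  vnames <- igraph::V(network)$name
  if (is.null(targets)) targets <- vnames[kind == "target"]
  if (length(targets) != 2) {
    stop("shared-scaffold analysis is pairwise; got ",
         length(targets), " target(s)", call. = FALSE)
  }
  scaff <- vnames[kind == "scaffold"]
  rows <- list()
  for (s in scaff) {
    sup <- pdb <- setNames(rep(NA, 2), targets)
    for (t in targets) {
      eid <- suppressWarnings(igraph::get_edge_ids(network, c(s, t)))
      if (eid > 0) {
        sup[t] <- igraph::E(network)$support_count[eid]
        pdb[t] <- igraph::E(network)$pdb_evidence[eid]
      }
    }
    if (all(!is.na(sup))) {
      rows[[length(rows) + 1]] <- data.frame(
        scaffold_key = s, support_a = sup[1], support_b = sup[2],
        min_support = min(sup), pdb_evidence = any(as.logical(pdb)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(scaffold_key = character(), support_a = integer(),
                      support_b = integer(), min_support = integer(),
                      pdb_evidence = logical()))
  }
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("support_", targets)
  out <- out[order(-out$pdb_evidence, -out$min_support, out$scaffold_key), ]
  rownames(out) <- NULL
  out
}

#' Growth-vector profile of a scaffold for one target
#'
#' For every canonical atom position of the scaffold, counts how many
#' supporting parent compounds carry a substituent there.
#'
#' @param scaffold_rows output of [fragment_molecules()].
#' @param scaffold_key the scaffold canonical key.
#' @param target_id label stored on the profile.
#' @return object of class `growth_profile`: scaffold key, target id, and a
#'   named integer vector position -> substitution frequency.
#' @export
growth_vector_profile <- function(scaffold_rows, scaffold_key,
                                  target_id = NA_character_) {
  rows <- scaffold_rows[scaffold_rows$scaffold_key == scaffold_key, ,
                        drop = FALSE]
  freq <- integer(0)
  for (ps in rows$attachment_positions) {
    if (!nzchar(ps)) next
    for (p in unique(strsplit(ps, ",")[[1]])) {
      freq[p] <- if (is.na(freq[p])) 1L else freq[p] + 1L
    }
  }
  structure(list(scaffold_key = scaffold_key, target_id = target_id,
                 freq = freq[order(as.integer(names(freq)))]),
            class = "growth_profile")
}

#' Common substitution sites of two growth-vector profiles
#'
#' @param profile_a,profile_b `growth_profile` objects for the same
#'   scaffold key (for two different targets).
#' @return integer vector of canonical positions substituted with nonzero
#'   frequency in both profiles.
#' @export
growth_vector_overlap <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "growth_profile"),
            inherits(profile_b, "growth_profile"))
  if (!identical(profile_a$scaffold_key, profile_b$scaffold_key)) {
    stop("growth-vector profiles refer to different scaffolds", call. = FALSE)
  }
  sort(as.integer(intersect(names(profile_a$freq[profile_a$freq > 0]),
                            names(profile_b$freq[profile_b$freq > 0]))))
}

#' Export a scaffold-target network
#'
#' @param network igraph network from [build_scaffold_network()].
#' @param path output path (for `csv`, the basename for `<path>_nodes.csv`
#'   and `<path>_edges.csv`).
#' @param format one of `"graphml"`, `"sif"`, `"csv"`.
#' @return the path(s) written, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "sif", "csv")) {
  if (!format[1] %in% c("graphml", "sif", "csv")) {
    stop("unsupported format '", format[1],
         "'; supported formats: graphml, sif, csv", call. = FALSE)
  }
  format <- format[1]
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(network)
  kind <- setNames(igraph::V(network)$kind, igraph::V(network)$name)
  if (format == "sif") {
    lines <- if (nrow(el)) {
      scaff_first <- kind[el[, 1]] == "scaffold"
      sprintf("%s\tinteracts\t%s",
              ifelse(scaff_first, el[, 1], el[, 2]),
              ifelse(scaff_first, el[, 2], el[, 1]))
    } else character(0)
    writeLines(lines, path)
    return(invisible(path))
  }
  nodes <- data.frame(name = igraph::V(network)$name,
                      kind = igraph::V(network)$kind)
  edges <- data.frame(scaffold = el[, 1], target = el[, 2],
                      support_count = igraph::E(network)$support_count,
                      pdb_evidence = igraph::E(network)$pdb_evidence)
  paths <- paste0(path, c("_nodes.csv", "_edges.csv"))
  write.csv(nodes, paths[1], row.names = FALSE)
  write.csv(edges, paths[2], row.names = FALSE)
  invisible(paths)
}

#' Top-N scaffold frequency table
#'
#' @param tally a (filtered) `scaffold_tally`.
#' @param n number of scaffolds to report.
#' @return data.frame `scaffold_key`, `support`, `rank` sorted by
#'   descending support (ties broken lexicographically).
#' @export
scaffold_frequency_table <- function(tally, n = 20L) {
  stopifnot(inherits(tally, "scaffold_tally"))
  sup <- vapply(tally$support, length, integer(1))
  ord <- order(-sup, names(sup))
  out <- data.frame(scaffold_key = names(sup)[ord], support = unname(sup[ord]))
  out <- head(out, n)
  out$rank <- seq_len(nrow(out))
  out
}
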