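# Bioactivity curation.
#
# Filters target-annotated potency measurements into one annotation per
# compound-target pair: relation filter (only "=" and "<"), conversion to
# pPOT = -log10(molar potency), aggregation by the maximum, and an activity
# threshold (default pPOT >= 5, i.e. 10 uM). Every dropped record carries a
# reason code in the drop log.

.an_measure_types <- c("Ki", "Kd", "IC50", "EC50")
.an_relations_keep <- c("=", "<")
.an_relations_drop <- c(">", "~")

# decimal exponents of the supported unit dialect (relative to molar)
.an_unit_exp <- c(M = 0, mM = -3, uM = -6, nM = -9, pM = -12)

.an_default_columns <- c(
  compound_id = "compound_id", smiles = "smiles", target_id = "target_id",
  type = "type", relation = "relation", value = "value", units = "units"
)

#' Read a bioactivity table
#'
#' Reads a CSV or TSV export of potency measurements (one row per
#' measurement) and maps its columns onto the canonical schema
#' `compound_id, smiles, target_id, type, relation, value, units`.
#'
#' @param path path to a CSV (".csv") or TSV (".tsv"/".txt") file with a
#'   header row.
#' @param config optional column mapping: a named list/vector mapping
#'   canonical names to file column names, or a path to a YAML file with a
#'   `columns:` block.
#' @return a data.frame in the canonical schema.
#' @export
read_bioactivity <- function(path, config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tsv <- grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)
  df <- if (tsv) read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
        else read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  mapping <- .an_default_columns
  if (!is.null(config)) {
    if (is.character(config) && length(config) == 1 && file.exists(config)) {
      config <- yaml::read_yaml(config)
    }
    cols <- if (!is.null(config$columns)) config$columns else config
    for (nm in names(cols)) {
      if (nm %in% names(mapping)) mapping[[nm]] <- cols[[nm]]
    }
  }
  missing <- setdiff(unname(mapping), names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- df[, unname(mapping)]
  names(out) <- names(mapping)
  out$value <- as.numeric(out$value)
  out
}

#' Keep measurements with exact or upper-bounding relations
#'
#' Measurements whose relation symbol is `"="` or `"<"` are retained;
#' approximate (`"~"`) and lower-bound (`">"`) measurements are dropped, as
#' are records with unrecognized symbols (with a warning). Row order is
#' preserved.
#'
#' @param records data.frame with at least a `relation` column.
#' @return the filtered data.frame; dropped rows are recorded in the
#'   `drop_log` attribute with a reason code.
#' @export
filter_relations <- function(records) {
  rel <- as.character(records$relation)
  keep <- rel %in% .an_relations_keep
  known_drop <- rel %in% .an_relations_drop
  unknown <- !keep & !known_drop
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unknown relation symbol dropped: ",
            paste(unique(rel[unknown]), collapse = ", "), call. = FALSE)
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "drop_log") <- data.frame(
    row = which(!keep),
    reason = ifelse(unknown[!keep], "unknown_relation", "approximate_relation")
  )
  out
}

#' Convert a potency value to pPOT
#'
#' pPOT is the negative base-10 logarithm of the molar potency. The unit
#' dialect is fixed to M, mM, uM, nM, pM.
#'
#' @param value positive numeric vector of potency values.
#' @param units character vector of unit symbols (recycled).
#' @return numeric vector of pPOT values.
#' @examples
#' to_ppot(1, "uM")    # 6
#' to_ppot(10, "uM")   # 5, the usual activity cutoff
#' @export
to_ppot <- function(value, units) {
  if (any(!is.finite(value) | value <= 0)) {
    stop("potency values must be positive and finite", call. = FALSE)
  }
  ex <- .an_unit_exp[as.character(units)]
  if (anyNA(ex)) {
    stop("unknown unit(s): ",
         paste(unique(units[is.na(ex)]), collapse = ", "), call. = FALSE)
  }
  -(log10(value) + unname(ex))
}

#' Aggregate measurements into one potency annotation per pair
#'
#' When a compound-target pair has several surviving measurements (across
#' Ki, Kd, IC50 and EC50), the highest pPOT is used as the final annotation.
#'
#' @param records data.frame with columns `compound_id`, `target_id`,
#'   `ppot`, and optionally `standardized_smiles`.
#' @return data.frame with one row per (compound, target) pair.
#' @export
aggregate_potency <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(compound_id = character(), target_id = character(),
                      standardized_smiles = character(), ppot = numeric()))
  }
  key <- paste(records$compound_id, records$target_id, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  rows <- vapply(idx, function(ii) ii[which.max(records$ppot[ii])], integer(1))
  rows <- sort(unname(rows))
  out <- records[rows, , drop = FALSE]
  cols <- intersect(c("compound_id", "target_id", "standardized_smiles",
                      "ppot"), names(out))
  out <- out[, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep annotations at or above a pPOT threshold
#'
#' @param annotations data.frame with a `ppot` column.
#' @param threshold inclusive pPOT cutoff; the default 5 corresponds to
#'   10 uM.
#' @return the filtered data.frame.
#' @export
filter_actives <- function(annotations, threshold = 5.0) {
  annotations[annotations$ppot >= threshold, , drop = FALSE]
}

#' Curate a bioactivity table into potency annotations
#'
#' Runs the full curation cascade: target filter (exact id match), schema
#' and enumeration validation, relation filter, structure standardization
#' with deduplication by standardized structure, pPOT conversion,
#' per-pair aggregation by the maximum, and the activity threshold.
#'
#' @param records data.frame in the canonical schema (see
#'   [read_bioactivity()]).
#' @param targets optional character vector of target ids to keep.
#' @param threshold inclusive pPOT activity cutoff (default 5.0).
#' @param standardize logical; standardize structures and deduplicate by
#'   standardized SMILES (default TRUE).
#' @return data.frame of potency annotations (`compound_id`, `target_id`,
#'   `standardized_smiles`, `ppot`), with a `drop_log` attribute recording
#'   every dropped record and its reason code.
#' @export
curate_activities <- function(records, targets = NULL, threshold = 5.0,
                              standardize = TRUE) {
  log <- list()
  note <- function(rows, reason) {
    if (length(rows)) {
      log[[length(log) + 1]] <<- data.frame(
        compound_id = as.character(records$compound_id[rows]),
        reason = reason)
    }
  }
  keep <- rep(TRUE, nrow(records))
  if (!is.null(targets)) {
    bad <- !(records$target_id %in% targets)
    note(which(bad), "off_target")
    keep <- keep & !bad
  }
  bad <- !(records$type %in% .an_measure_types)
  note(which(bad & keep), "unsupported_measure_type")
  keep <- keep & !bad
  bad <- !(records$units %in% names(.an_unit_exp))
  if (any(bad & keep)) {
    warning(sum(bad & keep), " record(s) with unknown units dropped",
            call. = FALSE)
  }
  note(which(bad & keep), "unknown_units")
  keep <- keep & !bad
  bad <- !is.finite(records$value) | records$value <= 0
  note(which(bad & keep), "nonpositive_value")
  keep <- keep & !bad
  rec <- records[keep, , drop = FALSE]

  rec2 <- filter_relations(rec)
  rl <- attr(rec2, "drop_log")
  if (nrow(rl)) {
    log[[length(log) + 1]] <- data.frame(
      compound_id = as.character(rec$compound_id[rl$row]), reason = rl$reason)
  }
  rec <- rec2

  if (nrow(rec)) {
    if (standardize) {
      smi_map <- unique(data.frame(compound_id = rec$compound_id,
                                   smiles = rec$smiles))
      std <- character(nrow(smi_map))
      ok <- rep(TRUE, nrow(smi_map))
      for (i in seq_len(nrow(smi_map))) {
        std[i] <- tryCatch(standardize_structure(smi_map$smiles[i]),
                           error = function(e) {ok[i] <<- FALSE; NA_character_})
      }
      if (any(!ok)) {
        log[[length(log) + 1]] <- data.frame(
          compound_id = as.character(smi_map$compound_id[!ok]),
          reason = "unparseable_structure")
      }
      smi_map$standardized_smiles <- std
      drop_cpd <- smi_map$compound_id[!ok]
      rec <- rec[!(rec$compound_id %in% drop_cpd), , drop = FALSE]
      rec$standardized_smiles <-
        smi_map$standardized_smiles[match(rec$compound_id, smi_map$compound_id)]
      # deduplicate compounds sharing a standardized structure: all their
      # measurements are pooled under one representative id
      canon <- vapply(
        split(rec$compound_id, rec$standardized_smiles),
        function(ids) sort(unique(as.character(ids)))[1], character(1))
      id_map <- unique(data.frame(
        original = as.character(rec$compound_id),
        representative = unname(canon[rec$standardized_smiles]),
        stringsAsFactors = FALSE))
      rec$compound_id <- unname(canon[rec$standardized_smiles])
    } else {
      rec$standardized_smiles <- rec$smiles
      id_map <- unique(data.frame(
        original = as.character(rec$compound_id),
        representative = as.character(rec$compound_id),
        stringsAsFactors = FALSE))
    }
    rec$ppot <- to_ppot(rec$value, rec$units)
  } else {
    rec$standardized_smiles <- character(0)
    rec$ppot <- numeric(0)
    id_map <- data.frame(original = character(), representative = character())
  }
  ann <- aggregate_potency(rec)
  act <- filter_actives(ann, threshold)
  inact <- setdiff(paste(ann$compound_id, ann$target_id),
                   paste(act$compound_id, act$target_id))
  if (length(inact)) {
    log[[length(log) + 1]] <- data.frame(
      compound_id = vapply(strsplit(inact, " "), `[`, character(1), 1),
      reason = "below_ppot_threshold")
  }
  rownames(act) <- NULL
  attr(act, "drop_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(compound_id = character(), reason = character())
  # original id -> representative id after structure deduplication, so that
  # external tables keyed by original ids can be re-joined
  attr(act, "id_map") <- id_map
  act
}

#' Write a curation drop log
#'
#' @param annotations result of [curate_activities()].
#' @param path output file; one line per dropped record with its reason code.
#' @return the path, invisibly.
#' @export
write_drop_log <- function(annotations, path) {
  log <- attr(annotations, "drop_log")
  writeLines(sprintf("%s\t%s", log$compound_id, log$reason), path)
  invisible(path)
}
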