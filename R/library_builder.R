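# Curation of raw bioactivity records into the target-as-ligand-set
# reference library, and preparation of validation query sets.

.MEASURES <- c("IC50", "Ki", "Kd", "EC50", "deltaG")
.CONC_UNITS <- c(nM = 1e-3, uM = 1, M = 1e6)   # factors to micromolar

#' Read a bioactivity table
#'
#' TSV with header columns \code{ligand_id}, \code{target_id},
#' \code{measure} (IC50/Ki/Kd/EC50/deltaG), \code{value}, \code{unit}
#' (nM/uM/M for concentrations, kJ_per_mol for binding free energies).
#'
#' @param path Path to the TSV file.
#' @return A validated activity data frame.
#' @export
read_activity_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_activities(df)
}

#' Validate activity records
#'
#' Checks measure/unit consistency (concentration measures carry nM/uM/M,
#' free energies carry kJ_per_mol) and that concentrations are positive.
#'
#' @param records Data frame with the activity-table columns.
#' @return The records, invisibly checked.
#' @export
validate_activities <- function(records) {
  need <- c("ligand_id", "target_id", "measure", "value", "unit")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("activity table lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- !records$measure %in% .MEASURES
  if (any(bad)) stop("unknown measure: ",
                     paste(unique(records$measure[bad]), collapse = ", "))
  conc <- records$measure != "deltaG"
  if (any(conc & !records$unit %in% names(.CONC_UNITS)))
    stop("concentration measures require unit nM, uM or M")
  if (any(!conc & records$unit != "kJ_per_mol"))
    stop("deltaG records require unit kJ_per_mol")
  if (any(conc & records$value <= 0))
    stop("non-positive concentration value")
  records
}

#' Keep only records that pass the activity threshold
#'
#' A ligand counts as active on a target when its IC50, Ki, Kd or EC50 is
#' strictly below the concentration threshold (default 10 micromolar, after
#' unit conversion), or when its binding free energy has magnitude at least
#' the energy threshold (default 28.53 kJ/mol, which is -RT ln(10 uM) at
#' 298 K; the sign convention is accepted either way).
#'
#' @param records Activity data frame.
#' @param concentration_threshold_uM Strict upper bound in micromolar.
#' @param energy_threshold_kJ Minimum |deltaG| in kJ/mol.
#' @return The surviving records, with a \code{filter_report} attribute
#'   (counts kept/dropped).
#' @export
apply_activity_filter <- function(records,
                                  concentration_threshold_uM = 10,
                                  energy_threshold_kJ = 28.53) {
  records <- validate_activities(records)
  conc <- records$measure != "deltaG"
  keep <- logical(nrow(records))
  if (any(conc)) {
    uM <- records$value[conc] * .CONC_UNITS[records$unit[conc]]
    keep[conc] <- uM < concentration_threshold_uM
  }
  keep[!conc] <- abs(records$value[!conc]) >= energy_threshold_kJ
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- list(
    n_in = nrow(records), n_kept = nrow(out),
    n_dropped = nrow(records) - nrow(out)
  )
  out
}

#' Read a target-merge mapping
#'
#' TSV with header columns \code{source_target_id}, \code{merged_target_id};
#' the external stand-in for homology-based grouping of redundant targets.
#'
#' @param path Path to the TSV file.
#' @return A named character vector (source id -> merged id).
#' @export
read_merge_mapping <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source_target_id", "merged_target_id")
  if (!all(need %in% names(df)))
    stop("merge mapping lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  stats::setNames(as.character(df$merged_target_id),
                  as.character(df$source_target_id))
}

#' Rewrite target ids under a merge mapping
#'
#' Pools all active ligands of targets grouped together under one merged id.
#' Duplicate ligand entries created by pooling collapse later at the
#' per-target deduplication stage.
#'
#' @param records Activity data frame.
#' @param mapping Named character vector (source id -> merged id), or
#'   \code{NULL} for the identity mapping.
#' @param strict Error on a target id absent from the mapping instead of
#'   passing it through unchanged.
#' @return Records with \code{target_id} rewritten.
#' @export
merge_targets <- function(records, mapping = NULL, strict = FALSE) {
  if (is.null(mapping) || length(mapping) == 0L) return(records)
  hit <- records$target_id %in% names(mapping)
  if (strict && any(!hit))
    stop("unmapped target ids: ",
         paste(unique(records$target_id[!hit]), collapse = ", "))
  records$target_id[hit] <- unname(mapping[records$target_id[hit]])
  records
}

#' Group activity records into per-target ligand sets
#'
#' @param records Activity data frame (post filter/merge).
#' @return Named list: target id -> character vector of ligand ids in first
#'   appearance order, possibly still containing structural duplicates.
#' @export
group_target_sets <- function(records) {
  .split_unique(as.character(records$ligand_id), records$target_id)
}

#' Deduplicate ligands within each target by structure
#'
#' Within a target at most one ligand per canonical identity key is kept
#' (first occurrence wins). Deduplication is strictly per-target: one
#' molecule may legitimately be active on many targets.
#'
#' @param targets Named list of ligand-id vectors.
#' @param molecules Data frame with \code{id} and \code{canonical_key}.
#' @return The deduplicated list, with a \code{dedup_report} attribute
#'   listing collapsed ligand ids per target.
#' @export
deduplicate <- function(targets, molecules) {
  key <- stats::setNames(molecules$canonical_key, molecules$id)
  collapsed <- list()
  out <- lapply(names(targets), function(t) {
    ids <- targets[[t]]
    missing <- ids[!ids %in% names(key)]
    if (length(missing))
      stop("ligand ids without molecule records in target ", t, ": ",
           paste(missing, collapse = ", "))
    dup <- duplicated(key[ids])
    if (any(dup)) collapsed[[t]] <<- ids[dup]
    ids[!dup]
  })
  names(out) <- names(targets)
  attr(out, "dedup_report") <- collapsed
  out
}

#' Remove targets with too few unique ligands
#'
#' Drops every target whose deduplicated ligand set has at most
#' \code{min_ligands} members (default 10), so each surviving target has a
#' meaningful set of representatives. Survivor order is preserved.
#'
#' @param targets Named list of ligand-id vectors (already deduplicated).
#' @param min_ligands Targets with \code{<= min_ligands} ligands are removed.
#' @return The filtered list.
#' @export
drop_small_targets <- function(targets, min_ligands = 10L) {
  targets[lengths(targets) > min_ligands]
}

#' Construct a reference library
#'
#' Low-level constructor tying together target ligand sets, molecule
#' records and fingerprints, and building the sparse similarity index used
#' by target fishing.
#'
#' @param targets Named list: target id -> character vector of ligand ids.
#' @param fingerprints Named list of \code{"ligfish_fp"}, covering every
#'   ligand id that occurs in \code{targets}.
#' @param molecules Optional data frame (\code{id}, \code{smiles},
#'   \code{canonical_key}); fingerprint-level synthetic libraries omit it.
#' @param fp_params List with \code{radius} and \code{bit_length}.
#' @param build_report Optional list of stage counts.
#' @return A \code{"ligfish_library"} object.
#' @export
reference_library <- function(targets, fingerprints, molecules = NULL,
                              fp_params = list(radius = 2L,
                                               bit_length = NA_integer_),
                              build_report = NULL) {
  stopifnot(length(targets) > 0, !is.null(names(targets)))
  all_ids <- unique(unlist(targets, use.names = FALSE))
  miss <- setdiff(all_ids, names(fingerprints))
  if (length(miss))
    stop("ligands without fingerprints: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (!is.null(molecules)) {
    miss <- setdiff(all_ids, molecules$id)
    if (length(miss))
      stop("ligands without molecule records: ",
           paste(utils::head(miss, 5), collapse = ", "))
  }
  fps <- fingerprints[all_ids]
  structure(list(
    targets = targets,
    molecules = molecules,
    fingerprints = fps,
    fp_params = fp_params,
    index = fp_index(fps),
    build_report = build_report
  ), class = "ligfish_library")
}

#' @export
print.ligfish_library <- function(x, ...) {
  sizes <- lengths(x$targets)
  cat(sprintf(
    "<reference library: %d targets, %d unique ligands, %d ligand-target pairs>\n",
    length(x$targets), length(x$fingerprints), sum(sizes)))
  cat(sprintf("  ligands per target: %d-%d (median %g)\n",
              min(sizes), max(sizes), stats::median(sizes)))
  invisible(x)
}

#' Number of ligands per target
#' @param library A \code{"ligfish_library"}.
#' @return Named integer vector of set sizes (the per-target N).
#' @export
target_sizes <- function(library) lengths(library$targets)

#' Build a reference library from molecules and activity records
#'
#' Runs the full curation pipeline: activity threshold filter, target
#' merging under an externally supplied homology mapping, grouping into
#' per-target ligand sets, per-target structural deduplication, removal of
#' under-represented targets, then fingerprinting of every surviving ligand.
#' Stage counts (targets, unique actives, ligand-target pairs) are recorded
#' in the build report.
#'
#' @param molecules Data frame from \code{\link{parse_molecules}}.
#' @param activities Activity data frame.
#' @param mapping Optional named merge mapping (see
#'   \code{\link{merge_targets}}).
#' @param concentration_threshold_uM,energy_threshold_kJ Activity
#'   thresholds (see \code{\link{apply_activity_filter}}).
#' @param min_ligands Size filter (see \code{\link{drop_small_targets}}).
#' @param radius,bit_length Fingerprint parameters.
#' @param fingerprints Optional precomputed named fingerprint list; when
#'   supplied, structures are not re-fingerprinted (used by the
#'   fingerprint-level synthetic benchmark).
#' @return A \code{"ligfish_library"} with a populated build report.
#' @export
build_library <- function(molecules, activities, mapping = NULL,
                          concentration_threshold_uM = 10,
                          energy_threshold_kJ = 28.53,
                          min_ligands = 10L,
                          radius = 2L, bit_length = NA_integer_,
                          fingerprints = NULL) {
  report <- list()
  report$input <- list(
    records = nrow(activities),
    targets = length(unique(activities$target_id)),
    ligands = length(unique(activities$ligand_id))
  )
  kept <- apply_activity_filter(activities,
                                concentration_threshold_uM,
                                energy_threshold_kJ)
  report$after_activity_filter <- list(
    records = nrow(kept),
    dropped = attr(kept, "filter_report")$n_dropped,
    targets = length(unique(kept$target_id))
  )
  merged <- merge_targets(kept, mapping)
  report$after_merge <- list(targets = length(unique(merged$target_id)))
  if (nrow(merged) == 0L) stop("empty library: no records pass the activity filter")

  sets <- group_target_sets(merged)
  sets <- deduplicate(sets, molecules)
  report$after_dedup <- list(
    targets = length(sets),
    pairs = sum(lengths(sets)),
    collapsed = sum(lengths(attr(sets, "dedup_report")))
  )
  sets <- drop_small_targets(sets, min_ligands)
  if (length(sets) == 0L)
    stop("empty library: no target retains more than ", min_ligands,
         " unique ligands")
  report$after_size_filter <- list(
    targets = length(sets),
    pairs = sum(lengths(sets)),
    ligands = length(unique(unlist(sets, use.names = FALSE)))
  )

  ids <- unique(unlist(sets, use.names = FALSE))
  if (is.null(fingerprints)) {
    smi <- stats::setNames(molecules$smiles, molecules$id)
    fingerprints <- lapply(ids, function(i)
      compute_fingerprint(smi[[i]], radius = radius, bit_length = bit_length))
    names(fingerprints) <- ids
  }
  reference_library(sets, fingerprints,
                    molecules = molecules[molecules$id %in% ids, , drop = FALSE],
                    fp_params = list(radius = as.integer(radius),
                                     bit_length = as.integer(bit_length)),
                    build_report = report)
}

#' Remove query molecules already present in the reference library
#'
#' Validation queries whose canonical identity key occurs anywhere in the
#' library are dropped, so evaluation never scores a molecule against a
#' reference set that contains it.
#'
#' @param queries Molecule data frame with \code{canonical_key}.
#' @param library A \code{"ligfish_library"} built with molecule records.
#' @return The retained queries, with a \code{removal_report} attribute
#'   listing removed ids.
#' @export
remove_overlap <- function(queries, library) {
  if (is.null(library$molecules))
    stop("library carries no molecule records; overlap removal needs canonical keys")
  lib_keys <- library$molecules$canonical_key
  drop <- queries$canonical_key %in% lib_keys
  out <- queries[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removal_report") <- list(
    n_in = nrow(queries), n_removed = sum(drop),
    removed = queries$id[drop]
  )
  out
}

#' Serialize a reference library to JSON
#'
#' Targets with their ligand-id lists, molecule records (when present),
#' fingerprints as sorted feature-id lists, and the fingerprint parameters.
#' Output is deterministic: rebuilding from the same inputs gives a
#' byte-identical file.
#'
#' @param library A \code{"ligfish_library"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_library <- function(library, path) {
  obj <- list(
    format = "ligfish_library",
    version = 1L,
    fp_params = library$fp_params,
    targets = library$targets,
    molecules = library$molecules,
    fingerprints = lapply(library$fingerprints, function(f)
      as.integer(unclass(f))),
    build_report = library$build_report
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a reference library from JSON
#'
#' @param path Path written by \code{\link{write_library}}.
#' @return A \code{"ligfish_library"}.
#' @export
read_library <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  if (!identical(obj$format, "ligfish_library"))
    stop("not a serialized reference library: ", path)
  as_int_or_na <- function(x)
    if (is.null(x) || length(x) == 0L) NA_integer_ else as.integer(x)
  fp_params <- list(radius = as_int_or_na(obj$fp_params$radius),
                    bit_length = as_int_or_na(obj$fp_params$bit_length))
  fps <- lapply(obj$fingerprints, function(f)
    new_fingerprint(f, radius = fp_params$radius,
                    bit_length = fp_params$bit_length))
  targets <- lapply(obj$targets, as.character)
  mols <- obj$molecules
  if (!is.null(mols) && !is.data.frame(mols)) mols <- as.data.frame(mols)
  reference_library(targets, fps, molecules = mols, fp_params = fp_params,
                    build_report = obj$build_report)
}
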