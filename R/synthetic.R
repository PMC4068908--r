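# Synthetic benchmark: clustered reference libraries and query sets with
# controlled within- and between-target similarity, so the whole pipeline
# is testable without any external database.

#' Specification of a synthetic benchmark library
#'
#' Defines a clustered library in which each target is a cluster of
#' related ligands. At the fingerprint level the within- and between-target
#' Tanimoto levels are controlled analytically: each target has a feature
#' prototype, every ligand retains each prototype feature independently
#' with probability p, and prototypes share a common-core fraction c of
#' their features. Under independent retention the expected Jaccard
#' similarity of two same-target ligands is p/(2-p) and of two
#' cross-target ligands cp/(2-cp), so p and c are solved from the requested
#' levels (feasible whenever between < within).
#'
#' @param n_targets Number of targets (default 20).
#' @param ligands_per_target Ligands per target (default 30).
#' @param mode \code{"fingerprint"} (exact similarity control, bypasses
#'   chemistry) or \code{"smiles"} (scaffold-decoration molecules that
#'   exercise the real parser and fingerprinter).
#' @param within_similarity Requested mean within-target Tanimoto, in
#'   (0, 1] (default 0.7).
#' @param between_similarity Requested mean between-target Tanimoto, in
#'   [0, within) (default 0.2).
#' @param multi_target_fraction Fraction of ligands assigned to a second
#'   target, in [0, 1) (default 0.1).
#' @param n_queries_per_target Fresh hold-out queries generated per target
#'   (default 2).
#' @param n_prototype_features Prototype feature count per target
#'   (fingerprint mode; default 50, the order of the unique circular-feature
#'   count of a drug-like molecule).
#' @param n_noise_features Ligand-specific noise features added to each
#'   fingerprint from a pool disjoint from all prototypes (default 3); the
#'   calibration of p and c accounts for them.
#' @param seed Integer seed.
#' @return A validated \code{"ligfish_synspec"} list.
#' @export
synthetic_spec <- function(n_targets = 20L, ligands_per_target = 30L,
                           mode = c("fingerprint", "smiles"),
                           within_similarity = 0.7,
                           between_similarity = 0.2,
                           multi_target_fraction = 0.1,
                           n_queries_per_target = 2L,
                           n_prototype_features = 50L,
                           n_noise_features = 3L,
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_targets >= 2, ligands_per_target >= 2,
            within_similarity > 0, within_similarity <= 1,
            between_similarity >= 0,
            multi_target_fraction >= 0, multi_target_fraction < 1,
            n_prototype_features >= 10, n_noise_features >= 0)
  if (between_similarity >= within_similarity)
    stop("between_similarity must be strictly below within_similarity")
  structure(list(
    n_targets = as.integer(n_targets),
    ligands_per_target = as.integer(ligands_per_target),
    mode = mode,
    within_similarity = within_similarity,
    between_similarity = between_similarity,
    multi_target_fraction = multi_target_fraction,
    n_queries_per_target = as.integer(n_queries_per_target),
    n_prototype_features = as.integer(n_prototype_features),
    n_noise_features = as.integer(n_noise_features),
    seed = as.integer(seed)
  ), class = "ligfish_synspec")
}

# Retention probability and shared-core fraction from the requested
# similarity levels, accounting for `m` ligand-specific noise features on
# top of an F-feature prototype. Under independent retention,
#   E within-pair Jaccard ~ p^2 F / (F(2p - p^2) + 2m)
#   E between-pair Jaccard ~ c p^2 F / (2pF - c p^2 F + 2m)
# solved for p and c in closed form.
.calibrate <- function(within, between, FF, m_noise) {
  w <- within
  p <- (w * FF + sqrt(w^2 * FF^2 + 2 * FF * (1 + w) * w * m_noise)) /
    (FF * (1 + w))
  if (p > 1)
    stop("infeasible spec: too much noise for the requested within_similarity")
  b <- between
  c_frac <- if (b == 0) 0 else
    2 * b * (p * FF + m_noise) / (p^2 * FF * (1 + b))
  if (c_frac > 1) stop("infeasible (within, between) combination")
  list(p = p, core_fraction = c_frac)
}

.bern_subset <- function(features, p) features[stats::runif(length(features)) < p]

# realized similarity statistics on sampled pairs, deterministic given the
# RNG state at call time
.realized_stats <- function(fps, targets, max_pairs = 400L) {
  tids <- names(targets)
  within <- numeric(0)
  for (t in tids) {
    ids <- targets[[t]]
    if (length(ids) < 2) next
    n_pairs <- min(max_pairs %/% length(tids) + 1L, choose(length(ids), 2))
    for (i in seq_len(n_pairs)) {
      pair <- sample(ids, 2)
      within <- c(within, tanimoto(fps[[pair[1]]], fps[[pair[2]]]))
    }
  }
  between <- numeric(0)
  for (i in seq_len(max_pairs)) {
    ts <- sample(tids, 2)
    a <- sample(targets[[ts[1]]], 1); b <- sample(targets[[ts[2]]], 1)
    if (a == b) next
    between <- c(between, tanimoto(fps[[a]], fps[[b]]))
  }
  list(within_mean = mean(within), between_mean = mean(between),
       n_within_pairs = length(within), n_between_pairs = length(between))
}

.syn_molecules <- function(ids, smiles = NULL, keys = NULL) {
  data.frame(
    id = ids,
    smiles = if (is.null(smiles)) rep(NA_character_, length(ids)) else smiles,
    canonical_key = if (is.null(keys)) paste0("synthetic:", ids) else keys,
    stringsAsFactors = FALSE
  )
}

.finish_synlib <- function(targets, fps, molecules, queries, truth, spec,
                           fp_params) {
  lib <- reference_library(targets, fps, molecules = molecules,
                           fp_params = fp_params)
  stats <- .realized_stats(fps, targets)
  structure(list(library = lib, queries = queries, truth = truth,
                 stats = stats, spec = spec),
            class = "ligfish_synlib")
}

#' @export
print.ligfish_synlib <- function(x, ...) {
  cat(sprintf(
    "<synthetic %s-level benchmark: %d targets, %d queries>\n",
    x$spec$mode, length(x$library$targets), length(x$queries)))
  cat(sprintf(
    "  requested within/between Tanimoto: %.2f / %.2f; realized: %.3f / %.3f\n",
    x$spec$within_similarity, x$spec$between_similarity,
    x$stats$within_mean, x$stats$between_mean))
  invisible(x)
}

#' Generate a fingerprint-level synthetic benchmark library
#'
#' Draws one feature prototype per target (a shared common core plus
#' target-unique features, sized by the calibration in
#' \code{\link{synthetic_spec}}), then samples each ligand by independent
#' feature retention. A \code{multi_target_fraction} of ligands retain
#' features from a second target's prototype as well and join both ligand
#' sets, giving queries with several true targets. Fresh hold-out queries
#' are drawn by the same process. Fully deterministic given the seed.
#'
#' @param spec A \code{"ligfish_synspec"} with \code{mode = "fingerprint"}.
#' @return A \code{"ligfish_synlib"}: \code{library} (a
#'   \code{"ligfish_library"}), \code{queries} (named fingerprint list),
#'   \code{truth} (named list of true-target vectors), \code{stats}
#'   (realized within/between similarity), \code{spec}.
#' @export
generate_fingerprint_library <- function(spec) {
  stopifnot(inherits(spec, "ligfish_synspec"), spec$mode == "fingerprint")
  set.seed(spec$seed)
  FF <- spec$n_prototype_features
  cal <- .calibrate(spec$within_similarity, spec$between_similarity,
                    FF, spec$n_noise_features)
  n_core <- round(cal$core_fraction * FF)
  n_unique <- FF - n_core
  core <- seq_len(n_core)
  protos <- lapply(seq_len(spec$n_targets), function(j)
    c(core, 10000L + (j - 1L) * n_unique + seq_len(n_unique)))
  tids <- sprintf("T%03d", seq_len(spec$n_targets))
  names(protos) <- tids

  # ligand-specific noise features: sequential ids from a pool disjoint
  # from every prototype, so two fingerprints never share a noise feature
  noise_next <- 10000000L
  draw_noise <- function() {
    if (spec$n_noise_features == 0L) return(integer(0))
    out <- noise_next + seq_len(spec$n_noise_features)
    noise_next <<- noise_next + spec$n_noise_features
    out
  }
  fps <- list(); targets <- stats::setNames(
    replicate(spec$n_targets, character(0), simplify = FALSE), tids)
  lig_i <- 0L
  for (j in seq_len(spec$n_targets)) {
    for (l in seq_len(spec$ligands_per_target)) {
      lig_i <- lig_i + 1L
      id <- sprintf("L%05d", lig_i)
      second <- if (stats::runif(1) < spec$multi_target_fraction) {
        sample(setdiff(seq_len(spec$n_targets), j), 1L)
      } else NA_integer_
      proto <- if (is.na(second)) protos[[j]] else
        union(protos[[j]], protos[[second]])
      feats <- .bern_subset(proto, cal$p)
      if (length(feats) == 0L) feats <- sample(protos[[j]], 1L)
      fps[[id]] <- new_fingerprint(c(feats, draw_noise()),
                                   radius = NA_integer_,
                                   bit_length = NA_integer_)
      targets[[j]] <- c(targets[[j]], id)
      if (!is.na(second)) targets[[second]] <- c(targets[[second]], id)
    }
  }
  queries <- list(); truth <- list()
  if (spec$n_queries_per_target > 0) {
    for (j in seq_len(spec$n_targets)) {
      for (q in seq_len(spec$n_queries_per_target)) {
        id <- sprintf("Q_%s_%02d", tids[j], q)
        feats <- .bern_subset(protos[[j]], cal$p)
        if (length(feats) == 0L) feats <- sample(protos[[j]], 1L)
        queries[[id]] <- new_fingerprint(c(feats, draw_noise()),
                                         radius = NA_integer_,
                                         bit_length = NA_integer_)
        truth[[id]] <- tids[j]
      }
    }
  }
  .finish_synlib(targets, fps, .syn_molecules(names(fps)), queries, truth,
                 spec, fp_params = list(radius = NA_integer_,
                                        bit_length = NA_integer_))
}

# scaffold vocabulary: aromatic and saturated cores with two open
# substitution points, decorated from a small R-group vocabulary
.SCAFFOLDS <- c(
  "c1cc(%s)ccc1%s",       # benzene, 1,4
  "c1cc(%s)cnc1%s",       # pyridine
  "c1cc(%s)sc1%s",        # thiophene
  "c1cc(%s)oc1%s",        # furan
  "c1cc(%s)[nH]c1%s",     # pyrrole
  "C1CC(%s)CC1%s",        # cyclopentane
  "C1CC(%s)CCC1%s",       # cyclohexane
  "C1CC(%s)CCN1%s",       # piperidine (N-substituted)
  "C1COC(%s)CN1%s",       # morpholine
  "c1nc(%s)cnc1%s",       # pyrazine
  "c1cc2cc(%s)ccc2cc1%s", # naphthalene-like fused ring
  "C1CC(%s)CCO1%s"        # oxane
)

.R_GROUPS <- c(
  "C", "CC", "CCC", "CCCC", "C(C)C", "CC(C)C", "O", "OC", "OCC", "OC(C)C",
  "N", "NC", "N(C)C", "NCC", "F", "Cl", "Br", "I", "C#N", "C(=O)O",
  "C(=O)OC", "C(=O)N", "C(=O)C", "C(F)(F)F", "S", "SC", "CO", "CCO",
  "CN", "CCN", "C=C", "CCC(C)C", "OCCC", "C(=O)NC", "CCCl"
)

#' Generate a SMILES-level synthetic benchmark library
#'
#' Each target is a chemical series: one core scaffold from a packaged
#' vocabulary, decorated at two positions with substituents from a small
#' R-group vocabulary. All molecules are chemically valid, parsed and
#' fingerprinted through the real chemistry path, and deduplicated by
#' canonical key, so structural clustering (not feature-level control)
#' produces the within-target similarity. When \code{n_targets} exceeds the
#' scaffold vocabulary, scaffolds are reused, giving deliberately hard
#' target pairs with elevated cross-target similarity.
#'
#' @param spec A \code{"ligfish_synspec"} with \code{mode = "smiles"};
#'   similarity levels are ignored in this mode (structure dictates them).
#' @return A \code{"ligfish_synlib"}; the library carries real molecule
#'   records (SMILES and canonical keys) and circular fingerprints.
#' @export
generate_smiles_library <- function(spec) {
  stopifnot(inherits(spec, "ligfish_synspec"), spec$mode == "smiles")
  if (length(.R_GROUPS) < 2)
    stop("decoration vocabulary is empty")
  set.seed(spec$seed)
  tids <- sprintf("T%03d", seq_len(spec$n_targets))
  combos <- expand.grid(r1 = .R_GROUPS, r2 = .R_GROUPS,
                        stringsAsFactors = FALSE)
  targets <- stats::setNames(vector("list", spec$n_targets), tids)
  ids <- character(0); smis <- character(0); keys <- character(0)
  lig_i <- 0L
  for (j in seq_len(spec$n_targets)) {
    scaffold <- .SCAFFOLDS[((j - 1L) %% length(.SCAFFOLDS)) + 1L]
    pick <- combos[sample(nrow(combos)), , drop = FALSE]
    got <- 0L; row <- 0L; t_ids <- character(0)
    while (got < spec$ligands_per_target) {
      row <- row + 1L
      if (row > nrow(pick))
        stop("decoration vocabulary exhausted for target ", tids[j])
      smi <- sprintf(scaffold, pick$r1[row], pick$r2[row])
      key <- canonical_key(smi)
      if (is.na(key) || key %in% keys) next
      lig_i <- lig_i + 1L
      id <- sprintf("L%05d", lig_i)
      ids <- c(ids, id); smis <- c(smis, smi); keys <- c(keys, key)
      t_ids <- c(t_ids, id)
      got <- got + 1L
    }
    targets[[j]] <- t_ids
  }
  fps <- lapply(stats::setNames(smis, ids), compute_fingerprint,
                radius = 2L, bit_length = NA_integer_)
  # queries: further decorations of each target's scaffold, not in the library
  queries <- list(); truth <- list()
  if (spec$n_queries_per_target > 0) {
    for (j in seq_len(spec$n_targets)) {
      scaffold <- .SCAFFOLDS[((j - 1L) %% length(.SCAFFOLDS)) + 1L]
      pick <- combos[sample(nrow(combos)), , drop = FALSE]
      got <- 0L; row <- 0L
      while (got < spec$n_queries_per_target) {
        row <- row + 1L
        if (row > nrow(pick))
          stop("decoration vocabulary exhausted for queries of ", tids[j])
        smi <- sprintf(scaffold, pick$r1[row], pick$r2[row])
        key <- canonical_key(smi)
        if (is.na(key) || key %in% keys) next
        keys <- c(keys, key)
        got <- got + 1L
        qid <- sprintf("Q_%s_%02d", tids[j], got)
        queries[[qid]] <- compute_fingerprint(smi, radius = 2L,
                                              bit_length = NA_integer_)
        truth[[qid]] <- tids[j]
      }
    }
  }
  mols <- .syn_molecules(ids, smiles = smis,
                         keys = keys[seq_along(ids)])
  .finish_synlib(targets, fps, mols, queries, truth, spec,
                 fp_params = list(radius = 2L, bit_length = NA_integer_))
}

#' Generate a bioactivity table with known filter outcomes
#'
#' Emits one active record per ligand-target pair of a synthetic library,
#' with potencies strictly below the 10 micromolar activity threshold
#' (units mixed between nM and uM, and a fraction expressed as binding free
#' energies beyond the energy threshold), plus \code{decoy_fraction} extra
#' records with supra-threshold potencies that the activity filter must
#' remove. The exact expected post-filter counts are attached as ground
#' truth, so curation can be verified record-for-record.
#'
#' @param synlib A \code{"ligfish_synlib"}.
#' @param active_range_uM Potency range for actives, strictly inside
#'   (0, 10) micromolar.
#' @param decoy_fraction Decoy records as a fraction of true records.
#' @param deltaG_fraction Fraction of actives expressed as free energies.
#' @param seed Integer seed.
#' @return Activity data frame with a \code{ground_truth} attribute:
#'   \code{n_active}, \code{n_decoy}, \code{expected_kept}.
#' @export
generate_activity_table <- function(synlib, active_range_uM = c(0.001, 9.9),
                                    decoy_fraction = 0.2,
                                    deltaG_fraction = 0.1,
                                    seed = 1L) {
  stopifnot(inherits(synlib, "ligfish_synlib"),
            active_range_uM[1] > 0, active_range_uM[2] < 10,
            decoy_fraction >= 0, deltaG_fraction >= 0, deltaG_fraction <= 1)
  set.seed(seed)
  lib <- synlib$library
  pairs <- data.frame(
    ligand_id = unlist(lib$targets, use.names = FALSE),
    target_id = rep(names(lib$targets), lengths(lib$targets)),
    stringsAsFactors = FALSE
  )
  n <- nrow(pairs)
  is_dg <- stats::runif(n) < deltaG_fraction
  measure <- ifelse(is_dg, "deltaG",
                    sample(c("IC50", "Ki", "Kd", "EC50"), n, replace = TRUE))
  value <- numeric(n); unit <- character(n)
  uM <- stats::runif(n, active_range_uM[1], active_range_uM[2])
  as_nM <- stats::runif(n) < 0.5
  value[!is_dg & as_nM] <- uM[!is_dg & as_nM] * 1000
  unit[!is_dg & as_nM] <- "nM"
  value[!is_dg & !as_nM] <- uM[!is_dg & !as_nM]
  unit[!is_dg & !as_nM] <- "uM"
  value[is_dg] <- -stats::runif(sum(is_dg), 29, 60)
  unit[is_dg] <- "kJ_per_mol"
  actives <- data.frame(pairs, measure = measure, value = value,
                        unit = unit, stringsAsFactors = FALSE)

  n_decoy <- round(decoy_fraction * n)
  decoys <- NULL
  if (n_decoy > 0) {
    d_lig <- sample(unique(pairs$ligand_id), n_decoy, replace = TRUE)
    d_tgt <- sample(names(lib$targets), n_decoy, replace = TRUE)
    d_dg <- stats::runif(n_decoy) < deltaG_fraction
    d_measure <- ifelse(d_dg, "deltaG",
                        sample(c("IC50", "Ki", "Kd", "EC50"), n_decoy,
                               replace = TRUE))
    d_value <- numeric(n_decoy); d_unit <- character(n_decoy)
    d_value[!d_dg] <- stats::runif(sum(!d_dg), 10, 1000)
    d_unit[!d_dg] <- "uM"
    d_value[d_dg] <- -stats::runif(sum(d_dg), 5, 28)
    d_unit[d_dg] <- "kJ_per_mol"
    decoys <- data.frame(ligand_id = d_lig, target_id = d_tgt,
                         measure = d_measure, value = d_value,
                         unit = d_unit, stringsAsFactors = FALSE)
  }
  out <- rbind(actives, decoys)
  out <- out[sample(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ground_truth") <- list(
    n_active = n, n_decoy = n_decoy, expected_kept = n
  )
  out
}

#' Write a synthetic benchmark to plain-text files
#'
#' Emits molecules (SMILES, when the benchmark is structure-level),
#' activities (TSV), truth (TSV), the serialized library (JSON) and a
#' realized-statistics report (JSON) under one directory.
#'
#' @param synlib A \code{"ligfish_synlib"}.
#' @param dir Output directory (created if missing).
#' @param activities Optional activity table to include.
#' @return \code{dir}, invisibly.
#' @export
write_synthetic <- function(synlib, dir, activities = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- synlib$library
  if (!is.null(lib$molecules) && !all(is.na(lib$molecules$smiles))) {
    writeLines(paste(lib$molecules$smiles, lib$molecules$id, sep = "\t"),
               file.path(dir, "molecules.smi"))
  }
  truth_df <- data.frame(
    query_id = rep(names(synlib$truth), lengths(synlib$truth)),
    target_id = unlist(synlib$truth, use.names = FALSE)
  )
  utils::write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(activities))
    utils::write.table(activities, file.path(dir, "activities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_library(lib, file.path(dir, "library.json"))
  writeLines(jsonlite::toJSON(synlib$stats, auto_unbox = TRUE, digits = NA),
             file.path(dir, "realized_stats.json"))
  invisible(dir)
}
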