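# Ranked-retrieval metrics over target profiles and the experiment
# protocols: k-fold cross-validation, reference-fraction subsampling,
# nearest-neighbour similarity binning and target-size binning.

#' Read query truth annotations
#'
#' TSV with header columns \code{query_id}, \code{target_id}, one row per
#' known query-target interaction.
#'
#' @param path Path to the TSV file.
#' @return Named list: query id -> character vector of true target ids.
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("query_id", "target_id") %in% names(df)))
    stop("truth table needs columns query_id, target_id")
  truth_list(df)
}

#' Convert a long truth table to a truth list
#'
#' @param df Data frame with \code{query_id} and \code{target_id}.
#' @return Named list of unique true-target vectors; every query has at
#'   least one target.
#' @export
truth_list <- function(df) {
  .split_unique(as.character(df$target_id), df$query_id)
}

# plain named list of unique values per key, keys in first-appearance order
.split_unique <- function(values, keys) {
  lapply(split(values, factor(keys, levels = unique(keys))), unique)
}

.true_ranks <- function(profile, true_targets) {
  profile$rank[match(true_targets, profile$target_id)]
}

#' Precision over the top n ranked targets
#'
#' Fraction of the top-n predictions that are experimentally known targets:
#' TP(n) / n. True targets absent from the ranking (e.g. omitted by a
#' hold-out exclusion) can never count as found. If the ranking is shorter
#' than n, the count runs over the available ranks but n stays the divisor.
#'
#' @param profile A \code{"ligfish_profile"}.
#' @param true_targets Character vector of the query's known targets.
#' @param n Cutoff rank, >= 1.
#' @return Precision in [0, 1].
#' @export
precision_at <- function(profile, true_targets, n) {
  stopifnot(n >= 1)
  r <- .true_ranks(profile, true_targets)
  sum(!is.na(r) & r <= n) / n
}

#' Recall over the top n ranked targets
#'
#' Fraction of the query's m known targets found in the top n: TP(n) / m.
#'
#' @inheritParams precision_at
#' @return Recall in [0, 1].
#' @export
recall_at <- function(profile, true_targets, n) {
  stopifnot(n >= 1)
  m <- length(true_targets)
  if (m == 0L) stop("a query must have at least one true target")
  r <- .true_ranks(profile, true_targets)
  sum(!is.na(r) & r <= n) / m
}

#' F score (harmonic mean of precision and recall)
#'
#' Defined as 0 when both inputs are 0.
#'
#' @param prn,ren Precision and recall values in [0, 1].
#' @return The F score, vectorized over its inputs.
#' @export
f_measure <- function(prn, ren) {
  ifelse(prn + ren == 0, 0, 2 * prn * ren / (prn + ren))
}

#' Uninterpolated average precision capped at rank m
#'
#' For a query with m known targets, every known target ranked at position
#' i <= m contributes the precision at its own rank, PR(i); known targets
#' ranked outside the top m (or absent from the ranking) contribute 0. The
#' score is the mean of the m contributions, so it is 1 exactly when the m
#' known targets fill ranks 1..m.
#'
#' @inheritParams precision_at
#' @return A number in [0, 1].
#' @examples
#' # m = 2, true targets at ranks 1 and 3 -> (1 + 0) / 2 = 0.5
#' @export
uninterpolated_precision <- function(profile, true_targets) {
  m <- length(true_targets)
  if (m == 0L) stop("a query must have at least one true target")
  r <- .true_ranks(profile, true_targets)
  r <- sort(r[!is.na(r) & r <= m])
  if (length(r) == 0L) return(0)
  # precision at rank r_i counts the true targets ranked at or above it
  sum(seq_along(r) / r) / m
}

#' Evaluate a set of query profiles against their truths
#'
#' Per-query precision, recall and F curves for n = 1..N, averaged over
#' queries, plus the mean uninterpolated precision with its standard error
#' over queries.
#'
#' @param profiles List of \code{"ligfish_profile"} objects.
#' @param truths Named truth list covering every profile's query id.
#' @param N Curve length (top-N ranks; default 20).
#' @return A \code{"ligfish_curves"} list: \code{curves} (data frame with
#'   \code{n}, \code{PRn}, \code{REn}, \code{Fn}), \code{prprime_mean},
#'   \code{prprime_se}, \code{n_queries}, \code{per_query} (data frame with
#'   \code{query_id}, \code{m}, \code{prprime}).
#' @export
evaluate_queries <- function(profiles, truths, N = 20L) {
  stopifnot(length(profiles) > 0)
  qids <- vapply(profiles, function(p) attr(p, "query_id"), character(1))
  miss <- setdiff(qids, names(truths))
  if (length(miss))
    stop("profiles without truth: ", paste(utils::head(miss, 5), collapse = ", "))
  nq <- length(profiles)
  PR <- matrix(0, nq, N); RE <- matrix(0, nq, N)
  prp <- numeric(nq); mvec <- integer(nq)
  for (qi in seq_len(nq)) {
    tt <- truths[[qids[qi]]]
    mvec[qi] <- length(tt)
    r <- .true_ranks(profiles[[qi]], tt)
    r <- r[!is.na(r)]
    tp <- vapply(seq_len(N), function(n) sum(r <= n), numeric(1))
    PR[qi, ] <- tp / seq_len(N)
    RE[qi, ] <- tp / mvec[qi]
    prp[qi] <- uninterpolated_precision(profiles[[qi]], tt)
  }
  Fq <- f_measure(PR, RE)
  curves <- data.frame(n = seq_len(N),
                       PRn = colMeans(PR), REn = colMeans(RE),
                       Fn = colMeans(Fq))
  structure(list(
    curves = curves,
    prprime_mean = mean(prp),
    prprime_se = if (nq > 1) stats::sd(prp) / sqrt(nq) else NA_real_,
    n_queries = nq,
    per_query = data.frame(query_id = qids, m = mvec, prprime = prp,
                           stringsAsFactors = FALSE)
  ), class = "ligfish_curves")
}

#' @export
print.ligfish_curves <- function(x, ...) {
  cat(sprintf("<evaluation over %d queries: PR' = %.4f (SE %.4f)>\n",
              x$n_queries, x$prprime_mean, x$prprime_se))
  print(utils::head(x$curves, 5))
  invisible(x)
}

#' Assign library ligands to cross-validation folds
#'
#' Seeded shuffle of the library's unique ligand ids into folds whose sizes
#' differ by at most one. The split unit is the ligand: a molecule active
#' on several targets leaves all of their reference sets during its fold.
#'
#' @param library A \code{"ligfish_library"}.
#' @param folds Number of folds, >= 2.
#' @param seed Integer seed.
#' @return Named integer vector: ligand id -> fold id in 1..folds.
#' @export
assign_folds <- function(library, folds = 10L, seed = 1L) {
  ids <- names(library$fingerprints)
  stopifnot(folds >= 2L, length(ids) >= folds)
  set.seed(seed)
  shuffled <- sample(ids)
  stats::setNames(rep(seq_len(folds), length.out = length(shuffled)),
                  shuffled)
}

#' k-fold cross-validation of target fishing on a reference library
#'
#' The library's ligands are split at random into folds. Each ligand in
#' turn becomes a query: its whole fold is excluded from every reference
#' set, its targets are predicted from the remaining folds, and the truth
#' is the set of targets whose reference set contained it. A true target
#' whose reference set is emptied by the exclusion stays in m and scores 0
#' (the task is penalized, not shrunk). Also records, per query, the
#' Tanimoto similarity to its nearest neighbour among the retained ligands
#' of its true targets.
#'
#' @param library A \code{"ligfish_library"}.
#' @param folds Number of folds (default 10).
#' @param config A \code{"ligfish_fusion"}.
#' @param seed Integer seed for the fold split.
#' @param N Curve length for the pooled evaluation.
#' @return A \code{"ligfish_cv"} list: \code{pooled} (ligfish_curves over
#'   all queries), \code{fold_summary} (data frame: fold, n_queries,
#'   prprime_mean, prprime_se), \code{per_query} (with fold, m, prprime,
#'   nn_similarity), \code{fold_assignment}, \code{config}, \code{seed}.
#' @export
cross_validate <- function(library, folds = 10L,
                           config = fusion_config("knn", 3), seed = 1L,
                           N = 20L) {
  assignment <- assign_folds(library, folds, seed)
  ligand_targets <- membership_map(library)
  profiles <- vector("list", length(assignment))
  qids <- names(assignment)
  nnsim <- numeric(length(assignment))
  truths <- ligand_targets[qids]
  for (qi in seq_along(qids)) {
    qid <- qids[qi]
    held_out <- qids[assignment == assignment[[qid]]]
    prof <- fish_targets(library$fingerprints[[qid]], library,
                         config = config,
                         exclude_ligand_ids = held_out, query_id = qid)
    profiles[[qi]] <- prof
    own_ids <- setdiff(
      unique(unlist(library$targets[truths[[qid]]], use.names = FALSE)),
      held_out)
    nnsim[qi] <- if (length(own_ids) == 0L) NA_real_ else
      max(tanimoto_all(library$fingerprints[[qid]], library$index)[own_ids])
  }
  pooled <- evaluate_queries(profiles, truths, N = N)
  pq <- pooled$per_query
  pq$fold <- unname(assignment[pq$query_id])
  pq$nn_similarity <- nnsim
  fold_summary <- do.call(rbind, lapply(seq_len(folds), function(f) {
    v <- pq$prprime[pq$fold == f]
    data.frame(fold = f, n_queries = length(v), prprime_mean = mean(v),
               prprime_se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                            else NA_real_)
  }))
  structure(list(pooled = pooled, fold_summary = fold_summary,
                 per_query = pq, fold_assignment = assignment,
                 truths = truths, config = config, seed = seed),
            class = "ligfish_cv")
}

#' @export
print.ligfish_cv <- function(x, ...) {
  cat(sprintf(
    "<%d-fold cross-validation (%s%s): pooled PR' = %.4f (SE %.4f), %d queries>\n",
    nrow(x$fold_summary), x$config$scheme,
    if (x$config$scheme == "knn") paste0(", k=", x$config$k) else "",
    x$pooled$prprime_mean, x$pooled$prprime_se, x$pooled$n_queries))
  invisible(x)
}

#' Map each library ligand to the targets containing it
#' @param library A \code{"ligfish_library"}.
#' @return Named list: ligand id -> character vector of target ids.
#' @export
membership_map <- function(library) {
  pairs <- data.frame(
    ligand_id = unlist(library$targets, use.names = FALSE),
    target_id = rep(names(library$targets), lengths(library$targets)),
    stringsAsFactors = FALSE
  )
  .split_unique(pairs$target_id, pairs$ligand_id)[
    names(library$fingerprints)]
}

# restrict a library to a subset of ligand ids, dropping emptied targets
.restrict_library <- function(library, keep_ids) {
  sets <- lapply(library$targets, function(ids) ids[ids %in% keep_ids])
  dropped <- names(sets)[lengths(sets) == 0L]
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) == 0L) stop("subsample fraction empties the whole library")
  lib <- reference_library(sets, library$fingerprints,
                           molecules = library$molecules,
                           fp_params = library$fp_params)
  attr(lib, "dropped_targets") <- dropped
  lib
}

#' Reference-fraction subsampling experiment
#'
#' Measures how prediction accuracy depends on reference-library size. Per
#' replicate: a test set is drawn by picking \code{queries_per_target}
#' ligands from each target, the remaining ligands form the reference pool,
#' and for each fraction a random subset of the pool of that size becomes
#' the reference library. Every test ligand is then fished against that
#' reference and scored by uninterpolated precision against its full-library
#' truth; targets emptied by the subsample are dropped from the ranking for
#' that replicate (queries whose true target dropped keep it in m and are
#' penalized). Replicates are aggregated to a mean and standard deviation
#' per fraction.
#'
#' @param library A \code{"ligfish_library"}.
#' @param fractions Numeric vector in (0, 1].
#' @param queries_per_target Ligands held out from each target per
#'   replicate (default 5).
#' @param repeats Number of replicates (default 5).
#' @param config A \code{"ligfish_fusion"}.
#' @param seed Integer seed.
#' @return A \code{"ligfish_subsample"} list: \code{table} (data frame:
#'   fraction, prprime_mean, prprime_sd, n_repeats), \code{replicates}
#'   (per-replicate rows with dropped-target counts), \code{seed}.
#' @export
subsample_experiment <- function(library, fractions = c(0.01, 0.1, 0.5, 1),
                                 queries_per_target = 5L, repeats = 5L,
                                 config = fusion_config("knn", 3),
                                 seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1), repeats >= 1)
  fractions <- sort(fractions)
  ligand_targets <- membership_map(library)
  rep_rows <- list()
  for (rr in seq_len(repeats)) {
    set.seed(seed + rr * 1000L)
    test_ids <- unique(unlist(lapply(library$targets, function(ids) {
      take <- min(queries_per_target, length(ids) - 1L)
      if (take < 1L) return(character(0))
      sample(ids, take)
    }), use.names = FALSE))
    pool <- setdiff(names(library$fingerprints), test_ids)
    if (length(pool) == 0L) stop("no reference ligands left after hold-out")
    for (f in fractions) {
      size <- max(1L, round(f * length(pool)))
      ref_ids <- if (size >= length(pool)) pool else sample(pool, size)
      sub <- .restrict_library(library, ref_ids)
      prp <- vapply(test_ids, function(qid) {
        prof <- fish_targets(library$fingerprints[[qid]], sub,
                             config = config, query_id = qid)
        uninterpolated_precision(prof, ligand_targets[[qid]])
      }, numeric(1))
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        fraction = f, repeat_id = rr, n_queries = length(test_ids),
        n_reference = length(ref_ids),
        n_targets_dropped = length(attr(sub, "dropped_targets")),
        prprime = mean(prp)
      )
    }
  }
  reps <- do.call(rbind, rep_rows)
  tab <- do.call(rbind, lapply(fractions, function(f) {
    v <- reps$prprime[reps$fraction == f]
    data.frame(fraction = f, prprime_mean = mean(v),
               prprime_sd = stats::sd(v), n_repeats = length(v))
  }))
  structure(list(table = tab, replicates = reps, config = config,
                 seed = seed),
            class = "ligfish_subsample")
}

#' @export
print.ligfish_subsample <- function(x, ...) {
  cat("<reference-fraction subsampling experiment>\n")
  print(x$table)
  invisible(x)
}

#' Bin per-query accuracy by nearest-neighbour similarity
#'
#' Groups queries by the Tanimoto similarity to their closest neighbour in
#' their own true-target reference set and averages uninterpolated
#' precision within each bin. Empty bins are reported with NA means rather
#' than 0.
#'
#' @param per_query Data frame with \code{prprime} and
#'   \code{nn_similarity} columns (e.g. from \code{\link{cross_validate}}).
#' @param bin_edges Increasing break points spanning [0, 1].
#' @return Data frame: \code{bin}, \code{lower}, \code{upper},
#'   \code{n_queries}, \code{prprime_mean}.
#' @export
nn_similarity_binning <- function(per_query,
                                  bin_edges = seq(0, 1, by = 0.1)) {
  stopifnot(all(c("prprime", "nn_similarity") %in% names(per_query)),
            length(bin_edges) >= 2, !is.unsorted(bin_edges))
  idx <- cut(per_query$nn_similarity, breaks = bin_edges,
             include.lowest = TRUE, labels = FALSE)
  nb <- length(bin_edges) - 1L
  do.call(rbind, lapply(seq_len(nb), function(b) {
    v <- per_query$prprime[!is.na(idx) & idx == b]
    data.frame(bin = b, lower = bin_edges[b], upper = bin_edges[b + 1L],
               n_queries = length(v),
               prprime_mean = if (length(v)) mean(v) else NA_real_)
  }))
}

#' Bin targets by reference-set size and average their accuracy
#'
#' Targets are sorted by ligand count and split into \code{n_bins}
#' equal-count bins; a target's accuracy is the mean uninterpolated
#' precision over the cross-validation queries whose truth includes it.
#'
#' @param library A \code{"ligfish_library"}.
#' @param cv A \code{"ligfish_cv"} result on that library.
#' @param n_bins Number of size bins (default 10).
#' @return Data frame: \code{bin}, \code{size_min}, \code{size_max},
#'   \code{n_targets}, \code{prprime_mean}, \code{prprime_se}.
#' @export
target_size_binning <- function(library, cv, n_bins = 10L) {
  sizes <- target_sizes(library)
  if (length(sizes) < n_bins)
    stop("fewer targets (", length(sizes), ") than bins (", n_bins, ")")
  prp <- stats::setNames(cv$per_query$prprime, cv$per_query$query_id)
  target_prp <- vapply(names(library$targets), function(t) {
    qs <- names(cv$truths)[vapply(cv$truths, function(tt) t %in% tt,
                                  logical(1))]
    if (length(qs) == 0L) return(NA_real_)
    mean(prp[qs])
  }, numeric(1))
  ord <- order(sizes, names(sizes), method = "radix")
  bin <- ceiling(seq_along(ord) * n_bins / length(ord))
  do.call(rbind, lapply(seq_len(n_bins), function(b) {
    t_in <- names(sizes)[ord[bin == b]]
    v <- target_prp[t_in]
    v <- v[!is.na(v)]
    data.frame(bin = b,
               size_min = min(sizes[t_in]), size_max = max(sizes[t_in]),
               n_targets = length(t_in),
               prprime_mean = if (length(v)) mean(v) else NA_real_,
               prprime_se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                            else NA_real_)
  }))
}
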