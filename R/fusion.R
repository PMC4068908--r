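# Similarity fusion: score a query against every target in the reference
# library and rank targets in descending order of fused score.

#' Fusion scheme configuration
#'
#' The three data-fusion schemes: \code{"max"} scores a target by the single
#' nearest reference ligand, \code{"knn"} by the mean similarity of the k
#' nearest (k of 1, 3 and 5 are the conventional Max, 3NN and 5NN settings;
#' Max is exactly knn with k = 1), and \code{"centroid"} by the mean over
#' the whole ligand set.
#'
#' @param scheme \code{"max"}, \code{"knn"} or \code{"centroid"}.
#' @param k Number of neighbours for \code{"knn"}; forced to 1 for
#'   \code{"max"}, ignored for \code{"centroid"}.
#' @return A \code{"ligfish_fusion"} list with \code{scheme} and \code{k}.
#' @examples
#' fusion_config("knn", k = 3)
#' @export
fusion_config <- function(scheme = c("knn", "max", "centroid"), k = 3L) {
  scheme <- match.arg(scheme)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (scheme == "max") k <- 1L
  structure(list(scheme = scheme, k = k), class = "ligfish_fusion")
}

#' @export
print.ligfish_fusion <- function(x, ...) {
  lab <- switch(x$scheme,
                max = "Max (nearest ligand)",
                knn = sprintf("%dNN (mean of %d nearest ligands)", x$k, x$k),
                centroid = "Centroid (mean over the whole set)")
  cat("<fusion scheme: ", lab, ">\n", sep = "")
  invisible(x)
}

#' Tanimoto similarities of a query to one target's ligand set
#'
#' One value per reference ligand of the target, in the library's ligand
#' order; downstream fusion is order-independent.
#'
#' @param query_fp A \code{"ligfish_fp"}.
#' @param target_id Target identifier in the library.
#' @param library A \code{"ligfish_library"}.
#' @return Named numeric vector of similarities in [0, 1], length N of the
#'   target.
#' @export
similarities_to_target <- function(query_fp, target_id, library) {
  ids <- library$targets[[target_id]]
  if (is.null(ids)) stop("unknown target: ", target_id)
  vapply(ids, function(i) tanimoto(query_fp, library$fingerprints[[i]]),
         numeric(1))
}

#' k-nearest-neighbour fusion score
#'
#' Mean of the k largest similarity values. When the reference set holds
#' fewer than k ligands the mean is taken over all of them, so the score
#' degrades gracefully toward the centroid rather than failing. k = 1 is
#' the Max score.
#'
#' @param sims Non-empty numeric vector of similarities.
#' @param k Positive integer.
#' @return The fusion score.
#' @examples
#' knn_score(c(0.9, 0.5, 0.1), k = 1)  # 0.9
#' knn_score(c(0.9, 0.5, 0.1), k = 3)  # 0.5
#' @export
knn_score <- function(sims, k) {
  if (length(sims) == 0L) stop("empty similarity vector")
  if (k < 1L) stop("k must be >= 1")
  kk <- min(as.integer(k), length(sims))
  mean(sort(sims, decreasing = TRUE)[seq_len(kk)])
}

#' Centroid fusion score
#'
#' Arithmetic mean similarity over the target's whole ligand set.
#'
#' @param sims Non-empty numeric vector of similarities.
#' @return The fusion score.
#' @export
centroid_score <- function(sims) {
  if (length(sims) == 0L) stop("empty similarity vector")
  mean(sims)
}

.fuse <- function(sims, config) {
  switch(config$scheme,
         max = ,
         knn = knn_score(sims, config$k),
         centroid = centroid_score(sims))
}

#' Rank all targets for a query molecule (target fishing)
#'
#' Computes the configured fusion score of the query against every target's
#' reference ligand set and returns the full descending ranking — the
#' query's target-interaction profile. Ties are broken by target id
#' (ascending) for determinism. \code{exclude_ligand_ids} removes ligands
#' from every reference set before scoring (the hold-out mechanism for
#' cross-validation); targets emptied by the exclusion are omitted from the
#' ranking and listed in the profile's metadata rather than scored 0, since
#' 0 is a legitimate similarity value.
#'
#' @param query A \code{"ligfish_fp"}, a SMILES string, or a one-row
#'   molecule data frame.
#' @param library A \code{"ligfish_library"}.
#' @param config A \code{"ligfish_fusion"} (default 3NN).
#' @param exclude_ligand_ids Optional character vector of ligand ids to
#'   hold out from all reference sets.
#' @param query_id Identifier recorded on the profile.
#' @return A \code{"ligfish_profile"}: data frame with columns \code{rank},
#'   \code{target_id}, \code{score}, \code{n_reference_ligands},
#'   \code{k_used}; attributes \code{query_id}, \code{config},
#'   \code{omitted_targets}.
#' @export
fish_targets <- function(query, library, config = fusion_config("knn", 3),
                         exclude_ligand_ids = NULL, query_id = NULL) {
  stopifnot(inherits(library, "ligfish_library"))
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    if (is.null(query_id)) query_id <- query$id
    query <- query$smiles
  }
  if (is.character(query)) {
    query <- compute_fingerprint(query,
                                 radius = library$fp_params$radius,
                                 bit_length = library$fp_params$bit_length)
  }
  if (is.null(query_id)) query_id <- "query"
  sims_all <- tanimoto_all(query, library$index)

  tids <- names(library$targets)
  scores <- numeric(length(tids))
  nref <- integer(length(tids))
  kused <- integer(length(tids))
  keep <- logical(length(tids))
  for (ti in seq_along(tids)) {
    ids <- library$targets[[ti]]
    if (!is.null(exclude_ligand_ids))
      ids <- ids[!ids %in% exclude_ligand_ids]
    if (length(ids) == 0L) next
    sims <- sims_all[ids]
    keep[ti] <- TRUE
    nref[ti] <- length(ids)
    kused[ti] <- if (config$scheme == "centroid") length(ids)
                 else min(config$k, length(ids))
    scores[ti] <- .fuse(sims, config)
  }
  omitted <- tids[!keep]
  tids <- tids[keep]
  scores <- scores[keep]; nref <- nref[keep]; kused <- kused[keep]
  if (length(tids) == 0L) stop("all targets were emptied by the exclusion")
  ord <- order(-scores, tids, method = "radix")
  out <- data.frame(
    rank = seq_along(ord),
    target_id = tids[ord],
    score = scores[ord],
    n_reference_ligands = nref[ord],
    k_used = kused[ord],
    stringsAsFactors = FALSE
  )
  structure(out, class = c("ligfish_profile", "data.frame"),
            query_id = query_id, config = config,
            omitted_targets = omitted)
}

#' @export
print.ligfish_profile <- function(x, n = 10L, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<target profile for '%s' (%s%s): %d targets>\n",
              attr(x, "query_id"), cfg$scheme,
              if (cfg$scheme == "knn") paste0(", k=", cfg$k) else "",
              nrow(x)))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}

#' Write target profiles as TSV
#'
#' One row per (query, rank): \code{query_id}, \code{rank},
#' \code{target_id}, \code{score}, \code{scheme}, \code{k},
#' \code{n_reference_ligands}.
#'
#' @param profiles A \code{"ligfish_profile"} or list of them.
#' @param path Output path.
#' @param top Keep only the first \code{top} ranks per query (\code{Inf}
#'   for the full ranking).
#' @return \code{path}, invisibly.
#' @export
write_profiles <- function(profiles, path, top = Inf) {
  if (inherits(profiles, "ligfish_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    cfg <- attr(p, "config")
    h <- utils::head(as.data.frame(p), top)
    data.frame(query_id = attr(p, "query_id"), h[, 1:3],
               scheme = cfg$scheme, k = cfg$k,
               n_reference_ligands = h$n_reference_ligands,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
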