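# Independent brute-force oracles used to cross-check the implementation.
# These deliberately take the plainest possible route: scalar set
# operations, explicit loops, direct sorts.

# Tanimoto on folded bit vectors via logical popcount, the dual route to
# the sparse set representation.
popcount_tanimoto <- function(a, b, bit_length) {
  va <- logical(bit_length); vb <- logical(bit_length)
  va[(unclass(a) %% bit_length) + 1L] <- TRUE
  vb[(unclass(b) %% bit_length) + 1L] <- TRUE
  un <- sum(va | vb)
  if (un == 0L) return(0)
  sum(va & vb) / un
}

# All-pairs similarity fishing: score every target by looping over its
# ligands with scalar tanimoto, fuse, and sort by (-score, target id).
naive_fish <- function(query_fp, target_sets, fps, scheme, k = 1L) {
  tids <- names(target_sets)
  scores <- vapply(tids, function(t) {
    sims <- vapply(target_sets[[t]],
                   function(l) tanimoto(query_fp, fps[[l]]), numeric(1))
    if (scheme == "centroid") {
      mean(sims)
    } else {
      kk <- min(k, length(sims))
      mean(sort(sims, decreasing = TRUE)[seq_len(kk)])
    }
  }, numeric(1))
  ord <- order(-scores, tids, method = "radix")
  data.frame(rank = seq_along(ord), target_id = tids[ord],
             score = unname(scores[ord]), stringsAsFactors = FALSE)
}

# Metrics by direct enumeration over a ranked target vector.
naive_precision_at <- function(ranked, truth, n) {
  sum(ranked[seq_len(min(n, length(ranked)))] %in% truth) / n
}
naive_recall_at <- function(ranked, truth, n) {
  sum(ranked[seq_len(min(n, length(ranked)))] %in% truth) / length(truth)
}
naive_prprime <- function(ranked, truth) {
  m <- length(truth)
  total <- 0
  for (t in truth) {
    r <- match(t, ranked)
    if (!is.na(r) && r <= m) {
      total <- total + sum(ranked[seq_len(r)] %in% truth) / r
    }
  }
  total / m
}

# wrap a plain ranked target vector as a profile-shaped data frame
as_profile <- function(ranked, query_id = "q") {
  structure(
    data.frame(rank = seq_along(ranked), target_id = ranked,
               score = seq(1, 0, length.out = length(ranked)),
               n_reference_ligands = 1L, k_used = 1L,
               stringsAsFactors = FALSE),
    class = c("ligfish_profile", "data.frame"),
    query_id = query_id, config = fusion_config("max"),
    omitted_targets = character(0))
}
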