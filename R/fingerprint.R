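# Circular (Morgan-type) fingerprints computed on a kekulized connection
# table, plus set-based and folded-bitvector Tanimoto similarity.

# Deterministic 31-bit polynomial hash of an integer vector. Arithmetic is
# done in doubles below 2^53, so results are exact and platform-independent.
.hash_ints <- function(x) {
  h <- 16777619
  for (v in x) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

.ELEMENT_CODES <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Se = 34L, Br = 35L, I = 53L
)

.element_code <- function(sym) {
  code <- .ELEMENT_CODES[sym]
  miss <- is.na(code)
  if (any(miss)) {
    # unknown elements get a stable code derived from the symbol itself
    code[miss] <- vapply(
      sym[miss],
      function(s) 200L + .hash_ints(utf8ToInt(s)) %% 1000L,
      integer(1)
    )
  }
  unname(code)
}

#' Compute a circular fingerprint for one molecule
#'
#' Hashed circular substructure fingerprint in the extended-connectivity
#' family: atom environments of increasing radius are encoded by iterative
#' neighbourhood hashing of atom invariants (element, heavy-atom degree, sum
#' of bond orders) over the kekulized connection table. The default
#' \code{radius = 2} corresponds to the common diameter-4 convention (ECFP4).
#'
#' @param mol A single-molecule \code{SDF}/\code{SDFset} (ChemmineR) or a
#'   SMILES string.
#' @param radius Maximum environment radius (number of bond-expansion
#'   rounds); non-negative integer.
#' @param bit_length Fold the feature identifiers into this many bits, or
#'   \code{NA} for the unfolded sparse feature set.
#' @return An integer vector of sorted unique feature identifiers with class
#'   \code{"ligfish_fp"} and attributes \code{radius} and \code{bit_length}.
#' @examples
#' fp <- compute_fingerprint("c1ccccc1O")
#' length(fp)
#' @export
compute_fingerprint <- function(mol, radius = 2L, bit_length = NA_integer_) {
  stopifnot(length(radius) == 1L, radius >= 0)
  if (is.character(mol)) {
    stopifnot(length(mol) == 1L, !is.na(mol), nzchar(mol))
    mol <- ChemmineR::smiles2sdf(mol)
  }
  if (inherits(mol, "SDFset")) {
    stopifnot(length(mol) == 1L)
    mol <- mol[[1]]
  }
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  sym <- sub("_\\d+$", "", rownames(ab))
  keep <- sym != "H"
  if (!any(keep)) stop("molecule has no heavy atoms")
  idx_map <- cumsum(keep)          # old index -> heavy-atom index
  n <- sum(keep)
  elem <- .element_code(sym[keep])

  # heavy-atom adjacency with bond orders
  nbrs <- vector("list", n)
  orders <- vector("list", n)
  if (!is.null(bb) && nrow(bb) > 0) {
    for (r in seq_len(nrow(bb))) {
      a1 <- bb[r, 1L]; a2 <- bb[r, 2L]; o <- bb[r, 3L]
      if (keep[a1] && keep[a2]) {
        i <- idx_map[a1]; j <- idx_map[a2]
        nbrs[[i]] <- c(nbrs[[i]], j); orders[[i]] <- c(orders[[i]], o)
        nbrs[[j]] <- c(nbrs[[j]], i); orders[[j]] <- c(orders[[j]], o)
      }
    }
  }
  degree <- lengths(nbrs)
  bondsum <- vapply(orders, function(o) as.integer(sum(o)), integer(1))

  inv <- mapply(function(e, d, b) .hash_ints(c(e, d, b)),
                elem, degree, bondsum)
  features <- inv
  if (radius >= 1) {
    for (round in seq_len(radius)) {
      inv_new <- integer(n)
      for (i in seq_len(n)) {
        if (degree[i] == 0L) {
          inv_new[i] <- .hash_ints(c(round, inv[i]))
        } else {
          pairs <- rbind(orders[[i]], inv[nbrs[[i]]])
          pairs <- pairs[, order(pairs[1L, ], pairs[2L, ]), drop = FALSE]
          inv_new[i] <- .hash_ints(c(round, inv[i], as.vector(pairs)))
        }
      }
      inv <- inv_new
      features <- c(features, inv)
    }
  }
  features <- sort(unique(as.integer(features)))
  if (!is.na(bit_length)) {
    stopifnot(bit_length >= 1)
    features <- sort(unique(features %% as.integer(bit_length)))
  }
  new_fingerprint(features, radius = radius, bit_length = bit_length)
}

#' Construct a fingerprint from explicit feature identifiers
#'
#' Low-level constructor used by the fingerprint-level synthetic benchmark
#' and by deserialization; features are deduplicated and sorted.
#'
#' @param features Non-negative integer feature identifiers.
#' @param radius,bit_length Generation parameters recorded on the object.
#' @return A \code{"ligfish_fp"} object.
#' @export
new_fingerprint <- function(features, radius = 2L, bit_length = NA_integer_) {
  features <- sort(unique(as.integer(features)))
  stopifnot(all(features >= 0L))
  structure(features, class = "ligfish_fp",
            radius = as.integer(radius),
            bit_length = as.integer(bit_length))
}

#' @export
print.ligfish_fp <- function(x, ...) {
  bl <- attr(x, "bit_length")
  cat(sprintf("<circular fingerprint: %d features, radius %d, %s>\n",
              length(x), attr(x, "radius"),
              if (is.na(bl)) "unfolded" else paste0(bl, " bits")))
  invisible(x)
}

.fp_params_match <- function(a, b) {
  identical(attr(a, "radius"), attr(b, "radius")) &&
    identical(attr(a, "bit_length"), attr(b, "bit_length"))
}

#' Tanimoto similarity between two fingerprints
#'
#' Set-overlap similarity |A intersect B| / |A union B| in [0, 1]. Two empty
#' fingerprints score 0 by convention, so structureless inputs never rank
#' highly. Fingerprints must share radius and folding length.
#'
#' @param a,b \code{"ligfish_fp"} objects (or plain integer feature vectors).
#' @return A number in [0, 1].
#' @examples
#' tanimoto(new_fingerprint(1:3), new_fingerprint(2:4))  # 2/4
#' @export
tanimoto <- function(a, b) {
  if (inherits(a, "ligfish_fp") && inherits(b, "ligfish_fp") &&
      !.fp_params_match(a, b)) {
    stop("fingerprints were computed with different (radius, bit_length)")
  }
  ni <- length(intersect(a, b))
  nu <- length(a) + length(b) - ni
  if (nu == 0L) return(0)
  ni / nu
}

# Sparse ligand-by-feature index for vectorized similarity of one query
# against many reference ligands. `fps` is a named list of fingerprints.
fp_index <- function(fps) {
  stopifnot(length(fps) > 0, !is.null(names(fps)))
  feats <- sort(unique(unlist(fps, use.names = FALSE)))
  j <- match(unlist(fps, use.names = FALSE), feats)
  i <- rep.int(seq_along(fps), lengths(fps))
  mat <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(fps), length(feats)))
  structure(list(mat = mat, features = feats, ligand_ids = names(fps),
                 sizes = lengths(fps)),
            class = "ligfish_fp_index")
}

# Tanimoto of `query_fp` against every ligand in the index, in index order.
tanimoto_all <- function(query_fp, index) {
  q <- match(unclass(query_fp), index$features)
  q <- q[!is.na(q)]
  nq <- length(query_fp)
  if (length(q) == 0L) {
    inter <- numeric(length(index$ligand_ids))
  } else {
    inter <- as.numeric(index$mat[, q, drop = FALSE] %*% rep(1, length(q)))
  }
  un <- index$sizes + nq - inter
  sim <- ifelse(un == 0, 0, inter / un)
  names(sim) <- index$ligand_ids
  sim
}
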