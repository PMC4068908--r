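# Programmatic fixtures shared across test files.

fp <- function(features) new_fingerprint(features)

random_fp <- function(pool = 1:100, size_range = c(5, 30)) {
  fp(sample(pool, sample(size_range[1]:size_range[2], 1)))
}

# a toy library with explicit per-ligand fingerprints
toy_library <- function(target_sets, fps,
                        keys = NULL) {
  ids <- unique(unlist(target_sets, use.names = FALSE))
  mols <- data.frame(
    id = ids, smiles = NA_character_,
    canonical_key = if (is.null(keys)) paste0("key:", ids)
                    else keys[ids],
    stringsAsFactors = FALSE)
  reference_library(target_sets, fps, molecules = mols,
                    fp_params = list(radius = 2L, bit_length = NA_integer_))
}

# random clustered toy library: n_targets clusters around disjoint feature
# blocks; returns the pieces naive_fish needs alongside the library
random_toy_library <- function(n_targets = NULL, max_ligands = 30) {
  if (is.null(n_targets)) n_targets <- sample(3:20, 1)
  fps <- list(); sets <- list()
  li <- 0L
  for (j in seq_len(n_targets)) {
    n_lig <- sample(2:max_ligands, 1)
    base <- (j - 1L) * 40L + 1:30
    ids <- character(n_lig)
    for (l in seq_len(n_lig)) {
      li <- li + 1L
      ids[l] <- sprintf("L%04d", li)
      fps[[ids[l]]] <- fp(c(sample(base, 15), sample(1000:1100, 5)))
    }
    sets[[sprintf("T%03d", j)]] <- ids
  }
  list(library = toy_library(sets, fps), sets = sets, fps = fps)
}

# valid three-record SDF text with an optional corrupted middle block
write_sdf_fixture <- function(path, corrupt_middle = FALSE) {
  sdf <- ChemmineR::smiles2sdf(c(m1 = "CCO", m2 = "c1ccccc1", m3 = "CCN"))
  lines <- unlist(as(as(sdf, "SDFstr"), "list"))
  if (corrupt_middle) {
    # truncate the second molecule's atom block to break the record
    starts <- which(lines == "$$$$")
    block2 <- (starts[1] + 1):(starts[2] - 1)
    drop <- block2[6:9]
    lines <- lines[-drop]
  }
  writeLines(lines, path)
  path
}

expect_same_ranking <- function(profile, oracle) {
  expect_equal(profile$target_id, oracle$target_id)
  expect_equal(profile$score, oracle$score, tolerance = 1e-12)
}
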