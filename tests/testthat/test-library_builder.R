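act <- function(ligand, target, measure, value, unit) {
  data.frame(ligand_id = ligand, target_id = target, measure = measure,
             value = value, unit = unit, stringsAsFactors = FALSE)
}

test_that("activity filter applies the strict 10 uM cutoff across units", {
  recs <- rbind(
    act("a", "T", "Ki", 9999, "nM"),     # 9.999 uM -> kept
    act("b", "T", "IC50", 10, "uM"),     # boundary -> dropped
    act("c", "T", "IC50", 10000, "nM"),  # boundary in nM -> dropped
    act("d", "T", "EC50", 9e-6, "M"),    # 9 uM -> kept
    act("e", "T", "Kd", 0.5, "uM")
  )
  kept <- apply_activity_filter(recs)
  expect_setequal(kept$ligand_id, c("a", "d", "e"))
  expect_equal(attr(kept, "filter_report")$n_dropped, 2L)
})

test_that("free-energy records are kept by magnitude beyond 28.53 kJ/mol", {
  recs <- rbind(
    act("a", "T", "deltaG", -30.0, "kJ_per_mol"),
    act("b", "T", "deltaG", -20.0, "kJ_per_mol"),
    act("c", "T", "deltaG", 35.0, "kJ_per_mol"),   # sign accepted either way
    act("d", "T", "deltaG", -28.53, "kJ_per_mol")  # boundary inclusive
  )
  kept <- apply_activity_filter(recs)
  expect_setequal(kept$ligand_id, c("a", "c", "d"))
})

test_that("malformed activity records are rejected", {
  expect_error(apply_activity_filter(act("a", "T", "IC50", 5, "kJ_per_mol")),
               "nM, uM or M")
  expect_error(apply_activity_filter(act("a", "T", "deltaG", -30, "uM")),
               "kJ_per_mol")
  expect_error(apply_activity_filter(act("a", "T", "pIC50", 7, "uM")),
               "unknown measure")
  expect_error(apply_activity_filter(act("a", "T", "Ki", -5, "nM")),
               "non-positive")
})

test_that("target merging pools ligands and respects strictness", {
  recs <- rbind(act("L1", "A", "Ki", 1, "uM"), act("L2", "B", "Ki", 1, "uM"))
  merged <- merge_targets(recs, c(A = "M", B = "M"))
  expect_equal(unique(merged$target_id), "M")
  expect_identical(merge_targets(recs, c(A = "A", B = "B")), recs)
  expect_identical(merge_targets(recs, NULL), recs)
  expect_error(merge_targets(recs, c(A = "M"), strict = TRUE), "unmapped")
})

test_that("merging then dedup collapses one ligand seen under both targets", {
  recs <- rbind(act("L", "A", "Ki", 1, "uM"), act("L", "B", "Ki", 1, "uM"))
  merged <- merge_targets(recs, c(A = "M", B = "M"))
  sets <- group_target_sets(merged)
  mols <- data.frame(id = "L", canonical_key = "k1")
  dd <- deduplicate(sets, mols)
  expect_equal(dd$M, "L")
})

test_that("dedup is per-target: first key occurrence wins, cross-target copies stay", {
  sets <- list(A = c("asp1", "asp2", "x"), B = c("asp2", "y"))
  mols <- data.frame(id = c("asp1", "asp2", "x", "y"),
                     canonical_key = c("asp", "asp", "kx", "ky"))
  dd <- deduplicate(sets, mols)
  expect_equal(dd$A, c("asp1", "x"))
  expect_equal(dd$B, c("asp2", "y"))   # retained in B despite collapse in A
  expect_equal(attr(dd, "dedup_report")$A, "asp2")
  expect_error(deduplicate(list(A = "ghost"), mols), "without molecule")
})

test_that("size filter removes targets at and below the boundary", {
  mk <- function(n) sprintf("l%d", seq_len(n))
  sets <- list(s5 = mk(5), s10 = mk(10), s11 = mk(11), s200 = mk(200))
  out <- drop_small_targets(sets)
  expect_equal(names(out), c("s11", "s200"))
})

test_that("build_library runs every curation stage with hand-counted results", {
  # 12 targets; sizes after dedup: 4 targets at <= 10 unique ligands
  sizes <- c(3, 8, 10, 10, 11, 12, 13, 14, 15, 16, 17, 18)
  fps <- list(); mols <- NULL; rows <- NULL
  li <- 0L
  for (j in seq_along(sizes)) {
    tid <- sprintf("T%02d", j)
    for (l in seq_len(sizes[j])) {
      li <- li + 1L
      id <- sprintf("L%03d", li)
      fps[[id]] <- fp(j * 50 + 1:20)
      rows <- rbind(rows, act(id, tid, "Ki", 100, "nM"))
    }
  }
  mols <- data.frame(id = names(fps), smiles = NA_character_,
                     canonical_key = paste0("k", names(fps)))
  # decoy records that the activity filter must drop
  decoys <- act(sprintf("L%03d", 1:5), "T12", "IC50", 50, "uM")
  lib <- build_library(mols, rbind(rows, decoys), fingerprints = fps)
  expect_s3_class(lib, "ligfish_library")
  expect_equal(length(lib$targets), 8L)
  expect_equal(lib$build_report$after_activity_filter$dropped, 5L)
  expect_equal(sum(target_sizes(lib)), sum(sizes[sizes > 10]))
  # stage pair counts never increase
  expect_lte(lib$build_report$after_size_filter$pairs,
             lib$build_report$after_dedup$pairs)

  expect_error(
    build_library(mols, act("L001", "T01", "IC50", 50, "uM"),
                  fingerprints = fps),
    "empty library")
})

test_that("curation is idempotent on its own output", {
  r <- random_toy_library(n_targets = 4, max_ligands = 20)
  sizes <- lengths(r$sets)
  sets <- r$sets[sizes > 2]
  mols <- data.frame(id = names(r$fps), smiles = NA_character_,
                     canonical_key = paste0("k", names(r$fps)))
  dd <- deduplicate(sets, mols)
  expect_identical(unname(unclass(dd)[names(dd)]),
                   unname(deduplicate(dd, mols)[names(dd)]))
  expect_identical(drop_small_targets(dd, 2),
                   drop_small_targets(drop_small_targets(dd, 2), 2))
})

test_that("library serialization round-trips and is byte-stable", {
  r <- random_toy_library(n_targets = 3, max_ligands = 8)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_library(r$library, p1)
  write_library(r$library, p2)
  expect_identical(readLines(p1), readLines(p2))
  lib2 <- read_library(p1)
  expect_equal(lib2$targets, r$library$targets)
  expect_equal(lapply(lib2$fingerprints, unclass),
               lapply(r$library$fingerprints, unclass))
  # ranking identical through the round-trip
  q <- r$fps[[1]]
  expect_equal(fish_targets(q, lib2)$target_id,
               fish_targets(q, r$library)$target_id)
})

test_that("overlap removal drops queries present in the library", {
  r <- random_toy_library(n_targets = 3, max_ligands = 8)
  lib <- r$library
  queries <- data.frame(
    id = c("q1", "q2", "q3", "q4", "q5"),
    smiles = NA_character_,
    canonical_key = c(lib$molecules$canonical_key[1], "fresh1",
                      lib$molecules$canonical_key[5], "fresh2", "fresh3"))
  out <- remove_overlap(queries, lib)
  expect_equal(out$id, c("q2", "q4", "q5"))
  expect_equal(attr(out, "removal_report")$n_removed, 2L)
  expect_setequal(attr(out, "removal_report")$removed, c("q1", "q3"))
})
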