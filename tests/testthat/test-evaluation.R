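test_that("precision and recall at n match hand counts", {
  prof <- as_profile(c("A", "B", "C", "D", "E"))
  expect_equal(precision_at(prof, c("A", "C"), 3), 2 / 3)
  expect_equal(precision_at(prof, "Z", 3), 0)
  expect_equal(precision_at(prof, c("A", "B", "C"), 3), 1)
  expect_equal(recall_at(prof, c("A", "Z"), 3), 0.5)
  expect_equal(recall_at(prof, c("A", "C"), 5), 1)
  expect_equal(recall_at(prof, "B", 1), 0)
  expect_error(recall_at(prof, character(0), 3), "at least one")
})

test_that("F score is the harmonic mean with a defined zero limit", {
  expect_equal(f_measure(0.5, 1.0), 2 / 3, tolerance = 1e-4)
  expect_equal(f_measure(0.3, 0.3), 0.3)
  expect_equal(f_measure(0, 0), 0)
})

test_that("uninterpolated precision caps contributions at rank m", {
  prof <- as_profile(c("A", "B", "C", "D"))
  expect_equal(uninterpolated_precision(prof, c("A", "B")), 1)
  expect_equal(uninterpolated_precision(prof, c("A", "C")), 0.5)
  expect_equal(uninterpolated_precision(prof, "B"), 0)      # m=1, rank 2
  expect_equal(uninterpolated_precision(prof, "A"), 1)
  # a true target absent from the ranking contributes 0 but stays in m
  expect_equal(uninterpolated_precision(prof, c("A", "ZZZ")), 0.5)
})

test_that("metrics agree with the brute-force oracle on random rankings", {
  set.seed(23)
  targets <- sprintf("T%02d", 1:25)
  for (i in 1:300) {
    ranked <- sample(targets)
    truth <- sample(targets, sample(1:4, 1))
    prof <- as_profile(ranked)
    n <- sample(1:20, 1)
    expect_equal(precision_at(prof, truth, n),
                 naive_precision_at(ranked, truth, n))
    expect_equal(recall_at(prof, truth, n),
                 naive_recall_at(ranked, truth, n))
    expect_equal(uninterpolated_precision(prof, truth),
                 naive_prprime(ranked, truth))
  }
})

test_that("evaluate_queries averages per-query values and reports SE", {
  p1 <- as_profile(c("A", "B", "C"), "q1")  # truth A -> PR' 1
  p2 <- as_profile(c("A", "B", "C"), "q2")  # truth C, m=1 -> PR' 0
  res <- evaluate_queries(list(p1, p2), list(q1 = "A", q2 = "C"), N = 3)
  expect_equal(res$prprime_mean, 0.5)
  expect_equal(res$prprime_se, sd(c(1, 0)) / sqrt(2))
  expect_equal(res$curves$PRn[1], 0.5)  # q1 hits at rank 1, q2 misses
  single <- evaluate_queries(list(p1), list(q1 = "A"), N = 3)
  expect_equal(single$prprime_mean, 1)
  expect_error(evaluate_queries(list(p1), list(zz = "A")), "without truth")
})

test_that("recall and true-positive counts never decrease with n", {
  set.seed(31)
  r <- random_toy_library(n_targets = 10)
  truths <- list(); profiles <- list()
  for (i in 1:12) {
    qid <- sprintf("q%d", i)
    profiles[[i]] <- fish_targets(random_fp(pool = 1:1100), r$library,
                                  query_id = qid)
    truths[[qid]] <- sample(names(r$sets), sample(1:3, 1))
  }
  res <- evaluate_queries(profiles, truths, N = 10)
  expect_true(all(diff(res$curves$REn) >= -1e-12))
  tpn <- res$curves$PRn * res$curves$n
  expect_true(all(diff(tpn) >= -1e-9))
  expect_true(all(res$curves$Fn >= 0 & res$curves$Fn <= 1))
})

test_that("fold assignment is a seeded partition with near-equal sizes", {
  r <- random_toy_library(n_targets = 6)
  a1 <- assign_folds(r$library, folds = 10, seed = 4)
  a2 <- assign_folds(r$library, folds = 10, seed = 4)
  expect_identical(a1, a2)
  expect_setequal(names(a1), names(r$library$fingerprints))
  sizes <- table(a1)
  expect_lte(max(sizes) - min(sizes), 1)
  a3 <- assign_folds(r$library, folds = 10, seed = 5)
  expect_false(identical(a1, a3))
})

test_that("cross-validation separates tight disjoint clusters perfectly", {
  # two targets with near-identical ligands and no cross-talk
  fps <- c(
    setNames(lapply(1:6, function(i) fp(c(1:18, 18 + i))), paste0("a", 1:6)),
    setNames(lapply(1:6, function(i) fp(c(101:118, 118 + i))), paste0("b", 1:6))
  )
  lib <- toy_library(list(A = paste0("a", 1:6), B = paste0("b", 1:6)), fps)
  cv <- cross_validate(lib, folds = 3, config = fusion_config("knn", 3),
                       seed = 2)
  expect_equal(cv$pooled$prprime_mean, 1.0)
  cv2 <- cross_validate(lib, folds = 3, config = fusion_config("knn", 3),
                        seed = 2)
  expect_identical(cv$per_query, cv2$per_query)
  expect_equal(nrow(cv$fold_summary), 3L)
  expect_equal(sum(cv$fold_summary$n_queries), 12L)
})

test_that("multi-target ligands are held out of all their reference sets", {
  # ligand 'shared' sits in both targets; during its fold neither set may
  # contain it, and its truth has m = 2
  fps <- c(
    setNames(lapply(1:5, function(i) fp(c(1:15, 15 + i))), paste0("a", 1:5)),
    setNames(lapply(1:5, function(i) fp(c(201:215, 215 + i))), paste0("b", 1:5)),
    list(shared = fp(c(1:8, 201:208)))
  )
  lib <- toy_library(list(A = c(paste0("a", 1:5), "shared"),
                          B = c(paste0("b", 1:5), "shared")), fps)
  cv <- cross_validate(lib, folds = 11, config = fusion_config("max"),
                       seed = 3)
  pq <- cv$per_query
  expect_equal(pq$m[pq$query_id == "shared"], 2L)
  expect_setequal(cv$truths[["shared"]], c("A", "B"))
})

test_that("subsampling at fraction 1 equals the plain hold-out evaluation", {
  set.seed(77)
  r <- random_toy_library(n_targets = 6, max_ligands = 12)
  res <- subsample_experiment(r$library, fractions = 1,
                              queries_per_target = 2, repeats = 2,
                              config = fusion_config("knn", 3), seed = 6)
  expect_equal(nrow(res$table), 1L)
  # recompute replicate 1 by hand with the same seed stream
  set.seed(6 + 1000)
  test_ids <- unique(unlist(lapply(r$library$targets, function(ids) {
    take <- min(2, length(ids) - 1L)
    sample(ids, take)
  }), use.names = FALSE))
  pool <- setdiff(names(r$library$fingerprints), test_ids)
  sets <- lapply(r$library$targets, function(ids) ids[ids %in% pool])
  sub <- reference_library(sets[lengths(sets) > 0],
                           r$library$fingerprints,
                           fp_params = r$library$fp_params)
  mm <- membership_map(r$library)
  prp <- vapply(test_ids, function(qid) {
    uninterpolated_precision(
      fish_targets(r$library$fingerprints[[qid]], sub,
                   fusion_config("knn", 3)),
      mm[[qid]])
  }, numeric(1))
  expect_equal(res$replicates$prprime[1], mean(prp))
  # determinism of the full table
  res2 <- subsample_experiment(r$library, fractions = 1,
                               queries_per_target = 2, repeats = 2,
                               config = fusion_config("knn", 3), seed = 6)
  expect_identical(res$table, res2$table)
})

test_that("nearest-neighbour bins partition queries as assigned", {
  pq <- data.frame(query_id = c("q1", "q2"), prprime = c(0.2, 0.8),
                   nn_similarity = c(0.3, 0.7))
  tab <- nn_similarity_binning(pq, bin_edges = c(0, 0.5, 1))
  expect_equal(tab$n_queries, c(1L, 1L))
  expect_equal(tab$prprime_mean, c(0.2, 0.8))
  one <- nn_similarity_binning(pq, bin_edges = c(0, 1))
  expect_equal(one$prprime_mean, 0.5)
  empty <- nn_similarity_binning(pq, bin_edges = c(0, 0.1, 0.5, 1))
  expect_true(is.na(empty$prprime_mean[1]))
  expect_equal(empty$n_queries[1], 0L)
})

test_that("target-size bins are equal-count, size-sorted, and hand-averaged", {
  fps <- list(); sets <- list()
  sizes <- c(T1 = 3, T2 = 4, T3 = 5, T4 = 6)
  li <- 0
  for (t in names(sizes)) {
    ids <- character(sizes[t])
    for (l in seq_len(sizes[t])) {
      li <- li + 1
      ids[l] <- sprintf("L%02d", li)
      fps[[ids[l]]] <- fp(match(t, names(sizes)) * 30 + 1:10)
    }
    sets[[t]] <- ids
  }
  lib <- toy_library(sets, fps)
  cv <- cross_validate(lib, folds = 2, seed = 1)
  tab <- target_size_binning(lib, cv, n_bins = 2)
  expect_equal(tab$n_targets, c(2L, 2L))
  expect_equal(tab$size_max, c(4L, 6L))
  # bin mean equals the mean of per-target means computed directly
  prp <- setNames(cv$per_query$prprime, cv$per_query$query_id)
  t_mean <- vapply(names(sizes), function(t)
    mean(prp[sets[[t]]]), numeric(1))
  expect_equal(tab$prprime_mean, c(mean(t_mean[c("T1", "T2")]),
                                   mean(t_mean[c("T3", "T4")])))
  expect_error(target_size_binning(lib, cv, n_bins = 10), "fewer targets")
})
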