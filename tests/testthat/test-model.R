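make_trained <- function(seed = 5, n_trees = 60, ds = NULL) {
  ds <- ds %||% simulate_dataset(sim_config(n_proteins = 12, seed = 99))
  pssm <- build_pssm_from_dataset(ds)
  feats <- assemble_features(ds, pssm = pssm)
  list(ds = ds, feats = feats,
       ranker = train_ranker(ds, forest_config(n_trees = n_trees,
                                               seed = seed),
                             features = feats, pssm = pssm))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("training matrix pairs positives with same-protein negatives", {
  ds <- make_manual_dataset()
  pssm <- build_pssm_from_dataset(ds)
  feats <- assemble_features(ds, pssm = pssm)
  tm <- build_training_matrix(feats, ds$labels, seed = 1)
  expect_equal(length(tm$y), nrow(feats))
  expect_equal(sum(tm$y == "docking"), 2L)

  no_pos <- ds$labels; no_pos$label <- 0L
  expect_error(build_training_matrix(feats, no_pos, seed = 1),
               "no positive class")

  # downsampling caps negatives per positive, seeded
  big <- simulate_dataset(sim_config(n_proteins = 10, seed = 3))
  pssm_b <- build_pssm_from_dataset(big)
  feats_b <- assemble_features(big, pssm = pssm_b)
  tm1 <- build_training_matrix(feats_b, big$labels, seed = 2,
                               class_balance = "downsample",
                               downsample_ratio = 5)
  n_pos <- sum(tm1$y == "docking")
  expect_lte(sum(tm1$y == "other"), 5L * n_pos)
  tm2 <- build_training_matrix(feats_b, big$labels, seed = 2,
                               class_balance = "downsample",
                               downsample_ratio = 5)
  expect_identical(tm1$info, tm2$info)
})

test_that("training is deterministic under the seed", {
  a <- make_trained(seed = 5)
  b <- make_trained(seed = 5)
  pa <- predict_ranks(a$ranker, a$feats)
  pb <- predict_ranks(b$ranker, b$feats)
  expect_identical(pa$total_score, pb$total_score)
  expect_identical(pa$ptmdis_score, pb$ptmdis_score)
  expect_identical(pa$seq_score, pb$seq_score)
})

test_that("separable PTM signal separates held-out classes", {
  ds <- make_separable_dataset(n_proteins = 10, seed = 7)
  hold <- make_separable_dataset(n_proteins = 2, seed = 8)
  hold$proteins$protein_id <- sub("SEP", "HLD", hold$proteins$protein_id)
  hold$observations$sites$protein_id <-
    sub("SEP", "HLD", hold$observations$sites$protein_id)
  hold$observations <- observation_table(hold$observations$sites)
  hold$labels$protein_id <- sub("SEP", "HLD", hold$labels$protein_id)
  pssm <- build_pssm_from_dataset(ds)
  ranker <- train_ranker(ds, forest_config(n_trees = 100, seed = 2),
                         features = assemble_features(ds, pssm = pssm),
                         pssm = pssm)
  hold_feats <- assemble_features(
    dock_dataset(hold$proteins, hold$observations, hold$labels),
    pssm = pssm)
  pred <- suppressWarnings(predict_ranks(ranker, hold_feats))
  key <- paste(pred$protein_id, pred$position)
  pos_key <- paste(hold$labels$protein_id, hold$labels$position)
  is_pos <- key %in% pos_key
  expect_gt(min(pred$total_score[is_pos]), max(pred$total_score[!is_pos]))
  expect_gt(min(pred$ptmdis_score[is_pos]),
            max(pred$ptmdis_score[!is_pos]))
})

test_that("each ensemble only sees its own feature subset", {
  tr <- make_trained()
  feats <- tr$feats
  base <- predict_ranks(tr$ranker, feats)
  # sequence ensemble is blind to the PTM score
  perm <- feats
  set.seed(1); perm$ptm_score <- sample(perm$ptm_score)
  perm$disorder <- sample(perm$disorder)
  shuffled <- predict_ranks(tr$ranker, perm)
  expect_identical(shuffled$seq_score, base$seq_score)
  # and the PTM+disorder ensemble is blind to the sequence scores
  perm2 <- feats
  set.seed(2)
  for (col in c("ann", "svm", "pssm")) perm2[[col]] <- sample(perm2[[col]])
  shuffled2 <- predict_ranks(tr$ranker, perm2)
  expect_identical(shuffled2$ptmdis_score, base$ptmdis_score)
})

test_that("ranks sort scores with the documented tie rule", {
  feats <- data.frame(protein_id = "P", position = c(10L, 20L, 30L),
                      residue = "S", n_obs = c(1L, 1L, 1L),
                      ptm_score = c(0.3, 0.3, 0.4), disorder = 0.5,
                      ann = c(0.9, 0.2, 0.5), svm = c(0.9, 0.2, 0.5),
                      pssm = c(0.9, 0.2, 0.5))
  ac <- adapted_consensus(feats$ann, feats$svm, feats$pssm,
                          position = feats$position)
  expect_equal(ac$score, c(0.9, 0.2, 0.5))
  expect_equal(ac$rank, c(1L, 3L, 2L))
  expect_equal(adapted_consensus(0.2, 0.4, 0.6)$score, 0.4)
  expect_equal(adapted_consensus(0.7, 0.7, 0.7)$score, 0.7)

  # PTM-aware columns: equal scores resolved by higher PTM, then position
  expect_equal(dock1433:::rank_scores(c(0.5, 0.5), c(0.1, 0.3), c(1L, 2L)),
               c(2L, 1L))
  expect_equal(dock1433:::rank_scores(c(0.5, 0.5), c(0.2, 0.2), c(9L, 4L)),
               c(2L, 1L))
  # sequence-derived columns: ties by position only, blind to PTM
  tie <- adapted_consensus(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5),
                           position = c(7L, 3L))
  expect_equal(tie$rank, c(2L, 1L))
})

test_that("rank columns are permutations within each protein", {
  tr <- make_trained()
  pred <- predict_ranks(tr$ranker, tr$feats)
  for (pid in unique(pred$protein_id)) {
    sub <- pred[pred$protein_id == pid, ]
    for (col in c("total_rank", "ptmdis_rank", "seq_rank", "adapted_rank")) {
      expect_setequal(sub[[col]], seq_len(nrow(sub)))
    }
  }
  expect_true(all(pred$total_score >= 0 & pred$total_score <= 1))

  # a single-candidate protein gets rank 1 in all four columns
  one <- tr$feats[tr$feats$protein_id == tr$feats$protein_id[1], ][1, ]
  p1 <- predict_ranks(tr$ranker, one)
  expect_equal(unlist(p1[c("total_rank", "ptmdis_rank", "seq_rank",
                           "adapted_rank")], use.names = FALSE),
               rep(1L, 4))
})

test_that("importances are non-negative with the right arity", {
  tr <- make_trained()
  imp <- feature_importance(tr$ranker)
  expect_named(imp, c("total", "ptm_disorder", "sequence"))
  expect_length(imp$total, 5L)
  expect_length(imp$ptm_disorder, 2L)
  expect_length(imp$sequence, 3L)
  expect_true(all(unlist(imp) >= 0))
})

test_that("save/load round-trips predictions bit-exactly", {
  tr <- make_trained()
  path <- tempfile(fileext = ".rds")
  save_ranker(tr$ranker, path)
  back <- load_ranker(path)
  expect_identical(predict_ranks(back, tr$feats)$total_score,
                   predict_ranks(tr$ranker, tr$feats)$total_score)

  # corrupted file
  writeLines("not a model", path)
  expect_error(load_ranker(path), "corrupted")

  # version mismatch
  saveRDS(list(format_version = "0.0", ranker = NULL), path)
  expect_error(load_ranker(path), "version mismatch")
})

test_that("scoring against a different observation table warns", {
  tr <- make_trained()
  other <- simulate_dataset(sim_config(n_proteins = 12, seed = 100))
  other_feats <- assemble_features(other,
                                   pssm = build_pssm_from_dataset(other))
  expect_warning(predict_ranks(tr$ranker, other_feats),
                 "different observation table")
})

test_that("degenerate single-class data is rejected", {
  ds <- make_manual_dataset()
  pssm <- build_pssm_from_dataset(ds)
  feats <- assemble_features(ds, pssm = pssm)
  all_pos <- feats[paste(feats$protein_id, feats$position) %in%
                   paste(ds$labels$protein_id, ds$labels$position), ]
  ds2 <- ds
  expect_error(
    suppressWarnings(
      train_ranker(ds2, forest_config(n_trees = 10, seed = 1),
                   features = all_pos, pssm = pssm)),
    "one class|no positive")
  # and a positive-only protein is a warning, not an error
  expect_warning(
    build_training_matrix(all_pos[1, , drop = FALSE],
                          ds$labels[1, , drop = FALSE], seed = 1),
    "no negative candidates")
})
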