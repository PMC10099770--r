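test_that("PTM score follows the observation-frequency equation", {
  expect_equal(as.numeric(compute_ptm_score(5, 20)), 0.25)
  expect_equal(as.numeric(compute_ptm_score(7, 7)), 1.0)
  s <- compute_ptm_score(0, 20)
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "missing"))
  s0 <- compute_ptm_score(0, 0)   # protein never observed at all
  expect_equal(as.numeric(s0), 0)
  expect_true(attr(s0, "missing"))
})

test_that("per-protein PTM scores sum to 1 and respond monotonically", {
  ds <- simulate_dataset(sim_config(n_proteins = 15, seed = 21))
  feats <- assemble_features(ds, pssm = build_pssm_from_dataset(ds))
  observed <- feats[feats$n_obs > 0, ]
  sums <- tapply(observed$ptm_score, observed$protein_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # raising one site's count raises its score and weakly lowers the others
  tot <- 20; n <- c(5, 10, 5)
  before <- n / tot
  n2 <- c(8, 10, 5)
  after <- n2 / sum(n2)
  expect_gt(after[1], before[1])
  expect_true(all(after[-1] <= before[-1]))
})

test_that("window extraction uses sentinels at boundaries and X", {
  w <- extract_window("MRSXSP", 5, c(-3, 2))
  expect_equal(unname(w), c("R", "-"))          # +2 runs off the end
  w2 <- extract_window("MRSASPAA", 5, c(-2, -1, 1, 2))
  expect_equal(unname(w2), c("S", "A", "P", "A"))
  # offset 0 is never part of a window
  expect_error(extract_window("MRSASP", 5, c(-1, 0, 1)))
  # X masked as sentinel
  expect_equal(unname(extract_window("MXSASP", 3, c(-1, 1))), c("-", "A"))
})

test_that("PSSM cells match a brute-force log-odds computation", {
  # reduced 4-letter alphabet, hand-specified background
  bg <- c(A = 0.4, R = 0.3, S = 0.2, P = 0.1)
  offsets <- c(-1L, 1L)
  windows <- rbind(c("R", "P"), c("R", "A"), c("S", "P"))
  pc <- 1
  model <- build_pssm(windows, background = bg, pseudocount = pc,
                      offsets = offsets)
  # independent brute force over the counting formula
  for (j in seq_along(offsets)) {
    for (a in names(bg)) {
      cnt <- sum(windows[, j] == a)
      expected <- log2(((cnt + pc * bg[[a]]) / (nrow(windows) + pc)) /
                       bg[[a]])
      expect_equal(model$cells[j, a], expected, tolerance = 1e-12)
    }
  }
  # letter absent from positives is finite and negative
  expect_true(is.finite(model$cells[1, "P"]) && model$cells[1, "P"] < 0)
})

test_that("conserved-column limit gives log2(1/background)", {
  bg <- c(A = 0.25, R = 0.25, S = 0.25, P = 0.25)
  windows <- rbind(c("R", "A"), c("R", "S"), c("R", "P"), c("R", "A"))
  model <- build_pssm(windows, background = bg, pseudocount = 1e-9,
                      offsets = c(-3L, 1L))
  expect_equal(model$cells[1, "R"], log2(1 / 0.25), tolerance = 1e-6)
})

test_that("PSSM scoring is additive and zero for truncated windows", {
  set.seed(31)
  offsets <- setdiff(-5:4, 0L)
  windows <- t(replicate(8, sample(AAS, length(offsets), replace = TRUE)))
  model <- build_pssm(windows, offsets = offsets)
  for (i in 1:100) {
    s <- random_sequence(40)
    pos <- sample(6:34, 1)
    brute <- 0
    w <- extract_window(s, pos, offsets)
    for (j in seq_along(offsets)) {
      if (w[j] != "-") brute <- brute + model$cells[j, w[j]]
    }
    expect_equal(score_pssm(model, s, pos), brute, tolerance = 1e-12)
  }
  # single terminal residue: every offset out of range
  expect_equal(score_pssm(model, "S", 1), 0)
  # vectorized scorer agrees with the scalar one
  cand <- data.frame(protein_id = "P", position = 6:30)
  seqs <- data.frame(protein_id = "P", sequence = random_sequence(40))
  W <- dock1433:::candidate_windows(seqs, cand, offsets)
  expect_equal(score_pssm_windows(model, W),
               vapply(6:30, function(p) score_pssm(model, seqs$sequence, p),
                      numeric(1)))
})

test_that("PSSM score ignores sequence outside the window", {
  set.seed(32)
  offsets <- setdiff(-5:4, 0L)
  model <- build_pssm(
    t(replicate(5, sample(AAS, length(offsets), replace = TRUE))),
    offsets = offsets)
  core <- random_sequence(30)
  s1 <- paste0(random_sequence(10), core, random_sequence(10))
  s2 <- paste0(random_sequence(25), core, random_sequence(3))
  expect_equal(score_pssm(model, s1, 10 + 15), score_pssm(model, s2, 25 + 15))
})

test_that("built-in disorder hits the charged and hydrophobic limits", {
  poly_e <- strrep("E", 60)
  poly_i <- strrep("I", 60)
  expect_gt(builtin_disorder(poly_e)[30], 0.5)
  expect_lt(builtin_disorder(poly_i)[30], 0.5)
})

test_that("built-in disorder reproduces the closed form at each residue", {
  kd <- dock1433:::KD_HYDROPATHY
  chg <- c(K = 1, R = 1, D = -1, E = -1)
  set.seed(33)
  s <- random_sequence(80)
  letters <- strsplit(s, "")[[1L]]
  prof <- builtin_disorder(s, half_window = 25, logistic_k = 10)
  for (i in c(1, 7, 40, 77, 80)) {
    w <- max(1, i - 25):min(80, i + 25)
    mh <- mean(kd[letters[w]])
    q <- chg[letters[w]]; q[is.na(q)] <- 0
    fi <- 2.785 * (mh + 4.5) / 9 - abs(mean(q)) - 1.151
    expect_equal(prof[i], plogis(-10 * fi), tolerance = 1e-12)
  }
  # translation invariance in the interior: same local window, same score
  s2 <- paste0("AAAAA", s)
  prof2 <- builtin_disorder(s2, half_window = 10)
  prof1 <- builtin_disorder(s, half_window = 10)
  expect_equal(prof2[5 + 40], prof1[40])
})

test_that("external disorder ingestion demands complete bounded profiles", {
  proteins <- data.frame(protein_id = "P1", sequence = "MSTA")
  f <- tempfile(fileext = ".tsv")
  write_tsv(data.frame(protein_id = "P1", position = 1:4,
                       score = c(0.1, 0.9, 0.5, 0.2)), f)
  prof <- read_disorder(f, proteins)
  expect_equal(prof$P1, c(0.1, 0.9, 0.5, 0.2))

  write_tsv(data.frame(protein_id = "P1", position = c(1, 2, 4),
                       score = 0.5), f)
  expect_error(read_disorder(f, proteins), "incomplete")

  write_tsv(data.frame(protein_id = "P1", position = 1:4,
                       score = c(0.1, 1.2, 0.5, 0.2)), f)
  expect_error(read_disorder(f, proteins), "\\[0, 1\\]")
})

test_that("sequence-score ingestion round-trips and rejects duplicates", {
  f <- tempfile(fileext = ".tsv")
  write_tsv(data.frame(protein_id = "P1", position = 2L,
                       ann = 0.3, svm = 0.4, pssm = 0.5), f)
  sq <- read_sequence_scores(f)
  expect_equal(sq$ann, 0.3)

  write_tsv(data.frame(protein_id = character(), position = integer(),
                       ann = numeric(), svm = numeric(), pssm = numeric()),
            f)
  expect_equal(nrow(read_sequence_scores(f)), 0L)

  write_tsv(data.frame(protein_id = c("P1", "P1"), position = c(2L, 2L),
                       ann = 0.1, svm = 0.1, pssm = 0.1), f)
  expect_error(read_sequence_scores(f), "duplicate")
})

test_that("feature assembly fills externals, falls back and flags", {
  ds <- make_manual_dataset()
  # external scores for one site only; the rest use the built-in PSSM
  seqscores <- data.frame(protein_id = "P1", position = 7L,
                          ann = 0.3, svm = 0.4, pssm = 0.5)
  ds_ext <- dock_dataset(ds$proteins, ds$observations, ds$labels,
                         seqscores = seqscores)
  pssm <- build_pssm_from_dataset(ds_ext)
  feats <- assemble_features(ds_ext, pssm = pssm)
  ext_row <- feats$protein_id == "P1" & feats$position == 7L
  expect_equal(feats$ann[ext_row], 0.3)
  expect_false(feats$flag_builtin_seq[ext_row])
  other <- !ext_row
  expect_true(all(feats$flag_builtin_seq[other]))
  # built-in fallback replicates one PSSM-derived score into all three slots
  expect_equal(feats$ann[other], feats$svm[other])
  expect_equal(feats$svm[other], feats$pssm[other])
  # unobserved sites carry PTM score 0 with the missing flag
  expect_true(all(feats$ptm_score[feats$n_obs == 0] == 0))
  expect_true(all(feats$flag_missing_ptm[feats$n_obs == 0]))
  expect_true(all(!feats$flag_missing_ptm[feats$n_obs > 0]))
  # disorder is the per-residue profile value at the site itself
  prof <- builtin_disorder(ds$proteins$sequence[1])
  i <- which(feats$protein_id == "P1")
  expect_equal(feats$disorder[i], prof[feats$position[i]])
})
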