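# Validation machinery: leave-one-protein-out, repeated protein-level
# holdout, the non-canonical-subset analysis, and feature enrichment.

#' Evaluation configuration
#'
#' @param k_fractions Rank-percentile cutoffs for hit rates
#'   (default top 10% and top 25%).
#' @param holdout_fraction Fraction of proteins held out per repetition
#'   (default 0.20).
#' @param holdout_reps Number of holdout repetitions (default 200).
#' @param top_n_cutoff Absolute rank cutoff for the non-canonical analysis
#'   (default 15).
#' @param consensus_cutoffs Consensus-score cutoffs defining non-canonical
#'   sites (default 0.5 and 0.8).
#' @param seed Integer seed governing every random choice in a protocol run.
#' @return An `eval_config` list.
#' @export
eval_config <- function(k_fractions = c(0.10, 0.25), holdout_fraction = 0.20,
                        holdout_reps = 200, top_n_cutoff = 15,
                        consensus_cutoffs = c(0.5, 0.8), seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(all(k_fractions > 0 & k_fractions < 1),
            holdout_fraction > 0, holdout_fraction < 1,
            holdout_reps >= 1, top_n_cutoff >= 1)
  structure(list(k_fractions = k_fractions,
                 holdout_fraction = holdout_fraction,
                 holdout_reps = as.integer(holdout_reps),
                 top_n_cutoff = as.integer(top_n_cutoff),
                 consensus_cutoffs = consensus_cutoffs,
                 seed = as.integer(seed)),
            class = "eval_config")
}

#' Top-k% rank hit
#'
#' A true site is a hit when its rank is within the top `k_fraction` of the
#' protein's candidates, with a ceiling threshold: rank 1 of 5 candidates is
#' a top-10% hit because `ceiling(0.5) = 1`.
#'
#' @param rank Rank(s) of the true site (1 = best).
#' @param n_candidates Number of candidate S/T on the protein.
#' @param k_fraction Fraction in (0, 1).
#' @return Logical vector.
#' @export
topk_hit <- function(rank, n_candidates, k_fraction) {
  stopifnot(all(rank >= 1), all(rank <= n_candidates),
            k_fraction > 0, k_fraction < 1)
  rank <= ceiling(k_fraction * n_candidates)
}

RANK_COLUMNS <- c(total = "total_rank", ptmdis = "ptmdis_rank",
                  seq = "seq_rank", adapted = "adapted_rank")

# Shared precomputation for the retraining protocols. All five features are
# fixed inputs across splits: PTM and disorder are per-site values, and the
# sequence scores come either from ingested pretrained-predictor output or
# from the fixed canonical consensus PSSM — in both cases nothing about the
# held-out protein leaks into its own scores, so only the forest needs
# retraining per split (exactly the published protocol, where the external
# sequence predictors are never refit).
#' @noRd
prep_eval_context <- function(dataset, pssm = canonical_pssm()) {
  features <- assemble_features(dataset, pssm = pssm)
  pos <- dataset$labels[dataset$labels$label == 1L, , drop = FALSE]
  pos_rows <- match(paste(pos$protein_id, pos$position),
                    paste(features$protein_id, features$position))
  if (anyNA(pos_rows)) {
    stop("true docking site is not a candidate: ",
         paste(pos$protein_id[is.na(pos_rows)][1L],
               pos$position[is.na(pos_rows)][1L]), call. = FALSE)
  }
  list(dataset = dataset, features = features, pssm = pssm, pos = pos,
       pos_rows = pos_rows, digest = attr(features, "dataset_digest"))
}

# Train on a subset of proteins, rank the candidates of the evaluation
# proteins, and return one record per evaluated positive site.
#' @noRd
eval_split <- function(ctx, train_ids, test_ids, config) {
  dataset <- ctx$dataset
  features <- ctx$features
  train_lab <- dataset$labels[dataset$labels$protein_id %in% train_ids &
                              dataset$labels$label == 1L, , drop = FALSE]
  train_feats <- features[features$protein_id %in% train_ids, , drop = FALSE]
  attr(train_feats, "dataset_digest") <- ctx$digest
  obs_sites <- dataset$observations$sites
  train_ds <- dock_dataset(
    dataset$proteins[dataset$proteins$protein_id %in% train_ids, ,
                     drop = FALSE],
    observations = observation_table(
      obs_sites[obs_sites$protein_id %in% train_ids, , drop = FALSE]),
    labels = train_lab,
    disorder = dataset$disorder, seqscores = dataset$seqscores)
  ranker <- train_ranker(train_ds, config, features = train_feats,
                         pssm = ctx$pssm)
  test_feats <- features[features$protein_id %in% test_ids, , drop = FALSE]
  attr(test_feats, "dataset_digest") <- ctx$digest
  pred <- predict_ranks(ranker, test_feats)
  pos <- dataset$labels[dataset$labels$protein_id %in% test_ids &
                        dataset$labels$label == 1L, , drop = FALSE]
  if (!nrow(pos)) return(NULL)
  n_by_protein <- table(pred$protein_id)
  records <- data.frame(protein_id = pos$protein_id,
                        position = pos$position,
                        n_candidates = as.integer(
                          n_by_protein[pos$protein_id]),
                        stringsAsFactors = FALSE)
  pk <- paste(pred$protein_id, pred$position)
  idx <- match(paste(pos$protein_id, pos$position), pk)
  if (anyNA(idx)) {
    stop("true docking site is not a candidate: ",
         paste(pos$protein_id[is.na(idx)][1L], pos$position[is.na(idx)][1L]),
         call. = FALSE)
  }
  for (col in names(RANK_COLUMNS)) {
    records[[RANK_COLUMNS[col]]] <- pred[[RANK_COLUMNS[col]]][idx]
  }
  records$flag_missing_ptm <- pred$flag_missing_ptm[idx]
  records
}

# Aggregate per-site records into hit-rate tables. Site-level rates count
# every positive site; protein-level rates count a protein as hit when any
# of its positives is a hit (reported alongside for dual-site proteins).
#' @noRd
hit_table <- function(records, k_fractions) {
  rows <- list()
  for (col in names(RANK_COLUMNS)) {
    rk <- records[[RANK_COLUMNS[col]]]
    for (k in k_fractions) {
      hit <- topk_hit(rk, records$n_candidates, k)
      by_prot <- tapply(hit, records$protein_id, any)
      rows[[length(rows) + 1L]] <- data.frame(
        column = col, k_fraction = k,
        hits = sum(hit), n = length(hit),
        hit_rate = sum(hit) / length(hit),
        hits_protein = sum(by_prot), n_protein = length(by_prot),
        hit_rate_protein = mean(by_prot),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @noRd
make_report <- function(protocol, records, config, eval_cfg) {
  structure(list(protocol = protocol,
                 records = records,
                 hit_rates = hit_table(records, eval_cfg$k_fractions),
                 forest_config = config, eval_config = eval_cfg),
            class = "dock_eval_report")
}

#' @export
print.dock_eval_report <- function(x, ...) {
  cat("Evaluation protocol:", x$protocol, "(", nrow(x$records),
      "evaluated sites )\n")
  print(x$hit_rates[c("column", "k_fraction", "hits", "n", "hit_rate")],
        row.names = FALSE)
  invisible(x)
}

#' Leave-one-protein-out cross-validation
#'
#' For each client protein carrying a validated docking site: remove it,
#' retrain the ranker on the remaining proteins, rank the removed protein's
#' candidate S/T residues, and record the rank of its true site(s) in all
#' four output columns. Hit rates are aggregated per top-k% threshold, both
#' per site and per protein (for dual-site clients).
#'
#' @param dataset A `dock_dataset` with labels.
#' @param forest_cfg A [forest_config()].
#' @param eval_cfg An [eval_config()].
#' @param context Optional precomputed evaluation context (internal reuse).
#' @return A `dock_eval_report`.
#' @export
evaluate_loo <- function(dataset, forest_cfg, eval_cfg, context = NULL) {
  stopifnot(inherits(dataset, "dock_dataset"))
  ctx <- context %||% prep_eval_context(dataset)
  client_ids <- unique(dataset$labels$protein_id[dataset$labels$label == 1L])
  if (length(client_ids) < 2L) {
    stop("leave-one-out needs at least two client proteins", call. = FALSE)
  }
  seeds <- derive_seeds(eval_cfg$seed, length(client_ids))
  records <- list()
  for (i in seq_along(client_ids)) {
    cfg_i <- forest_cfg
    cfg_i$seed <- seeds[i]
    records[[i]] <- eval_split(ctx,
                               train_ids = setdiff(
                                 dataset$proteins$protein_id, client_ids[i]),
                               test_ids = client_ids[i], cfg_i)
  }
  make_report("loo", do.call(rbind, records), forest_cfg, eval_cfg)
}

#' Repeated holdout validation
#'
#' Each repetition holds out a fraction of the client proteins (split at the
#' protein level, so no protein contributes sites to both sides), trains on
#' the rest, and evaluates the held-out positives; hit rates aggregate over
#' all repetitions.
#'
#' @inheritParams evaluate_loo
#' @return A `dock_eval_report` with a `rep` column in its records.
#' @export
evaluate_holdout <- function(dataset, forest_cfg, eval_cfg, context = NULL) {
  stopifnot(inherits(dataset, "dock_dataset"))
  ctx <- context %||% prep_eval_context(dataset)
  client_ids <- unique(dataset$labels$protein_id[dataset$labels$label == 1L])
  n_test <- max(1L, round(eval_cfg$holdout_fraction * length(client_ids)))
  if (n_test >= length(client_ids)) {
    stop("holdout fraction leaves no proteins to train on", call. = FALSE)
  }
  seeds <- derive_seeds(eval_cfg$seed, 2L * eval_cfg$holdout_reps)
  records <- list()
  for (r in seq_len(eval_cfg$holdout_reps)) {
    set.seed(seeds[2L * r - 1L])
    test_ids <- sample(client_ids, n_test)
    cfg_r <- forest_cfg
    cfg_r$seed <- seeds[2L * r]
    rec <- eval_split(ctx,
                      train_ids = setdiff(dataset$proteins$protein_id,
                                          test_ids),
                      test_ids = test_ids, cfg_r)
    if (!is.null(rec)) {
      rec$rep <- r
      records[[length(records) + 1L]] <- rec
    }
  }
  make_report("holdout", do.call(rbind, records), forest_cfg, eval_cfg)
}

#' Select the non-canonical docking sites
#'
#' Validated docking sites whose consensus-sequence score — the adapted
#' average of ANN, SVM and PSSM — falls below the cutoff, i.e. sites that
#' classical consensus matching scores poorly.
#'
#' @param dataset A `dock_dataset` with labels.
#' @param features Feature data frame covering all positives.
#' @param cutoff Consensus-score cutoff (conventionally 0.5; 0.8 gives a
#'   less stringent superset).
#' @return Subset of the positive labeled sites, with an
#'   `adapted_score` column appended.
#' @export
noncanonical_subset <- function(dataset, features, cutoff = 0.5) {
  pos <- dataset$labels[dataset$labels$label == 1L, , drop = FALSE]
  idx <- match(paste(pos$protein_id, pos$position),
               paste(features$protein_id, features$position))
  if (anyNA(idx)) {
    stop("positive site missing from features", call. = FALSE)
  }
  pos$adapted_score <- (features$ann[idx] + features$svm[idx] +
                        features$pssm[idx]) / 3
  pos[pos$adapted_score < cutoff, , drop = FALSE]
}

#' Evaluate recovery of non-canonical docking sites
#'
#' Leave-one-out restricted to the non-canonical subset: each subset site's
#' protein is removed from training, the ranker retrained, and the site
#' predicted de novo. The hit criterion is an absolute rank cutoff (default
#' top 15) rather than a percentile. Hit rates are also stratified by
#' whether the site lacks a PTM score (never observed by MS).
#'
#' @param dataset A `dock_dataset` with labels.
#' @param subset Output of [noncanonical_subset()].
#' @param forest_cfg A [forest_config()].
#' @param eval_cfg An [eval_config()]; `top_n_cutoff` sets the criterion.
#' @param context Optional precomputed evaluation context (internal reuse).
#' @return A `dock_eval_report` (protocol `"noncanonical"`) whose
#'   `top_n_hits` element tabulates hits per column, overall and by
#'   missing-PTM stratum.
#' @export
evaluate_noncanonical <- function(dataset, subset, forest_cfg, eval_cfg,
                                  context = NULL) {
  if (!nrow(subset)) stop("non-canonical subset is empty", call. = FALSE)
  ctx <- context %||% prep_eval_context(dataset)
  seeds <- derive_seeds(eval_cfg$seed, nrow(subset))
  records <- list()
  for (i in seq_len(nrow(subset))) {
    cfg_i <- forest_cfg
    cfg_i$seed <- seeds[i]
    rec <- eval_split(ctx,
                      train_ids = setdiff(dataset$proteins$protein_id,
                                          subset$protein_id[i]),
                      test_ids = subset$protein_id[i], cfg_i)
    # keep only the subset site itself (the protein may have other positives)
    rec <- rec[rec$position == subset$position[i], , drop = FALSE]
    records[[i]] <- rec
  }
  records <- do.call(rbind, records)
  report <- make_report("noncanonical", records, forest_cfg, eval_cfg)
  cut <- eval_cfg$top_n_cutoff
  strata <- list(all = rep(TRUE, nrow(records)),
                 with_ptm = !records$flag_missing_ptm,
                 missing_ptm = records$flag_missing_ptm)
  tabs <- list()
  for (s in names(strata)) {
    sel <- strata[[s]]
    for (col in names(RANK_COLUMNS)) {
      rk <- records[[RANK_COLUMNS[col]]][sel]
      tabs[[length(tabs) + 1L]] <- data.frame(
        stratum = s, column = col, cutoff = cut,
        hits = sum(rk <= cut), n = length(rk),
        hit_rate = if (length(rk)) sum(rk <= cut) / length(rk) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  report$top_n_hits <- do.call(rbind, tabs)
  report
}

#' Relative mean difference between two groups, as a percentage
#'
#' `|(mean_a - mean_ref) / mean_ref| * 100`: how far group A's mean sits
#' from the reference group's mean, relative to the reference.
#'
#' @param mean_a Mean of the comparison group.
#' @param mean_ref Mean of the reference group (must be nonzero).
#' @return Percentage (non-negative).
#' @export
relative_mean_difference <- function(mean_a, mean_ref) {
  if (any(mean_ref == 0)) {
    stop("reference mean must be nonzero", call. = FALSE)
  }
  abs((mean_a - mean_ref) / mean_ref) * 100
}

#' Feature enrichment at validated docking sites
#'
#' Compares model features between validated docking-site phosphorylations
#' and all other candidate sites with Welch's unequal-variance t test
#' (two-sided), and reports the relative mean difference as a percentage of
#' the docking-group mean. The default feature set is the two continuous
#' protein-level features (PTM observation-frequency score and disorder);
#' the consensus-sequence scores can be added but are strongly bimodal, and
#' t-based p-values on them should be treated as descriptive.
#'
#' @param dataset A `dock_dataset` with labels.
#' @param features Feature data frame from [assemble_features()].
#' @param feature_names Which feature columns to test.
#' @param alpha Significance threshold for the flag column (default 0.001).
#' @return Data frame with columns `feature`, `mean_docking`, `mean_other`,
#'   `t`, `p`, `rel_diff_pct`, `significant`, `degenerate`.
#' @export
welch_enrichment <- function(dataset, features,
                             feature_names = c("ptm_score", "disorder"),
                             alpha = 0.001) {
  pos_key <- paste(dataset$labels$protein_id[dataset$labels$label == 1L],
                   dataset$labels$position[dataset$labels$label == 1L])
  is_dock <- paste(features$protein_id, features$position) %in% pos_key
  if (sum(is_dock) < 2L || sum(!is_dock) < 2L) {
    stop("need at least two sites per group", call. = FALSE)
  }
  rows <- lapply(feature_names, function(f) {
    a <- features[[f]][is_dock]
    b <- features[[f]][!is_dock]
    degenerate <- stats::var(a) == 0 && stats::var(b) == 0
    if (degenerate) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
    }
    rel <- if (mean(a) == 0) NA_real_ else
      relative_mean_difference(mean(b), mean(a))
    data.frame(feature = f, mean_docking = mean(a), mean_other = mean(b),
               t = unname(tt$statistic), p = tt$p.value,
               rel_diff_pct = rel,
               significant = is.finite(tt$p.value) && tt$p.value < alpha,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
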