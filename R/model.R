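# The random-forest ranker: three ensembles over feature subsets, four
# ranked output columns per protein, Gini importances, persistence.
# The ranger import is load-bearing: it guarantees ranger's S3 predict
# method is registered even when a saved ranker is the first ranger object
# the session sees.
#' @importFrom ranger ranger
NULL

RANKER_FORMAT_VERSION <- "1.0"

FEATURE_SETS <- list(
  total = c("ann", "svm", "pssm", "disorder", "ptm_score"),
  ptm_disorder = c("ptm_score", "disorder"),
  sequence = c("ann", "svm", "pssm"))

#' Random-forest configuration
#'
#' @param n_trees Number of trees per ensemble (default 500, several hundred
#'   being the conventional forest size for this problem scale).
#' @param mtry Features tried per split; `NULL` uses the library default
#'   (floor of the square root of the feature count).
#' @param min_leaf Minimum terminal-node size (default 1).
#' @param class_balance `"weight"` (inverse-frequency class weights, the
#'   default) or `"downsample"` (cap negatives per positive).
#' @param downsample_ratio Max negatives per positive when downsampling.
#' @param seed Integer seed; mandatory, every training run is reproducible.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 500, mtry = NULL, min_leaf = 1,
                          class_balance = c("weight", "downsample"),
                          downsample_ratio = 5, seed) {
  if (missing(seed)) stop("a seed is mandatory for training", call. = FALSE)
  stopifnot(n_trees >= 1, min_leaf >= 1, downsample_ratio >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_leaf = as.integer(min_leaf),
                 class_balance = match.arg(class_balance),
                 downsample_ratio = downsample_ratio,
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Build the training matrix from a labeled dataset
#'
#' Positives are the validated docking-site phosphorylations; negatives are
#' every other candidate Ser/Thr on the same client proteins (not random
#' proteome background). Rows are shuffled under the seed.
#'
#' @param features Feature data frame from [assemble_features()].
#' @param labels Labeled-site data frame (`label` 1 = docking).
#' @param seed Integer seed for the row shuffle.
#' @param class_balance,downsample_ratio See [forest_config()].
#' @return List with `x` (feature matrix columns only), `y` (factor
#'   `"other"`/`"docking"`), and `info` (identification columns).
#' @export
build_training_matrix <- function(features, labels, seed,
                                  class_balance = "weight",
                                  downsample_ratio = 5) {
  key <- paste(features$protein_id, features$position)
  pos <- labels[labels$label == 1L, , drop = FALSE]
  if (!nrow(pos)) stop("no positive class in labels", call. = FALSE)
  pos_key <- paste(pos$protein_id, pos$position)
  unresolved <- setdiff(pos_key, key)
  if (length(unresolved)) {
    stop("labeled positive not among candidates: ", unresolved[1L],
         call. = FALSE)
  }
  y <- ifelse(key %in% pos_key, "docking", "other")
  keep <- seq_along(y)
  set.seed(seed)
  if (class_balance == "downsample") {
    neg_idx <- which(y == "other")
    cap <- downsample_ratio * sum(y == "docking")
    if (length(neg_idx) > cap) {
      drop_idx <- sample(neg_idx, length(neg_idx) - cap)
      keep <- setdiff(keep, drop_idx)
    }
  }
  n_neg_by_protein <- table(features$protein_id[y == "other"])
  lonely <- setdiff(unique(pos$protein_id), names(n_neg_by_protein))
  if (length(lonely)) {
    warning("protein(s) with a docking site but no negative candidates: ",
            paste(lonely, collapse = ", "), call. = FALSE)
  }
  keep <- sample(keep)   # seeded shuffle
  list(x = features[keep, FEATURE_SETS$total, drop = FALSE],
       y = factor(y[keep], levels = c("other", "docking")),
       info = features[keep, c("protein_id", "position", "residue"),
                       drop = FALSE])
}

#' Train the three-ensemble ranker
#'
#' Fits one probability forest per feature subset: all five inputs
#' (`total`), PTM score plus disorder (`ptm_disorder`), and the three
#' consensus-sequence scores (`sequence`). Identical seed and data give
#' identical predictions. The PSSM used for built-in sequence scores is
#' stored alongside so prediction on new proteins reuses it.
#'
#' @param dataset A `dock_dataset` with labels.
#' @param config A [forest_config()].
#' @param features Optional precomputed [assemble_features()] output.
#' @param pssm `pssm_model` used for built-in sequence scores; defaults to
#'   the fixed [canonical_pssm()]. Pass a [build_pssm_from_dataset()] matrix
#'   to use a corpus-estimated model instead.
#' @return An object of class `dock_ranker`.
#' @export
train_ranker <- function(dataset, config, features = NULL,
                         pssm = canonical_pssm()) {
  stopifnot(inherits(dataset, "dock_dataset"),
            inherits(config, "forest_config"))
  if (is.null(features)) features <- assemble_features(dataset, pssm = pssm)
  tm <- build_training_matrix(features, dataset$labels, config$seed,
                              config$class_balance, config$downsample_ratio)
  if (nlevels(droplevels(tm$y)) < 2L) {
    stop("degenerate training data: only one class present", call. = FALSE)
  }
  weights <- NULL
  if (config$class_balance == "weight") {
    tab <- table(tm$y)
    weights <- as.numeric(sum(tab) / (2 * tab))   # inverse frequency
    names(weights) <- names(tab)
  }
  seeds <- derive_seeds(config$seed, length(FEATURE_SETS))
  forests <- list()
  for (i in seq_along(FEATURE_SETS)) {
    nm <- names(FEATURE_SETS)[i]
    cols <- FEATURE_SETS[[nm]]
    dat <- cbind(tm$x[cols], .label = tm$y)
    forests[[nm]] <- ranger::ranger(
      dependent.variable.name = ".label", data = dat,
      num.trees = config$n_trees,
      mtry = config$mtry %||% max(1L, floor(sqrt(length(cols)))),
      min.node.size = config$min_leaf,
      probability = TRUE, importance = "impurity",
      class.weights = weights, seed = seeds[i], num.threads = 1L,
      verbose = FALSE)
  }
  structure(list(forests = forests, feature_sets = FEATURE_SETS,
                 config = config, pssm = pssm,
                 metadata = list(
                   format_version = RANKER_FORMAT_VERSION,
                   seed = config$seed,
                   dataset_digest = attr(features, "dataset_digest"),
                   n_train = length(tm$y),
                   n_positive = sum(tm$y == "docking"),
                   trained = TRUE)),
            class = "dock_ranker")
}

#' @export
print.dock_ranker <- function(x, ...) {
  cat("14-3-3 docking-site ranker:", x$config$n_trees,
      "trees per ensemble;", x$metadata$n_positive, "docking sites among",
      x$metadata$n_train, "training sites\n")
  invisible(x)
}

# Probability of the docking class from one ensemble.
#' @noRd
forest_prob <- function(forest, features) {
  p <- stats::predict(forest, data = features, num.threads = 1L)$predictions
  unname(p[, "docking"])
}

# Competition-free deterministic ranking: score descending, ties broken by
# higher PTM score (only for columns whose ensemble uses the PTM channel)
# then lower position. Sequence-derived columns must never read the PTM
# channel, not even through tie-breaks, or feature-subset independence is
# silently violated.
#' @noRd
rank_scores <- function(score, ptm_score, position) {
  ord <- order(-score, -ptm_score, position)
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  rank
}

#' Adapted consensus score and rank
#'
#' The adapted column averages the three consensus-sequence scores (ANN,
#' SVM, PSSM) per site and turns them into a rank-order list, mirroring how
#' cutoff-style consensus output is adapted for comparison against the
#' forest columns. Ties break toward the lower position only — the adapted
#' column is a pure sequence baseline and never consults the PTM channel.
#'
#' @param ann,svm,pssm Numeric score vectors (one protein's sites).
#' @param position Tie-break key (default input order).
#' @return List with `score` and `rank` vectors.
#' @export
adapted_consensus <- function(ann, svm, pssm, position = NULL) {
  score <- (ann + svm + pssm) / 3
  n <- length(score)
  rank <- rank_scores(score, rep(0, n), position %||% seq_len(n))
  list(score = score, rank = rank)
}

#' Rank a protein's candidate sites
#'
#' Produces the four output columns per candidate: `total` (all five
#' features), `ptmdis` (PTM score + disorder), `seq` (the three sequence
#' scores), each a forest probability for the docking class, plus the
#' `adapted` consensus average. Within each protein each column's sites are
#' ranked 1..n (1 = most likely docking site). Ties in the `total` and
#' `ptmdis` columns break toward the higher PTM score, then the lower
#' position; ties in the sequence-derived `seq` and `adapted` columns break
#' by position only, so those columns never read the PTM channel.
#'
#' @param ranker A trained `dock_ranker`.
#' @param features Feature data frame from [assemble_features()] (one or
#'   more proteins).
#' @return Data frame of ranked predictions with the standard columns.
#' @export
predict_ranks <- function(ranker, features) {
  stopifnot(inherits(ranker, "dock_ranker"))
  if (!nrow(features)) {
    out <- features
    for (col in c("total_score", "ptmdis_score", "seq_score",
                  "adapted_score")) out[[col]] <- numeric(0L)
    for (col in c("total_rank", "ptmdis_rank", "seq_rank",
                  "adapted_rank")) out[[col]] <- integer(0L)
    return(out)
  }
  digest <- attr(features, "dataset_digest")
  if (!is.null(digest) && !is.null(ranker$metadata$dataset_digest) &&
      !identical(digest, ranker$metadata$dataset_digest)) {
    warning("features were built from a different observation table than ",
            "the ranker was trained on", call. = FALSE)
  }
  out <- features
  out$total_score <- forest_prob(ranker$forests$total,
                                 features[FEATURE_SETS$total])
  out$ptmdis_score <- forest_prob(ranker$forests$ptm_disorder,
                                  features[FEATURE_SETS$ptm_disorder])
  out$seq_score <- forest_prob(ranker$forests$sequence,
                               features[FEATURE_SETS$sequence])
  out$adapted_score <- (out$ann + out$svm + out$pssm) / 3
  out$total_rank <- NA_integer_
  out$ptmdis_rank <- NA_integer_
  out$seq_rank <- NA_integer_
  out$adapted_rank <- NA_integer_
  uses_ptm <- c(total = TRUE, ptmdis = TRUE, seq = FALSE, adapted = FALSE)
  for (pid in unique(out$protein_id)) {
    rows <- which(out$protein_id == pid)
    for (col in c("total", "ptmdis", "seq", "adapted")) {
      tie_ptm <- if (uses_ptm[[col]]) out$ptm_score[rows] else
        rep(0, length(rows))
      out[[paste0(col, "_rank")]][rows] <- rank_scores(
        out[[paste0(col, "_score")]][rows], tie_ptm, out$position[rows])
    }
  }
  out
}

#' Gini feature importances per ensemble
#'
#' Mean decrease in node impurity attributable to each feature, as
#' accumulated over each ensemble's trees: the larger the value, the more
#' the ensemble's splits rely on that feature.
#'
#' @param ranker A trained `dock_ranker`.
#' @return Named list (one element per ensemble) of named non-negative
#'   numeric vectors.
#' @export
feature_importance <- function(ranker) {
  stopifnot(inherits(ranker, "dock_ranker"))
  lapply(ranker$forests, function(f) f$variable.importance)
}

#' Save / load a trained ranker
#'
#' The archive embeds a metadata block (format version, seed, configuration,
#' feature names, training-dataset digest); loading verifies the version and
#' round-trips predictions bit-exactly.
#'
#' @param ranker A `dock_ranker`.
#' @param path File path.
#' @export
save_ranker <- function(ranker, path) {
  stopifnot(inherits(ranker, "dock_ranker"))
  payload <- list(format_version = RANKER_FORMAT_VERSION,
                  metadata = ranker$metadata,
                  config = unclass(ranker$config),
                  feature_sets = ranker$feature_sets,
                  ranker = ranker)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_ranker
#' @return `load_ranker` returns the restored `dock_ranker`.
#' @export
load_ranker <- function(path) {
  assert_file(path)
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop("corrupted or unreadable ",
                                               "model file: ", path,
                                               call. = FALSE))
  if (!is.list(payload) || is.null(payload$format_version)) {
    stop("corrupted or unreadable model file: ", path, call. = FALSE)
  }
  if (!identical(payload$format_version, RANKER_FORMAT_VERSION)) {
    stop("model format version mismatch: file has ",
         payload$format_version, ", expected ", RANKER_FORMAT_VERSION,
         call. = FALSE)
  }
  payload$ranker
}
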