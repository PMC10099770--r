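# The five model inputs per candidate site: PTM score, disorder, and three
# consensus-sequence scores (external 14-3-3Pred-style files, or the built-in
# PSSM replicated into all three sequence slots).

#' Normalized MS observation-frequency score (PTM score)
#'
#' The PTM score of a phosphosite is its number of independent MS-based
#' observations divided by the total number of observations of all
#' phosphorylations on the same protein. Sites never observed (and proteins
#' with no observed phosphosites at all) score 0 and are flagged as missing,
#' since an unobserved site carries no frequency information.
#'
#' @param n_obs Observation count(s) for the site(s).
#' @param total Total observation count for the protein (scalar or vector).
#' @return Numeric vector in `[0, 1]` with attribute `missing` (logical):
#'   `TRUE` where the score is 0 because no observation backs it.
#' @export
compute_ptm_score <- function(n_obs, total) {
  stopifnot(all(n_obs >= 0), all(total >= 0))
  total <- rep_len(total, length(n_obs))
  score <- ifelse(total > 0, n_obs / total, 0)
  structure(score, missing = n_obs == 0)
}

# Kyte-Doolittle hydropathy, used by the built-in disorder proxy.
KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

AA_CHARGE <- c(K = 1, R = 1, D = -1, E = -1)

#' Built-in per-residue disorder profile
#'
#' A charge/hydropathy disorder proxy used when no external predictor output
#' (e.g. an IUPred2A score table) is supplied. For each residue it computes,
#' over a clipped sliding window, the mean Kyte-Doolittle hydropathy rescaled
#' to `[0, 1]` and the absolute mean net charge, combines them with the
#' FoldIndex closed form
#' `2.785 * <H> - |<q>| - 1.151`, and maps the result through a logistic so
#' that negative fold indices (predicted unfolded) give disorder above 0.5.
#'
#' @param sequence Amino-acid sequence string.
#' @param half_window Half-width of the sliding window in residues
#'   (default 25).
#' @param logistic_k Steepness of the logistic mapping (default 10).
#' @return Numeric vector in `[0, 1]`, one score per residue.
#' @export
builtin_disorder <- function(sequence, half_window = 25, logistic_k = 10) {
  stopifnot(half_window >= 1)
  letters <- strsplit(sequence, "")[[1L]]
  n <- length(letters)
  hyd <- unname(KD_HYDROPATHY[letters])
  hyd[is.na(hyd)] <- 0          # X scored as neutral
  chg <- unname(AA_CHARGE[letters])
  chg[is.na(chg)] <- 0
  cs_h <- cumsum(c(0, hyd))
  cs_q <- cumsum(c(0, chg))
  lo <- pmax(seq_len(n) - half_window, 1L)
  hi <- pmin(seq_len(n) + half_window, n)
  w <- hi - lo + 1
  mean_h <- (cs_h[hi + 1L] - cs_h[lo]) / w
  mean_q <- (cs_q[hi + 1L] - cs_q[lo]) / w
  h01 <- (mean_h + 4.5) / 9     # rescale KD range [-4.5, 4.5] to [0, 1]
  foldindex <- 2.785 * h01 - abs(mean_q) - 1.151
  stats::plogis(-logistic_k * foldindex)
}

#' Extract the residue window around a phosphosite
#'
#' Returns the letters at `position + offset` for each offset. Positions
#' outside the sequence, and unknown `X` residues, yield the sentinel `"-"`,
#' which every scoring routine treats as background (log-odds contribution
#' zero). Offsets exclude 0, so the phosphosite letter itself is never part
#' of the window.
#'
#' @param sequence Amino-acid sequence string.
#' @param position 1-based phosphosite position.
#' @param offsets Integer offsets relative to the phosphosite.
#' @return Character vector of window letters, named by offset.
#' @export
extract_window <- function(sequence, position, offsets = default_offsets()) {
  stopifnot(position >= 1, position <= nchar(sequence), all(offsets != 0))
  letters <- strsplit(sequence, "")[[1L]]
  idx <- position + offsets
  out <- ifelse(idx >= 1 & idx <= length(letters), letters[pmax(idx, 1L)], "-")
  out[out == "X"] <- "-"
  stats::setNames(out, offsets)
}

#' Default PSSM window offsets
#'
#' Positions -5..+4 around the phosphosite (0 excluded): wide enough to cover
#' both classical 14-3-3 consensus determinants, the mode I `RXXpS/TXP`
#' (Arg at -3, Pro at +2) and the mode II `RXF/YXpSXP` (Arg at -4, aromatic
#' at -2).
#'
#' @return Integer vector of offsets.
#' @export
default_offsets <- function() setdiff(-5:4, 0L)

#' Build a position-specific scoring matrix from docking-site windows
#'
#' Log-odds with pseudocounts proportional to the background:
#' `cell(o, a) = log2( ((count(o, a) + pc * bg(a)) / (N + pc)) / bg(a) )`.
#' Sentinel (`"-"`) columns are fixed at zero so truncated windows score as
#' background.
#'
#' @param windows Character matrix (rows = sites, columns = offsets) or list
#'   of equal-length window vectors from [extract_window()].
#' @param background Named probability vector over the residue alphabet
#'   (default: uniform over the 20 amino acids). Must sum to 1 with no zero
#'   entries.
#' @param pseudocount Positive smoothing mass (default 1, i.e. one
#'   background-distributed pseudo-observation).
#' @param offsets Integer offsets labelling the columns.
#' @return An object of class `pssm_model`.
#' @export
build_pssm <- function(windows, background = NULL, pseudocount = 1,
                       offsets = default_offsets()) {
  if (is.list(windows)) windows <- do.call(rbind, windows)
  if (!is.matrix(windows) || nrow(windows) < 1L) {
    stop("need at least one positive window", call. = FALSE)
  }
  if (ncol(windows) != length(offsets)) {
    stop("window width does not match offsets", call. = FALSE)
  }
  alphabet <- names(background) %||% AA_ALPHABET
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / length(alphabet), length(alphabet)),
                                  alphabet)
  }
  if (abs(sum(background) - 1) > 1e-6) {
    stop("background frequencies must sum to 1", call. = FALSE)
  }
  if (any(background <= 0)) {
    stop("background frequencies must be positive", call. = FALSE)
  }
  stopifnot(pseudocount > 0)
  n <- nrow(windows)
  cells <- matrix(0, nrow = length(offsets), ncol = length(alphabet),
                  dimnames = list(as.character(offsets), alphabet))
  for (j in seq_along(offsets)) {
    counts <- table(factor(windows[, j], levels = alphabet))
    # sentinel letters contribute no counts; denominator still N + pc so a
    # column of pure sentinels shrinks toward (slightly below) background
    p_hat <- (as.numeric(counts) + pseudocount * background) /
      (n + pseudocount)
    cells[j, ] <- log2(p_hat / background)
  }
  if (any(!is.finite(cells))) stop("non-finite PSSM cell", call. = FALSE)
  structure(list(offsets = as.integer(offsets), cells = cells,
                 background = background, pseudocount = pseudocount,
                 n_positives = n),
            class = "pssm_model")
}

#' @export
print.pssm_model <- function(x, ...) {
  if (isTRUE(x$canonical)) {
    cat("Canonical mode I/II consensus PSSM over offsets",
        paste(range(x$offsets), collapse = ".."), "\n")
  } else {
    cat("PSSM over offsets", paste(range(x$offsets), collapse = ".."),
        "built from", x$n_positives, "docking-site windows\n")
  }
  invisible(x)
}

#' Score a candidate site against a PSSM
#'
#' The score is the sum of log-odds cells over the window offsets; sentinel
#' positions (sequence ends, `X`) contribute zero.
#'
#' @param model A `pssm_model`.
#' @param sequence Amino-acid sequence string.
#' @param position 1-based phosphosite position.
#' @return Numeric log-odds score (0 for a fully truncated window).
#' @export
score_pssm <- function(model, sequence, position) {
  stopifnot(inherits(model, "pssm_model"))
  win <- extract_window(sequence, position, model$offsets)
  total <- 0
  for (j in seq_along(win)) {
    if (win[j] != "-") total <- total + model$cells[j, win[j]]
  }
  unname(total)
}

#' Score many windows against a PSSM at once
#'
#' Vectorized form of [score_pssm()]: takes a character matrix of windows
#' (rows = sites, columns = offsets in the model's order) and returns one
#' log-odds score per row. Sentinels score zero.
#'
#' @param model A `pssm_model`.
#' @param windows Character matrix of window letters.
#' @return Numeric vector of scores.
#' @export
score_pssm_windows <- function(model, windows) {
  stopifnot(inherits(model, "pssm_model"),
            ncol(windows) == length(model$offsets))
  alphabet <- colnames(model$cells)
  total <- numeric(nrow(windows))
  for (j in seq_len(ncol(windows))) {
    li <- match(windows[, j], alphabet)
    v <- model$cells[j, ]
    total <- total + ifelse(is.na(li), 0, v[li])
  }
  total
}

# Laplace-smoothed pooled residue frequencies of a set of windows
# (sentinels excluded). Used as the default PSSM background so the matrix
# models positional preferences, not the compositional bias of the
# disordered regions docking sites sit in.
#' @noRd
window_background <- function(windows, alphabet = AA_ALPHABET) {
  letters <- windows[windows != "-"]
  counts <- table(factor(letters, levels = alphabet))
  stats::setNames((as.numeric(counts) + 1) /
                    (length(letters) + length(alphabet)), alphabet)
}

# Window matrix for a candidate table; rows align with candidates.
#' @noRd
candidate_windows <- function(proteins, candidates, offsets) {
  seq_by_id <- stats::setNames(proteins$sequence, proteins$protein_id)
  if (!nrow(candidates)) {
    return(matrix(character(0), 0, length(offsets)))
  }
  t(vapply(seq_len(nrow(candidates)), function(i) {
    extract_window(seq_by_id[[candidates$protein_id[i]]],
                   candidates$position[i], offsets)
  }, character(length(offsets))))
}

#' Fixed canonical 14-3-3 consensus PSSM
#'
#' A reference log-odds matrix encoding the classical mode I (`RXXpS/TXP`)
#' and mode II (`RXF/YXpSXP`) determinants: Arg at -3 (strong) and -4
#' (moderate), Pro at +2 (strong), Phe/Tyr at -2 (moderate); all other
#' window positions are neutral. It plays the role of a pretrained
#' consensus predictor: because it is fixed, its scores are legitimate
#' fixed inputs to every evaluation protocol (nothing about the dataset
#' under study leaks into them), exactly as externally ingested
#' sequence-model scores are. Use [build_pssm()] /
#' [build_pssm_from_dataset()] instead when you want a matrix estimated
#' from your own corpus of validated sites.
#'
#' @param offsets Window offsets (default -5..+4 excluding 0).
#' @param background Named background probabilities (default uniform).
#' @param emissions Named list: offset (as character) to named vector of
#'   emission probabilities for the preferred letters at that offset.
#' @return A `pssm_model`.
#' @export
canonical_pssm <- function(offsets = default_offsets(), background = NULL,
                           emissions = list(
                             "-4" = c(R = 0.25),
                             "-3" = c(R = 0.50),
                             "-2" = c(F = 0.15, Y = 0.15),
                             "2"  = c(P = 0.45))) {
  alphabet <- names(background) %||% AA_ALPHABET
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / length(alphabet), length(alphabet)),
                                  alphabet)
  }
  cells <- matrix(0, nrow = length(offsets), ncol = length(alphabet),
                  dimnames = list(as.character(offsets), alphabet))
  for (off in names(emissions)) {
    if (!off %in% rownames(cells)) next
    em <- emissions[[off]]
    rest <- setdiff(alphabet, names(em))
    p <- stats::setNames(numeric(length(alphabet)), alphabet)
    p[names(em)] <- em
    # remaining emission mass spread over the other letters in proportion
    # to background
    p[rest] <- (1 - sum(em)) * background[rest] / sum(background[rest])
    cells[off, ] <- log2(p / background)
  }
  structure(list(offsets = as.integer(offsets), cells = cells,
                 background = background, pseudocount = NA_real_,
                 n_positives = 0L, canonical = TRUE),
            class = "pssm_model")
}

#' Read external per-residue disorder scores
#'
#' Tab-separated with header `protein_id`, `position`, `score`; scores in
#' `[0, 1]` (e.g. IUPred2A output). Profiles must be complete: every residue
#' of every covered protein needs a row.
#'
#' @param path Path to the TSV file.
#' @param proteins Data frame from [read_fasta()] giving sequence lengths.
#' @return Named list of numeric per-residue profiles.
#' @export
read_disorder <- function(path, proteins) {
  assert_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "score")
  if (!all(need %in% names(df))) {
    stop("disorder table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$score < 0 | df$score > 1)) {
    stop("disorder scores must lie in [0, 1]", call. = FALSE)
  }
  profiles <- list()
  for (pid in unique(df$protein_id)) {
    i <- match(pid, proteins$protein_id)
    if (is.na(i)) stop("disorder rows for unknown protein ", pid,
                       call. = FALSE)
    len <- nchar(proteins$sequence[i])
    sub <- df[df$protein_id == pid, ]
    if (any(sub$position < 1 | sub$position > len)) {
      stop("disorder position outside sequence for ", pid, call. = FALSE)
    }
    if (anyDuplicated(sub$position)) {
      stop("duplicate disorder position for ", pid, call. = FALSE)
    }
    if (nrow(sub) != len) {
      stop("incomplete disorder profile for ", pid, " (", nrow(sub), " of ",
           len, " residues)", call. = FALSE)
    }
    prof <- numeric(len)
    prof[sub$position] <- sub$score
    profiles[[pid]] <- prof
  }
  profiles
}

#' Read external sequence-model scores
#'
#' Tab-separated with header `protein_id`, `position`, `ann`, `svm`, `pssm`
#' (14-3-3Pred-style per-site outputs). Scores are taken verbatim; sites
#' absent from the file fall back to the built-in PSSM downstream.
#'
#' @param path Path to the TSV file.
#' @return Data frame keyed by (protein_id, position).
#' @export
read_sequence_scores <- function(path) {
  assert_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "ann", "svm", "pssm")
  if (!all(need %in% names(df))) {
    stop("sequence-score table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  for (col in c("ann", "svm", "pssm")) {
    if (nrow(df) && !is.numeric(df[[col]])) {
      stop("non-numeric values in column ", col, call. = FALSE)
    }
  }
  key <- paste(df$protein_id, df$position)
  if (anyDuplicated(key)) {
    stop("duplicate sequence-score entry: ", key[duplicated(key)][1L],
         call. = FALSE)
  }
  df$position <- as.integer(df$position)
  df
}

#' Assemble the five-feature matrix for candidate sites
#'
#' For every candidate Ser/Thr this fills the five model inputs: `ann`,
#' `svm`, `pssm` (external scores where available, otherwise the built-in
#' PSSM log-odds mapped through a logistic into `[0, 1]` and replicated into
#' all three slots), `disorder` (external profile value at the site, else
#' the built-in charge/hydropathy proxy), and `ptm_score`. Provenance flags
#' record missing-PTM sites and built-in fallbacks.
#'
#' @param dataset A `dock_dataset`.
#' @param pssm A `pssm_model` used for the built-in sequence fallback;
#'   defaults to the fixed [canonical_pssm()]. May be `NULL` only when
#'   external sequence scores cover every candidate.
#' @param candidates Optional pre-enumerated candidate data frame; default is
#'   every S/T of every protein in the dataset.
#' @param half_window,logistic_k Parameters of [builtin_disorder()].
#' @return Data frame with identification columns, the five features, and
#'   logical flags `flag_missing_ptm`, `flag_builtin_seq`,
#'   `flag_builtin_disorder`; attribute `dataset_digest` identifies the
#'   observation table used.
#' @export
assemble_features <- function(dataset, pssm = canonical_pssm(),
                              candidates = NULL,
                              half_window = 25, logistic_k = 10) {
  stopifnot(inherits(dataset, "dock_dataset"))
  if (is.null(candidates)) {
    candidates <- do.call(rbind, lapply(seq_len(nrow(dataset$proteins)),
      function(i) enumerate_candidates(dataset$proteins$protein_id[i],
                                       dataset$proteins$sequence[i],
                                       dataset$observations)))
    if (is.null(candidates)) {
      candidates <- data.frame(protein_id = character(), position = integer(),
                               residue = character(), n_obs = integer())
    }
  }
  n <- nrow(candidates)
  feats <- candidates
  feats$ptm_score <- numeric(n)
  feats$disorder <- numeric(n)
  feats$ann <- numeric(n)
  feats$svm <- numeric(n)
  feats$pssm <- numeric(n)
  feats$flag_missing_ptm <- logical(n)
  feats$flag_builtin_seq <- logical(n)
  feats$flag_builtin_disorder <- logical(n)

  seq_by_id <- stats::setNames(dataset$proteins$sequence,
                               dataset$proteins$protein_id)
  ext_seq <- dataset$seqscores
  ext_key <- if (!is.null(ext_seq)) paste(ext_seq$protein_id,
                                          ext_seq$position)

  for (pid in unique(candidates$protein_id)) {
    rows <- which(candidates$protein_id == pid)
    sequence <- seq_by_id[[pid]]
    if (is.null(sequence)) stop("candidate on unknown protein ", pid,
                                call. = FALSE)
    tot <- total_obs(dataset$observations, pid)
    ptm <- compute_ptm_score(candidates$n_obs[rows], tot)
    feats$ptm_score[rows] <- as.numeric(ptm)
    feats$flag_missing_ptm[rows] <- attr(ptm, "missing")

    if (!is.null(dataset$disorder) && !is.null(dataset$disorder[[pid]])) {
      prof <- dataset$disorder[[pid]]
      if (length(prof) != nchar(sequence)) {
        stop("disorder profile length mismatch for ", pid, call. = FALSE)
      }
    } else {
      prof <- builtin_disorder(sequence, half_window, logistic_k)
      feats$flag_builtin_disorder[rows] <- TRUE
    }
    feats$disorder[rows] <- prof[candidates$position[rows]]

    for (r in rows) {
      hit <- if (!is.null(ext_seq)) {
        match(paste(pid, candidates$position[r]), ext_key)
      } else NA_integer_
      if (!is.na(hit)) {
        feats$ann[r] <- ext_seq$ann[hit]
        feats$svm[r] <- ext_seq$svm[hit]
        feats$pssm[r] <- ext_seq$pssm[hit]
      } else {
        if (is.null(pssm)) {
          stop("no sequence-score source for ", pid, ":",
               candidates$position[r],
               " (supply external scores or a PSSM model)", call. = FALSE)
        }
        s <- stats::plogis(score_pssm(pssm, sequence, candidates$position[r]))
        feats$ann[r] <- s
        feats$svm[r] <- s
        feats$pssm[r] <- s
        feats$flag_builtin_seq[r] <- TRUE
      }
    }
  }
  attr(feats, "dataset_digest") <- content_digest(dataset$observations$sites)
  feats
}

#' Build a PSSM from a dataset's validated docking sites
#'
#' Convenience wrapper: extracts the window around every positive labeled
#' site and fits the log-odds matrix. By default the background is
#' estimated from the pooled residue frequencies of the positive windows
#' themselves (Laplace-smoothed over the 20-letter alphabet), so the matrix
#' captures position-specific consensus preferences rather than the overall
#' compositional bias of the (typically disordered) regions docking sites
#' sit in — mirroring what pretrained consensus predictors measure.
#'
#' @param dataset A `dock_dataset` with at least one positive label.
#' @param offsets,background,pseudocount Passed to [build_pssm()];
#'   `background = NULL` uses the window-derived composition.
#' @return A `pssm_model`.
#' @export
build_pssm_from_dataset <- function(dataset, offsets = default_offsets(),
                                    background = NULL, pseudocount = 1) {
  stopifnot(inherits(dataset, "dock_dataset"))
  pos <- dataset$labels[dataset$labels$label == 1L, , drop = FALSE]
  if (is.null(pos) || !nrow(pos)) {
    stop("dataset has no validated docking sites to build a PSSM from",
         call. = FALSE)
  }
  seq_by_id <- stats::setNames(dataset$proteins$sequence,
                               dataset$proteins$protein_id)
  windows <- t(vapply(seq_len(nrow(pos)), function(i) {
    extract_window(seq_by_id[[pos$protein_id[i]]], pos$position[i], offsets)
  }, character(length(offsets))))
  if (is.null(background)) background <- window_background(windows)
  build_pssm(windows, background, pseudocount, offsets)
}
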