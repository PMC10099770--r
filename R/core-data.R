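# Input parsing, candidate enumeration and output writing.
#
# Coordinates are 1-based throughout, matching the residue-naming convention
# used for phosphosites (e.g. "S502" is the serine at position 502).

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the 20-letter amino-acid
#' alphabet. `X` (unknown residue) is tolerated; any other non-canonical
#' letter is an error, as are duplicate identifiers and empty sequences.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A data frame with columns `protein_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  assert_file(path)
  if (!any(startsWith(readLines(path, warn = FALSE), ">"))) {
    return(data.frame(protein_id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  aa <- tryCatch(suppressWarnings(Biostrings::readAAStringSet(path)),
                 error = function(e) stop("failed to parse FASTA '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  names(seqs) <- NULL
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[1L], " in ", path, call. = FALSE)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for ", ids[!nzchar(seqs)][1L], call. = FALSE)
  }
  bad <- vapply(seqs, function(s) {
    letters <- strsplit(s, "")[[1L]]
    any(!letters %in% c(AA_ALPHABET, "X"))
  }, logical(1L))
  if (any(bad)) {
    stop("non-canonical amino-acid letters in sequence for ",
         ids[bad][1L], call. = FALSE)
  }
  data.frame(protein_id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Read a phosphosite observation-count table
#'
#' Expects a tab-separated file with header columns `protein_id`, `position`,
#' `residue`, `n_obs`: one row per observed phosphosite, `n_obs` being the
#' number of independent MS studies reporting that site. Per-protein totals
#' (the PTM-score denominator) are computed on read.
#'
#' @param path Path to the TSV file.
#' @return An object of class `obs_table`: list with `sites` (data frame)
#'   and `totals` (named numeric, total observations per protein).
#' @export
read_observation_table <- function(path) {
  assert_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  observation_table(df)
}

#' Build an observation table from a data frame
#'
#' @param df Data frame with columns `protein_id`, `position`, `residue`,
#'   `n_obs`.
#' @return An `obs_table` object.
#' @export
observation_table <- function(df) {
  need <- c("protein_id", "position", "residue", "n_obs")
  if (!all(need %in% names(df))) {
    stop("observation table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  if (nrow(df)) {
    if (any(df$position != as.integer(df$position)) || any(df$position < 1)) {
      stop("positions must be positive integers", call. = FALSE)
    }
    if (any(df$n_obs != as.integer(df$n_obs)) || any(df$n_obs < 1)) {
      stop("n_obs must be integer >= 1 for every stored entry", call. = FALSE)
    }
    key <- paste(df$protein_id, df$position)
    if (anyDuplicated(key)) {
      stop("duplicate (protein, position) entry: ", key[duplicated(key)][1L],
           call. = FALSE)
    }
    if (any(!df$residue %in% c("S", "T"))) {
      stop("observation residues must be S or T", call. = FALSE)
    }
  }
  df$position <- as.integer(df$position)
  df$n_obs <- as.integer(df$n_obs)
  totals <- if (nrow(df)) {
    vapply(split(df$n_obs, df$protein_id), sum, numeric(1L))
  } else {
    stats::setNames(numeric(0L), character(0L))
  }
  structure(list(sites = df, totals = totals), class = "obs_table")
}

#' @export
print.obs_table <- function(x, ...) {
  cat("Phosphosite observation table:", nrow(x$sites), "sites on",
      length(x$totals), "proteins\n")
  invisible(x)
}

#' Look up total observations for a protein
#'
#' @param table An `obs_table`.
#' @param protein_id Protein identifier.
#' @return Total MS observation count over all the protein's phosphosites
#'   (0 if the protein has none).
#' @export
total_obs <- function(table, protein_id) {
  stopifnot(inherits(table, "obs_table"))
  out <- table$totals[protein_id]
  out[is.na(out)] <- 0
  unname(out)
}

#' Enumerate candidate sites for a protein
#'
#' The prediction universe is every Ser/Thr residue in the sequence, not just
#' observed phosphosites; unobserved sites carry `n_obs = 0`. Observation
#' entries whose residue letter disagrees with the sequence at the stated
#' position are a hard error (guards against isoform or coordinate drift).
#'
#' @param protein_id Protein identifier.
#' @param sequence Amino-acid sequence string.
#' @param observations An `obs_table` (optional).
#' @return Data frame of candidates with columns `protein_id`, `position`,
#'   `residue`, `n_obs`, in ascending position order.
#' @export
enumerate_candidates <- function(protein_id, sequence, observations = NULL) {
  letters <- strsplit(sequence, "")[[1L]]
  pos <- which(letters %in% c("S", "T"))
  out <- data.frame(protein_id = rep(protein_id, length(pos)),
                    position = as.integer(pos),
                    residue = letters[pos],
                    n_obs = rep(0L, length(pos)),
                    stringsAsFactors = FALSE)
  if (!is.null(observations)) {
    stopifnot(inherits(observations, "obs_table"))
    tab <- observations$sites[observations$sites$protein_id == protein_id, ]
    if (nrow(tab)) {
      if (any(tab$position > length(letters))) {
        stop("observation position beyond sequence end for ", protein_id,
             call. = FALSE)
      }
      seq_res <- letters[tab$position]
      if (any(seq_res != tab$residue)) {
        i <- which(seq_res != tab$residue)[1L]
        stop("coordinate mismatch for ", protein_id, " position ",
             tab$position[i], ": table says ", tab$residue[i],
             ", sequence has ", seq_res[i], call. = FALSE)
      }
      idx <- match(tab$position, out$position)
      out$n_obs[idx] <- tab$n_obs
    }
  }
  out
}

#' Read a labeled-site table
#'
#' Tab-separated with header `protein_id`, `position`, `label` (1 =
#' validated 14-3-3 docking phosphorylation, 0 = other) and an optional
#' `noncanonical` column (0/1) written by the simulator.
#'
#' @param path Path to the TSV file.
#' @return Data frame of labeled sites.
#' @export
read_labels <- function(path) {
  assert_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(df))) {
    stop("labels table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) && any(!df$label %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  key <- paste(df$protein_id, df$position)
  if (anyDuplicated(key)) {
    stop("duplicate labeled site: ", key[duplicated(key)][1L], call. = FALSE)
  }
  df$position <- as.integer(df$position)
  df$label <- as.integer(df$label)
  df
}

#' Assemble a validated dataset
#'
#' Bundles proteins, the observation table, labels and optional external
#' per-residue disorder and sequence-score tables, checking cross-references:
#' every labeled site must resolve to an S or T in its protein, and every
#' observation entry must belong to a known protein.
#'
#' @param proteins Data frame from [read_fasta()].
#' @param observations An `obs_table` (default: empty).
#' @param labels Data frame of labeled sites (optional).
#' @param disorder Named list of per-residue disorder profiles (optional),
#'   as returned by [read_disorder()].
#' @param seqscores Data frame of external sequence-model scores (optional),
#'   as returned by [read_sequence_scores()].
#' @return An object of class `dock_dataset`.
#' @export
dock_dataset <- function(proteins, observations = NULL, labels = NULL,
                         disorder = NULL, seqscores = NULL) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$protein_id)) {
    stop("duplicate protein_id in proteins", call. = FALSE)
  }
  if (is.null(observations)) {
    observations <- observation_table(
      data.frame(protein_id = character(), position = integer(),
                 residue = character(), n_obs = integer()))
  }
  stopifnot(inherits(observations, "obs_table"))
  orphan <- setdiff(observations$sites$protein_id, proteins$protein_id)
  if (length(orphan)) {
    stop("observation entries for unknown protein: ", orphan[1L],
         call. = FALSE)
  }
  if (!is.null(labels) && nrow(labels)) {
    idx <- match(labels$protein_id, proteins$protein_id)
    if (anyNA(idx)) {
      stop("labeled site on unknown protein: ",
           labels$protein_id[is.na(idx)][1L], call. = FALSE)
    }
    for (i in seq_len(nrow(labels))) {
      s <- proteins$sequence[idx[i]]
      p <- labels$position[i]
      if (p < 1L || p > nchar(s) ||
          !substr(s, p, p) %in% c("S", "T")) {
        stop("labeled site ", labels$protein_id[i], ":", p,
             " does not resolve to an S or T residue", call. = FALSE)
      }
    }
  }
  structure(list(proteins = proteins, observations = observations,
                 labels = labels, disorder = disorder,
                 seqscores = seqscores),
            class = "dock_dataset")
}

#' @export
print.dock_dataset <- function(x, ...) {
  n_pos <- if (is.null(x$labels)) 0L else sum(x$labels$label == 1L)
  cat("14-3-3 site dataset:", nrow(x$proteins), "proteins,",
      nrow(x$observations$sites), "observed phosphosites,",
      n_pos, "validated docking sites\n")
  invisible(x)
}

PREDICTION_COLUMNS <- c(
  "protein_id", "position", "residue", "n_obs", "ptm_score", "disorder",
  "ann", "svm", "pssm", "total_score", "total_rank", "ptmdis_score",
  "ptmdis_rank", "seq_score", "seq_rank", "adapted_score", "adapted_rank")

#' Write ranked predictions to a TSV file
#'
#' Rows are sorted by protein and ascending `total_rank`; scores are written
#' with enough precision to round-trip to at least 6 decimals.
#'
#' @param predictions Data frame from [predict_ranks()].
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  missing_cols <- setdiff(PREDICTION_COLUMNS, names(predictions))
  if (length(missing_cols)) {
    stop("predictions missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- predictions[PREDICTION_COLUMNS]
  out <- out[order(out$protein_id, out$total_rank), ]
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(v) sprintf("%.9g", v))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write predictions to ", path, call. = FALSE)
  invisible(path)
}

#' Read back a predictions TSV
#'
#' @param path Path written by [write_predictions()].
#' @return Data frame with the standard prediction columns.
#' @export
read_predictions <- function(path) {
  assert_file(path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
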