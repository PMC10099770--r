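# Seeded synthetic datasets with the statistical structure the method
# assumes: consensus-like motifs around planted docking sites, local
# disorder-promoting composition, and an MS observation-count model in which
# docking sites are observed more often than decoy phosphosites.

DISORDER_POOL <- c("E", "K", "S", "P", "Q", "G", "D")

#' Simulation configuration
#'
#' Defaults describe a plausible set of 14-3-3 client proteins: large
#' multidomain regulatory proteins (300-600 residues here, so a few dozen
#' candidate Ser/Thr each), mostly one validated docking site with a 20%
#' chance of a second (dual-site clients), mode I/II-like motif letters
#' around docking sites, disorder-promoting composition within +/-10
#' residues of them, and negative-binomial MS observation counts that shift
#' docking sites well above decoys without making them separable.
#'
#' @param n_proteins Number of proteins to simulate.
#' @param length_range Min/max sequence length.
#' @param p_sites Probabilities of 0, 1 or 2 docking sites per protein.
#' @param p_R_minus3 Probability of Arg at offset -3 (mode I determinant).
#' @param p_P_plus2 Probability of Pro at offset +2 (mode I determinant).
#' @param p_FY_minus2 Probability of Phe/Tyr at offset -2 (mode II
#'   determinant).
#' @param disorder_pool_prob Probability a residue within
#'   `disorder_halfwidth` of a docking site is drawn from the
#'   disorder-promoting pool `{E,K,S,P,Q,G,D}`.
#' @param disorder_halfwidth Half-width of the disorder-enriched window.
#' @param mean_true,mean_decoy Negative-binomial mean observation counts for
#'   docking vs decoy phosphosites.
#' @param dispersion Negative-binomial size parameter.
#' @param p_true_obs,p_decoy_obs Probability that a docking / decoy site is
#'   observed by MS at all.
#' @param motif_on,disorder_on,ptm_on Signal switches. With a switch off the
#'   corresponding feature channel is exchangeable between docking and decoy
#'   sites (`ptm_on = FALSE` makes docking sites use the decoy observation
#'   model).
#' @param background `"uniform"` over the 20 amino acids (keeps the PSSM
#'   null zero-mean) or a named probability vector.
#' @param seed Integer seed; mandatory.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 100, length_range = c(300, 600),
                       p_sites = c(0, 0.8, 0.2),
                       p_R_minus3 = 0.85, p_P_plus2 = 0.7, p_FY_minus2 = 0.3,
                       disorder_pool_prob = 0.8, disorder_halfwidth = 10,
                       mean_true = 20, mean_decoy = 3, dispersion = 1,
                       p_true_obs = 0.95, p_decoy_obs = 0.3,
                       motif_on = TRUE, disorder_on = TRUE, ptm_on = TRUE,
                       background = "uniform", seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_proteins >= 0, length(length_range) == 2L,
            length_range[1L] >= 30, length_range[2L] >= length_range[1L],
            length(p_sites) == 3L, abs(sum(p_sites) - 1) < 1e-9,
            all(p_sites >= 0),
            all(c(p_R_minus3, p_P_plus2, p_FY_minus2, disorder_pool_prob,
                  p_true_obs, p_decoy_obs) >= 0),
            all(c(p_R_minus3, p_P_plus2, p_FY_minus2, disorder_pool_prob,
                  p_true_obs, p_decoy_obs) <= 1),
            mean_true >= mean_decoy, dispersion > 0)
  if (identical(background, "uniform")) {
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  stopifnot(abs(sum(background) - 1) < 1e-6, all(background > 0))
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 p_sites = p_sites, p_R_minus3 = p_R_minus3,
                 p_P_plus2 = p_P_plus2, p_FY_minus2 = p_FY_minus2,
                 disorder_pool_prob = disorder_pool_prob,
                 disorder_halfwidth = as.integer(disorder_halfwidth),
                 mean_true = mean_true, mean_decoy = mean_decoy,
                 dispersion = dispersion, p_true_obs = p_true_obs,
                 p_decoy_obs = p_decoy_obs, motif_on = motif_on,
                 disorder_on = disorder_on, ptm_on = ptm_on,
                 background = background, seed = as.integer(seed)),
            class = "sim_config")
}

# Truncated negative binomial: counts for observed sites are >= 1.
#' @noRd
rnbinom_pos <- function(n, mean, size) {
  1L + stats::rnbinom(n, mu = max(mean - 1, 0), size = size)
}

# One protein, generated from its own seed so protein content is independent
# of generation order.
#' @noRd
simulate_protein <- function(pid, config, protein_seed, nc_fraction = 0) {
  set.seed(protein_seed)
  len <- sample(config$length_range[1L]:config$length_range[2L], 1L)
  letters <- sample(names(config$background), len, replace = TRUE,
                    prob = config$background)
  n_sites <- sample(0:2, 1L, prob = config$p_sites)
  # planted docking positions: uniform over the sequence, min separation 12
  positions <- integer(0)
  tries <- 0L
  while (length(positions) < n_sites && tries < 200L) {
    p <- sample.int(len, 1L)
    if (all(abs(p - positions) >= 12L)) positions <- c(positions, p)
    tries <- tries + 1L
  }
  if (length(positions) < n_sites) {
    stop("could not place ", n_sites, " docking sites in a ", len,
         "-residue protein", call. = FALSE)
  }
  positions <- sort(positions)
  noncanonical <- stats::runif(length(positions)) < nc_fraction

  for (i in seq_along(positions)) {
    p <- positions[i]
    # local disorder-promoting composition (docking sites sit in or near
    # intrinsically disordered regions)
    if (config$disorder_on) {
      w <- max(1L, p - config$disorder_halfwidth):
        min(len, p + config$disorder_halfwidth)
      enrich <- stats::runif(length(w)) < config$disorder_pool_prob
      letters[w[enrich]] <- sample(DISORDER_POOL, sum(enrich),
                                   replace = TRUE)
    }
    letters[p] <- sample(c("S", "T"), 1L, prob = c(0.75, 0.25))
    # consensus determinants (mode I: R at -3, P at +2; mode II: F/Y at -2)
    if (config$motif_on && !noncanonical[i]) {
      if (p - 3L >= 1L && stats::runif(1L) < config$p_R_minus3) {
        letters[p - 3L] <- "R"
      }
      if (p + 2L <= len && stats::runif(1L) < config$p_P_plus2) {
        letters[p + 2L] <- "P"
      }
      if (p - 2L >= 1L && stats::runif(1L) < config$p_FY_minus2) {
        letters[p - 2L] <- sample(c("F", "Y"), 1L)
      }
    }
  }
  sequence <- paste(letters, collapse = "")

  # observation counts: docking sites from the true-site model (unless the
  # PTM channel is switched off), decoy S/T from the decoy model
  st_pos <- which(letters %in% c("S", "T"))
  decoy_pos <- setdiff(st_pos, positions)
  obs <- list()
  true_mean <- if (config$ptm_on) config$mean_true else config$mean_decoy
  true_p <- if (config$ptm_on) config$p_true_obs else config$p_decoy_obs
  for (p in positions) {
    if (stats::runif(1L) < true_p) {
      obs[[length(obs) + 1L]] <- data.frame(
        protein_id = pid, position = p, residue = letters[p],
        n_obs = rnbinom_pos(1L, true_mean, config$dispersion))
    }
  }
  for (p in decoy_pos) {
    if (stats::runif(1L) < config$p_decoy_obs) {
      obs[[length(obs) + 1L]] <- data.frame(
        protein_id = pid, position = p, residue = letters[p],
        n_obs = rnbinom_pos(1L, config$mean_decoy, config$dispersion))
    }
  }
  labels <- if (length(positions)) {
    data.frame(protein_id = pid, position = positions, label = 1L,
               noncanonical = as.integer(noncanonical))
  }
  list(protein = data.frame(protein_id = pid, sequence = sequence,
                            stringsAsFactors = FALSE),
       obs = if (length(obs)) do.call(rbind, obs),
       labels = labels)
}

#' Simulate a labeled 14-3-3 client dataset
#'
#' Draws protein sequences from background amino-acid frequencies, plants
#' docking sites with consensus-motif letters and disorder-favorable local
#' composition, and assigns MS observation counts with docking sites drawn
#' from a higher-count distribution than decoy phosphosites. Fully
#' reproducible from the config seed; each protein is generated from its own
#' derived seed.
#'
#' @param config A [sim_config()].
#' @param noncanonical_fraction Fraction of docking sites generated without
#'   consensus-motif enrichment (their windows stay at background); used for
#'   the non-canonical analysis. Default 0.
#' @return A `dock_dataset` whose labels carry a `noncanonical` flag column.
#' @export
simulate_dataset <- function(config, noncanonical_fraction = 0) {
  stopifnot(inherits(config, "sim_config"),
            noncanonical_fraction >= 0, noncanonical_fraction <= 1)
  n <- config$n_proteins
  if (n == 0L) {
    return(dock_dataset(
      data.frame(protein_id = character(), sequence = character()),
      labels = data.frame(protein_id = character(), position = integer(),
                          label = integer(), noncanonical = integer())))
  }
  protein_seeds <- derive_seeds(config$seed, n)
  parts <- lapply(seq_len(n), function(i) {
    simulate_protein(sprintf("SIM%04d", i), config, protein_seeds[i],
                     noncanonical_fraction)
  })
  proteins <- do.call(rbind, lapply(parts, `[[`, "protein"))
  obs <- do.call(rbind, Filter(Negate(is.null), lapply(parts, `[[`, "obs")))
  labels <- do.call(rbind, Filter(Negate(is.null),
                                  lapply(parts, `[[`, "labels")))
  if (is.null(obs)) {
    obs <- data.frame(protein_id = character(), position = integer(),
                      residue = character(), n_obs = integer())
  }
  if (is.null(labels)) {
    labels <- data.frame(protein_id = character(), position = integer(),
                         label = integer(), noncanonical = integer())
  }
  dock_dataset(proteins, observation_table(obs), labels)
}

#' Simulate a dataset enriched in non-canonical docking sites
#'
#' Same generative model as [simulate_dataset()] but motif emission is
#' disabled for the stated fraction of docking sites (their windows stay at
#' background composition) while the PTM-count and disorder signals are
#' retained; the `noncanonical` flag in the labels records which sites were
#' de-motifed.
#'
#' @param config A [sim_config()].
#' @param fraction Fraction of docking sites without motif enrichment
#'   (default 1).
#' @return A `dock_dataset`.
#' @export
simulate_noncanonical <- function(config, fraction = 1) {
  simulate_dataset(config, noncanonical_fraction = fraction)
}

#' Write a simulated dataset to pipeline input files
#'
#' Writes the same formats the real pipeline reads — `proteins.fasta`,
#' `observations.tsv`, `labels.tsv` — plus `truth.json` (config echo and
#' per-site ground truth).
#'
#' @param dataset A simulated `dock_dataset`.
#' @param dir Output directory (created if absent).
#' @param config The generating [sim_config()], echoed into `truth.json`.
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulated_dataset <- function(dataset, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "proteins.fasta"),
             observations = file.path(dir, "observations.tsv"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "truth.json"))
  fasta_lines <- if (nrow(dataset$proteins)) {
    paste0(">", dataset$proteins$protein_id, "\n",
           dataset$proteins$sequence)
  } else character(0)
  writeLines(fasta_lines, paths["fasta"])
  utils::write.table(dataset$observations$sites, paths["observations"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$labels, paths["labels"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(config = if (!is.null(config)) unclass(config),
                sites = dataset$labels)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
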