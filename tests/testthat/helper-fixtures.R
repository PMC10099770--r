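# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(len) {
  paste(sample(AAS, len, replace = TRUE), collapse = "")
}

# A dataset in which the docking site is the only observed phosphosite on
# each protein (PTM score 1 vs 0): trivially separable through the PTM
# channel, with sequence content uninformative.
make_separable_dataset <- function(n_proteins = 10, len = 120, seed = 1) {
  set.seed(seed)
  proteins <- data.frame(protein_id = sprintf("SEP%02d", seq_len(n_proteins)),
                         sequence = vapply(seq_len(n_proteins), function(i) {
                           s <- strsplit(random_sequence(len), "")[[1L]]
                           # guarantee a healthy candidate count
                           extra <- sample(seq_len(len), 15)
                           s[extra] <- sample(c("S", "T"), 15, replace = TRUE)
                           paste(s, collapse = "")
                         }, character(1L)),
                         stringsAsFactors = FALSE)
  pos <- integer(n_proteins)
  for (i in seq_len(n_proteins)) {
    st <- which(strsplit(proteins$sequence[i], "")[[1L]] %in% c("S", "T"))
    pos[i] <- sample(st, 1L)
  }
  res <- substring(proteins$sequence, pos, pos)
  obs <- observation_table(data.frame(
    protein_id = proteins$protein_id, position = pos, residue = res,
    n_obs = 5L, stringsAsFactors = FALSE))
  labels <- data.frame(protein_id = proteins$protein_id, position = pos,
                       label = 1L, stringsAsFactors = FALSE)
  dock_dataset(proteins, obs, labels)
}

# Like make_separable_dataset but with low-count observed decoys, so PTM
# scores differ strongly between groups without either group being constant
# (Welch's test needs within-group variance).
make_enrichment_dataset <- function(n_proteins = 12, len = 120, seed = 1) {
  set.seed(seed)
  base <- make_separable_dataset(n_proteins, len, seed)
  extra <- list()
  for (i in seq_len(n_proteins)) {
    st <- which(strsplit(base$proteins$sequence[i], "")[[1L]] %in%
                c("S", "T"))
    pos_i <- base$labels$position[i]
    decoys <- sample(setdiff(st, pos_i), 3L)
    extra[[i]] <- data.frame(
      protein_id = base$proteins$protein_id[i], position = decoys,
      residue = substring(base$proteins$sequence[i], decoys, decoys),
      n_obs = sample(1:3, 3L, replace = TRUE), stringsAsFactors = FALSE)
  }
  sites <- rbind(base$observations$sites, do.call(rbind, extra))
  sites$n_obs[match(paste(base$labels$protein_id, base$labels$position),
                    paste(sites$protein_id, sites$position))] <- 20L
  dock_dataset(base$proteins, observation_table(sites), base$labels)
}

# Minimal hand-built dataset with explicit external feature tables, so every
# feature value is controlled by the test.
make_manual_dataset <- function() {
  proteins <- data.frame(
    protein_id = c("P1", "P2"),
    sequence = c("MASRRATSLPSE", "MSTTKSPRSQAT"),
    stringsAsFactors = FALSE)
  obs <- observation_table(data.frame(
    protein_id = c("P1", "P1", "P2"),
    position = c(7L, 11L, 2L),
    residue = c("T", "S", "S"),
    n_obs = c(15L, 5L, 7L)))
  labels <- data.frame(protein_id = c("P1", "P2"),
                       position = c(7L, 2L), label = 1L,
                       stringsAsFactors = FALSE)
  dock_dataset(proteins, obs, labels)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_fasta <- function(proteins, path) {
  writeLines(paste0(">", proteins$protein_id, "\n", proteins$sequence), path)
  path
}

# Write a simulated dataset's input files to a temp dir for CLI tests.
write_dataset_files <- function(dataset, dir = tempfile("ds")) {
  dir.create(dir)
  list(fasta = write_fasta(dataset$proteins, file.path(dir, "p.fasta")),
       obs = write_tsv(dataset$observations$sites, file.path(dir, "o.tsv")),
       labels = write_tsv(dataset$labels, file.path(dir, "l.tsv")),
       dir = dir)
}
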