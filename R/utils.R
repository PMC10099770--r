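# Internal helpers shared across modules.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Cheap deterministic content hash (FNV-1a over UTF-8 bytes), used to tag a
# trained ranker with the dataset it was fitted on so that scoring against
# features from a different dataset can be flagged.
#' @noRd
content_digest <- function(x) {
  bytes <- utf8ToInt(paste(as.character(unlist(x)), collapse = "\x1f"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @noRd
assert_file <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read file: ", path, call. = FALSE)
  }
  invisible(path)
}

# Derive a stream of child seeds from one master seed without disturbing the
# caller's RNG state beyond the draw itself.  Kept below 2^31 - 1.
#' @noRd
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
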