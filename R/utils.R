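#' @useDynLib ligprobe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rmultinom rpois rbinom runif rnorm median sd var cor
#'   lm coef pt phyper pchisq prcomp hclust as.dist quantile setNames
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible sub-stream seed for a named pipeline stage
#'
#' All randomness in the package flows from one top-level seed; each stage
#' (read sampling, error injection, chimera formation, ...) draws from its
#' own sub-stream so that adding a stage never perturbs another stage's draws.
#'
#' @param seed integer top-level seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

#' Generate random DNA sequences
#'
#' @param n number of sequences.
#' @param width sequence length in nt.
#' @return character vector of uppercase DNA strings.
#' @export
random_dna <- function(n, width) {
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

## Hamming distance between equal-length strings (vectorised over x)
hamming_dist <- function(x, y) {
  stopifnot(length(y) == 1L)
  w <- nchar(y)
  out <- integer(length(x))
  ym <- utf8ToInt(y)
  for (i in seq_along(x)) {
    out[i] <- sum(utf8ToInt(x[i]) != ym)
  }
  out
}

## substitute a different base at 1-based position pos
substitute_base <- function(seq, pos) {
  old <- substr(seq, pos, pos)
  new <- sample(setdiff(DNA_BASES, old), 1L)
  substr(seq, pos, pos) <- new
  seq
}

## inject per-base substitution errors into a character vector of reads
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) seqs[i] <- substitute_base(seqs[i], p)
  }
  seqs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pkg_version_string <- function() {
  as.character(utils::packageVersion("ligprobe"))
}

## cheap deterministic hash of an R object, for config stamping only
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

## single header comment line stamped on every artifact file
artifact_header <- function(seed = NA, config = NULL) {
  hash <- if (is.null(config)) "none" else config_hash(config)
  sprintf("# ligprobe %s seed=%s config=%s", pkg_version_string(), seed, hash)
}

## write a TSV with an artifact header comment; read back with read_artifact_tsv
write_artifact_tsv <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(artifact_header(seed, config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_artifact_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}
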