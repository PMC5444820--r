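#' Write reads to a FASTQ file
#'
#' Standard 4-line FASTQ with a constant quality (the assay has no
#' quality-aware steps downstream). Gzip output is selected by a `.gz`
#' suffix.
#'
#' @param reads data frame with columns `id` and `seq`
#'   (as returned in `simulate_sample()$reads`).
#' @param path output path (`.fastq` or `.fastq.gz`).
#' @param qual_char constant quality character (default `"I"`, Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  qual <- vapply(nchar(reads$seq), function(w) strrep(qual_char, w), "")
  rec <- paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (plain or gzip).
#' @return data frame with columns `id` (full header after `@`) and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(x), seq = unname(as.character(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}
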