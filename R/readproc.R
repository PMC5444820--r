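#' Demultiplex inline-indexed reads against a sample sheet
#'
#' Reads carry their dual 9-mer indexes inline as the first 18 nt of the
#' sequence (`index1` then `index2`). A read is assigned to a sample iff
#' both of its indexes are within `max_index_mismatch` of exactly one
#' sample's index pair; reads matching no sample, or more than one, go to
#' `undetermined`. Assigned reads have the 18-nt index prefix stripped.
#'
#' @param reads data frame with columns `id`, `seq` (e.g. [read_fastq()]).
#' @param sheet sample sheet (see [read_sample_sheet()]).
#' @param max_index_mismatch tolerance per index (default 1, the common
#'   demultiplexer default).
#' @return named list of per-sample read data frames plus `undetermined`.
#' @export
demultiplex <- function(reads, sheet, max_index_mismatch = 1L) {
  sheet <- validate_sample_sheet(sheet)
  ## a sheet is usable only if no two samples could both match one read
  n <- nrow(sheet)
  if (n > 1L) {
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        d1 <- sum(utf8ToInt(sheet$index1[a]) != utf8ToInt(sheet$index1[b]))
        d2 <- sum(utf8ToInt(sheet$index2[a]) != utf8ToInt(sheet$index2[b]))
        if (d1 <= 2 * max_index_mismatch && d2 <= 2 * max_index_mismatch) {
          stop(sprintf(
            "index collision: samples '%s' and '%s' are within %d mismatches on both indexes",
            sheet$sample_id[a], sheet$sample_id[b], 2 * max_index_mismatch),
            call. = FALSE)
        }
      }
    }
  }

  i1 <- substr(reads$seq, 1L, 9L)
  i2 <- substr(reads$seq, 10L, 18L)
  assigned <- rep(NA_integer_, nrow(reads))
  n_hits <- integer(nrow(reads))

  ## exact pairs first (covers almost all reads), then per-sample tolerant pass
  exact <- match(paste(i1, i2), paste(sheet$index1, sheet$index2))
  assigned[!is.na(exact)] <- exact[!is.na(exact)]
  n_hits[!is.na(exact)] <- 1L

  rest <- which(is.na(assigned))
  if (length(rest) && max_index_mismatch > 0) {
    for (s in seq_len(n)) {
      d1 <- index_mismatches(i1[rest], sheet$index1[s])
      d2 <- index_mismatches(i2[rest], sheet$index2[s])
      hit <- d1 <= max_index_mismatch & d2 <= max_index_mismatch
      n_hits[rest][hit] <- n_hits[rest][hit] + 1L
      assigned[rest][hit] <- s
    }
    assigned[rest][n_hits[rest] != 1L] <- NA_integer_
  }

  out <- lapply(seq_len(n), function(s) {
    sel <- which(!is.na(assigned) & assigned == s)
    data.frame(id = reads$id[sel],
               seq = substr(reads$seq[sel], 19L, nchar(reads$seq[sel])),
               stringsAsFactors = FALSE)
  })
  names(out) <- sheet$sample_id
  out$undetermined <- reads[is.na(assigned), c("id", "seq")]
  rownames(out$undetermined) <- NULL
  out
}

## mismatches of each 9-mer in x against a single 9-mer y, vectorised over x
index_mismatches <- function(x, y) {
  d <- integer(length(x))
  for (p in 1:9) {
    d <- d + (substr(x, p, p) != substr(y, p, p))
  }
  d
}

#' Align reads to a probe pool
#'
#' Hamming-only matching of each read against the pool's ligated 50-mers,
#' allowing up to `max_mm` mismatches (no indels: the templates are
#' fixed-length synthetic constructs). Ties at the best distance are
#' discarded as ambiguous, keeping counts deterministic. Reads of 40--49 nt
#' are rescued by prefix matching over their full length; shorter reads are
#' unmapped (a sub-40-nt fragment no longer guarantees panel-wide
#' specificity). Unmapped full-length reads are then screened for
#' mis-ligation chimeras: a read whose first 25 nt match one probe's
#' downstream half and whose last 25 nt match a *different* probe's upstream
#' half (each half within `max_half_mm` mismatches, so sequencing errors do
#' not hide chimeras) is classed `chimera`. Chimeras are never counted as
#' expression.
#'
#' @param reads character vector of read sequences, or a data frame with a
#'   `seq` column.
#' @param pool a [probe_pool()].
#' @param max_mm maximum mismatches for a mapped read (default 2).
#' @param min_len minimum read length for prefix rescue (default 40).
#' @param max_half_mm per-half mismatch tolerance of the chimera screen
#'   (default 1).
#' @return data frame with one row per read: `class`
#'   (`mapped`/`chimera`/`unmapped`), `probe_id`, `mismatches`,
#'   `chimera_probe_a`, `chimera_probe_b`.
#' @export
align_reads <- function(reads, pool, max_mm = 2L, min_len = 40L,
                        max_half_mm = 1L) {
  stopifnot(inherits(pool, "probe_pool"))
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  res <- align_reads_cpp(seqs, pool$ligated, max_mm = max_mm,
                         min_len = min_len)
  out <- data.frame(
    class = ifelse(res$index > 0L, "mapped", "unmapped"),
    probe_id = ifelse(res$index > 0L, pool$probe_id[pmax(res$index, 1L)],
                      NA_character_),
    mismatches = res$mismatches,
    read_length = nchar(seqs),
    chimera_probe_a = rep(NA_character_, length(seqs)),
    chimera_probe_b = rep(NA_character_, length(seqs)),
    stringsAsFactors = FALSE
  )
  ## chimera screen on unmapped full-length reads only
  cand <- which(res$index == 0L & nchar(seqs) == 50L)
  if (length(cand)) {
    ch <- chimera_scan_cpp(seqs[cand], pool$ligated, max_half_mm = max_half_mm)
    hit <- ch$down_index > 0L
    sel <- cand[hit]
    out$class[sel] <- "chimera"
    out$chimera_probe_a[sel] <- pool$probe_id[ch$down_index[hit]]
    out$chimera_probe_b[sel] <- pool$probe_id[ch$up_index[hit]]
  }
  out
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] for one sequence.
#'
#' @param read a single read sequence.
#' @inheritParams align_reads
#' @return one-row alignment data frame (see [align_reads()]).
#' @export
align_read <- function(read, pool, max_mm = 2L, min_len = 40L,
                       max_half_mm = 1L) {
  align_reads(read, pool, max_mm = max_mm, min_len = min_len,
              max_half_mm = max_half_mm)
}

#' Count aligned reads for one sample
#'
#' Tabulates mapped reads per probe and assembles the sample's read
#' accounting: `total = mapped + chimera + unmapped` and the mapped
#' fraction. The mis-ligation fraction estimates the biochemical chimera
#' rate as classified chimeras over *full-length* reads (only 50-nt reads
#' can be split-half classified, and truncation strikes chimeras and
#' genuine products alike, so restricting the denominator to classifiable
#' reads keeps the estimator unbiased under partial-read loss). When read
#' lengths are unavailable the denominator falls back to the total.
#'
#' @param alignments alignment data frame from [align_reads()] for one
#'   sample.
#' @param pool a [probe_pool()] (fixes the probe universe and order).
#' @return list with `counts` (named integer vector over all pool probes)
#'   and `accounting` (one-row data frame: `total`, `mapped`, `chimera`,
#'   `unmapped`, `mapped_fraction`, `misligation_fraction`).
#' @export
count_sample <- function(alignments, pool) {
  stopifnot(inherits(pool, "probe_pool"))
  mapped <- alignments$probe_id[alignments$class == "mapped"]
  counts <- table(factor(mapped, levels = pool$probe_id))
  counts <- setNames(as.integer(counts), pool$probe_id)
  total <- nrow(alignments)
  n_map <- sum(alignments$class == "mapped")
  n_chim <- sum(alignments$class == "chimera")
  n_un <- total - n_map - n_chim
  n_full <- if (!is.null(alignments$read_length)) {
    sum(alignments$read_length >= 50L)
  } else {
    total
  }
  acct <- data.frame(
    total = total, mapped = n_map, chimera = n_chim, unmapped = n_un,
    full_length = n_full,
    mapped_fraction = if (total > 0) n_map / total else 0,
    misligation_fraction = if (n_full > 0) n_chim / n_full else 0
  )
  list(counts = counts, accounting = acct)
}
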