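#' Assemble a count matrix from per-sample counts
#'
#' @param count_list named list of per-probe count vectors (all over the
#'   same probe universe, e.g. from [count_sample()]).
#' @return integer matrix, probes x samples.
#' @export
assemble_counts <- function(count_list) {
  stopifnot(length(count_list) > 0)
  m <- do.call(cbind, count_list)
  colnames(m) <- names(count_list)
  m
}

#' Normalize a count matrix to the average total reads per sample
#'
#' Each column is scaled by `mean(column totals) / its total`, so all
#' column totals equal the pre-normalization mean. Zero-total columns are
#' left unscaled and flagged in the `"unscaled"` attribute.
#'
#' @param counts numeric matrix, probes x samples.
#' @return scaled matrix with attribute `"scale_factors"` and, if any,
#'   `"unscaled"` (names of zero-total columns).
#' @export
normalize_total <- function(counts) {
  totals <- colSums(counts)
  if (all(totals == 0)) stop("all columns have zero total", call. = FALSE)
  target <- mean(totals)
  sf <- ifelse(totals > 0, target / totals, 1)
  out <- sweep(counts, 2L, sf, `*`)
  attr(out, "scale_factors") <- sf
  zero <- colnames(counts)[totals == 0]
  if (length(zero)) attr(out, "unscaled") <- zero
  out
}

#' Back-calculate unattenuated read counts
#'
#' A probe attenuated at ratio `a` (attenuator:functional DO) collects
#' `1/(a+1)` of the reads it would have unattenuated, so the corrected
#' count is `count * (a + 1)` ("fold attenuation"): an observed 10,000 at
#' 4:1 back-calculates to 50,000. Unattenuated probes (`a = 0`) are
#' unchanged.
#'
#' @param counts numeric matrix or vector of counts, rows/names = probes.
#' @param pool a [probe_pool()] carrying per-probe `attenuation_ratio`, or
#'   a named numeric vector of ratios.
#' @return corrected counts of the same shape.
#' @export
backcalculate_attenuation <- function(counts, pool) {
  ratios <- if (inherits(pool, "probe_pool")) {
    setNames(pool$attenuation_ratio, pool$probe_id)
  } else {
    pool
  }
  if (any(ratios < 0, na.rm = TRUE)) {
    stop("attenuation ratios must be non-negative", call. = FALSE)
  }
  ids <- if (is.matrix(counts)) rownames(counts) else names(counts)
  if (is.null(ids)) {
    stopifnot(length(ratios) == NROW(counts))
    a <- unname(ratios)
  } else {
    a <- ratios[ids]
    if (anyNA(a)) stop("missing attenuation ratio for some probes", call. = FALSE)
  }
  counts * (1 + a)
}

#' Pairwise replicate R-squared on log counts
#'
#' Pearson R^2 between `log2(count + 1)` of every within-group sample pair;
#' the pseudocount keeps zero-count probes on the scale.
#'
#' @param counts numeric matrix, probes x samples.
#' @param groups factor/character of group labels per column (default: all
#'   one group).
#' @return data frame per pair: `group`, `sample_a`, `sample_b`, `r2`, plus
#'   per-group mean R^2 as attribute `"group_summary"`.
#' @export
replicate_r2 <- function(counts, groups = rep("all", ncol(counts))) {
  stopifnot(ncol(counts) >= 2, length(groups) == ncol(counts))
  lg <- log2(counts + 1)
  out <- NULL
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    cmb <- utils::combn(cols, 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      out <- rbind(out, data.frame(
        group = g,
        sample_a = colnames(counts)[a] %||% as.character(a),
        sample_b = colnames(counts)[b] %||% as.character(b),
        r2 = cor(lg[, a], lg[, b])^2,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) stop("no group has >= 2 samples", call. = FALSE)
  attr(out, "group_summary") <- tapply(out$r2, out$group, mean)
  out
}

#' Background fraction from no-input controls
#'
#' `(mean total reads of no-input samples) / (mean total reads of positive
#' samples)` -- the assay-background metric reported alongside replicate
#' correlations.
#'
#' @param counts numeric matrix, probes x samples.
#' @param no_input_samples,positive_samples column names or indices.
#' @return a single fraction.
#' @export
background_fraction <- function(counts, no_input_samples, positive_samples) {
  stopifnot(length(no_input_samples) > 0, length(positive_samples) > 0)
  pos <- mean(colSums(counts[, positive_samples, drop = FALSE]))
  if (pos == 0) stop("positive samples have zero total reads", call. = FALSE)
  neg <- mean(colSums(counts[, no_input_samples, drop = FALSE]))
  neg / pos
}

#' QC report for a processed run
#'
#' @param counts numeric matrix, probes x samples.
#' @param accounting data frame of per-sample read accounting
#'   (rows in column order of `counts`), or `NULL`.
#' @param groups replicate group labels per column.
#' @param no_input_samples optional no-input column names/indices.
#' @return list with `replicate_r2`, `group_summary`, `background_fraction`
#'   (or `NA`), and per-sample `mapped_fraction` / `misligation_fraction`
#'   when accounting is given.
#' @export
qc_report <- function(counts, accounting = NULL,
                      groups = rep("all", ncol(counts)),
                      no_input_samples = NULL) {
  pos <- setdiff(colnames(counts), no_input_samples)
  grp_pos <- groups[match(pos, colnames(counts))]
  r2 <- if (length(pos) >= 2) replicate_r2(counts[, pos, drop = FALSE], grp_pos) else NULL
  bg <- if (length(no_input_samples)) {
    background_fraction(counts, no_input_samples, pos)
  } else NA_real_
  list(replicate_r2 = r2,
       group_summary = if (!is.null(r2)) attr(r2, "group_summary") else NULL,
       background_fraction = bg,
       mapped_fraction = if (!is.null(accounting)) accounting$mapped_fraction else NULL,
       misligation_fraction = if (!is.null(accounting)) accounting$misligation_fraction else NULL)
}

#' Read/write a count matrix TSV
#'
#' First column `probe_id`, one column per sample. Lines starting with `#`
#' are artifact headers and are skipped on read.
#'
#' @param counts probes x samples matrix.
#' @param path file path.
#' @param seed,config optional stamps for the artifact header.
#' @return [write_counts()]: `path` invisibly; [read_counts()]: a numeric
#'   matrix with probe rownames.
#' @export
write_counts <- function(counts, path, seed = NA, config = NULL) {
  df <- data.frame(probe_id = rownames(counts), counts, check.names = FALSE)
  write_artifact_tsv(df, path, seed = seed, config = config)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read_artifact_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  storage.mode(m) <- "numeric"
  m
}
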