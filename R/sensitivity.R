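#' Molecules carried into the amplification reaction
#'
#' The assay builds its reaction additively (sample + annealing mix +
#' nuclease mix + ligase mix) and transfers a fixed volume of ligated
#' product into amplification, so only `transfer / sum(volumes)` of the
#' ligated molecules are amplified. With the standard step volumes
#' 2 + 2 + 24 + 24 uL and a 10 uL transfer, that fraction is 10/52 (~19%).
#'
#' @param input_molecules ligated molecules in the full reaction.
#' @param volumes additive step volumes in uL
#'   (default `c(sample = 2, annealing = 2, nuclease = 24, ligase = 24)`).
#' @param transfer_volume volume transferred to amplification (default 10).
#' @return molecules entering amplification
#'   (`input_molecules * transfer_volume / sum(volumes)`).
#' @export
molecules_in_amplification <- function(input_molecules,
                                       volumes = c(sample = 2, annealing = 2,
                                                   nuclease = 24, ligase = 24),
                                       transfer_volume = 10) {
  stopifnot(all(volumes > 0), transfer_volume > 0)
  reaction <- sum(volumes)
  if (transfer_volume > reaction) {
    stop("transfer volume exceeds the reaction volume", call. = FALSE)
  }
  input_molecules * transfer_volume / reaction
}

#' Fit the limit of detection from a molecule-titrated panel
#'
#' Least-squares fit of `log10(reads)` on `log10(molecules)` across probes
#' with known input molecule counts (spike-in style), after removing probes
#' whose replicate CV is at or above `cv_max` (noisy probes dominate near
#' the detection limit). Zero-read replicate points are excluded rather
#' than pseudocounted: the x-intercept, the molecule count at which the
#' fit predicts a single read, concerns the positive regime. Per-probe
#' x-intercepts (from mean reads per probe) are also reported with their
#' range, median and mean.
#'
#' @param reads numeric matrix, probes x replicates of read counts.
#' @param molecules named numeric vector: molecules per probe in the
#'   amplification reaction.
#' @param cv_max maximum replicate coefficient of variation (default 0.60).
#' @return a `lod_fit` list: `slope`, `intercept`, `r2`,
#'   `x_intercept_molecules`, `probes_used`, and `per_probe`
#'   (data frame with per-probe x-intercepts) plus its `range`, `median`,
#'   `mean`.
#' @export
fit_lod <- function(reads, molecules, cv_max = 0.60) {
  stopifnot(is.matrix(reads), nrow(reads) == length(molecules),
            all(molecules > 0))
  mu <- rowMeans(reads)
  if (ncol(reads) >= 2) {
    cv <- apply(reads, 1L, sd) / mu
    cv[!is.finite(cv)] <- Inf
  } else {
    cv <- rep(0, nrow(reads))   # no replicates: CV filter not applicable
  }
  keep <- cv < cv_max & mu > 0
  x <- log10(rep(molecules[keep], ncol(reads)))
  y <- suppressWarnings(log10(as.vector(reads[keep, , drop = FALSE])))
  ok <- is.finite(y)
  if (sum(ok) < 2) stop("fewer than 2 usable points for the fit", call. = FALSE)
  fit <- lm(y[ok] ~ x[ok])
  b0 <- unname(coef(fit)[1]); b1 <- unname(coef(fit)[2])
  ## reads = 1  <=>  log10 reads = 0  <=>  molecules = 10^(-b0/b1)
  x_int <- 10^(-b0 / b1)
  per <- data.frame(
    probe_id = rownames(reads)[keep] %||% as.character(which(keep)),
    molecules = molecules[keep],
    mean_reads = mu[keep],
    ## per-probe x-intercept: molecules per read at this probe's efficiency
    x_intercept = molecules[keep] / mu[keep],
    stringsAsFactors = FALSE
  )
  structure(list(
    slope = b1, intercept = b0,
    r2 = suppressWarnings(summary(fit)$r.squared),
    x_intercept_molecules = x_int,
    probes_used = per$probe_id,
    per_probe = per,
    per_probe_range = range(per$x_intercept),
    per_probe_median = median(per$x_intercept),
    per_probe_mean = mean(per$x_intercept)
  ), class = "lod_fit")
}

#' @export
print.lod_fit <- function(x, ...) {
  cat(sprintf(
    "lod_fit: slope %.3f, R2 %.3f, x-intercept %.1f molecules (per-probe %.0f-%.0f, median %.0f)\n",
    x$slope, x$r2, x$x_intercept_molecules,
    x$per_probe_range[1], x$per_probe_range[2], x$per_probe_median))
  invisible(x)
}

#' Minor-population detection across a dilution series
#'
#' For each marker gene, the detection threshold is the mean plus 3
#' standard deviations of its read counts in the 0% minor-population
#' control samples. At each dilution level, a gene is detected when its
#' mean count across replicates exceeds its threshold; the result is the
#' fraction of panel genes detected per level.
#'
#' @param counts numeric matrix, genes x samples.
#' @param panel character vector of marker genes (rownames of `counts`);
#'   missing genes are dropped with a warning.
#' @param control_samples columns of the 0% controls (>= 2).
#' @param dilution_series named list: level label -> columns of that
#'   level's replicates.
#' @return a data frame per level: `level`, `fraction_detected`,
#'   `n_detected`, `n_genes`; per-gene thresholds as attribute
#'   `"thresholds"`.
#' @export
minor_population_detection <- function(counts, panel, control_samples,
                                       dilution_series) {
  stopifnot(length(control_samples) >= 2)
  missing <- setdiff(panel, rownames(counts))
  if (length(missing)) {
    warning("panel genes absent from matrix, excluded: ",
            paste(missing, collapse = ", "))
    panel <- setdiff(panel, missing)
  }
  stopifnot(length(panel) > 0)
  ctrl <- counts[panel, control_samples, drop = FALSE]
  thr <- rowMeans(ctrl) + 3 * apply(ctrl, 1L, sd)
  out <- do.call(rbind, lapply(names(dilution_series), function(lv) {
    cols <- dilution_series[[lv]]
    mu <- rowMeans(counts[panel, cols, drop = FALSE])
    det <- mu > thr
    data.frame(level = lv, fraction_detected = mean(det),
               n_detected = sum(det), n_genes = length(panel),
               stringsAsFactors = FALSE)
  }))
  attr(out, "thresholds") <- thr
  out
}

#' Marker-gene panels for minor-population detection
#'
#' The two published breast-line marker panels used to detect a minor cell
#' population diluted into the other line: 14 MCF-7-specific genes and 13
#' MDA-MB-231-specific genes.
#'
#' @param name `"MCF7_minor"` or `"MDAMB231_minor"`.
#' @return character vector of gene symbols.
#' @export
load_panel <- function(name) {
  panels <- list(
    MCF7_minor = c("ARHGAP8", "CBS", "GREB1", "GSTT1", "HIST1H1B",
                   "HIST1H2BH", "HIST1H4E", "IGFBP2", "IRX2", "LAD1",
                   "SLC6A14", "SULF2", "TBX2", "TFF1"),
    MDAMB231_minor = c("ACSL5", "BDNF", "C4BPB", "CDA", "CNN3", "EDIL3",
                       "ETS1", "HMGA2", "IFI16", "LDHB", "MYL9", "PTX3",
                       "WBP5")
  )
  if (!name %in% names(panels)) {
    stop("unknown panel '", name, "'; available: ",
         paste(names(panels), collapse = ", "), call. = FALSE)
  }
  panels[[name]]
}
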