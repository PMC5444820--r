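#' Median-of-ratios size factors
#'
#' Per-sample depth factors computed against a geometric-mean reference
#' profile: for each sample, the median over probes (restricted to probes
#' with all-positive counts) of `count / geometric mean across samples`.
#' Columns that are exact scalar multiples of one another recover those
#' scalars up to a common constant.
#'
#' @param counts numeric matrix, probes x samples.
#' @return numeric vector of size factors, one per column.
#' @export
estimate_size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no probe has positive counts in every sample", call. = FALSE)
  log_gm <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2L, function(col) {
    exp(median(log(col) - log_gm))
  })
  unname(sf)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' The FDR-controlling step-up adjustment: sort p ascending, compute
#' `p_(i) * m / i`, enforce monotonicity by a reverse cumulative minimum,
#' cap at 1, and restore the original order. `NA`s are passed through and
#' excluded from `m`.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv)
  adj <- pv[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out[ok][o] <- adj
  out
}

#' Negative-binomial differential expression between two groups
#'
#' A two-group NB Wald test in the style of count-based DE tools:
#' \enumerate{
#'   \item size factors by median-of-ratios ([estimate_size_factors()]);
#'   \item per-probe dispersion by method of moments on normalized counts
#'     (pooled within-group variance), shrunk toward a fitted parametric
#'     mean-dispersion trend `a0 + a1/mean` and floored at the trend --
#'     raw moment estimates are unstable at 3 replicates, and flooring at
#'     the trend keeps the test conservative there;
#'   \item Wald statistic on `log2(mean_B / mean_A)` with a delta-method
#'     standard error, referred to a t distribution with `n - 2` degrees of
#'     freedom (the dispersion is estimated from few replicates, so normal
#'     tails would be anti-conservative);
#'   \item Benjamini-Hochberg adjustment over tested probes.
#' }
#' Probes with zero counts in all samples are excluded from testing; probes
#' expressed in only one group get `log2FC = +/-Inf` and no p-value.
#'
#' @param counts integer matrix, probes x samples (raw counts).
#' @param group_a,group_b column names or indices of the two groups
#'   (disjoint; at least 2 replicates each, 3 to match common practice).
#' @param alpha significance level stored on the result (default 0.05).
#' @return a `de_result` data frame: `probe_id`, `baseMean`, `log2FC`,
#'   `pvalue`, `padj`.
#' @export
run_de <- function(counts, group_a, group_b, alpha = 0.05) {
  if (is.character(group_a)) group_a <- match(group_a, colnames(counts))
  if (is.character(group_b)) group_b <- match(group_b, colnames(counts))
  stopifnot(!anyNA(group_a), !anyNA(group_b))
  if (length(intersect(group_a, group_b))) {
    stop("groups overlap", call. = FALSE)
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)

  keep <- rowSums(sub) > 0
  sf <- estimate_size_factors(sub)
  q <- sweep(sub, 2L, sf, `/`)          # normalized counts

  base_mean <- rowMeans(q)
  mu_a <- rowMeans(q[, ia, drop = FALSE])
  mu_b <- rowMeans(q[, ib, drop = FALSE])

  ## pooled within-group method-of-moments dispersion on normalized counts:
  ## Var(K/s) = mu/s + alpha*mu^2, so alpha = (s2 - mu*mean(1/s)) / mu^2
  na <- length(ia); nb <- length(ib)
  ssa <- rowSums((q[, ia, drop = FALSE] - mu_a)^2)
  ssb <- rowSums((q[, ib, drop = FALSE] - mu_b)^2)
  s2 <- (ssa + ssb) / (na + nb - 2)
  inv_s <- mean(1 / sf)
  disp_mom <- (s2 - base_mean * inv_s) / base_mean^2
  disp_mom[!is.finite(disp_mom)] <- NA_real_

  disp_trend <- fit_dispersion_trend(base_mean, disp_mom)
  excess <- pmax(disp_mom - disp_trend, 0)
  excess[is.na(excess)] <- 0
  disp <- pmax(disp_trend + 0.5 * excess, 1e-8)

  ## delta-method variance of log2(mu) per group
  var_log2_mean <- function(cols, mu, n) {
    v <- sweep(matrix(mu, nrow = length(mu), ncol = length(cols)), 2L,
               sf[cols], `/`) + disp * mu^2
    rowSums(v) / (n^2 * mu^2 * log(2)^2)
  }
  lfc <- log2(mu_b / mu_a)
  se <- sqrt(var_log2_mean(ia, mu_a, na) + var_log2_mean(ib, mu_b, nb))
  stat <- lfc / se
  df <- na + nb - 2
  pval <- 2 * pt(-abs(stat), df = df)

  testable <- keep & is.finite(lfc) & is.finite(se) & se > 0
  ## identical groups give se = 0 and lfc = 0: define p = 1, not NA
  degenerate <- keep & is.finite(lfc) & lfc == 0 & (!is.finite(se) | se == 0)
  pval[!testable] <- NA_real_
  pval[degenerate] <- 1
  lfc[keep & mu_a == 0 & mu_b > 0] <- Inf
  lfc[keep & mu_b == 0 & mu_a > 0] <- -Inf
  lfc[!keep] <- NA_real_

  res <- data.frame(
    probe_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    baseMean = base_mean,
    log2FC = lfc,
    pvalue = pval,
    padj = bh_adjust(ifelse(keep, pval, NA_real_)),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "size_factors") <- sf
  attr(res, "dispersion") <- disp
  class(res) <- c("de_result", "data.frame")
  res
}

## parametric mean-dispersion trend a0 + a1/mean. Per-probe moment
## estimates are far too noisy at 2-3 replicates to regress on directly
## (spurious huge values at low means drag the fit), so probes are binned
## by mean and the trend is fitted to bin medians, which are robust to the
## heavy upper tail of the moment estimator.
fit_dispersion_trend <- function(base_mean, disp_mom, n_bins = 20L) {
  ok <- which(is.finite(disp_mom) & base_mean > 0)
  a0 <- 1e-8; a1 <- 0
  if (length(ok) >= 20) {
    r <- rank(base_mean[ok], ties.method = "first")
    bin <- ceiling(r / (length(ok) / min(n_bins, floor(length(ok) / 5))))
    med_y <- tapply(disp_mom[ok], bin, median)
    med_x <- tapply(1 / base_mean[ok], bin, mean)
    if (length(med_y) >= 3) {
      fit <- lm(med_y ~ med_x)
      a0 <- max(unname(coef(fit)[1]), 1e-8)
      a1 <- max(unname(coef(fit)[2]), 0)
      if (is.na(a1)) a1 <- 0
    }
  }
  pmax(a0 + a1 / pmax(base_mean, .Machine$double.eps), 1e-8)
}

#' @export
print.de_result <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  n_sig <- sum(x$padj < alpha, na.rm = TRUE)
  cat(sprintf("de_result: %d probes tested, %d with padj < %g\n",
              sum(!is.na(x$pvalue)), n_sig, alpha))
  invisible(x)
}

#' Low-count filter for cross-platform comparison
#'
#' Retains genes with at least `threshold` reads in every sample on both
#' platforms -- the rule used before comparing fold changes across
#' platforms, to avoid artefactual ratios from small denominators.
#'
#' @param matrix_a,matrix_b count matrices (genes x samples) with shared
#'   rownames.
#' @param threshold minimum reads (default 20; "fewer than 20" is removed).
#' @return character vector of retained gene identifiers.
#' @export
low_count_filter <- function(matrix_a, matrix_b, threshold = 20) {
  shared <- intersect(rownames(matrix_a), rownames(matrix_b))
  ok_a <- rowSums(matrix_a[shared, , drop = FALSE] >= threshold) ==
    ncol(matrix_a)
  ok_b <- rowSums(matrix_b[shared, , drop = FALSE] >= threshold) ==
    ncol(matrix_b)
  shared[ok_a & ok_b]
}

#' Compare fold changes between two platforms
#'
#' @param de_a,de_b `de_result` data frames (or any data frames with
#'   `probe_id` and `log2FC`).
#' @param retained gene/probe identifiers to compare (e.g. from
#'   [low_count_filter()]).
#' @return list with `table` (per-gene paired log2FCs) and `r2` (Pearson
#'   R^2 of the pairing).
#' @export
compare_foldchanges <- function(de_a, de_b, retained) {
  stopifnot(length(retained) > 0)
  fa <- de_a$log2FC[match(retained, de_a$probe_id)]
  fb <- de_b$log2FC[match(retained, de_b$probe_id)]
  ok <- is.finite(fa) & is.finite(fb)
  tab <- data.frame(probe_id = retained[ok], log2FC_a = fa[ok],
                    log2FC_b = fb[ok], stringsAsFactors = FALSE)
  list(table = tab, r2 = cor(tab$log2FC_a, tab$log2FC_b)^2)
}

#' Check measured fold changes against a known mixture design
#'
#' For libraries built from designed mixtures (e.g. two reference RNAs
#' blended 60:40 vs 50:50), compares per-probe measured `log2FC` with the
#' design-expected `log2FC`.
#'
#' @param counts_a,counts_b count matrices (probes x replicates) for the
#'   two mixes; normalized internally to equal totals.
#' @param design_ratios named vector of expected linear fold changes (B/A)
#'   per probe.
#' @return list with `table` (`probe_id`, `measured_log2FC`,
#'   `expected_log2FC`) and `r2`.
#' @export
known_ratio_check <- function(counts_a, counts_b, design_ratios) {
  ids <- names(design_ratios)
  stopifnot(all(ids %in% rownames(counts_a)), all(ids %in% rownames(counts_b)))
  na <- normalize_total(cbind(counts_a, counts_b))
  ma <- rowMeans(na[ids, seq_len(ncol(counts_a)), drop = FALSE])
  mb <- rowMeans(na[ids, ncol(counts_a) + seq_len(ncol(counts_b)), drop = FALSE])
  tab <- data.frame(probe_id = ids,
                    measured_log2FC = log2(mb / ma),
                    expected_log2FC = log2(unname(design_ratios)),
                    stringsAsFactors = FALSE)
  ok <- is.finite(tab$measured_log2FC)
  r2 <- if (sum(ok) > 1 && sd(tab$expected_log2FC[ok]) > 0) {
    cor(tab$measured_log2FC[ok], tab$expected_log2FC[ok])^2
  } else NA_real_
  list(table = tab, r2 = r2)
}

#' Designed fold changes of a two-component mixture pair
#'
#' For transcripts with abundance `u` in component 1 and `b` in component
#' 2, mixing proportions `p1` vs `p2` give the expected linear fold change
#' `(p2[1] u + p2[2] b) / (p1[1] u + p1[2] b)`. A transcript exclusive to
#' component 1 changes by `p2[1]/p1[1]`; for 60/40 vs 50/50 the designed
#' fold differences therefore span `[40/50, 60/50]`, at most 1.2-fold.
#'
#' @param abund_1,abund_2 named abundance vectors of the two components
#'   (same probe universe).
#' @param p1,p2 mixing proportions (length-2, summing to 1) of the two
#'   mixtures.
#' @return named vector of expected linear fold changes (mix2 / mix1).
#' @export
mixture_fold_changes <- function(abund_1, abund_2, p1, p2) {
  stopifnot(length(p1) == 2, length(p2) == 2,
            abs(sum(p1) - 1) < 1e-9, abs(sum(p2) - 1) < 1e-9,
            identical(names(abund_1), names(abund_2)))
  (p2[1] * abund_1 + p2[2] * abund_2) / (p1[1] * abund_1 + p1[2] * abund_2)
}
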