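#' Rank-profile utilities and compound-signature extraction
#'
#' A rank profile set is a genes x samples integer matrix in which each
#' column is a permutation of `1..N`: rank 1 is the most up-regulated gene
#' in that sample's compound-response profile, rank N the most
#' down-regulated (the convention is fixed package-wide). These emulate the
#' ranked profiles exported by compound-connectivity databases.
#'
#' @param ranks genes x samples integer matrix.
#' @param cell_type character vector of per-sample cell-type labels.
#' @return a `rank_profile_set` (the matrix with a `cell_type` attribute).
#' @export
rank_profile_set <- function(ranks, cell_type = rep("cell", ncol(ranks))) {
  stopifnot(is.matrix(ranks), length(cell_type) == ncol(ranks),
            !is.null(rownames(ranks)))
  n <- nrow(ranks)
  for (j in seq_len(ncol(ranks))) {
    if (!identical(sort(as.integer(ranks[, j])), seq_len(n))) {
      stop("column ", j, " is not a permutation of 1..", n, call. = FALSE)
    }
  }
  structure(ranks, cell_type = cell_type, class = c("rank_profile_set",
                                                    class(ranks)))
}

#' Remove outlier samples by PCA distance
#'
#' Per cell type: columns are centred and scaled per gene, projected onto
#' the first two principal components, and samples whose distance from the
#' component-space centroid exceeds `sd_cut` standard deviations of the
#' distances are dropped. A single pass; refusing to drop more than half a
#' cell type's samples (that indicates a data problem, not outliers).
#'
#' @param ranks a [rank_profile_set()] (or plain genes x samples matrix).
#' @param sd_cut distance cutoff in SD units (default 3).
#' @param cell_type per-sample labels (defaults to the attribute).
#' @return list with `retained` (column indices kept), `removed`, and
#'   `distances` (named per-sample PC-space distance).
#' @export
remove_outlier_samples <- function(ranks, sd_cut = 3,
                                   cell_type = attr(ranks, "cell_type")) {
  if (is.null(cell_type)) cell_type <- rep("cell", ncol(ranks))
  removed <- integer(0)
  distances <- numeric(ncol(ranks))
  for (ct in unique(cell_type)) {
    cols <- which(cell_type == ct)
    if (length(cols) < 4) {
      stop("cell type '", ct, "' has fewer than 4 samples", call. = FALSE)
    }
    x <- t(scale(t(ranks[, cols, drop = FALSE])))  # centre/scale per gene
    x[!is.finite(x)] <- 0
    pc <- prcomp(t(x), center = TRUE, scale. = FALSE, rank. = 2)
    sc <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
    ctr <- colMeans(sc)
    d <- sqrt(rowSums(sweep(sc, 2L, ctr)^2))
    distances[cols] <- d
    drop <- cols[d > sd_cut * sd(d)]
    if (length(drop) > length(cols) / 2) {
      stop("outlier rule would drop more than half of cell type '", ct,
           "'", call. = FALSE)
    }
    removed <- c(removed, drop)
  }
  names(distances) <- colnames(ranks)
  list(retained = setdiff(seq_len(ncol(ranks)), removed),
       removed = removed, distances = distances)
}

#' Median rank per gene
#'
#' @param ranks genes x samples rank matrix (outliers already removed).
#' @return named numeric vector of per-gene median ranks, in rownames
#'   order; downstream ties are broken by gene identifier order.
#' @export
median_rank <- function(ranks) {
  setNames(apply(ranks, 1L, median), rownames(ranks))
}

#' Extract the extreme (top/bottom) signature from median ranks
#'
#' `up` = the `floor(frac * N)` genes with the smallest median rank (most
#' up-regulated), `down` = the same number with the largest; each ordered
#' by median rank, ties broken by gene identifier.
#'
#' @param medians named median-rank vector ([median_rank()]).
#' @param frac tail fraction (default 0.05).
#' @return a `signature_set` list with `up` and `down` gene vectors.
#' @export
extreme_sets <- function(medians, frac = 0.05) {
  stopifnot(frac > 0, frac < 0.5)
  n <- length(medians)
  k <- floor(frac * n)
  if (k == 0) {
    warning("tail fraction selects zero genes")
    return(structure(list(up = character(0), down = character(0)),
                     class = "signature_set"))
  }
  ord_up <- order(medians, names(medians))
  ord_down <- order(-medians, names(medians))
  structure(list(up = names(medians)[ord_up][seq_len(k)],
                 down = names(medians)[ord_down][seq_len(k)]),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d up, %d down\n", length(x$up),
              length(x$down)))
  invisible(x)
}

#' Intersect signatures across cell types
#'
#' Genes common to every cell type's signature, per direction, ordered by
#' mean median-rank when `medians_list` is supplied (lexical otherwise).
#'
#' @param sets list of `signature_set`s (>= 2), one per cell type.
#' @param medians_list optional list of median-rank vectors matching
#'   `sets`, used to order the output.
#' @return a `signature_set` with the common `up` and `down` genes.
#' @export
intersect_signatures <- function(sets, medians_list = NULL) {
  stopifnot(length(sets) >= 2)
  common <- function(dir) {
    g <- Reduce(intersect, lapply(sets, `[[`, dir))
    if (!is.null(medians_list) && length(g)) {
      mr <- rowMeans(matrix(sapply(medians_list, function(m) m[g]),
                            nrow = length(g)))
      g <- g[order(mr, g)]
      if (dir == "down") g <- rev(g)
    } else {
      g <- sort(g)
    }
    g
  }
  structure(list(up = common("up"), down = common("down")),
            class = "signature_set")
}

#' Middle-band genes (no significant rank response)
#'
#' Genes whose median rank lies within `width_frac * N` of the rank-scale
#' midpoint `N/2` -- where compound response is not significant in the
#' ranked profiles. `mode = "percentile"` instead takes the central
#' `2 * width_frac` percentile band of the median ranks.
#'
#' @param medians named median-rank vector.
#' @param width_frac half-width as a fraction of `N` (default 0.10).
#' @param mode `"rank"` (distance from `N/2`, the default reading) or
#'   `"percentile"`.
#' @return character vector of middle-band genes, gene-id ordered.
#' @export
middle_band <- function(medians, width_frac = 0.10, mode = c("rank",
                                                             "percentile")) {
  stopifnot(width_frac > 0, width_frac < 0.5)
  mode <- match.arg(mode)
  n <- length(medians)
  sel <- if (mode == "rank") {
    abs(medians - n / 2) <= width_frac * n
  } else {
    lo <- quantile(medians, 0.5 - width_frac)
    hi <- quantile(medians, 0.5 + width_frac)
    medians >= lo & medians <= hi
  }
  sort(names(medians)[sel])
}

#' Candidate novel responders: middle-band genes significant by DE
#'
#' Genes that sit in the middle of the ranked database profiles (no
#' reported response) yet test significant in the assay's own differential
#' expression -- the candidates the database missed.
#'
#' @param middle character vector of middle-band genes (harmonized gene
#'   symbols).
#' @param de a `de_result` (probe/gene ids must be the same symbols).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return character vector of candidate genes, gene-id ordered.
#' @export
novel_candidates <- function(middle, de, alpha = 0.05) {
  if (!length(middle)) return(character(0))
  sig <- de$probe_id[!is.na(de$padj) & de$padj < alpha]
  sort(intersect(middle, sig))
}

#' Split genes by known-association status
#'
#' Partitions a gene set by a curated chemical-gene association table
#' (e.g. an export in the style of a toxicogenomics database): genes
#' flagged as associated are `known`, covered-but-unflagged genes are
#' `novel`, and genes absent from the table are reported separately as
#' `uncovered`.
#'
#' @param genes character vector of query genes.
#' @param table data frame with columns `gene` and `flag` (logical or
#'   0/1), or a named logical vector.
#' @return list with `known`, `novel`, `uncovered` (each gene-id ordered).
#' @export
novelty_split <- function(genes, table) {
  if (is.data.frame(table)) {
    flags <- setNames(as.logical(table$flag), table$gene)
  } else {
    flags <- as.logical(table)
    names(flags) <- names(table)
  }
  covered <- genes[genes %in% names(flags)]
  uncovered <- setdiff(genes, covered)
  list(known = sort(covered[flags[covered]]),
       novel = sort(covered[!flags[covered]]),
       uncovered = sort(uncovered))
}

#' Enrichment of a query signature in one ranked profile
#'
#' A documented, deterministic stand-in for proprietary connectivity
#' scores: hypergeometric enrichment of the query's up genes in the
#' profile's top `frac` ranks and of its down genes in the bottom `frac`,
#' combined by Fisher's method (chi-squared with 4 df). Mid-p
#' hypergeometric tails are used so that null combined p-values are close
#' to uniform despite the discreteness of the overlaps. If the *reversed*
#' query (up in bottom, down in top) scores more strongly, the profile is
#' flagged anticorrelated.
#'
#' @param query a `signature_set`.
#' @param profile one rank-profile column: named integer vector of ranks
#'   (1 = most up-regulated).
#' @param frac extreme fraction of the profile used per direction
#'   (default 0.05).
#' @return list with `p_combined`, `p_up`, `p_down`, `overlap_up`,
#'   `overlap_down`, `anticorrelated` (logical), `p_reverse`.
#' @export
overlap_score <- function(query, profile, frac = 0.05) {
  stopifnot(all(c(query$up, query$down) %in% names(profile)))
  n <- length(profile)
  k <- max(1L, floor(frac * n))
  top <- names(profile)[profile <= k]
  bottom <- names(profile)[profile > n - k]
  score <- function(up, down) {
    pu <- hyper_midp(length(intersect(up, top)), length(up), k, n)
    pd <- hyper_midp(length(intersect(down, bottom)), length(down), k, n)
    stat <- -2 * (log(pu) + log(pd))
    list(p = pchisq(stat, df = 4, lower.tail = FALSE), pu = pu, pd = pd)
  }
  fwd <- score(query$up, query$down)
  rev_ <- score(query$down, query$up)
  list(p_combined = fwd$p, p_up = fwd$pu, p_down = fwd$pd,
       overlap_up = length(intersect(query$up, top)),
       overlap_down = length(intersect(query$down, bottom)),
       anticorrelated = rev_$p < fwd$p,
       p_reverse = rev_$p)
}

## mid-p upper-tail hypergeometric: P(X > x) + 0.5 P(X = x)
hyper_midp <- function(x, m_query, k_tail, n_total) {
  p_gt <- phyper(x, k_tail, n_total - k_tail, m_query, lower.tail = FALSE)
  p_eq <- stats::dhyper(x, k_tail, n_total - k_tail, m_query)
  max(min(p_gt + 0.5 * p_eq, 1), .Machine$double.xmin)
}

#' Simulate ranked compound-response profiles
#'
#' Synthetic-data generator for the signature pipeline. Each sample's
#' profile is the rank of `signal + noise`, where planted `up_genes` get a
#' strong negative score (rank toward 1) and `down_genes` a strong
#' positive score, in every non-outlier sample of every cell type.
#' Planted outlier samples are independent random permutations.
#'
#' @param n_genes universe size.
#' @param samples_per_type named integer vector: cell type -> sample count.
#' @param up_genes,down_genes planted responsive genes (character).
#' @param n_outliers outlier samples per cell type.
#' @param effect planted score magnitude in noise-SD units (default 3).
#' @param seed integer seed.
#' @return a [rank_profile_set()] with attribute `"outliers"` (column
#'   indices of the planted outliers).
#' @export
simulate_rank_profiles <- function(n_genes, samples_per_type,
                                   up_genes = character(0),
                                   down_genes = character(0),
                                   n_outliers = 0, effect = 3, seed = 1L) {
  set.seed(substream_seed(seed, "rank_profiles"))
  genes <- sprintf("G%05d", seq_len(n_genes))
  stopifnot(all(c(up_genes, down_genes) %in% genes))
  cols <- list(); labels <- character(0); outlier_cols <- integer(0)
  base_sig <- setNames(numeric(n_genes), genes)
  base_sig[up_genes] <- -effect
  base_sig[down_genes] <- effect
  for (ct in names(samples_per_type)) {
    n_s <- samples_per_type[[ct]]
    ## per-cell-type baseline expression ordering, shared by its samples
    baseline <- rnorm(n_genes)
    for (s in seq_len(n_s)) {
      score <- base_sig + 0.5 * baseline + rnorm(n_genes)
      cols[[length(cols) + 1L]] <- rank(score, ties.method = "first")
      labels <- c(labels, ct)
    }
    for (s in seq_len(n_outliers)) {
      cols[[length(cols) + 1L]] <- sample.int(n_genes)
      labels <- c(labels, ct)
      outlier_cols <- c(outlier_cols, length(cols))
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- genes
  colnames(m) <- sprintf("%s_s%02d", labels, stats::ave(seq_along(labels),
                                                        labels, FUN = seq_along))
  out <- rank_profile_set(m, cell_type = labels)
  attr(out, "outliers") <- outlier_cols
  out
}

#' Read/write rank profiles and signatures (TSV)
#'
#' Rank profiles: genes x samples TSV whose header row carries cell-type
#' labels as `label.n` column names; signatures: two-column TSV
#' (`gene`, `direction`).
#'
#' @param path file path.
#' @param ranks a [rank_profile_set()].
#' @param sig a `signature_set`.
#' @return readers return the corresponding object.
#' @export
write_rank_profiles <- function(ranks, path) {
  df <- data.frame(gene = rownames(ranks), as.data.frame(unclass(ranks)),
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cell_type\t", paste(attr(ranks, "cell_type"),
                                           collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rank_profiles
#' @export
read_rank_profiles <- function(path) {
  first <- readLines(path, n = 1L)
  ct <- strsplit(sub("^# cell_type\t", "", first), "\t")[[1]]
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "integer"
  rank_profile_set(m, cell_type = ct)
}

#' @rdname write_rank_profiles
#' @export
write_signature <- function(sig, path) {
  df <- data.frame(gene = c(sig$up, sig$down),
                   direction = rep(c("up", "down"),
                                   c(length(sig$up), length(sig$down))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rank_profiles
#' @export
read_signature <- function(path) {
  df <- read.delim(path, comment.char = "#")
  structure(list(up = df$gene[df$direction == "up"],
                 down = df$gene[df$direction == "down"]),
            class = "signature_set")
}
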