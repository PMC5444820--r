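#' Construct a detector-oligo probe pool
#'
#' A probe pool is the manifest of detector-oligo (DO) pairs used by a
#' ligation assay. Each pair targets one 50-nt window of a transcript: a
#' downstream arm whose 3' end sits at the ligation junction and an upstream
#' arm whose 5' end sits at the junction. Successful ligation creates the
#' 50-nt template `downstream_arm + upstream_arm` that is amplified and
#' sequenced. High-abundance targets may carry a non-zero attenuation ratio
#' `a` (attenuator:functional DO), which reduces their expected signal by the
#' factor `a + 1` (see [expected_counts()] and [backcalculate_attenuation()]).
#'
#' @param probe_id unique probe identifiers.
#' @param gene_id gene symbol per probe.
#' @param downstream_arm 25-nt uppercase DNA, 3' end at the junction.
#' @param upstream_arm 25-nt uppercase DNA, 5' end at the junction.
#' @param attenuation_ratio non-negative attenuator:functional ratio
#'   (0 = unattenuated). Recycled if length 1.
#' @param name pool name.
#' @return an object of class `probe_pool`: a data frame with one row per
#'   DO pair and a `ligated` column holding the 50-mer.
#' @export
probe_pool <- function(probe_id, gene_id, downstream_arm, upstream_arm,
                       attenuation_ratio = 0, name = "pool") {
  n <- length(probe_id)
  attenuation_ratio <- rep_len(attenuation_ratio, n)
  pool <- data.frame(
    probe_id = as.character(probe_id),
    gene_id = as.character(gene_id),
    downstream_arm = as.character(downstream_arm),
    upstream_arm = as.character(upstream_arm),
    attenuation_ratio = as.numeric(attenuation_ratio),
    stringsAsFactors = FALSE
  )
  check_pool_fields(pool)
  pool$ligated <- paste0(pool$downstream_arm, pool$upstream_arm)
  attr(pool, "name") <- name
  class(pool) <- c("probe_pool", "data.frame")
  pool
}

check_pool_fields <- function(pool) {
  bad_seq <- function(x, width) {
    nchar(x) != width | grepl("[^ACGT]", x)
  }
  for (field in c("downstream_arm", "upstream_arm")) {
    bad <- which(bad_seq(pool[[field]], 25L))
    if (length(bad)) {
      stop(sprintf("row %d: %s is not 25-nt uppercase DNA ('%s')",
                   bad[1], field, pool[[field]][bad[1]]), call. = FALSE)
    }
  }
  dup <- which(duplicated(pool$probe_id))
  if (length(dup)) {
    stop(sprintf("row %d: duplicate probe_id '%s'", dup[1], pool$probe_id[dup[1]]),
         call. = FALSE)
  }
  bad <- which(is.na(pool$attenuation_ratio) | pool$attenuation_ratio < 0)
  if (length(bad)) {
    stop(sprintf("row %d: attenuation_ratio must be a non-negative number",
                 bad[1]), call. = FALSE)
  }
  invisible(pool)
}

#' @export
print.probe_pool <- function(x, ...) {
  cat(sprintf("probe_pool '%s': %d DO pairs, %d genes, %d attenuated\n",
              attr(x, "name") %||% "pool", nrow(x),
              length(unique(x$gene_id)), sum(x$attenuation_ratio > 0)))
  invisible(x)
}

#' Read a probe manifest (TSV)
#'
#' The manifest is a UTF-8 tab-separated file with header columns
#' `probe_id`, `gene_id`, `downstream_arm`, `upstream_arm`,
#' `attenuation_ratio`. Row order is preserved.
#'
#' @param path file path.
#' @param name pool name (defaults to the file name).
#' @return a validated [probe_pool()].
#' @export
read_manifest <- function(path, name = basename(path)) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   colClasses = "character")
  need <- c("probe_id", "gene_id", "downstream_arm", "upstream_arm",
            "attenuation_ratio")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ratio <- suppressWarnings(as.numeric(df$attenuation_ratio))
  bad <- which(is.na(ratio) & nzchar(df$attenuation_ratio))
  if (length(bad)) {
    stop(sprintf("row %d: attenuation_ratio '%s' is not numeric",
                 bad[1], df$attenuation_ratio[bad[1]]), call. = FALSE)
  }
  probe_pool(df$probe_id, df$gene_id, df$downstream_arm, df$upstream_arm,
             ratio, name = name)
}

#' Write a probe manifest (TSV)
#'
#' Inverse of [read_manifest()]: `read_manifest(write_manifest(pool, f))`
#' returns a pool equal to `pool`.
#'
#' @param pool a [probe_pool()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(pool, path) {
  df <- as.data.frame(pool)[, c("probe_id", "gene_id", "downstream_arm",
                                "upstream_arm", "attenuation_ratio")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a probe pool for junction specificity
#'
#' The assay's single-base specificity rests on every ligation junction being
#' unique across gene targets: a read is only informative if the `2k`-nt
#' window spanning the junction (last `k` nt of the downstream arm plus first
#' `k` nt of the upstream arm) identifies one gene. This validator reports
#' duplicate ligated 50-mers and cross-gene junction-window collisions; it
#' never throws.
#'
#' @param pool a [probe_pool()].
#' @param junction_k window half-width in nt (1--25); default 3, matching the
#'   -3..+3 positions where a single mismatch measurably suppresses ligation.
#' @return a list with `pass` (logical), `duplicate_ligated` (data frame of
#'   probe pairs sharing a 50-mer) and `junction_conflicts` (data frame of
#'   cross-gene probe pairs sharing a junction window).
#' @export
validate_pool <- function(pool, junction_k = 3L) {
  stopifnot(inherits(pool, "probe_pool"), nrow(pool) > 0,
            junction_k >= 1, junction_k <= 25)
  k <- as.integer(junction_k)
  window <- paste0(substr(pool$downstream_arm, 26L - k, 25L),
                   substr(pool$upstream_arm, 1L, k))

  dup_pairs <- collision_pairs(pool$probe_id, pool$ligated)
  win_pairs <- collision_pairs(pool$probe_id, window, pool$gene_id)

  structure(list(
    pass = nrow(dup_pairs) == 0L && nrow(win_pairs) == 0L,
    junction_k = k,
    duplicate_ligated = dup_pairs,
    junction_conflicts = win_pairs
  ), class = "pool_validation")
}

## all unordered probe pairs sharing a key; if gene given, only cross-gene pairs
collision_pairs <- function(ids, key, gene = NULL) {
  out <- data.frame(probe_a = character(), probe_b = character(),
                    key = character(), stringsAsFactors = FALSE)
  groups <- split(seq_along(key), key)
  groups <- groups[lengths(groups) > 1L]
  for (g in groups) {
    cmb <- utils::combn(g, 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      if (!is.null(gene) && gene[a] == gene[b]) next
      out <- rbind(out, data.frame(probe_a = ids[a], probe_b = ids[b],
                                   key = key[a], stringsAsFactors = FALSE))
    }
  }
  out
}

#' @export
print.pool_validation <- function(x, ...) {
  cat(sprintf("pool validation (junction_k = %d): %s\n", x$junction_k,
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  duplicate ligated 50-mers: %d\n", nrow(x$duplicate_ligated)))
  cat(sprintf("  cross-gene junction conflicts: %d\n", nrow(x$junction_conflicts)))
  invisible(x)
}

#' Probes shared between two pools
#'
#' Returns the probe ids whose ligated 50-mers occur (with the same id) in
#' both pools, e.g. to compare measurements of a common probe set in two
#' different pool contexts. Symmetric in its arguments.
#'
#' @param a,b [probe_pool()] objects.
#' @return character vector of shared probe ids.
#' @export
pool_intersection <- function(a, b) {
  stopifnot(inherits(a, "probe_pool"), inherits(b, "probe_pool"))
  key_a <- paste(a$probe_id, a$ligated)
  key_b <- paste(b$probe_id, b$ligated)
  a$probe_id[key_a %in% key_b]
}

#' Read or write a sample sheet (CSV)
#'
#' A sample sheet maps each sample to its dual 9-nt indexes. Columns:
#' `sample_id`, `index1`, `index2`.
#'
#' @param path file path.
#' @return data frame with validated sheet.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet sample-sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.csv(sheet[, c("sample_id", "index1", "index2")], path,
                   quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_sample_sheet
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "index1", "index2")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (field in c("index1", "index2")) {
    bad <- which(nchar(sheet[[field]]) != 9L | grepl("[^ACGT]", sheet[[field]]))
    if (length(bad)) {
      stop(sprintf("row %d: %s must be 9-nt uppercase DNA", bad[1], field),
           call. = FALSE)
    }
  }
  if (anyDuplicated(paste(sheet$index1, sheet$index2))) {
    stop("index pairs must be unique within a sample sheet", call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("sample_id must be unique within a sample sheet", call. = FALSE)
  }
  sheet
}

#' Generate a random probe pool
#'
#' Synthetic-data generator for DO pools: arms are uniform random DNA,
#' redrawn until probe 50-mers and cross-gene junction windows are unique,
#' so generated pools always pass [validate_pool()]. One probe per gene by
#' default.
#'
#' @param n_probes number of DO pairs.
#' @param seed integer seed.
#' @param attenuated_fraction fraction of probes given a non-zero
#'   attenuation ratio.
#' @param attenuation_ratios ratios sampled for attenuated probes.
#' @param junction_k junction window half-width used for the uniqueness
#'   screen.
#' @param name pool name.
#' @return a [probe_pool()].
#' @export
random_pool <- function(n_probes, seed = 1L, attenuated_fraction = 0,
                        attenuation_ratios = c(4, 9, 19), junction_k = 3L,
                        name = "random_pool") {
  set.seed(substream_seed(seed, "pool"))
  down <- random_dna(n_probes, 25L)
  up <- random_dna(n_probes, 25L)
  k <- as.integer(junction_k)
  win <- function(d, u) paste0(substr(d, 26L - k, 25L), substr(u, 1L, k))
  ## redraw any probe whose junction window collides with an earlier one
  for (iter in 1:50) {
    w <- win(down, up)
    dup <- which(duplicated(w) | duplicated(paste0(down, up)))
    if (!length(dup)) break
    down[dup] <- random_dna(length(dup), 25L)
    up[dup] <- random_dna(length(dup), 25L)
  }
  ratio <- numeric(n_probes)
  n_att <- round(attenuated_fraction * n_probes)
  if (n_att > 0) {
    idx <- sample.int(n_probes, n_att)
    ratio[idx] <- sample(attenuation_ratios, n_att, replace = TRUE)
  }
  probe_pool(
    probe_id = sprintf("P%05d", seq_len(n_probes)),
    gene_id = sprintf("GENE%05d", seq_len(n_probes)),
    downstream_arm = down, upstream_arm = up,
    attenuation_ratio = ratio, name = name
  )
}

#' Generate a random sample sheet
#'
#' Dual 9-mer indexes drawn at random and redrawn until every pair of
#' samples differs by more than `2 * max_index_mismatch` in at least one
#' index, so demultiplexing at that tolerance is collision-free.
#'
#' @param sample_ids character vector of sample names.
#' @param seed integer seed.
#' @param max_index_mismatch tolerance the sheet must support (default 1).
#' @return a sample-sheet data frame.
#' @export
random_sample_sheet <- function(sample_ids, seed = 1L, max_index_mismatch = 1L) {
  set.seed(substream_seed(seed, "sheet"))
  n <- length(sample_ids)
  repeat {
    i1 <- random_dna(n, 9L)
    i2 <- random_dna(n, 9L)
    ok <- TRUE
    if (n > 1L) {
      for (a in 1:(n - 1)) {
        for (b in (a + 1):n) {
          d1 <- sum(utf8ToInt(i1[a]) != utf8ToInt(i1[b]))
          d2 <- sum(utf8ToInt(i2[a]) != utf8ToInt(i2[b]))
          if (d1 <= 2 * max_index_mismatch && d2 <= 2 * max_index_mismatch) {
            ok <- FALSE
          }
        }
      }
    }
    if (ok) break
  }
  validate_sample_sheet(data.frame(sample_id = sample_ids, index1 = i1,
                                   index2 = i2, stringsAsFactors = FALSE))
}

#' Add single-mismatch junction variants of a probe to a pool
#'
#' For specificity studies: creates the six single-base variants of one
#' probe's ligated sequence at junction positions -3..-1 (3' end of the
#' downstream arm) and +1..+3 (5' end of the upstream arm). Variant probes
#' carry `variant_of` and `mm_position` columns; [expected_counts()] scales
#' their weight by the mismatch ligation-efficiency profile.
#'
#' @param pool a [probe_pool()].
#' @param probe_id the probe to derive variants from.
#' @param seed seed for the substituted bases.
#' @return the pool with six variant rows appended.
#' @export
add_mismatch_variants <- function(pool, probe_id, seed = 1L) {
  i <- match(probe_id, pool$probe_id)
  if (is.na(i)) stop("unknown probe_id: ", probe_id, call. = FALSE)
  set.seed(substream_seed(seed, paste0("variants_", probe_id)))
  positions <- c(-3L, -2L, -1L, 1L, 2L, 3L)
  down <- pool$downstream_arm[i]; up <- pool$upstream_arm[i]
  rows <- lapply(positions, function(p) {
    d <- down; u <- up
    if (p < 0) d <- substitute_base(d, 25L + p + 1L) else u <- substitute_base(u, p)
    data.frame(probe_id = sprintf("%s_mm%+d", probe_id, p),
               gene_id = pool$gene_id[i], downstream_arm = d, upstream_arm = u,
               attenuation_ratio = 0, stringsAsFactors = FALSE)
  })
  ext <- do.call(rbind, rows)
  base <- as.data.frame(pool)[, c("probe_id", "gene_id", "downstream_arm",
                                  "upstream_arm", "attenuation_ratio")]
  out <- probe_pool(c(base$probe_id, ext$probe_id),
                    c(base$gene_id, ext$gene_id),
                    c(base$downstream_arm, ext$downstream_arm),
                    c(base$upstream_arm, ext$upstream_arm),
                    c(base$attenuation_ratio, ext$attenuation_ratio),
                    name = attr(pool, "name") %||% "pool")
  out$variant_of <- c(rep(NA_character_, nrow(base)), rep(probe_id, 6L))
  out$mm_position <- c(rep(NA_integer_, nrow(base)), positions)
  out
}
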