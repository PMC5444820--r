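#' Run the full processing pipeline on a directory of FASTQ files
#'
#' Demultiplex -> align -> count -> QC -> normalize (optional) ->
#' back-calculate attenuation (optional) -> differential expression
#' (optional), writing the standard flat files: count matrix, per-sample
#' read accounting, QC summary, sample-clustering dendrogram (hierarchical,
#' correlation distance, average linkage) and PCA coordinates. Every output
#' file carries a header comment with the tool version, configuration hash
#' and seed, and each stage can be re-run from the previous stage's files.
#'
#' @param fastq one FASTQ path with inline indexes, or a named list/vector
#'   of per-sample FASTQ paths (already demultiplexed; names are sample
#'   ids).
#' @param manifest path to the probe manifest TSV, or a [probe_pool()].
#' @param sample_sheet path to the sample sheet CSV (required when `fastq`
#'   is a single inline-indexed file), or a data frame.
#' @param out_dir output directory.
#' @param normalize scale counts to the average total ([normalize_total()]).
#' @param backcalculate multiply attenuated probes by their fold
#'   attenuation ([backcalculate_attenuation()]).
#' @param de_groups optional list of two character vectors of sample ids;
#'   runs [run_de()] between them.
#' @param no_input_samples sample ids treated as no-input controls in QC.
#' @param groups replicate-group labels per sample for QC (defaults to one
#'   group).
#' @param max_index_mismatch demultiplex tolerance.
#' @param seed seed stamped on outputs.
#' @return list with `counts`, `accounting`, `qc`, `de` (or `NULL`),
#'   `files` (paths written).
#' @export
run_pipeline <- function(fastq, manifest, sample_sheet = NULL,
                         out_dir = tempfile("ligprobe_run_"),
                         normalize = TRUE, backcalculate = TRUE,
                         de_groups = NULL, no_input_samples = NULL,
                         groups = NULL, max_index_mismatch = 1L,
                         seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pool <- if (inherits(manifest, "probe_pool")) manifest else read_manifest(manifest)
  cfg <- list(normalize = normalize, backcalculate = backcalculate,
              max_index_mismatch = max_index_mismatch, seed = seed)

  ## --- demultiplex ---------------------------------------------------
  per_sample <- tryCatch({
    if (length(fastq) == 1L && is.null(names(fastq))) {
      sheet <- if (is.data.frame(sample_sheet)) sample_sheet else
        read_sample_sheet(sample_sheet)
      dm <- demultiplex(read_fastq(fastq), sheet, max_index_mismatch)
      dm[setdiff(names(dm), "undetermined")]
    } else {
      lapply(fastq, read_fastq)
    }
  }, error = function(e) stop("demultiplex stage: ", conditionMessage(e),
                              call. = FALSE))

  ## --- align + count -------------------------------------------------
  counts_list <- list(); acct <- NULL
  for (sid in names(per_sample)) {
    res <- tryCatch({
      aln <- align_reads(per_sample[[sid]], pool)
      count_sample(aln, pool)
    }, error = function(e) stop("align/count stage (", sid, "): ",
                                conditionMessage(e), call. = FALSE))
    counts_list[[sid]] <- res$counts
    acct <- rbind(acct, cbind(sample_id = sid, res$accounting))
  }
  counts <- assemble_counts(counts_list)

  files <- c(counts = file.path(out_dir, "counts.tsv"),
             accounting = file.path(out_dir, "accounting.tsv"))
  write_counts(counts, files[["counts"]], seed = seed, config = cfg)
  write_artifact_tsv(acct, files[["accounting"]], seed = seed, config = cfg)

  ## --- QC -------------------------------------------------------------
  if (is.null(groups)) groups <- rep("all", ncol(counts))
  qc <- tryCatch(
    qc_report(counts, acct, groups = groups,
              no_input_samples = no_input_samples),
    error = function(e) stop("qc stage: ", conditionMessage(e), call. = FALSE))
  qc_df <- data.frame(
    metric = c("background_fraction",
               paste0("mapped_fraction_", acct$sample_id),
               paste0("misligation_fraction_", acct$sample_id)),
    value = c(qc$background_fraction, acct$mapped_fraction,
              acct$misligation_fraction))
  files["qc"] <- file.path(out_dir, "qc.tsv")
  write_artifact_tsv(qc_df, files[["qc"]], seed = seed, config = cfg)
  if (!is.null(qc$replicate_r2)) {
    files["replicate_r2"] <- file.path(out_dir, "replicate_r2.tsv")
    write_artifact_tsv(qc$replicate_r2, files[["replicate_r2"]], seed = seed,
                       config = cfg)
  }

  ## --- normalize / back-calculate ------------------------------------
  mat <- counts
  if (normalize) {
    mat <- normalize_total(mat)
    files["normalized"] <- file.path(out_dir, "counts_normalized.tsv")
    write_counts(mat, files[["normalized"]], seed = seed, config = cfg)
  }
  if (backcalculate && any(pool$attenuation_ratio > 0)) {
    mat <- backcalculate_attenuation(mat, pool)
    files["backcalculated"] <- file.path(out_dir, "counts_backcalculated.tsv")
    write_counts(mat, files[["backcalculated"]], seed = seed, config = cfg)
  }

  ## --- clustering + PCA ----------------------------------------------
  ## clustering needs >= 3 samples with reads (empty libraries have no
  ## correlation structure and would poison the distance matrix)
  pos_cols <- which(colSums(counts) > 0)
  if (length(pos_cols) >= 3) {
    lg <- log2(counts[, pos_cols, drop = FALSE] + 1)
    keep <- apply(lg, 1L, sd) > 0
    cc <- cor(lg[keep, , drop = FALSE])
    hc <- hclust(as.dist(1 - cc), method = "average")
    files["dendrogram"] <- file.path(out_dir, "dendrogram.txt")
    con <- file(files[["dendrogram"]], "w")
    writeLines(c(artifact_header(seed, cfg),
                 utils::capture.output(print(as.dendrogram(hc)))), con)
    close(con)
    pcs <- prcomp(t(lg[keep, , drop = FALSE]), rank. = 2)
    files["pca"] <- file.path(out_dir, "pca.tsv")
    write_artifact_tsv(
      data.frame(sample_id = colnames(counts)[pos_cols], pcs$x),
      files[["pca"]], seed = seed, config = cfg)
  }

  ## --- differential expression ---------------------------------------
  de <- NULL
  if (!is.null(de_groups)) {
    de <- tryCatch(
      run_de(counts, de_groups[[1]], de_groups[[2]]),
      error = function(e) stop("de stage: ", conditionMessage(e),
                               call. = FALSE))
    files["de"] <- file.path(out_dir, "de.tsv")
    gene <- pool$gene_id[match(de$probe_id, pool$probe_id)]
    write_artifact_tsv(cbind(de[, 1, drop = FALSE], gene_id = gene,
                             de[, -1]), files[["de"]], seed = seed,
                       config = cfg)
  }

  jsonlite::write_json(c(cfg, list(version = pkg_version_string())),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, null = "null")
  list(counts = counts, accounting = acct, qc = qc, de = de, files = files)
}

#' @importFrom stats as.dendrogram
NULL
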