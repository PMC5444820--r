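#' Simulate a complete named experiment
#'
#' Emits a full synthetic experiment -- probe pool, sample sheet, per-sample
#' reads with ground truth, and the design -- for one of the packaged
#' scenarios:
#' \describe{
#'   \item{`repeatability`}{triplicates of two reference-RNA-like profiles
#'     (log-uniform over 5 decades) plus a no-input sample, on a
#'     whole-transcriptome-scale pool with attenuated high-abundance
#'     probes.}
#'   \item{`titration`}{10-fold input dilution series of one profile with
#'     amplification saturation at the top.}
#'   \item{`mixtures`}{four groups of three samples blending two reference
#'     profiles at 60/40, 50/50, 50/50 and 40/60 -- designed fold
#'     differences of at most 1.2.}
#'   \item{`specificity`}{one high-abundance target plus its six
#'     single-mismatch junction variants (weighted by the packaged
#'     mismatch efficiency profile) over 20 normalization targets.}
#'   \item{`tsa_like`}{a six-dose compound-response series: responsive
#'     genes shift monotonically (Hill-shaped, onset at `onset_dose`) up
#'     or down from a shared baseline, in triplicate.}
#' }
#'
#' @param scenario scenario name.
#' @param seed integer top-level seed.
#' @param n_probes pool size (default 20629, whole-transcriptome scale;
#'   smaller scenarios override).
#' @param cfg a [sim_config()]; `cfg$seed` is overridden by `seed`.
#' @param write_fastq_to optional directory: write per-sample FASTQ, truth
#'   TSVs, manifest, sample sheet and a JSON config echo there.
#' @param onset_dose dose at which `tsa_like` responses reach half effect.
#' @param doses dose series for `tsa_like`.
#' @param sample_subset optional sample ids: simulate reads only for these
#'   samples (pool, sheet and design are unchanged), e.g. to process a
#'   single library of a large scenario.
#' @return list with `pool`, `sheet`, `samples` (per sample: `reads`,
#'   `truth`), `design` (per-sample metadata), `profiles`, `config`.
#' @export
simulate_scenario <- function(scenario = c("repeatability", "titration",
                                           "mixtures", "specificity",
                                           "tsa_like"),
                              seed = 1L, n_probes = 20629L,
                              cfg = sim_config(),
                              write_fastq_to = NULL,
                              onset_dose = 1,
                              doses = c(0.03, 0.1, 0.3, 1, 3, 10),
                              sample_subset = NULL) {
  scenario <- match.arg(scenario)
  cfg$seed <- as.integer(seed)
  out <- switch(
    scenario,
    repeatability = scenario_repeatability(seed, n_probes, cfg, sample_subset),
    titration = scenario_titration(seed, n_probes, cfg),
    mixtures = scenario_mixtures(seed, n_probes, cfg, sample_subset),
    specificity = scenario_specificity(seed, cfg, sample_subset),
    tsa_like = scenario_tsa_like(seed, n_probes, cfg, onset_dose, doses,
                                 sample_subset)
  )
  out$config <- list(scenario = scenario, seed = seed, n_probes = n_probes,
                     sim = unclass(cfg))

  if (!is.null(write_fastq_to)) {
    dir.create(write_fastq_to, showWarnings = FALSE, recursive = TRUE)
    write_manifest(out$pool, file.path(write_fastq_to, "manifest.tsv"))
    write_sample_sheet(out$sheet, file.path(write_fastq_to, "samples.csv"))
    for (sid in names(out$samples)) {
      write_fastq(out$samples[[sid]]$reads,
                  file.path(write_fastq_to, paste0(sid, ".fastq")))
      write_artifact_tsv(out$samples[[sid]]$truth,
                         file.path(write_fastq_to, paste0(sid, "_truth.tsv")),
                         seed = seed, config = out$config)
    }
    jsonlite::write_json(out$config,
                         file.path(write_fastq_to, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  out
}

## simulate only the requested libraries; per-sample determinism is
## preserved because each sample draws from its own seed substream
sim_all_samples <- function(pool, profiles, cfg, sheet, subset = NULL,
                            inline_index = TRUE) {
  if (!is.null(subset)) {
    sheet <- sheet[sheet$sample_id %in% subset, , drop = FALSE]
  }
  samples <- lapply(seq_len(nrow(sheet)), function(i) {
    simulate_sample(pool, profiles[[sheet$sample_id[i]]], cfg, sheet[i, ],
                    inline_index = inline_index)
  })
  names(samples) <- sheet$sample_id
  samples
}

scenario_repeatability <- function(seed, n_probes, cfg, subset = NULL) {
  pool <- random_pool(n_probes, seed = seed, attenuated_fraction = 0.01)
  prof_a <- loguniform_profile(pool, seed = substream_seed(seed, "urr_like"))
  prof_b <- loguniform_profile(pool, seed = substream_seed(seed, "brain_like"))
  ids <- c(paste0("refA_", 1:3), paste0("refB_", 1:3), "no_input")
  sheet <- random_sample_sheet(ids, seed = seed)
  profiles <- c(rep(list(prof_a), 3), rep(list(prof_b), 3),
                list(setNames(numeric(0), character(0))))
  names(profiles) <- ids
  design <- data.frame(sample_id = ids,
                       group = c(rep("refA", 3), rep("refB", 3), "no_input"),
                       stringsAsFactors = FALSE)
  list(pool = pool, sheet = sheet, profiles = profiles, design = design,
       samples = sim_all_samples(pool, profiles, cfg, sheet, subset))
}

scenario_titration <- function(seed, n_probes, cfg) {
  n_probes <- min(n_probes, 2244L)
  pool <- random_pool(n_probes, seed = seed)
  prof <- loguniform_profile(pool, seed = seed)
  if (is.null(cfg$saturation_capacity)) {
    cfg$saturation_capacity <- 0.1 * sum(prof)
  }
  dil <- 10^-(0:5)
  tit <- simulate_titration(pool, prof, dil, cfg)
  list(pool = pool, sheet = NULL, profiles = list(stock = prof),
       design = tit, samples = list(),
       counts = attr(tit, "counts"), expected = attr(tit, "expected"))
}

scenario_mixtures <- function(seed, n_probes, cfg, subset = NULL) {
  n_probes <- min(n_probes, 2244L)   # the mixture study used a 2,244-plex pool
  pool <- random_pool(n_probes, seed = seed)
  comp_a <- loguniform_profile(pool, seed = substream_seed(seed, "brain_like"))
  comp_b <- loguniform_profile(pool, seed = substream_seed(seed, "urr_like"))
  ## equalize component masses so mixing proportions act on comparable scales
  comp_a <- comp_a / sum(comp_a); comp_b <- comp_b / sum(comp_b)
  mixes <- list(mix60_40 = c(0.6, 0.4), mix50_50a = c(0.5, 0.5),
                mix50_50b = c(0.5, 0.5), mix40_60 = c(0.4, 0.6))
  ids <- unlist(lapply(names(mixes), paste0, "_r", 1:3))
  sheet <- random_sample_sheet(ids, seed = seed)
  profiles <- lapply(ids, function(id) {
    p <- mixes[[sub("_r[0-9]+$", "", id)]]
    p[1] * comp_a + p[2] * comp_b
  })
  names(profiles) <- ids
  design <- data.frame(sample_id = ids,
                       group = sub("_r[0-9]+$", "", ids),
                       prop_a = sapply(ids, function(id)
                         mixes[[sub("_r[0-9]+$", "", id)]][1]),
                       stringsAsFactors = FALSE)
  list(pool = pool, sheet = sheet, profiles = profiles, design = design,
       components = list(a = comp_a, b = comp_b), mixes = mixes,
       samples = sim_all_samples(pool, profiles, cfg, sheet, subset))
}

scenario_specificity <- function(seed, cfg, subset = NULL) {
  pool <- random_pool(21L, seed = seed)
  target <- pool$probe_id[1]
  pool <- add_mismatch_variants(pool, target, seed = seed)
  prof <- setNames(rep(1, 21), pool$probe_id[is.na(pool$variant_of)])
  prof[target] <- 20   # high-abundance target, as in the mismatch study
  ids <- paste0("spec_", 1:3)
  sheet <- random_sample_sheet(ids, seed = seed)
  profiles <- setNames(rep(list(prof), 3), ids)
  design <- data.frame(sample_id = ids, group = "specificity",
                       stringsAsFactors = FALSE)
  list(pool = pool, sheet = sheet, profiles = profiles, design = design,
       target = target,
       samples = sim_all_samples(pool, profiles, cfg, sheet, subset))
}

scenario_tsa_like <- function(seed, n_probes, cfg, onset_dose, doses,
                              subset = NULL) {
  n_probes <- min(n_probes, 5000L)
  pool <- random_pool(n_probes, seed = seed)
  base <- loguniform_profile(pool, seed = seed)
  set.seed(substream_seed(seed, "tsa_genes"))
  n_resp <- round(0.05 * n_probes)
  resp <- sample(names(base), 2 * n_resp)
  up <- resp[seq_len(n_resp)]
  down <- resp[n_resp + seq_len(n_resp)]
  max_fold <- setNames(2^runif(2 * n_resp, 0.5, 3), resp)
  ## Hill response: fold(dose) interpolates 1 -> max_fold with half effect
  ## at onset_dose (down genes use the reciprocal)
  fold_at <- function(dose) {
    h <- dose / (dose + onset_dose)
    f <- setNames(rep(1, length(base)), names(base))
    f[up] <- max_fold[up]^h
    f[down] <- max_fold[down]^-h
    f
  }
  ids <- unlist(lapply(seq_along(doses), function(d)
    sprintf("dose%d_r%d", d, 1:3)))
  sheet <- random_sample_sheet(ids, seed = seed)
  profiles <- list()
  for (d in seq_along(doses)) {
    p <- base * fold_at(doses[d])
    for (r in 1:3) profiles[[sprintf("dose%d_r%d", d, r)]] <- p
  }
  design <- data.frame(sample_id = ids,
                       dose = rep(doses, each = 3),
                       group = rep(sprintf("dose%d", seq_along(doses)),
                                   each = 3),
                       stringsAsFactors = FALSE)
  truth_trend <- data.frame(gene = resp,
                            direction = rep(c("up", "down"), each = n_resp),
                            max_fold = unname(max_fold))
  list(pool = pool, sheet = sheet, profiles = profiles, design = design,
       response_genes = truth_trend, doses = doses,
       samples = sim_all_samples(pool, profiles, cfg, sheet, subset))
}
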