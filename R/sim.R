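#' Simulator configuration
#'
#' Bundles every generative rate of the read simulator. Identical
#' configuration + inputs + seed gives byte-identical FASTQ output.
#'
#' Defaults emulate the assay's published operating regime: 2M reads per
#' sample, mis-ligation (chimera) rate 0.05% (well under the < 0.1% the
#' assay exhibits), ~0.1 stray background reads per probe (so a no-input
#' sample collects ~0.1% of a positive sample's reads on a
#' whole-transcriptome pool), 15% partial reads truncated uniformly to
#' 10--49 nt (the dominant source of unmapped reads, yielding 85--90%
#' mapped), and a 0.1% per-base substitution error.
#'
#' @param reads_per_sample positive integer read depth.
#' @param chimera_rate fraction of reads that are mis-ligation chimeras.
#' @param background_rate_per_probe expected stray reads per probe,
#'   independent of input.
#' @param partial_read_rate fraction of reads truncated to 10--49 nt.
#' @param seq_error_rate_per_base per-base substitution probability.
#' @param saturation_capacity optional amplification capacity (molecules);
#'   `NULL` disables saturation. Used by [simulate_titration()].
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(reads_per_sample = 2e6,
                       chimera_rate = 5e-4,
                       background_rate_per_probe = 0.1,
                       partial_read_rate = 0.15,
                       seq_error_rate_per_base = 1e-3,
                       saturation_capacity = NULL,
                       seed = 1L) {
  stopifnot(reads_per_sample >= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            background_rate_per_probe >= 0,
            partial_read_rate >= 0, partial_read_rate <= 1,
            seq_error_rate_per_base >= 0, seq_error_rate_per_base <= 1,
            is.null(saturation_capacity) || saturation_capacity > 0)
  structure(list(reads_per_sample = as.numeric(reads_per_sample),
                 chimera_rate = chimera_rate,
                 background_rate_per_probe = background_rate_per_probe,
                 partial_read_rate = partial_read_rate,
                 seq_error_rate_per_base = seq_error_rate_per_base,
                 saturation_capacity = saturation_capacity,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default mismatch ligation-efficiency profile
#'
#' Relative ligation efficiency of a DO pair carrying a single-base mismatch
#' at junction positions -3..-1 (3' end of the downstream arm, the ligating
#' 3' hydroxyl) and +1..+3 (5' end of the upstream arm), relative to the
#' perfect match (efficiency 1). The -1 value 0.004 is the measured residual
#' signal of the most disruptive mismatch (0.4% of perfect-match reads,
#' i.e. 99.6% single-base specificity); the other positions are illustrative
#' values reproducing the measured trend that disruption decays with
#' distance from the junction and is strongest on the 3'-hydroxyl side.
#'
#' @return named numeric vector over positions `-3,-2,-1,+1,+2,+3`.
#' @export
default_mismatch_profile <- function() {
  c(`-3` = 0.12, `-2` = 0.025, `-1` = 0.004,
    `+1` = 0.008, `+2` = 0.04, `+3` = 0.15)
}

check_mismatch_profile <- function(mm) {
  stopifnot(all(c("-3", "-2", "-1", "+1", "+2", "+3") %in% names(mm)),
            all(mm >= 0), all(mm <= 1))
  mm
}

#' Expected read counts under the attenuation model
#'
#' Converts relative transcript abundances into expected per-probe read
#' counts at a given depth. A probe with attenuation ratio `a` (attenuator :
#' functional DO) has its weight multiplied by `1/(1+a)`, because only the
#' functional fraction of hybridisation events yields sequenceable product:
#' a 4:1 ratio reduces a probe that would collect 50,000 reads to 10,000.
#' Probes carrying a `mm_position` (see [add_mismatch_variants()]) have
#' their weight further scaled by the ligation efficiency at that position.
#'
#' @param pool a [probe_pool()].
#' @param profile named numeric vector of relative abundances (names are
#'   probe ids; missing probes get abundance 0). Variant probes inherit
#'   their parent's abundance automatically.
#' @param depth total expected reads.
#' @param mm_profile mismatch efficiency profile
#'   (default [default_mismatch_profile()]).
#' @return named numeric vector of expected counts summing to `depth`.
#' @export
expected_counts <- function(pool, profile, depth,
                            mm_profile = default_mismatch_profile()) {
  stopifnot(inherits(pool, "probe_pool"), depth > 0)
  extra <- setdiff(names(profile), pool$probe_id)
  if (length(extra)) {
    stop("profile names not in pool: ", paste(head(extra), collapse = ", "),
         call. = FALSE)
  }
  ab <- setNames(numeric(nrow(pool)), pool$probe_id)
  ab[names(profile)] <- profile
  if (!is.null(pool$variant_of)) {
    v <- which(!is.na(pool$variant_of))
    if (length(v)) {
      mm <- check_mismatch_profile(mm_profile)
      ab[v] <- ab[pool$variant_of[v]] * mm[sprintf("%+d", pool$mm_position[v])]
    }
  }
  stopifnot(all(ab >= 0))
  w <- attenuate_expectation(ab, pool$attenuation_ratio)
  if (sum(w) == 0) {
    stop("all-zero expression profile with positive depth; ",
         "use the background-only path (all-zero profile in simulate_sample)",
         call. = FALSE)
  }
  depth * w / sum(w)
}

#' Attenuated expectation of a probe's signal
#'
#' The per-probe attenuation model: spiking non-functional competitor DOs
#' at ratio `a : 1` against the functional pair leaves a fraction
#' `1/(1+a)` of ligation events sequenceable, so an expectation of 50,000
#' reads at `a = 4` becomes 10,000. The inverse map is
#' [backcalculate_attenuation()].
#'
#' @param expected unattenuated expected counts.
#' @param ratio attenuation ratio(s) `a >= 0` (0 = unattenuated).
#' @return attenuated expectation `expected / (1 + ratio)`.
#' @export
attenuate_expectation <- function(expected, ratio) {
  stopifnot(all(ratio >= 0))
  expected / (1 + ratio)
}

#' Simulate one sample's reads
#'
#' Generative model of the assay library for one sample:
#' \enumerate{
#'   \item target reads: multinomial over [expected_counts()];
#'   \item chimeras: a `chimera_rate` fraction of target reads replaced by
#'     the downstream half of one random probe joined to the upstream half
#'     of a different probe (mis-ligation artifacts);
#'   \item background: `Poisson(background_rate_per_probe x n_probes)`
#'     stray reads carrying a random probe's 50-mer, present even with no
#'     input (an all-zero profile yields only background);
#'   \item partial reads: a `partial_read_rate` fraction truncated to a
#'     uniform length in 10--49 nt;
#'   \item sequencing error: per-base substitutions at
#'     `seq_error_rate_per_base`.
#' }
#' Read names encode `sample_id:class:probe:serial` so that every read's
#' truth is recoverable; the ground-truth table aggregates true counts per
#' probe and class. In `inline_index` mode the dual 9-mer indexes are
#' prepended to the sequence (for demultiplex testing); otherwise reads are
#' post-demultiplex and indexes live only in the sample sheet.
#'
#' @param pool a [probe_pool()].
#' @param profile named abundance vector (see [expected_counts()]); all
#'   zeros (or empty) simulates a no-input sample.
#' @param cfg a [sim_config()].
#' @param sample one row of a sample sheet (list or data frame row with
#'   `sample_id`, `index1`, `index2`).
#' @param mm_profile mismatch efficiency profile.
#' @param inline_index prepend `index1` and `index2` to each read.
#' @return list with `reads` (data frame: `id`, `seq`, `class`, `probe_id`)
#'   and `truth` (data frame: `read_class`, `probe_id`, `count`).
#' @export
simulate_sample <- function(pool, profile, cfg, sample,
                            mm_profile = default_mismatch_profile(),
                            inline_index = FALSE) {
  stopifnot(inherits(pool, "probe_pool"), inherits(cfg, "sim_config"))
  sample_id <- as.character(sample$sample_id)
  set.seed(substream_seed(cfg$seed, paste0("sample_", sample_id)))

  n_probes <- nrow(pool)
  no_input <- length(profile) == 0L || all(profile == 0)

  ## --- target + chimera reads ---------------------------------------
  if (!no_input) {
    exp_counts <- expected_counts(pool, profile, cfg$reads_per_sample,
                                  mm_profile)
    n_chim <- rbinom(1L, cfg$reads_per_sample, cfg$chimera_rate)
    n_target <- cfg$reads_per_sample - n_chim
    counts <- as.vector(rmultinom(1L, n_target, exp_counts))
    target_idx <- rep.int(seq_len(n_probes), counts)
  } else {
    n_chim <- 0L
    target_idx <- integer(0)
  }

  if (n_chim > 0) {
    a <- sample.int(n_probes, n_chim, replace = TRUE)
    shift <- sample.int(n_probes - 1L, n_chim, replace = TRUE)
    b <- ((a - 1L + shift) %% n_probes) + 1L   # guaranteed distinct from a
    chim_seq <- paste0(substr(pool$ligated[a], 1L, 25L),
                       substr(pool$ligated[b], 26L, 50L))
    chim_probe <- paste0(pool$probe_id[a], "|", pool$probe_id[b])
  } else {
    chim_seq <- character(0); chim_probe <- character(0)
  }

  ## --- background reads ---------------------------------------------
  n_bg <- rpois(1L, cfg$background_rate_per_probe * n_probes)
  bg_idx <- if (n_bg > 0) sample.int(n_probes, n_bg, replace = TRUE) else integer(0)

  seqs <- c(pool$ligated[target_idx], chim_seq, pool$ligated[bg_idx])
  classes <- rep(c("target", "chimera", "background"),
                 c(length(target_idx), n_chim, n_bg))
  probes <- c(pool$probe_id[target_idx], chim_probe, pool$probe_id[bg_idx])

  n <- length(seqs)
  if (n > 0) {
    ord <- sample.int(n)
    seqs <- seqs[ord]; classes <- classes[ord]; probes <- probes[ord]

    ## --- partial reads ----------------------------------------------
    n_part <- rbinom(1L, n, cfg$partial_read_rate)
    if (n_part > 0) {
      pi <- sample.int(n, n_part)
      lens <- sample(10:49, n_part, replace = TRUE)
      seqs[pi] <- substr(seqs[pi], 1L, lens)
    }

    ## --- sequencing errors ------------------------------------------
    ## with inline indexes, errors strike index bases too (demultiplexing
    ## must tolerate them like a real demultiplexer)
    if (inline_index) seqs <- paste0(sample$index1, sample$index2, seqs)
    seqs <- inject_errors(seqs, cfg$seq_error_rate_per_base)
  } else if (inline_index) {
    seqs <- paste0(sample$index1, sample$index2, seqs)
  }

  ids <- sprintf("%s:%s:%s:%d", sample_id, classes, probes, seq_len(n))

  truth <- as.data.frame(table(read_class = classes, probe_id = probes),
                         stringsAsFactors = FALSE)
  truth <- truth[truth$Freq > 0, ]
  names(truth)[3] <- "count"
  rownames(truth) <- NULL

  list(reads = data.frame(id = ids, seq = seqs, class = classes,
                          probe_id = probes, stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate a log-uniform expression profile
#'
#' Relative abundances spanning `decades` orders of magnitude on a log10
#' scale, the dynamic range the assay covers.
#'
#' @param pool a [probe_pool()] (variant probes are excluded; they inherit
#'   abundance from their parent in [expected_counts()]).
#' @param seed integer seed.
#' @param decades dynamic range in log10 units (default 5).
#' @return named abundance vector.
#' @export
loguniform_profile <- function(pool, seed = 1L, decades = 5) {
  set.seed(substream_seed(seed, "profile"))
  ids <- pool$probe_id
  if (!is.null(pool$variant_of)) ids <- ids[is.na(pool$variant_of)]
  setNames(10^runif(length(ids), 0, decades), ids)
}

#' Simulate an input titration with optional amplification saturation
#'
#' Scales input molecules by each dilution factor. With a finite
#' `saturation_capacity` `cap`, the amplified yield of `m` input molecules
#' is `y = cap * m / (m + cap)`: proportional to `m` when `m << cap` and
#' plateauing at `cap` when `m >> cap`, reproducing the saturation seen at
#' the top of real titration series. Reads are then allocated across levels
#' proportionally to yield (all levels pooled into one library at equal
#' volume), and per-level counts are multinomial draws over the probe
#' proportions.
#'
#' @param pool a [probe_pool()].
#' @param profile named abundance vector at the undiluted level; abundances
#'   are read as relative molecule counts.
#' @param dilution_factors positive, descending dilution factors
#'   (e.g. `c(1, 0.1, 0.01)`).
#' @param cfg a [sim_config()]; `cfg$reads_per_sample` is the total reads
#'   over all levels and `cfg$saturation_capacity` the plateau (in the same
#'   molecule units as `sum(profile)`), `NULL` for no saturation.
#' @param input_molecules molecules at dilution factor 1
#'   (default `sum(profile)`).
#' @return data frame per level: `dilution`, `input_molecules`, `yield`,
#'   `reads`; plus a `counts` matrix (probes x levels) as attribute
#'   `"counts"`, and expected counts as attribute `"expected"`.
#' @export
simulate_titration <- function(pool, profile, dilution_factors, cfg,
                               input_molecules = sum(profile)) {
  stopifnot(all(dilution_factors > 0),
            !is.unsorted(rev(dilution_factors), strictly = FALSE))
  set.seed(substream_seed(cfg$seed, "titration"))
  m <- input_molecules * dilution_factors
  yield <- amplification_yield(m, cfg$saturation_capacity)
  reads <- as.vector(rmultinom(1L, cfg$reads_per_sample, yield))
  exp_prop <- expected_counts(pool, profile, 1)
  counts <- sapply(reads, function(r) {
    if (r == 0) integer(nrow(pool)) else as.vector(rmultinom(1L, r, exp_prop))
  })
  rownames(counts) <- pool$probe_id
  colnames(counts) <- sprintf("dil_%g", dilution_factors)
  expected <- outer(exp_prop, reads)
  dimnames(expected) <- dimnames(counts)
  out <- data.frame(dilution = dilution_factors, input_molecules = m,
                    yield = yield, reads = reads)
  attr(out, "counts") <- counts
  attr(out, "expected") <- expected
  out
}

#' Amplified yield under saturation
#'
#' `y = cap * m / (m + cap)`; with `cap = NULL` the yield is `m` (linear).
#'
#' @param m input molecules.
#' @param cap saturation capacity or `NULL`.
#' @return numeric yields.
#' @export
amplification_yield <- function(m, cap = NULL) {
  stopifnot(all(m >= 0))
  if (is.null(cap)) m else cap * m / (m + cap)
}

#' Estimate single-base specificity from specificity-experiment counts
#'
#' Given per-probe counts for a perfect-match probe and its single-mismatch
#' junction variants, returns `100 * (1 - min(variant / perfect))`: the
#' specificity implied by the most disruptive junction mismatch.
#'
#' @param counts named numeric count vector.
#' @param perfect_id probe id of the perfect-match probe.
#' @param variant_ids probe ids of its mismatch variants (default: names
#'   matching `paste0(perfect_id, "_mm")`).
#' @return list with `specificity_percent`, `worst_variant`,
#'   `relative_signal` (per-variant fraction of perfect-match counts).
#' @export
estimate_specificity <- function(counts, perfect_id,
                                 variant_ids = grep(paste0("^", perfect_id, "_mm"),
                                                    names(counts), value = TRUE)) {
  stopifnot(perfect_id %in% names(counts), length(variant_ids) > 0,
            counts[perfect_id] > 0)
  rel <- counts[variant_ids] / counts[perfect_id]
  ## the most disruptive mismatch is the one with the smallest residual signal
  list(specificity_percent = 100 * (1 - unname(min(rel))),
       worst_variant = names(rel)[which.min(rel)],
       relative_signal = rel)
}
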