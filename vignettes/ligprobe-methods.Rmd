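---
title: "Generative model and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative model and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligprobe)
```

`ligprobe` simulates and analyses a ligation-probe targeted expression
assay: each transcript target is interrogated by a detector-oligo (DO)
pair whose two 25-nt arms hybridize adjacently on the target; enzymatic
ligation of the arms creates a 50-nt template that is amplified and
sequenced. Counting reads per template measures expression. This vignette
documents the generative model, the default parameters and why they were
chosen, the analysis methods, and the limits of what the simulator
emulates.

## The probe model

A `probe_pool()` is a manifest of DO pairs: `probe_id`, `gene_id`, the two
25-nt arms, and an `attenuation_ratio`. The ligated 50-mer
(`downstream_arm` then `upstream_arm`) is the unit the aligner matches
against. Pool validity (`validate_pool()`) requires unique 50-mers and, at
the default junction half-width of 3 nt, unique cross-gene junction
windows: the assay's single-base specificity is a property of the ligation
junction, so two genes sharing a junction window would be mutually
confusable exactly where the assay is most discriminating.

**Attenuation.** High-abundance targets can swamp a library. Spiking
non-functional competitor DOs at ratio $a{:}1$ against the functional pair
leaves a fraction $1/(1+a)$ of ligation events sequenceable, so a probe
with unattenuated expectation $\mu$ yields $\mu/(1+a)$ reads
(`attenuate_expectation()`), and observed counts are restored by the fold
attenuation $(1+a)$ (`backcalculate_attenuation()`). At $a = 4$ an
expectation of 50,000 reads becomes 10,000, and an observation of 10,000
back-calculates to 50,000 — both maps are exact and mutually inverse,
which the test suite checks.

**Junction mismatches.** `default_mismatch_profile()` gives the relative
ligation efficiency of a single-base mismatch at junction positions
$-3..-1$ (3'-hydroxyl side) and $+1..+3$ (5'-phosphate side):

```{r}
default_mismatch_profile()
```

The $-1$ value 0.004 encodes the measured residual signal of the most
disruptive junction mismatch — 0.4% of the perfect-match signal, i.e.
99.6% single-base specificity. The other four positions are illustrative
values reproducing the qualitative trend (disruption decays with distance
from the junction and is strongest on the ligating 3'-hydroxyl side); they
are not measurements, and analyses in this package only ever rely on the
minimum of the profile.

## The read simulator

`simulate_sample()` draws one library in five stages, in this order:

1. **Target reads** — multinomial over `expected_counts()`, which converts
   relative abundances to expected reads, applying attenuation and, for
   mismatch-variant probes, the junction-efficiency profile.
2. **Chimeras** — a `chimera_rate` fraction of reads instead joins the
   downstream half of one random probe to the upstream half of a different
   random probe, emulating mis-ligation between neighbouring DO pairs.
3. **Background** — `Poisson(background_rate_per_probe × n_probes)` stray
   reads, each carrying a random probe's 50-mer, present even with no
   input RNA.
4. **Partial reads** — a `partial_read_rate` fraction truncated to a
   uniform length in 10–49 nt.
5. **Sequencing error** — independent per-base substitutions at
   `seq_error_rate_per_base`. In inline-index mode the dual 9-mer sample
   indexes are prepended *before* this stage, so index bases accumulate
   errors like every other base and demultiplexing has to tolerate them.

Read names encode `sample:class:probe:serial`, and a ground-truth table
accompanies every simulated library, so any downstream quantity can be
checked against truth exactly.

### Default parameters and rationale

```{r}
unclass(sim_config())
```

* `reads_per_sample = 2e6`: a realistic per-library depth for a
  whole-transcriptome-scale targeted panel.
* `chimera_rate = 5e-4`: mis-ligation is a sub-0.1% phenomenon in a
  well-behaved assay; 0.05% puts the simulator comfortably inside that
  regime while leaving enough chimeras per library (~1,000 at 2M reads)
  for the estimator's precision to be testable.
* `background_rate_per_probe = 0.1`: makes a no-input library collect
  about 0.1 stray reads per probe, i.e. roughly 0.1% of a positive
  library on a ~20k-probe pool — the order of magnitude of assay
  background.
* `partial_read_rate = 0.15` with uniform 10–49 nt truncation: partial
  templates are the dominant loss mode; this setting yields 85–90% mapped
  reads under the default aligner, matching the mapped fraction a healthy
  run shows.
* `seq_error_rate_per_base = 1e-3`: a typical short-read substitution
  rate; indels are not modelled because the templates are fixed-length
  synthetic constructs.
* Random seeds: all randomness flows from one top-level seed through
  `substream_seed(seed, stage)`, so each stage (pool, per-sample reads,
  titration, …) has its own reproducible substream and adding one stage
  never perturbs another's draws.

### Packaged scenarios

`simulate_scenario()` wires the simulator into five named experiments:
`repeatability` (two triplicate reference profiles plus a no-input
control, 20,629 probes by default with 1% of probes attenuated),
`titration` (six 10-fold dilutions with amplification saturation
$y = \mathrm{cap}\cdot m/(m+\mathrm{cap})$), `mixtures` (four groups of
three blending two reference profiles 60/40, 50/50, 50/50, 40/60 on a
2,244-probe pool, so no transcript's designed fold change exceeds 1.2),
`specificity` (one 20-fold-abundant target plus its six single-mismatch
junction variants over 20 normalization targets), and `tsa_like` (a
six-dose series in which 5% of genes respond monotonically with
Hill-shaped onset). The pool sizes are this package's own choices, picked
to put each analysis in a realistic regime at desk-scale runtimes.

## Read processing

**Demultiplexing** (`demultiplex()`) assigns a read to a sample when both
inline 9-mer indexes are within 1 mismatch (default) of exactly one
sample's pair, after verifying the sheet itself cannot produce ambiguous
assignments at that tolerance.

**Alignment** (`align_reads()`) is Hamming-only matching against the
pool's 50-mers with up to 2 mismatches, implemented in C++ with a
pigeonhole chunk index (a read within 2 mismatches must match one of three
probe chunks exactly). No indel alignment is attempted — the templates
are synthetic and fixed-length, so substitutions are the only realistic
divergence. Ties at the best distance are discarded as ambiguous, keeping
counts deterministic. Reads of 40–49 nt are rescued by prefix matching;
shorter fragments no longer guarantee panel-wide uniqueness and stay
unmapped.

**Chimera classification.** Unmapped full-length reads whose first 25 nt
match one probe's downstream half and whose last 25 nt match a *different*
probe's upstream half (each half within 1 mismatch, so sequencing errors
do not hide chimeras) are classed as mis-ligation products and never
counted as expression. The reported `misligation_fraction` divides
classified chimeras by *full-length* reads only: truncation strikes
chimeras and genuine templates alike, but only 50-nt reads can be
split-half classified, so restricting the denominator keeps the estimator
unbiased under partial-read loss.

## Quantification and differential expression

Counts are normalized to the mean library total (`normalize_total()`),
and attenuated probes are restored by their fold attenuation. Replicate
agreement is summarized as pairwise Pearson $R^2$ on $\log_2(n+1)$.

`run_de()` is a two-group negative-binomial Wald test: median-of-ratios
size factors; per-probe method-of-moments dispersion on normalized counts,
shrunk toward a parametric trend $a_0 + a_1/\mu$ and floored at the trend;
and a Wald statistic on $\log_2$ fold change referred to a $t$
distribution with $n_A + n_B - 2$ degrees of freedom. Two numerical
choices matter at triplicate scale:

* the trend is fitted to *bin medians* (probes binned by mean), because
  raw moment estimates of dispersion have a heavy upper tail at low means
  that would otherwise dominate a least-squares fit and inflate the trend
  everywhere;
* flooring each probe's dispersion at the trend, and using $t$ rather than
  normal tails, keeps the test conservative where the dispersion is
  estimated from two or three replicates. The test suite verifies both
  directions: planted 4-fold changes are recovered, and identically
  distributed triplicate groups produce no discoveries in almost all
  seeded runs.

Benjamini–Hochberg adjustment is implemented in `bh_adjust()` and tested
against both `stats::p.adjust` and a brute-force step-up.

## Sensitivity analytics

`molecules_in_amplification()` models the additive reaction build
(2 + 2 + 24 + 24 µL with a 10 µL transfer by default): only
$10/52 \approx 19\%$ of ligated molecules enter amplification, which is
the correction needed when quoting molecule-scale detection limits.

`fit_lod()` regresses $\log_{10}$ reads on $\log_{10}$ input molecules
across a spike-in-style titration, after excluding probes with replicate
CV ≥ 60% (noise near the detection limit otherwise dominates the fit) and
excluding zero-read points rather than pseudocounting them (the
x-intercept concerns the positive regime, and a pseudocount would bend the
low end of the fit). The limit of detection is the x-intercept — the
molecule count at which the fit predicts a single read; a fixed 5%
reads-per-molecule efficiency puts it at exactly 20 molecules, which the
suite checks in closed form.

`minor_population_detection()` calls a marker gene detected at a dilution
level when its replicate-mean count exceeds the mean + 3 SD of the
0%-minor control samples — the usual background-threshold rule.

## Signature extraction

Ranked compound-response profiles (columns = samples, each a permutation
of $1..N$; rank 1 is fixed package-wide as most up-regulated) are
processed per cell type: PCA outlier removal (first two components, drop
samples beyond 3 SD of the centroid distance, single pass, refusing to
drop more than half a cell type — that pattern indicates a data problem,
not outliers), per-gene median ranks, extreme tails of size
$\lfloor 0.05N \rfloor$ per direction, and set intersection across cell
types. The middle band (genes within $\pm 10\%\cdot N$ of rank $N/2$) is
read as rank distance by default, with the percentile reading exposed as a
mode flag since the phrase is ambiguous. `overlap_score()` is a
deliberately simple, documented stand-in for proprietary connectivity
scores: mid-p hypergeometric enrichment of the query's up genes in the
profile's top 5% and down genes in the bottom 5%, Fisher-combined; mid-p
tails are used so the combined null p-values stay close to uniform despite
the discreteness of small overlaps. Ties everywhere break on gene
identifier, so the whole pipeline is deterministic.

## What the simulator does not emulate

* No indels, no quality-score model (qualities are written as a constant),
  no PCR duplicate structure, and no GC- or sequence-composition bias.
* Chimeras form uniformly over probe pairs; real mis-ligation is likely
  biased toward co-localized or sequence-similar pairs.
* The mismatch profile outside position $-1$ is illustrative.
* Amplification saturation is a single-capacity hyperbola, not a
  cycle-resolved PCR model.
* Cross-platform comparison utilities (`low_count_filter()`,
  `compare_foldchanges()`) operate on whatever matrices they are given;
  no probe-to-probe-set harmonization is attempted.

These omissions are deliberate: the package's purpose is a controlled,
fully truth-tracked test bed for the *analysis* chain, not a sequencer
emulator.

## A small end-to-end run

```{r, eval = TRUE}
cfg <- sim_config(reads_per_sample = 20000, seed = 1)
sc <- simulate_scenario("mixtures", seed = 1, n_probes = 200, cfg = cfg)
aln <- align_reads(substr(sc$samples$mix60_40_r1$reads$seq, 19, 100),
                   sc$pool)
cs <- count_sample(aln, sc$pool)
cs$accounting
```

The designed fold changes of the mixture experiment are bounded by the
mixing proportions:

```{r}
fc <- mixture_fold_changes(sc$components$a, sc$components$b,
                           p1 = c(0.5, 0.5), p2 = c(0.6, 0.4))
range(fc)
```
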