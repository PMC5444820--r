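test_that("sim_config rejects out-of-range rates", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(reads_per_sample = 0))
  expect_error(sim_config(chimera_rate = -0.1))
  expect_error(sim_config(partial_read_rate = 1.5))
  expect_error(sim_config(saturation_capacity = 0))
})

test_that("attenuation halves of the model are exact inverses", {
  expect_identical(attenuate_expectation(50000, 4), 10000)
  expect_identical(backcalculate_attenuation(c(P = 10000), c(P = 4)),
                   c(P = 50000))
  x <- c(a = 120, b = 4500)
  r <- c(a = 0, b = 9)
  expect_equal(backcalculate_attenuation(attenuate_expectation(x, r), r), x)
  expect_identical(attenuate_expectation(7, 0), 7)
  expect_error(attenuate_expectation(1, -1))
})

test_that("the packaged mismatch profile has the junction structure", {
  mm <- default_mismatch_profile()
  expect_setequal(names(mm), c("-3", "-2", "-1", "+1", "+2", "+3"))
  expect_identical(unname(mm["-1"]), 0.004)       # most disruptive position
  expect_identical(names(which.min(mm)), "-1")
  expect_true(all(mm > 0 & mm < 1))
})

test_that("expected_counts applies abundance, attenuation and variant efficiency", {
  pool <- probe_pool(c("P1", "P2"), c("G1", "G2"),
                     random_dna(2, 25), random_dna(2, 25),
                     attenuation_ratio = c(0, 4))
  ec <- expected_counts(pool, c(P1 = 1, P2 = 5), depth = 1000)
  ## attenuated weight: 1 vs 5/(1+4) = 1, so an even split
  expect_equal(unname(ec), c(500, 500))
  expect_equal(sum(ec), 1000)

  ext <- add_mismatch_variants(random_pool(3, seed = 2), "P00001", seed = 1)
  ec2 <- expected_counts(ext, c(P00001 = 10, P00002 = 1, P00003 = 1),
                         depth = 1)
  mm <- default_mismatch_profile()
  ## variants inherit the parent abundance scaled by junction efficiency
  expect_equal(unname(ec2["P00001_mm-1"] / ec2["P00001"]), mm[["-1"]])
  expect_equal(unname(ec2["P00001_mm+3"] / ec2["P00001"]), mm[["+3"]])

  expect_error(expected_counts(pool, c(BAD = 1), 100), "not in pool")
  expect_error(expected_counts(pool, c(P1 = 0, P2 = 0), 100), "all-zero")
})

test_that("a noise-free simulated sample is recovered exactly", {
  pool <- random_pool(40, seed = 7)
  prof <- loguniform_profile(pool, seed = 7, decades = 2)
  cfg <- noise_free_config(reads = 5000, seed = 3)
  sim <- simulate_sample(pool, prof, cfg, sheet_row())
  expect_identical(nrow(sim$reads), 5000L)
  expect_true(all(sim$reads$class == "target"))
  expect_true(all(nchar(sim$reads$seq) == 50L))

  aln <- align_reads(sim$reads, pool)
  cs <- count_sample(aln, pool)
  truth <- setNames(sim$truth$count, sim$truth$probe_id)
  expect_identical(cs$counts[names(truth)], truth)
  expect_identical(sum(cs$counts), 5000L)
  expect_identical(cs$accounting$mapped, 5000L)
  expect_identical(cs$accounting$misligation_fraction, 0)
})

test_that("simulated read ids and truth table agree with the reads", {
  pool <- random_pool(20, seed = 4)
  prof <- loguniform_profile(pool, seed = 4)
  cfg <- sim_config(reads_per_sample = 2000, seed = 5)
  sim <- simulate_sample(pool, prof, cfg, sheet_row("x7"))
  expect_true(all(startsWith(sim$reads$id, "x7:")))
  tab <- table(paste(sim$reads$class, sim$reads$probe_id))
  truth <- setNames(sim$truth$count,
                    paste(sim$truth$read_class, sim$truth$probe_id))
  expect_identical(as.integer(tab[names(truth)]), unname(truth))
  ## same seed reproduces the library byte for byte
  again <- simulate_sample(pool, prof, cfg, sheet_row("x7"))
  expect_identical(sim$reads, again$reads)
})

test_that("inline_index mode prepends the dual indexes before errors strike", {
  pool <- random_pool(10, seed = 1)
  prof <- loguniform_profile(pool, seed = 1)
  row <- sheet_row()
  cfg <- noise_free_config(reads = 200, seed = 2)
  sim <- simulate_sample(pool, prof, cfg, row, inline_index = TRUE)
  expect_true(all(substr(sim$reads$seq, 1, 18) ==
                    paste0(row$index1, row$index2)))
  expect_true(all(nchar(sim$reads$seq) == 68L))
})

test_that("a no-input sample yields only background reads", {
  pool <- random_pool(50, seed = 6)
  cfg <- sim_config(reads_per_sample = 1000,
                    background_rate_per_probe = 0.5, seed = 8)
  sim <- simulate_sample(pool, setNames(numeric(0), character(0)), cfg,
                         sheet_row())
  expect_true(all(sim$reads$class == "background"))
  ## Poisson(0.5 * 50): tiny compared with a positive library
  expect_lt(nrow(sim$reads), 100)
})

test_that("loguniform profiles span the requested decades and skip variants", {
  pool <- add_mismatch_variants(random_pool(30, seed = 2), "P00005", seed = 2)
  prof <- loguniform_profile(pool, seed = 3, decades = 5)
  expect_length(prof, 30)
  expect_false(any(grepl("_mm", names(prof))))
  expect_true(all(prof >= 1 & prof <= 1e5))
})

test_that("titration yields follow the saturation curve", {
  expect_identical(amplification_yield(c(0, 10, 100), NULL), c(0, 10, 100))
  expect_equal(amplification_yield(100, 100), 50)
  expect_equal(amplification_yield(1e9, 100), 100, tolerance = 1e-6)

  pool <- random_pool(30, seed = 9)
  prof <- loguniform_profile(pool, seed = 9)
  cfg <- sim_config(reads_per_sample = 60000,
                    saturation_capacity = 0.5 * sum(prof), seed = 10)
  tit <- simulate_titration(pool, prof, c(1, 0.1, 0.01), cfg)
  cap <- cfg$saturation_capacity
  m <- sum(prof) * c(1, 0.1, 0.01)
  expect_equal(tit$yield, cap * m / (m + cap))
  expect_identical(sum(tit$reads), 60000L)
  counts <- attr(tit, "counts")
  expect_identical(dim(counts), c(30L, 3L))
  expect_equal(unname(colSums(counts)), tit$reads, ignore_attr = TRUE)
  ## without saturation reads split in proportion to dilution
  cfg2 <- sim_config(reads_per_sample = 1e5, saturation_capacity = NULL,
                     seed = 10)
  tit2 <- simulate_titration(pool, prof, c(1, 0.1), cfg2)
  expect_equal(tit2$reads[1] / tit2$reads[2], 10, tolerance = 0.05)
})

test_that("estimate_specificity reads off the most disruptive variant", {
  counts <- c(P = 10000, P_mm1 = 40, P_mm2 = 900)
  est <- estimate_specificity(counts, "P",
                              variant_ids = c("P_mm1", "P_mm2"))
  expect_equal(est$specificity_percent, 100 * (1 - 40 / 10000))
  expect_identical(est$worst_variant, "P_mm1")
  expect_equal(unname(est$relative_signal), c(0.004, 0.09))
  expect_error(estimate_specificity(c(P = 0, P_mm1 = 1), "P",
                                    variant_ids = "P_mm1"))
})
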