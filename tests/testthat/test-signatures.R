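perm_matrix <- function(cols) {
  m <- do.call(cbind, cols)
  rownames(m) <- sprintf("G%05d", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("rank_profile_set insists on per-column permutations", {
  m <- perm_matrix(list(1:4, c(4, 3, 2, 1)))
  rps <- rank_profile_set(m, cell_type = c("a", "a"))
  expect_identical(attr(rps, "cell_type"), c("a", "a"))
  bad <- m; bad[1, 1] <- 2L
  expect_error(rank_profile_set(bad), "not a permutation")
  expect_error(rank_profile_set(unname(m)))
})

test_that("median_rank matches hand-checked cases", {
  m <- perm_matrix(list(1:3, c(3, 2, 1)))
  expect_equal(unname(median_rank(m)), c(2, 2, 2))
  one <- perm_matrix(list(c(2, 3, 1)))
  expect_equal(unname(median_rank(one)), c(2, 3, 1))
  odd <- perm_matrix(list(1:5, c(2, 1, 3, 5, 4), c(5, 4, 3, 2, 1)))
  expect_true(all(median_rank(odd) %in% 1:5))
})

test_that("extreme_sets selects floor(frac * N) per tail, tie-broken by gene id", {
  set.seed(1)
  n <- 200
  med <- setNames(sample(n), sprintf("G%05d", 1:n))
  sig <- extreme_sets(med, frac = 0.05)
  want <- oracle_tails(med, 0.05)
  expect_length(sig$up, 10)
  expect_identical(sig$up, want$up)
  expect_identical(sig$down, want$down)

  ## ties break lexically
  tied <- setNames(c(1, 1, 2, 3, 3, 3, rep(10, 54)),
                   sprintf("G%05d", c(6, 2, 9, 3, 1, 5, 10:63)))
  sig2 <- extreme_sets(tied, frac = 0.05)
  expect_identical(sig2$up, c("G00002", "G00006", "G00009"))

  expect_warning(empty <- extreme_sets(med[1:10], frac = 0.05), "zero genes")
  expect_length(empty$up, 0)
})

test_that("intersect_signatures is exact set algebra ordered by mean rank", {
  a <- structure(list(up = c("G1", "G2", "G3"), down = c("G8", "G9")),
                 class = "signature_set")
  b <- structure(list(up = c("G3", "G2"), down = c("G9", "G7")),
                 class = "signature_set")
  both <- intersect_signatures(list(a, b))
  expect_identical(both$up, c("G2", "G3"))
  expect_identical(both$down, "G9")
  disj <- intersect_signatures(list(
    a, structure(list(up = "GX", down = "GY"), class = "signature_set")))
  expect_length(disj$up, 0)
  same <- intersect_signatures(list(a, a))
  expect_setequal(same$up, a$up)

  ## ordering follows the mean median-rank when supplied
  meds <- list(c(G1 = 5, G2 = 1, G3 = 2, G8 = 90, G9 = 99, G7 = 80),
               c(G1 = 6, G2 = 3, G3 = 1, G8 = 85, G9 = 98, G7 = 70))
  ordered <- intersect_signatures(list(a, b), meds)
  expect_identical(ordered$up, c("G3", "G2"))  # mean ranks 1.5 < 2
})

test_that("middle_band implements both the rank and percentile readings", {
  n <- 100
  med <- setNames(1:n, sprintf("G%05d", 1:n))
  mid <- middle_band(med, width_frac = 0.10, mode = "rank")
  ## |rank - 50| <= 10 -> ranks 40..60
  expect_identical(mid, sort(names(med)[40:60]))
  expect_true(sprintf("G%05d", 50) %in% mid)
  pct <- middle_band(med, width_frac = 0.10, mode = "percentile")
  expect_equal(length(pct) / n, 0.2, tolerance = 0.05)
  skewed <- setNames(c(rep(1, 90), 91:100), sprintf("G%05d", 1:100))
  expect_gt(length(middle_band(skewed, mode = "percentile")),
            length(middle_band(skewed, mode = "rank")))
})

test_that("novel_candidates and novelty_split partition correctly", {
  de <- data.frame(probe_id = c("G1", "G2", "G3", "G4"),
                   padj = c(0.01, 0.2, NA, 0.03), stringsAsFactors = FALSE)
  expect_identical(novel_candidates(c("G2", "G4", "G9"), de), "G4")
  expect_identical(novel_candidates(character(0), de), character(0))

  tab <- data.frame(gene = c("G1", "G2", "G3"), flag = c(TRUE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  sp <- novelty_split(c("G1", "G2", "G3", "G5"), tab)
  expect_identical(sp$known, c("G1", "G3"))
  expect_identical(sp$novel, "G2")
  expect_identical(sp$uncovered, "G5")
})

test_that("overlap_score counts overlaps exactly and flags anticorrelation", {
  n <- 1000
  genes <- sprintf("G%05d", 1:n)
  profile <- setNames(1:n, genes)
  sig <- structure(list(up = genes[1:20], down = genes[(n - 19):n]),
                   class = "signature_set")
  sc <- overlap_score(sig, profile, frac = 0.05)
  expect_identical(sc$overlap_up, 20L)
  expect_identical(sc$overlap_down, 20L)
  expect_lt(sc$p_combined, 1e-20)
  expect_false(sc$anticorrelated)
  ## a reversed query is flagged
  rev_sig <- structure(list(up = sig$down, down = sig$up),
                       class = "signature_set")
  expect_true(overlap_score(rev_sig, profile, frac = 0.05)$anticorrelated)

  ## the mid-p components agree with direct hypergeometric arithmetic
  set.seed(7)
  q <- structure(list(up = sample(genes, 30), down = sample(genes, 30)),
                 class = "signature_set")
  sc2 <- overlap_score(q, profile, frac = 0.05)
  k <- 50
  ou <- length(intersect(q$up, genes[1:k]))
  want <- phyper(ou, k, n - k, 30, lower.tail = FALSE) +
    0.5 * dhyper(ou, k, n - k, 30)
  expect_equal(sc2$p_up, want)
  expect_identical(sc2$overlap_up, ou)
})

test_that("overlap_score null p-values are roughly uniform", {
  set.seed(31)
  genes <- sprintf("G%05d", 1:500)
  ps <- replicate(300, {
    prof <- setNames(sample(500), genes)
    q <- structure(list(up = sample(genes, 25), down = sample(genes, 25)),
                   class = "signature_set")
    overlap_score(q, prof)$p_combined
  })
  expect_lt(abs(mean(ps) - 0.5), 0.06)
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.06)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.1)
})

test_that("planted PCA outliers are removed exactly", {
  r <- simulate_rank_profiles(n_genes = 1000,
                              samples_per_type = c(t1 = 69),
                              up_genes = sprintf("G%05d", 1:25),
                              down_genes = sprintf("G%05d", 26:50),
                              n_outliers = 5, seed = 3)
  keep <- remove_outlier_samples(r, cell_type = attr(r, "cell_type"))
  expect_identical(sort(keep$removed), sort(attr(r, "outliers")))
  expect_length(keep$retained, 69)
  expect_error(remove_outlier_samples(r[, 1:3],
                                      cell_type = rep("t1", 3)),
               "fewer than 4")
})

test_that("rank profiles and signatures round-trip through TSV", {
  r <- simulate_rank_profiles(n_genes = 50,
                              samples_per_type = c(a = 4, b = 4), seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_rank_profiles(r, path)
  back <- read_rank_profiles(path)
  expect_identical(unclass(back)[, ], unclass(r)[, ])
  expect_identical(attr(back, "cell_type"), attr(r, "cell_type"))

  sig <- structure(list(up = c("G1", "G2"), down = "G9"),
                   class = "signature_set")
  sp <- tempfile(fileext = ".tsv")
  write_signature(sig, sp)
  back_sig <- read_signature(sp)
  expect_identical(back_sig$up, sig$up)
  expect_identical(back_sig$down, sig$down)
})
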