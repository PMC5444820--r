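make_sheet <- function() {
  data.frame(sample_id = c("s1", "s2"),
             index1 = c("AAAAAAAAA", "CCCCCCCCC"),
             index2 = c("GGGGGGGGG", "TTTTTTTTT"),
             stringsAsFactors = FALSE)
}

test_that("demultiplex assigns exact and near-exact index pairs", {
  sheet <- make_sheet()
  insert <- strrep("ACGTG", 10)
  reads <- data.frame(
    id = paste0("r", 1:4),
    seq = c(paste0("AAAAAAAAA", "GGGGGGGGG", insert),   # exact s1
            paste0("CAAAAAAAA", "GGGGGGGGG", insert),   # 1 mm on index1 -> s1
            paste0("CCCCCCCCC", "TTTTTTTTA", insert),   # 1 mm on index2 -> s2
            paste0("AACCAAAAA", "GGGGGGGGG", insert)),  # 2 mm -> undetermined
    stringsAsFactors = FALSE)
  dm <- demultiplex(reads, sheet, max_index_mismatch = 1)
  expect_identical(dm$s1$id, c("r1", "r2"))
  expect_identical(dm$s2$id, "r3")
  expect_identical(dm$undetermined$id, "r4")
  ## the 18-nt index prefix is stripped from assigned reads
  expect_true(all(dm$s1$seq == insert))
  ## at zero tolerance only the exact read survives
  dm0 <- demultiplex(reads, sheet, max_index_mismatch = 0)
  expect_identical(dm0$s1$id, "r1")
  expect_identical(sort(dm0$undetermined$id), c("r2", "r3", "r4"))
})

test_that("demultiplex refuses sheets whose indexes can collide", {
  sheet <- data.frame(sample_id = c("s1", "s2"),
                      index1 = c("AAAAAAAAA", "AAAAAAAAT"),
                      index2 = c("GGGGGGGGG", "GGGGGGGGC"),
                      stringsAsFactors = FALSE)
  reads <- data.frame(id = "r", seq = strrep("A", 68),
                      stringsAsFactors = FALSE)
  expect_error(demultiplex(reads, sheet, max_index_mismatch = 1),
               "index collision")
  ## the same sheet is fine at zero tolerance
  expect_silent(demultiplex(reads, sheet, max_index_mismatch = 0))
})

test_that("the aligner agrees with the exhaustive Hamming oracle", {
  set.seed(21)
  pool <- random_pool(30, seed = 21)
  src <- sample.int(30, 200, replace = TRUE)
  reads <- pool$ligated[src]
  for (i in seq_along(reads)) {
    n_err <- sample(0:3, 1)
    for (p in sample.int(50, n_err)) reads[i] <- flip_base(reads[i], p)
    if (runif(1) < 0.3) reads[i] <- substr(reads[i], 1, sample(35:50, 1))
  }
  aln <- align_reads(reads, pool)
  for (i in seq_along(reads)) {
    want <- oracle_align_one(reads[i], pool$ligated)
    if (want$index > 0) {
      expect_identical(aln$class[i], "mapped")
      expect_identical(aln$probe_id[i], pool$probe_id[want$index])
      expect_identical(aln$mismatches[i], want$mismatches)
    } else {
      expect_true(aln$class[i] %in% c("unmapped", "chimera"))
    }
  }
})

test_that("ambiguous best hits are discarded", {
  pool <- random_pool(4, seed = 2)
  ## duplicate the first 50-mer under a second id: every read from it ties
  dup <- probe_pool(c(pool$probe_id, "PDUP"), c(pool$gene_id, "GDUP"),
                    c(pool$downstream_arm, pool$downstream_arm[1]),
                    c(pool$upstream_arm, pool$upstream_arm[1]))
  aln <- align_reads(pool$ligated[1], dup)
  expect_identical(aln$class, "unmapped")
})

test_that("partial reads are rescued down to 40 nt and no further", {
  pool <- random_pool(10, seed = 5)
  r40 <- substr(pool$ligated[3], 1, 40)
  r39 <- substr(pool$ligated[3], 1, 39)
  aln <- align_reads(c(r40, r39), pool)
  expect_identical(aln$class, c("mapped", "unmapped"))
  expect_identical(aln$probe_id[1], pool$probe_id[3])
  ## a rescued read still tolerates mismatches within its length
  aln2 <- align_reads(flip_base(r40, 17), pool)
  expect_identical(aln2$class, "mapped")
  expect_identical(aln2$mismatches, 1L)
})

test_that("chimera reads are classified with both contributing probes", {
  pool <- random_pool(12, seed = 8)
  chim <- paste0(substr(pool$ligated[2], 1, 25), substr(pool$ligated[7], 26, 50))
  aln <- align_read(chim, pool)
  expect_identical(aln$class, "chimera")
  expect_identical(aln$chimera_probe_a, pool$probe_id[2])
  expect_identical(aln$chimera_probe_b, pool$probe_id[7])
  ## one sequencing error per half must not hide the chimera
  noisy <- flip_base(flip_base(chim, 10), 40)
  expect_identical(align_read(noisy, pool)$class, "chimera")
  ## both halves from one probe is just that probe, not a chimera
  expect_identical(align_read(pool$ligated[2], pool)$class, "mapped")
  ## truncated chimeras cannot be split-half classified
  expect_identical(align_read(substr(chim, 1, 45), pool)$class, "unmapped")
})

test_that("count_sample accounting adds up and restricts the chimera denominator", {
  pool <- random_pool(6, seed = 3)
  chim <- paste0(substr(pool$ligated[1], 1, 25), substr(pool$ligated[4], 26, 50))
  reads <- c(rep(pool$ligated[1], 5), rep(pool$ligated[2], 3),
             substr(pool$ligated[3], 1, 45),        # mapped partial
             substr(pool$ligated[3], 1, 20),        # unmapped short
             chim)
  cs <- count_sample(align_reads(reads, pool), pool)
  expect_identical(unname(cs$counts[pool$probe_id[1:3]]), c(5L, 3L, 1L))
  a <- cs$accounting
  expect_identical(a$total, 11L)
  expect_identical(a$total, a$mapped + a$chimera + a$unmapped)
  expect_identical(a$mapped, 9L)
  expect_identical(a$chimera, 1L)
  expect_identical(a$full_length, 9L)          # the 50-nt reads only
  expect_equal(a$misligation_fraction, 1 / 9)  # chimeras over full length
  expect_equal(a$mapped_fraction, 9 / 11)
})

test_that("FASTQ files round-trip, including gzip", {
  reads <- data.frame(id = c("a:1", "b:2"), seq = c("ACGT", "GGCCA"),
                      stringsAsFactors = FALSE)
  for (ext in c(".fastq", ".fastq.gz")) {
    path <- tempfile(fileext = ext)
    write_fastq(reads, path)
    back <- read_fastq(path)
    expect_equal(back, reads)
  }
})
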