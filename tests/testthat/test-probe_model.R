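test_that("probe_pool builds the ligated 50-mer and validates its fields", {
  p <- probe_pool("P1", "G1", strrep("A", 25), strrep("C", 25))
  expect_s3_class(p, "probe_pool")
  expect_identical(p$ligated, paste0(strrep("A", 25), strrep("C", 25)))
  expect_identical(p$attenuation_ratio, 0)

  expect_error(probe_pool("P1", "G1", strrep("A", 24), strrep("C", 25)),
               "row 1.*downstream_arm.*25-nt")
  expect_error(probe_pool("P1", "G1", strrep("a", 25), strrep("C", 25)),
               "downstream_arm")
  expect_error(probe_pool(c("P1", "P1"), c("G1", "G2"),
                          rep(strrep("A", 25), 2), rep(strrep("C", 25), 2)),
               "row 2.*duplicate probe_id")
  expect_error(probe_pool("P1", "G1", strrep("A", 25), strrep("C", 25),
                          attenuation_ratio = -1),
               "non-negative")
})

test_that("manifests round-trip through TSV", {
  pool <- random_pool(8, seed = 3, attenuated_fraction = 0.25)
  path <- tempfile(fileext = ".tsv")
  write_manifest(pool, path)
  back <- read_manifest(path, name = attr(pool, "name"))
  expect_equal(as.data.frame(back), as.data.frame(pool))
  expect_error(read_manifest(textConnection("probe_id\tgene_id\nP1\tG1")),
               "missing column")
})

test_that("validate_pool finds duplicate 50-mers and cross-gene junction clashes", {
  base <- random_pool(5, seed = 11)
  ok <- validate_pool(base)
  expect_true(ok$pass)

  ## plant an exact duplicate 50-mer under a new probe id
  dup <- probe_pool(c(base$probe_id, "PDUP"), c(base$gene_id, "GDUP"),
                    c(base$downstream_arm, base$downstream_arm[1]),
                    c(base$upstream_arm, base$upstream_arm[1]))
  v <- validate_pool(dup)
  expect_false(v$pass)
  expect_identical(sort(c(v$duplicate_ligated$probe_a[1],
                          v$duplicate_ligated$probe_b[1])),
                   sort(c(base$probe_id[1], "PDUP")))

  ## same junction window on a different gene is a conflict ...
  d2 <- paste0(substr(random_dna(1, 25), 1, 22),
               substr(base$downstream_arm[2], 23, 25))
  u2 <- paste0(substr(base$upstream_arm[2], 1, 3),
               substr(random_dna(1, 25), 4, 25))
  clash <- probe_pool(c(base$probe_id, "PX"), c(base$gene_id, "GX"),
                      c(base$downstream_arm, d2), c(base$upstream_arm, u2))
  v2 <- validate_pool(clash, junction_k = 3)
  expect_false(v2$pass)
  expect_true(nrow(v2$junction_conflicts) >= 1)

  ## ... but the same junction window within one gene is allowed
  same_gene <- probe_pool(c(base$probe_id, "PX"),
                          c(base$gene_id, base$gene_id[2]),
                          c(base$downstream_arm, d2),
                          c(base$upstream_arm, u2))
  expect_identical(nrow(validate_pool(same_gene)$junction_conflicts), 0L)
})

test_that("pool_intersection returns shared probes and is symmetric", {
  a <- random_pool(10, seed = 5)
  b_ids <- a$probe_id[3:7]
  b <- probe_pool(b_ids, a$gene_id[3:7], a$downstream_arm[3:7],
                  a$upstream_arm[3:7])
  expect_identical(pool_intersection(a, b), b_ids)
  expect_identical(sort(pool_intersection(b, a)), sort(b_ids))
  ## same id but different sequence does not count as shared
  c_pool <- probe_pool(a$probe_id[1], "G", random_dna(1, 25), random_dna(1, 25))
  expect_length(pool_intersection(a, c_pool), 0)
})

test_that("sample sheets are validated on read and write", {
  sheet <- data.frame(sample_id = c("s1", "s2"),
                      index1 = c("AAAAAAAAA", "CCCCCCCCC"),
                      index2 = c("GGGGGGGGG", "TTTTTTTTT"),
                      stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write_sample_sheet(sheet, path)
  expect_equal(read_sample_sheet(path), sheet)

  bad <- sheet; bad$index1[1] <- "AAAA"
  expect_error(validate_sample_sheet(bad), "9-nt")
  dup <- sheet; dup$index1[2] <- "AAAAAAAAA"; dup$index2[2] <- "GGGGGGGGG"
  expect_error(validate_sample_sheet(dup), "unique")
  dup_id <- sheet; dup_id$sample_id[2] <- "s1"
  expect_error(validate_sample_sheet(dup_id), "sample_id")
})

test_that("random_pool generates valid pools with the requested attenuation", {
  pool <- random_pool(200, seed = 1, attenuated_fraction = 0.1,
                      attenuation_ratios = c(4, 9))
  expect_identical(nrow(pool), 200L)
  expect_true(validate_pool(pool)$pass)
  expect_identical(sum(pool$attenuation_ratio > 0), 20L)
  expect_true(all(pool$attenuation_ratio %in% c(0, 4, 9)))
  ## deterministic in the seed
  expect_equal(as.data.frame(random_pool(50, seed = 9)),
               as.data.frame(random_pool(50, seed = 9)))
})

test_that("random_sample_sheet separates every pair of index pairs", {
  sheet <- random_sample_sheet(paste0("s", 1:6), seed = 2,
                               max_index_mismatch = 1)
  for (a in 1:5) {
    for (b in (a + 1):6) {
      d1 <- sum(utf8ToInt(sheet$index1[a]) != utf8ToInt(sheet$index1[b]))
      d2 <- sum(utf8ToInt(sheet$index2[a]) != utf8ToInt(sheet$index2[b]))
      expect_true(d1 > 2 || d2 > 2)
    }
  }
})

test_that("add_mismatch_variants creates the six junction variants", {
  pool <- tiny_pool()
  target <- pool$probe_id[2]
  ext <- add_mismatch_variants(pool, target, seed = 1)
  v <- ext[!is.na(ext$variant_of), ]
  expect_identical(nrow(v), 6L)
  expect_identical(sort(v$mm_position), c(-3L, -2L, -1L, 1L, 2L, 3L))
  parent <- pool$ligated[2]
  for (i in seq_len(6)) {
    diff_pos <- which(strsplit(v$ligated[i], "")[[1]] !=
                        strsplit(parent, "")[[1]])
    ## exactly one substitution, at the declared junction offset
    expect_length(diff_pos, 1)
    p <- v$mm_position[i]
    expect_identical(diff_pos, if (p < 0) 26L + p else 25L + p)
    expect_identical(v$probe_id[i], sprintf("%s_mm%+d", target, p))
  }
  expect_error(add_mismatch_variants(pool, "nope"), "unknown probe_id")
})
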