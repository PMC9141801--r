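test_that("read_pedigree builds trios and reports incomplete families", {
  ped <- tempfile(fileext = ".ped")
  writeLines(c(
    "fam1\tdad1\t0\t0\t1\t1",
    "fam1\tmom1\t0\t0\t2\t1",
    "fam1\tkid1\tdad1\tmom1\t1\t2",
    "fam2\tmom2\t0\t0\t2\t1",
    "fam2\tkid2\t0\tmom2\t1\t2",      # duo: father absent
    "fam3\tlone\t0\t0\t1\t1"),        # singleton founder
    ped)
  expect_warning(ts <- read_pedigree(ped), "kid2")
  expect_equal(n_trios(ts), 1)
  expect_equal(ts$trios$child_id, "kid1")
  expect_true(ts$trios$child_affected)
  # the duo child, the duo's founder, and the singleton are all reported
  expect_setequal(ts$exclusions$id, c("kid2", "mom2", "lone"))
  expect_match(ts$exclusions$reason[ts$exclusions$id == "kid2"],
               "missing father")
})

test_that("read_pedigree errors on duplicated child IDs", {
  ped <- tempfile(fileext = ".ped")
  writeLines(c(
    "f1\td\t0\t0\t1\t1", "f1\tm\t0\t0\t2\t1",
    "f1\tk\td\tm\t1\t2", "f2\tk\td\tm\t1\t2"), ped)
  expect_error(read_pedigree(ped), "duplicated")
})

test_that("a cohort-scale pedigree yields the full trio count", {
  # 83 families -> 249 samples, matching a full sequencing release
  n <- 83
  lines <- unlist(lapply(seq_len(n), function(i) {
    f <- sprintf("f%02d", i)
    c(sprintf("%s\t%s_d\t0\t0\t1\t1", f, f),
      sprintf("%s\t%s_m\t0\t0\t2\t1", f, f),
      sprintf("%s\t%s_k\t%s_d\t%s_m\t1\t2", f, f, f, f))
  }))
  ped <- tempfile(fileext = ".ped")
  writeLines(lines, ped)
  ts <- read_pedigree(ped)
  expect_equal(n_trios(ts), 83)
  expect_equal(length(ts$samples), 249)
})

test_that("region membership uses the 1-based inclusive user convention", {
  rs <- region_spec("20", 7065143, 7202442)
  # a documented in-target position is retained; the flanks behave as
  # closed bounds
  expect_true(in_regions(rs, "20", 7117108))
  expect_true(in_regions(rs, "20", 7065143))
  expect_true(in_regions(rs, "20", 7202442))
  expect_false(in_regions(rs, "20", 7065142))
  expect_false(in_regions(rs, "20", 7202443))
  expect_false(in_regions(rs, "7", 7117108))
  # internal half-open invariant: start0 < p <= end0
  iv <- rs$intervals
  expect_equal(iv$start0, 7065142)
  expect_equal(iv$end0, 7202442)
})

test_that("region_spec merges overlapping intervals", {
  rs <- region_spec(c("1", "1", "2"), c(100, 150, 100), c(200, 300, 200))
  expect_equal(nrow(rs$intervals), 2)
  expect_equal(rs$intervals$end0[rs$intervals$chrom == "1"], 300)
})

test_that("VCF ingest restricts to regions, reorders samples, derives alt_ratio", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="d">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="q">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="a">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tpa\tma\tkid",
    "20\t7117108\trsA\tA\tG\t.\tPASS\t.\tGT:DP:GQ:AD\t0/1:30:99:22,8\t0/0:25:80:25,0\t0/1:40:99:34,6",
    "20\t9999999\trsOut\tC\tT\t.\tPASS\t.\tGT:DP:GQ:AD\t0/0:30:99:30,0\t0/0:30:99:30,0\t0/0:30:99:30,0",
    "20\t7120000\trsB\tC\tT\t.\tPASS\t.\tGT:DP:GQ:AD\t0/1:8:20:6,2\t./.:.:.:.\t1/1:50:99:1,49"),
    vcf)
  ts <- trio_set(data.frame(trio_id = "t1", child_id = "kid",
                            mother_id = "ma", father_id = "pa",
                            child_affected = TRUE, stringsAsFactors = FALSE))
  rs <- region_spec("20", 7065143, 7202442)
  x <- read_genotypes(vcf, rs, ts)
  expect_equal(nrow(x$variants), 2)           # rsOut dropped
  expect_equal(x$variants$id, c("rsA", "rsB"))
  expect_equal(x$samples, c("kid", "ma", "pa"))  # trio order, not VCF order
  dos <- cohort_dosage(x)
  expect_equal(unname(dos["rsA", ]), c(1L, 0L, 1L))
  expect_equal(unname(dos["rsB", ]), c(2L, NA_integer_, 1L))
  ar <- cohort_alt_ratio(x)
  expect_equal(ar[2, 3], 2 / 8)               # AD (6,2) -> 0.25
  expect_equal(x$dp[1, 1], 40)
  # missing trio sample is a hard error naming the sample
  ts2 <- trio_set(data.frame(trio_id = "t1", child_id = "ghost",
                             mother_id = "ma", father_id = "pa",
                             child_affected = TRUE, stringsAsFactors = FALSE))
  expect_error(read_genotypes(vcf, rs, ts2), "ghost")
})

test_that("split_multiallelic separates alternates and masks cross-alt genotypes", {
  variants <- data.frame(chrom = "1", pos = 500, id = "tri", ref = "A",
                         alt = "G,T", stringsAsFactors = FALSE)
  # samples: 0/0, 0/1 (alt G), 0/2 (alt T), 1/2 (both), 2/2, ./.
  a1 <- matrix(c(0L, 0L, 0L, 1L, 2L, NA), 1)
  a2 <- matrix(c(0L, 1L, 2L, 2L, 2L, NA), 1)
  x <- trio_cohort(variants, paste0("s", 1:6), a1, a2,
                   ad = matrix(c("10,0,0", "5,5,0", "6,0,4", "1,4,5",
                                 "0,0,9", "."), 1))
  y <- split_multiallelic(x)
  expect_equal(nrow(y$variants), 2)
  expect_equal(y$variants$alt, c("G", "T"))
  dos <- cohort_dosage(y)
  # G record: 0/2 and 1/2 and 2/2 carry the other alt -> missing
  expect_equal(unname(dos[1, ]), c(0L, 1L, NA, NA, NA, NA))
  # T record: 0/1 carries the other alt -> missing; 2/2 is hom focal
  expect_equal(unname(dos[2, ]), c(0L, NA, 1L, NA, 2L, NA))
  # alt_ratio follows the focal alternate
  ar <- cohort_alt_ratio(y)
  expect_equal(ar[1, 2], 0.5)
  expect_equal(ar[2, 3], 0.4)
  # idempotent
  z <- split_multiallelic(y)
  expect_identical(cohort_dosage(z), cohort_dosage(y))
  expect_identical(z$variants, y$variants)
  # biallelic input is returned unchanged
  b <- make_cohort(matrix(c(0L, 1L, 2L), 1))
  expect_identical(split_multiallelic(b), b)
})

test_that("half-called genotypes are set fully missing", {
  variants <- data.frame(chrom = "1", pos = 1, id = "v", ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  x <- trio_cohort(variants, c("s1", "s2"),
                   a1 = matrix(c(0L, NA), 1), a2 = matrix(c(NA, 1L), 1))
  expect_true(all(is.na(cohort_dosage(x))))
})

test_that("VCF round trip preserves dosage, DP and GQ", {
  set.seed(7)
  sim <- simulate_cohort(sim_config(n_trios = 6, n_variants = 30, seed = 11,
                                    missing_rate = 0.05))
  dir <- tempfile(); paths <- write_cohort(sim, dir)
  ts <- read_pedigree(paths$ped)
  expect_equal(n_trios(ts), 6)
  rs <- read_bed(paths$bed)
  x <- read_genotypes(paths$vcf, rs, ts)
  expect_identical(cohort_dosage(x), cohort_dosage(sim$cohort))
  expect_equal(x$dp, sim$cohort$dp)
  expect_equal(x$gq, sim$cohort$gq)
  expect_equal(cohort_alt_ratio(x), cohort_alt_ratio(sim$cohort))
})
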