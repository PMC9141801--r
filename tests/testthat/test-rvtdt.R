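# deterministic rare-variant fixture: explicit event structure via dosages
# trios columns are (child, mother, father)
rare_fixture <- function() {
  # 6 trios, 3 variants; alt is rare (few carriers among 12 parents)
  # v1: trios 1,2,3 het mother transmits; v2: trio 4 het father does not;
  # v3: trio 5 het mother transmits, trio 6 het father transmits
  d <- rbind(
    c(1,1,0, 1,1,0, 1,1,0, 0,0,0, 0,0,0, 0,0,0),
    c(0,0,0, 0,0,0, 0,0,0, 0,0,1, 0,0,0, 0,0,0),
    c(0,0,0, 0,0,0, 0,0,0, 0,0,0, 1,1,0, 1,0,1))
  storage.mode(d) <- "integer"
  list(x = make_cohort(d), tr = make_trios(6))
}

test_that("collapse_region selects by founder MAF with an inclusive bound", {
  fx <- rare_fixture()
  # founder MAFs: v1 3/24, v2 1/24, v3 2/24 -> threshold 3/24 keeps all,
  # 1.5/24 keeps v2 only, common threshold 0 keeps none
  rvs_all <- collapse_region(fx$x, fx$tr, "r", maf_threshold = 3 / 24)
  expect_equal(nrow(rvs_all$variants), 3)
  rvs_exact <- collapse_region(fx$x, fx$tr, "r", maf_threshold = 1 / 24)
  expect_equal(rvs_exact$variants$id, "v2")   # MAF == threshold included
  rvs_none <- collapse_region(fx$x, fx$tr, "r", maf_threshold = 1 / 100)
  expect_equal(nrow(rvs_none$variants), 0)
  expect_equal(nrow(rvs_none$events), 0)
  # a common-variant region collapses to an empty set
  common <- make_cohort(matrix(rep(c(1L, 1L, 0L), 6), 1))
  rvs_c <- collapse_region(common, make_trios(6), "c", maf_threshold = 0.01)
  expect_equal(nrow(rvs_c$variants), 0)
})

test_that("one event is recorded per heterozygous parent", {
  fx <- rare_fixture()
  rvs <- collapse_region(fx$x, fx$tr, "r", maf_threshold = 0.2)
  expect_equal(nrow(rvs$events), 6)
  expect_equal(sum(rvs$events$transmitted), 5)  # five transmitted, one not
  # double-het parents contribute two events
  d <- trio_dosage_row(c(1L, 1L, 1L))
  x <- make_cohort(rbind(d, matrix(rep(c(0L, 0L, 0L), 1), 1)))
  rvs2 <- collapse_region(x, make_trios(1), "r", maf_threshold = 0.6)
  expect_equal(nrow(rvs2$events), 2)
  expect_equal(sort(rvs2$events$transmitted), c(0L, 1L))
})

test_that("burden statistics behave as defined on forced cases", {
  fx <- rare_fixture()
  rvs <- collapse_region(fx$x, fx$tr, "r", maf_threshold = 0.2)
  # BRV: T - U = 5 - 1
  expect_equal(burden_statistic(rvs, "BRV"), 4)
  # CMC: trios transmitting >=1 (1,2,3,5,6) minus un-transmitting >=1 (4)
  expect_equal(burden_statistic(rvs, "CMC"), 4)
  expect_error(burden_statistic(rvs, "SKAT"), "unknown")
  # single rare variant with T=3, U=0
  single <- cohort_subset(fx$x, 1)
  rvs1 <- collapse_region(single, fx$tr, "r", maf_threshold = 0.2)
  expect_equal(burden_statistic(rvs1, "BRV"), 3)
  # balanced transmissions give BRV 0
  bal <- make_cohort(rbind(c(1L,1L,0L, 0L,1L,0L, 0L,0L,0L, 0L,0L,0L)))
  rvsb <- collapse_region(bal, make_trios(4), "r", maf_threshold = 0.2)
  expect_equal(burden_statistic(rvsb, "BRV"), 0)
})

test_that("BRV is additive over the region's variants", {
  sim <- simulate_cohort(sim_config(
    n_trios = 40, n_variants = 80, seed = 303,
    maf = list(p_rare = 0.5, rare_range = c(0.002, 0.01),
               common_range = c(0.1, 0.5))))
  x <- sim$cohort; tr <- sim$trios
  rvs <- collapse_region(x, tr, "all", maf_threshold = 0.01)
  expect_gt(nrow(rvs$events), 0)
  # per-variant (T - U) from the single-variant engine, minor-oriented
  f_alt <- triotdt:::founder_alt_freq(x, tr)
  per_var <- vapply(seq_len(nrow(rvs$variants)), function(k) {
    i <- match(rvs$variants$id[k], x$variants$id)
    sub <- cohort_subset(x, i)
    if (f_alt[i] > 0.5) { sub$a1 <- 1L - sub$a1; sub$a2 <- 1L - sub$a2 }
    res <- run_tdt(sub, tr, significance_thresholds())
    if (nrow(res) == 0) 0 else res$T - res$U
  }, numeric(1))
  expect_equal(burden_statistic(rvs, "BRV"), sum(per_var))
})

test_that("WSS equals a hand-computed weighted sum and matches BRV under equal weights", {
  fx <- rare_fixture()
  rvs <- collapse_region(fx$x, fx$tr, "r", maf_threshold = 0.2)
  # per variant: (n, T, U) = v1 (3,3,0), v2 (1,0,1), v3 (2,2,0)
  byhand <- sum(mapply(function(n, t, u) {
    q <- (u + 1) / (n + 2); (t - u) / sqrt(n * q * (1 - q))
  }, c(3, 1, 2), c(3, 0, 2), c(0, 1, 0)))
  expect_equal(burden_statistic(rvs, "WSS"), byhand)
})

test_that("VT maximizes over thresholds and dominates BRV", {
  fx <- rare_fixture()
  rvs <- collapse_region(fx$x, fx$tr, "r", maf_threshold = 0.2)
  vt <- vt_statistic(rvs)
  expect_gte(vt$statistic, burden_statistic(rvs, "BRV"))
  # MAF order: v2 (1/24, T-U = -1), v3 (2/24, +2), v1 (3/24, +3)
  # cumulative: -1, 1, 4 -> max 4 at the largest threshold
  expect_equal(vt$statistic, 4)
  expect_equal(vt$chosen_threshold, 3 / 24)
  # degenerate: one distinct MAF -> identical to BRV
  single <- cohort_subset(fx$x, 1)
  rvs1 <- collapse_region(single, fx$tr, "r", maf_threshold = 0.2)
  expect_equal(vt_statistic(rvs1)$statistic, burden_statistic(rvs1, "BRV"))
})

test_that("permutation p-values are reproducible, positive, and sane", {
  fx <- rare_fixture()
  rvs <- collapse_region(fx$x, fx$tr, "r", maf_threshold = 0.2)
  r1 <- permutation_p(rvs, "BRV", n_permutations = 500, seed = 17)
  r2 <- permutation_p(rvs, "BRV", n_permutations = 500, seed = 17)
  expect_identical(r1, r2)
  expect_true(r1$p > 0 && r1$p <= 1)
  expect_warning(permutation_p(rvs, "BRV", n_permutations = 50, seed = 1),
                 "coarse")
  expect_error(permutation_p(rvs, "BRV", n_permutations = 500), "seed")
  # statistic 0 under a symmetric null gives p at (or near) 1
  bal <- make_cohort(rbind(c(1L,1L,0L, 0L,1L,0L, 0L,0L,0L, 0L,0L,0L)))
  rvsb <- collapse_region(bal, make_trios(4), "r", maf_threshold = 0.2)
  rb <- permutation_p(rvsb, "BRV", n_permutations = 200, seed = 5)
  expect_equal(rb$p, 1)
})

test_that("a planted rare-variant transmission excess is detected", {
  # region of 5 rare variants, each with forced transmissions: T=10, U=2
  set.seed(23)
  nt <- 30
  rows <- lapply(1:5, function(v) {
    d <- matrix(0L, 1, 3 * nt)
    carriers <- sample(nt, 12)
    tx <- c(rep(TRUE, 10), rep(FALSE, 2))
    for (j in seq_along(carriers)) {
      t <- carriers[j]
      d[1, 3 * t - 1] <- 1L                 # het mother
      if (tx[j]) d[1, 3 * t - 2] <- 1L      # transmitted to child
    }
    d
  })
  x <- make_cohort(do.call(rbind, rows))
  tr <- make_trios(nt)
  rvs <- collapse_region(x, tr, "sig", maf_threshold = 0.15)
  expect_equal(nrow(rvs$variants), 5)
  for (tn in c("CMC", "BRV", "WSS", "VT")) {
    r <- permutation_p(rvs, tn, n_permutations = 1000, seed = 99)
    expect_lt(r$p, 0.05)
  }
})

test_that("rvtdt_scan runs multiple regions and tests", {
  sim <- simulate_cohort(sim_config(
    n_trios = 40, n_variants = 60, seed = 404,
    maf = list(p_rare = 0.6, rare_range = c(0.002, 0.01),
               common_range = c(0.1, 0.5))))
  x <- sim$cohort; tr <- sim$trios
  regions <- list(first_half = seq_len(30), second_half = 31:60)
  res <- rvtdt_scan(x, tr, regions, tests = c("BRV", "VT"),
                    n_permutations = 200, seed = 7)
  expect_true(all(res$test %in% c("BRV", "VT")))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$n_permutations == 200))
})
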