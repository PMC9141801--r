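# Published worked examples: transmitted/untransmitted counts with their
# printed odds ratios and p-values (3 significant figures).
worked_examples <- data.frame(
  id = c("rs147839746", "rs3028890", "rs6054770", "rs2207588", "rs71330228",
         "rs71330230", "rs11763098", "rs2006387", "rs10262453", "rs4723276",
         "rs12538649", "rs1978333", "rs3067084", "rs35111023", "rs182795",
         "rs1475000", "rs172982", "rs56404749", "rs2180780", "rs35420824"),
  T = c(80, 90, 83, 81, 10, 76, 14, 15, 58, 58, 59, 52, 0, 0, 1, 1, 1, 1, 1, 0),
  U = c(11, 13, 13, 12, 82, 12, 55, 53, 10, 10, 11, 11, 24, 23, 24, 24, 24,
        20, 24, 21),
  OR = c(7.273, 6.923, 6.385, 6.75, 0.122, 6.333, 0.2545, 0.2830, 5.8, 5.8,
         5.364, 4.727, 0, 0, 0.04167, 0.04167, 0.04167, 0.05, 0.04167, 0),
  p = c(4.72e-13, 3.27e-14, 9.04e-13, 8.37e-13, 6.07e-14, 8.95e-12,
        7.98e-7, 4.06e-6, 5.86e-9, 5.86e-9, 9.63e-9, 2.40e-7, 9.63e-7,
        1.62e-6, 4.23e-6, 4.23e-6, 4.23e-6, 3.38e-5, 4.23e-6, 4.59e-6),
  stringsAsFactors = FALSE)

sig3 <- function(x) signif(x, 3)

test_that("tdt_statistic reproduces every published (T, U) worked example", {
  st <- tdt_statistic(worked_examples$T, worked_examples$U)
  # agreement at 3 significant figures: within half a unit in the third
  # digit (0.5% relative) of each printed value
  expect_true(all(abs(st$p - worked_examples$p) / worked_examples$p < 0.005))
  # odds ratios match at the precision each row was printed with
  printed_digits <- nchar(sub("^[0.]*", "", sub("\\.", "", worked_examples$OR)))
  for (k in seq_len(nrow(worked_examples))) {
    expect_equal(signif(st$OR[k], max(printed_digits[k], 1)),
                 worked_examples$OR[k],
                 info = worked_examples$id[k])
  }
})

test_that("tdt_statistic handles degenerate and symmetric counts", {
  st <- tdt_statistic(c(5, 0, 7), c(5, 24, 0))
  expect_equal(st$chi2[1], 0); expect_equal(st$p[1], 1); expect_equal(st$OR[1], 1)
  expect_equal(st$OR[2], 0)
  expect_equal(st$OR[3], Inf)
  und <- tdt_statistic(0, 0)
  expect_true(is.na(und$chi2) && is.na(und$p))
})

test_that("tdt_statistic matches an independent McNemar implementation", {
  set.seed(19)
  T <- rpois(1000, 20); U <- rpois(1000, 20)
  keep <- T + U > 0
  st <- tdt_statistic(T[keep], U[keep])
  ref <- mapply(function(t, u) {
    m <- matrix(c(0, t, u, 0), 2)
    unname(stats::mcnemar.test(m, correct = FALSE)$statistic)
  }, T[keep], U[keep])
  expect_equal(st$chi2, unname(ref), tolerance = 1e-12)
})

test_that("count_transmissions scores one count per heterozygous parent", {
  expect_equal(count_transmissions(1L, 1L, 0L), c(T = 1, U = 0))
  expect_equal(count_transmissions(1L, 1L, 1L), c(T = 1, U = 1))
  expect_equal(count_transmissions(0L, 1L, 1L), c(T = 0, U = 2))
  expect_equal(count_transmissions(2L, 1L, 1L), c(T = 2, U = 0))
  # exhaustive check over every Mendelian-consistent configuration against
  # the brute-force gamete-enumeration oracle
  grid <- expand.grid(child = 0:2, mother = 0:2, father = 0:2)
  for (k in seq_len(nrow(grid))) {
    cons <- oracle_mendel(grid$child[k], grid$mother[k], grid$father[k])
    if (!cons) next
    got <- count_transmissions(grid$child[k], grid$mother[k], grid$father[k])
    want <- oracle_transmissions(grid$child[k], grid$mother[k], grid$father[k])
    expect_equal(got, want, info = paste(grid[k, ], collapse = "/"))
    n_het <- (grid$mother[k] == 1) + (grid$father[k] == 1)
    expect_equal(unname(sum(got)), n_het)
  }
})

test_that("run_tdt orders by p, flags thresholds, and skips untestable variants", {
  # v1: aggregate T=58, U=10 split over trios; v2 weaker; v3 uninformative
  n <- 80
  d1 <- matrix(0L, 1, 3 * n)
  # 58 trios: het mother transmits (child 1); 10 trios: het mother does not
  for (t in seq_len(58)) { d1[1, 3 * t - 2] <- 1L; d1[1, 3 * t - 1] <- 1L }
  for (t in 59:68) d1[1, 3 * t - 1] <- 1L
  d2 <- matrix(0L, 1, 3 * n)
  for (t in seq_len(12)) { d2[1, 3 * t - 2] <- 1L; d2[1, 3 * t - 1] <- 1L }
  for (t in 13:20) d2[1, 3 * t - 1] <- 1L
  d3 <- matrix(0L, 1, 3 * n)  # no heterozygous parents anywhere
  x <- make_cohort(rbind(d1, d2, d3))
  tr <- make_trios(n)
  res <- run_tdt(x, tr)
  expect_equal(nrow(res), 2)              # v3 untestable
  expect_equal(res$id[1], "v1")           # strongest first
  expect_equal(res$T[1], 58); expect_equal(res$U[1], 10)
  expect_equal(res$OR[1], 5.8)
  expect_true(res$suggestive[1] && res$genomewide[1])
  expect_false(res$suggestive[2])
  # minor allele is the alternate here and it is over-transmitted
  expect_equal(res$direction[1], "minor_over_transmitted")
})

test_that("relabeling ref/alt inverts OR and preserves p", {
  sim <- simulate_cohort(sim_config(
    n_trios = 30, n_variants = 60, seed = 13,
    risk_loci = list(risk_locus(1, 30, tau = 0.8))))
  x <- sim$cohort
  tr <- sim$trios
  res <- run_tdt(x, tr)
  y <- x
  y$a1 <- 1L - x$a1; y$a2 <- 1L - x$a2
  res_f <- run_tdt(y, tr)
  m <- match(res$id, res_f$id)
  expect_equal(res_f$T[m], res$U)
  expect_equal(res_f$U[m], res$T)
  expect_equal(res_f$p[m], res$p, tolerance = 1e-12)
  or_f <- res_f$OR[m]
  both_pos <- is.finite(or_f) & or_f > 0 & is.finite(res$OR) & res$OR > 0
  expect_equal(or_f[both_pos], 1 / res$OR[both_pos], tolerance = 1e-12)
})

test_that("trios with two homozygous parents are transparent to the TDT", {
  d <- trio_dosage_row(c(1L, 1L, 0L))                 # informative trio
  x1 <- make_cohort(d)
  res1 <- run_tdt(x1, make_trios(1))
  d2 <- cbind(d, trio_dosage_row(c(1L, 0L, 2L)))      # uninformative trio
  x2 <- make_cohort(d2)
  res2 <- run_tdt(x2, make_trios(2))
  expect_equal(res1[, c("T", "U", "chi2", "p")], res2[, c("T", "U", "chi2", "p")])
})

test_that("type-I error is nominal on a null cohort", {
  sim <- simulate_cohort(sim_config(n_trios = 80, n_variants = 500, seed = 29,
                                    missing_rate = 0))
  res <- run_tdt(sim$cohort, sim$trios)
  frac <- mean(res$p < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(frac - 0.05), 3 * se + 0.01)  # small-count discreteness slack
})
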