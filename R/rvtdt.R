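#' Collapse a region's rare variants into transmission events
#'
#' Rarity is judged on the founder (parental) minor-allele frequency
#' computed from the cohort itself; a variant with founder MAF exactly equal
#' to `maf_threshold` is included. Each variant is oriented to its founder
#' minor allele, so the "rare allele" is the minor allele regardless of
#' ref/alt labelling. One transmission event is recorded per heterozygous
#' parent per rare variant in every complete, Mendelian-consistent trio:
#' `transmitted` is 1 when the rare allele went to the child and 0
#' otherwise (a double-heterozygous parent pair contributes two events).
#'
#' @param x an analysis-ready biallelic [trio_cohort()].
#' @param trios a [trio_set()].
#' @param region_label label for the collapsed unit (gene or intergenic
#'   region).
#' @param variant_idx logical or integer index selecting the region's
#'   variants within `x`; `NULL` uses all variants.
#' @param maf_threshold founder MAF bound defining "rare", default 0.01.
#' @return an object of class `rare_variant_set`: list with `region_label`,
#'   `variants` (data.frame incl. `founder_maf`), `events` (data.frame
#'   `trio_id`, `variant`, `transmitted`), `maf_threshold`. Zero rare
#'   variants yield an empty set (no test is run on it).
#' @export
collapse_region <- function(x, trios, region_label, variant_idx = NULL,
                            maf_threshold = 0.01) {
  stopifnot(inherits(x, "trio_cohort"), inherits(trios, "trio_set"))
  if (!is.null(variant_idx)) x <- cohort_subset(x, variant_idx)
  f_alt <- founder_alt_freq(x, trios)
  maf <- pmin(f_alt, 1 - f_alt)
  rare <- !is.na(maf) & maf <= maf_threshold & maf > 0
  x <- cohort_subset(x, rare)
  vinfo <- cbind(x$variants, founder_maf = maf[rare])
  events <- data.frame(trio_id = character(), variant = integer(),
                       transmitted = integer(), stringsAsFactors = FALSE)
  if (nrow(vinfo) > 0) {
    # orient dosages to the minor allele before counting transmissions
    flip <- f_alt[rare] > 0.5
    if (any(flip)) {
      a1 <- x$a1; a2 <- x$a2
      a1[flip, ] <- 1L - x$a1[flip, , drop = FALSE]
      a2[flip, ] <- 1L - x$a2[flip, , drop = FALSE]
      x$a1 <- a1; x$a2 <- a2
    }
    ct <- transmission_contributions(x, trios)
    expand <- function(m, transmitted) {
      idx <- which(m > 0, arr.ind = TRUE)
      reps <- m[idx]
      data.frame(trio_id = rep(trios$trios$trio_id[idx[, 2]], reps),
                 variant = rep(idx[, 1], reps),
                 transmitted = rep(transmitted, sum(reps)),
                 stringsAsFactors = FALSE)
    }
    events <- rbind(expand(ct$T, 1L), expand(ct$U, 0L))
    events <- events[order(events$variant, events$trio_id,
                           -events$transmitted), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(region_label = region_label, variants = vinfo,
                 events = events, maf_threshold = maf_threshold),
            class = "rare_variant_set")
}

#' @exportS3Method base::print
print.rare_variant_set <- function(x, ...) {
  cat(sprintf("rare_variant_set '%s': %d rare variant(s), %d transmission event(s)\n",
              x$region_label, nrow(x$variants), nrow(x$events)))
  invisible(x)
}

# statistic engines operate on a 0/1 transmitted vector (possibly a matrix
# of permuted copies, permutations in rows) plus the event layout
.stat_brv <- function(tr, rvs) {
  if (is.matrix(tr)) rowSums(2 * tr - 1) else sum(2 * tr - 1)
}

.stat_cmc <- function(tr, rvs) {
  G <- rvs$trio_indicator  # events x trios-with-events
  if (is.matrix(tr)) {
    anyT <- (tr %*% G) > 0
    anyU <- ((1 - tr) %*% G) > 0
    rowSums(anyT) - rowSums(anyU)
  } else {
    anyT <- (tr %*% G) > 0
    anyU <- ((1 - tr) %*% G) > 0
    sum(anyT) - sum(anyU)
  }
}

.stat_wss <- function(tr, rvs) {
  V <- rvs$variant_indicator  # events x variants
  nv <- rvs$events_per_variant
  if (!is.matrix(tr)) tr <- matrix(tr, nrow = 1)
  Tm <- tr %*% V
  Um <- matrix(nv, nrow(Tm), length(nv), byrow = TRUE) - Tm
  # Madsen-Browning-style weights from the untransmitted (pseudo-control)
  # chromosomes, re-estimated inside each permutation
  q <- (Um + 1) / (matrix(nv, nrow(Tm), length(nv), byrow = TRUE) + 2)
  w <- 1 / sqrt(matrix(nv, nrow(Tm), length(nv), byrow = TRUE) * q * (1 - q))
  # a variant with no transmission event carries no information: weight 0,
  # not 1/sqrt(0)
  w[, nv == 0] <- 0
  s <- rowSums(w * (Tm - Um))
  if (length(s) == 1) s[[1]] else s
}

.stat_vt <- function(tr, rvs) {
  V <- rvs$variant_indicator_mafsorted  # events x variants (ascending MAF)
  if (!is.matrix(tr)) tr <- matrix(tr, nrow = 1)
  D <- (2 * tr - 1) %*% V              # per-variant T - U
  if (ncol(D) == 1) C <- D
  else C <- t(apply(D, 1, cumsum))     # cumulative over MAF order
  bounds <- rvs$threshold_bounds       # last column index per distinct MAF
  M <- C[, bounds, drop = FALSE]
  s <- apply(M, 1, max)
  if (length(s) == 1) s[[1]] else s
}

# augment a rare_variant_set with the index structures the statistics need
.rvs_prepare <- function(rvs) {
  ev <- rvs$events
  ne <- nrow(ev)
  trios_u <- unique(ev$trio_id)
  G <- matrix(0, ne, length(trios_u))
  G[cbind(seq_len(ne), match(ev$trio_id, trios_u))] <- 1
  nvtot <- nrow(rvs$variants)
  V <- matrix(0, ne, nvtot)
  V[cbind(seq_len(ne), ev$variant)] <- 1
  ord <- order(rvs$variants$founder_maf)
  mafs <- rvs$variants$founder_maf[ord]
  bounds <- which(!duplicated(mafs, fromLast = TRUE))
  rvs$trio_indicator <- G
  rvs$variant_indicator <- V
  rvs$events_per_variant <- colSums(V)
  rvs$variant_indicator_mafsorted <- V[, ord, drop = FALSE]
  rvs$threshold_bounds <- bounds
  rvs$thresholds <- mafs[bounds]
  rvs
}

#' Rare-variant burden statistic
#'
#' CMC: number of trios transmitting at least one rare allele minus the
#' number un-transmitting at least one (McNemar-style carrier contrast).
#' BRV: total transmitted minus untransmitted rare-allele count. WSS:
#' frequency-weighted transmitted-minus-untransmitted sum with weights
#' 1/sqrt(n q (1 - q)) per variant, q estimated from the untransmitted
#' parental chromosomes.
#'
#' @param rvs a [collapse_region()] result with at least one event.
#' @param test one of `"CMC"`, `"BRV"`, `"WSS"`.
#' @return the statistic (single number).
#' @export
burden_statistic <- function(rvs, test = c("BRV", "CMC", "WSS")) {
  stopifnot(inherits(rvs, "rare_variant_set"))
  test <- toupper(test[1])
  if (!test %in% c("CMC", "BRV", "WSS"))
    stop("unknown burden test: ", test)
  if (nrow(rvs$events) == 0) stop("empty rare variant set")
  rvs <- .rvs_prepare(rvs)
  fn <- switch(test, CMC = .stat_cmc, BRV = .stat_brv, WSS = .stat_wss)
  fn(rvs$events$transmitted, rvs)
}

#' Variable-threshold burden statistic
#'
#' The BRV-style transmitted-minus-untransmitted count is maximized over
#' the distinct founder-MAF thresholds present in the region; because the
#' largest threshold includes every variant, the VT statistic always
#' dominates the plain BRV statistic.
#'
#' @param rvs a [collapse_region()] result with at least one event.
#' @return list with `statistic` and `chosen_threshold`.
#' @export
vt_statistic <- function(rvs) {
  stopifnot(inherits(rvs, "rare_variant_set"))
  if (nrow(rvs$events) == 0) stop("empty rare variant set")
  rvs <- .rvs_prepare(rvs)
  tr <- rvs$events$transmitted
  V <- rvs$variant_indicator_mafsorted
  D <- as.numeric(matrix(2 * tr - 1, nrow = 1) %*% V)
  C <- cumsum(D)
  M <- C[rvs$threshold_bounds]
  k <- which.max(M)
  list(statistic = M[k], chosen_threshold = rvs$thresholds[k])
}

#' Permutation p-value for a rare-variant collapsing TDT
#'
#' The null is generated by independently flipping each transmission
#' event's transmitted/untransmitted status with probability 1/2, which is
#' valid under Mendel's law and preserves each trio's heterozygous-parent
#' count exactly. CMC/BRV/WSS p-values are two-sided (on the absolute
#' statistic); VT is one-sided on the threshold-maximized statistic, with
#' the maximization repeated inside every permutation. The +1 correction
#' guarantees p > 0.
#'
#' @param rvs a [collapse_region()] result.
#' @param test one of `"CMC"`, `"BRV"`, `"WSS"`, `"VT"`.
#' @param n_permutations number of permutations, default 10000 (a warning
#'   is issued below 100).
#' @param seed integer seed (mandatory for reproducibility).
#' @return data.frame with `region`, `test`, `statistic`,
#'   `chosen_threshold` (`NA` except for VT), `p`, `n_permutations`, `seed`.
#' @export
permutation_p <- function(rvs, test = c("BRV", "CMC", "WSS", "VT"),
                          n_permutations = 10000, seed) {
  stopifnot(inherits(rvs, "rare_variant_set"))
  test <- toupper(test[1])
  if (missing(seed)) stop("a seed is required")
  if (n_permutations < 100)
    warning("fewer than 100 permutations gives a coarse p-value", call. = FALSE)
  if (nrow(rvs$events) == 0) stop("empty rare variant set")
  rvs <- .rvs_prepare(rvs)
  tr <- rvs$events$transmitted
  ne <- length(tr)
  set.seed(as.integer(seed))
  flips <- matrix(stats::rbinom(n_permutations * ne, 1, 0.5),
                  n_permutations, ne)
  perm_tr <- abs(sweep(flips, 2, tr, "-"))  # xor with observed
  chosen <- NA_real_
  if (test == "VT") {
    vt <- vt_statistic(rvs)
    obs <- vt$statistic; chosen <- vt$chosen_threshold
    perm <- .stat_vt(perm_tr, rvs)
    exceed <- sum(perm >= obs)
  } else {
    fn <- switch(test, CMC = .stat_cmc, BRV = .stat_brv, WSS = .stat_wss,
                 stop("unknown burden test: ", test))
    obs <- fn(tr, rvs)
    perm <- fn(perm_tr, rvs)
    exceed <- sum(abs(perm) >= abs(obs))
  }
  data.frame(region = rvs$region_label, test = test, statistic = obs,
             chosen_threshold = chosen,
             p = (1 + exceed) / (1 + n_permutations),
             n_permutations = n_permutations, seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

#' Rare-variant collapsing TDT over a set of regions
#'
#' Runs [collapse_region()] and [permutation_p()] for every region and
#' requested test. Regions with no rare variant are skipped.
#'
#' @param x an analysis-ready [trio_cohort()].
#' @param trios a [trio_set()].
#' @param regions named list: region label -> variant index (logical or
#'   integer into `x`), or a [region_spec()] per label.
#' @param tests character vector among CMC/BRV/WSS/VT.
#' @param maf_threshold founder MAF bound, default 0.01.
#' @param n_permutations permutations per test, default 10000.
#' @param seed integer seed; region/test runs use derived sub-seeds.
#' @return data.frame, one row per region x test.
#' @export
rvtdt_scan <- function(x, trios, regions, tests = c("CMC", "BRV", "WSS", "VT"),
                       maf_threshold = 0.01, n_permutations = 10000, seed) {
  if (missing(seed)) stop("a seed is required")
  out <- list()
  for (k in seq_along(regions)) {
    lab <- names(regions)[k]
    idx <- regions[[k]]
    if (inherits(idx, "region_spec"))
      idx <- in_regions(idx, x$variants$chrom, x$variants$pos)
    rvs <- collapse_region(x, trios, lab, idx, maf_threshold)
    if (nrow(rvs$events) == 0) next
    for (tn in tests) {
      sub_seed <- (as.integer(seed) + 7919L * k +
                     match(toupper(tn), c("CMC", "BRV", "WSS", "VT"))) %% .Machine$integer.max
      out[[length(out) + 1]] <-
        permutation_p(rvs, tn, n_permutations, seed = sub_seed)
    }
  }
  if (!length(out))
    return(data.frame(region = character(), test = character(),
                      statistic = numeric(), chosen_threshold = numeric(),
                      p = numeric(), n_permutations = integer(),
                      seed = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
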