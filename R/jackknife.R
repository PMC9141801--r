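#' Define a locus signal for the leave-one-out scan
#'
#' @param locus_id label for the locus.
#' @param region a [region_spec()] covering the signal.
#' @param index_variant id of the index variant, or `NULL` to take the
#'   full-cohort top TDT hit inside the region.
#' @return an object of class `locus_signal`.
#' @export
locus_signal <- function(locus_id, region, index_variant = NULL) {
  stopifnot(inherits(region, "region_spec"))
  structure(list(locus_id = locus_id, region = region,
                 index_variant = index_variant),
            class = "locus_signal")
}

# resolve each locus's index variant to a row of the cohort, using the
# full-cohort TDT top hit within the region when none was supplied
resolve_index_variants <- function(x, trios, loci, full_tdt = NULL) {
  if (is.null(full_tdt)) full_tdt <- run_tdt(x, trios)
  vapply(loci, function(lo) {
    if (!is.null(lo$index_variant)) {
      i <- match(lo$index_variant, x$variants$id)
      if (is.na(i)) stop("index variant not in cohort: ", lo$index_variant)
      if (!in_regions(lo$region, x$variants$chrom[i], x$variants$pos[i]))
        stop("index variant lies outside its locus region: ", lo$index_variant)
      return(i)
    }
    inside <- in_regions(lo$region, full_tdt$chrom, full_tdt$pos)
    if (!any(inside)) stop("no testable variant inside locus ", lo$locus_id)
    match(full_tdt$id[inside][1], x$variants$id)  # table is sorted by p
  }, integer(1))
}

#' Leave-one-out (jackknife) influence of each trio on each locus
#'
#' For every trio and locus, the TDT at the locus's index variant is
#' recomputed with that trio removed. The influence entry is
#' -log10 p(full cohort) - (-log10 p(cohort minus trio)): positive entries
#' mark trios that strengthen the signal. Index variants are fixed before
#' the scan and never re-selected inside the loop, so the scan is
#' deterministic. Removing a trio that is uninformative at the index variant
#' gives influence exactly 0. If removal makes the index variant untestable
#' (no transmissions left), the influence is recorded as the full-cohort
#' -log10 p (maximal influence).
#'
#' @param x an analysis-ready [trio_cohort()].
#' @param trios a [trio_set()].
#' @param loci list of [locus_signal()] objects.
#' @return an object of class `influence_matrix`: list with `influence`
#'   (trios x loci matrix), `index_variants` (ids), `full_log10p` (per
#'   locus), `loci` (labels).
#' @export
leave_one_out_scan <- function(x, trios, loci) {
  stopifnot(inherits(x, "trio_cohort"), length(loci) >= 1)
  if (inherits(loci, "locus_signal")) loci <- list(loci)
  idx <- resolve_index_variants(x, trios, loci)
  ct <- transmission_contributions(x, trios)
  nt <- n_trios(trios)
  infl <- matrix(NA_real_, nt, length(loci),
                 dimnames = list(trios$trios$trio_id,
                                 vapply(loci, `[[`, "", "locus_id")))
  full_l10 <- numeric(length(loci))
  for (k in seq_along(loci)) {
    tvec <- ct$T[idx[k], ]; uvec <- ct$U[idx[k], ]
    Tfull <- sum(tvec); Ufull <- sum(uvec)
    lp_full <- tdt_statistic(Tfull, Ufull)$log10_p  # NA if untestable overall
    full_l10[k] <- -lp_full
    Tl <- Tfull - tvec; Ul <- Ufull - uvec
    lp_loo <- tdt_statistic(Tl, Ul)$log10_p
    inf_k <- lp_loo - lp_full  # = (-log10 p_full) - (-log10 p_loo)
    inf_k[Tl + Ul == 0] <- -lp_full  # untestable after removal: maximal
    # exact zero for uninformative trios (avoid -0 noise)
    inf_k[tvec + uvec == 0] <- 0
    infl[, k] <- inf_k
  }
  structure(list(influence = infl,
                 index_variants = x$variants$id[idx],
                 full_log10p = full_l10,
                 loci = colnames(infl)),
            class = "influence_matrix")
}

#' Assign trios to the locus they influence most
#'
#' Default rule: each trio goes to the locus at which its influence is
#' maximal, provided that influence strictly exceeds `min_influence`
#' (default 0); otherwise, and on exact ties between loci, the trio is
#' unassigned.
#'
#' @param infl an `influence_matrix` from [leave_one_out_scan()].
#' @param min_influence positivity threshold for assignment, default 0.
#' @return an object of class `trio_partition`: list with `assignment`
#'   (named character vector, locus id or `"unassigned"`) and `group_sizes`.
#' @export
assign_trios <- function(infl, min_influence = 0) {
  stopifnot(inherits(infl, "influence_matrix"))
  m <- infl$influence
  assignment <- apply(m, 1, function(row) {
    mx <- max(row)
    if (!is.finite(mx) || mx <= min_influence) return("unassigned")
    hits <- which(row == mx)
    if (length(hits) > 1) return("unassigned")
    colnames(m)[hits]
  })
  sizes <- table(factor(assignment, levels = c(colnames(m), "unassigned")))
  structure(list(assignment = assignment,
                 group_sizes = stats::setNames(
                   as.integer(sizes)[seq_len(ncol(m))], colnames(m)),
                 n_unassigned = as.integer(sizes[["unassigned"]])),
            class = "trio_partition")
}

#' @exportS3Method base::print
print.trio_partition <- function(x, ...) {
  cat("trio_partition:",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
            collapse = ", "),
      sprintf("(unassigned=%d)\n", x$n_unassigned))
  invisible(x)
}

#' Re-run the TDT within each locus group
#'
#' Unassigned trios are excluded from every group run. A group of size zero
#' yields an empty table with a warning.
#'
#' @param x an analysis-ready [trio_cohort()].
#' @param trios a [trio_set()].
#' @param partition a `trio_partition` from [assign_trios()].
#' @param thr a [significance_thresholds()].
#' @return named list of TDT result tables, one per locus.
#' @export
per_group_tdt <- function(x, trios, partition,
                          thr = significance_thresholds()) {
  stopifnot(inherits(partition, "trio_partition"))
  loci <- names(partition$group_sizes)
  out <- lapply(loci, function(lo) {
    run_tdt(x, trios, thr, trio_subset = partition$assignment == lo)
  })
  stats::setNames(out, loci)
}

#' Write an influence matrix as TSV
#' @param infl an `influence_matrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_influence <- function(infl, path) {
  df <- data.frame(trio_id = rownames(infl$influence), infl$influence,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
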