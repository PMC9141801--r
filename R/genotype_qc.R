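#' Genotype quality-control thresholds
#'
#' Boundary semantics follow the filter cascade as stated: a call passes on
#' depth at DP >= 15 and on quality at GQ >= 20; a homozygous-reference call
#' fails at alternate read fraction >= `homref_ab_max`; a homozygous-
#' alternate call fails at <= `homalt_ab_min`; a heterozygous call passes
#' inside the closed window \[`het_ab_low`, `het_ab_high`\]. A variant is
#' dropped when its missing rate strictly exceeds `max_missing_rate`, and
#' (optionally) when it is monomorphic among the non-missing calls. Setting
#' an allele-balance bound to `NA` disables that filter (useful for
#' pass-through configurations).
#'
#' @param min_depth minimum read depth (reads), default 15.
#' @param min_gq minimum genotype quality (phred), default 20.
#' @param homref_ab_max hom-ref allele-balance fail bound, default 0.15.
#' @param homalt_ab_min hom-alt allele-balance fail bound, default 0.85.
#' @param het_ab_low,het_ab_high heterozygous allele-balance window,
#'   default \[0.3, 0.7\].
#' @param max_missing_rate maximum per-variant missing fraction, default 0.20.
#' @param drop_monomorphic drop variants with no alternate (or no reference)
#'   allele among non-missing calls, default `TRUE`.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_depth = 15, min_gq = 20,
                          homref_ab_max = 0.15, homalt_ab_min = 0.85,
                          het_ab_low = 0.3, het_ab_high = 0.7,
                          max_missing_rate = 0.20, drop_monomorphic = TRUE) {
  chain <- c(0, homref_ab_max, het_ab_low, het_ab_high, homalt_ab_min, 1)
  chain <- chain[!is.na(chain)]  # NA disables an allele-balance filter
  stopifnot(!is.unsorted(chain))
  structure(list(min_depth = min_depth, min_gq = min_gq,
                 homref_ab_max = homref_ab_max, homalt_ab_min = homalt_ab_min,
                 het_ab_low = het_ab_low, het_ab_high = het_ab_high,
                 max_missing_rate = max_missing_rate,
                 drop_monomorphic = drop_monomorphic),
            class = "qc_thresholds")
}

qc_log_row <- function(stage, calls_set_missing = 0L, variants_dropped = 0L,
                       variants_remaining = NA_integer_) {
  data.frame(stage = stage, calls_set_missing = calls_set_missing,
             variants_dropped = variants_dropped,
             variants_remaining = variants_remaining,
             stringsAsFactors = FALSE)
}

set_calls_missing <- function(x, bad) {
  x$a1[bad] <- NA_integer_
  x$a2[bad] <- NA_integer_
  x
}

#' Per-call depth, quality and allele-balance filters
#'
#' Calls failing the depth, genotype-quality or genotype-class-specific
#' allele-balance criterion are set missing; all other calls are untouched.
#' Calls without a measured allele balance (no allele depths) are exempt
#' from the allele-balance filter. Filters never drop whole variants.
#'
#' @param x a biallelic [trio_cohort()].
#' @param thr a [qc_thresholds()].
#' @return list with elements `cohort` (filtered) and `log` (per-filter
#'   counts of calls newly set missing).
#' @export
apply_call_filters <- function(x, thr = qc_thresholds()) {
  stopifnot(inherits(x, "trio_cohort"), inherits(thr, "qc_thresholds"))
  log <- list()
  called <- !is.na(x$a1)

  bad_dp <- called & !is.na(x$dp) & x$dp < thr$min_depth
  x <- set_calls_missing(x, bad_dp)
  log[[1]] <- qc_log_row("call_depth", sum(bad_dp),
                         variants_remaining = nrow(x$variants))

  called <- !is.na(x$a1)
  bad_gq <- called & !is.na(x$gq) & x$gq < thr$min_gq
  x <- set_calls_missing(x, bad_gq)
  log[[2]] <- qc_log_row("call_gq", sum(bad_gq),
                         variants_remaining = nrow(x$variants))

  called <- !is.na(x$a1)
  dos <- cohort_dosage(x)
  ar <- cohort_alt_ratio(x)
  measured <- called & !is.na(ar)
  test_on <- function(cond, enabled) if (is.na(enabled)) FALSE else cond
  bad_ab <- measured & (
    test_on(dos == 0L & ar >= thr$homref_ab_max, thr$homref_ab_max) |
    test_on(dos == 2L & ar <= thr$homalt_ab_min, thr$homalt_ab_min) |
    test_on(dos == 1L & (ar < thr$het_ab_low | ar > thr$het_ab_high),
            thr$het_ab_low))
  x <- set_calls_missing(x, bad_ab)
  log[[3]] <- qc_log_row("call_allele_balance", sum(bad_ab),
                         variants_remaining = nrow(x$variants))

  list(cohort = x, log = do.call(rbind, log))
}

#' Variant-level missingness and monomorphism filters
#'
#' Missingness is computed over all cohort samples (parents and children).
#' A variant with missing rate strictly above the threshold is dropped; a
#' variant whose non-missing calls carry no alternate allele, or no
#' reference allele, is dropped as monomorphic (evaluated after call
#' filtering, so a variant can become monomorphic through filtering).
#'
#' @param x a biallelic [trio_cohort()] with call filters already applied.
#' @param thr a [qc_thresholds()].
#' @return list with elements `cohort` and `log`.
#' @export
filter_variants <- function(x, thr = qc_thresholds()) {
  stopifnot(inherits(x, "trio_cohort"))
  log <- list()
  ns <- length(x$samples)
  miss_rate <- rowSums(is.na(x$a1)) / ns
  drop_miss <- miss_rate > thr$max_missing_rate
  x <- cohort_subset(x, !drop_miss)
  log[[1]] <- qc_log_row("variant_missingness", variants_dropped = sum(drop_miss),
                         variants_remaining = nrow(x$variants))
  if (thr$drop_monomorphic) {
    dos <- cohort_dosage(x)
    nalt <- rowSums(dos, na.rm = TRUE)
    nref <- rowSums(2L - dos, na.rm = TRUE)
    mono <- nalt == 0 | nref == 0
    x <- cohort_subset(x, !mono)
    log[[2]] <- qc_log_row("variant_monomorphic", variants_dropped = sum(mono),
                           variants_remaining = nrow(x$variants))
  }
  list(cohort = x, log = do.call(rbind, log))
}

#' Full genotype quality-control cascade
#'
#' Applies, in order: region restriction, multiallelic splitting, per-call
#' depth/quality/allele-balance filters, variant-level missingness and
#' monomorphism filters, and finally the Mendelian-error policy (zero-out at
#' one inconsistency, drop at two or more). The log records survivors after
#' each stage.
#'
#' @param x a [trio_cohort()] as returned by [read_genotypes()].
#' @param trios a [trio_set()].
#' @param thr a [qc_thresholds()].
#' @param mendel a [mendel_policy()], or `NULL` to skip the Mendelian stage.
#' @return list with elements `cohort` (analysis-ready), `log` (QC log
#'   data.frame), and `mendel_counts` (per-variant inconsistency counts on
#'   the pre-policy cohort, `NULL` when skipped).
#' @export
qc_pipeline <- function(x, trios, thr = qc_thresholds(),
                        mendel = mendel_policy()) {
  stopifnot(inherits(x, "trio_cohort"), inherits(trios, "trio_set"))
  log <- qc_log_row("input", variants_remaining = nrow(x$variants))

  x <- restrict_regions(x)
  log <- rbind(log, qc_log_row("region_restrict",
                               variants_remaining = nrow(x$variants)))
  x <- split_multiallelic(x)
  log <- rbind(log, qc_log_row("multiallelic_split",
                               variants_remaining = nrow(x$variants)))
  cf <- apply_call_filters(x, thr)
  x <- cf$cohort; log <- rbind(log, cf$log)
  vf <- filter_variants(x, thr)
  x <- vf$cohort; log <- rbind(log, vf$log)

  mendel_counts <- NULL
  if (!is.null(mendel)) {
    scan <- scan_mendelian(x, trios)
    mendel_counts <- scan$counts
    pol <- apply_mendel_policy(x, trios, scan$counts, mendel)
    zeroed <- sum(scan$counts == 1L & scan$counts < mendel$drop_threshold)
    log <- rbind(log,
                 qc_log_row("mendel_zero_out",
                            calls_set_missing = 3L * sum(mendel$zero_out_single) * zeroed,
                            variants_remaining = nrow(x$variants)),
                 qc_log_row("mendel_drop",
                            variants_dropped = sum(scan$counts >= mendel$drop_threshold),
                            variants_remaining = nrow(pol$variants)))
    x <- pol
  }
  list(cohort = x, log = log, mendel_counts = mendel_counts)
}

#' Write a QC log as TSV
#' @param log QC log data.frame from [qc_pipeline()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_qc_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
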