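#' Significance thresholds for TDT reporting
#'
#' Defaults are the suggestive threshold used for targeted panels
#' (1e-5) and the conventional genome-wide threshold (5e-8).
#'
#' @param suggestive suggestive p-value threshold, default `1e-5`.
#' @param genomewide genome-wide p-value threshold, default `5e-8`.
#' @return an object of class `significance_thresholds`.
#' @export
significance_thresholds <- function(suggestive = 1e-5, genomewide = 5e-8) {
  stopifnot(genomewide <= suggestive)
  structure(list(suggestive = suggestive, genomewide = genomewide),
            class = "significance_thresholds")
}

# Per-trio transmission contributions at every variant.
# Returns T and U matrices (variants x trios): each heterozygous parent of a
# complete, Mendelian-consistent trio scores exactly one transmission.
transmission_contributions <- function(x, trios) {
  td <- trio_dosage_matrices(x, trios)
  mm <- mendel_masks(td)
  valid <- mm$complete & mm$consistent
  if (any(mm$complete & !mm$consistent))
    warning(sprintf("%d Mendelian-inconsistent trio genotype(s) skipped",
                    sum(mm$complete & !mm$consistent)), call. = FALSE)
  C <- td$child; M <- td$mother; F <- td$father
  Tm <- matrix(0, nrow(C), ncol(C)); Um <- Tm

  # mother heterozygous, father homozygous: transmitted allele is the child
  # dosage minus the father's contributed allele
  mf <- valid & M == 1L & F != 1L
  t1 <- C - F / 2
  Tm[mf] <- Tm[mf] + t1[mf]; Um[mf] <- Um[mf] + (1 - t1[mf])
  # father heterozygous, mother homozygous
  fm <- valid & F == 1L & M != 1L
  t2 <- C - M / 2
  Tm[fm] <- Tm[fm] + t2[fm]; Um[fm] <- Um[fm] + (1 - t2[fm])
  # both heterozygous: child 0 -> U+=2; child 1 -> T+=1, U+=1; child 2 -> T+=2
  bh <- valid & M == 1L & F == 1L
  Tm[bh] <- Tm[bh] + C[bh]; Um[bh] <- Um[bh] + (2 - C[bh])
  list(T = Tm, U = Um)
}

#' Count transmitted and untransmitted alternate alleles at one variant
#'
#' For each heterozygous parent of a complete, Mendelian-consistent trio
#' exactly one transmission is scored: the alternate allele is either
#' transmitted (T) or untransmitted (U). Trios with a missing member are
#' skipped; inconsistent trios are skipped with a warning.
#'
#' @param child,mother,father dosage vectors (one entry per trio).
#' @return named numeric vector `c(T = , U = )`.
#' @export
count_transmissions <- function(child, mother, father) {
  n <- length(child)
  stopifnot(length(mother) == n, length(father) == n)
  x <- trio_cohort(
    data.frame(chrom = "1", pos = 1, id = "v", ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    samples = paste0("s", seq_len(3 * n)),
    a1 = matrix(as.integer(c(rbind(child, mother, father)) >= 1L), 1),
    a2 = matrix(as.integer(c(rbind(child, mother, father)) == 2L), 1))
  tr <- trio_set(data.frame(
    trio_id = paste0("t", seq_len(n)),
    child_id = paste0("s", 3 * seq_len(n) - 2),
    mother_id = paste0("s", 3 * seq_len(n) - 1),
    father_id = paste0("s", 3 * seq_len(n)),
    child_affected = TRUE, stringsAsFactors = FALSE))
  ct <- transmission_contributions(x, tr)
  c(T = sum(ct$T), U = sum(ct$U))
}

#' TDT statistic, p-value and odds ratio from transmission counts
#'
#' The McNemar chi-square is (T-U)^2/(T+U) with an upper-tail chi-square
#' p-value on 1 df, computed in log space so values near 1e-16 keep full
#' relative accuracy. The odds ratio is T/U, reported as 0 when T = 0 and
#' `Inf` when U = 0.
#'
#' @param T,U transmitted / untransmitted counts (vectors allowed).
#' @return data.frame with columns `T`, `U`, `n_informative`, `chi2`, `p`,
#'   `log10_p`, `OR`. Pairs with T + U = 0 are undefined and returned as
#'   `NA` statistics.
#' @export
tdt_statistic <- function(T, U) {
  stopifnot(length(T) == length(U), all(T >= 0), all(U >= 0))
  n <- T + U
  chi2 <- ifelse(n > 0, (T - U)^2 / n, NA_real_)
  logp <- stats::pchisq(chi2, df = 1, lower.tail = FALSE, log.p = TRUE)
  p <- exp(logp)
  or <- ifelse(U > 0, T / U, ifelse(T > 0, Inf, NA_real_))
  data.frame(T = T, U = U, n_informative = n, chi2 = chi2, p = p,
             log10_p = logp / log(10), OR = or)
}

# founder (parental) alternate-allele frequency per variant
founder_alt_freq <- function(x, trios) {
  dos <- cohort_dosage(x)
  cols <- trio_columns(trios, x$samples)
  par <- dos[, c(cols$mother, cols$father), drop = FALSE]
  rowSums(par, na.rm = TRUE) / (2 * rowSums(!is.na(par)))
}

#' Run the transmission disequilibrium test over a cohort
#'
#' One result per testable variant (at least one scored transmission),
#' sorted by p-value. The transmission direction records whether the
#' over-transmitted allele is the cohort minor or major allele, with
#' minor/major orientation taken from founder (parental) allele frequencies
#' so the children's distortion cannot flip the reference frame.
#'
#' @param x an analysis-ready biallelic [trio_cohort()] (QC and Mendelian
#'   policy applied).
#' @param trios a [trio_set()].
#' @param thr a [significance_thresholds()].
#' @param trio_subset optional logical/integer index restricting the test to
#'   a subset of trios.
#' @return data.frame with columns `chrom`, `id`, `pos`, `ref`, `alt`, `T`,
#'   `U`, `n_informative`, `chi2`, `p`, `log10_p`, `OR`, `alt_is_minor`,
#'   `direction` (`"minor_over_transmitted"`, `"major_over_transmitted"`,
#'   `"balanced"`), `suggestive`, `genomewide`, sorted by ascending p.
#' @export
run_tdt <- function(x, trios, thr = significance_thresholds(),
                    trio_subset = NULL) {
  stopifnot(inherits(x, "trio_cohort"), inherits(trios, "trio_set"))
  if (!is.null(trio_subset)) {
    tt <- trios$trios[trio_subset, , drop = FALSE]
    if (nrow(tt) == 0) {
      warning("empty trio group: returning empty TDT table", call. = FALSE)
      trios <- NULL
    } else trios <- trio_set(tt)
  }
  empty <- data.frame(chrom = character(), id = character(), pos = numeric(),
                      ref = character(), alt = character(), T = numeric(),
                      U = numeric(), n_informative = numeric(),
                      chi2 = numeric(), p = numeric(), log10_p = numeric(),
                      OR = numeric(), alt_is_minor = logical(),
                      direction = character(), suggestive = logical(),
                      genomewide = logical(), stringsAsFactors = FALSE)
  if (is.null(trios) || nrow(x$variants) == 0) return(empty)
  ct <- transmission_contributions(x, trios)
  T <- rowSums(ct$T); U <- rowSums(ct$U)
  testable <- (T + U) >= 1
  if (!any(testable)) return(empty)
  st <- tdt_statistic(T[testable], U[testable])
  f_alt <- founder_alt_freq(x, trios)[testable]
  alt_is_minor <- !is.na(f_alt) & f_alt <= 0.5
  over_alt <- st$T > st$U
  direction <- ifelse(st$T == st$U, "balanced",
                      ifelse(over_alt == alt_is_minor,
                             "minor_over_transmitted",
                             "major_over_transmitted"))
  v <- x$variants[testable, , drop = FALSE]
  out <- cbind(data.frame(chrom = v$chrom, id = v$id, pos = v$pos,
                          ref = v$ref, alt = v$alt, stringsAsFactors = FALSE),
               st,
               data.frame(alt_is_minor = alt_is_minor, direction = direction,
                          suggestive = st$p < thr$suggestive,
                          genomewide = st$p < thr$genomewide,
                          stringsAsFactors = FALSE))
  out <- out[order(out$p, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a TDT result table as TSV
#'
#' Infinite odds ratios are serialized as the sentinel `"inf"`. A companion
#' two-column (marker, p) file suitable for regional-association plotting is
#' written when `plot_file` is given.
#'
#' @param res result table from [run_tdt()].
#' @param path output TSV path.
#' @param plot_file optional path for the (marker, p) companion file.
#' @return `path`, invisibly.
#' @export
write_tdt <- function(res, path, plot_file = NULL) {
  out <- res
  out$OR <- ifelse(is.infinite(out$OR), "inf", format(out$OR, digits = 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(plot_file))
    utils::write.table(data.frame(MarkerName = res$id, `P-value` = res$p,
                                  check.names = FALSE),
                       plot_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
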