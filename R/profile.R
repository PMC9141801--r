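#' Genotype-frequency profile of children or parents over a variant set
#'
#' Calls are classified as homozygous-major / heterozygous / homozygous-
#' minor with major/minor orientation taken from founder (parental) allele
#' frequencies, so the children's transmission distortion cannot flip the
#' reference frame. Fractions are computed over non-missing calls pooled
#' across the variant set; the per-variant breakdown is retained. Variants
#' with parental MAF exactly 0.5 are oriented by ref/alt (alternate treated
#' as minor) with a warning.
#'
#' @param x an analysis-ready biallelic [trio_cohort()].
#' @param trios a [trio_set()].
#' @param variant_ids ids of the variants to profile.
#' @param role `"children"` or `"parents"`.
#' @param exclude optional ids to leave out of the pooling (e.g. a variant
#'   the trios were ascertained on).
#' @return an object of class `genotype_profile`: list with `role`,
#'   `pooled` (named fractions hom_major/het/hom_minor), `per_variant`
#'   (data.frame with counts and fractions), `n_calls`.
#' @export
genotype_frequencies <- function(x, trios, variant_ids,
                                 role = c("children", "parents"),
                                 exclude = NULL) {
  stopifnot(inherits(x, "trio_cohort"), inherits(trios, "trio_set"))
  role <- match.arg(role)
  variant_ids <- setdiff(variant_ids, exclude)
  if (length(variant_ids) == 0) stop("variant set is empty")
  vi <- match(variant_ids, x$variants$id)
  if (anyNA(vi)) stop("variant id(s) not in cohort: ",
                      paste(variant_ids[is.na(vi)], collapse = ", "))
  cols <- trio_columns(trios, x$samples)
  f_alt <- founder_alt_freq(x, trios)[vi]
  at_half <- !is.na(f_alt) & f_alt == 0.5
  if (any(at_half))
    warning(sprintf("%d variant(s) with parental MAF exactly 0.5 oriented by ref/alt",
                    sum(at_half)), call. = FALSE)
  dos <- cohort_dosage(x)[vi, , drop = FALSE]
  scols <- if (role == "children") cols$child else c(cols$mother, cols$father)
  d <- dos[, scols, drop = FALSE]
  # orient to minor-allele dosage: flip where the alternate is the major allele
  flip <- !is.na(f_alt) & f_alt > 0.5
  d[flip, ] <- 2L - d[flip, , drop = FALSE]
  count3 <- function(row) c(hom_major = sum(row == 0, na.rm = TRUE),
                            het = sum(row == 1, na.rm = TRUE),
                            hom_minor = sum(row == 2, na.rm = TRUE))
  counts <- t(apply(d, 1, count3))
  totals <- rowSums(counts)
  per_variant <- data.frame(id = variant_ids, counts,
                            n_calls = totals,
                            frac_hom_major = counts[, "hom_major"] / totals,
                            frac_het = counts[, "het"] / totals,
                            frac_hom_minor = counts[, "hom_minor"] / totals,
                            stringsAsFactors = FALSE)
  pooled_counts <- colSums(counts)
  pooled <- pooled_counts / sum(pooled_counts)
  structure(list(role = role, pooled = pooled, per_variant = per_variant,
                 n_calls = sum(pooled_counts)),
            class = "genotype_profile")
}

#' @exportS3Method base::print
print.genotype_profile <- function(x, ...) {
  cat(sprintf("genotype_profile (%s, %d calls): %.1f%% hom-major, %.1f%% het, %.1f%% hom-minor\n",
              x$role, x$n_calls, 100 * x$pooled["hom_major"],
              100 * x$pooled["het"], 100 * x$pooled["hom_minor"]))
  invisible(x)
}

#' Label each variant's over-transmission direction
#'
#' Each tested variant is labelled by whether the over-transmitted allele is
#' the cohort minor or major allele (orientation from founder frequencies,
#' already carried in the TDT table).
#'
#' @param res a TDT result table from [run_tdt()].
#' @param p_max optional p-value bound; only variants with p < `p_max` are
#'   returned.
#' @return data.frame `id`, `chrom`, `pos`, `p`, `direction`.
#' @export
transmission_direction <- function(res, p_max = NULL) {
  out <- res[, c("id", "chrom", "pos", "p", "direction")]
  if (!is.null(p_max)) out <- out[out$p < p_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variants with opposite transmission direction in two cohorts
#'
#' Finds variants (matched on chrom, pos, ref, alt) with p below `p_max` in
#' both result tables and a different over-transmitted allele: transmitted-
#' excess of the alternate in one cohort, of the reference in the other.
#'
#' @param res_a,res_b TDT result tables from [run_tdt()] for two cohorts
#'   analyzed over a shared region.
#' @param p_max p-value bound applied to both tables.
#' @return data.frame of discordant variants with the per-cohort T, U and p.
#' @export
opposite_effect_scan <- function(res_a, res_b, p_max) {
  key <- function(r) paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")
  a <- res_a[res_a$p < p_max, , drop = FALSE]
  b <- res_b[res_b$p < p_max, , drop = FALSE]
  m <- match(key(a), key(b))
  hit <- !is.na(m)
  a <- a[hit, , drop = FALSE]; b <- b[m[hit], , drop = FALSE]
  sgn_a <- sign(a$T - a$U); sgn_b <- sign(b$T - b$U)
  disc <- sgn_a != 0 & sgn_b != 0 & sgn_a != sgn_b
  out <- data.frame(id = a$id, chrom = a$chrom, pos = a$pos,
                    ref = a$ref, alt = a$alt,
                    T_a = a$T, U_a = a$U, p_a = a$p,
                    T_b = b$T, U_b = b$U, p_b = b$p,
                    stringsAsFactors = FALSE)[disc, , drop = FALSE]
  rownames(out) <- NULL
  out
}
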