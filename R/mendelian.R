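# Consistency of a child dosage with biallelic biparental inheritance:
# the child's genotype must decompose as one gamete from each parent.
# Possible gametes: dosage 0 -> {0}; 1 -> {0,1}; 2 -> {1}.
.mendel_consistent_lookup <- local({
  arr <- array(NA, dim = c(3, 3, 3))  # [child+1, mother+1, father+1]
  gam <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  for (m in 0:2) for (f in 0:2) for (c in 0:2) {
    ok <- any(outer(gam[[as.character(m)]], gam[[as.character(f)]], "+") == c)
    arr[c + 1, m + 1, f + 1] <- ok
  }
  arr
})

#' Mendelian consistency of one trio genotype
#'
#' Checks whether the child's biallelic dosage can arise from one gamete
#' from each parent. The de-novo-consistent pattern (both parents carry no
#' alternate allele, child carries at least one) is distinguished from all
#' other inconsistencies, which are treated as genotyping errors. A trio
#' with any missing member is untestable and returned consistent-by-default.
#'
#' @param child,mother,father dosages in \{0, 1, 2\} or `NA`; vectors are
#'   recycled to a common length.
#' @return data.frame with columns `consistent` (logical) and `error_class`
#'   (`"none"`, `"de_novo_pattern"`, `"other_inconsistency"`).
#' @export
mendelian_check <- function(child, mother, father) {
  n <- max(length(child), length(mother), length(father))
  child <- rep_len(child, n); mother <- rep_len(mother, n)
  father <- rep_len(father, n)
  vals <- c(child, mother, father)
  if (any(!is.na(vals) & !(vals %in% 0:2)))
    stop("dosages must be 0, 1, 2 or NA")
  complete <- !is.na(child) & !is.na(mother) & !is.na(father)
  consistent <- rep(TRUE, n)
  consistent[complete] <- .mendel_consistent_lookup[
    cbind(child[complete] + 1, mother[complete] + 1, father[complete] + 1)]
  error_class <- rep("none", n)
  denovo <- complete & !consistent & mother == 0 & father == 0 & child > 0
  error_class[complete & !consistent] <- "other_inconsistency"
  error_class[denovo] <- "de_novo_pattern"
  data.frame(consistent = consistent, error_class = error_class,
             stringsAsFactors = FALSE)
}

# variants x trios logical matrix of Mendelian consistency; NA-complete only
trio_dosage_matrices <- function(x, trios) {
  dos <- cohort_dosage(x)
  cols <- trio_columns(trios, x$samples)
  list(child = dos[, cols$child, drop = FALSE],
       mother = dos[, cols$mother, drop = FALSE],
       father = dos[, cols$father, drop = FALSE])
}

mendel_masks <- function(td) {
  complete <- !is.na(td$child) & !is.na(td$mother) & !is.na(td$father)
  cons <- matrix(TRUE, nrow(td$child), ncol(td$child))
  if (any(complete))
    cons[complete] <- .mendel_consistent_lookup[
      cbind(td$child[complete] + 1, td$mother[complete] + 1,
            td$father[complete] + 1)]
  list(complete = complete, consistent = cons)
}

#' Scan a cohort for Mendelian inconsistencies
#'
#' One verdict per (variant, trio) pair in which all three members are
#' non-missing; trios with a missing member are skipped, not counted as
#' errors.
#'
#' @param x a biallelic [trio_cohort()] (QC call filters applied).
#' @param trios a [trio_set()].
#' @return list with `verdicts` (data.frame of inconsistent pairs: variant
#'   index, id, trio_id, error_class) and `counts` (per-variant
#'   inconsistency counts, length `nrow(x$variants)`).
#' @export
scan_mendelian <- function(x, trios) {
  stopifnot(inherits(x, "trio_cohort"), inherits(trios, "trio_set"))
  td <- trio_dosage_matrices(x, trios)
  mm <- mendel_masks(td)
  bad <- mm$complete & !mm$consistent
  counts <- rowSums(bad)
  idx <- which(bad, arr.ind = TRUE)
  verdicts <- data.frame(
    variant = idx[, 1],
    id = x$variants$id[idx[, 1]],
    trio_id = trios$trios$trio_id[idx[, 2]],
    error_class = ifelse(td$mother[idx] == 0 & td$father[idx] == 0 &
                           td$child[idx] > 0,
                         "de_novo_pattern", "other_inconsistency"),
    stringsAsFactors = FALSE)
  list(verdicts = verdicts, counts = as.integer(counts))
}

#' Mendelian error-handling policy
#'
#' Variants accumulating `drop_threshold` or more inconsistencies are
#' removed before association analysis; a variant with a single
#' inconsistency is kept but the offending trio's three genotypes are set
#' missing (zeroed out) at that variant. De novo calling uses the stricter
#' `denovo_max_missing` variant missingness bound.
#'
#' @param drop_threshold inconsistency count at which a variant is dropped,
#'   default 2.
#' @param zero_out_single zero out the involved trio at single-error
#'   variants, default `TRUE`.
#' @param denovo_max_missing variant missing-rate bound for de novo calling,
#'   default 0.02.
#' @return an object of class `mendel_policy`.
#' @export
mendel_policy <- function(drop_threshold = 2L, zero_out_single = TRUE,
                          denovo_max_missing = 0.02) {
  stopifnot(drop_threshold >= 1)
  structure(list(drop_threshold = as.integer(drop_threshold),
                 zero_out_single = zero_out_single,
                 denovo_max_missing = denovo_max_missing),
            class = "mendel_policy")
}

#' Apply the Mendelian error policy to a cohort
#'
#' @param x a biallelic [trio_cohort()].
#' @param trios a [trio_set()].
#' @param counts per-variant inconsistency counts from [scan_mendelian()].
#' @param policy a [mendel_policy()].
#' @return the filtered [trio_cohort()]; genotypes of trios without errors
#'   are never altered.
#' @export
apply_mendel_policy <- function(x, trios, counts, policy = mendel_policy()) {
  stopifnot(length(counts) == nrow(x$variants))
  if (policy$zero_out_single && any(counts == 1L & counts < policy$drop_threshold)) {
    td <- trio_dosage_matrices(x, trios)
    mm <- mendel_masks(td)
    bad <- mm$complete & !mm$consistent
    single <- which(counts == 1L & counts < policy$drop_threshold)
    cols <- trio_columns(trios, x$samples)
    for (v in single) {
      t <- which(bad[v, ])
      cells <- cbind(v, c(cols$child[t], cols$mother[t], cols$father[t]))
      x$a1[cells] <- NA_integer_
      x$a2[cells] <- NA_integer_
    }
  }
  cohort_subset(x, counts < policy$drop_threshold)
}

#' Call de novo variants
#'
#' Operates on a copy of the cohort restricted to variants passing the
#' strict de novo missingness bound, *before* any zero-out, so the de novo
#' signal is not erased. Every (variant, trio) pair showing the
#' de-novo-consistent pattern (both parents homozygous reference, child
#' carrying the alternate) is reported together with the cohort minor-allele
#' frequency of the variant and its recurrence count across trios.
#'
#' @param x a biallelic [trio_cohort()] with call filters applied (no
#'   zero-out).
#' @param trios a [trio_set()].
#' @param policy a [mendel_policy()] supplying `denovo_max_missing`.
#' @return data.frame with one row per de novo call: `id`, `chrom`, `pos`,
#'   `ref`, `alt`, `trio_id`, `child_dosage`, `mother_dosage`,
#'   `father_dosage`, `cohort_maf`, `n_trios_recurrent`.
#' @export
call_de_novo <- function(x, trios, policy = mendel_policy()) {
  stopifnot(inherits(x, "trio_cohort"), inherits(trios, "trio_set"))
  miss_rate <- rowSums(is.na(x$a1)) / length(x$samples)
  x <- cohort_subset(x, miss_rate <= policy$denovo_max_missing)
  if (nrow(x$variants) == 0)
    return(data.frame(id = character(), chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      trio_id = character(), child_dosage = integer(),
                      mother_dosage = integer(), father_dosage = integer(),
                      cohort_maf = numeric(), n_trios_recurrent = integer(),
                      stringsAsFactors = FALSE))
  td <- trio_dosage_matrices(x, trios)
  complete <- !is.na(td$child) & !is.na(td$mother) & !is.na(td$father)
  dn <- complete & td$mother == 0 & td$father == 0 & td$child > 0
  dos <- cohort_dosage(x)
  f_alt <- rowSums(dos, na.rm = TRUE) / (2 * rowSums(!is.na(dos)))
  maf <- pmin(f_alt, 1 - f_alt)
  idx <- which(dn, arr.ind = TRUE)
  rec <- rowSums(dn)
  out <- data.frame(
    id = x$variants$id[idx[, 1]], chrom = x$variants$chrom[idx[, 1]],
    pos = x$variants$pos[idx[, 1]], ref = x$variants$ref[idx[, 1]],
    alt = x$variants$alt[idx[, 1]],
    trio_id = trios$trios$trio_id[idx[, 2]],
    child_dosage = td$child[idx], mother_dosage = td$mother[idx],
    father_dosage = td$father[idx],
    cohort_maf = maf[idx[, 1]],
    n_trios_recurrent = as.integer(rec[idx[, 1]]),
    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos, out$trio_id), , drop = FALSE]
}
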