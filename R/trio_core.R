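#' Trio cohort containers
#'
#' `trio_cohort` holds per-variant, per-sample genotype calls over a set of
#' target regions. Genotypes are stored as two allele-index matrices (`a1`,
#' `a2`; 0 = reference, k = k-th alternate, `NA` = missing) together with the
#' read depth (`dp`), genotype quality (`gq`) and allele-depth (`ad`,
#' "ref,alt,..." strings) payload. After [split_multiallelic()] every record
#' is biallelic and allele indices are 0/1, so the alternate-allele dosage of
#' a call is simply `a1 + a2`.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt` (comma-separated if multiallelic).
#' @param samples character vector of sample identifiers (column order).
#' @param a1,a2 integer matrices (variants x samples) of allele indices.
#' @param dp,gq numeric matrices of read depth and genotype quality (`NA`
#'   where absent).
#' @param ad character matrix of comma-separated allele depths, or `NULL`.
#' @param regions a [region_spec()] the cohort is restricted to, or `NULL`.
#' @return an object of class `trio_cohort`.
#' @export
trio_cohort <- function(variants, samples, a1, a2, dp = NULL, gq = NULL,
                        ad = NULL, regions = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)))
  nv <- nrow(variants); ns <- length(samples)
  dimcheck <- function(m, what) {
    if (!is.null(m)) {
      if (!identical(dim(m), c(nv, ns)))
        stop(sprintf("matrix '%s' must be %d x %d", what, nv, ns))
      dimnames(m) <- NULL
    }
    m
  }
  a1 <- dimcheck(a1, "a1"); a2 <- dimcheck(a2, "a2")
  dp <- dimcheck(dp, "dp"); gq <- dimcheck(gq, "gq")
  ad <- dimcheck(ad, "ad")
  # half-called genotypes are treated as fully missing
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) { a1[half] <- NA_integer_; a2[half] <- NA_integer_ }
  structure(list(variants = variants, samples = as.character(samples),
                 a1 = a1, a2 = a2, dp = dp, gq = gq, ad = ad,
                 regions = regions),
            class = "trio_cohort")
}

#' @exportS3Method base::print
print.trio_cohort <- function(x, ...) {
  cat(sprintf("trio_cohort: %d variants x %d samples\n",
              nrow(x$variants), length(x$samples)))
  if (!is.null(x$regions))
    cat(sprintf("  restricted to %d target interval(s)\n",
                nrow(x$regions$intervals)))
  invisible(x)
}

#' @export
dim.trio_cohort <- function(x) c(nrow(x$variants), length(x$samples))

#' Alternate-allele dosage matrix
#'
#' Requires biallelic records (run [split_multiallelic()] first if needed).
#' Any residual allele index above 1 is returned as missing.
#'
#' @param x a [trio_cohort()].
#' @return integer matrix (variants x samples) with entries 0/1/2 or `NA`.
#' @export
cohort_dosage <- function(x) {
  stopifnot(inherits(x, "trio_cohort"))
  d <- (x$a1 == 1L) + (x$a2 == 1L)
  d[x$a1 > 1L | x$a2 > 1L] <- NA_integer_
  storage.mode(d) <- "integer"
  dimnames(d) <- list(x$variants$id, x$samples)
  d
}

#' Alternate-allele read fraction per call
#'
#' Computed from allele depths as alt reads over total reads; `NA` where
#' allele depths were not recorded.
#'
#' @param x a [trio_cohort()].
#' @return numeric matrix (variants x samples) in \[0, 1\] or `NA`.
#' @export
cohort_alt_ratio <- function(x) {
  stopifnot(inherits(x, "trio_cohort"))
  nv <- nrow(x$variants); ns <- length(x$samples)
  if (is.null(x$ad)) return(matrix(NA_real_, nv, ns))
  ar <- matrix(NA_real_, nv, ns)
  ok <- !is.na(x$ad) & x$ad != "." & x$ad != ""
  if (any(ok)) {
    vals <- strsplit(x$ad[ok], ",", fixed = TRUE)
    tot <- vapply(vals, function(v) sum(suppressWarnings(as.numeric(v))),
                  numeric(1))
    alt <- vapply(vals, function(v) {
      v <- suppressWarnings(as.numeric(v))
      if (length(v) >= 2) sum(v[-1]) else NA_real_
    }, numeric(1))
    ar[ok] <- ifelse(is.finite(tot) & tot > 0, alt / tot, NA_real_)
  }
  ar
}

#' Subset a cohort by variant and/or sample
#' @param x a [trio_cohort()].
#' @param i variant index (logical or integer), `NULL` keeps all.
#' @param j sample index, `NULL` keeps all.
#' @return a [trio_cohort()].
#' @export
cohort_subset <- function(x, i = NULL, j = NULL) {
  stopifnot(inherits(x, "trio_cohort"))
  if (is.null(i)) i <- seq_len(nrow(x$variants))
  if (is.null(j)) j <- seq_along(x$samples)
  sub <- function(m) if (is.null(m)) NULL else m[i, j, drop = FALSE]
  trio_cohort(x$variants[i, , drop = FALSE], x$samples[j],
              sub(x$a1), sub(x$a2), sub(x$dp), sub(x$gq), sub(x$ad),
              x$regions)
}

#' Define target regions
#'
#' User-facing coordinates are 1-based inclusive (the convention of printed
#' genomic intervals); internally intervals are stored 0-based half-open and
#' all arithmetic happens in that representation. Overlapping or abutting
#' intervals on the same chromosome are merged.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @param label single label for the region set.
#' @return an object of class `region_spec` with a normalized `intervals`
#'   data.frame (`chrom`, `start0`, `end0`, half-open).
#' @export
region_spec <- function(chrom, start, end, label = "target") {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(start > end)) stop("region start must be <= end (1-based inclusive)")
  iv <- data.frame(chrom = as.character(chrom),
                   start0 = as.numeric(start) - 1, end0 = as.numeric(end),
                   stringsAsFactors = FALSE)
  # sort within chromosome but keep chromosomes in first-appearance order,
  # so interval indices stay meaningful to the caller
  chrom_order <- unique(iv$chrom)
  iv <- iv[order(match(iv$chrom, chrom_order), iv$start0), , drop = FALSE]
  # merge overlapping/adjacent intervals per chromosome
  out <- iv[0, ]
  for (ch in chrom_order) {
    v <- iv[iv$chrom == ch, , drop = FALSE]
    s <- v$start0[1]; e <- v$end0[1]
    for (k in seq_len(nrow(v))[-1]) {
      if (v$start0[k] <= e) e <- max(e, v$end0[k])
      else { out <- rbind(out, data.frame(chrom = ch, start0 = s, end0 = e)); s <- v$start0[k]; e <- v$end0[k] }
    }
    out <- rbind(out, data.frame(chrom = ch, start0 = s, end0 = e))
  }
  rownames(out) <- NULL
  structure(list(intervals = out, label = label), class = "region_spec")
}

#' @exportS3Method base::print
print.region_spec <- function(x, ...) {
  cat(sprintf("region_spec '%s': %d interval(s), %s bp\n", x$label,
              nrow(x$intervals),
              format(sum(x$intervals$end0 - x$intervals$start0), big.mark = ",")))
  invisible(x)
}

#' Read target regions from a BED file
#'
#' BED coordinates are already 0-based half-open; they are converted to the
#' 1-based inclusive convention expected by [region_spec()].
#'
#' @param path BED file (3+ columns, tab- or whitespace-delimited).
#' @param label region set label.
#' @return a [region_spec()].
#' @export
read_bed <- function(path, label = "target") {
  bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED file must have at least 3 columns")
  region_spec(bed[[1]], as.numeric(bed[[2]]) + 1, as.numeric(bed[[3]]), label)
}

#' Which positions fall inside a region set
#' @param regions a [region_spec()].
#' @param chrom,pos vectors of chromosome and 1-based position.
#' @return logical vector.
#' @export
in_regions <- function(regions, chrom, pos) {
  stopifnot(inherits(regions, "region_spec"))
  iv <- regions$intervals
  keep <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(iv))) {
    # 1-based pos p is inside [start0, end0) iff start0 < p <= end0
    keep <- keep | (chrom == iv$chrom[k] & pos > iv$start0[k] & pos <= iv$end0[k])
  }
  keep
}

#' Define a set of child-parent trios
#'
#' @param trios data.frame with columns `trio_id`, `child_id`, `mother_id`,
#'   `father_id`, `child_affected` (logical). The three sample identifiers of
#'   a trio must be distinct and no identifier may appear in two trios.
#' @param exclusions optional data.frame recording excluded pedigree members
#'   (columns `id`, `family`, `reason`).
#' @return an object of class `trio_set`. Sample order is child, mother,
#'   father within each trio, trios in input order; `sample_index` maps each
#'   identifier to its column position.
#' @export
trio_set <- function(trios, exclusions = NULL) {
  need <- c("trio_id", "child_id", "mother_id", "father_id", "child_affected")
  stopifnot(is.data.frame(trios), all(need %in% names(trios)))
  trios <- trios[, need, drop = FALSE]
  ids <- c(rbind(trios$child_id, trios$mother_id, trios$father_id))
  if (anyDuplicated(ids))
    stop("sample identifier appears in more than one trio role: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- trios$child_id == trios$mother_id | trios$child_id == trios$father_id |
    trios$mother_id == trios$father_id
  if (any(bad)) stop("trio members must be three distinct samples: ",
                     paste(trios$trio_id[bad], collapse = ", "))
  if (is.null(exclusions))
    exclusions <- data.frame(id = character(), family = character(),
                             reason = character(), stringsAsFactors = FALSE)
  structure(list(trios = trios, samples = ids,
                 sample_index = stats::setNames(seq_along(ids), ids),
                 exclusions = exclusions),
            class = "trio_set")
}

#' @exportS3Method base::print
print.trio_set <- function(x, ...) {
  cat(sprintf("trio_set: %d trios (%d samples)", nrow(x$trios),
              length(x$samples)))
  if (nrow(x$exclusions) > 0)
    cat(sprintf(", %d pedigree member(s) excluded", nrow(x$exclusions)))
  cat("\n")
  invisible(x)
}

#' Number of trios
#' @param x a [trio_set()].
#' @return integer.
#' @export
n_trios <- function(x) nrow(x$trios)

# column positions of children / mothers / fathers in a cohort's sample order
trio_columns <- function(trios, samples) {
  idx <- function(ids) {
    m <- match(ids, samples)
    if (anyNA(m)) stop("sample(s) missing from cohort: ",
                       paste(ids[is.na(m)], collapse = ", "))
    m
  }
  list(child = idx(trios$trios$child_id),
       mother = idx(trios$trios$mother_id),
       father = idx(trios$trios$father_id))
}

#' Read a pedigree of child-parent trios from a PED file
#'
#' Expects the standard 6-column PED layout (family, individual, father,
#' mother, sex, phenotype; phenotype 2 = affected). One trio is formed per
#' child whose two named parents are present in the file; singletons, duos
#' and children referencing absent parents are excluded and reported in the
#' returned `trio_set`'s `exclusions` table.
#'
#' @param path PED file path (whitespace-delimited).
#' @return a [trio_set()].
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ped) < 6) stop("PED file must have 6 columns")
  names(ped)[1:6] <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  if (anyDuplicated(ped$iid))
    stop("duplicated individual ID in PED: ",
         paste(unique(ped$iid[duplicated(ped$iid)]), collapse = ", "))
  is_child <- ped$pat != "0" | ped$mat != "0"
  children <- ped[is_child, , drop = FALSE]
  if (anyDuplicated(children$iid))
    stop("duplicated child ID in PED")
  excl <- list()
  keep <- logical(nrow(children))
  for (k in seq_len(nrow(children))) {
    ch <- children[k, ]
    has_f <- ch$pat != "0" && ch$pat %in% ped$iid
    has_m <- ch$mat != "0" && ch$mat %in% ped$iid
    if (has_f && has_m) { keep[k] <- TRUE; next }
    miss <- c(if (!has_f) "father", if (!has_m) "mother")
    excl[[length(excl) + 1]] <- data.frame(
      id = ch$iid, family = ch$fid,
      reason = paste0("incomplete trio: missing ", paste(miss, collapse = " and ")),
      stringsAsFactors = FALSE)
    warning(sprintf("child %s excluded (missing %s)", ch$iid,
                    paste(miss, collapse = " and ")), call. = FALSE)
  }
  kept <- children[keep, , drop = FALSE]
  used <- c(kept$iid, kept$pat, kept$mat)
  # founders that belong to no complete trio are reported too
  founders <- ped$iid[!is_child]
  orphan <- setdiff(founders, used)
  for (id in orphan)
    excl[[length(excl) + 1]] <- data.frame(
      id = id, family = ped$fid[ped$iid == id],
      reason = "not a member of any complete trio", stringsAsFactors = FALSE)
  exclusions <- if (length(excl)) do.call(rbind, excl) else NULL
  trios <- data.frame(trio_id = kept$fid, child_id = kept$iid,
                      mother_id = kept$mat, father_id = kept$pat,
                      child_affected = kept$pheno == "2",
                      stringsAsFactors = FALSE)
  if (anyDuplicated(trios$trio_id))
    trios$trio_id <- paste(trios$trio_id, trios$child_id, sep = "_")
  trio_set(trios, exclusions)
}

#' Write the pedigree exclusion report
#' @param trios a [trio_set()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_exclusions <- function(trios, path) {
  utils::write.table(trios$exclusions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read cohort genotypes from a multi-sample VCF
#'
#' Records are restricted to the target regions, sample columns are
#' reordered to the `trio_set` order (child, mother, father per trio), and
#' the GT/DP/GQ/AD FORMAT payload is extracted. Fields absent from the VCF
#' are recorded as missing. Every sample named in the trio set must be
#' present in the VCF.
#'
#' @param path VCF file (plain or bgzipped).
#' @param regions a [region_spec()] of target intervals.
#' @param trios a [trio_set()].
#' @return a [trio_cohort()] (possibly still multiallelic; see
#'   [split_multiallelic()]).
#' @export
read_genotypes <- function(path, regions, trios) {
  stopifnot(inherits(regions, "region_spec"), inherits(trios, "trio_set"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                         id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, ":", fix$POS),
                                     fix$ID),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  keep <- in_regions(regions, variants$chrom, variants$pos)
  if (!any(keep))
    return(trio_cohort(variants[0, ], trios$samples,
                       matrix(NA_integer_, 0, length(trios$samples)),
                       matrix(NA_integer_, 0, length(trios$samples)),
                       regions = regions))
  vcf_samples <- colnames(v@gt)[-1]
  missing_s <- setdiff(trios$samples, vcf_samples)
  if (length(missing_s))
    stop("trio sample(s) absent from VCF: ", paste(missing_s, collapse = ", "))
  ord <- match(trios$samples, vcf_samples)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, ord, drop = FALSE]
  getfmt <- function(el, numeric = TRUE) {
    fmt <- unique(unlist(strsplit(v@gt[, 1], ":", fixed = TRUE)))
    if (!el %in% fmt) return(NULL)
    m <- vcfR::extract.gt(v, element = el, as.numeric = numeric)
    m[keep, ord, drop = FALSE]
  }
  dp <- getfmt("DP"); gq <- getfmt("GQ"); ad <- getfmt("AD", numeric = FALSE)

  parse_allele <- function(gt, which) {
    al <- sub("^([^/|]*)[/|]([^/|]*)$", paste0("\\", which), gt)
    al[!grepl("[/|]", gt)] <- NA_character_
    suppressWarnings(as.integer(al))
  }
  a1 <- matrix(parse_allele(gt, 1), nrow(gt), ncol(gt))
  a2 <- matrix(parse_allele(gt, 2), nrow(gt), ncol(gt))
  variants <- variants[keep, , drop = FALSE]
  rownames(variants) <- NULL
  # warn on alleles the caller left non-normalized (shared leading base both
  # longer than 1); no left-alignment is attempted here
  nonnorm <- nchar(variants$ref) > 1 & nchar(variants$alt) > 1 &
    !grepl(",", variants$alt) &
    substr(variants$ref, 1, 1) == substr(variants$alt, 1, 1)
  if (any(nonnorm))
    warning(sprintf("%d variant(s) look non-left-normalized", sum(nonnorm)),
            call. = FALSE)
  trio_cohort(variants, trios$samples, a1, a2, dp, gq, ad, regions)
}

#' Split multiallelic records into biallelic records
#'
#' Each alternate allele of a multiallelic record becomes its own biallelic
#' record. On a split record a sample's dosage counts only the focal
#' alternate; genotypes carrying a *different* alternate allele are set
#' missing on that record (recoding them as reference would inflate
#' reference transmissions). Biallelic records pass through unchanged, so
#' the operation is idempotent.
#'
#' @param x a [trio_cohort()].
#' @return a [trio_cohort()] in which every record has a single alternate
#'   allele and allele indices are 0/1.
#' @export
split_multiallelic <- function(x) {
  stopifnot(inherits(x, "trio_cohort"))
  nalt <- lengths(strsplit(x$variants$alt, ",", fixed = TRUE))
  if (nrow(x$variants) == 0 || all(nalt == 1)) {
    # normalize residual allele indices > 1 (can't occur on true biallelics)
    return(x)
  }
  rows <- list(); a1 <- list(); a2 <- list(); dp <- list(); gq <- list(); ad <- list()
  for (i in seq_len(nrow(x$variants))) {
    alts <- strsplit(x$variants$alt[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      vr <- x$variants[i, , drop = FALSE]
      vr$alt <- alts[k]
      if (length(alts) > 1) vr$id <- paste0(vr$id, "_alt", k)
      rows[[length(rows) + 1]] <- vr
      b1 <- x$a1[i, ]; b2 <- x$a2[i, ]
      # other-alternate contamination -> missing on this split record
      other <- (!is.na(b1) & b1 != 0 & b1 != k) | (!is.na(b2) & b2 != 0 & b2 != k)
      n1 <- ifelse(b1 == k, 1L, 0L); n2 <- ifelse(b2 == k, 1L, 0L)
      n1[other] <- NA_integer_; n2[other] <- NA_integer_
      a1[[length(a1) + 1]] <- n1; a2[[length(a2) + 1]] <- n2
      if (!is.null(x$dp)) dp[[length(dp) + 1]] <- x$dp[i, ]
      if (!is.null(x$gq)) gq[[length(gq) + 1]] <- x$gq[i, ]
      if (!is.null(x$ad)) {
        # collapse AD to focal alt: ref stays total non-focal? No: keep
        # ref and focal alt reads; alt_ratio = focal alt / total reads
        adrow <- x$ad[i, ]
        ad[[length(ad) + 1]] <- vapply(adrow, function(s) {
          if (is.na(s) || s == ".") return(NA_character_)
          vals <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
          if (length(vals) < k + 1 || anyNA(vals)) return(NA_character_)
          paste0(sum(vals) - vals[k + 1], ",", vals[k + 1])
        }, character(1), USE.NAMES = FALSE)
      }
    }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  variants <- do.call(rbind, rows); rownames(variants) <- NULL
  trio_cohort(variants, x$samples, bind(a1), bind(a2), bind(dp), bind(gq),
              bind(ad), x$regions)
}

#' Restrict a cohort to its target regions
#' @param x a [trio_cohort()].
#' @param regions a [region_spec()]; defaults to the cohort's own.
#' @return a [trio_cohort()].
#' @export
restrict_regions <- function(x, regions = x$regions) {
  if (is.null(regions)) return(x)
  keep <- in_regions(regions, x$variants$chrom, x$variants$pos)
  out <- cohort_subset(x, keep)
  out$regions <- regions
  out
}
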