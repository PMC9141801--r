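#' Write a simulated cohort as VCF, PED, BED and truth tables
#'
#' Emits a VCF 4.2 file with per-call `GT:DP:GQ:AD`, a 6-column PED (father,
#' mother, affected child per family), a BED of the target regions, a truth
#' TSV with one row per planted feature (risk locus, de novo, Mendelian
#' error, QC plant) and a subgroup TSV with the per-trio truth labels.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix, default `"cohort"`.
#' @return named list of written paths (`vcf`, `ped`, `bed`, `truth`,
#'   `subgroups`).
#' @export
write_cohort <- function(sim, dir, prefix = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  x <- sim$cohort; trios <- sim$trios; truth <- sim$truth
  paths <- list(vcf = file.path(dir, paste0(prefix, ".vcf")),
                ped = file.path(dir, paste0(prefix, ".ped")),
                bed = file.path(dir, paste0(prefix, ".bed")),
                truth = file.path(dir, paste0(prefix, "_truth.tsv")),
                subgroups = file.path(dir, paste0(prefix, "_subgroups.tsv")))
  write_vcf(x, paths$vcf)

  tt <- trios$trios
  ped <- rbind(
    data.frame(fid = tt$trio_id, iid = tt$father_id, pat = "0", mat = "0",
               sex = 1L, pheno = 1L, stringsAsFactors = FALSE),
    data.frame(fid = tt$trio_id, iid = tt$mother_id, pat = "0", mat = "0",
               sex = 2L, pheno = 1L, stringsAsFactors = FALSE),
    data.frame(fid = tt$trio_id, iid = tt$child_id, pat = tt$father_id,
               mat = tt$mother_id, sex = 1L,
               pheno = ifelse(tt$child_affected, 2L, 1L),
               stringsAsFactors = FALSE))
  ped <- ped[order(match(ped$fid, tt$trio_id)), ]
  utils::write.table(ped, paths$ped, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  iv <- x$regions$intervals
  utils::write.table(data.frame(iv$chrom, format(iv$start0, scientific = FALSE),
                                format(iv$end0, scientific = FALSE)),
                     paths$bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  rows <- list()
  add <- function(type, variant_id, trio_id, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      record = type, variant_id = variant_id, trio_id = trio_id,
      value = as.character(value), stringsAsFactors = FALSE)
  }
  rl <- truth$risk_loci
  for (k in seq_len(nrow(rl)))
    add("risk_locus", rl$id[k], ".", rl$tau[k])
  dn <- truth$denovo
  for (k in seq_len(nrow(dn)))
    add("de_novo", dn$id[k], dn$trio_id[k], 1)
  me <- truth$mendel
  for (k in seq_len(nrow(me)))
    add("mendel_error", me$id[k], me$trio_id[k], me$n_errors[k])
  for (nm in c("low_dp", "low_gq", "bad_ab")) {
    df <- truth$qc[[nm]]
    for (k in seq_len(nrow(df)))
      add(nm, x$variants$id[df$variant[k]], x$samples[df$sample[k]], ".")
  }
  for (v in truth$qc$high_missing) add("high_missing", x$variants$id[v], ".", ".")
  for (v in truth$qc$monomorphic) add("monomorphic", x$variants$id[v], ".", ".")
  truth_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record = character(), variant_id = character(),
               trio_id = character(), value = character(),
               stringsAsFactors = FALSE)
  utils::write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(trio_id = names(truth$subgroup),
                                subgroup = truth$subgroup),
                     paths$subgroups, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Write a trio cohort as a multi-sample VCF 4.2 file
#'
#' Genotypes are written unphased (`0/1` style) with DP, GQ and AD when the
#' cohort carries them; missing calls become `./.` with `.` payload.
#'
#' @param x a biallelic [trio_cohort()].
#' @param path output path (use a `.vcf` suffix; bgzip afterwards if a
#'   compressed file is needed).
#' @return the path, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "trio_cohort"))
  v <- x$variants
  ord <- order(v$chrom, v$pos)
  x <- cohort_subset(x, ord)
  v <- x$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##source=triotdt",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
           paste0("##contig=<ID=", unique(v$chrom), ">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  gt <- matrix(".\\.", nrow(v), length(x$samples))
  gt <- paste0(ifelse(is.na(x$a1), ".", x$a1), "/",
               ifelse(is.na(x$a2), ".", x$a2))
  fmt_num <- function(m) {
    if (is.null(m)) return(NULL)
    out <- matrix(".", nrow(v), length(x$samples))
    ok <- !is.na(m)
    out[ok] <- format(m[ok], trim = TRUE, scientific = FALSE)
    out
  }
  dp <- fmt_num(x$dp); gq <- fmt_num(x$gq)
  ad <- x$ad; if (!is.null(ad)) { ad[is.na(ad)] <- "." }
  pieces <- list(gt)
  fmt <- "GT"
  if (!is.null(dp)) { pieces <- c(pieces, list(dp)); fmt <- paste0(fmt, ":DP") }
  if (!is.null(gq)) { pieces <- c(pieces, list(gq)); fmt <- paste0(fmt, ":GQ") }
  if (!is.null(ad)) { pieces <- c(pieces, list(ad)); fmt <- paste0(fmt, ":AD") }
  cells <- do.call(function(...) paste(..., sep = ":"), pieces)
  cells <- matrix(cells, nrow(v), length(x$samples))
  body <- apply(cbind(v$chrom, format(v$pos, trim = TRUE, scientific = FALSE),
                      v$id, v$ref, v$alt, ".", "PASS", ".", fmt, cells),
                1, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
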