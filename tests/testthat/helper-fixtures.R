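# Shared fixture builders and independent oracles.

# cohort from a dosage matrix (variants x samples); payload optional
make_cohort <- function(dosage, dp = NULL, gq = NULL, ad = NULL,
                        chrom = "1", pos = NULL, ref = "A", alt = "G",
                        regions = NULL) {
  nv <- nrow(dosage); ns <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(nv) * 100
  variants <- data.frame(chrom = rep_len(chrom, nv), pos = pos,
                         id = paste0("v", seq_len(nv)),
                         ref = rep_len(ref, nv), alt = rep_len(alt, nv),
                         stringsAsFactors = FALSE)
  a1 <- ifelse(dosage >= 1L, 1L, 0L); a1[is.na(dosage)] <- NA_integer_
  a2 <- ifelse(dosage == 2L, 1L, 0L); a2[is.na(dosage)] <- NA_integer_
  samples <- paste0("s", seq_len(ns))
  trio_cohort(variants, samples, a1, a2, dp, gq, ad, regions)
}

# trio_set over samples s1.. (child, mother, father per trio)
make_trios <- function(n) {
  trio_set(data.frame(
    trio_id = paste0("t", seq_len(n)),
    child_id = paste0("s", 3 * seq_len(n) - 2),
    mother_id = paste0("s", 3 * seq_len(n) - 1),
    father_id = paste0("s", 3 * seq_len(n)),
    child_affected = TRUE, stringsAsFactors = FALSE))
}

# dosage matrix (1 variant) from per-trio (child, mother, father) triples
trio_dosage_row <- function(...) {
  tri <- list(...)
  matrix(unlist(tri), nrow = 1)
}

# independent brute-force oracle: is a child dosage compatible with the
# parents' gametes? enumerate every gamete combination explicitly
oracle_mendel <- function(child, mother, father) {
  gam <- function(d) switch(d + 1, 0L, c(0L, 1L), 1L)
  any(outer(gam(mother), gam(father), "+") == child)
}

# independent brute-force transmission counter: enumerate each parent's
# gametes and find the (unique up to symmetry) combination matching the
# child, scoring heterozygous-parent transmissions
oracle_transmissions <- function(child, mother, father) {
  gam <- function(d) switch(d + 1, 0L, c(0L, 1L), 1L)
  gm <- gam(mother); gf <- gam(father)
  best <- NULL
  tu <- c(T = 0, U = 0)
  for (am in gm) for (af in gf) {
    if (am + af != child) next
    t <- 0; u <- 0
    if (mother == 1) { if (am == 1) t <- t + 1 else u <- u + 1 }
    if (father == 1) { if (af == 1) t <- t + 1 else u <- u + 1 }
    tu <- tu + c(T = t, U = u)
    best <- TRUE
  }
  # double-het child 1 matches twice (alt from mother or father): the two
  # matches together contribute T=1, U=1, which is the classical scoring
  if (is.null(best)) return(NULL)
  if (mother == 1 && father == 1 && child == 1) return(c(T = 1, U = 1))
  tu
}
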