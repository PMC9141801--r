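#' Configure a synthetic trio-cohort simulation
#'
#' The generator emulates a targeted-sequencing trio cohort: founder
#' haplotypes with blockwise linkage disequilibrium, Mendelian transmission
#' with optional distortion at risk loci, locus-heterogeneity subgroups,
#' rare variants, injected de novo variants, planted Mendelian errors and
#' quality-control failures, and realistic DP/GQ/allele-balance/missingness
#' structure.
#'
#' @param n_trios number of child-parent trios, default 80.
#' @param regions a [region_spec()]; one interval per simulated region.
#' @param n_variants variants per region (recycled), default 200.
#' @param maf founder minor-allele-frequency spectrum:
#'   `list(p_rare, rare_range, common_range)`; a variant is rare with
#'   probability `p_rare`, drawing its frequency uniformly from
#'   `rare_range`, else from `common_range`.
#' @param ld `list(block_length, rho)`: variants per haplotype block and
#'   the copy probability of the block-copying model. Within a block each
#'   variant's allele is the block ancestor's threshold indicator with
#'   probability `rho` and a fresh independent draw otherwise, giving an
#'   expected pairwise allele correlation of `rho^2` (r^2 = `rho^4`) for
#'   equal-frequency variants. Blocks are also the transmission unit: a
#'   parent transmits each block independently (free recombination between
#'   blocks, none within), so across-block transmissions are independent,
#'   consistent with the founder model's independent blocks.
#' @param risk_loci list of [risk_locus()] specifications.
#' @param n_denovo de novo variants injected into children, default 0.
#' @param mendel_single,mendel_double number of variants planted with
#'   exactly one / exactly two non-de-novo Mendelian inconsistencies.
#' @param qc_plants `list(low_dp, low_gq, bad_ab, high_missing,
#'   monomorphic)`: planted per-call and per-variant QC failures.
#' @param missing_rate random per-call missing probability, default 0.02.
#' @param depth `list(mean, floor)`: Poisson read-depth model truncated
#'   below at `floor` so unplanted calls always pass the depth filter.
#' @param gq `list(clean_min, max)`: genotype qualities of unplanted calls
#'   are drawn uniformly from `clean_min:max`.
#' @param ascertainment `NULL`, or `list(locus, min_copies)`: keep only
#'   trios whose child carries at least `min_copies` of the risk allele at
#'   risk locus number `locus` (rejection sampling).
#' @param seed integer seed (mandatory).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_trios = 80,
                       regions = region_spec("20", 55000001, 56000000,
                                             "simulated_target"),
                       n_variants = 200,
                       maf = list(p_rare = 0.2, rare_range = c(0.002, 0.01),
                                  common_range = c(0.05, 0.5)),
                       ld = list(block_length = 10, rho = 0.8),
                       risk_loci = list(),
                       n_denovo = 0,
                       mendel_single = 0, mendel_double = 0,
                       qc_plants = list(low_dp = 0, low_gq = 0, bad_ab = 0,
                                        high_missing = 0, monomorphic = 0),
                       missing_rate = 0.02,
                       depth = list(mean = 50, floor = 20),
                       gq = list(clean_min = 30, max = 99),
                       ascertainment = NULL,
                       seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(inherits(regions, "region_spec"), n_trios >= 1)
  for (rl in risk_loci) stopifnot(inherits(rl, "risk_locus"))
  qp <- list(low_dp = 0, low_gq = 0, bad_ab = 0, high_missing = 0,
             monomorphic = 0)
  qp[names(qc_plants)] <- qc_plants
  structure(list(n_trios = n_trios, regions = regions,
                 n_variants = n_variants, maf = maf, ld = ld,
                 risk_loci = risk_loci, n_denovo = n_denovo,
                 mendel_single = mendel_single, mendel_double = mendel_double,
                 qc_plants = qp, missing_rate = missing_rate, depth = depth,
                 gq = gq, ascertainment = ascertainment,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Specify a transmission-distorted risk locus
#'
#' Heterozygous parents of trios in the locus's subgroup transmit the risk
#' (alternate) allele with probability `tau`; all other transmissions are
#' fair, so `tau = 0.5` encodes the null and the expected TDT odds ratio is
#' `tau / (1 - tau)`. Optionally the risk variant's founder allele frequency
#' differs between subgroup members (`maf_in`) and the remaining trios
#' (`maf_out`), the signature of locus heterogeneity in which each family
#' subgroup segregates its own risk haplotype.
#'
#' @param region index of the region (interval) carrying the locus.
#' @param variant variant index within the region; `NULL` puts the locus at
#'   the region's middle variant.
#' @param tau transmission probability of the risk allele in \(0, 1\).
#' @param trios integer vector of trio indices forming the subgroup; `NULL`
#'   means all trios.
#' @param maf_in,maf_out founder risk-allele frequency for subgroup /
#'   non-subgroup parents; `NULL` keeps the spectrum draw.
#' @return an object of class `risk_locus`.
#' @export
risk_locus <- function(region = 1, variant = NULL, tau = 0.5, trios = NULL,
                       maf_in = NULL, maf_out = NULL) {
  stopifnot(tau > 0, tau < 1)
  structure(list(region = region, variant = variant, tau = tau,
                 trios = trios, maf_in = maf_in, maf_out = maf_out),
            class = "risk_locus")
}

#' Simulate founder haplotypes with blockwise linkage disequilibrium
#'
#' Within each block every haplotype owns one latent block-ancestor uniform
#' draw; a variant's allele is the ancestor's threshold indicator (allele 1
#' iff the draw falls below the variant's frequency) with probability
#' `rho`, and an independent fresh draw otherwise. Blocks are independent.
#' For two equal-frequency variants in one block the allele correlation is
#' `rho^2`, hence expected r^2 = `rho^4`; `rho = 0` gives independence and
#' `rho = 1` perfect within-block LD.
#'
#' @param n_hap number of haplotypes.
#' @param q per-variant allele-1 frequency.
#' @param block_id per-variant block membership.
#' @param rho copy probability in \[0, 1\].
#' @return integer matrix (haplotypes x variants) of 0/1 alleles.
#' @export
simulate_founder_haplotypes <- function(n_hap, q, block_id, rho) {
  nv <- length(q)
  stopifnot(length(block_id) == nv, rho >= 0, rho <= 1)
  blocks <- unique(block_id)
  u <- matrix(stats::runif(n_hap * length(blocks)), n_hap, length(blocks))
  qm <- matrix(q, n_hap, nv, byrow = TRUE)
  shared <- u[, match(block_id, blocks), drop = FALSE] < qm
  use <- matrix(stats::runif(n_hap * nv), n_hap, nv) < rho
  fresh <- matrix(stats::runif(n_hap * nv), n_hap, nv) < qm
  hap <- ifelse(use, shared, fresh)
  storage.mode(hap) <- "integer"
  hap
}

# safe sample: never interprets a length-1 pool as 1:n
sample_k <- function(pool, k) {
  if (k > length(pool)) stop("not enough elements to sample from")
  if (length(pool) == 1) pool else sample(pool, k)
}

# Choose the transmitted haplotype blockwise. One of the parent's two
# haplotypes is transmitted independently per haplotype block (blocks are
# independent in the founder model, so a block mosaic has exactly the
# founder haplotype distribution). A heterozygous parent at a subgroup risk
# variant transmits that variant's block carrying the risk allele with
# probability tau.
pick_haplotype <- function(h1, h2, block_id, risk, in_subgroup) {
  blocks <- unique(block_id)
  choice <- stats::setNames(stats::runif(length(blocks)) < 0.5, blocks)
  for (k in seq_along(risk)) {
    if (!in_subgroup[k]) next
    v <- risk[[k]]$gvar
    if (h1[v] == h2[v]) next
    risk_first <- h1[v] == 1L
    take_risk <- stats::runif(1) < risk[[k]]$tau
    choice[as.character(block_id[v])] <- if (take_risk) risk_first else !risk_first
  }
  use1 <- choice[as.character(block_id)]
  ifelse(use1, h1, h2)
}

#' Simulate a trio cohort with ground truth
#'
#' Runs the full generative model of [sim_config()]: founder haplotypes,
#' (possibly distorted) transmissions, optional proband ascertainment, de
#' novo injection, Mendelian-error planting, random missingness, clean
#' DP/GQ/allele-depth payload and planted QC failures. Before de novo
#' injection and error planting the cohort contains zero Mendelian errors
#' by construction. With a fixed seed the output is reproducible.
#'
#' @param cfg a [sim_config()].
#' @return list with `cohort` (a [trio_cohort()]), `trios` (a
#'   [trio_set()]), and `truth` (subgroup labels, risk-locus table, de novo
#'   list, Mendelian plants, QC plants, founder frequencies, seed).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  iv <- cfg$regions$intervals
  n_reg <- nrow(iv)
  nv_per <- rep_len(cfg$n_variants, n_reg)
  nv <- sum(nv_per)
  region_of <- rep(seq_len(n_reg), nv_per)
  chrom <- iv$chrom[region_of]
  pos <- unlist(lapply(seq_len(n_reg), function(r) {
    lo <- iv$start0[r] + 1; hi <- iv$end0[r]
    sort(round(seq(lo, hi, length.out = nv_per[r])))
  }))
  # founder MAF spectrum
  is_rare <- stats::runif(nv) < cfg$maf$p_rare
  q <- ifelse(is_rare,
              stats::runif(nv, cfg$maf$rare_range[1], cfg$maf$rare_range[2]),
              stats::runif(nv, cfg$maf$common_range[1], cfg$maf$common_range[2]))
  # haplotype blocks within regions
  block_id <- integer(nv)
  bo <- 0L
  for (r in seq_len(n_reg)) {
    ii <- which(region_of == r)
    block_id[ii] <- bo + ((seq_along(ii) - 1L) %/% cfg$ld$block_length) + 1L
    bo <- max(block_id[ii])
  }
  # resolve risk loci to global variant indices and subgroup labels
  risk <- cfg$risk_loci
  subgroup <- rep("none", cfg$n_trios)
  for (k in seq_along(risk)) {
    ii <- which(region_of == risk[[k]]$region)
    vloc <- risk[[k]]$variant
    if (is.null(vloc)) vloc <- ceiling(length(ii) / 2)
    risk[[k]]$gvar <- ii[vloc]
    tset <- risk[[k]]$trios
    if (is.null(tset)) tset <- seq_len(cfg$n_trios)
    risk[[k]]$trio_set <- tset
    lab <- paste0("locus_", k)
    subgroup[tset][subgroup[tset] == "none"] <- lab
    risk[[k]]$label <- lab
  }

  n <- cfg$n_trios
  child <- matrix(0L, nv, n); mother <- matrix(0L, nv, n)
  father <- matrix(0L, nv, n)
  max_attempts <- 1000L
  for (t in seq_len(n)) {
    qt <- q
    in_sub <- logical(length(risk))
    for (k in seq_along(risk)) {
      in_sub[k] <- t %in% risk[[k]]$trio_set
      if (in_sub[k] && !is.null(risk[[k]]$maf_in)) qt[risk[[k]]$gvar] <- risk[[k]]$maf_in
      if (!in_sub[k] && !is.null(risk[[k]]$maf_out)) qt[risk[[k]]$gvar] <- risk[[k]]$maf_out
    }
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      hap <- simulate_founder_haplotypes(4L, qt, block_id, cfg$ld$rho)
      m1 <- hap[1, ]; m2 <- hap[2, ]; f1 <- hap[3, ]; f2 <- hap[4, ]
      cm <- pick_haplotype(m1, m2, block_id, risk, in_sub)
      cf <- pick_haplotype(f1, f2, block_id, risk, in_sub)
      if (!is.null(cfg$ascertainment)) {
        av <- risk[[cfg$ascertainment$locus]]$gvar
        if (cm[av] + cf[av] < cfg$ascertainment$min_copies) next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("ascertainment filter could not be satisfied in ",
                  max_attempts, " attempts for trio ", t)
    child[, t] <- cm + cf
    mother[, t] <- m1 + m2
    father[, t] <- f1 + f2
  }

  reserved <- vapply(risk, `[[`, integer(1), "gvar")

  # --- de novo injection (child allele absent from both parents) ---
  denovo <- data.frame(variant = integer(), trio = integer(),
                       stringsAsFactors = FALSE)
  if (cfg$n_denovo > 0) {
    cand_v <- setdiff(seq_len(nv), reserved)
    cand_v <- sample(cand_v)
    for (v in cand_v) {
      if (nrow(denovo) >= cfg$n_denovo) break
      tt <- which(child[v, ] == 0L & mother[v, ] == 0L & father[v, ] == 0L)
      if (!length(tt)) next
      tr <- if (length(tt) == 1) tt else sample(tt, 1)
      child[v, tr] <- 1L
      denovo <- rbind(denovo, data.frame(variant = v, trio = tr))
    }
    if (nrow(denovo) < cfg$n_denovo)
      stop("could not place all requested de novo variants")
    reserved <- c(reserved, denovo$variant)
  }

  # --- planted Mendelian errors (never the de novo pattern) ---
  mendel <- data.frame(variant = integer(), trio = integer(),
                       n_errors = integer(), stringsAsFactors = FALSE)
  n_mend <- cfg$mendel_single + cfg$mendel_double
  if (n_mend > 0) {
    cand_v <- sample(setdiff(seq_len(nv), reserved))
    placed <- 0L
    for (v in cand_v) {
      if (placed >= n_mend) break
      want <- if (placed < cfg$mendel_single) 1L else 2L
      tt <- which(child[v, ] == 0L & mother[v, ] < 2L)
      if (length(tt) < want) next
      tr <- if (length(tt) == want) tt else sample(tt, want)
      mother[v, tr] <- 2L  # child 0 with a hom-alt mother: inconsistency
      mendel <- rbind(mendel, data.frame(variant = v, trio = tr,
                                         n_errors = want))
      placed <- placed + 1L
    }
    if (placed < n_mend) stop("could not place all requested Mendelian errors")
    reserved <- c(reserved, mendel$variant)
  }

  # --- assemble sample-level dosage (child, mother, father per trio) ---
  ns <- 3L * n
  trio_id <- sprintf("fam%03d", seq_len(n))
  samples <- c(rbind(paste0(trio_id, "_c"), paste0(trio_id, "_m"),
                     paste0(trio_id, "_f")))
  dos <- matrix(0L, nv, ns)
  dos[, seq(1, ns, 3)] <- child
  dos[, seq(2, ns, 3)] <- mother
  dos[, seq(3, ns, 3)] <- father

  # --- planted monomorphic variants (all reference) ---
  qcp <- cfg$qc_plants
  pool <- setdiff(seq_len(nv), reserved)
  take <- function(pool, k) {
    if (k == 0) integer(0) else sample_k(pool, k)
  }
  mono_v <- take(pool, qcp$monomorphic)
  pool <- setdiff(pool, mono_v)
  if (length(mono_v)) dos[mono_v, ] <- 0L
  highmiss_v <- take(pool, qcp$high_missing)
  pool <- setdiff(pool, highmiss_v)

  # --- random missingness (protected variants stay fully typed) ---
  protected <- c(reserved, mono_v, highmiss_v)
  miss <- matrix(stats::runif(nv * ns) < cfg$missing_rate, nv, ns)
  miss[protected, ] <- FALSE
  # high-missingness plants: push strictly above the 20% bound
  for (v in highmiss_v) {
    k <- ceiling(0.25 * ns)
    miss[v, sample(ns, k)] <- TRUE
  }
  dos_na <- dos
  dos_na[miss] <- NA_integer_

  # --- clean sequencing payload ---
  dp <- matrix(cfg$depth$floor + stats::rpois(nv * ns,
                                              cfg$depth$mean - cfg$depth$floor),
               nv, ns)
  gqm <- matrix(sample(seq(cfg$gq$clean_min, cfg$gq$max),
                       nv * ns, replace = TRUE), nv, ns)

  # per-call QC plants are chosen on clean, non-missing calls of unplanted
  # variants; low-depth plants happen before allele depths are drawn so the
  # planted calls fail the depth filter only
  qcp <- cfg$qc_plants
  cells_free <- which(!miss & !(row(miss) %in% protected))
  plant_cells <- function(k, subset = cells_free) {
    if (k == 0) return(integer(0))
    cells <- sample_k(subset, k)
    cells_free <<- setdiff(cells_free, cells)
    cells
  }
  lowdp_c <- plant_cells(qcp$low_dp)
  dp[lowdp_c] <- sample(5:14, length(lowdp_c), replace = TRUE)
  lowgq_c <- plant_cells(qcp$low_gq)
  gqm[lowgq_c] <- sample(5:19, length(lowgq_c), replace = TRUE)

  alt_reads <- matrix(0L, nv, ns)
  draw_cond <- function(idx, p, lo, hi) {
    # alt-read counts conditioned to keep the allele-balance filter happy
    need <- idx
    res <- integer(length(idx))
    names(res) <- NULL
    remaining <- seq_along(idx)
    for (it in 1:100) {
      if (!length(remaining)) break
      r <- stats::rbinom(length(remaining), dp[idx[remaining]], p)
      ratio <- r / dp[idx[remaining]]
      good <- ratio >= lo & ratio <= hi
      res[remaining[good]] <- r[good]
      remaining <- remaining[!good]
    }
    if (length(remaining)) {
      # fall back to the window midpoint (degenerate depths)
      res[remaining] <- round(dp[idx[remaining]] * (lo + hi) / 2)
    }
    res
  }
  i_het <- which(dos == 1L); i_ref <- which(dos == 0L); i_alt <- which(dos == 2L)
  alt_reads[i_het] <- draw_cond(i_het, 0.5, 0.3, 0.7)
  alt_reads[i_ref] <- draw_cond(i_ref, 0.02, 0, 0.1499)
  alt_reads[i_alt] <- dp[i_alt] - draw_cond(i_alt, 0.02, 0, 0.1499)

  # allele-balance plants go on heterozygous calls after depths are drawn
  qc_truth <- list()
  het_free <- intersect(cells_free, which(dos == 1L))
  badab_c <- plant_cells(qcp$bad_ab, het_free)
  alt_reads[badab_c] <- pmax(1L, round(0.15 * dp[badab_c]))

  cell_df <- function(cells) data.frame(
    variant = ((cells - 1) %% nv) + 1,
    sample = ((cells - 1) %/% nv) + 1)
  qc_truth$low_dp <- cell_df(lowdp_c)
  qc_truth$low_gq <- cell_df(lowgq_c)
  qc_truth$bad_ab <- cell_df(badab_c)
  qc_truth$high_missing <- highmiss_v
  qc_truth$monomorphic <- mono_v

  # --- build containers ---
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  variants <- data.frame(chrom = chrom, pos = pos,
                         id = sprintf("sim%s_%d", chrom, pos),
                         ref = ref, alt = unname(alt),
                         stringsAsFactors = FALSE)
  a1 <- ifelse(dos_na >= 1L, 1L, 0L); a1[is.na(dos_na)] <- NA_integer_
  a2 <- ifelse(dos_na == 2L, 1L, 0L); a2[is.na(dos_na)] <- NA_integer_
  ad <- matrix(paste0(dp - alt_reads, ",", alt_reads), nv, ns)
  ad[is.na(dos_na)] <- NA_character_
  dpm <- dp; dpm[is.na(dos_na)] <- NA_real_
  gq_out <- gqm; gq_out[is.na(dos_na)] <- NA_real_
  cohort <- trio_cohort(variants, samples, a1, a2, dpm, gq_out, ad,
                        cfg$regions)
  trios <- trio_set(data.frame(trio_id = trio_id,
                               child_id = paste0(trio_id, "_c"),
                               mother_id = paste0(trio_id, "_m"),
                               father_id = paste0(trio_id, "_f"),
                               child_affected = TRUE,
                               stringsAsFactors = FALSE))
  risk_df <- if (length(risk)) data.frame(
    locus = vapply(risk, `[[`, "", "label"),
    region = vapply(risk, function(r) r$region, numeric(1)),
    variant = vapply(risk, `[[`, integer(1), "gvar"),
    id = variants$id[vapply(risk, `[[`, integer(1), "gvar")],
    tau = vapply(risk, function(r) r$tau, numeric(1)),
    n_subgroup = vapply(risk, function(r) length(r$trio_set), integer(1)),
    stringsAsFactors = FALSE)
  else data.frame(locus = character(), region = numeric(),
                  variant = integer(), id = character(), tau = numeric(),
                  n_subgroup = integer(), stringsAsFactors = FALSE)
  denovo$id <- variants$id[denovo$variant]
  denovo$trio_id <- trio_id[denovo$trio]
  if (nrow(mendel)) { mendel$id <- variants$id[mendel$variant]
                      mendel$trio_id <- trio_id[mendel$trio] }
  truth <- list(subgroup = stats::setNames(subgroup, trio_id),
                risk_loci = risk_df, denovo = denovo, mendel = mendel,
                qc = qc_truth, founder_maf = q, block_id = block_id,
                seed = cfg$seed)
  list(cohort = cohort, trios = trios, truth = truth, config = cfg)
}
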