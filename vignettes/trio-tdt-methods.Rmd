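---
title: "Trio-based transmission disequilibrium analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based transmission disequilibrium analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triotdt)
```

## The scientific setting

Targeted resequencing of regions flagged by a genome-wide association study
is a standard fine-mapping design for rare congenital disorders such as
nonsyndromic craniosynostosis: a dense marker map over a few megabases is
genotyped in affected child–parent trios, and association is re-assessed
with family-based tests that are immune to population stratification.
`triotdt` implements the full analysis chain for such a design — genotype
quality control, Mendelian-error handling, de novo detection, the
single-variant transmission disequilibrium test (TDT), a leave-one-out
jackknife for locus heterogeneity, rare-variant collapsing TDTs, and
genotype-frequency profiling — together with a synthetic cohort generator
that produces data with the statistical structure these analyses assume.

## The transmission disequilibrium test

For each variant, every heterozygous parent of an affected child
contributes exactly one observation: the alternate allele was either
transmitted (T) or untransmitted (U). Under the null of no association
(in the presence of linkage), transmissions are fair coin flips, and

$$\chi^2 = \frac{(T-U)^2}{T+U} \sim \chi^2_1,$$

the McNemar statistic. The odds ratio is reported as $T/U$ (0 when
$T = 0$, infinite when $U = 0$, matching how extreme rows are printed in
association tables). Both-heterozygous parent pairs contribute two counts
(child dosage 0 adds two untransmitted, dosage 2 two transmitted, dosage 1
one of each). Trios with a missing or Mendelian-inconsistent genotype at
the variant are skipped.

Two numerical points matter here:

* p-values are computed as the upper chi-square tail in **log space**
  (`pchisq(..., lower.tail = FALSE, log.p = TRUE)`), never as
  $1 - F(\chi^2)$, which underflows near $10^{-16}$; the worked-example
  tests check 3-significant-figure agreement at $p \approx 5 \times
  10^{-16}$.
* the *minor/major* orientation used in reporting over-transmission
  direction comes from **founder (parental) allele frequencies**, not from
  ref/alt labels and not from the children: the children of a distorted
  locus are exactly the individuals whose allele frequencies are shifted,
  so using them would flip the reference frame the comparison needs.

## The genotype QC cascade

Filters are applied in a fixed order, each stage logged: region
restriction, multiallelic splitting, per-call filters, per-variant
filters, then the Mendelian policy.

| parameter | default | semantics |
|---|---|---|
| `min_depth` | 15 reads | call kept at DP $\ge$ 15 (15 passes) |
| `min_gq` | 20 (phred) | call kept at GQ $\ge$ 20 (20 passes) |
| `homref_ab_max` | 0.15 | hom-ref call fails at alt fraction $\ge$ 0.15 |
| `het_ab_low/high` | 0.30 / 0.70 | het call passes inside the closed window |
| `homalt_ab_min` | 0.85 | hom-alt call fails at alt fraction $\le$ 0.85 |
| `max_missing_rate` | 0.20 | variant dropped strictly above 20% missing |
| `drop_monomorphic` | TRUE | evaluated after call filtering |

The depth/quality/allele-balance criteria are read as **per-call** filters
(the call is set missing), not whole-variant drops: DP, GQ and allele
depths are per-genotype FORMAT fields, and the subsequent missingness
filter is only meaningful if failing calls accumulate as missingness. The
log records both readings' ingredients (calls removed per filter, variants
removed per stage) so the alternative interpretation can be audited.
Missingness is computed over all samples — parents and children. Calls
with no measured allele depths are exempt from the allele-balance filter:
one cannot test what was not measured. A half-called genotype (one missing
allele) is treated as fully missing.

Multiallelic records are split into one biallelic record per alternate
allele. On a split record, a genotype carrying a *different* alternate is
set missing rather than recoded as reference — recoding would
systematically inflate reference transmissions in the TDT.

## Mendelian errors and de novo variants

A trio genotype is checked against biparental gamete enumeration (the
package's checker is itself tested against an independent brute-force
oracle over all 27 dosage triples, 12 of which are inconsistent). Trios
with any missing member are untestable and skipped — counting them as
errors would conflate QC with inheritance. The policy, applied **after**
de novo calling so zero-out cannot erase the signal: variants with two or
more inconsistencies are dropped; a variant with exactly one has the
offending trio's three genotypes set missing.

De novo calling uses a stricter variant missingness bound (2%) and reports
only the de-novo-consistent pattern: both parents homozygous reference,
child carrying the alternate. Other inconsistencies (e.g. child 0 with a
hom-alt parent) are genotyping errors, never de novo calls. Each call is
annotated with the cohort minor-allele frequency and a recurrence count
across trios; recurrent "de novos" are reported, not suppressed —
interpretation is left to the analyst.

## Leave-one-out locus partitioning

With several associated regions, different trio subsets may drive
different signals. For each locus an index variant is fixed (the
full-cohort top hit in the region by default, overridable), and the TDT at
that variant is recomputed once per trio with that trio removed. The
influence of trio $i$ on locus $\ell$ is

$$\Delta_{i\ell} = -\log_{10} p_\ell^{\text{full}} + \log_{10}
p_\ell^{(-i)},$$

positive when the trio strengthens the signal. Removing an uninformative
trio (no heterozygous parent at the index variant) gives exactly 0; if
removal leaves no transmissions, the influence is recorded as the full
$-\log_{10} p$ (maximal). Index variants are *not* re-selected inside the
loop — re-selection would make influence entries incomparable across
trios; the alternative can be emulated by passing explicit index variants.

Trios are then assigned to the locus at which their influence is maximal,
provided it is strictly positive; ties and all-nonpositive rows stay
unassigned, and unassigned trios are excluded from the per-group reruns
rather than forced into a group. Partition **accuracy** against simulation
truth is scored among *assigned* trios, with the assignment rate reported
separately: a trio with no heterozygous parent at any index variant
carries no information about its subgroup at those variants, and calling
its non-assignment an error would measure informativeness, not the
partitioning rule.

## Rare-variant collapsing TDTs

Rare variants (founder minor-allele frequency $\le$ 0.01, inclusive;
frequency estimated from the cohort's parents, not an external database)
are collapsed per gene or intergenic region into transmission events — one
event per heterozygous parent per variant in a complete, consistent trio,
with each variant oriented to its founder minor allele. Four statistics
are offered:

* **BRV** — total transmitted minus untransmitted rare-allele count,
  $T_r - U_r$;
* **CMC** — number of trios transmitting at least one rare allele minus
  the number un-transmitting at least one (carrier-level McNemar
  contrast);
* **WSS** — $\sum_v w_v (T_v - U_v)$ with Madsen–Browning-style weights
  $w_v = 1/\sqrt{n_v q_v (1-q_v)}$, $q_v = (U_v + 1)/(n_v + 2)$ estimated
  from the **untransmitted** parental chromosomes (the within-family
  pseudo-control), re-estimated inside every permutation; a variant with
  no events gets weight 0;
* **VT** — the BRV-style count maximized over the distinct founder-MAF
  thresholds present in the region, the maximization repeated inside each
  permutation; by construction the observed VT statistic dominates BRV.

The null is generated by flipping each event's transmitted status
independently with probability ½ — exactly Mendel's law for unlinked
transmissions. p-values carry the $+1$ correction, so $p \in (0, 1]$;
CMC/BRV/WSS are two-sided on $|$statistic$|$ (a statistic of 0 under a
symmetric null gives $p = 1$), VT one-sided on the maximized count.

A calibration subtlety: BRV and CMC statistics are integer-valued, so
their permutation p-values are *discrete* and therefore superuniform —
the atom at $p = 1$ has probability $\approx P(|S| = \min) \sim
1/\sqrt{n_\text{events}}$, and a literal Kolmogorov–Smirnov uniformity
check must reject them at realistic region sizes. The package's
uniformity calibration therefore uses WSS, whose frequency-dependent
weights give the statistic effectively continuous support; BRV/CMC
calibration is demonstrated as type-I error control at $\alpha = 0.05$.
Because flips are within-family, all four tests are immune to founder
population structure by construction.

## The synthetic cohort generator

The generator emulates the ~80-trio targeted-sequencing design over 1–4 Mb
regions.

**Founder haplotypes.** Within a block of `block_length` variants
(default 10), each haplotype owns one latent uniform draw; variant $v$'s
allele is the threshold indicator $\mathbf{1}\{u < q_v\}$ with probability
$\rho$ (default 0.8) and an independent fresh draw otherwise. For two
equal-frequency variants in a block the allele correlation is $\rho^2$,
hence expected $r^2 = \rho^4$ — a closed form the tests check at $n =
10{,}000$ haplotypes, along with the $\rho = 0$ and $\rho = 1$ limits.
Blocks are independent; a coalescent backend is out of scope, so only
qualitative block structure (not a specific empirical LD landscape) is
reproduced.

**Transmission.** Each parent transmits one of their two haplotypes *per
block*, independently across blocks. Because founder blocks are
independent, a block mosaic has exactly the founder haplotype
distribution, keeping the model self-consistent; it also makes
transmissions at unlinked variants independent, which is the regime the
event-flipping permutation null assumes (with `block_length = 1` the match
is exact). At a risk locus, heterozygous parents of subgroup trios
transmit the risk allele with probability $\tau$; $\tau = 0.5$ is the
null, and the expected TDT odds ratio is the closed form
$\tau/(1-\tau)$ — the reason distortion is parameterized by $\tau$ rather
than by penetrances. Locus-heterogeneity scenarios additionally give the
risk variant a subgroup-specific founder frequency (`maf_in` vs
`maf_out`): families belong to a subgroup *because* they segregate that
locus's risk haplotype.

**Payload and plants.** Unplanted calls are *calibrated clean*: depth is
floor-truncated Poisson (floor 20 $\ge$ the DP filter), GQ uniform on
30–99, and alt-read counts are drawn conditioned to the passing
allele-balance window of the call's genotype class. QC failures are then
planted explicitly (low-DP calls, low-GQ calls, out-of-window het calls,
high-missingness variants, monomorphic variants), as are de novo events
and Mendelian errors, all recorded in a truth table — so every pipeline
stage can be scored exactly against ground truth. De-novo target variants
are protected from random missingness so that strict-filter recall is a
property of the caller, not of missingness luck. Optional ascertainment
(keep only trios whose child carries the risk allele, by rejection
sampling with a bounded attempt count) mirrors proband-carrier selection
and produces the child-versus-parent genotype-frequency enrichment the
profiling operation is designed to detect.

## Problem sizes and scenario parameters

The test-suite and acceptance scenarios use sizes chosen to make each
check statistically meaningful at interactive runtimes:

* **null TDT calibration** — 80 trios × 2,000 independent variants; the
  fraction of $p < 0.05$ is compared with 0.05 within 3 binomial standard
  errors;
* **permutation calibration** — 200 null regions × 20 rare variants
  (founder MAF 0.005–0.01), 1,000 permutations, KS on the WSS p-values;
* **parameter recovery** — $\tau = 0.8$, risk-allele frequency 0.3, 500
  trios, 25 replicates; the replicate-mean OR is compared with 4.0 via its
  99% Monte-Carlo confidence interval (the $T/U$ ratio has a small
  $O(1/U)$ upward bias, well inside that interval);
* **heterogeneity recovery** — 80 trios split 60/20 over two regions with
  $\tau = 0.85$ and $\tau = 0.96$ (the effect sizes implied by the
  published 58/10 and 0/24–1/24 transmission rows), `maf_in` 0.35,
  `maf_out` 0.02; partition accuracy among assigned trios must reach 0.9.

## Known limitations

* The generator's LD is blockwise-exchangeable; real haplotype maps have
  nested, decaying LD that the copying model does not reproduce.
* Event-level permutation is exact for unlinked variants; for rare
  variants in strong LD within one parent the flips ignore phase
  coupling, as does any event-level null.
* The jackknife influence is measured at a single index variant per
  locus; signals spread over many partially-linked variants dilute it.
* X-chromosome inheritance, parent-of-origin effects, sibships, and
  covariate adjustment are out of scope.
* Passing tests on simulated cohorts demonstrate correctness of the
  accounting and calibration under the generator's assumptions — clean
  biallelic calls, block LD, no contamination — not performance on any
  particular real dataset.
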