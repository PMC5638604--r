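---
title: "Models and design choices in paradapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in paradapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paradapt)
```

paradapt asks two questions about the repeatability of adaptation in
*Drosophila*: do latitudinally separated populations of distantly related
species differentiate at the same genes, and do distantly related clades fix
adaptive amino-acid changes in the same proteins? This vignette explains the
estimators, the tests, the synthetic-data generators, and the places where
the design was genuinely open and a choice had to be made.

## Pooled diversity and differentiation

All population-genetic quantities are computed from read counts of pooled
DNA samples; the number of chromosomes in each pool never enters the
estimators. This mirrors the upstream sequencing design and is a documented
limitation: at low coverage, read counts underrepresent the pool's true
allele-frequency precision.

Per site and pool, with coverage $c = \sum_a c_a$ over base calls only
(N and deletion calls are discarded everywhere — the analysis concerns point
variation), expected heterozygosity is

$$H = \frac{c}{c-1}\Big(1 - \sum_a (c_a/c)^2\Big).$$

The $c/(c-1)$ factor removes the sampling bias of the plug-in sum of squared
frequencies: under binomial read sampling, $E[H] = 2p(1-p)$ exactly, which
the test suite verifies empirically at coverage 60.

Sites enter the scan when both pools reach 20× base-call coverage and the
alternate allele is seen at least twice across the dataset; triallelic sites
are excluded. Per-SNP differentiation is

$$F_{ST} = \frac{\pi_T - \pi_W}{\pi_T},$$

with $\pi_W$ the unweighted mean of the two pools' $H$ and $\pi_T$ the $H$
of the summed counts. Negative values are retained — clamping would distort
the empirical tails that the outlier machinery feeds on. One subtlety is
deliberate and documented rather than "fixed": because the correction factor
is evaluated at combined coverage $2c$ inside $\pi_T$ but at $c$ inside
$\pi_W$, two pools with *identical* counts give a slightly negative
$F_{ST}$ of order $-1/(2c)$, vanishing with coverage. Removing the
correction would instead break the estimator's agreement with its worked
finite-coverage values; the bias is small relative to the outlier threshold
(0.15) by two orders of magnitude.

Windows are 1 kb, non-overlapping, with trailing sub-window scaffold ends
discarded. Window π divides the summed per-site $H$ by the number of
*covered* sites, not the window length, so missing data is not silently
treated as invariance (the two denominators agree when coverage is
complete, which the suite checks). Windows below 50% site coverage are
dropped. Window $F_{ST}$ is the unweighted mean of per-SNP $F_{ST}$; a
covered window with no SNPs contributes 0 to the distribution — an
undifferentiated window is evidence, not missingness. Tail thresholds at
fractions $f \in \{0.01, 0.025, 0.05\}$ take the $\lfloor fn \rfloor$-th
largest window value, and ties at the threshold are all flagged:
deterministic, conservative supersets.

## Outlier testing

Each SNP's 2×2 table of read counts (alleles × populations) gets a central
two-sided mid-p exact test: with margins fixed the top-left cell is
hypergeometric, the one-sided mid-p values count half the observed table's
probability, and the two-sided value doubles the smaller side (capped at 1).
Doubling was chosen over minimal-likelihood two-sided variants for
determinism and to match standard epidemiology-toolkit behaviour. Testing
raw read counts pseudo-replicates chromosomes and is anti-conservative in
absolute terms; the p-values are used to *rank* SNPs into an empirical FDR,
not as calibrated single-SNP tests (see the README note).

False discovery rates are estimated independently per chromosome arm
(Muller element; unassigned scaffolds form a pseudo-arm), since arms differ
in diversity and differentiation. The q-values are Storey's:
$\hat\pi_0(\lambda)$ on the grid $\lambda = 0.05, \dots, 0.95$, smoothed
with a df-3 cubic spline and read off at $\lambda = 0.95$, then
$q_i = \hat\pi_0 \cdot \min_{p_j \ge p_i} m p_j / \mathrm{rank}(p_j)$.
Whether the upstream FDR used the smoother or a bootstrap $\pi_0$ is not
knowable from the record; the smoother is the published default. Arms with
fewer than 100 tests, or a degenerate smoother fit, fall back to
$\pi_0 = 1$ — plain Benjamini–Hochberg — because the smoother is unstable
on short p-value vectors (the 100 cutoff is this package's choice). An
outlier is $q \le 10^{-5}$ **and** $F_{ST} > 0.15$, strict on the second
inequality.

SNP polarization uses an outgroup base at the aligned position: exactly one
of the two alleles must match it, otherwise the SNP is excluded from
polarized (directionality) analyses.

## Gene assignment and effect classes

A SNP belongs to a gene when it falls within the transcript span ±1 kb,
boundary-inclusive (inclusivity was unstated upstream; inclusive chosen). A
SNP under several overlapping genes is counted once per gene — dropping all
but a "primary" gene would silently delete signal from nested genes. When a
gene has isoforms, the longest-CDS transcript represents it. Effect classes
are assigned with priority CDS > UTR > intron > flanking (the record does
not say how feature conflicts were resolved; this priority is the package's
rule, stated once and tested as exhaustive and exclusive). Coding SNPs
substitute the alternate allele into the reference codon — the other two
positions stay at reference state, minus-strand genes are handled in
transcript orientation — and compare amino acids under the standard nuclear
code. The suite validates 1000 random coding SNPs against an independent
oracle that mutates the whole spliced CDS, translates both proteins with
Biostrings, and diffs them.

Scaffolds join Muller elements when at least 55% (inclusive — "55% had"
reads as attained) of their annotated genes best-align to one element.

## McDonald–Kreitman analysis

From a codon alignment of the two focal alleles and an outgroup, a site
where the focal alleles differ is a polymorphism and a site where they
agree but differ from the outgroup is a fixed difference. Every change is
classified against the focal reference codon with the other two positions
at reference state; multi-hit codons are decomposed site by site in that
same context (no mutational-pathway enumeration — deterministic and
standard in MK pipelines, a known approximation at deeply diverged
codons). A codon may contribute a polymorphism and a fixed difference
independently. Codons with a gap or N are skipped.

MK SNPs pass a stricter filter than the scan — minor allele called ≥3
times — to keep low-frequency, slightly deleterious amino-acid variants
from inflating $P_n$ and masking adaptive divergence. A gene is testable
with at least one variant in each marginal category (polymorphic, fixed,
synonymous, nonsynonymous). Then

$$\alpha = 1 - \frac{D_s P_n}{D_n P_s}, \qquad
  \mathrm{DoS} = \frac{D_n}{D_n + D_s} - \frac{P_n}{P_n + P_s},$$

with Fisher's exact (minimal-likelihood two-sided) p on the 2×2 table.
$\alpha$ is left undefined — not clipped — when $D_n = 0$ or $P_s = 0$, and
undefined genes are excluded from the cross-clade α correlation (Spearman,
average ranks, t-approximation p). A gene shows recurrent adaptive protein
evolution when $p < 0.05$, $\mathrm{DoS} > 0$ and $\alpha > 0$.

Sex-bias classes partition FPKM pairs: expressed means FPKM > 1 in at least
one sex; ≥2-fold difference (≥ chosen where the record says "two-fold
greater") makes a gene biased; biased plus ≤0.2 FPKM in the other sex makes
it specific.

## Sharing statistics

Set overlap is tested against the upper-tail hypergeometric
$P(X \ge k)$ with fold enrichment $k/(Kn/N)$. But outlier lists are not
uniform draws: genes with more nonsynonymous SNPs have more chances to
contain an outlier in *both* species, so gene size alone inflates sharing.
The matched bootstrap replaces each outlier gene by a random universe gene
with an **equal or greater total nsSNP count** (without replacement within a
replicate, largest requirements drawn first from the smallest eligible
pools), recomputes the cross-species overlap B = 1000 times, and reports
the add-one empirical p, $(1 + \#\{k_b \ge k_{obs}\})/(B+1)$. The upstream
record describes the matching criterion both as "nsSNP outliers" and as
"nsSNPs"; the total-count reading is implemented because the confounder
being corrected is SNP opportunity, not outlier status itself.

Two properties of this null deserve statement. First, when all genes carry
equal counts it reduces exactly to uniform resampling, making observed and
replicate overlaps exchangeable and the p-value uniform — this is the null
under which the suite calibrates it (500 datasets, B = 1000, KS at
α = 0.01). Second, when counts vary and outliers are uniform, the matched
replicates are *deliberately* pulled toward high-count genes, making the
test conservative; and when outliers themselves arise purely from SNP
density (counts varying 10-fold, inclusion proportional to count, no
biological sharing), the naive hypergeometric test rejects several times
above nominal while the matched bootstrap stays at or below it — the
suite demonstrates exactly this contrast, which is the method's reason to
exist.

Directional bias (derived allele more often up in one population) is a 1-df
Pearson χ² against 50:50 without continuity correction (counts in all
applications are large). Evidence across species combines as Fisher's
$-2\sum\ln p_i \sim \chi^2_{2k}$. One upstream discrepancy is recorded and
not chased: a printed p of 0.014 for a 537:463 split does not match the
1-df χ² (0.019) or an exact binomial (0.021).

## Expression parallelism

Because one species lacks biological replicates, differential expression is
purely rank-based: genes expressed in both species (FPKM > 1 in at least one
population sample per species) are ranked by
$|\log_2((F_1 + 0.1)/(F_2 + 0.1))|$ — the 0.1 pseudo-count keeps zero-FPKM
genes defined — and the top-N lists are compared hypergeometrically, ties
broken by gene id. The overlap is invariant to monotone transforms of the
ranking statistic.

The direction-split analysis separates sign-concordant from sign-discordant
genes (zero fold changes excluded from both groups) and compares the
Pearson correlations of fold-change *magnitudes* within groups — absolute
values, following the record's "r abs" phrasing — via Fisher's z, and via a
permutation null that redraws two disjoint groups of the observed sizes
from the pooled genes ("correcting gene number" is read as size-matched
resampling; label shuffling was the alternative reading).

## Synthetic data: what it emulates, what it does not

The generators define the package's study conditions:

* **popgen**: pool coverages Poisson with means 60 and 70 (the study's two
  pool coverages), derived-allele ancestral frequencies from a 1/x density
  on [0.05, 0.95], one binomial drift step per population (denominator 200),
  SNP density 0.006/bp so genome π lands near 0.002, 2% of SNPs shifted by
  +0.6 in population 1, intron-containing gene models on both strands, an
  outgroup carrying the ancestral allele plus 5% divergence (optionally
  third-positions-only, to steer the syn/nonsyn divergence ratio).
* **mk**: per-gene true α on a grid; $E[D_n] = (E[D_s]E[P_n]/E[P_s])/(1-\alpha)$
  with Poisson counts; optionally the realized counts are planted as
  substitutions in generated in-frame codon alignments that the counting
  code must recover exactly.
* **expression**: 3000 ortholog pairs (of the order of the study's expressed
  ortholog sets), 5% truly DE per species with log2 effects
  $\mathcal{N}(0, 3)$ — top-ranked latitudinal DE genes in flies commonly
  exceed 8-fold — half of them shared with concordant sign, log-normal
  observation noise (σ = 0.25 per sample). The non-shared part of each
  species' DE set is drawn independently, so a zero shared fraction is a
  true independence null; calibration runs use no DE at all, because genes
  must be exchangeable for the naive top-N overlap to be exactly
  hypergeometric (with unshared-but-heterogeneous DE, top-list inclusion
  probabilities vary by gene — the same artifact family the matched
  bootstrap exists for).

Drift is one binomial step, not a Wright–Fisher trajectory, and there is no
linkage, no recombination structure, no base-quality error model (sync
inputs are assumed already quality-filtered, Q ≥ 30 upstream) and no
coalescent realism. Passing tests therefore show that the *estimators and
tests* behave as specified on data with the right marginal structure —
coverage, frequency spectra, selection shifts, count confounds — not that
the pipeline is robust to linked selection or demographic complexity in
real genomes.

## Problem sizes and numerics

The test suite runs at desk scale, chosen to finish in minutes while
keeping every check at the size its statistic needs: enumeration-oracle
equivalence on hundreds of random tables (margins ≤ 30/40) and exhaustive
set-pair enumeration up to N = 25 where $\binom{N}{n}$ stays tractable;
α recovery at expected counts ≥ 100 over 800–1000 genes (median bias
< 0.05); scan-null uniformity on 500 simulated SNPs; overlap and
matched-bootstrap calibration over 500 simulated datasets (the latter at
B = 1000); the SNP-density confound contrast over 150 datasets at B = 199,
where nominal-level resolution, not p-value resolution, is what matters.
Exact-test p-values agree with their enumeration oracles to 10⁻¹²;
quantile-type choices (tail thresholds as order statistics, all ties
flagged) are deterministic by construction. All stochastic operations take
explicit integer seeds, restore the caller's RNG state, and record the seed
in their results and in the run manifest written by `run_pipeline()`.

## Known limitations

Pool counts stand in for chromosome counts throughout; the mid-p outlier
test is a ranking device, not a calibrated test; multi-hit codons are
classified against the reference context rather than by pathway averaging;
the matched bootstrap is conservative when outliers are uniform but counts
vary; and window F_ST treats SNP-free windows as zero differentiation,
which slightly compresses the lower tail in sparse data.
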