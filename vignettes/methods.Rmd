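---
title: "Methods: models, estimators and design choices in herdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in herdscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdscan)
```

`herdscan` packages the analysis stack for low-coverage livestock genotype
panels: platform concordance, windowed diversity and differentiation, the
PBS and CLR selection scans, ABBA-BABA introgression tests, PCA/NJ
structure inference, and window-to-gene overlap accounting, together with a
synthetic-data generator that makes every stage testable end to end. This
vignette explains the models behind each stage, the parameters that matter,
and the design decisions taken where the methods literature leaves a
choice.

## The synthetic panel generator

### Drift model

Real panels of this kind pool a large target population genotyped at low
coverage with smaller reference populations and two outgroup species. The
generator reproduces that statistical structure with a Balding–Nichols
frequency-perturbation model on a fixed caterpillar tree rather than a full
coalescent: an ancestral allele frequency per site is drawn from a
neutral-like spectrum with density proportional to $1/p$ (truncated to
$[0.02, 0.98]$ to keep sites informative), and every branch of length $t$
generations through effective size $N_e$ replaces $p$ by a Beta draw with
mean $p$ and variance $p(1-p)F$, where

$$F = 1 - e^{-t/(2N_e)}.$$

Diploid genotypes are then binomial draws from the tip frequencies. The
model is fast, has no linkage, and gives closed-form expectations: two
sister populations split $t$ generations ago have expected per-site F_ST of
$1 - e^{-t/(2N_e)}$, which is exactly the quantity the parameter-recovery
tests check (at 10^4+ sites, within ±0.02). A coalescent would add
realistic linkage disequilibrium but none of the estimators under test
depend on it for their correctness, only for their standard errors — which
the block jackknife in the D-statistic module handles empirically.

The default panel (`default_demography()`) mirrors a West-African zebu
study design at desk scale: a 20-diploid target zebu population, 12 other
African zebu, 8 Asian zebu, 7 European taurine, and 5 + 4 outgroup-species
samples (banteng-like, water-buffalo-like), on two 10 Mb chromosomes at
2.6e-4 segregating sites per bp (the density of a filtered joint cattle
panel). Split times (100 / 250 / 600 / 2500 / 5000 generations at
$N_e = 1000$) place pairwise F_ST near 0.05 within zebu, 0.2–0.3 zebu vs
taurine, and above 0.7 against the outgroups, which is where cattle panels
put them.

### Sweeps

A `sweep_spec(chrom, center, radius, intensity)` injects ground truth for
the selection scans. Within the radius, a site is hitch-hiked with
probability `intensity`; at a hitch-hiked site each sampled lineage escapes
the sweep with probability $d/r$ (distance over radius, so 0 at the
center), escapees draw their allele from the drifted frequency and
non-escapees carry the derived allele. The expected derived frequency is
therefore pushed toward fixation as

$$p' = p + I\,(1 - d/r)\,(1 - p),$$

while the sampled spectrum at small $d$ shows the excess of rare and
high-frequency-derived variants that a real sweep leaves. An earlier,
purely deterministic variant (replacing every frequency by $p'$) was
rejected: it creates a band of *intermediate*-frequency sites at the taper
edge that no sweep produces, and the CLR model correctly refuses to call it
a sweep, which defeats the purpose of the ground truth. Intensity 0 leaves
the spectrum statistically unchanged; overlapping sweeps on one chromosome
are rejected as ill-defined truth.

### Platform emulation

`emulate_platform()` models a reduced-representation low-coverage re-call:
each *site* survives restriction-site subsetting independently with the
retention probability; each retained genotype receives a read depth
$\sim\text{Poisson}(\lambda)$; reads are drawn binomially from the true two
alleles with a per-read error rate; and the genotype is re-called by
flat-prior maximum likelihood over RR/RA/AA, with likelihood ties broken
toward RR (the simplest rule that reproduces the heterozygote-undercall
asymmetry seen in real GBS-vs-WGS comparisons). Depth 0 is a missing call;
an optional phred-scale genotype-quality floor can censor marginal calls.
Heterozygote undercalling is emergent, not parameterized: at depth $d$ a
true het is miscalled homozygous with probability $2^{1-d}$ (error-free
case), which the tests verify against exact enumeration over read draws.
The emulator never touches positions, alleles or sample order — only
genotype values and site retention — so concordance accounting downstream
is exact.

What the generator does *not* emulate: linkage disequilibrium, indels,
multiallelic sites, reference bias, batch effects correlated across sites,
and allele-specific error. Passing tests therefore certify the estimators
and their wiring, not robustness to those real-data pathologies.

## Concordance accounting

`classify_sites()` partitions every query site into exactly one of
concordant-shared, alt-discordant-shared, or novel (position absent from
the reference), and self-checks that the partition sums. "Novel" is
defined purely by position; the alt-discordant class is exposed separately
so users can combine classes as they see fit, because published "partial
novel" terminology is ambiguous. Percentages are reported at two decimals
with round-half-up so printed figures are exactly reproducible from the
counts. Genotype match rates condition on the *reference* call's class
(the benchmark-platform framing) and drop pairs with a missing call on
either side. The allele-sharing distance is
$D(i,j) = \text{mean}_s |g_i - g_j|/2$ over co-called sites —
pairwise-complete, never imputed — and platform agreement is summarized by
the Pearson correlation of the strictly-lower-triangle entries of two
distance matrices with the standard t-test p-value.

## Diversity and differentiation

Per-site diversity uses the unbiased estimator $2j(n-j)/(n(n-1))$ on
called allele counts; window values divide the summed site diversities by
the window length in bp. Windows with zero usable sites carry `NA` — a
window with no *data* is not a window with no *diversity*.

Per-site F_ST defaults to the Weir–Cockerham (1984) two-population
variance components $(a, a+b+c)$, with Hudson's estimator (Bhatia et al.
2013 form) selectable; both are windowed as a ratio of summed components,
never an average of per-site ratios, following standard recommendations.
Sites need at least two called alleles per population (and more than one
diploid per population for WC) or they are flagged unusable.

Windowing follows the two conventions in use: diversity in non-overlapping
100 kb windows tiled from position 1, differentiation in 50 kb windows
sliding by 2 kb. Published descriptions of the latter ("non-overlapping
windows of 50 kb … in each consecutive 2 kb interval step") conflate the
two modes, so the sliding configuration is the default and
`step_bp = window_bp` gives the non-overlapping mode. Windows are anchored
at the first variant per chromosome (genome-wide anchoring across
chromosome boundaries would tie window phase to chromosome order, which
nothing downstream wants).

## The PBS scan

For target N, control group OT and distant group D, each pairwise windowed
F_ST is clamped into $[0, 1 - 10^{-9}]$ and transformed to a branch length
$t = -\ln(1 - F_{ST})$, and

$$\mathrm{PBS} = \tfrac{1}{2}\,(t_{N,OT} + t_{N,D} - t_{OT,D}).$$

The clamping guarantees no `NaN`/`Inf` ever reaches the ranking: negative
F_ST estimates become branch length 0. Printed versions of this equation
sometimes mix symbols for the three terms; the standard three-branch form
with all terms log-transformed is used. Control and distant groups may
pool several population labels, which covers the usual four scenarios
(European control, Asian control, Euro-Asian pooled, other-zebu pooled)
with the outgroup species pooled as D. Outliers are the empirical top 1%:
the threshold is the `ceiling(q n)`-th largest non-missing window value and
ties at the threshold are included.

## The CLR sweep scan

The background site-frequency spectrum is tallied over segregating sites
with complete calls in the scanned population (complete-call restriction
keeps the sample size per site constant, avoiding projection). Folded mode
(minor-allele counts, no polarization risk) is the default; unfolded mode
polarizes by requiring every outgroup group to be fixed for the same
allele and drops disagreeing sites.

The sweep model follows the classic composite-likelihood construction: a
lineage at distance $d$ from the sweep escapes with probability
$p_e = 1 - e^{-\alpha d}$; escapes are independent; all non-escapees
coalesce into one ancestral lineage at the sweep; the $(B+1)$ surviving
lineages are a hypergeometric draw from the background sample; and the
sample is restored to size $n$ by copying the ancestral lineage. Two edge
cases are fixed by consistency: $B = n$ leaves nothing coalesced and
reduces to the background sample (so $\alpha d \to \infty$ recovers the
background spectrum exactly), and at $\alpha d \to 0^+$ the spectrum
conditional on segregation concentrates on the singleton/(n−1) classes —
the size-2-sample expansion — while the unconditional mass collapses to
monomorphic classes. Both limits are tested, and the whole transition
matrix is verified against brute-force enumeration over all escape subsets
and copy assignments for n ≤ 6.

The scan evaluates `grid` evenly spaced positions per chromosome
(mirroring the grid-based CLI tools; 1000 grid points genome-wide is the
published configuration, scaled down here with the chromosome count),
maximizes the conditional composite likelihood over a log-spaced `alpha`
grid spanning $10/L$ to $10^6/L$ per bp (footprints from chromosome-scale
to point-scale; no recombination map, so `alpha` is in 1/bp), and reports
$\mathrm{CLR} = 2(\ln CL_{\text{sweep}} - \ln CL_{\text{background}})$.
The alpha grid carries an `Inf` sentinel meaning "escape everywhere",
which *is* the background model; CLR is therefore non-negative by
construction, ties prefer the smallest alpha, and `alpha_hat = Inf` reads
as "no sweep signal here". Invariant sites are not modeled (segregating
sites only, the default of grid-based sweep scanners); neither choice
claims to reproduce any specific external tool's numeric output.

## ABBA-BABA introgression tests

With derived frequencies $p_1..p_4$ polarized so the outgroup carries the
major allele (sites with outgroup derived frequency above 0.1 are dropped
as unpolarizable), the site weights are
$ABBA = (1-p_1)p_2p_3(1-p_4)$ and $BABA = p_1(1-p_2)p_3(1-p_4)$, and
$D = \Sigma(ABBA-BABA)/\Sigma(ABBA+BABA)$. Population frequencies rather
than single genomes are used because the tests are population-level;
single-sample mode is the same formula with $p \in \{0, \frac12, 1\}$.
Standard errors come from a delete-one jackknife over contiguous genomic
blocks — by default each chromosome is cut into 20 blocks, since a fixed
5 Mb block size only makes sense at genome scale — and significance uses
the conventional $|Z| \ge 3$ with no multiple-testing correction.
`all_quadruples()` enumerates every unordered pair (P1, P2) against every
third population and the fixed outgroup ($\binom{m}{2}(m-2)$ tests),
de-duplicating the sign-flip symmetry.

## Structure

PCA uses Patterson normalization — center by $2\hat p$, scale by
$\sqrt{2\hat p(1-\hat p)}$ — with per-site mean imputation of missing
genotypes (imputation is confined to PCA; distances are always
pairwise-complete). Variance explained is eigenvalue over trace of the
sample covariance. NJ trees are built by Saitou–Nei neighbour joining on
the allele-sharing distance matrix, population-averaged first for
population-level trees; negative branch-length estimates are clamped to
zero with the excess pushed onto adjacent branches, preserving path
lengths through the affected node. Newick export writes six significant
digits, and optional outgroup rooting splits the outgroup's branch at its
midpoint. Multiple-sequence alignment plays no role here: distances are
computed directly from genotypes.

## Annotation overlap

A gene is assigned to an outlier window on ≥1 bp interval overlap with
zero flank by default (published window-to-gene rules rarely state their
flank; the flank is a parameter). GTF/GFF3 input prefers `gene` features
and falls back to per-`gene_id` envelopes; BED is 0-based half-open per
the standard. Gene-set comparison is case-insensitive exact symbol
matching — no orthology inference — and the Venn accounting reports exact
region counts, per-set totals, pairwise intersections and shared-by-k
counts, which always sum to the union size.

## Numerical and testing choices

All randomness flows through one seeded generator per operation call;
the same seed yields byte-identical VCF output. Coordinates are 1-based
inclusive internally (VCF convention) with a single utility converting to
0-based half-open for BED export. Probability guards use a floor of
1e-300 inside logs; spectrum normalization is checked to 1e-9.

The test-suite problem sizes are chosen so the whole suite runs in
minutes on one core while leaving each check statistically sharp:
drift-recovery at ~10^4 sites (±0.02 tolerance), sweep scans on 5 Mb
chromosomes with 100 grid points (50 kb localization resolution, five
seeds), D-statistics on 20 Mb chromosomes (~20,000 sites, ten seeds), and
oracle equivalences at machine tolerance. Genome-scale published figures
(hundreds of selected genes per scan, distance correlations at the fourth
decimal, per-component variance percentages of a 268-genome panel) are
functions of the full data and are deliberately not targets; the
acceptance checks replace them with the printed-count arithmetic they rest
on plus the property suites above.

## Known limitations

No haplotype statistics (iHS, XP-EHH), no recombination maps, no
invariant-site handling in the CLR scan, no f4-ratio or graph fitting, no
Tracy–Widom significance for PCs, no bootstrap supports on trees, and no
genotype imputation. The simulator's independence across sites means
window-level sampling noise is optimistic relative to linked real data;
conclusions about statistical power at genome scale should not be read off
the desk-scale defaults.
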