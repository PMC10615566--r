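---
title: "Haplotype-based selection scans in structured populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based selection scans in structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sweepscan implements a complete scan pipeline for recent positive selection
from phased SNP array data in populations with fine-scale structure, of the
kind used to contrast the two major Japanese subpopulation clusters (the
main-island Hondo cluster and the Ryukyu Archipelago cluster): quality
control with population-structure-aware Hardy–Weinberg recovery, PCA
stratification, the integrated haplotype score (iHS), Hudson's F~ST~ with a
scaled chi-square significance model, and an identity-by-descent (IBD) based
density-of-recent-coalescence (DRC) statistic with a Gamma empirical null.
Because cohort genotypes of this kind are not publicly distributable, the
package ships a forward Wright–Fisher simulator that generates phased
two-subpopulation panels with known truth, and every statistical claim made
by the test suite is made on simulated data whose generating process is
described here.

## The simulator

`simulate_panel()` runs a discrete-generation Wright–Fisher model of one
chromosome:

* **Founders.** `n_founders` haplotypes are drawn site-wise with
  derived-allele frequencies from a neutral frequency spectrum with density
  proportional to $1/x$, truncated to $[1/(2 n_\text{founders}), 1]$ so all
  sites start polymorphic. Founders are mutually unrelated, so the
  between-haplotype background diversity at generation 0 is at the scale of
  single markers.
* **Demography.** A panmictic population of $2 \times$ `pop_size` diploids
  evolves for `n_generations_burnin` generations, then splits into two
  subpopulations of `pop_size` diploids that evolve independently for
  `split_generation` generations, except for symmetric migration (each
  parent of a child is drawn from the other subpopulation with probability
  `migration_rate`).
* **Recombination.** Each meiosis draws a Poisson number of crossovers with
  mean `chrom_length_cM`/100, at positions uniform on the genetic map.
  There is no mutation: all variation segregates from the founders, which is
  adequate for haplotype statistics over the tens-to-hundreds of
  generations the scans target.
* **Selection.** An optional sweep multiplies a parent's sampling weight by
  $(1+s)$ per derived copy at the focal site, in the targeted
  subpopulation(s), from `sweep_start_generation` generations before
  present. `focal_founder_freq` pins the focal site's founder frequency;
  sweeps started from a low frequency behave as hard sweeps (the derived
  class descends from few founder haplotypes), higher starting frequencies
  give soft sweeps.

All randomness flows from one integer seed recorded in the returned truth
object; runs are bit-reproducible. With `track_ancestry = TRUE` the founder
origin of every allele is propagated alongside the alleles, and
`true_ibd_segments()` extracts ground-truth IBD tracts (maximal runs where
two haplotypes inherit the same founder haplotype) for detector validation.

The default configuration (1,000 founders, 500 diploids per subpopulation,
10 burn-in generations, a 3-generation split) reproduces the differentiation
scale of the motivating study system, a weighted F~ST~ of a few times
$10^{-3}$ between subpopulations — the approximate expectation is
$F_{ST} \approx t/(2N)$ for a split $t$ generations ago. The simulator's
parameters are otherwise free knobs: no attempt is made to calibrate them to
any particular cohort's demography.

**What the simulator does not emulate:** genotyping error, array
ascertainment of SNPs, mutation, gene conversion, variable recombination
rate along the chromosome, overlapping generations, and realistic deep
demography (bottlenecks, admixture). Tests passing on these panels show the
statistics behave as designed under a clean neutral/sweep dichotomy; they do
not certify behaviour under array artefacts.

## Quality control

`hwe_exact_test()` is the standard exact conditional test: given the allele
counts, the two-sided p-value sums the probabilities of all heterozygote
counts no more probable than the observed one. `filter_variants_two_stage()`
removes variants below a 97% call rate or below HWE $p = 10^{-6}$ pooled,
then *recovers* a variant failing only pooled HWE when it passes at the same
level in every subpopulation separately — pooled deviations can be a pure
Wahlund effect of structure, and the two-stage rule mirrors that reasoning.
"Passes in every subgroup" is the operationalisation chosen for "deviates
only when the whole dataset is considered"; it is the conservative reading.

`relatedness_pihat()` is the method-of-moments PLINK-style estimator: the
IBS0/IBS1/IBS2 pair counts are equated with their allele-frequency
expectations under 0/1/2 alleles shared identical by descent, and
$\hat\pi = P(\text{IBD}=1)/2 + P(\text{IBD}=2)$, clipped to $[0,1]$. One
member of each pair with $\hat\pi \ge 0.25$ is removed greedily (highest
flagged-pair degree first, ties by lower call rate, then input order — the
removal order is a convention, not identifiability).

`ld_prune()` implements sliding-window greedy pruning with the conventional
window/step/threshold 100/10/0.2 at MAF $\ge$ 5%, removing the later-indexed
member of each high-$r^2$ pair. `pca_top_k()` takes the SVD of
frequency-standardised dosages ($(g - 2p)/\sqrt{2p(1-p)}$); the PC outlier
rule is a single pass removing samples more than 3 SD from the mean on PC1
or PC2.

## iHS

For a core allele, EHH at distance $x$ is the probability two random
carrier haplotypes are identical at every marker from the core to $x$,
computed by refining carrier groups marker by marker. iHH integrates EHH
over genetic distance by the trapezoid rule outward on each side until the
first marker with EHH below 0.05 — that crossing trapezoid is included,
then integration stops; a side hitting the chromosome end first is flagged
edge-truncated (kept, flagged, because a fixed-size simulated chromosome
truncates many sites). The cutoff 0.05 and the boundary convention follow
the de-facto standard implementation of the statistic. No between-marker
gap penalty is applied: the simulator emits uniformly dense markers, and
array data of the motivating design are similarly dense; this is a
documented simplification.

`ihs_raw` $= \ln(\text{iHH}_A/\text{iHH}_D)$; variants with MAF < 1% or
an undetermined ancestral state are excluded, and zero iHH on either allele
flags the score undefined. Raw scores are standardised within 100
equal-width derived-allele-frequency bins (sample SD; bins with fewer than
two scores or zero SD are flagged rather than imputed). P-values are
two-sided normal, $2\Phi(-|z|)$: selection may lengthen either allele's
background, and the two-sided choice is the conservative reading of
"assuming a normal distribution".

`normalize_ihs()` accepts an optional `reference` scan whose bin statistics
are used instead of the scanned records' own. This matters for small
simulated genomes: on a 60-cM chromosome a sweep's hitchhikers are several
percent of all markers and contaminate their own normalization bins,
shrinking the focal z-score — whereas in a real genome-wide scan candidate
regions are a negligible fraction. Standardising a sweep-condition scan
against matched neutral panels restores the genome-wide interpretation; the
power study below does exactly that.

## Hudson F~ST~

Per SNP, $N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
\frac{p_2(1-p_2)}{n_2-1}$ and $D = p_1(1-p_2) + p_2(1-p_1)$. Multi-SNP
summaries use the ratio of averages $\sum N / \sum D$, with a
delete-one-block jackknife SE over 100 contiguous variant blocks — the
standard genome-scan choice where LD makes per-SNP resampling invalid.
Negative per-SNP estimates are reported as-is; they are clipped to zero only
inside the p-value fit. The significance model treats per-SNP F~ST~ as a
scaled $\chi^2_1$: the scale is the method-of-moments fit
$\hat c = \overline{\max(F_{ST}, 0)}$ (since $E[\chi^2_1] = 1$), and the
one-sided p-value is the $\chi^2_1$ survival function at
$\max(F_{ST},0)/\hat c$. One degree of freedom corresponds to a biallelic
frequency contrast; the df is exposed as a parameter since the fitting
procedure behind the published analysis is not fully specified.

## IBD detection and DRC

`detect_ibd()` replaces a coalescent-HMM IBD caller with a documented
detector: exact-match runs of at least 64 markers seed candidate segments,
extended through isolated mismatches while each extension step's marginal
mismatch density stays at or below 1 per cM (a step crosses one mismatching
site to the end of the next exact-match run; clusters of mismatches are
therefore crossed only if locally plausible, and a dense cluster splits the
segment). Quality is the within-segment match fraction, a bounded [0,1]
weight. Segment age is the tract-length heuristic
$\hat g = 50/\ell_\text{cM}$ generations — the expected IBD tract length
for a common ancestor $g$ generations back is about $100/(2g)$ cM.
Consequently DRC at timescale $T$ is driven by segments of at least $50/T$
cM (2.5 / 1 / 1/3 cM at $T$ = 20 / 50 / 150).

`drc_bins()` tiles the chromosome with non-overlapping 0.05-cM bins;
DRC$_T$ of a bin is the quality sum of overlapping segments with
$\hat g \le T$, each haplotype pair counted at most once per bin, divided
by the number of pairs. The per-pair normalisation bounds the statistic in
[0,1]; nesting DRC$_{20} \le$ DRC$_{50} \le$ DRC$_{150}$ holds by
construction.

The empirical null fits a Gamma distribution by maximum likelihood
(moment-fit start) to the positive bin values, computes upper-tail
p-values, excludes bins below the exclusion level, and iterates until the
exclusion set stabilises. The exclusion level defaults to the Bonferroni
scan threshold, appropriate at genome scale where true signals are a
vanishing fraction of bins. On the short simulated chromosomes of the
power study the swept region is several percent of all bins and a Bonferroni
level never engages (the fit simply absorbs the signal); there the study
uses an exclusion level of 0.01 — the analog of seeding the exclusion with
known selection loci before iterating, as done at genome scale. Zero-valued
bins are excluded from the likelihood and their mass recorded, so p-values
are tail probabilities conditional on a positive statistic.

## Thresholds, loci, SV filtering

`bonferroni_threshold()` divides the family-wise level by tests ×
subpopulations × timescales and reports both full precision and the
3-significant-digit form usually printed. `merge_to_loci()` joins
significant records within 0.1 cM (two bins) into loci with the member
minimum as lead p — the merge gap is a convention, exposed as a parameter.
`sv_overlap_filter()` flags a locus when its physical overlap with a common
structural variant (length ≥ 10 kb, AF ≥ 1%) covers at least 10% of the SV
length, inclusive at the boundary; flagged loci are retained with flags
rather than dropped, and the same operation serves segmental-duplication
interval sets.

## Study sizes used by the tests

The test suite and the acceptance script run everything on simulated
panels; sizes were chosen once, for statistical validity of each check:

* **Neutral iHS calibration** — two panmictic populations of 200 diploids
  expanded from 2,000 founders for 500 generations, 50,000 markers each on
  a 100-cM chromosome. The deep history matters: the within-bin
  distribution of iHS approaches normality only when haplotype mosaics are
  many recombination generations old, as in real cohorts; shallow founder
  expansions give visibly light-tailed scores. The p < 0.01 tail fraction
  is compared with its binomial 99% interval, which presumes independent
  draws, so it is evaluated on cores thinned to at least 0.5 cM spacing
  (neighbouring scores share most of their haplotype window and are far
  from independent); normalization itself remains genome-wide.
* **Sweep power study** (`sweep_power_study()`) — 60-cM chromosomes with
  9,000 markers; two subpopulations of 600 diploids, split 120 generations
  ago after a 40-generation expansion from 2,000 founders; additive
  selection $s = 0.05$ on a focal allele starting at 1% founder frequency
  95 generations before present, in the second subpopulation only.
  Replicates are accepted when the focal derived-allele frequency at
  sampling lies in [0.4, 0.8] (re-seeding otherwise), so the sweep is
  segregating, not fixed. iHS detection compares the focal |z| (normalised
  against matched neutral reference panels) with the neutral 99th
  percentile; DRC detection requires a 0.05-cM bin within 1 cM of the focal
  site to reach the Bonferroni genome-wide level — the scan's own notion of
  a discovered locus. At this bin granularity the exact position of the
  plateau peak within the swept region is set by single early recombination
  events in the sweep genealogy (and a small simulated genome always
  carries some drift-driven sharing hotspot elsewhere), so locus
  significance, not global-argmin bin identity, is the meaningful notion of
  "detected at the right place". The down-sampling check repeats the DRC
  scan with half the haplotypes.
* **Structure checks** — a 20-generation split of 80-diploid
  subpopulations (weighted F~ST~ ≈ 0.06) for PC1 separation, and three
  pooled panmictic 10,000-marker panels on 500-cM chromosomes for the
  F~ST~-consistent-with-zero check. The pooling is deliberate: jackknife
  blocks must exceed the LD correlation length, and parent-sharing within
  one Wright–Fisher generation leaves a small genome-wide random effect
  that only between-panel variation can expose to the jackknife.

## Numerical conventions and degenerate inputs

Coordinates are 1-based for variants (VCF convention) and 0-based
half-open for intervals (BED convention). Monomorphic sites: HWE returns
p = 1 (no test, flagged); Hudson F~ST~ flags and excludes pooled-monomorphic
sites rather than dropping silently; `ld_r2()` errors. Undetermined
ancestral states are flagged and excluded downstream, never guessed.
Ties in the exact HWE enumeration are included in the rejection set with a
$1 + 10^{-9}$ relative tolerance to make the "probability not exceeding the
observed" rule robust to floating-point noise. The Gamma MLE falls back to
nothing: degenerate (constant) input is an error, and non-convergence of
the exclusion iteration returns the last fit with a warning flag.

## Known limitations

* The IBD detector is deliberately simple; its quality score is a match
  fraction, not a posterior, and its age heuristic ignores the variance of
  tract lengths. DRC values are therefore comparable within a dataset but
  not across detectors.
* iHS requires phased, complete haplotypes; the package does not phase.
* The two-subpopulation simulator does not model the four-island
  substructure of the Ryukyu cluster; subanalysis-style scans are exercised
  only via the threshold arithmetic.
* The pipeline's unknown-key configuration validation is shallow (one level
  of nesting), matching its flat configuration schema.
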