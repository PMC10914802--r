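---
title: "Methods: bulked-segregant QTL mapping in autotetraploid crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked-segregant QTL mapping in autotetraploid crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaqtl)
library(dplyr)
```

## The problem

Bulked-segregant analysis with whole-genome sequencing (BSA-Seq) maps
quantitative trait loci by pooling the DNA of the phenotypically most
extreme individuals of a segregating population into two bulks and
sequencing the pools. At a locus linked to the trait, selection of the
extremes shifts the allele frequencies of the two pools apart; everywhere
else the pools are random samples of the same cross and their frequencies
agree up to sampling noise. `bsaqtl` implements this strategy for
*autotetraploid* crops — its motivating case is drought tolerance in
starch potato (2n = 4x = 48), phenotyped by tuber starch yield — together
with the downstream steps a practitioner needs: variant filtering, a
smoothed G' genome scan, interval summarisation against a gene
annotation, parental attribution of bulk SNPs, candidate-SNP selection
for a targeted genotyping panel, and marker–trait association tests on
that panel.

Because the motivating data sets are hundreds of gigabytes of reads, the
package ships a generative model of the whole design (`sim_config()` and
the `simulate_*()` functions) so that every stage is testable offline and
end to end.

## Phenotype model: RelSY and DRYM

Drought tolerance is quantified per genotype $G$ and experiment $E$ by
the relative starch yield

$$\mathrm{RelSY}_{G\times E} = \frac{SY_{\text{stress}}}{SY_{\text{control}}},$$

and by its deviation from the experiment median,

$$\mathrm{DRYM}_{G\times E} = \mathrm{RelSY}_{G\times E} - \operatorname{median}_G(\mathrm{RelSY}_{G \times E}).$$

DRYM is centred within every experiment (the median of DRYM is zero by
construction, a conservation property the tests assert) and is invariant
to rescaling all yields of an experiment, which makes trials with very
different yield levels comparable. `compute_relsy()` drops genotype ×
experiment cells with a missing treatment or a zero control yield, with a
warning, because the ratio is undefined there.

Bulk selection (`select_bulks()`) ranks genotypes by DRYM within each
experiment (rank 1 = most tolerant, average ranks for ties), averages the
ranks over the experiments in which a genotype was observed, and takes
the `n_bulk` genotypes from each end. Orientation is fixed by the bulk
means, so the "tolerant" bulk is always the one with the higher mean
DRYM. An optional 1.5·IQR outlier filter on per-experiment DRYM can be
switched on (`flag_outliers = TRUE`); it is off by default because
outlier handling is survey-specific. Only the mean rank drives selection;
minimum and maximum ranks are reported for inspection. Bulk separation is
tested with Welch's unequal-variance *t* test (`bulk_separation_test()`),
with the convention that two identical constant bulks give $t = 0$,
$p = 1$.

## Variant filtering

`filter_variants()` retains biallelic SNP records whose per-sample depth
lies in [`min_depth`, `max_depth`] (defaults 20–360 reads), whose
alternative-allele frequency lies in [0.10, 0.90], and whose genotype
quality is at least 99. All bounds are inclusive: the stated exclusion
rules are "below 20 / above 360" and "below 10% / above 90%", so the
endpoints themselves pass, and the boundary fixtures in the test suite
pin this down. Records missing a required field fail closed and are
tallied as `missing-field`; each rejected record is counted under the
first failing rule so the tally plus the retained count always equals the
input count.

Multiallelic sites are split into one record per alternative allele with
$af = ad_{alt} / (ad_{ref} + \sum ad_{alt})$ — a conservative
apportionment that can never exceed the frequency the allele would show
at a biallelic site.

A *difference SNP* (`intersect_bulks()`) is a key passing the filter in
exactly one bulk: the exclusivity criterion that drives candidate
selection. A frequency-difference mode (`af_diff`) is available for
sensitivity analyses but off by default.

## The G' scan

Per SNP, the four allelic depths (ref/alt × tolerant/sensitive) form a
2×2 table tested with the likelihood-ratio statistic

$$G = 2\sum_{i} n_i \ln(n_i/\hat n_i),$$

with expected cells $\hat n_i$ from the margins under independence;
zero cells contribute nothing and a zero margin gives $G = 0$
(an uninformative site). The test suite cross-checks $G$ against an
independent $2N\,\mathrm{KL}$ brute-force oracle to $10^{-9}$.

Raw $G$ is noisy at a single SNP; linked SNPs share signal. G' is the
tricube-weighted local average: a focal SNP at position $x$ averages
the $G$ of neighbours within $h = \texttt{window\_size}/2$ with weights
$w_j = (1 - (|x_j - x|/h)^3)^3$. The default `window_size` of 1 Mb is
the full smoothing extent (so $h$ = 500 kb); smoothing never crosses a
chromosome boundary. The smoother is linear in $G$ and shift-invariant
in position, both asserted as properties.

The null distribution of G' is estimated from SNPs with
$|\Delta \mathrm{SNP}| < \texttt{filter\_threshold}$ (default 0.1) —
sites with essentially no bulk contrast, whose smoothed G reflects
sampling noise only. A log-normal null is fitted robustly with the
median and MAD of $\ln G'$, so SNPs under true QTLs (which inflate the
tail) do not distort the fit. P-values are the upper-tail survival of
the fitted law; multiple testing uses Bonferroni at $\alpha = 0.01$ by
default (Benjamini–Hochberg q-values are also emitted). On simulated
null data the 1% level is recovered within ±0.003, an acceptance
property.

QTL intervals are maximal runs of significant SNPs; runs closer than
`merge_gap` (default one window) merge. Interval bounds sit on the
outermost significant SNPs — reproducible from discrete data, unlike
threshold-crossing interpolation, which is why we chose it even though
it slightly shortens intervals at sparse SNP density.

## Interval summaries

`summarize_qtl()` completes intervals with `area_bp = end − start`
(coordinate span, no +1 — the convention that reproduces every span of
the published potato overview table exactly), the count of genes
overlapping by any basepair, the gene density
$\lceil n_\text{genes} / (\text{area}/10^6) \rceil$ (the ceiling is
forced empirically: all fifteen published densities, e.g. 24.29 → 25 and
291.35 → 292, follow it), and SNP counts inside the interval.
`summarize_qtl_totals()` sums spans, genes and SNPs and averages the
per-interval densities (rounded to one decimal), which reproduces the
published summary row (96.5 = 1448/15). The published regions ship as a
package data set (`exa_qtl_regions()`), and the acceptance tests
recompute the whole table arithmetic from them.

`probe_design_yield()` truncates (never rounds up) the design-yield
percentage to one decimal — the convention under which 410/1034 = 39.65%
is quoted as 39.6%.

## Parental attribution and windows

`classify_origin()` assigns each bulk SNP key to `A-only`, `E-only`,
`both` or `neither` by presence among the two parents' calls. Parent
presence uses *unfiltered* parent calls (a genuinely shared SNP that
fails a filter in one parent would otherwise masquerade as unique), but
requires at least `min_alt_reads = 3` alternative reads so that isolated
sequencing-error reads do not create spurious parental calls — with the
default error rate of 0.002 and 80–120× depth, three reads bound the
false-presence probability below $10^{-3}$, giving the ≥99% attribution
accuracy asserted in simulation. `venn_counts()` tallies the four
classes genome-wide and per interval; the classes partition the bulk, so
counts always sum to the classified total and percentages to 100.

`rolling_windows()` computes overlapping window means and standard
deviations of any per-SNP value (defaults 1 Mb windows stepped by
500 kb, anchored at position 1, final partial window retained). With
step = size it reduces exactly to a disjoint tiling, which the tests
check against an independent binning oracle. Empty windows are emitted
with `n_snps = 0` and `NA` statistics; a single-SNP window has `NA`
standard deviation.

## Candidate selection and the panel

Round 1 (`round1_select()`) works on difference SNPs in *literature*
genes (genes with published evidence for the trait, given as input)
inside the QTL intervals. Gene extents are extended strand-awarely by
2000 bp at the 5' end and 500 bp at the 3' end — fixed flank windows
covering promoter/UTR variation, since fixed sizes cannot be annotation
UTRs. At most `max_snps_per_gene = 3` SNPs are kept per gene,
prioritised by effect severity (nonsense > missense > synonymous > UTR >
intron > up/downstream; the placement of synonymous above the
non-coding classes follows the usual impact ordering of effect
annotators) with ties broken by position. The severity priority among
more than three qualifying SNPs is our rule; published descriptions of
such panels state only the cap.

Round 2 (`round2_select()`) adds missense and nonsense difference SNPs
in *any* annotated gene under a QTL, minus what round 1 already took.
`panel_design()` unions the rounds (duplicate keys are impossible and
guarded), and `write_probe_bed()` emits ±200 bp flanks for
oligonucleotide design. Effect classes come from `parse_effects()`,
which reads either SnpEff-style `ANN` fields from a VCF or a plain
effect TSV, maps terms onto a closed vocabulary (unknown terms become
`other` and are tallied), and keeps the most severe annotation per
SNP–gene pair.

## Association testing

`split_panel()` orders the variety panel by tolerance rank and assigns
the top half to the tolerant group (the middle variety of an odd panel
goes to the sensitive group). `fisher_association()` dichotomises each
variety per SNP into carrier / non-carrier of the alternative allele —
the only dichotomy available from presence-style targeted-genotyping
spreadsheets; a per-variety dosage mode is available for the
Kruskal–Wallis path — and applies the two-sided Fisher exact test at
$\alpha = 0.05$ without multiple-testing correction (q-values are
emitted informationally, matching how such targeted panels are usually
reported). The implementation's p equals an exhaustive hypergeometric
enumeration oracle for every 2×2 table with $n \le 30$ to $10^{-12}$,
and on a null panel the empirical significance rate stays below 0.07
(the discreteness of the exact test makes it conservative).

`kruskal_wallis_eta2()` is the tie-corrected Kruskal–Wallis H with
$\chi^2$ p-value and effect size $\eta^2 = (H - k + 1)/(n - k)$, which
can be slightly negative under the null; complete ties return $H = 0$
by convention. H is invariant under monotone transforms of the
tolerance values, asserted as a property.

## The synthetic cross

The generator is a first-class, tested model of the study design:

* **Genome and loci.** Loci are placed by a Poisson process at
  `snp_density` along `n_chromosomes` × `chrom_length_bp`. Defaults are
  a scaled-down genome — 5 chromosomes × 5 Mb at one SNP per 10 kb
  (~2,500 loci) — chosen so a full simulate-to-scan replicate runs in
  seconds while leaving hundreds of SNPs per smoothing window.
* **Parents.** Per locus each parent draws a dosage from a uniform prior
  on 0..4 and the dosage is phased onto four homologues. Loci where both
  parents are 0 (or 4) are retained: they model sites where the
  cultivars jointly differ from the reference assembly and segregate in
  neither bulk, the dominant class in real cultivar-vs-reference data.
* **Meiosis.** Gametes form by random bivalent pairing: two of the four
  homologues drawn uniformly, so a parent of dosage $d$ transmits $k$
  alternative alleles with probability
  $\binom{d}{k}\binom{4-d}{2-k}/\binom{4}{2}$ — the tetrasomic
  hypergeometric law, verified by a χ² goodness-of-fit test at
  $n = 10^5$ gametes. Double reduction is available as a parameter and
  defaults to 0 (the simplest model consistent with autotetraploidy).
  With `linkage_block_bp` set (default 1 Mb) all loci in a block share
  one homologue-pair draw, producing the locally correlated inheritance
  that gives QTL peaks realistic width; `NULL` gives fully unlinked
  loci, used where a test needs a pure single-locus signal.
* **QTL.** At a planted QTL the tolerant parent carries dosage 3 and the
  other dosage 1 (triplex × simplex) so the locus segregates over
  offspring dosages 1–3 and "high-dosage" clones exist for enrichment
  checks. The phenotype follows
  $\mathrm{RelSY} = 0.5 + \sum_q \beta_q (d_q - 2)/2 + \varepsilon$,
  $\varepsilon \sim N(0, 0.05)$, over 3 experiments (three independent
  drought trials being the typical design), clipped at 0; a dosage-4
  clone at a QTL of effect 0.2 sits exactly 0.2 above a dosage-2 clone.
* **Sequencing.** Equimolar pooling is assumed (the pooling protocol of
  the motivating studies does not state otherwise), so the pool
  frequency is mean dosage / 4. Site depth is negative-binomial with
  mean 120 (the targeted coverage of the motivating experiment; 80× in
  the recovery battery) and dispersion 0.2, because real WGS depth is
  overdispersed relative to Poisson; dispersion 0 recovers Poisson.
  Alternative reads are binomial with error-perturbed success
  probability $f(1-e) + (1-f)e$, $e = 0.002$. GQ is 99 at comfortable
  depth and degrades below 20× so the GQ filter is exercisable.
* **Annotation.** Non-overlapping gene models of fixed internal
  structure (UTRs, two introns, three exonic segments) are tiled every
  20 kb (~50 genes/Mb, comparable to a gene-rich plant genome),
  alternating strands; exonic SNPs draw missense/synonymous/nonsense at
  0.5/0.45/0.05. The GFF3 and effect-table outputs are positionally
  consistent by construction and cross-checked by interval lookup.
* **Panel.** `simulate_panel()` emulates the provider's presence/absence
  spreadsheet for 34 varieties with a latent tolerance index; SNPs named
  as associated get a logistic dependence of carrier probability on
  tolerance.

What the generator does **not** emulate: read-level artifacts
(alignment errors, indel realignment, mapping bias near repeats),
multiallelic sites and indels (the reader handles them; the generator
emits biallelic SNPs only), polyploid genotype-calling uncertainty
(allele frequencies come from read counts, not called dosages), LD decay
within blocks (inheritance is block-constant rather than distance
decaying), and selection on anything but the planted QTLs. Passing tests
therefore demonstrate the statistical machinery under the stated
generative assumptions, not robustness to alignment- or caller-level
pathologies.

## Numerical choices and edge cases

* Inclusive filter bounds at 20/360, 0.10/0.90, GQ ≥ 99; first-failing-
  rule rejection tallies; missing fields fail closed.
* Tricube half-window $h$ = `window_size`/2; a lone SNP keeps its own G.
* Null fit needs ≥ 50 SNPs below the ΔSNP threshold, else an error
  advises raising `filter_threshold`; a zero MAD (degenerate null)
  errors rather than emitting meaningless p-values.
* $p$ is set to 1 where G' ≤ 0 or undefined.
* Interval coordinates are 1-based inclusive internally; BED exports are
  0-based half-open.
* `area_bp` is end − start without +1; gene density uses the ceiling;
  the totals row averages densities and rounds to one decimal;
  probe-design yield truncates to one decimal.
* The per-gene cap takes severity first, then position; shrinking the
  flank windows can only remove candidates (monotonicity property).
* Fisher tables drop missing calls per SNP; monomorphic SNPs get
  $p = 1$; the odd panel's middle variety goes to the sensitive group.
* Full determinism under a fixed seed, end to end, including the
  pipeline manifest's record counts.

## Problem sizes used by the test and acceptance batteries

The shipped batteries simulate 5 × 5 Mb genomes with ~2,500 loci, 100 F1
clones and bulks of 20 at 80× (recovery) or 120× (default), 10 seeded
recovery replicates, $10^4$ SNPs for null calibration, $10^5$ gametes
for the inheritance law, and a 1,000-SNP null panel — sizes chosen to
give stable statistics at interactive runtimes.

## Known limitations

* The log-normal null is an approximation; under strong genome-wide
  linkage or very sparse SNPs its tail can misestimate, which is why
  calibration is asserted only on the generative model.
* Interval bounds at the outermost significant SNP undercover the true
  QTL edge at low SNP density.
* The per-gene severity priority and the parent-presence read threshold
  are pragmatic defaults, both exposed as parameters.
* The association module tests presence/absence (or dosage classes); it
  does not model tetraploid allele dosage likelihoods.
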