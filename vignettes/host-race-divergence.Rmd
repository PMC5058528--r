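---
title: "Models and methods behind hostscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hostscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hostscan implements a complete analysis pipeline for detecting host
plant-associated genetic divergence in an insect sampled from two host
plants at several locations, using two complementary data types: a panel of
anonymous dominant (presence/absence) markers of the AFLP type, and one
nuclear sequence locus genotyped as diploid Sanger traces with IUPAC
ambiguity codes at heterozygous positions. This vignette explains the
statistical models behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical decisions made where the design was open.

## The dominant-marker model

Every dominant locus is treated as biallelic with a band-presence allele
(frequency $p$) and a silent absence allele ($q = 1 - p$), in
Hardy--Weinberg proportions within each population. Only the recessive
homozygote is observable as band absence, so all allele-frequency
information comes from the absence count $k \sim \mathrm{Binomial}(n, q^2)$.
`estimate_allele_freq()` offers three estimators:

* `sqrt` — $\hat q = \sqrt{k/n}$, the plain HWE inversion; unbiased for
  $q^2$, slightly biased for $q$, exact at the boundaries. Used by the test
  oracles because of its transparency.
* `lynch_milligan` — the Taylor bias correction
  $\hat q = \sqrt{x} \,/\, (1 - \mathrm{Var}(x) / 8x^2)$ with
  $x = k/n$; the correction is skipped when it would overshoot at very
  small $x$.
* `zhivotovsky` (default) — the Bayesian posterior mean of $q$ under a
  uniform prior on $q$, which has the closed form
  $B(k+1,\,n-k+1)\,/\,B(k+\tfrac12,\,n-k+1)$. It never returns exactly 0
  or 1, which stabilises the downstream variance components; the uniform
  prior is this package's fixed convention (the per-dataset empirical-beta
  prior used by some AFLP software is a dialect we deliberately do not
  reproduce, so that results are a deterministic function of the counts).

### FST and its permutation test

Per locus, with $r$ groups of sizes $n_i$ and estimated frequencies
$\hat q_i$, `fst_dominant()` forms method-of-moments components: the
among-group variance $s^2 = \sum_i (\hat q_i - \bar q)^2/(r-1)$ corrected
by the mean delta-method sampling variance
$v_i = (1-\hat q_i^2)/(4 n_i)$ of the frequency estimates, over a total
variance estimate $\bar q (1 - \bar q) + s^2/r$ whose expectation is the
ancestral $q_0(1-q_0)$. The global statistic is the ratio of summed
numerators to summed denominators across loci (the usual multilocus
ratio-of-sums), and significance comes from permuting individuals among
groups with group sizes preserved, $p = (1 + \#\{F^\ast \ge F\}) /
(1 + B)$. Permuting individuals rather than loci preserves linkage
structure across the panel. Negative per-locus estimates are retained: they
are legitimate sampling outcomes, and the trimmed mean used by the outlier
scan handles tails by construction.

A recovery check (also run by `scripts/acceptance.R`) simulates 250
neutral loci for 2 hosts x 90 individuals at a between-host divergence of
0.12 and requires the global estimate to land within 0.02 of the FST
realised by the recorded true frequencies. Recovery fixtures are generated
without genotyping error: a miscall rate $m$ attenuates dominant-marker
FST noticeably (by roughly 0.03--0.04 at $m = 0.055$), and in the
workflow this package mirrors, error-affected loci are removed by QC
before FST is estimated, so the attenuated regime is not the one the
estimators are asked to recover.

## Quality control

`estimate_error_rate()` is the fraction of discordant calls between
replicate genotypings of the same individuals; if each genotyping flips a
true call independently with probability $m$, replicate pairs disagree at
rate $2m(1-m)$, which the estimator recovers. `filter_markers()` applies
four rules in a fixed order — (1) drop any locus with a replicate
discordance, (2) drop loci at negative-control fragment sizes, (3)
collapse same-size loci from different primer pairs that are in
significant gametic disequilibrium (nonspecific primer binding), keeping
the lexicographically first locus of each linked cluster, and (4) drop
singleton loci — logging counts so that the initial panel size is always
reconstructable, and idempotently. Rule 3 tests only the candidate
same-size cross-primer pairs and applies an FDR threshold of 0.05 within
those candidates; rule 1 is strict (any discordance) because mismatches
concentrate on unstable loci, so the per-locus removal rate legitimately
exceeds the average call-level error rate. The Pearson correlation of band
frequency against fragment size (`size_frequency_correlation()`) is the
panel-level homoplasy warning: small and non-significant is the desired
outcome.

## Two-locus disequilibrium from dominant phenotypes

With two dominant loci only four phenotype classes are observable. Under
random union of gametes with haplotype frequencies
$(h_{AB}, h_{Ab}, h_{aB}, h_{ab})$,

$$P(\text{both absent}) = h_{ab}^2,\quad
P(\text{A absent}) = q_a^2 - h_{ab}^2,\quad
P(\text{B absent}) = q_b^2 - h_{ab}^2,$$

with $q_a = h_{aB} + h_{ab}$, $q_b = h_{Ab} + h_{ab}$, and the
double-presence class taking the remainder. `em_haplotype_freqs_dominant()`
maximises the multinomial likelihood by EM over the latent gamete pairs;
the E-step expectations have closed forms obtained by restricting the iid
gamete pair to each class's support. Because this likelihood can be flat or
multimodal at small $n$, the EM is multi-started (independence start plus
four corner-biased starts) and converges on an absolute log-likelihood
change below $10^{-10}$ (at most $10^4$ iterations). The disequilibrium
coefficient is $D = h_{AB} - p_A p_B$ at the MLE. The null fit ($D = 0$)
factorises into two marginal square-root estimates, and
$2(\ln L_1 - \ln L_0)$ is referred to $\chi^2_1$ — also when the MLE sits
on the simplex boundary, which keeps the test mildly approximate there;
its realised size at $\alpha = 0.05$ is checked on 1000 independent pairs.
Tests verify the EM against an exhaustive profiled grid search over
$(q_a, q_b, h_{ab})$ refined to a $10^{-5}$ mesh.

Multiple testing uses Benjamini--Hochberg by default; `pike_robust` is the
adaptive variant that first estimates the number of true nulls by the
lowest-slope rule and uses it in the step-up adjustment.

## The FDist-style outlier scan

The neutral envelope conditions locus FST on heterozygosity. Simulated
loci draw an ancestral frequency from $\mathrm{Uniform}(0.01, 0.99)$ and
per-deme frequencies from the Balding--Nichols beta
$\mathrm{Beta}\!\big(p_0(1-F)/F,\ (1-p_0)(1-F)/F\big)$, then sample
dominant phenotypes at the empirical group sizes and re-estimate
$(H_e, F_{ST})$ with exactly the estimators used on the data. The beta
model replaces a coalescent island simulation: it has the matching
stationary frequency distribution for the purpose of conditional
quantiles, with one-parameter control and closed-form expectations.

Because the per-locus estimates that enter the empirical trimmed mean are
biased at finite sample sizes, the simulation parameter is *calibrated*:
`calibrate_envelope_seed()` bisects on $F$ until the trimmed mean of the
simulated per-locus estimates matches the observed trimmed mean (trim
0.30 per tail by default, so outliers cannot inflate the null). The
envelope itself is built from 50,000 simulated loci by default, reduced to
equal-occupancy $H_e$ bins (adaptive count, at least 20 bins and 50 loci
per bin) carrying the 50/95/99% FST quantiles; loci are classified
against their bin, with a nearest-bin rule outside the covered range.
Per-comparison scans (the combined host contrast plus each location with
at least five individuals per host) feed a consensus rule: loci flagged at
the 95% level in two or more independent comparisons form the robust
set, and `outlier_report()` exposes the four nested counts (flagged
anywhere / in multiple comparisons / in the combined comparison / robust).
A reversible-jump Bayesian scan is intentionally out of scope; the
consensus rule approximates the "significant in more than one analysis"
criterion.

In the generator, planted outliers are drawn from the Balding--Nichols
model *conditioned on realised divergence near the configured value*
(rejection sampling with an intermediate ancestral frequency). This
matters: unconditional draws at $F = 0.49$ frequently fix both hosts for
the same allele, which is drift, not divergent selection — a planted
"outlier" with no realised divergence is undetectable by any scan and
meaningless for power assessment. Detection power for loci planted at
divergence 0.49 against a 0.057 background, 90 individuals per host,
exceeds 80%, while fully neutral panels are flagged at the nominal 5%.

## The sequence locus

`call_snps()` expands two-base IUPAC codes into allele pairs, excluding
columns with N or gaps, and flags columns with more than two alleles
(excluded from phasing). `em_phase()` estimates haplotype frequencies by
EM over the latent gametic phase and assigns each individual its maximum
a posteriori pair. Two numerical choices matter:

* enumeration is bounded at `max_het = 12` heterozygous sites (2048
  candidate pairs); individuals beyond it are left unphased;
* assignment confidence is computed under pseudocount-smoothed frequencies
  ($\alpha = 0.5$ copies added to every candidate haplotype). Raw EM
  frequencies assign exactly zero to every haplotype not used by the ML
  configuration, which would make single-individual resolutions look
  certain. Smoothing keeps genuinely ambiguous individuals below the
  default confidence threshold of 0.9, and they are dropped — the
  single-program analogue of consensus phasing across multiple programs
  with a vote threshold. On truth-known fixtures this yields roughly
  80--90% of individuals phased with at least 90% (typically 94--97%)
  of phases correct.

`haplotype_summary()` reports, per group of haplotype copies: the number
of phased samples, distinct haplotypes, polymorphic sites, singleton
haplotypes, haplotype diversity $H_d = \frac{n}{n-1}(1 - \sum p_i^2)$,
nucleotide diversity $\pi$ (mean pairwise difference per site over the
alignment length), and $R_m$, the four-gamete minimum number of
recombination events (incompatible intervals reduced to a maximal
disjoint set). Distances between haplotypes use the F84 substitution
model via `ape` with pairwise deletion (`f84_distance()`), and
`phi_st()` runs a two-group AMOVA on squared distances — for Hamming
input, the number of pairwise differences is itself the squared-distance
convention — with individuals permuted between groups keeping their two
copies together. `annotate_codon_effect()` translates both codon variants
of each SNP with the standard genetic code.

## Median-joining networks

`build_mj_network()` iterates: compute the minimum spanning network (the
union of all minimum spanning trees) over the current sequences; for
every pair of links sharing a node, propose the site-wise majority
(median) sequence of the triplet; add the proposals with minimal
connection cost (within `epsilon`, default 0); stop when nothing new is
proposed, then prune median nodes of degree below 2. Determinism comes
from fixed tie-breaks: at sites where all three triplet members differ
the hub's state is used, and candidate sets are ordered
lexicographically. Sites with gaps or N are excluded before networking.

On compatible (infinite-sites-like) data every MST edge between observed
haplotypes is realised as an exact geodesic in the network — this is
verified against an independent MST oracle on random perfect-phylogeny
instances. Under heavy homoplasy, paths longer than the pairwise Hamming
distance are genuine (repeated mutation), so only the weaker bounds
(connectivity, path weight at least the Hamming distance, median degree)
are guaranteed. `annotate_root()` marks the observed node(s) closest in
total distance to user-supplied outgroup sequences, keeping ties;
rooting is an annotation, never an added edge.

## Ordination and distance-based MANOVA

`jaccard_matrix()` uses the presence-only Jaccard distance, the
appropriate choice for dominant data because absence carries genotype
ambiguity. `nmds()` wraps monotone-regression NMDS (Kruskal stress-1,
reported as a fraction; best of 20 restarts, the first from classical
metric scaling). `fit_factor()` measures a categorical factor on the
score matrix as $R^2 = 1 - SS_{\text{within}}/SS_{\text{total}}$ with a
label-permutation p-value; it is invariant to the rotation/reflection
freedom of NMDS solutions. `adonis_partition()` delegates to vegan's
`adonis2` (sequential sums of squares via the Gower-centred matrix);
nesting such as host within location is expressed as `location/host`
with free permutation of individuals within location strata. Sequential
(not marginal) partitioning is this package's fixed convention. Tests pin
the pseudo-F to classical one-way ANOVA on univariate Euclidean toys and
to a brute-force projection oracle.

## The synthetic-data generator

`simulate_dominant_markers()` and `simulate_sequences()` produce the
study design the pipeline expects, with every latent quantity recorded:
true per-host allele frequencies and locus classes, true haplotype pairs,
and the miscall rate. Defaults mirror the emulated study: 265 dominant
loci of which 15 are planted outliers, background between-host divergence
0.057 and outlier divergence 0.49, a 5.5% miscall rate with six replicate
genotypings, a 910-bp locus with 22 segregating third-codon-position
sites, one nearly host-diagnostic SNP (derived-allele frequencies 0.8755
and 0.007 in the two hosts), and haplotype pools of 36 and 15 with one
dominant haplotype each (frequencies 0.42 and 0.70 plus a uniform rare
tail, putting per-host haplotype diversities near 0.79 and 0.49 while
keeping the full richness observable at around 270 sampled copies).
Locations are balanced by default; imbalance is left to configuration.
Sex-associated loci (divergence between sexes rather than hosts) are off
by default and switched on to emulate the sex axis of the ordination.

What the generator does **not** emulate: linkage between marker loci
(loci are independent given their frequencies), within-locus
recombination at the sequence locus (sites are placed independently, so
four-gamete counts run higher than in real data), mutation-rate calibration
in time units, selection dynamics (outliers are planted as elevated
divergence, not forward-simulated), plate effects, and electropherogram-
level artefacts beyond symmetric call flipping. Passing recovery tests
therefore demonstrate estimator and bookkeeping correctness under the
stated models, not robustness to every artefact of real fragment data.

## Problem sizes and reproducibility

All randomness flows from integer seeds through a deterministic
splitter, so every fixture, permutation test, envelope and report is
bit-reproducible from a single seed. The shipped test-suite and
acceptance-script runs use study-scale designs (2 x 90 individuals, 250
to 295 loci, 50,000-locus envelopes, 1000-permutation tests, 135
sequenced individuals per host) — sizes chosen to match the emulated
study while keeping any single check in the seconds-to-a-minute range.
Permutation defaults inside the pipeline are 5000 where the emulated
analyses used 5000; callers may lower them for exploratory runs.

## Known limitations

* The dominant-marker FST components use a delta-method sampling variance
  for all three frequency estimators; at very small group sizes (< ~8)
  the correction is rough and per-locus estimates are noisy — the
  multilocus ratio and the trimmed mean are the intended consumers.
* The $\chi^2_1$ reference for the LD likelihood ratio is approximate at
  simplex boundaries.
* EM phasing is frequency-based only; it uses no positional (recombination)
  model, which is consistent with the single-locus, low-recombination
  setting it targets.
* The median-joining implementation targets `epsilon = 0` semantics;
  larger epsilon values widen candidate retention but are not tuned to
  reproduce any particular published network topology.
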