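---
title: "Statistical methods for bypass-of-essentiality suppressor screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for bypass-of-essentiality suppressor screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boescan)
```

## The problem

An essential gene can sometimes be made dispensable by a second genetic
change — deleting, mutating or overexpressing another gene. Systematic
screens for such *bypass-of-essentiality* (BOE) suppressors in fission
yeast use "query strains" that lack the chromosomal copy of an essential
gene but survive on a counter-selectable rescuing plasmid; cells that lose
the plasmid survive only if a suppressor arose. Three kinds of mutagens
give three screen types, each with its own readout and its own calling
statistics:

* **T-BOE** — *piggyBac* transposon insertions, mapped by junction
  sequencing. The transposon integrates exclusively at TTAA
  tetranucleotides, so enrichment must be judged against the local density
  of *potential* target sites.
* **OP-BOE** — an integrated overexpression plasmid library, quantified by
  sequencing both ends of each ORF in selected and input pools.
* **C-BOE** — chemical point mutagenesis, with the causal mutation mapped
  by bulk segregant analysis (BSA): progeny of a backcross selected for
  suppression are pooled and sequenced, and the causal locus is revealed by
  depletion of the reference allele.

`boescan` implements the candidate-calling statistics for all three
screens, the downstream association statistics (gene features, protein
complexes, network-level functional relatedness), and a synthetic-data
generator that emulates the statistical structure of each screen so that
every caller can be exercised, calibrated and power-tested end to end.

## The synthetic screens

All simulators draw from one `sim_params()` object and a single seed;
identical parameters give byte-identical outputs.

**Genome.** Random chromosome sequences at a configurable GC content
(default 0.36, fission-yeast-like) carry non-overlapping protein-coding
gene models: ATG start, TAA stop, interior codons drawn with probabilities
proportional to their composition under the background base frequencies so
that coding sequence honours the genome-wide GC content (this matters: the
density of TTAA target sites inside ORFs must match the background, or
insertion enrichment statistics would be biased). A configurable fraction
of genes carries one intron with canonical GT..AG ends. Every TTAA
occurrence is enumerated as a potential transposon target site.

**Transposon screen.** `n_insertions` mapped insertions are drawn over the
TTAA sites, with sites inside planted suppressor ORFs upweighted by
`enrichment_fold` (default 50). Read counts per insertion are geometric
(mean 20) — the simplest heavy-tailed count model; the calling statistic
uses read counts only to break deduplication ties, so this choice is not
load-bearing. Defaults (2000 insertions on a ~500-kb genome, two samples)
describe one query screen.

**Overexpression screen.** Plasmid input abundances are log-normal
(sdlog 1). The pooled input control is a multinomial draw at 18 times the
per-screen depth — the control pools many independent input samples, and
its depth matters: the control is *shared* across replicate screens, so
per-plasmid control noise is a common offset that only averages out when
the control is much deeper than any single screen. Each of the three
replicate screens is a multinomial draw at depth 1e5 from abundances
multiplied by `selection_fold` (default 30) for planted suppressors, and
counts are split between N- and C-terminal reads by a fair binomial.

**Backcross pool.** Background SNPs are uniform over the genome. The
expected reference-allele fraction of a SNP at physical distance *b* from
the causal site is the Haldane recombinant fraction
$r = (1 - e^{-2d})/2$ with $d = b \cdot \rho$ Morgans — the standard
no-interference model for a single backcross meiosis; unlinked SNPs sit at
0.5 and the causal SNP at 0. The default rate $\rho = 4\times10^{-5}$
Morgan/bp compresses a ~2000-cM genome-scale map onto a genome of a few
hundred kb, keeping the *shape* of linkage decay comparable per base.
Observed reference reads are binomial at 50x depth. Configurable fractions
of background SNPs are drawn with sub-threshold quality scores (10%), with
0–1 alternate reads (5%), or as members of the compiled background list
(50%), so each filter rule is exercised.

**Annotation tables.** The generator also produces per-gene feature
tables, GO-slim and localization maps, a PPI set, a complex catalog and a
suppressor network with planted effects: a standardized feature shift in
bypassable genes, bypassability coherence within complexes
(`complex_assort`), and GO-assortative network edges (`go_odds`). Setting
every effect to its neutral value (shift 0, assortativity 0, odds 1) gives
a fully null dataset; the test suite uses this to verify that every
downstream caller is calibrated.

What the generator does *not* emulate: real sequence composition and codon
usage, chromatin-driven insertion biases, mutagen dose–response, mapping
artefacts, or correlated annotation structure (GO terms are independent
draws). Passing tests therefore demonstrate correctness of the statistics
under the stated models, not robustness to every bias of real screens.

## Calling statistics

### T-BOE: per-region G-tests against TTAA counts

Insertions closer than 3 bp within one sample are collapsed, keeping the
higher read count (greedy left-to-right sweep; ties keep the leftmost;
the kept record becomes the new anchor). Identical positions in different
samples are independent events and both survive. The genome is partitioned
into ORFs and intergenic regions that tile each chromosome exactly, and
each region is tested with a two-cell goodness-of-fit G-test of its
observed insertion count $O$ against the expectation
$E = N_{obs} T / N_{pot}$ from its TTAA share:

$$G = 2\left[O \ln\frac{O}{E} + (N_{obs}-O)\ln\frac{N_{obs}-O}{N_{obs}-E}\right],$$

with $0\ln 0 = 0$ and an upper-tail $\chi^2_1$ p-value. The table shape is
a design choice: a one-region-versus-rest comparison is the most direct
reading of "observed insertions versus potential insertion sites". The
degenerate case (a region holding *all* target sites but not all
insertions) is flagged rather than returned as an infinite statistic.
Manual candidate inspection is replaced by Benjamini–Hochberg control
across regions (`alpha = 0.05`) plus a minimum insertion count (2);
candidates must be ORFs with $O > E$. Samples of one query are pooled by
default (a `samples` argument restricts them).

### OP-BOE: consistency-gated BOE-scores

For each plasmid, per-screen, per-end depth-normalised log2 ratios with
pseudocounts,

$$\mathrm{N\_ratio} = \log_2\!\left(\frac{N_{ctl}+1}{N_{sel}+1}\cdot
\frac{\mathrm{tot}_{sel}}{\mathrm{tot}_{ctl}}\right),$$

are combined into a read-weighted average (WA ratio); the BOE-score is
$C \cdot \mu$ where $\mu$ is the mean WA ratio over screens, $\sigma$ the
sample (n−1) standard deviation, and the consistency score $C$ is 0 when
$|\mu/\sigma| < 1$ and $1 - 1/|\mu/\sigma|$ otherwise. Because the control
sits in the numerator, selection-enriched plasmids score *negative*, and
candidates are ranked by ascending score — a documented choice, as is the
per-screen computation of totals. Edge conventions: $\sigma = 0$ gives
$C = 1$ for nonzero $\mu$ (the limit) and 0 otherwise; zero reads at both
ends fall back to the unweighted mean of the two end ratios. A per-plasmid
"no abundance change" p-value is attached as a calibration diagnostic:
conditioning a plasmid's pooled selection reads on its pooled
selection-plus-control total makes the unknown input abundance cancel,
leaving a binomial with the depth share of the selection libraries as the
null proportion (a replicate-wise t-test is *not* valid here: the pooled
control is shared across screens, so its noise is a common offset that the
across-screen variance cannot see). This diagnostic is approximately
uniform under a null screen — the calibration suite checks exactly that —
and is not the selection statistic.

### C-BOE: variant filtering on toy gene models

Variant effects are classified minimally but strand-awarely: intergenic,
splice site (first or last 2 nt of an intron — the canonical GT/AG
positions), intronic, else the affected codon is translated (standard
code) to synonymous / missense / stop gain / stop loss. The candidate
filter applies, in order: quality ≥ 100 **and** ≥ 2 alternate-supporting
reads (the discard rule is read disjunctively — discarding on *either*
failure — since keeping single-read or low-quality variants would defeat
the filter; `literal_and = TRUE` restores the literal conjunction);
absence from the compiled background list; distance ≥ 500 kb from the
query gene, measured from the gene boundary on the same chromosome only;
a candidate effect class; and reference-allele fraction < 10%. Rejections
are tallied under the first failing rule.

## Downstream statistics

* **Fisher's exact test** conditions on both margins; the one-sided p is
  the upper tail of the first cell, the two-sided p uses the
  point-probability convention (all tables with point probability not
  exceeding the observed, with a 1e-7 relative tie tolerance). The
  reported odds ratio is the sample $ad/bc$. GO-slim enrichment runs one
  test per term (foreground versus the rest of the background) with BH
  q-values within the run.
* **Feature comparisons** use the two-sided Mann–Whitney U (exact for ≤ 20
  untied observations, else the tie- and continuity-corrected normal
  approximation). The ROC AUC for complex features is computed from the
  same statistic as $U/(n_1 n_2)$ — an exact identity, checked against a
  pairwise-count oracle. The rank-sum test is used for the two independent
  complex groups; a paired signed-rank test is undefined for unpaired
  groups.
* **Stratified retests** rerun any test inside a stratum (e.g. genes with
  slow spore lethality, a proxy for lower gene importance) and demand
  genes on both sides of the bypassability split.
* **Complex permutation test.** Complex membership is held fixed while the
  observed number of bypassable labels is redrawn uniformly over the
  queried genes of eligible complexes (≥ 2 queried subunits). The gene is
  the permutation unit — a shared subunit keeps one label everywhere.
  Expected counts are permutation means; p-values are one-sided with an
  add-one correction, in the direction of the observed deviation unless a
  fixed tail is requested. Because category counts are small integers, the
  add-one p is conservatively non-uniform under the null; a
  tie-randomized p (`randomized = TRUE`) is exactly uniform and is what
  the calibration suite checks.
* **Clustering and prediction.** Complex features are median-imputed,
  z-scored (both configurable — the choice is not dictated by any
  reference output) and clustered with average linkage on Euclidean
  distances. The predicted bypassable set is read from the lowest tree
  node containing all known bypassable complexes.
* **Pair enrichment.** Interacting pairs are the distinct
  (query, suppressor) edges; interactor-sharing pairs are suppressor pairs
  co-suppressing at least one query, deduplicated across queries so hub
  suppressors are not double-counted. Predicates: shared GO-slim term;
  co-localization, ignoring the two generic compartments (nucleus,
  cytosol) so that a pair sharing only those is *not* co-localized;
  physical interaction. Pairs with an unannotated gene are indeterminate
  and leave both numerator and denominator. Backgrounds are enumerated
  exhaustively up to 1e7 pairs (all screened-essential × non-essential
  combinations for interacting pairs; all non-essential pairs for sharing
  pairs) and sampled uniformly beyond that. Under the null, the positive
  count of a random pair set of the observed size is exactly
  hypergeometric, so the permutation p is computed by Monte Carlo
  hypergeometric draws (add-one corrected) with the exact tail reported
  alongside.

## Numerical and design notes

* Coordinates are 0-based half-open internally; GFF3 and VCF are converted
  at the I/O boundary (1-based closed). BED insertion tables carry the
  0-based TTAA start and `end = start + 4`.
* All tabular outputs begin with `#` comment headers recording the tool
  version and seed; the pipeline writes a JSON manifest of MD5 checksums
  and a resolved-config YAML, and identical configurations reproduce
  identical checksums.
* Tie-breaks: deduplication keeps the leftmost on equal reads; ranking
  breaks BOE-score ties by plasmid id; region tables sort by ascending p
  then descending insertion count.
* Degenerate inputs have documented conventions rather than errors where a
  limit exists (all-identical Mann–Whitney inputs give p = 1; zero-read
  WA ratios fall back to the unweighted mean; σ = 0 BOE-scores use the
  gate's limit), and errors where no sensible value exists (empty TTAA
  lists, zero sequencing depth, one-sided strata).

## Problem sizes used in the shipped studies

The test suite and `scripts/acceptance.R` exercise recovery at the
screens' stated conditions — T-BOE: 50-fold enrichment, 2000 insertions,
~500-kb genome; OP-BOE: 3 planted plasmids at 30-fold selection among 500
plasmids, depth 1e5, 3 screens; C-BOE: 50x depth, 200 background SNPs. The
C-BOE study runs on a single 2.4-Mb chromosome so that the stated
geometry — a causal suppressor ≥ 500 kb from the query gene on the same
chromosome — exists at all; on a compressed few-hundred-kb genome, 200
SNPs correspond to a many-fold higher mutation density than real
mutagenesis, and co-mutations tightly linked to the causal site then
produce spurious extra survivors. Calibration studies use 100–200
replicate seeds with reduced problem sizes (smaller genomes and
libraries), chosen to estimate the relevant rates with useful precision.

## Limitations

The effect classifier reproduces only the coarse effect classes on toy
single-intron gene models, not the full rule set of a production effect
predictor. The annotation generator plants marginal effects, not realistic
correlation structure, so multivariate analyses (clustering, AUC
screening) are validated for recovery of planted signatures rather than
for behaviour on real complex catalogs. Real screen artefacts — mapping
error, index hopping, chimeric junctions — are out of scope: the
simulators produce mapped-level events.
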