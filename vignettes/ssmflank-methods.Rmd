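---
title: "Detecting purifying selection on somatic synonymous mutations at splice-associated sequences"
author: "ssmflank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting purifying selection on somatic synonymous mutations at splice-associated sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Somatic synonymous mutations (SSMs) in tumours are conventionally treated as
selectively neutral, which makes their local density a popular proxy for the
background mutation rate. That assumption fails wherever synonymous sites
carry splicing information: the terminal ~20 bp of internal coding exons and
exonic splice enhancer (ESE) hexamers are dense in splice-regulatory signal,
and a synonymous change there can destroy an exon's recognition by the
spliceosome. If some of those changes are lethal to the tumour cell lineage,
the variant caller never observes them and SSM density is locally depleted.

`ssmflank` tests for that depletion with a within-exon contrast. Each
internal coding exon of length $L \ge 160$ bp is partitioned into two
*flanks* — 20 bp at each exon end — and a *core*, 40 bp centred on
$M = \lfloor L/2 \rfloor$. Flank and core then have identical footprints (40
bp per exon each), sit in the same gene, the same nucleosome and replication
environment, and the same tumour, so the comparison controls for most
regional mutation-rate covariates by construction. Density is expressed per
bp per tumour:

$$ \hat\lambda_r = \frac{\text{SSM count in region class } r}
                        {\text{effective bp}_r \times n_{\text{tumours}}} $$

and the headline quantity is the **depletion fraction**

$$ \hat\delta = 1 - \hat\lambda_{\text{flank}} / \hat\lambda_{\text{core}}, $$

read as the share of flank mutational events rendered unobservable by
purifying selection when the core rate is taken as the local background.

Two models can generate a flank deficit: selection (uniform mutation rate,
purging at flanks) and mutation bias (e.g. CpG-driven excess at the
GC-richer core). The package therefore re-estimates densities under CpG
masking, under substitution-class normalization, under trinucleotide-context
normalization, and within covariate strata; a deficit that survives all of
these is hard to attribute to composition alone.

## Interval geometry

Coordinates are 0-based half-open internally; 1-based inputs (MAF positions)
are converted at the I/O boundary, and BED output goes through
`rtracklayer`. For an exon `[start, end)`:

* left flank `[start + e, start + 20)`, right flank `[end - 20, end - e)`,
  where the end exclusion `e` is 0 by default and 3 in the splice-site-free
  variant (the terminal 3 nt of each exon end cover the exonic part of the
  canonical splice sites);
* core `[start + M - 20, start + M + 20)` with $M = \lfloor L/2 \rfloor$ —
  for odd-length exons the floor fixes the centring convention;
* `orient_flanks()` relabels the genomically left/right flanks as 5'/3'
  using the transcript strand; the operation recomputes labels from
  coordinates, so it is idempotent.

"Internal" means neither the first nor the last coding exon of its
transcript; the length threshold is inclusive ($\ge 160$ bp) and exposed as
`min_exon_length`. At these defaults flanks and core can never overlap; the
constructor verifies this per exon and refuses otherwise.

## ESE and control hexamer regions

ESE catalogues are hexamer lists; the package scans the coding-strand
sequence of each eligible exon for perfect 6-mer matches whose start lies
within 69 bp of either exon end (the zone known to concentrate
splice-associated sequence), merges overlapping same-set matches into
maximal regions, and maps them back to genome coordinates (reverse
complementing for minus-strand genes; a `watson_only` flag reproduces
plus-strand-restricted runs). Control ("non-ESE") hexamers are built by
`build_non_ese_set()`: all 4096 hexamers at Hamming distance $\ge 2$ (the
default, exposed as `non_ese_min_distance`) from every ESE. ESE regions that
overlap non-ESE regions are discarded symmetrically — both sides are dropped
— so no base is claimed by both classes and neither class absorbs ambiguous
sequence; an asymmetric mode (dropping only the ESE side) is available.

One structural property matters in practice: the full distance-filtered
complement of an 84-motif ESE set contains thousands of hexamers, so in the
sliding-window scan nearly every position of typical sequence matches *some*
control hexamer. Merged control regions then blanket the scan zone and the
symmetric overlap discard removes essentially every ESE region. The pipeline
therefore accepts an explicit control list, or draws a seeded size-matched
sample of the derived complement (`non_ese_sample = 84` in the validation
runs). A size-matched control also equalizes the two classes' sampling
properties, which is desirable independently of the degeneracy it avoids.

## Mutation records, classes and contexts

Input calls are MAF or any delimited table via a column map. Only
single-nucleotide substitutions with valid ACGT alleles are retained; indels
and multi-allelic records are dropped with a count. Synonymous status is
taken from the annotation (`Silent`) by default, or recomputed from the
transcript structure and the standard genetic code (`recompute` mode), which
is also how the simulator's output is audited.

Substitutions are collapsed with their reverse complements into six classes
(A>C, A>G, A>T, C>G, C>T, G>T), and class-normalized rates divide each
class's count by the number of eligible reference bases — occurrences of the
reference base *and its complement* in the region's sequence — times the
tumour count. Trinucleotide contexts add the 5' and 3' neighbour, giving 96
canonical classes; denominators count occurrences of each class's reference
trinucleotide on both strands (the trinucleotide plus its reverse
complement), with 1 bp of genome context beyond interval edges so terminal
bases keep their context. The six-class convention (A- and C-centred plus
G>T) is kept throughout so that the "number of X plus number of
complement(X)" denominators line up with the class labels.

CpG masking removes every position whose base participates in a CG
dinucleotide on the plus strand, again using genome context across interval
boundaries, because hypermutability follows the sequence context rather than
the interval; masked positions are subtracted from the effective bp and
mutations at masked positions from the counts.

## Synonymous-opportunity normalization

Raw per-bp densities are comparable between flank and core because both are
unconstrained sequence of equal footprint. They are *not* directly
comparable between ESE and control regions: motif-constrained sequence has a
different codon-position composition, hence a different density of
synonymous opportunities per bp. The package therefore also reports an
opportunity-normalized density. For each unmasked coding site $i$ the
opportunity is

$$ o_i = \sum_{a \ne \mathrm{ref}_i} \Pr(a \mid \mathrm{ref}_i)\,
         \mathbf{1}[\text{ref}_i \to a \text{ is synonymous}], $$

with the alternate-allele conditionals $\Pr(a \mid \mathrm{ref})$ estimated
from *all* observed records (purging removes mutations irrespective of the
alternate allele, so these conditionals are undistorted by selection).
Dividing a region class's SSM count by $\sum_i o_i \times n_{\text{tumours}}$
gives a rate whose ratio between classes is free of composition effects, and
`depletion_adjusted` is the depletion fraction on that scale. For flank vs
core the raw and adjusted estimates essentially coincide; for ESE vs non-ESE
the adjusted estimate is the one that recovers planted selection
coefficients without composition bias.

## The statistical battery

Cohorts are processed independently and then combined:

* **Per cohort**: a per-tumour table (explicit zeros for tumours without
  SSMs in a class, so pairing never drops tumours), the two-sided Wilcoxon
  signed-rank test on per-tumour flank vs core rates, percentile bootstrap
  CIs of the mean per-tumour rate (B = 500 resamples, 95%, explicit seed; the
  caller's RNG state is untouched), pooled rates and the depletion fraction.
  Zero differences are discarded before ranking (the classic policy, matching
  the default of the usual R toolchain; a Pratt option keeps them). The exact
  signed-rank distribution is used for $n \le 25$ untied differences;
  otherwise the normal approximation with tie and continuity correction.
* **Across cohorts**: Fisher's method on the per-cohort Wilcoxon p-values
  ($\chi^2 = -2\sum\ln p_i$, $2k$ df); Cohen's d between the $k$ cohort-level
  mean flank rates and the $k$ mean core rates, with the normal-theory
  variance $\mathrm{Var}(d) = (n_a+n_b)/(n_a n_b) + d^2/(2(n_a+n_b))$ — at
  k cohorts of each the interval is intentionally wide; and a one-sided exact
  binomial sign test on how many cohorts show a lower 5' than 3' flank rate
  (per-tumour within the cohort when only one cohort is supplied).

Inputs at the boundaries are contract-checked: p-values of exactly 0 are
rejected by `fishers_combined()` (callers should clamp at the machine
minimum), degenerate quantile strata and zero pooled standard deviations are
errors rather than silent NaNs, and all-zero difference vectors return p = 1.

## The synthetic cohort simulator

The simulator exists so that every stage is testable by parameter recovery
without consortium data. It emulates:

* multi-exon coding genes (default 750 genes x 6 exons of 180-240 bp,
  introns 120 bp, GC 0.5, both strands; coding length forced to a multiple
  of 3) — 4 internal exons per gene, so the default run analyses 3,000
  internal exons, comfortably above the >= 500 the validation conditions
  require;
* ESE planting: hexamers from a supplied list written into the coding strand
  within 69 bp of internal-exon ends at a Poisson rate (default 1.5 per
  zone);
* per-tumour mutations: each coding site mutates independently with
  probability `mu` (default 0.006 — far above somatic reality, chosen so a
  200-tumour desk-scale cohort yields tens of thousands of core SSMs and
  recovery is judged against estimator noise of well under one percentage
  point rather than simulation noise), times `cpg_multiplier` (default 10)
  at CpG sites, at most one mutation per site per tumour; alternate alleles
  follow a six-class signature (default C>T-heavy);
* selection as independent thinning: a mutation arising in a flank is
  removed with probability `purge_flank`, in an ESE region with `purge_ese`,
  the larger applying where both; per-gene-class overrides (e.g. tumour
  suppressors exempt) take a gene-class table. Thinning is exactly the
  quantity the depletion fraction estimates, which is what makes recovery a
  sharp test;
* null covariate fixtures (uniform per-exon scores, gene and sample labels
  at configurable fractions) matching the stratification inputs.

All randomness flows from one seed through derived per-stage seeds: the same
parameters give byte-identical FASTA, transcripts, MAF and truth tables. The
truth table records arisen, purged and retained counts per region class, so
`retained = arisen - purged` is assertable, and the realized depletion
(purged/arisen) is available next to the pipeline's estimate.

What the simulator deliberately does **not** emulate: human exome
composition and codon usage, clonal evolution, sequencing error,
exome-capture coverage bias, and inter-tumour mutation-rate heterogeneity
beyond Poisson noise. Passing recovery therefore shows the estimators and
their normalizations are correct under the stated generative model — not
that real cohorts are free of unmodelled mutation biases, which is exactly
the caveat that applies to the original analysis design as well.

## Validation conditions and problem sizes

The acceptance suite (and `scripts/acceptance.R`) uses:

* flank recovery: defaults above, `purge_flank` in {0, 0.1, 0.2, 0.3},
  200 tumours, CpG masking on; the estimate must land within +/- 0.03 of the
  planted value, with >= 2,000 retained core SSMs (the runs yield > 30,000);
* ESE recovery: 500 genes, `purge_ese = 0.25`, an 84-motif synthetic ESE
  fixture (a seeded uniform sample of the 4096 hexamers — it stands in for an
  intersection-based catalogue and is labelled synthetic) against an
  84-motif seeded control sample; the opportunity-adjusted estimate must land
  within +/- 0.04;
* type-I calibration: 100 independent null cohorts (40 genes, 40 tumours,
  `mu = 0.004`, no purging, fresh genome per replicate so composition noise
  averages out); the per-cohort Wilcoxon test must reject at 0.05 in 1-12%
  of replicates (the exact binomial 95% band around the nominal 5%);
* oracle equivalences: interval construction against brute-force membership
  over 1,000 random exon lengths; control-set construction against
  exhaustive filtering; exact Wilcoxon and rank-sum p-values against full
  enumeration at n <= 10; Fisher's method against the closed-form chi-square;
  class and trinucleotide denominators against sliding-window tallies;
* normalization nulls: with CpG hypermutability and no selection, masked
  flank/core rates agree within sampling error; with a strongly skewed
  signature and no selection, opportunity-adjusted and class-normalized
  ESE/non-ESE rates agree within sampling error;
* conservation: pooled counts equal per-tumour sums, class sums and
  trinucleotide sums on every run.

These sizes keep the whole suite within a few minutes on one CPU while
leaving the recovery tolerances several standard errors wide.

## Known limitations

* The depletion fraction is a ratio estimator; at very low counts it is
  biased and its sampling error is asymmetric. The validation scales avoid
  that regime, and real cohorts with few SSMs should be pooled before
  estimation.
* Gene-level annotation uses one transcript per gene; mutations falling in
  overlapping transcripts of other genes are annotated against the supplied
  model only.
* The 5'-vs-3' flank contrast is reported but the simulator purges both
  flanks equally, so that asymmetry is exercised only by the exact binomial
  arithmetic, not by recovery.
* Per-base score summaries (`region_mean_score`) expect scores as a long
  TSV; converting bigWig tracks to that form is the caller's responsibility.
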