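# ssmflank

Detects purifying selection on **somatic synonymous mutations (SSMs)** at
splice-associated exonic sequence in tumour cohorts. Synonymous variant
density is widely used as a neutral background rate in cancer genomics; near
exon ends and inside exonic splice enhancer (ESE) hexamers, synonymous
changes can disrupt splicing and be selected against, so variant callers see
fewer of them. `ssmflank` quantifies that deficit and runs the control
battery needed to distinguish selection from mutational composition.

For each internal coding exon of length `L >= 160` bp the package builds a
20-bp **flank** at each end and a 40-bp **core** centred on
`M = floor(L/2)`, giving equal footprints inside the same exon. SSM density
is `count / (effective bp x n_tumours)` and the headline estimate is the
**depletion fraction**

```
depletion = 1 - flank_rate / core_rate
```

the share of flank mutational events rendered unobservable by selection if
the core rate is the local background. The same contrast runs for ESE vs
control hexamer regions (perfect-match scanning within 69 bp of exon ends,
controls at Hamming distance >= 2 from every ESE), under CpG masking,
substitution-class (6 classes) and trinucleotide-context (96 classes)
normalization, a synonymous-opportunity normalization for motif-constrained
regions, and within covariate strata (nucleosome occupancy, replication
timing, cancer gene class, essentiality, alternative/constitutive exons,
MSI status). Statistics follow the paired design: per-cohort Wilcoxon signed
rank on per-tumour rates, Fisher's combined p across cohorts, bootstrap CIs
(B = 500), Cohen's d over cohort means, and an exact binomial sign test for
the 5'-vs-3' flank contrast.

Because the consortium call sets behind such analyses cannot ship with a
package, `ssmflank` includes a seeded synthetic cohort simulator with known
region-dependent selection (independent thinning of arisen mutations), so
the entire pipeline is validated by **parameter recovery**: plant a purge
probability, run the analysis, get it back.

## Worked example

Simulate a 100-tumour cohort over 200 five-exon genes with a planted flank
purge probability of 0.20, then ask the pipeline to recover it:

```r
library(ssmflank)

p   <- sim_params(n_genes = 200, exons_per_gene = 5, n_tumours = 100,
                  mu = 0.006, purge_flank = 0.2, seed = 1)
gen <- generate_genome_and_transcripts(p)
regions <- orient_flanks(make_flank_core_regions(
  select_internal_coding_exons(gen$transcripts)))
sim <- simulate_cohort(gen$genome, gen$transcripts, regions, p)

cfg <- run_config(genome = gen$genome, transcripts = gen$transcripts,
                  mutations = sim$mutations, cpg_mask = TRUE, seed = 1)
res <- run_flank_core(cfg)
res$per_cohort
#>    cohort n_tumours count_a count_b pooled_rate_a pooled_rate_b wilcoxon_p depletion
#> 1 cohort1       100    2776    3363      0.001323      0.001597   9.26e-09    0.1718
```

Reading the row: 100 tumours contributed 2,776 flank and 3,363 core SSMs
after CpG masking; the flank rate (1.32e-3 per bp per tumour) sits below the
core rate (1.60e-3), the paired Wilcoxon test is decisive (p = 9.3e-9), and
the estimated depletion is 0.172 — the planted 0.20 within the sampling
error of a few thousand counts (the simulator's truth table records a
realized flank depletion of 0.202 for this seed). At the validation scale
(3,000 internal exons, 200 tumours) the estimate lands within ±0.03 of the
planted value; see the methods vignette.

`run_ese(cfg)` runs the ESE vs control-hexamer contrast plus the class and
trinucleotide tables, `run_strata(cfg)` the covariate strata, and
`report_results(res, dir, cfg)` writes tidy TSVs and a run log. A thin CLI
(`inst/scripts/ssmflank-cli.R`) exposes `simulate`, `intervals`, `ese-scan`,
`flank-core`, `ese`, `strata` and `all` over a YAML config.

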