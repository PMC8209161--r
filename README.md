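# methscreen

Targeted bisulfite amplicon panels for methylation-based liquid biopsy.

Tumours carry dense, tumour-specific DNA hypermethylation that survives in
the circulating cell-free DNA (cfDNA) of patients. `methscreen` implements
the computational arm of an assay that detects this signal: short PCR
amplicons (<150 bp, matched to the fragment length of cfDNA) are placed on
regions hypermethylated in tumours but unmethylated in normal tissues and
blood, amplified from bisulfite-converted DNA with methylation-biased
primers, and sequenced deeply. Because tumour methylation in these regions
is essentially all-or-none, the informative statistic per amplicon
("probe") is the **fully-methylated-read fraction**

> f = (reads methylated at *every* CpG between the primers) / (reads
> passing the quality filter),

and the per-sample summary is the **Methylation Index (MI)** — the number
of probes with f ≥ 0.1 among probes with ≥ 100 passing reads. A sample is
called positive when MI exceeds 2.5 (i.e. MI ≥ 3). The package covers:

- **Panel discovery** — selection of candidate CpGs from 450k-style beta
  matrices (β − 0.5 > −0.1 in ≥ 50% of tumours; each normal-tissue mean
  β − 0.5 < −0.3), chaining of selected CpGs within 300 bp into candidate
  regions, blood-methylation exclusion masks, and primer-constraint
  checking (product 75–150 bp, primer 21–31 bp, Tm 64–72 °C, ≥ 2
  inter-primer CpGs).
- **Bisulfite references** — in-silico conversion and per-probe converted
  reference construction with scored CpG offsets.
- **Read processing** — >100 bp length filter, forward-primer
  demultiplexing (≤ 2 mismatches, ties unassigned), bisulfite-aware
  global alignment with free end gaps (read T over reference C is the
  unmethylated state, not an error), the 90% identity filter, and
  per-read CpG state calls.
- **Scoring** — probe positivity, MI, sample classification, control-based
  probe QC (drop probes positive in ≥ 3 controls), rank-based AUC and
  sensitivity at 100% specificity.
- **CHIP variant filtering** — the clonal-hematopoiesis inclusion rules
  (exonic, non-synonymous, p < 0.01, coverage > 50, VAF 0.02–0.43,
  no common-SNP/MAF > 0.02 hits).
- **A seeded simulator** — synthetic genomes/panels, beta matrices with
  planted DMRs, and amplicon read cohorts with tunable tumour fraction,
  conversion failure, sequencing error and amplification bias, each with a
  ground-truth table.

## Worked example

```r
library(methscreen)

# a 10-probe synthetic panel and a serum-like sample at 30% tumour fraction
cfg <- sim_config(seed = 2, n_probes = 10, amplicon_len = c(105, 150),
                  depth_per_probe = 500, tumour_fraction = 0.3)
gp  <- simulate_genome_and_panel(cfg)
sim <- simulate_reads(gp$panel, cfg, sample_id = "S1")
report <- process_sample(sim$reads, gp$panel, sample_id = "S1")
report
#> SampleReport S1: MI = 6 -> POSITIVE (10/10 probes evaluable)

head(report$probe_results, 3)
#>   probe_id pass_reads fully_methylated_reads  fraction evaluable positive
#> 1 probe_01        420                    130 0.3095238      TRUE     TRUE
#> 2 probe_02        432                      0 0.0000000      TRUE    FALSE
#> 3 probe_03        490                    140 0.2857143      TRUE     TRUE
```

Six of ten probes carry a fully-methylated-read fraction at or above 0.1
(the tumour compartment of this simulated sample is methylated at six
probes), so MI = 6 > 2.5 and the sample is called positive; probes like
`probe_02` belong to the unmethylated compartment and stay at f ≈ 0.

Discovery works the same way from a beta matrix:

```r
simb <- simulate_beta_matrix(seed = 5)
candidates <- discover_regions(simb$beta)   # chained >=2-CpG regions
```

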