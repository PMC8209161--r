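# Deterministic toy probe: 24-bp C-free primer footprints around a 28-bp
# interior with exactly 5 CpGs (amplicon 76 bp). Because the footprints are
# C-free, the forward primer equals its genomic footprint after conversion.
toy_fwd_g <- "GATTAGGTTGAAGTTAGGATTTGA"
toy_interior <- "TTCGATTCGGTATCGTTACGTTTACGTT"
toy_rev_g <- "AGGTTGATTAGGTTGAAGTTAGGA"

make_toy_probe <- function(probe_id = "toy", is_brca1 = FALSE) {
  amp <- paste0(toy_fwd_g, toy_interior, toy_rev_g)
  fwd <- bisulfite_convert(toy_fwd_g, methylated = TRUE)
  conv <- bisulfite_convert(amp, methylated = TRUE)
  rev <- methscreen:::revcomp(substr(conv, nchar(amp) - 23, nchar(amp)))
  build_probe(amp, fwd, rev, probe_id = probe_id, is_brca1 = is_brca1)
}

# Small simulated panel whose amplicons all exceed the 100-bp read-retention
# cutoff (the real assay's universal primer tails keep read lengths above it;
# the simulator emits bare amplicons).
make_test_panel <- function(seed = 11, n_probes = 8, ...) {
  cfg <- sim_config(seed = seed, n_probes = n_probes,
                    amplicon_len = c(105, 150), ...)
  list(config = cfg, sim = simulate_genome_and_panel(cfg))
}

# A CHIP-style variant record; defaults mirror a passing TET2 nonsense call.
chip_record <- function(gene = "TET2", exonic = TRUE, nonsynonymous = TRUE,
                        p_value = 0.001, coverage = 500, vaf = 0.0427,
                        common_snp = FALSE, maf_global = 0.001,
                        maf_population = NA_real_) {
  data.frame(chrom = "chr4", pos = 106157698L, ref = "G", alt = "T",
             gene = gene, exonic = exonic, nonsynonymous = nonsynonymous,
             p_value = p_value, coverage = coverage, vaf = vaf,
             common_snp = common_snp, maf_global = maf_global,
             maf_population = maf_population, stringsAsFactors = FALSE)
}
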