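make_beta <- function(values, groups, pos = seq_len(nrow(values)) * 1000L,
                      chrom = rep("chr1", nrow(values))) {
  rownames(values) <- sprintf("cg%03d", seq_len(nrow(values)))
  beta_matrix(values, chrom, pos, groups)
}

test_that("selection applies both criteria on the centered scale", {
  groups <- c(rep("tumour", 4), "normal-breast", "normal-lung",
              "normal-colon", "normal-prostate")
  # CpG 1: all tumours high (beta 0.95 -> centered 0.45), normals 0.10
  # CpG 2: only 1/4 tumours high -> frequency criterion fails
  # CpG 3: tumours high but one normal tissue mean too high
  v <- rbind(c(0.95, 0.95, 0.95, 0.95, 0.10, 0.10, 0.10, 0.10),
             c(0.95, 0.05, 0.05, 0.05, 0.10, 0.10, 0.10, 0.10),
             c(0.95, 0.95, 0.95, 0.95, 0.45, 0.10, 0.10, 0.10))
  sel <- select_dmr_cpgs(make_beta(v, groups))
  expect_identical(sel, "cg001")
})

test_that("missing betas are excluded pairwise from the tumour fraction", {
  groups <- c(rep("tumour", 4), "normal-breast")
  # 2 of 2 observed tumours exceed the threshold -> fraction 1
  v <- rbind(c(0.95, 0.95, NA, NA, 0.05))
  sel <- select_dmr_cpgs(make_beta(v, groups))
  expect_identical(sel, "cg001")
})

test_that("degenerate groups and out-of-range thresholds error", {
  v <- rbind(c(0.9, 0.1))
  expect_error(select_dmr_cpgs(make_beta(v, c("tumour", "tumour"))),
               "normal")
  expect_error(select_dmr_cpgs(make_beta(v, c("normal-breast", "normal-lung")),
                               tumour_group = "tumour"), "tumour")
  b <- make_beta(v, c("tumour", "normal-breast"))
  expect_error(select_dmr_cpgs(b, tumour_threshold = 0.7), "centered-beta")
  expect_error(select_dmr_cpgs(b, normal_threshold = -0.9), "centered-beta")
})

test_that("planted DMR CpGs are recovered exactly (oracle scan)", {
  sim <- simulate_beta_matrix(n_tumour = 12, n_normal_per_tissue = 4,
                              n_cpgs = 1000, noise_sd = 0.02, seed = 5)
  sel <- select_dmr_cpgs(sim$beta)
  expect_setequal(sel, sim$truth$planted_ids)
  expect_identical(sort(sel), sort(oracle_dmr_scan(sim$beta)))
})

test_that("selection is monotone in its thresholds", {
  sim <- simulate_beta_matrix(n_tumour = 10, n_normal_per_tissue = 4,
                              n_cpgs = 300, noise_sd = 0.1, seed = 8)
  base <- select_dmr_cpgs(sim$beta)
  # stricter tumour criterion or frequency never adds CpGs
  expect_true(all(select_dmr_cpgs(sim$beta, tumour_threshold = 0.1) %in% base))
  expect_true(all(select_dmr_cpgs(sim$beta, min_tumour_fraction = 0.8) %in% base))
  # relaxing the normal bound never removes CpGs
  expect_true(all(base %in% select_dmr_cpgs(sim$beta, normal_threshold = -0.2)))
  # idempotence / sample-order independence within groups
  perm <- sample(ncol(sim$beta$values))
  b2 <- beta_matrix(sim$beta$values[, perm], sim$beta$chrom, sim$beta$pos,
                    sim$beta$groups[perm], cpg_ids = sim$beta$cpg_ids)
  expect_identical(select_dmr_cpgs(b2), base)
})

test_that("CpG pairing chains runs at the gap cutoff and drops singletons", {
  sel <- data.frame(cpg_id = c("a", "b", "c"), chrom = "chr4",
                    pos = c(100L, 250L, 900L))
  cand <- pair_cpgs_to_regions(sel, max_gap = 300)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 100)
  expect_equal(cand$end, 251)          # half-open over member cytosines
  expect_equal(cand$member_cpgs, "a,b")
  # isolated CpG pairs with nothing
  expect_equal(nrow(pair_cpgs_to_regions(sel[3, ])), 0)
  # chromosome change breaks a run even at small gaps
  sel2 <- data.frame(cpg_id = c("a", "b"), chrom = c("chr1", "chr2"),
                     pos = c(100L, 150L))
  expect_equal(nrow(pair_cpgs_to_regions(sel2)), 0)
  # unsorted input is refused, not silently re-sorted
  expect_error(pair_cpgs_to_regions(sel[c(2, 1, 3), ]), "sorted")
})

test_that("pairing equals single-linkage clustering at 300 bp (oracle)", {
  sim <- simulate_beta_matrix(n_tumour = 12, n_normal_per_tissue = 4,
                              n_cpgs = 500, noise_sd = 0.02, seed = 13)
  tab <- dmr_cpg_table(sim$beta)
  sel <- tab[tab$selected, c("cpg_id", "chrom", "pos", "tumour_fraction")]
  cand <- pair_cpgs_to_regions(sel, max_gap = 300)
  oracle <- oracle_single_linkage(sel$chrom, sel$pos, 300)
  expect_equal(nrow(cand), length(oracle))
  expect_equal(nrow(cand), nrow(sim$truth$regions))
  for (i in seq_along(oracle))
    expect_equal(cand$member_cpgs[i],
                 paste(sel$cpg_id[oracle[[i]]], collapse = ","))
})

test_that("exclusion mask removes overlapping candidates only", {
  cand <- data.frame(region_id = "r1", chrom = "chr4", start = 100L,
                     end = 300L, n_cpgs = 2L, member_cpgs = "a,b",
                     tumour_frequency = 1)
  # >= 1 bp overlap removes
  expect_equal(nrow(apply_exclusion_mask(
    cand, data.frame(chrom = "chr4", start = 250L, end = 400L))), 0)
  # half-open abutment is not an overlap
  expect_equal(nrow(apply_exclusion_mask(
    cand, data.frame(chrom = "chr4", start = 300L, end = 400L))), 1)
  # unmatched mask chromosomes warn
  expect_warning(apply_exclusion_mask(
    cand, data.frame(chrom = "chr7", start = 0L, end = 10L)), "chr7")
})

test_that("masking a subset of discovered candidates leaves the rest", {
  sim <- simulate_beta_matrix(seed = 21, noise_sd = 0.02)
  cand <- discover_regions(sim$beta)
  expect_equal(nrow(cand), nrow(sim$truth$regions))
  mask <- sim$truth$regions[1:2, c("chrom", "start", "end")]
  kept <- apply_exclusion_mask(cand, mask)
  expect_equal(nrow(kept), nrow(cand) - 2)
  # oracle: overlap scan
  overlaps <- vapply(seq_len(nrow(cand)), function(i)
    any(cand$chrom[i] == mask$chrom &
          cand$start[i] < mask$end & mask$start < cand$end[i]), logical(1))
  expect_setequal(kept$region_id, cand$region_id[!overlaps])
})

test_that("primer pair validation reports each constraint", {
  # search (deterministically) for a converted-strand primer pair with
  # in-range melting temperatures around a CpG-bearing interior
  set.seed(3)
  make_primer <- function() {
    repeat {
      p <- paste(sample(c("A", "G", "T", "G"), 28, replace = TRUE),
                 collapse = "")
      tm <- melting_temperature(p)
      if (tm >= 66 && tm <= 70) return(p)
    }
  }
  fwd <- make_primer()
  rev_site <- make_primer()   # genomic footprint, C-free
  interior <- "TTCGATTCGGTATCGTTACGTTTACGTTTTATTTGGTTTTTTTTGGGTTTATTTTATTGATTAG"
  amp <- paste0(fwd, interior, rev_site)   # 28 + 64 + 28 = 120 bp, 5 CpGs
  rev <- methscreen:::revcomp(rev_site)
  rep <- validate_primer_pair(fwd, rev, amp)
  expect_true(rep$pass)
  expect_equal(rep$product_length, 120)
  expect_equal(rep$inter_primer_cpgs, 5)
  expect_false(rep$three_prime_cpg_flag)

  # an oversized product fails the length constraint only
  amp_long <- paste0(fwd, interior, strrep("T", 40), rev_site)
  rep2 <- validate_primer_pair(fwd, rev, amp_long)
  chk <- rep2$checks
  expect_false(chk$pass[chk$constraint == "product_length"])
  expect_true(all(chk$pass[chk$constraint != "product_length"]))

  # a weak (low-Tm) primer fails its Tm bound
  weak <- strrep("AT", 11)   # 22-mer, Tm far below 64
  amp3 <- paste0(weak, interior, rev_site)
  rep3 <- validate_primer_pair(weak, rev, amp3)
  expect_lt(rep3$fwd_tm, 64)
  expect_false(rep3$checks$pass[rep3$checks$constraint == "fwd_tm"])

  # a primer absent from the amplicon errors by name
  expect_error(validate_primer_pair("GGGGGGGGGGGGGGGGGGGGGG", rev, amp),
               "forward primer")
})
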