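test_that("length filter retains strictly longer reads only", {
  reads <- data.frame(read_id = c("a", "b", "c"),
                      seq = strrep("A", c(99, 100, 101)))
  kept <- length_filter(reads, min_len = 100)
  expect_identical(kept$read_id, "c")
  expect_equal(attr(kept, "n_retained"), 1)
  expect_equal(attr(kept, "n_removed"), 2)
  empty <- length_filter(reads[0, ], 100)
  expect_equal(nrow(empty), 0)
})

test_that("length filter counts agree with an independent recount", {
  got <- make_test_panel(seed = 31, n_probes = 4,
                         depth_per_probe = 250, short_read_fraction = 0.1)
  sim <- simulate_reads(got$sim$panel, got$config)
  kept <- length_filter(sim$reads, 100)
  expect_equal(attr(kept, "n_retained"), sum(nchar(sim$reads$seq) > 100))
  expect_equal(nrow(kept) + attr(kept, "n_removed"), nrow(sim$reads))
  # truncated reads (80 bp) are exactly the removed ones here
  expect_equal(attr(kept, "n_removed"), sum(sim$truth$truncated))
})

test_that("demultiplexing assigns by primer prefix and resolves orientation", {
  panel <- panel_definition(list(make_toy_probe("p1")))
  probe <- panel$probes$p1
  perfect <- probe$ref_methylated
  rc <- methscreen:::revcomp(perfect)
  two_subs <- paste0("TT", substr(perfect, 3, nchar(perfect)))
  dm <- demultiplex(data.frame(read_id = c("fwd", "rev", "mm2"),
                               seq = c(perfect, rc, two_subs)), panel)
  expect_equal(dm$assigned_probe_id, c("p1", "p1", "p1"))
  expect_equal(dm$orientation, c("as-is", "revcomp", "as-is"))
  # primer is trimmed and the read reported in reference orientation
  expect_equal(dm$seq[2], substr(perfect, probe$fwd_len + 1, nchar(perfect)))
  # three mismatches exceed the default tolerance
  three <- paste0("CCC", substr(perfect, 4, nchar(perfect)))
  dm3 <- demultiplex(data.frame(read_id = "x", seq = three), panel)
  expect_true(is.na(dm3$assigned_probe_id))
  expect_equal(attr(dm3, "counts")[["unassigned"]], 1)
})

test_that("demultiplexing leaves ties unassigned", {
  # two probes sharing a primer: any read matching one matches the other
  p1 <- make_toy_probe("p1")
  p2 <- make_toy_probe("p2")
  panel <- panel_definition(list(p1, p2))
  dm <- demultiplex(data.frame(read_id = "r", seq = p1$ref_methylated), panel)
  expect_true(is.na(dm$assigned_probe_id))
})

test_that("demultiplexing on a noisy simulated cohort is near-perfect", {
  got <- make_test_panel(seed = 47, n_probes = 10, depth_per_probe = 1000,
                         seq_error = 0.005, short_read_fraction = 0)
  sim <- simulate_reads(got$sim$panel, got$config)
  dm <- demultiplex(sim$reads, got$sim$panel)
  truth <- sim$truth$probe_id[match(dm$read_id, sim$truth$read_id)]
  acc <- mean(!is.na(dm$assigned_probe_id) & dm$assigned_probe_id == truth)
  expect_gte(acc, 0.99)
})

test_that("alignment calling distinguishes methylation state from error", {
  probe <- make_toy_probe()
  meth <- probe$ref_methylated
  unmeth_interior <- probe$ref_unmethylated
  # simulate primer-overwritten footprints on an unmethylated template
  L <- nchar(meth)
  unmeth_read <- paste0(substr(meth, 1, probe$fwd_len),
                        substr(unmeth_interior, probe$fwd_len + 1, L - probe$rev_len),
                        substr(meth, L - probe$rev_len + 1, L))
  trim <- function(s) substr(s, probe$fwd_len + 1, nchar(s))
  calls <- align_and_call(
    data.frame(read_id = c("m", "u"), seq = c(trim(meth), trim(unmeth_read))),
    probe)
  expect_equal(calls$identity, c(1, 1))       # CpG T counts as a match
  expect_equal(calls$cpg_states, c("MMMMM", "UUUUU"))
  expect_equal(calls$passes_filter, c(TRUE, TRUE))
  expect_equal(calls$fully_methylated, c(TRUE, FALSE))
})

test_that("heavily mutated and truncated reads fail with the right reason", {
  probe <- make_toy_probe()
  trim <- function(s) substr(s, probe$fwd_len + 1, nchar(s))
  set.seed(1)
  noisy <- mutate_seq(trim(probe$ref_methylated), n_sub = 12)  # ~23% of 52 bp
  short <- substr(trim(probe$ref_methylated), 1, 20)           # < half amplicon
  calls <- align_and_call(data.frame(read_id = c("noisy", "short"),
                                     seq = c(noisy, short)), probe)
  expect_false(any(calls$passes_filter))
  expect_lt(calls$identity[1], 0.90)
  expect_equal(calls$fail_reason[2], "short_alignment")
  # a non-C/T base over a CpG makes the read unscorable, not miscalled
  ch <- strsplit(trim(probe$ref_methylated), "", fixed = TRUE)[[1]]
  at <- probe$cpg_offsets[3] - probe$fwd_len + 1
  ch[at] <- "A"
  acall <- align_and_call(data.frame(read_id = "a",
                                     seq = paste(ch, collapse = "")), probe)
  expect_match(acall$cpg_states, "\\?")
  expect_equal(acall$fail_reason, "cpg_not_identifiable")
})

test_that("alignment scores match the brute-force DP oracle", {
  probe <- make_toy_probe()
  set.seed(7)
  for (k in 1:40) {
    read <- mutate_seq(probe$ref_methylated, n_sub = sample(0:5, 1),
                       n_indel = sample(0:2, 1))
    calls <- align_and_call(data.frame(read_id = "r", seq = read), probe)
    expect_equal(calls$score, oracle_align_score(read, probe$ref_methylated))
  }
})

test_that("lowering the identity threshold never loses passing reads", {
  got <- make_test_panel(seed = 53, n_probes = 3, depth_per_probe = 150,
                         seq_error = 0.05, short_read_fraction = 0)
  sim <- simulate_reads(got$sim$panel, got$config)
  dm <- demultiplex(sim$reads, got$sim$panel)
  for (id in probe_ids(got$sim$panel)) {
    sub <- dm[!is.na(dm$assigned_probe_id) & dm$assigned_probe_id == id, ]
    strict <- align_and_call(sub, got$sim$panel$probes[[id]], min_identity = 0.95)
    loose <- align_and_call(sub, got$sim$panel$probes[[id]], min_identity = 0.85)
    expect_true(all(loose$passes_filter[strict$passes_filter]))
    expect_gte(sum(loose$passes_filter), sum(strict$passes_filter))
  }
})

test_that("aggregation counts reads and is order-invariant", {
  calls <- data.frame(
    read_id = sprintf("r%d", 1:10), probe_id = "p",
    score = 1, identity = 1,
    cpg_states = c(rep("MMM", 6), rep("MUM", 2), rep("???", 2)),
    passes_filter = c(rep(TRUE, 8), FALSE, FALSE),
    fully_methylated = c(rep(TRUE, 6), rep(FALSE, 4)),
    fail_reason = NA_character_)
  agg <- aggregate_calls(calls)
  expect_equal(agg$total_reads, 10)
  expect_equal(agg$pass_reads, 8)
  expect_equal(agg$fully_methylated_reads, 6)
  perm <- aggregate_calls(calls[sample(10), ])
  expect_equal(perm, agg)
  expect_equal(aggregate_calls(calls[0, ], probe_id = "p")$total_reads, 0)
  calls2 <- calls; calls2$probe_id[1] <- "q"
  expect_error(aggregate_calls(calls2), "mix")
})

test_that("FASTQ round-trips through disk", {
  reads <- data.frame(read_id = c("r1", "r2"), seq = c("ACGT", "GGGTTTAA"))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_amplicon_fastq(reads, f)
  back <- read_amplicon_fastq(f)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$seq, reads$seq)
})
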