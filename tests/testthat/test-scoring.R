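cs <- function(probe_id, total, pass, fully)
  data.frame(probe_id = probe_id, total_reads = total, pass_reads = pass,
             fully_methylated_reads = fully, stringsAsFactors = FALSE)

test_that("probe scoring honours the read floor and fraction boundary", {
  # fraction exactly 0.1 with enough reads is positive ("at or above 0.1")
  r <- score_probe(cs("p", 160, 150, 15))
  expect_equal(r$fraction, 0.1)
  expect_true(r$positive)
  # 99 passing reads are below the evaluability floor, whatever the fraction
  r2 <- score_probe(cs("p", 99, 99, 99))
  expect_false(r2$evaluable)
  expect_false(r2$positive)
  # a low fraction with ample reads is negative
  r3 <- score_probe(cs("p", 210, 200, 10))
  expect_equal(r3$fraction, 0.05)
  expect_true(r3$evaluable)
  expect_false(r3$positive)
  # zero passing reads: fraction undefined
  expect_true(is.na(score_probe(cs("p", 0, 0, 0))$fraction))
})

test_that("Methylation Index counts positive non-BRCA1 probes", {
  panel <- panel_definition(list(make_toy_probe("p1"), make_toy_probe("p2"),
                                 make_toy_probe("brca1", is_brca1 = TRUE)))
  res <- rbind(score_probe(cs("p1", 160, 150, 30)),
               score_probe(cs("p2", 160, 150, 30)),
               score_probe(cs("brca1", 160, 150, 30)))
  expect_true(all(res$positive))
  expect_equal(methylation_index(res, panel), 2)   # BRCA1 excluded
  res$positive <- FALSE
  expect_equal(methylation_index(res, panel), 0)
  res$probe_id[1] <- "ghost"
  expect_error(methylation_index(res, panel), "ghost")
})

test_that("classification is strict at the 2.5-probe threshold", {
  expect_false(classify_mi(2))   # patient at score 2 falls below threshold
  expect_true(classify_mi(3))    # controls range 0-2, so 3 is positive
  expect_false(classify_mi(0))
  expect_equal(classify_mi(0:5), c(F, F, F, T, T, T))
})

test_that("sample reports surface BRCA1 with a caveat when panel-negative", {
  panel <- panel_definition(list(make_toy_probe("p1"), make_toy_probe("p2"),
                                 make_toy_probe("p3"), make_toy_probe("p4"),
                                 make_toy_probe("brca1", is_brca1 = TRUE)))
  sets <- rbind(cs("p1", 160, 150, 30), cs("p2", 160, 150, 2),
                cs("p3", 160, 150, 0), cs("p4", 50, 40, 40),
                cs("brca1", 160, 150, 50))
  rep <- sample_report("s1", sets, panel)
  expect_equal(rep$mi, 1L)                 # p1 only; p4 not evaluable
  expect_false(rep$call)
  expect_true(rep$brca1_methylated)
  expect_true(rep$brca1_caveat)
  expect_equal(rep$n_evaluable, 4)
  # MI is non-decreasing when thresholds relax
  rep_lo <- sample_report("s1", sets, panel, fraction_threshold = 0.01)
  expect_gte(rep_lo$mi, rep$mi)
  rep_floor <- sample_report("s1", sets, panel, min_reads = 40)
  expect_gte(rep_floor$mi, rep$mi)
})

test_that("probe QC drops probes positive in >= 3 controls, BRCA1 exempt", {
  pos <- matrix(FALSE, nrow = 20, ncol = 4,
                dimnames = list(NULL, c("a", "b", "c", "brca1")))
  pos[1:3, "a"] <- TRUE     # 3 positives: dropped
  pos[1:2, "b"] <- TRUE     # 2 positives: kept
  pos[1:4, "brca1"] <- TRUE # over threshold but exempt
  expect_identical(qc_probes(pos, exempt = "brca1"), "a")
  expect_error(qc_probes(pos[0, , drop = FALSE]), "empty")
  # a probe positive in zero controls is never dropped
  expect_false("c" %in% qc_probes(pos))
})

test_that("QC matches a column-count oracle on a synthetic control cohort", {
  set.seed(77)
  n_probes <- 68; n_controls <- 25
  elevated <- sample(n_probes, 14)
  rate <- rep(0.01, n_probes); rate[elevated] <- 0.25
  pos <- t(vapply(seq_len(n_controls),
                  function(i) stats::runif(n_probes) < rate,
                  logical(n_probes)))
  colnames(pos) <- sprintf("probe_%02d", seq_len(n_probes))
  drop <- qc_probes(pos, max_control_positives = 3)
  expect_setequal(drop, colnames(pos)[colSums(pos) >= 3])
})

test_that("ROC handles separation, ties, and matches the pairwise oracle", {
  perfect <- roc_mi(c(10, 20, 0, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sens_at_full_spec, 1)
  tied <- roc_mi(c(1, 1, 1, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(tied$auc, 0.5)
  expect_equal(tied$sens_at_full_spec, 0)
  ex <- roc_mi(c(3, 2, 0, 5, 0, 1, 0, 2),
               c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(ex$auc, oracle_auc(c(3, 2, 0, 5), c(0, 1, 0, 2)))
  expect_error(roc_mi(c(1, 2), c(TRUE, TRUE)), "control")
  # operating table: thresholds are exhaustive and sens/spec consistent
  expect_equal(ex$table$sensitivity[ex$table$threshold == -Inf], 1)
  expect_equal(ex$table$specificity[ex$table$threshold == max(ex$table$threshold)], 1)
})

test_that("ROC agrees with pROC on random cohorts", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (k in 1:20) {
    n1 <- sample(2:10, 1); n0 <- sample(2:10, 1)
    scores <- c(rpois(n1, 5), rpois(n0, 2))
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    ours <- roc_mi(scores, lab)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(lab, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref)
  }
})

test_that("correlation recovers exact and planted relationships", {
  x <- 1:5
  r <- correlate_scores(x, 2 * x)
  expect_equal(r$r, 1)
  expect_equal(r$r_squared, 1)
  # orthogonal by construction
  x2 <- c(-1, 0, 1, 0)
  y2 <- c(0, 1, 0, -1)
  expect_equal(correlate_scores(x2, y2)$r, 0)
  # planted correlation recovered within sampling error; matches the
  # closed-form covariance computation
  set.seed(5)
  n <- 100
  a <- rnorm(n)
  b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  got <- correlate_scores(a, b)
  expect_equal(got$r, stats::cov(a, b) / (sd(a) * sd(b)))
  expect_lt(abs(got$r - 0.5), 0.25)
  # degenerate inputs error
  expect_error(correlate_scores(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(correlate_scores(c(1, NA, 3), c(1, 2, NA)), "3 complete")
})

test_that("cohort matrices mask non-evaluable fractions", {
  panel <- panel_definition(list(make_toy_probe("p1"), make_toy_probe("p2")))
  r1 <- sample_report("s1", rbind(cs("p1", 160, 150, 30), cs("p2", 60, 50, 25)),
                      panel)
  r2 <- sample_report("s2", rbind(cs("p1", 160, 150, 0), cs("p2", 160, 150, 80)),
                      panel)
  cm <- cohort_matrix(list(r1, r2), c("case", "control"))
  expect_true(is.na(cm$fraction["s1", "p2"]))   # below the read floor
  expect_equal(cm$fraction["s2", "p2"], 80 / 150)
  expect_equal(cm$mi, c(1L, 1L))
  expect_equal(dim(cm$positive), c(2, 2))
})
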