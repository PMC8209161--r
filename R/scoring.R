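# -- per-probe scoring --------------------------------------------------------

#' Score one probe in one sample
#'
#' The fully-methylated-read fraction f is `fully_methylated_reads /
#' pass_reads`. A probe is evaluable only with at least `min_reads` passing
#' reads (low-read probes can show spurious methylation from partially
#' converted templates) and positive when evaluable and f is at or above
#' `fraction_threshold`.
#'
#' @param callset one-row data.frame from [aggregate_calls()].
#' @param min_reads evaluability floor on passing reads. Default 100.
#' @param fraction_threshold positivity cutoff on f. Default 0.1.
#' @return One-row data.frame (`ProbeResult`): `probe_id`, `pass_reads`,
#'   `fully_methylated_reads`, `fraction`, `evaluable`, `positive`.
#' @export
score_probe <- function(callset, min_reads = 100, fraction_threshold = 0.1) {
  stopifnot(nrow(callset) == 1)
  pass <- callset$pass_reads
  fully <- callset$fully_methylated_reads
  f <- if (pass > 0) fully / pass else NA_real_
  evaluable <- pass >= min_reads
  data.frame(probe_id = callset$probe_id, pass_reads = pass,
             fully_methylated_reads = fully, fraction = f,
             evaluable = evaluable,
             positive = evaluable && !is.na(f) && f >= fraction_threshold,
             stringsAsFactors = FALSE)
}

#' Methylation Index of a sample
#'
#' Count of positive probes among the MI-eligible (non-BRCA1) panel probes.
#' BRCA1 promoter methylation is reported separately and never counts
#' toward the index.
#'
#' @param probe_results data.frame of [score_probe()] rows, one per panel
#'   probe.
#' @param panel a [panel_definition()].
#' @return Integer MI.
#' @export
methylation_index <- function(probe_results, panel) {
  stopifnot(inherits(panel, "PanelDefinition"))
  unknown <- setdiff(probe_results$probe_id, probe_ids(panel))
  if (length(unknown))
    stop("results for probes not in the panel: ", paste(unknown, collapse = ", "))
  brca1 <- vapply(panel$probes[probe_results$probe_id], `[[`, logical(1),
                  "is_brca1")
  sum(probe_results$positive & !brca1)
}

#' Classify a sample from its Methylation Index
#'
#' Positive when MI strictly exceeds `mi_threshold`; the default threshold
#' of 2.5 positive probes makes MI >= 3 positive and MI <= 2 negative.
#'
#' @param mi integer Methylation Index (vectorised).
#' @param mi_threshold classification threshold. Default 2.5.
#' @return Logical vector of calls.
#' @export
classify_mi <- function(mi, mi_threshold = 2.5) {
  mi > mi_threshold
}

#' Build a per-sample report
#'
#' Scores every panel probe, computes the Methylation Index and the sample
#' call, and surfaces BRCA1 promoter methylation. A methylated BRCA1 probe
#' in an otherwise negative sample is flagged with a caveat: promoter
#' status is interpretable only in the context of a positive panel finding.
#'
#' @param sample_id sample identifier.
#' @param callsets data.frame of per-probe counts ([aggregate_calls()]
#'   rows), one per panel probe.
#' @param panel a [panel_definition()].
#' @param min_reads,fraction_threshold see [score_probe()].
#' @param mi_threshold see [classify_mi()].
#' @return An object of class `SampleReport`: list with `sample_id`,
#'   `probe_results`, `mi`, `call`, `brca1_methylated`, `brca1_caveat`,
#'   `n_evaluable`.
#' @export
sample_report <- function(sample_id, callsets, panel, min_reads = 100,
                          fraction_threshold = 0.1, mi_threshold = 2.5) {
  stopifnot(inherits(panel, "PanelDefinition"))
  missing <- setdiff(probe_ids(panel), callsets$probe_id)
  if (length(missing)) {
    zero <- data.frame(probe_id = missing, total_reads = 0L, pass_reads = 0L,
                       fully_methylated_reads = 0L, stringsAsFactors = FALSE)
    callsets <- rbind(callsets[, names(zero)], zero)
  }
  res <- do.call(rbind, lapply(seq_len(nrow(callsets)), function(i)
    score_probe(callsets[i, , drop = FALSE], min_reads, fraction_threshold)))
  mi <- methylation_index(res, panel)
  call <- classify_mi(mi, mi_threshold)
  brca1_ids <- names(which(vapply(panel$probes, `[[`, logical(1), "is_brca1")))
  brca1_methylated <- any(res$positive[res$probe_id %in% brca1_ids])
  structure(list(sample_id = sample_id, probe_results = res,
                 mi = as.integer(mi), call = call,
                 brca1_methylated = brca1_methylated,
                 brca1_caveat = brca1_methylated && !call,
                 n_evaluable = sum(res$evaluable)),
            class = "SampleReport")
}

#' @export
print.SampleReport <- function(x, ...) {
  cat(sprintf("SampleReport %s: MI = %d -> %s (%d/%d probes evaluable)\n",
              x$sample_id, x$mi, if (x$call) "POSITIVE" else "negative",
              x$n_evaluable, nrow(x$probe_results)))
  if (x$brca1_methylated)
    cat("BRCA1 promoter methylated",
        if (x$brca1_caveat)
          "(caveat: overall panel call is negative; interpret with care)\n"
        else "\n")
  invisible(x)
}

# -- cohorts ------------------------------------------------------------------

#' Combine sample reports into a cohort matrix
#'
#' @param reports list of [sample_report()] objects.
#' @param groups character vector of group labels (`"case"` / `"control"`),
#'   one per report.
#' @return An object of class `CohortMatrix`: list with `fraction`
#'   (samples x probes, `NA` where not evaluable), `positive` (logical
#'   matrix), `mi`, `call`, `group`, `sample_ids`.
#' @export
cohort_matrix <- function(reports, groups) {
  stopifnot(length(reports) == length(groups), length(reports) > 0)
  ids <- vapply(reports, `[[`, character(1), "sample_id")
  probes <- reports[[1]]$probe_results$probe_id
  frac <- t(vapply(reports, function(r) {
    stopifnot(identical(r$probe_results$probe_id, probes))
    ifelse(r$probe_results$evaluable, r$probe_results$fraction, NA_real_)
  }, numeric(length(probes))))
  pos <- t(vapply(reports, function(r) r$probe_results$positive,
                  logical(length(probes))))
  dimnames(frac) <- dimnames(pos) <- list(ids, probes)
  structure(list(fraction = frac, positive = pos,
                 mi = vapply(reports, `[[`, integer(1), "mi"),
                 call = vapply(reports, `[[`, logical(1), "call"),
                 group = as.character(groups), sample_ids = ids),
            class = "CohortMatrix")
}

#' Control-based probe quality control
#'
#' Flags probes positive in `max_control_positives` or more control
#' samples for removal ("three or more positive normal samples"). BRCA1
#' probes (or any id in `exempt`) are never dropped: the promoter probe is
#' retained for its clinical value despite occasional control positivity.
#'
#' @param controls a `CohortMatrix` of control samples only, or a logical
#'   samples x probes positivity matrix.
#' @param max_control_positives drop threshold. Default 3.
#' @param exempt probe ids never dropped.
#' @return Character vector of probe ids to drop.
#' @export
qc_probes <- function(controls, max_control_positives = 3, exempt = character()) {
  pos <- if (inherits(controls, "CohortMatrix")) controls$positive else controls
  if (is.null(dim(pos)) || nrow(pos) == 0) stop("empty control cohort")
  counts <- colSums(pos, na.rm = TRUE)
  setdiff(colnames(pos)[counts >= max_control_positives], exempt)
}

#' ROC summary for a scored cohort
#'
#' Rank-based AUC (probability a random case outscores a random control,
#' ties counted 1/2) plus the sensitivity at 100% specificity — the
#' fraction of cases scoring strictly above the maximum control score —
#' and a full operating table over thresholds (a sample is called positive
#' when its score strictly exceeds the threshold).
#'
#' @param scores numeric per-sample scores (typically MI).
#' @param is_case logical vector, `TRUE` for cases.
#' @return list with `auc`, `sens_at_full_spec`, `table` (threshold,
#'   sensitivity, specificity), `n_cases`, `n_controls`.
#' @export
roc_mi <- function(scores, is_case) {
  stopifnot(length(scores) == length(is_case), !anyNA(scores))
  is_case <- as.logical(is_case)
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0)
    stop("ROC needs at least one case and one control")
  r <- rank(scores)
  auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  sens100 <- mean(scores[is_case] > max(scores[!is_case]))
  th <- c(-Inf, sort(unique(scores)))
  tab <- data.frame(
    threshold = th,
    sensitivity = vapply(th, function(t) mean(scores[is_case] > t), numeric(1)),
    specificity = vapply(th, function(t) mean(scores[!is_case] <= t), numeric(1)))
  list(auc = auc, sens_at_full_spec = sens100, table = tab,
       n_cases = n1, n_controls = n0)
}

#' Pearson correlation of two per-sample score vectors
#'
#' Pairwise-complete Pearson correlation with R-squared and a two-sided
#' p-value; the comparison style used to relate the Methylation Index to
#' external markers such as CA15-3 or mutation-based ctDNA levels.
#'
#' @param x,y numeric vectors of equal length.
#' @param method correlation method passed to [stats::cor.test()].
#' @return list with `r`, `r_squared`, `p_value`, `n`.
#' @export
correlate_scores <- function(x, y, method = "pearson") {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x[ok], y[ok], method = method)
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value, n = sum(ok))
}

#' Write a sample report to disk
#'
#' Emits a per-probe TSV and a JSON summary (MI, call, BRCA1 flags).
#'
#' @param report a [sample_report()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sample_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$probe_results,
                     file.path(dir, paste0(report$sample_id, "_probes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(sample_id = report$sample_id, mi = report$mi, call = report$call,
         brca1_methylated = report$brca1_methylated,
         brca1_caveat = report$brca1_caveat,
         n_evaluable = report$n_evaluable),
    file.path(dir, paste0(report$sample_id, "_summary.json")),
    auto_unbox = TRUE)
  invisible(dir)
}
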