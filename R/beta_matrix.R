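#' Construct a beta matrix for methylation-array data
#'
#' A `BetaMatrix` holds per-CpG methylation levels (beta values in \[0,1\])
#' across a cohort, together with genomic coordinates and a per-sample group
#' label. It is the input to DMR discovery ([select_dmr_cpgs()]).
#'
#' @param values numeric matrix of beta values, rows = CpG probes,
#'   columns = samples. `NA` marks missing values.
#' @param chrom character vector of chromosome names, one per row.
#' @param pos integer vector of 0-based genomic coordinates of the CpG
#'   cytosine, one per row.
#' @param groups character vector of cohort tags, one per column
#'   (e.g. `"tumour"`, `"normal-breast"`, `"normal-lung"`).
#' @param cpg_ids character vector of unique probe identifiers; defaults to
#'   `rownames(values)`.
#'
#' @return An object of class `BetaMatrix`: a list with elements
#'   `values`, `chrom`, `pos`, `cpg_ids`, `groups`.
#'
#' @details Rows must be sorted by `(chrom, pos)`; beta values outside
#'   \[0,1\] are an error (use `NA` for missing).
#' @export
beta_matrix <- function(values, chrom, pos, groups, cpg_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(cpg_ids)) stop("cpg_ids are required (or set rownames on 'values')")
  n <- nrow(values)
  if (length(chrom) != n || length(pos) != n || length(cpg_ids) != n)
    stop("chrom, pos and cpg_ids must each have one entry per row of 'values'")
  if (length(groups) != ncol(values))
    stop("groups must have one entry per column of 'values'")
  if (anyDuplicated(cpg_ids)) stop("cpg_ids must be unique")
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad))
    stop("beta values must lie in [0,1] or be NA; first offender at index ", bad[1])
  ord <- order(chrom, pos)
  if (!identical(ord, seq_len(n)))
    stop("rows must be sorted by (chrom, pos)")
  rownames(values) <- cpg_ids
  structure(
    list(values = values, chrom = as.character(chrom), pos = as.integer(pos),
         cpg_ids = as.character(cpg_ids), groups = as.character(groups)),
    class = "BetaMatrix")
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d CpGs x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("groups:", paste(sprintf("%s (%d)", names(table(x$groups)),
                               as.integer(table(x$groups))), collapse = ", "), "\n")
  invisible(x)
}

#' Read a beta matrix and sample sheet from TSV files
#'
#' The beta file has columns `cpg_id`, `chrom`, `pos` followed by one column
#' per sample; the sample sheet has columns `sample_id` and `group`.
#'
#' @param beta_file path to the beta TSV.
#' @param samples_file path to the sample-sheet TSV.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(beta_file, samples_file) {
  tab <- utils::read.delim(beta_file, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cpg_id", "chrom", "pos")
  if (!all(need %in% names(tab)))
    stop("beta file must have columns: ", paste(need, collapse = ", "))
  ss <- utils::read.delim(samples_file, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(ss)))
    stop("sample sheet must have columns sample_id and group")
  sample_cols <- setdiff(names(tab), need)
  missing <- setdiff(ss$sample_id, sample_cols)
  if (length(missing))
    stop("samples missing from beta file: ", paste(missing, collapse = ", "))
  vals <- as.matrix(tab[, ss$sample_id, drop = FALSE])
  storage.mode(vals) <- "double"
  beta_matrix(vals, tab$chrom, tab$pos, ss$group, cpg_ids = tab$cpg_id)
}
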