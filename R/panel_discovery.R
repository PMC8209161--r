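#' Select tumour-specific hypermethylated CpGs from a beta matrix
#'
#' Applies the two discovery criteria on the centered beta scale
#' (beta' = beta - `center`): a CpG is selected when at least
#' `min_tumour_fraction` of tumour samples have beta' greater than
#' `tumour_threshold` (default -0.1, i.e. beta > 0.4) and the mean beta'
#' of *each* normal-tissue group is below `normal_threshold`
#' (default -0.3, i.e. mean beta < 0.2).
#'
#' @param beta a [beta_matrix()]; group labels must contain `tumour_group`
#'   and at least one other group (treated as normal tissues).
#' @param tumour_threshold centered-beta threshold a tumour sample must
#'   exceed. Default -0.1.
#' @param normal_threshold centered-beta bound each per-tissue normal mean
#'   must stay below. Default -0.3.
#' @param min_tumour_fraction minimum fraction of tumour samples exceeding
#'   `tumour_threshold`. Default 0.5.
#' @param tumour_group label identifying tumour columns. Default `"tumour"`.
#' @param center offset subtracted from beta before thresholding; set to 0
#'   to pass thresholds on the raw scale (e.g. after an M-value transform
#'   applied upstream). Default 0.5.
#'
#' @return Character vector of selected CpG ids (a subset of
#'   `beta$cpg_ids`, in matrix order).
#'
#' @details Missing values are excluded pairwise: they enter neither the
#'   numerator nor the denominator of the tumour fraction, and normal means
#'   ignore them. Selection is idempotent and independent of sample order.
#' @seealso [pair_cpgs_to_regions()], [dmr_cpg_table()]
#' @export
select_dmr_cpgs <- function(beta, tumour_threshold = -0.1, normal_threshold = -0.3,
                            min_tumour_fraction = 0.5, tumour_group = "tumour",
                            center = 0.5) {
  stopifnot(inherits(beta, "BetaMatrix"))
  if (tumour_threshold < -center || tumour_threshold > 1 - center)
    stop("tumour_threshold outside the centered-beta range [",
         -center, ", ", 1 - center, "]")
  if (normal_threshold < -center || normal_threshold > 1 - center)
    stop("normal_threshold outside the centered-beta range [",
         -center, ", ", 1 - center, "]")
  sel <- dmr_cpg_table(beta, tumour_threshold, normal_threshold,
                       min_tumour_fraction, tumour_group, center)
  sel$cpg_id[sel$selected]
}

#' Per-CpG discovery statistics
#'
#' Returns the quantities behind [select_dmr_cpgs()] for every CpG: the
#' fraction of tumour samples above the tumour criterion, the worst
#' (largest) per-tissue normal mean on the centered scale, and the selection
#' flag.
#'
#' @inheritParams select_dmr_cpgs
#' @return data.frame with columns `cpg_id`, `chrom`, `pos`,
#'   `tumour_fraction`, `max_normal_mean`, `selected`.
#' @export
dmr_cpg_table <- function(beta, tumour_threshold = -0.1, normal_threshold = -0.3,
                          min_tumour_fraction = 0.5, tumour_group = "tumour",
                          center = 0.5) {
  stopifnot(inherits(beta, "BetaMatrix"))
  g <- beta$groups
  if (!any(g == tumour_group))
    stop("no samples in tumour group '", tumour_group, "'")
  normal_groups <- setdiff(unique(g), tumour_group)
  if (!length(normal_groups))
    stop("no normal-tissue groups present (only '", tumour_group, "')")
  vprime <- beta$values - center

  tum <- vprime[, g == tumour_group, drop = FALSE]
  n_obs <- rowSums(!is.na(tum))
  n_hit <- rowSums(tum > tumour_threshold, na.rm = TRUE)
  tumour_fraction <- ifelse(n_obs > 0, n_hit / n_obs, NA_real_)

  normal_means <- vapply(normal_groups, function(ng) {
    cols <- vprime[, g == ng, drop = FALSE]
    if (ncol(cols) == 0) stop("empty normal group '", ng, "'")
    rowMeans(cols, na.rm = TRUE)
  }, numeric(nrow(vprime)))
  if (is.null(dim(normal_means))) normal_means <- matrix(normal_means, nrow = 1)
  max_normal_mean <- apply(normal_means, 1, max)

  selected <- !is.na(tumour_fraction) &
    tumour_fraction >= min_tumour_fraction &
    max_normal_mean < normal_threshold

  data.frame(cpg_id = beta$cpg_ids, chrom = beta$chrom, pos = beta$pos,
             tumour_fraction = tumour_fraction,
             max_normal_mean = max_normal_mean,
             selected = selected,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pair selected CpGs into candidate regions
#'
#' Chains coordinate-sorted selected CpGs into maximal runs in which
#' consecutive members on the same chromosome are at most `max_gap` apart
#' (single linkage between CpG cytosine coordinates). Runs with a single
#' member are discarded: a candidate needs at least two supporting CpGs.
#'
#' @param selected data.frame with columns `cpg_id`, `chrom`, `pos`
#'   (0-based CpG cytosine coordinate) and optionally `tumour_fraction`;
#'   must already be sorted by `(chrom, pos)` — unsorted input is an error,
#'   not silently re-sorted.
#' @param max_gap maximum distance in bp between consecutive member CpGs.
#'   Default 300.
#'
#' @return data.frame of candidates with columns `region_id`, `chrom`,
#'   `start`, `end` (0-based half-open, spanning the member CpG cytosines),
#'   `n_cpgs`, `member_cpgs` (comma-separated ids) and `tumour_frequency`
#'   (mean of member `tumour_fraction`, `NA` if not supplied).
#' @export
pair_cpgs_to_regions <- function(selected, max_gap = 300) {
  need <- c("cpg_id", "chrom", "pos")
  if (!all(need %in% names(selected)))
    stop("selected must have columns: ", paste(need, collapse = ", "))
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_cpgs = integer(),
                      member_cpgs = character(), tumour_frequency = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(selected) == 0) return(empty)
  ord <- order(selected$chrom, selected$pos)
  if (!identical(ord, seq_len(nrow(selected))))
    stop("selected CpGs must be sorted by (chrom, pos); refusing to re-sort")
  new_chrom <- c(TRUE, selected$chrom[-1] != selected$chrom[-nrow(selected)])
  gap <- c(Inf, diff(selected$pos))
  run <- cumsum(new_chrom | gap > max_gap)
  pieces <- split(seq_len(nrow(selected)), run)
  pieces <- pieces[vapply(pieces, length, integer(1)) >= 2]
  if (!length(pieces)) return(empty)
  out <- do.call(rbind, lapply(pieces, function(idx) {
    tf <- if ("tumour_fraction" %in% names(selected))
      mean(selected$tumour_fraction[idx]) else NA_real_
    data.frame(chrom = selected$chrom[idx[1]],
               start = selected$pos[idx[1]],
               end = selected$pos[idx[length(idx)]] + 1L,
               n_cpgs = length(idx),
               member_cpgs = paste(selected$cpg_id[idx], collapse = ","),
               tumour_frequency = tf,
               stringsAsFactors = FALSE)
  }))
  out <- cbind(data.frame(region_id = sprintf("dmr_%03d", seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Remove candidates overlapping an exclusion mask
#'
#' Drops candidate regions that overlap any masked interval by at least one
#' base pair (e.g. regions methylated in blood cells). Intervals are
#' 0-based half-open on both sides, so abutting intervals do not overlap.
#'
#' @param candidates data.frame as returned by [pair_cpgs_to_regions()].
#' @param mask data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), or a `GRanges`.
#' @return The surviving rows of `candidates`, unchanged.
#' @export
apply_exclusion_mask <- function(candidates, mask) {
  if (nrow(candidates) == 0) return(candidates)
  if (!inherits(mask, "GRanges")) {
    if (!all(c("chrom", "start", "end") %in% names(mask)))
      stop("mask must have columns chrom, start, end (or be a GRanges)")
    if (nrow(mask) == 0) return(candidates)
    mask <- GenomicRanges::GRanges(mask$chrom,
                                   IRanges::IRanges(mask$start + 1L, mask$end))
  }
  unmatched <- setdiff(unique(as.character(GenomicRanges::seqnames(mask))),
                       unique(candidates$chrom))
  if (length(unmatched))
    warning("mask chromosomes absent from candidate set: ",
            paste(unmatched, collapse = ", "))
  cand_gr <- GenomicRanges::GRanges(candidates$chrom,
                                    IRanges::IRanges(candidates$start + 1L,
                                                     candidates$end))
  # seqlevel-mismatch chatter is covered by the warning above
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(cand_gr, mask, minoverlap = 1L))
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) candidates[-drop, , drop = FALSE] else candidates
}

#' Discover candidate regions from a beta matrix
#'
#' Convenience wrapper: [select_dmr_cpgs()] then [pair_cpgs_to_regions()],
#' optionally followed by [apply_exclusion_mask()].
#'
#' @inheritParams select_dmr_cpgs
#' @inheritParams pair_cpgs_to_regions
#' @param mask optional exclusion mask (see [apply_exclusion_mask()]).
#' @return Candidate data.frame (see [pair_cpgs_to_regions()]).
#' @export
discover_regions <- function(beta, tumour_threshold = -0.1, normal_threshold = -0.3,
                             min_tumour_fraction = 0.5, tumour_group = "tumour",
                             center = 0.5, max_gap = 300, mask = NULL) {
  tab <- dmr_cpg_table(beta, tumour_threshold, normal_threshold,
                       min_tumour_fraction, tumour_group, center)
  sel <- tab[tab$selected, c("cpg_id", "chrom", "pos", "tumour_fraction")]
  rownames(sel) <- NULL
  cand <- pair_cpgs_to_regions(sel, max_gap = max_gap)
  if (!is.null(mask)) cand <- apply_exclusion_mask(cand, mask)
  cand
}

#' Write candidate regions as BED
#'
#' @param candidates data.frame from [pair_cpgs_to_regions()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_candidates_bed <- function(candidates, file) {
  bed <- data.frame(candidates$chrom, candidates$start, candidates$end,
                    candidates$region_id, candidates$n_cpgs,
                    ifelse(is.na(candidates$tumour_frequency), ".",
                           format(candidates$tumour_frequency, digits = 4)))
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
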