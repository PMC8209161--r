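# -- FASTQ I/O ----------------------------------------------------------------

#' Read amplicon sequencing reads from FASTQ
#'
#' @param file path to a FASTQ file (optionally gzipped).
#' @return data.frame with columns `read_id`, `seq`, `qual`.
#' @export
read_amplicon_fastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq", with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  data.frame(read_id = names(x), seq = as.character(x),
             qual = if (is.null(q)) NA_character_ else as.character(q),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `read_id` and `seq` (and optionally `qual`;
#'   a constant quality is written otherwise).
#' @param file output path (".gz" suffix compresses).
#' @return `file`, invisibly.
#' @export
write_amplicon_fastq <- function(reads, file) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  quals <- if ("qual" %in% names(reads) && !anyNA(reads$qual)) reads$qual
           else strrep("I", nchar(reads$seq))
  Biostrings::writeXStringSet(x, file, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = grepl("\\.gz$", file))
  invisible(file)
}

# -- length filter ------------------------------------------------------------

#' Filter reads by length
#'
#' Retains reads strictly longer than `min_len` (the ">100 bp" rule:
#' a 100-bp read is removed). Counts of retained and removed reads are
#' attached as attributes `n_retained` / `n_removed`.
#'
#' @param reads data.frame with a `seq` column.
#' @param min_len length threshold in bp. Default 100.
#' @return The retained rows of `reads`.
#' @export
length_filter <- function(reads, min_len = 100) {
  keep <- nchar(reads$seq) > min_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

# -- demultiplexing -----------------------------------------------------------

# Hamming mismatches between each sequence prefix and a primer; Inf when the
# sequence is shorter than the primer.
prefix_mismatches <- function(seqs, primer) {
  plen <- nchar(primer)
  pm <- strsplit(primer, "", fixed = TRUE)[[1]]
  res <- rep(Inf, length(seqs))
  ok <- nchar(seqs) >= plen
  if (any(ok)) {
    pref <- substr(seqs[ok], 1L, plen)
    mat <- matrix(unlist(strsplit(pref, "", fixed = TRUE), use.names = FALSE),
                  nrow = plen)
    res[ok] <- colSums(mat != pm)
  }
  res
}

#' Assign reads to panel probes by forward-primer prefix
#'
#' Each read (tried as-is and reverse-complemented) is assigned to the
#' unique probe whose forward primer matches the read prefix with at most
#' `max_mismatches` mismatches. If two probes tie at the best mismatch
#' count the read is left unassigned; `max_mismatches = 0` reproduces
#' exact-prefix barcode splitting. The matched primer bases are trimmed and
#' the read is reported in reference orientation.
#'
#' @param reads data.frame with `read_id` and `seq`.
#' @param panel a [panel_definition()].
#' @param max_mismatches maximum primer mismatches. Default 2.
#' @return data.frame with columns `read_id`, `seq` (primer-trimmed, in
#'   reference orientation), `assigned_probe_id` (`NA` if unassigned) and
#'   `orientation` (`"as-is"`, `"revcomp"` or `NA`). Per-probe and
#'   unassigned counts are attached as attribute `counts`.
#' @export
demultiplex <- function(reads, panel, max_mismatches = 2) {
  stopifnot(inherits(panel, "PanelDefinition"))
  ids <- probe_ids(panel)
  n <- nrow(reads)
  if (n == 0) {
    out <- data.frame(read_id = character(), seq = character(),
                      assigned_probe_id = character(), orientation = character(),
                      stringsAsFactors = FALSE)
    attr(out, "counts") <- c(stats::setNames(integer(length(ids)), ids),
                             unassigned = 0L)
    return(out)
  }
  fwd <- reads$seq
  rc <- revcomp(fwd)
  mm_fwd <- vapply(ids, function(id)
    prefix_mismatches(fwd, panel$probes[[id]]$fwd_primer), numeric(n))
  mm_rc <- vapply(ids, function(id)
    prefix_mismatches(rc, panel$probes[[id]]$fwd_primer), numeric(n))
  if (n == 1) { mm_fwd <- rbind(mm_fwd); mm_rc <- rbind(mm_rc) }
  mm_best <- pmin(mm_fwd, mm_rc)                       # n x probes
  best <- do.call(pmin, c(as.data.frame(mm_best), list(Inf)))
  assigned <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  seq_out <- reads$seq
  cand <- which(best <= max_mismatches)
  for (i in cand) {
    hits <- which(mm_best[i, ] == best[i])
    if (length(hits) != 1) next                        # ambiguous: tie
    id <- ids[hits]
    ori <- if (mm_fwd[i, hits] <= mm_rc[i, hits]) "as-is" else "revcomp"
    s <- if (ori == "as-is") fwd[i] else rc[i]
    assigned[i] <- id
    orientation[i] <- ori
    seq_out[i] <- substr(s, nchar(panel$probes[[id]]$fwd_primer) + 1L, nchar(s))
  }
  out <- data.frame(read_id = reads$read_id, seq = seq_out,
                    assigned_probe_id = assigned, orientation = orientation,
                    stringsAsFactors = FALSE, row.names = NULL)
  counts <- c(vapply(ids, function(id) sum(assigned == id, na.rm = TRUE),
                     integer(1)),
              unassigned = sum(is.na(assigned)))
  attr(out, "counts") <- counts
  out
}

# -- alignment and methylation calling ----------------------------------------

# Substitution matrix for bisulfite-aware alignment against the methylated
# converted reference: a read T opposite a reference C scores as a match
# (the unmethylated state), while a read C opposite a reference T does not.
# In a converted reference the only Cs left are CpG cytosines, so this is
# exactly CpG-aware C/T matching.
bisulfite_submat <- function(match = 1, mismatch = -1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  mat["T", "C"] <- match
  mat
}

#' Align reads to a probe reference and call per-CpG methylation
#'
#' Globally aligns primer-trimmed reads against the probe's
#' fully-methylated converted reference with free end gaps, treating a read
#' T at a CpG cytosine as a match (the unmethylated state is not an error).
#' Identity is matching columns over alignment columns. The methylation
#' state at each scored CpG offset is read off the aligned base: C is
#' methylated (`M`), T unmethylated (`U`), anything else including a gap is
#' ambiguous (`?`). A read passes the filter when identity is at least
#' `min_identity` (the 90% homology rule) and every scored CpG is
#' identifiable; it is fully methylated when it passes and every state is
#' `M`. Reads shorter than half the amplicon fail with reason
#' `"short_alignment"`.
#'
#' @param reads data.frame of reads assigned to this probe (`read_id`,
#'   `seq`, primer-trimmed, reference orientation).
#' @param probe a [build_probe()] object.
#' @param min_identity identity threshold. Default 0.90.
#' @param match,mismatch,gap alignment scores (linear gap penalty,
#'   `gap` given as a positive cost). Defaults 1 / -1 / 2.
#' @return data.frame (per-read `ReadCall`s) with columns `read_id`,
#'   `probe_id`, `score`, `identity`, `cpg_states` (string over `M`/`U`/`?`),
#'   `passes_filter`, `fully_methylated`, `fail_reason`.
#' @export
align_and_call <- function(reads, probe, min_identity = 0.90,
                           match = 1, mismatch = -1, gap = 2) {
  ref <- probe$ref_methylated
  L <- nchar(ref)
  n_cpg <- length(probe$cpg_offsets)
  # scored CpG positions relative to the trimmed read's reference frame:
  # the reference is the full amplicon; trimmed reads start at fwd_len+1.
  cpg_ref_pos <- probe$cpg_offsets + 1L        # 1-based on full amplicon
  empty <- data.frame(read_id = character(), probe_id = character(),
                      score = numeric(), identity = numeric(),
                      cpg_states = character(), passes_filter = logical(),
                      fully_methylated = logical(), fail_reason = character(),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0) return(empty)

  short <- nchar(reads$seq) < ceiling(L / 2)
  out <- data.frame(read_id = reads$read_id, probe_id = probe$probe_id,
                    score = NA_real_, identity = NA_real_,
                    cpg_states = strrep("?", n_cpg),
                    passes_filter = FALSE, fully_methylated = FALSE,
                    fail_reason = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$fail_reason[short] <- "short_alignment"
  idx <- which(!short)
  if (!length(idx)) return(out)

  submat <- bisulfite_submat(match, mismatch)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads$seq[idx]), Biostrings::DNAString(ref),
    substitutionMatrix = submat, gapOpening = 0, gapExtension = gap,
    type = "overlap")
  ap <- strsplit(as.character(Biostrings::pattern(pa)), "", fixed = TRUE)
  as_ <- strsplit(as.character(Biostrings::subject(pa)), "", fixed = TRUE)
  s_start <- BiocGenerics::start(Biostrings::subject(pa))
  out$score[idx] <- BiocGenerics::score(pa)

  for (k in seq_along(idx)) {
    i <- idx[k]
    pc <- ap[[k]]; sc <- as_[[k]]
    is_match <- pc == sc | (pc == "T" & sc == "C")
    out$identity[i] <- sum(is_match) / length(pc)
    states <- rep("?", n_cpg)
    if (n_cpg > 0) {
      subj_cols <- which(sc != "-")
      rel <- cpg_ref_pos - s_start[k] + 1L       # index among subject bases
      inb <- rel >= 1L & rel <= length(subj_cols)
      if (any(inb)) {
        bases <- pc[subj_cols[rel[inb]]]
        states[inb] <- ifelse(bases == "C", "M", ifelse(bases == "T", "U", "?"))
      }
    }
    out$cpg_states[i] <- paste(states, collapse = "")
    ok_id <- out$identity[i] >= min_identity
    ok_cpg <- !any(states == "?")
    out$passes_filter[i] <- ok_id && ok_cpg
    out$fully_methylated[i] <- out$passes_filter[i] && n_cpg > 0 &&
      all(states == "M")
    if (!ok_id) out$fail_reason[i] <- "low_identity"
    else if (!ok_cpg) out$fail_reason[i] <- "cpg_not_identifiable"
  }
  out
}

#' Aggregate per-read calls into per-probe counts
#'
#' @param calls data.frame from [align_and_call()]; all rows must carry the
#'   same `probe_id`.
#' @param probe_id expected probe id (defaults to the one in `calls`).
#' @return One-row data.frame (`ReadCallSet`): `probe_id`, `total_reads`,
#'   `pass_reads`, `fully_methylated_reads`.
#' @export
aggregate_calls <- function(calls, probe_id = NULL) {
  if (nrow(calls) == 0) {
    if (is.null(probe_id)) stop("probe_id required when no calls are given")
    return(data.frame(probe_id = probe_id, total_reads = 0L, pass_reads = 0L,
                      fully_methylated_reads = 0L, stringsAsFactors = FALSE))
  }
  ids <- unique(calls$probe_id)
  if (length(ids) != 1)
    stop("calls mix probe ids: ", paste(ids, collapse = ", "))
  if (!is.null(probe_id) && ids != probe_id)
    stop("calls are for probe ", ids, ", expected ", probe_id)
  data.frame(probe_id = ids, total_reads = nrow(calls),
             pass_reads = sum(calls$passes_filter),
             fully_methylated_reads = sum(calls$fully_methylated),
             stringsAsFactors = FALSE)
}

#' Process raw reads to per-probe call sets
#'
#' Full read-processing chain: length filter, primer demultiplexing, and
#' per-probe alignment-based methylation calling.
#'
#' @param reads data.frame with `read_id` and `seq`.
#' @param panel a [panel_definition()].
#' @param min_len length-filter threshold. Default 100.
#' @param max_mismatches demultiplexing primer mismatches. Default 2.
#' @param min_identity alignment identity threshold. Default 0.90.
#' @return list with `calls` (per-read data.frame across probes),
#'   `callsets` (per-probe counts, one row per panel probe) and `log`
#'   (filter and demultiplex counters).
#' @export
process_reads <- function(reads, panel, min_len = 100, max_mismatches = 2,
                          min_identity = 0.90) {
  stopifnot(inherits(panel, "PanelDefinition"))
  kept <- length_filter(reads, min_len)
  dm <- demultiplex(kept, panel, max_mismatches)
  calls <- list(); callsets <- list()
  for (id in probe_ids(panel)) {
    sub <- dm[!is.na(dm$assigned_probe_id) & dm$assigned_probe_id == id,
              c("read_id", "seq"), drop = FALSE]
    cl <- align_and_call(sub, panel$probes[[id]], min_identity = min_identity)
    calls[[id]] <- cl
    callsets[[id]] <- aggregate_calls(cl, probe_id = id)
  }
  list(calls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
       callsets = do.call(rbind, c(callsets, list(make.row.names = FALSE))),
       log = list(length_filter = c(retained = attr(kept, "n_retained"),
                                    removed = attr(kept, "n_removed")),
                  demultiplex = attr(dm, "counts")))
}
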