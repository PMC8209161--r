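# -- small sequence helpers ---------------------------------------------------

revcomp <- function(s) {
  vapply(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# 1-based start positions of exact (fixed) matches of 'needle' in 'hay',
# including overlapping matches
find_all <- function(hay, needle) {
  hits <- integer(0)
  from <- 1L
  repeat {
    m <- regexpr(needle, substr(hay, from, nchar(hay)), fixed = TRUE)
    if (m == -1) break
    hits <- c(hits, from + as.integer(m) - 1L)
    from <- from + as.integer(m)
  }
  hits
}

find_exact <- function(hay, needle) find_all(hay, needle)

# -- bisulfite conversion -----------------------------------------------------

#' In-silico bisulfite conversion (top strand)
#'
#' Converts a DNA sequence as complete bisulfite treatment would: every
#' cytosine outside a CpG context becomes thymine; a CpG cytosine is
#' retained as C when the template is methylated and converted to T when it
#' is not. Other bases, including N, are unchanged; a terminal C with no
#' following base is treated as non-CpG.
#'
#' @param seq DNA sequence over A/C/G/T/N (character scalar).
#' @param methylated logical: is the template fully methylated at CpGs?
#' @return The converted sequence.
#' @export
#' @examples
#' bisulfite_convert("ACGTCCG", methylated = TRUE)   # "ACGTTCG"
#' bisulfite_convert("ACGTCCG", methylated = FALSE)  # "ATGTTTG"
bisulfite_convert <- function(seq, methylated = TRUE) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("invalid base '", chars[bad[1]], "' at position ", bad[1])
  n <- length(chars)
  if (n == 0) return("")
  is_c <- chars == "C"
  next_g <- c(chars[-1] == "G", FALSE)  # terminal C is non-CpG
  out <- chars
  out[is_c & (!next_g | !methylated)] <- "T"
  paste(out, collapse = "")
}

# 1-based positions of CpG cytosines in a genomic (unconverted) sequence
cpg_positions <- function(seq) find_all(toupper(seq), "CG")

# -- probe construction -------------------------------------------------------

#' Build a panel probe from a genomic region and its primer pair
#'
#' Locates the primers on the fully-methylated bisulfite-converted top
#' strand of `genomic_seq` (the reverse primer as its reverse complement),
#' takes the amplicon as the span between the primer outer bounds, and
#' derives both converted reference variants plus the offsets of CpG
#' cytosines strictly between the primer footprints (the only positions the
#' assay scores).
#'
#' @param genomic_seq unconverted genomic sequence containing the amplicon.
#' @param fwd_primer,rev_primer primer sequences on the converted strand;
#'   each must occur exactly once.
#' @param probe_id probe identifier.
#' @param region_id region identifier; several probes may share one region.
#' @param chrom,start genomic location of `genomic_seq` (0-based start) used
#'   to place the probe; defaults give coordinates relative to the input.
#' @param is_brca1 flag for the BRCA1 promoter probe, which is excluded
#'   from the Methylation Index.
#'
#' @return An object of class `PanelProbe`: a list with `probe_id`,
#'   `region_id`, `chrom`, `start`, `end`, `fwd_primer`, `rev_primer`,
#'   `amplicon_genomic`, `ref_methylated`, `ref_unmethylated`,
#'   `cpg_offsets` (0-based offsets of scored CpG cytosines within the
#'   amplicon), `fwd_len`, `rev_len`, `is_brca1`.
#'
#' @details A CpG that straddles a primer footprint boundary is assigned to
#'   the footprint and not scored. Between 3 and 21 scored CpGs is the
#'   expected design band; probes outside 2-21 raise a warning but are
#'   still built (useful for testing). Amplicons longer than 150 bp warn:
#'   cell-free DNA is too fragmented for long products.
#' @export
build_probe <- function(genomic_seq, fwd_primer, rev_primer, probe_id,
                        region_id = probe_id, chrom = NA_character_,
                        start = 0L, is_brca1 = FALSE) {
  genomic_seq <- toupper(genomic_seq)
  fwd_primer <- toupper(fwd_primer); rev_primer <- toupper(rev_primer)
  conv <- bisulfite_convert(genomic_seq, methylated = TRUE)
  f_hit <- find_exact(conv, fwd_primer)
  if (length(f_hit) != 1)
    stop("forward primer '", fwd_primer, "' found ", length(f_hit),
         " times on the converted sequence (need exactly 1)")
  rc <- revcomp(rev_primer)
  r_hit <- find_exact(conv, rc)
  if (length(r_hit) != 1)
    stop("reverse primer '", rev_primer, "' found ", length(r_hit),
         " times on the converted sequence (need exactly 1)")
  f_len <- nchar(fwd_primer); r_len <- nchar(rev_primer)
  amp_start <- f_hit                      # 1-based within genomic_seq
  amp_end <- r_hit + r_len - 1
  if (amp_end <= amp_start) stop("reverse primer lies upstream of forward primer")
  amp <- substr(genomic_seq, amp_start, amp_end)
  L <- nchar(amp)
  if (L > 150)
    warning("amplicon length ", L, " exceeds 150 bp; cfDNA fragments are short")

  cpg <- cpg_positions(amp)               # 1-based C positions in amplicon
  n_pos <- find_all(amp, "N")
  if (length(n_pos)) {
    near_n <- cpg[(cpg + 1) %in% n_pos | cpg %in% n_pos]
    if (length(near_n)) {
      warning("dropping ", length(near_n), " CpG(s) adjacent to N")
      cpg <- setdiff(cpg, near_n)
    }
  }
  inter <- cpg[cpg >= f_len + 1 & (cpg + 1) <= L - r_len]
  if (length(inter) < 2 || length(inter) > 21)
    warning("probe '", probe_id, "' has ", length(inter),
            " inter-primer CpGs (design band is 2-21, typical 3-21)")

  structure(list(
    probe_id = probe_id, region_id = region_id,
    chrom = chrom, start = as.integer(start + amp_start - 1L),
    end = as.integer(start + amp_end),
    fwd_primer = fwd_primer, rev_primer = rev_primer,
    amplicon_genomic = amp,
    ref_methylated = bisulfite_convert(amp, methylated = TRUE),
    ref_unmethylated = bisulfite_convert(amp, methylated = FALSE),
    cpg_offsets = as.integer(inter - 1L),
    fwd_len = f_len, rev_len = r_len,
    is_brca1 = isTRUE(is_brca1)), class = "PanelProbe")
}

#' @export
print.PanelProbe <- function(x, ...) {
  cat(sprintf("PanelProbe %s (region %s): %d bp amplicon, %d scored CpGs%s\n",
              x$probe_id, x$region_id, nchar(x$ref_methylated),
              length(x$cpg_offsets), if (x$is_brca1) " [BRCA1]" else ""))
  invisible(x)
}

#' Assemble a panel definition
#'
#' @param probes list of [build_probe()] objects with unique ids.
#' @param version free-form version tag.
#' @return An object of class `PanelDefinition` with elements `probes`
#'   (named list), `version` and `n_mi_eligible` (probes counted by the
#'   Methylation Index, i.e. all non-BRCA1 probes).
#' @export
panel_definition <- function(probes, version = "1") {
  stopifnot(length(probes) > 0,
            all(vapply(probes, inherits, logical(1), "PanelProbe")))
  ids <- vapply(probes, `[[`, character(1), "probe_id")
  if (anyDuplicated(ids)) stop("probe ids must be unique")
  names(probes) <- ids
  structure(list(probes = probes, version = version,
                 n_mi_eligible = sum(!vapply(probes, `[[`, logical(1), "is_brca1"))),
            class = "PanelDefinition")
}

#' @export
print.PanelDefinition <- function(x, ...) {
  cat(sprintf("PanelDefinition v%s: %d probes (%d MI-eligible)\n",
              x$version, length(x$probes), x$n_mi_eligible))
  invisible(x)
}

#' @rdname panel_definition
#' @param panel a `PanelDefinition`.
#' @export
probe_ids <- function(panel) names(panel$probes)

# -- panel I/O ----------------------------------------------------------------

#' Write / read a panel definition
#'
#' `write_panel()` emits `probes.tsv` (probe metadata and primers),
#' `amplicons_genomic.fasta` (unconverted amplicon sequences) and
#' `probes.bed` into `dir`; `read_panel()` rebuilds the panel from them via
#' [build_probe()], so converted references and CpG offsets are always
#' derived, never stored.
#'
#' @param panel a [panel_definition()].
#' @param dir directory to write to / read from.
#' @return `write_panel()` returns `dir` invisibly; `read_panel()` returns
#'   a `PanelDefinition`.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "PanelDefinition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- panel$probes
  tab <- data.frame(
    probe_id = names(p),
    region_id = vapply(p, `[[`, character(1), "region_id"),
    chrom = vapply(p, `[[`, character(1), "chrom"),
    start = vapply(p, `[[`, integer(1), "start"),
    end = vapply(p, `[[`, integer(1), "end"),
    fwd_primer = vapply(p, `[[`, character(1), "fwd_primer"),
    rev_primer = vapply(p, `[[`, character(1), "rev_primer"),
    is_brca1 = vapply(p, `[[`, logical(1), "is_brca1"),
    stringsAsFactors = FALSE)
  utils::write.table(tab, file.path(dir, "probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  seqs <- Biostrings::DNAStringSet(vapply(p, `[[`, character(1),
                                          "amplicon_genomic"))
  names(seqs) <- names(p)
  Biostrings::writeXStringSet(seqs, file.path(dir, "amplicons_genomic.fasta"))
  bed <- data.frame(tab$chrom, tab$start, tab$end, tab$probe_id)
  utils::write.table(bed, file.path(dir, "probes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_panel
#' @param version version tag for the rebuilt panel.
#' @export
read_panel <- function(dir, version = "1") {
  tab <- utils::read.delim(file.path(dir, "probes.tsv"), stringsAsFactors = FALSE)
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "amplicons_genomic.fasta"))
  probes <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$probe_id[i]
    if (!id %in% names(seqs)) stop("no amplicon sequence for probe ", id)
    build_probe(as.character(seqs[[id]]), tab$fwd_primer[i], tab$rev_primer[i],
                probe_id = id, region_id = tab$region_id[i],
                chrom = tab$chrom[i], start = tab$start[i],
                is_brca1 = tab$is_brca1[i])
  })
  panel_definition(probes, version = version)
}
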