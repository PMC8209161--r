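#' Primer design constraints
#'
#' Default constraint set for bisulfite PCR primer pairs: product size
#' 75-150 bp (short products suit highly fragmented cell-free DNA), primer
#' length 21-31 bp (optimum 28), melting temperature 64-72 degC (optimum 68)
#' with at most 5 degC difference within a pair, and at least two CpG
#' dinucleotides strictly between the primer footprints.
#'
#' @param product_min,product_max PCR product size bounds in bp.
#' @param primer_min,primer_opt,primer_max primer length bounds in bp.
#' @param tm_min,tm_opt,tm_max melting temperature bounds in degC.
#' @param tm_diff_max maximum |Tm difference| within a pair, degC.
#' @param min_inter_primer_cpgs minimum number of CpGs between the primers.
#' @return A list of class `PrimerConstraints`.
#' @export
primer_constraints <- function(product_min = 75, product_max = 150,
                               primer_min = 21, primer_opt = 28, primer_max = 31,
                               tm_min = 64, tm_opt = 68, tm_max = 72,
                               tm_diff_max = 5, min_inter_primer_cpgs = 2) {
  stopifnot(product_min < product_max, tm_min <= tm_opt, tm_opt <= tm_max,
            product_min > 0, primer_min > 0, tm_min > 0, tm_diff_max > 0,
            min_inter_primer_cpgs >= 0)
  structure(list(product_min = product_min, product_max = product_max,
                 primer_min = primer_min, primer_opt = primer_opt,
                 primer_max = primer_max, tm_min = tm_min, tm_opt = tm_opt,
                 tm_max = tm_max, tm_diff_max = tm_diff_max,
                 min_inter_primer_cpgs = min_inter_primer_cpgs),
            class = "PrimerConstraints")
}

# SantaLucia (1998) unified nearest-neighbour parameters.
# dH in kcal/mol, dS in cal/(mol K); keyed by the top-strand dinucleotide.
.nn_params <- local({
  dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
          CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  # complements share parameters
  alias <- c(TT = "AA", TG = "CA", AC = "GT", AG = "CT", TC = "GA", CC = "GG")
  list(dH = c(dH, stats::setNames(dH[alias], names(alias))),
       dS = c(dS, stats::setNames(dS[alias], names(alias))))
})

#' Nearest-neighbour melting temperature
#'
#' Duplex Tm from the unified nearest-neighbour thermodynamic parameter set
#' with terminal-base initiation terms and a sodium-concentration
#' correction (16.6 * log10\[Na+\]). Intended for ranking and constraint
#' checking of bisulfite PCR primers, not for matching any particular
#' commercial calculator.
#'
#' @param seq primer sequence (A/C/G/T), 5' to 3'.
#' @param primer_nM primer concentration in nM. Default 500.
#' @param na_mM monovalent cation concentration in mM. Default 50.
#' @return Tm in degC.
#' @export
melting_temperature <- function(seq, primer_nM = 500, na_mM = 50) {
  s <- toupper(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(chars) < 2) stop("sequence too short for a nearest-neighbour Tm")
  if (any(!chars %in% c("A", "C", "G", "T")))
    stop("Tm model accepts A/C/G/T only")
  nn <- paste0(chars[-length(chars)], chars[-1])
  dH <- sum(.nn_params$dH[nn])
  dS <- sum(.nn_params$dS[nn])
  for (term in chars[c(1, length(chars))]) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1;  dS <- dS - 2.8 }
    else                       { dH <- dH + 2.3;  dS <- dS + 4.1 }
  }
  R <- 1.987  # cal/(mol K)
  ct <- primer_nM * 1e-9
  tm_K <- dH * 1000 / (dS + R * log(ct / 4))
  tm_K - 273.15 + 16.6 * log10(na_mM / 1000)
}

#' Validate a primer pair against panel design constraints
#'
#' Checks a forward/reverse primer pair on a fully-methylated
#' bisulfite-converted amplicon: product length, primer lengths, melting
#' temperatures and their difference, the number of CpGs strictly between
#' the primer footprints, the per-primer CpG content (the methylation bias
#' of the assay comes from CpGs inside the primers), and whether either
#' primer terminates 3' on a CpG cytosine.
#'
#' @param fwd forward primer, as found on the converted top strand.
#' @param rev reverse primer; its reverse complement must occur on the
#'   converted top strand.
#' @param amplicon fully-methylated converted amplicon sequence (character),
#'   or a `PanelProbe` whose `ref_methylated` is used.
#' @param constraints a [primer_constraints()] object.
#' @param primer_nM,na_mM passed to [melting_temperature()].
#'
#' @return A list of class `primer_report`: `checks` (data.frame with
#'   columns `constraint`, `value`, `pass`), `pass` (all checks passed),
#'   `fwd_cpgs`, `rev_cpgs`, `inter_primer_cpgs`,
#'   `three_prime_cpg_flag`.
#'
#' @details In a fully-methylated converted sequence the only remaining
#'   cytosines are CpG cytosines, so CpGs are located as `CG` matches.
#' @export
validate_primer_pair <- function(fwd, rev, amplicon,
                                 constraints = primer_constraints(),
                                 primer_nM = 500, na_mM = 50) {
  if (inherits(amplicon, "PanelProbe")) amplicon <- amplicon$ref_methylated
  fwd <- toupper(fwd); rev <- toupper(rev); amplicon <- toupper(amplicon)
  rev_rc <- revcomp(rev)
  f_hit <- find_exact(amplicon, fwd)
  if (length(f_hit) != 1)
    stop("forward primer found ", length(f_hit), " times on the amplicon: ", fwd)
  r_hit <- find_exact(amplicon, rev_rc)
  if (length(r_hit) != 1)
    stop("reverse primer (reverse-complemented) found ", length(r_hit),
         " times on the amplicon: ", rev)
  f_len <- nchar(fwd); r_len <- nchar(rev)
  product_len <- (r_hit + r_len - 1) - f_hit + 1
  inter_start <- f_hit + f_len        # first base after fwd footprint (1-based)
  inter_end <- r_hit - 1              # last base before rev footprint

  cpg_pos <- find_all(amplicon, "CG")
  inter_cpgs <- sum(cpg_pos >= inter_start & cpg_pos + 1 <= inter_end)
  fwd_cpgs <- sum(cpg_pos >= f_hit & cpg_pos + 1 <= f_hit + f_len - 1)
  rev_cpgs <- sum(cpg_pos >= r_hit & cpg_pos + 1 <= r_hit + r_len - 1)
  # 3' terminal genomic positions: fwd ends at f_hit+f_len-1; the reverse
  # primer's 3' end anneals at the first base of its footprint (r_hit).
  three_prime_flag <- (f_hit + f_len - 1) %in% cpg_pos || r_hit %in% cpg_pos

  tm_f <- melting_temperature(fwd, primer_nM, na_mM)
  tm_r <- melting_temperature(rev, primer_nM, na_mM)

  cs <- constraints
  checks <- rbind(
    data.frame(constraint = "product_length", value = product_len,
               pass = product_len >= cs$product_min & product_len <= cs$product_max),
    data.frame(constraint = "fwd_length", value = f_len,
               pass = f_len >= cs$primer_min & f_len <= cs$primer_max),
    data.frame(constraint = "rev_length", value = r_len,
               pass = r_len >= cs$primer_min & r_len <= cs$primer_max),
    data.frame(constraint = "fwd_tm", value = round(tm_f, 2),
               pass = tm_f >= cs$tm_min & tm_f <= cs$tm_max),
    data.frame(constraint = "rev_tm", value = round(tm_r, 2),
               pass = tm_r >= cs$tm_min & tm_r <= cs$tm_max),
    data.frame(constraint = "tm_difference", value = round(abs(tm_f - tm_r), 2),
               pass = abs(tm_f - tm_r) <= cs$tm_diff_max),
    data.frame(constraint = "inter_primer_cpgs", value = inter_cpgs,
               pass = inter_cpgs >= cs$min_inter_primer_cpgs))
  structure(list(checks = checks, pass = all(checks$pass),
                 fwd_cpgs = fwd_cpgs, rev_cpgs = rev_cpgs,
                 inter_primer_cpgs = inter_cpgs,
                 three_prime_cpg_flag = three_prime_flag,
                 fwd_tm = tm_f, rev_tm = tm_r,
                 product_length = product_len),
            class = "primer_report")
}

#' @export
print.primer_report <- function(x, ...) {
  cat("Primer pair report:", if (x$pass) "PASS" else "FAIL", "\n")
  print(x$checks, row.names = FALSE)
  cat(sprintf("CpGs in primers: fwd %d, rev %d; 3'-on-CpG flag: %s\n",
              x$fwd_cpgs, x$rev_cpgs, x$three_prime_cpg_flag))
  invisible(x)
}
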