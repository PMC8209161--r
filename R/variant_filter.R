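#' Filter variant calls for clonal hematopoiesis (CHIP)
#'
#' Applies the CHIP inclusion/exclusion rules to annotated variant records:
#' a record passes when it is exonic, non-synonymous, has call p-value
#' < 0.01 and coverage > 50 (both strict), a variant allele fraction
#' between 0.02 and 0.43 inclusive (above ~0.43 suggests germline), is not
#' flagged in a common-SNP database, every provided minor allele frequency
#' is <= 0.02, and it is not on the visual-review blacklist.
#'
#' @param records data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `exonic` (logical), `nonsynonymous` (logical), `p_value`,
#'   `coverage`, `vaf`, `common_snp` (logical), plus any number of
#'   `maf_*` columns (e.g. `maf_global`, `maf_population`; `NA` means
#'   not provided and is ignored). A record with `NA` in a required
#'   annotation is rejected with reason `"unannotated"`.
#' @param p_max p-value bound (strict). Default 0.01.
#' @param min_coverage coverage bound (strict). Default 50.
#' @param vaf_range inclusive VAF bounds. Default `c(0.02, 0.43)`.
#' @param maf_max maximum allowed minor allele frequency. Default 0.02.
#' @param blacklist optional data.frame of `(chrom, pos, alt)` excluded
#'   sites standing in for visual IGV review.
#'
#' @return list with `pass` (the passing rows), `tally` (named integer:
#'   rejections attributed to the first failing rule, in documented order:
#'   unannotated, not_exonic, synonymous, p_value, coverage, vaf,
#'   common_snp, maf, blacklisted) and `reasons` (per-record reason, `NA`
#'   for passing records).
#'
#' @details The filter is a pure conjunction: the pass set does not depend
#'   on record or rule order; only the tally attribution follows the
#'   documented order.
#' @export
filter_chip <- function(records, p_max = 0.01, min_coverage = 50,
                        vaf_range = c(0.02, 0.43), maf_max = 0.02,
                        blacklist = NULL) {
  need <- c("exonic", "nonsynonymous", "p_value", "coverage", "vaf",
            "common_snp")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack required columns: ", paste(miss, collapse = ", "))
  n <- nrow(records)
  maf_cols <- grep("^maf", names(records), value = TRUE)
  reasons <- rep(NA_character_, n)

  unannot <- Reduce(`|`, lapply(need, function(cn) is.na(records[[cn]])))
  maf_fail <- if (length(maf_cols)) {
    m <- as.matrix(records[, maf_cols, drop = FALSE])
    apply(m, 1, function(r) any(!is.na(r) & r > maf_max))
  } else rep(FALSE, n)
  blacklisted <- rep(FALSE, n)
  if (!is.null(blacklist) && nrow(blacklist)) {
    key <- function(d) paste(d$chrom, d$pos, d$alt, sep = ":")
    blacklisted <- key(records) %in% key(blacklist)
  }

  rules <- list(
    unannotated = unannot,
    not_exonic = !unannot & !records$exonic,
    synonymous = !records$nonsynonymous,
    p_value = records$p_value >= p_max,
    coverage = records$coverage <= min_coverage,
    vaf = records$vaf < vaf_range[1] | records$vaf > vaf_range[2],
    common_snp = records$common_snp,
    maf = maf_fail,
    blacklisted = blacklisted)
  for (rule in names(rules)) {
    hit <- which(is.na(reasons) & !is.na(rules[[rule]]) & rules[[rule]])
    reasons[hit] <- rule
  }
  tally <- vapply(names(rules), function(rule)
    sum(reasons == rule, na.rm = TRUE), integer(1))
  pass <- records[is.na(reasons), , drop = FALSE]
  rownames(pass) <- NULL
  list(pass = pass, tally = tally, reasons = reasons)
}

#' Read a variant table from TSV
#'
#' @param file path to a tab-separated variant table carrying the columns
#'   described in [filter_chip()].
#' @return data.frame of variant records.
#' @export
read_variant_table <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' Read annotated variants from a VCF
#'
#' Extracts the [filter_chip()] annotation columns from VCF INFO keys.
#' Key names are configurable; flag-type keys (`exonic`, `nonsynonymous`,
#' `common_snp`) are interpreted as logical presence/`1`, the rest as
#' numeric.
#'
#' @param file path to a VCF.
#' @param info_keys named character vector mapping record columns to INFO
#'   keys.
#' @return data.frame of variant records suitable for [filter_chip()].
#' @export
read_variant_vcf <- function(file,
                             info_keys = c(gene = "GENE", exonic = "EXONIC",
                                           nonsynonymous = "NONSYN",
                                           p_value = "PV", coverage = "DP",
                                           vaf = "VAF", common_snp = "COMMON",
                                           maf_global = "MAF_G",
                                           maf_population = "MAF_P")) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package; use read_variant_table() for TSV")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  flags <- c("exonic", "nonsynonymous", "common_snp")
  info_tokens <- strsplit(vcfR::getINFO(v), ";", fixed = TRUE)
  for (col in names(info_keys)) {
    key <- info_keys[[col]]
    if (col %in% flags) {
      # flag-type keys carry no value; test token presence (KEY or KEY=1)
      out[[col]] <- vapply(info_tokens, function(tok)
        key %in% tok || paste0(key, "=1") %in% tok, logical(1))
      next
    }
    raw <- vcfR::extract.info(v, element = key)
    if (col == "gene") {
      out[[col]] <- raw
    } else {
      out[[col]] <- suppressWarnings(as.numeric(raw))
    }
  }
  out
}
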