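# -- configuration ------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters for the synthetic panel, read and cohort generators. All
#' randomness flows through R's RNG seeded once with `seed` at the top of
#' each public `simulate_*` call, so identical configurations reproduce
#' identical output byte for byte.
#'
#' @param seed integer RNG seed.
#' @param n_probes number of panel probes.
#' @param cpgs_per_probe integer range of scored (inter-primer) CpGs per
#'   probe. Default `c(3, 21)`, the design band of the assay.
#' @param amplicon_len amplicon length range in bp. Default `c(75, 150)`.
#' @param primer_len primer length range in bp. Default `c(21, 31)`.
#' @param depth_per_probe mean reads per probe (Poisson). Default 500.
#' @param tumour_fraction proportion of templates drawn from the tumour
#'   compartment. Default 0.1.
#' @param conversion_rate probability an unmethylated cytosine converts
#'   (applies to non-CpG cytosines and to CpGs on unmethylated templates;
#'   failures read as spurious methylation). Default 0.99.
#' @param meth_cpg_error probability a methylated CpG reads as converted.
#'   Default 0.005.
#' @param seq_error per-base substitution rate. Default 0.005.
#' @param short_read_fraction fraction of reads truncated (to exercise the
#'   length filter). Default 0.1.
#' @param short_read_len truncation length in bp. Default 80.
#' @param probe_meth_prob per-probe probability that the tumour compartment
#'   is methylated, modelling heterogeneity between tumours (roughly half
#'   the panel reports for a typical tumour). Default 0.6.
#' @param meth_bias methylated-template amplification weight (scalar, or a
#'   range `c(lo, hi)` sampled log-uniformly per probe), standing in for
#'   the methylation-biased primers' preference. Default 1 (no bias).
#' @param control_background_rate per-probe per-sample probability of a
#'   sporadic methylated signal in controls (independent across probes).
#'   Default 0.014.
#' @param revcomp_fraction fraction of reads emitted reverse-complemented.
#'   Default 0.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_probes = 10, cpgs_per_probe = c(3, 21),
                       amplicon_len = c(75, 150), primer_len = c(21, 31),
                       depth_per_probe = 500, tumour_fraction = 0.1,
                       conversion_rate = 0.99, meth_cpg_error = 0.005,
                       seq_error = 0.005, short_read_fraction = 0.1,
                       short_read_len = 80, probe_meth_prob = 0.6,
                       meth_bias = 1, control_background_rate = 0.014,
                       revcomp_fraction = 0) {
  probs <- c(tumour_fraction = tumour_fraction, conversion_rate = conversion_rate,
             meth_cpg_error = meth_cpg_error, seq_error = seq_error,
             short_read_fraction = short_read_fraction,
             probe_meth_prob = probe_meth_prob,
             control_background_rate = control_background_rate,
             revcomp_fraction = revcomp_fraction)
  bad <- probs[probs < 0 | probs > 1]
  if (length(bad))
    stop("probabilities outside [0,1]: ", paste(names(bad), collapse = ", "))
  stopifnot(n_probes >= 1, length(cpgs_per_probe) == 2,
            cpgs_per_probe[1] >= 1, diff(cpgs_per_probe) >= 0,
            length(amplicon_len) == 2, diff(amplicon_len) >= 0,
            length(primer_len) == 2, primer_len[1] >= 1,
            depth_per_probe > 0, all(meth_bias > 0),
            length(meth_bias) %in% c(1, 2), short_read_len >= 1)
  structure(list(seed = as.integer(seed), n_probes = as.integer(n_probes),
                 cpgs_per_probe = as.integer(cpgs_per_probe),
                 amplicon_len = as.integer(amplicon_len),
                 primer_len = as.integer(primer_len),
                 depth_per_probe = depth_per_probe,
                 tumour_fraction = tumour_fraction,
                 conversion_rate = conversion_rate,
                 meth_cpg_error = meth_cpg_error, seq_error = seq_error,
                 short_read_fraction = short_read_fraction,
                 short_read_len = as.integer(short_read_len),
                 probe_meth_prob = probe_meth_prob, meth_bias = meth_bias,
                 control_background_rate = control_background_rate,
                 revcomp_fraction = revcomp_fraction),
            class = "sim_config")
}

#' Noise-free variant of a configuration
#'
#' Convenience: switches off conversion failure, methylated-CpG miscalls,
#' substitution errors, truncation and orientation flips.
#'
#' @param config a [sim_config()].
#' @return Modified `sim_config`.
#' @export
noise_free <- function(config) {
  config$conversion_rate <- 1
  config$meth_cpg_error <- 0
  config$seq_error <- 0
  config$short_read_fraction <- 0
  config$revcomp_fraction <- 0
  config
}

# random sequence over an alphabet
rand_seq <- function(n, alphabet = c("A", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# sample() without the length-1 surprise
sample1 <- function(x) x[sample.int(length(x), 1L)]
pick <- function(x, k) x[sample.int(length(x), k)]

# genomic primer footprint of length len containing n_cpg CG units; no C
# outside the units; no CpG C at positions forbidden (1-based indices)
rand_primer_footprint <- function(len, n_cpg, forbid_c_at = integer()) {
  for (attempt in 1:50) {
    fill <- strsplit(rand_seq(len), "", fixed = TRUE)[[1]]
    if (n_cpg == 0) return(paste(fill, collapse = ""))
    # candidate C positions: CG unit occupies (p, p+1)
    cand <- setdiff(seq_len(len - 1), forbid_c_at)
    if (length(cand) < n_cpg) next
    pos <- sort(pick(cand, n_cpg))
    if (any(diff(pos) < 2)) next          # units must not overlap
    fill[pos] <- "C"; fill[pos + 1] <- "G"
    return(paste(fill, collapse = ""))
  }
  stop("could not place ", n_cpg, " CpGs in a ", len, "-bp primer footprint")
}

# inter-primer genomic region of length len with exactly n_cpg CpGs
rand_inter_region <- function(len, n_cpg) {
  n_fill <- len - 2 * n_cpg
  if (n_fill < 0) stop("inter-primer region too short for ", n_cpg, " CpGs")
  fill <- if (n_fill > 0) strsplit(rand_seq(n_fill), "", fixed = TRUE)[[1]]
          else character(0)
  cuts <- sort(sample(0:n_fill, n_cpg, replace = TRUE))
  out <- character(0)
  prev <- 0
  for (cut in cuts) {
    if (cut > prev) out <- c(out, fill[(prev + 1):cut])
    out <- c(out, "C", "G")
    prev <- cut
  }
  if (prev < n_fill) out <- c(out, fill[(prev + 1):n_fill])
  paste(out, collapse = "")
}

# -- genome + panel -----------------------------------------------------------

#' Simulate a genome and amplicon panel
#'
#' Generates a synthetic single-chromosome genome carrying
#' `config$n_probes` non-overlapping amplicons. Each amplicon has primer
#' footprints containing two or three CpGs (mimicking methylation-biased
#' primers, which average about 2.4 CpGs each) and an inter-primer region
#' with a known number of scored CpGs; outside the amplicons the genome is
#' C-free spacer so primers cannot occur off target. Product length and
#' CpG-count constraints of [primer_constraints()] hold by construction;
#' melting temperatures are advisory.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character, one chromosome), `panel`
#'   (a [panel_definition()]) and `probe_table` (per-probe truth: scored
#'   CpG count, amplicon length).
#' @export
simulate_genome_and_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  min_primer <- config$primer_len[1]
  # placing k CpGs needs >= 3k-1 bp between the primers (CG units plus gaps
  # is the worst case the generator allows: units may abut, so 2k suffices,
  # but keep headroom for fill)
  need_len <- function(k) 2 * k + 2 * min_primer
  if (need_len(config$cpgs_per_probe[1]) > config$amplicon_len[2])
    stop("infeasible configuration: ", config$cpgs_per_probe[1],
         " CpGs cannot fit in a ", config$amplicon_len[2], "-bp amplicon")
  probes <- vector("list", config$n_probes)
  chrom <- "sim_chr1"
  genome_parts <- character(0)
  pos <- 0L
  rows <- list()
  for (i in seq_len(config$n_probes)) {
    for (attempt in 1:50) {
      L <- sample1(seq(config$amplicon_len[1], config$amplicon_len[2]))
      k_max <- min(config$cpgs_per_probe[2], floor((L - 2 * min_primer) / 2))
      if (k_max < config$cpgs_per_probe[1]) next
      k <- sample1(seq(config$cpgs_per_probe[1], k_max))
      f_max <- min(config$primer_len[2], L - min_primer - 2 * k)
      f_len <- sample1(seq(min_primer, f_max))
      r_max <- min(config$primer_len[2], L - f_len - 2 * k)
      r_len <- sample1(seq(min_primer, r_max))
      inter_len <- L - f_len - r_len
      n_fcpg <- sample(2:3, 1, prob = c(0.6, 0.4))  # panel average ~2.4 CpGs/primer
      n_rcpg <- sample(2:3, 1, prob = c(0.6, 0.4))
      fwd_g <- rand_primer_footprint(f_len, n_fcpg,
                                     forbid_c_at = c(f_len - 1L, f_len))
      rev_g <- rand_primer_footprint(r_len, n_rcpg, forbid_c_at = 1L)
      inter_g <- rand_inter_region(inter_len, k)
      amp <- paste0(fwd_g, inter_g, rev_g)
      fwd_primer <- bisulfite_convert(fwd_g, methylated = TRUE)
      conv_amp <- bisulfite_convert(amp, methylated = TRUE)
      rev_primer <- revcomp(substr(conv_amp, L - r_len + 1L, L))
      if (length(find_exact(conv_amp, fwd_primer)) != 1) next
      if (length(find_exact(conv_amp, revcomp(rev_primer))) != 1) next
      spacer <- rand_seq(100)
      probe <- withCallingHandlers(
        build_probe(amp, fwd_primer, rev_primer,
                    probe_id = sprintf("probe_%02d", i),
                    region_id = sprintf("region_%02d", i),
                    chrom = chrom, start = pos + 100L),
        warning = function(w) invokeRestart("muffleWarning"))
      if (length(probe$cpg_offsets) != k) next
      probes[[i]] <- probe
      genome_parts <- c(genome_parts, spacer, amp)
      pos <- pos + 100L + L
      rows[[i]] <- data.frame(probe_id = probe$probe_id, n_cpgs = k,
                              amplicon_len = L, stringsAsFactors = FALSE)
      break
    }
    if (is.null(probes[[i]]))
      stop("failed to construct probe ", i, " under the given constraints")
  }
  genome <- stats::setNames(paste(genome_parts, collapse = ""), chrom)
  list(genome = genome, panel = panel_definition(probes),
       probe_table = do.call(rbind, rows))
}

# -- read simulation ----------------------------------------------------------

# Simulate n reads for one probe. tf: tumour-template probability before
# amplification bias; flag: tumour compartment methylated; bias: methylated
# template sampling weight. Returns list(seqs, truth).
sim_probe_reads <- function(probe, n, tf, flag, bias, config, id_prefix) {
  L <- nchar(probe$amplicon_genomic)
  g <- strsplit(probe$amplicon_genomic, "", fixed = TRUE)[[1]]
  conv <- strsplit(probe$ref_methylated, "", fixed = TRUE)[[1]]
  interior <- seq_len(L) > probe$fwd_len & seq_len(L) <= L - probe$rev_len
  cpg_c <- probe$cpg_offsets + 1L                       # scored CpG cytosines
  nonCpG_c <- which(g == "C" & interior)
  nonCpG_c <- setdiff(nonCpG_c, cpg_c)

  p_t <- if (flag) tf * bias / (tf * bias + (1 - tf)) else tf
  tumour <- stats::runif(n) < p_t
  methylated <- tumour & flag

  if (n == 0) {
    return(list(seqs = character(0),
                truth = data.frame(read_id = character(), probe_id = character(),
                                   template = character(), methylated = logical(),
                                   truncated = logical(), orientation = character(),
                                   stringsAsFactors = FALSE)))
  }
  M <- matrix(conv, nrow = L, ncol = n)                 # methylated-converted base
  # scored CpGs: per-template state with conversion noise
  if (length(cpg_c)) {
    u <- matrix(stats::runif(length(cpg_c) * n), nrow = length(cpg_c))
    meth_mat <- matrix(methylated, nrow = length(cpg_c), ncol = n, byrow = TRUE)
    # methylated template: C unless miscalled; unmethylated: T unless
    # conversion fails and leaves a C
    state <- ifelse(meth_mat, ifelse(u < config$meth_cpg_error, "T", "C"),
                    ifelse(u < config$conversion_rate, "T", "C"))
    M[cpg_c, ] <- state
  }
  # interior non-CpG cytosines: conversion failure restores C
  if (length(nonCpG_c)) {
    fail <- matrix(stats::runif(length(nonCpG_c) * n) >= config$conversion_rate,
                   nrow = length(nonCpG_c))
    if (any(fail)) {
      sub <- M[nonCpG_c, , drop = FALSE]
      sub[fail] <- "C"
      M[nonCpG_c, ] <- sub
    }
  }
  # substitution errors anywhere in the read
  if (config$seq_error > 0) {
    err <- matrix(stats::runif(L * n) < config$seq_error, nrow = L)
    if (any(err)) {
      bases <- c("A", "C", "G", "T")
      old <- match(M[err], bases)
      old[is.na(old)] <- sample(4, sum(is.na(old)), replace = TRUE)  # N etc.
      M[err] <- bases[(old - 1 + sample(1:3, sum(err), replace = TRUE)) %% 4 + 1]
    }
  }
  seqs <- apply(M, 2, paste, collapse = "")
  truncated <- stats::runif(n) < config$short_read_fraction
  seqs[truncated] <- substr(seqs[truncated], 1L,
                            pmin(config$short_read_len, nchar(seqs[truncated])))
  flipped <- stats::runif(n) < config$revcomp_fraction
  if (any(flipped)) seqs[flipped] <- revcomp(seqs[flipped])
  ids <- sprintf("%s_%s_r%05d", id_prefix, probe$probe_id, seq_len(n))
  list(seqs = seqs,
       truth = data.frame(read_id = ids, probe_id = probe$probe_id,
                          template = ifelse(tumour, "tumour", "background"),
                          methylated = methylated, truncated = truncated,
                          orientation = ifelse(flipped, "revcomp", "as-is"),
                          stringsAsFactors = FALSE))
}

# per-probe amplification bias vector from config$meth_bias
probe_bias <- function(config, n) {
  b <- config$meth_bias
  if (length(b) == 1) rep(b, n)
  else exp(stats::runif(n, log(b[1]), log(b[2])))
}

#' Simulate a targeted bisulfite read set for one sample
#'
#' Draws, for each probe, a Poisson number of reads around
#' `depth_per_probe`. Each read derives from a tumour template with
#' probability given by `tumour_fraction` (re-weighted by `meth_bias` when
#' the probe's tumour compartment is methylated) and is fully methylated or
#' fully unmethylated at the scored CpGs apart from conversion noise —
#' templates are all-or-none, as bisulfite amplicon data of clonal tumour
#' regions shows. Primer footprints always carry the methylated-converted
#' primer sequence (primers overwrite them during PCR). Substitution noise,
#' truncation and optional reverse-complement orientation follow.
#'
#' @param panel a [panel_definition()].
#' @param config a [sim_config()].
#' @param sample_id prefix for read ids.
#' @return list with `reads` (data.frame `read_id`, `seq`), `truth`
#'   (per-read origin), and `probe_truth` (per-probe: methylated-compartment
#'   flag, realized tumour-template count/fraction, bias used).
#' @export
simulate_reads <- function(panel, config, sample_id = "S1") {
  stopifnot(inherits(panel, "PanelDefinition"), inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- probe_ids(panel)
  flags <- stats::runif(length(ids)) < config$probe_meth_prob
  bias <- probe_bias(config, length(ids))
  out <- sim_sample(panel, config, sample_id,
                    tf = rep(config$tumour_fraction, length(ids)),
                    flags = flags, bias = bias)
  out
}

# shared worker: per-probe tumour fractions and flags are given
sim_sample <- function(panel, config, sample_id, tf, flags, bias) {
  ids <- probe_ids(panel)
  seqs <- list(); truth <- list(); ptruth <- list()
  for (j in seq_along(ids)) {
    probe <- panel$probes[[ids[j]]]
    n <- stats::rpois(1, config$depth_per_probe)
    r <- sim_probe_reads(probe, n, tf[j], flags[j], bias[j], config, sample_id)
    seqs[[j]] <- r$seqs
    truth[[j]] <- r$truth
    n_meth <- sum(r$truth$methylated)
    ptruth[[j]] <- data.frame(
      probe_id = ids[j], meth_flag = flags[j], tumour_fraction = tf[j],
      bias = bias[j], n_reads = n, n_methylated_templates = n_meth,
      methylated_template_fraction = if (n > 0) n_meth / n else NA_real_,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  list(reads = data.frame(read_id = truth$read_id,
                          seq = unlist(seqs, use.names = FALSE),
                          stringsAsFactors = FALSE),
       truth = truth,
       probe_truth = do.call(rbind, c(ptruth, list(make.row.names = FALSE))))
}

# -- beta-matrix simulation ---------------------------------------------------

#' Simulate a methylation-array beta matrix with planted DMRs
#'
#' Background CpGs are low-beta in every group; planted DMR clusters are
#' high-beta in a fixed fraction of tumour samples and low-beta everywhere
#' else. Cluster members are spaced `dmr_spacing` bp apart (within the
#' 300-bp pairing reach) while background CpGs sit 1000 bp apart so no
#' spurious pairing geometry exists. Values are clipped to \[0,1\].
#'
#' @param n_tumour,n_normal_per_tissue cohort sizes; normals cover breast,
#'   lung, colon and prostate.
#' @param n_cpgs total number of CpGs including planted ones.
#' @param dmr_sizes integer vector of planted cluster sizes (>= 2 each).
#' @param tumour_beta,normal_beta mean beta of methylated / unmethylated
#'   CpGs. Defaults 0.9 / 0.05.
#' @param planted_tumour_fraction fraction of tumour samples methylated at
#'   each planted DMR (deterministic count `round(f * n_tumour)`, drawn per
#'   cluster so members share carriers). Default 0.9.
#' @param noise_sd Gaussian noise sd added to every value. Default 0.02.
#' @param dmr_spacing intra-cluster CpG spacing in bp. Default 50.
#' @param seed RNG seed.
#' @return list with `beta` (a [beta_matrix()]) and `truth` (list:
#'   `planted_ids`, `regions` data.frame of planted cluster coordinates).
#' @export
simulate_beta_matrix <- function(n_tumour = 20, n_normal_per_tissue = 8,
                                 n_cpgs = 1000,
                                 dmr_sizes = c(2, 2, 3, 3, 3, 3, 4),
                                 tumour_beta = 0.9, normal_beta = 0.05,
                                 planted_tumour_fraction = 0.9,
                                 noise_sd = 0.02, dmr_spacing = 50,
                                 seed = 1L) {
  stopifnot(all(dmr_sizes >= 2), sum(dmr_sizes) < n_cpgs, dmr_spacing <= 300)
  set.seed(seed)
  n_planted <- sum(dmr_sizes)
  n_bg <- n_cpgs - n_planted
  tissues <- c("breast", "lung", "colon", "prostate")
  groups <- c(rep("tumour", n_tumour),
              rep(paste0("normal-", tissues), each = n_normal_per_tissue))
  n_samples <- length(groups)

  # lay out blocks: background singletons and planted clusters, shuffled
  blocks <- c(as.list(rep(1L, n_bg)),
              lapply(seq_along(dmr_sizes), function(i) dmr_sizes[i]))
  block_is_dmr <- c(rep(FALSE, n_bg), rep(TRUE, length(dmr_sizes)))
  ord <- sample(length(blocks))
  blocks <- blocks[ord]; block_is_dmr <- block_is_dmr[ord]

  pos <- integer(0); planted <- logical(0); block_id <- integer(0)
  cur <- 0L; dmr_counter <- 0L
  for (b in seq_along(blocks)) {
    size <- blocks[[b]]
    cur <- cur + 1000L
    if (block_is_dmr[b]) dmr_counter <- dmr_counter + 1L
    for (k in seq_len(size)) {
      pos <- c(pos, cur)
      planted <- c(planted, block_is_dmr[b])
      block_id <- c(block_id, if (block_is_dmr[b]) dmr_counter else NA_integer_)
      if (k < size) cur <- cur + as.integer(dmr_spacing)
    }
  }
  cpg_ids <- sprintf("cg%06d", seq_len(n_cpgs))

  mean_mat <- matrix(normal_beta, nrow = n_cpgs, ncol = n_samples)
  n_carriers <- round(planted_tumour_fraction * n_tumour)
  regions <- list()
  for (d in seq_len(dmr_counter)) {
    members <- which(!is.na(block_id) & block_id == d)
    carriers <- sample(n_tumour, n_carriers)
    mean_mat[members, carriers] <- tumour_beta
    regions[[d]] <- data.frame(
      dmr = d, chrom = "chr1", start = pos[members[1]],
      end = pos[members[length(members)]] + 1L,
      n_cpgs = length(members),
      member_cpgs = paste(cpg_ids[members], collapse = ","),
      stringsAsFactors = FALSE)
  }
  values <- mean_mat
  if (noise_sd > 0)
    values <- values + matrix(stats::rnorm(n_cpgs * n_samples, sd = noise_sd),
                              nrow = n_cpgs)
  values <- pmin(pmax(values, 0), 1)
  rownames(values) <- cpg_ids
  beta <- beta_matrix(values, chrom = rep("chr1", n_cpgs), pos = pos,
                      groups = groups, cpg_ids = cpg_ids)
  list(beta = beta,
       truth = list(planted_ids = cpg_ids[planted],
                    regions = do.call(rbind, regions)))
}

# -- cohort simulation --------------------------------------------------------

#' Simulate a case/control cohort of read sets
#'
#' Controls are simulated at tumour fraction 0 apart from sporadic
#' background: independently per probe and per sample, with probability
#' `control_background_rate`, a probe receives a methylated signal at a
#' random fraction between 0.2 and 0.8 (sporadic control positives are
#' random and unlinked across probes). Cases draw a sample-level tumour
#' fraction from `tumour_fraction_sampler` and per-probe
#' methylated-compartment flags with probability `probe_meth_prob`.
#'
#' @param panel a [panel_definition()].
#' @param n_cases,n_controls cohort sizes.
#' @param tumour_fraction_sampler function of `n` returning case tumour
#'   fractions. Default `runif(n, 0.05, 0.5)`.
#' @param config a [sim_config()].
#' @return list with `samples` (named list of per-sample `reads`/`truth`),
#'   `labels` (data.frame `sample_id`, `group`, `tumour_fraction`) and
#'   `probe_truth` (per-sample per-probe truth).
#' @export
simulate_cohort <- function(panel, n_cases = 20, n_controls = 20,
                            tumour_fraction_sampler = function(n)
                              stats::runif(n, 0.05, 0.5),
                            config = sim_config()) {
  stopifnot(inherits(panel, "PanelDefinition"), inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- probe_ids(panel)
  np <- length(ids)
  bias <- probe_bias(config, np)
  case_tf <- tumour_fraction_sampler(n_cases)
  samples <- list(); labels <- list(); ptruth <- list()
  for (s in seq_len(n_cases + n_controls)) {
    is_case <- s <= n_cases
    sid <- if (is_case) sprintf("case_%02d", s)
           else sprintf("control_%02d", s - n_cases)
    if (is_case) {
      tf <- rep(case_tf[s], np)
      flags <- stats::runif(np) < config$probe_meth_prob
    } else {
      sporadic <- stats::runif(np) < config$control_background_rate
      tf <- ifelse(sporadic, stats::runif(np, 0.2, 0.8), 0)
      flags <- sporadic
    }
    sim <- sim_sample(panel, config, sid, tf = tf, flags = flags, bias = bias)
    samples[[sid]] <- sim[c("reads", "truth")]
    ptruth[[sid]] <- cbind(sample_id = sid, sim$probe_truth,
                           stringsAsFactors = FALSE)
    labels[[sid]] <- data.frame(
      sample_id = sid, group = if (is_case) "case" else "control",
      tumour_fraction = if (is_case) case_tf[s] else 0,
      stringsAsFactors = FALSE)
  }
  list(samples = samples,
       labels = do.call(rbind, c(labels, list(make.row.names = FALSE))),
       probe_truth = do.call(rbind, c(ptruth, list(make.row.names = FALSE))))
}

# -- end-to-end convenience ---------------------------------------------------

#' Process one sample's reads into a report
#'
#' Chains [process_reads()] and [sample_report()].
#'
#' @param reads data.frame with `read_id`, `seq`.
#' @param panel a [panel_definition()].
#' @param sample_id sample identifier.
#' @param min_len,max_mismatches,min_identity see [process_reads()].
#' @param min_reads,fraction_threshold,mi_threshold see [sample_report()].
#' @return A [sample_report()].
#' @export
process_sample <- function(reads, panel, sample_id = "sample",
                           min_len = 100, max_mismatches = 2,
                           min_identity = 0.90, min_reads = 100,
                           fraction_threshold = 0.1, mi_threshold = 2.5) {
  pr <- process_reads(reads, panel, min_len = min_len,
                      max_mismatches = max_mismatches,
                      min_identity = min_identity)
  sample_report(sample_id, pr$callsets, panel, min_reads = min_reads,
                fraction_threshold = fraction_threshold,
                mi_threshold = mi_threshold)
}

#' Run the full pipeline over a simulated cohort
#'
#' @param cohort output of [simulate_cohort()].
#' @param panel a [panel_definition()].
#' @param ... passed to [process_sample()].
#' @return list with `reports`, `cohort` (a [cohort_matrix()]) and `roc`
#'   (a [roc_mi()] summary on the Methylation Index).
#' @export
run_cohort <- function(cohort, panel, ...) {
  reports <- lapply(names(cohort$samples), function(sid)
    process_sample(cohort$samples[[sid]]$reads, panel, sample_id = sid, ...))
  cm <- cohort_matrix(reports, cohort$labels$group)
  list(reports = reports, cohort = cm,
       roc = roc_mi(cm$mi, cm$group == "case"))
}
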