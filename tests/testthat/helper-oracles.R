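# Independent brute-force oracles used to cross-check the implementation.

# Ends-free global alignment score by plain dynamic programming, linear gap
# penalty, with a read T opposite a reference C scoring as a match.
oracle_align_score <- function(read, ref, match = 1, mismatch = -1, gap = 2) {
  p <- strsplit(read, "", fixed = TRUE)[[1]]
  s <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(p); m <- length(s)
  H <- matrix(0, n + 1, m + 1)          # free leading end gaps
  for (i in seq_len(n)) {
    sub <- ifelse(p[i] == s | (p[i] == "T" & s == "C"), match, mismatch)
    for (j in seq_len(m)) {
      H[i + 1, j + 1] <- max(H[i, j] + sub[j],
                             H[i, j + 1] - gap,
                             H[i + 1, j] - gap)
    }
  }
  max(H[n + 1, ], H[, m + 1])           # free trailing end gaps
}

# AUC by exhaustive enumeration of case-control pairs (ties count 1/2).
oracle_auc <- function(cases, controls) {
  tot <- 0
  for (x in cases) for (y in controls)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(cases) * length(controls))
}

# Single-linkage clustering of sorted positions at a distance cutoff;
# returns a list of index vectors (runs of length >= 2).
oracle_single_linkage <- function(chrom, pos, cutoff = 300) {
  groups <- list()
  cur <- 1
  for (i in seq_along(pos)[-1]) {
    if (chrom[i] == chrom[i - 1] && pos[i] - pos[i - 1] <= cutoff) {
      cur <- c(cur, i)
    } else {
      groups[[length(groups) + 1]] <- cur
      cur <- i
    }
  }
  groups[[length(groups) + 1]] <- cur
  Filter(function(g) length(g) >= 2, groups)
}

# Row-wise discovery scan applying the two selection inequalities directly.
oracle_dmr_scan <- function(beta, tumour_threshold = -0.1,
                            normal_threshold = -0.3,
                            min_tumour_fraction = 0.5) {
  v <- beta$values - 0.5
  tum <- v[, beta$groups == "tumour", drop = FALSE]
  normal_groups <- setdiff(unique(beta$groups), "tumour")
  hits <- character(0)
  for (i in seq_len(nrow(v))) {
    tv <- tum[i, ][!is.na(tum[i, ])]
    if (!length(tv)) next
    if (mean(tv > tumour_threshold) < min_tumour_fraction) next
    ok <- TRUE
    for (ng in normal_groups) {
      if (mean(v[i, beta$groups == ng], na.rm = TRUE) >= normal_threshold) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- c(hits, beta$cpg_ids[i])
  }
  hits
}

# Mutate a sequence with substitutions and indels (for alignment tests).
mutate_seq <- function(seq, n_sub = 0, n_indel = 0) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  if (n_sub > 0) {
    at <- sample(length(ch), min(n_sub, length(ch)))
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(bases, b), 1),
                     character(1))
  }
  if (n_indel > 0) {
    for (k in seq_len(n_indel)) {
      if (stats::runif(1) < 0.5 && length(ch) > 2) {
        ch <- ch[-sample(length(ch), 1)]
      } else {
        at <- sample(length(ch), 1)
        ch <- append(ch, sample(bases, 1), after = at)
      }
    }
  }
  paste(ch, collapse = "")
}
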