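# independent oracles: brute-force reference implementations kept separate
# from the code paths they validate

# two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins
fisher_enum_oracle <- function(tab) {
  tab <- as.matrix(tab)
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled ranks to the first sample (no ties assumed)
mw_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  u_all <- apply(splits, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  # rank() of the pooled sample is a permutation of 1..(nx+ny), so U over
  # splits is the exact null distribution
  lo <- mean(u_all <= u_obs); hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# brute-force count of qualifying SNVs for the TMB definition
tmb_count_oracle <- function(variants, af_min = 0.10) {
  n <- 0L
  for (i in seq_len(nrow(variants))) {
    if (variants$var_class[i] == "SNV" &&
        variants$impact[i] %in% c("high", "moderate") &&
        variants$allele_fraction[i] >= af_min) {
      n <- n + 1L
    }
  }
  n
}

# nested-loop pairwise shared-alteration counts over per-tumor gene sets
comutation_oracle <- function(gene_sets, gene_set) {
  n <- length(gene_sets)
  out <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- length(intersect(intersect(gene_sets[[i]], gene_set),
                                    intersect(gene_sets[[j]], gene_set)))
    }
  }
  out
}

# EBV > MSI > CIN/GS precedence, written as a plain conditional cascade
subtype_truth_oracle <- function(ebv_positive, msi_status, scna_count,
                                 cutoff = 4) {
  if (ebv_positive) return("EBV")
  if (msi_status == "MSI-H") return("MSI")
  if (scna_count >= cutoff) return("CIN")
  "GS"
}
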