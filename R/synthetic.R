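#' Default planted co-alteration cluster layout
#'
#' Five driver-defined clusters over the non-hypermutated pool, each with a
#' label event: ERBB2 amplification, CDKN2A/CDKN2B co-deletion (one 9p21
#' event covering both genes), and KRAS, BRCA2 and ATM mutations; the
#' remaining tumors form the background "minor alterations" cluster.
#'
#' @return data.frame `label`, `size`, `class` with a list-column `genes`.
#' @export
default_planted_clusters <- function() {
  df <- data.frame(label = c("ERBB2", "CDKN2A/B", "KRAS", "BRCA2", "ATM"),
                   size = c(25L, 10L, 10L, 9L, 12L),
                   class = c("AMP", "DEL", "SNV", "SNV", "SNV"),
                   stringsAsFactors = FALSE)
  df$genes <- list("ERBB2", c("CDKN2A", "CDKN2B"), "KRAS", "BRCA2", "ATM")
  df
}

#' Default per-gene alteration probabilities
#'
#' Cohort-level alteration frequencies of the published landscape table:
#' the twenty most frequently mutated genes and the twenty most frequent
#' gene-level copy-number alterations.
#'
#' @return data.frame `gene`, `class` (`mutation`/`AMP`/`DEL`), `freq`.
#' @export
default_gene_freqs <- function() {
  rbind(
    data.frame(gene = TABLE1_MUTATION_GENES, class = "mutation",
               freq = c(0.531, 0.159, 0.140, 0.106, 0.101, 0.097, 0.087,
                        0.082, 0.072, 0.063, 0.063, 0.058, 0.058, 0.053,
                        0.043, 0.043, 0.043, 0.043, 0.039, 0.039)),
    data.frame(gene = TABLE1_SCNA_GENES,
               class = c("AMP", "AMP", "AMP", "AMP", "DEL", "DEL", "AMP",
                         "AMP", "AMP", "AMP", "AMP", "AMP", "AMP", "AMP",
                         "AMP", "AMP", "AMP", "AMP", "DEL", "DEL"),
               freq = c(0.121, 0.068, 0.058, 0.058, 0.053, 0.053, 0.043,
                        0.024, 0.019, 0.019, 0.019, 0.019, 0.019, 0.019,
                        0.019, 0.014, 0.014, 0.014, 0.014, 0.014))
  )
}

#' Specification of a synthetic cohort
#'
#' Collects every parameter of the generator: cohort size and seed, the
#' TCGA subtype mixture, the hypermutated-set size, the planted
#' co-alteration clusters, the TMB distributions of the MSI-H and MSS arms,
#' per-gene alteration probabilities, and the emission models for MSI indel
#' counts, viral read fractions, SCNA locus counts and clinical covariates.
#' Defaults reproduce the structure of the 207-tumor study cohort; see
#' [paper_default_spec()].
#'
#' @param n_tumors cohort size.
#' @param seed integer seed governing every draw.
#' @param subtype_mixture proportions over EBV/MSI/CIN/GS, summing to 1.
#' @param n_hypermutated size of the hypermutated set; must cover the MSI
#'   arm (every MSI-H tumor is hypermutated under a min-derived cutoff).
#' @param planted_clusters data.frame as [default_planted_clusters()].
#' @param within_prob probability that a planted tumor carries its label
#'   event.
#' @param background_prob probability that a background tumor carries a
#'   given label event (events are mutually exclusive per tumor, the usual
#'   driver-exclusivity pattern).
#' @param tmb_msih,tmb_mss TMB range (counts/Mb) of each arm.
#' @param tmb_shape `"uniform"` over the range, or `"triangular"` peaked at
#'   the arm medians `tmb_msih_mode`/`tmb_mss_mode`.
#' @param tmb_msih_mode,tmb_mss_mode triangular modes (arm medians).
#' @param gene_freqs data.frame as [default_gene_freqs()].
#' @param subtype_enrichment data.frame `gene`, `subtype`, `multiplier`
#'   applied to `gene_freqs` probabilities; the default enriches TP53
#'   mutation in CIN and depletes it in GS, with multipliers whose
#'   mixture-weighted mean is close to 1 so the cohort-wide frequency
#'   keeps its nominal value.
#' @param actionable_nonhyper_factor factor applied to actionable-gene
#'   probabilities in non-hypermutated tumors (actionable mutations
#'   concentrate in the hypermutated arm).
#' @param actionable_hyper_boost multiplier applied to actionable-gene
#'   probabilities in hypermutated tumors, chosen so the cohort-wide
#'   frequency stays near the nominal value
#'   (`(175 * 0.35 + 32 * 4.5) / 207` is approximately 1).
#' @param msi_threshold,msi_indel_mean_msih,msi_indel_mean_mss MSI model:
#'   Poisson means of the two arms, clamped to the correct side of the
#'   threshold.
#' @param viral list: `ebv_positive_range` (uniform % range for intended
#'   EBV tumors), `ebv_background_prob`/`ebv_background_max` (sub-cutoff
#'   noise), `hpv_background_prob`.
#' @param scna list: `cin_extra_loci_mean` (Poisson extra loci beyond the
#'   SCNA-high floor of 4), `gs_max_loci`, `gain_fold_range`,
#'   `loss_fold_range`, `neutral_fold_range`, `neutral_mean`.
#' @param noise list of Poisson means for non-qualifying variant noise:
#'   `low_af`, `silent`, `indel_mss`, `indel_msih_extra`.
#' @param clinical list: `male_prop`, `age_mean`, `age_sd`, `age_range`,
#'   `lauren_by_subtype` (matrix of intestinal/diffuse/mixed proportions),
#'   `stage_probs`.
#' @param roi_size_mb captured region size in Mb.
#' @param panel a [gene_panel]; defaults to [synthetic_panel()].
#' @return object of class `cohort_spec`.
#' @export
synthetic_cohort_spec <- function(
    n_tumors = 207L, seed = 1L,
    subtype_mixture = c(EBV = 0.04, MSI = 0.08, CIN = 0.58, GS = 0.30),
    n_hypermutated = 32L,
    planted_clusters = default_planted_clusters(),
    within_prob = 0.9, background_prob = 0.05,
    tmb_msih = c(18.5, 66.9), tmb_mss = c(3.1, 27.7),
    tmb_shape = c("uniform", "triangular"),
    tmb_msih_mode = 31.5, tmb_mss_mode = 11.2,
    gene_freqs = default_gene_freqs(),
    subtype_enrichment = data.frame(
      gene = c("TP53", "TP53"), subtype = c("CIN", "GS"),
      multiplier = c(1.3, 0.35)),
    actionable_nonhyper_factor = 0.35, actionable_hyper_boost = 4.5,
    msi_threshold = 20L, msi_indel_mean_msih = 45, msi_indel_mean_mss = 3,
    viral = list(ebv_positive_range = c(0.001, 0.05),
                 ebv_background_prob = 0.1, ebv_background_max = 4e-4,
                 hpv_background_prob = 0.02),
    scna = list(cin_extra_loci_mean = 2, gs_max_loci = 3L,
                gain_fold_range = c(2.6, 8), loss_fold_range = c(0.2, 0.7),
                neutral_fold_range = c(0.8, 2.3), neutral_mean = 2),
    noise = list(low_af = 1.5, silent = 1, indel_mss = 0.5,
                 indel_msih_extra = 6),
    clinical = list(male_prop = 146 / 207, age_mean = 66, age_sd = 10,
                    age_range = c(27, 87),
                    lauren_by_subtype = rbind(
                      EBV = c(0.45, 0.35, 0.20), MSI = c(0.45, 0.35, 0.20),
                      CIN = c(0.65, 0.20, 0.15), GS = c(0.20, 0.65, 0.15)),
                    stage_probs = c(I = 0.2, II = 0.3, III = 0.3, IV = 0.2)),
    roi_size_mb = 1.7, panel = NULL) {
  tmb_shape <- match.arg(tmb_shape)
  if (is.null(panel)) panel <- synthetic_panel(roi_size_mb)
  if (abs(sum(subtype_mixture) - 1) > 1e-9) {
    stop("subtype_mixture must sum to 1", call. = FALSE)
  }
  if (any(subtype_mixture < 0)) stop("mixture proportions must be >= 0", call. = FALSE)
  probs <- c(within_prob, background_prob, gene_freqs$freq)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  if (n_hypermutated > n_tumors) stop("n_hypermutated exceeds n_tumors", call. = FALSE)
  if (sum(planted_clusters$size) > n_tumors - n_hypermutated) {
    stop("planted cluster sizes exceed the non-hypermutated pool", call. = FALSE)
  }
  bad_genes <- setdiff(c(unlist(planted_clusters$genes), gene_freqs$gene),
                       panel$genes)
  if (length(bad_genes) > 0) {
    stop("spec references genes outside the panel: ",
         paste(bad_genes, collapse = ", "), call. = FALSE)
  }
  structure(list(
    n_tumors = as.integer(n_tumors), seed = as.integer(seed),
    subtype_mixture = subtype_mixture, n_hypermutated = as.integer(n_hypermutated),
    planted_clusters = planted_clusters, within_prob = within_prob,
    background_prob = background_prob, tmb_msih = tmb_msih, tmb_mss = tmb_mss,
    tmb_shape = tmb_shape, tmb_msih_mode = tmb_msih_mode,
    tmb_mss_mode = tmb_mss_mode, gene_freqs = gene_freqs,
    subtype_enrichment = subtype_enrichment,
    actionable_nonhyper_factor = actionable_nonhyper_factor,
    actionable_hyper_boost = actionable_hyper_boost,
    msi_threshold = as.integer(msi_threshold),
    msi_indel_mean_msih = msi_indel_mean_msih,
    msi_indel_mean_mss = msi_indel_mean_mss,
    viral = viral, scna = scna, noise = noise, clinical = clinical,
    roi_size_mb = roi_size_mb, panel = panel), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> n=%d, seed=%d, hypermutated=%d, ",
                     "%d planted clusters, ROI %.2f Mb\n"),
              x$n_tumors, x$seed, x$n_hypermutated,
              nrow(x$planted_clusters), x$roi_size_mb))
  invisible(x)
}

#' Study-default synthetic cohort specification
#'
#' The generator parameterized to the published cohort structure: 207
#' tumors, subtype mixture 4/8/58/30% (EBV/MSI/CIN/GS), 32 hypermutated
#' tumors, MSI-H TMB on 18.5-66.9 counts/Mb vs MSS on 3.1-27.7, and five
#' planted actionable-gene clusters of sizes 25/10/10/9/12 over the
#' 175-tumor non-hypermutated pool.
#'
#' @param seed integer seed.
#' @return a `cohort_spec`.
#' @export
paper_default_spec <- function(seed = 1L) {
  synthetic_cohort_spec(seed = seed)
}

# largest-remainder apportionment of n into round(p * n) with sum n
apportion <- function(n, p) {
  raw <- p * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  stats::setNames(as.integer(base), names(p))
}

rtriangular <- function(n, lo, mode, hi) {
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc, lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

rdunif <- function(lo, hi) {
  if (hi <= lo) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

random_protein_change <- function(n) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  sprintf("p.%s%d%s", sample(aa, n, replace = TRUE),
          sample.int(900L, n, replace = TRUE) + 10L,
          sample(aa, n, replace = TRUE))
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a full cohort from a [synthetic_cohort_spec()]: intended TCGA
#' subtypes by largest-remainder apportionment of the mixture, a designated
#' hypermutated set covering the whole MSI arm, planted co-alteration
#' clusters over the non-hypermutated pool, and per-tumor variant,
#' copy-number, viral, microsatellite and clinical emissions consistent
#' with those intents. Identical seeds give identical cohorts.
#'
#' Mutation counts are drawn as discrete uniform (or triangular) over the
#' count range implied by the arm's TMB interval, so the realized TMB of
#' every designated hypermutated tumor lies at or above the MSI-H arm
#' minimum and every non-hypermutated tumor below it.
#'
#' The ground-truth cluster of a non-hypermutated tumor is its *realized*
#' label-event content (clusters are defined by observed alterations, so a
#' background tumor that received an ERBB2 amplification belongs to the
#' ERBB2 cluster).
#'
#' @param spec a `cohort_spec`.
#' @return list with elements `cohort` (a [gc_cohort]) and `truth`
#'   (data.frame `tumor_id`, `subtype`, `hypermutated`, `cluster`, `tmb`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  panel <- spec$panel
  roi <- spec$roi_size_mb
  n <- spec$n_tumors
  ids <- sprintf("T%04d", seq_len(n))

  # intended subtypes and the designated hypermutated set
  counts <- apportion(n, spec$subtype_mixture)
  subtype <- sample(rep(names(counts), counts))
  is_msi <- subtype == "MSI"
  if (sum(is_msi) > spec$n_hypermutated) {
    stop("n_hypermutated must cover the MSI arm", call. = FALSE)
  }
  hyper <- is_msi
  extra_needed <- spec$n_hypermutated - sum(is_msi)
  if (extra_needed > 0) {
    hyper[sample(which(!is_msi), extra_needed)] <- TRUE
  }

  # planted clusters over the non-hypermutated pool; remaining tumors are
  # background and may carry one label event at background_prob each
  pc <- spec$planted_clusters
  planted <- rep(NA_integer_, n)
  pool <- sample(which(!hyper))
  offset <- 0L
  for (j in seq_len(nrow(pc))) {
    take <- pool[offset + seq_len(pc$size[j])]
    planted[take] <- j
    offset <- offset + pc$size[j]
  }
  n_events <- nrow(pc)

  label_genes <- unique(unlist(pc$genes))
  actionable <- panel$actionable
  gf <- spec$gene_freqs
  enrich <- spec$subtype_enrichment
  nonact_pool <- setdiff(panel$genes, actionable)
  # filler/noise mutations land on genes without a modeled frequency, so
  # the frequency table stays governed by gene_freqs and the planting model
  freq_genes <- unique(gf$gene)
  fill_nonhyper <- setdiff(nonact_pool, freq_genes)
  fill_hyper <- setdiff(panel$genes, c(freq_genes, label_genes))

  # TMB count bounds per arm (counts, not rates, so sides of the
  # hypermutation boundary are exact)
  lo_h <- as.integer(ceiling(spec$tmb_msih[1] * roi))
  hi_msi <- max(lo_h, as.integer(floor(spec$tmb_msih[2] * roi)))
  hi_mss_hyper <- max(lo_h, as.integer(floor(spec$tmb_mss[2] * roi)))
  lo_n <- as.integer(ceiling(spec$tmb_mss[1] * roi))
  hi_n <- max(lo_n, min(as.integer(floor(spec$tmb_mss[2] * roi)), lo_h - 1L))

  draw_count <- function(lo, hi, mode_rate) {
    if (hi <= lo) return(lo)
    if (spec$tmb_shape == "triangular") {
      mode_count <- min(max(mode_rate * roi, lo), hi)
      min(max(as.integer(round(rtriangular(1, lo, mode_count, hi))), lo), hi)
    } else {
      rdunif(lo, hi)
    }
  }

  # draw mutation-count targets up front: the MSI arm first, so designated
  # hypermutated MSS tumors can be bounded below by the realized MSI
  # minimum (the derived cutoff) and the hypermutated set stays intact
  target_counts <- integer(n)
  for (i in which(is_msi)) {
    target_counts[i] <- draw_count(lo_h, hi_msi, spec$tmb_msih_mode)
  }
  min_msi <- if (any(is_msi)) min(target_counts[is_msi]) else lo_h
  for (i in which(hyper & !is_msi)) {
    lo_i <- max(lo_h, min_msi)
    target_counts[i] <- draw_count(lo_i, max(hi_mss_hyper, lo_i),
                                   spec$tmb_mss_mode)
  }
  for (i in which(!hyper)) {
    target_counts[i] <- draw_count(lo_n, hi_n, spec$tmb_mss_mode)
  }

  tumors <- vector("list", n)
  truth_cluster <- rep(NA_character_, n)
  realized_tmb <- numeric(n)

  for (i in seq_len(n)) {
    st <- subtype[i]
    # --- label event -------------------------------------------------------
    event <- 0L
    if (!hyper[i]) {
      if (!is.na(planted[i])) {
        if (stats::runif(1) < spec$within_prob) event <- planted[i]
      } else if (n_events > 0) {
        u <- stats::runif(1)
        if (u < n_events * spec$background_prob) {
          event <- as.integer(ceiling(u / spec$background_prob))
        }
      }
      truth_cluster[i] <- if (event > 0L) pc$label[event] else "none"
    }

    mut_genes <- character(); mut_pc <- character()
    cnv_gene <- character(); cnv_fold <- numeric()

    if (event > 0L) {
      ev_genes <- pc$genes[[event]]
      if (pc$class[event] == "SNV") {
        mut_genes <- ev_genes
      } else if (pc$class[event] == "AMP") {
        cnv_gene <- ev_genes
        cnv_fold <- stats::runif(length(ev_genes),
                                 spec$scna$gain_fold_range[1],
                                 spec$scna$gain_fold_range[2])
      } else {
        cnv_gene <- ev_genes
        cnv_fold <- stats::runif(length(ev_genes),
                                 spec$scna$loss_fold_range[1],
                                 spec$scna$loss_fold_range[2])
      }
    }

    # --- frequency-driven alterations -------------------------------------
    for (r in seq_len(nrow(gf))) {
      g <- gf$gene[r]
      if (!hyper[i] && g %in% label_genes) next  # planting governs these
      p <- gf$freq[r]
      m <- enrich$multiplier[enrich$gene == g & enrich$subtype == st]
      if (length(m) == 1L) p <- p * m
      if (g %in% actionable && !g %in% label_genes) {
        p <- p * if (hyper[i]) spec$actionable_hyper_boost else spec$actionable_nonhyper_factor
      }
      if (stats::runif(1) >= min(p, 1)) next
      if (gf$class[r] == "mutation") {
        if (!g %in% mut_genes) mut_genes <- c(mut_genes, g)
      } else if (!g %in% cnv_gene) {
        rng <- if (gf$class[r] == "AMP") spec$scna$gain_fold_range else spec$scna$loss_fold_range
        cnv_gene <- c(cnv_gene, g)
        cnv_fold <- c(cnv_fold, stats::runif(1, rng[1], rng[2]))
      }
    }

    # --- TMB filler mutations ----------------------------------------------
    target <- target_counts[i]
    fill_pool <- if (hyper[i]) fill_hyper else fill_nonhyper
    need <- target - length(mut_genes)
    if (need > 0) {
      avail <- setdiff(fill_pool, mut_genes)
      mut_genes <- c(mut_genes, sample(avail, min(need, length(avail))))
    }
    n_mut <- length(mut_genes)
    realized_tmb[i] <- n_mut / roi

    # --- variant table: qualifying SNVs plus filtered-out noise ------------
    v_gene <- mut_genes
    v_class <- rep("SNV", n_mut)
    v_af <- stats::runif(n_mut, 0.10, 0.90)
    v_imp <- sample(c("high", "moderate"), n_mut, replace = TRUE,
                    prob = c(0.35, 0.65))
    noise_pool <- fill_pool
    n_low <- stats::rpois(1, spec$noise$low_af)
    if (n_low > 0) {
      v_gene <- c(v_gene, sample(noise_pool, n_low, replace = TRUE))
      v_class <- c(v_class, rep("SNV", n_low))
      v_af <- c(v_af, stats::runif(n_low, 0.01, 0.095))
      v_imp <- c(v_imp, sample(c("high", "moderate"), n_low, replace = TRUE))
    }
    n_sil <- stats::rpois(1, spec$noise$silent)
    if (n_sil > 0) {
      v_gene <- c(v_gene, sample(noise_pool, n_sil, replace = TRUE))
      v_class <- c(v_class, rep("SNV", n_sil))
      v_af <- c(v_af, stats::runif(n_sil, 0.10, 0.90))
      v_imp <- c(v_imp, sample(c("silent", "low"), n_sil, replace = TRUE))
    }
    n_ind <- stats::rpois(1, spec$noise$indel_mss) +
      if (is_msi[i]) 2L + stats::rpois(1, spec$noise$indel_msih_extra) else 0L
    if (n_ind > 0) {
      v_gene <- c(v_gene, sample(noise_pool, n_ind, replace = TRUE))
      v_class <- c(v_class, sample(c("insertion", "deletion"), n_ind,
                                   replace = TRUE))
      v_af <- c(v_af, stats::runif(n_ind, 0.10, 0.90))
      v_imp <- c(v_imp, sample(c("high", "moderate"), n_ind, replace = TRUE))
    }
    variants <- variant_calls(v_gene, v_class, v_af, v_imp,
                              random_protein_change(length(v_gene)))

    # --- copy-number table: enforce the intended SCNA stratum --------------
    n_loci <- length(cnv_gene)
    planted_cnv <- if (event > 0L && pc$class[event] != "SNV") pc$genes[[event]] else character()
    if (st == "CIN") {
      target_loci <- 4L + stats::rpois(1, spec$scna$cin_extra_loci_mean)
      if (n_loci < target_loci) {
        pad_pool <- setdiff(fill_nonhyper, c(cnv_gene, mut_genes))
        add <- sample(pad_pool, min(target_loci - n_loci, length(pad_pool)))
        gains <- stats::runif(length(add)) < 0.7
        cnv_gene <- c(cnv_gene, add)
        cnv_fold <- c(cnv_fold, ifelse(
          gains,
          stats::runif(length(add), spec$scna$gain_fold_range[1],
                       spec$scna$gain_fold_range[2]),
          stats::runif(length(add), spec$scna$loss_fold_range[1],
                       spec$scna$loss_fold_range[2])))
      }
    } else if (st == "GS" && n_loci > spec$scna$gs_max_loci) {
      # trim frequency-driven events first; planted label events survive
      removable <- which(!cnv_gene %in% planted_cnv)
      n_drop <- min(n_loci - spec$scna$gs_max_loci, length(removable))
      if (n_drop > 0) {
        drop <- removable[seq_len(n_drop)]
        cnv_gene <- cnv_gene[-drop]
        cnv_fold <- cnv_fold[-drop]
      }
    }
    n_neutral <- stats::rpois(1, spec$scna$neutral_mean)
    if (n_neutral > 0) {
      pad_pool <- setdiff(fill_nonhyper, c(cnv_gene, mut_genes))
      add <- sample(pad_pool, min(n_neutral, length(pad_pool)))
      cnv_gene <- c(cnv_gene, add)
      cnv_fold <- c(cnv_fold, stats::runif(length(add),
                                           spec$scna$neutral_fold_range[1],
                                           spec$scna$neutral_fold_range[2]))
    }
    cnvs <- copy_number_calls(cnv_gene, cnv_fold)

    # --- MSI, viral and clinical emissions ---------------------------------
    msi_count <- if (is_msi[i]) {
      max(stats::rpois(1, spec$msi_indel_mean_msih), spec$msi_threshold)
    } else {
      min(stats::rpois(1, spec$msi_indel_mean_mss), spec$msi_threshold - 1L)
    }
    ebv <- if (st == "EBV") {
      stats::runif(1, spec$viral$ebv_positive_range[1],
                   spec$viral$ebv_positive_range[2])
    } else if (stats::runif(1) < spec$viral$ebv_background_prob) {
      stats::runif(1, 0, spec$viral$ebv_background_max)
    } else 0
    hpv16 <- if (stats::runif(1) < spec$viral$hpv_background_prob) {
      stats::runif(1, 0, 0.018)
    } else 0
    hpv18 <- if (stats::runif(1) < spec$viral$hpv_background_prob) {
      stats::runif(1, 0, 0.009)
    } else 0

    cl <- spec$clinical
    lauren <- sample(c("intestinal", "diffuse", "mixed"), 1,
                     prob = cl$lauren_by_subtype[st, ])
    age <- round(min(max(stats::rnorm(1, cl$age_mean, cl$age_sd),
                         cl$age_range[1]), cl$age_range[2]))
    tumors[[i]] <- tumor_profile(
      ids[i], variants = variants, cnvs = cnvs,
      viral = c(ebv_pct = ebv, hpv16_pct = hpv16, hpv18_pct = hpv18),
      msi_indel_count = msi_count,
      clinical = list(age = age,
                      sex = if (stats::runif(1) < cl$male_prop) "M" else "F",
                      lauren_type = lauren,
                      stage = sample(names(cl$stage_probs), 1,
                                     prob = cl$stage_probs)))
  }

  truth <- data.frame(tumor_id = ids, subtype = subtype,
                      hypermutated = hyper, cluster = truth_cluster,
                      tmb = realized_tmb, stringsAsFactors = FALSE)
  list(cohort = gc_cohort(panel, tumors), truth = truth)
}
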