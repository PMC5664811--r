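#' Tumor mutational burden
#'
#' TMB is the rate of peptide-changing SNVs per megabase of captured
#' region: only single-nucleotide variants with allele fraction at or above
#' `af_min` and high or moderate putative impact are counted; indels and
#' silent/low-impact variants are excluded.
#'
#' @param variants data.frame from [variant_calls()].
#' @param roi_size_mb positive number, captured region size in Mb.
#' @param af_min minimum allele fraction (default 0.10).
#' @return TMB in counts/Mb.
#' @examples
#' v <- variant_calls(c("TP53", "KRAS"), c("SNV", "SNV"), c(0.4, 0.05),
#'                    c("high", "high"))
#' compute_tmb(v, roi_size_mb = 1.0) # only the AF 0.4 call counts
#' @export
compute_tmb <- function(variants, roi_size_mb, af_min = 0.10) {
  if (!is_scalar_number(roi_size_mb) || roi_size_mb <= 0) {
    stop("roi_size_mb must be a positive number", call. = FALSE)
  }
  if (!is_scalar_number(af_min) || af_min < 0 || af_min > 1) {
    stop("af_min must be in [0, 1]", call. = FALSE)
  }
  n <- sum(variants$var_class == "SNV" &
             variants$impact %in% c("high", "moderate") &
             variants$allele_fraction >= af_min)
  n / roi_size_mb
}

#' Microsatellite instability call
#'
#' A tumor is MSI-high when its indel count over the tandem-repeat locus
#' panel reaches the threshold (inclusive), otherwise microsatellite
#' stable.
#'
#' @param msi_indel_count non-negative integer vector.
#' @param msi_threshold positive integer; the default of 20 indels is a
#'   configuration value calibrated so the synthetic generator's arms
#'   separate cleanly (the locus-panel design itself carries no published
#'   cutoff).
#' @return character vector, `"MSI-H"` or `"MSS"`.
#' @export
call_msi <- function(msi_indel_count, msi_threshold = 20) {
  if (any(!is.finite(msi_indel_count)) || any(msi_indel_count < 0)) {
    stop("msi_indel_count must be non-negative", call. = FALSE)
  }
  if (!is_scalar_number(msi_threshold) || msi_threshold < 1) {
    stop("msi_threshold must be >= 1", call. = FALSE)
  }
  ifelse(msi_indel_count >= msi_threshold, "MSI-H", "MSS")
}

#' Default viral positivity cutoffs (% of total reads)
#' @export
default_viral_cutoffs <- function() c(hpv16 = 0.02, hpv18 = 0.01, ebv = 0.0005)

#' Viral positivity calls
#'
#' A sample is positive for a virus when the percentage of total reads
#' mapped to that viral genome reaches the empirical cutoff (inclusive).
#'
#' @param viral named numeric `c(ebv_pct=, hpv16_pct=, hpv18_pct=)`.
#' @param cutoffs named numeric `c(hpv16=, hpv18=, ebv=)`, percentages.
#' @return named logical `c(ebv_positive=, hpv16_positive=, hpv18_positive=)`.
#' @export
call_viral <- function(viral, cutoffs = default_viral_cutoffs()) {
  if (any(viral < 0)) stop("viral fractions must be >= 0", call. = FALSE)
  c(ebv_positive = unname(viral[["ebv_pct"]] >= cutoffs[["ebv"]]),
    hpv16_positive = unname(viral[["hpv16_pct"]] >= cutoffs[["hpv16"]]),
    hpv18_positive = unname(viral[["hpv18_pct"]] >= cutoffs[["hpv18"]]))
}

#' Somatic copy-number call from fold change
#'
#' Gains are fold changes strictly above `gain_threshold` (default 2.5),
#' losses strictly below `loss_threshold` (default 0.75); everything in
#' between is neutral. The three intervals partition the positive axis.
#'
#' @param fold_change positive numeric vector of read-depth fold changes.
#' @param gain_threshold,loss_threshold calling thresholds.
#' @return character vector over `gain`/`loss`/`neutral`.
#' @export
call_scna <- function(fold_change, gain_threshold = 2.5, loss_threshold = 0.75) {
  if (any(!is.finite(fold_change)) || any(fold_change <= 0)) {
    stop("fold_change must be positive", call. = FALSE)
  }
  ifelse(fold_change > gain_threshold, "gain",
         ifelse(fold_change < loss_threshold, "loss", "neutral"))
}

#' Number of SCNA loci in a tumor
#'
#' Counts distinct genes called gain or loss; repeated rows on the same
#' gene count once.
#'
#' @param cnvs data.frame from [copy_number_calls()].
#' @return non-negative integer.
#' @export
count_scna_loci <- function(cnvs) {
  length(unique(cnvs$gene[cnvs$call %in% c("gain", "loss")]))
}

#' Per-tumor biomarker table for a cohort
#'
#' Runs the four biomarker callers over every tumor and returns one row per
#' tumor: TMB, MSI status, the three viral positivity flags and the SCNA
#' locus count.
#'
#' @param cohort a [gc_cohort].
#' @param af_min TMB allele-fraction filter.
#' @param msi_threshold MSI indel-count threshold.
#' @param viral_cutoffs see [call_viral()].
#' @param gain_threshold,loss_threshold copy-number thresholds; fold
#'   changes are re-called so the thresholds given here always govern.
#' @return data.frame with columns `tumor_id`, `tmb`, `msi_status`,
#'   `ebv_positive`, `hpv16_positive`, `hpv18_positive`, `scna_locus_count`.
#' @export
compute_biomarkers <- function(cohort, af_min = 0.10, msi_threshold = 20,
                               viral_cutoffs = default_viral_cutoffs(),
                               gain_threshold = 2.5, loss_threshold = 0.75) {
  roi <- cohort$panel$roi_size_mb
  rows <- lapply(cohort$tumors, function(t) {
    cn <- t$cnvs
    if (nrow(cn) > 0L) {
      cn$call <- call_scna(cn$fold_change, gain_threshold, loss_threshold)
    }
    vir <- call_viral(t$viral, viral_cutoffs)
    data.frame(tumor_id = t$tumor_id,
               tmb = compute_tmb(t$variants, roi, af_min),
               msi_status = call_msi(t$msi_indel_count, msi_threshold),
               ebv_positive = vir[["ebv_positive"]],
               hpv16_positive = vir[["hpv16_positive"]],
               hpv18_positive = vir[["hpv18_positive"]],
               scna_locus_count = count_scna_loci(cn))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
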