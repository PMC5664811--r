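#' TCGA molecular subtype decision tree
#'
#' Assigns each tumor one of the four TCGA gastric-cancer subtypes with
#' precedence EBV > MSI > CIN/GS: EBV-positive tumors are EBV subtype;
#' of the rest, MSI-high tumors are MSI subtype; the remainder are split by
#' SCNA burden, with `scna_locus_count >= scna_cutoff` (default four loci)
#' giving CIN and the rest GS. Every tumor receives exactly one subtype.
#'
#' @param biomarkers data.frame from [compute_biomarkers()] (or any frame
#'   with `ebv_positive`, `msi_status`, `scna_locus_count`).
#' @param scna_cutoff SCNA-high cutoff in loci (default 4).
#' @return character vector of subtypes (`EBV`/`MSI`/`CIN`/`GS`), one per row.
#' @export
classify_tcga <- function(biomarkers, scna_cutoff = 4) {
  ifelse(biomarkers$ebv_positive, "EBV",
         ifelse(biomarkers$msi_status == "MSI-H", "MSI",
                ifelse(biomarkers$scna_locus_count >= scna_cutoff,
                       "CIN", "GS")))
}

#' Hypermutation cutoff from the MSI-H arm
#'
#' The hypermutation cutoff is derived from the data as the minimum TMB
#' among MSI-high tumors, so that by construction every MSI-H tumor is
#' hypermutated and tumors of other subtypes can join the hypermutated set.
#'
#' @param biomarkers data.frame with `tmb` and `msi_status` columns.
#' @return the cutoff in counts/Mb.
#' @export
derive_hypermutation_cutoff <- function(biomarkers) {
  tmb_msih <- biomarkers$tmb[biomarkers$msi_status == "MSI-H"]
  if (length(tmb_msih) == 0L) {
    stop("no MSI-H tumor in the cohort; supply an explicit hypermutation ",
         "cutoff instead of deriving one", call. = FALSE)
  }
  min(tmb_msih)
}

#' Flag hypermutated tumors
#'
#' The comparison is inclusive (`tmb >= cutoff`): the MSI-H tumor that
#' defines the derived cutoff is itself hypermutated, which matches the
#' composition where the hypermutated set contains the whole MSI arm.
#' Set `inclusive = FALSE` for a strict reading.
#'
#' @param tmb numeric vector of TMB values (counts/Mb).
#' @param cutoff positive cutoff in counts/Mb.
#' @param inclusive logical; include tumors exactly at the cutoff.
#' @return logical vector.
#' @export
flag_hypermutated <- function(tmb, cutoff, inclusive = TRUE) {
  if (!is_scalar_number(cutoff) || cutoff <= 0) {
    stop("cutoff must be a positive number", call. = FALSE)
  }
  if (inclusive) tmb >= cutoff else tmb > cutoff
}

#' Subtype and hypermutation calls for a whole cohort
#'
#' @param biomarkers data.frame from [compute_biomarkers()].
#' @param scna_cutoff SCNA-high cutoff in loci.
#' @param hypermutation_cutoff `"auto"` to derive it with
#'   [derive_hypermutation_cutoff()], or an explicit counts/Mb value.
#' @return data.frame `tumor_id`, `subtype`, `hypermutated`, `tmb`,
#'   `scna_locus_count`; the cutoff used is attached as attribute
#'   `"hypermutation_cutoff"`.
#' @export
classify_cohort <- function(biomarkers, scna_cutoff = 4,
                            hypermutation_cutoff = "auto") {
  cutoff <- if (identical(hypermutation_cutoff, "auto")) {
    derive_hypermutation_cutoff(biomarkers)
  } else {
    as.numeric(hypermutation_cutoff)
  }
  out <- data.frame(tumor_id = biomarkers$tumor_id,
                    subtype = classify_tcga(biomarkers, scna_cutoff),
                    hypermutated = flag_hypermutated(biomarkers$tmb, cutoff),
                    tmb = biomarkers$tmb,
                    scna_locus_count = biomarkers$scna_locus_count)
  attr(out, "hypermutation_cutoff") <- cutoff
  out
}

#' Derive the SCNA-high cutoff from TP53 and histology
#'
#' The CIN/GS boundary is chosen so that SCNA-high tumors align with TP53
#' mutation (a CIN hallmark) and SCNA-low tumors with diffuse Lauren
#' histology (a GS hallmark). Each candidate cutoff k in `candidate_range`
#' is scored by the product of two two-tailed Fisher p-values — association
#' of (SCNA count >= k) with TP53 mutation and of (SCNA count < k) with
#' diffuse type — and the k minimizing the product wins; ties break toward
#' smaller k.
#'
#' @param cohort a [gc_cohort] (provides TP53 status and Lauren type).
#' @param biomarkers data.frame from [compute_biomarkers()].
#' @param candidate_range integer candidates (default 1:10).
#' @return the selected cutoff (integer); the per-candidate score table is
#'   attached as attribute `"scan"`.
#' @export
derive_scna_cutoff <- function(cohort, biomarkers, candidate_range = 1:10) {
  ids <- biomarkers$tumor_id
  loci <- biomarkers$scna_locus_count
  tp53 <- vapply(cohort$tumors[ids], function(t) {
    any(t$variants$gene == "TP53" &
          t$variants$impact %in% c("high", "moderate"))
  }, logical(1))
  diffuse <- vapply(cohort$tumors[ids], function(t) {
    identical(t$clinical$lauren_type, "diffuse")
  }, logical(1))

  split_exists <- vapply(candidate_range, function(k) {
    any(loci >= k) && any(loci < k)
  }, logical(1))
  if (!any(split_exists)) {
    stop("degenerate cohort: no candidate cutoff splits the tumors",
         call. = FALSE)
  }
  p_tp53 <- p_diffuse <- rep(NA_real_, length(candidate_range))
  for (i in seq_along(candidate_range)) {
    if (!split_exists[i]) next
    k <- candidate_range[i]
    high <- loci >= k
    p_tp53[i] <- fisher_two_tailed(table(factor(high, c(FALSE, TRUE)),
                                         factor(tp53, c(FALSE, TRUE))))
    p_diffuse[i] <- fisher_two_tailed(table(factor(!high, c(FALSE, TRUE)),
                                            factor(diffuse, c(FALSE, TRUE))))
  }
  score <- p_tp53 * p_diffuse
  best <- which(score == min(score, na.rm = TRUE))[1]  # ties -> smaller k
  out <- candidate_range[best]
  attr(out, "scan") <- data.frame(cutoff = candidate_range, p_tp53 = p_tp53,
                                  p_diffuse = p_diffuse, score = score)
  out
}
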