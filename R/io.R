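IMPACT_LEVELS <- c("high", "moderate", "low", "silent")
VAR_CLASSES <- c("SNV", "insertion", "deletion")

#' Normalize variant annotation vocabularies
#'
#' Impact strings are matched case-insensitively; the annotation-tool
#' synonym `MODIFIER` maps to `silent`. Variant classes accept the common
#' synonyms `SNP`/`substitution`, `ins`, `del`.
#'
#' @param x character vector of raw annotation strings.
#' @return character vector over the closed vocabulary
#'   (`high`/`moderate`/`low`/`silent`, resp. `SNV`/`insertion`/`deletion`).
#' @export
normalize_impact <- function(x) {
  z <- tolower(trimws(as.character(x)))
  z[z == "modifier"] <- "silent"
  bad <- !z %in% IMPACT_LEVELS
  if (any(bad)) {
    stop("unknown impact value(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  z
}

#' @rdname normalize_impact
#' @export
normalize_var_class <- function(x) {
  z <- tolower(trimws(as.character(x)))
  z[z %in% c("snv", "snp", "substitution")] <- "SNV"
  z[z %in% c("ins", "insertion")] <- "insertion"
  z[z %in% c("del", "deletion")] <- "deletion"
  bad <- !z %in% VAR_CLASSES
  if (any(bad)) {
    stop("unknown variant class value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  z
}

#' Construct a table of somatic variant calls
#'
#' One row per call with the fields the downstream biomarker logic needs:
#' gene symbol, variant class, allele fraction, putative functional impact
#' and an optional protein change.
#'
#' @param gene,var_class,impact character vectors (vocabularies are
#'   normalized, see [normalize_impact()]).
#' @param allele_fraction numeric in \[0, 1\].
#' @param protein_change optional character (HGVS p. style or `NA`).
#' @return data.frame with columns `gene`, `var_class`, `allele_fraction`,
#'   `impact`, `protein_change`, canonically sorted.
#' @export
variant_calls <- function(gene = character(), var_class = character(),
                          allele_fraction = numeric(), impact = character(),
                          protein_change = NA_character_) {
  n <- length(gene)
  allele_fraction <- as.numeric(allele_fraction)
  if (any(!is.finite(allele_fraction)) ||
      any(allele_fraction < 0 | allele_fraction > 1)) {
    stop("allele_fraction must be in [0, 1]", call. = FALSE)
  }
  df <- data.frame(gene = as.character(gene),
                   var_class = normalize_var_class(var_class),
                   allele_fraction = allele_fraction,
                   impact = normalize_impact(impact),
                   protein_change = rep_len(as.character(protein_change), n),
                   stringsAsFactors = FALSE)
  sort_variants(df)
}

sort_variants <- function(df) {
  df <- df[order(df$gene, df$var_class, df$allele_fraction, df$impact,
                 method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct a table of gene-level copy-number calls
#'
#' Fold changes are read-depth ratios against a diploid baseline; the
#' `call` column is derived from them with [call_scna()].
#'
#' @param gene character vector of gene symbols.
#' @param fold_change positive numeric vector.
#' @param gain_threshold,loss_threshold thresholds passed to [call_scna()].
#' @return data.frame with columns `gene`, `fold_change`, `call`,
#'   canonically sorted by gene.
#' @export
copy_number_calls <- function(gene = character(), fold_change = numeric(),
                              gain_threshold = 2.5, loss_threshold = 0.75) {
  fold_change <- as.numeric(fold_change)
  df <- data.frame(gene = as.character(gene), fold_change = fold_change,
                   call = call_scna(fold_change, gain_threshold, loss_threshold),
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene, df$fold_change, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_viral <- function() c(ebv_pct = 0, hpv16_pct = 0, hpv18_pct = 0)

#' Construct a per-tumor molecular profile
#'
#' Bundles everything the classifier consumes for one tumor: variant calls,
#' copy-number calls, viral read fractions (percent of total reads mapped to
#' each viral genome), the indel count over the microsatellite repeat-locus
#' panel, and basic clinical fields.
#'
#' @param tumor_id character scalar.
#' @param variants data.frame from [variant_calls()].
#' @param cnvs data.frame from [copy_number_calls()].
#' @param viral named numeric `c(ebv_pct=, hpv16_pct=, hpv18_pct=)`,
#'   each in \[0, 100\].
#' @param msi_indel_count non-negative integer.
#' @param clinical list with `age`, `sex`, `lauren_type`
#'   (intestinal/diffuse/mixed/unknown) and `stage`.
#' @return An object of class `tumor_profile`.
#' @export
tumor_profile <- function(tumor_id, variants = variant_calls(),
                          cnvs = copy_number_calls(),
                          viral = empty_viral(), msi_indel_count = 0,
                          clinical = list(age = NA_real_, sex = NA_character_,
                                          lauren_type = "unknown",
                                          stage = NA_character_)) {
  stopifnot(is.character(tumor_id), length(tumor_id) == 1L)
  viral <- viral[c("ebv_pct", "hpv16_pct", "hpv18_pct")]
  if (any(is.na(viral)) || any(viral < 0) || any(viral > 100)) {
    stop("viral read fractions must be percentages in [0, 100]", call. = FALSE)
  }
  if (!is_scalar_number(msi_indel_count) || msi_indel_count < 0) {
    stop("msi_indel_count must be a non-negative integer", call. = FALSE)
  }
  lt <- clinical$lauren_type %||% "unknown"
  if (!lt %in% c("intestinal", "diffuse", "mixed", "unknown")) {
    stop("lauren_type must be intestinal/diffuse/mixed/unknown", call. = FALSE)
  }
  structure(list(tumor_id = tumor_id, variants = variants, cnvs = cnvs,
                 viral = viral, msi_indel_count = as.integer(msi_indel_count),
                 clinical = clinical),
            class = "tumor_profile")
}

#' @export
print.tumor_profile <- function(x, ...) {
  cat(sprintf("<tumor_profile> %s: %d variants, %d CNV rows, MSI indels %d\n",
              x$tumor_id, nrow(x$variants), nrow(x$cnvs), x$msi_indel_count))
  invisible(x)
}

#' Construct a cohort
#'
#' A cohort is a gene panel plus an ordered list of tumor profiles with
#' unique ids. Variant and copy-number rows on genes outside the panel are
#' dropped with a warning: calling is restricted to the captured region of
#' interest, so off-panel symbols indicate an input mismatch rather than
#' signal.
#'
#' @param panel a [gene_panel].
#' @param tumors list of [tumor_profile] objects.
#' @return An object of class `gc_cohort`.
#' @export
gc_cohort <- function(panel, tumors) {
  stopifnot(inherits(panel, "gene_panel"))
  if (length(tumors) < 1L) stop("a cohort needs at least one tumor", call. = FALSE)
  ids <- vapply(tumors, function(t) t$tumor_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate tumor_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  dropped <- character()
  tumors <- lapply(tumors, function(t) {
    bad_v <- !t$variants$gene %in% panel$genes
    bad_c <- !t$cnvs$gene %in% panel$genes
    if (any(bad_v) || any(bad_c)) {
      dropped <<- c(dropped, t$variants$gene[bad_v], t$cnvs$gene[bad_c])
      t$variants <- t$variants[!bad_v, , drop = FALSE]
      t$cnvs <- t$cnvs[!bad_c, , drop = FALSE]
    }
    t
  })
  if (length(dropped) > 0) {
    warning("dropped calls on genes outside the panel: ",
            paste(unique(dropped), collapse = ", "), call. = FALSE)
  }
  names(tumors) <- ids
  structure(list(panel = panel, tumors = tumors), class = "gc_cohort")
}

#' @export
print.gc_cohort <- function(x, ...) {
  cat(sprintf("<gc_cohort> %d tumors, panel of %d genes (%d actionable)\n",
              length(x$tumors), length(x$panel$genes),
              length(x$panel$actionable)))
  invisible(x)
}

#' @rdname gc_cohort
#' @param cohort a `gc_cohort`.
#' @export
tumor_ids <- function(cohort) names(cohort$tumors)

#' @rdname gc_cohort
#' @export
n_tumors <- function(cohort) length(cohort$tumors)

#' Restrict a cohort to a subset of tumors
#'
#' Used e.g. to drop hypermutated tumors before co-alteration clustering.
#'
#' @param cohort a [gc_cohort].
#' @param ids tumor ids to keep (order preserved as given).
#' @return a [gc_cohort] with the selected tumors.
#' @export
subset_cohort <- function(cohort, ids) {
  missing <- setdiff(ids, tumor_ids(cohort))
  if (length(missing) > 0) {
    stop("unknown tumor id(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(panel = cohort$panel, tumors = cohort$tumors[ids]),
            class = "gc_cohort")
}

#' Genes altered in a tumor
#'
#' The alteration predicate used for frequency tables and co-alteration
#' clustering: a gene counts as altered if it carries a peptide-changing
#' mutation (impact high or moderate; SNV or indel) or a copy-number gain
#' or loss. The clusters this package models are defined by amplifications
#' and deletions as much as by mutations, so copy-number events are part of
#' the default predicate.
#'
#' @param profile a [tumor_profile].
#' @param include which alteration classes to consider.
#' @param impacts variant impacts that qualify.
#' @return character vector of gene symbols (possibly empty).
#' @export
altered_genes <- function(profile, include = c("mutation", "scna"),
                          impacts = c("high", "moderate")) {
  include <- match.arg(include, c("mutation", "scna"), several.ok = TRUE)
  out <- character()
  if ("mutation" %in% include) {
    out <- c(out, profile$variants$gene[profile$variants$impact %in% impacts])
  }
  if ("scna" %in% include) {
    out <- c(out, profile$cnvs$gene[profile$cnvs$call %in% c("gain", "loss")])
  }
  unique(out)
}

# ---- readers ---------------------------------------------------------------

#' Read somatic variant calls
#'
#' The canonical dialect is a MAF-like TSV with columns `tumor_id`, `gene`,
#' `var_class`, `allele_fraction`, `impact` and optionally `protein_change`.
#' A VCF (one sample per file) is also accepted: the gene symbol and impact
#' are taken from INFO keys, the allele fraction from FORMAT `AF` or
#' computed from FORMAT `AD`.
#'
#' @param path input file.
#' @param panel optional [gene_panel]; when given, calls on off-panel genes
#'   are dropped with a warning.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param vcf_gene_key,vcf_impact_key INFO keys used for VCF input.
#' @return named list of variant data.frames, one per `tumor_id`, each
#'   canonically sorted.
#' @export
read_variants <- function(path, panel = NULL, format = c("auto", "tsv", "vcf"),
                          vcf_gene_key = "GENE", vcf_impact_key = "IMPACT") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  groups <- if (format == "vcf") {
    read_variants_vcf(path, vcf_gene_key, vcf_impact_key)
  } else {
    read_variants_tsv(path)
  }
  if (!is.null(panel)) {
    all_dropped <- character()
    groups <- lapply(groups, function(df) {
      bad <- !df$gene %in% panel$genes
      if (any(bad)) all_dropped <<- c(all_dropped, df$gene[bad])
      df[!bad, , drop = FALSE]
    })
    if (length(all_dropped) > 0) {
      warning("dropped variants on genes outside the panel: ",
              paste(unique(all_dropped), collapse = ", "), call. = FALSE)
    }
  }
  groups
}

read_variants_tsv <- function(path) {
  df <- read_tsv_checked(path, required = c("tumor_id", "gene", "var_class",
                                            "allele_fraction", "impact"))
  if (nrow(df) == 0L) return(structure(list(), names = character()))
  af <- suppressWarnings(as.numeric(df$allele_fraction))
  bad <- which(is.na(af) & !is.na(df$allele_fraction))
  if (length(bad) > 0) {
    stop(sprintf("%s: line %d: unparseable allele_fraction '%s'",
                 basename(path), bad[1] + 1L, df$allele_fraction[bad[1]]),
         call. = FALSE)
  }
  if (!"protein_change" %in% names(df)) df$protein_change <- NA_character_
  split_ids <- df$tumor_id
  out <- lapply(split(seq_len(nrow(df)), split_ids), function(i) {
    variant_calls(df$gene[i], df$var_class[i], af[i], df$impact[i],
                  df$protein_change[i])
  })
  out[order(names(out))]
}

read_variants_vcf <- function(path, gene_key = "GENE", impact_key = "IMPACT") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2L) {
    stop("VCF must carry exactly one sample column", call. = FALSE)
  }
  sample_id <- colnames(gt)[2]
  keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  if (sum(keep) == 0L) {
    return(structure(list(variant_calls())[0], names = character()))
  }
  gene <- vcfR::extract.info(vcf, element = gene_key)
  impact <- vcfR::extract.info(vcf, element = impact_key)
  af <- suppressWarnings(as.numeric(vcfR::extract.gt(vcf, element = "AF")[, 1]))
  if (all(is.na(af))) {
    ad <- vcfR::extract.gt(vcf, element = "AD")[, 1]
    counts <- lapply(strsplit(ad, ","), as.numeric)
    af <- vapply(counts, function(z) {
      if (length(z) < 2 || sum(z) == 0) NA_real_ else z[2] / sum(z)
    }, numeric(1))
  }
  if (any(is.na(af[keep]))) {
    stop("VCF record without a usable AF or AD field at row ",
         which(keep & is.na(af))[1], call. = FALSE)
  }
  ref <- fix$REF
  alt <- fix$ALT
  var_class <- ifelse(nchar(ref) == nchar(alt), "SNV",
                      ifelse(nchar(ref) < nchar(alt), "insertion", "deletion"))
  df <- variant_calls(gene[keep], var_class[keep], af[keep], impact[keep])
  structure(list(df), names = sample_id)
}

#' Read a full cohort from its component tables
#'
#' One [tumor_profile] is built per `tumor_id` in the clinical table (the
#' cohort roster). Tumors missing from an auxiliary table get empty or zero
#' defaults with a warning; tumor ids appearing only in auxiliary tables are
#' dropped with a warning; a duplicated id in the clinical table is an error.
#'
#' @param variants_path MAF-like TSV or VCF (see [read_variants()]).
#' @param cnv_path TSV `tumor_id`, `gene`, `fold_change`.
#' @param viral_path TSV `tumor_id`, `ebv_pct`, `hpv16_pct`, `hpv18_pct`.
#' @param msi_path TSV `tumor_id`, `indel_count`.
#' @param clinical_path TSV `tumor_id`, `age`, `sex`, `lauren_type`, `stage`.
#' @param panel_path panel TSV (see [read_panel()]).
#' @param roi_size_mb captured ROI size in Mb.
#' @param gain_threshold,loss_threshold copy-number calling thresholds.
#' @return a [gc_cohort].
#' @export
read_cohort <- function(variants_path, cnv_path, viral_path, msi_path,
                        clinical_path, panel_path, roi_size_mb = 1.7,
                        gain_threshold = 2.5, loss_threshold = 0.75) {
  panel <- read_panel(panel_path, roi_size_mb = roi_size_mb)
  clinical <- read_tsv_checked(clinical_path,
                               required = c("tumor_id", "age", "sex",
                                            "lauren_type", "stage"))
  if (anyDuplicated(clinical$tumor_id)) {
    stop("duplicate tumor_id in clinical table: ",
         paste(unique(clinical$tumor_id[duplicated(clinical$tumor_id)]),
               collapse = ", "), call. = FALSE)
  }
  roster <- clinical$tumor_id

  var_groups <- read_variants(variants_path, panel = NULL)
  cnv <- read_tsv_checked(cnv_path, required = c("tumor_id", "gene", "fold_change"))
  viral <- read_tsv_checked(viral_path, required = c("tumor_id", "ebv_pct",
                                                     "hpv16_pct", "hpv18_pct"))
  msi <- read_tsv_checked(msi_path, required = c("tumor_id", "indel_count"))

  extra <- setdiff(unique(c(names(var_groups), cnv$tumor_id, viral$tumor_id,
                            msi$tumor_id)), roster)
  if (length(extra) > 0) {
    warning("tumor id(s) absent from the clinical table dropped: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }

  defaults_used <- character()
  tumors <- lapply(seq_along(roster), function(i) {
    id <- roster[i]
    v <- var_groups[[id]] %||% variant_calls()
    ci <- cnv[cnv$tumor_id == id, , drop = FALSE]
    cn <- copy_number_calls(ci$gene, as.numeric(ci$fold_change),
                            gain_threshold, loss_threshold)
    vi <- viral[viral$tumor_id == id, , drop = FALSE]
    vv <- if (nrow(vi) >= 1L) {
      c(ebv_pct = as.numeric(vi$ebv_pct[1]),
        hpv16_pct = as.numeric(vi$hpv16_pct[1]),
        hpv18_pct = as.numeric(vi$hpv18_pct[1]))
    } else {
      defaults_used <<- c(defaults_used, id)
      empty_viral()
    }
    mi <- msi$indel_count[msi$tumor_id == id]
    mm <- if (length(mi) >= 1L) as.integer(mi[1]) else {
      defaults_used <<- c(defaults_used, id)
      0L
    }
    tumor_profile(id, variants = v, cnvs = cn, viral = vv,
                  msi_indel_count = mm,
                  clinical = list(age = as.numeric(clinical$age[i]),
                                  sex = as.character(clinical$sex[i]),
                                  lauren_type = as.character(clinical$lauren_type[i]),
                                  stage = as.character(clinical$stage[i])))
  })
  if (length(defaults_used) > 0) {
    warning("auxiliary data missing, zero defaults used for: ",
            paste(unique(defaults_used), collapse = ", "), call. = FALSE)
  }
  gc_cohort(panel, tumors)
}

#' Read or write a cohort as a directory of TSV tables
#'
#' The directory layout is the one [write_cohort()] produces:
#' `variants.tsv`, `cnv.tsv`, `viral.tsv`, `msi.tsv`, `clinical.tsv`,
#' `panel.tsv` and a small `meta.json` holding `roi_size_mb` and generator
#' provenance.
#'
#' @param dir directory path.
#' @param ... passed on to [read_cohort()].
#' @return `read_cohort_dir()` a [gc_cohort]; `write_cohort()` the directory
#'   path, invisibly.
#' @export
read_cohort_dir <- function(dir, ...) {
  meta_path <- file.path(dir, "meta.json")
  args <- list(...)
  if (is.null(args$roi_size_mb) && file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$roi_size_mb)) args$roi_size_mb <- as.numeric(meta$roi_size_mb)
  }
  do.call(read_cohort, c(list(
    variants_path = file.path(dir, "variants.tsv"),
    cnv_path = file.path(dir, "cnv.tsv"),
    viral_path = file.path(dir, "viral.tsv"),
    msi_path = file.path(dir, "msi.tsv"),
    clinical_path = file.path(dir, "clinical.tsv"),
    panel_path = file.path(dir, "panel.tsv")), args))
}

#' @rdname read_cohort_dir
#' @param cohort a [gc_cohort].
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tumors <- cohort$tumors

  vv <- do.call(rbind, lapply(tumors, function(t) {
    if (nrow(t$variants) == 0L) return(NULL)
    cbind(tumor_id = t$tumor_id, t$variants)
  }))
  if (is.null(vv)) {
    vv <- data.frame(tumor_id = character(), gene = character(),
                     var_class = character(), allele_fraction = numeric(),
                     impact = character(), protein_change = character())
  }
  write_tsv_atomic(vv, file.path(dir, "variants.tsv"))

  cc <- do.call(rbind, lapply(tumors, function(t) {
    if (nrow(t$cnvs) == 0L) return(NULL)
    data.frame(tumor_id = t$tumor_id, gene = t$cnvs$gene,
               fold_change = t$cnvs$fold_change)
  }))
  if (is.null(cc)) {
    cc <- data.frame(tumor_id = character(), gene = character(),
                     fold_change = numeric())
  }
  write_tsv_atomic(cc, file.path(dir, "cnv.tsv"))

  vir <- do.call(rbind, lapply(tumors, function(t) {
    data.frame(tumor_id = t$tumor_id, ebv_pct = t$viral[["ebv_pct"]],
               hpv16_pct = t$viral[["hpv16_pct"]],
               hpv18_pct = t$viral[["hpv18_pct"]])
  }))
  write_tsv_atomic(vir, file.path(dir, "viral.tsv"))

  msi <- do.call(rbind, lapply(tumors, function(t) {
    data.frame(tumor_id = t$tumor_id, indel_count = t$msi_indel_count)
  }))
  write_tsv_atomic(msi, file.path(dir, "msi.tsv"))

  cl <- do.call(rbind, lapply(tumors, function(t) {
    data.frame(tumor_id = t$tumor_id, age = t$clinical$age,
               sex = t$clinical$sex, lauren_type = t$clinical$lauren_type,
               stage = t$clinical$stage)
  }))
  write_tsv_atomic(cl, file.path(dir, "clinical.tsv"))

  write_panel(cohort$panel, file.path(dir, "panel.tsv"))
  jsonlite::write_json(
    list(roi_size_mb = cohort$panel$roi_size_mb,
         generator = paste0("panelclass ",
                            as.character(utils::packageVersion("panelclass")))),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a long-format oncoprint table
#'
#' One row per (tumor, gene, alteration class) with
#' `alteration_class` in mutation/amplification/deletion, sorted by tumor
#' id, then gene, then class, so repeated runs are byte-identical.
#'
#' @param cohort a [gc_cohort].
#' @param path output TSV path.
#' @return the oncoprint data.frame, invisibly.
#' @export
write_oncoprint <- function(cohort, path) {
  rows <- do.call(rbind, lapply(cohort$tumors, function(t) {
    mut <- unique(t$variants$gene[t$variants$impact %in% c("high", "moderate")])
    amp <- unique(t$cnvs$gene[t$cnvs$call == "gain"])
    del <- unique(t$cnvs$gene[t$cnvs$call == "loss"])
    n <- length(mut) + length(amp) + length(del)
    if (n == 0L) return(NULL)
    data.frame(tumor_id = t$tumor_id,
               gene = c(mut, amp, del),
               alteration_class = c(rep("mutation", length(mut)),
                                    rep("amplification", length(amp)),
                                    rep("deletion", length(del))))
  }))
  if (is.null(rows)) {
    rows <- data.frame(tumor_id = character(), gene = character(),
                       alteration_class = character())
  }
  rows <- rows[order(rows$tumor_id, rows$gene, rows$alteration_class,
                     method = "radix"), , drop = FALSE]
  rownames(rows) <- NULL
  write_tsv_atomic(rows, path)
  invisible(rows)
}
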