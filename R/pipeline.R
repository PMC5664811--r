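#' Pipeline configuration
#'
#' Assembles all stage parameters with the published defaults: copy-number
#' thresholds 2.5/0.75, SCNA-high at 4 loci, AF filter 0.10, the three viral
#' cutoffs, auto-derived hypermutation cutoff, actionable-gene clustering at
#' k = 6. Either `cohort_dir` (read an existing cohort) or `simulate = TRUE`
#' (generate one from `spec`) must be chosen.
#'
#' @param out_dir output directory.
#' @param cohort_dir directory in [write_cohort()] layout, or NULL.
#' @param simulate generate the input cohort from `spec`.
#' @param spec a `cohort_spec` used when `simulate` is TRUE.
#' @param seed integer; when simulating, overrides `spec$seed`.
#' @param roi_size_mb,af_min,msi_threshold,viral_cutoffs biomarker stage.
#' @param gain_threshold,loss_threshold,scna_cutoff copy-number calling and
#'   the CIN/GS locus cutoff.
#' @param hypermutation_cutoff `"auto"` or counts/Mb.
#' @param gene_set `"actionable"` or `"all"` clustering gene set.
#' @param k number of clusters or `"auto"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, cohort_dir = NULL, simulate = is.null(cohort_dir),
                            spec = paper_default_spec(), seed = NULL,
                            roi_size_mb = 1.7, af_min = 0.10,
                            msi_threshold = 20,
                            viral_cutoffs = default_viral_cutoffs(),
                            gain_threshold = 2.5, loss_threshold = 0.75,
                            scna_cutoff = 4, hypermutation_cutoff = "auto",
                            gene_set = "actionable", k = 6) {
  if (!simulate && is.null(cohort_dir)) {
    stop("either simulate = TRUE or a cohort_dir is required", call. = FALSE)
  }
  stopifnot(gain_threshold > 0, loss_threshold > 0, af_min >= 0, af_min <= 1,
            msi_threshold >= 1, scna_cutoff >= 1)
  structure(list(out_dir = out_dir, cohort_dir = cohort_dir,
                 simulate = simulate, spec = spec, seed = seed,
                 roi_size_mb = roi_size_mb, af_min = af_min,
                 msi_threshold = msi_threshold, viral_cutoffs = viral_cutoffs,
                 gain_threshold = gain_threshold,
                 loss_threshold = loss_threshold, scna_cutoff = scna_cutoff,
                 hypermutation_cutoff = hypermutation_cutoff,
                 gene_set = gene_set, k = k),
            class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' Chains the stages of the analysis in the order of the study: cohort
#' acquisition (simulation or ingestion), biomarker calling, TCGA subtype
#' assignment with hypermutation flagging, co-alteration clustering of the
#' non-hypermutated tumors, and cohort statistics. Stage outputs are
#' written as TSV via atomic renames; a machine-readable `summary.json`
#' records subtype counts, the hypermutation cutoff and count, cluster
#' sizes and labels, and the top of the frequency table. A stage failure
#' aborts the run before any downstream output is written.
#'
#' @param config a [pipeline_config()] (or a list/YAML path with the same
#'   fields).
#' @return the summary list, invisibly.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- do.call(pipeline_config, yaml::read_yaml(config))
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)

  if (config$simulate) {
    spec <- config$spec
    if (!is.null(config$seed)) {
      spec$seed <- as.integer(config$seed)
    }
    message("[simulate] n=", spec$n_tumors, " seed=", spec$seed)
    sim <- generate_cohort(spec)
    cohort <- sim$cohort
    truth <- sim$truth
  } else {
    message("[ingest] cohort_dir=", config$cohort_dir)
    cohort <- read_cohort_dir(config$cohort_dir,
                              roi_size_mb = config$roi_size_mb,
                              gain_threshold = config$gain_threshold,
                              loss_threshold = config$loss_threshold)
    truth <- NULL
  }

  message("[biomarkers] af_min=", config$af_min,
          " msi_threshold=", config$msi_threshold)
  biomarkers <- compute_biomarkers(
    cohort, af_min = config$af_min, msi_threshold = config$msi_threshold,
    viral_cutoffs = config$viral_cutoffs,
    gain_threshold = config$gain_threshold,
    loss_threshold = config$loss_threshold)

  message("[classify] scna_cutoff=", config$scna_cutoff,
          " hypermutation_cutoff=", config$hypermutation_cutoff)
  subtypes <- classify_cohort(biomarkers, scna_cutoff = config$scna_cutoff,
                              hypermutation_cutoff = config$hypermutation_cutoff)
  cutoff_used <- attr(subtypes, "hypermutation_cutoff")

  message("[cluster] gene_set=", config$gene_set, " k=", config$k)
  clustering <- cluster_cohort(cohort, biomarkers,
                               gene_set = config$gene_set, k = config$k,
                               hypermutation_cutoff = cutoff_used)

  message("[stats]")
  freqs <- alteration_frequencies(cohort)
  clin <- do.call(rbind, lapply(cohort$tumors, function(t) {
    data.frame(tumor_id = t$tumor_id, age = t$clinical$age,
               sex = t$clinical$sex, lauren_type = t$clinical$lauren_type,
               stage = t$clinical$stage)
  }))
  clin <- merge(clin, biomarkers[, c("tumor_id", "scna_locus_count")],
                by = "tumor_id")
  grouping <- stats::setNames(clustering$assignments$cluster,
                              clustering$assignments$tumor_id)
  assoc <- associate_groups(
    clin[clin$tumor_id %in% names(grouping), , drop = FALSE], grouping)

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (config$simulate) {
    write_cohort(cohort, file.path(out_dir, "cohort"))
    if (!is.null(truth)) {
      write_tsv_atomic(truth, file.path(out_dir, "truth.tsv"))
    }
  }
  write_tsv_atomic(biomarkers, file.path(out_dir, "biomarkers.tsv"))
  st_out <- subtypes
  attr(st_out, "hypermutation_cutoff") <- NULL
  write_tsv_atomic(st_out, file.path(out_dir, "subtypes.tsv"))
  write_tsv_atomic(clustering$assignments, file.path(out_dir, "clusters.tsv"))
  if (!is.null(clustering$stability)) {
    write_tsv_atomic(clustering$stability, file.path(out_dir, "stability.tsv"))
  }
  write_tsv_atomic(freqs, file.path(out_dir, "frequencies.tsv"))
  write_tsv_atomic(assoc, file.path(out_dir, "associations.tsv"))
  write_oncoprint(cohort, file.path(out_dir, "oncoprint.tsv"))

  cluster_sizes <- table(clustering$assignments$cluster)
  summary <- list(
    schema_version = "1.0",
    n_tumors = n_tumors(cohort),
    subtype_counts = as.list(table(factor(subtypes$subtype,
                                          c("EBV", "MSI", "CIN", "GS")))),
    hypermutation_cutoff = cutoff_used,
    hypermutated_n = sum(subtypes$hypermutated),
    cluster_k = clustering$k,
    cluster_sizes = as.list(cluster_sizes),
    cluster_labels = as.list(clustering$labels),
    top_frequencies = utils::head(freqs, 20)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(summary)
}
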