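#' Gene panel definition
#'
#' A targeted sequencing panel: the captured gene symbols, the actionable
#' subset (genes paired with an FDA-approved targeted therapy) and the size
#' of the captured region of interest in megabases, which is the denominator
#' of the tumor mutational burden.
#'
#' @param genes character vector of unique gene symbols.
#' @param actionable character vector, subset of `genes`.
#' @param roi_size_mb positive number, captured region size in Mb.
#' @return An object of class `gene_panel`: a list with elements `genes`,
#'   `actionable` and `roi_size_mb`.
#' @examples
#' gene_panel(c("TP53", "ERBB2"), actionable = "ERBB2", roi_size_mb = 1.7)
#' @export
gene_panel <- function(genes, actionable = character(), roi_size_mb = 1.7) {
  genes <- as.character(genes)
  actionable <- as.character(actionable)
  if (anyDuplicated(genes)) {
    stop("panel gene symbols must be unique", call. = FALSE)
  }
  if (!all(actionable %in% genes)) {
    stop("actionable genes must be a subset of panel genes: ",
         paste(setdiff(actionable, genes), collapse = ", "), call. = FALSE)
  }
  if (!is_scalar_number(roi_size_mb) || roi_size_mb <= 0) {
    stop("roi_size_mb must be a positive number", call. = FALSE)
  }
  structure(list(genes = genes, actionable = unique(actionable),
                 roi_size_mb = roi_size_mb),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %d genes (%d actionable), ROI %.2f Mb\n",
              length(x$genes), length(x$actionable), x$roi_size_mb))
  invisible(x)
}

# Gene symbols with published cohort-level alteration frequencies
# (mutation and copy-number columns of the frequency table).
TABLE1_MUTATION_GENES <- c(
  "TP53", "ARID1A", "CDH1", "BRCA2", "ARID1B", "ATM", "PIK3CA", "APC",
  "ACVR2A", "CHD2", "KMT2D", "RNF43", "EPHA2", "TGFBR2", "FLCN", "PALB2",
  "PTPRT", "RAD50", "BRCA1", "STK11"
)

TABLE1_SCNA_GENES <- c(
  "ERBB2", "CCNE1", "KRAS", "ZNF217", "CDKN2A", "CDKN2B", "GATA4", "MYC",
  "CCND3", "CD274", "CDK6", "EGFR", "FGFR2", "JAK2", "GNAS", "CCND1",
  "MET", "HSP90AB1", "SMAD4", "TEK"
)

#' Synthetic 435-gene panel
#'
#' A stand-in panel with the 435-gene / 69-actionable-gene structure of a
#' commercial pan-cancer assay. The true panel content is proprietary, so
#' this synthetic reconstruction uses real symbols for all genes carrying
#' published cohort frequencies plus well-known FDA-target genes, and
#' clearly marked filler symbols (`SYNGENExxx`) for the remainder.
#'
#' @param roi_size_mb captured region size in Mb (default 1.7).
#' @return A [gene_panel] with 435 genes, 69 of them actionable.
#' @export
synthetic_panel <- function(roi_size_mb = 1.7) {
  actionable <- c(
    # actionable genes of the published frequency table
    "ERBB2", "KRAS", "CDKN2A", "CDKN2B", "BRCA2", "ATM", "PIK3CA", "RNF43",
    "FLCN", "PALB2", "BRCA1", "STK11", "CCND3", "CD274", "CDK6", "EGFR",
    "FGFR2", "JAK2", "CCND1", "MET",
    # other genes paired with FDA-approved targeted therapies
    "ALK", "ROS1", "RET", "BRAF", "KIT", "PDGFRA", "PDGFRB", "NTRK1",
    "NTRK2", "NTRK3", "ERBB3", "ERBB4", "FGFR1", "FGFR3", "FGFR4", "MTOR",
    "AKT1", "AKT2", "AKT3", "PTEN", "NF1", "NF2", "TSC1", "TSC2", "SMO",
    "PTCH1", "IDH1", "IDH2", "ESR1", "AR", "BTK", "MAP2K1", "MAP2K2",
    "JAK1", "JAK3", "CSF1R", "FLT1", "FLT3", "FLT4", "KDR", "ABL1", "SRC",
    "CHEK1", "CHEK2", "MLH1", "MSH2", "MSH6", "PMS2", "POLE"
  )
  stopifnot(length(actionable) == 69L)
  other_real <- c(
    setdiff(TABLE1_MUTATION_GENES, actionable),
    setdiff(TABLE1_SCNA_GENES, actionable),
    "CTNNB1", "SMARCA4", "SMARCB1", "KEAP1", "NFE2L2", "RB1", "VHL", "WT1",
    "MEN1", "FBXW7", "NOTCH1", "NOTCH2", "NOTCH3", "GATA3", "RUNX1",
    "KMT2A", "KMT2C", "CREBBP", "EP300", "SETD2", "KDM6A", "ASXL1", "BCOR",
    "STAG2", "RAD21", "ATRX", "DAXX", "DNMT3A", "TET2", "SPOP", "MDM2",
    "MDM4", "CDK4", "CDK12", "AXIN1", "AXIN2", "SOX9", "TCF7L2", "PTPN11",
    "NRAS", "HRAS", "RHOA", "STAT3", "MYCN", "MYCL", "GNA11", "GNAQ",
    "POLD1", "MUTYH", "BAP1", "PBRM1", "ARID2", "PIK3R1", "ERCC2", "FANCA",
    "FANCC", "FANCD2", "BLM", "WRN", "NBN", "MRE11", "TERT", "TOP2A"
  )
  real <- unique(c(actionable, other_real))
  n_fill <- 435L - length(real)
  filler <- sprintf("SYNGENE%03d", seq_len(n_fill))
  gene_panel(c(real, filler), actionable = actionable,
             roi_size_mb = roi_size_mb)
}

#' Read and write a panel definition TSV
#'
#' The panel dialect is a two-column TSV: `gene` and an `actionable` 0/1
#' flag. The ROI size is not part of the file and is supplied separately.
#'
#' @param path file path.
#' @param roi_size_mb ROI size in Mb attached to the returned panel.
#' @return `read_panel()` returns a [gene_panel]; `write_panel()` returns
#'   the path invisibly.
#' @export
read_panel <- function(path, roi_size_mb = 1.7) {
  df <- read_tsv_checked(path, required = c("gene", "actionable"))
  gene_panel(df$gene, actionable = df$gene[df$actionable %in% c(1, "1", TRUE)],
             roi_size_mb = roi_size_mb)
}

#' @param panel a [gene_panel].
#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gene_panel"))
  df <- data.frame(gene = panel$genes,
                   actionable = as.integer(panel$genes %in% panel$actionable))
  write_tsv_atomic(df, path)
}
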