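# small in-code fixtures shared across test files

tiny_panel <- function(roi = 1.0) {
  gene_panel(c("TP53", "ERBB2", "KRAS", "CDH1", "CDKN2A", "CDKN2B",
               sprintf("G%02d", 1:12)),
             actionable = c("ERBB2", "KRAS", "CDKN2A", "CDKN2B"),
             roi_size_mb = roi)
}

# quick profile builder: mutated genes arrive as qualifying SNVs, gains and
# losses as fold changes on the right side of the default thresholds
make_profile <- function(id, muts = character(), gains = character(),
                         losses = character(), ebv = 0, msi = 0,
                         lauren = "intestinal", age = 65) {
  v <- variant_calls(muts, rep("SNV", length(muts)),
                     rep(0.4, length(muts)), rep("high", length(muts)))
  cn <- copy_number_calls(c(gains, losses),
                          c(rep(3.0, length(gains)), rep(0.5, length(losses))))
  tumor_profile(id, variants = v, cnvs = cn,
                viral = c(ebv_pct = ebv, hpv16_pct = 0, hpv18_pct = 0),
                msi_indel_count = msi,
                clinical = list(age = age, sex = "M", lauren_type = lauren,
                                stage = "II"))
}

make_cohort <- function(profiles, panel = tiny_panel()) {
  gc_cohort(panel, profiles)
}

write_cohort_fixture <- function(dir, variants, cnv, viral, msi, clinical,
                                 panel = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(variants, "variants.tsv"); w(cnv, "cnv.tsv"); w(viral, "viral.tsv")
  w(msi, "msi.tsv"); w(clinical, "clinical.tsv")
  if (is.null(panel)) {
    panel <- data.frame(gene = tiny_panel()$genes,
                        actionable = as.integer(tiny_panel()$genes %in%
                                                  tiny_panel()$actionable))
  }
  w(panel, "panel.tsv")
  dir
}

empty_aux_tables <- function() {
  list(cnv = data.frame(tumor_id = character(), gene = character(),
                        fold_change = numeric()),
       viral = data.frame(tumor_id = character(), ebv_pct = numeric(),
                          hpv16_pct = numeric(), hpv18_pct = numeric()),
       msi = data.frame(tumor_id = character(), indel_count = integer()))
}
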