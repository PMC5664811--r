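test_that("gene_panel enforces its invariants", {
  expect_error(gene_panel(c("A", "A")), "unique")
  expect_error(gene_panel(c("A", "B"), actionable = "C"), "subset")
  expect_error(gene_panel("A", roi_size_mb = 0), "positive")
  p <- synthetic_panel()
  expect_length(p$genes, 435L)
  expect_length(p$actionable, 69L)
  expect_true(all(p$actionable %in% p$genes))
})

test_that("TSV variant reader groups rows by tumor and sorts canonically", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tumor_id\tgene\tvar_class\tallele_fraction\timpact",
               "T2\tKRAS\tSNV\t0.2\tMODERATE",
               "T1\tTP53\tsnv\t0.5\tHIGH",
               "T1\tCDH1\tdeletion\t0.3\thigh"), path)
  got <- read_variants(path)
  expect_named(got, c("T1", "T2"))
  expect_equal(nrow(got$T1), 2L)
  expect_equal(nrow(got$T2), 1L)
  expect_equal(got$T1$gene, c("CDH1", "TP53"))  # canonical gene order
  expect_equal(got$T2$impact, "moderate")

  # row order of the input must not matter after canonical sorting
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tumor_id\tgene\tvar_class\tallele_fraction\timpact",
               "T1\tTP53\tsnv\t0.5\tHIGH",
               "T1\tCDH1\tdeletion\t0.3\thigh",
               "T2\tKRAS\tSNV\t0.2\tMODERATE"), path2)
  expect_identical(read_variants(path2), got)
})

test_that("variant reader reports format problems precisely", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("tumor_id\tgene\tvar_class\tallele_fraction\timpact", p1)
  expect_identical(unname(lengths(read_variants(p1))), integer(0))

  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tumor_id\tgene\tvar_class\timpact", "T1\tTP53\tSNV\thigh"), p2)
  expect_error(read_variants(p2), "allele_fraction")

  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tumor_id\tgene\tvar_class\tallele_fraction\timpact",
               "T1\tTP53\tSNV\t0.5\thigh",
               "T1\tKRAS\tSNV\toops\thigh"), p3)
  expect_error(read_variants(p3), "line 3")
})

test_that("VCF ingestion maps AF, gene and impact onto variant calls", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Impact\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr17\t7578406\t.\tC\tT\t50\tPASS\tGENE=TP53;IMPACT=HIGH\tGT:AF\t0/1:0.25",
    "chr12\t25398284\t.\tCA\tC\t50\tPASS\tGENE=KRAS;IMPACT=MODERATE\tGT:AF\t0/1:0.4"),
    path)
  got <- read_variants(path, format = "vcf")
  expect_named(got, "S1")
  df <- got$S1
  expect_equal(df$allele_fraction[df$gene == "TP53"], 0.25)
  expect_equal(df$var_class[df$gene == "TP53"], "SNV")
  expect_equal(df$var_class[df$gene == "KRAS"], "deletion")
  expect_equal(df$impact, c("moderate", "high"))
})

test_that("off-panel genes are dropped with a warning, not an error", {
  prof <- make_profile("T1", muts = c("TP53", "NOT_ON_PANEL"))
  expect_warning(co <- make_cohort(list(prof)), "NOT_ON_PANEL")
  expect_equal(co$tumors$T1$variants$gene, "TP53")
})

test_that("read_cohort assembles profiles and fills missing auxiliaries", {
  dir <- withr::local_tempdir()
  aux <- empty_aux_tables()
  write_cohort_fixture(
    dir,
    variants = data.frame(tumor_id = c("T1", "T1", "T2"),
                          gene = c("TP53", "ERBB2", "KRAS"),
                          var_class = "SNV", allele_fraction = 0.5,
                          impact = "high"),
    cnv = data.frame(tumor_id = "T1", gene = "ERBB2", fold_change = 3.2),
    viral = data.frame(tumor_id = c("T1", "T2"), ebv_pct = c(0.01, 0),
                       hpv16_pct = 0, hpv18_pct = 0),
    msi = data.frame(tumor_id = c("T1", "T2"), indel_count = c(3L, 30L)),
    clinical = data.frame(tumor_id = c("T1", "T2", "T3"), age = 60,
                          sex = "F", lauren_type = "diffuse", stage = "III"))
  expect_warning(co <- read_cohort_dir(dir), "T3")
  expect_equal(n_tumors(co), 3L)
  expect_equal(co$tumors$T3$viral[["ebv_pct"]], 0)
  expect_equal(co$tumors$T3$msi_indel_count, 0L)
  expect_equal(co$tumors$T1$cnvs$call, "gain")

  # duplicated clinical rows are a hard error
  clin_dup <- data.frame(tumor_id = c("T1", "T1"), age = 60, sex = "F",
                         lauren_type = "mixed", stage = "I")
  utils::write.table(clin_dup, file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(suppressWarnings(read_cohort_dir(dir)), "duplicate tumor_id")
})

test_that("a synthetic cohort round-trips through the TSV dialect", {
  pc <- default_planted_clusters()
  pc$size <- c(4L, 3L, 3L, 2L, 2L)
  sim <- generate_cohort(synthetic_cohort_spec(n_tumors = 24, seed = 11,
                                               n_hypermutated = 6,
                                               planted_clusters = pc))
  dir <- withr::local_tempdir()
  write_cohort(sim$cohort, dir)
  back <- read_cohort_dir(dir)
  expect_identical(tumor_ids(back), tumor_ids(sim$cohort))
  for (id in tumor_ids(sim$cohort)) {
    a <- sim$cohort$tumors[[id]]; b <- back$tumors[[id]]
    expect_equal(b$variants$gene, a$variants$gene)
    expect_equal(b$variants$allele_fraction, a$variants$allele_fraction,
                 tolerance = 1e-6)
    expect_equal(b$cnvs$fold_change, a$cnvs$fold_change, tolerance = 1e-6)
    expect_equal(b$cnvs$call, a$cnvs$call)
    expect_equal(unname(b$viral), unname(a$viral), tolerance = 1e-6)
    expect_identical(b$msi_indel_count, a$msi_indel_count)
    expect_identical(b$clinical$lauren_type, a$clinical$lauren_type)
  }
})

test_that("oncoprint output is long-format, complete and deterministic", {
  co <- make_cohort(list(
    make_profile("T1", muts = "TP53", gains = "ERBB2"),
    make_profile("T2")))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  df <- write_oncoprint(co, p1)
  expect_equal(nrow(df), 2L)
  expect_setequal(df$alteration_class, c("mutation", "amplification"))
  expect_false("T2" %in% df$tumor_id)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_oncoprint(co, p2)
  expect_identical(readLines(p1), readLines(p2))
})
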