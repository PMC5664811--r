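test_that("co-alteration counts equal the nested-loop oracle", {
  p <- tiny_panel()
  co <- make_cohort(list(
    make_profile("T1", muts = c("TP53", "KRAS"), gains = "ERBB2"),
    make_profile("T2", muts = "TP53", gains = "ERBB2"),
    make_profile("T3", muts = "CDH1")))
  gs <- p$genes
  m <- comutation_counts(co, gs)
  expect_true(isSymmetric(m[, ]))
  expect_equal(m["T1", "T2"], 2L)   # share exactly {TP53, ERBB2}
  expect_equal(m["T1", "T3"], 0L)   # disjoint
  expect_equal(m["T1", "T1"], 3L)   # diagonal = own altered count
  expect_error(comutation_counts(co, character()), "non-empty")

  set.seed(91)
  for (rep in 1:10) {
    genes <- paste0("G", sprintf("%02d", 1:12))
    profs <- lapply(1:8, function(i) {
      make_profile(paste0("S", i),
                   muts = sample(genes, sample(0:6, 1)))
    })
    coh <- make_cohort(profs)
    sets <- lapply(coh$tumors, altered_genes)
    expect_equal(unname(unclass(comutation_counts(coh, genes))[, ]),
                 comutation_oracle(sets, genes))
  }
})

test_that("1/(c+1) normalization has the stated analytic properties", {
  expect_equal(normalize_comutation(matrix(0))[1], 1.0)
  expect_equal(normalize_comutation(matrix(1))[1], 0.5)
  expect_equal(normalize_comutation(matrix(3))[1], 0.25)
  expect_error(normalize_comutation(matrix(-1)), "non-negative")
  set.seed(92)
  for (rep in 1:10) {
    c0 <- matrix(rpois(36, 3), 6, 6)
    counts <- c0 + t(c0)                 # symmetric
    norm <- normalize_comutation(counts)
    expect_true(all(norm > 0 & norm <= 1))
    expect_true(isSymmetric(norm))
    expect_equal(norm == 1, counts == 0) # fixed point only at zero
    # strictly decreasing in c
    expect_true(all((normalize_comutation(counts + 1L) < norm)))
  }
})

test_that("Ward clustering handles edge cases and recovers planted blocks", {
  co <- make_cohort(list(
    make_profile("A1", muts = c("TP53", "CDH1")),
    make_profile("A2", muts = "TP53"),
    make_profile("A3", muts = "CDH1"),
    make_profile("B1", gains = "ERBB2"),
    make_profile("B2", gains = "ERBB2")))
  norm <- normalize_comutation(comutation_counts(co, tiny_panel()$genes))
  expect_equal(as.vector(ward_cluster(norm, 1)), rep(1L, 5))
  expect_error(ward_cluster(norm, 6), "between 1")
  # B1/B2 are the only identical profiles: zero distance keeps them
  # together at every cut below N
  for (k in 2:4) {
    cl <- ward_cluster(norm, k)
    expect_equal(cl[["B1"]], cl[["B2"]])
  }
  # two planted blocks, exhaustive check at small N: perfect recovery
  set.seed(93)
  genes <- paste0("G", sprintf("%02d", 1:12))
  profs <- c(
    lapply(1:5, function(i) make_profile(paste0("X", i),
                                         muts = c("G01", "G02", "G03"))),
    lapply(1:5, function(i) make_profile(paste0("Y", i),
                                         muts = c("G07", "G08", "G09"))))
  coh <- make_cohort(profs)
  nm <- normalize_comutation(comutation_counts(coh, genes))
  truth <- rep(1:2, each = 5)
  expect_equal(adjusted_rand_index(ward_cluster(nm, 2), truth), 1)
})

test_that("cluster assignments are invariant under tumor permutation", {
  set.seed(94)
  pc <- default_planted_clusters()
  pc$size <- c(10L, 8L, 8L, 6L, 8L)
  sim <- generate_cohort(synthetic_cohort_spec(n_tumors = 60, seed = 94,
                                               n_hypermutated = 10,
                                               planted_clusters = pc))
  bm <- compute_biomarkers(sim$cohort)
  nonhyper <- bm$tumor_id[!flag_hypermutated(bm$tmb,
                                             derive_hypermutation_cutoff(bm))]
  pool <- subset_cohort(sim$cohort, nonhyper)
  nm <- normalize_comutation(comutation_counts(pool, sim$cohort$panel$actionable))
  cl1 <- ward_cluster(nm, 4)
  perm <- sample(nrow(nm))
  cl2 <- ward_cluster(nm[perm, perm], 4)
  expect_equal(adjusted_rand_index(cl1[rownames(nm)[perm]], cl2), 1)
})

test_that("silhouette-based k selection finds well-separated blocks", {
  genes <- paste0("G", sprintf("%02d", 1:12))
  profs <- c(
    lapply(1:6, function(i) make_profile(paste0("A", i), muts = c("G01", "G02"))),
    lapply(1:6, function(i) make_profile(paste0("B", i), muts = c("G05", "G06"))),
    lapply(1:6, function(i) make_profile(paste0("C", i), muts = c("G09", "G10"))))
  coh <- make_cohort(profs)
  nm <- normalize_comutation(comutation_counts(coh, genes))
  k <- select_k(nm, 2:6)
  expect_equal(as.integer(k), 3L)
  tab <- attr(k, "stability")
  expect_equal(tab$k, 2:6)              # one row per candidate
  expect_named(tab, c("k", "connectivity", "silhouette", "dunn"))
  # degenerate input: all profiles identical
  same <- make_cohort(lapply(1:5, function(i) make_profile(paste0("S", i),
                                                           muts = "TP53")))
  nms <- normalize_comutation(comutation_counts(same, genes))
  expect_error(select_k(nms, 2:3), "identical")
  expect_error(select_k(nm, integer()), "non-empty")
})

test_that("silhouette and ARI agree with reference implementations", {
  skip_if_not_installed("cluster")
  skip_if_not_installed("mclust")
  set.seed(95)
  x <- matrix(rnorm(80), 20, 4)
  d <- dist(x)
  cl <- cutree(hclust(d, "ward.D2"), 3)
  ours <- panelclass:::silhouette_score(as.matrix(d), cl)
  ref <- mean(cluster::silhouette(cl, d)[, 3])
  expect_equal(ours, ref, tolerance = 1e-12)
  for (rep in 1:20) {
    a <- sample(1:4, 30, TRUE); b <- sample(1:3, 30, TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("cluster labels flag the enriched gene or stay unassigned", {
  set.seed(96)
  genes <- paste0("G", sprintf("%02d", 1:12))
  profs <- c(
    lapply(1:8, function(i) make_profile(paste0("E", i), muts = "G01")),
    lapply(1:8, function(i) make_profile(paste0("N", i),
                                         muts = sample(genes[5:12], 1))))
  coh <- make_cohort(profs)
  assignments <- stats::setNames(rep(1:2, each = 8), names(coh$tumors))
  labels <- label_clusters(assignments, coh, genes)
  expect_equal(labels[["1"]], "G01")
  expect_equal(labels[["2"]], "unassigned")  # nothing reaches 50%
  # invariant to tumor order
  perm <- sample(16)
  labels2 <- label_clusters(assignments[perm], coh, genes)
  expect_identical(labels, labels2)
})
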