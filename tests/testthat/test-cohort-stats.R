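test_that("alteration frequencies match a brute-force recount", {
  # 110 of 207 mutated tumors prints as 53.1%
  profs <- lapply(1:207, function(i) {
    make_profile(sprintf("T%03d", i),
                 muts = if (i <= 110) "TP53" else character())
  })
  co <- make_cohort(profs)
  f <- alteration_frequencies(co)
  expect_equal(f$frequency_pct[f$gene == "TP53"], 53.1)
  expect_false("ERBB2" %in% f$gene)   # never altered -> absent

  set.seed(101)
  genes <- paste0("G", sprintf("%02d", 1:12))
  profs <- lapply(1:40, function(i) {
    make_profile(paste0("S", i), muts = sample(genes, sample(0:4, 1)),
                 gains = sample(genes, sample(0:2, 1)))
  })
  co2 <- make_cohort(profs)
  f2 <- alteration_frequencies(co2)
  for (r in seq_len(nrow(f2))) {
    cnt <- sum(vapply(co2$tumors, function(t) {
      if (f2$alteration_class[r] == "mutation") {
        f2$gene[r] %in% t$variants$gene[t$variants$impact %in% c("high", "moderate")]
      } else if (f2$alteration_class[r] == "AMP") {
        f2$gene[r] %in% t$cnvs$gene[t$cnvs$call == "gain"]
      } else {
        f2$gene[r] %in% t$cnvs$gene[t$cnvs$call == "loss"]
      }
    }, logical(1)))
    expect_equal(f2$frequency_pct[r], round_half_away(100 * cnt / 40, 1))
  }
  # each class has consecutive ranks sorted by descending frequency
  for (cls in unique(f2$alteration_class)) {
    blk <- f2[f2$alteration_class == cls, ]
    if (cls %in% c("AMP", "DEL")) blk <- f2[f2$alteration_class %in% c("AMP", "DEL"), ]
    expect_true(all(diff(blk$frequency_pct) <= 0))
  }
})

test_that("a tumor contributes once per gene and class however many calls", {
  v <- variant_calls(c("TP53", "TP53"), c("SNV", "deletion"), c(0.4, 0.3),
                     c("high", "moderate"))
  t1 <- tumor_profile("T1", variants = v)
  co <- make_cohort(list(t1, make_profile("T2")))
  f <- alteration_frequencies(co)
  expect_equal(f$frequency_pct[f$gene == "TP53"], 50.0)
})

test_that("two-tailed Fisher matches exhaustive enumeration", {
  expect_equal(fisher_two_tailed(matrix(1, 2, 2)), 1.0)
  expect_error(fisher_two_tailed(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  m <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(fisher_two_tailed(m), fisher_enum_oracle(m), tolerance = 1e-7)
  expect_equal(fisher_two_tailed(m), 2 / choose(10, 5), tolerance = 1e-7)
  set.seed(102)
  for (rep in 1:200) {
    tab <- matrix(rpois(4, sample(1:4, 1)), 2)
    if (sum(tab) < 1) next
    expect_equal(fisher_two_tailed(tab), fisher_enum_oracle(tab),
                 tolerance = 1e-7)
  }
})

test_that("Mann-Whitney switches correctly between exact and approximate", {
  x <- c(1.2, 3.4, 5.1, 7.9)
  expect_equal(mann_whitney(x, x), 1.0)           # identical samples
  expect_error(mann_whitney(numeric(), 1), "non-empty")
  # complete separation at n = 5: the smallest attainable two-sided p
  lo <- c(1, 2, 3, 4, 5); hi <- c(10, 11, 12, 13, 14)
  expect_equal(mann_whitney(hi, lo), 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(mann_whitney(hi, lo), mw_enum_oracle(hi, lo), tolerance = 1e-12)
  # within-sample ordering cannot matter
  set.seed(103)
  a <- rnorm(7); b <- rnorm(9)
  expect_equal(mann_whitney(a, b), mann_whitney(sample(a), sample(b)))
  # exact branch vs full rank-split enumeration on random no-tie data
  for (rep in 1:15) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    z <- sample(seq_len(40), nx + ny)   # distinct values, no ties
    x <- z[seq_len(nx)]; y <- z[-seq_len(nx)]
    expect_equal(mann_whitney(x, y), mw_enum_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("group association screen mirrors the underlying tests", {
  set.seed(104)
  n <- 120
  feats <- data.frame(
    tumor_id = paste0("T", 1:n),
    lauren_type = c(sample(c("diffuse", "intestinal"), 20, TRUE,
                           prob = c(0.9, 0.1)),
                    sample(c("diffuse", "intestinal"), 100, TRUE,
                           prob = c(0.1, 0.9))),
    age = rnorm(n, 65, 8))
  grouping <- stats::setNames(rep(c("g1", "g2"), c(20, 100)), feats$tumor_id)
  res <- associate_groups(feats, grouping)
  # planted diffuse enrichment must reach significance and match the
  # directly constructed Fisher table
  row <- res[which(res$group == "g1" & res$level == "diffuse"), ]
  expect_true(row$significant)
  hit <- feats$lauren_type == "diffuse"
  inside <- grouping[feats$tumor_id] == "g1"
  tab <- matrix(c(sum(hit & inside), sum(!hit & inside),
                  sum(hit & !inside), sum(!hit & !inside)), 2)
  expect_equal(row$p_value, fisher_enum_oracle(tab), tolerance = 1e-7)
  expect_equal(row$direction, "enriched")
  # 2 groups x (2 levels + 1 continuous) rows, BH column present
  expect_equal(nrow(res), 2 * 3)
  expect_true(all(res$p_bh >= res$p_value))
  # a feature distributed identically between group and rest -> p = 1
  same <- data.frame(tumor_id = paste0("T", 1:40),
                     flag = rep(c("yes", "no"), 20))
  g2 <- stats::setNames(rep(c("a", "b"), each = 20), same$tumor_id)
  r2 <- associate_groups(same, g2)
  expect_equal(r2$p_value, rep(1, 4), tolerance = 1e-12)
})
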