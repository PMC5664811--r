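#' Pairwise co-alteration counts
#'
#' Builds the N x N matrix whose element c_ij is the number of genes in
#' `gene_set` altered in both tumor i and tumor j; the diagonal c_ii is the
#' tumor's own altered-gene count. "Altered" defaults to [altered_genes()]
#' (peptide-changing mutation or copy-number gain/loss) and is injectable
#' for sensitivity analysis. Hypermutated tumors are expected to be
#' excluded by the caller (see [subset_cohort()]).
#'
#' @param cohort a [gc_cohort].
#' @param gene_set non-empty character vector of genes to consider.
#' @param altered_fun function(tumor_profile) -> character vector of
#'   altered genes.
#' @return symmetric integer matrix with tumor ids as dimnames; the binary
#'   tumor-by-gene alteration matrix is attached as attribute
#'   `"alteration_matrix"`.
#' @export
comutation_counts <- function(cohort, gene_set, altered_fun = altered_genes) {
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) == 0L) stop("gene_set must be non-empty", call. = FALSE)
  a <- t(vapply(cohort$tumors,
                function(t) gene_set %in% altered_fun(t),
                logical(length(gene_set))))
  dimnames(a) <- list(tumor_ids(cohort), gene_set)
  counts <- a %*% t(a)
  storage.mode(counts) <- "integer"
  attr(counts, "alteration_matrix") <- a
  counts
}

#' Similarity normalization of co-alteration counts
#'
#' Replaces each count c by 1/(c + 1), mapping counts into (0, 1]: tumor
#' pairs sharing no altered gene sit at 1 and pairs sharing many approach
#' 0, so the normalized value behaves as a dissimilarity-like similarity
#' score. The transform is applied verbatim to every element, diagonal
#' included, and is strictly decreasing in c.
#'
#' @param counts non-negative matrix from [comutation_counts()].
#' @return numeric matrix of the same shape with entries in (0, 1].
#' @export
normalize_comutation <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  out <- 1 / (unclass(counts) + 1)
  attr(out, "alteration_matrix") <- NULL
  out
}

#' Ward hierarchical clustering of the normalized matrix
#'
#' Rows of the normalized matrix are treated as feature vectors; pairwise
#' Euclidean distances feed agglomerative clustering under Ward's
#' minimum-variance criterion (`stats::hclust`, method `"ward.D2"`, the
#' Ward criterion appropriate for unsquared Euclidean input). The
#' agglomeration is deterministic for a given input.
#'
#' @param normalized square symmetric matrix from [normalize_comutation()].
#' @param k number of clusters, 1 <= k <= N.
#' @param method linkage passed to `stats::hclust`.
#' @return named integer vector of cluster indices (1..k) keyed by tumor
#'   id, with the `hclust` tree attached as attribute `"hclust"`.
#' @export
ward_cluster <- function(normalized, k, method = "ward.D2") {
  n <- nrow(normalized)
  if (!is.matrix(normalized) || n != ncol(normalized)) {
    stop("normalized must be a square matrix", call. = FALSE)
  }
  if (!is_scalar_number(k) || k < 1 || k > n) {
    stop("k must be between 1 and the number of tumors", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(normalized), method = method)
  assignments <- stats::cutree(hc, k = as.integer(k))
  attr(assignments, "hclust") <- hc
  assignments
}

# ---- internal validation measures (standard definitions) -------------------

# connectivity (Handl et al.): for each observation, penalize the nearest
# neighbors not sharing its cluster with weight 1/rank; lower is better
connectivity_score <- function(dmat, assignments, neighbor_size = 10) {
  n <- nrow(dmat)
  L <- min(neighbor_size, n - 1L)
  total <- 0
  for (i in seq_len(n)) {
    nn <- order(dmat[i, -i])  # ranks among the other observations
    others <- seq_len(n)[-i][nn[seq_len(L)]]
    total <- total + sum((assignments[others] != assignments[i]) / seq_len(L))
  }
  total
}

# average silhouette width from a distance matrix; singletons score 0
silhouette_score <- function(dmat, assignments) {
  n <- nrow(dmat)
  ks <- unique(assignments)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignments[i]
    same <- which(assignments == own)
    if (length(same) == 1L) { s[i] <- 0; next }
    a <- mean(dmat[i, setdiff(same, i)])
    b <- min(vapply(setdiff(ks, own),
                    function(kk) mean(dmat[i, assignments == kk]),
                    numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Dunn index: smallest between-cluster distance over largest diameter
dunn_score <- function(dmat, assignments) {
  ks <- unique(assignments)
  diam <- max(vapply(ks, function(kk) {
    idx <- which(assignments == kk)
    if (length(idx) < 2L) 0 else max(dmat[idx, idx])
  }, numeric(1)))
  sep <- min(vapply(seq_along(ks)[-1], function(i) {
    min(vapply(seq_len(i - 1L), function(j) {
      min(dmat[assignments == ks[i], assignments == ks[j], drop = FALSE])
    }, numeric(1)))
  }, numeric(1)))
  sep / diam
}

#' Clustering stability table and k selection
#'
#' Computes three internal validation measures per candidate k —
#' connectivity (lower is better), average silhouette width and Dunn index
#' (higher is better) — over cuts of the same Ward tree, and selects the k
#' maximizing average silhouette width, with ties broken toward smaller k.
#'
#' @param normalized square matrix from [normalize_comutation()].
#' @param k_range integer candidates, each in 2..N-1.
#' @param neighbor_size neighborhood size of the connectivity measure.
#' @param method Ward linkage variant.
#' @return `cluster_stability()`: data.frame with one row per k
#'   (`k`, `connectivity`, `silhouette`, `dunn`). `select_k()`: the chosen
#'   k, with the full table attached as attribute `"stability"`.
#' @export
cluster_stability <- function(normalized, k_range = 2:10, neighbor_size = 10,
                              method = "ward.D2") {
  n <- nrow(normalized)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("k_range must be non-empty", call. = FALSE)
  if (any(k_range < 2L | k_range > n - 1L)) {
    stop("k_range must lie within 2..N-1", call. = FALSE)
  }
  d <- stats::dist(normalized)
  if (max(d) == 0) {
    stop("all tumor profiles are identical; silhouette is undefined",
         call. = FALSE)
  }
  dmat <- as.matrix(d)
  hc <- stats::hclust(d, method = method)
  rows <- lapply(k_range, function(k) {
    cl <- stats::cutree(hc, k = k)
    data.frame(k = k,
               connectivity = connectivity_score(dmat, cl, neighbor_size),
               silhouette = silhouette_score(dmat, cl),
               dunn = dunn_score(dmat, cl))
  })
  do.call(rbind, rows)
}

#' @rdname cluster_stability
#' @export
select_k <- function(normalized, k_range = 2:10, neighbor_size = 10,
                     method = "ward.D2") {
  tab <- cluster_stability(normalized, k_range, neighbor_size, method)
  k <- tab$k[which.max(tab$silhouette)]  # table sorted by k: ties -> smaller
  attr(k, "stability") <- tab
  k
}

#' Label clusters by their characteristic actionable gene
#'
#' For each cluster, candidate genes are those altered in at least
#' `min_freq` of the cluster's tumors; among candidates the gene with the
#' smallest two-tailed Fisher p-value (cluster vs all other tumors) wins,
#' with ties broken by higher within-cluster frequency and then
#' alphabetically. A cluster with no qualifying gene — the "minor
#' alterations" group — is labelled `"unassigned"`.
#'
#' @param assignments named integer vector from [ward_cluster()].
#' @param cohort the [gc_cohort] the assignments refer to.
#' @param gene_set genes eligible as labels.
#' @param min_freq minimum within-cluster alteration frequency (default 0.5).
#' @param altered_fun alteration predicate, as in [comutation_counts()].
#' @return named character vector: cluster index -> gene symbol or
#'   `"unassigned"`.
#' @export
label_clusters <- function(assignments, cohort, gene_set, min_freq = 0.5,
                           altered_fun = altered_genes) {
  ids <- names(assignments)
  sub <- subset_cohort(cohort, ids)
  a <- t(vapply(sub$tumors, function(t) gene_set %in% altered_fun(t),
                logical(length(gene_set))))
  colnames(a) <- gene_set
  ks <- sort(unique(assignments))
  labels <- vapply(ks, function(kk) {
    inside <- assignments == kk
    n_in <- sum(inside)
    freq <- colSums(a[inside, , drop = FALSE]) / n_in
    cand <- which(freq >= min_freq)
    if (length(cand) == 0L) return("unassigned")
    p <- vapply(cand, function(g) {
      fisher_two_tailed(matrix(c(sum(a[inside, g]), n_in - sum(a[inside, g]),
                                 sum(a[!inside, g]),
                                 sum(!inside) - sum(a[!inside, g])),
                               nrow = 2, byrow = TRUE))
    }, numeric(1))
    ord <- order(p, -freq[cand], gene_set[cand], method = "radix")
    gene_set[cand[ord[1]]]
  }, character(1))
  names(labels) <- as.character(ks)
  labels
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to score recovery of planted cluster structure. 1 means identical
#' partitions (up to label permutation), 0 the expectation under random
#' labeling.
#'
#' @param x,y vectors of cluster labels of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  n <- length(x)
  sum_comb <- function(v) sum(choose(v, 2))
  idx <- sum_comb(as.vector(tab))
  a <- sum_comb(rowSums(tab))
  b <- sum_comb(colSums(tab))
  expected <- a * b / choose(n, 2)
  maximum <- (a + b) / 2
  if (maximum == expected) return(1)  # both partitions trivial
  (idx - expected) / (maximum - expected)
}

#' Co-alteration clustering of a cohort, end to end
#'
#' Convenience wrapper mirroring the published analysis: drop hypermutated
#' tumors, count shared actionable-gene alterations, normalize with
#' 1/(c+1), cluster with Euclidean/Ward, and label clusters by their
#' enriched gene.
#'
#' @param cohort a [gc_cohort].
#' @param biomarkers data.frame from [compute_biomarkers()].
#' @param gene_set `"actionable"`, `"all"`, or an explicit character vector.
#' @param k number of clusters, or `"auto"` for silhouette-based selection
#'   over `k_range`.
#' @param exclude_hypermutated drop hypermutated tumors first (default TRUE).
#' @param hypermutation_cutoff `"auto"` or an explicit counts/Mb value.
#' @param k_range candidate k values when `k = "auto"`.
#' @return list with `assignments` (data.frame `tumor_id`, `cluster`,
#'   `label`), `labels`, `k`, `stability` (NULL unless `k = "auto"`),
#'   `hclust`, `counts`, `normalized` and `excluded` (hypermutated ids).
#' @export
cluster_cohort <- function(cohort, biomarkers, gene_set = "actionable",
                           k = 6, exclude_hypermutated = TRUE,
                           hypermutation_cutoff = "auto", k_range = 2:10) {
  genes <- if (identical(gene_set, "actionable")) {
    cohort$panel$actionable
  } else if (identical(gene_set, "all")) {
    cohort$panel$genes
  } else {
    as.character(gene_set)
  }
  excluded <- character()
  pool <- cohort
  if (exclude_hypermutated) {
    cutoff <- if (identical(hypermutation_cutoff, "auto")) {
      derive_hypermutation_cutoff(biomarkers)
    } else {
      as.numeric(hypermutation_cutoff)
    }
    hyper <- flag_hypermutated(biomarkers$tmb, cutoff)
    excluded <- biomarkers$tumor_id[hyper]
    pool <- subset_cohort(cohort, setdiff(biomarkers$tumor_id, excluded))
  }
  counts <- comutation_counts(pool, genes)
  normalized <- normalize_comutation(counts)
  stability <- NULL
  if (identical(k, "auto")) {
    k <- select_k(normalized, k_range)
    stability <- attr(k, "stability")
    k <- as.integer(k)
  }
  assignments <- ward_cluster(normalized, k)
  labels <- label_clusters(assignments, pool, genes)
  list(assignments = data.frame(tumor_id = names(assignments),
                                cluster = as.integer(assignments),
                                label = unname(labels[as.character(assignments)])),
       labels = labels, k = k, stability = stability,
       hclust = attr(assignments, "hclust"),
       counts = counts, normalized = normalized, excluded = excluded)
}
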