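#' Cohort alteration frequency table
#'
#' Per-gene alteration frequencies in the style of a published landscape
#' table: the mutation column counts tumors with at least one
#' peptide-changing mutation of the gene; the SCNA columns count tumors
#' with a gain (`AMP`) or loss (`DEL`) of the gene, reported separately.
#' Frequencies are percentages of the cohort, rounded to one decimal with
#' halves away from zero; genes never altered are omitted; ranks are
#' consecutive within each alteration class (ties share frequency but are
#' ordered alphabetically).
#'
#' @param cohort a [gc_cohort].
#' @param classes which classes to tabulate (`"mutation"`, `"SCNA"`).
#' @return data.frame `rank`, `gene`, `alteration_class`
#'   (`mutation`/`AMP`/`DEL`), `frequency_pct`, `actionable`.
#' @export
alteration_frequencies <- function(cohort, classes = c("mutation", "SCNA")) {
  classes <- match.arg(classes, c("mutation", "SCNA"), several.ok = TRUE)
  n <- n_tumors(cohort)
  out <- list()
  if ("mutation" %in% classes) {
    per_tumor <- lapply(cohort$tumors, function(t) {
      unique(t$variants$gene[t$variants$impact %in% c("high", "moderate")])
    })
    counts <- table(unlist(per_tumor))
    out$mutation <- rank_block(counts, "mutation", n)
  }
  if ("SCNA" %in% classes) {
    amp <- table(unlist(lapply(cohort$tumors, function(t) {
      unique(t$cnvs$gene[t$cnvs$call == "gain"])
    })))
    del <- table(unlist(lapply(cohort$tumors, function(t) {
      unique(t$cnvs$gene[t$cnvs$call == "loss"])
    })))
    scna <- rbind(rank_block(amp, "AMP", n), rank_block(del, "DEL", n))
    if (nrow(scna) > 0L) {
      # one shared ranking across AMP and DEL, as in the published table
      ord <- order(-scna$frequency_pct, scna$gene, method = "radix")
      scna <- scna[ord, , drop = FALSE]
      scna$rank <- seq_len(nrow(scna))
    }
    out$SCNA <- scna
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(rank = integer(), gene = character(),
                      alteration_class = character(),
                      frequency_pct = numeric(), actionable = logical())
  }
  res$actionable <- res$gene %in% cohort$panel$actionable
  rownames(res) <- NULL
  res
}

rank_block <- function(counts, class_name, n) {
  if (length(counts) == 0L) {
    return(data.frame(rank = integer(), gene = character(),
                      alteration_class = character(),
                      frequency_pct = numeric()))
  }
  df <- data.frame(gene = names(counts),
                   frequency_pct = round_half_away(100 * as.vector(counts) / n, 1))
  df <- df[order(-df$frequency_pct, df$gene, method = "radix"), , drop = FALSE]
  data.frame(rank = seq_len(nrow(df)), gene = df$gene,
             alteration_class = class_name, frequency_pct = df$frequency_pct)
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities, over
#' all tables with the observed margins, that do not exceed the probability
#' of the observed table.
#'
#' @param tab 2x2 matrix (or table) of non-negative counts, grand total >= 1.
#' @return the p-value in (0, 1].
#' @export
fisher_two_tailed <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2", call. = FALSE)
  if (any(tab < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (sum(tab) < 1) stop("grand total must be >= 1", call. = FALSE)
  min(1, stats::fisher.test(tab)$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration of the rank-sum distribution when the smaller sample
#' has at most `exact_max_n` observations and there are no ties; otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_max_n largest minimum-sample size for the exact branch.
#' @return two-sided p-value.
#' @export
mann_whitney <- function(x, y, exact_max_n = 8) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- min(length(x), length(y)) <= exact_max_n && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  )
  min(1, p)
}

#' Group-vs-rest association screen
#'
#' For every group of a partition and every feature, tests the group
#' against the remaining tumors: Fisher's two-tailed exact test per level
#' for categorical features (multi-level features are dichotomized one
#' level at a time) and the Mann-Whitney U test for continuous features.
#' Raw p-values carry the significance flag at P < 0.05, mirroring the
#' published analysis which applies no multiple-testing correction; a
#' Benjamini-Hochberg column is emitted alongside for responsible reuse but
#' never feeds the flag.
#'
#' @param features data.frame with a `tumor_id` column plus feature
#'   columns; numeric columns are treated as continuous, everything else as
#'   categorical.
#' @param grouping named vector (names = tumor ids) of group labels
#'   covering the rows of `features`.
#' @param reference optional tumor ids to use as the comparison set instead
#'   of "all other tumors" (e.g. non-hypermutated donors as reference for
#'   the hypermutated contrast).
#' @return data.frame `group`, `feature`, `level`, `test`, `p_value`,
#'   `direction`, `significant`, `p_bh`.
#' @export
associate_groups <- function(features, grouping, reference = NULL) {
  stopifnot("tumor_id" %in% names(features))
  ids <- features$tumor_id
  if (!all(ids %in% names(grouping))) {
    stop("grouping must cover every tumor in features", call. = FALSE)
  }
  groups <- unique(grouping[ids])
  feature_cols <- setdiff(names(features), "tumor_id")
  rows <- list()
  for (g in groups) {
    inside <- grouping[ids] == g
    if (sum(inside) == 0L) {
      warning("group with 0 members skipped: ", g, call. = FALSE)
      next
    }
    rest <- if (is.null(reference)) !inside else ids %in% setdiff(reference, ids[inside])
    if (sum(rest) == 0L) {
      warning("group with empty comparison set skipped: ", g, call. = FALSE)
      next
    }
    for (f in feature_cols) {
      v <- features[[f]]
      if (is.numeric(v)) {
        p <- mann_whitney(v[inside], v[rest])
        dir <- if (stats::median(v[inside], na.rm = TRUE) >=
                   stats::median(v[rest], na.rm = TRUE)) "higher" else "lower"
        rows[[length(rows) + 1L]] <- data.frame(
          group = as.character(g), feature = f, level = NA_character_,
          test = "mann_whitney", p_value = p, direction = dir)
      } else {
        for (lev in sort(unique(as.character(v)))) {
          hit <- as.character(v) == lev
          tab <- matrix(c(sum(hit & inside), sum(!hit & inside),
                          sum(hit & rest), sum(!hit & rest)), nrow = 2)
          p <- fisher_two_tailed(tab)
          dir <- if (mean(hit[inside]) >= mean(hit[rest])) "enriched" else "depleted"
          rows[[length(rows) + 1L]] <- data.frame(
            group = as.character(g), feature = f, level = lev,
            test = "fisher_two_tailed", p_value = p, direction = dir)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(group = character(), feature = character(),
                      level = character(), test = character(),
                      p_value = numeric(), direction = character(),
                      significant = logical(), p_bh = numeric()))
  }
  out$significant <- out$p_value < 0.05
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
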