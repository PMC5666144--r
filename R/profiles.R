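#' One-way analysis of variance
#'
#' Fixed-effects one-way ANOVA computed from the sums-of-squares
#' definitions: F = MS_between / MS_within on (k - 1, N - k) degrees of
#' freedom, p from the upper tail of the F distribution. Degenerate inputs
#' are reported rather than hidden: zero within-group variance with unequal
#' means gives p = 0 with `degenerate = TRUE`; completely constant data give
#' F = 0, p = 1.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation (>= 2 groups, each with >= 2
#'   finite values).
#' @return List with `F`, `p_value`, `df1`, `df2`, `degenerate`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  N <- length(values); k <- nlevels(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tabulate(groups)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- k - 1L; df2 <- N - k
  tol <- 1e-12 * max(1, sum((values - gm)^2))
  if (ssw <= tol) {
    if (ssb <= tol)
      return(list(F = 0, p_value = 1, df1 = df1, df2 = df2,
                  degenerate = FALSE))
    return(list(F = Inf, p_value = 0, df1 = df1, df2 = df2,
                degenerate = TRUE))
  }
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, p_value = pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, degenerate = FALSE)
}

#' Differential-expression filter (fold change + ANOVA p)
#'
#' Per row, the fold change is the ratio of linear-scale group means,
#' `mean(group_a) / mean(group_b)`, and the p-value comes from
#' [one_way_anova()] on the two groups. A row is `up` when FC >=
#' `fc_threshold` and p < `p_threshold`, `down` when FC <= 1/`fc_threshold`
#' and p < `p_threshold`; the sets are disjoint by construction. Rows whose
#' `group_b` mean is zero are excluded and tallied.
#'
#' @param pm a [profile_matrix].
#' @param group_a,group_b group labels to contrast (`a` relative to `b`).
#' @param fc_threshold linear fold-change threshold (e.g. 2 or 5).
#' @param p_threshold p-value threshold (the study design uses 0.01).
#' @return List with `up`, `down` (row-id character vectors), `table`
#'   (per-row fold change, p, means) and `n_excluded`.
#' @export
de_filter <- function(pm, group_a, group_b, fc_threshold = 2,
                      p_threshold = 0.01) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (!all(c(group_a, group_b) %in% levels(pm$groups)))
    stop("unknown group label")
  sel <- pm$groups %in% c(group_a, group_b)
  v <- pm$values[, sel, drop = FALSE]
  gl <- droplevels(pm$groups[sel])
  if (any(table(gl) < 2)) stop("both groups need at least 2 samples")
  a_cols <- gl == group_a
  mean_a <- rowMeans(v[, a_cols, drop = FALSE])
  mean_b <- rowMeans(v[, !a_cols, drop = FALSE])
  p <- vapply(seq_len(nrow(v)), function(i) {
    if (mean_b[i] == 0) return(NA_real_)
    one_way_anova(v[i, ], gl)$p_value
  }, numeric(1))
  tab <- data.frame(row_id = rownames(v), mean_a = mean_a, mean_b = mean_b,
                    fold_change = ifelse(mean_b == 0, NA_real_,
                                         mean_a / mean_b),
                    p_value = p, stringsAsFactors = FALSE, row.names = NULL)
  excluded <- is.na(tab$fold_change)
  ok <- !excluded
  up <- tab$row_id[ok & tab$fold_change >= fc_threshold &
                     tab$p_value < p_threshold]
  down <- tab$row_id[ok & tab$fold_change <= 1 / fc_threshold &
                       tab$p_value < p_threshold]
  if (fc_threshold <= 1) down <- setdiff(down, up)  # keep sets disjoint
  list(up = up, down = down, table = tab, n_excluded = sum(excluded))
}

#' Hierarchical clustering of expression/growth patterns
#'
#' Agglomerative clustering of rows with correlation distance
#' (1 - Pearson) or Euclidean distance and a configurable linkage, cut to
#' exactly `k` clusters. Rows with zero variance (undefined correlation)
#' are set aside and assigned afterwards to the cluster with the nearest
#' Euclidean centroid, so constant ("flat") rows land in the flat cluster
#' instead of breaking the distance computation. Deterministic for a given
#' input order.
#'
#' @param x a [profile_matrix] or numeric matrix.
#' @param k number of clusters (1 <= k <= number of rows).
#' @param distance `"one_minus_pearson"` (default) or `"euclidean"`.
#' @param linkage an [stats::hclust()] method (default `"average"`).
#' @return List with `labels` (named integer vector, labels 1..k contiguous
#'   in order of first appearance), `tree` (the `hclust` object over the
#'   clustered rows, or `NULL` when fewer than 2 rows were clustered) and
#'   `n_constant` (rows assigned by the nearest-centroid post-pass).
#' @export
hierarchical_cluster <- function(x, k,
                                 distance = c("one_minus_pearson",
                                              "euclidean"),
                                 linkage = "average") {
  distance <- match.arg(distance)
  v <- if (inherits(x, "profile_matrix")) x$values else x
  stopifnot(is.matrix(v), !is.null(rownames(v)))
  n <- nrow(v)
  if (k > n) stop("k exceeds the number of rows")
  if (k < 1) stop("k must be >= 1")
  rsd <- apply(v, 1, sd)
  constant <- distance == "one_minus_pearson" & rsd == 0
  core <- v[!constant, , drop = FALSE]
  if (nrow(core) < k)
    stop("fewer rows with variance than clusters requested")
  if (nrow(core) >= 2) {
    d <- if (distance == "one_minus_pearson")
      as.dist(1 - cor(t(core))) else stats::dist(core)
    tree <- hclust(d, method = linkage)
    raw <- cutree(tree, k = k)
  } else {
    tree <- NULL
    raw <- setNames(rep(1L, nrow(core)), rownames(core))
  }
  # relabel contiguously in order of first appearance
  lev <- unique(raw)
  labels <- setNames(match(raw, lev), names(raw))
  if (any(constant)) {
    centroids <- t(vapply(seq_len(k), function(cl)
      colMeans(core[labels == cl, , drop = FALSE]), numeric(ncol(v))))
    for (rid in rownames(v)[constant]) {
      dd <- rowSums((centroids - matrix(v[rid, ], k, ncol(v),
                                        byrow = TRUE))^2)
      labels[rid] <- which.min(dd)
    }
  }
  list(labels = labels[rownames(v)], tree = tree,
       n_constant = sum(constant),
       distance = distance, linkage = linkage)
}

#' Relative growth of one strain versus another
#'
#' Summarizes paired replicate readings (e.g. turbidity on one carbon
#' source) as mean percent growth of strain `a` relative to strain `b`,
#' with a standard deviation. Equal replicate counts are paired replicate
#' i to replicate i and the SD is that of the per-pair ratios; unequal
#' counts fall back to the ratio of means with a seeded-by-caller
#' resampling SD. Non-positive readings are excluded with a tally.
#'
#' @param a,b numeric replicate vectors (>= 2 positive values each).
#' @param n_boot bootstrap resamples for the unequal-count case.
#' @return List with `percent`, `sd`, `method` (`"paired"` or
#'   `"bootstrap"`) and `n_excluded`.
#' @export
relative_growth <- function(a, b, n_boot = 1000) {
  drop_a <- sum(a <= 0 | !is.finite(a)); drop_b <- sum(b <= 0 | !is.finite(b))
  a <- a[a > 0 & is.finite(a)]; b <- b[b > 0 & is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 positive replicates per strain")
  if (length(a) == length(b)) {
    ratios <- 100 * a / b
    return(list(percent = mean(ratios), sd = sd(ratios),
                method = "paired", n_excluded = drop_a + drop_b))
  }
  est <- 100 * mean(a) / mean(b)
  boot <- vapply(seq_len(n_boot), function(i)
    100 * mean(sample(a, replace = TRUE)) / mean(sample(b, replace = TRUE)),
    numeric(1))
  list(percent = est, sd = sd(boot), method = "bootstrap",
       n_excluded = drop_a + drop_b)
}

#' Hypergeometric enrichment of functional categories
#'
#' One-sided hypergeometric upper-tail test per category: the probability
#' of drawing at least the observed overlap when `length(gene_set)` genes
#' are sampled from the universe. Raw p-values are reported by default
#' (matching classical functional-category analyses); a correction can be
#' requested.
#'
#' @param gene_set character vector, subset of `universe`.
#' @param universe character vector of all genes.
#' @param categories named list of character vectors (genes may appear in
#'   several categories).
#' @param adjust a [stats::p.adjust()] method (`"none"` by default).
#' @return data.frame with `category`, `n_category`, `n_overlap`,
#'   `expected`, `p_value`, `adjusted_p`.
#' @export
enrich_categories <- function(gene_set, universe, categories,
                              adjust = "none") {
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  if (!length(categories) || is.null(names(categories)))
    stop("categories must be a named list")
  N <- length(universe); n <- length(gene_set)
  res <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(unique(categories[[nm]]), universe)
    m <- length(cat_genes)
    x <- length(intersect(cat_genes, gene_set))
    p <- if (n == 0 || m == 0) 1 else
      phyper(x - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(category = nm, n_category = m, n_overlap = x,
               expected = m * n / N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- p.adjust(out$p_value, method = adjust)
  rownames(out) <- NULL
  out
}
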