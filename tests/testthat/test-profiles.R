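test_that("one-way ANOVA reproduces the definitional sums of squares", {
  # identical groups: no between-group variance at all
  r0 <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r0$F, 0)
  expect_equal(r0$p_value, 1)

  # hand-computed: SSB = 13.5, SSW = 4, F = 13.5 on (1, 4) df
  r <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$F, 13.5)
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 4)
  expect_equal(r$p_value, pf(13.5, 1, 4, lower.tail = FALSE))

  # independent oracle: stats::anova on a linear model
  set.seed(701)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    g <- factor(rep(seq_len(k), each = sample(2:5, 1)))
    y <- rnorm(length(g), mean = as.integer(g))
    mine <- one_way_anova(y, g)
    ref <- stats::anova(stats::lm(y ~ g))
    expect_equal(mine$F, ref$`F value`[1])
    expect_equal(mine$p_value, ref$`Pr(>F)`[1])
  }

  # degenerate: zero within-group variance with unequal means
  rd <- one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(rd$degenerate)
  expect_equal(rd$p_value, 0)

  expect_error(one_way_anova(1:4, rep("a", 4)), "2 groups")
  expect_error(one_way_anova(1:3, c("a", "a", "b")), "at least 2 values")
})

test_that("two-group ANOVA equals the squared pooled-variance t-test", {
  set.seed(702)
  for (i in 1:30) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    x <- rnorm(na); y <- rnorm(nb, mean = runif(1, -1, 1))
    a <- one_way_anova(c(x, y), rep(c("a", "b"), c(na, nb)))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("DE filter applies fold-change and p thresholds with planted truth", {
  set.seed(703)
  n_true <- 50; n_null <- 500
  vals <- rbind(
    matrix(rnorm(n_true * 6, mean = rep(c(8, 1), each = 3), sd = 0.3),
           n_true, 6, byrow = TRUE),
    matrix(rnorm(n_null * 6, mean = 1, sd = 0.3), n_null, 6))
  vals[vals < 0.01] <- 0.01
  rownames(vals) <- c(sprintf("true%02d", 1:n_true),
                      sprintf("null%03d", 1:n_null))
  colnames(vals) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  pm <- profile_matrix(vals, rep(c("A", "B"), each = 3))
  de <- de_filter(pm, "A", "B", fc_threshold = 5, p_threshold = 0.01)
  expect_gte(sum(startsWith(de$up, "true")), n_true - 2)
  expect_lte(sum(startsWith(de$up, "null") | startsWith(de$down, "null")),
             0.05 * n_null)
  expect_length(intersect(de$up, de$down), 0)

  # swapping the contrast swaps up and down exactly
  de_sw <- de_filter(pm, "B", "A", fc_threshold = 5, p_threshold = 0.01)
  expect_setequal(de_sw$down, de$up)
  expect_setequal(de_sw$up, de$down)

  # vacuous thresholds catch every non-degenerate row
  de_all <- de_filter(pm, "A", "B", fc_threshold = 1, p_threshold = 1)
  expect_equal(sort(unique(c(de_all$up, de_all$down))),
               sort(rownames(vals)))

  # zero group-b mean rows are excluded with a tally
  vz <- vals
  vz[1, 4:6] <- 0
  pz <- profile_matrix(vz, rep(c("A", "B"), each = 3))
  dez <- de_filter(pz, "A", "B", 2, 0.01)
  expect_equal(dez$n_excluded, 1)
})

test_that("hierarchical clustering recovers planted archetypes and handles edge cases", {
  set.seed(704)
  sim <- simulate_expression_profiles(n_per_cluster = c(25, 10, 20),
                                      noise_sd = 0.05)
  # Euclidean geometry: the flat archetype is a level, not a pattern, and
  # correlation distance is blind to it (noisy flat rows are mutually
  # uncorrelated)
  cl <- hierarchical_cluster(sim$matrix, k = 3, distance = "euclidean")
  expect_equal(adjusted_rand_index(cl$labels, sim$truth), 1)
  # cross-check the agreement statistic itself against mclust
  if (requireNamespace("mclust", quietly = TRUE))
    expect_equal(mclust::adjustedRandIndex(cl$labels, sim$truth), 1)

  # two groups of identical rows split perfectly at k = 2
  v <- rbind(matrix(rep(c(5, 5, 1, 1), 4), 4, byrow = TRUE),
             matrix(rep(c(1, 1, 5, 5), 3), 3, byrow = TRUE))
  v <- v + matrix(rnorm(28, sd = 1e-4), 7, 4)
  rownames(v) <- sprintf("r%d", 1:7); colnames(v) <- sprintf("s%d", 1:4)
  cl2 <- hierarchical_cluster(v, k = 2)
  expect_equal(unname(cl2$labels), c(1, 1, 1, 1, 2, 2, 2))

  # k = 1 puts everything in one cluster; k > n errors
  expect_true(all(hierarchical_cluster(v, k = 1)$labels == 1))
  expect_error(hierarchical_cluster(v, k = 10), "exceeds")

  # constant rows go to the nearest-centroid cluster under correlation
  # distance instead of breaking it
  low <- matrix(rep(c(1, 2, 3, 4), 8), 8, byrow = TRUE) +
    matrix(rnorm(32, sd = 0.05), 8)
  high <- matrix(rep(c(10, 9, 8, 7), 8), 8, byrow = TRUE) +
    matrix(rnorm(32, sd = 0.05), 8)
  vals <- rbind(low, high, flatrow = rep(1.5, 4))
  rownames(vals) <- c(sprintf("lo%d", 1:8), sprintf("hi%d", 1:8), "flatrow")
  colnames(vals) <- sprintf("s%d", 1:4)
  cl3 <- hierarchical_cluster(vals, k = 2)
  expect_equal(cl3$n_constant, 1)
  expect_equal(unname(cl3$labels["flatrow"]),
               unname(cl3$labels["lo1"]))    # nearest centroid is the low set
})

test_that("clustering is invariant under row permutation up to relabeling", {
  set.seed(705)
  sim <- simulate_expression_profiles(n_per_cluster = c(15, 10, 12),
                                      noise_sd = 0.2)
  v <- sim$matrix$values
  cl <- hierarchical_cluster(v, k = 3)
  perm <- sample(nrow(v))
  cl_p <- hierarchical_cluster(v[perm, ], k = 3)
  expect_equal(adjusted_rand_index(cl$labels[rownames(v)],
                                   cl_p$labels[rownames(v)]), 1)
})

test_that("relative growth summarizes paired ratios and excludes bad readings", {
  r0 <- relative_growth(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r0$percent, 100)
  expect_equal(r0$sd, 0)
  r1 <- relative_growth(c(2, 2, 2), c(1, 1, 1))
  expect_equal(r1$percent, 200)
  expect_equal(r1$sd, 0)
  # paired ratios 50% and 60%: mean 55, sd 7.07
  r2 <- relative_growth(c(1.0, 1.2), c(2.0, 2.0))
  expect_equal(r2$percent, 55)
  expect_equal(r2$sd, sd(c(50, 60)))
  expect_equal(r2$sd, 7.0710678, tolerance = 1e-6)

  # unequal counts: ratio of means with bootstrap spread
  set.seed(706)
  r3 <- relative_growth(c(4, 4.4, 3.6, 4.2), c(2, 2.2))
  expect_equal(r3$method, "bootstrap")
  expect_equal(r3$percent, 100 * mean(c(4, 4.4, 3.6, 4.2)) / 2.1)
  expect_gt(r3$sd, 0)

  # non-positive readings excluded with a tally
  r4 <- relative_growth(c(2, 2, 0, 2), c(1, 1, -1, 1))
  expect_equal(r4$n_excluded, 2)
  expect_error(relative_growth(c(1, -1), c(2, 2)), "at least 2")
})

test_that("category enrichment matches the hypergeometric tail", {
  uni <- sprintf("g%03d", 1:100)
  cat10 <- uni[1:10]
  # full overlap of a 10-gene category: p = 1 / C(100, 10)
  r <- enrich_categories(uni[1:10], uni, list(cat = cat10))
  expect_equal(r$p_value, 1 / choose(100, 10))
  expect_equal(r$p_value, hyper_tail_oracle(10, 10, 100, 10))

  # overlap at the expectation is far from significant
  set10 <- c(uni[10], uni[51:59])     # one hit in the category
  r2 <- enrich_categories(set10, uni, list(cat = cat10))
  expect_equal(r2$p_value, hyper_tail_oracle(1, 10, 100, 10))
  expect_equal(r2$p_value, 0.6695237889, tolerance = 1e-9)
  expect_gt(r2$p_value, 0.05)

  # a category equal to the universe can never be enriched
  r3 <- enrich_categories(set10, uni, list(all = uni))
  expect_equal(r3$p_value, 1)

  # empty gene set: all p = 1
  r4 <- enrich_categories(character(0), uni,
                          list(cat = cat10, all = uni))
  expect_true(all(r4$p_value == 1))

  expect_error(enrich_categories("nope", uni, list(cat = cat10)), "subset")
})

test_that("type-I rate of the ANOVA filter is calibrated at the 1% threshold", {
  set.seed(707)
  n <- 4000
  vals <- matrix(rnorm(n * 6, mean = 5), n, 6)
  rownames(vals) <- sprintf("g%04d", seq_len(n))
  colnames(vals) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  pm <- profile_matrix(vals, rep(c("A", "B"), each = 3))
  de <- de_filter(pm, "A", "B", fc_threshold = 1, p_threshold = 0.01)
  rate <- (length(de$up) + length(de$down)) / n
  expect_gt(rate, 0.004)
  expect_lt(rate, 0.016)
})
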