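#' Expected donor-genome retention after backcrossing
#'
#' Without a linked selected marker, each backcross halves the expected
#' donor-genome fraction, so after `n` crosses the unselected retention is
#' `0.5^n`; over a genome of `G` genes the expected donor-origin gene count
#' is that fraction times `G`, rounded to the nearest integer.
#'
#' @param n number of backcrosses (total crosses), >= 0.
#' @param G number of genes in the genome, >= 1.
#' @return List of class `retention_expectation`: `n_backcrosses`,
#'   `genome_genes`, `expected_fraction` (= 0.5^n), `expected_genes`
#'   (nearest integer) and `expected_genes_continuous` (unrounded).
#' @examples
#' expected_retention(10, 9127)  # fraction 0.5^10, 9 genes
#' @export
expected_retention <- function(n, G) {
  stopifnot(n >= 0, G >= 1)
  f <- 0.5^n
  structure(list(n_backcrosses = as.integer(n),
                 genome_genes = as.integer(G),
                 expected_fraction = f,
                 expected_genes = as.integer(floor(f * G + 0.5)),
                 expected_genes_continuous = f * G),
            class = "retention_expectation")
}

#' @export
print.retention_expectation <- function(x, ...) {
  cat(sprintf("after %d backcrosses: expected donor fraction %.10g, %d of %d genes (%.4g unrounded)\n",
              x$n_backcrosses, x$expected_fraction, x$expected_genes,
              x$genome_genes, x$expected_genes_continuous))
  invisible(x)
}

#' Exact test of a segregation ratio
#'
#' Two-sided exact binomial test of the observed fertile:sterile split
#' against an expected proportion `p0` (default 1:1, the single-locus
#' expectation for a haploid cross). Two-sidedness follows the
#' minimum-likelihood convention: outcomes with probability no greater than
#' the observed outcome's are summed.
#'
#' @param n_fertile,n_sterile observed progeny counts (sum >= 1).
#' @param p0 expected fertile proportion.
#' @return List with `p_value`, `n_fertile`, `n_sterile`,
#'   `observed_fraction` and `p0`.
#' @export
segregation_test <- function(n_fertile, n_sterile, p0 = 0.5) {
  n <- n_fertile + n_sterile
  stopifnot(n >= 1, n_fertile >= 0, n_sterile >= 0)
  p <- binom.test(n_fertile, n, p = p0)$p.value
  list(p_value = p, n_fertile = n_fertile, n_sterile = n_sterile,
       observed_fraction = n_fertile / n, p0 = p0)
}

#' Marker-trait association in a fertile/sterile panel
#'
#' Per marker, builds the 2x2 table of parental origin (donor/recurrent)
#' against fertility phenotype and applies Fisher's exact test (two-sided)
#' or a chi-squared test. Markers with missing calls are analysed on
#' complete cases and the reduced margins are reported. Multiple-testing
#' correction is applied across the tested markers (default Bonferroni).
#'
#' @param genotypes a [genotype_table].
#' @param phenotypes a [phenotype_table] covering all genotyped
#'   individuals.
#' @param correction a [stats::p.adjust()] method name.
#' @param method `"fisher"` (exact, default) or `"chisq"`.
#' @return data.frame with one row per marker: the four table cells
#'   (`n_donor_fertile`, `n_donor_sterile`, `n_recurrent_fertile`,
#'   `n_recurrent_sterile`), `n_complete`, `p_value`, `adjusted_p` and
#'   `direction` (`donor_with_fertile`, `donor_with_sterile` or `none`).
#' @export
associate_markers <- function(genotypes, phenotypes,
                              correction = "bonferroni",
                              method = c("fisher", "chisq")) {
  method <- match.arg(method)
  validate_panel(genotypes, phenotypes)
  fert <- setNames(phenotypes$fertility, phenotypes$individual_id)
  fert <- fert[rownames(genotypes$calls)]
  if (!all(c("fertile", "sterile") %in% fert))
    stop("a phenotype class is empty; association is undefined")
  markers <- colnames(genotypes$calls)
  res <- lapply(markers, function(m) {
    call <- genotypes$calls[, m]
    keep <- !is.na(call)
    a <- sum(call[keep] == "donor" & fert[keep] == "fertile")
    b <- sum(call[keep] == "donor" & fert[keep] == "sterile")
    c_ <- sum(call[keep] == "recurrent" & fert[keep] == "fertile")
    d <- sum(call[keep] == "recurrent" & fert[keep] == "sterile")
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    p <- if (sum(tab) == 0) 1 else if (method == "fisher")
      fisher.test(tab)$p.value
    else
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    if (is.na(p)) p <- 1   # degenerate margins under chisq
    f_d <- if (a + c_ > 0) a / (a + c_) else NA
    s_d <- if (b + d > 0) b / (b + d) else NA
    dir <- if (is.na(f_d) || is.na(s_d) || f_d == s_d) "none"
    else if (f_d > s_d) "donor_with_fertile" else "donor_with_sterile"
    data.frame(marker_id = m, n_donor_fertile = a, n_donor_sterile = b,
               n_recurrent_fertile = c_, n_recurrent_sterile = d,
               n_complete = sum(keep), p_value = p, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- p.adjust(out$p_value, method = correction)
  if (!is.null(genotypes$markers)) {
    out$group_id <- genotypes$markers$group_id
    out$pos <- genotypes$markers$pos
  }
  rownames(out) <- NULL
  out
}

#' Localize the candidate locus from association results
#'
#' Returns the maximal run of adjacent significant markers (after
#' correction) containing the smallest p-value as the candidate locus
#' interval; adjacency is within a linkage group along the tested marker
#' order. With the true FS marker supplied (simulation), reports whether it
#' lies inside the interval.
#'
#' @param results output of [associate_markers()] with `group_id`/`pos`
#'   columns (i.e. from a genotype table with marker metadata).
#' @param alpha significance level on the corrected p-values.
#' @param fs_marker optional true FS marker id.
#' @return List with `interval` (0- or 1-row data.frame `group_id`,
#'   `start`, `end`), `markers` (ids in the run), `contains_fs` (logical or
#'   `NA`) and `note`.
#' @export
rank_candidate_locus <- function(results, alpha = 0.05, fs_marker = NULL) {
  stopifnot(all(c("group_id", "pos", "p_value", "adjusted_p") %in%
                  names(results)))
  r <- results[order(match(results$group_id, unique(results$group_id)),
                     results$pos), ]
  sig <- r$adjusted_p < alpha
  empty <- data.frame(group_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (!any(sig))
    return(list(interval = empty, markers = character(),
                contains_fs = NA,
                note = "no marker significant after correction"))
  new_run <- c(TRUE, r$group_id[-1] != r$group_id[-nrow(r)] | !sig[-nrow(r)])
  run_id <- cumsum(new_run)
  run_id[!sig] <- NA
  best <- run_id[which.min(ifelse(sig, r$p_value, Inf))]
  members <- which(!is.na(run_id) & run_id == best)
  interval <- data.frame(group_id = r$group_id[members[1]],
                         start = min(r$pos[members]),
                         end = max(r$pos[members]),
                         stringsAsFactors = FALSE)
  contains <- NA
  if (!is.null(fs_marker))
    contains <- fs_marker %in% r$marker_id[members]
  list(interval = interval, markers = r$marker_id[members],
       contains_fs = contains, note = "ok")
}
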