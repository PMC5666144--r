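#' Simulate genome sequences over a map
#'
#' Uniform random nucleotides per linkage group; uses the session RNG.
#'
#' @param map a [genome_map].
#' @return Named character vector (one sequence per group).
#' @export
simulate_genome_sequences <- function(map) {
  setNames(vapply(seq_len(nrow(map$groups)), function(i) {
    paste(sample(c("A", "C", "G", "T"), map$groups$physical_length[i],
                 replace = TRUE), collapse = "")
  }, ""), map$groups$group_id)
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

# reverse complement / whole-sequence translation on plain strings
.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

.translate_seq <- function(s) {
  n <- nchar(s) %/% 3L
  i <- 3L * (seq_len(n) - 1L) + 1L
  paste(Biostrings::GENETIC_CODE[substring(s, i, i + 2L)], collapse = "")
}

# generator-side truth oracle: mutate the full CDS, translate the whole
# reference and mutant proteins, compare. Deliberately a different route
# from the codon-local arithmetic in classify_snps().
.true_effect <- function(genome_seq, cds_gene, strand, pos, alt) {
  inside <- pos >= cds_gene$start & pos <= cds_gene$end
  if (!any(inside)) return("noncoding")
  pieces <- substring(genome_seq, cds_gene$start, cds_gene$end)
  seg <- which(inside)
  off <- pos - cds_gene$start[seg] + 1L
  mut <- pieces
  substr(mut[seg], off, off) <- alt
  fwd_ref <- paste(pieces, collapse = "")
  fwd_mut <- paste(mut, collapse = "")
  if (strand == "-") {
    fwd_ref <- .revcomp(fwd_ref)
    fwd_mut <- .revcomp(fwd_mut)
  }
  if (identical(.translate_seq(fwd_ref), .translate_seq(fwd_mut)))
    "synonymous" else "nonsynonymous"
}

# sample one SNP of the desired class inside a gene (retry loop)
.plant_snp <- function(genome_seq, gene, cds_gene, want, taken,
                       max_tries = 200L) {
  span <- gene$start:gene$end
  coding <- unlist(mapply(seq, cds_gene$start, cds_gene$end,
                          SIMPLIFY = FALSE))
  pool <- switch(want,
                 noncoding = setdiff(span, coding),
                 coding)
  pool <- setdiff(pool, taken)
  for (t in seq_len(max_tries)) {
    if (!length(pool)) return(NULL)
    pos <- if (length(pool) == 1L) pool else sample(pool, 1L)
    ref <- substr(genome_seq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    if (want == "noncoding")
      return(list(pos = pos, ref = ref, alt = alt, effect = "noncoding"))
    eff <- .true_effect(genome_seq, cds_gene, gene$strand, pos, alt)
    if (eff == want)
      return(list(pos = pos, ref = ref, alt = alt, effect = eff))
  }
  NULL
}

#' Simulate a parental SNP catalog with planted structure
#'
#' Lays biallelic SNPs between the donor and recurrent parents over the
#' map's genes: a configurable number of planted regions of consecutive
#' genes each carrying many nonsynonymous SNPs (high-density regions), a set
#' of genes forced to zero nonsynonymous SNPs, Poisson background SNPs of
#' random effect in the remaining genes, and intergenic SNPs. The truth
#' (per-gene effect counts, planted region spans) is determined by a
#' whole-CDS translation oracle, independently of [classify_snps()].
#'
#' @param map a [genome_map] with gene annotation.
#' @param genome named character vector from
#'   [simulate_genome_sequences()].
#' @param n_regions planted high-nonsynonymous regions.
#' @param genes_per_region consecutive genes per planted region.
#' @param nonsyn_per_region_gene nonsynonymous SNPs planted in each region
#'   gene (default clears the "more than 10" selection threshold).
#' @param zero_nonsyn_frac fraction of non-region genes forced to carry no
#'   nonsynonymous SNP.
#' @param background_lambda Poisson mean of background SNPs per gene.
#' @param n_intergenic intergenic SNPs.
#' @return List with `snps` (data.frame `group_id`, `pos`, `ref`, `alt`),
#'   `truth` (list: `gene_counts` data.frame of per-gene planted effect
#'   counts, `planted_regions` data.frame of region spans and member genes).
#' @export
simulate_snp_catalog <- function(map, genome,
                                 n_regions = 3,
                                 genes_per_region = 5,
                                 nonsyn_per_region_gene = 12,
                                 zero_nonsyn_frac = 0.25,
                                 background_lambda = 2,
                                 n_intergenic = 50) {
  stopifnot(inherits(map, "genome_map"), !is.null(map$genes))
  genes <- map$genes[order(match(map$genes$group_id, map$groups$group_id),
                           map$genes$start), ]
  cds_by_gene <- split(map$cds, map$cds$gene_id)

  # choose planted regions: runs of consecutive genes, one per random group
  region_genes <- character(); planted <- list()
  groups_avail <- map$groups$group_id[
    tabulate(match(genes$group_id, map$groups$group_id)) >= genes_per_region]
  pick_groups <- sample(rep(groups_avail, length.out = max(n_regions, length(groups_avail))),
                        n_regions)
  for (r in seq_len(n_regions)) {
    rows <- which(genes$group_id == pick_groups[r])
    ok <- FALSE
    for (t in 1:50) {
      s <- sample(seq_len(length(rows) - genes_per_region + 1L), 1L)
      ids <- genes$gene_id[rows[s:(s + genes_per_region - 1L)]]
      if (!any(ids %in% region_genes)) { ok <- TRUE; break }
    }
    if (!ok) next
    region_genes <- c(region_genes, ids)
    planted[[length(planted) + 1L]] <- data.frame(
      group_id = pick_groups[r],
      start = min(genes$start[genes$gene_id %in% ids]),
      end = max(genes$end[genes$gene_id %in% ids]),
      gene_ids = paste(ids, collapse = ","),
      stringsAsFactors = FALSE)
  }
  rest <- setdiff(genes$gene_id, region_genes)
  zero_genes <- sample(rest, round(zero_nonsyn_frac * length(rest)))

  snp_rows <- list()
  counts <- data.frame(gene_id = genes$gene_id,
                       n_synonymous = 0L, n_nonsynonymous = 0L,
                       n_noncoding_in_span = 0L, stringsAsFactors = FALSE)
  add_for_gene <- function(gid, wants) {
    gi <- match(gid, genes$gene_id)
    gene <- genes[gi, ]
    seqg <- genome[[gene$group_id]]
    cdsg <- cds_by_gene[[gid]]
    taken <- integer()
    out <- list()
    for (w in wants) {
      s <- .plant_snp(seqg, gene, cdsg, w, taken)
      if (is.null(s)) next
      taken <- c(taken, s$pos)
      out[[length(out) + 1L]] <- data.frame(
        group_id = gene$group_id, pos = s$pos, ref = s$ref, alt = s$alt,
        stringsAsFactors = FALSE)
      col <- switch(s$effect, synonymous = "n_synonymous",
                    nonsynonymous = "n_nonsynonymous",
                    noncoding = "n_noncoding_in_span")
      counts[[col]][gi] <<- counts[[col]][gi] + 1L
    }
    out
  }

  for (gid in region_genes) {
    wants <- c(rep("nonsynonymous", nonsyn_per_region_gene),
               rep("synonymous", rpois(1L, 1)),
               rep("noncoding", rpois(1L, 1)))
    snp_rows <- c(snp_rows, add_for_gene(gid, wants))
  }
  for (gid in zero_genes) {
    n <- rpois(1L, background_lambda)
    if (!n) next
    wants <- sample(c("synonymous", "noncoding"), n, replace = TRUE)
    snp_rows <- c(snp_rows, add_for_gene(gid, wants))
  }
  free_genes <- setdiff(rest, zero_genes)
  for (gid in free_genes) {
    n <- rpois(1L, background_lambda)
    if (!n) next
    # unconstrained background: random positions, truth recorded from oracle
    gi <- match(gid, genes$gene_id)
    gene <- genes[gi, ]
    seqg <- genome[[gene$group_id]]
    cdsg <- cds_by_gene[[gid]]
    pool <- gene$start:gene$end
    pos <- sample(pool, min(n, length(pool)))
    for (p in pos) {
      ref <- substr(seqg, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      eff <- .true_effect(seqg, cdsg, gene$strand, p, alt)
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        group_id = gene$group_id, pos = p, ref = ref, alt = alt,
        stringsAsFactors = FALSE)
      col <- switch(eff, synonymous = "n_synonymous",
                    nonsynonymous = "n_nonsynonymous",
                    noncoding = "n_noncoding_in_span")
      counts[[col]][gi] <- counts[[col]][gi] + 1L
    }
  }
  # intergenic SNPs (outside every gene span)
  for (k in seq_len(n_intergenic)) {
    g <- sample(map$groups$group_id, 1L)
    for (t in 1:50) {
      p <- sample.int(map$groups$physical_length[
        match(g, map$groups$group_id)], 1L)
      covered <- any(genes$group_id == g & genes$start <= p & genes$end >= p)
      if (!covered) break
    }
    if (covered) next
    ref <- substr(genome[[g]], p, p)
    snp_rows[[length(snp_rows) + 1L]] <- data.frame(
      group_id = g, pos = p, ref = ref,
      alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1L),
      stringsAsFactors = FALSE)
  }

  snps <- unique(do.call(rbind, snp_rows))
  snps <- snps[order(match(snps$group_id, map$groups$group_id), snps$pos), ]
  rownames(snps) <- NULL
  counts$n_snps_total <- counts$n_synonymous + counts$n_nonsynonymous +
    counts$n_noncoding_in_span
  list(snps = snps,
       truth = list(gene_counts = counts,
                    planted_regions = do.call(rbind, planted),
                    zero_nonsyn_genes = zero_genes,
                    region_genes = region_genes))
}

#' Simulate expression profiles with planted cluster archetypes
#'
#' Emulates the pattern structure of a two-background comparison: rows
#' follow one of three archetypes — up in group A, flat, or up in group B —
#' plus Gaussian noise. Used to exercise hierarchical pattern clustering and
#' the fold-change/ANOVA filters against known truth.
#'
#' @param n_per_cluster rows per archetype (length-3 vector or scalar).
#' @param groups named integer vector of samples per group (exactly two
#'   groups for the archetype contrast), e.g. `c(A = 3, B = 3)`.
#' @param effect linear-scale fold difference of the "up" archetypes.
#' @param noise_sd Gaussian noise SD added on the linear scale.
#' @param baseline flat expression level.
#' @return List with `matrix` (a [profile_matrix]) and `truth` (integer
#'   archetype labels 1 = up-in-A, 2 = flat, 3 = up-in-B).
#' @export
simulate_expression_profiles <- function(n_per_cluster = c(60, 20, 50),
                                         groups = c(A = 3, B = 3),
                                         effect = 4,
                                         noise_sd = 0.1,
                                         baseline = 1) {
  stopifnot(length(groups) == 2, !is.null(names(groups)))
  n_per_cluster <- rep_len(n_per_cluster, 3L)
  glab <- rep(names(groups), groups)
  n_s <- sum(groups)
  n_r <- sum(n_per_cluster)
  truth <- rep(1:3, n_per_cluster)
  mu <- matrix(baseline, n_r, n_s)
  mu[truth == 1, glab == names(groups)[1]] <- baseline * effect
  mu[truth == 3, glab == names(groups)[2]] <- baseline * effect
  vals <- mu + matrix(rnorm(n_r * n_s, sd = noise_sd), n_r, n_s)
  vals[vals < 0] <- 0
  rownames(vals) <- sprintf("row%03d", seq_len(n_r))
  colnames(vals) <- paste0(glab, stats::ave(seq_len(n_s), glab,
                                            FUN = seq_along))
  list(matrix = profile_matrix(vals, setNames(glab, colnames(vals))),
       truth = setNames(truth, rownames(vals)))
}
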