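# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# --- whole-protein translation oracle for SNP coding effects -------------
# Mutates the full CDS, translates reference and mutant proteins with
# Biostrings::translate (C implementation, one vectorized call), compares.
oracle_effects <- function(snps, ann, genome) {
  eff <- rep("noncoding", nrow(snps))
  refs <- character(); muts <- character(); idx <- integer()
  for (i in seq_len(nrow(snps))) {
    gid <- snps$gene_id[i]
    if (is.na(gid)) next
    gene <- ann$genes[ann$genes$gene_id == gid, ]
    cds <- ann$cds[ann$cds$gene_id == gid, , drop = FALSE]
    inside <- snps$pos[i] >= cds$start & snps$pos[i] <= cds$end
    if (!any(inside)) next
    pieces <- substring(genome[[gene$group_id]], cds$start, cds$end)
    seg <- which(inside)
    off <- snps$pos[i] - cds$start[seg] + 1L
    mut <- pieces
    substr(mut[seg], off, off) <- snps$alt[i]
    r <- paste(pieces, collapse = "")
    m <- paste(mut, collapse = "")
    if (gene$strand == "-") {
      r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
      m <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
    }
    refs <- c(refs, r); muts <- c(muts, m); idx <- c(idx, i)
  }
  if (length(idx)) {
    pr <- as.character(Biostrings::translate(Biostrings::DNAStringSet(refs)))
    pm <- as.character(Biostrings::translate(Biostrings::DNAStringSet(muts)))
    eff[idx] <- ifelse(pr == pm, "synonymous", "nonsynonymous")
  }
  eff
}

# random gene structures (1-3 CDS segments, both strands, introns/UTRs)
# on a fresh random genome; returns annotation, genome and random coding
# and noncoding SNPs with their containing gene
random_gene_fixture <- function(n_genes = 30, snps_per_gene = 10) {
  span_w <- 1200L
  starts <- 2000L * seq_len(n_genes)
  glen <- starts[n_genes] + span_w + 2000L
  genome <- list(chr = paste(sample(c("A", "C", "G", "T"), glen,
                                    replace = TRUE), collapse = ""))
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
                      group_id = "chr", start = starts,
                      end = starts + span_w - 1L,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
  cds_rows <- list()
  for (i in seq_len(n_genes)) {
    n_seg <- sample(1:3, 1)
    lens <- 3L * sample(20:80, n_seg)          # each segment a codon multiple
    gaps <- sample(30:120, n_seg)
    s0 <- starts[i] + sample(20:120, 1)
    cs <- integer(n_seg); ce <- integer(n_seg)
    for (k in seq_len(n_seg)) {
      cs[k] <- s0
      ce[k] <- s0 + lens[k] - 1L
      s0 <- ce[k] + gaps[k]
    }
    stopifnot(max(ce) <= genes$end[i])
    cds_rows[[i]] <- data.frame(gene_id = genes$gene_id[i],
                                start = cs, end = ce,
                                stringsAsFactors = FALSE)
  }
  ann <- gene_annotation(genes, do.call(rbind, cds_rows))
  snp_rows <- list()
  for (i in seq_len(n_genes)) {
    cds <- ann$cds[ann$cds$gene_id == genes$gene_id[i], ]
    coding <- unlist(mapply(seq, cds$start, cds$end, SIMPLIFY = FALSE))
    span <- genes$start[i]:genes$end[i]
    pos <- unique(c(sample(coding, min(snps_per_gene, length(coding))),
                    sample(setdiff(span, coding), 2)))
    ref <- substring(genome$chr, pos, pos)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    snp_rows[[i]] <- data.frame(group_id = "chr", pos = pos, ref = ref,
                                alt = unname(alt),
                                gene_id = genes$gene_id[i],
                                stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, snp_rows)
  rownames(snps) <- NULL
  list(ann = ann, genome = genome, snps = snps)
}

# --- exact-test oracles --------------------------------------------------
# two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins (minimum-likelihood convention)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  x <- max(0, k - n):min(k, m)
  p <- dhyper(x, m, n, k)
  sum(p[p <= p[x == a] * (1 + 1e-7)])
}

# two-sided exact binomial p by enumeration (minimum-likelihood convention)
binom_oracle <- function(x, n, p0 = 0.5) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# upper-tail hypergeometric enrichment p by direct summation
hyper_tail_oracle <- function(overlap, cat_size, uni_size, set_size) {
  x <- overlap:min(cat_size, set_size)
  sum(choose(cat_size, x) * choose(uni_size - cat_size, set_size - x)) /
    choose(uni_size, set_size)
}

# --- clustering agreement ------------------------------------------------
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  a <- sum(choose(tab, 2))
  b1 <- sum_comb(rowSums(tab)); b2 <- sum_comb(colSums(tab))
  expected <- b1 * b2 / choose(n, 2)
  (a - expected) / ((b1 + b2) / 2 - expected)
}
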