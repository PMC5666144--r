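# codon-local classification for one SNP inside one gene's CDS.
# cds_gene: segments (start/end) in genomic order; cds_seq: the gene's CDS
# in translation orientation (reverse-complemented for '-' strand).
.classify_coding <- function(cds_gene, cds_seq, strand, pos, ref, alt,
                             seg_offsets, total_len) {
  seg <- which(pos >= cds_gene$start & pos <= cds_gene$end)
  if (!length(seg)) return("noncoding")
  i0 <- seg_offsets[seg] + (pos - cds_gene$start[seg])   # 0-based, genomic order
  if (strand == "+") {
    j0 <- i0
    ref_b <- ref; alt_b <- alt
  } else {
    j0 <- total_len - 1L - i0
    ref_b <- .COMP[[ref]]; alt_b <- .COMP[[alt]]
  }
  codon_start <- (j0 %/% 3L) * 3L + 1L
  within <- j0 %% 3L + 1L
  codon <- substr(cds_seq, codon_start, codon_start + 2L)
  if (substr(codon, within, within) != ref_b)
    stop("internal: CDS base does not match reference allele")
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt_b
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (identical(aa_ref, aa_alt)) "synonymous" else "nonsynonymous"
}

#' Classify SNP coding effects against gene models
#'
#' Assigns each SNP its gene context by span overlap and classifies it as
#' `noncoding` (outside every CDS segment, including introns/UTRs within a
#' gene span and intergenic positions), `synonymous` or `nonsynonymous`.
#' The codon containing the position is rebuilt from the concatenated CDS
#' (reverse-complemented on the minus strand), the alternate allele is
#' substituted (complemented on the minus strand), and both codons are
#' translated with the standard genetic code; stop gain/loss counts as
#' nonsynonymous. Each SNP is evaluated independently against the reference
#' codon. A SNP overlapping several (overlapping) genes yields one row per
#' gene and is tallied in the `n_multi_gene` attribute. SNPs falling in the
#' CDS of a non-annotatable gene (CDS length not divisible by 3) get `NA`
#' effect for that gene.
#'
#' @param snps data.frame with `group_id`, `pos`, `ref`, `alt`.
#' @param annotation a [gene_annotation] (or a [genome_map] carrying one).
#' @param genome named character vector of group sequences.
#' @return data.frame with one row per (SNP, gene) pair plus one row per
#'   gene-free SNP: columns of `snps` plus `gene_id` (NA when intergenic)
#'   and `effect`. Attribute `n_multi_gene` counts SNPs hitting more than
#'   one gene.
#' @export
classify_snps <- function(snps, annotation, genome) {
  if (inherits(annotation, "genome_map"))
    annotation <- gene_annotation(annotation$genes[, c("gene_id", "group_id",
                                                       "start", "end",
                                                       "strand")],
                                  annotation$cds)
  stopifnot(inherits(annotation, "gene_annotation"))
  genes <- annotation$genes
  cds_by_gene <- split(annotation$cds, annotation$cds$gene_id)
  if (!nrow(snps)) {
    out <- cbind(snps, data.frame(gene_id = character(),
                                  effect = character(),
                                  stringsAsFactors = FALSE))
    attr(out, "n_multi_gene") <- 0L
    return(out)
  }

  # guard against coordinate bugs: reference alleles must match the genome
  for (g in unique(snps$group_id)) {
    if (!g %in% names(genome)) stop("no genome sequence for group ", g)
    sel <- snps$group_id == g
    obs <- substring(genome[[g]], snps$pos[sel], snps$pos[sel])
    bad <- which(obs != snps$ref[sel])
    if (length(bad)) {
      i <- which(sel)[bad[1]]
      stop("reference allele mismatch at ", snps$group_id[i], ":",
           snps$pos[i], " (VCF says ", snps$ref[i], ", genome has ",
           obs[bad[1]], ")")
    }
  }

  # span overlap per group via IRanges
  hit_snp <- integer(); hit_gene <- integer()
  for (g in unique(snps$group_id)) {
    srows <- which(snps$group_id == g)
    grows <- which(genes$group_id == g)
    if (!length(grows)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(snps$pos[srows], width = 1L),
      IRanges::IRanges(genes$start[grows], genes$end[grows]))
    hit_snp <- c(hit_snp, srows[S4Vectors::queryHits(ov)])
    hit_gene <- c(hit_gene, grows[S4Vectors::subjectHits(ov)])
  }
  n_multi <- sum(table(hit_snp) > 1L)

  rows <- list()
  no_gene <- setdiff(seq_len(nrow(snps)), unique(hit_snp))
  if (length(no_gene)) {
    r <- snps[no_gene, , drop = FALSE]
    r$gene_id <- NA_character_
    r$effect <- "noncoding"
    rows[[length(rows) + 1L]] <- r
  }
  for (gi in unique(hit_gene)) {
    gene <- genes[gi, ]
    srows <- hit_snp[hit_gene == gi]
    r <- snps[srows, , drop = FALSE]
    r$gene_id <- gene$gene_id
    cdsg <- cds_by_gene[[gene$gene_id]]
    if (is.null(cdsg) || !gene$annotatable) {
      in_cds <- if (is.null(cdsg)) rep(FALSE, nrow(r)) else
        vapply(r$pos, function(p) any(p >= cdsg$start & p <= cdsg$end),
               logical(1))
      r$effect <- ifelse(in_cds, NA_character_, "noncoding")
      rows[[length(rows) + 1L]] <- r
      next
    }
    lens <- cdsg$end - cdsg$start + 1L
    seg_offsets <- cumsum(c(0L, lens[-length(lens)]))
    total_len <- sum(lens)
    fwd <- paste(substring(genome[[gene$group_id]], cdsg$start, cdsg$end),
                 collapse = "")
    cds_seq <- if (gene$strand == "+") fwd else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
    r$effect <- vapply(seq_len(nrow(r)), function(k)
      .classify_coding(cdsg, cds_seq, gene$strand, r$pos[k], r$ref[k],
                       r$alt[k], seg_offsets, total_len), "")
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$group_id, unique(snps$group_id)), out$pos), ]
  rownames(out) <- NULL
  attr(out, "n_multi_gene") <- n_multi
  out
}

#' Classify a single SNP against one gene model
#'
#' Convenience scalar wrapper around the same codon logic as
#' [classify_snps()].
#'
#' @param snp one-row data.frame (`group_id`, `pos`, `ref`, `alt`).
#' @param gene one-row data.frame of the gene model (`gene_id`, `group_id`,
#'   `start`, `end`, `strand`).
#' @param cds CDS segments of that gene (`start`, `end`).
#' @param genome named character vector of group sequences.
#' @return `"noncoding"`, `"synonymous"` or `"nonsynonymous"`.
#' @export
classify_snp <- function(snp, gene, cds, genome) {
  ann <- gene_annotation(
    data.frame(gene_id = gene$gene_id, group_id = gene$group_id,
               start = gene$start, end = gene$end, strand = gene$strand,
               stringsAsFactors = FALSE),
    data.frame(gene_id = gene$gene_id, start = cds$start, end = cds$end,
               stringsAsFactors = FALSE))
  res <- classify_snps(snp, ann, genome)
  res$effect[which(!is.na(res$gene_id))[1]] %||% res$effect[1]
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Per-gene SNP effect counts
#'
#' Aggregates classified SNPs into one record per gene (zero counts for
#' genes without SNPs). SNPs counted in several overlapping genes are
#' double-counted by design, with the tally reported; SNPs with `NA` effect
#' (non-annotatable genes) are dropped with a tally.
#'
#' @param classified output of [classify_snps()].
#' @param annotation the [gene_annotation] (or [genome_map]) used.
#' @return data.frame ordered by (group, start) with columns `gene_id`,
#'   `group_id`, `start`, `end`, `n_snps_total`, `n_synonymous`,
#'   `n_nonsynonymous`, `n_noncoding_in_span`; attributes `n_multi_gene`
#'   and `n_unclassified`.
#' @export
count_effects <- function(classified, annotation) {
  if (inherits(annotation, "genome_map")) {
    genes <- annotation$genes
  } else {
    genes <- annotation$genes
  }
  n_na <- sum(is.na(classified$effect))
  cl <- classified[!is.na(classified$gene_id) & !is.na(classified$effect), ,
                   drop = FALSE]
  tab <- table(factor(cl$gene_id, levels = genes$gene_id),
               factor(cl$effect, levels = c("synonymous", "nonsynonymous",
                                            "noncoding")))
  out <- data.frame(gene_id = genes$gene_id,
                    group_id = genes$group_id,
                    start = genes$start, end = genes$end,
                    n_synonymous = as.integer(tab[, "synonymous"]),
                    n_nonsynonymous = as.integer(tab[, "nonsynonymous"]),
                    n_noncoding_in_span = as.integer(tab[, "noncoding"]),
                    stringsAsFactors = FALSE)
  out$n_snps_total <- out$n_synonymous + out$n_nonsynonymous +
    out$n_noncoding_in_span
  out <- out[order(match(out$group_id, unique(genes$group_id)), out$start), ]
  rownames(out) <- NULL
  attr(out, "n_multi_gene") <- attr(classified, "n_multi_gene")
  attr(out, "n_unclassified") <- n_na
  out
}

#' Select gene sets by nonsynonymous-SNP count rules
#'
#' `"zero_nonsyn"` selects genes with no nonsynonymous SNP (conserved
#' genes); `"high_nonsyn"` selects genes with strictly more than
#' `threshold` nonsynonymous SNPs (genes under diversifying pressure).
#'
#' @param counts output of [count_effects()].
#' @param rule `"zero_nonsyn"` or `"high_nonsyn"`.
#' @param threshold count threshold for `"high_nonsyn"` (exclusive).
#' @return Character vector of gene ids.
#' @export
select_genes <- function(counts, rule = c("zero_nonsyn", "high_nonsyn"),
                         threshold = 10) {
  rule <- match.arg(rule)
  switch(rule,
         zero_nonsyn = counts$gene_id[counts$n_nonsynonymous == 0L],
         high_nonsyn = counts$gene_id[counts$n_nonsynonymous > threshold])
}
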