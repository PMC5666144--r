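#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `CDS` features (CDS linked to its gene through the
#' `Parent` attribute, directly or via an intermediate mRNA). Coordinates
#' stay 1-based closed as in GFF3. CDS records lying outside their gene's
#' span are rejected with a warning naming the gene; genes whose total CDS
#' length is not divisible by 3 are flagged non-annotatable.
#'
#' @param path path to a GFF3 file.
#' @return A [gene_annotation].
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  gg <- gr[type == "gene"]
  if (!length(gg)) stop("no gene features in ", path)
  gid <- as.character(gg$ID)
  genes <- data.frame(gene_id = gid,
                      group_id = as.character(GenomicRanges::seqnames(gg)),
                      start = GenomicRanges::start(gg),
                      end = GenomicRanges::end(gg),
                      strand = as.character(GenomicRanges::strand(gg)),
                      stringsAsFactors = FALSE)
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene without explicit strand in ", path)

  # resolve mRNA -> gene indirection if present
  parent_of <- character()
  mr <- gr[type %in% c("mRNA", "transcript")]
  if (length(mr))
    parent_of <- setNames(vapply(mr$Parent, function(p) p[1], ""),
                          as.character(mr$ID))

  cg <- gr[type == "CDS"]
  cds <- NULL
  if (length(cg)) {
    par <- vapply(cg$Parent, function(p) if (length(p)) p[1] else NA_character_,
                  "")
    par_gene <- ifelse(par %in% names(parent_of), parent_of[par], par)
    known <- par_gene %in% genes$gene_id
    if (any(!known))
      warning("CDS with unresolvable parent skipped: ",
              paste(unique(par[!known]), collapse = ", "))
    cds <- data.frame(gene_id = par_gene[known],
                      start = GenomicRanges::start(cg)[known],
                      end = GenomicRanges::end(cg)[known],
                      stringsAsFactors = FALSE)
    span <- genes[match(cds$gene_id, genes$gene_id), ]
    out_of_span <- cds$start < span$start | cds$end > span$end
    if (any(out_of_span)) {
      warning("CDS outside gene span rejected for gene: ",
              paste(unique(cds$gene_id[out_of_span]), collapse = ", "))
      cds <- cds[!out_of_span, , drop = FALSE]
    }
  }
  if (is.null(cds) || !nrow(cds))
    cds <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  ann <- gene_annotation(genes, cds)
  if (any(!ann$genes$annotatable))
    message(sum(!ann$genes$annotatable),
            " gene(s) flagged non-annotatable (no CDS or CDS length not ",
            "divisible by 3)")
  ann
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_gff3()] on the retained fields (gene id, group, span,
#' strand, CDS segments). CDS phase is computed along the translation
#' direction.
#'
#' @param annotation a [gene_annotation].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  g <- annotation$genes
  cc <- annotation$cds
  gr_gene <- GenomicRanges::GRanges(
    g$group_id, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id)
  grl <- list(gr_gene)
  if (nrow(cc)) {
    idx <- match(cc$gene_id, g$gene_id)
    phase <- integer(nrow(cc))
    for (gene in unique(cc$gene_id)) {
      rows <- which(cc$gene_id == gene)
      lens <- cc$end[rows] - cc$start[rows] + 1L
      ord <- if (g$strand[match(gene, g$gene_id)] == "+") seq_along(rows) else rev(seq_along(rows))
      before <- cumsum(c(0L, lens[ord][-length(rows)]))
      phase[rows[ord]] <- (3L - before %% 3L) %% 3L
    }
    gr_cds <- GenomicRanges::GRanges(
      g$group_id[idx], IRanges::IRanges(cc$start, cc$end),
      strand = g$strand[idx], type = "CDS",
      ID = paste0(cc$gene_id, ".cds", stats::ave(cc$start, cc$gene_id,
                                                 FUN = seq_along)),
      Parent = cc$gene_id, phase = phase)
    grl <- c(grl, list(gr_cds))
  }
  all_gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(all_gr, path, format = "gff3")
  invisible(path)
}

#' Read genome sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences (names are linkage group /
#'   scaffold ids).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write genome sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 80L)
  invisible(path)
}
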