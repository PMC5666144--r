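#' Construct a genome map
#'
#' A genome map is the shared coordinate system of the pipeline: an ordered
#' set of linkage groups with physical (bp) and genetic (Morgan) lengths, an
#' ordered marker grid per group, optional gene models, and named selected
#' loci (at minimum `FS`, the female-fertility locus, and `MAT`, the
#' mating-type locus, for breeding-scheme simulations). All coordinates are
#' 1-based closed; genetic marker positions are obtained by linear
#' interpolation of the group's genetic length along its physical length.
#'
#' @param groups data.frame with columns `group_id`, `physical_length` (bp,
#'   >= 1) and `genetic_length` (Morgans, >= 0); `group_id` must be unique.
#' @param markers data.frame with columns `group_id` and `pos` (1-based bp),
#'   optionally `marker_id`. Positions must be strictly increasing within a
#'   group and lie inside the group's physical length.
#' @param annotation optional [gene_annotation] object laid over the map.
#' @param selected_loci named character vector of marker ids, e.g.
#'   `c(FS = "LG2_M0600", MAT = "LG6_M0600")`.
#' @return An object of class `genome_map`: a list with elements `groups`,
#'   `markers` (with derived columns `marker_id`, `gpos` in Morgans and
#'   `index`), `genes`, `cds` and `selected_loci`.
#' @export
genome_map <- function(groups, markers, annotation = NULL,
                       selected_loci = character()) {
  stopifnot(is.data.frame(groups),
            all(c("group_id", "physical_length", "genetic_length") %in% names(groups)))
  groups$group_id <- as.character(groups$group_id)
  if (anyDuplicated(groups$group_id))
    stop("duplicated linkage group ids")
  if (any(groups$physical_length < 1))
    stop("physical_length must be >= 1 bp")
  if (any(groups$genetic_length < 0))
    stop("genetic_length must be >= 0 Morgans")

  stopifnot(is.data.frame(markers), all(c("group_id", "pos") %in% names(markers)))
  markers$group_id <- as.character(markers$group_id)
  if (!all(markers$group_id %in% groups$group_id))
    stop("marker on unknown linkage group")
  ord <- order(match(markers$group_id, groups$group_id), markers$pos)
  markers <- markers[ord, , drop = FALSE]
  for (g in unique(markers$group_id)) {
    p <- markers$pos[markers$group_id == g]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within group ", g)
    if (any(p < 1) || any(p > groups$physical_length[groups$group_id == g]))
      stop("marker position outside physical length of group ", g)
  }
  if (is.null(markers$marker_id)) {
    markers$marker_id <- unlist(lapply(unique(markers$group_id), function(g) {
      n <- sum(markers$group_id == g)
      sprintf("%s_M%04d", g, seq_len(n))
    }))
  }
  markers$marker_id <- as.character(markers$marker_id)
  if (anyDuplicated(markers$marker_id)) stop("duplicated marker ids")
  gl <- setNames(groups$genetic_length, groups$group_id)
  pl <- setNames(groups$physical_length, groups$group_id)
  markers$gpos <- gl[markers$group_id] * markers$pos / pl[markers$group_id]
  markers$index <- seq_len(nrow(markers))
  rownames(markers) <- NULL

  genes <- NULL; cds <- NULL
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "gene_annotation"))
    genes <- annotation$genes
    cds <- annotation$cds
    if (!all(genes$group_id %in% groups$group_id))
      stop("gene on unknown linkage group")
    bad <- genes$end > pl[genes$group_id] | genes$start < 1
    if (any(bad))
      stop("gene interval outside physical length: ",
           paste(genes$gene_id[bad], collapse = ", "))
  }

  if (length(selected_loci)) {
    if (is.null(names(selected_loci)) || any(names(selected_loci) == ""))
      stop("selected_loci must be a named character vector")
    miss <- setdiff(selected_loci, markers$marker_id)
    if (length(miss))
      stop("selected locus refers to unknown marker: ",
           paste(miss, collapse = ", "))
    if (all(c("FS", "MAT") %in% names(selected_loci))) {
      gfs <- markers$group_id[markers$marker_id == selected_loci[["FS"]]]
      gmat <- markers$group_id[markers$marker_id == selected_loci[["MAT"]]]
      if (identical(gfs, gmat))
        warning("FS and MAT loci lie on the same linkage group")
    }
  }

  structure(list(groups = groups, markers = markers, genes = genes,
                 cds = cds, selected_loci = selected_loci),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", nrow(x$groups), "linkage groups,",
      nrow(x$markers), "markers,",
      if (is.null(x$genes)) 0L else nrow(x$genes), "genes\n")
  if (length(x$selected_loci))
    cat("selected loci:",
        paste(names(x$selected_loci), x$selected_loci, sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}

# marker row indices per group, in map order
.group_rows <- function(map) {
  split(map$markers$index, factor(map$markers$group_id,
                                  levels = map$groups$group_id))
}

.marker_index <- function(map, marker_id) {
  i <- match(marker_id, map$markers$marker_id)
  if (anyNA(i)) stop("unknown marker id: ",
                     paste(marker_id[is.na(i)], collapse = ", "))
  i
}

#' Gene annotation container
#'
#' Holds gene models (span, strand) and their CDS segments in genomic
#' coordinates. CDS segments of a gene must be non-overlapping, sorted by
#' genomic position and contained in the gene span. Genes whose concatenated
#' CDS length is not divisible by 3 are flagged non-annotatable and are
#' excluded from coding-effect classification but retained everywhere else.
#'
#' @param genes data.frame with columns `gene_id`, `group_id`, `start`,
#'   `end`, `strand` (`+`/`-`).
#' @param cds data.frame with columns `gene_id`, `start`, `end`.
#' @return An object of class `gene_annotation` with elements `genes`
#'   (including a derived logical `annotatable` column) and `cds`.
#' @export
gene_annotation <- function(genes, cds) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "group_id", "start", "end", "strand") %in% names(genes)),
            is.data.frame(cds),
            all(c("gene_id", "start", "end") %in% names(cds)))
  genes$gene_id <- as.character(genes$gene_id)
  genes$group_id <- as.character(genes$group_id)
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene ids")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$start > genes$end)) stop("gene start > end")
  cds$gene_id <- as.character(cds$gene_id)
  if (!all(cds$gene_id %in% genes$gene_id))
    stop("CDS for unknown gene: ",
         paste(setdiff(cds$gene_id, genes$gene_id), collapse = ", "))
  cds <- cds[order(match(cds$gene_id, genes$gene_id), cds$start), , drop = FALSE]
  rownames(cds) <- NULL
  span <- genes[match(cds$gene_id, genes$gene_id), c("start", "end")]
  if (any(cds$start < span$start | cds$end > span$end))
    stop("CDS outside gene span for gene: ",
         paste(unique(cds$gene_id[cds$start < span$start | cds$end > span$end]),
               collapse = ", "))
  lens <- tapply(cds$end - cds$start + 1L, cds$gene_id, sum)
  for (g in unique(cds$gene_id)) {
    s <- cds[cds$gene_id == g, ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping CDS segments in gene ", g)
  }
  genes$annotatable <- TRUE
  has_cds <- genes$gene_id %in% names(lens)
  genes$annotatable[!has_cds] <- FALSE
  bad <- names(lens)[lens %% 3 != 0]
  genes$annotatable[genes$gene_id %in% bad] <- FALSE
  structure(list(genes = genes, cds = cds), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,",
      nrow(x$cds), "CDS segments;",
      sum(!x$genes$annotatable), "non-annotatable\n")
  invisible(x)
}

#' Genotype table of a progeny panel
#'
#' Haploid calls at a set of markers for a set of individuals. Each call is
#' `"donor"`, `"recurrent"` or `NA` (missing); calls are never imputed.
#'
#' @param calls character matrix, individuals x markers, with unique
#'   rownames (individual ids) and colnames (marker ids).
#' @param markers optional data.frame describing the marker columns
#'   (`marker_id`, `group_id`, `pos`), in column order.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(calls, markers = NULL) {
  stopifnot(is.matrix(calls))
  ok <- is.na(calls) | calls %in% c("donor", "recurrent")
  if (!all(ok)) stop("calls must be 'donor', 'recurrent' or NA")
  if (is.null(rownames(calls)) || anyDuplicated(rownames(calls)))
    stop("calls must have unique individual ids as rownames")
  if (is.null(colnames(calls))) stop("calls must have marker ids as colnames")
  if (!is.null(markers)) {
    stopifnot(all(c("marker_id", "group_id", "pos") %in% names(markers)))
    if (!identical(as.character(markers$marker_id), colnames(calls)))
      stop("marker metadata does not match call columns")
  }
  structure(list(calls = calls, markers = markers), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$calls), "individuals x",
      ncol(x$calls), "markers;",
      sum(is.na(x$calls)), "missing calls\n")
  invisible(x)
}

#' Phenotype table
#'
#' @param individual_id character vector of ids.
#' @param fertility `"fertile"` or `"sterile"` per individual.
#' @param mating_type `"MAT1-1"` or `"MAT1-2"` per individual (NA allowed).
#' @return data.frame of class `phenotype_table`.
#' @export
phenotype_table <- function(individual_id, fertility, mating_type = NA) {
  individual_id <- as.character(individual_id)
  if (anyDuplicated(individual_id)) stop("duplicated individual ids")
  if (!all(fertility %in% c("fertile", "sterile")))
    stop("fertility must be 'fertile' or 'sterile'")
  if (!all(is.na(mating_type) | mating_type %in% c("MAT1-1", "MAT1-2")))
    stop("mating_type must be 'MAT1-1', 'MAT1-2' or NA")
  out <- data.frame(individual_id = individual_id,
                    fertility = fertility,
                    mating_type = mating_type,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Check that a phenotype table covers a genotype table
#'
#' @param genotypes a [genotype_table].
#' @param phenotypes a [phenotype_table].
#' @return Invisibly `TRUE`; errors if any genotyped individual lacks a
#'   phenotype.
#' @export
validate_panel <- function(genotypes, phenotypes) {
  miss <- setdiff(rownames(genotypes$calls), phenotypes$individual_id)
  if (length(miss))
    stop("individuals without phenotype: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

# normalize a haplotype / genotype row to integer origin coding
# (1 = donor, 0 = recurrent, NA = missing)
.as_origin_int <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (!all(is.na(x) | x %in% c(0L, 1L))) stop("origin codes must be 0/1/NA")
    return(x)
  }
  if (is.character(x)) {
    out <- rep(NA_integer_, length(x))
    out[x == "donor"] <- 1L
    out[x == "recurrent"] <- 0L
    if (any(!is.na(x) & !x %in% c("donor", "recurrent", "missing")))
      stop("unknown origin label")
    return(out)
  }
  stop("cannot interpret origin vector")
}
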