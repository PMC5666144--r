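#' Scan for regions of clustered high-nonsynonymous genes
#'
#' A region is a maximal run of positionally consecutive genes each carrying
#' at least `min_snps_per_gene` nonsynonymous SNPs, allowing up to
#' `max_gap_genes` interposed below-threshold genes between qualifying
#' neighbours; a run is reported when it holds at least `min_genes`
#' qualifying genes. In `"cumulative"` mode, windows of `min_genes`
#' consecutive genes whose summed nonsynonymous counts reach
#' `min_snps_per_gene * min_genes` are flagged and merged (sensitivity
#' analysis for the per-gene reading of the criterion).
#'
#' @param counts output of [count_effects()] (must be sorted by group and
#'   start; unsorted input is an error).
#' @param min_genes minimum qualifying genes per region.
#' @param min_snps_per_gene per-gene nonsynonymous threshold (inclusive).
#' @param max_gap_genes below-threshold genes tolerated inside a run.
#' @param mode `"per_gene"` (default) or `"cumulative"`.
#' @return data.frame of regions: `group_id`, `start`, `end`, `n_genes`,
#'   `gene_ids` (comma-separated qualifying members), `statistic`.
#' @export
scan_nonsyn_regions <- function(counts, min_genes = 5,
                                min_snps_per_gene = 10,
                                max_gap_genes = 0,
                                mode = c("per_gene", "cumulative")) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene_id", "group_id", "start", "end",
                  "n_nonsynonymous") %in% names(counts)))
  for (g in unique(counts$group_id)) {
    s <- counts$start[counts$group_id == g]
    if (is.unsorted(s)) stop("genes not sorted by position within group ", g)
  }
  empty <- data.frame(group_id = character(), start = integer(),
                      end = integer(), n_genes = integer(),
                      gene_ids = character(), statistic = character(),
                      stringsAsFactors = FALSE)
  res <- list()
  for (g in unique(counts$group_id)) {
    cc <- counts[counts$group_id == g, , drop = FALSE]
    if (mode == "per_gene") {
      qual <- which(cc$n_nonsynonymous >= min_snps_per_gene)
      if (!length(qual)) next
      gap <- c(0L, diff(qual) - 1L)            # non-qualifying genes between
      run_id <- cumsum(gap > max_gap_genes)
      for (r in unique(run_id)) {
        members <- qual[run_id == r]
        if (length(members) < min_genes) next
        res[[length(res) + 1L]] <- data.frame(
          group_id = g,
          start = min(cc$start[members]),
          end = max(cc$end[members]),
          n_genes = length(members),
          gene_ids = paste(cc$gene_id[members], collapse = ","),
          statistic = "nonsyn_cluster",
          stringsAsFactors = FALSE)
      }
    } else {
      n <- nrow(cc)
      if (n < min_genes) next
      total <- min_snps_per_gene * min_genes
      csum <- cumsum(c(0L, cc$n_nonsynonymous))
      starts <- seq_len(n - min_genes + 1L)
      flagged <- starts[csum[starts + min_genes] - csum[starts] >= total]
      if (!length(flagged)) next
      run_id <- cumsum(c(1L, diff(flagged) > 1L))
      for (r in unique(run_id)) {
        w <- flagged[run_id == r]
        members <- min(w):(max(w) + min_genes - 1L)
        res[[length(res) + 1L]] <- data.frame(
          group_id = g,
          start = min(cc$start[members]),
          end = max(cc$end[members]),
          n_genes = length(members),
          gene_ids = paste(cc$gene_id[members], collapse = ","),
          statistic = "nonsyn_cluster_cumulative",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Detect donor introgression blocks in a backcrossed line
#'
#' Slides windows of `window_markers` consecutive markers along each
#' linkage group and flags windows whose donor-call fraction among
#' non-missing calls reaches `min_donor_frac`; overlapping or adjacent
#' flagged windows are merged into maximal blocks spanning their first to
#' last marker. Missing calls are excluded from denominators; windows with
#' fewer than 50% non-missing calls are skipped. A window larger than a
#' group's marker count degrades to a single whole-group window with a
#' warning. Note the resolution floor: donor runs shorter than
#' `ceiling(min_donor_frac * window_markers)` markers cannot be flagged.
#'
#' @param calls one individual's haploid calls over the full marker grid:
#'   integer origin vector (1/0/NA) or character (`donor`/`recurrent`/
#'   `missing`), in map marker order.
#' @param map a [genome_map].
#' @param window_markers window size in markers.
#' @param min_donor_frac donor fraction threshold.
#' @return data.frame of blocks: `group_id`, `start`, `end`, `first_marker`,
#'   `last_marker`, `n_markers`, `statistic`.
#' @export
detect_donor_blocks <- function(calls, map, window_markers = 25,
                                min_donor_frac = 0.9) {
  h <- .as_origin_int(calls)
  if (length(h) != nrow(map$markers))
    stop("calls are not indexed on the map's marker grid")
  rows_by_group <- .group_rows(map)
  res <- list()
  for (g in names(rows_by_group)) {
    rows <- rows_by_group[[g]]
    n <- length(rows)
    if (!n) next
    w <- window_markers
    if (w > n) {
      warning("window_markers exceeds marker count of group ", g,
              "; scanning it as a single window")
      w <- n
    }
    x <- h[rows]
    donor <- cumsum(c(0L, ifelse(is.na(x), 0L, x)))
    seen <- cumsum(c(0L, !is.na(x)))
    starts <- seq_len(n - w + 1L)
    nd <- donor[starts + w] - donor[starts]
    ns <- seen[starts + w] - seen[starts]
    ok <- ns >= 0.5 * w & ns > 0 & nd / pmax(ns, 1L) >= min_donor_frac
    flagged <- starts[ok]
    if (!length(flagged)) next
    run_id <- cumsum(c(1L, diff(flagged) > w))   # merge overlapping/adjacent
    for (r in unique(run_id)) {
      f <- flagged[run_id == r]
      i1 <- min(f); i2 <- max(f) + w - 1L
      res[[length(res) + 1L]] <- data.frame(
        group_id = g,
        start = map$markers$pos[rows[i1]],
        end = map$markers$pos[rows[i2]],
        first_marker = map$markers$marker_id[rows[i1]],
        last_marker = map$markers$marker_id[rows[i2]],
        n_markers = i2 - i1 + 1L,
        statistic = "donor_block",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(group_id = character(), start = integer(),
                      end = integer(), first_marker = character(),
                      last_marker = character(), n_markers = integer(),
                      statistic = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Consensus regions across independent lines
#'
#' Interval intersection of donor blocks across at least two independent
#' lines; a consensus region is genome retained from the donor parent in
#' every line. Member genes are those whose span overlaps the intersection.
#'
#' @param blocks_per_line list (length >= 2) of block data.frames
#'   (`group_id`, `start`, `end`), e.g. from [detect_donor_blocks()].
#' @param map a [genome_map] (validates group ids).
#' @param annotation optional [gene_annotation] or [genome_map] with genes
#'   for member-gene reporting.
#' @return data.frame of consensus regions: `group_id`, `start`, `end`,
#'   `support` (number of lines), `n_genes`, `gene_ids`; attribute
#'   `total_genes` counts distinct member genes over all regions.
#' @export
consensus_regions <- function(blocks_per_line, map, annotation = NULL) {
  if (!is.list(blocks_per_line) || length(blocks_per_line) < 2)
    stop("need blocks from at least 2 independent lines")
  for (b in blocks_per_line) {
    stopifnot(all(c("group_id", "start", "end") %in% names(b)))
    if (nrow(b) && !all(b$group_id %in% map$groups$group_id))
      stop("blocks refer to linkage groups absent from the map")
  }
  genes <- if (!is.null(annotation)) annotation$genes else NULL
  res <- list()
  for (g in map$groups$group_id) {
    ir <- lapply(blocks_per_line, function(b) {
      bb <- b[b$group_id == g, , drop = FALSE]
      IRanges::reduce(IRanges::IRanges(bb$start, bb$end))
    })
    inter <- Reduce(IRanges::intersect, ir)
    if (!length(inter)) next
    for (k in seq_along(inter)) {
      s <- IRanges::start(inter)[k]; e <- IRanges::end(inter)[k]
      ids <- character(0)
      if (!is.null(genes)) {
        sel <- genes$group_id == g & genes$start <= e & genes$end >= s
        ids <- genes$gene_id[sel]
      }
      res[[length(res) + 1L]] <- data.frame(
        group_id = g, start = s, end = e,
        support = length(blocks_per_line),
        n_genes = length(ids),
        gene_ids = paste(ids, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(group_id = character(), start = integer(), end = integer(),
               support = integer(), n_genes = integer(),
               gene_ids = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total_genes") <-
    length(unique(unlist(strsplit(out$gene_ids[out$gene_ids != ""], ","))))
  out
}
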