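#' Simulation configuration for the backcross breeding scheme
#'
#' Defaults describe the emulated study design: a haploid genome of 7
#' linkage groups (the T. reesei karyotype) carrying a biallelic SNP catalog
#' between a donor (CBS999.97-like, female fertile, MAT1-1) and a recurrent
#' (QM6a-like, female sterile, MAT1-2) parent; 10 rounds of backcrossing to
#' the recurrent parent with selection for the donor allele at the fertility
#' locus FS and for mating type; three independent breeding lines; and a
#' final 20 fertile + 20 sterile association panel genotyped at 17 markers.
#' Physical and gene-count scales are reduced relative to a real fungal
#' genome (1.2 Mb / 150 genes / 1200 markers per group) so that every
#' analysis runs at desk scale; genetic lengths of 1 Morgan per group give
#' realistic fungal recombination densities.
#'
#' @param n_groups number of linkage groups.
#' @param genetic_lengths Morgans per group (recycled to `n_groups`).
#' @param physical_lengths bp per group (recycled).
#' @param markers_per_group markers on the uniform grid of each group.
#' @param genes_per_group gene models laid along each group.
#' @param n_backcrosses total number of crosses; the expected unselected
#'   donor-genome fraction after `n` crosses is `0.5^n`.
#' @param n_lines independent breeding lines.
#' @param panel_fertile,panel_sterile association panel sizes.
#' @param n_assoc_markers markers genotyped in the panel (donor-interval
#'   markers plus matched controls).
#' @param select_mat_allele mating-type selection applied each round:
#'   `"MAT1-1"` (donor allele at MAT, the default — the female-fertile
#'   partner must be compatible with the MAT1-2 recurrent parent),
#'   `"MAT1-2"` or `"none"`.
#' @param final_mat_allele optional different selection in the last round
#'   (e.g. `"MAT1-2"` to construct FF2-style lines); `NULL` keeps
#'   `select_mat_allele`.
#' @param fs_group,mat_group linkage groups carrying the FS and MAT loci
#'   (placed at the marker nearest mid-group).
#' @param max_rejects cap on rejection-sampled gametes per selection round.
#' @param seed integer seed used by [run_backcross_line()] /
#'   [emit_dataset()] when not `NULL`.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_groups = 7,
                       genetic_lengths = 1.0,
                       physical_lengths = 1.2e6,
                       markers_per_group = 1200,
                       genes_per_group = 150,
                       n_backcrosses = 10,
                       n_lines = 3,
                       panel_fertile = 20,
                       panel_sterile = 20,
                       n_assoc_markers = 17,
                       select_mat_allele = c("MAT1-1", "MAT1-2", "none"),
                       final_mat_allele = NULL,
                       fs_group = 2,
                       mat_group = 6,
                       max_rejects = 10000,
                       seed = NULL) {
  select_mat_allele <- match.arg(select_mat_allele)
  counts <- c(n_groups = n_groups, markers_per_group = markers_per_group,
              genes_per_group = genes_per_group, n_lines = n_lines,
              panel_fertile = panel_fertile, panel_sterile = panel_sterile,
              n_assoc_markers = n_assoc_markers, max_rejects = max_rejects)
  if (any(counts < 1)) stop("counts must be >= 1")
  if (n_backcrosses < 0) stop("n_backcrosses must be >= 0")
  genetic_lengths <- rep_len(genetic_lengths, n_groups)
  physical_lengths <- rep_len(physical_lengths, n_groups)
  if (any(genetic_lengths < 0)) stop("genetic lengths must be >= 0")
  if (fs_group > n_groups || mat_group > n_groups)
    stop("fs_group/mat_group outside 1..n_groups")
  if (!is.null(final_mat_allele) &&
      !final_mat_allele %in% c("MAT1-1", "MAT1-2", "none"))
    stop("final_mat_allele must be 'MAT1-1', 'MAT1-2' or 'none'")
  structure(list(n_groups = as.integer(n_groups),
                 genetic_lengths = genetic_lengths,
                 physical_lengths = physical_lengths,
                 markers_per_group = as.integer(markers_per_group),
                 genes_per_group = as.integer(genes_per_group),
                 n_backcrosses = as.integer(n_backcrosses),
                 n_lines = as.integer(n_lines),
                 panel_fertile = as.integer(panel_fertile),
                 panel_sterile = as.integer(panel_sterile),
                 n_assoc_markers = as.integer(n_assoc_markers),
                 select_mat_allele = select_mat_allele,
                 final_mat_allele = final_mat_allele,
                 fs_group = as.integer(fs_group),
                 mat_group = as.integer(mat_group),
                 max_rejects = as.integer(max_rejects),
                 seed = seed),
            class = "sim_config")
}

#' Build the genome map described by a simulation configuration
#'
#' Deterministic (no random numbers): markers on a uniform grid, genes
#' evenly spaced with two CDS segments each (alternating strand), FS and MAT
#' at the marker nearest the middle of their groups.
#'
#' @param config a [sim_config].
#' @return A [genome_map] with gene annotation and `FS`/`MAT` selected loci.
#' @export
build_genome_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gid <- sprintf("LG%d", seq_len(config$n_groups))
  groups <- data.frame(group_id = gid,
                       physical_length = as.integer(config$physical_lengths),
                       genetic_length = config$genetic_lengths,
                       stringsAsFactors = FALSE)
  mk <- do.call(rbind, lapply(seq_len(config$n_groups), function(i) {
    m <- config$markers_per_group
    spacing <- groups$physical_length[i] %/% (m + 1L)
    if (spacing < 1L) stop("too many markers for group physical length")
    data.frame(group_id = gid[i], pos = spacing * seq_len(m),
               stringsAsFactors = FALSE)
  }))

  ng <- config$genes_per_group
  gene_rows <- list(); cds_rows <- list()
  for (i in seq_len(config$n_groups)) {
    gs <- groups$physical_length[i] %/% (ng + 1L)
    if (gs < 2000L) stop("gene spacing too tight; reduce genes_per_group")
    start <- gs * seq_len(ng)
    ids <- sprintf("%s_G%03d", gid[i], seq_len(ng))
    gene_rows[[i]] <- data.frame(
      gene_id = ids, group_id = gid[i],
      start = start, end = start + 1800L,
      strand = ifelse(seq_len(ng) %% 2L == 1L, "+", "-"),
      stringsAsFactors = FALSE)
    cds_rows[[i]] <- data.frame(
      gene_id = rep(ids, each = 2L),
      start = as.vector(rbind(start + 200L, start + 650L)),
      end = as.vector(rbind(start + 499L, start + 949L)),
      stringsAsFactors = FALSE)
  }
  ann <- gene_annotation(do.call(rbind, gene_rows), do.call(rbind, cds_rows))

  mid_marker <- function(group_i) {
    rows <- which(mk$group_id == gid[group_i])
    target <- groups$physical_length[group_i] / 2
    rows[which.min(abs(mk$pos[rows] - target))]
  }
  map <- genome_map(groups, mk, annotation = ann)
  sel <- c(FS = map$markers$marker_id[mid_marker(config$fs_group)],
           MAT = map$markers$marker_id[mid_marker(config$mat_group)])
  genome_map(groups, mk[, c("group_id", "pos")], annotation = ann,
             selected_loci = sel)
}

#' Founder haplotypes
#'
#' @param map a [genome_map].
#' @param origin `"donor"` or `"recurrent"`.
#' @return Integer haplotype vector over the map's markers
#'   (1 = donor, 0 = recurrent).
#' @export
founder_haplotype <- function(map, origin = c("donor", "recurrent")) {
  origin <- match.arg(origin)
  rep(if (origin == "donor") 1L else 0L, nrow(map$markers))
}
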