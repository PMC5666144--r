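#' Demo pipeline configuration
#'
#' Bundles the stage parameters of the end-to-end demonstration. Only the
#' listed keys exist; anything else is a construction error, so configs
#' cannot silently carry typos.
#'
#' @param seed global seed; per-stage streams are derived deterministically
#'   from it.
#' @param out_dir output directory for the demo artifacts.
#' @param sim a [sim_config] for the breeding simulation.
#' @param window_markers introgression-scan window. The default (13) spans
#'   about 1.1 cM on the default marker grid — sized well below the typical
#'   10-20 cM drag block so that error-free donor runs around the selected
#'   loci sit above the caller's resolution floor.
#' @param min_donor_frac donor fraction threshold of the scan.
#' @param alpha significance level for the corrected association p-values.
#' @param correction multiple-testing correction across panel markers.
#' @return List of class `demo_config`.
#' @export
demo_config <- function(seed = 1, out_dir = tempfile("introgmap_demo"),
                        sim = sim_config(seed = seed),
                        window_markers = 13, min_donor_frac = 0.9,
                        alpha = 0.05, correction = "bonferroni") {
  stopifnot(inherits(sim, "sim_config"))
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
                 window_markers = window_markers,
                 min_donor_frac = min_donor_frac,
                 alpha = alpha, correction = correction),
            class = "demo_config")
}

#' Run the end-to-end breeding-scheme demonstration
#'
#' Simulates the full mapping experiment and re-derives its analytic
#' expectations: independent backcross lines with selection at FS and MAT;
#' donor introgression blocks per line; consensus regions across lines
#' (with member genes); an extra backcross round yielding a fertile/sterile
#' association panel; exact marker-trait association with correction and
#' candidate-locus localization; the segregation test of the pre-binning
#' fertile fraction; and the comparison of the observed retained-gene count
#' against the unselected expectation `0.5^n * G`. Artifacts (blocks BED,
#' association TSV, report JSON) are written under `config$out_dir`.
#'
#' @param config a [demo_config].
#' @return The report, invisibly (also written as `report.json`): seed and
#'   key parameters, per-line donor fractions, consensus summary (including
#'   `fs_in_consensus`), association summary (including `contains_fs`),
#'   segregation p-value, expected vs observed retention, artifact paths.
#' @export
run_demo <- function(config = demo_config()) {
  stopifnot(inherits(config, "demo_config"))
  if (!dir.exists(config$out_dir) &&
      !dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("demo stage 'setup' failed: cannot create ", config$out_dir,
         " (seed ", config$seed, ")")
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("demo stage '", stage, "' failed (seed ", config$seed, "): ",
           conditionMessage(e), call. = FALSE))
  }
  set.seed(config$seed)
  sim <- config$sim; sim$seed <- NULL    # one global stream, seeded above

  map <- run_stage("genome_map", build_genome_map(config$sim))
  lines <- run_stage("backcross", lapply(seq_len(config$sim$n_lines),
                                         function(i)
                                           run_backcross_line(map, sim)))
  blocks <- run_stage("introgression", lapply(lines, function(l)
    detect_donor_blocks(l$haplotype, map,
                        window_markers = config$window_markers,
                        min_donor_frac = config$min_donor_frac)))
  ann <- gene_annotation(map$genes[, c("gene_id", "group_id", "start",
                                       "end", "strand")], map$cds)
  consensus <- run_stage("consensus",
                         consensus_regions(blocks, map, annotation = ann))
  fs_id <- map$selected_loci[["FS"]]
  fs_pos <- map$markers$pos[.marker_index(map, fs_id)]
  fs_group <- map$markers$group_id[.marker_index(map, fs_id)]
  fs_in_consensus <- any(consensus$group_id == fs_group &
                           consensus$start <= fs_pos &
                           consensus$end >= fs_pos)

  panel <- run_stage("panel",
                     simulate_association_panel(lines[[1]], map, sim))
  assoc <- run_stage("association",
                     associate_markers(panel$genotypes, panel$phenotypes,
                                       correction = config$correction))
  locus <- run_stage("locus",
                     rank_candidate_locus(assoc, alpha = config$alpha,
                                          fs_marker = fs_id))
  seg <- segregation_test(panel$n_fertile_seen,
                          panel$n_draws - panel$n_fertile_seen)

  G <- nrow(map$genes)
  exp_ret <- expected_retention(config$sim$n_backcrosses, G)
  fs_truth_genes <- vapply(lines, function(l) {
    tr <- l$truth[l$truth$group_id == fs_group, , drop = FALSE]
    length(unique(unlist(lapply(seq_len(nrow(tr)), function(i)
      map$genes$gene_id[map$genes$group_id == fs_group &
                          map$genes$start <= tr$end[i] &
                          map$genes$end >= tr$start[i]]))))
  }, integer(1))

  paths <- list(
    blocks_bed = file.path(config$out_dir, "donor_blocks.bed"),
    consensus_tsv = file.path(config$out_dir, "consensus_regions.tsv"),
    association_tsv = file.path(config$out_dir, "association.tsv"),
    genotypes_tsv = file.path(config$out_dir, "panel_genotypes.tsv"),
    phenotypes_tsv = file.path(config$out_dir, "panel_phenotypes.tsv"),
    report_json = file.path(config$out_dir, "report.json"))
  all_blocks <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (nrow(b)) b$name <- sprintf("line%d_block%d", i, seq_len(nrow(b)))
    b
  }))
  write_bed(all_blocks, paths$blocks_bed)
  write.table(consensus, paths$consensus_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(assoc, paths$association_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_genotypes_tsv(panel$genotypes, paths$genotypes_tsv)
  write_phenotypes_tsv(panel$phenotypes, paths$phenotypes_tsv)

  report <- list(
    seed = config$seed,
    n_backcrosses = config$sim$n_backcrosses,
    n_lines = config$sim$n_lines,
    lines = list(donor_fraction = vapply(lines, `[[`, numeric(1),
                                         "donor_fraction"),
                 n_donor_intervals = vapply(lines, function(l) nrow(l$truth),
                                            integer(1)),
                 donor_genes_near_fs = fs_truth_genes),
    consensus = list(n_regions = nrow(consensus),
                     total_genes = attr(consensus, "total_genes"),
                     fs_in_consensus = fs_in_consensus),
    association = list(n_markers = nrow(assoc),
                       n_significant = sum(assoc$adjusted_p < config$alpha),
                       candidate_interval = locus$interval,
                       contains_fs = locus$contains_fs),
    segregation = list(n_fertile_seen = panel$n_fertile_seen,
                       n_draws = panel$n_draws,
                       p_value = seg$p_value),
    retention = list(expected_fraction = exp_ret$expected_fraction,
                     expected_genes = exp_ret$expected_genes,
                     genome_genes = G,
                     observed_consensus_genes = attr(consensus,
                                                     "total_genes")),
    paths = paths)
  jsonlite::write_json(report, paths$report_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
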