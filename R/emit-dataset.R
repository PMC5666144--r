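#' Emit a complete synthetic dataset to disk
#'
#' Runs the whole generator under one seed and writes every artifact the
#' analysis stages consume, in standard formats: the genome (FASTA), gene
#' models (GFF3), the parental SNP catalog with two haploid parent columns
#' (VCF), the association panel (genotype and phenotype TSV), the breeding
#' lines' marker-origin vectors (TSV) and a truth JSON (donor intervals per
#' line, planted SNP regions, per-gene effect counts, selected loci).
#' Identical configurations (including seed) produce byte-identical files.
#'
#' @param config a [sim_config] with a non-`NULL` seed.
#' @param out_dir output directory (created if needed).
#' @param catalog_args optional list of overrides passed to
#'   [simulate_snp_catalog()].
#' @return Invisibly, a list with the generated objects and a `paths`
#'   element naming every file written.
#' @export
emit_dataset <- function(config, out_dir, catalog_args = list()) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) stop("emit_dataset requires config$seed")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  set.seed(config$seed)

  map <- build_genome_map(config)
  genome <- simulate_genome_sequences(map)
  catalog <- do.call(simulate_snp_catalog,
                     c(list(map = map, genome = genome), catalog_args))

  line_cfg <- config; line_cfg$seed <- NULL  # RNG already seeded
  lines <- lapply(seq_len(config$n_lines), function(i)
    run_backcross_line(map, line_cfg))
  panel <- simulate_association_panel(lines[[1]], map, line_cfg)

  paths <- list(
    genome = file.path(out_dir, "genome.fasta"),
    genes = file.path(out_dir, "genes.gff3"),
    snps = file.path(out_dir, "snps.vcf"),
    genotypes = file.path(out_dir, "panel_genotypes.tsv"),
    phenotypes = file.path(out_dir, "panel_phenotypes.tsv"),
    line_origins = file.path(out_dir, "line_origins.tsv"),
    truth = file.path(out_dir, "truth.json"))

  write_fasta(genome, paths$genome)
  write_gff3(gene_annotation(map$genes[, c("gene_id", "group_id", "start",
                                           "end", "strand")], map$cds),
             paths$genes)
  parent_calls <- matrix(rep(c("donor", "recurrent"),
                             each = nrow(catalog$snps)),
                         nrow = 2L, byrow = TRUE,
                         dimnames = list(c("donor_parent", "recurrent_parent"),
                                         paste0(catalog$snps$group_id, ":",
                                                catalog$snps$pos)))
  write_vcf(catalog$snps, paths$snps, genotypes = genotype_table(parent_calls))
  write_genotypes_tsv(panel$genotypes, paths$genotypes)
  write_phenotypes_tsv(panel$phenotypes, paths$phenotypes)

  lo <- do.call(rbind, lapply(seq_along(lines), function(i)
    c("recurrent", "donor")[lines[[i]]$haplotype + 1L]))
  rownames(lo) <- sprintf("line%d", seq_along(lines))
  colnames(lo) <- map$markers$marker_id
  write_genotypes_tsv(genotype_table(lo), paths$line_origins)

  truth <- list(
    seed = config$seed,
    selected_loci = as.list(map$selected_loci),
    lines = lapply(lines, function(l)
      list(donor_fraction = l$donor_fraction, donor_intervals = l$truth)),
    panel = list(markers = panel$truth$markers,
                 n_draws = panel$n_draws,
                 n_fertile_seen = panel$n_fertile_seen),
    snp_truth = list(gene_counts = catalog$truth$gene_counts,
                     planted_regions = catalog$truth$planted_regions,
                     zero_nonsyn_genes = catalog$truth$zero_nonsyn_genes))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(map = map, genome = genome, catalog = catalog,
                 lines = lines, panel = panel, paths = paths))
}
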