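# small genome maps built directly (no sim_config), for meiosis and
# block-detection tests with custom grids

make_map <- function(markers_per_group, genetic_length = 1,
                     n_groups = 1, physical_length = NULL,
                     fs_marker = NULL, mat_marker = NULL) {
  if (is.null(physical_length)) physical_length <- markers_per_group * 1000L
  gid <- sprintf("G%d", seq_len(n_groups))
  groups <- data.frame(group_id = gid,
                       physical_length = physical_length,
                       genetic_length = genetic_length)
  spacing <- physical_length %/% (markers_per_group + 1L)
  mk <- do.call(rbind, lapply(gid, function(g)
    data.frame(group_id = g, pos = spacing * seq_len(markers_per_group))))
  sel <- character()
  m <- genome_map(groups, mk)
  if (!is.null(fs_marker)) sel <- c(sel, FS = m$markers$marker_id[fs_marker])
  if (!is.null(mat_marker)) sel <- c(sel, MAT = m$markers$marker_id[mat_marker])
  genome_map(groups, mk, selected_loci = sel)
}

# two markers exactly d Morgans apart on one group
make_two_marker_map <- function(d) {
  phys <- 100000L
  p1 <- 1L; p2 <- phys
  L <- d * phys / (p2 - p1)
  genome_map(data.frame(group_id = "A", physical_length = phys,
                        genetic_length = L),
             data.frame(group_id = "A", pos = c(p1, p2)))
}

# a small breeding-scheme config for fast simulation tests
small_sim_config <- function(...) {
  sim_config(n_groups = 7, markers_per_group = 80,
             physical_lengths = 2e5, genes_per_group = 40,
             ...)
}
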