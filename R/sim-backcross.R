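# selection rule at the MAT locus: the MAT1-1 idiomorph is the donor allele
# (the donor parent is MAT1-1, the recurrent parent MAT1-2)
.mat_ok <- function(gamete, mat_i, allele) {
  switch(allele,
         "MAT1-1" = gamete[mat_i] == 1L,
         "MAT1-2" = gamete[mat_i] == 0L,
         "none" = TRUE)
}

#' Simulate one backcross breeding line
#'
#' Generation 1 crosses the all-donor haplotype (fertile wild isolate) with
#' the all-recurrent haplotype (female-sterile laboratory strain); each
#' following generation crosses the selected progeny back to the recurrent
#' parent. Every round, gametes are rejection-sampled until the donor allele
#' is present at FS (female fertility is restored only by the donor allele)
#' and the configured mating-type rule holds. After `n_backcrosses` total
#' crosses the surviving haplotype and its true donor intervals are
#' returned.
#'
#' @param map a [genome_map] with `FS` (and, if mating-type selection is
#'   requested, `MAT`) among its selected loci.
#' @param config a [sim_config]; `config$seed`, when non-`NULL`, seeds the
#'   session RNG before simulation.
#' @return An object of class `backcross_line`: list with `haplotype`,
#'   `truth` (donor intervals, see [donor_intervals()]), `donor_fraction`,
#'   and `gametes_per_round` (rejection-sampling effort).
#' @export
run_backcross_line <- function(map, config = sim_config()) {
  stopifnot(inherits(map, "genome_map"), inherits(config, "sim_config"))
  if (!"FS" %in% names(map$selected_loci))
    stop("map has no FS locus; selection is impossible")
  fs_i <- .marker_index(map, map$selected_loci[["FS"]])
  mat_rule <- config$select_mat_allele
  mat_i <- NA_integer_
  if (mat_rule != "none" ||
      (!is.null(config$final_mat_allele) && config$final_mat_allele != "none")) {
    if (!"MAT" %in% names(map$selected_loci))
      stop("mating-type selection requested but map has no MAT locus")
    mat_i <- .marker_index(map, map$selected_loci[["MAT"]])
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  donor <- founder_haplotype(map, "donor")
  recur <- founder_haplotype(map, "recurrent")
  current <- donor
  effort <- integer(config$n_backcrosses)
  for (round in seq_len(config$n_backcrosses)) {
    rule <- if (round == config$n_backcrosses && !is.null(config$final_mat_allele))
      config$final_mat_allele else mat_rule
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > config$max_rejects)
        stop("selection failed within max_rejects gametes at round ", round)
      g <- meiosis_gamete(current, recur, map)
      if (g[fs_i] == 1L && .mat_ok(g, mat_i, rule)) break
    }
    effort[round] <- tries
    current <- g
  }
  structure(list(haplotype = current,
                 truth = donor_intervals(current, map),
                 donor_fraction = mean(current == 1L),
                 gametes_per_round = effort),
            class = "backcross_line")
}

#' @export
print.backcross_line <- function(x, ...) {
  cat("backcross_line:", length(x$haplotype), "markers; donor fraction",
      signif(x$donor_fraction, 3), ";", nrow(x$truth),
      "donor interval(s)\n")
  invisible(x)
}

#' Fertility of progeny gametes from a line x recurrent-parent cross
#'
#' Draws `n` meiotic gametes from the cross of `line` with the all-recurrent
#' parent and reports whether each carries the donor (fertility-restoring)
#' allele at FS.
#'
#' @param line a `backcross_line` (or an integer haplotype).
#' @param map a [genome_map] with an `FS` selected locus.
#' @param n number of gametes.
#' @return Logical vector of length `n` (`TRUE` = female fertile).
#' @export
progeny_fertility <- function(line, map, n) {
  h <- if (inherits(line, "backcross_line")) line$haplotype else line
  fs_i <- .marker_index(map, map$selected_loci[["FS"]])
  recur <- founder_haplotype(map, "recurrent")
  vapply(seq_len(n),
         function(i) meiosis_gamete(h, recur, map)[fs_i] == 1L,
         logical(1))
}

# default association-marker subset: markers inside the line's true donor
# intervals (FS marker forced in) plus matched control markers on groups
# without retained donor segments
.select_assoc_markers <- function(truth, map, n_total, fs_marker) {
  mk <- map$markers
  in_interval <- rep(FALSE, nrow(mk))
  for (i in seq_len(nrow(truth))) {
    in_interval <- in_interval |
      (mk$group_id == truth$group_id[i] &
         mk$pos >= truth$start[i] & mk$pos <= truth$end[i])
  }
  case_pool <- which(in_interval)
  if (!length(case_pool)) case_pool <- .marker_index(map, fs_marker)
  n_case <- min(length(case_pool), ceiling(n_total * 9 / 17))
  case_idx <- unique(c(.marker_index(map, fs_marker),
                       case_pool[round(seq(1, length(case_pool),
                                           length.out = n_case))]))
  ctrl_groups <- setdiff(map$groups$group_id, unique(truth$group_id))
  ctrl_pool <- which(mk$group_id %in% ctrl_groups)
  if (!length(ctrl_pool)) ctrl_pool <- setdiff(seq_len(nrow(mk)), case_idx)
  n_ctrl <- max(0L, n_total - length(case_idx))
  ctrl_idx <- if (n_ctrl > 0 && length(ctrl_pool))
    unique(ctrl_pool[round(seq(1, length(ctrl_pool),
                               length.out = min(n_ctrl, length(ctrl_pool))))])
  else integer()
  sort(unique(c(case_idx, ctrl_idx)))
}

#' Simulate a fertile/sterile association panel
#'
#' Performs the additional backcross round of the mapping design: gametes
#' are drawn from the cross of a final fertile line with the recurrent
#' parent and binned by fertility phenotype (donor allele at FS) until the
#' requested numbers of fertile and sterile individuals are collected.
#' Genotypes are reported at a marker subset emulating the study design of a
#' handful of SNP markers covering the retained donor regions plus matched
#' controls elsewhere.
#'
#' @param line a `backcross_line` from [run_backcross_line()].
#' @param map the [genome_map] the line was simulated on.
#' @param config a [sim_config] (panel sizes, `n_assoc_markers`).
#' @param markers optional explicit character vector of marker ids to
#'   genotype (overrides the default subset); must be non-empty.
#' @return List with `genotypes` (a [genotype_table]), `phenotypes` (a
#'   [phenotype_table]), `truth` (fs/mat marker ids, marker subset, the
#'   line's donor intervals), `n_draws` and `n_fertile_seen` (pre-binning
#'   segregation bookkeeping).
#' @export
simulate_association_panel <- function(line, map, config = sim_config(),
                                       markers = NULL) {
  stopifnot(inherits(line, "backcross_line"))
  fs_marker <- map$selected_loci[["FS"]]
  fs_i <- .marker_index(map, fs_marker)
  if (is.null(markers)) {
    idx <- .select_assoc_markers(line$truth, map, config$n_assoc_markers,
                                 fs_marker)
  } else {
    if (!length(markers)) stop("requested marker subset is empty")
    idx <- sort(.marker_index(map, markers))
  }
  mat_i <- if ("MAT" %in% names(map$selected_loci))
    .marker_index(map, map$selected_loci[["MAT"]]) else NA_integer_
  recur <- founder_haplotype(map, "recurrent")
  nf <- config$panel_fertile; ns <- config$panel_sterile
  kept <- matrix(NA_integer_, nf + ns, length(idx))
  fert <- logical(nf + ns); mat <- integer(nf + ns)
  got_f <- 0L; got_s <- 0L; draws <- 0L; fertile_seen <- 0L
  cap <- 1000L * (nf + ns)
  while (got_f < nf || got_s < ns) {
    draws <- draws + 1L
    if (draws > cap) stop("panel binning exceeded draw cap")
    g <- meiosis_gamete(line$haplotype, recur, map)
    f <- g[fs_i] == 1L
    fertile_seen <- fertile_seen + as.integer(f)
    if (f && got_f < nf) {
      got_f <- got_f + 1L; k <- got_f
    } else if (!f && got_s < ns) {
      got_s <- got_s + 1L; k <- nf + got_s
    } else next
    kept[k, ] <- g[idx]
    fert[k] <- f
    mat[k] <- if (is.na(mat_i)) NA_integer_ else g[mat_i]
  }
  ids <- sprintf("P%03d", seq_len(nf + ns))
  calls <- matrix(c("recurrent", "donor")[kept + 1L], nrow = nf + ns,
                  dimnames = list(ids, map$markers$marker_id[idx]))
  mk_info <- map$markers[idx, c("marker_id", "group_id", "pos")]
  rownames(mk_info) <- NULL
  list(genotypes = genotype_table(calls, markers = mk_info),
       phenotypes = phenotype_table(
         ids,
         ifelse(fert, "fertile", "sterile"),
         ifelse(is.na(mat), NA_character_,
                ifelse(mat == 1L, "MAT1-1", "MAT1-2"))),
       truth = list(fs_marker = fs_marker,
                    mat_marker = if (is.na(mat_i)) NULL else
                      map$selected_loci[["MAT"]],
                    markers = map$markers$marker_id[idx],
                    donor_intervals = line$truth),
       n_draws = draws,
       n_fertile_seen = fertile_seen)
}
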