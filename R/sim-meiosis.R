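#' Draw one meiotic gamete from a haploid x haploid cross
#'
#' Crossover model without interference (Haldane): per linkage group the
#' crossover count is Poisson with mean equal to the group's genetic length
#' in Morgans and breakpoints fall uniformly on the genetic map; the gamete
#' alternates parental origin at the breakpoints, starting from either
#' parent with probability 1/2. The recombination fraction between two loci
#' d Morgans apart is therefore the probability of an odd crossover count on
#' the interval, r = (1 - exp(-2d)) / 2 — Haldane's map function.
#'
#' Randomness comes from the session RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param parent_a,parent_b integer haplotypes (1 = donor, 0 = recurrent)
#'   indexed on `map`'s markers.
#' @param map a [genome_map].
#' @return Integer gamete haplotype of the same length.
#' @export
meiosis_gamete <- function(parent_a, parent_b, map) {
  n <- nrow(map$markers)
  if (length(parent_a) != n || length(parent_b) != n)
    stop("parent haplotypes are not indexed on the same marker grid as the map")
  out <- integer(n)
  rows_by_group <- .group_rows(map)
  gl <- map$groups$genetic_length
  gpos <- map$markers$gpos
  for (i in seq_along(rows_by_group)) {
    rows <- rows_by_group[[i]]
    if (!length(rows)) next
    L <- gl[i]
    k <- if (L > 0) rpois(1L, L) else 0L
    start <- rbinom(1L, 1L, 0.5)       # 0 = begin with parent_a
    if (k > 0L) {
      br <- sort(runif(k, 0, L))
      phase <- (start + findInterval(gpos[rows], br)) %% 2L
    } else {
      phase <- rep(start, length(rows))
    }
    a_side <- phase == 0L
    out[rows[a_side]] <- parent_a[rows[a_side]]
    out[rows[!a_side]] <- parent_b[rows[!a_side]]
  }
  out
}

#' Maximal donor-origin runs of a haplotype, as physical intervals
#'
#' The truth record of a simulated line: each interval covers exactly one
#' maximal run of donor-origin markers (bp of the first to the last marker
#' of the run).
#'
#' @param haplotype integer haplotype over `map`'s markers.
#' @param map a [genome_map].
#' @return data.frame with `group_id`, `start`, `end`, `first_marker`,
#'   `last_marker`, `n_markers`.
#' @export
donor_intervals <- function(haplotype, map) {
  h <- .as_origin_int(haplotype)
  rows_by_group <- .group_rows(map)
  res <- list()
  for (g in names(rows_by_group)) {
    rows <- rows_by_group[[g]]
    if (!length(rows)) next
    r <- rle(h[rows] == 1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) next
    res[[g]] <- data.frame(
      group_id = g,
      start = map$markers$pos[rows[starts[keep]]],
      end = map$markers$pos[rows[ends[keep]]],
      first_marker = map$markers$marker_id[rows[starts[keep]]],
      last_marker = map$markers$marker_id[rows[ends[keep]]],
      n_markers = r$lengths[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(group_id = character(), start = integer(),
                      end = integer(), first_marker = character(),
                      last_marker = character(), n_markers = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
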