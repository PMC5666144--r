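counts_from <- function(nonsyn, group = "c1") {
  n <- length(nonsyn)
  data.frame(gene_id = sprintf("%s_g%02d", group, seq_len(n)),
             group_id = group,
             start = 1000L * seq_len(n), end = 1000L * seq_len(n) + 500L,
             n_nonsynonymous = as.integer(nonsyn),
             stringsAsFactors = FALSE)
}

test_that("nonsyn region scan applies the run definition and gap rule", {
  # five consecutive qualifying genes form one region
  r1 <- scan_nonsyn_regions(counts_from(c(12, 15, 11, 20, 13)))
  expect_equal(nrow(r1), 1)
  expect_equal(r1$n_genes, 5)
  expect_equal(r1$start, 1000L)
  expect_equal(r1$end, 5500L)

  # a below-threshold gene splits the run unless one gap gene is allowed
  x <- c(12, 15, 3, 11, 20, 13)
  expect_equal(nrow(scan_nonsyn_regions(counts_from(x))), 0)
  r2 <- scan_nonsyn_regions(counts_from(x), max_gap_genes = 1)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$n_genes, 5)   # qualifying members only
  expect_false(grepl("g03", r2$gene_ids))

  # brute-force check of the gap rule over random count vectors
  set.seed(501)
  brute <- function(v, min_genes, thr, gap) {
    qual <- which(v >= thr)
    if (!length(qual)) return(0L)
    runs <- split(qual, cumsum(c(0, diff(qual) - 1 > gap)))
    sum(vapply(runs, length, 1L) >= min_genes)
  }
  for (i in 1:50) {
    v <- sample(0:15, 12, replace = TRUE)
    gap <- sample(0:2, 1)
    expect_equal(nrow(scan_nonsyn_regions(counts_from(v), min_genes = 3,
                                          max_gap_genes = gap)),
                 brute(v, 3, 10, gap))
  }

  expect_equal(nrow(scan_nonsyn_regions(counts_from(rep(4, 10)))), 0)
  expect_error(scan_nonsyn_regions(counts_from(1:6)[6:1, ]), "sorted")
})

test_that("region scan is invariant under coordinate mirroring", {
  set.seed(502)
  v <- c(0, 12, 13, 14, 15, 16, 2, 0, 11, 12, 13, 11, 10, 1)
  cc <- counts_from(v)
  fwd <- scan_nonsyn_regions(cc, min_genes = 4)
  L <- max(cc$end) + 1000L
  mir <- cc
  mir$start <- L - cc$end
  mir$end <- L - counts_from(v)$start
  mir <- mir[order(mir$start), ]
  rev_ <- scan_nonsyn_regions(mir, min_genes = 4)
  expect_equal(nrow(fwd), nrow(rev_))
  expect_setequal(paste(L - fwd$end, L - fwd$start),
                  paste(rev_$start, rev_$end))
})

test_that("cumulative mode flags windows by summed counts", {
  v <- c(0, 0, 30, 30, 0, 0, 0, 0)   # two hot genes, rest empty
  r <- scan_nonsyn_regions(counts_from(v), min_genes = 3,
                           min_snps_per_gene = 10, mode = "cumulative")
  expect_equal(nrow(r), 1)           # windows of 3 summing >= 30
  expect_true(grepl("g03", r$gene_ids) && grepl("g04", r$gene_ids))
  expect_equal(nrow(scan_nonsyn_regions(counts_from(v), min_genes = 3,
                                        min_snps_per_gene = 25,
                                        mode = "cumulative")), 0)
})

test_that("donor block detection recovers planted blocks within one window", {
  map <- make_map(markers_per_group = 1000, genetic_length = 1)
  h <- rep(0L, 1000)
  h[301:360] <- 1L                  # 60-marker planted block
  b <- detect_donor_blocks(h, map, window_markers = 25)
  expect_equal(nrow(b), 1)
  pos <- map$markers$pos
  expect_lte(abs(b$start - pos[301]), pos[25] - pos[1])
  expect_lte(abs(b$end - pos[360]), pos[25] - pos[1])

  # all-recurrent and all-donor edge cases
  expect_equal(nrow(detect_donor_blocks(rep(0L, 1000), map)), 0)
  full <- detect_donor_blocks(rep(1L, 1000), map)
  expect_equal(nrow(full), 1)
  expect_equal(full$n_markers, 1000L)

  # missing calls are excluded from denominators, not counted as recurrent
  h2 <- h
  h2[seq(302, 358, by = 7)] <- NA
  b2 <- detect_donor_blocks(h2, map, window_markers = 25)
  expect_equal(nrow(b2), 1)

  # window larger than the group degrades to one window with a warning
  small <- make_map(markers_per_group = 10)
  expect_warning(one <- detect_donor_blocks(rep(1L, 10), small,
                                            window_markers = 25),
                 "single window")
  expect_equal(one$n_markers, 10L)
})

test_that("randomized planted blocks >= 2x window are recovered at >= 95%", {
  set.seed(503)
  map <- make_map(markers_per_group = 800, genetic_length = 1)
  hits <- 0L; total <- 0L
  for (i in 1:40) {
    h <- rep(0L, 800)
    len <- sample(50:120, 1)
    s <- sample(800 - len, 1)
    h[s:(s + len - 1L)] <- 1L
    b <- detect_donor_blocks(h, map, window_markers = 25)
    total <- total + 1L
    pos <- map$markers$pos
    ok <- nrow(b) == 1 &&
      abs(b$start - pos[s]) <= pos[25] - pos[1] &&
      abs(b$end - pos[s + len - 1L]) <= pos[25] - pos[1]
    hits <- hits + as.integer(ok)
  }
  expect_gte(hits / total, 0.95)
})

test_that("consensus regions are the across-line interval intersection", {
  map <- make_map(markers_per_group = 100, n_groups = 1,
                  physical_length = 400000L)
  blk <- function(s, e) data.frame(group_id = "G1", start = s, end = e,
                                   stringsAsFactors = FALSE)
  # identical blocks intersect to themselves
  r <- consensus_regions(list(blk(100000, 200000), blk(100000, 200000),
                              blk(100000, 200000)), map)
  expect_equal(r$start, 100000)
  expect_equal(r$end, 200000)
  expect_equal(r$support, 3)

  # staggered blocks: [100-200], [150-250], [180-300] kb -> [180-200] kb
  r2 <- consensus_regions(list(blk(100000, 200000), blk(150000, 250000),
                               blk(180000, 300000)), map)
  expect_equal(r2$start, 180000)
  expect_equal(r2$end, 200000)

  # disjoint blocks: empty consensus
  r3 <- consensus_regions(list(blk(1, 1000), blk(300000, 301000)), map)
  expect_equal(nrow(r3), 0)

  expect_error(consensus_regions(list(blk(1, 10)), map), "at least 2")
  expect_error(consensus_regions(list(blk(1, 10),
                                      data.frame(group_id = "ZZ", start = 1,
                                                 end = 5)), map),
               "absent from the map")
})

test_that("consensus is associative and order-independent", {
  set.seed(504)
  map <- make_map(markers_per_group = 100, n_groups = 2,
                  physical_length = 100000L)
  rand_blocks <- function() {
    k <- sample(1:3, 1)
    do.call(rbind, lapply(seq_len(k), function(i) {
      g <- sample(c("G1", "G2"), 1)
      s <- sample.int(80000, 1)
      data.frame(group_id = g, start = s, end = s + sample.int(30000, 1),
                 stringsAsFactors = FALSE)
    }))
  }
  for (i in 1:20) {
    a <- rand_blocks(); b <- rand_blocks(); c <- rand_blocks()
    direct <- consensus_regions(list(a, b, c), map)
    nested <- consensus_regions(list(consensus_regions(list(a, b), map), c),
                                map)
    perm <- consensus_regions(list(c, a, b), map)
    cols <- c("group_id", "start", "end")
    expect_equal(direct[, cols], nested[, cols])
    expect_equal(direct[, cols], perm[, cols])
  }
})

test_that("FS lies in the consensus whenever line blocks clear the resolution floor", {
  set.seed(505)
  cfg <- sim_config(markers_per_group = 1200, n_backcrosses = 10)
  map <- build_genome_map(cfg)
  fs_id <- map$selected_loci[["FS"]]
  fs_i <- match(fs_id, map$markers$marker_id)
  fs_group <- map$markers$group_id[fs_i]
  fs_pos <- map$markers$pos[fs_i]
  w <- 13
  checked <- 0L
  for (rep in 1:6) {
    lines <- lapply(1:3, function(i) run_backcross_line(map, cfg))
    floor_ok <- all(vapply(lines, function(l) {
      tr <- l$truth
      fs_run <- tr$group_id == fs_group & tr$start <= fs_pos &
        tr$end >= fs_pos
      any(fs_run) && max(tr$n_markers[fs_run]) >= 2 * w
    }, logical(1)))
    if (!floor_ok) next
    checked <- checked + 1L
    blocks <- lapply(lines, function(l)
      detect_donor_blocks(l$haplotype, map, window_markers = w))
    cons <- consensus_regions(blocks, map)
    expect_true(any(cons$group_id == fs_group & cons$start <= fs_pos &
                      cons$end >= fs_pos))
  }
  # the detection-floor condition holds for nearly all simulated lines
  expect_gte(checked, 4)
})
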