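test_that("genome_map validates its invariants", {
  groups <- data.frame(group_id = c("A", "B"), physical_length = 1e5,
                       genetic_length = 1)
  mk <- data.frame(group_id = rep(c("A", "B"), each = 3),
                   pos = rep(c(10, 20, 30) * 1000, 2))
  map <- genome_map(groups, mk)
  expect_s3_class(map, "genome_map")
  expect_equal(nrow(map$markers), 6)
  expect_true(all(diff(map$markers$gpos[map$markers$group_id == "A"]) > 0))

  expect_error(genome_map(groups[c(1, 1), ], mk), "duplicated")
  bad <- mk; bad$pos[2] <- bad$pos[1]
  expect_error(genome_map(groups, bad), "strictly increasing")
  expect_error(genome_map(groups, transform(mk, pos = pos * 10)),
               "outside physical length")
  expect_error(genome_map(groups, mk, selected_loci = c(FS = "nope")),
               "unknown marker")
  expect_warning(
    genome_map(groups, mk,
               selected_loci = c(FS = map$markers$marker_id[1],
                                 MAT = map$markers$marker_id[2])),
    "same linkage group")
})

test_that("GFF3 reader parses, sorts CDS, flags and rejects bad records", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=gA",
           # CDS listed out of order in the file
           "chr1\tsrc\tCDS\t301\t360\t.\t+\t0\tID=gA.c2;Parent=gA",
           "chr1\tsrc\tCDS\t101\t160\t.\t+\t0\tID=gA.c1;Parent=gA",
           "chr1\tsrc\tgene\t501\t700\t.\t-\t.\tID=gB",
           "chr1\tsrc\tCDS\t521\t640\t.\t-\t0\tID=gB.c1;Parent=gB")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, f)
  ann <- read_gff3(f)
  expect_equal(ann$genes$gene_id, c("gA", "gB"))
  cds_a <- ann$cds[ann$cds$gene_id == "gA", ]
  expect_equal(cds_a$start, c(101, 301))     # sorted by genomic position
  expect_equal(sum(cds_a$end - cds_a$start + 1), 120)
  expect_true(all(ann$genes$annotatable))

  # CDS outside span rejected with a diagnostic naming the gene;
  # CDS length not divisible by 3 flags the gene non-annotatable
  gff2 <- c("##gff-version 3",
            "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gC",
            "chr1\tsrc\tCDS\t150\t400\t.\t+\t0\tID=gC.c1;Parent=gC",
            "chr1\tsrc\tgene\t501\t700\t.\t+\t.\tID=gD",
            "chr1\tsrc\tCDS\t501\t600\t.\t+\t0\tID=gD.c1;Parent=gD")
  f2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff2, f2)
  expect_warning(ann2 <- read_gff3(f2), "gC")
  expect_false(ann2$genes$annotatable[ann2$genes$gene_id == "gD"])
})

test_that("GFF3 write/read round-trips the retained fields", {
  genes <- data.frame(gene_id = c("x1", "x2"), group_id = "s1",
                      start = c(100L, 900L), end = c(700L, 1500L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  cds <- data.frame(gene_id = c("x1", "x1", "x2"),
                    start = c(150L, 400L, 1000L),
                    end = c(299L, 549L, 1299L), stringsAsFactors = FALSE)
  ann <- gene_annotation(genes, cds)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, f)
  back <- read_gff3(f)
  expect_equal(back$genes[, names(genes)], genes)
  expect_equal(back$cds, cds)
})

test_that("VCF reader keeps biallelic SNVs, tallies skips, maps haploid GT", {
  vcf <- c("##fileformat=VCFv4.2",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "ind1", sep = "\t"),
           "s1\t100\t.\tA\tG\t.\t.\t.\tGT\t1",
           "s1\t200\t.\tAT\tA\t.\t.\t.\tGT\t0",      # indel: skipped
           "s1\t300\t.\tC\tT\t.\t.\t.\tGT\t.")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  res <- read_vcf(f)
  expect_equal(nrow(res$snps), 2)
  expect_equal(res$n_skipped, 1)
  expect_equal(unname(res$genotypes$calls["ind1", ]),
               c("donor", NA))

  # header-only file: empty table, no error
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf[1:2], f2)
  res2 <- read_vcf(f2)
  expect_equal(nrow(res2$snps), 0)
  expect_equal(res2$n_skipped, 0)

  # missing ##fileformat header is an error
  f3 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf[-1], f3)
  expect_error(read_vcf(f3), "fileformat")

  # diploid GT rejected
  f4 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf[1:2], "s1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1"), f4)
  expect_error(read_vcf(f4), "haploid")
})

test_that("VCF write/read round-trips SNPs, genotypes and effect field", {
  snps <- data.frame(group_id = c("s1", "s1", "s2"),
                     pos = c(11L, 55L, 70L),
                     ref = c("A", "C", "G"), alt = c("T", "G", "A"),
                     effect = c("synonymous", NA, "nonsynonymous"),
                     stringsAsFactors = FALSE)
  calls <- matrix(c("donor", "recurrent", NA,
                    "recurrent", "recurrent", "donor"),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("i1", "i2"),
                                  c("s1:11", "s1:55", "s2:70")))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(snps, f, genotypes = genotype_table(calls))
  back <- read_vcf(f)
  expect_equal(back$snps, snps)
  expect_equal(back$genotypes$calls, calls)
})

test_that("matrix TSV reader enforces numeric cells and unique ids", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ta1\ta2\tb1", "r1\t1\t2\t3", "r2\t4\t5\t6"), f)
  expect_warning(pm <- read_matrix_tsv(f, c(a1 = "A", a2 = "A", b1 = "B")),
                 "fewer than 2")
  expect_equal(attr(pm, "flagged_groups"), "B")
  expect_equal(dim(pm$values), c(2, 3))

  writeLines(c("id\ta1\ta2", "r1\t1\tNA", "r2\t4\t5"), f)
  expect_error(suppressWarnings(read_matrix_tsv(f, c(a1 = "A", a2 = "A"))),
               "row 'r1', column 'a2'")

  writeLines(c("id\ta1\ta2", "r1\t1\t2", "r1\t4\t5"), f)
  expect_error(suppressWarnings(read_matrix_tsv(f, c(a1 = "A", a2 = "A"))),
               "duplicate")
})

test_that("matrix, genotype, phenotype and BED writers round-trip", {
  vals <- matrix(c(1.5, 2, 3, 4.25, 5, 6), 2, byrow = TRUE,
                 dimnames = list(c("r1", "r2"), c("a1", "a2", "b1")))
  grp <- c(a1 = "A", a2 = "A", b1 = "B")
  pm <- suppressWarnings(profile_matrix(vals, grp))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(pm, f)
  back <- suppressWarnings(read_matrix_tsv(f, grp))
  expect_equal(back$values, vals)

  calls <- matrix(c("donor", NA, "recurrent", "donor"), 2,
                  dimnames = list(c("i1", "i2"), c("m1", "m2")))
  gt <- genotype_table(calls)
  fg <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(gt, fg)
  expect_equal(read_genotypes_tsv(fg)$calls, calls)

  ph <- phenotype_table(c("i1", "i2"), c("fertile", "sterile"),
                        c("MAT1-1", NA))
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes_tsv(ph, fp)
  expect_equal(read_phenotypes_tsv(fp), ph)
  expect_true(validate_panel(gt, ph))
  expect_error(validate_panel(gt, ph[1, ]), "without phenotype")

  # BED is the only 0-based half-open surface; conversion is lossless
  regions <- data.frame(group_id = c("A", "B"), start = c(1L, 501L),
                        end = c(100L, 1500L), name = c("x", "y"),
                        stringsAsFactors = FALSE)
  fb <- withr::local_tempfile(fileext = ".bed")
  write_bed(regions, fb)
  raw <- read.delim(fb, header = FALSE)
  expect_equal(raw$V2, c(0L, 500L))            # 0-based starts on disk
  expect_equal(read_bed(fb), regions)
})

test_that("randomized small files round-trip through every reader/writer", {
  set.seed(401)
  for (rep in 1:5) {
    n <- sample(3:12, 1)
    snps <- data.frame(
      group_id = "sc", pos = sort(sample.int(5000, n)),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    snps$alt <- vapply(snps$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    snps$effect <- sample(c("noncoding", "synonymous", "nonsynonymous"),
                          n, replace = TRUE)
    f <- tempfile(fileext = ".vcf")
    write_vcf(snps, f)
    expect_equal(read_vcf(f)$snps, snps)
    unlink(f)

    k <- sample(2:5, 1)
    regions <- data.frame(group_id = "sc",
                          start = sort(sample.int(900, k)) * 10L,
                          stringsAsFactors = FALSE)
    regions$end <- regions$start + sample.int(50, k) * 10L
    fb <- tempfile(fileext = ".bed")
    write_bed(regions, fb)
    expect_equal(read_bed(fb)[, c("group_id", "start", "end")], regions)
    unlink(fb)
  }
})
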