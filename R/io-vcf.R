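#' Read a SNP table (and optional haploid genotypes) from VCF
#'
#' Supports the biallelic single-nucleotide subset of VCF 4.x. Multiallelic
#' or non-SNV records (indels) are skipped and tallied, not errors. Haploid
#' genotype columns are translated as `0` = recurrent (reference allele),
#' `1` = donor (alternate allele), `.` = missing; diploid genotype fields
#' are rejected because the pipeline models haploid ascospore-derived
#' progeny. A coding-effect annotation written by [write_vcf()] (INFO key
#' `EFF`) is read back into the `effect` column.
#'
#' @param path path to a VCF file (must start with a `##fileformat` header).
#' @return A list with elements `snps` (data.frame `group_id`, `pos`, `ref`,
#'   `alt`, `effect`), `genotypes` (a [genotype_table] or `NULL`) and
#'   `n_skipped` (count of non-SNV / multiallelic records).
#' @export
read_vcf <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, "##fileformat"))
    stop("missing VCF header (##fileformat) in ", path)
  n_body <- sum(!startsWith(readLines(path), "#"))
  if (n_body == 0L) {
    return(list(snps = data.frame(group_id = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  effect = character(),
                                  stringsAsFactors = FALSE),
                genotypes = NULL, n_skipped = 0L))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  nt <- c("A", "C", "G", "T")
  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% nt & fix$ALT %in% nt
  n_skipped <- sum(!keep)
  eff <- rep(NA_character_, nrow(fix))
  if (!is.null(fix$INFO)) {
    m <- regmatches(fix$INFO, regexpr("EFF=[a-z]+", fix$INFO))
    has <- grepl("EFF=", fix$INFO)
    eff[has] <- sub("EFF=", "", m)
  }
  snps <- data.frame(group_id = fix$CHROM[keep],
                     pos = as.integer(fix$POS[keep]),
                     ref = fix$REF[keep],
                     alt = fix$ALT[keep],
                     effect = eff[keep],
                     stringsAsFactors = FALSE)
  genotypes <- NULL
  if (!is.null(v@gt) && ncol(v@gt) > 1L) {
    gt <- vcfR::extract.gt(v, element = "GT")
    if (any(grepl("[/|]", gt[!is.na(gt)])))
      stop("diploid genotype fields are not supported (haploid calls only)")
    gt <- gt[keep, , drop = FALSE]
    calls <- matrix(NA_character_, nrow = ncol(gt), ncol = nrow(gt))
    tg <- t(gt)
    calls[tg == "1"] <- "donor"
    calls[tg == "0"] <- "recurrent"
    rownames(calls) <- colnames(gt)
    colnames(calls) <- paste0(snps$group_id, ":", snps$pos)
    genotypes <- genotype_table(calls)
  }
  list(snps = snps, genotypes = genotypes, n_skipped = n_skipped)
}

#' Write a SNP table (and optional haploid genotypes) to VCF
#'
#' Plain-text VCF 4.2 writer for the biallelic SNV subset used throughout
#' the package; inverse of [read_vcf()] on the retained fields. An `effect`
#' column, if present, is passed through as `EFF=` in INFO.
#'
#' @param snps data.frame with columns `group_id`, `pos`, `ref`, `alt` and
#'   optionally `effect`.
#' @param path output path.
#' @param genotypes optional [genotype_table] whose marker columns match
#'   `snps` row order (coded back as haploid GT `1`/`0`/`.`).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(snps, path, genotypes = NULL) {
  stopifnot(all(c("group_id", "pos", "ref", "alt") %in% names(snps)))
  info <- rep(".", nrow(snps))
  if (!is.null(snps$effect)) {
    has <- !is.na(snps$effect)
    info[has] <- paste0("EFF=", snps$effect[has])
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=introgmap",
              "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Coding effect: noncoding, synonymous or nonsynonymous\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  body <- data.frame(snps$group_id, snps$pos, ".", snps$ref, snps$alt,
                     ".", ".", info, stringsAsFactors = FALSE)
  if (!is.null(genotypes)) {
    stopifnot(inherits(genotypes, "genotype_table"))
    if (ncol(genotypes$calls) != nrow(snps))
      stop("genotype columns do not match SNP rows")
    gt <- t(genotypes$calls)              # markers x individuals
    code <- matrix(".", nrow(gt), ncol(gt))
    code[gt == "donor"] <- "1"
    code[gt == "recurrent"] <- "0"
    body$FORMAT <- "GT"
    for (j in seq_len(ncol(code))) body[[8L + 1L + j]] <- code[, j]
    cols <- c(cols, "FORMAT", rownames(genotypes$calls))
  }
  lines <- c(header, paste(cols, collapse = "\t"),
             do.call(paste, c(unname(as.list(body)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}
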