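#' Write / read a genotype table as TSV
#'
#' Individuals in rows, markers in columns; missing calls are written as
#' `missing`.
#'
#' @param genotypes a [genotype_table].
#' @param path TSV path.
#' @return `write_genotypes_tsv` invisibly returns `path`;
#'   `read_genotypes_tsv` returns a [genotype_table].
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_table"))
  m <- genotypes$calls
  m[is.na(m)] <- "missing"
  df <- data.frame(individual_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @param markers optional marker metadata forwarded to [genotype_table()].
#' @export
read_genotypes_tsv <- function(path, markers = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df[[1]]
  calls[calls == "missing"] <- NA_character_
  genotype_table(calls, markers = markers)
}

#' Write / read a phenotype table as TSV
#'
#' @param phenotypes a [phenotype_table].
#' @param path TSV path.
#' @return `write_phenotypes_tsv` invisibly returns `path`;
#'   `read_phenotypes_tsv` returns a [phenotype_table].
#' @export
write_phenotypes_tsv <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  mt <- df$mating_type
  mt[mt %in% c("NA", "")] <- NA_character_
  phenotype_table(df$individual_id, df$fertility, mt)
}

#' Export regions to BED / import BED intervals
#'
#' The package's data model is 1-based closed throughout; BED is the single
#' 0-based half-open surface, and the conversion round-trips losslessly.
#'
#' @param regions data.frame with `group_id`, `start`, `end` and optionally
#'   a `name` column.
#' @param path BED path.
#' @return `write_bed` invisibly returns `path`; `read_bed` returns a
#'   data.frame with 1-based closed `start`/`end`.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("group_id", "start", "end") %in% names(regions)))
  nm <- if (!is.null(regions$name)) regions$name else
    paste0("region_", seq_len(nrow(regions)))
  df <- data.frame(regions$group_id, regions$start - 1L, regions$end, nm,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  out <- data.frame(group_id = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  out
}
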