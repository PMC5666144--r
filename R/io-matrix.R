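#' Profile matrix (rows x grouped samples)
#'
#' Container for expression or growth profiles: rows are genes or carbon
#' sources, columns are samples carrying a group label (strain background,
#' mating type, ...). Groups with fewer than 2 samples are flagged; testing
#' operations ([one_way_anova()], [de_filter()]) refuse them.
#'
#' @param values numeric matrix with unique rownames and colnames.
#' @param groups group label per sample column: either a character vector in
#'   column order or a named vector (names = colnames).
#' @return An object of class `profile_matrix` with elements `values` and
#'   `groups` (factor), and attribute `flagged_groups` listing groups with
#'   fewer than 2 samples.
#' @export
profile_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique rownames")
  if (is.null(colnames(values))) stop("values must have colnames")
  if (!is.null(names(groups))) {
    miss <- setdiff(colnames(values), names(groups))
    if (length(miss))
      stop("no group label for sample(s): ", paste(miss, collapse = ", "))
    groups <- groups[colnames(values)]
  } else if (length(groups) != ncol(values)) {
    stop("groups must label every sample column")
  }
  groups <- factor(as.character(groups))
  flagged <- names(which(table(groups) < 2))
  if (length(flagged))
    warning("group(s) with fewer than 2 samples: ",
            paste(flagged, collapse = ", "))
  out <- structure(list(values = values, groups = groups),
                   class = "profile_matrix")
  attr(out, "flagged_groups") <- flagged
  out
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix:", nrow(x$values), "rows x", ncol(x$values),
      "samples; groups:",
      paste(sprintf("%s(%d)", levels(x$groups), table(x$groups)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read a profile matrix from TSV
#'
#' First column holds row ids; remaining columns are numeric sample values.
#' Any non-numeric cell (including literal `NA`) is an error naming the row
#' and column; duplicate row ids are an error.
#'
#' @param path TSV path.
#' @param groups group spec passed to [profile_matrix()].
#' @return A [profile_matrix].
#' @export
read_matrix_tsv <- function(path, groups) {
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2) stop("matrix TSV needs an id column plus data columns")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate row ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                 dimnames = list(ids, names(raw)[-1]))
  for (j in seq(2L, ncol(raw))) {
    x <- raw[[j]]
    num <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(num))
    if (length(bad))
      stop("non-numeric cell at row '", ids[bad[1]], "', column '",
           names(raw)[j], "'")
    vals[, j - 1L] <- num
  }
  profile_matrix(vals, groups)
}

#' Write a profile matrix to TSV
#'
#' Inverse of [read_matrix_tsv()] on the matrix values and ids (group labels
#' travel separately).
#'
#' @param pm a [profile_matrix].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(pm, path) {
  stopifnot(inherits(pm, "profile_matrix"))
  df <- data.frame(id = rownames(pm$values), pm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
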