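#' Construct a regions-by-samples count matrix
#'
#' The central input container: an integer matrix of read counts with regions
#' as rows and samples as columns. Region and sample identifiers must be
#' unique; counts must be nonnegative integers.
#'
#' @param counts Numeric matrix of nonnegative integer counts,
#'   regions x samples.
#' @param region_ids Character vector of unique region identifiers
#'   (defaults to `rownames(counts)`).
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to `colnames(counts)`).
#' @return A `count_matrix` object (an integer matrix with dimnames).
#' @examples
#' m <- count_matrix(matrix(1:6, 3, 2), paste0("r", 1:3), c("a", "b"))
#' sample_ids(m)
#' @export
count_matrix <- function(counts, region_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(region_ids)) region_ids <- paste0("region_", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(counts)))
  region_ids <- as.character(region_ids)
  sample_ids <- as.character(sample_ids)
  if (length(region_ids) != nrow(counts))
    stop("length(region_ids) must equal nrow(counts)")
  if (length(sample_ids) != ncol(counts))
    stop("length(sample_ids) must equal ncol(counts)")
  if (anyDuplicated(region_ids)) stop("region_ids contain duplicates")
  if (anyDuplicated(sample_ids)) stop("sample_ids contain duplicates")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be nonnegative and non-missing")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(region_ids, sample_ids)
  structure(counts, class = c("count_matrix", "matrix", "array"))
}

#' @rdname count_matrix
#' @param x A `count_matrix`.
#' @export
region_ids <- function(x) rownames(x)

#' @rdname count_matrix
#' @export
sample_ids <- function(x) colnames(x)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d regions x %d samples (total reads %s)\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  print(utils::head(unclass(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more regions\n", nrow(x) - 5L))
  invisible(x)
}

#' Read / write the counts-matrix TSV interchange format
#'
#' The on-disk format is a tab-separated table: first column `region_id`,
#' one further column of integer counts per sample, with sample identifiers
#' in the header row.
#'
#' @param path Path to a TSV file.
#' @return `read_counts_tsv` returns a [count_matrix()];
#'   `write_counts_tsv` returns `path` invisibly.
#' @export
read_counts_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("counts TSV needs a region_id column plus >= 1 sample")
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  count_matrix(m, region_ids = ids, sample_ids = colnames(tab)[-1L])
}

#' @rdname read_counts_tsv
#' @param x A `count_matrix`.
#' @export
write_counts_tsv <- function(x, path) {
  df <- data.frame(region_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Extract one sample's counts as a plain numeric vector, with a clear error
# for unknown identifiers.
sample_counts <- function(x, id) {
  if (!id %in% colnames(x))
    stop(sprintf("sample '%s' not found in count matrix", id))
  as.numeric(x[, id])
}
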