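#' Read and write the package's tab-separated formats
#'
#' Expression matrices are stored samples x features with a leading
#' `sample_id` column; target maps as three columns
#' (`mirna_id`, `target_id`, `target_class`); clinical tables with the
#' columns produced by [generate_clinical()]. Gene sets are read from GMT
#' (set name, description, member ids, tab-separated).
#'
#' @param path file path.
#' @name io
NULL

#' @param mat samples x features numeric matrix with rownames.
#' @rdname io
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

as_target_map <- function(df) {
  stopifnot(all(c("mirna_id", "target_id", "target_class") %in% names(df)))
  bad <- setdiff(unique(df$target_class), c("gene", "lncrna"))
  if (length(bad)) {
    stop("unknown target_class value(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df[, c("mirna_id", "target_id")])) {
    stop("duplicate (mirna_id, target_id) associations")
  }
  class(df) <- c("target_map", "data.frame")
  df
}

#' @rdname io
#' @export
read_target_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_target_map(df)
}

#' @rdname io
#' @export
read_clinical <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("malformed GMT line (need name, description, >=1 gene): ", l)
    }
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}
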