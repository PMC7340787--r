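#' Read an expression matrix from TSV or GEO series-matrix text
#'
#' Plain format: tab-separated, first column gene ids, header row sample ids.
#' GEO series-matrix files are recognized by their `!`-prefixed metadata
#' lines; only the table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` is read.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples, with id dimnames.
#' @export
read_expression <- function(path) {
  head_lines <- readLines(path, n = 200L)
  if (any(startsWith(head_lines, "!"))) {
    all_lines <- readLines(path)
    begin <- grep("^!series_matrix_table_begin", all_lines)
    end <- grep("^!series_matrix_table_end", all_lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
      stop("malformed series-matrix file: table delimiters not found in ", path)
    txt <- all_lines[(begin + 1L):(end - 1L)]
    df <- read.table(text = txt, header = TRUE, sep = "\t", quote = "\"",
                     row.names = 1L, check.names = FALSE)
  } else {
    df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                     row.names = 1L, check.names = FALSE,
                     comment.char = "")
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  check_expression_matrix(m)
  m
}

#' Write an expression matrix as TSV (gene id first column)
#' @param x genes x samples numeric matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  check_expression_matrix(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a clinical trait table from CSV
#'
#' First column sample id; remaining columns traits (e.g. `time`, `event`,
#' `recurrence`, `age`, `grade`).
#' @param path file path.
#' @return data.frame with sample ids as rownames.
#' @export
read_traits <- function(path) {
  df <- read.csv(path, row.names = 1L, check.names = FALSE)
  if (anyDuplicated(rownames(df))) stop("duplicated sample ids in ", path)
  df
}

#' Write a clinical trait table as CSV
#' @param traits data.frame with sample rownames.
#' @param path output path.
#' @export
write_traits <- function(traits, path) {
  write.csv(data.frame(sample = rownames(traits), traits,
                       check.names = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: name, description, members...).
#' @return named list of character vectors; per-set descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": need name, description, >=1 gene")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  attr(sets, "description") <- setNames(vapply(parts, `[`, "", 2L),
                                        names(sets))
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector (defaults to the
#'   `description` attribute, else `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("set names must be unique")
  if (any(lengths(sets) == 0L)) stop("empty gene set not allowed in GMT")
  if (is.null(descriptions)) descriptions <- attr(sets, "description")
  if (is.null(descriptions))
    descriptions <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
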