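# RNG discipline: every stochastic operation draws from a stream derived from
# one user-visible integer seed, and the caller's .Random.seed is restored on
# exit, so the package never perturbs global random state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Named substreams keep the generator stages independent while everything
# remains a pure function of one integer seed. Offsets keep results < 2^31.
stream_seed <- function(seed, stream) {
  offsets <- c(expression = 0L, traits = 1L, ppi = 2L, gene_sets = 3L,
               cohorts = 4L, gsea = 5L, pipeline = 6L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  as.integer((abs(as.numeric(seed)) %% 1e9) + 1000003 * offsets[[stream]])
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used here to score recovery of planted co-expression modules. 1 means
#' identical partitions (up to label names), 0 is the chance level.
#'
#' @param x,y label vectors of equal length (any atomic type).
#' @return a number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  tab <- table(as.character(x), as.character(y))
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(length(x))
  maxi <- (sum_i + sum_j) / 2
  if (isTRUE(all.equal(maxi, expected))) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Size-ordered module color vocabulary (largest module gets "turquoise",
# unassigned genes are always "grey"), extended programmatically when a
# clustering yields more modules than named colors.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "skyblue", "saddlebrown", "steelblue", "violet"
)

module_color_names <- function(k) {
  if (k <= length(MODULE_COLORS)) return(MODULE_COLORS[seq_len(k)])
  c(MODULE_COLORS, sprintf("module%03d", seq_len(k - length(MODULE_COLORS))))
}

check_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(x))) stop("duplicated gene ids in ", what)
  if (anyDuplicated(colnames(x))) stop("duplicated sample ids in ", what)
  invisible(x)
}

row_vars <- function(x, na.rm = FALSE) {
  apply(x, 1L, var, na.rm = na.rm)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
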