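#' Filter genes and samples by missingness and variance
#'
#' Removes genes whose missing fraction exceeds `max_missing_fraction` or
#' whose variance over non-missing entries is `<= min_variance` (so
#' constant genes go even at `min_variance = 0`); removes samples whose
#' missing fraction exceeds the same threshold; imputes any remaining
#' missing entries with the gene median. Gene order is preserved.
#'
#' @param x genes x samples numeric matrix (NAs allowed).
#' @param max_missing_fraction in \[0, 1).
#' @param min_variance genes with variance at or below this are dropped.
#' @return filtered, imputed matrix.
#' @export
filter_missing <- function(x, max_missing_fraction = 0.5,
                           min_variance = 0) {
  check_expression_matrix(x)
  stopifnot(max_missing_fraction >= 0, max_missing_fraction < 1)
  miss_g <- rowMeans(is.na(x))
  v <- row_vars(x, na.rm = TRUE)
  v[is.na(v)] <- 0
  keep_g <- miss_g <= max_missing_fraction & v > min_variance
  if (!any(keep_g))
    stop("all genes removed at max_missing_fraction = ",
         max_missing_fraction, ", min_variance = ", min_variance)
  x <- x[keep_g, , drop = FALSE]
  miss_s <- colMeans(is.na(x))
  keep_s <- miss_s <= max_missing_fraction
  if (!any(keep_s)) stop("all samples removed by missingness filter")
  x <- x[, keep_s, drop = FALSE]
  if (anyNA(x)) {
    med <- apply(x, 1L, median, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- med[idx[, 1L]]
  }
  x
}

#' Keep the top fraction of genes by expression variance
#'
#' Retains the `floor(fraction * n_genes)` genes of largest sample
#' variance (e.g. the conventional top 25% most variable genes before
#' network construction). Variance ties are broken by gene id so the
#' selection is deterministic; input gene order is preserved in the output.
#'
#' @param x genes x samples matrix.
#' @param fraction in (0, 1].
#' @return matrix restricted to the selected genes.
#' @export
top_variance <- function(x, fraction = 0.25) {
  check_expression_matrix(x)
  stopifnot(fraction > 0, fraction <= 1)
  n_keep <- floor(fraction * nrow(x))
  if (n_keep < 2L) stop("top_variance would retain fewer than 2 genes")
  v <- row_vars(x)
  ord <- order(-v, rownames(x))
  keep <- rownames(x)[ord[seq_len(n_keep)]]
  x[rownames(x) %in% keep, , drop = FALSE]
}

#' Flag outlier samples by hierarchical clustering
#'
#' Samples are clustered by average linkage on the Euclidean distance
#' between expression profiles. `k_sd` flags a sample when the height at
#' which it first joins the tree exceeds `mean + param * sd` of the other
#' samples' joining heights (leave-one-out, so a single extreme sample
#' cannot mask itself). `static_height` cuts the tree at `h = param` and
#' flags everything outside the largest cluster.
#'
#' As a hard guard the function errors rather than flag more than 20% of
#' samples.
#'
#' @param x genes x samples matrix, >= 4 samples.
#' @param method `"k_sd"` (default) or `"static_height"`.
#' @param param k for `k_sd` (default 3), cut height for `static_height`;
#'   must be > 0.
#' @return character vector of flagged sample ids (possibly empty).
#' @export
detect_sample_outliers <- function(x, method = c("k_sd", "static_height"),
                                   param = 3) {
  check_expression_matrix(x)
  method <- match.arg(method)
  if (param <= 0) stop("param must be > 0")
  n <- ncol(x)
  if (n < 4L) stop("need at least 4 samples")
  hc <- hclust(dist(t(x)), method = "average")
  if (method == "k_sd") {
    leaf_h <- numeric(n)
    for (r in seq_len(nrow(hc$merge))) {
      for (k in 1:2) {
        if (hc$merge[r, k] < 0) leaf_h[-hc$merge[r, k]] <- hc$height[r]
      }
    }
    flagged <- vapply(seq_len(n), function(i) {
      others <- leaf_h[-i]
      s <- sd(others)
      if (is.na(s)) s <- 0
      leaf_h[i] > mean(others) + param * s
    }, logical(1))
    out <- colnames(x)[flagged]
  } else {
    cl <- cutree(hc, h = param)
    sizes <- table(cl)
    main <- as.integer(names(sizes)[which.max(sizes)])
    out <- colnames(x)[cl != main]
  }
  if (length(out) > 0.2 * n)
    stop("refusing to flag ", length(out), " of ", n,
         " samples (> 20%); inspect the clustering instead")
  out
}

#' Drop named samples from an expression matrix
#'
#' Verbatim exclusion list (e.g. outliers identified by inspection of the
#' sample dendrogram). Unknown ids are ignored with a warning.
#'
#' @param x genes x samples matrix.
#' @param ids sample ids to drop.
#' @return matrix without those samples.
#' @export
drop_samples <- function(x, ids) {
  check_expression_matrix(x)
  missing <- setdiff(ids, colnames(x))
  if (length(missing))
    warning("ids not present, ignored: ", paste(missing, collapse = ", "))
  keep <- setdiff(colnames(x), ids)
  if (!length(keep)) stop("drop_samples would remove every sample")
  x[, keep, drop = FALSE]
}

#' Align an expression matrix and a trait table on common samples
#'
#' @param x genes x samples matrix.
#' @param traits data.frame with sample rownames.
#' @return list `expression`, `traits`, both restricted to the common
#'   samples in the matrix's order.
#' @export
align_samples <- function(x, traits) {
  check_expression_matrix(x)
  common <- intersect(colnames(x), rownames(traits))
  if (!length(common)) stop("no samples shared between matrix and traits")
  list(expression = x[, common, drop = FALSE],
       traits = traits[common, , drop = FALSE])
}

#' Collapse probes to genes by maximal variance
#'
#' For platform-level matrices whose rows are probes: keeps, for each gene,
#' the probe with the largest variance and renames the row to the gene
#' symbol. Probes absent from the map are dropped.
#'
#' @param x probes x samples matrix.
#' @param map data.frame with columns `probe`, `gene`.
#' @return genes x samples matrix.
#' @export
collapse_probes <- function(x, map) {
  check_expression_matrix(x)
  stopifnot(all(c("probe", "gene") %in% colnames(map)))
  map <- map[map$probe %in% rownames(x) & nzchar(map$gene), , drop = FALSE]
  if (!nrow(map)) stop("no probes in the map match the matrix")
  v <- row_vars(x)[map$probe]
  ord <- order(map$gene, -v, map$probe)
  map <- map[ord, , drop = FALSE]
  best <- map[!duplicated(map$gene), , drop = FALSE]
  out <- x[best$probe, , drop = FALSE]
  rownames(out) <- best$gene
  out
}
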