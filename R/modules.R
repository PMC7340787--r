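# --- adaptive dendrogram cutting -------------------------------------------

# Quality-scored adaptive cut. Candidate cut heights are scanned; at each,
# branches holding >= min_size leaves are scored by how much tighter their
# internal topological overlap is than the network at large,
#   score(h) = sum_c n_c * (mean within-TOM_c - mean TOM),
# and the cut maximizing the total is kept (chance aggregates of
# background genes score ~0; merging two real modules dilutes the mean and
# lowers the score, so contaminated cuts lose). `tie_tol` accepts the
# lowest (finest) cut scoring within a fraction of the maximum. Clusters
# no tighter than the network average are left unassigned. Returns integer
# labels, 0 = unassigned.
quality_cut <- function(hc, tom, min_size, tie_tol = 0.05,
                        max_candidates = 150L) {
  n <- length(hc$order)
  hs <- sort(unique(hc$height))
  cand <- if (length(hs) > 1L) (hs[-1L] + hs[-length(hs)]) / 2 else hs / 2
  if (length(cand) > max_candidates)
    cand <- unique(quantile(cand, seq(0, 1, length.out = max_candidates),
                            names = FALSE, type = 1L))
  cand <- sort(cand)
  off <- tom
  diag(off) <- 0
  w_bar <- sum(off) / (n * (n - 1))

  cls <- cutree(hc, h = cand)
  if (is.null(dim(cls))) cls <- matrix(cls, ncol = 1L)
  scores <- numeric(length(cand))
  cluster_means <- vector("list", length(cand))
  for (j in seq_along(cand)) {
    cl <- cls[, j]
    sizes <- tabulate(cl)
    big <- which(sizes >= min_size)
    if (!length(big)) { scores[j] <- 0; next }
    s1 <- rowsum(off, cl)
    within_sum <- diag(rowsum(t(s1), cl))
    wc <- within_sum[big] / (sizes[big]^2 - sizes[big])
    cluster_means[[j]] <- setNames(wc, big)
    scores[j] <- sum(sizes[big] * pmax(wc - w_bar, 0))
  }
  best <- max(scores)
  if (best <= 0) return(integer(n))
  j_star <- which(scores >= (1 - tie_tol) * best)[1L]
  cl <- cls[, j_star]
  sizes <- tabulate(cl)
  wc <- cluster_means[[j_star]]
  keep <- as.integer(names(wc)[wc > w_bar])
  keep <- intersect(keep, which(sizes >= min_size))
  labels <- integer(n)
  for (j in seq_along(keep)) labels[cl == keep[j]] <- j
  labels
}

#' Detect modules by adaptive cutting of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, followed by an
#' adaptive cut: candidate cut heights are scanned and scored by how much
#' tighter the internal topological overlap of their min-size branches is
#' than the network average, and the best-scoring cut wins (an
#' approximation of the dynamic hybrid branch cut, validated by
#' planted-partition recovery rather than label-for-label agreement with
#' any reference implementation). `deep_split` (0-3) widens the score
#' tolerance within which the finest cut is preferred, so larger values
#' split more aggressively. When the expression matrix is supplied,
#' unassigned genes are rescued to the module whose eigengene they
#' correlate with at module membership > 0.3, and modules whose eigengenes
#' correlate above `1 - merge_height` are merged (which also repairs
#' over-splitting). Final labels are color names ordered by module size
#' (largest = "turquoise"); unassignable genes are `"grey"`.
#'
#' @param tom TOM similarity matrix with gene dimnames.
#' @param min_module_size smallest allowed module (>= 2).
#' @param deep_split 0-3; score tolerance 0/0.02/0.05/0.10 for preferring
#'   finer cuts.
#' @param merge_height eigengene dissimilarity below which modules merge
#'   (requires `expr`).
#' @param expr optional genes x samples matrix enabling the membership
#'   rescue and eigengene merge stages.
#' @return named character vector gene -> module color (incl. `"grey"`).
#' @export
cluster_and_cut <- function(tom, min_module_size = 10L, deep_split = 2L,
                            merge_height = 0.25, expr = NULL) {
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom),
            !is.null(rownames(tom)), min_module_size >= 2L,
            deep_split %in% 0:3, merge_height >= 0, merge_height < 1)
  genes <- rownames(tom)
  n <- length(genes)
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(setNames(rep("grey", n), genes))
  }
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")
  tie_tol <- c(`0` = 0, `1` = 0.02, `2` = 0.05, `3` = 0.10)
  labels <- quality_cut(hc, tom, min_module_size,
                        tie_tol = tie_tol[[as.character(deep_split)]])

  if (!is.null(expr)) {
    check_expression_matrix(expr)
    stopifnot(identical(rownames(expr), genes))
    labels <- rescue_by_membership(labels, expr, mm_threshold = 0.3)
    labels <- merge_by_eigengene(labels, expr,
                                 cor_threshold = 1 - merge_height)
  }
  # drop groups that fell below the size floor after merging/rescue
  sizes <- table(labels[labels > 0L])
  for (m in as.integer(names(sizes)[sizes < min_module_size]))
    labels[labels == m] <- 0L

  finalize_labels(labels, genes)
}

finalize_labels <- function(labels, genes) {
  mods <- unique(labels[labels > 0L])
  sizes <- vapply(mods, function(m) sum(labels == m), 0L)
  ord <- mods[order(-sizes, mods)]
  colors <- module_color_names(length(ord))
  out <- rep("grey", length(labels))
  for (i in seq_along(ord)) out[labels == ord[i]] <- colors[i]
  setNames(out, genes)
}

first_pc_scores <- function(xs) {
  sv <- svd(xs, nu = 0L, nv = 1L)
  e <- sv$v[, 1L]
  e <- as.numeric(scale(e))
  mean_profile <- colMeans(xs)
  if (sd(mean_profile) > 0 && cor(e, mean_profile) < 0) e <- -e
  list(scores = e, var_explained = sv$d[1L]^2 / sum(sv$d^2))
}

rescue_by_membership <- function(labels, expr, mm_threshold = 0.3) {
  mods <- setdiff(unique(labels), 0L)
  if (!length(mods) || !any(labels == 0L)) return(labels)
  eig <- vapply(mods, function(m) {
    xs <- t(scale(t(expr[labels == m, , drop = FALSE])))
    first_pc_scores(xs)$scores
  }, numeric(ncol(expr)))
  grey_idx <- which(labels == 0L)
  mm <- cor(t(expr[grey_idx, , drop = FALSE]), eig)
  mm[is.na(mm)] <- 0
  best <- apply(mm, 1L, which.max)
  ok <- mm[cbind(seq_along(grey_idx), best)] > mm_threshold
  labels[grey_idx[ok]] <- mods[best[ok]]
  labels
}

merge_by_eigengene <- function(labels, expr, cor_threshold = 0.75) {
  repeat {
    mods <- setdiff(unique(labels), 0L)
    if (length(mods) < 2L) return(labels)
    eig <- vapply(mods, function(m) {
      xs <- t(scale(t(expr[labels == m, , drop = FALSE])))
      first_pc_scores(xs)$scores
    }, numeric(ncol(expr)))
    cc <- cor(eig)
    diag(cc) <- 0
    if (max(cc) <= cor_threshold) return(labels)
    hit <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    labels[labels == mods[hit[2L]]] <- mods[hit[1L]]
  }
}

#' Module eigengenes
#'
#' Each non-grey module is summarized by the sample scores of the first
#' principal component of its standardized expression (unit sample
#' variance, sign oriented to correlate positively with the module's mean
#' standardized expression). Constant genes are dropped from the PCA with
#' a warning.
#'
#' @param x genes x samples matrix.
#' @param assignment named gene -> module vector from [cluster_and_cut()].
#' @return list of class `module_eigengenes`: `eigengenes` (samples x
#'   modules matrix), `variance_explained`, `module_sizes`.
#' @export
module_eigengenes <- function(x, assignment) {
  check_expression_matrix(x)
  stopifnot(all(names(assignment) %in% rownames(x)))
  mods <- setdiff(unique(assignment), "grey")
  if (!length(mods)) stop("no non-grey modules to summarize")
  ve <- setNames(numeric(length(mods)), mods)
  sizes <- setNames(integer(length(mods)), mods)
  eig <- matrix(NA_real_, ncol(x), length(mods),
                dimnames = list(colnames(x), mods))
  for (m in mods) {
    members <- names(assignment)[assignment == m]
    xm <- x[members, , drop = FALSE]
    const <- apply(xm, 1L, sd) == 0
    if (any(const)) {
      warning("dropping constant gene(s) from module ", m, ": ",
              paste(head(members[const], 3L), collapse = ", "))
      xm <- xm[!const, , drop = FALSE]
    }
    if (nrow(xm) < 2L) stop("module ", m, " has fewer than 2 usable genes")
    xs <- t(scale(t(xm)))
    pc <- first_pc_scores(xs)
    eig[, m] <- pc$scores
    ve[m] <- pc$var_explained
    sizes[m] <- length(members)
  }
  structure(list(eigengenes = eig, variance_explained = ve,
                 module_sizes = sizes),
            class = "module_eigengenes")
}

#' Module-trait and gene-level network statistics
#'
#' Pearson correlation of every module eigengene with every numeric trait,
#' with two-sided Student p from `t = r sqrt((n - 2)/(1 - r^2))`. When the
#' expression matrix and assignment are supplied, per-gene statistics are
#' added: gene significance (GS, correlation with each trait) and module
#' membership (MM, correlation with the gene's own module eigengene).
#' Zero-variance traits are flagged and reported as r = 0, p = 1.
#'
#' @param eigengenes a [module_eigengenes()] object.
#' @param traits data.frame with sample rownames; non-numeric columns are
#'   ignored.
#' @param expr,assignment optional, for GS/MM.
#' @return list of class `module_trait_stats`: `module_trait` (module,
#'   trait, r, p, n_genes, flagged), `gene_stats` (gene, module, MM,
#'   GS_<trait>...) or NULL.
#' @export
module_trait_stats <- function(eigengenes, traits, expr = NULL,
                               assignment = NULL) {
  stopifnot(inherits(eigengenes, "module_eigengenes"))
  e <- eigengenes$eigengenes
  common <- intersect(rownames(e), rownames(traits))
  if (length(common) < 4L) stop("need at least 4 aligned samples")
  e <- e[common, , drop = FALSE]
  tr <- traits[common, , drop = FALSE]
  num <- vapply(tr, is.numeric, logical(1))
  tr <- as.matrix(tr[, num, drop = FALSE])
  n <- length(common)

  cor_p <- function(r, n) {
    r2 <- pmin(r^2, 1 - 1e-15)
    t <- abs(r) * sqrt((n - 2) / (1 - r2))
    pmax(2 * pt(t, df = n - 2, lower.tail = FALSE), .Machine$double.xmin)
  }
  rows <- list()
  for (m in colnames(e)) for (tn in colnames(tr)) {
    flagged <- sd(tr[, tn]) == 0
    r <- if (flagged) 0 else cor(e[, m], tr[, tn])
    p <- if (flagged) 1 else cor_p(r, n)
    rows[[length(rows) + 1L]] <- data.frame(
      module = m, trait = tn, r = r, p = p,
      n_genes = unname(eigengenes$module_sizes[m]), flagged = flagged)
  }
  module_trait <- do.call(rbind, rows)

  gene_stats <- NULL
  if (!is.null(expr) && !is.null(assignment)) {
    check_expression_matrix(expr)
    genes <- names(assignment)
    xe <- expr[genes, common, drop = FALSE]
    gs <- vapply(colnames(tr), function(tn) {
      if (sd(tr[, tn]) == 0) rep(0, length(genes))
      else as.numeric(cor(t(xe), tr[, tn]))
    }, numeric(length(genes)))
    colnames(gs) <- colnames(tr)
    mm <- rep(NA_real_, length(genes))
    for (m in colnames(e)) {
      idx <- which(assignment == m)
      if (length(idx))
        mm[idx] <- cor(t(xe[idx, , drop = FALSE]), e[, m])
    }
    gene_stats <- data.frame(gene = genes,
                             module = unname(assignment),
                             MM = mm, stringsAsFactors = FALSE)
    for (tn in colnames(tr)) gene_stats[[paste0("GS_", tn)]] <- gs[, tn]
    rownames(gene_stats) <- NULL
  }
  structure(list(module_trait = module_trait, gene_stats = gene_stats),
            class = "module_trait_stats")
}

#' Select the trait-associated critical module
#'
#' Among modules significant for the named trait (p < alpha), picks the
#' one with the largest absolute correlation; ties go to the smaller p,
#' then to the larger module.
#'
#' @param stats a [module_trait_stats()] object.
#' @param trait trait name.
#' @param alpha significance threshold.
#' @return module label (character scalar).
#' @export
select_critical_module <- function(stats, trait, alpha = 0.05) {
  stopifnot(inherits(stats, "module_trait_stats"))
  mt <- stats$module_trait
  mt <- mt[mt$trait == trait & mt$module != "grey", , drop = FALSE]
  if (!nrow(mt)) stop("trait not found in module-trait statistics: ", trait)
  sig <- mt[mt$p < alpha, , drop = FALSE]
  if (!nrow(sig)) {
    best <- mt[which.max(abs(mt$r)), ]
    stop("no module significant for '", trait, "' at alpha = ", alpha,
         "; best candidate: ", best$module, " (r = ", signif(best$r, 3),
         ", p = ", signif(best$p, 3), ")")
  }
  sig <- sig[order(-abs(sig$r), sig$p, -sig$n_genes, sig$module), ]
  sig$module[1L]
}
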