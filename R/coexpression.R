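# --- weighted network construction -----------------------------------------

adjacency_from_cor <- function(cc, power, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  a <- switch(mode,
              unsigned = abs(cc)^power,
              signed = ((1 + cc) / 2)^power)
  a[a > 1] <- 1
  a[a < 0] <- 0
  diag(a) <- 1
  a
}

#' Soft-threshold adjacency from an expression matrix
#'
#' Pearson correlations between gene profiles raised to the soft power:
#' `|cor|^beta` (unsigned, default) or `((1 + cor)/2)^beta` (signed).
#' Soft thresholding preserves the continuous nature of co-expression
#' while suppressing weak correlations.
#'
#' @param x genes x samples matrix, >= 3 samples.
#' @param power integer soft-thresholding exponent beta >= 1.
#' @param mode `"unsigned"` or `"signed"`.
#' @return symmetric genes x genes adjacency in \[0, 1\], unit diagonal.
#' @export
soft_adjacency <- function(x, power, mode = c("unsigned", "signed")) {
  check_expression_matrix(x)
  stopifnot(power >= 1, abs(power - round(power)) < 1e-8, ncol(x) >= 3)
  sds <- apply(x, 1L, sd)
  if (any(sds == 0))
    stop("constant gene(s), correlation undefined: ",
         paste(head(rownames(x)[sds == 0], 5L), collapse = ", "))
  adjacency_from_cor(cor(t(x)), round(power), match.arg(mode))
}

#' Scale-free topology fit of a weighted network
#'
#' Connectivity `k_i = sum_{j != i} a_ij` is binned into `n_bins`
#' equal-width bins; log10 frequency is regressed on log10 mean
#' connectivity over non-empty bins. The returned fit index is signed,
#' `-sign(slope) * r^2`, so that a decreasing degree distribution (the
#' scale-free signature) scores positively and the conventional
#' "R^2 > 0.9" criterion applies directly.
#'
#' @param x an adjacency matrix (>= 10 genes) or a precomputed
#'   connectivity vector.
#' @param n_bins number of equal-width connectivity bins.
#' @return list: `r_squared` (signed), `slope`, `mean_connectivity`,
#'   `flagged` (TRUE when the degree distribution is degenerate and the
#'   fit is reported as 0), `fit_points` (the binned log-log points).
#' @export
scale_free_fit <- function(x, n_bins = 10L) {
  if (is.matrix(x)) {
    if (nrow(x) < 10L) stop("need at least 10 genes")
    k <- rowSums(x) - diag(x)
  } else {
    k <- as.numeric(x)
  }
  mean_k <- mean(k)
  degenerate <- (max(k) - min(k)) < 1e-12
  if (!degenerate) {
    breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
    bin <- cut(k, breaks, include.lowest = TRUE)
    cnt <- tapply(k, bin, length)
    mk <- tapply(k, bin, mean)
    ok <- !is.na(cnt) & cnt > 0 & !is.na(mk) & mk > 0
    pts <- data.frame(log_k = log10(mk[ok]),
                      log_freq = log10(cnt[ok] / length(k)))
    degenerate <- nrow(pts) < 2L || var(pts$log_k) < 1e-20
  }
  if (degenerate) {
    return(list(r_squared = 0, slope = NA_real_,
                mean_connectivity = mean_k, flagged = TRUE,
                fit_points = NULL))
  }
  fit <- lm(log_freq ~ log_k, data = pts)
  slope <- unname(coef(fit)[2L])
  r2 <- if (var(pts$log_freq) < 1e-20) 0 else
    cor(pts$log_k, pts$log_freq)^2
  list(r_squared = -sign(slope) * r2, slope = slope,
       mean_connectivity = mean_k, flagged = FALSE, fit_points = pts)
}

pick_power <- function(fit_table, threshold) {
  hit <- which(fit_table$r_squared > threshold)
  if (length(hit)) return(fit_table$power[hit[1L]])
  best <- fit_table$power[which.max(fit_table$r_squared)]
  warning("no candidate power reaches signed R^2 > ", threshold,
          "; using the best fit, power = ", best)
  best
}

#' Choose the soft-thresholding power by the scale-free criterion
#'
#' Evaluates the scale-free fit index over candidate powers and returns
#' the smallest power whose signed R^2 exceeds the threshold (default
#' 0.9); when none does, the power maximizing R^2 is returned with a
#' warning.
#'
#' @param x genes x samples matrix.
#' @param candidates ascending integer powers to try.
#' @param threshold signed R^2 criterion.
#' @param mode network signedness, see [soft_adjacency()].
#' @param n_bins bins for [scale_free_fit()].
#' @return list of class `sft_choice`: `power`, `fit_table` (data.frame
#'   power / r_squared / slope / mean_connectivity).
#' @export
choose_power <- function(x, candidates = 1:20, threshold = 0.9,
                         mode = c("unsigned", "signed"), n_bins = 10L) {
  check_expression_matrix(x)
  mode <- match.arg(mode)
  stopifnot(length(candidates) > 0, !is.unsorted(candidates))
  sds <- apply(x, 1L, sd)
  if (any(sds == 0))
    stop("constant gene(s), correlation undefined: ",
         paste(head(rownames(x)[sds == 0], 5L), collapse = ", "))
  cc <- cor(t(x))
  rows <- lapply(candidates, function(b) {
    f <- scale_free_fit(adjacency_from_cor(cc, b, mode), n_bins = n_bins)
    data.frame(power = b, r_squared = f$r_squared,
               slope = if (is.null(f$slope)) NA_real_ else f$slope,
               mean_connectivity = f$mean_connectivity)
  })
  fit_table <- do.call(rbind, rows)
  structure(list(power = pick_power(fit_table, threshold),
                 fit_table = fit_table),
            class = "sft_choice")
}

#' Topological overlap from a weighted adjacency
#'
#' `tom_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` (u != i, j) and `k_i` the connectivity of i
#' excluding itself; diagonal 1. Genes sharing many strong neighbors get
#' high overlap even if their direct adjacency is modest, which makes
#' `1 - TOM` a robust clustering dissimilarity.
#'
#' @param adjacency symmetric matrix in \[0, 1\] with unit diagonal.
#' @return TOM similarity matrix, same dimnames.
#' @export
tom_similarity <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (max(abs(adjacency - t(adjacency))) > 1e-10)
    stop("adjacency must be symmetric")
  b <- adjacency
  diag(b) <- 0
  l <- b %*% b
  k <- rowSums(b)
  denom <- outer(k, k, pmin) + 1 - adjacency
  tom <- (l + adjacency) / denom
  tom[denom <= 0] <- 0
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  # enforce exact symmetry against floating-point drift
  (tom + t(tom)) / 2
}

#' Build the full co-expression model
#'
#' Convenience wrapper: picks (or accepts) the soft power, computes the
#' adjacency and the TOM.
#'
#' @param x genes x samples matrix.
#' @param power fixed power, or NULL to select via [choose_power()].
#' @param candidates,threshold,mode,n_bins passed to [choose_power()] /
#'   [soft_adjacency()].
#' @return list of class `coexpression_model`: `power`, `adjacency`,
#'   `tom`, `fit_table` (NULL when `power` was fixed), `mode`.
#' @export
build_coexpression_model <- function(x, power = NULL, candidates = 1:20,
                                     threshold = 0.9,
                                     mode = c("unsigned", "signed"),
                                     n_bins = 10L) {
  mode <- match.arg(mode)
  fit_table <- NULL
  if (is.null(power)) {
    sel <- choose_power(x, candidates = candidates, threshold = threshold,
                        mode = mode, n_bins = n_bins)
    power <- sel$power
    fit_table <- sel$fit_table
  }
  adj <- soft_adjacency(x, power, mode = mode)
  structure(list(power = power, adjacency = adj,
                 tom = tom_similarity(adj), fit_table = fit_table,
                 mode = mode),
            class = "coexpression_model")
}

#' @export
print.coexpression_model <- function(x, ...) {
  cat("coexpression_model:", nrow(x$adjacency), "genes,", x$mode,
      "network, soft power", x$power, "\n")
  invisible(x)
}
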