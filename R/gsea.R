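# --- ranked-list enrichment (weighted Kolmogorov-Smirnov running sum) -------

#' Rank genes by a two-group differential metric
#'
#' `signal2noise` is `(mu1 - mu0) / (s1 + s0)` with each group SD floored
#' at `max(0.2 * |mu|, 0.2)` (the desktop-GSEA convention, which keeps
#' low-variance genes from dominating); `t_stat` is the two-sample
#' t statistic with unpooled variances. Group 1 is the second factor
#' level (or the value 1 of a 0/1 vector), so positive scores mean higher
#' expression in group 1.
#'
#' @param x genes x samples matrix.
#' @param groups binary vector over samples (0/1, logical, or two-level
#'   factor); both groups need >= 3 samples.
#' @param metric `"signal2noise"` or `"t_stat"`.
#' @return data.frame (gene, score) sorted by decreasing score, ties by
#'   gene id.
#' @export
gsea_rank <- function(x, groups, metric = c("signal2noise", "t_stat")) {
  check_expression_matrix(x)
  metric <- match.arg(metric)
  g <- as.integer(as.factor(groups)) - 1L
  if (length(g) != ncol(x) || length(unique(g)) != 2L)
    stop("groups must be a binary vector over the samples")
  if (min(table(g)) < 3L) stop("each group needs at least 3 samples")
  score <- metric_scores(x, g, metric)
  out <- data.frame(gene = rownames(x), score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

metric_scores <- function(x, g, metric) {
  x1 <- x[, g == 1L, drop = FALSE]
  x0 <- x[, g == 0L, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  s1 <- apply(x1, 1L, sd); s0 <- apply(x0, 1L, sd)
  if (metric == "signal2noise") {
    s1 <- pmax(s1, 0.2 * abs(m1), 0.2)
    s0 <- pmax(s0, 0.2 * abs(m0), 0.2)
    (m1 - m0) / (s1 + s0)
  } else {
    (m1 - m0) / sqrt(s1^2 / ncol(x1) + s0^2 / ncol(x0))
  }
}

#' Enrichment score of a gene set on a ranked list
#'
#' Classic weighted Kolmogorov-Smirnov running sum over the list in its
#' given order: hits increment by `|score|^p / sum_hits |score|^p`,
#' misses decrement by `1 / (N - N_hits)`. The enrichment score is the
#' signed maximum deviation from zero; the leading edge is the hit genes
#' up to (positive ES) or from (negative ES) the extremum.
#'
#' @param scores named numeric vector, already ranked (the order given is
#'   the ranking used).
#' @param set character vector of gene ids; must intersect the list.
#' @param weight_p hit-weight exponent (1 = the standard weighted scheme;
#'   0 = classic unweighted KS).
#' @return list: `es`, `running_sum` (length N), `leading_edge`.
#' @export
gsea_es <- function(scores, set, weight_p = 1) {
  stopifnot(!is.null(names(scores)))
  genes <- names(scores)
  hits <- genes %in% set
  if (!any(hits)) stop("gene set does not intersect the ranked list")
  n <- length(scores)
  m <- sum(hits)
  w <- abs(scores[hits])^weight_p
  if (sum(w) == 0) w <- rep(1, m)   # all-zero scores: fall back to flat
  inc <- numeric(n)
  inc[hits] <- w / sum(w)
  if (n > m) inc[!hits] <- -1 / (n - m)
  rs <- cumsum(inc)
  hi <- max(rs); lo <- min(rs)
  es <- if (hi >= -lo) hi else lo
  if (es >= 0) {
    peak <- which.max(rs)
    leading <- genes[seq_len(peak)][hits[seq_len(peak)]]
  } else {
    peak <- which.min(rs)
    leading <- genes[peak:n][hits[peak:n]]
  }
  list(es = unname(es), running_sum = setNames(rs, genes),
       leading_edge = leading)
}

# O(set size) ES from hit positions in a ranked list: the running sum is
# piecewise linear between hits, so its extrema occur at hit positions
# (maxima) or just before them / at the end (minima).
es_from_positions <- function(hit_pos, hit_w, n) {
  m <- length(hit_pos)
  if (sum(hit_w) == 0) hit_w <- rep(1, m)
  cw <- cumsum(hit_w) / sum(hit_w)
  if (n == m) return(1)
  d <- 1 / (n - m)
  at_hit <- cw - (hit_pos - seq_len(m)) * d
  before_hit <- c(0, cw[-m]) - (hit_pos - seq_len(m)) * d
  hi <- max(at_hit)
  lo <- min(c(before_hit, 0))
  if (hi >= -lo) hi else lo
}

#' Permutation significance for gene-set enrichment
#'
#' Observed enrichment scores come from [gsea_rank()] + [gsea_es()];
#' the null is built by permuting phenotype labels (default) or gene
#' memberships, recomputing the metric and ES each time. Nominal p uses
#' the add-one rule over same-sign permutation scores, so it is never 0;
#' NES divides ES by the mean same-sign permutation |ES|; FDR follows the
#' pooled same-sign NES rule. When fewer distinct label assignments exist
#' than `n_perm`, all of them are enumerated instead (reported via
#' message).
#'
#' @param x genes x samples matrix.
#' @param groups binary phenotype over samples.
#' @param sets named list of gene sets.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; results are reproducible.
#' @param metric,weight_p see [gsea_rank()] / [gsea_es()].
#' @param permute `"phenotype"` (default) or `"geneset"`.
#' @return data.frame of class `enrichment_result`: set, size, es, nes,
#'   p, fdr, leading_edge; sorted by p.
#' @export
gsea_significance <- function(x, groups, sets, n_perm = 1000L, seed = 1L,
                              metric = c("signal2noise", "t_stat"),
                              weight_p = 1,
                              permute = c("phenotype", "geneset")) {
  check_expression_matrix(x)
  metric <- match.arg(metric)
  permute <- match.arg(permute)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  g <- as.integer(as.factor(groups)) - 1L
  if (length(g) != ncol(x) || length(unique(g)) != 2L)
    stop("groups must be a binary vector over the samples")
  if (min(table(g)) < 3L) stop("each group needs at least 3 samples")

  genes <- rownames(x)
  n <- length(genes)
  set_idx <- lapply(sets, function(s) which(genes %in% s))
  keep <- lengths(set_idx) > 0L
  if (!any(keep)) stop("no gene set intersects the expression matrix")
  set_idx <- set_idx[keep]
  sets <- sets[keep]

  rank_positions <- function(score) {
    ord <- order(-score, genes)
    pos <- integer(n)
    pos[ord] <- seq_len(n)
    list(pos = pos, w = abs(score)^weight_p)
  }
  es_all <- function(rp) {
    vapply(set_idx, function(idx) {
      hp <- sort(rp$pos[idx])
      ow <- rp$w[idx][order(rp$pos[idx])]
      es_from_positions(hp, ow, n)
    }, 0)
  }

  obs_score <- metric_scores(x, g, metric)
  names(obs_score) <- genes
  obs_rp <- rank_positions(obs_score)
  es_obs <- es_all(obs_rp)
  # deterministic tie order, matching rank_positions
  ranked_obs <- obs_score[order(-obs_score, genes)]
  leading <- vapply(names(sets), function(nm) {
    paste(gsea_es(ranked_obs, sets[[nm]], weight_p)$leading_edge,
          collapse = ",")
  }, "")

  es_perm <- with_seed(seed, {
    if (permute == "phenotype") {
      n1 <- sum(g == 1L)
      n_distinct <- choose(length(g), n1)
      if (is.finite(n_distinct) && n_distinct <= n_perm) {
        message("only ", n_distinct,
                " distinct label assignments; enumerating exactly")
        combos <- combn(length(g), n1)
        perms <- lapply(seq_len(ncol(combos)), function(j) {
          gp <- integer(length(g)); gp[combos[, j]] <- 1L; gp
        })
      } else {
        perms <- lapply(seq_len(n_perm), function(j) sample(g))
      }
      ep <- vapply(perms, function(gp) {
        es_all(rank_positions(metric_scores(x, gp, metric)))
      }, numeric(length(set_idx)))
      # vapply drops to a vector for a single set; keep sets as columns
      if (is.null(dim(ep))) ep <- matrix(ep, nrow = 1L)
      t(ep)
    } else {
      sizes <- lengths(set_idx)
      ranked_w <- obs_rp$w[order(obs_rp$pos)]
      ep <- vapply(seq_len(n_perm), function(j) {
        vapply(sizes, function(m) {
          hp <- sort(sample.int(n, m))
          es_from_positions(hp, ranked_w[hp], n)
        }, 0)
      }, numeric(length(set_idx)))
      if (is.null(dim(ep))) ep <- matrix(ep, nrow = 1L)
      t(ep)
    }
  })

  p <- nes <- numeric(length(es_obs))
  nes_perm <- es_perm
  for (j in seq_along(es_obs)) {
    ep <- es_perm[, j]
    pos_mean <- mean(ep[ep > 0])
    neg_mean <- mean(abs(ep[ep < 0]))
    nes_perm[, j] <- ifelse(ep >= 0,
                            ep / ifelse(is.nan(pos_mean), Inf, pos_mean),
                            ep / ifelse(is.nan(neg_mean), Inf, neg_mean))
    same <- if (es_obs[j] >= 0) ep >= 0 else ep < 0
    if (!any(same)) {
      p[j] <- 1; nes[j] <- NA_real_
    } else {
      p[j] <- (1 + sum(abs(ep[same]) >= abs(es_obs[j]))) / (1 + sum(same))
      denom <- mean(abs(ep[same]))
      nes[j] <- if (denom == 0) NA_real_ else es_obs[j] / denom
    }
  }
  fdr <- gsea_fdr(nes, nes_perm)
  out <- data.frame(set = names(sets), size = lengths(set_idx),
                    es = unname(es_obs), nes = nes, p = p, fdr = fdr,
                    leading_edge = unname(leading),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# Pooled same-sign FDR: q(S) = [share of permutation NES at least as
# extreme among same-sign permutation NES] / [share of observed NES at
# least as extreme among same-sign observed NES], capped at 1.
gsea_fdr <- function(nes, nes_perm) {
  pool <- as.numeric(nes_perm)
  vapply(seq_along(nes), function(j) {
    s <- nes[j]
    if (is.na(s)) return(NA_real_)
    if (s >= 0) {
      num_den <- sum(pool >= 0)
      num <- if (num_den == 0) 0 else sum(pool >= s) / num_den
      den_den <- sum(nes >= 0, na.rm = TRUE)
      den <- sum(nes >= s, na.rm = TRUE) / den_den
    } else {
      num_den <- sum(pool < 0)
      num <- if (num_den == 0) 0 else sum(pool <= s) / num_den
      den_den <- sum(nes < 0, na.rm = TRUE)
      den <- sum(nes <= s, na.rm = TRUE) / den_den
    }
    min(1, num / max(den, .Machine$double.eps))
  }, 0)
}
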