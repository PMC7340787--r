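#' Two-sample Wilcoxon rank-sum test
#'
#' Wraps the standard rank-sum test with the conventions used throughout
#' the pipeline: exact enumeration when the pooled sample is small
#' (`n <= 12`) and tie-free, otherwise the normal approximation with tie
#' and continuity corrections. Identical pooled values return p = 1.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param mode `"auto"` (default), `"exact"`, or `"normal_approx"`;
#'   `"exact"` with ties falls back to the approximation with a warning.
#' @param alternative `"two.sided"` (default), `"greater"` (x shifted
#'   right of y), or `"less"`.
#' @return list of class `rank_test`: `statistic` (U for x), `p`, `n_x`,
#'   `n_y`, `direction` (`"x"`, `"y"` or `"none"`, by rank-sum).
#' @export
wilcoxon_rank_sum <- function(x, y,
                              mode = c("auto", "exact", "normal_approx"),
                              alternative = c("two.sided", "greater",
                                              "less")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(structure(list(statistic = length(x) * length(y) / 2, p = 1,
                          n_x = length(x), n_y = length(y),
                          direction = "none"),
                     class = "rank_test"))
  }
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- switch(mode,
                      auto = (length(pooled) <= 12L) && !ties,
                      exact = TRUE,
                      normal_approx = FALSE)
  if (use_exact && ties) {
    warning("exact p undefined with ties; using normal approximation")
    use_exact <- FALSE
  }
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE,
                alternative = alternative))
  u <- unname(ht$statistic)
  mid <- length(x) * length(y) / 2
  direction <- if (u > mid) "x" else if (u < mid) "y" else "none"
  structure(list(statistic = u, p = unname(ht$p.value),
                 n_x = length(x), n_y = length(y), direction = direction),
            class = "rank_test")
}

#' Split samples into high/low groups by a gene's expression
#'
#' Samples strictly above the median go to `"high"`; samples at or below
#' the median (including ties at the median) go to `"low"`.
#'
#' @param x genes x samples matrix.
#' @param gene gene id present in `x`.
#' @param rule only `"median"` is implemented.
#' @return named character vector (sample -> "high"/"low").
#' @export
split_by_expression <- function(x, gene, rule = "median") {
  check_expression_matrix(x)
  rule <- match.arg(rule, "median")
  if (!gene %in% rownames(x)) stop("gene not in matrix: ", gene)
  v <- x[gene, ]
  if (sd(v) == 0) stop("constant gene, no expression split possible: ", gene)
  grp <- ifelse(v > median(v), "high", "low")
  if (length(unique(grp)) < 2L)
    stop("median split produced a single group for ", gene)
  setNames(grp, colnames(x))
}

as_survival_data <- function(time, event, group = NULL) {
  stopifnot(length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  if (is.null(group)) group <- rep("all", length(time))
  data.frame(time = as.numeric(time), event = as.integer(event),
             group = as.character(group), stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit curves
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times;
#' subjects censored at t still count as at risk at t.
#'
#' @param time positive survival/censoring times.
#' @param event 0/1 event indicators.
#' @param group optional group labels (one curve per group).
#' @return data.frame: group, time, n_risk, n_event, n_censor, surv —
#'   one row per distinct observed time.
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  d <- as_survival_data(time, event, group)
  fit <- survfit(Surv(time, event) ~ group, data = d)
  grp_of <- if (is.null(fit$strata)) unique(d$group) else
    sub("^group=", "", rep(names(fit$strata), fit$strata))
  out <- data.frame(group = grp_of, time = fit$time,
                    n_risk = fit$n.risk, n_event = fit$n.event,
                    n_censor = fit$n.censor, surv = fit$surv,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' @param km a [kaplan_meier()] table.
#' @param t time point.
#' @param group group label (default: the single group present).
#' @return S(t) (1 before the first event).
#' @export
km_survival_at <- function(km, t, group = NULL) {
  if (is.null(group)) {
    stopifnot(length(unique(km$group)) == 1L)
    group <- km$group[1L]
  }
  k <- km[km$group == group & km$time <= t, , drop = FALSE]
  if (!nrow(k)) return(1)
  k$surv[which.max(k$time)]
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square over distinct event times with
#' hypergeometric variance, on 1 df. Degenerate tables (zero variance)
#' return `p = NA` with `flagged = TRUE`.
#'
#' @param time,event,group as in [kaplan_meier()]; exactly two groups and
#'   at least one event required.
#' @return list of class `rank_test`-like: `chisq`, `p`, `n` (per group),
#'   `observed`, `expected` (events per group), `worse` (the group with
#'   more events than expected), `flagged`.
#' @export
log_rank <- function(time, event, group) {
  d <- as_survival_data(time, event, group)
  if (length(unique(d$group)) != 2L) stop("log_rank needs exactly 2 groups")
  if (sum(d$event) < 1L) stop("log_rank needs at least one event")
  sd_fit <- try(survdiff(Surv(time, event) ~ group, data = d),
                silent = TRUE)
  if (inherits(sd_fit, "try-error") || !is.finite(sd_fit$chisq)) {
    return(structure(list(chisq = NA_real_, p = NA_real_,
                          n = table(d$group), observed = NA, expected = NA,
                          worse = NA_character_, flagged = TRUE),
                     class = "logrank_test"))
  }
  grp_names <- sub("^group=", "", names(sd_fit$n))
  worse <- grp_names[which.max(sd_fit$obs - sd_fit$exp)]
  structure(list(chisq = unname(sd_fit$chisq),
                 p = pchisq(sd_fit$chisq, df = 1L, lower.tail = FALSE),
                 n = setNames(as.integer(sd_fit$n), grp_names),
                 observed = setNames(sd_fit$obs, grp_names),
                 expected = setNames(sd_fit$exp, grp_names),
                 worse = worse, flagged = FALSE),
            class = "logrank_test")
}

#' Screen candidate targets by differential expression and survival
#'
#' A candidate passes when (a) its tumor-vs-normal Wilcoxon p is below
#' `de_alpha` with the tumor median higher, and (b) the log-rank test on
#' its median expression split of the survival cohort is below
#' `surv_alpha` with the high-expression group faring worse. All
#' statistics are reported for every candidate regardless of the verdict.
#'
#' @param tumor genes x samples matrix of the survival cohort (also the
#'   tumor side of the differential test).
#' @param normal genes x samples matrix of the reference cohort, or NULL
#'   to skip the differential-expression filter.
#' @param traits data.frame with `time` and `event` columns, sample
#'   rownames matching `tumor`.
#' @param candidates gene ids to evaluate.
#' @param de_alpha,surv_alpha significance thresholds (defaults 0.05 and
#'   0.1).
#' @return list: `table` (per-candidate statistics and pass flags),
#'   `targets` (ids passing both filters, in candidate order).
#' @export
evaluate_targets <- function(tumor, normal, traits, candidates,
                             de_alpha = 0.05, surv_alpha = 0.1) {
  check_expression_matrix(tumor)
  stopifnot(length(candidates) > 0,
            all(c("time", "event") %in% colnames(traits)))
  al <- align_samples(tumor, traits)
  tumor_s <- al$expression
  tr <- al$traits
  rows <- lapply(candidates, function(g) {
    de_p <- NA_real_; de_dir <- NA; de_pass <- TRUE
    if (!is.null(normal)) {
      if (!g %in% rownames(tumor) || !g %in% rownames(normal)) {
        de_pass <- FALSE
      } else {
        w <- wilcoxon_rank_sum(tumor[g, ], normal[g, ])
        de_p <- w$p
        de_dir <- median(tumor[g, ]) > median(normal[g, ])
        de_pass <- !is.na(de_p) && de_p < de_alpha && isTRUE(de_dir)
      }
    }
    lr_chisq <- lr_p <- NA_real_; high_worse <- NA; surv_pass <- FALSE
    if (g %in% rownames(tumor_s)) {
      grp <- try(split_by_expression(tumor_s, g), silent = TRUE)
      if (!inherits(grp, "try-error")) {
        lr <- log_rank(tr$time, tr$event, grp[rownames(tr)])
        lr_chisq <- lr$chisq; lr_p <- lr$p
        high_worse <- identical(lr$worse, "high")
        surv_pass <- !is.na(lr_p) && lr_p < surv_alpha && high_worse
      }
    }
    data.frame(gene = g, wilcoxon_p = de_p, tumor_higher = de_dir,
               de_pass = de_pass, logrank_chisq = lr_chisq,
               logrank_p = lr_p, high_worse = high_worse,
               surv_pass = surv_pass, final = de_pass && surv_pass,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, targets = tab$gene[tab$final])
}
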