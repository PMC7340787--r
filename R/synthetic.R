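#' Describe a synthetic cohort with planted co-expression structure
#'
#' The generated world mirrors what the downstream pipeline assumes of a
#' real tumor cohort: gene modules driven by latent per-module factors, one
#' module tied to a binary recurrence trait, survival times whose hazard
#' rises with the expression of designated target genes, a PPI graph denser
#' inside modules than between them, and gene sets overlapping the modules.
#'
#' Defaults state a desk-scale cohort: 500 genes (three planted modules of
#' 60/50/40 plus 350 background genes), 200 samples, factor loadings
#' uniform on \[0.6, 0.9\], module 1 tied to recurrence with point-biserial
#' correlation 0.32, three target genes in that module with log hazard
#' ratio 1 per SD of mean target expression, 30% censoring, and PPI edge
#' probabilities 0.3 within / 0.02 between modules.
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param module_sizes integer vector, one planted module per entry (each
#'   >= 2); background genes are `n_genes - sum(module_sizes)`.
#' @param factor_loading_range loadings drawn uniformly from this range,
#'   both ends in (0, 1].
#' @param trait_module_index which module drives the binary trait.
#' @param trait_point_biserial target correlation between the trait module's
#'   factor and the binary recurrence trait, in (0, 1).
#' @param target_genes gene ids carrying the survival effect; default the
#'   first three genes of the trait module.
#' @param log_hazard_ratio log hazard ratio per unit of the mean
#'   standardized target-gene expression.
#' @param baseline_hazard exponential baseline hazard (events per month).
#' @param censoring_rate expected fraction of censored samples, in \[0, 1).
#' @param ppi_within_prob,ppi_between_prob Bernoulli edge probabilities;
#'   within must exceed between.
#' @param ppi_coverage fraction of genes present in the PPI universe (a
#'   drug-target interaction network covers only a small slice of the
#'   expressed genome; target genes are always included). Set 1 for a
#'   PPI over all genes.
#' @param n_normal_samples size of the synthetic normal-tissue cohort.
#' @param de_shift mean down-shift (in SD units) of target genes in the
#'   normal cohort, so tumor expression is higher.
#' @param seed integer; every generator draw flows from it.
#' @return an object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_genes = 500L, n_samples = 200L,
                             module_sizes = c(60L, 50L, 40L),
                             factor_loading_range = c(0.6, 0.9),
                             trait_module_index = 1L,
                             trait_point_biserial = 0.32,
                             target_genes = NULL,
                             log_hazard_ratio = 1,
                             baseline_hazard = 0.05,
                             censoring_rate = 0.3,
                             ppi_within_prob = 0.9,
                             ppi_between_prob = 0.02,
                             ppi_coverage = 0.02,
                             n_normal_samples = 50L,
                             de_shift = 1.5,
                             seed = 1L) {
  module_sizes <- as.integer(module_sizes)
  background_genes <- n_genes - sum(module_sizes)
  if (background_genes < 0L)
    stop("module_sizes sum to more than n_genes")
  if (length(module_sizes) && any(module_sizes < 2L))
    stop("module size < 2: eigengene undefined")
  stopifnot(length(factor_loading_range) == 2L,
            factor_loading_range[1] > 0, factor_loading_range[2] <= 1,
            factor_loading_range[1] <= factor_loading_range[2])
  if (!(ppi_within_prob > ppi_between_prob))
    stop("ppi_within_prob must exceed ppi_between_prob")
  stopifnot(ppi_coverage > 0, ppi_coverage <= 1)
  stopifnot(censoring_rate >= 0, censoring_rate < 1,
            trait_point_biserial > 0, trait_point_biserial < 1)
  if (length(module_sizes) &&
      (trait_module_index < 1L || trait_module_index > length(module_sizes)))
    stop("trait_module_index out of range")

  gene_ids <- sprintf("g%0*d", max(3L, nchar(n_genes)), seq_len(n_genes))
  sample_ids <- sprintf("s%0*d", max(3L, nchar(n_samples)),
                        seq_len(n_samples))
  module_labels <- if (length(module_sizes))
    paste0("M", seq_along(module_sizes)) else character(0)
  module_of_gene <- rep(c(module_labels, NA_character_),
                        c(module_sizes, background_genes))
  names(module_of_gene) <- gene_ids
  module_of_gene <- module_of_gene[!is.na(module_of_gene)]

  if (is.null(target_genes) && length(module_sizes)) {
    trait_mod <- module_labels[trait_module_index]
    pool <- names(module_of_gene)[module_of_gene == trait_mod]
    target_genes <- head(pool, 3L)
  }
  if (!all(target_genes %in% gene_ids))
    stop("target_genes must exist among the n_genes")

  structure(list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    module_sizes = module_sizes, background_genes = background_genes,
    factor_loading_range = factor_loading_range,
    trait_module_index = as.integer(trait_module_index),
    trait_point_biserial = trait_point_biserial,
    target_genes = target_genes,
    log_hazard_ratio = log_hazard_ratio,
    baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate,
    ppi_within_prob = ppi_within_prob,
    ppi_between_prob = ppi_between_prob,
    ppi_coverage = ppi_coverage,
    n_normal_samples = as.integer(n_normal_samples),
    de_shift = de_shift,
    gene_ids = gene_ids, sample_ids = sample_ids,
    module_labels = module_labels, module_of_gene = module_of_gene,
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("synthetic_design:", x$n_genes, "genes x", x$n_samples, "samples;",
      length(x$module_sizes), "planted modules (",
      paste(x$module_sizes, collapse = ", "), ") +",
      x$background_genes, "background genes; seed", x$seed, "\n")
  invisible(x)
}

#' Generate the planted-factor expression matrix
#'
#' Gene g in module m gets `x_gs = lambda_g f_ms + sqrt(1 - lambda_g^2)
#' eps_gs` with the factor f and noise eps standard normal and lambda drawn
#' uniformly from the design's loading range, so every gene row has
#' population mean 0 and variance 1. Background genes are pure noise.
#'
#' @param design a [synthetic_design()].
#' @return list with `expression` (genes x samples matrix) and `truth`
#'   (class `synthetic_truth`: module labels, factor matrix, loadings, and
#'   the expression matrix itself for downstream generators).
#' @export
generate_expression <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  G <- design$n_genes; S <- design$n_samples
  M <- length(design$module_sizes)
  with_seed(stream_seed(design$seed, "expression"), {
    expr <- matrix(rnorm(G * S), G, S,
                   dimnames = list(design$gene_ids, design$sample_ids))
    factors <- matrix(rnorm(M * S), M, S,
                      dimnames = list(design$module_labels,
                                      design$sample_ids))
    loadings <- setNames(rep(NA_real_, G), design$gene_ids)
    offset <- 0L
    for (m in seq_len(M)) {
      idx <- offset + seq_len(design$module_sizes[m])
      lam <- runif(length(idx), design$factor_loading_range[1],
                   design$factor_loading_range[2])
      expr[idx, ] <- lam %o% factors[m, ] +
        sqrt(1 - lam^2) * expr[idx, , drop = FALSE]
      loadings[idx] <- lam
      offset <- offset + design$module_sizes[m]
    }
    truth <- structure(list(
      module_of_gene = design$module_of_gene,
      factor_matrix = factors,
      loadings = loadings,
      gene_ids = design$gene_ids,
      sample_ids = design$sample_ids,
      target_genes = design$target_genes,
      expression = expr,
      seed = design$seed
    ), class = "synthetic_truth")
    list(expression = expr, truth = truth)
  })
}

# Calibrate the latent-threshold noise scale so the realized point-biserial
# correlation between the factor and the binary trait hits the target.
calibrate_binary_trait <- function(f, e, target) {
  pb <- function(sig) {
    y <- as.numeric(f + sig * e > 0)
    if (var(y) == 0) return(NA_real_)
    cor(f, y)
  }
  grid <- seq(0, 8, by = 0.01)
  vals <- vapply(grid, pb, 0)
  ok <- !is.na(vals)
  sig <- grid[ok][which.min(abs(vals[ok] - target))]
  list(sigma = sig, trait = as.numeric(f + sig * e > 0))
}

#' Generate clinical traits tied to the planted truth
#'
#' Binary recurrence is the trait module's factor plus calibrated Gaussian
#' noise, thresholded at zero; the noise scale is chosen by grid search so
#' the realized point-biserial correlation with the factor matches the
#' design target. Survival times are exponential with per-sample hazard
#' `h0 * exp(logHR * zbar)` where `zbar` is the mean standardized
#' expression of the target genes; censoring is independent exponential
#' with its rate solved so the expected censored fraction matches the
#' design. Age and grade are uninformative nuisance columns.
#'
#' @param design a [synthetic_design()].
#' @param truth the `synthetic_truth` from [generate_expression()] run with
#'   the same design.
#' @return list with `traits` (data.frame: time, event, recurrence, age,
#'   grade; sample rownames) and the augmented `truth` (adds
#'   `trait_vector`, `survival_times`, `event_flags`).
#' @export
generate_traits <- function(design, truth) {
  stopifnot(inherits(design, "synthetic_design"),
            inherits(truth, "synthetic_truth"))
  if (length(design$module_sizes) == 0L)
    stop("trait generation needs at least one planted module")
  if (design$trait_module_index > nrow(truth$factor_matrix))
    stop("trait_module_index out of range")
  f <- truth$factor_matrix[design$trait_module_index, ]
  with_seed(stream_seed(design$seed, "traits"), {
    e <- rnorm(length(f))
    cal <- calibrate_binary_trait(f, e, design$trait_point_biserial)
    recurrence <- cal$trait

    z <- truth$expression[design$target_genes, , drop = FALSE]
    z <- (z - rowMeans(z)) / apply(z, 1L, sd)
    zbar <- colMeans(z)
    hazard <- design$baseline_hazard * exp(design$log_hazard_ratio * zbar)
    t_event <- rexp(length(hazard), rate = hazard)
    if (design$censoring_rate > 0) {
      # mean_i rc/(rc + h_i) = censoring_rate defines the censoring rate rc
      target <- design$censoring_rate
      rc <- uniroot(function(r) mean(r / (r + hazard)) - target,
                    lower = 1e-9, upper = 1e6, tol = 1e-10)$root
      t_cens <- rexp(length(hazard), rate = rc)
    } else {
      t_cens <- rep(Inf, length(hazard))
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    age <- round(rnorm(length(f), 60, 10))
    grade <- sample(1:4, length(f), replace = TRUE)
    traits <- data.frame(time = time, event = event,
                         recurrence = recurrence, age = age, grade = grade,
                         row.names = truth$sample_ids)
    truth$trait_vector <- setNames(recurrence, truth$sample_ids)
    truth$trait_noise_sd <- cal$sigma
    truth$survival_times <- setNames(time, truth$sample_ids)
    truth$event_flags <- setNames(event, truth$sample_ids)
    list(traits = traits, truth = truth)
  })
}

#' Generate a modular PPI edge list
#'
#' The PPI universe is a random `ppi_coverage` fraction of the genes plus
#' the target genes (a drug-target network touches only a small slice of
#' the genome). Undirected edges among universe genes are Bernoulli
#' draws: probability `ppi_within_prob` for pairs in the same planted
#' module, `ppi_between_prob` otherwise (background genes count as
#' singleton non-modules). Confidence scores are uniform on \[0.4, 1\],
#' so the whole fixture passes the standard medium confidence filter;
#' `low_confidence = TRUE` adds sub-threshold edges (scores on
#' \[0.05, 0.4)) to exercise the filter.
#'
#' @param design a [synthetic_design()].
#' @param truth matching `synthetic_truth`.
#' @param low_confidence add sub-threshold edges?
#' @return data.frame `protein1`, `protein2`, `combined_score` (unit
#'   scale); no self-loops, each unordered pair at most once.
#' @export
generate_ppi <- function(design, truth, low_confidence = FALSE) {
  stopifnot(inherits(design, "synthetic_design"),
            inherits(truth, "synthetic_truth"))
  with_seed(stream_seed(design$seed, "ppi"), {
    g <- truth$gene_ids
    if (design$ppi_coverage < 1) {
      covered <- g[runif(length(g)) < design$ppi_coverage]
      g <- intersect(truth$gene_ids,
                     union(covered, design$target_genes))
    }
    lab <- design$module_of_gene[g]
    lab[is.na(lab)] <- paste0(".bg", which(is.na(lab)))
    ut <- which(upper.tri(matrix(0, length(g), length(g))), arr.ind = TRUE)
    same <- lab[ut[, 1]] == lab[ut[, 2]]
    p <- ifelse(same, design$ppi_within_prob, design$ppi_between_prob)
    keep <- runif(length(p)) < p
    edges <- data.frame(
      protein1 = g[ut[keep, 1]],
      protein2 = g[ut[keep, 2]],
      combined_score = runif(sum(keep), 0.4, 1.0),
      stringsAsFactors = FALSE
    )
    if (low_confidence) {
      rest <- which(!keep)
      extra <- rest[runif(length(rest)) < design$ppi_between_prob]
      if (length(extra)) {
        edges <- rbind(edges, data.frame(
          protein1 = g[ut[extra, 1]],
          protein2 = g[ut[extra, 2]],
          combined_score = runif(length(extra), 0.05, 0.3999),
          stringsAsFactors = FALSE
        ))
      }
    }
    rownames(edges) <- NULL
    edges
  })
}

#' Generate a gene-set collection overlapping the planted modules
#'
#' One "positive" set per planted module draws `overlap_fraction` of its
#' members from that module (the rest from outside it); the remaining sets
#' are random draws from all genes. A stand-in for a curated pathway GMT.
#'
#' @param truth a `synthetic_truth`.
#' @param n_sets total number of sets (must be >= number of modules).
#' @param overlap_fraction in \[0, 1\].
#' @param set_size_range inclusive range for set sizes.
#' @return named list of gene-id vectors (GMT-compatible; positive sets are
#'   named `POS_<module>`), descriptions in `attr(, "description")`.
#' @export
generate_gene_sets <- function(truth, n_sets = 50L, overlap_fraction = 0.8,
                               set_size_range = c(10L, 40L)) {
  stopifnot(inherits(truth, "synthetic_truth"),
            overlap_fraction >= 0, overlap_fraction <= 1)
  modules <- unique(truth$module_of_gene)
  if (n_sets < length(modules))
    stop("n_sets smaller than the number of planted modules")
  universe <- truth$gene_ids
  with_seed(stream_seed(truth$seed, "gene_sets"), {
    sets <- list()
    for (m in modules) {
      members <- names(truth$module_of_gene)[truth$module_of_gene == m]
      size <- sample(seq(set_size_range[1], set_size_range[2]), 1L)
      n_in <- min(round(overlap_fraction * size), length(members))
      inside <- if (n_in > 0) sample(members, n_in) else character(0)
      outside_pool <- setdiff(universe, members)
      outside <- sample(outside_pool, size - n_in)
      sets[[paste0("POS_", m)]] <- c(inside, outside)
    }
    for (i in seq_len(n_sets - length(modules))) {
      size <- sample(seq(set_size_range[1], set_size_range[2]), 1L)
      sets[[sprintf("RAND_%03d", i)]] <- sample(universe, size)
    }
    attr(sets, "description") <- setNames(
      c(rep("synthetic positive set", length(modules)),
        rep("synthetic random set", n_sets - length(modules))),
      names(sets))
    sets
  })
}

#' Generate a synthetic normal-tissue cohort
#'
#' Pure-noise expression for a reference (non-tumor) cohort; the design's
#' target genes are shifted down by `de_shift` SD so tumor expression is
#' planted higher — the ground truth for the tumor-vs-normal Wilcoxon
#' filter.
#'
#' @param design a [synthetic_design()].
#' @param truth matching `synthetic_truth`.
#' @return genes x samples matrix (samples named `n001`, ...).
#' @export
generate_normal <- function(design, truth) {
  stopifnot(inherits(design, "synthetic_design"),
            inherits(truth, "synthetic_truth"))
  G <- design$n_genes
  S <- design$n_normal_samples
  with_seed(stream_seed(design$seed, "cohorts"), {
    m <- matrix(rnorm(G * S), G, S,
                dimnames = list(truth$gene_ids,
                                sprintf("n%0*d", max(3L, nchar(S)),
                                        seq_len(S))))
    m[design$target_genes, ] <- m[design$target_genes, ] - design$de_shift
    m
  })
}

#' Generate the full synthetic bundle for one design
#'
#' Convenience wrapper running all generators: expression, traits, PPI,
#' gene sets, and the normal cohort.
#'
#' @param design a [synthetic_design()].
#' @param n_sets,overlap_fraction passed to [generate_gene_sets()].
#' @return list: `expression`, `traits`, `ppi`, `gene_sets`, `normal`,
#'   `truth`.
#' @export
synth_data <- function(design, n_sets = 50L, overlap_fraction = 0.8) {
  ge <- generate_expression(design)
  gt <- generate_traits(design, ge$truth)
  list(
    expression = ge$expression,
    traits = gt$traits,
    ppi = generate_ppi(design, gt$truth),
    gene_sets = generate_gene_sets(gt$truth, n_sets = n_sets,
                                   overlap_fraction = overlap_fraction),
    normal = generate_normal(design, gt$truth),
    truth = gt$truth
  )
}
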