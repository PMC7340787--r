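#' Assemble and validate a pipeline configuration
#'
#' Exactly one input mode must be supplied: file paths (`expr`, `traits`,
#' `ppi`, `gmt`) for a real cohort, or a [synthetic_design()] for the
#' planted-truth demo. All stage parameters live here so a run is fully
#' described by one object plus the seed.
#'
#' @param expr,traits,ppi,gmt input file paths (expression TSV / trait CSV
#'   / PPI TSV / GMT).
#' @param tumor,normal optional file paths for the differential-expression
#'   cohorts; when absent the DE filter is skipped (synthetic runs always
#'   have them).
#' @param design a [synthetic_design()], mutually exclusive with the file
#'   inputs.
#' @param out_dir directory for persisted stage outputs (created; default
#'   a fresh temporary directory).
#' @param top_var top-variance fraction kept before network construction.
#' @param powers,r2_threshold soft-power candidates and scale-free
#'   criterion.
#' @param min_module_size,deep_split,merge_height module detection
#'   parameters.
#' @param min_score PPI confidence threshold.
#' @param trait trait column used to pick the critical module.
#' @param module_alpha,de_alpha,surv_alpha significance thresholds.
#' @param n_perm GSEA permutations.
#' @param ppi_dialect score dialect for [read_ppi()].
#' @param outlier_k k for the sample-outlier rule (NULL disables).
#' @param exclude_samples ids dropped verbatim before analysis.
#' @param seed integer master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expr = NULL, traits = NULL, ppi = NULL,
                            gmt = NULL, tumor = NULL, normal = NULL,
                            design = NULL, out_dir = NULL,
                            top_var = 0.25, powers = 1:20,
                            r2_threshold = 0.9, min_module_size = 10L,
                            deep_split = 2L, merge_height = 0.25,
                            min_score = 0.4, trait = "recurrence",
                            module_alpha = 0.05, de_alpha = 0.05,
                            surv_alpha = 0.1, n_perm = 1000L,
                            ppi_dialect = "unit", outlier_k = 3,
                            exclude_samples = NULL, seed = 1L) {
  has_files <- !is.null(expr) || !is.null(traits) || !is.null(ppi) ||
    !is.null(gmt)
  has_design <- !is.null(design)
  if (has_files && has_design)
    stop("config error: supply file inputs or a synthetic design, not both")
  if (!has_files && !has_design)
    stop("config error: supply file inputs or a synthetic design")
  if (has_files && (is.null(expr) || is.null(traits)))
    stop("config error: file mode needs at least expr and traits")
  if (has_design && !inherits(design, "synthetic_design"))
    stop("config error: design must be a synthetic_design")
  stopifnot(top_var > 0, top_var <= 1,
            r2_threshold > 0, r2_threshold < 1,
            min_module_size >= 2, min_score >= 0, min_score <= 1,
            module_alpha > 0, module_alpha < 1,
            de_alpha >= 0, de_alpha < 1, surv_alpha > 0, surv_alpha < 1,
            n_perm >= 100)
  structure(list(expr = expr, traits = traits, ppi = ppi, gmt = gmt,
                 tumor = tumor, normal = normal, design = design,
                 out_dir = out_dir, top_var = top_var, powers = powers,
                 r2_threshold = r2_threshold,
                 min_module_size = as.integer(min_module_size),
                 deep_split = as.integer(deep_split),
                 merge_height = merge_height, min_score = min_score,
                 trait = trait, module_alpha = module_alpha,
                 de_alpha = de_alpha, surv_alpha = surv_alpha,
                 n_perm = as.integer(n_perm), ppi_dialect = ppi_dialect,
                 outlier_k = outlier_k,
                 exclude_samples = exclude_samples,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, code) {
  tryCatch(force(code),
           error = function(e)
             stop("pipeline stage '", name, "' failed: ",
                  conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline
#'
#' preprocess -> weighted network -> module detection -> module-trait
#' statistics -> PPI projection -> candidate extraction -> target
#' validation -> enrichment (ORA on the critical module, GSEA grouped by
#' the top validated target). Every intermediate is persisted as plain
#' TSV under the configured output directory and checksummed; the same
#' config and seed reproduce the report exactly.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report`; the output directory is in
#'   `attr(, "out_dir")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("coexppi_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  persist <- character(0)
  save_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    persist[[name]] <<- unname(md5sum(p))
  }

  inputs <- stage("input", {
    if (!is.null(config$design)) {
      syn <- synth_data(config$design)
      list(expr = syn$expression, traits = syn$traits, ppi = syn$ppi,
           sets = syn$gene_sets, tumor = syn$expression,
           normal = syn$normal, truth = syn$truth)
    } else {
      list(expr = read_expression(config$expr),
           traits = read_traits(config$traits),
           ppi = if (!is.null(config$ppi))
             read_ppi(config$ppi, config$ppi_dialect),
           sets = if (!is.null(config$gmt)) read_gmt(config$gmt),
           tumor = if (!is.null(config$tumor))
             read_expression(config$tumor),
           normal = if (!is.null(config$normal))
             read_expression(config$normal),
           truth = NULL)
    }
  })

  pre <- stage("preprocess", {
    x <- filter_missing(inputs$expr)
    n_before <- ncol(x)
    if (!is.null(config$exclude_samples))
      x <- drop_samples(x, config$exclude_samples)
    outliers <- character(0)
    if (!is.null(config$outlier_k)) {
      outliers <- detect_sample_outliers(x, "k_sd", config$outlier_k)
      if (length(outliers)) x <- drop_samples(x, outliers)
    }
    x <- top_variance(x, config$top_var)
    al <- align_samples(x, inputs$traits)
    save_tsv(data.frame(gene = rownames(al$expression), al$expression,
                        check.names = FALSE), "expression_filtered.tsv")
    save_tsv(data.frame(sample = rownames(al$traits), al$traits,
                        check.names = FALSE), "traits_aligned.tsv")
    c(al, list(outliers = outliers, n_samples_in = n_before))
  })

  net <- stage("wgcna", {
    model <- build_coexpression_model(pre$expression,
                                      candidates = config$powers,
                                      threshold = config$r2_threshold)
    assignment <- cluster_and_cut(model$tom,
                                  min_module_size = config$min_module_size,
                                  deep_split = config$deep_split,
                                  merge_height = config$merge_height,
                                  expr = pre$expression)
    eig <- module_eigengenes(pre$expression, assignment)
    stats <- module_trait_stats(eig, pre$traits, expr = pre$expression,
                                assignment = assignment)
    critical <- select_critical_module(stats, config$trait,
                                       alpha = config$module_alpha)
    if (!is.null(model$fit_table)) save_tsv(model$fit_table, "fit_table.tsv")
    save_tsv(data.frame(gene = names(assignment),
                        module = unname(assignment)), "modules.tsv")
    save_tsv(data.frame(sample = rownames(eig$eigengenes),
                        eig$eigengenes, check.names = FALSE),
             "eigengenes.tsv")
    save_tsv(stats$module_trait, "module_trait.tsv")
    list(model = model, assignment = assignment, eigengenes = eig,
         stats = stats, critical = critical)
  })

  mapped <- stage("map", {
    ppi <- inputs$ppi
    if (is.null(ppi)) stop("no PPI input available")
    ppi <- filter_confidence(ppi, config$min_score)
    mn <- map_modules(ppi, net$assignment, drop_grey = TRUE)
    save_tsv(mn$nodes, "mapped_nodes.tsv")
    save_tsv(mn$edges, "mapped_edges.tsv")
    save_tsv(mn$module_summary, "mapped_module_summary.tsv")
    mn
  })

  candidates <- stage("candidates", {
    cand <- candidate_targets(mapped, net$critical)
    writeLines(cand, file.path(out_dir, "candidates.txt"))
    persist[["candidates.txt"]] <-
      unname(md5sum(file.path(out_dir, "candidates.txt")))
    cand
  })

  validation <- stage("validate", {
    ev <- evaluate_targets(inputs$tumor, inputs$normal, pre$traits,
                           candidates, de_alpha = config$de_alpha,
                           surv_alpha = config$surv_alpha)
    save_tsv(ev$table, "validation.tsv")
    ev
  })

  enrich <- stage("enrichment", {
    ora_tab <- gsea_tab <- NULL
    if (!is.null(inputs$sets)) {
      module_genes <- names(net$assignment)[net$assignment == net$critical]
      ora_tab <- ora(module_genes, rownames(pre$expression), inputs$sets,
                     min_overlap = 1L)
      save_tsv(ora_tab, "ora.tsv")
      split_gene <- if (length(validation$targets))
        validation$targets[1L] else candidates[1L]
      grp <- try(split_by_expression(pre$expression, split_gene),
                 silent = TRUE)
      if (!inherits(grp, "try-error")) {
        gsea_tab <- gsea_significance(
          pre$expression, factor(grp, levels = c("low", "high")),
          inputs$sets, n_perm = config$n_perm,
          seed = stream_seed(config$seed, "gsea"))
        save_tsv(gsea_tab, "gsea.tsv")
      }
    }
    list(ora = ora_tab, gsea = gsea_tab)
  })

  # re-verify that no later stage touched an earlier stage's output
  for (nm in names(persist)) {
    now <- unname(md5sum(file.path(out_dir, nm)))
    if (!identical(now, persist[[nm]]))
      stop("persisted output modified after its stage: ", nm)
  }

  report <- structure(list(
    parameters = config[setdiff(names(config),
                                c("design", "out_dir"))],
    design = if (!is.null(config$design))
      config$design[c("n_genes", "n_samples", "module_sizes",
                      "target_genes", "seed")],
    dimensions = list(
      input = dim(inputs$expr),
      analyzed = dim(pre$expression),
      outliers_removed = pre$outliers),
    power = net$model$power,
    fit_table = net$model$fit_table,
    module_sizes = sort(table(net$assignment), decreasing = TRUE),
    critical_module = net$critical,
    module_trait = net$stats$module_trait,
    mapped_summary = mapped$module_summary,
    n_mapped_nodes = nrow(mapped$nodes),
    n_mapped_edges = nrow(mapped$edges),
    candidates = candidates,
    validation = validation$table,
    final_targets = validation$targets,
    ora = enrich$ora,
    gsea = enrich$gsea,
    checksums = persist,
    seed = config$seed
  ), class = "run_report")
  attr(report, "out_dir") <- out_dir
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("coexppi run report (seed ", x$seed, ")\n", sep = "")
  cat("  analyzed matrix: ", x$dimensions$analyzed[1], " genes x ",
      x$dimensions$analyzed[2], " samples\n", sep = "")
  cat("  soft power:", x$power, "\n")
  cat("  modules:",
      paste(names(x$module_sizes), as.integer(x$module_sizes),
            sep = "=", collapse = ", "), "\n")
  cat("  critical module:", x$critical_module, "\n")
  cat("  mapped network:", x$n_mapped_nodes, "nodes,",
      x$n_mapped_edges, "edges\n")
  cat("  candidates:", length(x$candidates), "->  final targets:",
      paste(x$final_targets, collapse = ", "), "\n")
  invisible(x)
}

#' Run the bundled synthetic demonstration
#'
#' Generates the default planted-truth cohort (500 genes x 200 samples,
#' three modules, three survival-driving target genes) and runs the whole
#' pipeline on it. `top_var = 1` because every synthetic gene has unit
#' variance by construction; `n_perm = 200` keeps the demo quick.
#'
#' @param seed integer master seed.
#' @param out_dir optional output directory.
#' @param n_perm GSEA permutations for the demo.
#' @return a `run_report`.
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, n_perm = 200L) {
  cfg <- pipeline_config(design = synthetic_design(seed = seed),
                         out_dir = out_dir, top_var = 1,
                         n_perm = n_perm, seed = seed)
  run_pipeline(cfg)
}
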