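test_that("generator is deterministic and respects the design invariants", {
  d <- small_design(seed = 11)
  s1 <- generate_expression(d)
  s2 <- generate_expression(d)
  expect_identical(s1$expression, s2$expression)
  expect_identical(dim(s1$expression), c(120L, 150L))
  # truth covers exactly the non-background genes
  expect_length(s1$truth$module_of_gene, 70L)
  expect_setequal(unique(s1$truth$module_of_gene), c("M1", "M2"))

  p1 <- generate_ppi(d, s1$truth)
  p2 <- generate_ppi(d, s1$truth)
  expect_identical(p1, p2)

  t1 <- generate_traits(d, s1$truth)
  t2 <- generate_traits(d, s1$truth)
  expect_identical(t1$traits, t2$traits)
  expect_true(all(t1$traits$time > 0))
  expect_true(all(t1$traits$event %in% 0:1))
})

test_that("design validation rejects impossible worlds", {
  expect_error(synthetic_design(n_genes = 10, module_sizes = c(8, 8)),
               "more than n_genes")
  expect_error(synthetic_design(module_sizes = c(1, 30)), "size < 2")
  expect_error(synthetic_design(ppi_within_prob = 0.1,
                                ppi_between_prob = 0.2), "exceed")
  expect_error(synthetic_design(target_genes = "nope"), "must exist")
  expect_error(synthetic_design(module_sizes = c(30, 30),
                                trait_module_index = 5), "out of range")
})

test_that("zero-noise modules are exact factor multiples", {
  d <- synthetic_design(n_genes = 25, n_samples = 30,
                        module_sizes = c(20L),
                        factor_loading_range = c(1, 1), seed = 2)
  s <- generate_expression(d)
  cc <- cor(t(s$expression[1:20, ]))
  expect_equal(max(abs(abs(cc) - 1)), 0, tolerance = 1e-12)
})

test_that("background-only designs are uncorrelated noise", {
  d <- synthetic_design(n_genes = 60, n_samples = 500,
                        module_sizes = integer(0), seed = 5)
  s <- generate_expression(d)
  cc <- cor(t(s$expression))
  off <- abs(cc[upper.tri(cc)])
  expect_lt(mean(off), 2 / sqrt(500))
})

test_that("within-module correlation exceeds between-module correlation", {
  for (seed in 1:20) {
    d <- synthetic_design(n_genes = 50, n_samples = 100,
                          module_sizes = c(20L, 20L),
                          factor_loading_range = c(0.4, 0.9), seed = seed)
    s <- generate_expression(d)
    cc <- abs(cor(t(s$expression[1:40, ])))
    within <- c(cc[1:20, 1:20][upper.tri(cc[1:20, 1:20])],
                cc[21:40, 21:40][upper.tri(cc[21:40, 21:40])])
    between <- cc[1:20, 21:40]
    expect_gt(mean(within), mean(between))
  }
})

test_that("binary trait calibration hits the target point-biserial", {
  d <- synthetic_design(n_genes = 60, n_samples = 500,
                        module_sizes = c(40L),
                        trait_point_biserial = 0.32, seed = 9)
  s <- generate_expression(d)
  tt <- generate_traits(d, s$truth)
  pb <- cor(s$truth$factor_matrix[1, ], tt$traits$recurrence)
  expect_gte(pb, 0.27)
  expect_lte(pb, 0.37)
})

test_that("censoring_rate = 0 gives all events; the rate is matched otherwise", {
  d0 <- small_design(seed = 3, censoring_rate = 0)
  s0 <- generate_expression(d0)
  expect_true(all(generate_traits(d0, s0$truth)$traits$event == 1))

  d <- synthetic_design(n_genes = 40, n_samples = 800,
                        module_sizes = c(20L), censoring_rate = 0.4,
                        seed = 4)
  s <- generate_expression(d)
  tr <- generate_traits(d, s$truth)$traits
  expect_equal(mean(1 - tr$event), 0.4, tolerance = 0.08)
})

test_that("null hazard means survival is unrelated to target expression", {
  p <- vapply(1:40, function(seed) {
    d <- synthetic_design(n_genes = 20, n_samples = 120,
                          module_sizes = c(10L), log_hazard_ratio = 0,
                          seed = seed)
    s <- generate_expression(d)
    tr <- generate_traits(d, s$truth)$traits
    grp <- split_by_expression(s$expression, d$target_genes[1])
    log_rank(tr$time, tr$event, grp)$p
  }, 0)
  expect_lte(mean(p < 0.05, na.rm = TRUE), 0.15)
})

test_that("PPI fixture: cliques at p = 1, binomial counts, no duplicates", {
  d <- synthetic_design(n_genes = 30, n_samples = 20,
                        module_sizes = c(10L, 10L), ppi_within_prob = 1,
                        ppi_between_prob = 1e-9, ppi_coverage = 1,
                        seed = 6)
  s <- generate_expression(d)
  ppi <- generate_ppi(d, s$truth)
  m1 <- names(d$module_of_gene)[d$module_of_gene == "M1"]
  within1 <- ppi$protein1 %in% m1 & ppi$protein2 %in% m1
  expect_identical(sum(within1), 45L)  # the module-1 clique: C(10,2)
  m2 <- names(d$module_of_gene)[d$module_of_gene == "M2"]
  expect_identical(sum(ppi$protein1 %in% m1 & ppi$protein2 %in% m2) +
                     sum(ppi$protein1 %in% m2 & ppi$protein2 %in% m1), 0L)
  # no duplicate unordered pairs, no self loops
  key <- paste(pmin(ppi$protein1, ppi$protein2),
               pmax(ppi$protein1, ppi$protein2))
  expect_false(any(duplicated(key)))
  expect_false(any(ppi$protein1 == ppi$protein2))
  expect_true(all(ppi$combined_score >= 0.4 & ppi$combined_score <= 1))

  d2 <- synthetic_design(n_genes = 20, n_samples = 20,
                         module_sizes = c(20L), ppi_within_prob = 0.3,
                         ppi_between_prob = 0.01, ppi_coverage = 1,
                         seed = 7)
  s2 <- generate_expression(d2)
  n_edges <- nrow(generate_ppi(d2, s2$truth))
  mu <- choose(20, 2) * 0.3
  sigma <- sqrt(choose(20, 2) * 0.3 * 0.7)
  expect_lt(abs(n_edges - mu), 3 * sigma)
})

test_that("low-confidence flag adds sub-threshold edges that the filter removes", {
  d <- synthetic_design(n_genes = 60, n_samples = 20,
                        module_sizes = c(30L), ppi_within_prob = 0.5,
                        ppi_between_prob = 0.2, ppi_coverage = 1, seed = 8)
  s <- generate_expression(d)
  ppi <- generate_ppi(d, s$truth, low_confidence = TRUE)
  expect_gt(sum(ppi$combined_score < 0.4), 0)
  kept <- filter_confidence(ppi, 0.4)
  expect_true(all(kept$combined_score >= 0.4))
})

test_that("gene sets overlap their module as requested and round-trip via GMT", {
  d <- small_design(seed = 10)
  s <- generate_expression(d)
  sets <- generate_gene_sets(s$truth, n_sets = 12, overlap_fraction = 1)
  m1 <- names(d$module_of_gene)[d$module_of_gene == "M1"]
  pos <- sets[["POS_M1"]]
  expect_true(all(pos %in% m1))  # set sizes <= module size here
  expect_false(anyDuplicated(names(sets)) > 0)

  gmt <- tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  back <- read_gmt(gmt)
  expect_identical(lapply(back, sort)[names(sets)], lapply(sets, sort))
})
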