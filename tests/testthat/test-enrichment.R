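test_that("hypergeometric tail equals the exact enumeration oracle", {
  # N = 20, K = 5, n = 5, k >= 3: sum_i C(5,i) C(15,5-i) / C(20,5)
  bg <- paste0("g", 1:20)
  set_genes <- bg[1:5]
  query <- c(bg[1:3], bg[6:7])  # overlap 3
  res <- ora(query, bg, list(S = set_genes), min_overlap = 1)
  enum <- sum(choose(5, 3:5) * choose(15, 5 - (3:5))) / choose(20, 5)
  expect_equal(res$p, enum, tolerance = 1e-12)
  expect_equal(res$p, 1126 / 15504, tolerance = 1e-12)

  # all n <= 30 style instances against direct enumeration
  for (seed in 1:20) {
    set.seed(seed)
    N <- sample(10:30, 1)
    bgN <- paste0("g", seq_len(N))
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    st <- sample(bgN, K)
    q <- sample(bgN, n)
    k <- length(intersect(st, q))
    if (k < 1) next
    res <- ora(q, bgN, list(S = st), min_overlap = 0)
    ks <- k:min(K, n)
    enum <- sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
    expect_equal(res$p, enum, tolerance = 1e-12)
  }
})

test_that("ORA degenerate tails behave: k = 0 and certain overlap give p = 1", {
  bg <- paste0("g", 1:30)
  res0 <- ora(bg[1:5], bg, list(S = bg[11:20]), min_overlap = 0)
  expect_identical(res0$overlap, 0L)
  expect_equal(res0$p, 1)
  res1 <- ora(bg, bg, list(S = bg), min_overlap = 0)
  expect_equal(res1$p, 1)
  expect_error(ora(character(0), bg, list(S = bg)), "empty query")
  expect_error(ora(c(bg[1], "alien"), bg, list(S = bg)), "missing")
})

test_that("ORA null sets are not enriched beyond chance", {
  d <- synthetic_design(n_genes = 500, n_samples = 20,
                        module_sizes = c(60L), seed = 17)
  s <- generate_expression(d)
  sets <- generate_gene_sets(s$truth, n_sets = 100, overlap_fraction = 0)
  query <- names(d$module_of_gene)
  res <- ora(query, s$truth$gene_ids, sets, min_overlap = 0)
  # hypergeometric p is conservative-discrete: at most mildly sub-alpha
  expect_lte(mean(res$p < 0.05), 0.10)
  # and BH adjustment is monotone in the raw p
  expect_false(is.unsorted(res$p_adj[order(res$p)]))
  expect_true(all(res$p_adj >= res$p))
})

test_that("signal-to-noise ranking follows the floored formula", {
  # mu1 = 2, mu0 = 1, sd = 0.5 in both groups: s2n = 1 / 1 = 1
  g1 <- c(1.5, 2, 2.5, 2, 1.5, 2.5)
  g0 <- c(0.5, 1, 1.5, 1, 0.5, 1.5)
  sd_adj <- sd(g1)  # same spread both groups
  x <- as_expr(rbind(c(g0, g1), rep(1, 12)), genes = c("a", "flat"))
  groups <- rep(0:1, each = 6)
  r <- gsea_rank(x, groups)
  expect_equal(r$score[r$gene == "a"], 1 / (2 * max(sd_adj, 0.4, 0.2)),
               tolerance = 1e-12)
  expect_identical(r$score[r$gene == "flat"], 0)

  # metric oracle on random data
  set.seed(3)
  x2 <- as_expr(matrix(rnorm(10 * 14), 10, 14))
  g <- rep(c(0, 1), 7)
  r2 <- gsea_rank(x2, g, metric = "signal2noise")
  oracle <- apply(x2, 1, function(v) {
    m1 <- mean(v[g == 1]); m0 <- mean(v[g == 0])
    s1 <- max(sd(v[g == 1]), 0.2 * abs(m1), 0.2)
    s0 <- max(sd(v[g == 0]), 0.2 * abs(m0), 0.2)
    (m1 - m0) / (s1 + s0)
  })
  expect_equal(setNames(r2$score, r2$gene),
               sort(oracle, decreasing = TRUE), tolerance = 1e-12)
  expect_error(gsea_rank(x2[, 1:4], g[1:4]), "at least 3")
})

test_that("running sum reproduces the 4-gene hand trace and its symmetries", {
  scores <- setNames(c(3, 2, 1, 0.5), c("a", "b", "c", "d"))
  es <- gsea_es(scores, set = "a", weight_p = 1)
  expect_equal(unname(es$running_sum), c(1, 1 - 1/3, 1/3, 0),
               tolerance = 1e-12)
  expect_equal(es$es, 1)
  expect_identical(es$leading_edge, "a")

  # set == whole list: running sum climbs to 1
  es_all <- gsea_es(scores, set = names(scores))
  expect_equal(es_all$es, 1)
  expect_equal(max(es_all$running_sum), 1)

  # mirrored scores and mirrored set negate the ES
  mirror <- setNames(rev(-unname(scores)), c("d", "c", "b", "a"))
  es_neg <- gsea_es(mirror, set = "a")
  expect_equal(es_neg$es, -es$es, tolerance = 1e-12)

  # ES invariant to positive rescaling of all scores
  es_scaled <- gsea_es(scores * 7.3, set = c("a", "c"))
  expect_equal(gsea_es(scores, set = c("a", "c"))$es, es_scaled$es,
               tolerance = 1e-12)
  expect_error(gsea_es(scores, set = "zz"), "does not intersect")
})

test_that("ES stays in [-1, 1] and the fast path agrees with the running sum", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(20:60, 1)
    scores <- setNames(sort(rnorm(n), decreasing = TRUE),
                       paste0("g", seq_len(n)))
    m <- sample(3:10, 1)
    idx <- sort(sample(n, m))
    set_genes <- names(scores)[idx]
    full <- gsea_es(scores, set_genes)
    fast <- coexppi:::es_from_positions(idx, abs(scores[idx]), n)
    expect_equal(full$es, fast, tolerance = 1e-12)
    expect_true(abs(full$es) <= 1 + 1e-12)
  }
})

test_that("permutation p-values are reproducible, bounded away from 0", {
  set.seed(11)
  x <- as_expr(matrix(rnorm(60 * 16), 60, 16))
  g <- rep(0:1, each = 8)
  x[1:12, g == 1] <- x[1:12, g == 1] + 2       # strong planted set
  sets <- list(planted = rownames(x)[1:12],
               null1 = rownames(x)[21:35], null2 = rownames(x)[41:55])
  r1 <- gsea_significance(x, g, sets, n_perm = 200, seed = 99)
  r2 <- gsea_significance(x, g, sets, n_perm = 200, seed = 99)
  expect_identical(r1, r2)
  expect_true(all(r1$p > 0))
  expect_gte(min(r1$p), 1 / 201)
  expect_lte(r1$p[r1$set == "planted"], 0.05)
  expect_true(all(abs(r1$es) <= 1))
})

test_that("tiny cohorts switch to exact enumeration of label assignments", {
  set.seed(12)
  x <- as_expr(matrix(rnorm(30 * 8), 30, 8))
  g <- rep(0:1, each = 4)
  sets <- list(s1 = rownames(x)[1:8])
  expect_message(r <- gsea_significance(x, g, sets, n_perm = 100,
                                        seed = 1),
                 "enumerating")
  expect_true(r$p > 0 && r$p <= 1)
})

test_that("gene-set permutation mode runs and is seeded", {
  set.seed(13)
  x <- as_expr(matrix(rnorm(40 * 12), 40, 12))
  g <- rep(0:1, each = 6)
  sets <- list(s1 = rownames(x)[1:10], s2 = rownames(x)[11:25])
  r1 <- gsea_significance(x, g, sets, n_perm = 150, seed = 5,
                          permute = "geneset")
  r2 <- gsea_significance(x, g, sets, n_perm = 150, seed = 5,
                          permute = "geneset")
  expect_identical(r1, r2)
})
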