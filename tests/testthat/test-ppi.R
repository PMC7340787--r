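write_ppi_fixture <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score", rows), f)
  f
}

test_that("read_ppi normalizes dialects, deduplicates and drops self-loops", {
  f <- write_ppi_fixture(c("A\tB\t900", "B\tA\t850", "A\tA\t990",
                           "C\tD\t400"))
  expect_message(ppi <- read_ppi(f, "string999"), "self-loop")
  expect_identical(nrow(ppi), 2L)
  ab <- ppi[ppi$protein1 == "A" & ppi$protein2 == "B", ]
  expect_equal(ab$combined_score, 0.9)   # max of the two orientations

  f2 <- write_ppi_fixture(c("A\tB\t0.2", "B\tC\t0.4", "C\tD\t0.9"))
  ppi2 <- read_ppi(f2, "unit")
  expect_identical(nrow(filter_confidence(ppi2, 0.4)), 2L)  # >= semantics
  expect_identical(nrow(filter_confidence(ppi2, 0)), 3L)
  expect_identical(filter_confidence(ppi2, 0.9)$protein1, "C")
  expect_error(filter_confidence(ppi2, 0.95), "no PPI edges")

  f3 <- write_ppi_fixture(c("A\tB\t0.5", "B\tC\tnot_a_number"))
  expect_error(read_ppi(f3, "unit"), "line 3")
})

test_that("filtered edge counts match a direct counting oracle", {
  set.seed(10)
  scores <- round(runif(200), 3)
  rows <- sprintf("a%03d\tb%03d\t%g", 1:200, 1:200, scores)
  ppi <- read_ppi(write_ppi_fixture(rows), "unit")
  expect_identical(nrow(filter_confidence(ppi, 0.4)),
                   sum(scores >= 0.4))
})

test_that("id mapping translates endpoints, drops unmapped, collapses dupes", {
  ppi <- data.frame(protein1 = c("P1", "P2", "P3"),
                    protein2 = c("P2", "P3", "P4"),
                    combined_score = c(0.5, 0.6, 0.7))
  map <- data.frame(from = c("P1", "P2", "P3"),
                    to = c("GENEA", "GENEB", "GENEA"))
  expect_message(out <- apply_id_map(ppi, map), "1 edge")
  # P2-P3 becomes GENEB-GENEA; P1-P2 is GENEA-GENEB: collapsed, max score
  expect_identical(nrow(out), 1L)
  expect_equal(out$combined_score, 0.6)
  expect_setequal(c(out$protein1, out$protein2), c("GENEA", "GENEB"))
})

test_that("module mapping keeps only fully labeled edges (hand trace)", {
  asg <- setNames(c("M1", "M1", "M2"), c("g1", "g2", "g3"))
  ppi <- data.frame(protein1 = c("g1", "g2", "g3"),
                    protein2 = c("g2", "g4", "g5"),
                    combined_score = c(0.9, 0.8, 0.7))
  net <- map_modules(ppi, asg, drop_grey = TRUE)
  expect_identical(sort(net$nodes$gene), c("g1", "g2"))
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$nodes$degree, c(1L, 1L))

  # assignment covering every node: mapped network == input network
  asg2 <- setNames(rep("M1", 5), paste0("g", 1:5))
  net2 <- map_modules(ppi, asg2)
  expect_identical(nrow(net2$edges), 3L)
  expect_identical(sort(net2$nodes$gene), paste0("g", 1:5))

  expect_error(map_modules(ppi, setNames(rep("grey", 2), c("g1", "g2"))),
               "grey")
  # keep_isolates retains labeled genes without retained edges
  net3 <- map_modules(ppi, asg, keep_isolates = TRUE)
  expect_identical(sort(net3$nodes$gene), c("g1", "g2", "g3"))
  expect_identical(net3$nodes$degree[net3$nodes$gene == "g3"], 0L)
})

test_that("node ranking is degree-descending with id tie-break", {
  star <- data.frame(protein1 = rep("hub", 4),
                     protein2 = paste0("leaf", 1:4),
                     combined_score = 0.9)
  asg <- setNames(rep("M1", 5), c("hub", paste0("leaf", 1:4)))
  ranked <- rank_nodes(map_modules(star, asg))
  expect_identical(ranked$gene[1], "hub")
  expect_identical(ranked$degree[1], 4L)
  expect_identical(ranked$gene[-1], paste0("leaf", 1:4))

  tri <- data.frame(protein1 = c("a", "b", "c"),
                    protein2 = c("b", "c", "a"), combined_score = 1)
  asg_t <- setNames(rep("M1", 3), c("a", "b", "c"))
  rt <- rank_nodes(map_modules(tri, asg_t))
  expect_true(all(rt$degree == 2L))
  expect_identical(rt$gene, c("a", "b", "c"))
})

test_that("degrees sum to twice the edge count and match row-sum oracle", {
  for (seed in 1:5) {
    d <- synthetic_design(n_genes = 40, n_samples = 20,
                          module_sizes = c(15L, 10L),
                          ppi_within_prob = 0.4, ppi_between_prob = 0.1,
                          ppi_coverage = 1, seed = seed)
    s <- generate_expression(d)
    ppi <- generate_ppi(d, s$truth)
    asg <- setNames(rep("M1", 40), s$truth$gene_ids)
    net <- map_modules(ppi, asg)
    expect_identical(sum(net$nodes$degree), 2L * nrow(net$edges))
    adj <- matrix(0L, nrow(net$nodes), nrow(net$nodes),
                  dimnames = list(net$nodes$gene, net$nodes$gene))
    for (r in seq_len(nrow(net$edges)))
      adj[net$edges$protein1[r], net$edges$protein2[r]] <-
      adj[net$edges$protein2[r], net$edges$protein1[r]] <- 1L
    expect_identical(unname(rowSums(adj)[net$nodes$gene]),
                     as.numeric(net$nodes$degree))
  }
})

test_that("trait-module nodes out-rank the rest of the mapped network", {
  for (seed in 1:20) {
    d <- synthetic_design(n_genes = 60, n_samples = 20,
                          module_sizes = c(30L, 15L),
                          ppi_within_prob = 0.5, ppi_between_prob = 0.02,
                          ppi_coverage = 1, seed = seed)
    s <- generate_expression(d)
    ppi <- generate_ppi(d, s$truth)
    asg <- setNames(rep("grey", 60), s$truth$gene_ids)
    asg[names(d$module_of_gene)] <- d$module_of_gene
    net <- map_modules(ppi, asg, drop_grey = TRUE)
    mean_deg <- mean(net$nodes$degree)
    m1_deg <- mean(net$nodes$degree[net$nodes$module == "M1"])
    expect_gt(m1_deg, mean_deg)
  }
})

test_that("candidate extraction returns the critical module, degree-ranked", {
  d <- synthetic_design(n_genes = 50, n_samples = 20,
                        module_sizes = c(20L, 15L),
                        ppi_within_prob = 0.8, ppi_between_prob = 0.02,
                        ppi_coverage = 1, seed = 4)
  s <- generate_expression(d)
  ppi <- generate_ppi(d, s$truth)
  asg <- setNames(rep("grey", 50), s$truth$gene_ids)
  asg[names(d$module_of_gene)] <- d$module_of_gene
  net <- map_modules(ppi, asg)
  cand <- candidate_targets(net, "M1")
  m1 <- names(d$module_of_gene)[d$module_of_gene == "M1"]
  expect_true(all(cand %in% m1))
  expect_gte(length(cand), 15L)
  expect_error(candidate_targets(net, "M9"), "not present")
})
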