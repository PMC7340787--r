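#' Read a protein-protein interaction edge list
#'
#' Expects a TSV with two id columns and a confidence score column
#' (`combined_score` if named, else the third column). The `string999`
#' dialect divides scores by 1000 (the STRING convention of integer scores
#' on 0-999). Self-loops are dropped (count reported via message);
#' duplicate and reversed pairs collapse to one edge keeping the maximum
#' score.
#'
#' @param path TSV path.
#' @param score_dialect `"unit"` (scores already in \[0, 1\]) or
#'   `"string999"`.
#' @return data.frame `protein1`, `protein2`, `combined_score` in \[0, 1\].
#' @export
read_ppi <- function(path, score_dialect = c("unit", "string999")) {
  score_dialect <- match.arg(score_dialect)
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (ncol(df) < 3L)
    stop("PPI file needs two id columns and a score column: ", path)
  sc_col <- if ("combined_score" %in% colnames(df)) "combined_score" else
    colnames(df)[3L]
  edges <- data.frame(protein1 = as.character(df[[1L]]),
                      protein2 = as.character(df[[2L]]),
                      combined_score = suppressWarnings(
                        as.numeric(df[[sc_col]])),
                      stringsAsFactors = FALSE)
  bad <- which(is.na(edges$combined_score) | !nzchar(edges$protein1) |
                 !nzchar(edges$protein2))
  if (length(bad))
    stop("malformed PPI row at line ", bad[1L] + 1L, " of ", path)
  if (score_dialect == "string999")
    edges$combined_score <- edges$combined_score / 1000
  if (any(edges$combined_score < 0 | edges$combined_score > 1))
    stop("scores outside [0, 1] after dialect normalization; ",
         "wrong score_dialect?")
  clean_ppi(edges)
}

clean_ppi <- function(edges) {
  loops <- edges$protein1 == edges$protein2
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$protein1, edges$protein2)
  b <- pmax(edges$protein1, edges$protein2)
  key <- paste(a, b, sep = "\r")
  score <- tapply(edges$combined_score, key, max)
  first <- !duplicated(key)
  out <- data.frame(protein1 = a[first], protein2 = b[first],
                    combined_score = as.numeric(score[key[first]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$protein1, out$protein2), , drop = FALSE]
}

#' Translate PPI node identifiers via a two-column mapping
#'
#' Replaces protein ids with gene symbols (or any target namespace) using
#' a `from`/`to` table — the local stand-in for live id-lookup services.
#' Edges with an unmapped endpoint are dropped (count reported);
#' duplicates arising from many-to-one mappings are collapsed keeping the
#' maximum score.
#'
#' @param ppi edge data.frame from [read_ppi()].
#' @param map data.frame with columns `from`, `to` (or a TSV path to one).
#' @return remapped edge data.frame.
#' @export
apply_id_map <- function(ppi, map) {
  if (is.character(map) && length(map) == 1L)
    map <- read.table(map, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to") %in% colnames(map)))
  lut <- setNames(as.character(map$to), as.character(map$from))
  p1 <- lut[ppi$protein1]
  p2 <- lut[ppi$protein2]
  ok <- !is.na(p1) & !is.na(p2)
  if (!all(ok))
    message("dropping ", sum(!ok), " edge(s) with unmapped endpoints")
  if (!any(ok)) stop("no PPI edge survives the id mapping")
  clean_ppi(data.frame(protein1 = p1[ok], protein2 = p2[ok],
                       combined_score = ppi$combined_score[ok],
                       stringsAsFactors = FALSE))
}

#' Filter PPI edges by confidence score
#'
#' Keeps edges with `combined_score >= min_score` (the conventional
#' "medium confidence" cut is 0.4, inclusive).
#'
#' @param ppi edge data.frame from [read_ppi()] or [generate_ppi()].
#' @param min_score in \[0, 1\].
#' @return filtered edge data.frame; errors when nothing survives.
#' @export
filter_confidence <- function(ppi, min_score = 0.4) {
  stopifnot(min_score >= 0, min_score <= 1,
            all(c("protein1", "protein2", "combined_score") %in%
                  colnames(ppi)))
  out <- ppi[ppi$combined_score >= min_score, , drop = FALSE]
  if (!nrow(out)) stop("no PPI edges at min_score = ", min_score)
  rownames(out) <- NULL
  out
}

#' Project co-expression modules onto the PPI network
#'
#' Keeps PPI edges whose both endpoints carry a module label (grey
#' excluded by default); nodes are the endpoints of retained edges — the
#' projected network is edge-defined, so isolated labeled genes drop out
#' unless `keep_isolates = TRUE`. Each node carries its module label and
#' its degree in the retained graph.
#'
#' @param ppi edge data.frame.
#' @param assignment named gene -> module vector.
#' @param drop_grey exclude grey-labeled genes?
#' @param keep_isolates also keep labeled genes without retained edges.
#' @return list of class `mapped_network`: `nodes` (gene, module, degree),
#'   `edges`, `module_summary` (module, n_nodes, n_edges, mean_degree).
#' @export
map_modules <- function(ppi, assignment, drop_grey = TRUE,
                        keep_isolates = FALSE) {
  stopifnot(length(assignment) > 0, !is.null(names(assignment)))
  labeled <- names(assignment)
  if (drop_grey) labeled <- labeled[assignment[labeled] != "grey"]
  if (!length(labeled)) stop("no labeled genes after grey removal")
  keep <- ppi$protein1 %in% labeled & ppi$protein2 %in% labeled
  edges <- ppi[keep, , drop = FALSE]
  if (!nrow(edges) && !keep_isolates)
    stop("no PPI edges with both endpoints in labeled modules")
  node_ids <- if (keep_isolates) sort(labeled) else
    sort(unique(c(edges$protein1, edges$protein2)))
  g <- graph_from_data_frame(edges[, c("protein1", "protein2")],
                             directed = FALSE, vertices = node_ids)
  deg <- degree(g)
  nodes <- data.frame(gene = node_ids,
                      module = unname(assignment[node_ids]),
                      degree = as.integer(deg[node_ids]),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  summ <- do.call(rbind, lapply(split(nodes, nodes$module), function(d) {
    within_edges <- sum(edges$protein1 %in% d$gene &
                          edges$protein2 %in% d$gene)
    data.frame(module = d$module[1L], n_nodes = nrow(d),
               n_edges = within_edges, mean_degree = mean(d$degree))
  }))
  rownames(summ) <- NULL
  structure(list(nodes = nodes, edges = edges, module_summary = summ),
            class = "mapped_network")
}

#' @export
print.mapped_network <- function(x, ...) {
  cat("mapped_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges,", nrow(x$module_summary), "modules\n")
  invisible(x)
}

#' Rank network nodes by degree
#'
#' @param network a [map_modules()] result.
#' @return data.frame (gene, module, degree) in descending degree order,
#'   ties broken by gene id.
#' @export
rank_nodes <- function(network) {
  stopifnot(inherits(network, "mapped_network"))
  if (!nrow(network$nodes)) stop("empty mapped network")
  nd <- network$nodes
  nd <- nd[order(-nd$degree, nd$gene), , drop = FALSE]
  rownames(nd) <- NULL
  nd
}

#' Candidate targets: critical-module nodes of the mapped network
#'
#' @param network a [map_modules()] result.
#' @param critical_module module label to extract.
#' @return character vector of gene ids, degree-ranked.
#' @export
candidate_targets <- function(network, critical_module) {
  ranked <- rank_nodes(network)
  if (!critical_module %in% ranked$module)
    stop("module not present in mapped network: ", critical_module)
  ranked$gene[ranked$module == critical_module]
}
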