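#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' observing at least the seen overlap between the query and the set,
#' given the background universe (plain hypergeometric tail — not the
#' EASE-modified score some web tools report). Sets are intersected with
#' the background first; p-values are Benjamini-Hochberg adjusted across
#' the tested sets.
#'
#' @param query character vector of genes (must be a subset of
#'   `background`).
#' @param background the gene universe.
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param min_overlap sets overlapping the query by fewer genes are
#'   skipped (use 0 to report every set).
#' @return data.frame of class `enrichment_result`: set, set_size,
#'   overlap, odds_ratio, p, p_adj, genes (comma-separated overlap),
#'   sorted by p.
#' @export
ora <- function(query, background, sets, min_overlap = 1L) {
  query <- unique(query)
  background <- unique(background)
  if (!length(query)) stop("empty query gene list")
  if (!all(query %in% background))
    stop("query genes missing from the background: ",
         paste(head(setdiff(query, background), 5L), collapse = ", "))
  n_bg <- length(background)
  n_q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), background)
    k_set <- length(s)
    ov <- intersect(s, query)
    k <- length(ov)
    if (k_set == 0L || k < min_overlap) return(NULL)
    p <- phyper(k - 1L, k_set, n_bg - k_set, n_q, lower.tail = FALSE)
    odds <- (k * (n_bg - k_set - n_q + k)) /
      max(1e-12, (n_q - k) * (k_set - k))
    data.frame(set = nm, set_size = k_set, overlap = k,
               odds_ratio = odds, p = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no gene set passes min_overlap = ", min_overlap)
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set),
             c("set", "set_size", "overlap", "odds_ratio", "p", "p_adj",
               "genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
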