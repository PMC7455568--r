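#' Translate gene symbols across the mouse/human ortholog map
#'
#' Returns the union of target-namespace symbols paired with any query
#' symbol; many-to-many pairs contribute every partner once.  Query genes
#' with no partner are dropped, counted and reported with a message — they
#' are not an error.
#'
#' @param genes Character vector of query symbols.
#' @param map Ortholog map from [read_ortholog_map()] (columns `human`,
#'   `mouse`).
#' @param direction `"mouse_to_human"` (default) or `"human_to_mouse"`.
#' @return Character vector of translated symbols, with attribute
#'   `n_unmapped` giving the number of query genes without a partner.
#' @export
map_orthologs <- function(genes, map,
                          direction = c("mouse_to_human", "human_to_mouse")) {
  direction <- match.arg(direction)
  if (is.null(map) || !nrow(map)) arg_error("ortholog map is empty")
  if (direction == "mouse_to_human") {
    from <- .capitalize(map$mouse); to <- toupper(map$human)
    query <- .capitalize(genes)
  } else {
    from <- toupper(map$human); to <- .capitalize(map$mouse)
    query <- toupper(genes)
  }
  hit <- query %in% from
  n_unmapped <- sum(!hit)
  if (n_unmapped > 0L)
    message(sprintf("map_orthologs: %d of %d query gene(s) had no ortholog partner",
                    n_unmapped, length(query)))
  out <- unique(to[from %in% query])
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Hypergeometric gene-set membership test
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' and a reference gene set within a fixed universe: `N = |universe|`,
#' `K = |gene_set ∩ universe|`, `n = |query ∩ universe|`,
#' `k = |query ∩ gene_set ∩ universe|`, `p = P(X >= k)`.
#'
#' @param query Character vector of query genes.
#' @param gene_set Character vector of reference-set genes.
#' @param universe Character vector defining the background.
#' @return Named list `(k, K, n, N, p)`.
#' @export
set_test <- function(query, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) arg_error("universe is empty")
  query <- intersect(unique(query), universe)
  gene_set <- intersect(unique(gene_set), universe)
  k <- length(intersect(query, gene_set))
  K <- length(gene_set)
  n <- length(query)
  N <- length(universe)
  p <- max(min(phyper(k - 1, K, N - K, n, lower.tail = FALSE), 1),
           .Machine$double.xmin)
  list(k = k, K = K, n = n, N = N, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values in `(0, 1]`.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues))
    val_error("pvalues must be numeric")
  if (length(pvalues) &&
      (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)))
    val_error("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Gene-set collection enrichment
#'
#' Runs [set_test()] for every set in the collection, adjusts across the
#' collection with [bh_fdr()], and scores each set as `-log10(q)`.  Rows
#' are sorted by score descending with ties broken by set name, so the
#' result is invariant to the input order of the collection.
#'
#' @param query Character vector of query genes (same namespace as the
#'   collection, i.e. after ortholog translation).
#' @param collection Named list of gene sets (from [read_gmt()]).
#' @param universe Character vector defining the background.
#' @return Data frame with columns `set`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `score`.
#' @export
enrich_collection <- function(query, collection, universe) {
  if (!length(collection)) arg_error("gene-set collection is empty")
  rows <- lapply(names(collection), function(nm) {
    r <- set_test(query, collection[[nm]], universe)
    data.frame(set = nm, k = r$k, K = r$K, n = r$n, N = r$N, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- pmax(bh_fdr(out$p), .Machine$double.xmin)
  out$score <- -log10(out$q)
  out <- out[order(-out$score, out$set), ]
  rownames(out) <- NULL
  out
}
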