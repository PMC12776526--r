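# Internal helpers shared across the pipeline.

#' @importFrom stats p.adjust quantile median sd cor wilcox.test pt
#'   t.test rnbinom rlnorm rpois lm setNames
#' @importFrom utils read.csv write.csv read.delim write.table
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream (community detection and permutation nulls must be
# reproducible even when called mid-simulation).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

cd_log <- function(fmt, ...) {
  if (isTRUE(getOption("cytodict.verbose", FALSE)))
    message(sprintf(fmt, ...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# counts-per-million over the rows of a genes-in-columns matrix
cpm_rows <- function(m) {
  tot <- rowSums(m)
  tot[tot == 0] <- 1
  sweep(m, 1, tot, "/") * 1e6
}

# Connected components of an undirected relation given as a logical
# adjacency matrix; returns integer component labels.
components_of <- function(adj) {
  stopifnot(nrow(adj) == ncol(adj))
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

# Leiden CPM partition of a weighted similarity matrix. Negative weights
# are floored at zero (CPM assumes non-negative weights); diagonal is
# dropped. Deterministic under `seed`.
leiden_cpm <- function(S, resolution, seed = 1L, n_iterations = 10L) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (any(!is.finite(S))) stop("similarity matrix has non-finite weights")
  W <- pmax(S, 0)
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- with_seed(seed, igraph::cluster_leiden(
    g, objective_function = "CPM", resolution = resolution,
    weights = igraph::E(g)$weight, n_iterations = n_iterations))
  out <- as.integer(igraph::membership(memb))
  names(out) <- rownames(S)
  out
}
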