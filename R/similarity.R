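#' Robustly expressed genes of a cell type
#'
#' Across all of a cell type's stimulation conditions a gene qualifies
#' when its maximum condition cpm reaches `min_max_cpm`, its mean cpm
#' over conditions reaches `min_mean_cpm`, and its maximum total
#' pseudobulk count reaches `min_count`.
#'
#' @param pb a [pseudobulk].
#' @param cell_type the cell type.
#' @param min_max_cpm,min_mean_cpm,min_count the rule (20, 4, 20).
#' @return Character vector of gene ids; errors when empty.
#' @export
robust_genes <- function(pb, cell_type, min_max_cpm = 20,
                         min_mean_cpm = 4, min_count = 20) {
  conds <- unique(pb$keys$condition[pb$keys$cell_type == cell_type])
  cpmm <- sapply(conds, function(cond) {
    v <- pooled_cpm(pb, cell_type, cond)
    if (is.null(v)) rep(NA_real_, length(pb$genes)) else v
  })
  cntm <- sapply(conds, function(cond) {
    rows <- pb_rows(pb, cell_type = cell_type, condition = cond)
    colSums(pb$raw[rows, , drop = FALSE])
  })
  keep <- apply(cpmm, 1, max, na.rm = TRUE) >= min_max_cpm &
    rowMeans(cpmm, na.rm = TRUE) >= min_mean_cpm &
    apply(cntm, 1, max) >= min_count
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("no robustly expressed genes in ", cell_type)
  pb$genes[keep]
}

#' Cytokine response-similarity matrix for one cell type
#'
#' Pearson correlation of consensus log2FC vectors between cytokines,
#' over the cell type's robustly expressed genes.
#'
#' @param det a [de_table] result.
#' @param pb a [pseudobulk] (for the robust gene set).
#' @param cell_type the cell type.
#' @param cytokines cytokines to include (default: those in `det`).
#' @return Symmetric correlation matrix (NA where vectors don't overlap).
#' @export
similarity_matrix <- function(det, pb, cell_type, cytokines = NULL) {
  cytokines <- cytokines %||%
    unique(det$cytokine[det$cell_type == cell_type])
  genes <- robust_genes(pb, cell_type)
  vecs <- sapply(cytokines, function(cy) {
    d <- det[det$cell_type == cell_type & det$cytokine == cy, ]
    stats::setNames(d$log2fc, d$gene)[genes]
  })
  rownames(vecs) <- genes
  S <- suppressWarnings(stats::cor(vecs, use = "pairwise.complete.obs"))
  S
}

#' Leiden communities of cytokine responses within a cell type
#'
#' Subsets the similarity matrix to strong-impact cytokines, zeroes the
#' diagonal, floors negative weights at zero, and partitions with the
#' Leiden CPM objective.
#'
#' @param S cytokine similarity matrix.
#' @param strong named logical vector of strong-impact flags.
#' @param resolution CPM resolution (0.5).
#' @param seed RNG seed for reproducible refinement.
#' @return Named integer membership vector, or `NULL` when fewer than
#'   two strong cytokines exist.
#' @export
leiden_groups <- function(S, strong, resolution = 0.5, seed = 1L) {
  keep <- names(strong)[strong %in% TRUE]
  keep <- intersect(rownames(S), keep)
  if (length(keep) < 2) {
    cd_log("leiden_groups: fewer than 2 strong cytokines; skipped")
    return(NULL)
  }
  Ssub <- S[keep, keep, drop = FALSE]
  Ssub[!is.finite(Ssub)] <- 0
  leiden_cpm(Ssub, resolution = resolution, seed = seed)
}

#' Consensus cytokine communities across cell types
#'
#' Counts how often two cytokines were co-clustered across cell types,
#' keeps cytokines that participated in clustering for at least
#' `min_celltypes` cell types, symmetrically normalizes the count
#' matrix by inverse square roots of its row sums (epsilon-guarded),
#' converts pairwise cosine distances of the normalized rows to a
#' similarity (1 - distance), and partitions with Leiden CPM.
#'
#' @param assignments list of per-cell-type membership vectors from
#'   [leiden_groups].
#' @param resolution CPM resolution (0.5).
#' @param min_celltypes participation filter (2).
#' @param eps row-sum guard (1e-9).
#' @param seed RNG seed.
#' @return list: `membership` (named consensus communities), `counts`
#'   (co-clustering count matrix).
#' @export
consensus_groups <- function(assignments, resolution = 0.5,
                             min_celltypes = 2, eps = 1e-9, seed = 1L) {
  assignments <- Filter(Negate(is.null), assignments)
  if (length(assignments) < 2)
    stop("need cluster assignments from at least 2 cell types")
  cyts <- sort(unique(unlist(lapply(assignments, names))))
  C <- matrix(0, length(cyts), length(cyts),
              dimnames = list(cyts, cyts))
  participation <- stats::setNames(integer(length(cyts)), cyts)
  for (a in assignments) {
    participation[names(a)] <- participation[names(a)] + 1L
    for (grp in unique(a)) {
      m <- names(a)[a == grp]
      C[m, m] <- C[m, m] + 1
    }
  }
  keep <- names(participation)[participation >= min_celltypes]
  if (length(keep) < 2) stop("fewer than 2 cytokines pass participation")
  C <- C[keep, keep, drop = FALSE]
  rs <- rowSums(C)
  N <- diag(1 / sqrt(rs + eps)) %*% C %*% diag(1 / sqrt(rs + eps))
  dimnames(N) <- dimnames(C)
  # cosine distance between normalized rows
  nrm <- sqrt(rowSums(N^2))
  # similarity fed to Leiden is 1 - cosine distance, i.e. the cosine
  # similarity of the normalized rows
  S <- (N %*% t(N)) / (outer(nrm, nrm) + eps)
  memb <- leiden_cpm(S, resolution = resolution, seed = seed)
  list(membership = memb, counts = C)
}

#' Highly similar cytokine groups across cell types
#'
#' Two cytokines relate when they share at least `min_shared` cell types
#' in which both have strong impact and their mean response correlation
#' over exactly those shared-strong cell types exceeds `min_r`; groups
#' are the transitive closure (connected components) of the relation.
#'
#' @param S_list named list of per-cell-type similarity matrices.
#' @param strong_list named list of per-cell-type logical strong flags
#'   (named by cytokine).
#' @param min_shared shared strong cell types required (3).
#' @param min_r mean correlation threshold (0.7).
#' @return list of character vectors (disjoint groups of size >= 2).
#' @export
highly_similar <- function(S_list, strong_list, min_shared = 3,
                           min_r = 0.7) {
  cyts <- sort(unique(unlist(lapply(strong_list, names))))
  n <- length(cyts)
  rel <- matrix(FALSE, n, n, dimnames = list(cyts, cyts))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    a <- cyts[i]; b <- cyts[j]
    rs <- vapply(names(S_list), function(ct) {
      st <- strong_list[[ct]]
      if (!isTRUE(st[a]) || !isTRUE(st[b])) return(NA_real_)
      S <- S_list[[ct]]
      if (!a %in% rownames(S) || !b %in% rownames(S)) return(NA_real_)
      S[a, b]
    }, 0)
    rs <- rs[!is.na(rs)]
    if (length(rs) >= min_shared && mean(rs) > min_r)
      rel[i, j] <- rel[j, i] <- TRUE
  }
  comp <- components_of(rel)
  grps <- split(cyts, comp)
  unname(grps[vapply(grps, length, 0L) >= 2])
}
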