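#' Donor baseline log2 fold change vs the cross-donor median
#'
#' Characterizes each donor's unstimulated state: per (donor, cell type),
#' `log2((cpm_d + 1) / (median cpm across donors + 1))` on PBS
#' pseudobulks, restricted to protein-coding, non-ribosomal,
#' non-mitochondrial, non-sex-chromosome genes with at least
#' `min_reads` raw reads in the donor's pseudobulk.
#'
#' @param pb a [pseudobulk].
#' @param ann a [gene_annotation] table.
#' @param cell_type the cell type.
#' @param min_reads per-gene raw-read filter (10).
#' @param min_donors minimum donors with PBS pseudobulks (3).
#' @return matrix donors x genes of baseline log2FCs (NA where the gene
#'   fails the per-donor read filter).
#' @export
baseline_lfc <- function(pb, ann, cell_type, min_reads = 10,
                         min_donors = 3) {
  bd <- pb_by_donor(pb, cell_type, "PBS")
  if (length(bd$donor) < min_donors)
    stop("need at least ", min_donors, " donors with PBS pseudobulks")
  flags <- lookup_annotation(ann, pb$genes)
  keep <- flags$protein_coding & !flags$ribosomal & !flags$mitochondrial &
    !flags$sex_chromosome
  raw <- bd$raw[, keep, drop = FALSE]
  cpm <- cpm_rows(bd$raw)[, keep, drop = FALSE]
  med <- apply(cpm, 2, stats::median)
  out <- log2((cpm + 1) / rep(med + 1, each = nrow(cpm)))
  out[raw < min_reads] <- NA_real_
  rownames(out) <- bd$donor
  colnames(out) <- pb$genes[keep]
  out
}

#' Per-donor response magnitude
#'
#' Euclidean distance between a donor's PBS and cytokine log2(cpm + 1)
#' pseudobulk vectors, normalized by the square root of the gene-vector
#' length. Genes must have at least `min_reads` raw reads in either of
#' the donor's two pseudobulks; the condition must retain at least
#' `min_genes` such genes, otherwise NA.
#'
#' @param pb a [pseudobulk].
#' @param donor,cell_type,cytokine the condition.
#' @param min_reads per-gene raw-read filter (10).
#' @param min_genes minimum filter-passing genes (1000).
#' @return Normalized donor magnitude, or `NA`.
#' @export
donor_magnitude <- function(pb, donor, cell_type, cytokine,
                            min_reads = 10, min_genes = 1000) {
  v <- donor_condition_cpm(pb, donor, cell_type, cytokine)
  if (is.null(v)) return(NA_real_)
  keep <- v$raw_p >= min_reads | v$raw_c >= min_reads
  if (sum(keep) < min_genes) {
    cd_log("donor_magnitude: %s/%s/%s has %d < %d filter-passing genes",
           donor, cell_type, cytokine, sum(keep), min_genes)
    return(NA_real_)
  }
  d <- log2(v$cpm_c[keep] + 1) - log2(v$cpm_p[keep] + 1)
  sqrt(sum(d^2)) / sqrt(sum(keep))
}

# one donor's paired PBS/cytokine pseudobulk cpm for a cell type
donor_condition_cpm <- function(pb, donor, cell_type, cytokine) {
  rp <- pb_rows(pb, donor = donor, cell_type = cell_type,
                condition = "PBS")
  rc <- pb_rows(pb, donor = donor, cell_type = cell_type,
                condition = cytokine)
  if (!length(rp) || !length(rc)) return(NULL)
  raw_p <- colSums(pb$raw[rp, , drop = FALSE])
  raw_c <- colSums(pb$raw[rc, , drop = FALSE])
  if (sum(raw_p) == 0 || sum(raw_c) == 0) return(NULL)
  list(raw_p = raw_p, raw_c = raw_c,
       cpm_p = raw_p / sum(raw_p) * 1e6,
       cpm_c = raw_c / sum(raw_c) * 1e6,
       n_cells_p = sum(pb$n_cells[rp]), n_cells_c = sum(pb$n_cells[rc]))
}

#' Donor-specific log2 fold-change vector
#'
#' `log2((cpm_cytokine + 1) / (cpm_PBS + 1))` for one donor, restricted
#' to genes with at least `min_reads` raw reads in either pseudobulk;
#' conditions backed by fewer than `min_cells` cells are discarded (NA).
#'
#' @inheritParams donor_magnitude
#' @param min_cells minimum cells in the cytokine condition (20).
#' @return Named log2FC vector over filter-passing genes, or `NULL`.
#' @export
donor_lfc <- function(pb, donor, cell_type, cytokine, min_reads = 10,
                      min_cells = 20) {
  v <- donor_condition_cpm(pb, donor, cell_type, cytokine)
  if (is.null(v) || v$n_cells_c < min_cells) return(NULL)
  keep <- v$raw_p >= min_reads | v$raw_c >= min_reads
  stats::setNames(log2((v$cpm_c[keep] + 1) / (v$cpm_p[keep] + 1)),
                  pb$genes[keep])
}

#' Raw (non-normalized) donor response strength
#'
#' `M_Raw = sum_i (2^max(|log2 rawFC_i| - 0.5, 0) - 1)` over a donor's
#' per-gene cpm ratios; subtracting 0.5 in log2 space discounts the
#' higher noise floor of single-donor pseudocount comparisons.
#'
#' @param raw_fc per-gene donor cpm ratio (condition / PBS), or its
#'   log2 if `log = TRUE`.
#' @param log whether `raw_fc` is already on the log2 scale.
#' @return `M_Raw`.
#' @export
raw_strength <- function(raw_fc, log = FALSE) {
  l <- if (log) raw_fc else log2(raw_fc)
  sum(2^pmax(abs(l) - 0.5, 0) - 1)
}

#' Detect donors whose response diverges from the consensus
#'
#' Pearson correlation `r` between each donor's log2FC vector and the
#' consensus log2FC; with `top8median` the median of the 8 largest r
#' values, a donor is an outlier iff
#' `|r - top8median| > 0.35 * max(top8median, 0.6)`.
#'
#' @param donor_lfcs named list of per-donor log2FC vectors (named by
#'   gene).
#' @param consensus_lfc named consensus log2FC vector.
#' @param c1,c2 the rule constants (0.35, 0.6).
#' @param top_n size of the reference set (8).
#' @return data.frame (`donor`, `r`, `outlier`) with the reference
#'   median as attribute `"top8median"`; `NULL` when fewer than `top_n`
#'   donors have computable correlations.
#' @export
detect_outliers <- function(donor_lfcs, consensus_lfc, c1 = 0.35,
                            c2 = 0.6, top_n = 8) {
  r <- vapply(donor_lfcs, function(v) {
    g <- intersect(names(v), names(consensus_lfc))
    if (length(g) < 3) return(NA_real_)
    suppressWarnings(stats::cor(v[g], consensus_lfc[g]))
  }, 0)
  ok <- !is.na(r)
  if (sum(ok) < top_n) {
    cd_log("detect_outliers: only %d donors with computable r; skipped",
           sum(ok))
    return(NULL)
  }
  ord <- order(r, decreasing = TRUE)  # stable: ties keep donor order
  topmed <- stats::median(r[ord[seq_len(top_n)]])
  out <- data.frame(donor = names(donor_lfcs), r = unname(r),
                    outlier = ok & abs(r - topmed) > c1 * max(topmed, c2),
                    stringsAsFactors = FALSE)
  attr(out, "top8median") <- topmed
  out
}

#' Detect substantial substructure in donor responses
#'
#' Clusters donors on their pairwise response-correlation matrix with
#' Leiden (CPM partition; negative weights floored at zero, diagonal
#' zeroed) at resolutions 0.3, 0.5 and 0.7 in turn, taking the smallest
#' resolution that succeeds. A resolution succeeds when it yields one
#' community of size >= 4 and a second of size >= 2, and every pair of
#' qualifying communities separates by
#' `mean within-community r - mean between-community r >=
#' max(0.2, 0.3 * max off-diagonal r)`.
#'
#' @param r_mat symmetric donors x donors Pearson correlation matrix.
#' @param resolutions Leiden CPM resolutions tried in ascending order.
#' @param min_size1,min_size2 community size gate (4, 2).
#' @param seed RNG seed for the Leiden refinement.
#' @return list (`found`, `resolution`, `membership`, `margin`), with
#'   `found = FALSE` and NULL details when no resolution succeeds.
#' @export
detect_substructure <- function(r_mat, resolutions = c(0.3, 0.5, 0.7),
                                min_size1 = 4, min_size2 = 2, seed = 1L) {
  stopifnot(is.matrix(r_mat), nrow(r_mat) == ncol(r_mat))
  if (any(!is.finite(r_mat))) stop("non-finite correlation weights")
  off <- r_mat[row(r_mat) != col(r_mat)]
  margin_req <- max(0.2, 0.3 * max(off))
  for (res in sort(resolutions)) {
    memb <- leiden_cpm(r_mat, resolution = res, seed = seed)
    sizes <- table(memb)
    qual <- as.integer(names(sizes)[sizes >= min_size2])
    if (length(qual) < 2 || max(sizes[as.character(qual)]) < min_size1)
      next
    # margin: each qualifying community pair must separate
    pass <- TRUE; min_margin <- Inf
    for (i in seq_along(qual)) for (j in seq_along(qual)) {
      if (i >= j) next
      a <- memb == qual[i]; b <- memb == qual[j]
      sub_a <- r_mat[a, a, drop = FALSE]
      sub_b <- r_mat[b, b, drop = FALSE]
      within <- c(sub_a[row(sub_a) != col(sub_a)],
                  sub_b[row(sub_b) != col(sub_b)])
      between <- r_mat[a, b]
      marg <- mean(within) - mean(between)
      min_margin <- min(min_margin, marg)
      if (marg < margin_req) pass <- FALSE
    }
    if (pass && is.finite(min_margin))
      return(list(found = TRUE, resolution = res, membership = memb,
                  margin = min_margin))
  }
  list(found = FALSE, resolution = NULL, membership = NULL, margin = NULL)
}

#' Donor heterogeneity profile for one (cell type, cytokine)
#'
#' Convenience wrapper assembling per-donor log2FCs, magnitudes, raw
#' strengths, outlier flags and substructure for a condition.
#'
#' @param pb a [pseudobulk].
#' @param det a [de_table] result supplying consensus log2FCs.
#' @param cell_type,cytokine the condition.
#' @param seed Leiden seed.
#' @return list (`donors` data.frame, `outliers`, `substructure`).
#' @export
donor_profile <- function(pb, det, cell_type, cytokine, seed = 1L) {
  donors <- unique(pb$keys$donor)
  lfcs <- list()
  for (d in donors) {
    v <- donor_lfc(pb, d, cell_type, cytokine)
    if (!is.null(v)) lfcs[[d]] <- v
  }
  cons_rows <- det$cell_type == cell_type & det$cytokine == cytokine
  consensus <- stats::setNames(det$log2fc[cons_rows], det$gene[cons_rows])
  outl <- detect_outliers(lfcs, consensus)
  sub <- NULL
  if (length(lfcs) >= 4) {
    genes <- Reduce(intersect, lapply(lfcs, names))
    if (length(genes) >= 3) {
      m <- sapply(lfcs, function(v) v[genes])
      r_mat <- suppressWarnings(stats::cor(m))
      r_mat[!is.finite(r_mat)] <- 0
      sub <- detect_substructure(r_mat, seed = seed)
    }
  }
  prof <- data.frame(
    donor = names(lfcs),
    magnitude = vapply(names(lfcs), function(d)
      donor_magnitude(pb, d, cell_type, cytokine), 0),
    m_raw = vapply(lfcs, function(v) raw_strength(v, log = TRUE), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  list(donors = prof, outliers = outl, substructure = sub)
}
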