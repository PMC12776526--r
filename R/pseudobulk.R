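#' Aggregate cells into pseudobulk profiles
#'
#' Sums counts over groups of cells sharing (donor, cell type, condition),
#' optionally keeping the six PBS control wells apart so that each well
#' can later serve as its own differential-expression reference. Records,
#' per group, the number of contributing cells and the number of cells in
#' which each gene was detected (used by the 5%-of-cells expression
#' filter).
#'
#' @param cc a [CellCounts] object.
#' @param by key columns, default `c("donor", "cell_type", "condition")`.
#' @param split_pbs_wells keep PBS wells as separate keys (default TRUE).
#' @return An object of class `Pseudobulk`: a list with `keys`
#'   (data.frame with the key columns plus `pbs_well`, `NA` for
#'   stimulated wells), `raw` (keys x genes summed counts), `cpm`
#'   (counts-per-million of `raw`), `n_cells`, `n_expr` (keys x genes
#'   detection counts) and `genes`.
#' @export
pseudobulk <- function(cc, by = c("donor", "cell_type", "condition"),
                       split_pbs_wells = TRUE) {
  stopifnot(inherits(cc, "CellCounts"))
  miss <- setdiff(by, names(cc$meta))
  if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  meta <- cc$meta
  well <- if (split_pbs_wells && "pbs_well" %in% names(meta)) {
    ifelse(meta$condition == "PBS", meta$pbs_well, NA_integer_)
  } else rep(NA_integer_, nrow(meta))
  keydf <- cbind(meta[by], pbs_well = well)
  keystr <- do.call(paste, c(keydf, sep = "\r"))
  grp <- factor(keystr, levels = unique(keystr))
  raw <- as.matrix(rowsum_sparse(cc$counts, grp))
  n_expr <- as.matrix(rowsum_sparse(methods::as(cc$counts > 0, "dMatrix"),
                                    grp))
  n_cells <- as.integer(table(grp)[levels(grp)])
  keys <- keydf[!duplicated(keystr), , drop = FALSE]
  rownames(keys) <- NULL
  structure(list(keys = keys, raw = raw, cpm = cpm_rows(raw),
                 n_cells = n_cells, n_expr = n_expr, genes = cc$genes),
            class = "Pseudobulk")
}

# group-wise column sums of a sparse matrix, rows ordered by levels(grp)
rowsum_sparse <- function(m, grp) {
  ind <- Matrix::sparseMatrix(i = seq_along(grp), j = as.integer(grp),
                              x = 1, dims = c(length(grp), nlevels(grp)))
  Matrix::t(ind) %*% m
}

#' @export
print.Pseudobulk <- function(x, ...) {
  cat(sprintf("Pseudobulk: %d keys x %d genes\n", nrow(x$raw),
              length(x$genes)))
  invisible(x)
}

# Row indices of pb$keys matching the given labels; NULL matches anything.
# wells: NULL = any, "pooled" = all PBS wells, integer vector = those wells.
pb_rows <- function(pb, donor = NULL, cell_type = NULL, condition = NULL,
                    wells = NULL) {
  k <- pb$keys
  sel <- rep(TRUE, nrow(k))
  if (!is.null(donor)) sel <- sel & k$donor %in% donor
  if (!is.null(cell_type)) sel <- sel & k$cell_type %in% cell_type
  if (!is.null(condition)) sel <- sel & k$condition %in% condition
  if (!is.null(wells) && !identical(wells, "pooled"))
    sel <- sel & !is.na(k$pbs_well) & k$pbs_well %in% wells
  which(sel)
}

# Per-donor pooled pseudobulk for one (cell_type, condition), summing PBS
# wells in `wells` (default all). Returns list(donor, raw, n_cells, n_expr)
# with one row per donor that has any cells.
pb_by_donor <- function(pb, cell_type, condition, wells = NULL) {
  rows <- pb_rows(pb, cell_type = cell_type, condition = condition)
  if (!is.null(wells) && condition == "PBS")
    rows <- intersect(rows, pb_rows(pb, wells = wells))
  if (!length(rows))
    return(list(donor = character(0),
                raw = matrix(0, 0, length(pb$genes)),
                n_cells = integer(0),
                n_expr = matrix(0, 0, length(pb$genes))))
  d <- factor(pb$keys$donor[rows])
  raw <- rowsum(pb$raw[rows, , drop = FALSE], d)
  n_expr <- rowsum(pb$n_expr[rows, , drop = FALSE], d)
  n_cells <- as.integer(rowsum(pb$n_cells[rows], d))
  list(donor = levels(d), raw = raw, n_cells = n_cells, n_expr = n_expr)
}

#' Differential cell-type abundance vs PBS
#'
#' Tests, per (cell type, cytokine), whether the number of recovered
#' cells changes relative to the PBS controls across donors. Well totals
#' are first adjusted for plate position by an ordinary least-squares fit
#' of total cells per well on the well's distance to the plate's center
#' row; the fitted value divided by the overall mean total gives a
#' multiplicative normalization factor applied to all cell types of that
#' well. The per-donor PBS reference is the mean normalized count across
#' that donor's PBS wells. log2 fold changes use a +1 pseudocount on both
#' sides (recorded in the result's metadata); p-values come from a
#' two-sided Wilcoxon signed-rank test across donors and are adjusted by
#' Benjamini-Hochberg over all tested pairs.
#'
#' @param cc a [CellCounts] object with a `plate_row` metadata column.
#' @param lfc_thresh absolute log2FC required for significance (0.5).
#' @param alpha adjusted-p threshold for significance (0.05).
#' @param min_donors minimum paired donors for a testable pair (3).
#' @return data.frame of class `AbundanceResult` with one row per
#'   (cell type, cytokine): `log2fc`, `p`, `padj`, `n_donors`,
#'   `significant`, `testable`.
#' @export
abundance_test <- function(cc, lfc_thresh = 0.5, alpha = 0.05,
                           min_donors = 3) {
  stopifnot(inherits(cc, "CellCounts"))
  if (!"plate_row" %in% names(cc$meta))
    stop("missing column: plate_row")
  meta <- cc$meta
  wellid <- paste(meta$donor, meta$condition,
                  ifelse(meta$condition == "PBS", meta$pbs_well, 0),
                  sep = "\r")
  wtab <- unique(data.frame(well = wellid, donor = meta$donor,
                            condition = meta$condition,
                            plate_row = meta$plate_row,
                            stringsAsFactors = FALSE))
  totals <- table(wellid)[wtab$well]
  center <- (min(wtab$plate_row) + max(wtab$plate_row)) / 2
  dist <- abs(wtab$plate_row - center)
  tot <- as.numeric(totals)
  fac <- if (length(unique(dist)) > 1) {
    fit <- stats::lm(tot ~ dist)
    stats::fitted(fit) / mean(tot)
  } else rep(1, length(tot))  # all wells equidistant: identity
  names(fac) <- wtab$well
  # normalized per-(well, cell type) counts
  ctab <- table(wellid, meta$cell_type)
  norm <- sweep(as.matrix(ctab), 1, fac[rownames(ctab)], "/")
  wmeta <- wtab[match(rownames(norm), wtab$well), ]
  cytokines <- setdiff(unique(meta$condition), "PBS")
  cell_types <- colnames(norm)
  is_pbs <- wmeta$condition == "PBS"
  res <- list()
  for (ct in cell_types) {
    pbs_by_donor <- tapply(norm[is_pbs, ct], wmeta$donor[is_pbs], mean)
    for (cy in cytokines) {
      sel <- wmeta$condition == cy
      cyt_by_donor <- tapply(norm[sel, ct], wmeta$donor[sel], mean)
      donors <- intersect(names(pbs_by_donor), names(cyt_by_donor))
      donors <- donors[!is.na(pbs_by_donor[donors]) &
                       !is.na(cyt_by_donor[donors])]
      n <- length(donors)
      if (n < min_donors) {
        res[[length(res) + 1L]] <- data.frame(
          cell_type = ct, cytokine = cy, log2fc = NA_real_, p = NA_real_,
          n_donors = n, testable = FALSE, stringsAsFactors = FALSE)
        next
      }
      a <- cyt_by_donor[donors]; b <- pbs_by_donor[donors]
      lfc <- mean(log2((a + 1) / (b + 1)))
      p <- suppressWarnings(
        stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
      if (is.na(p)) p <- 1  # all-zero differences
      res[[length(res) + 1L]] <- data.frame(
        cell_type = ct, cytokine = cy, log2fc = lfc, p = p, n_donors = n,
        testable = TRUE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$padj <- NA_real_
  out$padj[out$testable] <- stats::p.adjust(out$p[out$testable], "BH")
  out$significant <- out$testable & !is.na(out$padj) &
    out$padj < alpha & abs(out$log2fc) > lfc_thresh
  attr(out, "pseudocount") <- 1
  class(out) <- c("AbundanceResult", "data.frame")
  out
}
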