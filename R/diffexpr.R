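#' Consensus differential expression for one (cell type, cytokine)
#'
#' Default backend: a donor-adjusted linear model on log2(cpm + 1) of the
#' per-donor pseudobulks, with donor indicator covariates and a condition
#' coefficient. With one PBS and one stimulated pseudobulk per donor this
#' model's condition coefficient and t-statistic are exactly those of the
#' paired t-test on per-donor log2(cpm + 1) differences, which is how it
#' is computed (vectorised over genes). Donors contribute only if both
#' their PBS and cytokine pseudobulks contain at least `min_cells` cells;
#' genes are tested only if detected in at least `min_frac` of the
#' retained cells of either condition. p-values are BH-adjusted within
#' the (cell type, cytokine) test set.
#'
#' @param pb a [pseudobulk] built with `split_pbs_wells = TRUE`.
#' @param cell_type,cytokine the contrast to test (vs `"PBS"`).
#' @param wells `"pooled"` (all PBS wells summed, the consensus run) or
#'   an integer vector of PBS wells to use as the reference.
#' @param min_cells per-donor cell filter (10).
#' @param min_frac detection fraction filter (0.05).
#' @return data.frame (`gene`, `log2fc`, `p`, `padj`, `n_donors`), or
#'   `NULL` when fewer than two donors qualify.
#' @export
de_consensus <- function(pb, cell_type, cytokine, wells = "pooled",
                         min_cells = 10, min_frac = 0.05) {
  stopifnot(inherits(pb, "Pseudobulk"))
  pbs <- pb_by_donor(pb, cell_type, "PBS",
                     wells = if (identical(wells, "pooled")) NULL else wells)
  cyt <- pb_by_donor(pb, cell_type, cytokine)
  ok_p <- pbs$donor[pbs$n_cells >= min_cells]
  ok_c <- cyt$donor[cyt$n_cells >= min_cells]
  donors <- intersect(ok_p, ok_c)
  if (length(donors) < 2) {
    cd_log("de_consensus: %s/%s skipped (<2 qualifying donors)",
           cell_type, cytokine)
    return(NULL)
  }
  ip <- match(donors, pbs$donor); ic <- match(donors, cyt$donor)
  raw_p <- pbs$raw[ip, , drop = FALSE]
  raw_c <- cyt$raw[ic, , drop = FALSE]
  frac_p <- colSums(pbs$n_expr[ip, , drop = FALSE]) / sum(pbs$n_cells[ip])
  frac_c <- colSums(cyt$n_expr[ic, , drop = FALSE]) / sum(cyt$n_cells[ic])
  keep <- frac_p >= min_frac | frac_c >= min_frac
  if (!any(keep)) stop("no genes pass the expression filter")
  diffs <- log2(cpm_rows(raw_c)[, keep, drop = FALSE] + 1) -
           log2(cpm_rows(raw_p)[, keep, drop = FALSE] + 1)
  D <- length(donors)
  lfc <- colMeans(diffs)
  sdv <- apply(diffs, 2, stats::sd)
  tstat <- ifelse(sdv > 0, lfc / (sdv / sqrt(D)), ifelse(lfc == 0, 0, Inf))
  p <- 2 * stats::pt(-abs(tstat), df = D - 1)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(gene = pb$genes[keep], log2fc = lfc, p = p,
             padj = stats::p.adjust(p, "BH"), n_donors = D,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Validate and ingest an externally computed DE table
#'
#' Adapter for DE results produced by an external NB-GLM route (e.g.
#' edgeR via pseudobulk). The table must carry the canonical schema and
#' is passed through downstream exactly like the internal backend's
#' output.
#'
#' @param df data.frame with columns `cell_type`, `cytokine`, `gene`,
#'   `log2fc`, `p`, `padj`.
#' @return The validated table.
#' @export
de_external <- function(df) {
  req <- c("cell_type", "cytokine", "gene", "log2fc", "p", "padj")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("external DE table missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(df$padj < df$p, na.rm = TRUE))
    stop("external DE table has padj < p")
  df[req]
}

#' Per-PBS-well support for one (cell type, cytokine)
#'
#' Re-runs the consensus DE six times, each time with a single distinct
#' PBS well as the reference. A gene is counted as supported in a well
#' when that run gives adjusted p < 0.1 and |log2FC| > 0.25. Biologically
#' driven responses are expected to be supported across wells, plate
#' artifacts are not.
#'
#' @inheritParams de_consensus
#' @param well_padj,well_lfc the well-level DE rule (0.1, 0.25).
#' @param n_wells number of PBS wells on the plate (6).
#' @return list with `wells_supported` (named int per gene),
#'   `well_lfc` (genes x wells matrix), `n_wells_available`.
#' @export
per_well_support <- function(pb, cell_type, cytokine, well_padj = 0.1,
                             well_lfc = 0.25, n_wells = 6,
                             min_cells = 10, min_frac = 0.05) {
  genes <- pb$genes
  lfcmat <- matrix(NA_real_, length(genes), n_wells,
                   dimnames = list(genes, paste0("w", seq_len(n_wells))))
  support <- matrix(FALSE, length(genes), n_wells,
                    dimnames = dimnames(lfcmat))
  avail <- logical(n_wells)
  for (w in seq_len(n_wells)) {
    res <- tryCatch(de_consensus(pb, cell_type, cytokine, wells = w,
                                 min_cells = min_cells,
                                 min_frac = min_frac),
                    error = function(e) NULL)
    if (is.null(res)) next
    avail[w] <- TRUE
    idx <- match(res$gene, genes)
    lfcmat[idx, w] <- res$log2fc
    support[idx, w] <- res$padj < well_padj & abs(res$log2fc) > well_lfc
  }
  if (!all(avail))
    cd_log("per_well_support: %s/%s has %d/%d wells available",
           cell_type, cytokine, sum(avail), n_wells)
  list(wells_supported = rowSums(support[, avail, drop = FALSE]),
       well_lfc = lfcmat, n_wells_available = sum(avail))
}

#' Build the full differential-expression table
#'
#' Runs the consensus DE and the per-well support analysis for every
#' (cell type, cytokine) pair, applies the mean-to-stddev ratio filter,
#' and calls DEGs.
#'
#' @param pb a [pseudobulk] with wells split.
#' @param cell_types,cytokines subsets to analyse (default: all).
#' @param external optional [de_external] table replacing the internal
#'   consensus backend (per-well support is still computed internally).
#' @param ... passed to [de_consensus] / [per_well_support].
#' @return data.frame of class `DETable` with one row per
#'   (cell_type, cytokine, gene): `log2fc`, `p`, `padj`,
#'   `wells_supported`, `n_wells_available`, per-well log2FCs
#'   `lfc_w1..lfc_w6`, `ratio`, `high_ratio`, `removed_by_ratio`,
#'   `is_deg`, `direction`.
#' @export
de_table <- function(pb, cell_types = NULL, cytokines = NULL,
                     external = NULL, ...) {
  stopifnot(inherits(pb, "Pseudobulk"))
  cell_types <- cell_types %||% unique(pb$keys$cell_type)
  cytokines <- cytokines %||% setdiff(unique(pb$keys$condition), "PBS")
  rows <- list()
  for (ct in cell_types) for (cy in cytokines) {
    cons <- if (is.null(external)) {
      de_consensus(pb, ct, cy, ...)
    } else {
      ex <- external[external$cell_type == ct & external$cytokine == cy, ]
      if (nrow(ex)) ex[c("gene", "log2fc", "p", "padj")] else NULL
    }
    if (is.null(cons) || !nrow(cons)) next
    pws <- per_well_support(pb, ct, cy, ...)
    idx <- match(cons$gene, rownames(pws$well_lfc))
    wl <- pws$well_lfc[idx, , drop = FALSE]
    colnames(wl) <- paste0("lfc_", colnames(wl))
    rows[[length(rows) + 1L]] <- data.frame(
      cell_type = ct, cytokine = cy, cons,
      wells_supported = unname(pws$wells_supported[idx]),
      n_wells_available = pws$n_wells_available,
      wl, stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(rows)) stop("no testable (cell type, cytokine) pairs")
  det <- do.call(rbind, rows)
  det <- ratio_filter(det)
  det <- call_degs(det)
  class(det) <- c("DETable", "data.frame")
  det
}

#' Mean-to-stddev ratio filter on per-well log2 fold changes
#'
#' For each (gene, cell type, cytokine) the ratio
#' `sd(per-well log2FC) / (|mean(per-well log2FC)| + 0.25)` (sample sd,
#' n-1 denominator) flags genes whose apparent effect is unstable across
#' the six PBS references. Ratio > `ratio_thresh` marks the gene high in
#' that condition; high in at least `min_cytokines` cytokines of a cell
#' type marks it high in the cell type; high in at least `min_celltypes`
#' cell types removes it from all DEG sets.
#'
#' @param det a DETable-shaped data.frame with `lfc_w*` columns.
#' @param ratio_thresh ratio cutoff (1).
#' @param min_cytokines escalation count within a cell type (10).
#' @param min_celltypes escalation count across cell types (5).
#' @return `det` with `ratio`, `high_ratio`, `removed_by_ratio` columns.
#' @export
ratio_filter <- function(det, ratio_thresh = 1, min_cytokines = 10,
                         min_celltypes = 5) {
  wl <- as.matrix(det[grep("^lfc_w", names(det))])
  mu <- rowMeans(wl, na.rm = TRUE)
  n <- rowSums(!is.na(wl))
  sdv <- sqrt(rowSums((wl - mu)^2, na.rm = TRUE) / pmax(n - 1, 1))
  sdv[n < 2] <- 0
  det$ratio <- ifelse(is.finite(mu), sdv / (abs(mu) + 0.25), 0)
  det$high_ratio <- det$ratio > ratio_thresh
  hi <- det[det$high_ratio, c("gene", "cell_type", "cytokine")]
  removed_genes <- character(0)
  if (nrow(hi)) {
    per_ct <- stats::aggregate(cytokine ~ gene + cell_type, hi,
                               function(x) length(unique(x)))
    hi_ct <- per_ct[per_ct$cytokine >= min_cytokines, ]
    if (nrow(hi_ct)) {
      per_gene <- table(hi_ct$gene)
      removed_genes <- names(per_gene)[per_gene >= min_celltypes]
    }
  }
  det$removed_by_ratio <- det$gene %in% removed_genes
  det
}

#' Call differentially expressed genes
#'
#' The dictionary's DEG rule: adjusted p < `padj_thresh`,
#' |log2FC| > `lfc_thresh`, supported against at least `min_wells` of 6
#' PBS wells, and not removed by the ratio filter. When fewer than six
#' wells were available the well requirement scales proportionally
#' (`ceiling(min_wells / 6 * available)`).
#'
#' @param det a DETable-shaped data.frame.
#' @param padj_thresh,lfc_thresh,min_wells the DEG rule (0.05, 0.25, 4).
#' @return `det` with `is_deg` and `direction` (`"up"`, `"down"`,
#'   `"none"`) columns.
#' @export
call_degs <- function(det, padj_thresh = 0.05, lfc_thresh = 0.25,
                      min_wells = 4) {
  need <- ifelse(det$n_wells_available >= 6, min_wells,
                 ceiling(min_wells / 6 * det$n_wells_available))
  removed <- if ("removed_by_ratio" %in% names(det)) det$removed_by_ratio
             else FALSE
  det$is_deg <- det$padj < padj_thresh & abs(det$log2fc) > lfc_thresh &
    det$wells_supported >= need & !removed
  det$direction <- ifelse(!det$is_deg, "none",
                          ifelse(det$log2fc > 0, "up", "down"))
  det
}

#' Extract signed DEG sets from a DE table
#'
#' @param det a [de_table] result.
#' @return data.frame (`cell_type`, `cytokine`, `gene`, `direction`,
#'   `log2fc`) restricted to DEGs.
#' @export
deg_sets <- function(det) {
  det[det$is_deg, c("cell_type", "cytokine", "gene", "direction", "log2fc")]
}
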