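#' Euclidean component of the response magnitude
#'
#' Euclidean distance between the log2(cpm + 1) pseudobulk expression of
#' the cytokine condition and the PBS control in one cell type, over
#' genes with a total average pseudobulk count of at least
#' `min_avg_count` in at least one of the cell type's stimulation
#' conditions.
#'
#' @param pb a [pseudobulk].
#' @param cell_type,cytokine the condition.
#' @param min_avg_count gene-subset threshold (20).
#' @return Raw `M_euclid`, or `NA` when no genes qualify.
#' @export
magnitude_euclid <- function(pb, cell_type, cytokine, min_avg_count = 20) {
  keep <- magnitude_gene_set(pb, cell_type, min_avg_count)
  if (!any(keep)) {
    cd_log("magnitude_euclid: empty gene set for %s", cell_type)
    return(NA_real_)
  }
  v_p <- pooled_cpm(pb, cell_type, "PBS")
  v_c <- pooled_cpm(pb, cell_type, cytokine)
  if (is.null(v_p) || is.null(v_c)) return(NA_real_)
  sqrt(sum((log2(v_c[keep] + 1) - log2(v_p[keep] + 1))^2))
}

# genes with mean per-donor pseudobulk count >= min_avg_count in at
# least one condition of the cell type
magnitude_gene_set <- function(pb, cell_type, min_avg_count = 20) {
  conds <- unique(pb$keys$condition[pb$keys$cell_type == cell_type])
  keep <- rep(FALSE, length(pb$genes))
  for (cond in conds) {
    bd <- pb_by_donor(pb, cell_type, cond)
    if (!length(bd$donor)) next
    keep <- keep | colMeans(bd$raw) >= min_avg_count
  }
  keep
}

# condition-level cpm: per-gene counts summed over all donors (and PBS
# wells), then scaled to counts-per-million
pooled_cpm <- function(pb, cell_type, condition) {
  rows <- pb_rows(pb, cell_type = cell_type, condition = condition)
  if (!length(rows)) return(NULL)
  tot <- colSums(pb$raw[rows, , drop = FALSE])
  s <- sum(tot)
  if (s == 0) return(NULL)
  stats::setNames(tot / s * 1e6, pb$genes)
}

#' Significance-weighted component of the response magnitude
#'
#' `M_pw = sum_i |log2FC_i| * (-log10 max(padj_i, 1e-10))` over the
#' condition's DE results; adjusted p-values are clipped at 1e-10.
#'
#' @param det a [de_table] result (or any frame with `cell_type`,
#'   `cytokine`, `log2fc`, `padj`).
#' @param cell_type,cytokine the condition.
#' @param padj_clip significance clip (1e-10).
#' @return Raw `M_pw` (0 when no DE rows exist for the condition).
#' @export
magnitude_pw <- function(det, cell_type, cytokine, padj_clip = 1e-10) {
  d <- det[det$cell_type == cell_type & det$cytokine == cytokine, ]
  if (!nrow(d)) return(0)
  sum(abs(d$log2fc) * -log10(pmax(d$padj, padj_clip)))
}

#' Winsorize and normalize raw magnitude components
#'
#' Each raw component vector (over the cytokines of one cell type) is
#' clipped at its 95th percentile (upper tail only, linear-interpolation
#' quantile) and divided by its post-clip maximum, mapping it into
#' [0, 1]; the overall magnitude M is the mean of the two normalized
#' components.
#'
#' @param m_euclid,m_pw raw component vectors (same cytokine order).
#' @param probs winsorization percentile (0.95).
#' @return list with `m_euclid`, `m_pw` (normalized) and `M`.
#' @export
normalize_magnitudes <- function(m_euclid, m_pw, probs = 0.95) {
  ne <- winsor_norm(m_euclid, probs)
  np <- winsor_norm(m_pw, probs)
  list(m_euclid = ne, m_pw = np, M = (ne + np) / 2)
}

winsor_norm <- function(x, probs = 0.95) {
  ok <- is.finite(x)
  if (!any(ok) || all(x[ok] == 0)) {
    if (any(ok)) warning("all-zero magnitude component")
    return(ifelse(ok, 0, NA_real_))
  }
  cap <- stats::quantile(x[ok], probs, names = FALSE)  # type 7
  y <- pmin(x, cap)
  y / max(y[ok])
}

#' Strong-impact threshold for one cell type
#'
#' `T` is three times the mean of the normalized magnitudes lying below
#' the 35th percentile of the cell type's distribution — an empirical
#' floor capturing the no-effect part of the distribution without
#' assuming its shape. A cytokine has strong impact iff `M > T`.
#'
#' @param M normalized magnitude vector over cytokines.
#' @param probs percentile defining the low tail (0.35).
#' @return list with `T` and logical `strong` flags.
#' @export
strong_impact_threshold <- function(M, probs = 0.35) {
  ok <- is.finite(M)
  if (sum(ok) < 3) stop("need at least 3 cytokines to set a threshold")
  p35 <- stats::quantile(M[ok], probs, names = FALSE)
  low <- M[ok][M[ok] < p35]
  if (!length(low)) {  # ties collapse the strict sub-percentile set
    low <- M[ok][M[ok] <= p35]
    cd_log("strong_impact_threshold: fell back to values <= P%g",
           100 * probs)
  }
  T <- 3 * mean(low)
  list(T = T, strong = ifelse(ok, M > T, NA))
}

#' Tissue-specificity index of a cytokine response
#'
#' `tsi = sum_i (1 - max(M_i - T_i/2, 0.05) / max(M_max - T*/2, 0.05))
#' / (N - 1)` over the N cell types, where `T*` is the threshold of the
#' cell type attaining the maximal magnitude; subtracting half the
#' strong-impact threshold suppresses noise, and the 0.05 floor keeps
#' ratios defined. 0 means a uniform response across cell types, values
#' near 1 a single-cell-type response. Undefined (NA) when no cell type
#' shows a strong response.
#'
#' @param M normalized magnitudes over cell types for one cytokine.
#' @param T strong-impact thresholds per cell type (recycled).
#' @param floor noise floor (0.05).
#' @return `tsi` in [0, 1), or `NA`.
#' @export
tsi <- function(M, T, floor = 0.05) {
  T <- rep_len(T, length(M))
  ok <- is.finite(M)
  if (sum(ok) < 2) return(NA_real_)
  M <- M[ok]; T <- T[ok]
  if (!any(M > T)) return(NA_real_)  # no strong cell type
  imax <- which.max(M)
  denom <- max(M[imax] - T[imax] / 2, floor)
  terms <- 1 - pmax(M - T / 2, floor) / denom
  sum(terms) / (length(M) - 1)
}

#' Full magnitude table for a screen
#'
#' Computes both raw components for every (cell type, cytokine),
#' normalizes within cell type, derives the strong-impact threshold and
#' flags, and the per-cytokine tissue-specificity index.
#'
#' @param pb a [pseudobulk].
#' @param det a [de_table] result.
#' @param cell_types,cytokines subsets (default: all in `det`).
#' @return list of class `MagnitudeTable`: `table` (data.frame per
#'   (cell_type, cytokine) with raw/normalized components, `M`,
#'   `threshold`, `strong_impact`) and `tsi` (named per-cytokine vector).
#' @export
magnitude_table <- function(pb, det, cell_types = NULL, cytokines = NULL) {
  cell_types <- cell_types %||% unique(det$cell_type)
  cytokines <- cytokines %||% unique(det$cytokine)
  rows <- list()
  for (ct in cell_types) {
    me <- vapply(cytokines, function(cy)
      magnitude_euclid(pb, ct, cy), 0)
    mp <- vapply(cytokines, function(cy)
      magnitude_pw(det, ct, cy), 0)
    nm <- normalize_magnitudes(me, mp)
    th <- strong_impact_threshold(nm$M)
    rows[[ct]] <- data.frame(
      cell_type = ct, cytokine = cytokines, m_euclid_raw = me,
      m_pw_raw = mp, m_euclid = nm$m_euclid, m_pw = nm$m_pw, M = nm$M,
      threshold = th$T, strong_impact = th$strong,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tsi_v <- vapply(cytokines, function(cy) {
    d <- tab[tab$cytokine == cy, ]
    tsi(d$M, d$threshold)
  }, 0)
  structure(list(table = tab, tsi = tsi_v), class = "MagnitudeTable")
}

#' @export
print.MagnitudeTable <- function(x, ...) {
  cat(sprintf("MagnitudeTable: %d cell types x %d cytokines; %d strong\n",
              length(unique(x$table$cell_type)),
              length(unique(x$table$cytokine)),
              sum(x$table$strong_impact, na.rm = TRUE)))
  invisible(x)
}
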